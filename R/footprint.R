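#' Information footprint of a mutant library
#'
#' The per-position mutual information (bits) between base state and binned
#' expression across a variant library. By default the base variable is
#' coarse-grained to wild-type vs mutated and expression is split into two
#' bins at the mean count (counts exactly equal to the mean fall in the high
#' bin); with `n_bins > 2` expression is cut into equal-count (quantile)
#' bins, and `coarse_base = FALSE` keeps the four base identities. Joint
#' distributions are plug-in empirical frequencies; `0 * log(0)` terms
#' contribute 0. Positions where the library carries no mutation have
#' undefined association and are reported as 0 with `no_variation = TRUE`.
#'
#' Each position also carries the expression shift
#' `ds_l = (1/n) * sum_i xi_il * (c_i - mean(c))` (the mask-weighted mean
#' deviation from the mean count): positive values mark repressor-like sites
#' (mutations raise expression), negative values polymerase/activator-like
#' sites.
#'
#' @param library A [mutant_library()].
#' @param counts An expression table (tibble with a count column aligned to
#'   the library) or a bare numeric vector.
#' @param n_bins Number of expression bins (default 2, mean-threshold).
#' @param coarse_base Coarse-grain bases to wild-type/mutant (default TRUE).
#' @param count_col Which column of `counts` to use (default `"count"`; use
#'   `"sampled"` after [resample_counts()]).
#' @return An `mpra_footprint`: tibble with columns `position` (display
#'   coordinate), `mi` (bits), `shift`, `sign` ("repressor-like",
#'   "activator-like" or "none") and `no_variation`.
#' @export
#' @examples
#' fix <- minimal_promoter_library()
#' information_footprint(fix$library, fix$counts)
information_footprint <- function(library, counts, n_bins = 2L,
                                  coarse_base = TRUE, count_col = "count") {
  stopifnot(inherits(library, "mutant_library"))
  c_i <- resolve_counts(library, counts, count_col)
  if (nrow(library) < 2L) abort("Need at least 2 variants to estimate a footprint.")
  mu <- bin_expression(c_i, n_bins)
  bm <- seq_to_matrix(library$sequence)
  mask <- library_mask(library)
  wt <- library_wild_type(library)
  L <- ncol(bm)
  mi <- numeric(L)
  flagged <- logical(L)
  for (l in seq_len(L)) {
    b <- if (coarse_base) 1L - mask[, l] else match(bm[, l], DNA_BASES)
    if (all(mask[, l] == 0L)) {
      flagged[l] <- TRUE
      next
    }
    mi[l] <- mutual_information_bits(b, mu)
  }
  shift <- expression_shift_values(mask, c_i)
  out <- tibble::tibble(
    position = promoter_positions(wt),
    mi = mi,
    shift = shift,
    sign = dplyr::case_when(shift > 0 ~ "repressor-like",
                            shift < 0 ~ "activator-like",
                            TRUE ~ "none"),
    no_variation = flagged
  )
  structure(out, class = c("mpra_footprint", class(out)),
            n_bins = as.integer(n_bins), coarse_base = coarse_base)
}

resolve_counts <- function(library, counts, count_col = "count") {
  if (is.data.frame(counts)) {
    if (!count_col %in% colnames(counts)) {
      abort(sprintf("`counts` has no '%s' column.", count_col))
    }
    if (nrow(counts) != nrow(library)) {
      abort("`counts` is not aligned to the library (row counts differ).")
    }
    counts <- counts[[count_col]]
  }
  if (!is.numeric(counts) || length(counts) != nrow(library)) {
    abort("`counts` must supply one numeric count per variant.")
  }
  counts
}

# expression binning: mean threshold for 2 bins (ties to the high bin),
# equal-count quantile bins otherwise
bin_expression <- function(c_i, n_bins) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) abort("`n_bins` must be >= 2.")
  if (n_bins == 2L) {
    as.integer(c_i >= mean(c_i))
  } else {
    br <- unique(quantile(c_i, probs = seq(0, 1, length.out = n_bins + 1L)))
    as.integer(cut(c_i, breaks = br, include.lowest = TRUE))
  }
}

# plug-in MI in bits between two discrete vectors
mutual_information_bits <- function(x, y) {
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  terms <- joint * log2(joint / outer(px, py))
  sum(terms[joint > 0])
}

expression_shift_values <- function(mask, c_i) {
  as.numeric(crossprod(mask, c_i - mean(c_i))) / length(c_i)
}

#' Per-position expression shift
#'
#' `ds_l = (1/n) * sum_i xi_il * (c_i - <c>)`, the mask-weighted mean
#' deviation of counts from their mean at each promoter position. Positive
#' values indicate repressor-like sites, negative values
#' polymerase/activator-like sites.
#'
#' @inheritParams information_footprint
#' @return Tibble with columns `position` and `shift`.
#' @export
expression_shift <- function(library, counts, count_col = "count") {
  stopifnot(inherits(library, "mutant_library"))
  c_i <- resolve_counts(library, counts, count_col)
  tibble::tibble(position = promoter_positions(library_wild_type(library)),
                 shift = expression_shift_values(library_mask(library), c_i))
}

#' Expression-shift matrix
#'
#' Base-resolved relative expression shifts
#' `ds_bl = (1/n) * sum_i xi_bil * (c_i/<c> - 1)` for every mutant base b at
#' every position l; entries at the wild-type base are exactly 0, as are
#' bases never observed at a position.
#'
#' @inheritParams information_footprint
#' @return An `mpra_shift_matrix`: long tibble with columns `position`,
#'   `base`, `shift` and `wild_type` (logical).
#' @export
expression_shift_matrix <- function(library, counts, count_col = "count") {
  stopifnot(inherits(library, "mutant_library"))
  c_i <- resolve_counts(library, counts, count_col)
  bm <- seq_to_matrix(library$sequence)
  wt <- library_wild_type(library)
  wt_bases <- strsplit(wt$bases, "")[[1]]
  rel <- c_i / mean(c_i) - 1
  n <- length(c_i)
  per_base <- lapply(DNA_BASES, function(b) {
    ind <- (bm == b) * 1L
    # zero out wild-type entries: xi counts only mutations to b
    ind[, wt_bases == b] <- 0L
    as.numeric(crossprod(ind, rel)) / n
  })
  out <- tibble::tibble(
    position = rep(promoter_positions(wt), times = 4L),
    base = rep(DNA_BASES, each = ncol(bm)),
    shift = unlist(per_base)
  )
  out$wild_type <- out$base == rep(wt_bases, times = 4L)
  out$shift[out$wild_type] <- 0
  structure(out, class = c("mpra_shift_matrix", class(out)))
}

#' Average mutual information over a binding site
#'
#' Arithmetic mean of the footprint's per-position mutual information over a
#' set of site positions — the signal statistic S.
#'
#' @param footprint An [information_footprint()] result.
#' @param positions Display coordinates of the site (e.g.
#'   [site_positions()]).
#' @return Mean mutual information in bits.
#' @export
avg_site_information <- function(footprint, positions) {
  if (length(positions) == 0L) abort("Empty site: no positions supplied.")
  hit <- footprint$position %in% positions
  if (!any(hit)) abort("No footprint positions match the site.")
  mean(footprint$mi[hit])
}

#' Footprint signal-to-noise ratio
#'
#' Ratio of the mean per-position mutual information inside declared binding
#' sites to the mean outside them. A zero off-site mean (the noiseless
#' limit) is reported as `Inf` with `infinite = TRUE` rather than failing.
#'
#' @param footprint An [information_footprint()] result.
#' @param site_positions Display coordinates of all binding sites (vector or
#'   list of vectors).
#' @return One-row tibble with `snr`, `mean_site`, `mean_background`,
#'   `infinite`.
#' @export
snr <- function(footprint, site_positions) {
  pos <- unique(unlist(site_positions))
  inside <- footprint$position %in% pos
  if (!any(inside)) abort("No footprint positions match the sites.")
  if (all(inside)) abort("No non-binding positions exist; SNR is undefined.")
  ms <- mean(footprint$mi[inside])
  mb <- mean(footprint$mi[!inside])
  tibble::tibble(snr = if (mb == 0) Inf else ms / mb,
                 mean_site = ms, mean_background = mb, infinite = mb == 0)
}

#' The two-bp minimal-promoter fixture
#'
#' The analytic hitch-hiking example: a constitutive promoter two base pairs
#' long over a binary alphabet (strong base X = A, weak base Y = T) whose
#' second position is the specific polymerase site. The full library holds
#' all four sequences (XX and YX expressed high, XY and YY low); the reduced
#' library holds only XX (high) and YY (low), which makes the non-binding
#' first position carry exactly as much mutual information as the true site.
#'
#' @param reduced If `TRUE`, return the two-sequence reduced library.
#' @param high,low Expression counts of the high/low states.
#' @return List with `library` (a [mutant_library()], wild type "AA",
#'   `tss_index = 0`) and `counts` (expression table).
#' @export
minimal_promoter_library <- function(reduced = FALSE, high = 100, low = 0) {
  wt <- promoter("AA", tss_index = 0L)
  if (reduced) {
    seqs <- c("AA", "TT"); counts <- c(high, low)
  } else {
    seqs <- c("AA", "TA", "AT", "TT"); counts <- c(high, high, low, low)
  }
  lib <- mutant_library(seqs, wt)
  list(library = lib,
       counts = tibble::tibble(variant = lib$variant, sequence = lib$sequence,
                               count = counts))
}
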