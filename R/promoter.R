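#' Create a promoter sequence
#'
#' A promoter is a single-stranded DNA sequence together with the index of its
#' transcription start site (TSS). Positions are reported throughout the
#' package in TSS-relative "display" coordinates: the base at string index
#' `tss_index + 1` (1-based) is display position 0, so a 160-bp promoter with
#' `tss_index = 115` spans display positions −115..+44.
#'
#' @param bases Character scalar over the alphabet A/C/G/T.
#' @param tss_index Integer, 0-based offset of the transcription start site
#'   within the string (`0 <= tss_index < nchar(bases)`). Default 115.
#' @return An object of class `promoter`.
#' @export
#' @examples
#' p <- promoter("ACGTACGTAC", tss_index = 5)
#' promoter_positions(p)
promoter <- function(bases, tss_index = 115L) {
  if (!is.character(bases) || length(bases) != 1L || nchar(bases) < 1L) {
    abort("`bases` must be a single non-empty string.")
  }
  bases <- toupper(bases)
  check_alphabet(strsplit(bases, "")[[1]])
  tss_index <- as.integer(tss_index)
  if (tss_index < 0L || tss_index >= nchar(bases)) {
    abort("`tss_index` must satisfy 0 <= tss_index < nchar(bases).")
  }
  structure(list(bases = bases, tss_index = tss_index), class = "promoter")
}

#' @export
print.promoter <- function(x, ...) {
  cat(sprintf("<promoter> %d bp, TSS at index %d (display %d..%+d)\n",
              nchar(x$bases), x$tss_index, -x$tss_index,
              nchar(x$bases) - x$tss_index - 1L))
  cat(x$bases, "\n")
  invisible(x)
}

#' @export
length.promoter <- function(x) nchar(x$bases)

#' Display coordinates covered by a promoter
#' @param x A [promoter()].
#' @return Integer vector of display positions, one per base.
#' @export
promoter_positions <- function(x) {
  seq.int(-x$tss_index, length.out = nchar(x$bases))
}

# display coordinate -> 1-based string index
display_to_index <- function(pos, tss_index) {
  as.integer(pos + tss_index + 1L)
}

#' Generate a random promoter sequence
#'
#' Bases are drawn i.i.d. uniformly over A/C/G/T.
#'
#' @param length Promoter length in bp (default 160).
#' @param tss_index 0-based TSS index (default 115, display span −115..+44).
#' @param seed Integer seed.
#' @return A [promoter()].
#' @export
random_promoter <- function(length = 160L, tss_index = 115L, seed = 1L) {
  bases <- withr::with_seed(seed, sample(DNA_BASES, length, replace = TRUE))
  promoter(paste0(bases, collapse = ""), tss_index = tss_index)
}

#' The package's default wild-type promoter
#'
#' A fixed 160-bp sequence (display −115..+44) with canonical sigma-70
#' elements planted on an otherwise random background: the −35 hexamer
#' TTGACA at display −36..−31, the −10 hexamer TATAAT at −12..−7, and the
#' 20-bp LacI O1 operator sequence at +1..+20. The random background is
#' generated from an internal fixed seed so the sequence is a package
#' constant.
#'
#' @return A [promoter()].
#' @export
default_promoter <- function() {
  p <- random_promoter(160L, 115L, seed = 2024L)
  p <- insert_motif(p, "TTGACA", at = -36L)
  p <- insert_motif(p, "TATAAT", at = -12L)
  p <- insert_motif(p, "AATTGTGAGCGGATAACAAT", at = 1L)
  p
}

#' Substitute a motif into a promoter
#'
#' Replaces the bases starting at display position `at` with `motif`
#' (substitution in place, not insertion with shift); promoter length is
#' unchanged.
#'
#' @param x A [promoter()].
#' @param motif Character scalar over A/C/G/T.
#' @param at Display (TSS-relative) coordinate of the motif's first base.
#' @return A [promoter()].
#' @export
#' @examples
#' insert_motif(default_promoter(), "TAGAAT", at = -80)
insert_motif <- function(x, motif, at) {
  stopifnot(inherits(x, "promoter"))
  motif <- toupper(motif)
  check_alphabet(strsplit(motif, "")[[1]])
  i <- display_to_index(at, x$tss_index)
  j <- i + nchar(motif) - 1L
  if (i < 1L || j > nchar(x$bases)) {
    abort(sprintf("Motif at display position %d (length %d) falls outside the promoter.",
                  at, nchar(motif)))
  }
  bases <- x$bases
  substr(bases, i, j) <- motif
  promoter(bases, x$tss_index)
}

#' Read back a window of a promoter by display coordinates
#' @param x A [promoter()].
#' @param at Display coordinate of the first base.
#' @param width Window width in bp.
#' @return Character scalar.
#' @export
promoter_window <- function(x, at, width) {
  i <- display_to_index(at, x$tss_index)
  j <- i + width - 1L
  if (i < 1L || j > nchar(x$bases)) abort("Window falls outside the promoter.")
  substr(x$bases, i, j)
}
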