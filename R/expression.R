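#' Extrinsic-noise specification
#'
#' Per-factor cell-to-cell variability of copy numbers, modeled as
#' independent log-normal draws with a requested mean `m` and coefficient of
#' variation `v` (parameterization `sigma^2 = log(1 + v^2)`, `location =
#' log(m) - sigma^2/2`, so the arithmetic mean is exactly `m`). Defaults
#' follow the reference simulations: mean 5000 polymerases and 100
#' repressors.
#'
#' @param means Named numeric vector of mean copy numbers per factor, names
#'   matching the architecture's factor names.
#' @param cv Coefficient of variation (>= 0), shared across factors.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(means = c(P = 5000, R = 100), cv = 0.5) {
  if (is.null(names(means)) || any(names(means) == "")) {
    abort("`means` must be a named vector of factor copy numbers.")
  }
  if (any(means <= 0)) abort("Mean copy numbers must be > 0.")
  assert_scalar_number(cv, "cv", min = 0)
  structure(list(means = means, cv = cv), class = "noise_spec")
}

#' Draw per-variant factor copy numbers
#'
#' One independent log-normal draw per library variant per factor, with mean
#' and CV from the [noise_spec()]. `cv = 0` returns the mean exactly.
#'
#' @param noise A [noise_spec()].
#' @param n Number of variants (>= 1).
#' @param seed Integer seed.
#' @return A tibble with `n` rows and one column per factor.
#' @export
#' @examples
#' draw_copy_numbers(noise_spec(cv = 1), n = 5, seed = 1)
draw_copy_numbers <- function(noise, n, seed = 1L) {
  stopifnot(inherits(noise, "noise_spec"))
  n <- as.integer(n)
  if (n < 1L) abort("`n` must be >= 1.")
  sigma2 <- log(1 + noise$cv^2)
  draws <- withr::with_seed(seed, {
    lapply(noise$means, function(m) {
      if (noise$cv == 0) rep(m, n)
      else rlnorm(n, meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
    })
  })
  tibble::as_tibble(draws)
}

#' Expected mRNA counts for a variant library
#'
#' Applies the occupancy hypothesis: the steady-state expected count of
#' variant i is `m* = alpha * p_bound_i`, with `alpha = r/gamma` the ratio of
#' the (shared) transcription rate of active states to the mRNA degradation
#' rate. The scale `alpha` cancels from all downstream footprint statistics.
#' With a [noise_spec()], the named factor copy numbers are redrawn per
#' variant (one draw per variant, representing one measured cell/aggregate)
#' before occupancies are computed.
#'
#' @inheritParams pbound
#' @param noise Optional [noise_spec()] for extrinsic copy-number noise.
#' @param seed Seed for the noise draws.
#' @param pbound_fun Occupancy function called as
#'   `pbound_fun(library, architecture, params)`; default [pbound()].
#'   Substitute a wrapper around [pbound_multicopy()], [pbound_induction()],
#'   [pbound_nonspecific()] or a kinetic model to reuse the counting step.
#' @return An expression table: tibble with columns `variant`, `sequence`,
#'   `count` (expected counts, `alpha * p_bound`).
#' @export
#' @examples
#' lib <- mutagenize(default_promoter(), n = 50, seed = 1)
#' expected_counts(lib, architecture_preset("simple_repression"))
expected_counts <- function(library, architecture, params = thermo_params(),
                            noise = NULL, seed = 1L, pbound_fun = pbound) {
  stopifnot(inherits(library, "mutant_library"))
  if (!is.null(noise)) {
    draws <- draw_copy_numbers(noise, nrow(library), seed = seed)
    for (nm in names(draws)) params[[nm]] <- draws[[nm]]
  }
  pb <- pbound_fun(library, architecture, params)
  out <- tibble::tibble(variant = library$variant, sequence = library$sequence,
                        count = params$alpha * pb)
  if (!is.null(noise)) out <- dplyr::bind_cols(out, draws)
  out
}

#' Resample counts to a sequencing depth
#'
#' Emulates the sampling noise of library preparation and sequencing:
#' `mode = "multinomial"` draws exactly `depth` reads with probabilities
#' proportional to the expected counts; `mode = "poisson"` draws each
#' variant independently with mean scaled so the expected total is `depth`.
#'
#' @param table An expression table from [expected_counts()].
#' @param depth Total read depth (> 0).
#' @param mode "multinomial" or "poisson".
#' @param seed Integer seed.
#' @return The table with a `sampled` integer column added; downstream
#'   statistics accept it via their `count_col` argument.
#' @export
resample_counts <- function(table, depth, mode = c("multinomial", "poisson"),
                            seed = 1L) {
  mode <- match.arg(mode)
  assert_scalar_number(depth, "depth", min = .Machine$double.xmin)
  m <- table$count
  if (all(m == 0)) abort("All expected counts are zero; nothing to resample.")
  sampled <- withr::with_seed(seed, {
    if (mode == "multinomial") as.integer(rmultinom(1L, size = depth, prob = m))
    else rpois(length(m), lambda = m * depth / sum(m))
  })
  dplyr::mutate(table, sampled = sampled)
}
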