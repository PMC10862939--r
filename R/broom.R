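#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an information footprint
#'
#' Returns the footprint as a plain tibble (one row per promoter position).
#'
#' @param x An `mpra_footprint`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mpra_footprint <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("position", "mi", "shift", "sign", "no_variation")])
}

#' One-row summary of an information footprint
#'
#' @param x An `mpra_footprint`.
#' @param sites Optional display positions of the binding sites; when given,
#'   the summary includes the in-site mean and the signal-to-noise ratio.
#' @param ... Unused.
#' @return A one-row tibble with `n_positions`, `mean_mi`, `max_mi`,
#'   `n_no_variation`, and (with `sites`) `mean_site` and `snr`.
#' @export
glance.mpra_footprint <- function(x, sites = NULL, ...) {
  out <- tibble::tibble(n_positions = nrow(x), mean_mi = mean(x$mi),
                        max_mi = max(x$mi), n_no_variation = sum(x$no_variation))
  if (!is.null(sites)) {
    s <- snr(x, sites)
    out$mean_site <- s$mean_site
    out$snr <- s$snr
  }
  out
}

#' Tidy an expression-shift matrix
#'
#' @param x An `mpra_shift_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `position`, `base`, `shift`, `wild_type`.
#' @export
tidy.mpra_shift_matrix <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("position", "base", "shift", "wild_type")])
}
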