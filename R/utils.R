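#' @importFrom rlang abort warn .data
#' @importFrom stats rbinom rpois rmultinom rlnorm runif setNames uniroot quantile median
NULL

DNA_BASES <- c("A", "C", "G", "T")

# log(sum(exp(x))) along rows of a matrix, robust to -Inf columns
logsumexp_rows <- function(x) {
  m <- apply(x, 1L, max)
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(x - m)))
}

# deterministic per-stage seed derivation from a small master seed
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 1009 + counter * 9973) %% 2147483629)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a finite number in [%s, %s].", name, min, max))
  }
  invisible(x)
}

# split a character vector of equal-length sequences into an n x L base matrix
seq_to_matrix <- function(sequences) {
  L <- unique(nchar(sequences))
  if (length(L) != 1L) abort("All sequences must have equal length.")
  matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
         nrow = length(sequences), ncol = L, byrow = TRUE)
}

matrix_to_seq <- function(m) {
  apply(m, 1L, paste0, collapse = "")
}

check_alphabet <- function(chars) {
  bad <- setdiff(unique(as.vector(chars)), DNA_BASES)
  if (length(bad) > 0) {
    abort(sprintf("Sequence contains characters outside {A,C,G,T}: %s",
                  paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}
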