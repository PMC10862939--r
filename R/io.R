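#' Read and write promoter libraries as FASTA
#'
#' `write_fasta()` writes a [mutant_library()] (or a single [promoter()]) to a
#' FASTA file; the wild type is stored first under the record name
#' `wild_type` so the library round-trips losslessly. `read_fasta()` inverts
#' it.
#'
#' @param x A [mutant_library()] or [promoter()].
#' @param path File path.
#' @param tss_index TSS index to attach on read (default 115).
#' @return `read_fasta()` returns a [mutant_library()] (or a [promoter()] for
#'   a single-record file without a `wild_type` record).
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "promoter")) {
    set <- Biostrings::DNAStringSet(setNames(x$bases, "wild_type"))
  } else if (inherits(x, "mutant_library")) {
    wt <- library_wild_type(x)
    set <- Biostrings::DNAStringSet(
      setNames(c(wt$bases, x$sequence), c("wild_type", paste0("variant_", x$variant)))
    )
  } else {
    abort("`x` must be a promoter or a mutant_library.")
  }
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path, tss_index = 115L) {
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) abort(sprintf("Malformed FASTA '%s': %s", path, conditionMessage(e))))
  seqs <- as.character(set)
  if (length(seqs) == 1L) return(promoter(unname(seqs[1]), tss_index))
  if (names(seqs)[1] != "wild_type") {
    abort("Library FASTA must carry the wild type as its first record ('wild_type').")
  }
  mutant_library(unname(seqs[-1]), promoter(unname(seqs[1]), tss_index))
}

#' Read and write energy matrices as TSV
#'
#' The on-disk format is a tab-separated table with columns `pos` (display
#' coordinate) and `A`, `C`, `G`, `T` (kBT), preceded by comment header lines
#' `# factor:`, `# role:` and `# offset:`.
#'
#' @param x An [energy_matrix()].
#' @param path File path.
#' @param validate_normalized On read, error unless every row has a zero
#'   (wild-type) entry. Default `FALSE`.
#' @return `read_energy_matrix()` returns an [energy_matrix()].
#' @export
write_energy_matrix <- function(x, path) {
  stopifnot(inherits(x, "energy_matrix"))
  header <- c(sprintf("# factor: %s", x$factor_name),
              sprintf("# role: %s", x$factor_role),
              sprintf("# offset: %d", x$offset))
  df <- tibble::tibble(pos = site_positions(x),
                       A = x$energies[, "A"], C = x$energies[, "C"],
                       G = x$energies[, "G"], T = x$energies[, "T"])
  writeLines(header, path)
  # full-precision energies
  lines <- c(paste(colnames(df), collapse = "\t"),
             apply(df, 1L, function(r) paste(format(r, digits = 17, trim = TRUE, scientific = FALSE), collapse = "\t")))
  cat(lines, file = path, sep = "\n", append = TRUE)
  invisible(path)
}

#' @rdname write_energy_matrix
#' @export
read_energy_matrix <- function(path, validate_normalized = FALSE) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(m) != 1L) abort(sprintf("Matrix file '%s' is missing the '# %s:' header line.", path, key))
    trimws(sub(sprintf("^# %s:", key), "", m))
  }
  factor_name <- get_field("factor")
  role <- get_field("role")
  offset <- as.integer(get_field("offset"))
  body_start <- length(hdr) + 1L
  df <- tryCatch(
    suppressWarnings(
      readr::read_tsv(I(lines[body_start:length(lines)]), show_col_types = FALSE,
                      progress = FALSE)),
    error = function(e) abort(sprintf("Parse error in '%s' near line %d: %s",
                                      path, body_start, conditionMessage(e)))
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("Parse error in '%s' at line %d: %s", path,
                  body_start + probs$row[1], probs$expected[1]))
  }
  missing_cols <- setdiff(c("pos", DNA_BASES), colnames(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("Matrix file '%s' is missing column(s): %s (line %d).",
                  path, paste(missing_cols, collapse = ", "), body_start))
  }
  bad <- which(!vapply(df[DNA_BASES], is.numeric, logical(1)))
  if (length(bad) > 0) abort(sprintf("Non-numeric energy column in '%s'.", path))
  em <- energy_matrix(as.matrix(df[DNA_BASES]), offset, factor_name, role)
  if (validate_normalized && !is_normalized(em)) {
    abort(sprintf("Matrix in '%s' is not wild-type-normalized.", path))
  }
  em
}

#' Write an expression table, footprint or shift matrix as TSV
#'
#' Plain `readr::write_tsv()` wrappers keyed by display coordinate, provided
#' so pipeline outputs share one format.
#'
#' @param x A tibble.
#' @param path File path.
#' @export
write_mpra_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}
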