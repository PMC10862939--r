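test_that("total binding energy is additive over positions", {
  wt <- default_promoter()
  em <- synthetic_energy_matrix(wt, 1, 20, "R", "repressor")
  # wild-type window scores 0 under the normalization convention
  expect_identical(total_binding_energy(promoter_window(wt, 1, 20), em), 0)

  # a window with 3 mutant bases scores 3 kBT on a unit synthetic matrix
  win <- promoter_window(wt, 1, 20)
  mutated <- win
  for (i in 1:3) {
    b <- substr(mutated, i, i)
    substr(mutated, i, i) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  expect_equal(total_binding_energy(mutated, em), 3)

  # brute-force position-by-position summation oracle on a random matrix
  tm <- toy_matrix(l = 12, seed = 42)
  win <- random_window(12, seed = 7)
  chars <- strsplit(win, "")[[1]]
  oracle <- 0
  for (i in seq_len(12)) oracle <- oracle + unname(tm$energies[i, chars[i]])
  expect_equal(total_binding_energy(win, tm), oracle)

  expect_error(total_binding_energy("ACGT", tm), "length")
  expect_error(total_binding_energy(strrep("X", 12), tm), "outside")
})

test_that("average mutation effect matches its definition and invariances", {
  wt <- default_promoter()
  uni <- synthetic_energy_matrix(wt, 1, 20, "R", "repressor", effect = 1)
  expect_equal(average_mutation_effect(uni), 1)

  # single nonzero entry of 3 kBT on a length-10 site: 3 / (3 * 10)
  e <- matrix(0, 10, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  e[4, "G"] <- 3
  expect_equal(average_mutation_effect(energy_matrix(e, 0, "R", "repressor")), 0.1)

  # invariant under permutation of positions
  tm <- toy_matrix(l = 9, seed = 3)
  perm <- energy_matrix(tm$energies[sample(9), ], 0, "R", "repressor")
  expect_equal(average_mutation_effect(perm), average_mutation_effect(tm))

  bad <- energy_matrix(matrix(1, 5, 4), 0, "R", "repressor")
  expect_error(average_mutation_effect(bad), "normalized")
})

test_that("mutagenize obeys the rate, the spectrum and the mask invariant", {
  wt <- default_promoter()

  # theta = 0: identical wild-type copies, all-zero mask
  lib0 <- mutagenize(wt, n = 5, theta = 0, seed = 1)
  expect_true(all(lib0$sequence == wt$bases))
  expect_true(all(library_mask(lib0) == 0L))

  # theta = 1 with a G->A / C->T spectrum turns "GC" into "AT"
  gc <- promoter("GC", tss_index = 0L)
  lib1 <- mutagenize(gc, n = 8, theta = 1, spectrum = spectrum_ga_ct(), seed = 2)
  expect_true(all(lib1$sequence == "AT"))

  # immutable bases (A and T under ga_ct) never mutate even at theta = 1
  at <- promoter("ATAT", tss_index = 0L)
  lib_at <- mutagenize(at, n = 8, theta = 1, spectrum = spectrum_ga_ct(), seed = 3)
  expect_true(all(lib_at$sequence == "ATAT"))

  # per-position mutant fraction lies in the binomial 99% interval at n = 1e4
  lib <- mutagenize(wt, n = 1e4, theta = 0.1, seed = 4)
  frac <- colMeans(library_mask(lib))
  ci <- qbinom(c(0.005, 0.995), 1e4, 0.1) / 1e4
  expect_true(all(frac >= ci[1] & frac <= ci[2]))

  # mask and sequences are mutually consistent, variant by variant
  bm <- do.call(rbind, strsplit(lib$sequence[1:50], ""))
  wt_chars <- strsplit(wt$bases, "")[[1]]
  recomputed <- t(apply(bm, 1, function(r) as.integer(r != wt_chars)))
  expect_identical(unname(library_mask(lib)[1:50, ]), unname(recomputed))

  # reproducible under a fixed seed; different seed differs
  expect_identical(mutagenize(wt, n = 20, seed = 11)$sequence,
                   mutagenize(wt, n = 20, seed = 11)$sequence)
  expect_false(identical(mutagenize(wt, n = 20, seed = 11)$sequence,
                         mutagenize(wt, n = 20, seed = 12)$sequence))

  # optional inclusion of the wild type as variant 1
  libw <- mutagenize(wt, n = 10, seed = 5, include_wild_type = TRUE)
  expect_identical(libw$sequence[1], wt$bases)
})

test_that("motif insertion substitutes in place", {
  wt <- default_promoter()
  expect_identical(insert_motif(wt, promoter_window(wt, -50, 8), -50)$bases, wt$bases)

  ins <- insert_motif(wt, "TAGAAT", at = -80)
  expect_equal(sum(strsplit(ins$bases, "")[[1]] != strsplit(wt$bases, "")[[1]]) <= 6, TRUE)
  expect_identical(nchar(ins$bases), nchar(wt$bases))
  expect_identical(promoter_window(ins, -80, 6), "TAGAAT")

  expect_error(insert_motif(wt, "TAGAAT", at = 43), "outside")
})

test_that("designed overlap promoters minimize total binding energy", {
  wt <- default_promoter()
  rnap <- toy_matrix(l = 10, offset = -20, factor_name = "P",
                     factor_role = "polymerase", seed = 21)
  repr <- toy_matrix(l = 8, offset = 5, factor_name = "R",
                     factor_role = "repressor", seed = 22)

  # zero overlap: each site sits at its own minimum-energy sequence
  p <- design_overlap_promoter(rnap, repr, overlap_offset = 5, seed = 1)
  expect_equal(total_binding_energy(promoter_window(p, -20, 10), rnap),
               sum(apply(rnap$energies, 1, min)))
  expect_equal(total_binding_energy(promoter_window(p, 5, 8), repr),
               sum(apply(repr$energies, 1, min)))

  # overlapping placement: no single-base change at an overlap position can
  # lower the combined energy (exhaustive check over the 4 bases)
  off <- -15  # repressor at -15..-8 overlaps rnap at -20..-11
  p2 <- design_overlap_promoter(rnap, repr, overlap_offset = off, seed = 1)
  total <- function(pr) {
    total_binding_energy(promoter_window(pr, -20, 10), rnap) +
      total_binding_energy(promoter_window(pr, off, 8), repr)
  }
  base_total <- total(p2)
  for (pos in -15:-11) {
    for (b in c("A", "C", "G", "T")) {
      expect_gte(total(insert_motif(p2, b, pos)) + 1e-12, base_total)
    }
  }

  # wild-type-normalized matrices with positive mutant entries: the design
  # reproduces the wild type over the covered regions
  rn <- synthetic_energy_matrix(wt, -36, 30, "P", "polymerase")
  rp <- synthetic_energy_matrix(wt, 1, 20, "R", "repressor")
  p3 <- design_overlap_promoter(rn, rp, overlap_offset = 1, seed = 9)
  expect_identical(promoter_window(p3, -36, 30), promoter_window(wt, -36, 30))
  expect_identical(promoter_window(p3, 1, 20), promoter_window(wt, 1, 20))

  expect_error(design_overlap_promoter(rnap, repr, overlap_offset = 40), "outside")
})

test_that("FASTA and matrix files round-trip losslessly", {
  wt <- default_promoter()
  lib <- mutagenize(wt, n = 5000, theta = 0.1, seed = 31)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(lib, fa)
  back <- read_fasta(fa, tss_index = wt$tss_index)
  expect_identical(back$sequence, lib$sequence)
  expect_identical(library_wild_type(back)$bases, wt$bases)

  tm <- toy_matrix(l = 7, offset = -30, seed = 5)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_energy_matrix(tm, tf)
  back_m <- read_energy_matrix(tf, validate_normalized = TRUE)
  expect_equal(back_m$energies, tm$energies)
  expect_identical(back_m$offset, tm$offset)
  expect_identical(back_m$factor_role, tm$factor_role)

  # a missing base column is a parse error naming the column
  lines <- readLines(tf)
  lines <- vapply(lines, function(l) {
    if (startsWith(l, "#")) l else paste(strsplit(l, "\t")[[1]][1:4], collapse = "\t")
  }, character(1), USE.NAMES = FALSE)
  writeLines(lines, tf)
  expect_error(read_energy_matrix(tf), "missing column")

  # ragged rows are a parse error naming the line
  writeLines(c("# factor: X", "# role: repressor", "# offset: 0",
               "pos\tA\tC\tG\tT", "0\t1\t2", "1\t0\t0\t0\t0"), tf)
  expect_error(read_energy_matrix(tf), "Parse error")
})
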