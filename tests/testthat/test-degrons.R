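write_degron_tsv <- function(rows) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("motif\tdpsi", rows), f)
  f
}

test_that("degron table loading applies the dPSI cutoff and collapses duplicates", {
  f <- write_degron_tsv(c("GG\t-0.55", "AA\t-0.10"))
  set <- suppressMessages(load_degron_table(f, "C"))
  expect_equal(set$motifs$motif, "GG")

  f2 <- write_degron_tsv(c("GG\t-0.5", "GG\t-0.7", "EE\t-0.9"))
  set2 <- suppressMessages(load_degron_table(f2, "C"))
  expect_equal(set2$motifs$dpsi[set2$motifs$motif == "GG"], -0.7)

  f3 <- write_degron_tsv(character(0))
  expect_equal(length(suppressMessages(load_degron_table(f3, "N"))), 0L)

  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("motif\tvalue", "GG\t-0.5"), f4)
  expect_error(load_degron_table(f4, "N"), "columns")
  f5 <- write_degron_tsv("GG\tnot_a_number")
  expect_error(load_degron_table(f5, "N"), "non-numeric")
})

test_that("top-k selection keeps the most destabilizing motifs with lexicographic ties", {
  set <- degron_set(c("AA", "GG", "CC"), c(-0.9, -0.5, -0.7), "N")
  expect_equal(top_k_by_dpsi(set, 2)$motifs$motif, c("AA", "CC"))
  expect_equal(length(top_k_by_dpsi(set, 10)), 3L)
  tie <- degron_set(c("GG", "AA", "CC"), c(-0.9, -0.5, -0.5), "N")
  expect_equal(top_k_by_dpsi(tie, 2)$motifs$motif, c("GG", "AA"))
})

test_that("N-degron matching anchors after the initiator methionine", {
  set <- degron_set("GG", -0.5, "N")
  hit <- scan_n_degrons("MGGKLAAA", set)
  expect_equal(hit$start, 2L)
  expect_equal(hit$end, 3L)
  # non-AUG isoform: anchored at residue 1
  hit2 <- scan_n_degrons("GGKLAAA", set)
  expect_equal(hit2$start, 1L)
  # not anchored: no hit
  expect_equal(nrow(scan_n_degrons("MAGGKAAA", set)), 0L)
})

test_that("C-degron matching anchors at the terminus", {
  set <- degron_set("GG", -0.5, "C")
  hit <- scan_c_degrons("MKSAGG", set)
  expect_equal(hit$start, 5L)
  expect_equal(hit$end, 6L)
  expect_equal(nrow(scan_c_degrons("MKGGSA", set)), 0L)
  empty <- degron_set(character(0), numeric(0), "C")
  expect_equal(nrow(scan_c_degrons("MKGGSA", empty)), 0L)
})

test_that("scanners agree exactly with the brute-force anchored matcher", {
  withr::with_seed(101, {
    aa <- amino_acids()
    motifs <- unique(vapply(1:12, function(i)
      paste(sample(aa, sample(1:4, 1), replace = TRUE), collapse = ""), character(1)))
    n_set <- degron_set(motifs, -runif(length(motifs), 0.4, 1), "N")
    c_set <- degron_set(motifs, -runif(length(motifs), 0.4, 1), "C")
    for (rep in 1:500) {
      # short sequences enriched in the motif alphabet make anchored hits common
      seq <- paste(sample(aa[1:8], sample(6:30, 1), replace = TRUE), collapse = "")
      if (runif(1) < 0.5) seq <- paste0("M", seq)
      expect_setequal(scan_n_degrons(seq, n_set)$motif, bf_scan_n(seq, motifs))
      expect_setequal(scan_c_degrons(seq, c_set)$motif, bf_scan_c(seq, motifs))
    }
  })
})

test_that("hits under a top-k subset are a subset of full-set hits", {
  withr::with_seed(55, {
    motifs <- c("GG", "EG", "RG", "EEG", "VG")
    set <- degron_set(motifs, -runif(5, 0.4, 1), "C")
    for (k in 1:5) {
      sub <- top_k_by_dpsi(set, k)
      for (i in 1:50) {
        seq <- random_aa_seq(20)
        expect_true(all(scan_c_degrons(seq, sub)$motif %in%
                          scan_c_degrons(seq, set)$motif))
      }
    }
  })
})

test_that("scanning ignores sequence content outside the anchored window", {
  set <- degron_set("KLW", -0.6, "N")
  base <- "MKLWAAAAAA"
  modified <- paste0("MKLW", random_seq_fixed(12, seed = 4))
  expect_equal(scan_n_degrons(base, set)$motif, scan_n_degrons(modified, set)$motif)
})

test_that("dataset-level degron scan mirrors per-sequence scans", {
  n_set <- degron_set(c("DE", "KL"), c(-0.7, -0.5), "N")
  c_set <- degron_set(c("GG", "EN"), c(-0.9, -0.6), "C")
  ds <- toy_dataset(c("MDEAAAAGG", "MKLAAAAEN", "MAAAAAAAA"))
  tab <- scan_degrons_dataset(ds, n_set, c_set)
  expect_equal(tab$n_degron_present, c(TRUE, TRUE, FALSE))
  expect_equal(tab$c_degron_present, c(TRUE, TRUE, FALSE))
  expect_match(tab$motifs_matched[1], "N:DE")
  expect_match(tab$motifs_matched[1], "C:GG")
  tab2 <- scan_degrons_dataset(ds, n_set = n_set)
  expect_true(all(is.na(tab2$c_degron_present)))
})

test_that("bundled fixture tables load under the standard cutoff", {
  nf <- system.file("extdata", "toy_n_degrons.tsv", package = "degsig")
  cf <- system.file("extdata", "toy_c_degrons.tsv", package = "degsig")
  n_set <- suppressMessages(load_degron_table(nf, "N"))
  c_set <- suppressMessages(load_degron_table(cf, "C"))
  expect_true(all(n_set$motifs$dpsi <= -0.4))
  expect_true(all(c_set$motifs$dpsi <= -0.4))
  expect_false("QQ" %in% n_set$motifs$motif)
  expect_false("SS" %in% c_set$motifs$motif)
})
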