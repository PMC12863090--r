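write_disorder_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("disorder file parsing validates positions and score range", {
  f <- write_disorder_lines(c("# IUPred2a-style header", "1 M 0.9", "2 K 0.8", "3 T 0.2"))
  prof <- parse_disorder_file(f, sequence = "MKT")
  expect_equal(prof$scores, c(0.9, 0.8, 0.2))
  expect_error(parse_disorder_file(write_disorder_lines(c("1 M 0.9", "3 T 0.2"))),
               "consecutive")
  expect_error(parse_disorder_file(write_disorder_lines(c("1 M 1.2"))), "out of")
  expect_error(parse_disorder_file(f, sequence = "MKV"), "do not match")
})

test_that("terminal IDR calls use an inclusive 30-residue run threshold", {
  sat <- disorder_profile(rep(0.9, 60))
  call <- call_terminal_idrs(sat)
  expect_true(call$n_idr && call$c_idr)
  expect_equal(call$n_run_length, 60L)

  near <- disorder_profile(c(rep(0.9, 29), rep(0.1, 31)))
  expect_false(call_terminal_idrs(near)$n_idr)
  expect_equal(call_terminal_idrs(near)$n_run_length, 29L)

  exact <- disorder_profile(c(rep(0.9, 30), rep(0.1, 30)))
  expect_true(call_terminal_idrs(exact)$n_idr)

  # strict score threshold: 0.5 itself is not disordered
  boundary <- disorder_profile(rep(0.5, 60))
  expect_false(call_terminal_idrs(boundary)$n_idr)
})

test_that("reversing a profile swaps the N- and C-terminal calls exactly", {
  withr::with_seed(31, {
    for (i in 1:200) {
      scores <- runif(sample(30:120, 1))
      fwd <- call_terminal_idrs(disorder_profile(scores), min_len = 5)
      rev_ <- call_terminal_idrs(disorder_profile(rev(scores)), min_len = 5)
      expect_equal(fwd$n_run_length, rev_$c_run_length)
      expect_equal(fwd$c_run_length, rev_$n_run_length)
      expect_equal(fwd$n_idr, rev_$c_idr)
    }
  })
})

test_that("terminal runs agree with a naive per-residue scan", {
  naive_run <- function(x, thr) {
    r <- 0L
    for (v in x) {
      if (v > thr) r <- r + 1L else break
    }
    r
  }
  withr::with_seed(37, {
    for (i in 1:1000) {
      scores <- round(runif(sample(10:80, 1)), 2)
      call <- call_terminal_idrs(disorder_profile(scores), min_len = 10)
      expect_equal(call$n_run_length, naive_run(scores, 0.5))
      expect_equal(call$c_run_length, naive_run(rev(scores), 0.5))
    }
  })
})

test_that("surrogate disorder is deterministic and tracks residue propensity", {
  seq <- paste0(strrep("PESKQ", 12), strrep("ILVFA", 12))
  p1 <- surrogate_disorder(seq)
  p2 <- surrogate_disorder(seq)
  expect_identical(p1$scores, p2$scores)
  # disorder-promoting interior above 0.5, order-promoting interior below
  expect_true(all(p1$scores[11:50] > 0.5))
  expect_true(all(p1$scores[71:110] < 0.5))
  expect_true(all(p1$scores >= 0 & p1$scores <= 1))
})

test_that("disorder profiles round-trip through the three-column format", {
  prof <- surrogate_disorder(random_seq_fixed(70, seed = 9), sequence_id = "rt")
  f <- withr::local_tempfile(fileext = ".txt")
  write_disorder_file(prof, f)
  back <- parse_disorder_file(f, sequence_id = "rt")
  expect_equal(back$scores, round(prof$scores, 4))
})

test_that("topology strings decode into TMD intervals and signal flags", {
  topo <- topology_annotation(paste0(strrep("i", 4), strrep("M", 20), strrep("o", 3)))
  expect_equal(nrow(topo$tmd_intervals), 1L)
  expect_equal(topo$tmd_intervals$start, 5L)
  expect_equal(topo$tmd_intervals$end, 24L)
  expect_false(topo$has_signal_peptide)
  expect_true(topology_annotation("SSSSiiii")$has_signal_peptide)
  expect_error(topology_annotation("iiixiii"), "unknown topology letter")
})

test_that("topology files parse multiple wrapped records", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">p1", strrep("i", 30), strrep("M", 20), ">p2", "SSSSiiii"), f)
  topos <- parse_topology(f)
  expect_equal(names(topos), c("p1", "p2"))
  expect_equal(topos$p1$length, 50L)
  expect_equal(topos$p1$tmd_intervals$start, 31L)
  expect_true(topos$p2$has_signal_peptide)
})

test_that("tail-anchor classification applies the 29-residue limits in order", {
  mk <- function(pre, tmd, tail, sp = 0) {
    topology_annotation(paste0(strrep("S", sp), strrep("i", pre),
                               strrep("M", tmd), strrep("o", tail)))
  }
  expect_true(classify_ta(mk(40, 20, 10))$is_ta_like)
  expect_equal(classify_ta(mk(40, 20, 10, sp = 5))$reason, "signal_peptide")
  expect_equal(classify_ta(topology_annotation(strrep("i", 60)))$reason, "zero_tmds")
  two <- topology_annotation(paste0(strrep("i", 10), strrep("M", 15),
                                    strrep("i", 10), strrep("M", 15), "ooo"))
  expect_equal(classify_ta(two)$reason, "multiple_tmds")
  expect_equal(classify_ta(mk(40, 30, 10))$reason, "tmd_too_long")
  expect_true(classify_ta(mk(40, 29, 29))$is_ta_like) # both at the boundary
  expect_equal(classify_ta(mk(40, 20, 30))$reason, "tail_too_long")
})

test_that("extending the C-tail past the limit only ever disables the TA call", {
  for (tail in c(1, 10, 29, 30, 40, 80)) {
    topo <- topology_annotation(paste0(strrep("i", 30), strrep("M", 20),
                                       strrep("o", tail)))
    call <- classify_ta(topo)
    expect_equal(call$is_ta_like, tail <= 29)
  }
})

test_that("aggregation fraction counts qualifying residues", {
  expect_equal(aggregation_fraction(rep(-6, 100), rep(0.02, 100), 100), 1)
  expect_equal(aggregation_fraction(rep(-1, 50), rep(0.001, 50), 50), 0)
  e <- rep(-1, 200); p <- rep(0.001, 200)
  e[1:10] <- -6; p[1:10] <- 0.02
  expect_equal(aggregation_fraction(e, p, 200), 0.05)
  # both conditions required, strict comparisons
  expect_equal(aggregation_fraction(c(-6, -5, -6), c(0.02, 0.02, 0.01), 3), 1 / 3)
  expect_error(aggregation_fraction(rep(-6, 3), rep(0.02, 4), 4), "per residue")
  # permutation invariance: a count does not depend on order
  withr::with_seed(77, {
    e2 <- runif(60, -8, 0); p2 <- runif(60, 0, 0.05)
    ord <- sample(60)
    expect_equal(aggregation_fraction(e2, p2, 60),
                 aggregation_fraction(e2[ord], p2[ord], 60))
  })
})

test_that("aggregation tables and surrogate profiles round-trip", {
  prof <- surrogate_aggregation(paste0(strrep("A", 10), strrep("ILVFI", 3),
                                       strrep("G", 10)), "agg1")
  expect_equal(sum(prof$energies == -6), 15)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_aggregation_file(prof, f)
  back <- parse_aggregation_file(f, "agg1")
  expect_equal(back$energies, prof$energies)
  expect_equal(back$probabilities, prof$probabilities)
})
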