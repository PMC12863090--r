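test_that("generation is fully deterministic given the spec seed", {
  spec <- synthetic_spec(30, seed = 99, p_c_degron = 0.3, p_n_degron = 0.3,
                         p_ta = 0.2, p_idr_n = 0.2, p_idr_c = 0.2,
                         p_kferq = c(canonical = 0.3), tail_kd_shift = 0.1)
  g1 <- generate_dataset(spec)
  g2 <- generate_dataset(spec)
  expect_identical(g1$dataset$records, g2$dataset$records)
  expect_identical(g1$truth, g2$truth)
  expect_identical(g1$companions$topology_strings, g2$companions$topology_strings)
  expect_identical(lapply(g1$companions$disorder, `[[`, "scores"),
                   lapply(g2$companions$disorder, `[[`, "scores"))
  # a different seed changes the draw
  spec2 <- spec; spec2$seed <- 100L
  expect_false(identical(generate_dataset(spec2)$dataset$records,
                         g1$dataset$records))
})

test_that("infeasible specs and invalid probabilities are rejected", {
  expect_error(synthetic_spec(10, tail_kd_shift = 10), "infeasible")
  expect_error(synthetic_spec(10, p_c_degron = 1.4), "\\[0, 1\\]")
  expect_error(synthetic_spec(10, length_floor = 10), "length_floor")
  bad_comp <- human_aa_composition() * 2
  expect_error(synthetic_spec(10, composition = bad_comp), "sum to 1")
})

test_that("lengths respect the floor and sequences use the standard alphabet", {
  g <- generate_dataset(synthetic_spec(200, seed = 5), companions = FALSE)
  len <- nchar(g$dataset$records$sequence)
  expect_true(all(len >= 60))
  expect_true(all(grepl(paste0("^[", paste(amino_acids(), collapse = ""), "]+$"),
                        g$dataset$records$sequence)))
})

test_that("empirical residue composition matches the spec within 3 SD per residue", {
  spec <- synthetic_spec(900, length_meanlog = log(115), length_sdlog = 0.3,
                         seed = 12)
  g <- generate_dataset(spec, companions = FALSE)
  chars <- unlist(strsplit(g$dataset$records$sequence, ""), use.names = FALSE)
  n <- length(chars)
  expect_gt(n, 100000)
  freq <- table(factor(chars, levels = amino_acids())) / n
  p <- spec$composition[amino_acids()]
  sd3 <- 3 * sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) < sd3))
})

test_that("the tilted tail reaches the target hydropathy shift", {
  shift <- 0.3
  spec <- synthetic_spec(1200, tail_kd_shift = shift, seed = 21)
  g <- generate_dataset(spec, companions = FALSE)
  kd <- kyte_doolittle()
  seqs <- g$dataset$records$sequence
  tail_mean <- mean(vapply(seqs, ctth, numeric(1), USE.NAMES = FALSE))
  base_mean <- sum(spec$composition * kd[names(spec$composition)])
  expect_lt(abs(tail_mean - (base_mean + shift)), 0.05)
})

test_that("every planted determinant is rediscovered by its scanner", {
  spec <- synthetic_spec(120, seed = 8, p_c_degron = 0.4, p_n_degron = 0.4,
                         p_ta = 0.25, p_idr_n = 0.3, p_idr_c = 0.3,
                         p_kferq = c(canonical = 0.4, phospho_activated = 0.3,
                                     acetyl_activated = 0.3))
  g <- generate_dataset(spec)
  tr <- g$truth
  deg <- scan_degrons_dataset(g$dataset, default_n_degron_motifs(),
                              default_c_degron_motifs())
  expect_true(all(deg$n_degron_present[tr$n_degron_planted]))
  expect_true(all(deg$c_degron_present[tr$c_degron_planted]))
  kf <- dataset_kferq_rates(g$dataset)$per_sequence
  expect_true(all(kf$canonical_n[tr$kferq_canonical_planted] >= 1))
  expect_true(all(kf$phospho_n[tr$kferq_phospho_planted] >= 1))
  expect_true(all(kf$acetyl_n[tr$kferq_acetyl_planted] >= 1))
  for (i in which(tr$ta_planted)) {
    topo <- topology_annotation(g$companions$topology_strings[[i]])
    expect_true(classify_ta(topo)$is_ta_like)
  }
  for (i in which(tr$idr_n_planted)) {
    expect_true(call_terminal_idrs(g$companions$disorder[[i]])$n_idr)
  }
  for (i in which(tr$idr_c_planted)) {
    expect_true(call_terminal_idrs(g$companions$disorder[[i]])$c_idr)
  }
})

test_that("with no planting, anchored C-degron prevalence matches the analytic rate", {
  # closed-form anchored-match probability under i.i.d. composition
  spec <- synthetic_spec(4000, length_meanlog = log(90), length_sdlog = 0.3,
                         seed = 33)
  g <- generate_dataset(spec, companions = FALSE)
  comp <- spec$composition
  motifs <- default_c_degron_motifs()$motifs$motif
  p_motif <- vapply(motifs, function(mo) {
    prod(comp[strsplit(mo, "")[[1]]])
  }, numeric(1))
  # motifs share no suffix relation here, union bound is exact to first order
  p_any <- sum(p_motif)
  obs <- mean(scan_degrons_dataset(g$dataset,
                                   c_set = default_c_degron_motifs())$c_degron_present)
  se <- sqrt(p_any * (1 - p_any) / 4000)
  expect_lt(abs(obs - p_any), max(4 * se, 5e-4))
})

test_that("two-group study records the expected effects implied by its specs", {
  st <- generate_two_group_study(default_cp_spec(n = 80), default_ncp_spec(n = 80),
                                 seed = 3)
  ee <- st$expected_effects
  or_row <- ee[ee$feature == "c_degron_present", ]
  expect_equal(or_row$true_effect, (0.168 / 0.832) / (0.084 / 0.916),
               tolerance = 1e-12)
  expect_equal(round(or_row$true_effect, 2), 2.2)
  expect_equal(ee$true_effect[ee$feature == "ctth"], 0.15)
  # equal specs give null expected effects
  same <- generate_two_group_study(default_cp_spec(n = 60), default_cp_spec(n = 60),
                                   seed = 4)
  expect_true(all(same$expected_effects$true_effect[
    same$expected_effects$effect_name == "odds_ratio"] == 1))
  expect_equal(same$expected_effects$true_effect[3], 0)
  expect_error(default_cp_spec(n = 0), "n_sequences")
})
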