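# degsig

Degradation-signal analysis of canonical and noncanonical protein sequences.

Thousands of noncanonical proteins (NCPs) — products of uORFs, dORFs,
lncRNA ORFs, internal and pseudogene ORFs — are now detected by ribosome
profiling, but most appear short-lived in the cell. Whether an amino-acid
sequence carries *degradation determinants* is therefore a central question
when judging which noncanonical products could be functional. `degsig`
implements the sequence-level determinant analyses used in comparative
studies of canonical versus noncanonical human proteins, as a reusable,
tested R pipeline that runs end-to-end on synthetic data, with no external
predictors or downloads required.

## What it computes

For each protein sequence (length ≥ 60, standard 20-letter alphabet):

* **C-terminal tail hydrophobicity (CTTH)** — the mean Kyte–Doolittle
  hydropathy of the last 30 residues,
  `CTTH = (1/30) Σ_{i=L−29..L} kd(s_i)`, plus the GRAVY-style mean of the
  remaining residues and the positional profile of the last 60 positions.
  Elevated CTTH is a proteasomal degradation trigger.
* **Stability-pattern classification** — proteins with `CTTH < −0.963`
  (lower quartile of AUG canonical proteins) and a hydrophobic rest
  (`> 0`) are candidate *stabilized tails*; proteins with `CTTH > −0.110`
  (upper quartile), a highly hydrophilic rest (`< −1`), and no C-terminal
  TMD are candidate *destabilized tails*. Thresholds are configurable and
  re-derivable from any reference set with `ctth_quartiles()`.
* **Terminal degrons** — anchored scans of ΔPSI-annotated motif tables
  (kept at ΔPSI ≤ −0.4, optionally the top 20 by ΔPSI): N-end motifs must
  match immediately after the initiator methionine (or at residue 1 for
  non-AUG isoforms), C-end motifs must match the terminal residues.
* **KFERQ-like motifs** — pentapeptides routing proteins to
  chaperone-mediated autophagy / endosomal microautophagy, in three
  classes (canonical, phosphorylation-activated, acetylation-activated),
  with per-sequence counts and length-normalized (pooled) densities.
* **Terminal IDRs** — runs of per-residue disorder scores `> 0.5` of at
  least 30 residues at either terminus, parsed from IUPred2a-style files
  (a clearly labelled surrogate generator is bundled for testing).
* **Tail-anchored (TA) architecture** — no signal peptide, a single TMD of
  ≤ 29 residues, and a C-tail after the TMD of ≤ 29 residues, decoded from
  per-residue topology strings.
* **Aggregation fraction** — residues with pairing free energy < −5 and
  probability > 0.01, divided by protein length.

Around the per-sequence layer sit the study-level tools: dataset filters
and terminal-redundancy collapses (keep-the-longest per terminal k-mer),
composition-preserving within-sequence **shuffle nulls**, and the
comparison statistics: Wilcoxon rank-sum with the rank-biserial
correlation `r = 1 − 2U/(n₁n₂)`, Wilcoxon signed-rank and McNemar for
original-vs-shuffled pairs, Fisher's exact test with odds ratios, Wilson
proportion CIs, Spearman correlation, exact two-group Poisson rate tests,
and Benjamini–Hochberg adjustment. A synthetic-data generator plants every
determinant at controlled prevalences and effect sizes, so planting →
scanning → testing round-trips are fully verifiable.

## Worked example

```r
library(degsig)

# two synthetic groups at the default study conditions:
# C-degron prevalence 0.084 vs 0.168, C-tail hydropathy shift +0.15
cp  <- generate_dataset(default_cp_spec(n = 300, seed = 1), companions = FALSE)
ncp <- generate_dataset(default_ncp_spec(n = 300, seed = 2), companions = FALSE)

prof_cp  <- profile_dataset(filter_minimal(cp$dataset),
                            c_degrons = default_c_degron_motifs())
prof_ncp <- profile_dataset(filter_minimal(ncp$dataset),
                            c_degrons = default_c_degron_motifs())
report <- compare_profiles(prof_ncp, prof_cp, "NCP-like", "CP-like")
```

```
       determinant         test  n1  n2     p_bh   effect_name effect_value
1             ctth     rank_sum 300 300 3.99e-03 rank_biserial      -0.1433
2       rest_gravy     rank_sum 300 300 5.51e-01 rank_biserial       0.0281
3    kferq_density     rank_sum 300 300 5.54e-10 rank_biserial       0.2833
4 c_degron_present fisher_exact 300 300 5.09e-02    odds_ratio       1.6925
5    kferq_has_any fisher_exact 300 300 1.51e-26    odds_ratio       0.1530
```

The NCP-like group shows the planted signal: higher CTTH (rank-biserial
|r| ≈ 0.14 at n = 300; the sign follows the argument order) and a
C-degron odds ratio of ≈ 1.7 against a planted truth of 2.2 (the CI at
this sample size is wide). `rest_gravy` — where nothing was planted — is
null. The KFERQ rows reflect background motif arithmetic: longer CP-like
sequences contain at least one pentapeptide far more often, while
length-normalized density runs the other way.

The original-vs-shuffled null isolates *positional* signal from
composition:

```r
null_compare(cp$dataset, c_degrons = default_c_degron_motifs(), seed = 9)
```

```
       determinant        test  n1 statistic    p_raw effect_value
1             ctth signed_rank 300  2.00e+04 9.13e-02      -0.1125
2       rest_gravy signed_rank 300  2.51e+04 9.80e-02       0.1103
3    kferq_density signed_rank 222  1.12e+04 2.36e-01      -0.0919
4 c_degron_present     mcnemar  31  2.90e+01 7.12e-08      63.0000
5    kferq_has_any     mcnemar  99  1.62e-01 6.88e-01       1.1064
```

Planted anchored C-degrons are destroyed by shuffling (29 of 31
discordant pairs are original-only, McNemar p ≈ 7×10⁻⁸), whereas CTTH —
whose tilt is compositional, not positional — is correctly null.

A thin CLI over the same functions ships in `inst/cli/degsig.R`
(subcommands `profile`, `compare`, `null-compare`, `localize`,
`simulate`; every command is byte-reproducible under `--seed`).

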