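---
title: "Scoring protein degradation determinants with degsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring protein degradation determinants with degsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degsig)
```

## The model

Protein half-life in the cell is shaped by sequence-encoded degradation
determinants. `degsig` scores four of them on primary sequence alone, plus
two structure-adjacent quantities consumed from per-residue predictor
output, and wraps them in the statistics used to compare protein groups
(e.g. canonical versus noncanonical proteins) and original versus shuffled
sequences.

**C-terminal tail hydrophobicity (CTTH).** The mean Kyte–Doolittle
hydropathy of the last `w = 30` residues. The Kyte–Doolittle scale spans
\[−4.5, 4.5\]; positive means hydrophobic. Exposed hydrophobic C-tails are
a proteasomal degradation trigger, so a group whose tails are more
hydrophobic than expected is a group under weaker stabilizing selection.
The complementary `rest_gravy` is the mean over positions `1..L−w`. The
two decompose the full-sequence GRAVY exactly:
`(w·CTTH + (L−w)·rest)/L` equals the whole-sequence mean, a property the
test suite asserts to 1e−12. The minimum analyzable length of 60 residues
guarantees a rest at least as long as the tail.

**Stability patterns.** A protein with `CTTH < −0.963` (the lower CTTH
quartile of AUG-initiated canonical proteins) but a hydrophobic rest
(`> 0`) looks *selected for stability* in its tail; one with
`CTTH > −0.110` (the upper canonical quartile) but a highly hydrophilic
rest (`< −1`) looks *selected for instability*. All comparisons are
strict, so boundary values fall into `other` — this matches the
below/above wording of the thresholds' definition and makes the
classifier's behavior at the published constants exactly testable.
Proteins with a C-terminal TMD are excluded from the destabilized call:
their hydrophobic tail is a membrane anchor, not a degron. When no
topology is supplied, `profile_dataset()` computes the pattern with the
TMD flag false; users with real topology predictions should supply them,
since C-terminal TMDs otherwise inflate the destabilized class. The
quartile constants are configuration values; `ctth_quartiles()` recomputes
them from any reference dataset with the linear-interpolation (type 7)
quantile definition.

**Terminal degrons.** Degron motif tables carry the differential protein
stability index ΔPSI — the mean stability difference between polypeptides
carrying the motif terminally versus internally; more negative is more
destabilizing. Tables are filtered at ΔPSI ≤ −0.4 (the cutoff retaining
likely functional degrons) and optionally reduced to the top 20 by ΔPSI.
Matching is anchored and exact-letter: an N-end motif must equal the
prefix starting after the initiator methionine when the sequence begins
with `M`, and at residue 1 otherwise — the screens that measured ΔPSI
placed motifs after the initiator Met, and how non-AUG isoforms were
handled upstream is not recorded, so the residue-1 fallback is this
package's documented choice. C-end motifs must equal the terminal
residues. Wildcards are deliberately not interpreted: the source screens
report literal peptides, and silent pattern expansion would change
prevalence estimates. Users importing real curated tables should check
that their motifs are literal before relying on the scan.

**KFERQ-like motifs.** Pentapeptides recognized by HSC70 route proteins to
chaperone-mediated autophagy and endosomal microautophagy. The class
rules are fixed here because the upstream tool defines them operationally:
a window matches the *canonical* class when a glutamine anchors position 1
or 5 and the remaining four residues are 1–2 basic (K/R), 1–2 hydrophobic
(F/I/L/V) with basic+hydrophobic = 3, and exactly one acidic (E/D);
*phospho-activated* replaces the acidic slot with S/T (Y excluded by
default, available by flag, since its inclusion varies between
curations); *acetyl-activated* puts a lysine in the anchor slot, and that
lysine does not also count toward the basic tally. Every 5-residue window
is classified independently and overlaps all count — the only
decomposition under which a brute-force per-window oracle is
well-defined, which is how the scanner is tested. A window anchored at
both ends is counted once per class by default (`count_double_anchor`
flips this; the upstream convention is unrecorded). Because motif
presence is strongly length-dependent, dataset comparisons use the pooled
density: total motifs over total residues.

**Terminal IDRs.** From per-residue disorder scores in \[0, 1\] (IUPred2a
long-disorder output or equivalent), a terminal IDR is a run of scores
strictly `> 0.5` of **at least 30** residues starting at a terminus. The
source material states the length rule both as "longer than 30" and as
"30 or more"; the inclusive reading is adopted because the experimental
work underlying the 30-residue figure uses it, and the threshold is
configurable. Only terminal IDRs are called: internal IDR content scales
with length and would confound comparisons between long canonical and
short noncanonical proteins.

**Tail-anchored proteins.** From per-residue topology strings
(`i`/`o`/`M`/`S`), a TA-like protein has no signal peptide, exactly one
TMD of at most 29 residues, and at most 29 residues of C-tail after the
TMD. Checks run in that order and the first failure is reported, so
classification reasons are auditable. TA proteins matter here as the main
benign source of hydrophobic C-tails.

**Aggregation.** From per-residue cross-beta pairing energies and
probabilities (PASTA-style), the aggregation fraction is the share of
residues with energy < −5 and probability > 0.01. It is a count, hence
order-invariant — but the upstream energies themselves are not
composition-determined, which is why original and shuffled sequences can
differ.

## The shuffle null

The neutral expectation for every determinant is built by uniform
within-sequence permutation of residues (Fisher–Yates), preserving length
and composition exactly. Under this null, anchored and positional
features (degrons, motif placement, tail tilt) are randomized while
composition-driven effects survive, so original-vs-shuffled differences
isolate positional selection. One shuffled counterpart per sequence is
the default, matching the single-control design of the comparisons this
package implements; `n_reps` raises it for variance estimation. Paired
analyses use the Wilcoxon signed-rank test (continuous) and McNemar's
test on discordant pairs (binary). Reproducibility is handled by child
seeds: each record's shuffle seed is a hash of the master seed and the
record ordinal (iterated Lehmer steps modulo 2³¹−1, exact in double
arithmetic), so results do not depend on evaluation order and any record
can be re-derived in isolation.

## Statistics

Group comparisons follow the conventions of the studies this pipeline
supports: Wilcoxon rank-sum with the rank-biserial correlation
`r = 1 − 2U/(n₁n₂)` as the primary effect size (the `z/√N` variant is
reported alongside because a widely used implementation computes that
instead; the two differ under ties), Fisher's exact test with the
conditional-MLE odds ratio (plus the sample `ad/bc` ratio, 0.5-corrected
when a cell is empty), Wilson score intervals with continuity correction
for proportions, Spearman correlation for length-confound checks, and an
exact conditional-binomial Poisson rate test for motif counts with
sequence length as exposure — a deliberate simplification of a Poisson
regression to the two-group case, which is the only case the pipeline
compares. Exact/approximate switchovers are fixed constants (rank-sum:
exact below a combined n of 50 without ties; signed-rank: 25; McNemar:
25) so that p-values are reproducible with bounded runtime.
Benjamini–Hochberg adjustment is applied within one report — one
`compare_profiles()` or `null_compare()` call is one adjustment family,
and the report records that definition, since the appropriate family is
otherwise ambiguous.

## Dataset hygiene

Filters mirror standard practice: sequences shorter than 60 residues or
containing residues outside the 20-letter alphabet (selenocysteine `U`,
ambiguity codes `B/J/O/X/Z`, stray `*`) are removed — scales are
undefined for them, and editing them silently would corrupt provenance.
Redundancy collapses keep the longest isoform per identical terminal
k-mer (30-mer at the C-end before CTTH; 10-mer at the matching terminus
before degron and IDR analyses; none before KFERQ counting), with length
ties broken by input order for determinism. Full-sequence duplicate
removal uses exact equality; substring containment is not implemented.
Every filter appends an in/out record to the dataset's provenance log,
and the per-determinant analyzable counts that `profile_dataset()`
reports reconcile with those logs.

## The synthetic generator

`synthetic_spec()` describes a study arm: i.i.d. residues from a base
composition (default: approximate human-proteome frequencies), log-normal
lengths floored at 60, and planting probabilities for each determinant.
The i.i.d. model is chosen deliberately: it is the model under which the
shuffle null is exact, so null-calibration tests are clean. The
C-terminal tilt resamples the last 30 residues from an exponentially
tilted composition `p_i ∝ p_i·exp(θ·kd_i)`, with θ solved so the expected
tail mean exceeds the base mean by `tail_kd_shift`; the generator's
empirical tail mean is verified to land within 0.05 of the target at
n ≥ 1000. Planting order is tilt → TA block → anchored degrons → KFERQ
pentapeptides; later plants never overwrite an earlier planted window
(KFERQ positions are drawn uniformly from the feasible set, and an empty
feasible set is an error rather than a silent skip). Terminal IDRs are
planted in the companion disorder profiles; TA architectures get a
matching topology string. Surrogate disorder (smoothed TOP-IDP
propensities) and surrogate aggregation (hydrophobic-run heuristic) are
labelled test stand-ins — they emulate file formats and gross propensity,
not any real predictor's output.

The default two-group study fixes the conditions used throughout the
tests: a CP-like arm (median length ≈ 350, N-/C-degron prevalences
0.33/0.084, no tilt) versus an NCP-like arm (median ≈ 90, prevalences
0.44/0.168, tilt +0.15). These values reproduce the prevalence contrasts
and tail-hydrophobicity shift reported for human canonical-versus-
noncanonical comparisons; the implied true C-degron odds ratio is
(0.168/0.832)/(0.084/0.916) ≈ 2.20, and a +0.15 tail shift lands the
rank-biserial effect near 0.15 — the regime of the effect sizes those
studies report. The expected-effect table records effects implied by the
planting probabilities alone; anchored background matches from
composition add a small upward bias to prevalences (≤ ~0.005 with the
bundled 3-residue motifs), which is negligible against the sampling CI at
n = 5000 per arm.

What passing tests on this generator do **not** show: real proteomes have
dipeptide structure, compositional covariates (length–composition
correlations, signal peptides), and predictor-specific disorder and
aggregation landscapes that i.i.d. sequences and surrogates cannot
emulate. The generator validates the *machinery* — scanners, filters,
null, statistics — not biological effect sizes.

## Numerical choices and scales of the tests

Test and acceptance problem sizes are chosen so the full suite exercises
every guarantee at meaningful resolution: 500-sequence oracle sweeps for
both scanners, 10,000 shuffles per sequence for the null-calibration
check (3-standard-error band), complete enumeration of all 2×2 tables and
discordant splits with total n ≤ 10, 1,000 null replicates for the
type-I-error band \[0.03, 0.07\] at α = 0.05, and 20 replicated
5,000-per-arm studies for CI coverage (≥ 17/20) and effect-size recovery.
`scripts/acceptance.R` re-derives the headline quantities from scratch at
any seed.

## Known limitations

* Disorder, topology and aggregation inputs are consumed, not predicted;
  conclusions inherit the upstream predictor's biases.
* Degron matching is literal; position-specific scoring matrices or
  character-class motifs are out of scope.
* The MANE-style "identical to a longer sequence" collapse is implemented
  as exact equality, not substring containment.
* KFERQ surface exposure is not modelled; a matched motif buried in a
  folded core is not a functional CMA signal.
* The Poisson rate test conditions on totals and does not adjust for
  covariates the way a regression would.
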