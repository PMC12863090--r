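#' Default planted degron motif sets
#'
#' Small ΔPSI-annotated motif sets used by the synthetic generator and
#' bundled as fixture tables. These are synthetic stand-ins for curated
#' experimental degron lists: 3-residue motifs with assigned ΔPSI values
#' below the −0.4 retention cutoff, not measured degrons.
#'
#' @return A [degron_set()].
#' @export
default_n_degron_motifs <- function() {
  degron_set(c("DEG", "EED", "NKD", "DDW", "EEV"),
             c(-0.90, -0.85, -0.80, -0.75, -0.70),
             terminus = "N", filter_threshold = -0.4)
}

#' @rdname default_n_degron_motifs
#' @export
default_c_degron_motifs <- function() {
  degron_set(c("EGG", "RGG", "GGD", "VGG", "EEN"),
             c(-0.95, -0.88, -0.82, -0.74, -0.66),
             terminus = "C", filter_threshold = -0.4)
}

#' Specification of a synthetic protein dataset
#'
#' Describes one simulated sequence set: i.i.d. residues from a base
#' composition, log-normal lengths floored at 60 residues (the minimum
#' analyzable length), an optional hydrophobicity tilt of the C-terminal
#' tail, and planting probabilities for anchored terminal degrons,
#' KFERQ-like motifs, tail-anchored architectures, and terminal IDRs.
#'
#' @param n_sequences Number of sequences.
#' @param length_meanlog,length_sdlog Log-normal length parameters.
#' @param length_floor Minimum length (default 60).
#' @param composition Named base composition over the 20 residues,
#'   summing to 1 (default [human_aa_composition()]).
#' @param tail_kd_shift Target elevation of the mean Kyte-Doolittle value
#'   of the last `tail_window` residues over the base-composition mean
#'   (dimensionless; achieved by exponential tilting of the composition).
#' @param tail_window Tail length subject to the tilt (default 30).
#' @param p_n_degron,p_c_degron Per-sequence probabilities of planting an
#'   anchored N-/C-end degron drawn from the motif sets.
#' @param n_degron_motifs,c_degron_motifs [degron_set()]s to plant from
#'   (defaults [default_n_degron_motifs()] / [default_c_degron_motifs()]).
#' @param p_kferq Named per-class planting probabilities
#'   (`canonical`, `phospho_activated`, `acetyl_activated`).
#' @param p_ta Probability of a tail-anchored architecture (one 18–25
#'   residue hydrophobic block with a C-tail of at most 29 residues).
#' @param p_idr_n,p_idr_c Probabilities of planting a terminal IDR
#'   (disorder-score run of at least 30 residues above 0.5) at each
#'   terminus in the companion disorder profile.
#' @param seed Seed for all randomness of the dataset.
#' @param name Dataset name.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_sequences,
                           length_meanlog = log(120), length_sdlog = 0.5,
                           length_floor = 60,
                           composition = human_aa_composition(),
                           tail_kd_shift = 0, tail_window = 30,
                           p_n_degron = 0, p_c_degron = 0,
                           n_degron_motifs = default_n_degron_motifs(),
                           c_degron_motifs = default_c_degron_motifs(),
                           p_kferq = c(canonical = 0, phospho_activated = 0,
                                       acetyl_activated = 0),
                           p_ta = 0, p_idr_n = 0, p_idr_c = 0,
                           seed = 1, name = "synthetic") {
  n_sequences <- assert_count(n_sequences, "n_sequences")
  length_floor <- assert_count(length_floor, "length_floor", min = 60)
  if (!is.numeric(composition) || length(composition) != 20L ||
      !setequal(names(composition), amino_acids())) {
    stop("composition must be a named vector over the 20 standard residues",
         call. = FALSE)
  }
  if (abs(sum(composition) - 1) > 1e-9) {
    stop("composition must sum to 1 (within 1e-9)", call. = FALSE)
  }
  if (any(composition < 0)) stop("composition probabilities must be >= 0", call. = FALSE)
  probs <- c(p_n_degron, p_c_degron, p_ta, p_idr_n, p_idr_c)
  kf <- c(canonical = 0, phospho_activated = 0, acetyl_activated = 0)
  kf[names(p_kferq)] <- p_kferq
  if (any(c(probs, kf) < 0 | c(probs, kf) > 1)) {
    stop("planting probabilities must lie in [0, 1]", call. = FALSE)
  }
  kd <- kyte_doolittle()[names(composition)]
  base_mean <- sum(composition * kd)
  target <- base_mean + tail_kd_shift
  if (target <= min(kd[composition > 0]) || target >= max(kd[composition > 0])) {
    stop("infeasible tail_kd_shift: target tail mean ", signif(target, 3),
         " outside the achievable hydropathy range", call. = FALSE)
  }
  structure(list(n_sequences = n_sequences,
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 length_floor = length_floor, composition = composition,
                 tail_kd_shift = tail_kd_shift, tail_window = tail_window,
                 p_n_degron = p_n_degron, p_c_degron = p_c_degron,
                 n_degron_motifs = n_degron_motifs,
                 c_degron_motifs = c_degron_motifs,
                 p_kferq = kf, p_ta = p_ta,
                 p_idr_n = p_idr_n, p_idr_c = p_idr_c,
                 seed = as.integer(seed), name = name),
            class = "synthetic_spec")
}

# Exponentially tilt a composition so its mean KD value hits `target`.
tilt_composition <- function(composition, target, kd = kyte_doolittle()) {
  kd <- kd[names(composition)]
  f <- function(theta) {
    w <- composition * exp(theta * kd)
    sum(w * kd) / sum(w) - target
  }
  theta <- stats::uniroot(f, c(-20, 20), tol = 1e-12)$root
  w <- composition * exp(theta * kd)
  w / sum(w)
}

kferq_exemplars <- list(
  canonical = c("KFERQ", "QKILD", "QRIVE", "IKLDQ"),
  phospho_activated = c("KFSRQ", "QKILT", "QRIVS", "IKLTQ"),
  acetyl_activated = c("KKILD", "IKLDK", "KRIVE", "KFERK"))

overlaps_any <- function(start, end, reserved) {
  if (nrow(reserved) == 0) return(FALSE)
  any(start <= reserved$end & end >= reserved$start)
}

#' Generate a synthetic protein dataset with planted determinants
#'
#' Draws i.i.d. sequences from the spec's base composition, applies the
#' C-terminal hydrophobicity tilt, then plants (in this order, never
#' overwriting an earlier planted window) tail-anchored hydrophobic
#' blocks, anchored terminal degrons, and KFERQ-like pentapeptides; a
#' KFERQ position overlapping a reserved window is redrawn (up to 100
#' attempts, then an error). Terminal IDRs are planted in the companion
#' disorder profiles. All randomness derives from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param companions Also build companion disorder / topology /
#'   aggregation objects (default `TRUE`; disable for large
#'   sequence-only simulations).
#' @return A list: `dataset` (a [protein_dataset()]), `truth` (tibble of
#'   per-sequence ground truth), `companions` (list with `disorder`,
#'   `topology_strings`, `aggregation`, or `NULL`), and `spec`.
#' @export
generate_dataset <- function(spec, companions = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  aa <- names(spec$composition)
  kd <- kyte_doolittle()[aa]
  with_seed(spec$seed, {
    n <- spec$n_sequences
    L <- pmax(spec$length_floor,
              as.integer(round(stats::rlnorm(n, spec$length_meanlog, spec$length_sdlog))))
    chars <- sample(aa, sum(L), replace = TRUE, prob = spec$composition)
    seqs <- split(chars, rep.int(seq_len(n), L))
    reserved <- rep(list(tibble::tibble(start = integer(), end = integer())), n)

    # 1. tail tilt
    if (spec$tail_kd_shift != 0) {
      tilted <- tilt_composition(spec$composition,
                                 sum(spec$composition * kd) + spec$tail_kd_shift)
      w <- spec$tail_window
      tail_chars <- sample(aa, n * w, replace = TRUE, prob = tilted)
      for (i in seq_len(n)) {
        seqs[[i]][(L[i] - w + 1L):L[i]] <- tail_chars[((i - 1L) * w + 1L):(i * w)]
      }
    }

    # 2. tail-anchored architecture
    ta <- stats::runif(n) < spec$p_ta
    tmd_start <- rep(NA_integer_, n); tmd_end <- rep(NA_integer_, n)
    for (i in which(ta)) {
      tmd_len <- sample(18:25, 1)
      tail_len <- sample(6:29, 1)
      e <- L[i] - tail_len
      s <- e - tmd_len + 1L
      seqs[[i]][s:e] <- sample(c("I", "L", "V", "F", "A"), tmd_len, replace = TRUE,
                               prob = c(0.3, 0.3, 0.2, 0.1, 0.1))
      tmd_start[i] <- s; tmd_end[i] <- e
      reserved[[i]] <- rbind(reserved[[i]], tibble::tibble(start = s, end = e))
    }

    # 3. anchored degrons
    plant_n <- stats::runif(n) < spec$p_n_degron
    plant_c <- stats::runif(n) < spec$p_c_degron
    n_motif <- rep(NA_character_, n); c_motif <- rep(NA_character_, n)
    if (any(plant_n) && length(spec$n_degron_motifs) == 0) {
      stop("p_n_degron > 0 but no N-degron motifs in spec", call. = FALSE)
    }
    if (any(plant_c) && length(spec$c_degron_motifs) == 0) {
      stop("p_c_degron > 0 but no C-degron motifs in spec", call. = FALSE)
    }
    for (i in which(plant_n)) {
      mo <- sample(spec$n_degron_motifs$motifs$motif, 1)
      a <- if (seqs[[i]][1] == "M") 2L else 1L
      idx <- a:(a + nchar(mo) - 1L)
      seqs[[i]][idx] <- seq_chars(mo)
      n_motif[i] <- mo
      reserved[[i]] <- rbind(reserved[[i]], tibble::tibble(start = 1L, end = max(idx)))
    }
    for (i in which(plant_c)) {
      mo <- sample(spec$c_degron_motifs$motifs$motif, 1)
      idx <- (L[i] - nchar(mo) + 1L):L[i]
      seqs[[i]][idx] <- seq_chars(mo)
      c_motif[i] <- mo
      reserved[[i]] <- rbind(reserved[[i]], tibble::tibble(start = min(idx), end = L[i]))
    }

    # 4. KFERQ-like pentapeptides at uniform interior positions clear of
    # every reserved window (drawn directly from the feasible set, which is
    # the limit of redraw-until-clear; an empty feasible set is a spec error)
    kf_flag <- matrix(FALSE, nrow = n, ncol = 3,
                      dimnames = list(NULL, kferq_classes))
    for (cl in kferq_classes) {
      p <- spec$p_kferq[[cl]]
      if (p <= 0) next
      for (i in which(stats::runif(n) < p)) {
        cand <- 2:(L[i] - 4L)
        ok <- vapply(cand, function(s) !overlaps_any(s, s + 4L, reserved[[i]]),
                     logical(1))
        if (!any(ok)) {
          stop("no feasible KFERQ position left in sequence ", i,
               ": spec plants more windows than the sequence can hold",
               call. = FALSE)
        }
        feas <- cand[ok]
        s <- if (length(feas) == 1L) feas else sample(feas, 1L)
        seqs[[i]][s:(s + 4L)] <- seq_chars(sample(kferq_exemplars[[cl]], 1))
        reserved[[i]] <- rbind(reserved[[i]],
                               tibble::tibble(start = s, end = s + 4L))
        kf_flag[i, cl] <- TRUE
      }
    }

    # 5. terminal IDRs live in the companion disorder profiles
    idr_n <- stats::runif(n) < spec$p_idr_n
    idr_c <- stats::runif(n) < spec$p_idr_c
    idr_n_len <- ifelse(idr_n, sample(30:45, n, replace = TRUE), 0L)
    idr_c_len <- ifelse(idr_c, sample(30:45, n, replace = TRUE), 0L)

    ids <- sprintf("%s_%05d", spec$name, seq_len(n))
    sequences <- vapply(seqs, paste, character(1), collapse = "")
    ds <- protein_dataset(tibble::tibble(id = ids, sequence = sequences),
                          name = spec$name)

    comp <- NULL
    if (companions) {
      topo <- vapply(seq_len(n), function(i) {
        if (ta[i]) {
          paste0(strrep("i", tmd_start[i] - 1L),
                 strrep("M", tmd_end[i] - tmd_start[i] + 1L),
                 strrep("o", L[i] - tmd_end[i]))
        } else strrep("i", L[i])
      }, character(1))
      names(topo) <- ids
      disorder <- vector("list", n)
      for (i in seq_len(n)) {
        prof <- surrogate_disorder(sequences[i], sequence_id = ids[i])
        if (idr_n[i]) {
          prof$scores[seq_len(idr_n_len[i])] <- stats::runif(idr_n_len[i], 0.6, 0.95)
        }
        if (idr_c[i]) {
          prof$scores[(L[i] - idr_c_len[i] + 1L):L[i]] <-
            stats::runif(idr_c_len[i], 0.6, 0.95)
        }
        disorder[[i]] <- prof
      }
      names(disorder) <- ids
      aggregation <- lapply(seq_len(n), function(i)
        surrogate_aggregation(sequences[i], sequence_id = ids[i]))
      names(aggregation) <- ids
      comp <- list(disorder = disorder, topology_strings = topo,
                   aggregation = aggregation)
    }

    truth <- tibble::tibble(
      id = ids, length = L,
      ta_planted = ta, tmd_start = tmd_start, tmd_end = tmd_end,
      n_degron_planted = !is.na(n_motif), n_degron_motif = n_motif,
      c_degron_planted = !is.na(c_motif), c_degron_motif = c_motif,
      kferq_canonical_planted = kf_flag[, "canonical"],
      kferq_phospho_planted = kf_flag[, "phospho_activated"],
      kferq_acetyl_planted = kf_flag[, "acetyl_activated"],
      idr_n_planted = idr_n, idr_n_len = as.integer(idr_n_len),
      idr_c_planted = idr_c, idr_c_len = as.integer(idr_c_len),
      tail_kd_shift = rep(spec$tail_kd_shift, n))

    list(dataset = ds, truth = truth, companions = comp, spec = spec)
  })
}

#' Default CP-like and NCP-like study specifications
#'
#' The default two-group study conditions: a canonical-protein-like group
#' (longer sequences, N-/C-end degron prevalences 0.33 / 0.084, no tail
#' tilt) and a noncanonical-protein-like group (shorter sequences,
#' prevalences 0.44 / 0.168, C-terminal tail hydropathy elevated by
#' +0.15), matching the prevalence contrasts and tail-hydrophobicity
#' shift reported for human canonical-vs-noncanonical comparisons.
#'
#' @param n Sequences per group (default 5000).
#' @param seed Seed.
#' @return A [synthetic_spec()].
#' @export
default_cp_spec <- function(n = 5000, seed = 1) {
  synthetic_spec(n_sequences = n, length_meanlog = log(350), length_sdlog = 0.6,
                 p_n_degron = 0.33, p_c_degron = 0.084, tail_kd_shift = 0,
                 seed = seed, name = "CP_like")
}

#' @rdname default_cp_spec
#' @export
default_ncp_spec <- function(n = 5000, seed = 2) {
  synthetic_spec(n_sequences = n, length_meanlog = log(90), length_sdlog = 0.5,
                 p_n_degron = 0.44, p_c_degron = 0.168, tail_kd_shift = 0.15,
                 seed = seed, name = "NCP_like")
}

#' Generate a paired CP-like / NCP-like study
#'
#' Generates the two groups and the expected-effect table implied by
#' their specs (true odds ratios from the planting probabilities, true
#' mean CTTH difference from the tail tilts), for parameter-recovery
#' testing.
#'
#' @param cp_spec,ncp_spec [synthetic_spec()]s (defaults
#'   [default_cp_spec()] / [default_ncp_spec()]).
#' @param seed Master seed; group seeds are derived from it and override
#'   the specs' own seeds.
#' @param companions Build companion score objects (default `FALSE`).
#' @return List: `cp`, `ncp` (each as returned by [generate_dataset()])
#'   and `expected_effects` (tibble: `feature`, `cp_value`, `ncp_value`,
#'   `true_effect`, `effect_name`).
#' @export
generate_two_group_study <- function(cp_spec = default_cp_spec(),
                                     ncp_spec = default_ncp_spec(),
                                     seed = 1, companions = FALSE) {
  stopifnot(inherits(cp_spec, "synthetic_spec"), inherits(ncp_spec, "synthetic_spec"))
  cp_spec$seed <- child_seed(seed, 1)
  ncp_spec$seed <- child_seed(seed, 2)
  cp <- generate_dataset(cp_spec, companions = companions)
  ncp <- generate_dataset(ncp_spec, companions = companions)
  odds <- function(p) p / (1 - p)
  expected <- tibble::tibble(
    feature = c("c_degron_present", "n_degron_present", "ctth"),
    cp_value = c(cp_spec$p_c_degron, cp_spec$p_n_degron, cp_spec$tail_kd_shift),
    ncp_value = c(ncp_spec$p_c_degron, ncp_spec$p_n_degron, ncp_spec$tail_kd_shift),
    true_effect = c(odds(ncp_spec$p_c_degron) / odds(cp_spec$p_c_degron),
                    odds(ncp_spec$p_n_degron) / odds(cp_spec$p_n_degron),
                    ncp_spec$tail_kd_shift - cp_spec$tail_kd_shift),
    effect_name = c("odds_ratio", "odds_ratio", "mean_difference"))
  list(cp = cp, ncp = ncp, expected_effects = expected)
}
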