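#' Pipeline configuration
#'
#' Flat key-value configuration shared by the profiling and comparison
#' steps. Defaults are the standard analysis parameters: 30-residue
#' C-terminal tail, terminal 10-mer redundancy collapse for degron and
#' IDR analyses, 30-residue C-terminal 30-mer collapse for CTTH, IDR
#' call at score > 0.5 over runs of at least 30 residues, tail-anchor
#' limits of 29 residues for TMD and tail, canonical CTTH quartiles
#' −0.963 / −0.110, aggregation cutoffs −5 / 0.01, and a cytoplasmic
#' localization threshold of 0.5.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `degsig_config`.
#' @export
degsig_config <- function(...) {
  cfg <- list(
    tail_window = 30, ctth_collapse_k = 30, degron_collapse_k = 10,
    idr_collapse_k = 10, idr_min_len = 30, idr_threshold = 0.5,
    tmd_max = 29, tail_max = 29,
    low_q = -0.963, high_q = -0.110,
    rest_hydrophilic = -1.0, rest_hydrophobic = 0.0,
    agg_energy_max = -5, agg_prob_min = 0.01,
    localization_threshold = 0.5)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "degsig_config")
}

check_companion_ids <- function(ids, companion, what) {
  missing <- setdiff(ids, names(companion))
  if (length(missing) > 0) {
    stop("no ", what, " profile for record(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) paste0(" (and ", length(missing) - 5, " more)"),
         call. = FALSE)
  }
}

retained_ids <- function(ds, terminus, k) {
  suppressWarnings(collapse_terminal_redundancy(ds, terminus, k))$records$id
}

#' Profile degradation determinants across a dataset
#'
#' Computes the per-sequence determinant profile, applying the
#' determinant-specific redundancy collapses before each analysis:
#' C-terminal 30-mer uniqueness for CTTH and the stability-pattern call,
#' terminal 10-mer uniqueness (at the matching terminus) for degron and
#' terminal-IDR analyses, and no collapse for KFERQ-like motifs, TA
#' classification, or aggregation. Sequences removed by a collapse get
#' `NA` for that determinant only. Determinants whose inputs (degron
#' tables, disorder / topology / aggregation profiles) were not supplied
#' are `NA` throughout, never silently defaulted.
#'
#' @param ds A [protein_dataset()] (typically already passed through
#'   [filter_minimal()]).
#' @param n_degrons,c_degrons Optional [degron_set()]s.
#' @param disorder Optional named list of `disorder_profile`s covering
#'   every record id.
#' @param topology Optional named list of `topology_annotation`s
#'   covering every record id.
#' @param aggregation Optional named list of `aggregation_profile`s
#'   covering every record id.
#' @param config A [degsig_config()].
#' @return A tibble with one row per record and attribute
#'   `analyzable_counts` giving per-determinant analyzable set sizes.
#' @export
profile_dataset <- function(ds, n_degrons = NULL, c_degrons = NULL,
                            disorder = NULL, topology = NULL,
                            aggregation = NULL, config = degsig_config()) {
  stopifnot(inherits(ds, "protein_dataset"), inherits(config, "degsig_config"))
  if (nrow(ds$records) == 0) stop("empty dataset", call. = FALSE)
  ids <- ds$records$id
  seqs <- ds$records$sequence
  len <- nchar(seqs)
  n <- length(ids)
  counts <- list()

  # CTTH and stability pattern on the C-terminal-30-mer-unique subset
  hyd <- dataset_hydropathy(ds, window = config$tail_window)
  ctth_ids <- retained_ids(ds, "C", config$ctth_collapse_k)
  ctth_ok <- ids %in% ctth_ids & !is.na(hyd$ctth) & !is.na(hyd$rest_gravy)
  counts$ctth <- sum(ctth_ok)
  ctth_v <- ifelse(ctth_ok, hyd$ctth, NA_real_)
  rest_v <- ifelse(ctth_ok, hyd$rest_gravy, NA_real_)

  has_cterm_tmd <- rep(FALSE, n)
  ta_like <- rep(NA, n)
  if (!is.null(topology)) {
    check_companion_ids(ids, topology, "topology")
    for (i in seq_len(n)) {
      topo <- topology[[ids[i]]]
      if (topo$length != len[i]) {
        stop("topology length mismatch for '", ids[i], "'", call. = FALSE)
      }
      ta_like[i] <- classify_ta(topo, len[i], config$tmd_max, config$tail_max)$is_ta_like
      has_cterm_tmd[i] <- nrow(topo$tmd_intervals) > 0 &&
        max(topo$tmd_intervals$end) >= len[i] - config$tail_max
    }
    counts$ta <- n
  }
  pattern <- rep(NA_character_, n)
  for (i in which(ctth_ok)) {
    pattern[i] <- classify_stability_pattern(
      ctth_v[i], rest_v[i], has_cterm_tmd[i],
      low_q = config$low_q, high_q = config$high_q,
      rest_hydrophilic = config$rest_hydrophilic,
      rest_hydrophobic = config$rest_hydrophobic)$pattern
  }

  # anchored degrons on terminal-10-mer-unique subsets
  n_pres <- rep(NA, n); c_pres <- rep(NA, n)
  if (!is.null(n_degrons) || !is.null(c_degrons)) {
    hits <- scan_degrons_dataset(ds, n_set = n_degrons, c_set = c_degrons)
    if (!is.null(n_degrons)) {
      keep <- ids %in% retained_ids(ds, "N", config$degron_collapse_k)
      n_pres[keep] <- hits$n_degron_present[keep]
      counts$n_degron <- sum(keep)
    }
    if (!is.null(c_degrons)) {
      keep <- ids %in% retained_ids(ds, "C", config$degron_collapse_k)
      c_pres[keep] <- hits$c_degron_present[keep]
      counts$c_degron <- sum(keep)
    }
  }

  # terminal IDRs on terminal-unique subsets
  n_idr <- rep(NA, n); c_idr <- rep(NA, n)
  if (!is.null(disorder)) {
    check_companion_ids(ids, disorder, "disorder")
    keep_n <- ids %in% retained_ids(ds, "N", config$idr_collapse_k)
    keep_c <- ids %in% retained_ids(ds, "C", config$idr_collapse_k)
    for (i in seq_len(n)) {
      prof <- disorder[[ids[i]]]
      if (length(prof$scores) != len[i]) {
        stop("disorder profile length mismatch for '", ids[i], "'", call. = FALSE)
      }
      call <- call_terminal_idrs(prof, config$idr_min_len, config$idr_threshold)
      if (keep_n[i]) n_idr[i] <- call$n_idr
      if (keep_c[i]) c_idr[i] <- call$c_idr
    }
    counts$idr_n <- sum(keep_n)
    counts$idr_c <- sum(keep_c)
  }

  # KFERQ: every sequence
  kf <- dataset_kferq_rates(ds)$per_sequence
  counts$kferq <- n

  agg <- rep(NA_real_, n)
  if (!is.null(aggregation)) {
    check_companion_ids(ids, aggregation, "aggregation")
    for (i in seq_len(n)) {
      pr <- aggregation[[ids[i]]]
      agg[i] <- aggregation_fraction(pr$energies, pr$probabilities, len[i],
                                     config$agg_energy_max, config$agg_prob_min)
    }
    counts$aggregation <- n
  }

  out <- tibble::tibble(
    id = ids, length = len,
    ctth = ctth_v, rest_gravy = rest_v, stability_pattern = pattern,
    n_degron_present = n_pres, c_degron_present = c_pres,
    n_idr = n_idr, c_idr = c_idr, both_termini_idr = n_idr & c_idr,
    kferq_canonical_n = kf$canonical_n, kferq_phospho_n = kf$phospho_n,
    kferq_acetyl_n = kf$acetyl_n, kferq_total_n = kf$total_n,
    kferq_density = kf$density_total, kferq_has_any = kf$has_any,
    ta_like = ta_like, aggregation_fraction = agg)
  attr(out, "analyzable_counts") <- counts
  attr(out, "dataset") <- ds$name
  out
}

profile_columns <- function() {
  list(continuous = c("ctth", "rest_gravy", "kferq_density", "aggregation_fraction"),
       binary = c("n_degron_present", "c_degron_present", "n_idr", "c_idr",
                  "both_termini_idr", "kferq_has_any", "ta_like"))
}

#' Compare two determinant profiles
#'
#' Group comparison of every shared determinant between two profile
#' tables: continuous determinants by the Wilcoxon rank-sum test with
#' the rank-biserial correlation, binary determinants by Fisher's exact
#' test with the odds ratio and per-group Wilson proportion CIs.
#' P-values are Benjamini-Hochberg adjusted within the returned report
#' (the report is the adjustment family). Determinants absent or all-`NA`
#' in either profile are skipped with a message.
#'
#' @param profile_a,profile_b Tibbles from [profile_dataset()].
#' @param label_a,label_b Group labels for the report.
#' @return A tibble of class `comparison_report`: one row per
#'   determinant with `test`, `n1`, `n2`, `statistic`, `p_raw`, `p_bh`,
#'   `effect_name`, `effect_value`, `ci_low`, `ci_high`.
#' @export
compare_profiles <- function(profile_a, profile_b,
                             label_a = "A", label_b = "B") {
  cols <- profile_columns()
  rows <- list()
  for (col in cols$continuous) {
    x <- profile_a[[col]]; y <- profile_b[[col]]
    if (is.null(x) || is.null(y) || all(is.na(x)) || all(is.na(y))) {
      message("determinant '", col, "' skipped: missing in one profile")
      next
    }
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    cmp <- tryCatch(rank_sum_test(x, y), error = function(e) e)
    if (inherits(cmp, "error")) {
      message("determinant '", col, "' skipped: ", conditionMessage(cmp))
      next
    }
    rows[[col]] <- tibble::tibble(
      determinant = col, test = "rank_sum",
      n1 = length(x), n2 = length(y),
      statistic = cmp$statistic, p_raw = cmp$p_raw,
      effect_name = "rank_biserial", effect_value = cmp$effect$rank_biserial,
      ci_low = NA_real_, ci_high = NA_real_,
      prop1 = NA_real_, prop2 = NA_real_)
  }
  for (col in cols$binary) {
    x <- profile_a[[col]]; y <- profile_b[[col]]
    if (is.null(x) || is.null(y) || all(is.na(x)) || all(is.na(y))) {
      message("determinant '", col, "' skipped: missing in one profile")
      next
    }
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    m <- matrix(c(sum(x), length(x) - sum(x), sum(y), length(y) - sum(y)),
                nrow = 2, byrow = TRUE)
    cmp <- tryCatch(fisher_exact(m), error = function(e) e)
    if (inherits(cmp, "error")) {
      message("determinant '", col, "' skipped: ", conditionMessage(cmp))
      next
    }
    rows[[col]] <- tibble::tibble(
      determinant = col, test = "fisher_exact",
      n1 = length(x), n2 = length(y),
      statistic = cmp$statistic, p_raw = cmp$p_raw,
      effect_name = "odds_ratio", effect_value = cmp$effect$odds_ratio,
      ci_low = cmp$ci$low, ci_high = cmp$ci$high,
      prop1 = mean(x), prop2 = mean(y))
  }
  if (length(rows) == 0) stop("no comparable determinants", call. = FALSE)
  rep_tbl <- do.call(rbind, rows)
  rep_tbl$p_bh <- bh_adjust(rep_tbl$p_raw)
  rep_tbl <- rep_tbl[, c("determinant", "test", "n1", "n2", "statistic",
                         "p_raw", "p_bh", "effect_name", "effect_value",
                         "ci_low", "ci_high", "prop1", "prop2")]
  attr(rep_tbl, "groups") <- c(label_a, label_b)
  attr(rep_tbl, "adjustment_family") <- "all determinants in this report (BH)"
  class(rep_tbl) <- c("comparison_report", class(rep_tbl))
  rep_tbl
}

#' Original-versus-shuffled paired comparison
#'
#' Profiles the sequence-derived determinants (CTTH, rest-of-protein
#' hydropathy, anchored degrons, KFERQ-like motifs) of each record and of
#' one composition-preserving shuffle of it, then applies the paired
#' tests: Wilcoxon signed-rank for continuous determinants, McNemar for
#' binary ones. Shuffled values are computed for exactly the records
#' analyzable in the original profile (the redundancy collapses are not
#' re-run on shuffled sequences). Degenerate determinants (all paired
#' differences zero, or no discordant pairs) are reported with `NA`
#' p-values and a note rather than a spurious test.
#'
#' @param ds A [protein_dataset()].
#' @param n_degrons,c_degrons Optional [degron_set()]s.
#' @param seed Master seed for the shuffles.
#' @param config A [degsig_config()].
#' @return A tibble of class `comparison_report` with columns as in
#'   [compare_profiles()] plus `note`.
#' @export
null_compare <- function(ds, n_degrons = NULL, c_degrons = NULL, seed = 1,
                         config = degsig_config()) {
  stopifnot(inherits(ds, "protein_dataset"))
  seed <- assert_count(seed, "seed", min = 0)
  prof <- profile_dataset(ds, n_degrons = n_degrons, c_degrons = c_degrons,
                          config = config)
  shuf_seqs <- vapply(seq_len(nrow(ds$records)), function(i) {
    shuffle_sequence(ds$records$sequence[i], child_seed(seed, i))$shuffled_sequence
  }, character(1))
  sh_ds <- protein_dataset(tibble::tibble(id = ds$records$id, sequence = shuf_seqs),
                           name = paste0(ds$name, "_shuffled"))
  sh_hyd <- dataset_hydropathy(sh_ds, window = config$tail_window)
  sh_kf <- dataset_kferq_rates(sh_ds)$per_sequence
  sh_deg <- if (!is.null(n_degrons) || !is.null(c_degrons)) {
    scan_degrons_dataset(sh_ds, n_set = n_degrons, c_set = c_degrons)
  } else NULL

  rows <- list()
  cont <- list(ctth = list(o = prof$ctth, s = sh_hyd$ctth),
               rest_gravy = list(o = prof$rest_gravy, s = sh_hyd$rest_gravy),
               kferq_density = list(o = prof$kferq_density, s = sh_kf$density_total))
  for (col in names(cont)) {
    o <- cont[[col]]$o; s <- cont[[col]]$s
    ok <- !is.na(o) & !is.na(s)
    if (sum(ok) == 0) next
    d <- o[ok] - s[ok]
    cmp <- tryCatch(signed_rank_test(d), error = function(e) e)
    if (inherits(cmp, "error")) {
      rows[[col]] <- tibble::tibble(
        determinant = col, test = "signed_rank", n1 = sum(ok), n2 = NA_integer_,
        statistic = NA_real_, p_raw = NA_real_, effect_name = "rank_biserial",
        effect_value = NA_real_, note = conditionMessage(cmp))
      next
    }
    rows[[col]] <- tibble::tibble(
      determinant = col, test = "signed_rank", n1 = cmp$n1, n2 = NA_integer_,
      statistic = cmp$statistic, p_raw = cmp$p_raw,
      effect_name = "rank_biserial", effect_value = cmp$effect$rank_biserial,
      note = "")
  }
  bin <- list()
  if (!is.null(sh_deg)) {
    if (!is.null(n_degrons)) {
      bin$n_degron_present <- list(o = prof$n_degron_present,
                                   s = sh_deg$n_degron_present)
    }
    if (!is.null(c_degrons)) {
      bin$c_degron_present <- list(o = prof$c_degron_present,
                                   s = sh_deg$c_degron_present)
    }
  }
  bin$kferq_has_any <- list(o = prof$kferq_has_any, s = sh_kf$has_any)
  for (col in names(bin)) {
    o <- bin[[col]]$o; s <- bin[[col]]$s
    ok <- !is.na(o) & !is.na(s)
    if (sum(ok) == 0) next
    b <- sum(o[ok] & !s[ok]); cc <- sum(!o[ok] & s[ok])
    cmp <- tryCatch(mcnemar_test(b, cc), error = function(e) e)
    if (inherits(cmp, "error")) {
      rows[[col]] <- tibble::tibble(
        determinant = col, test = "mcnemar", n1 = sum(ok), n2 = NA_integer_,
        statistic = NA_real_, p_raw = NA_real_, effect_name = "paired_odds_ratio",
        effect_value = NA_real_, note = conditionMessage(cmp))
      next
    }
    rows[[col]] <- tibble::tibble(
      determinant = col, test = "mcnemar", n1 = b + cc, n2 = NA_integer_,
      statistic = cmp$statistic, p_raw = cmp$p_raw,
      effect_name = "paired_odds_ratio",
      effect_value = cmp$effect$paired_odds_ratio, note = "")
  }
  rep_tbl <- do.call(rbind, rows)
  rep_tbl$p_bh <- bh_adjust(rep_tbl$p_raw)
  attr(rep_tbl, "seed") <- seed
  attr(rep_tbl, "adjustment_family") <- "all determinants in this report (BH)"
  class(rep_tbl) <- c("comparison_report", class(rep_tbl))
  rep_tbl
}

#' Summarize lncRNA subcellular localization
#'
#' Computes per-transcript localization from compartment expression: the
#' cytoplasmic ratio `cyt / (cyt + nuc)` and the relative concentration
#' index `RCI = log2(cyt / nuc)` (finite only when both compartments are
#' positive). Alternatively accepts precomputed `ratio` or `rci` columns
#' (`value_type`); the column semantics are never guessed. Duplicate
#' transcript rows are averaged (arithmetic mean of the per-row values).
#' Transcripts are cross-tabulated by translation evidence against
#' cytoplasmic localization (`cytoplasmic_ratio > threshold`, or
#' `rci > 0` when only RCI is available) and tested with Fisher's exact
#' test; when a `ctth` column is present, CTTH of cytoplasmic versus
#' non-cytoplasmic translated transcripts is compared by rank-sum.
#'
#' @param tbl Data frame with `transcript_id`, `translated` (logical),
#'   and either `cyt` + `nuc`, or `ratio`, or `rci`; optionally `ctth`.
#' @param threshold Cytoplasmic-ratio threshold (default 0.5, strict).
#' @param value_type `"fpkm"`, `"ratio"` or `"rci"`.
#' @return List: `records` (tibble with `transcript_id`,
#'   `cytoplasmic_ratio`, `rci`, `cytoplasmic`, `translated`),
#'   `localization_test` (`group_comparison`), and `ctth_test`
#'   (or `NULL`).
#' @export
localization_summary <- function(tbl, threshold = 0.5,
                                 value_type = c("fpkm", "ratio", "rci")) {
  value_type <- match.arg(value_type)
  tbl <- tibble::as_tibble(tbl)
  if (!all(c("transcript_id", "translated") %in% names(tbl))) {
    stop("table must have columns 'transcript_id' and 'translated'", call. = FALSE)
  }
  if (value_type == "fpkm") {
    if (!all(c("cyt", "nuc") %in% names(tbl))) {
      stop("value_type 'fpkm' needs columns 'cyt' and 'nuc'", call. = FALSE)
    }
    if (any(tbl$cyt < 0 | tbl$nuc < 0)) stop("negative expression value", call. = FALSE)
    ratio <- ifelse(tbl$cyt + tbl$nuc > 0, tbl$cyt / (tbl$cyt + tbl$nuc), NA_real_)
    rci <- ifelse(tbl$cyt > 0 & tbl$nuc > 0, log2(tbl$cyt / tbl$nuc), NA_real_)
  } else if (value_type == "ratio") {
    if (!"ratio" %in% names(tbl)) stop("missing 'ratio' column", call. = FALSE)
    if (any(tbl$ratio < 0 | tbl$ratio > 1, na.rm = TRUE)) {
      stop("cytoplasmic ratio out of [0, 1]", call. = FALSE)
    }
    ratio <- tbl$ratio
    rci <- NA_real_
  } else {
    if (!"rci" %in% names(tbl)) stop("missing 'rci' column", call. = FALSE)
    ratio <- NA_real_
    rci <- tbl$rci
  }
  work <- tibble::tibble(transcript_id = tbl$transcript_id,
                         ratio = ratio, rci = rci,
                         translated = as.logical(tbl$translated),
                         ctth = if ("ctth" %in% names(tbl)) tbl$ctth else NA_real_)
  agg <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  split_idx <- split(seq_len(nrow(work)), work$transcript_id)
  # duplicate transcripts: per-row values averaged
  records <- tibble::tibble(
    transcript_id = names(split_idx),
    cytoplasmic_ratio = unname(vapply(split_idx, function(i) agg(work$ratio[i]),
                                      numeric(1))),
    rci = unname(vapply(split_idx, function(i) agg(work$rci[i]), numeric(1))),
    translated = unname(vapply(split_idx, function(i) any(work$translated[i]),
                               logical(1))),
    ctth = unname(vapply(split_idx, function(i) agg(work$ctth[i]), numeric(1))))
  records$cytoplasmic <- if (value_type == "rci") records$rci > 0 else
    records$cytoplasmic_ratio > threshold
  ok <- !is.na(records$cytoplasmic) & !is.na(records$translated)
  m <- matrix(c(sum(records$cytoplasmic[ok] & records$translated[ok]),
                sum(!records$cytoplasmic[ok] & records$translated[ok]),
                sum(records$cytoplasmic[ok] & !records$translated[ok]),
                sum(!records$cytoplasmic[ok] & !records$translated[ok])),
              nrow = 2, byrow = TRUE)
  loc_test <- tryCatch(fisher_exact(m), error = function(e) NULL)
  ctth_test <- NULL
  tr <- records[records$translated & !is.na(records$ctth) & !is.na(records$cytoplasmic), ]
  if (nrow(tr) > 1 && length(unique(tr$cytoplasmic)) == 2) {
    ctth_test <- tryCatch(
      rank_sum_test(tr$ctth[tr$cytoplasmic], tr$ctth[!tr$cytoplasmic]),
      error = function(e) NULL)
  }
  list(records = records, localization_test = loc_test, ctth_test = ctth_test)
}

#' Write a synthetic study bundle to disk
#'
#' Generates a dataset from a [synthetic_spec()] and writes the bundle:
#' `sequences.fasta`, `truth.tsv`, `topology.txt`, per-sequence
#' `disorder/` and `aggregation/` files, and `spec.json`, plus a
#' `manifest.json` listing every output with its MD5 hash. Files are
#' staged in a temporary directory and moved into place only on success,
#' so a failed run leaves no partial bundle.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created; must not already contain a
#'   bundle).
#' @param seed Optional seed overriding `spec$seed`.
#' @return Path to `manifest.json`, invisibly.
#' @export
simulate_study <- function(spec, out_dir, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) spec$seed <- assert_count(seed, "seed", min = 0)
  gen <- generate_dataset(spec, companions = TRUE)
  stage <- file.path(tempfile("degsig_bundle_"))
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  write_fasta(gen$dataset, file.path(stage, "sequences.fasta"))
  utils::write.table(gen$truth, file.path(stage, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_topology_file(gen$companions$topology_strings, file.path(stage, "topology.txt"))
  dir.create(file.path(stage, "disorder"))
  for (id in names(gen$companions$disorder)) {
    write_disorder_file(gen$companions$disorder[[id]],
                        file.path(stage, "disorder", paste0(id, ".txt")))
  }
  dir.create(file.path(stage, "aggregation"))
  for (id in names(gen$companions$aggregation)) {
    write_aggregation_file(gen$companions$aggregation[[id]],
                           file.path(stage, "aggregation", paste0(id, ".tsv")))
  }
  spec_out <- gen$spec
  spec_out$n_degron_motifs <- as.list(spec_out$n_degron_motifs$motifs)
  spec_out$c_degron_motifs <- as.list(spec_out$c_degron_motifs$motifs)
  jsonlite::write_json(unclass(spec_out), file.path(stage, "spec.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  entries <- c("sequences.fasta", "truth.tsv", "topology.txt",
               "disorder", "aggregation", "spec.json")
  manifest <- lapply(entries, function(p) {
    full <- file.path(stage, p)
    if (dir.exists(full)) {
      files <- sort(list.files(full, full.names = TRUE))
      # directory digest: md5 of the concatenated per-file md5s
      tmp <- tempfile()
      writeLines(paste(unname(tools::md5sum(files)), collapse = ""), tmp)
      on.exit(unlink(tmp), add = TRUE)
      list(path = p, n_files = length(files), md5 = unname(tools::md5sum(tmp)))
    } else {
      list(path = p, n_files = 1L, md5 = unname(tools::md5sum(full)))
    }
  })
  jsonlite::write_json(list(dataset = spec$name, seed = spec$seed,
                            files = manifest),
                       file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (p in c(entries, "manifest.json")) {
    target <- file.path(out_dir, p)
    if (file.exists(target)) unlink(target, recursive = TRUE)
    ok <- file.rename(file.path(stage, p), target)
    if (!ok) { # cross-device fallback
      if (dir.exists(file.path(stage, p))) {
        dir.create(target, showWarnings = FALSE)
        file.copy(list.files(file.path(stage, p), full.names = TRUE), target)
      } else {
        file.copy(file.path(stage, p), target)
      }
    }
  }
  invisible(file.path(out_dir, "manifest.json"))
}

#' Write a comparison report as TSV
#'
#' @param report A `comparison_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
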