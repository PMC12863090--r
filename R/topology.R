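#' Build a topology annotation from a per-residue topology string
#'
#' The string uses one letter per residue: `i` (inside), `o` (outside),
#' `M` (membrane), `S` (signal peptide), the residue-level encoding used
#' by consensus topology predictors. Maximal runs of `M` become
#' transmembrane-domain (TMD) intervals; any `S` sets the signal-peptide
#' flag.
#'
#' @param topo_string Per-residue topology string.
#' @param sequence_id Identifier.
#' @return List of class `topology_annotation`: `sequence_id`, `length`,
#'   `has_signal_peptide`, `tmd_intervals` (tibble `start`, `end`).
#' @export
topology_annotation <- function(topo_string, sequence_id = "seq") {
  assert_string(topo_string, "topology string")
  ch <- seq_chars(topo_string)
  bad <- setdiff(unique(ch), c("i", "o", "M", "S"))
  if (length(bad) > 0) {
    stop("unknown topology letter '", bad[1], "' (allowed: i o M S)", call. = FALSE)
  }
  r <- rle(ch == "M")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tmd <- tibble::tibble(start = starts[r$values], end = ends[r$values])
  structure(list(sequence_id = sequence_id, length = length(ch),
                 has_signal_peptide = any(ch == "S"), tmd_intervals = tmd),
            class = "topology_annotation")
}

#' Parse a topology file
#'
#' FASTA-like file: `>` headers followed by per-residue topology strings
#' over the alphabet `{i, o, M, S}` (possibly wrapped over several
#' lines).
#'
#' @param path Path to the topology file.
#' @return Named list of `topology_annotation` objects, keyed by id.
#' @export
parse_topology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0 || !startsWith(lines[1], ">")) {
    stop("malformed topology file: expected '>' header first", call. = FALSE)
  }
  hdr <- startsWith(lines, ">")
  grp <- cumsum(hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  out <- vector("list", length(ids))
  names(out) <- ids
  for (g in seq_along(ids)) {
    body <- paste(lines[grp == g & !hdr], collapse = "")
    if (!nzchar(body)) stop("empty topology for '", ids[g], "'", call. = FALSE)
    out[[g]] <- topology_annotation(body, sequence_id = ids[g])
  }
  out
}

#' Classify a tail-anchored (TA) protein architecture
#'
#' A TA-like protein has no signal peptide, exactly one TMD of at most
#' `tmd_max` residues, and a C-terminal tail after the TMD of at most
#' `tail_max` residues — the architecture that inserts the C-terminus
#' into a membrane post-translationally, shielding an otherwise
#' hydrophobic tail from the degradation machinery. Checks are applied
#' in order and the first failure is reported.
#'
#' @param topo A `topology_annotation`.
#' @param seq_length Protein length in residues (defaults to the
#'   annotation length).
#' @param tmd_max Maximum TMD length (default 29).
#' @param tail_max Maximum C-tail length after the TMD (default 29).
#' @return List: `is_ta_like`, `reason` (one of `ok`, `signal_peptide`,
#'   `zero_tmds`, `multiple_tmds`, `tmd_too_long`, `tail_too_long`).
#' @export
classify_ta <- function(topo, seq_length = NULL, tmd_max = 29, tail_max = 29) {
  stopifnot(inherits(topo, "topology_annotation"))
  if (is.null(seq_length)) seq_length <- topo$length
  seq_length <- assert_count(seq_length, "seq_length")
  n_tmd <- nrow(topo$tmd_intervals)
  reason <- if (topo$has_signal_peptide) "signal_peptide"
  else if (n_tmd == 0L) "zero_tmds"
  else if (n_tmd > 1L) "multiple_tmds"
  else if (topo$tmd_intervals$end[1] - topo$tmd_intervals$start[1] + 1L > tmd_max) "tmd_too_long"
  else if (seq_length - topo$tmd_intervals$end[1] > tail_max) "tail_too_long"
  else "ok"
  list(is_ta_like = reason == "ok", reason = reason)
}

#' Aggregation fraction from per-residue pairing energies
#'
#' The fraction of residues predicted to participate in cross-beta
#' aggregation: residues with pairing free energy strictly below
#' `energy_max` (default −5, in predictor energy units) and pairing
#' probability strictly above `prob_min` (default 0.01), divided by the
#' protein length.
#'
#' @param energies Numeric vector, one free energy per residue.
#' @param probabilities Numeric vector, one probability per residue.
#' @param seq_length Protein length; must equal both vector lengths.
#' @param energy_max Free-energy cutoff (default −5).
#' @param prob_min Probability cutoff (default 0.01).
#' @return Fraction in \[0, 1\].
#' @export
aggregation_fraction <- function(energies, probabilities, seq_length,
                                 energy_max = -5, prob_min = 0.01) {
  seq_length <- assert_count(seq_length, "seq_length")
  if (length(energies) != seq_length || length(probabilities) != seq_length) {
    stop("energies and probabilities must have one value per residue (",
         seq_length, ")", call. = FALSE)
  }
  sum(energies < energy_max & probabilities > prob_min) / seq_length
}

#' Parse a per-residue aggregation table
#'
#' TSV with header columns `position`, `energy`, `probability`.
#'
#' @param path Path to the table.
#' @param sequence_id Identifier (default: file name without extension).
#' @return List of class `aggregation_profile`: `sequence_id`,
#'   `energies`, `probabilities`.
#' @export
parse_aggregation_file <- function(path, sequence_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t")
  if (!all(c("position", "energy", "probability") %in% names(tab))) {
    stop("aggregation table must have columns position, energy, probability",
         call. = FALSE)
  }
  if (!identical(as.integer(tab$position), seq_len(nrow(tab)))) {
    stop("aggregation positions must be consecutive from 1", call. = FALSE)
  }
  if (is.null(sequence_id)) sequence_id <- sub("\\.[^.]*$", "", basename(path))
  structure(list(sequence_id = sequence_id,
                 energies = as.numeric(tab$energy),
                 probabilities = as.numeric(tab$probability)),
            class = "aggregation_profile")
}

#' Surrogate per-residue aggregation profile
#'
#' Deterministic stand-in for an external cross-beta aggregation
#' predictor, for testing and simulation only: residues inside runs of
#' five or more aggregation-prone residues (F/I/L/V/W/Y) are given free
#' energy −6 and pairing probability 0.02 (qualifying under the default
#' cutoffs); all other residues get energy −1 and probability 0.001.
#' This is **not** a reproduction of PASTA or of any pairing-energy
#' model.
#'
#' @param seq Amino-acid string.
#' @param sequence_id Identifier.
#' @return An `aggregation_profile`.
#' @export
surrogate_aggregation <- function(seq, sequence_id = "seq") {
  assert_string(seq)
  ch <- seq_chars(seq)
  prone <- ch %in% c("F", "I", "L", "V", "W", "Y")
  r <- rle(prone)
  hot <- inverse.rle(list(lengths = r$lengths, values = r$values & r$lengths >= 5L))
  structure(list(sequence_id = sequence_id,
                 energies = ifelse(hot, -6, -1),
                 probabilities = ifelse(hot, 0.02, 0.001)),
            class = "aggregation_profile")
}

#' Write an aggregation profile as TSV
#'
#' @param profile An `aggregation_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aggregation_file <- function(profile, path) {
  stopifnot(inherits(profile, "aggregation_profile"))
  utils::write.table(
    data.frame(position = seq_along(profile$energies),
               energy = profile$energies,
               probability = profile$probabilities),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write topology annotations as a FASTA-like topology file
#'
#' @param topo_strings Named character vector of per-residue topology
#'   strings, keyed by sequence id.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology_file <- function(topo_strings, path) {
  stopifnot(is.character(topo_strings), !is.null(names(topo_strings)))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(topo_strings)) {
    writeLines(c(paste0(">", id), topo_strings[[id]]), con)
  }
  invisible(path)
}
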