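#' Construct a degron motif set
#'
#' A set of terminal degron motifs annotated with the differential
#' protein stability index (ΔPSI): the mean stability difference between
#' polypeptides carrying the motif at the terminus and polypeptides
#' carrying it internally. More negative ΔPSI means a stronger
#' (destabilizing) degron.
#'
#' @param motifs Character vector of amino-acid motifs (length >= 1 each).
#' @param dpsi Numeric ΔPSI per motif.
#' @param terminus `"N"` or `"C"`.
#' @param source_id Optional character vector of source identifiers.
#' @param filter_threshold ΔPSI cutoff already applied to this set
#'   (`NA` if unfiltered).
#' @return An object of class `degron_set`.
#' @export
degron_set <- function(motifs, dpsi, terminus = c("N", "C"),
                       source_id = NULL, filter_threshold = NA_real_) {
  terminus <- match.arg(terminus)
  motifs <- as.character(motifs)
  dpsi <- as.numeric(dpsi)
  if (length(motifs) != length(dpsi)) stop("motifs and dpsi lengths differ", call. = FALSE)
  if (length(motifs) > 0) {
    if (any(!nzchar(motifs))) stop("empty motif", call. = FALSE)
    bad <- !grepl(paste0("^[", paste(amino_acids(), collapse = ""), "]+$"), motifs)
    if (any(bad)) stop("motif '", motifs[bad][1], "' contains nonstandard residues",
                       call. = FALSE)
    if (any(!is.finite(dpsi))) stop("dpsi must be finite", call. = FALSE)
    if (anyDuplicated(motifs)) stop("duplicate motif in degron set", call. = FALSE)
  }
  structure(list(terminus = terminus,
                 motifs = tibble::tibble(
                   motif = motifs, dpsi = dpsi,
                   source_id = if (is.null(source_id)) rep(NA_character_, length(motifs))
                               else as.character(source_id)),
                 filter_threshold = filter_threshold),
            class = "degron_set")
}

#' @export
print.degron_set <- function(x, ...) {
  cat("<degron_set> ", nrow(x$motifs), " ", x$terminus, "-end motif(s)",
      if (!is.na(x$filter_threshold)) paste0(", dPSI <= ", x$filter_threshold),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.degron_set <- function(x) nrow(x$motifs)

#' Load a ΔPSI-annotated degron table
#'
#' Reads a tab-delimited motif table with header columns `motif` and
#' `dpsi` (optionally `source_id`), keeps motifs with
#' `dpsi <= dpsi_max` (default −0.4, the threshold retaining likely
#' functional degrons), and collapses duplicate motifs keeping the most
#' negative ΔPSI.
#'
#' @param path Path to a TSV file.
#' @param terminus `"N"` or `"C"`.
#' @param dpsi_max ΔPSI retention cutoff (default −0.4).
#' @return A [degron_set()].
#' @export
load_degron_table <- function(path, terminus = c("N", "C"), dpsi_max = -0.4) {
  terminus <- match.arg(terminus)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (!all(c("motif", "dpsi") %in% names(tab))) {
    stop("degron table must have columns 'motif' and 'dpsi'", call. = FALSE)
  }
  dpsi <- suppressWarnings(as.numeric(tab$dpsi))
  if (nrow(tab) > 0 && anyNA(dpsi)) {
    stop("non-numeric dpsi value '", tab$dpsi[is.na(dpsi)][1], "'", call. = FALSE)
  }
  keep <- if (nrow(tab) == 0) logical(0) else dpsi <= dpsi_max
  tab <- tab[keep, , drop = FALSE]
  dpsi <- dpsi[keep]
  if (nrow(tab) > 0) {
    # duplicates collapse to the most negative dpsi
    ord <- order(tab$motif, dpsi)
    tab <- tab[ord, , drop = FALSE]
    dpsi <- dpsi[ord]
    first <- !duplicated(tab$motif)
    tab <- tab[first, , drop = FALSE]
    dpsi <- dpsi[first]
  }
  message(nrow(tab), " ", terminus, "-end degron(s) retained at dPSI <= ", dpsi_max)
  degron_set(tab$motif, dpsi, terminus,
             source_id = if ("source_id" %in% names(tab)) tab$source_id else NULL,
             filter_threshold = dpsi_max)
}

#' Keep the k most destabilizing degrons
#'
#' @param set A [degron_set()].
#' @param k Number of motifs to keep (default 20); ties at the cut are
#'   broken by motif lexicographic order.
#' @return A [degron_set()] with at most `k` motifs.
#' @export
top_k_by_dpsi <- function(set, k = 20) {
  stopifnot(inherits(set, "degron_set"))
  k <- assert_count(k, "k")
  m <- set$motifs
  ord <- order(m$dpsi, m$motif)
  set$motifs <- m[ord[seq_len(min(k, nrow(m)))], , drop = FALSE]
  set
}

# Anchored N-terminal start position: after the initiator methionine when
# the sequence begins with 'M', else position 1.
n_anchor_start <- function(seq) {
  if (startsWith(seq, "M")) 2L else 1L
}

#' Scan a sequence for anchored N-end degrons
#'
#' A motif of length m matches iff it equals the sequence prefix starting
#' immediately after the initiator methionine (position 2) when the
#' sequence begins with `M`, or at position 1 otherwise (non-AUG
#' isoforms). At most one hit per motif.
#'
#' @param seq Amino-acid string.
#' @param set A [degron_set()] with `terminus == "N"`.
#' @return Tibble of hits: `motif`, `start`, `end`, `terminus`, `dpsi`.
#' @export
scan_n_degrons <- function(seq, set) {
  stopifnot(inherits(set, "degron_set"))
  if (set$terminus != "N") stop("degron set terminus must be 'N'", call. = FALSE)
  assert_string(seq)
  start <- n_anchor_start(seq)
  m <- set$motifs
  if (nrow(m) == 0) return(empty_degron_hits("N"))
  hit <- substring(seq, start, start + nchar(m$motif) - 1L) == m$motif
  tibble::tibble(motif = m$motif[hit],
                 start = rep(start, sum(hit)),
                 end = start + nchar(m$motif[hit]) - 1L,
                 terminus = rep("N", sum(hit)),
                 dpsi = m$dpsi[hit])
}

#' Scan a sequence for anchored C-end degrons
#'
#' A motif of length m matches iff it equals the final m residues of the
#' sequence.
#'
#' @param seq Amino-acid string.
#' @param set A [degron_set()] with `terminus == "C"`.
#' @return Tibble of hits: `motif`, `start`, `end`, `terminus`, `dpsi`.
#' @export
scan_c_degrons <- function(seq, set) {
  stopifnot(inherits(set, "degron_set"))
  if (set$terminus != "C") stop("degron set terminus must be 'C'", call. = FALSE)
  assert_string(seq)
  m <- set$motifs
  if (nrow(m) == 0) return(empty_degron_hits("C"))
  L <- nchar(seq)
  hit <- substring(seq, L - nchar(m$motif) + 1L, L) == m$motif & nchar(m$motif) <= L
  tibble::tibble(motif = m$motif[hit],
                 start = L - nchar(m$motif[hit]) + 1L,
                 end = rep(L, sum(hit)),
                 terminus = rep("C", sum(hit)),
                 dpsi = m$dpsi[hit])
}

empty_degron_hits <- function(terminus) {
  tibble::tibble(motif = character(), start = integer(), end = integer(),
                 terminus = character(), dpsi = numeric())
}

#' Degron presence over a dataset
#'
#' Scans every record for anchored N-end and/or C-end degrons and returns
#' per-sequence presence flags and the matched motifs.
#'
#' @param ds A [protein_dataset()].
#' @param n_set Optional N-end [degron_set()].
#' @param c_set Optional C-end [degron_set()].
#' @return Tibble: `id`, `n_degron_present`, `c_degron_present`,
#'   `motifs_matched` (comma-separated). Flags are `NA` when the
#'   corresponding set was not supplied.
#' @export
scan_degrons_dataset <- function(ds, n_set = NULL, c_set = NULL) {
  stopifnot(inherits(ds, "protein_dataset"))
  seqs <- ds$records$sequence
  L <- nchar(seqs)
  n_pres <- rep(NA, length(seqs))
  c_pres <- rep(NA, length(seqs))
  matched <- vector("list", length(seqs))
  if (!is.null(n_set)) {
    stopifnot(inherits(n_set, "degron_set"), n_set$terminus == "N")
    n_pres <- rep(FALSE, length(seqs))
    starts <- ifelse(startsWith(seqs, "M"), 2L, 1L)
    for (i in seq_len(nrow(n_set$motifs))) {
      mo <- n_set$motifs$motif[i]
      hit <- substring(seqs, starts, starts + nchar(mo) - 1L) == mo
      n_pres <- n_pres | hit
      matched[hit] <- lapply(matched[hit], c, paste0("N:", mo))
    }
  }
  if (!is.null(c_set)) {
    stopifnot(inherits(c_set, "degron_set"), c_set$terminus == "C")
    c_pres <- rep(FALSE, length(seqs))
    for (i in seq_len(nrow(c_set$motifs))) {
      mo <- c_set$motifs$motif[i]
      hit <- nchar(mo) <= L & substring(seqs, L - nchar(mo) + 1L, L) == mo
      c_pres <- c_pres | hit
      matched[hit] <- lapply(matched[hit], c, paste0("C:", mo))
    }
  }
  tibble::tibble(
    id = ds$records$id,
    n_degron_present = n_pres,
    c_degron_present = c_pres,
    motifs_matched = vapply(matched, function(x) paste(x, collapse = ","), character(1)))
}
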