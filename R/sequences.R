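#' Construct a protein dataset
#'
#' A `protein_dataset` bundles an ordered set of protein records with a
#' name and a provenance log: one entry per filter applied, recording the
#' filter name, its parameters, and the record counts before and after.
#'
#' @param records A data frame with columns `id`, `sequence`, and
#'   optionally `dataset_label`, `start_class` (one of `"AUG"`,
#'   `"nonAUG"`, `"unknown"`) and `desc`.
#' @param name Dataset name.
#' @param provenance List of provenance entries (normally left empty and
#'   grown by the filter functions).
#' @return An object of class `protein_dataset`.
#' @export
protein_dataset <- function(records, name = "dataset", provenance = list()) {
  records <- tibble::as_tibble(records)
  if (!all(c("id", "sequence") %in% names(records))) {
    stop("records must have columns 'id' and 'sequence'", call. = FALSE)
  }
  if (nrow(records) > 0 && anyDuplicated(records$id)) {
    dup <- records$id[duplicated(records$id)][1]
    stop("duplicate record id: '", dup, "'", call. = FALSE)
  }
  if (nrow(records) > 0 && any(!nzchar(records$sequence))) {
    stop("empty sequence in record '",
         records$id[!nzchar(records$sequence)][1], "'", call. = FALSE)
  }
  if (!"dataset_label" %in% names(records)) records$dataset_label <- name
  if (!"start_class" %in% names(records)) {
    records$start_class <- ifelse(startsWith(records$sequence, "M"), "AUG", "nonAUG")
  }
  if (!all(records$start_class %in% c("AUG", "nonAUG", "unknown"))) {
    stop("start_class must be one of 'AUG', 'nonAUG', 'unknown'", call. = FALSE)
  }
  if (!"desc" %in% names(records)) records$desc <- ""
  structure(list(name = name, records = records, provenance = provenance),
            class = "protein_dataset")
}

#' @export
print.protein_dataset <- function(x, ...) {
  cat("<protein_dataset> '", x$name, "': ", nrow(x$records), " records, ",
      length(x$provenance), " filter step(s)\n", sep = "")
  invisible(x)
}

#' @export
length.protein_dataset <- function(x) nrow(x$records)

append_provenance <- function(ds, name, params, n_in, n_out) {
  ds$provenance[[length(ds$provenance) + 1L]] <-
    list(name = name, params = params,
         records_in = as.integer(n_in), records_out = as.integer(n_out))
  ds
}

#' Provenance of a protein dataset
#'
#' @param ds A `protein_dataset`.
#' @return A tibble with one row per filter step: `step`, `name`,
#'   `records_in`, `records_out`, `removed`.
#' @export
provenance <- function(ds) {
  stopifnot(inherits(ds, "protein_dataset"))
  if (length(ds$provenance) == 0) {
    return(tibble::tibble(step = integer(), name = character(),
                          records_in = integer(), records_out = integer(),
                          removed = integer()))
  }
  tibble::tibble(
    step = seq_along(ds$provenance),
    name = vapply(ds$provenance, `[[`, character(1), "name"),
    records_in = vapply(ds$provenance, `[[`, integer(1), "records_in"),
    records_out = vapply(ds$provenance, `[[`, integer(1), "records_out"),
    removed = vapply(ds$provenance, function(p) p$records_in - p$records_out, integer(1))
  )
}

#' Write provenance as JSON
#'
#' @param ds A `protein_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_provenance_json <- function(ds, path) {
  stopifnot(inherits(ds, "protein_dataset"))
  jsonlite::write_json(
    list(dataset = ds$name, n_records = nrow(ds$records), steps = ds$provenance),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a protein FASTA file
#'
#' Reads a multi-FASTA of amino-acid sequences. Sequences are uppercased
#' and trailing `*` stop characters are stripped (end only); the record id
#' is the first whitespace-delimited token of the header and the remainder
#' of the header is kept as `desc`. Duplicate ids and empty sequences are
#' rejected. Residues are otherwise left untouched: records with
#' nonstandard letters are removed later by [filter_minimal()], never
#' silently edited.
#'
#' @param path Path to a FASTA file.
#' @param name Dataset name (defaults to the file name without extension).
#' @return A [protein_dataset()].
#' @export
read_fasta <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0) stop("malformed FASTA (empty file): ", path, call. = FALSE)
  first <- nonblank[1]
  if (!startsWith(lines[first], ">")) {
    stop("malformed FASTA at line ", first, ": expected '>' header", call. = FALSE)
  }
  bad_header <- nonblank[startsWith(lines[nonblank], ">") &
                           !nzchar(trimws(substring(lines[nonblank], 2)))]
  if (length(bad_header) > 0) {
    stop("malformed FASTA at line ", bad_header[1], ": empty header", call. = FALSE)
  }
  aas <- Biostrings::readBStringSet(path)
  headers <- names(aas)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), trimws(sub("^\\S+\\s+", "", headers)), "")
  seqs <- toupper(as.character(aas))
  seqs <- sub("\\*+$", "", seqs)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: '", ids[duplicated(ids)][1], "'", call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for FASTA entry '", ids[!nzchar(seqs)][1], "'", call. = FALSE)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  protein_dataset(
    tibble::tibble(id = unname(ids), sequence = unname(seqs), desc = unname(descs)),
    name = name)
}

#' Write a protein dataset to FASTA
#'
#' Sequences are wrapped at 60 columns, so a written file re-read with
#' [read_fasta()] and written again is byte-identical.
#'
#' @param ds A `protein_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ds, path) {
  stopifnot(inherits(ds, "protein_dataset"))
  x <- Biostrings::BStringSet(ds$records$sequence)
  names(x) <- ifelse(nzchar(ds$records$desc),
                     paste(ds$records$id, ds$records$desc),
                     ds$records$id)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Remove short sequences and sequences with forbidden residues
#'
#' Applies the minimal dataset filter used before any determinant
#' analysis: sequences shorter than `min_len` residues (default 60, the
#' minimum at which a 30-residue C-terminal tail can be compared with a
#' 30-residue remainder) or containing any forbidden residue are removed.
#' The default forbidden set is selenocysteine `U` plus the ambiguity and
#' nonstandard codes `B J O X Z` and `*`, for which hydropathy and
#' downstream scales are undefined.
#'
#' @param ds A `protein_dataset`.
#' @param min_len Minimum retained length (default 60).
#' @param forbidden Character vector of forbidden residue letters.
#' @return The filtered `protein_dataset`, with a provenance entry.
#' @export
filter_minimal <- function(ds, min_len = 60, forbidden = c("U", "B", "J", "O", "X", "Z", "*")) {
  stopifnot(inherits(ds, "protein_dataset"))
  min_len <- assert_count(min_len, "min_len")
  n_in <- nrow(ds$records)
  keep <- rep(TRUE, n_in)
  if (n_in > 0) {
    keep <- nchar(ds$records$sequence) >= min_len
    if (length(forbidden) > 0) {
      pat <- paste0("[", paste(gsub("([*\\]\\[^-])", "\\\\\\1", forbidden), collapse = ""), "]")
      keep <- keep & !grepl(pat, ds$records$sequence)
    }
    # anything outside the 20-letter alphabet is also rejected
    keep <- keep & grepl(paste0("^[", paste(amino_acids(), collapse = ""), "]*$"),
                         ds$records$sequence)
  }
  ds$records <- ds$records[keep, , drop = FALSE]
  append_provenance(ds, "filter_minimal",
                    list(min_len = min_len, forbidden = forbidden),
                    n_in, nrow(ds$records))
}

#' Collapse fully identical sequences
#'
#' Keeps exactly one record per distinct full-length sequence; the first
#' record in input order wins.
#'
#' @param ds A `protein_dataset`.
#' @return The collapsed `protein_dataset`, with a provenance entry.
#' @export
collapse_identical <- function(ds) {
  stopifnot(inherits(ds, "protein_dataset"))
  n_in <- nrow(ds$records)
  keep <- !duplicated(ds$records$sequence)
  ds$records <- ds$records[keep, , drop = FALSE]
  append_provenance(ds, "collapse_identical", list(), n_in, nrow(ds$records))
}

#' Collapse terminal redundancy
#'
#' Among records sharing an identical k-mer at the chosen terminus, only
#' the longest is kept (length ties broken by input order), mirroring the
#' "keep the longest isoform" convention for terminal-redundancy removal.
#' Records shorter than `k` cannot participate in the k-mer contract and
#' are dropped with a warning.
#'
#' @param ds A `protein_dataset`.
#' @param terminus `"N"` or `"C"`.
#' @param k Terminal k-mer length (e.g. 30 for C-terminal-tail analyses,
#'   10 for degron analyses).
#' @return The collapsed `protein_dataset`, with a provenance entry.
#' @export
collapse_terminal_redundancy <- function(ds, terminus = c("N", "C"), k) {
  stopifnot(inherits(ds, "protein_dataset"))
  terminus <- match.arg(terminus)
  k <- assert_count(k, "k")
  n_in <- nrow(ds$records)
  if (n_in == 0) {
    return(append_provenance(ds, "collapse_terminal_redundancy",
                             list(terminus = terminus, k = k), 0L, 0L))
  }
  len <- nchar(ds$records$sequence)
  too_short <- len < k
  if (any(too_short)) {
    warning(sum(too_short), " record(s) shorter than k = ", k, " dropped", call. = FALSE)
  }
  rec <- ds$records[!too_short, , drop = FALSE]
  len <- len[!too_short]
  kmer <- if (terminus == "N") {
    substr(rec$sequence, 1L, k)
  } else {
    substring(rec$sequence, len - k + 1L, len)
  }
  # longest per k-mer, ties to earliest input position
  ord <- order(kmer, -len, seq_len(nrow(rec)))
  keep_sorted <- !duplicated(kmer[ord])
  keep_idx <- sort(ord[keep_sorted])
  ds$records <- rec[keep_idx, , drop = FALSE]
  append_provenance(ds, "collapse_terminal_redundancy",
                    list(terminus = terminus, k = k), n_in, nrow(ds$records))
}
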