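#' Hydropathy value of a single residue
#'
#' @param residue One standard amino-acid letter.
#' @param scale Named hydropathy scale (default [kyte_doolittle()]).
#' @return The scale value (dimensionless).
#' @examples
#' kd_value("A") # 1.8
#' @export
kd_value <- function(residue, scale = kyte_doolittle()) {
  validate_scale(scale)
  assert_string(residue, "residue")
  if (nchar(residue) != 1L || !(residue %in% names(scale))) {
    stop("unknown residue '", residue, "': not in the hydropathy scale", call. = FALSE)
  }
  unname(scale[[residue]])
}

# Mean hydropathy of a residue character vector; stops on unknown letters.
mean_kd <- function(chars, scale) {
  v <- scale[chars]
  if (anyNA(v)) {
    stop("unknown residue '", chars[is.na(v)][1], "': not in the hydropathy scale",
         call. = FALSE)
  }
  mean(v)
}

#' C-terminal tail hydrophobicity (CTTH)
#'
#' Arithmetic mean Kyte-Doolittle hydropathy of the last `window`
#' residues of a protein (terminal residue included). Elevated CTTH is a
#' proteasomal degradation determinant.
#'
#' @param seq Amino-acid string over the 20 standard residues.
#' @param window Tail window in residues (default 30).
#' @param scale Hydropathy scale.
#' @return A single dimensionless hydropathy value.
#' @examples
#' ctth(strrep("I", 60)) # 4.5
#' @export
ctth <- function(seq, window = 30, scale = kyte_doolittle()) {
  assert_string(seq)
  window <- assert_count(window, "window")
  validate_scale(scale)
  n <- nchar(seq)
  if (n < window) {
    stop("sequence length (", n, ") shorter than tail window (", window, ")",
         call. = FALSE)
  }
  mean_kd(seq_chars(substring(seq, n - window + 1L, n)), scale)
}

#' Mean hydropathy of the sequence excluding the tail
#'
#' GRAVY-style mean Kyte-Doolittle hydropathy over positions
#' `1 .. length - window`, i.e. the protein minus its C-terminal tail.
#'
#' @inheritParams ctth
#' @return A single dimensionless hydropathy value.
#' @export
rest_gravy <- function(seq, window = 30, scale = kyte_doolittle()) {
  assert_string(seq)
  window <- assert_count(window, "window")
  validate_scale(scale)
  n <- nchar(seq)
  if (n <= window) {
    stop("sequence length (", n, ") must exceed tail window (", window,
         ") to leave a rest", call. = FALSE)
  }
  mean_kd(seq_chars(substr(seq, 1L, n - window)), scale)
}

#' Positional hydropathy profile of the terminal tail
#'
#' Per-position mean Kyte-Doolittle hydropathy over the last `last_n`
#' residues of every sufficiently long record, aligned at the C-terminus.
#' Offsets run from `-last_n` (most internal) to `-1` (terminal residue).
#'
#' @param ds A [protein_dataset()].
#' @param last_n Number of terminal positions (default 60).
#' @param scale Hydropathy scale.
#' @return A tibble with columns `offset`, `mean_kd`, `n`. Records shorter
#'   than `last_n` are skipped; their count is reported in a message.
#' @export
tail_profile <- function(ds, last_n = 60, scale = kyte_doolittle()) {
  stopifnot(inherits(ds, "protein_dataset"))
  last_n <- assert_count(last_n, "last_n")
  validate_scale(scale)
  seqs <- ds$records$sequence
  long_enough <- nchar(seqs) >= last_n
  if (sum(long_enough) == 0) {
    stop("no record is at least ", last_n, " residues long; profile undefined",
         call. = FALSE)
  }
  n_skip <- sum(!long_enough)
  if (n_skip > 0) message(n_skip, " record(s) shorter than ", last_n, " skipped")
  seqs <- seqs[long_enough]
  len <- nchar(seqs)
  tails <- substring(seqs, len - last_n + 1L, len)
  m <- matrix(scale[unlist(strsplit(tails, "", fixed = TRUE), use.names = FALSE)],
              nrow = last_n)
  tibble::tibble(offset = seq(-last_n, -1L),
                 mean_kd = rowMeans(m),
                 n = rep(length(seqs), last_n))
}

#' Classify the C-terminal stability pattern of a protein
#'
#' Compares a protein's C-terminal tail hydrophobicity with the
#' hydropathy of the rest of the sequence against quartile thresholds
#' derived from AUG-initiated canonical proteins. A *stabilized tail*
#' (candidate selection toward stability) has CTTH below the lower
#' canonical quartile while the rest of the protein is hydrophobic
#' (positive); a *destabilized tail* (candidate selection toward
#' instability) has CTTH above the upper canonical quartile while the
#' rest is highly hydrophilic (below −1), and is never called for
#' proteins carrying a C-terminal transmembrane domain, whose hydrophobic
#' tail reflects membrane anchoring rather than a degradation signal.
#' All threshold comparisons are strict; boundary values fall into
#' `"other"`.
#'
#' @param ctth CTTH value.
#' @param rest_gravy Mean hydropathy of the rest of the sequence.
#' @param has_cterm_tmd Does the protein have a TMD at the C-end?
#' @param low_q Lower canonical CTTH quartile (default −0.963).
#' @param high_q Upper canonical CTTH quartile (default −0.110).
#' @param rest_hydrophilic Rest-hydropathy cutoff for the destabilized
#'   rule (default −1).
#' @param rest_hydrophobic Rest-hydropathy cutoff for the stabilized rule
#'   (default 0).
#' @return A list with `pattern` (`"stabilized_tail"`,
#'   `"destabilized_tail"` or `"other"`), the inputs, and
#'   `excluded_for_cterm_tmd`.
#' @export
classify_stability_pattern <- function(ctth, rest_gravy, has_cterm_tmd = FALSE,
                                       low_q = -0.963, high_q = -0.110,
                                       rest_hydrophilic = -1.0,
                                       rest_hydrophobic = 0.0) {
  stopifnot(is.finite(ctth), is.finite(rest_gravy), is.logical(has_cterm_tmd))
  pattern <- "other"
  excluded <- FALSE
  if (ctth < low_q && rest_gravy > rest_hydrophobic) {
    pattern <- "stabilized_tail"
  } else if (ctth > high_q && rest_gravy < rest_hydrophilic) {
    if (has_cterm_tmd) excluded <- TRUE else pattern <- "destabilized_tail"
  }
  list(pattern = pattern, ctth = ctth, rest_gravy = rest_gravy,
       excluded_for_cterm_tmd = excluded)
}

#' Empirical CTTH quartile thresholds from a reference dataset
#'
#' Recomputes the lower and upper quartiles of the CTTH distribution of a
#' user-supplied canonical reference set (linear-interpolation quantile
#' definition, `stats::quantile` type 7), for use in place of the bundled
#' defaults of [classify_stability_pattern()].
#'
#' @param ds Reference [protein_dataset()].
#' @param window Tail window (default 30).
#' @param scale Hydropathy scale.
#' @return Named numeric vector `c(low_q = , high_q = )`.
#' @export
ctth_quartiles <- function(ds, window = 30, scale = kyte_doolittle()) {
  stopifnot(inherits(ds, "protein_dataset"))
  seqs <- ds$records$sequence[nchar(ds$records$sequence) >= window]
  if (length(seqs) == 0) stop("no record long enough for CTTH", call. = FALSE)
  v <- vapply(seqs, ctth, numeric(1), window = window, scale = scale,
              USE.NAMES = FALSE)
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  c(low_q = q[1], high_q = q[2])
}

# Vectorized CTTH / rest over a dataset; NA where too short.
dataset_hydropathy <- function(ds, window = 30, scale = kyte_doolittle()) {
  seqs <- ds$records$sequence
  len <- nchar(seqs)
  ctth_v <- rep(NA_real_, length(seqs))
  rest_v <- rep(NA_real_, length(seqs))
  ok_t <- len >= window
  if (any(ok_t)) {
    tails <- substring(seqs[ok_t], len[ok_t] - window + 1L, len[ok_t])
    m <- matrix(scale[unlist(strsplit(tails, "", fixed = TRUE), use.names = FALSE)],
                nrow = window)
    ctth_v[ok_t] <- colMeans(m)
  }
  ok_r <- len > window
  if (any(ok_r)) {
    rests <- substr(seqs[ok_r], 1L, len[ok_r] - window)
    sp <- strsplit(rests, "", fixed = TRUE)
    rest_v[ok_r] <- vapply(sp, function(ch) mean(scale[ch]), numeric(1))
  }
  tibble::tibble(id = ds$records$id, length = len, ctth = ctth_v, rest_gravy = rest_v)
}
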