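#' Parse a per-residue disorder score file
#'
#' Reads IUPred2a-style output: comment lines starting with `#`, then
#' whitespace-delimited columns *position*, *residue*, *score*. Positions
#' must be consecutive from 1 and scores within \[0, 1\].
#'
#' @param path Path to the score file.
#' @param sequence_id Identifier to attach (default: file name without
#'   extension).
#' @param sequence Optional amino-acid string; when given, the residue
#'   column is cross-checked against it.
#' @return A list of class `disorder_profile`: `sequence_id`, `residues`,
#'   `scores`.
#' @export
parse_disorder_file <- function(path, sequence_id = NULL, sequence = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no data rows in disorder file: ", path, call. = FALSE)
  parts <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(parts) < 3)) {
    stop("disorder file row with fewer than 3 columns in ", path, call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 1)))
  res <- vapply(parts, `[[`, character(1), 2)
  sc <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3)))
  if (anyNA(pos) || anyNA(sc)) stop("non-numeric position or score in ", path, call. = FALSE)
  if (!identical(pos, seq_along(pos))) {
    stop("disorder positions must be consecutive from 1 (gap near position ",
         pos[which(pos != seq_along(pos))[1]], ")", call. = FALSE)
  }
  if (any(sc < 0 | sc > 1)) {
    stop("disorder score out of [0, 1]: ", sc[sc < 0 | sc > 1][1], call. = FALSE)
  }
  if (!is.null(sequence)) {
    want <- seq_chars(toupper(sequence))
    if (length(want) != length(res) || any(toupper(res) != want)) {
      stop("disorder file residues do not match the supplied sequence", call. = FALSE)
    }
  }
  if (is.null(sequence_id)) sequence_id <- sub("\\.[^.]*$", "", basename(path))
  structure(list(sequence_id = sequence_id, residues = toupper(res), scores = sc),
            class = "disorder_profile")
}

#' Build a disorder profile from scores in memory
#'
#' @param scores Numeric vector in \[0, 1\], one per residue.
#' @param sequence_id Identifier.
#' @param residues Optional residue letters.
#' @return A `disorder_profile`.
#' @export
disorder_profile <- function(scores, sequence_id = "seq", residues = NULL) {
  scores <- as.numeric(scores)
  if (length(scores) == 0 || any(!is.finite(scores)) || any(scores < 0 | scores > 1)) {
    stop("scores must be non-empty and within [0, 1]", call. = FALSE)
  }
  if (is.null(residues)) residues <- rep(NA_character_, length(scores))
  structure(list(sequence_id = sequence_id, residues = residues, scores = scores),
            class = "disorder_profile")
}

#' Call terminal intrinsically disordered regions
#'
#' Measures the maximal run of consecutive residues with disorder score
#' strictly above `threshold` starting at the first residue (N-terminal
#' run) and ending at the last residue (C-terminal run), and flags a
#' terminal IDR when the run reaches `min_len` residues (inclusive;
#' terminal IDRs of 30+ residues are the experimentally supported
#' degradation determinant).
#'
#' @param profile A `disorder_profile`.
#' @param min_len Minimum IDR length (default 30).
#' @param threshold Disorder score cutoff (default 0.5, strict).
#' @return List: `n_idr`, `c_idr`, `n_run_length`, `c_run_length`,
#'   `min_len`, `threshold`.
#' @export
call_terminal_idrs <- function(profile, min_len = 30, threshold = 0.5) {
  stopifnot(inherits(profile, "disorder_profile"))
  min_len <- assert_count(min_len, "min_len")
  dis <- profile$scores > threshold
  n_run <- if (!dis[1]) 0L else {
    r <- rle(dis)
    r$lengths[1]
  }
  c_run <- if (!dis[length(dis)]) 0L else {
    r <- rle(dis)
    r$lengths[length(r$lengths)]
  }
  list(n_idr = n_run >= min_len, c_idr = c_run >= min_len,
       n_run_length = as.integer(n_run), c_run_length = as.integer(c_run),
       min_len = min_len, threshold = threshold)
}

#' Surrogate per-residue disorder scores
#'
#' Deterministic stand-in for an external disorder predictor, for testing
#' and simulation only: each residue's TOP-IDP disorder propensity is
#' mapped to \[0, 1\] and smoothed with a centered moving average
#' (window 21, truncated at the ends). Disorder-promoting stretches
#' (P/E/S/K/Q-rich) score above 0.5 and order-promoting stretches
#' (I/L/V/F-rich) below. This is **not** a reproduction of IUPred2a or of
#' any energy-based predictor.
#'
#' @param seq Amino-acid string.
#' @param sequence_id Identifier for the resulting profile.
#' @param window Smoothing window (odd, default 21).
#' @return A `disorder_profile`.
#' @export
surrogate_disorder <- function(seq, sequence_id = "seq", window = 21) {
  assert_string(seq)
  window <- assert_count(window, "window")
  if (window %% 2L == 0L) stop("smoothing window must be odd", call. = FALSE)
  ch <- seq_chars(seq)
  raw <- top_idp_scale()[ch]
  if (anyNA(raw)) {
    stop("unknown residue '", ch[is.na(raw)][1], "' in sequence", call. = FALSE)
  }
  v <- pmin(1, pmax(0, 0.5 + raw / 2))
  n <- length(v)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  disorder_profile(sm, sequence_id = sequence_id, residues = ch)
}

#' Write a disorder profile in the three-column text format
#'
#' @param profile A `disorder_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_disorder_file <- function(profile, path) {
  stopifnot(inherits(profile, "disorder_profile"))
  res <- profile$residues
  res[is.na(res)] <- "X"
  writeLines(c(paste0("# disorder scores for ", profile$sequence_id),
               sprintf("%d\t%s\t%.4f", seq_along(profile$scores), res,
                       profile$scores)),
             path)
  invisible(path)
}
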