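kferq_classes <- c("canonical", "phospho_activated", "acetyl_activated")

# windowed count of a logical vector over windows of width 5
run5 <- function(x) {
  cs <- cumsum(c(0L, as.integer(x)))
  n <- length(x)
  if (n < 5L) return(integer(0))
  cs[6:(n + 1L)] - cs[1:(n - 4L)]
}

#' Find KFERQ-like chaperone-mediated-autophagy motifs
#'
#' Scans every pentapeptide window of a protein for KFERQ-like motifs,
#' the pentapeptides recognized by the chaperone HSC70 that target
#' proteins to chaperone-mediated autophagy and endosomal microautophagy.
#' Three classes are recognized:
#'
#' * **canonical** — a glutamine (Q) anchor at the first or fifth
#'   position; the remaining four residues comprise 1–2 basic residues
#'   (K/R), 1–2 hydrophobic residues (F/I/L/V) with basic + hydrophobic
#'   totalling 3, and exactly one acidic residue (E/D).
#' * **phospho_activated** — as canonical, but the acidic slot is filled
#'   by a phosphorylatable residue (S/T; Y optionally via
#'   `phospho_includes_y`) and no E/D is present.
#' * **acetyl_activated** — as canonical, but the anchor slot is occupied
#'   by a lysine (acetyl-K mimics Q); the anchor K does not count toward
#'   the basic tally.
#'
#' Overlapping windows each count; a window satisfying several requested
#' classes yields one hit per class. A window whose anchor condition
#' holds at both ends is counted once per class unless
#' `count_double_anchor` is set.
#'
#' @param seq Amino-acid string.
#' @param classes Which motif classes to report (default all three).
#' @param phospho_includes_y Include Y in the phosphorylatable set
#'   (default `FALSE`).
#' @param count_double_anchor Count a window twice when both terminal
#'   positions satisfy the anchor rule (default `FALSE`).
#' @return Tibble of hits: `start` (1-based), `pentapeptide`,
#'   `motif_class`. Sequences shorter than 5 residues yield zero hits.
#' @examples
#' find_kferq_motifs("KFERQ")$motif_class # canonical
#' @export
find_kferq_motifs <- function(seq, classes = kferq_classes,
                              phospho_includes_y = FALSE,
                              count_double_anchor = FALSE) {
  assert_string(seq)
  classes <- match.arg(classes, kferq_classes, several.ok = TRUE)
  ch <- seq_chars(seq)
  n <- length(ch)
  empty <- tibble::tibble(start = integer(), pentapeptide = character(),
                          motif_class = character())
  if (n < 5L) {
    message("sequence shorter than 5 residues: no KFERQ windows")
    return(empty)
  }
  basic <- ch %in% c("K", "R")
  hyd <- ch %in% c("F", "I", "L", "V")
  acid <- ch %in% c("E", "D")
  phos <- ch %in% (if (phospho_includes_y) c("S", "T", "Y") else c("S", "T"))
  isQ <- ch == "Q"
  isK <- ch == "K"
  nw <- n - 4L
  nb <- run5(basic); nh <- run5(hyd); na_ <- run5(acid); np <- run5(phos)
  q1 <- isQ[1:nw]; q5 <- isQ[5:n]
  k1 <- isK[1:nw]; k5 <- isK[5:n]

  # tallies exclude the anchor residue; Q contributes to no tally, so for
  # Q-anchored classes whole-window counts equal other-four counts, and for
  # the K anchor exactly one basic count is subtracted.
  canon_body <- nb >= 1L & nb <= 2L & nh >= 1L & nh <= 2L & na_ == 1L & (nb + nh) == 3L
  phos_body <- nb >= 1L & nb <= 2L & nh >= 1L & nh <= 2L & np == 1L & na_ == 0L &
    (nb + nh) == 3L
  acet_body <- (nb - 1L) >= 1L & (nb - 1L) <= 2L & nh >= 1L & nh <= 2L & na_ == 1L &
    (nb - 1L + nh) == 3L

  mult <- function(a1, a5, body) {
    if (count_double_anchor) as.integer(a1 & body) + as.integer(a5 & body)
    else as.integer((a1 | a5) & body)
  }
  out <- list()
  counts <- list(canonical = mult(q1, q5, canon_body),
                 phospho_activated = mult(q1, q5, phos_body),
                 acetyl_activated = mult(k1, k5, acet_body))
  for (cl in classes) {
    m <- counts[[cl]]
    idx <- rep(which(m > 0L), times = m[m > 0L])
    if (length(idx) > 0) {
      out[[cl]] <- tibble::tibble(start = idx,
                                  pentapeptide = substring(seq, idx, idx + 4L),
                                  motif_class = cl)
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res[order(res$start, match(res$motif_class, kferq_classes)), ]
}

#' Summarize KFERQ-like motif hits for one sequence
#'
#' @param hits A hit tibble from [find_kferq_motifs()].
#' @param seq_length Length of the scanned sequence (residues).
#' @return A list with per-class `counts`, `total_count`, per-class and
#'   total `density` (motifs per residue), and `has_any`.
#' @export
kferq_summary <- function(hits, seq_length) {
  seq_length <- assert_count(seq_length, "seq_length")
  counts <- vapply(kferq_classes, function(cl) sum(hits$motif_class == cl), integer(1))
  total <- sum(counts)
  list(counts = counts,
       total_count = total,
       density = c(counts / seq_length, total = total / seq_length),
       has_any = total > 0L)
}

#' Pooled KFERQ-like motif rates over a dataset
#'
#' Length-normalized motif rates: the pooled density of a class is its
#' total motif count divided by the summed residue count of the dataset,
#' the normalization used when comparing datasets of different length
#' distributions.
#'
#' @param ds A [protein_dataset()].
#' @param classes Motif classes to count (default all three).
#' @param ... Passed to [find_kferq_motifs()].
#' @return A list with `pooled_density` (named per class + `total`),
#'   `total_residues`, and `per_sequence` (tibble: `id`, `length`,
#'   `canonical_n`, `phospho_n`, `acetyl_n`, `total_n`, `density_total`,
#'   `has_any`).
#' @export
dataset_kferq_rates <- function(ds, classes = kferq_classes, ...) {
  stopifnot(inherits(ds, "protein_dataset"))
  if (nrow(ds$records) == 0) stop("empty dataset", call. = FALSE)
  classes <- match.arg(classes, kferq_classes, several.ok = TRUE)
  len <- nchar(ds$records$sequence)
  per <- matrix(0L, nrow = nrow(ds$records), ncol = 3,
                dimnames = list(NULL, kferq_classes))
  for (i in seq_len(nrow(ds$records))) {
    h <- suppressMessages(find_kferq_motifs(ds$records$sequence[i], classes, ...))
    for (cl in classes) per[i, cl] <- sum(h$motif_class == cl)
  }
  totals <- colSums(per)
  tot_res <- sum(len)
  pooled <- c(totals / tot_res, total = sum(totals) / tot_res)
  per_seq <- tibble::tibble(
    id = ds$records$id, length = len,
    canonical_n = per[, "canonical"],
    phospho_n = per[, "phospho_activated"],
    acetyl_n = per[, "acetyl_activated"],
    total_n = as.integer(rowSums(per)),
    density_total = rowSums(per) / len,
    has_any = rowSums(per) > 0)
  list(pooled_density = pooled, total_residues = tot_res, per_sequence = per_seq)
}
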