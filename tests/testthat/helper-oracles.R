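# Independent brute-force oracles and fixture builders used across tests.
# These deliberately re-derive expected results by direct enumeration or
# literal rule application, independent of the package's implementations.

random_aa_seq <- function(len, comp = degsig::human_aa_composition()) {
  paste(sample(names(comp), len, replace = TRUE, prob = comp), collapse = "")
}

random_seq_fixed <- function(len, seed = len) {
  withr::with_seed(seed, random_aa_seq(len))
}

toy_dataset <- function(seqs, ids = NULL, name = "toy") {
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  protein_dataset(tibble::tibble(id = ids, sequence = seqs), name = name)
}

# ---- degron scanning oracle: literal prefix/suffix comparison ----

bf_scan_n <- function(seq, motifs) {
  start <- if (substr(seq, 1, 1) == "M") 2L else 1L
  hits <- character(0)
  for (mo in motifs) {
    if (substr(seq, start, start + nchar(mo) - 1L) == mo) hits <- c(hits, mo)
  }
  hits
}

bf_scan_c <- function(seq, motifs) {
  hits <- character(0)
  for (mo in motifs) {
    L <- nchar(seq)
    if (nchar(mo) <= L && substr(seq, L - nchar(mo) + 1L, L) == mo) hits <- c(hits, mo)
  }
  hits
}

# ---- KFERQ oracle: per-window, per-anchor literal rule application ----

bf_kferq_window <- function(w, phospho_y = FALSE) {
  ch <- strsplit(w, "")[[1]]
  basic <- c("K", "R"); hyd <- c("F", "I", "L", "V"); acid <- c("E", "D")
  phos <- if (phospho_y) c("S", "T", "Y") else c("S", "T")
  classes <- character(0)
  body_canon <- function(others) {
    nb <- sum(others %in% basic); nh <- sum(others %in% hyd)
    na_ <- sum(others %in% acid)
    nb >= 1 && nb <= 2 && nh >= 1 && nh <= 2 && na_ == 1 && nb + nh == 3
  }
  body_phos <- function(others) {
    nb <- sum(others %in% basic); nh <- sum(others %in% hyd)
    np <- sum(others %in% phos); na_ <- sum(others %in% acid)
    nb >= 1 && nb <= 2 && nh >= 1 && nh <= 2 && np == 1 && na_ == 0 && nb + nh == 3
  }
  for (p in c(1L, 5L)) {
    others <- ch[-p]
    if (ch[p] == "Q" && body_canon(others)) classes <- c(classes, "canonical")
    if (ch[p] == "Q" && body_phos(others)) classes <- c(classes, "phospho_activated")
    if (ch[p] == "K" && body_canon(others)) classes <- c(classes, "acetyl_activated")
  }
  unique(classes)
}

bf_kferq <- function(seq, phospho_y = FALSE) {
  n <- nchar(seq)
  if (n < 5) return(tibble::tibble(start = integer(), motif_class = character()))
  out <- list()
  for (s in seq_len(n - 4L)) {
    cls <- bf_kferq_window(substr(seq, s, s + 4L), phospho_y = phospho_y)
    if (length(cls) > 0) out[[length(out) + 1L]] <- tibble::tibble(start = s,
                                                                  motif_class = cls)
  }
  if (length(out) == 0) return(tibble::tibble(start = integer(), motif_class = character()))
  do.call(rbind, out)
}

# ---- exact-test enumeration oracles ----

enum_rank_sum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  u_all <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% rk)
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
}

enum_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

enum_mcnemar_p <- function(b, cc) {
  n <- b + cc
  probs <- stats::dbinom(0:n, n, 0.5)
  sum(probs[probs <= stats::dbinom(b, n, 0.5) * (1 + 1e-7)])
}
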