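#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes, in the conventional
#' alphabetical order of the single-letter code.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values from Kyte & Doolittle (1982). Positive
#' values are hydrophobic, negative hydrophilic; the scale spans
#' \[−4.5, 4.5\] (dimensionless).
#'
#' @return Named numeric vector over the 20 standard residues.
#' @examples
#' kyte_doolittle()[["A"]] # 1.8
#' @export
kyte_doolittle <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

# TOP-IDP disorder propensity (Campen et al. 2008); higher = more
# disorder-promoting. Used only by the surrogate disorder generator.
top_idp_scale <- function() {
  c(W = -0.884, F = -0.697, Y = -0.510, I = -0.486, M = -0.397,
    L = -0.326, V = -0.121, N =  0.007, C =  0.020, T =  0.059,
    A =  0.060, G =  0.166, R =  0.180, D =  0.192, H =  0.303,
    Q =  0.318, S =  0.341, K =  0.586, E =  0.736, P =  0.987)
}

#' Human-proteome-like amino-acid composition
#'
#' Approximate residue frequencies of the reviewed human proteome,
#' normalized to sum to 1. Used as the default base composition of the
#' synthetic-sequence generator.
#'
#' @return Named numeric vector of 20 probabilities summing to 1.
#' @export
human_aa_composition <- function() {
  p <- c(A = 0.0702, R = 0.0564, N = 0.0359, D = 0.0473, C = 0.0230,
         Q = 0.0477, E = 0.0710, G = 0.0657, H = 0.0263, I = 0.0433,
         L = 0.0996, K = 0.0573, M = 0.0213, F = 0.0365, P = 0.0631,
         S = 0.0833, T = 0.0534, W = 0.0122, Y = 0.0266, V = 0.0597)
  p / sum(p)
}

#' Validate a hydropathy scale
#'
#' @param scale Named numeric vector with exactly the 20 standard residues.
#' @return The scale, invisibly, after validation.
#' @keywords internal
validate_scale <- function(scale) {
  if (!is.numeric(scale) || is.null(names(scale)) ||
      !setequal(names(scale), amino_acids()) || length(scale) != 20L) {
    stop("hydropathy scale must be a named numeric vector over the 20 standard residues",
         call. = FALSE)
  }
  if (any(!is.finite(scale))) stop("hydropathy scale values must be finite", call. = FALSE)
  invisible(scale)
}
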