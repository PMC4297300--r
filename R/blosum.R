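# BLOSUM-based residue encodings for the network input, and the
# substitution-derived pseudocount frequencies used when building logos.

#' BLOSUM residue encoding matrix
#'
#' Returns the 20 x 20 substitution-score matrix (rows and columns in
#' `AA_ORDER`) divided by `scale`, so each residue is encoded as its scaled
#' score row — the standard encoding for gapped-core network alignment.
#'
#' @param name name of a substitution matrix shipped with Biostrings
#'   (default `"BLOSUM50"`).
#' @param scale divisor applied to the integer scores (default 5).
#' @return Numeric 20 x 20 matrix.
#' @export
blosum_encoding <- function(name = "BLOSUM50", scale = 5) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  m <- get(name, envir = env)
  m <- m[AA_ORDER, AA_ORDER] / scale
  storage.mode(m) <- "double"
  m
}

#' Substitution-derived pseudocount matrix
#'
#' Conditional substitution probabilities `q(a | b)` reconstructed from the
#' BLOSUM62 half-bit log-odds scores: `q(a, b) proportional to
#' p(a) p(b) 2^(S(a, b) / 2)` with `p` the background composition, columns
#' normalized. Used to smooth observed core frequencies:
#' `g(p, a) = sum_b f_obs(p, b) q(a | b)`.
#'
#' @param background named residue frequency vector (defaults to the shipped
#'   proteome-average composition).
#' @return 20 x 20 matrix; column b holds `q(. | b)`.
#' @export
blosum_pseudocount_matrix <- function(background = BACKGROUND_FREQS) {
  env <- new.env()
  utils::data(list = "BLOSUM62", package = "Biostrings", envir = env)
  s <- get("BLOSUM62", envir = env)[AA_ORDER, AA_ORDER]
  p <- background[AA_ORDER]
  q <- outer(p, p) * 2^(s / 2)
  sweep(q, 2, colSums(q), "/")
}
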