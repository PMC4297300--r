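# Per-peptide SAM-style statistics with permutation calibration, Grenander
# estimation of the proportion of true nulls, and a global permutation test
# per allotype pair.

#' Enumerate or sample group-label permutations
#'
#' Returns a matrix whose columns are index sets for "group A" out of
#' `nA + nB` samples. When the number of distinct splits is at most
#' `exhaustive_limit` all splits are enumerated (the observed labelling is
#' among them); otherwise `B` random splits are drawn.
#'
#' @noRd
permutation_splits <- function(nA, nB, B, seed, exhaustive_limit = 10000) {
  n <- nA + nB
  n_splits <- choose(n, nA)
  if (n_splits <= exhaustive_limit) {
    list(splits = combn(n, nA), exhaustive = TRUE)
  } else {
    splits <- with_seed(seed, {
      vapply(seq_len(B), function(b) sort(sample.int(n, nA)), integer(nA))
    })
    list(splits = splits, exhaustive = FALSE)
  }
}

#' Resolve group sample indices from a repertoire matrix
#' @noRd
group_columns <- function(matrix, group, group_by = "allotype") {
  if (all(group %in% matrix$samples$sample_id)) {
    idx <- match(group, matrix$samples$sample_id)
  } else {
    idx <- which(matrix$samples[[group_by]] %in% group)
  }
  if (length(idx) == 0L) stop("no samples matching group: ", paste(group, collapse = ","))
  idx
}

#' SAM-style moderated statistics with permutation calibration
#'
#' For each peptide computes the moderated mean-difference statistic
#' `d = (mean_A - mean_B) / (s + s0)` with `s` the pooled standard error and
#' the fudge factor `s0 = median(s)` over all peptides, then calibrates it by
#' group-label permutation: `Z = (d - mean_perm(d)) / sd_perm(d)` and a
#' two-sided per-peptide permutation p-value. When the number of distinct
#' label splits is at most 10,000 the permutation null is exhaustive.
#'
#' @param matrix a [repertoire_matrix()].
#' @param groupA,groupB allotype labels or explicit sample-id vectors; each
#'   group needs at least 2 samples.
#' @param B number of random permutations when exhaustive enumeration is not
#'   feasible.
#' @param seed RNG seed for the permutation draw.
#' @param log_transform analyze `ln(x + 1e-5)` values (default) rather than
#'   raw normalized abundances.
#' @param drop_absent exclude peptides absent from every sample of both
#'   groups.
#' @return data.frame with columns `peptide`, `d`, `z`, `p`; attributes `s0`,
#'   `n_perm`, `exhaustive`.
#' @export
sam_statistic <- function(matrix, groupA, groupB, B = 9999, seed = 1,
                          log_transform = TRUE, drop_absent = TRUE) {
  ia <- group_columns(matrix, groupA)
  ib <- group_columns(matrix, groupB)
  if (length(ia) < 2L || length(ib) < 2L) stop("each group needs >= 2 samples")
  vals <- matrix$values[, c(ia, ib), drop = FALSE]
  peptides <- matrix$peptides
  if (drop_absent) {
    keep <- rowSums(vals) > 0
    vals <- vals[keep, , drop = FALSE]
    peptides <- peptides[keep]
  }
  if (log_transform) vals <- log(vals + 1e-5)
  nA <- length(ia); nB <- length(ib); n <- nA + nB

  d_for_split <- function(idxA, s0) {
    a <- vals[, idxA, drop = FALSE]
    b <- vals[, -idxA, drop = FALSE]
    ma <- rowMeans(a); mb <- rowMeans(b)
    ssa <- rowSums((a - ma)^2); ssb <- rowSums((b - mb)^2)
    s <- sqrt((1 / nA + 1 / nB) * (ssa + ssb) / (nA + nB - 2))
    d <- (ma - mb) / (s + s0)
    # 0/0 (constant peptide with s0 = 0) is 0 by convention; a real mean
    # difference with zero denominator keeps its sign at infinity
    d[!is.finite(d) & (ma - mb) == 0] <- 0
    d
  }
  # observed pooled standard errors define s0, reused across permutations
  a <- vals[, seq_len(nA), drop = FALSE]
  b <- vals[, nA + seq_len(nB), drop = FALSE]
  s_obs <- sqrt((1 / nA + 1 / nB) *
                  (rowSums((a - rowMeans(a))^2) + rowSums((b - rowMeans(b))^2)) /
                  (nA + nB - 2))
  s0 <- median(s_obs)
  d_obs <- d_for_split(seq_len(nA), s0)

  ps <- permutation_splits(nA, nB, B, seed)
  d_perm <- apply(ps$splits, 2, d_for_split, s0 = s0)
  if (!is.matrix(d_perm)) d_perm <- rbind(d_perm)
  mu <- rowMeans(d_perm)
  sdv <- apply(d_perm, 1, sd)
  z <- (d_obs - mu) / sdv
  z[!is.finite(z)] <- 0
  n_perm <- ncol(d_perm)
  exceed <- rowSums(abs(d_perm) >= abs(d_obs) - 1e-12)
  p <- if (ps$exhaustive) exceed / n_perm else (1 + exceed) / (n_perm + 1)
  out <- data.frame(peptide = peptides, d = d_obs, z = z, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "s0") <- s0
  attr(out, "n_perm") <- n_perm
  attr(out, "exhaustive") <- ps$exhaustive
  out
}

#' Estimate the proportion of true nulls from a p-value distribution
#'
#' Fits a non-increasing (Grenander-type) density to the p-value histogram by
#' pool-adjacent-violators and returns the fitted density at p = 1, clipped to
#' \[0, 1\]. Under a mixture of uniform null p-values and small alternative
#' p-values, the density at 1 estimates the null proportion pi0; the
#' proportion of truly differential features is `1 - pi0`.
#'
#' @param pvalues numeric vector of p-values in (0, 1\].
#' @param bins number of equal-width histogram bins.
#' @return `pi0` estimate in \[0, 1\].
#' @export
estimate_pi0_convex <- function(pvalues, bins = 20L) {
  if (any(pvalues <= 0 | pvalues > 1 | is.na(pvalues))) {
    stop("p-values must lie in (0, 1]")
  }
  if (length(pvalues) < 50L) {
    warning("fewer than 50 p-values: pi0 estimate will be unstable")
  }
  breaks <- seq(0, 1, length.out = bins + 1L)
  counts <- tabulate(pmin(bins, ceiling(pvalues * bins)), nbins = bins)
  dens <- counts / length(pvalues) * bins
  # non-increasing fit: isotonic regression on the reversed histogram
  fit <- rev(isoreg(rev(dens))$yf)
  min(max(fit[bins], 0), 1)
}

#' Global permutation test for an overall repertoire difference
#'
#' Tests whether two groups of samples differ anywhere in the repertoire
#' using the statistic `Q = sum_i (mean_A(i) - mean_B(i))^2` over
#' log-transformed values, with a group-label permutation null (exhaustive
#' when at most 10,000 distinct splits exist).
#'
#' @inheritParams sam_statistic
#' @return List with `Q`, `p`, `n_perm`, `exhaustive`.
#' @export
global_permutation_test <- function(matrix, groupA, groupB, B = 9999, seed = 1,
                                    log_transform = TRUE, drop_absent = TRUE) {
  ia <- group_columns(matrix, groupA)
  ib <- group_columns(matrix, groupB)
  if (length(ia) < 2L || length(ib) < 2L) stop("each group needs >= 2 samples")
  vals <- matrix$values[, c(ia, ib), drop = FALSE]
  if (drop_absent) vals <- vals[rowSums(vals) > 0, , drop = FALSE]
  if (log_transform) vals <- log(vals + 1e-5)
  nA <- length(ia)
  q_for_split <- function(idxA) {
    sum((rowMeans(vals[, idxA, drop = FALSE]) -
           rowMeans(vals[, -idxA, drop = FALSE]))^2)
  }
  q_obs <- q_for_split(seq_len(nA))
  ps <- permutation_splits(nA, length(ib), B, seed)
  q_perm <- apply(ps$splits, 2, q_for_split)
  n_perm <- length(q_perm)
  exceed <- sum(q_perm >= q_obs - 1e-12)
  p <- if (ps$exhaustive) exceed / n_perm else (1 + exceed) / (n_perm + 1)
  list(Q = q_obs, p = p, n_perm = n_perm, exhaustive = ps$exhaustive)
}

#' Differential-abundance analysis for one allotype pair
#'
#' Runs [sam_statistic()], [estimate_pi0_convex()] on the resulting p-values,
#' and [global_permutation_test()] for one pair of groups.
#'
#' @inheritParams sam_statistic
#' @return List of class `diff_result`: `pair`, `table` (per-peptide d, z, p),
#'   `pi0`, `prop_diff`, `global_Q`, `global_p`, `n_perm`.
#' @export
diff_abundance <- function(matrix, groupA, groupB, B = 9999, seed = 1,
                           log_transform = TRUE) {
  tab <- sam_statistic(matrix, groupA, groupB, B = B, seed = seed,
                       log_transform = log_transform)
  pi0 <- estimate_pi0_convex(tab$p)
  gt <- global_permutation_test(matrix, groupA, groupB, B = B, seed = seed + 1L,
                                log_transform = log_transform)
  structure(list(pair = c(paste(groupA, collapse = "+"),
                          paste(groupB, collapse = "+")),
                 table = tab, pi0 = pi0, prop_diff = 1 - pi0,
                 global_Q = gt$Q, global_p = gt$p, n_perm = gt$n_perm),
            class = "diff_result")
}

#' @export
print.diff_result <- function(x, ...) {
  cat("diff_result:", x$pair[1], "vs", x$pair[2], "\n")
  cat(sprintf("  peptides: %d   pi0: %.3f   prop_diff: %.3f   global p: %.3g\n",
              nrow(x$table), x$pi0, x$prop_diff, x$global_p))
  invisible(x)
}
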