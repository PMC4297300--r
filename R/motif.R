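# NNAlign-style quantitative motif discovery: an ensemble of feed-forward
# networks jointly learns a 9-mer binding-core alignment and an abundance
# prediction from variable-length peptides, then frequency matrices and
# Shannon-logo matrices are derived from the aligned cores.

#' Training configuration for the core-model ensemble
#'
#' @param motif_length binding-core length (9 for MHC class II grooves).
#' @param hidden number of hidden sigmoid units.
#' @param seeds number of random network initializations.
#' @param folds cross-validation folds; ensemble size is `seeds * folds`.
#' @param epochs training epochs (each peptide presented once per epoch; no
#'   early stopping).
#' @param lr_start,lr_end learning rate, linearly decayed across epochs.
#' @param encoding substitution matrix used to encode residues.
#' @param encoding_scale divisor for the substitution scores.
#' @return List of class `nn_config`.
#' @export
nn_config <- function(motif_length = 9L, hidden = 3L, seeds = 5L, folds = 5L,
                      epochs = 300L, lr_start = 0.05, lr_end = 0.005,
                      encoding = "BLOSUM50", encoding_scale = 5) {
  structure(list(motif_length = as.integer(motif_length),
                 hidden = as.integer(hidden), seeds = as.integer(seeds),
                 folds = as.integer(folds), epochs = as.integer(epochs),
                 lr_start = lr_start, lr_end = lr_end,
                 encoding = encoding, encoding_scale = encoding_scale),
            class = "nn_config")
}

#' Build a quantitative motif-training dataset for one allotype
#'
#' Selects the peptides detected in the group (group-mean abundance > 0),
#' drops excluded peptides (typically CLIP) and peptides shorter than the
#' motif length, and converts group-mean abundances X to regression targets
#' by `ln(X + 1e-5)` followed by linear rescaling to \[0, 1\]. If all
#' abundances are equal the targets are all 0.5 by convention.
#'
#' @param matrix a [repertoire_matrix()].
#' @param group allotype label.
#' @param exclude peptides to exclude: character vector of sequences, a named
#'   logical vector, or a predicate over sequences (e.g. from
#'   [annotate_clip()]).
#' @param motif_length minimum peptide length retained.
#' @param group_by metadata field defining groups.
#' @return List of class `quant_motif_dataset`: `peptides`, `raw_abundance`,
#'   `target`.
#' @export
build_dataset <- function(matrix, group, exclude = NULL, motif_length = 9L,
                          group_by = "allotype") {
  col <- group_mean_column(matrix, group, group_by)
  keep <- col > 0 & nchar(matrix$peptides) >= motif_length
  if (!is.null(exclude)) {
    drop <- if (is.function(exclude)) {
      exclude(matrix$peptides)
    } else if (is.logical(exclude)) {
      if (!is.null(names(exclude))) {
        out <- exclude[matrix$peptides]
        out[is.na(out)] <- FALSE
        out
      } else exclude
    } else {
      matrix$peptides %in% exclude
    }
    keep <- keep & !drop
  }
  if (!any(keep)) stop("empty dataset after filtering")
  x <- col[keep]
  lx <- log(x + 1e-5)
  rng <- range(lx)
  target <- if (rng[1] == rng[2]) rep(0.5, length(lx)) else {
    (lx - rng[1]) / (rng[2] - rng[1])
  }
  structure(list(peptides = matrix$peptides[keep],
                 raw_abundance = unname(x), target = unname(target)),
            class = "quant_motif_dataset")
}

#' Cross-validation folds with common-motif redundancy control
#'
#' Peptides that share any identical 9-mer (motif-length) substring are
#' forced into the same fold so no network is evaluated on a peptide whose
#' near-duplicate it trained on. Shared-k-mer clusters are built by
#' union-find, then dealt in decreasing size order onto the currently
#' smallest fold (ties among equal-size clusters broken by a seed-shuffled
#' order).
#'
#' @param peptides character vector of unique peptide sequences.
#' @param k_folds number of folds (>= 2).
#' @param seed RNG seed for the tie-breaking shuffle.
#' @param motif_length shared-substring length.
#' @return Named integer vector of fold ids (1..k_folds).
#' @export
assign_common_motif_folds <- function(peptides, k_folds = 5L, seed = 1,
                                      motif_length = 9L) {
  if (k_folds < 2L) stop("k_folds must be >= 2")
  n <- length(peptides)
  uf <- make_union_find(n)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    s <- peptides[i]
    L <- nchar(s)
    if (L < motif_length) next
    for (start in 1:(L - motif_length + 1L)) {
      kmer <- substr(s, start, start + motif_length - 1L)
      j <- get0(kmer, envir = seen, inherits = FALSE)
      if (is.null(j)) assign(kmer, i, envir = seen) else uf$union(i, j)
    }
  }
  comp <- uf$components()
  clusters <- split(seq_len(n), comp)
  sizes <- lengths(clusters)
  shuffled_rank <- with_seed(seed, sample.int(length(clusters)))
  deal_order <- order(-sizes, shuffled_rank)
  fold_sizes <- numeric(k_folds)
  folds <- integer(n)
  for (ci in deal_order) {
    f <- which.min(fold_sizes)
    folds[clusters[[ci]]] <- f
    fold_sizes[f] <- fold_sizes[f] + sizes[ci]
  }
  setNames(folds, peptides)
}

#' @noRd
derive_net_seed <- function(seed, s, f) {
  as.integer((as.numeric(seed) * 131L + s * 17L + f) %% 2147483629)
}

#' Train the core-model ensemble
#'
#' For every (network seed, held-out fold) combination a feed-forward network
#' (substitution-encoded 9-mer window -> hidden sigmoid layer -> sigmoid
#' output) is trained on the peptides outside the fold: weights start uniform
#' in \[-0.1, 0.1\]; each epoch presents every training peptide once in
#' shuffled order, picks the peptide's currently best-scoring 9-mer window
#' (ties to the smallest offset), and takes one gradient step on squared
#' error for that window; training runs a fixed epoch count with no early
#' stopping.
#'
#' @param data a [build_dataset()] result.
#' @param config an [nn_config()].
#' @param seed master seed; per-network seeds and the fold assignment derive
#'   from it.
#' @return List of class `core_model`: `networks` (each with weights, its
#'   seed index and held-out fold), `folds`, `config`, `encoding` matrix,
#'   plus the training `peptides` and `target`s.
#' @export
train_ensemble <- function(data, config = nn_config(), seed = 1) {
  stopifnot(inherits(data, "quant_motif_dataset"))
  folds <- assign_common_motif_folds(data$peptides, config$folds, seed = seed,
                                     motif_length = config$motif_length)
  enc <- blosum_encoding(config$encoding, config$encoding_scale)
  cm <- codes_matrix(aa_codes(data$peptides))
  networks <- vector("list", config$seeds * config$folds)
  idx <- 1L
  for (s in seq_len(config$seeds)) {
    for (f in seq_len(config$folds)) {
      train_idx <- which(folds != f) - 1L
      if (length(train_idx) == 0L) stop("fold ", f, " holds every peptide")
      net <- cpp_train_network(cm$codes, cm$lengths, data$target, train_idx,
                               enc, config$motif_length, config$hidden,
                               config$epochs, config$lr_start, config$lr_end,
                               derive_net_seed(seed, s, f))
      net$seed <- s
      net$fold <- f
      networks[[idx]] <- net
      idx <- idx + 1L
    }
  }
  structure(list(networks = networks, folds = folds, config = config,
                 encoding = enc, peptides = data$peptides,
                 target = data$target),
            class = "core_model")
}

#' @export
print.core_model <- function(x, ...) {
  cat("core_model:", length(x$networks), "networks (",
      x$config$seeds, "seeds x", x$config$folds, "folds ),",
      length(x$peptides), "training peptides\n")
  invisible(x)
}

#' Score every candidate binding core of one peptide with one network
#'
#' Encodes each 9-mer window of the peptide and runs the network's forward
#' pass; the best core is the window with the highest prediction (ties broken
#' toward the smallest offset).
#'
#' @param network one element of a `core_model`'s `networks` list (weights
#'   `w1`, `b1`, `w2`, `b2`).
#' @param peptide a single peptide sequence of length >= `motif_length`.
#' @param encoding 20 x 20 encoding matrix (e.g. [blosum_encoding()]).
#' @param motif_length core length.
#' @return data.frame with `offset` (1-based), `core`, `prediction`; the best
#'   offset is in attribute `best`.
#' @export
score_cores <- function(network, peptide, encoding = blosum_encoding(),
                        motif_length = 9L) {
  stopifnot(length(peptide) == 1L)
  if (nchar(peptide) < motif_length) {
    stop("peptide shorter than the motif length")
  }
  codes <- aa_codes(peptide)[[1]]
  if (anyNA(codes)) stop("unknown residue in peptide: ", peptide)
  cm <- codes_matrix(list(codes))
  preds <- cpp_offset_predictions(cm$codes, cm$lengths, encoding,
                                  as.integer(motif_length), network)[1, ]
  offs <- seq_along(preds)
  out <- data.frame(offset = offs,
                    core = substring(peptide, offs, offs + motif_length - 1L),
                    prediction = preds, stringsAsFactors = FALSE)
  attr(out, "best") <- which.max(preds) # first maximum = smallest offset
  out
}

#' @noRd
majority_offset <- function(offsets_row) {
  counts <- tabulate(offsets_row + 1L)
  which.max(counts) - 1L # ties resolve to the smallest offset
}

#' Ensemble predictions and binding-core calls
#'
#' For a peptide used in training, the prediction is the mean over the
#' networks for which it was held out (cross-validated); for a novel peptide
#' the mean over all networks. The reported core offset is the majority vote
#' of the best windows across the full ensemble (ties to the smallest
#' offset): individual networks can lock onto a shifted alignment register,
#' and the register consensus is a property of the whole ensemble, not of the
#' held-out subset.
#'
#' @param model a [train_ensemble()] model.
#' @param peptides peptide sequences; defaults to the training peptides.
#' @return data.frame with `peptide`, `prediction`, `offset` (1-based),
#'   `core`.
#' @export
predict_ensemble <- function(model, peptides = NULL) {
  novel <- !is.null(peptides)
  if (!novel) peptides <- model$peptides
  L <- model$config$motif_length
  if (any(nchar(peptides) < L)) stop("peptide(s) shorter than the motif length")
  cm <- codes_matrix(aa_codes(peptides))
  sc <- cpp_score_peptides(cm$codes, cm$lengths, model$encoding, L,
                           lapply(model$networks, function(x) x[c("w1", "b1", "w2", "b2")]))
  net_folds <- vapply(model$networks, `[[`, integer(1), "fold")
  n <- length(peptides)
  pred <- numeric(n)
  off <- integer(n)
  for (i in seq_len(n)) {
    use <- if (novel) seq_along(model$networks) else {
      which(net_folds == model$folds[[i]])
    }
    pred[i] <- mean(sc$pred[i, use])
    off[i] <- majority_offset(sc$offset[i, ])
  }
  data.frame(peptide = peptides, prediction = pred, offset = off + 1L,
             core = substring(peptides, off + 1L, off + L),
             stringsAsFactors = FALSE)
}

#' Build a Shannon-logo motif from aligned binding cores
#'
#' Applies sequence weighting by greedy clustering of the cores at the given
#' identity threshold (every cluster shares one unit of weight among its
#' members), smooths the weighted position frequencies with
#' substitution-derived pseudocounts, `f = (alpha f_obs + beta g) /
#' (alpha + beta)` with `alpha = n_clusters - 1`, and converts to Shannon
#' heights `height(p, a) = f(p, a) * I_p`, `I_p = log2(20) + sum_a f log2 f`.
#'
#' @param cores character vector of aligned core sequences (equal length).
#' @param beta pseudocount weight (0 disables pseudocounts).
#' @param cluster_threshold sequence-identity threshold for weighting.
#' @param background residue background for the pseudocount matrix.
#' @return List of class `motif_logo`: `freq` and `heights` ([pssm_matrix()]s),
#'   `n_cores`, `n_clusters`, `weighting`.
#' @export
build_logo <- function(cores, beta = 200, cluster_threshold = 0.63,
                       background = BACKGROUND_FREQS) {
  if (length(cores) == 0L) stop("no cores to build a logo from")
  L <- unique(nchar(cores))
  if (length(L) != 1L) stop("cores must share one length")
  code_mat <- do.call(rbind, aa_codes(cores)) + 1L
  if (anyNA(code_mat)) stop("unknown residue in cores")

  # greedy identity clustering: a core joins the first cluster whose
  # representative matches at >= threshold, else founds a new cluster
  min_match <- ceiling(cluster_threshold * L)
  reps <- matrix(code_mat[1, ], nrow = 1L)
  cluster <- integer(length(cores))
  cluster[1] <- 1L
  for (i in seq_along(cores)[-1]) {
    matches <- rowSums(reps == matrix(code_mat[i, ], nrow = nrow(reps),
                                      ncol = L, byrow = TRUE))
    hit <- which(matches >= min_match)
    if (length(hit) > 0L) {
      cluster[i] <- hit[1]
    } else {
      reps <- rbind(reps, code_mat[i, ])
      cluster[i] <- nrow(reps)
    }
  }
  n_clusters <- nrow(reps)
  w <- 1 / tabulate(cluster)[cluster]

  f_obs <- matrix(0, nrow = L, ncol = 20L)
  for (p in seq_len(L)) {
    f_obs[p, ] <- vapply(1:20, function(a) sum(w[code_mat[, p] == a]), numeric(1))
    f_obs[p, ] <- f_obs[p, ] / sum(w)
  }

  alpha <- n_clusters - 1
  if (beta > 0) {
    q <- blosum_pseudocount_matrix(background)
    g <- t(apply(f_obs, 1, function(frow) as.numeric(q %*% frow)))
    f <- if (alpha + beta > 0) (alpha * f_obs + beta * g) / (alpha + beta) else f_obs
  } else {
    f <- f_obs
  }
  f <- f / rowSums(f)

  info <- apply(f, 1, function(frow) {
    nz <- frow > 0
    log2(20) + sum(frow[nz] * log2(frow[nz]))
  })
  heights <- f * info
  structure(list(freq = pssm_matrix(f, "frequency"),
                 heights = pssm_matrix(heights, "shannon_height"),
                 n_cores = length(cores), n_clusters = n_clusters,
                 weighting = sprintf(
                   "greedy %.0f%% identity clustering, alpha = %d, beta = %g",
                   100 * cluster_threshold, as.integer(alpha), beta)),
            class = "motif_logo")
}

#' @export
print.motif_logo <- function(x, ...) {
  cat("motif_logo:", nrow(x$freq), "positions from", x$n_cores, "cores (",
      x$n_clusters, "weight clusters )\n")
  info <- rowSums(x$heights)
  cat("information (bits):", paste(sprintf("%.2f", info), collapse = " "), "\n")
  invisible(x)
}

#' Motif logo from the model's aligned training cores
#'
#' Collects the final binding core called for each training peptide (majority
#' vote over its held-out networks) and summarizes them as a weighted,
#' pseudocount-smoothed Shannon logo.
#'
#' @param model a [train_ensemble()] model.
#' @param top_fraction optionally restrict to this fraction of peptides with
#'   the highest cross-validated predictions (default: all).
#' @param beta,cluster_threshold,background passed to [build_logo()].
#' @return A `motif_logo`.
#' @export
motif_from_cores <- function(model, top_fraction = NULL, beta = 200,
                             cluster_threshold = 0.63,
                             background = BACKGROUND_FREQS) {
  calls <- predict_ensemble(model)
  if (!is.null(top_fraction)) {
    n_keep <- max(1L, floor(top_fraction * nrow(calls)))
    calls <- calls[order(-calls$prediction, seq_len(nrow(calls)))[seq_len(n_keep)], ]
  }
  build_logo(calls$core, beta = beta, cluster_threshold = cluster_threshold,
             background = background)
}

#' Motif logo from the strongest-scoring random peptides
#'
#' Samples random peptides i.i.d. from a background residue composition,
#' scores them with the ensemble, keeps the top `n_top` by predicted binding
#' (ties broken by sampling order), and builds the logo from their predicted
#' binding cores. This probes the motif encoded by the predictor itself
#' rather than by the training peptides.
#'
#' @param model a [train_ensemble()] model.
#' @param background named residue-frequency vector.
#' @param n_random number of random peptides to sample.
#' @param n_top number of top-scoring peptides kept.
#' @param length random peptide length.
#' @param seed RNG seed for the peptide sample.
#' @param beta,cluster_threshold passed to [build_logo()].
#' @return A `motif_logo`; the sampled top peptides are in attribute
#'   `top_peptides`.
#' @export
motif_from_top_scores <- function(model, background = BACKGROUND_FREQS,
                                  n_random = 200000L, n_top = 2000L,
                                  length = 15L, seed = 1, beta = 200,
                                  cluster_threshold = 0.63) {
  if (n_top > n_random) stop("n_top cannot exceed n_random")
  L <- model$config$motif_length
  if (length < L) stop("random peptide length below the motif length")
  codes <- with_seed(seed, {
    matrix(sample.int(20L, n_random * length, replace = TRUE,
                      prob = background[AA_ORDER]) - 1L,
           nrow = n_random, ncol = length)
  })
  lengths <- rep(as.integer(length), n_random)
  sc <- cpp_score_peptides(codes, lengths, model$encoding, L,
                           lapply(model$networks, function(x) x[c("w1", "b1", "w2", "b2")]))
  pred <- rowMeans(sc$pred)
  top <- order(-pred, seq_along(pred))[seq_len(n_top)]
  off <- vapply(top, function(i) majority_offset(sc$offset[i, ]), integer(1))
  seqs <- vapply(seq_len(n_top), function(k) {
    i <- top[k]
    paste(AA_ORDER[codes[i, ] + 1L], collapse = "")
  }, character(1))
  cores <- substring(seqs, off + 1L, off + L)
  logo <- build_logo(cores, beta = beta, cluster_threshold = cluster_threshold,
                     background = background)
  attr(logo, "top_peptides") <- seqs
  logo
}
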