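# Quantitative motif discovery: datasets, folds, core scoring, training,
# and logo construction.

test_that("dataset targets are rescaled log abundances in [0, 1]", {
  m <- toy_matrix(cbind(c(1e-5, 1e-3, 1e-1)), allotypes = "A",
                  peptides = random_peptides(3, 12, seed = 41))
  d <- build_dataset(m, "A")
  expect_equal(d$target[c(1, 3)], c(0, 1))
  # closed form: min-max rescale of ln(X + 1e-5)
  expected_mid <- (log(1e-3 + 1e-5) - log(2e-5)) / (log(0.1 + 1e-5) - log(2e-5))
  expect_equal(d$target[2], expected_mid, tolerance = 1e-12)
  # ln spacing is near-uniform across the two decades (floor offset compresses
  # the lower decade slightly)
  expect_equal(d$target[2], 0.5, tolerance = 0.1)

  m_eq <- toy_matrix(cbind(rep(0.25, 4)), allotypes = "A",
                     peptides = random_peptides(4, 12, seed = 42))
  expect_equal(build_dataset(m_eq, "A")$target, rep(0.5, 4))
})

test_that("dataset drops excluded peptides and short sequences", {
  peps <- c("MRMATPLLMQALP", "SGFHPSDIEVDLLK", "SHORTPP")
  m <- toy_matrix(cbind(c(0.3, 0.3, 0.4)), allotypes = "A", peptides = peps)
  clip <- annotate_clip(peps, clip_config(rules = "core"))
  d <- build_dataset(m, "A", exclude = clip)
  expect_equal(d$peptides, "SGFHPSDIEVDLLK") # CLIP core and 7-mer removed
  expect_error(build_dataset(m, "A", exclude = peps), "empty dataset")
})

test_that("fold assignment keeps shared-9-mer peptides together and balances", {
  p1 <- "AAAAAWWWWCCCCC"
  p2 <- paste0("DD", substr(p1, 3, 11), "EEE") # shares a 9-mer with p1
  folds <- assign_common_motif_folds(c(p1, p2, random_peptides(30, 12, 43)),
                                     k_folds = 5, seed = 1)
  expect_equal(folds[[1]], folds[[2]])

  singletons <- random_peptides(60, 9, seed = 44) # no shared 9-mers
  f2 <- assign_common_motif_folds(singletons, k_folds = 5, seed = 2)
  expect_lte(diff(range(table(f2))), 1)
})

test_that("fold clusters match the brute-force shared-9-mer oracle", {
  set.seed(45)
  fams <- random_peptides(10, 20, seed = 46)
  members <- unlist(lapply(fams, function(p) {
    starts <- sample(1:6, 4, replace = TRUE)
    vapply(starts, function(s) substr(p, s, s + 13), character(1))
  }))
  seqs <- unique(c(fams, members))
  comp <- bf_shared_kmer_components(seqs, 9)
  expect_equal(length(unique(comp)), 10L) # one cluster per family
  folds <- assign_common_motif_folds(seqs, k_folds = 5, seed = 3)
  for (cl in unique(comp)) {
    expect_length(unique(folds[comp == cl]), 1L) # cluster shares one fold
  }
})

test_that("score_cores enumerates windows and matches an independent forward pass", {
  enc <- blosum_encoding()
  net <- zero_network()
  nine <- random_peptides(1, 9, seed = 47)
  expect_equal(nrow(score_cores(net, nine, enc)), 1L)
  fifteen <- random_peptides(1, 15, seed = 48)
  sc <- score_cores(net, fifteen, enc)
  expect_equal(nrow(sc), 7L)
  expect_true(all(sc$prediction == sc$prediction[1])) # constant scorer
  expect_equal(attr(sc, "best"), 1L) # tie -> smallest offset

  set.seed(49)
  trained <- list(w1 = matrix(rnorm(180 * 3, sd = 0.3), 180, 3),
                  b1 = rnorm(3), w2 = rnorm(3), b2 = rnorm(1))
  for (pep in random_peptides(100, 13, seed = 50)) {
    sc <- score_cores(trained, pep, enc)
    expect_equal(sc$prediction, r_score_cores(trained, pep, enc),
                 tolerance = 1e-12)
  }
  expect_error(score_cores(trained, "SHORT", enc), "shorter")
})

test_that("training separates planted-consensus positives from negatives", {
  # 9-mers only (no alignment freedom): target 1 iff three anchors match
  set.seed(51)
  n <- 500
  peps <- unique(random_peptides(n, 9, seed = 52))
  # plant the consensus into half of the peptides at all three anchors
  pos <- seq_len(length(peps) %/% 2)
  peps[pos] <- vapply(peps[pos], function(p) {
    substr(p, 1, 1) <- "F"; substr(p, 4, 4) <- "D"; substr(p, 7, 7) <- "Y"; p
  }, character(1))
  target <- as.numeric(seq_along(peps) %in% pos)
  data <- structure(list(peptides = peps, raw_abundance = target,
                         target = target),
                    class = "quant_motif_dataset")
  model <- train_ensemble(data, nn_config(seeds = 2, folds = 3, epochs = 100),
                          seed = 1)
  pred <- predict_ensemble(model)$prediction
  expect_gt(mean(pred[target == 1]), mean(pred[target == 0]))
})

test_that("training is deterministic given config and seed", {
  m <- toy_matrix(cbind(seq(0.01, 0.1, length.out = 10) / sum(seq(0.01, 0.1, length.out = 10))),
                  allotypes = "A", peptides = random_peptides(10, 12, seed = 53))
  d <- build_dataset(m, "A")
  cfg <- nn_config(seeds = 2, folds = 2, epochs = 10)
  m1 <- train_ensemble(d, cfg, seed = 9)
  m2 <- train_ensemble(d, cfg, seed = 9)
  expect_identical(m1$networks, m2$networks)
  expect_identical(m1$folds, m2$folds)
})

test_that("cross-validated predictions never come from a fold-mate network", {
  d <- structure(list(peptides = random_peptides(40, 11, seed = 54),
                      raw_abundance = rep(0.1, 40),
                      target = runif(40)),
                 class = "quant_motif_dataset")
  model <- train_ensemble(d, nn_config(seeds = 2, folds = 4, epochs = 5), seed = 2)
  net_folds <- vapply(model$networks, `[[`, integer(1), "fold")
  # reproduce the CV mean from only held-out networks; must match predict_ensemble
  calls <- predict_ensemble(model)
  cm_pred <- vapply(seq_along(model$peptides), function(i) {
    use <- which(net_folds == model$folds[[i]])
    mean(vapply(use, function(w) {
      max(r_score_cores(model$networks[[w]], model$peptides[i], model$encoding))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(calls$prediction, cm_pred, tolerance = 1e-10)
})

test_that("logo information follows closed-form entropy cases", {
  cores <- rep("FDYWACDEF", 30)
  logo <- build_logo(cores, beta = 0)
  info <- rowSums(logo$heights)
  expect_equal(unname(info), rep(log2(20), 9), tolerance = 1e-12)
  expect_equal(unname(logo$freq[1, "F"]), 1)

  # position 3 fixed to S or T 50/50, others uniform over the alphabet
  set.seed(55)
  n <- 5000
  cores2 <- vapply(seq_len(n), function(i) {
    p <- paste(sample(aa20, 9, replace = TRUE), collapse = "")
    substr(p, 3, 3) <- sample(c("S", "T"), 1)
    p
  }, character(1))
  logo2 <- build_logo(cores2, beta = 0, cluster_threshold = 1.01) # no weighting
  info2 <- rowSums(logo2$heights)
  expect_equal(unname(info2[3]), log2(20) - 1, tolerance = 0.02)
  expect_lt(max(info2[-3]), 0.05) # uniform positions carry ~0 bits
})

test_that("null targets yield collapsed predictions and a flat logo", {
  m <- toy_matrix(cbind(rep(1 / 60, 60)), allotypes = "A",
                  peptides = random_peptides(60, 14, seed = 56))
  d <- build_dataset(m, "A")
  expect_equal(d$target, rep(0.5, 60))
  model <- train_ensemble(d, nn_config(seeds = 2, folds = 2, epochs = 40), seed = 4)
  calls <- predict_ensemble(model)
  expect_lt(max(abs(calls$prediction - 0.5)), 0.05)
  logo <- motif_from_cores(model)
  expect_lt(max(rowSums(logo$heights)), 0.5) # no planted signal to recover
})

test_that("top-score logo of a constant model reflects the background", {
  model <- structure(list(networks = list(zero_network()),
                          folds = setNames(1L, "AAAAAAAAA"),
                          config = nn_config(seeds = 1, folds = 2),
                          encoding = blosum_encoding(),
                          peptides = "AAAAAAAAA", target = 0.5),
                     class = "core_model")
  logo <- motif_from_top_scores(model, n_random = 2000, n_top = 2000,
                                length = 15, seed = 6, beta = 0)
  # the sampling background itself carries a little information vs uniform;
  # the logo should sit at that level, not above it
  bg <- motifquant:::BACKGROUND_FREQS
  info_bg <- log2(20) + sum(bg * log2(bg))
  expect_lt(max(abs(rowSums(logo$heights) - info_bg)), 0.1)
  for (p in c(1, 5, 9)) {
    expect_gt(cor(as.numeric(logo$freq[p, ]), as.numeric(bg)), 0.95)
  }
  expect_error(motif_from_top_scores(model, n_random = 10, n_top = 20),
               "exceed")
})

test_that("small planted-motif repertoire is recovered end to end", {
  sim <- generate_repertoire(sim_config(n_ligands = 100, seed = 7))
  mat <- normalize_scale_ratio(sim$records, sim$meta)
  clip <- annotate_clip(mat$peptides,
                        clip_config(clip_region = sim$clip_region),
                        setNames(sim$cd74, "CD74"))
  d <- build_dataset(mat, "DQ2.2", exclude = clip)
  model <- train_ensemble(d, nn_config(epochs = 60), seed = 3)
  logo <- motif_from_cores(model)
  pv <- planted_vs_recovered(default_pwms()$DQ2.2, logo,
                             anchors = c(3, 4, 6, 9))
  expect_true(all(pv$anchor_report$hit))
  expect_true(all(pv$correlation[c(3, 4, 6, 9)] > 0.7))

  # the predictor-derived logo (top-scored random 15-mers) exposes the same
  # anchors; with this small model only the top residue is held to account
  top <- motif_from_top_scores(model, n_random = 20000, n_top = 500, seed = 8)
  planted <- default_pwms()$DQ2.2
  for (p in c(3, 4, 6, 9)) {
    top1 <- aa20[which.max(top$freq[p, ])]
    planted_top2 <- aa20[order(-planted[p, ])[1:2]]
    expect_true(top1 %in% planted_top2)
  }
  pv_top <- planted_vs_recovered(planted, top)
  expect_true(all(pv_top$correlation[c(6, 9)] > 0.7))
})
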