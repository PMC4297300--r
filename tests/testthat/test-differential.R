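# SAM-style statistics, pi0 estimation and the global permutation test.

meta6 <- function() data.frame(
  sample_id = paste0("s", 1:6), cell_line = "c",
  allotype = rep(c("A", "B"), each = 3),
  bio_replicate = 1L, tech_replicate = rep(1:3, 2),
  stringsAsFactors = FALSE)

test_that("SAM separates a clean difference and zeroes constant peptides", {
  vals <- rbind(c(0.1, 0.1, 0.1, 0, 0, 0),    # all the difference
                c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05)) # constant
  m <- repertoire_matrix(vals, c("PEPTIDEAAA", "PEPTIDECCC"), meta6())
  res <- sam_statistic(m, "A", "B", log_transform = FALSE)
  expect_true(attr(res, "exhaustive"))
  expect_equal(attr(res, "n_perm"), 20L) # all C(6,3) label splits
  expect_equal(res$d[2], 0)
  expect_equal(res$p[2], 1)
  expect_equal(which.max(abs(res$d)), 1L)
  # only the true labelling and its mirror reach |d|: smallest achievable p
  expect_equal(res$p[1], 2 / 20)
})

test_that("SAM d is invariant to a global rescaling of the data", {
  set.seed(14)
  vals <- matrix(runif(12 * 6, 0, 0.4), nrow = 12)
  m1 <- repertoire_matrix(vals, random_peptides(12, 10, 5), meta6())
  m2 <- repertoire_matrix(vals * 2, random_peptides(12, 10, 5), meta6())
  r1 <- sam_statistic(m1, "A", "B", log_transform = FALSE)
  r2 <- sam_statistic(m2, "A", "B", log_transform = FALSE)
  expect_equal(r1$d, r2$d, tolerance = 1e-12) # s and s0 rescale together
  expect_error(sam_statistic(m1, "A", "s4"), ">= 2 samples")
})

test_that("permutation p-values depend only on the label multiset", {
  set.seed(15)
  vals <- matrix(runif(20 * 6, 0, 0.4), nrow = 20)
  m <- repertoire_matrix(vals, random_peptides(20, 10, 6), meta6())
  r1 <- sam_statistic(m, c("s1", "s2", "s3"), c("s4", "s5", "s6"),
                      log_transform = FALSE)
  r2 <- sam_statistic(m, "A", "B", log_transform = FALSE)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$z, r2$z)
})

test_that("type-I error is nominal under the null with exhaustive splits", {
  set.seed(16)
  n <- 5000
  vals <- matrix(runif(n * 12, 0, 1e-3), nrow = n)
  meta <- data.frame(sample_id = paste0("s", 1:12), cell_line = "c",
                     allotype = rep(c("A", "B"), each = 6),
                     bio_replicate = 1L, tech_replicate = rep(1:6, 2),
                     stringsAsFactors = FALSE)
  m <- repertoire_matrix(vals, random_peptides(n, 10, 7), meta)
  res <- sam_statistic(m, "A", "B", log_transform = FALSE)
  expect_true(attr(res, "exhaustive")) # C(12,6) = 924 splits
  frac <- mean(res$p < 0.05)
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.06)
})

test_that("pi0 estimation recovers null and mixture proportions", {
  set.seed(17)
  expect_gte(estimate_pi0_convex(runif(10000)), 0.9)
  p_mix <- c(runif(5000), rbeta(5000, 0.05, 1))
  p_mix <- pmax(p_mix, 1e-12)
  pi0 <- estimate_pi0_convex(p_mix)
  expect_gt(pi0, 0.45)
  expect_lt(pi0, 0.60)
  expect_equal(estimate_pi0_convex(rep(1, 100)), 1)
  expect_error(estimate_pi0_convex(c(0.5, 0)), "\\(0, 1\\]")
  expect_warning(estimate_pi0_convex(runif(10)), "unstable")
})

test_that("pi0 recovery holds across planted non-null fractions", {
  set.seed(18)
  for (f in c(0.1, 0.5, 0.9)) {
    n <- 10000
    n_alt <- round(f * n)
    p <- c(runif(n - n_alt), pmax(rbeta(n_alt, 0.05, 1), 1e-12))
    pi0 <- estimate_pi0_convex(p)
    expect_lt(abs((1 - pi0) - f), 0.1)
  }
})

test_that("pi0 agrees with limma's convex density estimate", {
  skip_if_not_installed("limma")
  set.seed(19)
  p <- c(runif(4000), pmax(rbeta(2000, 0.05, 1), 1e-12))
  ours <- estimate_pi0_convex(p)
  theirs <- limma::convest(p)
  expect_lt(abs(ours - theirs), 0.1)
})

test_that("global test: identical groups give Q = 0 and p = 1", {
  c1 <- c(0.2, 0.3); c2 <- c(0.25, 0.25)
  vals <- cbind(c1, c2, c1, c2)
  meta <- data.frame(sample_id = paste0("s", 1:4), cell_line = "c",
                     allotype = rep(c("A", "B"), each = 2),
                     bio_replicate = 1L, tech_replicate = rep(1:2, 2),
                     stringsAsFactors = FALSE)
  m <- repertoire_matrix(vals, c("PEPTIDEAAA", "PEPTIDECCC"), meta)
  res <- global_permutation_test(m, "A", "B")
  expect_equal(res$Q, 0)
  expect_equal(res$p, 1)
  expect_gte(res$p, 1 / (res$n_perm + 1)) # p bounded by permutation granularity
})

test_that("global test detects distinct synthetic repertoires at the floor p", {
  sim <- generate_repertoire(sim_config(n_ligands = 60, seed = 23))
  mat <- normalize_scale_ratio(sim$records, sim$meta)
  res <- global_permutation_test(mat, "DQ2.5", "DQ2.2", B = 999, seed = 4)
  expect_false(res$exhaustive) # C(36,18) splits: sampled null
  expect_equal(res$p, 1 / 1000)
})

test_that("diff_abundance bundles per-peptide and global results", {
  sim <- generate_repertoire(sim_config(n_ligands = 60, seed = 24))
  mat <- normalize_scale_ratio(sim$records, sim$meta)
  res <- diff_abundance(mat, "DQ2.5", "DQ7.5", B = 499, seed = 2)
  expect_s3_class(res, "diff_result")
  expect_true(all(res$table$p > 0 & res$table$p <= 1))
  expect_true(res$pi0 >= 0 && res$pi0 <= 1)
  expect_equal(res$prop_diff, 1 - res$pi0)
  expect_equal(res$global_p, 1 / 500)
})
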