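# Normalization, replicate averaging, abundance shares, lengths, nested
# sets and CLIP annotation.

test_that("scale-ratio normalization divides by per-sample totals", {
  recs <- toy_records(matrix(c(2, 3, 5), ncol = 1),
                      c("AAPEPTIDE", "CCPEPTIDE", "DDPEPTIDE"), "s1")
  m <- normalize_scale_ratio(recs, data.frame(
    sample_id = "s1", cell_line = "c", allotype = "a",
    bio_replicate = 1L, tech_replicate = 1L))
  expect_equal(unname(m$values[, 1]), c(0.2, 0.3, 0.5))

  single <- toy_records(matrix(42), "AAPEPTIDE", "s1")
  m1 <- normalize_scale_ratio(single, data.frame(
    sample_id = "s1", cell_line = "c", allotype = "a",
    bio_replicate = 1L, tech_replicate = 1L))
  expect_equal(unname(m1$values[1, 1]), 1)
})

test_that("normalization is invariant to per-sample loading scale", {
  vols <- matrix(c(2, 3, 5, 20, 30, 50), ncol = 2)
  recs <- toy_records(vols, c("AAPEPTIDE", "CCPEPTIDE", "DDPEPTIDE"),
                      c("s1", "s2"))
  meta <- data.frame(sample_id = c("s1", "s2"), cell_line = "c",
                     allotype = "a", bio_replicate = 1L,
                     tech_replicate = 1:2)
  m <- normalize_scale_ratio(recs, meta)
  expect_equal(unname(m$values[, 1]), unname(m$values[, 2]))
})

test_that("all-zero samples warn and stay zero; columns are stochastic", {
  vols <- matrix(c(1, 3, 0, 0), ncol = 2)
  recs <- toy_records(vols, c("AAPEPTIDE", "CCPEPTIDE"), c("s1", "s2"))
  meta <- data.frame(sample_id = c("s1", "s2"), cell_line = "c",
                     allotype = "a", bio_replicate = 1L, tech_replicate = 1:2)
  expect_warning(m <- normalize_scale_ratio(recs, meta), "all-zero")
  expect_equal(unname(colSums(m$values)), c(1, 0))
})

test_that("mean_by_group averages columns and is idempotent on duplicates", {
  m <- toy_matrix(cbind(c(0.4, 0.6), c(0.4, 0.6)), allotypes = c("A", "A"))
  g <- mean_by_group(m)
  expect_equal(unname(g$values[, 1]), c(0.4, 0.6))

  m2 <- toy_matrix(cbind(c(1, 0), c(0, 1)), allotypes = c("A", "A"))
  expect_equal(unname(mean_by_group(m2)$values[, 1]), c(0.5, 0.5))

  m3 <- toy_matrix(cbind(c(0.2, 0.8), c(0.7, 0.3)), allotypes = c("A", "B"))
  ident <- mean_by_group(m3, "sample_id")
  expect_equal(unname(ident$values), unname(m3$values))
  expect_error(mean_by_group(m3, "nonexistent"), "unknown metadata key")
})

test_that("abundance_share reproduces the published top-20 shares", {
  shares <- vapply(c(dq25 = "top20_dq25.tsv", dq22 = "top20_dq22.tsv",
                     dq75 = "top20_dq75.tsv"), function(f) {
    m <- read_share_table(extdata(f), "g")
    abundance_share(m, "g", top_n = 20)
  }, numeric(1))
  expect_equal(unname(shares[1]), 52.0, tolerance = 1e-9)
  expect_equal(unname(shares[2]), 23, tolerance = 0.01) # 22.9 printed as 23 %
  expect_equal(unname(shares[3]), 23, tolerance = 0.01) # 23.2 printed as 23 %
})

test_that("selecting all peptides yields a 100 % share; empty selection warns", {
  m <- toy_matrix(cbind(c(0.25, 0.75)), allotypes = "A")
  expect_equal(abundance_share(m, "A"), 100)
  expect_warning(s <- abundance_share(m, "A", sequences = "NOTPRESENT"))
  expect_equal(s, 0)
})

test_that("length distribution counts unique peptides and picks the mode", {
  peps <- c(strrep("A", 9), strrep("C", 14), strrep("D", 14), strrep("E", 21))
  m <- toy_matrix(cbind(rep(0.25, 4)), allotypes = "A", peptides = peps)
  ld <- length_distribution(m)
  expect_equal(ld$counts, c(`9` = 1L, `14` = 2L, `21` = 1L))
  expect_equal(ld$mode, 14L)
  expect_equal(sum(ld$counts), length(unique(peps)))

  empty <- toy_matrix(cbind(rep(0, 4)), allotypes = "A", peptides = peps)
  lde <- length_distribution(empty)
  expect_length(lde$counts, 0L)
  expect_true(is.na(lde$mode))
})

test_that("modal-length ties break toward the smaller length", {
  peps <- c(strrep("A", 10), strrep("C", 12), strrep("D", 12), strrep("E", 10))
  m <- toy_matrix(cbind(rep(0.25, 4)), allotypes = "A", peptides = peps)
  expect_equal(length_distribution(m)$mode, 10L)
})

test_that("nested sets follow containment, not overlap", {
  sets <- assign_nested_sets(c("MATPLLMQALPMGALPQ", "RMATPLLMQALPMGALPQ",
                               "AAAAAAAA"))
  expect_equal(sets[[1]], sets[[2]])
  expect_false(sets[[3]] == sets[[1]])

  overlap <- assign_nested_sets(c("ABCDEFGHIJ", "CDEFGHIJKL"))
  expect_false(overlap[[1]] == overlap[[2]]) # overlap without containment
})

test_that("nested sets match the brute-force containment oracle", {
  parents <- random_peptides(100, 15, seed = 21)
  set.seed(22)
  variants <- vapply(parents, function(p) {
    if (runif(1) < 0.5) substr(p, 2, 15) else substr(p, 1, 14)
  }, character(1))
  seqs <- unique(c(parents, unname(variants)))
  sets <- assign_nested_sets(seqs)
  oracle <- bf_nested_components(seqs)
  expect_true(same_partition(unname(sets), oracle))
  expect_equal(sum(table(sets) >= 2), 100L) # one non-singleton set per parent

  mixed <- random_peptides(80, 11, seed = 31)
  sets2 <- assign_nested_sets(mixed)
  expect_true(same_partition(unname(sets2), bf_nested_components(mixed)))
})

test_that("repertoire filtering drops short and non-nested peptides", {
  peps <- c("MATPLLMQALPMGALPQ", "RMATPLLMQALPMGALPQ", # nested pair
            "SGFHPSDIEVDLLK",                           # singleton
            "MATPLLMQAL")                                # nested but length 10
  m <- toy_matrix(cbind(rep(0.25, 4)), allotypes = "A", peptides = peps)
  f <- filter_repertoire(m, min_length = 11)
  expect_setequal(f$peptides, peps[1:2])
})

test_that("CLIP annotation combines region mapping and core motifs", {
  cfg <- clip_config(source_protein_ids = "CD74", clip_region = c(20, 40),
                     core_motifs = c(CLIP1 = "MRMATPLLM"), min_overlap = 5)
  set.seed(7)
  toy_cd74 <- paste(sample(aa20, 60, replace = TRUE), collapse = "")
  proteins <- c(CD74 = toy_cd74)

  # peptide mapping at [35, 50] overlaps [20, 40] by 6 >= 5 -> flagged
  pep_region <- substr(toy_cd74, 35, 50)
  # peptide mapping at [45, 56] has no overlap -> not flagged
  pep_out <- substr(toy_cd74, 45, 56)
  flags <- annotate_clip(c(pep_region, pep_out, "MRMATPLLM", "QQQQQQQQQ"),
                         cfg, proteins)
  expect_equal(unname(flags), c(TRUE, FALSE, TRUE, FALSE))

  expect_error(annotate_clip("AAA", cfg, c(OTHER = "MMMM")),
               "configuration error")
})
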