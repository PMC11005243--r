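# Multi-study merging and batch-structure QC.

make_study <- function(id, n) {
  e <- random_panel_expr(n)
  md <- tibble::tibble(
    sample_id = expr_samples(e),
    label = rep_len(c("response", "non-response"), n))
  study_dataset(id, e, md)
}

test_that("merging conserves samples, intersects genes, prefixes ids", {
  set.seed(31)
  s1 <- make_study("a", 5)
  s2 <- make_study("b", 7)
  merged <- merge_studies(list(s1, s2))
  expect_identical(nrow(merged$metadata), 12L)
  expect_identical(sort(expr_genes(merged$expression)),
                   sort(intersect(expr_genes(s1$expression),
                                  expr_genes(s2$expression))))
  expect_true(all(grepl("^(a|b):", merged$metadata$sample_id)))
  expect_identical(merged$metadata$label,
                   c(s1$metadata$label, s2$metadata$label))

  # gene sets {A,B,C} vs {B,C,D} merge to {B,C}
  g1 <- make_expr(2^c(1, 2, 3), c("A", "B", "C"), "s1", unit = "FPKM")
  g2 <- make_expr(2^c(4, 5, 6), c("B", "C", "D"), "t1", unit = "FPKM")
  lab <- function(sid) tibble::tibble(sample_id = sid, label = "response")
  st1 <- study_dataset("x", fpkm_to_tpm(g1), lab("s1"))
  st2 <- study_dataset("y", fpkm_to_tpm(g2), lab("t1"))
  m <- merge_studies(list(st1, st2))
  expect_identical(expr_genes(m$expression), c("B", "C"))
  # TPM columns are not re-normalized after subsetting
  expect_lt(sum(expr_values(m$expression)[, 1]), 1e6)

  # single study passes through with batch labels
  alone <- merge_studies(list(s1))
  expect_identical(nrow(alone$metadata), 5L)
  expect_identical(unique(alone$metadata$study_id), "a")

  g3 <- make_expr(2^c(1, 2), c("Q", "R"), "u1", unit = "FPKM")
  st3 <- study_dataset("z", fpkm_to_tpm(g3), lab("u1"))
  expect_error(merge_studies(list(st1, st3)), "empty gene intersection")
})

test_that("clustering recovers constructed batch separation", {
  set.seed(32)
  # two well-separated batches in 3-d feature space
  f <- rbind(matrix(rnorm(30, 0), ncol = 3), matrix(rnorm(30, 10), ncol = 3))
  rownames(f) <- paste0("s", 1:20)
  batch <- rep(c("A", "B"), each = 10)
  cl <- cluster_samples(f)
  pur <- batch_purity(cl, batch, k = 2)
  expect_equal(pur$purity, c(1, 1))
  expect_error(cluster_samples(f[1, , drop = FALSE]), "at least 2")
  expect_error(cluster_samples(f, distance = "hamming"), "binary")
})

test_that("agglomeration order matches a hand-built toy configuration", {
  # 1-d points 0, 1, 5, 6, 20: complete linkage merges (0,1), (5,6),
  # then {0,1}+{5,6} at height 6, then +{20} at height 20
  f <- matrix(c(0, 1, 5, 6, 20), ncol = 1,
              dimnames = list(paste0("p", 1:5), NULL))
  h <- cluster_samples(f)$hclust
  expect_equal(sort(h$height), c(1, 1, 6, 20))
  cut2 <- cutree(h, 2)
  expect_identical(unname(cut2), c(1L, 1L, 1L, 1L, 2L))
  cut3 <- cutree(h, 3)
  expect_identical(unname(cut3[1]), unname(cut3[2]))
  expect_identical(unname(cut3[3]), unname(cut3[4]))
})

test_that("clustering is permutation-equivariant on tie-free data", {
  set.seed(33)
  f <- matrix(rnorm(40), nrow = 8)
  rownames(f) <- paste0("s", 1:8)
  h1 <- cluster_samples(f)$hclust
  perm <- sample(8)
  h2 <- cluster_samples(f[perm, ])$hclust
  expect_equal(sort(h1$height), sort(h2$height))
  # same partitions at every cut, up to relabelling
  for (k in 2:7) {
    c1 <- cutree(h1, k)
    c2 <- cutree(h2, k)[rownames(f)]
    agree <- table(c1, c2) > 0
    expect_true(all(rowSums(agree) == 1) && all(colSums(agree) == 1))
  }
})

test_that("batch mixing score hits its two extremes and a hand case", {
  # disjoint supports: all neighbours same-batch -> 0
  f <- rbind(matrix(0, 5, 2), matrix(100, 5, 2)) + rnorm(20, 0, .01)
  rownames(f) <- paste0("s", 1:10)
  batch <- rep(c("A", "B"), each = 5)
  expect_equal(batch_mixing_score(f, batch, k = 3), 0)

  # randomly permuted labels over fixed features -> ~1
  set.seed(34)
  f2 <- matrix(rnorm(200), ncol = 2,
               dimnames = list(paste0("s", 1:100), NULL))
  scores <- replicate(20, batch_mixing_score(
    f2, sample(rep(c("A", "B"), each = 50)), k = 3))
  expect_equal(mean(scores), 1, tolerance = 0.08)

  # 6 hand-placed points, k = 1: positions 0,1,2, 10,11,12 with batches
  # A,A,B, B,B,A -> nearest neighbours (ties to the earlier index) are
  # s2,s1,s2, s5,s4,s5 -> same-batch indicators 1,1,0, 1,1,0 -> observed
  # 2/3; expected under random mixing 2*(3/6)*(2/5) = 0.4
  f3 <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1,
               dimnames = list(paste0("s", 1:6), NULL))
  b3 <- c("A", "A", "B", "B", "B", "A")
  expect_equal(batch_mixing_score(f3, b3, k = 1),
               (1 - 2 / 3) / (1 - 0.4))

  expect_error(batch_mixing_score(f3, rep("A", 6), k = 1), "2 batches")
  expect_error(batch_mixing_score(f3, b3, k = 6), "smaller")
})

test_that("batch standardization removes a planted shift and keeps identity", {
  set.seed(35)
  ng <- 30
  base <- matrix(2^rnorm(ng * 8, 6, 1), ng, 8)
  tpm <- sweep(base, 2, colSums(base), "/") * 1e6
  rownames(tpm) <- paste0("g", seq_len(ng))
  colnames(tpm) <- paste0("s", 1:8)
  e <- make_expr(tpm, rownames(tpm), colnames(tpm), unit = "TPM")

  # two identical batches: output equals input
  tpm2 <- cbind(tpm[, 1:4], tpm[, 1:4])
  colnames(tpm2) <- paste0("s", 1:8)
  e2 <- make_expr(tpm2, rownames(tpm2), colnames(tpm2), unit = "TPM")
  out2 <- batch_standardize(e2, rep(c("A", "B"), each = 4))
  expect_equal(expr_values(out2), expr_values(e2), tolerance = 1e-6)
  expect_identical(expr_unit(out2), "normalized")

  # +2 log-unit shift on one gene in batch B is removed
  lg <- log2(tpm + 1)
  lgB <- lg
  lgB["g1", 5:8] <- lgB["g1", 5:8] + 2
  eB <- make_expr(2^lgB - 1, rownames(tpm), colnames(tpm),
                  unit = "normalized")
  adj <- batch_standardize(eB, rep(c("A", "B"), each = 4))
  la <- log2(expr_values(adj) + 1)
  expect_equal(mean(la["g1", 1:4]), mean(la["g1", 5:8]), tolerance = 1e-8)

  expect_error(batch_standardize(e, c("A", rep("B", 7))), "< 2 samples")
})

test_that("pair features resist per-gene batch distortion better than raw", {
  skip_if_not_installed("withr")
  # mixing on raw expression decreases with distortion magnitude while
  # pair-feature mixing degrades more slowly (per-gene shifts) and is
  # untouched by per-sample monotone distortion
  pairs <- enumerate_pairs(checkpoint_panel())
  grid <- c(0, 0.5, 1)
  raw_mix <- pair_mix <- numeric(length(grid))
  for (i in seq_along(grid)) {
    sim <- simulate_studies(simulation_config(
      samples_per_study = c(24, 24), n_background_genes = 150,
      effect_delta = 0, batch_gene_shift_sd = grid[i], seed = 77))
    merged <- merge_studies(sim$studies)
    raw <- log2(t(expr_values(merged$expression)) + 1)
    rownames(raw) <- merged$metadata$sample_id
    f <- encode_pair_features(merged$expression, pairs)
    raw_mix[i] <- batch_mixing_score(raw, merged$metadata$study_id, k = 10)
    pair_mix[i] <- batch_mixing_score(f, merged$metadata$study_id, k = 10)
  }
  expect_true(all(diff(raw_mix) <= 0))          # monotone degradation
  expect_true(all(pair_mix >= raw_mix))         # never worse than raw ...
  expect_gt(pair_mix[2], raw_mix[2])            # ... and strictly better
                                                # at moderate distortion
})

test_that("assess_batch bundles clustering, purity and mixing", {
  set.seed(36)
  f <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 8), ncol = 2))
  rownames(f) <- paste0("s", 1:40)
  batch <- rep(c("A", "B"), each = 20)
  ba <- assess_batch(f, batch, k_neighbors = 5)
  expect_s3_class(ba, "batch_assessment")
  expect_equal(ba$mixing_score, 0)
  expect_equal(tidy(ba)$purity, c(1, 1))
  g <- glance(ba)
  expect_identical(g$n_batches, 2L)
  expect_s3_class(autoplot(ba), "ggplot")
})
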