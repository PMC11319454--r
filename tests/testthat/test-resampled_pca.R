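test_that("standardization centers, scales, and is idempotent", {
  set.seed(31)
  m <- matrix(rnorm(64, mean = 5, sd = 3), 8, 8,
              dimnames = list(NULL, paste0("v", 1:8)))
  z <- standardize_matrix(m)
  expect_equal(unname(colMeans(z)), rep(0, 8))
  expect_equal(unname(apply(z, 2, sd)), rep(1, 8))
  # hand-computed z-scores
  expect_equal(z[, 1], (m[, 1] - mean(m[, 1])) / sd(m[, 1]),
               ignore_attr = TRUE)
  expect_equal(standardize_matrix(z), z)

  m[, 4] <- 2
  expect_error(standardize_matrix(m), "v4")
  expect_error(standardize_matrix(matrix(c(1, NA, 3, 4), 2)), "missing")
})

test_that("a single full-fraction run reproduces the full-data PCA exactly", {
  set.seed(32)
  m <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, paste0("v", 1:6)))
  res <- run_resampled_pca(m, pca_config(n_runs = 1, fraction = 1, seed = 5))
  expect_equal(res$runs$var_pc1, res$full_var_pct[1], tolerance = 0)
  expect_equal(res$runs$var_pc2, res$full_var_pct[2], tolerance = 0)
  expect_equal(res$variance$sd_pct, c(NA_real_, NA_real_))
})

test_that("two-parameter variance explained matches the closed form", {
  set.seed(33)
  x <- rnorm(50)
  y <- 0.6 * x + rnorm(50, 0, 0.8)
  m <- cbind(a = x, b = y)
  z <- standardize_matrix(m)
  rho <- cor(z[, 1], z[, 2])
  res <- run_resampled_pca(z, pca_config(n_runs = 1, fraction = 1))
  expect_equal(res$runs$var_pc1, 100 * (1 + abs(rho)) / 2, tolerance = 1e-9)
  expect_equal(res$runs$var_pc2, 100 * (1 - abs(rho)) / 2, tolerance = 1e-9)
})

test_that("resampled PCA is seed-reproducible and column-equivariant", {
  set.seed(34)
  m <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("v", 1:6)))
  cfg <- pca_config(n_runs = 25, seed = 17, pc1_ref = "v1", pc2_ref = "v1")
  r1 <- run_resampled_pca(m, cfg)
  r2 <- run_resampled_pca(m, cfg)
  expect_identical(r1$runs, r2$runs)
  expect_identical(r1$top_counts, r2$top_counts)

  perm <- c(4, 1, 6, 2, 5, 3)
  r3 <- run_resampled_pca(m[, perm], cfg)
  expect_identical(r3$top_counts, r1$top_counts[perm])
  expect_equal(r3$runs$var_pc1, r1$runs$var_pc1)
  expect_equal(r3$mean_contribution, r1$mean_contribution[perm])
})

test_that("a dominant-variance parameter always ranks on top", {
  set.seed(35)
  m <- cbind(big = rnorm(40, sd = 10),
             matrix(rnorm(40 * 7), 40, 7,
                    dimnames = list(NULL, paste0("v", 1:7))))
  cfg <- pca_config(n_runs = 100, seed = 2, pc1_ref = "big", pc2_ref = "big")
  res <- run_resampled_pca(m, cfg, scale = FALSE)
  expect_equal(unname(res$top_counts["big"]), 100)
  expect_equal(ranking_table(res)$parameter[1], "big")
})

test_that("exchangeable noise gives near-uniform top-position counts", {
  # within one dataset the ranking is anchored to that sample's realized
  # correlation quirks, so the uniformity of the Monte-Carlo expectation
  # only emerges over fresh datasets
  set.seed(36)
  total <- stats::setNames(numeric(8), paste0("v", 1:8))
  n_data <- 30
  n_runs <- 40
  for (i in seq_len(n_data)) {
    m <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, names(total)))
    cfg <- pca_config(n_runs = n_runs, seed = i, pc1_ref = "v1", pc2_ref = "v1")
    res <- run_resampled_pca(m, cfg)
    expect_equal(sum(res$top_counts), n_runs * 4)
    total <- total + res$top_counts
  }
  prop <- total / (n_data * n_runs)
  # expected appearance probability is top_positions / n_parameters = 1/2
  expect_true(all(abs(prop - 0.5) < 0.1))
})

test_that("orientation pins the reference loading non-negative", {
  co <- generate_cohort(generator_config(seed = 13))
  m <- assemble_severity_matrix(co, sex = "male")
  red <- reduce_parameters(spearman_matrix(m),
                           keep_priority = c("distance_dark", "distance_light"))
  z <- standardize_matrix(m[, red$retained])
  res <- run_resampled_pca(z, pca_config(seed = 13))
  expect_gte(res$loadings["mgs", 1], 0)
  # severe animals score high on PC1: MGS column correlates positively
  expect_gt(cor(res$scores$PC1, z[, "mgs"]), 0)
  # resampled mean variance stays within 3 resampling SDs of the full PCA
  v <- res$variance
  expect_lt(abs(v$mean_pct[1] - res$full_var_pct[1]), 3 * v$sd_pct[1])
  # every retained parameter surfaces among the top ranks somewhere
  expect_true(all(res$top_counts > 0))
})

test_that("degenerate subsamples abort once they dominate", {
  pat <- rbind(c(1, 2, 3), c(4, 5, 6))
  m <- pat[rep(1:2, each = 6), ]
  colnames(m) <- paste0("v", 1:3)
  z <- standardize_matrix(m)
  expect_error(
    suppressWarnings(run_resampled_pca(z, pca_config(n_runs = 10, seed = 1),
                                       scale = FALSE)),
    "degenerate"
  )
})
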