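# Resampled principal component analysis: repeated PCA on random 80%
# subsamples of the standardized severity matrix, reporting the variance
# explained by PC1/PC2 (mean +/- SD over runs) and counting how often each
# parameter ranks among the top contributors.

#' Standardize a severity matrix
#'
#' Centers every column to mean 0 and scales it to unit standard deviation
#' (denominator `n - 1`). Standardization puts parameters with different
#' units (seconds, grams, scores, ng/g) on a common scale before PCA.
#'
#' @param m A numeric matrix, animals in rows.
#' @return The standardized matrix, same attributes.
#' @export
standardize_matrix <- function(m) {
  if (any(is.na(m))) stop("matrix has missing cells", call. = FALSE)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  out <- scale(m, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  for (a in c("day", "sex", "class")) {
    if (!is.null(attr(m, a))) attr(out, a) <- attr(m, a)
  }
  out
}

#' Configuration for resampled PCA
#'
#' @param n_runs Number of resampling runs (default 100).
#' @param fraction Fraction of animals drawn (without replacement) per run
#'   (default 0.8).
#' @param top_positions Number of top ranking positions counted per run
#'   (default 4).
#' @param seed Master seed; run `r` uses the seed stream `seed + r`.
#' @param ranking `"joint"` ranks parameters by the eigenvalue-weighted sum
#'   of squared PC1 and PC2 loadings; `"pc1"` ranks by `|PC1 loading|` only.
#' @param pc1_ref,pc2_ref Reference parameters used to orient the sign of
#'   PC1 and PC2: each component is flipped so its reference parameter
#'   loads non-negatively (default `"mgs"`, so higher PC1 = more severe).
#'   Ignored for a component whose reference is not among the columns.
#' @return A `pca_config` list.
#' @export
pca_config <- function(n_runs = 100, fraction = 0.8, top_positions = 4,
                       seed = 1L, ranking = c("joint", "pc1"),
                       pc1_ref = "mgs", pc2_ref = "mgs") {
  stopifnot(n_runs >= 1, fraction > 0, fraction <= 1, top_positions >= 1)
  structure(
    list(n_runs = as.integer(n_runs), fraction = fraction,
         top_positions = as.integer(top_positions), seed = as.integer(seed),
         ranking = match.arg(ranking), pc1_ref = pc1_ref, pc2_ref = pc2_ref),
    class = "pca_config"
  )
}

# single PCA on rows `idx` of the standardized matrix; covariance
# eigendecomposition via prcomp, PC1/PC2 oriented by reference parameters
pca_once <- function(m, idx, cfg) {
  sub <- m[idx, , drop = FALSE]
  fit <- prcomp(sub, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  if (sum(ev > ev[1] * 1e-12) < 2) return(NULL) # degenerate, rank < 2
  load <- fit$rotation[, 1:2, drop = FALSE]
  scores <- fit$x[, 1:2, drop = FALSE]
  for (comp in 1:2) {
    ref <- if (comp == 1) cfg$pc1_ref else cfg$pc2_ref
    if (ref %in% rownames(load) && load[ref, comp] < 0) {
      load[, comp] <- -load[, comp]
      scores[, comp] <- -scores[, comp]
    }
  }
  list(var_pct = 100 * ev[1:2] / sum(ev), loadings = load, scores = scores,
       eigenvalues = ev[1:2])
}

# contribution of each parameter to the PC1/PC2 plane
pca_contribution <- function(run, ranking) {
  if (ranking == "joint") {
    run$eigenvalues[1] * run$loadings[, 1]^2 +
      run$eigenvalues[2] * run$loadings[, 2]^2
  } else {
    abs(run$loadings[, 1])
  }
}

#' Resampled PCA of a standardized severity matrix
#'
#' Runs `n_runs` PCA fits, each on a random subsample of
#' `ceiling(fraction * n)` animals drawn without replacement, and aggregates
#' the percentage of variance explained by PC1 and PC2 (mean and SD over
#' runs) together with, per parameter, the number of runs in which it
#' ranked within the first `top_positions` contributors to the PC1/PC2
#' plane. A parameter's per-run contribution is
#' `lambda_1 * l_1^2 + lambda_2 * l_2^2` (eigenvalue-weighted squared
#' loadings), or `|PC1 loading|` when `ranking = "pc1"`. One full-data PCA
#' supplies oriented PC1/PC2 scores per animal for downstream clustering.
#'
#' Degenerate subsamples (rank < 2) are skipped with a warning; more than
#' 10% skipped runs aborts.
#'
#' @param m A severity matrix; standardized internally unless
#'   `scale = FALSE` (standardization is idempotent, so passing an already
#'   standardized matrix is fine).
#' @param cfg A [pca_config()].
#' @param scale Standardize columns before resampling? Set to `FALSE` to
#'   run PCA on the raw covariance scale.
#' @return A `cms_pca` list: `runs` (per-run variance tibble), `top_counts`,
#'   `mean_contribution`, `variance` (aggregated mean/SD), `scores`
#'   (full-data oriented PC1/PC2 per animal), `full_var_pct`, `loadings`
#'   (full-data oriented), and the config.
#' @export
run_resampled_pca <- function(m, cfg = pca_config(), scale = TRUE) {
  m <- as.matrix(m)
  if (scale) m <- standardize_matrix(m)
  if (any(is.na(m))) stop("matrix has missing cells", call. = FALSE)
  n <- nrow(m)
  p <- ncol(m)
  n_sub <- ceiling(cfg$fraction * n)
  if (n_sub < p + 1) {
    stop("subsample size ", n_sub, " too small for ", p, " parameters",
         call. = FALSE)
  }
  runs <- vector("list", cfg$n_runs)
  counts <- stats::setNames(integer(p), colnames(m))
  contrib_sum <- stats::setNames(numeric(p), colnames(m))
  skipped <- 0L
  for (r in seq_len(cfg$n_runs)) {
    idx <- sort(with_run_seed(cfg$seed, r, sample.int(n, n_sub)))
    fit <- pca_once(m, idx, cfg)
    if (is.null(fit)) {
      warning("run ", r, " skipped: degenerate subsample", call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    contrib <- pca_contribution(fit, cfg$ranking)
    top <- names(sort(contrib, decreasing = TRUE))[seq_len(cfg$top_positions)]
    counts[top] <- counts[top] + 1L
    contrib_sum <- contrib_sum + contrib
    runs[[r]] <- tibble::tibble(run = r, var_pc1 = fit$var_pct[1],
                                var_pc2 = fit$var_pct[2])
  }
  if (skipped > 0.1 * cfg$n_runs) {
    stop("more than 10% of PCA runs degenerate (", skipped, "/", cfg$n_runs,
         ")", call. = FALSE)
  }
  runs <- dplyr::bind_rows(runs)
  full <- pca_once(m, seq_len(n), cfg)
  if (is.null(full)) stop("full-data PCA is degenerate", call. = FALSE)
  n_ok <- cfg$n_runs - skipped
  structure(
    list(
      runs = runs,
      top_counts = counts,
      mean_contribution = contrib_sum / n_ok,
      variance = tibble::tibble(
        component = c("PC1", "PC2"),
        mean_pct = c(mean(runs$var_pc1), mean(runs$var_pc2)),
        sd_pct = c(sd(runs$var_pc1), sd(runs$var_pc2))
      ),
      scores = tibble::tibble(
        animal_id = rownames(m),
        PC1 = full$scores[, 1], PC2 = full$scores[, 2]
      ),
      full_var_pct = full$var_pct,
      loadings = full$loadings,
      n_skipped = skipped,
      config = cfg
    ),
    class = "cms_pca"
  )
}

#' @export
print.cms_pca <- function(x, ...) {
  v <- x$variance
  cat("<cms_pca> ", nrow(x$runs), " runs; PC1 ",
      sprintf("%.2f%% (SD %.2f)", v$mean_pct[1], v$sd_pct[1]), ", PC2 ",
      sprintf("%.2f%% (SD %.2f)", v$mean_pct[2], v$sd_pct[2]), "\n", sep = "")
  print(ranking_table(x), ...)
  invisible(x)
}

#' Parameter ranking table from resampled PCA
#'
#' Orders parameters by how often they ranked within the top contributing
#' positions across resampling runs; ties are broken by mean contribution,
#' then by name.
#'
#' @param res A [run_resampled_pca()] result.
#' @return A tibble with `parameter`, `top_count`, `mean_contribution`.
#' @export
ranking_table <- function(res) {
  stopifnot(inherits(res, "cms_pca"))
  tbl <- tibble::tibble(
    parameter = names(res$top_counts),
    top_count = as.integer(res$top_counts),
    mean_contribution = as.numeric(res$mean_contribution)
  )
  tbl[order(-tbl$top_count, -tbl$mean_contribution, tbl$parameter), ]
}

#' PCA score plot
#'
#' Oriented full-data PC1/PC2 scores, optionally colored by experimental
#' group (pass the cohort's animal table).
#'
#' @param res A `cms_pca`.
#' @param animals Optional animal table with `animal_id` and `group`.
#' @return A ggplot object.
#' @export
plot_scores <- function(res, animals = NULL) {
  stopifnot(inherits(res, "cms_pca"))
  df <- res$scores
  if (!is.null(animals)) {
    df <- dplyr::left_join(df, animals[, c("animal_id", "group")],
                           by = "animal_id")
    gg <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                           colour = .data$group))
  } else {
    gg <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  }
  gg + ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", res$full_var_pct[1]),
      y = sprintf("PC2 (%.1f%%)", res$full_var_pct[2])
    ) +
    ggplot2::theme_minimal()
}
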