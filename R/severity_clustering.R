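# Severity clustering on the PC1/PC2 score plane: within-cluster sum of
# squares scree for choosing k, 100-fold resampled k-means with severity-
# ordered cluster labels, and per-group allocation reports.

#' Clustering configuration
#'
#' @param k Number of severity clusters (default 4; cluster 1 = lowest,
#'   cluster k = highest observed severity). The scree is advisory and
#'   never overrides `k`.
#' @param n_runs Number of resampling runs (default 100).
#' @param fraction Fraction of animals subsampled per run (default 0.8).
#' @param k_range Range of k values scanned by [scree_wss()].
#' @param n_restarts k-means++ restarts per fit; the best (lowest
#'   within-cluster SS) fit is kept.
#' @param seed Master seed; run `r` uses the stream `seed + r`.
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(k = 4, n_runs = 100, fraction = 0.8,
                           k_range = c(1, 8), n_restarts = 10, seed = 1L) {
  stopifnot(k >= 2, n_runs >= 1, fraction > 0, fraction <= 1,
            length(k_range) == 2, k_range[1] >= 1, k_range[2] >= k_range[1],
            n_restarts >= 1)
  structure(
    list(k = as.integer(k), n_runs = as.integer(n_runs), fraction = fraction,
         k_range = as.integer(k_range), n_restarts = as.integer(n_restarts),
         seed = as.integer(seed)),
    class = "cluster_config"
  )
}

# k-means++ seeding: first center uniform, later centers drawn with
# probability proportional to squared distance from the nearest chosen one
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    if (sum(d2) <= 0) {
      stop("fewer than k distinct points; cannot seed k-means", call. = FALSE)
    }
    pick <- sample.int(n, 1, prob = d2)
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

# best-of-restarts k-means with k-means++ seeding; retries on the rare
# empty-cluster failure of the underlying fit
kmeans_best <- function(x, k, n_restarts, max_retries = 20) {
  if (k == 1) {
    center <- colMeans(x)
    return(list(cluster = rep(1L, nrow(x)), centers = matrix(center, 1),
                tot.withinss = sum(sweep(x, 2, center)^2)))
  }
  if (k == nrow(x)) {
    if (anyDuplicated(x)) {
      stop("fewer than k distinct points; cannot seed k-means", call. = FALSE)
    }
    return(list(cluster = seq_len(k), centers = x, tot.withinss = 0))
  }
  best <- NULL
  attempts <- 0
  restarts_done <- 0
  while (restarts_done < n_restarts && attempts < n_restarts + max_retries) {
    attempts <- attempts + 1
    fit <- tryCatch(
      suppressWarnings(kmeans(x, centers = kmeanspp_centers(x, k),
                              iter.max = 100)),
      error = function(e) NULL
    )
    if (is.null(fit) || any(fit$size == 0)) next
    restarts_done <- restarts_done + 1
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed to produce a non-empty clustering",
                          call. = FALSE)
  best
}

#' Within-cluster sum of squares scree
#'
#' Fits best-of-restarts k-means for every k in the configured range and
#' tabulates the total within-cluster sum of squares, the standard elbow
#' diagnostic for choosing the number of severity clusters. The choice of
#' k remains with the analyst; [cluster_config()] is not modified.
#'
#' @param scores Tibble or matrix of animal PC1/PC2 scores (as produced by
#'   [run_resampled_pca()]).
#' @param cfg A [cluster_config()].
#' @return A tibble with columns `k` and `wss`.
#' @export
scree_wss <- function(scores, cfg = cluster_config()) {
  x <- score_matrix(scores)
  ks <- seq(cfg$k_range[1], cfg$k_range[2])
  if (max(ks) > nrow(x)) {
    stop("k_range upper bound exceeds the number of animals", call. = FALSE)
  }
  wss <- vapply(seq_along(ks), function(i) {
    with_run_seed(cfg$seed, i,
                  kmeans_best(x, ks[i], cfg$n_restarts)$tot.withinss)
  }, numeric(1))
  tibble::tibble(k = ks, wss = wss)
}

score_matrix <- function(scores) {
  if (is.matrix(scores)) {
    x <- scores[, 1:2, drop = FALSE]
    ids <- rownames(scores)
  } else {
    stopifnot(all(c("PC1", "PC2") %in% names(scores)))
    x <- cbind(scores$PC1, scores$PC2)
    ids <- scores$animal_id
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  rownames(x) <- ids
  colnames(x) <- c("PC1", "PC2")
  x
}

#' Resampled k-means severity clustering
#'
#' Per run, a random subsample of `ceiling(fraction * n)` animals is drawn
#' without replacement and k-means (k-means++ seeding, best of
#' `n_restarts`) is fitted on its PC1/PC2 scores. Fitted centroids are
#' ordered by their PC1 coordinate and relabeled 1..k, so cluster 1 is
#' always the lowest-severity and cluster k the highest-severity class
#' (severity increases along the oriented PC1 axis). Every animal —
#' inside or outside the subsample — is then assigned to its nearest
#' centroid, giving each animal one label per run; reported group
#' percentages therefore pool over (animal, run) pairs.
#'
#' Consensus severity thresholds are the midpoints between consecutive
#' run-averaged ordered centroid PC1 coordinates (k - 1 cut points).
#'
#' @param scores Animal PC1/PC2 scores, oriented so PC1 increases with
#'   severity (see [run_resampled_pca()]).
#' @param cfg A [cluster_config()].
#' @return A `cms_allocation` list: `labels` (animals x runs integer
#'   matrix), `fractions` (animals x k, each row summing to 1),
#'   `modal_cluster` (per animal), `thresholds` (k - 1 PC1 cut points),
#'   `mean_centroids` (run-averaged ordered centroids) and the config.
#' @export
resampled_kmeans <- function(scores, cfg = cluster_config()) {
  x <- score_matrix(scores)
  n <- nrow(x)
  k <- cfg$k
  n_sub <- ceiling(cfg$fraction * n)
  if (k > n_sub) stop("k exceeds the subsample size", call. = FALSE)
  labels <- matrix(NA_integer_, n, cfg$n_runs,
                   dimnames = list(rownames(x), NULL))
  centroid_sum <- matrix(0, k, 2)
  for (r in seq_len(cfg$n_runs)) {
    run_fit <- with_run_seed(cfg$seed, r, {
      idx <- sample.int(n, n_sub)
      kmeans_best(x[idx, , drop = FALSE], k, cfg$n_restarts)
    })
    ord <- order(run_fit$centers[, 1])
    centers <- run_fit$centers[ord, , drop = FALSE]
    labels[, r] <- nearest_center(x, centers)
    centroid_sum <- centroid_sum + centers
  }
  mean_centroids <- centroid_sum / cfg$n_runs
  fractions <- t(apply(labels, 1, function(lab) {
    tabulate(lab, nbins = k) / cfg$n_runs
  }))
  colnames(fractions) <- paste0("cluster_", seq_len(k))
  modal <- apply(fractions, 1, which.max)
  thresholds <- (mean_centroids[-k, 1] + mean_centroids[-1, 1]) / 2
  structure(
    list(labels = labels, fractions = fractions,
         modal_cluster = as.integer(modal),
         thresholds = as.numeric(thresholds),
         mean_centroids = mean_centroids, config = cfg),
    class = "cms_allocation"
  )
}

nearest_center <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  max.col(-d2, ties.method = "first")
}

#' @export
print.cms_allocation <- function(x, ...) {
  cat("<cms_allocation> ", nrow(x$labels), " animals, ",
      ncol(x$labels), " runs, k = ", x$config$k, "; PC1 thresholds: ",
      paste(sprintf("%.3f", x$thresholds), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-group severity cluster allocation
#'
#' Pools cluster labels over (animal, run) pairs within each
#' (group, regimen, sex) cell and reports the percentage of assignments
#' falling into each severity cluster, to one decimal place.
#'
#' @param alloc A [resampled_kmeans()] allocation.
#' @param animals Animal table with `animal_id`, `sex`, `group`, `regimen`.
#' @return A tibble with `sex`, `group`, `regimen`, `cluster`, `percent`.
#' @export
allocation_report <- function(alloc, animals) {
  stopifnot(inherits(alloc, "cms_allocation"))
  ids <- rownames(alloc$labels)
  unknown <- setdiff(ids, animals$animal_id)
  if (length(unknown) > 0) {
    stop("animal(s) without a record: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  k <- alloc$config$k
  long <- tibble::tibble(
    animal_id = rep(ids, times = ncol(alloc$labels)),
    cluster = as.integer(alloc$labels)
  )
  long <- dplyr::left_join(
    long, animals[, c("animal_id", "sex", "group", "regimen")],
    by = "animal_id"
  )
  out <- long |>
    dplyr::count(.data$sex, .data$group, .data$regimen, .data$cluster) |>
    dplyr::group_by(.data$sex, .data$group, .data$regimen) |>
    tidyr::complete(cluster = seq_len(k), fill = list(n = 0L)) |>
    dplyr::mutate(percent = round(100 * .data$n / sum(.data$n), 1)) |>
    dplyr::ungroup() |>
    dplyr::select(!"n") |>
    dplyr::arrange(.data$sex, .data$group, .data$regimen, .data$cluster)
  out
}

#' Stacked-bar plot of severity cluster allocation
#'
#' @param report An [allocation_report()] table.
#' @return A ggplot object, one stacked bar per (group, regimen) cell,
#'   faceted by sex.
#' @export
plot_allocation <- function(report) {
  report$cell <- paste(report$group, report$regimen, sep = " ")
  ggplot2::ggplot(report, ggplot2::aes(.data$cell, .data$percent,
                                       fill = factor(.data$cluster))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$sex)) +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1) +
    ggplot2::labs(x = NULL, y = "% of (animal, run) assignments",
                  fill = "severity\ncluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
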