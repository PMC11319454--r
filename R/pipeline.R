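# One-call composite measure scheme: severity matrix -> redundancy filter
# -> resampled PCA -> resampled k-means severity allocation, per sex.

#' Run the full composite measure scheme for one sex
#'
#' Assembles the day-1 severity matrix for the requested sex, screens the
#' preselected parameters for redundancy (Spearman, high pairs collapsed to
#' one representative), runs the 100-fold 80%-resampled PCA on the retained
#' parameters, and allocates animals to ordered severity clusters by
#' 100-fold resampled k-means on the PC1/PC2 plane.
#'
#' @param cohort A `cms_cohort` (e.g. from [load_cohort()] or
#'   [generate_cohort()]).
#' @param sex `"male"` or `"female"`; analyses are always per sex.
#' @param parameters Preselected parameter names (default the 11-parameter
#'   set, [cms_default_parameters()]).
#' @param keep_priority Preferred representatives of correlated parameter
#'   groups (default the phase-resolved distances, matching the usual
#'   exclusion of velocity and wheel-running proxies).
#' @param day Assessment day (default `"day1"`).
#' @param seed Master seed for both resampling stages.
#' @param log_parameters Parameters entered on a log10 scale. Right-skewed,
#'   strictly positive read-outs (latencies, hormone metabolite
#'   concentrations) carry multiplicative noise; on the raw scale their
#'   high-severity values would dominate the standardized variance, so the
#'   CMS takes them as log10 values. Spearman screening is unaffected (log
#'   is monotone); PCA and clustering operate on the transformed scale.
#'   Set to `character()` to analyze every parameter raw.
#' @param pca_cfg,cluster_cfg Optional [pca_config()] / [cluster_config()];
#'   by default constructed from `seed` with standard settings.
#' @return A `cms_result` list: `matrix`, `correlation`, `reduction`,
#'   `pca`, `scree`, `allocation`, `report`.
#' @export
run_cms <- function(cohort, sex = c("male", "female"),
                    parameters = cms_default_parameters(),
                    keep_priority = c("distance_dark", "distance_light"),
                    day = "day1", seed = 1L,
                    log_parameters = c("burrowing_latency", "fcm"),
                    pca_cfg = NULL, cluster_cfg = NULL) {
  sex <- match.arg(sex)
  if (is.null(pca_cfg)) pca_cfg <- pca_config(seed = seed)
  if (is.null(cluster_cfg)) cluster_cfg <- cluster_config(seed = seed)
  m <- assemble_severity_matrix(cohort, parameters, day = day, sex = sex)
  for (p in intersect(log_parameters, colnames(m))) {
    if (any(m[, p] <= 0)) {
      stop("cannot log-transform '", p, "': non-positive values", call. = FALSE)
    }
    m[, p] <- log10(m[, p])
  }
  correlation <- spearman_matrix(m)
  reduction <- reduce_parameters(correlation, keep_priority = keep_priority)
  m_red <- standardize_matrix(m[, reduction$retained, drop = FALSE])
  pca <- run_resampled_pca(m_red, pca_cfg)
  scree <- scree_wss(pca$scores, cluster_cfg)
  allocation <- resampled_kmeans(pca$scores, cluster_cfg)
  report <- allocation_report(allocation, cohort$animals)
  structure(
    list(matrix = m, correlation = correlation, reduction = reduction,
         pca = pca, scree = scree, allocation = allocation, report = report,
         sex = sex),
    class = "cms_result"
  )
}

#' @export
print.cms_result <- function(x, ...) {
  cat("<cms_result> sex =", x$sex, "\n")
  print(x$reduction)
  print(x$pca)
  print(x$allocation)
  invisible(x)
}
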