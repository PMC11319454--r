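# Spearman redundancy screening: flag correlated parameter pairs, and
# collapse groups of highly correlated parameters to a single representative
# before principal component analysis.

#' Pairwise Spearman correlation of a severity matrix
#'
#' Computes the Spearman rank correlation (midrank ties) between every pair
#' of parameters, with two-sided p-values from the standard t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Pairs are *flagged* as correlated at `|r| > 0.5` with `p < 0.05` and
#' *high* at `|r| > 0.7` with `p < 0.05`; the high pairs drive parameter
#' exclusion in [reduce_parameters()]. The thresholds are a screening rule,
#' so p-values are deliberately not adjusted for multiple testing.
#'
#' @param m A [assemble_severity_matrix()] matrix (or any numeric matrix
#'   with named columns), animals in rows.
#' @param flag_r,high_r Absolute correlation thresholds for flagged and high
#'   pairs.
#' @param alpha Significance threshold applied to both classes.
#' @return A `cms_correlation` list: `r` and `p` matrices, tibbles `flagged`
#'   and `high` of qualifying pairs, and the thresholds used.
#' @export
spearman_matrix <- function(m, flag_r = 0.5, high_r = 0.7, alpha = 0.05) {
  m <- as.matrix(m)
  if (nrow(m) < 3) stop("need at least 3 animals", call. = FALSE)
  if (ncol(m) < 2) stop("need at least 2 parameters", call. = FALSE)
  constant <- apply(m, 2, function(x) length(unique(x[!is.na(x)])) < 2)
  if (any(constant)) {
    warning("constant column(s), correlations recorded as missing: ",
            paste(colnames(m)[constant], collapse = ", "), call. = FALSE)
  }
  r <- suppressWarnings(cor(m, method = "spearman", use = "pairwise.complete.obs"))
  n <- nrow(m)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  diag(p) <- NA_real_
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  pair_tbl <- tibble::tibble(
    parameter_1 = colnames(r)[pairs[, 1]],
    parameter_2 = colnames(r)[pairs[, 2]],
    r = r[pairs],
    p = p[pairs]
  )
  ok <- !is.na(pair_tbl$r)
  flagged <- pair_tbl[ok & abs(pair_tbl$r) > flag_r & pair_tbl$p < alpha, ]
  high <- pair_tbl[ok & abs(pair_tbl$r) > high_r & pair_tbl$p < alpha, ]
  structure(
    list(r = r, p = p, pairs = pair_tbl, flagged = flagged, high = high,
         flag_r = flag_r, high_r = high_r, alpha = alpha),
    class = "cms_correlation"
  )
}

#' @export
print.cms_correlation <- function(x, ...) {
  cat("<cms_correlation> ", ncol(x$r), " parameters; ",
      nrow(x$flagged), " flagged pair(s) (|r| > ", x$flag_r, "), ",
      nrow(x$high), " high pair(s) (|r| > ", x$high_r, ")\n", sep = "")
  invisible(x)
}

#' Reduce a parameter set by collapsing highly correlated groups
#'
#' Builds the graph whose edges are the *high* correlation pairs
#' (`|r| > 0.7`, `p < 0.05`) and keeps exactly one parameter per connected
#' component: the component member named first in `keep_priority` if one is
#' named, otherwise the member with the largest mean `|r|` to the rest of
#' its component (ties broken lexicographically). Parameters outside any
#' high-correlation component are always retained. Naming two members of
#' the same component in `keep_priority` is ambiguous and raises an error.
#'
#' @param report A [spearman_matrix()] result.
#' @param keep_priority Ordered character vector of parameters to prefer as
#'   component representatives.
#' @return A `cms_reduction` list: `retained` and `excluded` parameter
#'   names, and `components` (list of component memberships).
#' @export
reduce_parameters <- function(report, keep_priority = character()) {
  stopifnot(inherits(report, "cms_correlation"))
  params <- colnames(report$r)
  high <- report$high
  if (nrow(high) == 0) {
    comps <- list()
  } else {
    g <- igraph::graph_from_data_frame(
      high[, c("parameter_1", "parameter_2")], directed = FALSE,
      vertices = data.frame(name = params)
    )
    membership <- igraph::components(g)$membership
    sizes <- table(membership)
    comp_ids <- names(sizes)[sizes > 1]
    comps <- lapply(comp_ids, function(id) names(membership)[membership == id])
  }
  excluded <- character()
  for (comp in comps) {
    prio <- intersect(keep_priority, comp)
    if (length(prio) > 1) {
      stop("keep_priority names several members of one correlated group (",
           paste(comp, collapse = ", "), "): ", paste(prio, collapse = ", "),
           call. = FALSE)
    }
    if (length(prio) == 1) {
      keeper <- prio
    } else {
      mean_abs_r <- vapply(comp, function(p) {
        mean(abs(report$r[p, setdiff(comp, p)]), na.rm = TRUE)
      }, numeric(1))
      ord <- order(-mean_abs_r, comp)
      keeper <- comp[ord[1]]
    }
    excluded <- c(excluded, setdiff(comp, keeper))
  }
  structure(
    list(retained = setdiff(params, excluded), excluded = excluded,
         components = comps),
    class = "cms_reduction"
  )
}

#' @export
print.cms_reduction <- function(x, ...) {
  cat("<cms_reduction> retained ", length(x$retained), " parameter(s); ",
      "excluded: ",
      if (length(x$excluded)) paste(x$excluded, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

#' Correlation heat map
#'
#' Visualizes the Spearman correlation matrix of a [spearman_matrix()]
#' report as a ggplot2 tile map, the usual companion to the redundancy
#' screen.
#'
#' @param report A `cms_correlation`.
#' @return A ggplot object.
#' @export
plot_correlation <- function(report) {
  stopifnot(inherits(report, "cms_correlation"))
  df <- as.data.frame(as.table(report$r))
  names(df) <- c("parameter_1", "parameter_2", "r")
  ggplot2::ggplot(df, ggplot2::aes(.data$parameter_1, .data$parameter_2,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
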