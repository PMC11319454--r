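# Synthetic cohort generator. Emulates the study design (3 experimental
# groups, 4 analgesic regimens, 2 sexes, 8 animals per cell = 144 animals)
# and the statistical structure the CMS pipeline assumes: a 4-level latent
# postsurgical severity per animal, severity-dependent directional shifts
# in 8 core parameters, near-collinear locomotion read-outs to exercise the
# redundancy filter, and right-censored burrowing latencies.

#' Default latent severity means per (group, regimen)
#'
#' Cell means on the abstract 0-3 severity scale. Naive-control and
#' drug-control animals sit near the bottom of the scale (drug regimens
#' add a small tolerability burden, largest for the opioid-containing
#' `+NO`), surgery animals sit substantially higher, with the `+NO`
#' regimen most and `+N` least severe — reproducing the qualitative
#' ordering of severity-cluster occupancy across regimens.
#'
#' @return A tibble with columns `group`, `regimen`, `mean`.
#' @export
default_latent_means <- function() {
  tibble::tribble(
    ~group,          ~regimen, ~mean,
    "naive-control", "none",   0.2,
    "drug-control",  "+N",     0.45,
    "drug-control",  "+NL",    0.6,
    "drug-control",  "+NO",    1.1,
    "drug-control",  "+NLO",   0.8,
    "surgery",       "+N",     1.7,
    "surgery",       "+NL",    2.0,
    "surgery",       "+NO",    2.7,
    "surgery",       "+NLO",   2.2
  )
}

#' Default per-parameter severity effects
#'
#' Each of the 8 core parameters shifts directionally with the integer
#' latent severity level `L` (0-3): grimace score, corticosterone
#' metabolites, Neuro score and burrowing latency increase; locomotion,
#' nest score and body weight change decrease. Continuous parameters are
#' Gaussian (`value = base + slope * L + noise`), ordinal scores are the
#' same draw rounded and clamped to their scale, and right-skewed
#' parameters (FCM, burrowing latency) are log-normal with the linear
#' model on the log scale. Noise SDs are calibrated so that distinct core
#' parameters correlate at most moderately with each other (|Spearman r|
#' around 0.4-0.5) while the severity signal stays clearly recoverable;
#' only the engineered locomotion proxies exceed the high-correlation
#' threshold.
#'
#' @return A tibble with columns `parameter`, `family`, `base`, `slope`,
#'   `noise_sd`, `min`, `max`.
#' @export
default_parameter_effects <- function() {
  tibble::tribble(
    ~parameter,           ~family,     ~base, ~slope, ~noise_sd, ~min, ~max,
    "mgs",                "gaussian",   0.30,   0.35,      0.35,    0,    2,
    "body_weight_change", "gaussian",   0.50,  -2.80,      2.80, -Inf,  Inf,
    "nest_score",         "ordinal",    4.80,  -0.90,      0.90,    1,    5,
    "neuro_score",        "ordinal",    0.50,   2.20,      2.20,    0,   20,
    "fcm",                "lognormal",  3.90,   0.30,      0.30,    0,  Inf,
    "burrowing_latency",  "lognormal",  6.50,   0.90,      0.90,    0, 72000,
    "distance_dark",      "gaussian", 260.00, -45.00,     45.00,    1,  Inf,
    "distance_light",     "gaussian",  90.00, -15.00,     15.00,  0.5,  Inf
  )
}

#' Synthetic cohort generator configuration
#'
#' @param n_per_cell Animals per (sex, group, regimen) cell (default 8;
#'   with the 9 group/regimen cells and 2 sexes this gives 144 animals).
#' @param latent_means Tibble of latent severity means per cell, see
#'   [default_latent_means()].
#' @param latent_sd SD of the continuous latent severity draw around its
#'   cell mean; the draw is clamped to `[0, 3]` and rounded to the integer
#'   severity level that drives all parameters.
#' @param effects Per-parameter effect table, see
#'   [default_parameter_effects()].
#' @param collinearity Named vector of target Pearson correlations for the
#'   engineered locomotion proxies: `velocity` (velocity vs distance, per
#'   phase) and `vwr` (wheel running vs dark-phase distance). Values must
#'   lie strictly inside `(-1, 1)` excluding 0.
#' @param window Burrowing observation window (s); latencies are censored
#'   (clamped) there.
#' @param seed Master seed; identical config + seed gives a bit-identical
#'   cohort.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_per_cell = 8,
                             latent_means = default_latent_means(),
                             latent_sd = 0.45,
                             effects = default_parameter_effects(),
                             collinearity = c(velocity = 0.9, vwr = 0.85),
                             window = 72000,
                             seed = 1L) {
  stopifnot(n_per_cell >= 1, latent_sd >= 0, window > 0,
            all(c("velocity", "vwr") %in% names(collinearity)))
  bad <- collinearity[abs(collinearity) >= 1 | collinearity == 0]
  if (length(bad) > 0) {
    stop("collinearity target(s) out of the attainable range 0 < |r| < 1: ",
         paste(names(bad), "=", bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(n_per_cell = as.integer(n_per_cell), latent_means = latent_means,
         latent_sd = latent_sd, effects = effects,
         collinearity = collinearity, window = window,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# add noise to a linear proxy of `x` so that cor(x, proxy) targets r
make_proxy <- function(x, beta, r) {
  signal <- beta * x
  noise_sd <- abs(beta) * sd(x) * sqrt(1 / r^2 - 1)
  signal + rnorm(length(x), 0, noise_sd)
}

#' Generate a synthetic cohort
#'
#' Draws, per animal, a continuous latent severity around its cell mean,
#' integerizes it to a 4-level severity (levels 1-4), and emits the day-1
#' severity parameters plus the raw baseline observations needed by the
#' derived-parameter functions (baseline body weights, baseline burrowing
#' latency, baseline grimace score). Velocity (dark/light) and voluntary
#' wheel running (dark) are affine proxies of the matching distance
#' parameter with noise tuned to the configured collinearity targets, so
#' the redundancy filter has real work to do.
#'
#' @param cfg A [generator_config()].
#' @return A `cms_synth_cohort` (subclass of `cms_cohort`) whose planted
#'   severity levels are recoverable with [planted_truth()].
#' @export
generate_cohort <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  with_run_seed(cfg$seed, 0L, generate_cohort_impl(cfg))
}

generate_cohort_impl <- function(cfg) {
  cells <- dplyr::bind_rows(
    dplyr::mutate(cfg$latent_means, sex = "male"),
    dplyr::mutate(cfg$latent_means, sex = "female")
  )
  cells <- cells[rep(seq_len(nrow(cells)), each = cfg$n_per_cell), ]
  n <- nrow(cells)
  animals <- tibble::tibble(
    animal_id = sprintf("M%03d", seq_len(n)),
    sex = cells$sex,
    group = cells$group,
    regimen = cells$regimen,
    batch = ifelse(cells$sex == "male", "B1", "B2")
  )
  s <- pmin(pmax(rnorm(n, cells$mean, cfg$latent_sd), 0), 3)
  level <- as.integer(round(s))

  day1 <- matrix(NA_real_, n, 0)
  for (i in seq_len(nrow(cfg$effects))) {
    e <- cfg$effects[i, ]
    lin <- e$base + e$slope * level + rnorm(n, 0, e$noise_sd)
    val <- switch(e$family,
      gaussian = lin,
      ordinal = round(lin),
      lognormal = exp(lin),
      stop("unknown effect family: ", e$family)
    )
    val <- pmin(pmax(val, e$min), e$max)
    day1 <- cbind(day1, val)
    colnames(day1)[ncol(day1)] <- e$parameter
  }
  # per-sex locomotion proxies so the collinearity targets hold within the
  # stratum the filter actually sees
  vel_d <- vel_l <- vwr <- numeric(n)
  for (sx in c("male", "female")) {
    sel <- animals$sex == sx
    vel_d[sel] <- make_proxy(day1[sel, "distance_dark"], 0.015,
                             cfg$collinearity[["velocity"]])
    vel_l[sel] <- make_proxy(day1[sel, "distance_light"], 0.015,
                             cfg$collinearity[["velocity"]])
    vwr[sel] <- pmax(make_proxy(day1[sel, "distance_dark"], 15,
                                cfg$collinearity[["vwr"]]), 0)
  }
  day1 <- cbind(day1, velocity_dark = vel_d, velocity_light = vel_l,
                vwr_dark = vwr)

  # raw baselines feeding the derived-parameter functions
  bw_mean <- rnorm(n, ifelse(animals$sex == "male", 25, 21.5), 1.2)
  bw_bl1 <- bw_mean + rnorm(n, 0, 0.15)
  bw_bl2 <- bw_mean + rnorm(n, 0, 0.15)
  bw_day1 <- bw_mean * (1 + day1[, "body_weight_change"] / 100)
  burrow_bl <- pmin(exp(rnorm(n, 6.5, 0.6)), cfg$window)
  mgs_bl <- pmin(pmax(rnorm(n, 0.25, 0.2), 0), 2)

  phase_of <- function(p) {
    if (grepl("_dark$", p)) "dark" else if (grepl("_light$", p)) "light" else "n/a"
  }
  day1_long <- tidyr::pivot_longer(
    tibble::as_tibble(day1) |>
      dplyr::mutate(animal_id = animals$animal_id, .before = 1),
    cols = !"animal_id", names_to = "parameter", values_to = "value"
  )
  day1_long$phase <- vapply(day1_long$parameter, phase_of, character(1))
  day1_long$timepoint <- "day1"
  extra <- tibble::tibble(
    animal_id = rep(animals$animal_id, 5),
    parameter = rep(c("body_weight", "body_weight", "body_weight",
                      "burrowing_latency", "mgs"), each = n),
    phase = "n/a",
    timepoint = rep(c("BL1", "BL2", "day1", "BL", "BL"), each = n),
    value = c(bw_bl1, bw_bl2, bw_day1, burrow_bl, mgs_bl)
  )
  observations <- dplyr::bind_rows(
    day1_long[, c("animal_id", "parameter", "phase", "timepoint", "value")],
    extra
  ) |>
    dplyr::arrange(.data$animal_id, .data$parameter, .data$timepoint)

  cohort <- new_cohort(animals, observations)
  attr(cohort, "truth") <- tibble::tibble(
    animal_id = animals$animal_id,
    latent = s,
    level = level + 1L # severity levels 1..4, aligned with cluster indices
  )
  attr(cohort, "config") <- cfg
  class(cohort) <- c("cms_synth_cohort", class(cohort))
  cohort
}

#' Planted severity truth of a synthetic cohort
#'
#' Returns the integer severity level (1 = lowest, 4 = highest) planted in
#' each animal of a cohort produced by [generate_cohort()], for parameter-
#' recovery scoring against the severity clusters.
#'
#' @param cohort A `cms_synth_cohort`.
#' @return A tibble with `animal_id`, `latent` (continuous draw) and
#'   `level` (integerized, 1-4).
#' @export
planted_truth <- function(cohort) {
  if (!inherits(cohort, "cms_synth_cohort") || is.null(attr(cohort, "truth"))) {
    stop("not a cohort generated by generate_cohort(); no planted truth",
         call. = FALSE)
  }
  attr(cohort, "truth")
}
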