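# Derived severity parameters: grimace scale aggregates, relative body
# weight change, censored burrowing latency, and the carprofen drinking
# water concentration.

#' Construct a grimace image score table
#'
#' One table holds the action-unit scores for all images of a single animal
#' at a single timepoint: at most 10 images, five action units (orbital
#' tightening, nose bulge, cheek bulge, ear position, whisker change), each
#' scored 0 (not present), 1 (moderately present) or 2 (obviously present),
#' or `NA` where an action unit could not be evaluated on an image.
#'
#' @param scores Numeric matrix or data frame, images in rows, the five
#'   action units in columns (named as in [mgs_action_units()]).
#' @return A validated numeric matrix of class `grimace_scores`.
#' @export
grimace_scores <- function(scores) {
  m <- as.matrix(scores)
  storage.mode(m) <- "double"
  units <- mgs_action_units()
  if (is.null(colnames(m)) && ncol(m) == length(units)) colnames(m) <- units
  if (!setequal(colnames(m), units)) {
    stop("grimace score columns must be exactly the five action units: ",
         paste(units, collapse = ", "), call. = FALSE)
  }
  m <- m[, units, drop = FALSE]
  if (nrow(m) > 10) stop("at most 10 images per animal and timepoint",
                         call. = FALSE)
  ok <- is.na(m) | m %in% c(0, 1, 2)
  if (!all(ok)) stop("grimace scores must be 0, 1, 2 or NA", call. = FALSE)
  structure(m, class = c("grimace_scores", "matrix", "array"))
}

#' Mean mouse grimace scale score
#'
#' Arithmetic mean over all scored (image, action-unit) cells; cells where
#' an action unit could not be evaluated are excluded from both numerator
#' and denominator, so partial scorings still yield a valid mean.
#'
#' @param scores A [grimace_scores()] table.
#' @return Mean MGS score in `[0, 2]`.
#' @export
mgs_mean <- function(scores) {
  scores <- grimace_scores(scores)
  if (all(is.na(scores))) stop("no assessable action units", call. = FALSE)
  mean(scores, na.rm = TRUE)
}

#' Sum mouse grimace scale score
#'
#' For each action unit the mean score over images with an assessable score
#' is computed; the sum score adds these per-unit means. With the whisker
#' change unit included the range is `[0, 10]`; without it, `[0, 8]`.
#' Action units with no assessable image are omitted from the sum.
#'
#' @param scores A [grimace_scores()] table.
#' @param include_whiskers Include the whisker change action unit?
#' @return Sum MGS score.
#' @export
mgs_sum <- function(scores, include_whiskers = TRUE) {
  scores <- grimace_scores(scores)
  if (all(is.na(scores))) stop("no assessable action units", call. = FALSE)
  if (!include_whiskers) {
    scores <- scores[, setdiff(colnames(scores), "whisker_change"), drop = FALSE]
  }
  unit_means <- colMeans(scores, na.rm = TRUE)
  sum(unit_means[!is.nan(unit_means)])
}

#' Relative body weight change
#'
#' Percentage change of each weight relative to the animal's mean baseline
#' weight: `100 * (w - mean(baseline)) / mean(baseline)`.
#'
#' @param weights Numeric vector of body weights (g) at the timepoints of
#'   interest.
#' @param baseline Numeric vector of baseline body weights (g).
#' @return Numeric vector of percentage changes, same length as `weights`.
#' @export
body_weight_change <- function(weights, baseline) {
  if (length(baseline) == 0) stop("baseline is empty", call. = FALSE)
  if (any(!is.finite(c(weights, baseline))) ||
      any(c(weights, baseline) <= 0)) {
    stop("body weights must be positive and finite", call. = FALSE)
  }
  mb <- mean(baseline)
  100 * (weights - mb) / mb
}

#' Construct a burrowing bout log
#'
#' Video-scored burrowing bouts within one observation window. Bouts are
#' `(start, end)` intervals in seconds from window start; they must be
#' ordered, non-overlapping and inside the window.
#'
#' @param starts,ends Numeric vectors of bout start/end times (s); may be
#'   empty (no burrowing observed).
#' @param window Observation window length (s); default 72000 s (20 h).
#' @return A `burrowing_log` list.
#' @export
burrowing_log <- function(starts = numeric(), ends = numeric(), window = 72000) {
  stopifnot(length(starts) == length(ends), window > 0)
  if (length(starts) > 0) {
    if (any(ends <= starts)) stop("bout ends must exceed starts", call. = FALSE)
    if (any(starts < 0) || any(ends > window)) {
      stop("bouts must lie within the observation window", call. = FALSE)
    }
    if (is.unsorted(starts, strictly = TRUE) ||
        any(starts[-1] < ends[-length(ends)])) {
      stop("bouts must be ordered and non-overlapping", call. = FALSE)
    }
  }
  structure(list(starts = as.numeric(starts), ends = as.numeric(ends),
                 window = as.numeric(window)),
            class = "burrowing_log")
}

#' Latency to burrow with censoring
#'
#' The latency is the start time of the first qualifying burrowing episode.
#' An episode qualifies if (a) a single bout lasts more than `min_bout`
#' seconds, or (b) a chain of bouts separated by breaks of at most
#' `max_break` seconds accumulates more than `bridged_min` seconds of
#' burrowing. When no episode qualifies the latency is right-censored at the
#' window length (72000 s for the standard 20-h overnight window).
#'
#' @param log A [burrowing_log()].
#' @param min_bout Single-bout qualification threshold (s), strict.
#' @param bridged_min Chained-bout qualification threshold (s), strict.
#' @param max_break Longest break allowed inside a chain (s), inclusive.
#' @return A list with `latency` (s) and `censored` (logical).
#' @export
burrowing_latency <- function(log, min_bout = 10, bridged_min = 20,
                              max_break = 5) {
  stopifnot(inherits(log, "burrowing_log"))
  starts <- log$starts
  durations <- log$ends - log$starts
  n <- length(starts)
  for (i in seq_len(n)) {
    if (durations[i] > min_bout) {
      return(list(latency = starts[i], censored = FALSE))
    }
    # chain forward while breaks stay short; chains may span many bouts
    total <- durations[i]
    j <- i
    while (j < n && (starts[j + 1] - log$ends[j]) <= max_break) {
      j <- j + 1
      total <- total + durations[j]
      if (total > bridged_min) {
        return(list(latency = starts[i], censored = FALSE))
      }
    }
  }
  list(latency = log$window, censored = TRUE)
}

#' Change in burrowing latency from baseline
#'
#' @param post Postsurgical latency (s), as returned by
#'   [burrowing_latency()] (the `latency` element or a bare number).
#' @param baseline Baseline latency (s).
#' @return `post - baseline` in seconds; negative values mean faster
#'   burrowing than at baseline.
#' @export
delta_burrowing_latency <- function(post, baseline) {
  if (is.list(post)) post <- post$latency
  if (is.list(baseline)) baseline <- baseline$latency
  post - baseline
}

#' Carprofen drinking-water stock concentration
#'
#' Concentration of drug in the drinking water needed to deliver a target
#' daily oral dose, given the batch's mean body weight and mean daily water
#' intake (measured gravimetrically; 1 g intake is taken as 1 ml):
#' `dose[mg/kg/day] * bodyweight[kg] / intake[ml/day]`.
#'
#' An optional subtractive bottle-drip correction (g per weighing) is
#' applied to the intake before use; the default is 0.
#'
#' @param dose Target dose in mg per kg body weight per day.
#' @param body_weight_g Mean body weight of the batch (g).
#' @param intake_g Mean daily water intake of the batch (g ~ ml).
#' @param drip_correction_g Bottle-drip correction subtracted from intake.
#' @return Concentration in mg/ml.
#' @export
drinking_water_concentration <- function(dose, body_weight_g, intake_g,
                                         drip_correction_g = 0) {
  stopifnot(dose >= 0, body_weight_g > 0)
  intake <- intake_g - drip_correction_g
  if (intake <= 0) stop("daily intake must be positive after drip correction",
                        call. = FALSE)
  dose * (body_weight_g / 1000) / intake
}
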