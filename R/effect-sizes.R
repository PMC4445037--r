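#' Hedges' g standardized mean difference between two arms
#'
#' Bias-corrected standardized mean difference of arm X versus arm Y:
#' pooled SD \eqn{s_p = \sqrt{((n_x-1)s_x^2 + (n_y-1)s_y^2)/(n_x+n_y-2)}},
#' \eqn{d = (\bar x - \bar y)/s_p}, correction
#' \eqn{J = 1 - 3/(4(n_x+n_y-2)-1)}, \eqn{g = Jd}, sampling variance
#' \eqn{(n_x+n_y)/(n_x n_y) + g^2/(2(n_x+n_y))}. Outcomes are severity
#' scores (pain, dysfunction), so negative g favors arm X.
#'
#' @param arm_x,arm_y Lists or one-row data frames with `n`, `mean`, `sd`
#'   (and optionally `study`, `treatment`).
#' @return A `contrast_estimate`: `study`, `comparison` (X vs Y), `effect`,
#'   `variance`, `scale = "smd"`.
#' @export
#' @examples
#' hedges_g(list(n = 100, mean = 1, sd = 2), list(n = 100, mean = 2, sd = 2))
hedges_g <- function(arm_x, arm_y) {
  nx <- arm_x$n; ny <- arm_y$n
  if (!is.null(arm_x$study) && !is.null(arm_y$study) &&
      arm_x$study != arm_y$study)
    stop("arms come from different studies", call. = FALSE)
  if (arm_x$sd <= 0 || arm_y$sd <= 0) stop("sd must be positive", call. = FALSE)
  if (nx + ny < 3) stop("need nx + ny >= 3", call. = FALSE)
  sp2 <- ((nx - 1) * arm_x$sd^2 + (ny - 1) * arm_y$sd^2) / (nx + ny - 2)
  if (sp2 == 0) stop("degenerate data: pooled SD is zero", call. = FALSE)
  d <- (arm_x$mean - arm_y$mean) / sqrt(sp2)
  J <- 1 - 3 / (4 * (nx + ny - 2) - 1)
  g <- J * d
  v <- (nx + ny) / (nx * ny) + g^2 / (2 * (nx + ny))
  new_contrast(arm_x, arm_y, g, v, "smd")
}

#' Log odds ratio between two binary-outcome arms
#'
#' From the 2x2 table a = events_x, b = n_x - events_x, c = events_y,
#' d = n_y - events_y: effect \eqn{\ln(ad/(bc))}, variance
#' \eqn{1/a + 1/b + 1/c + 1/d}. If any cell is zero, `zero_cell` (the
#' Haldane-Anscombe 0.5 by default) is added to all four cells first.
#' Double-zero trials (no events, or all events, in both arms) still give
#' finite output but are flagged for exclusion from classical pooling; the
#' Bayesian binomial model needs no correction and uses the raw counts.
#'
#' @param arm_x,arm_y Lists or one-row data frames with `n`, `events`.
#' @param zero_cell Continuity correction added to all cells when any cell
#'   is zero.
#' @return A `contrast_estimate` with `scale = "log_or"` and a
#'   `double_zero` flag.
#' @export
#' @examples
#' log_odds_ratio(list(n = 100, events = 20), list(n = 100, events = 10))
log_odds_ratio <- function(arm_x, arm_y, zero_cell = 0.5) {
  if (!is.null(arm_x$study) && !is.null(arm_y$study) &&
      arm_x$study != arm_y$study)
    stop("arms come from different studies", call. = FALSE)
  a <- arm_x$events; b <- arm_x$n - arm_x$events
  cc <- arm_y$events; d <- arm_y$n - arm_y$events
  double_zero <- (a == 0 && cc == 0) || (b == 0 && d == 0)
  if (min(a, b, cc, d) == 0) {
    a <- a + zero_cell; b <- b + zero_cell
    cc <- cc + zero_cell; d <- d + zero_cell
  }
  est <- new_contrast(arm_x, arm_y, log((a * d) / (b * cc)),
                      1 / a + 1 / b + 1 / cc + 1 / d, "log_or")
  est$double_zero <- double_zero
  est
}

new_contrast <- function(arm_x, arm_y, effect, variance, scale) {
  structure(list(
    study = if (!is.null(arm_x$study)) arm_x$study else NA_character_,
    comparison = c(
      if (!is.null(arm_x$treatment)) arm_x$treatment else "X",
      if (!is.null(arm_y$treatment)) arm_y$treatment else "Y"),
    effect = unname(effect), variance = unname(variance), scale = scale),
    class = "contrast_estimate")
}

#' @export
print.contrast_estimate <- function(x, ...) {
  lab <- if (x$scale == "smd") "SMD (Hedges' g)" else "log odds ratio"
  cat(sprintf("%s, %s vs %s: %.4f (variance %.5f)\n", lab,
              x$comparison[1], x$comparison[2], x$effect, x$variance))
  if (isTRUE(x$double_zero)) cat("  [double-zero trial]\n")
  invisible(x)
}

#' Per-study contrasts for one comparison
#'
#' Computes, for every study containing both treatments, the effect of
#' `comparison[1]` versus `comparison[2]` ([hedges_g()] or
#' [log_odds_ratio()] according to the outcome kind).
#'
#' @param data An `arm_data` data frame.
#' @param comparison Character vector `c(X, Y)`.
#' @param outcome_kind Defaults to the attribute carried by `data`.
#' @return Data frame `study`, `effect`, `variance`, `double_zero` with the
#'   scale and comparison as attributes.
#' @export
pairwise_contrasts <- function(data, comparison,
                               outcome_kind = outcome_kind_of(data)) {
  stopifnot(length(comparison) == 2, comparison[1] != comparison[2])
  studies <- unique(data$study)
  rows <- list()
  for (s in studies) {
    arms <- data[data$study == s, , drop = FALSE]
    if (!all(comparison %in% arms$treatment)) next
    ax <- as.list(arms[arms$treatment == comparison[1], , drop = FALSE])
    ay <- as.list(arms[arms$treatment == comparison[2], , drop = FALSE])
    est <- if (outcome_kind == "continuous") hedges_g(ax, ay)
           else log_odds_ratio(ax, ay)
    rows[[length(rows) + 1]] <- data.frame(
      study = s, effect = est$effect, variance = est$variance,
      double_zero = isTRUE(est$double_zero), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(study = character(), effect = numeric(), variance = numeric(),
               double_zero = logical())
  attr(out, "scale") <- if (outcome_kind == "continuous") "smd" else "log_or"
  attr(out, "comparison") <- comparison
  out
}

#' Outcome-scale hierarchies
#'
#' Default priority orderings used when a trial reports several pain or
#' function scales: the highest-ranked reported scale is analyzed. `"other"`
#' acts as a wildcard matching any remaining scale. Both are plain
#' character vectors, so analyses can supply their own ordering.
#'
#' @return Character vector of scale names, highest priority first.
#' @name hierarchies
NULL

#' @rdname hierarchies
#' @export
pain_hierarchy <- function() c("VAS_walking", "WOMAC_pain", "VAS_global", "other")

#' @rdname hierarchies
#' @export
function_hierarchy <- function() c("WOMAC_function", "WOMAC_total", "Lequesne", "other")

#' Select the reported outcome highest on a scale hierarchy
#'
#' @param candidates Named list (names are scale names) of reported outcome
#'   summaries, or a data frame with a `scale` column.
#' @param hierarchy Character vector of scale names, highest priority
#'   first; `"other"` matches any candidate.
#' @return The chosen candidate (list element or data frame row), with the
#'   winning scale name in attribute `"scale"`.
#' @export
#' @examples
#' select_outcome(list(WOMAC_total = 1, WOMAC_function = 2), function_hierarchy())
select_outcome <- function(candidates, hierarchy) {
  stopifnot(length(hierarchy) > 0, !anyDuplicated(hierarchy))
  scales <- if (is.data.frame(candidates)) candidates$scale else names(candidates)
  if (length(scales) == 0) stop("no candidates supplied", call. = FALSE)
  pick <- NULL
  for (h in hierarchy) {
    hit <- if (h == "other") which(!scales %in% hierarchy)
           else which(scales == h)
    if (length(hit)) { pick <- hit[1]; break }
  }
  if (is.null(pick))
    stop("no candidate matches the hierarchy", call. = FALSE)
  out <- if (is.data.frame(candidates)) candidates[pick, , drop = FALSE]
         else candidates[[pick]]
  attr(out, "scale") <- scales[pick]
  out
}
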