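#' DerSimonian-Laird random-effects pooling
#'
#' Classical moment-based random-effects meta-analysis of one comparison:
#' fixed-effect weights \eqn{w_i = 1/v_i}, Cochran's
#' \eqn{Q = \sum w_i (y_i - \bar y_{FE})^2}, heterogeneity
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w - \sum w^2 / \sum w))},
#' random-effects weights \eqn{w_i^* = 1/(v_i + \tau^2)}, pooled effect
#' \eqn{\sum w_i^* y_i / \sum w_i^*} with Wald 95% CI (1.96 SE), and
#' \eqn{I^2 = \max(0, 100 (Q - df)/Q)}. With a single study the pooled
#' effect is that study and Q, tau-squared and I-squared are zero.
#' Log-odds-ratio results are reported exponentiated by the print method.
#'
#' @param x Either a contrasts data frame from [pairwise_contrasts()] or a
#'   numeric vector of effects.
#' @param variance Numeric vector of sampling variances (when `x` is a
#'   vector).
#' @param scale `"smd"` or `"log_or"`; taken from `x` when available.
#' @param drop_double_zero Drop trials flagged double-zero (no information
#'   about the odds ratio) before pooling. Default `TRUE`.
#' @return A `pairwise_result` list: `k`, `pooled`, `se`, `ci95`, `tau2`,
#'   `Q`, `df`, `p_Q`, `I2`, `scale`, plus the inputs.
#' @export
#' @examples
#' dl_pool(c(0, 1), c(0.1, 0.1))  # Q = 5, tau2 = 0.4, pooled = 0.5
dl_pool <- function(x, variance = NULL, scale = NULL,
                    drop_double_zero = TRUE) {
  comparison <- NULL
  if (is.data.frame(x)) {
    if (is.null(scale)) scale <- attr(x, "scale")
    comparison <- attr(x, "comparison")
    if (drop_double_zero && "double_zero" %in% names(x))
      x <- x[!x$double_zero, , drop = FALSE]
    y <- x$effect; v <- x$variance
  } else {
    y <- x; v <- variance
  }
  if (is.null(scale)) scale <- "smd"
  k <- length(y)
  if (k == 0) stop("no estimates to pool", call. = FALSE)
  stopifnot(length(v) == k, all(v > 0))
  w <- 1 / v
  yfe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yfe)^2)
  df <- k - 1L
  tau2 <- if (k == 1) 0 else max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (v + tau2)
  pooled <- sum(ws * y) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  I2 <- if (Q > 0) max(0, 100 * (Q - df) / Q) else 0
  p_Q <- if (df > 0) stats::pchisq(Q, df, lower.tail = FALSE) else 1
  structure(list(k = k, pooled = pooled, se = se,
                 ci95 = c(pooled - 1.96 * se, pooled + 1.96 * se),
                 tau2 = tau2, Q = Q, df = df, p_Q = p_Q, I2 = I2,
                 scale = scale, comparison = comparison,
                 effects = y, variances = v),
            class = "pairwise_result")
}

#' @export
print.pairwise_result <- function(x, ...) {
  if (!is.null(x$comparison))
    cat(sprintf("Comparison: %s vs %s\n", x$comparison[1], x$comparison[2]))
  if (x$scale == "log_or") {
    cat(sprintf("Pooled OR %.3f (95%% CI %.3f to %.3f), k = %d studies\n",
                exp(x$pooled), exp(x$ci95[1]), exp(x$ci95[2]), x$k))
  } else {
    cat(sprintf("Pooled SMD %.3f (95%% CI %.3f to %.3f), k = %d studies\n",
                x$pooled, x$ci95[1], x$ci95[2], x$k))
  }
  cat(sprintf("Heterogeneity: Q = %.3f (df = %d, p = %.3f), tau2 = %.4f, I2 = %.1f%%\n",
              x$Q, x$df, x$p_Q, x$tau2, x$I2))
  invisible(x)
}

#' Begg's rank-correlation test for publication bias
#'
#' Correlates the standardized deviates
#' \eqn{u_i = (y_i - \bar y_{FE}) / \sqrt{v_i - 1/\sum w}} with the
#' sampling variances using Kendall's tau-b (ties handled by the tau-b
#' convention) and the normal approximation with continuity correction.
#' With fewer than three studies the test is uninformative and returns
#' p = 1 with `flagged = TRUE`.
#'
#' @inheritParams dl_pool
#' @return A `begg_result` list: `kendall_tau`, `z`, `p`, `k`, `flagged`.
#' @export
beggs_test <- function(x, variance = NULL) {
  if (is.data.frame(x)) { y <- x$effect; v <- x$variance } else {
    y <- x; v <- variance
  }
  k <- length(y)
  if (k < 3)
    return(structure(list(kendall_tau = NA_real_, z = NA_real_, p = 1,
                          k = k, flagged = TRUE), class = "begg_result"))
  w <- 1 / v
  yfe <- sum(w * y) / sum(w)
  u <- (y - yfe) / sqrt(v - 1 / sum(w))
  ct <- suppressWarnings(stats::cor.test(u, v, method = "kendall",
                                         exact = FALSE, continuity = TRUE))
  structure(list(kendall_tau = unname(ct$estimate), z = unname(ct$statistic),
                 p = ct$p.value, k = k, flagged = FALSE),
            class = "begg_result")
}

#' @export
print.begg_result <- function(x, ...) {
  if (x$flagged) {
    cat(sprintf("Begg's test: not computed (k = %d < 3), p = 1\n", x$k))
  } else {
    cat(sprintf("Begg's test: Kendall tau = %.3f, z = %.3f, p = %.3f (k = %d)\n",
                x$kendall_tau, x$z, x$p, x$k))
  }
  invisible(x)
}
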