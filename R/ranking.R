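#' Rank probabilities, SUCRA and probability-best from a fitted NMA
#'
#' Ranks the treatments within every posterior draw (the reference
#' included at effect 0) in the stated direction, tallies the ranks into a
#' rank-probability matrix, and summarizes each treatment by its
#' cumulative ranking curve, SUCRA and probability of being best. Because
#' the rank-1 probabilities of the treatments sum to 1 while SUCRA is a
#' whole-curve summary, both are always reported side by side. Ties within
#' a draw (measure-zero for continuous draws) are broken uniformly at
#' random with a dedicated, seeded RNG substream.
#'
#' @param x A fitted `nma` object.
#' @param direction `"lower_is_better"` (effectiveness on the SMD scale,
#'   harms on the log-OR scale) or `"higher_is_better"`.
#' @param seed Seed for the tie-break substream (defaults to the fit's
#'   base seed plus 1000).
#' @return An `nma_rank` list: `rank_matrix` (treatments x ranks),
#'   `cumulative`, `sucra` (percent), `p_best`, `direction`.
#' @export
rank_probabilities <- function(x,
                               direction = c("lower_is_better",
                                             "higher_is_better"),
                               seed = x$config$seed + 1000) {
  direction <- match.arg(direction)
  D <- d_draws(x)
  if (direction == "higher_is_better") D <- -D
  Tn <- ncol(D)
  set.seed(seed)
  key <- matrix(stats::runif(length(D)), nrow(D), Tn) # tie-break keys
  ranks <- matrix(1L, nrow(D), Tn)
  for (a in seq_len(Tn)) for (b in seq_len(Tn)) {
    if (a == b) next
    ranks[, a] <- ranks[, a] +
      (D[, b] < D[, a] | (D[, b] == D[, a] & key[, b] < key[, a]))
  }
  P <- vapply(seq_len(Tn), function(r) colMeans(ranks == r),
              numeric(Tn))
  dimnames(P) <- list(treatment = colnames(D), rank = seq_len(Tn))
  cum <- t(apply(P, 1, cumsum))
  structure(list(rank_matrix = P, cumulative = cum, sucra = sucra(P),
                 p_best = P[, 1], direction = direction,
                 treatments = colnames(D)),
            class = "nma_rank")
}

#' Surface under the cumulative ranking curve
#'
#' \eqn{SUCRA_t = 100 \sum_{j=1}^{T-1} cum_{t,j} / (T-1)}: 100 for a
#' treatment certain to rank first, 0 for one certain to rank last, and
#' the mean over treatments is always 50.
#'
#' @param x A rank-probability matrix (treatments x ranks, rows summing to
#'   1) or an `nma_rank` object.
#' @return Named vector of SUCRA values in percent.
#' @export
sucra <- function(x) {
  P <- if (inherits(x, "nma_rank")) x$rank_matrix else as.matrix(x)
  Tn <- ncol(P)
  stopifnot(Tn >= 2, all(abs(rowSums(P) - 1) < 1e-8))
  cum <- t(apply(P, 1, cumsum))
  100 * rowSums(cum[, seq_len(Tn - 1), drop = FALSE]) / (Tn - 1)
}

#' @export
print.nma_rank <- function(x, ...) {
  cat(sprintf("Treatment ranking (%s):\n", gsub("_", " ", x$direction)))
  for (t in x$treatments)
    cat(sprintf("  %-8s SUCRA %5.1f%%  P(best) %.3f\n", t, x$sucra[t],
                x$p_best[t]))
  invisible(x)
}

#' Cumulative ranking curves
#'
#' @param x An `nma_rank` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.nma_rank <- function(x, ...) {
  graphics::matplot(t(x$cumulative), type = "b", pch = 19, lty = 1,
                    xlab = "rank", ylab = "cumulative probability",
                    ylim = c(0, 1), ...)
  graphics::legend("bottomright", legend = x$treatments,
                   col = seq_along(x$treatments), lty = 1, pch = 19,
                   bty = "n")
  invisible(x)
}
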