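#' Split-chain potential scale reduction factor
#'
#' Computes R-hat for a draws matrix after splitting each chain in half,
#' so within-chain drift also inflates the statistic.
#'
#' @param mat Numeric matrix, iterations x chains.
#' @return The split-chain R-hat.
#' @export
rhat_split <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 chains", call. = FALSE)
  n <- nrow(mat)
  half <- floor(n / 2)
  pieces <- c(lapply(seq_len(ncol(mat)), function(j) mat[seq_len(half), j]),
              lapply(seq_len(ncol(mat)), function(j) mat[(n - half + 1):n, j]))
  m <- length(pieces)
  means <- vapply(pieces, mean, numeric(1))
  vars <- vapply(pieces, stats::var, numeric(1))
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Convergence diagnostics for a fitted network meta-analysis
#'
#' Split-chain R-hat per monitored parameter (basic parameters, trial
#' baselines where present, heterogeneity SD unless fixed).
#'
#' @param x A fitted `nma` object with at least two chains.
#' @return Named vector of R-hat values, with the names of any parameters
#'   exceeding 1.05 in attribute `"warnings"`.
#' @export
gelman_rubin <- function(x) {
  stopifnot(inherits(x, "nma"))
  if (x$config$n_chains < 2)
    stop("need at least 2 chains for R-hat", call. = FALSE)
  out <- c()
  for (j in seq_len(ncol(x$chains[[1]]$d))) {
    m <- vapply(x$chains, function(cc) cc$d[, j], numeric(nrow(x$chains[[1]]$d)))
    out[paste0("d[", colnames(x$chains[[1]]$d)[j], "]")] <- rhat_split(m)
  }
  if (ncol(x$chains[[1]]$mu) > 0) {
    for (j in seq_len(ncol(x$chains[[1]]$mu))) {
      m <- vapply(x$chains, function(cc) cc$mu[, j],
                  numeric(nrow(x$chains[[1]]$mu)))
      out[paste0("mu[", x$model$studies[j], "]")] <- rhat_split(m)
    }
  }
  if (is.null(x$config$tau_fixed)) {
    m <- vapply(x$chains, `[[`, numeric(length(x$chains[[1]]$tau)), "tau")
    out["tau"] <- rhat_split(m)
  }
  attr(out, "warnings") <- names(out)[out > 1.05]
  out
}

# effective sample size of one stacked draws matrix (iterations x chains),
# Geyer-style truncation at the first negative autocorrelation
ess_matrix <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); m <- ncol(mat)
  max_lag <- min(n - 1, 500)
  rho <- rowMeans(vapply(seq_len(m), function(j)
    as.numeric(stats::acf(mat[, j], lag.max = max_lag,
                          plot = FALSE)$acf)[-1],
    numeric(max_lag)))
  s <- 0
  for (t in seq_along(rho)) {
    if (rho[t] < 0) break
    s <- s + rho[t]
  }
  n * m / (1 + 2 * s)
}

#' Effective sample size of the basic parameters and tau
#'
#' @param x A fitted `nma` object.
#' @return Named vector of effective sample sizes.
#' @export
effective_size <- function(x) {
  stopifnot(inherits(x, "nma"))
  out <- c()
  nk <- nrow(x$chains[[1]]$d)
  for (j in seq_len(ncol(x$chains[[1]]$d))) {
    m <- vapply(x$chains, function(cc) cc$d[, j], numeric(nk))
    out[paste0("d[", colnames(x$chains[[1]]$d)[j], "]")] <- ess_matrix(m)
  }
  if (is.null(x$config$tau_fixed)) {
    m <- vapply(x$chains, `[[`, numeric(nk), "tau")
    out["tau"] <- ess_matrix(m)
  }
  out
}

#' Posterior mean residual deviance
#'
#' Model-fit statistic: the deviance of each data point from its fitted
#' value, averaged over posterior draws and summed over points. Binary
#' models contribute one point per arm,
#' \eqn{2[r \ln(r/\hat r) + (n-r)\ln((n-r)/(n-\hat r))]} with
#' \eqn{\hat r = n \hat p} (and \eqn{0 \ln 0 = 0}); continuous models one
#' point per contrast, the components of the quadratic form
#' \eqn{(y-\delta)' S^{-1} (y-\delta)}. A value close to the number of
#' data points indicates adequate fit.
#'
#' @param x A fitted `nma` object.
#' @return An `nma_deviance` list: `D_res`, `n_datapoints`, `ratio` and
#'   per-point `contributions`.
#' @export
residual_deviance <- function(x) {
  stopifnot(inherits(x, "nma"))
  model <- x$model
  mu <- do.call(rbind, lapply(x$chains, `[[`, "mu"))
  delta <- do.call(rbind, lapply(x$chains, `[[`, "delta"))
  if (x$outcome_kind == "binary") {
    arms <- model$arms
    contrib <- numeric(nrow(arms))
    for (a in seq_len(nrow(arms))) {
      th <- mu[, arms$trial[a]]
      if (arms$re_idx[a] >= 0) th <- th + delta[, arms$re_idx[a] + 1]
      rhat <- arms$n[a] * stats::plogis(th)
      r <- arms$events[a]; n <- arms$n[a]
      t1 <- if (r > 0) r * log(r / rhat) else 0
      t2 <- if (r < n) (n - r) * log((n - r) / (n - rhat)) else 0
      contrib[a] <- mean(2 * (t1 + t2))
    }
    labels <- paste(arms$study, arms$treatment)
  } else {
    contrib <- numeric(model$n_re)
    for (i in seq_len(model$n_trials)) {
      m <- model$trial_re_m[i]; off <- model$trial_re_off[i]
      idx <- off + seq_len(m)
      E <- matrix(model$y[idx], nrow(delta), m, byrow = TRUE) -
        delta[, idx, drop = FALSE]
      Si <- model$S_inv[[i]]
      contrib[idx] <- colMeans((E %*% Si) * E)
    }
    sel <- model$arms$re_idx >= 0
    labels <- paste(model$arms$study[sel], model$arms$treatment[sel])
  }
  structure(list(D_res = sum(contrib), n_datapoints = model$n_datapoints,
                 ratio = sum(contrib) / model$n_datapoints,
                 contributions = stats::setNames(contrib, labels)),
            class = "nma_deviance")
}

#' @export
print.nma_deviance <- function(x, ...) {
  cat(sprintf("Posterior mean residual deviance: %.2f (%d data points, ratio %.2f)\n",
              x$D_res, x$n_datapoints, x$ratio))
  invisible(x)
}
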