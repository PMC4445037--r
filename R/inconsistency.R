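#' Bucher adjusted indirect comparison
#'
#' Combines two pooled estimates against a common comparator C into the
#' indirect estimate of A vs B: effect `effect_AC - effect_BC`, variance
#' `var_AC + var_BC`.
#'
#' @param ac,bc Pooled estimates of A vs C and B vs C: `pairwise_result`
#'   objects or lists with `effect`/`pooled` and `variance` (`se^2`).
#' @return List `effect`, `variance`, `scale`.
#' @export
#' @examples
#' bucher_indirect(list(effect = -0.38, variance = 0.003),
#'                 list(effect = -0.42, variance = 0.008))
bucher_indirect <- function(ac, bc) {
  g <- function(e) {
    if (inherits(e, "pairwise_result"))
      list(effect = e$pooled, variance = e$se^2, scale = e$scale,
           comparator = if (!is.null(e$comparison)) e$comparison[2] else NA)
    else list(effect = e$effect, variance = e$variance,
              scale = if (!is.null(e$scale)) e$scale else NA,
              comparator = if (!is.null(e$comparison)) e$comparison[2] else NA)
  }
  a <- g(ac); b <- g(bc)
  if (!is.na(a$scale) && !is.na(b$scale) && a$scale != b$scale)
    stop("scale mismatch between the two estimates", call. = FALSE)
  if (!is.na(a$comparator) && !is.na(b$comparator) &&
      a$comparator != b$comparator)
    stop("estimates do not share a common comparator", call. = FALSE)
  list(effect = a$effect - b$effect, variance = a$variance + b$variance,
       scale = a$scale)
}

#' Loop inconsistency: direct versus indirect evidence
#'
#' Compares the direct and indirect estimates of the same edge:
#' z = (effect_direct - effect_indirect) / sqrt(var_d + var_i), 95% CI of
#' the discrepancy by 1.96 SE. On the log-odds scale the discrepancy is
#' reported as the ratio of odds ratios (RoR), oriented so RoR >= 1; the
#' loop is significantly inconsistent when the CI of the oriented
#' discrepancy lies entirely above the null, equivalently |z| > 1.96.
#' Swapping the direct and indirect inputs leaves the significance
#' unchanged.
#'
#' @param direct,indirect Lists with `effect` and `variance` (e.g. from
#'   [dl_pool()] -- use `pooled`/`se^2` -- or [bucher_indirect()]).
#' @param scale `"smd"` or `"log_or"`.
#' @return A `loop_inconsistency` list: `direct`, `indirect`,
#'   `discrepancy` (absolute difference), `ci95` (of the oriented
#'   discrepancy), `RoR` and `RoR_ci95` (log-odds scale), `z`,
#'   `significant`.
#' @export
loop_ror <- function(direct, indirect, scale = c("smd", "log_or")) {
  scale <- match.arg(scale)
  g <- function(e) if (inherits(e, "pairwise_result"))
    list(effect = e$pooled, variance = e$se^2) else e
  d <- g(direct); i <- g(indirect)
  diff <- d$effect - i$effect
  se <- sqrt(d$variance + i$variance)
  z <- diff / se
  disc <- abs(diff)
  ci <- c(disc - 1.96 * se, disc + 1.96 * se)
  out <- list(direct = d, indirect = i, discrepancy = disc, ci95 = ci,
              z = z, significant = abs(z) > 1.96, scale = scale)
  if (scale == "log_or") {
    out$RoR <- exp(disc)
    out$RoR_ci95 <- exp(ci)
  }
  structure(out, class = "loop_inconsistency")
}

#' @export
print.loop_inconsistency <- function(x, ...) {
  if (x$scale == "log_or") {
    cat(sprintf("Ratio of odds ratios (direct vs indirect): %.3f (95%% CI %.3f to %.3f)\n",
                x$RoR, x$RoR_ci95[1], x$RoR_ci95[2]))
  } else {
    cat(sprintf("Direct-indirect SMD discrepancy: %.3f (95%% CI %.3f to %.3f)\n",
                x$discrepancy, x$ci95[1], x$ci95[2]))
  }
  cat(sprintf("z = %.3f; %ssignificant inconsistency\n", x$z,
              if (x$significant) "" else "no "))
  invisible(x)
}

#' Evaluate the closed loop of a three-treatment network
#'
#' Direct evidence for the edge A-B is the DerSimonian-Laird pooling of
#' trials containing both A and B; indirect evidence is the Bucher
#' combination of the A-C and B-C edges, each pooled from the two-arm
#' designs not containing the target edge. This keeps the check
#' independent of the MCMC engine.
#'
#' @param data An `arm_data` data frame.
#' @param loop Treatment triple `c(A, B, C)`: the edge A vs B is tested
#'   via common comparator C.
#' @param outcome_kind Defaults to the attribute on `data`.
#' @return A `loop_inconsistency` object (see [loop_ror()]).
#' @export
loop_inconsistency <- function(data, loop,
                               outcome_kind = outcome_kind_of(data)) {
  stopifnot(length(loop) == 3, !anyDuplicated(loop))
  A <- loop[1]; B <- loop[2]; C <- loop[3]
  scale <- if (outcome_kind == "continuous") "smd" else "log_or"
  has <- function(study, t)
    t %in% data$treatment[data$study == study]
  studies <- unique(data$study)
  with_ab <- studies[vapply(studies, function(s) has(s, A) && has(s, B),
                            logical(1))]
  ac_only <- studies[vapply(studies, function(s)
    has(s, A) && has(s, C) && !has(s, B), logical(1))]
  bc_only <- studies[vapply(studies, function(s)
    has(s, B) && has(s, C) && !has(s, A), logical(1))]
  if (!length(with_ab) || !length(ac_only) || !length(bc_only))
    stop("loop not closed: need trials on every edge", call. = FALSE)
  pool_edge <- function(st, cmp) {
    dl_pool(pairwise_contrasts(data[data$study %in% st, , drop = FALSE],
                               cmp, outcome_kind))
  }
  direct <- pool_edge(with_ab, c(A, B))
  indirect <- bucher_indirect(pool_edge(ac_only, c(A, C)),
                              pool_edge(bc_only, c(B, C)))
  loop_ror(direct, indirect, scale = scale)
}
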