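#' Build the treatment network implied by arm-level data
#'
#' Collects the direct comparisons made within trials into an edge list with
#' per-edge trial counts and verifies that every treatment is reachable from
#' the reference. A `weight` column, if present, multiplies each trial's
#' contribution to the counts (used by the packaged trial table, where one
#' printed row can stand for several pooled RCTs).
#'
#' @param arms Data frame with at least `study` and `treatment` columns
#'   (e.g. from [read_arm_data()] or [table1_arms()]).
#' @param reference Reference treatment id (the network must contain it).
#' @return An `nma_network` list: `treatments`, `reference`, `edges` (data
#'   frame `t1`, `t2`, `n_trials`), `n_trials`, `n_arms`, `studies`.
#' @export
#' @examples
#' build_network(table1_arms())
build_network <- function(arms, reference = "PBO") {
  stopifnot(all(c("study", "treatment") %in% names(arms)))
  if (nrow(arms) == 0) stop("no arms supplied", call. = FALSE)
  treatments <- unique(arms$treatment)
  if (!reference %in% treatments)
    stop("reference treatment '", reference, "' absent from network",
         call. = FALSE)
  treatments <- c(reference, sort(setdiff(treatments, reference)))
  w <- if ("weight" %in% names(arms)) arms$weight else rep(1, nrow(arms))
  studies <- unique(arms$study)
  edge_list <- list()
  study_w <- numeric(length(studies))
  for (i in seq_along(studies)) {
    sel <- arms$study == studies[i]
    tr <- arms$treatment[sel]
    if (length(tr) < 2)
      stop("trial '", studies[i], "' has fewer than two arms", call. = FALSE)
    study_w[i] <- w[sel][1]
    pairs <- utils::combn(sort(tr), 2)
    edge_list[[i]] <- data.frame(t1 = pairs[1, ], t2 = pairs[2, ],
                                 w = study_w[i], stringsAsFactors = FALSE)
  }
  ed <- do.call(rbind, edge_list)
  edges <- stats::aggregate(w ~ t1 + t2, data = ed, FUN = sum)
  names(edges)[3] <- "n_trials"
  edges <- edges[order(edges$t1, edges$t2), , drop = FALSE]
  rownames(edges) <- NULL
  # connectivity from the reference by breadth-first search
  reach <- reference
  repeat {
    nxt <- unique(c(edges$t2[edges$t1 %in% reach],
                    edges$t1[edges$t2 %in% reach]))
    nxt <- setdiff(nxt, reach)
    if (!length(nxt)) break
    reach <- c(reach, nxt)
  }
  unreachable <- setdiff(treatments, reach)
  if (length(unreachable))
    stop("network disconnected; unreachable from '", reference, "': ",
         paste(unreachable, collapse = ", "), call. = FALSE)
  structure(list(treatments = treatments, reference = reference,
                 edges = edges, n_trials = sum(study_w),
                 n_arms = sum(w), studies = studies),
            class = "nma_network")
}

#' @export
print.nma_network <- function(x, ...) {
  cat(sprintf("Treatment network: %d treatments, %g trials, %g arms (reference %s)\n",
              length(x$treatments), x$n_trials, x$n_arms, x$reference))
  cat("Direct comparisons:\n")
  for (i in seq_len(nrow(x$edges)))
    cat(sprintf("  %s - %s: %g trial(s)\n", x$edges$t1[i], x$edges$t2[i],
                x$edges$n_trials[i]))
  invisible(x)
}
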