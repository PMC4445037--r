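#' The packaged trial characteristics table
#'
#' Loads the bundled table of the 24 included osteoarthritis RCTs (placebo,
#' celecoxib 200 mg QD, celecoxib 100 mg BID): per-arm sample sizes and
#' female percentage, mean ages, treatment duration, follow-up time points
#' and modified-Oxford quality subscores (0-7 total). One printed row
#' ("Lisse 2001") pools three RCTs; it is stored exactly as printed with
#' `combined_rcts = 3`, and counting operations weight by that column.
#' Female percentage and mean age are carried for provenance only and play
#' no role in inference.
#'
#' @return A data frame with one row per printed trial; multi-arm fields
#'   (`treatments`, `n`, `female_pct`, `mean_age`, `followup_weeks`) are
#'   list columns.
#' @seealso [table1_arms()], [fixture_counts()]
#' @export
oa_table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "nmacox")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  split_num <- function(v) lapply(strsplit(v, ";", fixed = TRUE), as.numeric)
  tab <- data.frame(study = raw$study, location = raw$location,
                    stringsAsFactors = FALSE)
  tab$treatments <- strsplit(raw$treatments, ";", fixed = TRUE)
  tab$n <- split_num(raw$n)
  tab$female_pct <- split_num(raw$female_pct)
  tab$mean_age <- split_num(raw$mean_age)
  tab$duration_weeks <- raw$duration_weeks
  tab$followup_weeks <- split_num(raw$followup_weeks)
  tab$rand_score <- raw$rand_score
  tab$conceal_score <- raw$conceal_score
  tab$blind_score <- raw$blind_score
  tab$withdrawal_score <- raw$withdrawal_score
  tab$quality_score <- raw$quality_score
  tab$combined_rcts <- raw$combined_rcts
  n_arms <- lengths(tab$treatments)
  stopifnot(all(n_arms %in% 2:3), all(n_arms == lengths(tab$n)),
            all(tab$quality_score >= 0 & tab$quality_score <= 7))
  structure(tab, class = c("oa_table1", "data.frame"))
}

#' Arm-level view of the packaged trial table
#'
#' Expands the trial table to one row per arm, keeping the per-row RCT
#' weight, so that network and counting operations can consume it like any
#' other arm-level dataset.
#'
#' @param tab The trial table, as returned by [oa_table1()].
#' @return Data frame with columns `study`, `treatment`, `n`, `female_pct`,
#'   `mean_age`, `location`, `weight`.
#' @export
table1_arms <- function(tab = oa_table1()) {
  idx <- rep(seq_len(nrow(tab)), lengths(tab$treatments))
  data.frame(study = tab$study[idx],
             treatment = unlist(tab$treatments),
             n = unlist(tab$n),
             female_pct = unlist(tab$female_pct),
             mean_age = unlist(tab$mean_age),
             location = tab$location[idx],
             weight = tab$combined_rcts[idx],
             stringsAsFactors = FALSE)
}

#' Descriptive counts of the packaged trial table
#'
#' Totals obtained by summation and filtering only: number of RCTs (rows
#' weighted by `combined_rcts`), arms, randomized patients per treatment
#' and overall, and trial counts by joint location.
#'
#' @param tab The trial table, as returned by [oa_table1()].
#' @return A `fixture_counts` list with elements `n_trials`, `n_rows`,
#'   `n_arms`, `patients` (named vector including `total`) and
#'   `by_location`.
#' @export
fixture_counts <- function(tab = oa_table1()) {
  arms <- table1_arms(tab)
  pat <- tapply(arms$n, arms$treatment, sum)
  patients <- c(pat, total = sum(arms$n))
  structure(list(
    n_trials = sum(tab$combined_rcts),
    n_rows = nrow(tab),
    n_arms = sum(arms$weight),
    patients = patients,
    by_location = table(tab$location)
  ), class = "fixture_counts")
}

#' @export
print.fixture_counts <- function(x, ...) {
  cat(sprintf("Included RCTs: %g (%d printed rows, %g arms)\n",
              x$n_trials, x$n_rows, x$n_arms))
  cat("Randomized patients:\n")
  for (nm in names(x$patients))
    cat(sprintf("  %-8s %6g\n", nm, x$patients[[nm]]))
  cat("Trials by OA location (printed rows):\n")
  for (nm in names(x$by_location))
    cat(sprintf("  %-12s %3d\n", nm, x$by_location[[nm]]))
  invisible(x)
}
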