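# shared fixture builders (everything generated in code)

two_arm_continuous <- function(study = "S1", mean_x = 1, mean_y = 2,
                               sd = 2, n = 100) {
  as_arm_data(data.frame(
    study = study, treatment = c("X", "PBO"), n = n,
    mean = c(mean_x, mean_y), sd = sd, stringsAsFactors = FALSE),
    "continuous")
}

write_csv_fixture <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# small binary network: 2 three-arm + 4 two-arm trials, fixed counts
small_binary_network <- function() {
  as_arm_data(data.frame(
    study = c("T1", "T1", "T1", "T2", "T2", "T2",
              "T3", "T3", "T4", "T4", "T5", "T5", "T6", "T6"),
    treatment = c("PBO", "A", "B", "PBO", "A", "B",
                  "PBO", "A", "PBO", "A", "PBO", "B", "PBO", "B"),
    n = 200,
    events = c(50, 42, 38, 55, 40, 36, 48, 39, 52, 44, 47, 35, 51, 40),
    stringsAsFactors = FALSE), "binary")
}

# balanced consistent loop used for the frequentist calibration checks
balanced_loop_config <- function(seed) {
  sim_config(
    d = c(C200QD = -0.38, C100BID = -0.42), tau = 0.15,
    designs = list(
      list(treatments = c("C100BID", "C200QD"), n_trials = 8),
      list(treatments = c("PBO", "C200QD"), n_trials = 8),
      list(treatments = c("PBO", "C100BID"), n_trials = 8)),
    n_range = c(117, 481), seed = seed)
}

fast_fit <- function(arms, ...) {
  nma(arms, n_iter = 3000, n_burnin = 1000, seed = 99, ...)
}
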