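#' Read arm-level trial data from CSV
#'
#' Reads one row per treatment arm. Continuous outcomes need columns
#' `study, treatment, n, mean, sd`; binary (event-count) outcomes need
#' `study, treatment, n, events`. The file must be comma-separated UTF-8
#' with a header and `.` as decimal mark. Multi-arm trials appear as
#' multiple rows sharing `study`.
#'
#' @param path Path to a CSV file.
#' @param outcome_kind `"continuous"` or `"binary"`.
#' @return A validated `arm_data` data frame (row order preserved) with the
#'   outcome kind stored as an attribute.
#' @seealso [write_arm_data()], [build_network()], [nma()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("study,treatment,n,mean,sd", "S1,PBO,100,2.1,1.0",
#'              "S1,C200QD,100,1.6,1.0"), f)
#' read_arm_data(f, "continuous")
read_arm_data <- function(path, outcome_kind = c("continuous", "binary")) {
  outcome_kind <- match.arg(outcome_kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_arm_data(df, outcome_kind)
}

#' Validate a data frame of trial arms
#'
#' @param df Data frame with the columns described in [read_arm_data()].
#' @param outcome_kind `"continuous"` or `"binary"`.
#' @return The validated `arm_data` data frame.
#' @export
as_arm_data <- function(df, outcome_kind = c("continuous", "binary")) {
  outcome_kind <- match.arg(outcome_kind)
  req <- c("study", "treatment", "n",
           if (outcome_kind == "continuous") c("mean", "sd") else "events")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  df <- df[, req, drop = FALSE]
  num_cols <- setdiff(req, c("study", "treatment"))
  for (cl in num_cols) {
    v <- df[[cl]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric or missing '%s' at row %d", cl, bad[1]),
           call. = FALSE)
    df[[cl]] <- v
  }
  bad <- which(df$n < 1 | df$n != round(df$n))
  if (length(bad))
    stop(sprintf("n must be a positive integer at row %d", bad[1]),
         call. = FALSE)
  if (outcome_kind == "continuous") {
    bad <- which(df$sd <= 0)
    if (length(bad))
      stop(sprintf("sd must be positive at row %d", bad[1]), call. = FALSE)
  } else {
    bad <- which(df$events < 0 | df$events != round(df$events))
    if (length(bad))
      stop(sprintf("events must be a non-negative integer at row %d", bad[1]),
           call. = FALSE)
    bad <- which(df$events > df$n)
    if (length(bad))
      stop(sprintf("events exceed n at row %d", bad[1]), call. = FALSE)
  }
  key <- paste(df$study, df$treatment, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1]
    stop(sprintf("duplicate (study, treatment) pair at row %d", bad),
         call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, outcome_kind = outcome_kind,
            class = c("arm_data", "data.frame"))
}

#' Write arm-level trial data to CSV
#'
#' Inverse of [read_arm_data()]: valid data round-trips identically.
#'
#' @param x An `arm_data` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_arm_data <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.arm_data <- function(x, ...) {
  cat(sprintf("Arm-level %s outcome data: %d arms, %d trials, %d treatments\n",
              attr(x, "outcome_kind"), nrow(x), length(unique(x$study)),
              length(unique(x$treatment))))
  print(as.data.frame(x), ...)
  invisible(x)
}

outcome_kind_of <- function(data) {
  kind <- attr(data, "outcome_kind")
  if (is.null(kind)) {
    kind <- if ("events" %in% names(data)) "binary" else "continuous"
  }
  kind
}
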