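#' Validate a long ratings table
#'
#' Checks the schema (`subject_id`, `item_id`, `score_type`, `value`),
#' score-type values, duplicates, completeness of the five series per
#' (subject, item), the \[0, 10\] value range, and that judges' scores (y3)
#' are integers in 4--10. Error messages name the offending row and column.
#'
#' @param ratings Long ratings table.
#' @return The validated tibble, invisibly.
#' @export
validate_ratings <- function(ratings) {
  assert_columns(ratings, c("subject_id", "item_id", "score_type", "value"),
    "`ratings`")
  bad <- which(is.na(ratings$value) | ratings$value < 0 | ratings$value > 10)
  if (length(bad) > 0) {
    abort(sprintf(
      "Column `value`, row %d: value %s outside [0, 10].",
      bad[1], format(ratings$value[bad[1]])
    ))
  }
  y3 <- ratings[ratings$score_type == "y3", , drop = FALSE]
  bad3 <- which(y3$value %% 1 != 0 | y3$value < 4 | y3$value > 10)
  if (length(bad3) > 0) {
    abort(sprintf(
      "Column `value` (score_type y3), item_id %s of subject %s: judges' scores must be integers in 4..10, got %s.",
      y3$item_id[bad3[1]], y3$subject_id[bad3[1]],
      format(y3$value[bad3[1]])
    ))
  }
  ratings_to_wide(ratings) # completeness + duplicate checks
  invisible(tibble::as_tibble(ratings))
}

#' Read or write a long ratings table as CSV
#'
#' The CSV round-trip is lossless at 10 significant digits. Both directions
#' validate the schema (see [validate_ratings()]).
#'
#' @param ratings Long ratings table.
#' @param path File path.
#' @return `read_ratings()` returns the validated tibble; `write_ratings()`
#'   returns `path` invisibly.
#' @export
write_ratings <- function(ratings, path) {
  validate_ratings(ratings)
  out <- ratings[, c("subject_id", "item_id", "score_type", "value")]
  out$value <- signif(out$value, 10)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8"))
  validate_ratings(df)
  df
}

#' Write a simulated cohort to a directory
#'
#' Writes `ratings.csv`, `schedules.csv` and a `truth.json` sidecar holding
#' the per-subject ground-truth biases and the generating configuration.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fb_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ratings(cohort$ratings, file.path(dir, "ratings.csv"))
  utils::write.csv(
    cohort$schedules[, c(
      "subject_id", "trial", "item_id", "expected", "score",
      "condition", "pe"
    )],
    file.path(dir, "schedules.csv"),
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  truth <- list(
    n_subjects = cohort$config$n_subjects,
    n_items = cohort$config$n_items,
    true_self_eval_bias = cohort$subjects$true_self_eval_bias,
    true_self_efficacy_bias = cohort$subjects$true_self_efficacy_bias
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
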