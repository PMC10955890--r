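#' The fixed composition of judges' feedback scores
#'
#' The social-feedback task presents each participant with exactly 40 judge
#' scores drawn from a fixed multiset: neutral scores (4--6) and positive
#' scores (7--10) in the composition 4x6, 5x7, 6x7, 7x5, 8x7, 9x6, 10x2.
#' The maximal score of 10 appears only twice to keep the feedback
#' believable. For item counts other than 40 (used for reduced simulation
#' studies), the per-condition composition is scaled by the largest-remainder
#' method so that half the items remain neutral and half positive.
#'
#' @param n_items Total number of items (even, >= 2). Default 40.
#' @return A tibble with columns `score` (integer 4--10), `n` (count), and
#'   `condition` (`"neutral"` for scores 4--6, `"positive"` for 7--10).
#' @export
#' @examples
#' feedback_composition()
feedback_composition <- function(n_items = 40) {
  if (n_items %% 2 != 0 || n_items < 2) {
    abort("`n_items` must be an even number >= 2.")
  }
  base <- tibble::tibble(
    score = 4:10,
    n = c(6L, 7L, 7L, 5L, 7L, 6L, 2L),
    condition = c(rep("neutral", 3), rep("positive", 4))
  )
  if (n_items == 40) {
    return(base)
  }
  half <- n_items / 2
  scaled <- base |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(n = largest_remainder(.data$n, half)) |>
    dplyr::ungroup()
  scaled
}

# Apportion `total` among categories proportionally to `weights` using the
# largest-remainder method (deterministic, preserves the total exactly).
largest_remainder <- function(weights, total) {
  quota <- weights / sum(weights) * total
  n <- floor(quota)
  short <- total - sum(n)
  if (short > 0) {
    extra <- order(quota - n, decreasing = TRUE)[seq_len(short)]
    n[extra] <- n[extra] + 1
  }
  as.integer(n)
}

#' Catalog of the 40 speech-performance attributes
#'
#' Participants rate their speech on 40 performance attributes; 29 are
#' positively valenced and 11 negatively valenced (the latter are
#' reverse-coded in analysis, see [reverse_code()]). Item texts are not part
#' of this package, so labels are placeholders.
#'
#' @return A tibble with columns `item_id` (1--40), `label`, and `valence`
#'   (`"positive"` or `"negative"`).
#' @export
build_attribute_catalog <- function() {
  valence <- c(rep("positive", 29), rep("negative", 11))
  tibble::tibble(
    item_id = 1:40,
    label = sprintf("attribute_%02d", 1:40),
    valence = valence
  )
}

#' Assign judges' feedback scores to items under prediction-error constraints
#'
#' Reproduces the task's feedback-generation algorithm: the fixed score
#' composition (see [feedback_composition()]) is assigned to items such that
#' half receive neutral (4--6) and half positive (7--10) feedback, in a
#' partially randomized manner constrained by the prediction error
#' (PE = assigned score minus the participant's expected score). The
#' algorithm keeps PEs inside the "believable and positively biased" band
#' \[-2, +4\] whenever the remaining score inventory allows; when an extreme
#' expected score makes that impossible, it emits the next smallest possible
#' error (preferring the positive direction on ties, e.g. +5 over -3).
#' At most four items may have a null PE (feedback equal to the expectation).
#'
#' Expected scores are rounded to the nearest integer before PE bookkeeping,
#' because "feedback equals expectation" is treated as an exact event on the
#' visual-analogue grid.
#'
#' @param expected A data frame with columns `item_id` and `expected`
#'   (numbers in \[0, 10\]), or a bare numeric vector of expected scores.
#' @param seed Integer seed making the assignment reproducible; `NULL` uses
#'   the current RNG stream.
#' @param n_retries Number of fresh condition splits to try before giving up
#'   on the null-PE cap.
#' @return A tibble (class `fb_schedule`) with columns `item_id`, `expected`,
#'   `score`, `condition`, `pe`.
#' @export
#' @examples
#' sched <- assign_feedback(runif(40, 2, 9), seed = 1)
#' schedule_summary(sched)
assign_feedback <- function(expected, seed = NULL, n_retries = 1000) {
  if (is.numeric(expected)) {
    expected <- tibble::tibble(
      item_id = seq_along(expected),
      expected = as.numeric(expected)
    )
  }
  assert_columns(expected, c("item_id", "expected"), "`expected`")
  if (anyNA(expected$expected) ||
    any(expected$expected < 0 | expected$expected > 10)) {
    abort("Expected scores must be complete and lie in [0, 10].")
  }
  n_items <- nrow(expected)
  comp <- feedback_composition(n_items)
  with_seed(seed, assign_feedback_impl(expected, comp, n_retries))
}

assign_feedback_impl <- function(expected, comp, n_retries) {
  n_items <- nrow(expected)
  half <- n_items / 2
  exp_round <- round_vas(expected$expected)
  inventory0 <- list(
    neutral = rep(comp$score[comp$condition == "neutral"],
      comp$n[comp$condition == "neutral"]),
    positive = rep(comp$score[comp$condition == "positive"],
      comp$n[comp$condition == "positive"])
  )

  for (attempt in seq_len(n_retries)) {
    neutral_items <- sample.int(n_items, half)
    cond <- rep("positive", n_items)
    cond[neutral_items] <- "neutral"
    inv <- inventory0
    score <- rep(NA_integer_, n_items)
    n_null <- 0L
    ok <- TRUE
    trace <- vector("list", n_items)
    step <- 0L

    for (i in sample.int(n_items, n_items)) {
      pool <- inv[[cond[i]]]
      pe_pool <- pool - exp_round[i]
      in_band <- pe_pool >= -2 & pe_pool <= 4
      if (n_null >= 4L) {
        in_band <- in_band & pe_pool != 0
      }
      if (any(in_band)) {
        pick <- if (sum(in_band) == 1L) which(in_band) else {
          sample(which(in_band), 1L)
        }
      } else {
        cand <- seq_along(pool)
        if (n_null >= 4L) cand <- cand[pe_pool[cand] != 0]
        if (length(cand) == 0L) {
          ok <- FALSE
          break
        }
        excess <- pmax(0, -2 - pe_pool[cand], pe_pool[cand] - 4)
        best <- cand[excess == min(excess)]
        # equidistant outside the band: prefer the positive-direction error
        if (length(best) > 1L) {
          pos_side <- best[pe_pool[best] > 0]
          best <- if (length(pos_side) > 0) pos_side else best
        }
        pick <- if (length(best) == 1L) best else sample(best, 1L)
      }
      score[i] <- pool[pick]
      step <- step + 1L
      trace[[step]] <- list(
        item_id = expected$item_id[i], expected_rounded = exp_round[i],
        pool = pool, n_null_before = n_null, chosen = pool[pick]
      )
      if (pe_pool[pick] == 0) n_null <- n_null + 1L
      inv[[cond[i]]] <- pool[-pick]
    }

    if (ok && n_null <= 4L) {
      out <- tibble::tibble(
        item_id = expected$item_id,
        expected = expected$expected,
        score = as.integer(score),
        condition = cond,
        pe = as.numeric(score - exp_round)
      )
      class(out) <- c("fb_schedule", class(out))
      # audit trail of the greedy pass (processing order, remaining
      # inventory, null-PE count) for independent compliance checks
      attr(out, "trace") <- trace
      return(out)
    }
  }
  abort(paste(
    "No assignment of the fixed score composition satisfies the cap of",
    "4 null prediction errors for these expected scores (binding",
    "constraint: too many expected scores coincide with the available",
    "feedback scores)."
  ))
}

#' Order trials with a run-length restriction on feedback condition
#'
#' Trials are presented in uniformly random order apart from the restriction
#' that no more than two consecutive trials carry feedback from the same
#' condition. Sampling is by rejection from unconstrained permutations, which
#' is exactly uniform over the constraint-satisfying orderings.
#'
#' @param schedule A feedback schedule from [assign_feedback()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param max_tries Rejection-sampling cap.
#' @return The schedule rows reordered, with a `trial` column prepended.
#' @export
order_trials <- function(schedule, seed = NULL, max_tries = 1e6) {
  assert_columns(schedule, c("item_id", "condition"), "`schedule`")
  n <- nrow(schedule)
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      perm <- sample.int(n, n)
      runs <- rle(schedule$condition[perm])
      if (max(runs$lengths) <= 2) {
        out <- schedule[perm, , drop = FALSE]
        out <- dplyr::bind_cols(tibble::tibble(trial = seq_len(n)), out)
        return(out)
      }
    }
    abort("No admissible trial ordering found (rejection cap reached).")
  })
}

#' Summarize a feedback schedule
#'
#' Recounts the schedule: per-condition item counts, mean assigned score and
#' mean prediction error, the number of null PEs, and the per-subject PE
#' imbalance `delta_pe` = mean(PE | positive) - mean(PE | neutral) used
#' downstream as a nuisance covariate.
#'
#' @param schedule A feedback schedule from [assign_feedback()].
#' @return A one-row tibble.
#' @export
schedule_summary <- function(schedule) {
  assert_columns(schedule, c("score", "condition", "pe"), "`schedule`")
  by_cond <- schedule |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_score = mean(.data$score),
      mean_pe = mean(.data$pe),
      .groups = "drop"
    )
  get <- function(cond, col) {
    v <- by_cond[[col]][by_cond$condition == cond]
    if (length(v) == 0) NA_real_ else v
  }
  tibble::tibble(
    n_neutral = as.integer(get("neutral", "n")),
    n_positive = as.integer(get("positive", "n")),
    mean_score_neutral = get("neutral", "mean_score"),
    mean_score_positive = get("positive", "mean_score"),
    mean_pe_neutral = get("neutral", "mean_pe"),
    mean_pe_positive = get("positive", "mean_pe"),
    n_null_pe = sum(schedule$pe == 0),
    delta_pe = get("positive", "mean_pe") - get("neutral", "mean_pe")
  )
}

#' Read or write a feedback schedule as CSV
#'
#' @param schedule A feedback schedule tibble.
#' @param path File path.
#' @return `read_schedule()` returns the schedule tibble; `write_schedule()`
#'   returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  assert_columns(schedule, c("item_id", "expected", "score", "condition", "pe"))
  utils::write.csv(
    schedule[, c("item_id", "expected", "score", "condition", "pe")],
    path,
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  assert_columns(df, c("item_id", "expected", "score", "condition", "pe"))
  out <- tibble::as_tibble(df)
  out$score <- as.integer(out$score)
  class(out) <- c("fb_schedule", class(out))
  out
}
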