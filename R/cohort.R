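#' Configuration for a synthetic speech-feedback cohort
#'
#' Defines the population from which synthetic subjects are drawn. Ratings
#' for the five score series (y1 pre-speech self-efficacy, y2 post-speech
#' self-evaluation, y3 judges' feedback, y4 post-feedback self-evaluation,
#' y5 post-feedback self-efficacy) follow the multivariate-normal structure
#' the analysis model assumes: per subject and condition (positive vs.
#' neutral feedback) a covariance `Sigma = diag(tau) %*% Omega %*% diag(tau)`,
#' with y3 fixed by the feedback schedule and the remaining four scores drawn
#' from the conditional normal given y3.
#'
#' Population means default to the study-scale values (pre-speech
#' self-efficacy 5.28, post-speech self-evaluation 4.97, post-feedback
#' self-evaluation 5.62, post-feedback self-efficacy 5.85); the fixed y3
#' means are the per-condition schedule means 5.05 (neutral) and 8.25
#' (positive) implied by the printed score composition. The update biases
#' plant a per-subject gap between the positive and neutral correlation of
#' y3 with y4 (self-evaluation) and y5 (self-efficacy).
#'
#' @param n_subjects Number of subjects (default 50).
#' @param n_items Number of items per subject (even; default 40).
#' @param mu Population means of (y1, y2, y4, y5).
#' @param tau Population scales of (y1..y5) used for both conditions.
#' @param omega_base Population 5x5 correlation matrix shared by the neutral
#'   condition; the positive condition adds the biases at cells (3,4)/(3,5).
#' @param self_eval_bias,self_efficacy_bias Per-subject true biases; scalars
#'   are recycled to `n_subjects`.
#' @param jitter_z Between-subject SD of correlation jitter on the Fisher-z
#'   scale (applied to all off-diagonal cells except the planted-bias cells).
#' @param mu_jitter Between-subject SD of the four free means.
#' @param tau_jitter Between-subject log-scale SD of the scales.
#' @param discretize If `TRUE`, ratings are clipped to \[0, 10\] and rounded
#'   to the 0.1 VAS grid; default `FALSE` (matches the model's assumption of
#'   continuous unbounded normals).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 50,
                          n_items = 40,
                          mu = c(y1 = 5.28, y2 = 4.97, y4 = 5.62, y5 = 5.85),
                          tau = c(1.30, 1.40, 0.90, 1.05, 1.30),
                          omega_base = default_omega_base(),
                          self_eval_bias = 0,
                          self_efficacy_bias = 0,
                          jitter_z = 0.05,
                          mu_jitter = 0.5,
                          tau_jitter = 0.10,
                          discretize = FALSE) {
  stopifnot(length(mu) == 4, length(tau) == 5, all(tau > 0))
  if (n_items %% 2 != 0) abort("`n_items` must be even.")
  self_eval_bias <- rep_len(self_eval_bias, n_subjects)
  self_efficacy_bias <- rep_len(self_efficacy_bias, n_subjects)
  if (any(abs(self_eval_bias) > 2) || any(abs(self_efficacy_bias) > 2)) {
    abort("Biases are differences of correlations and must lie in [-2, 2].")
  }
  cfg <- list(
    n_subjects = n_subjects, n_items = n_items,
    mu = mu, tau = tau, omega_base = omega_base,
    self_eval_bias = self_eval_bias,
    self_efficacy_bias = self_efficacy_bias,
    jitter_z = jitter_z, mu_jitter = mu_jitter, tau_jitter = tau_jitter,
    discretize = discretize,
    mu3 = c(neutral = 5.05, positive = 8.25)
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' @rdname cohort_config
#' @export
default_omega_base <- function() {
  om <- diag(5)
  rownames(om) <- colnames(om) <- score_types()
  set <- function(i, j, v) {
    om[i, j] <<- v
    om[j, i] <<- v
  }
  # couplings among self-ratings across time points
  set(1, 2, 0.55); set(1, 4, 0.45); set(1, 5, 0.35)
  set(2, 4, 0.55); set(2, 5, 0.35); set(4, 5, 0.60)
  # judges' feedback row: anchored neutral-condition coupling
  set(1, 3, 0.25); set(2, 3, 0.30); set(3, 4, 0.45); set(3, 5, 0.45)
  om
}

# Project a symmetric matrix to the nearest valid correlation matrix by
# eigenvalue clipping (floor 1e-6) and diagonal rescaling.
nearest_correlation <- function(m, floor = 1e-6) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (all(e$values > floor)) {
    diag(m) <- 1
    return(m)
  }
  vals <- pmax(e$values, floor)
  m2 <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(m2))
  m2 <- m2 / tcrossprod(d)
  (m2 + t(m2)) / 2
}

is_positive_definite <- function(m, tol = 1e-8) {
  all(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values > tol)
}

#' Draw subject-level generating parameters
#'
#' Jitters the population means, scales and correlations to produce one
#' parameter set per subject. Correlations are perturbed on the Fisher-z
#' scale and projected back to the nearest valid correlation matrix
#' (eigenvalue clipping), so every subject's positive and neutral matrices
#' are symmetric, unit-diagonal and positive definite. The recorded ground
#' truth is always the realized `Omega_pos - Omega_neu` at cells (3,4) and
#' (3,5) of the final matrices.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A tibble with one row per subject: `subject_id`, list-columns
#'   `mu` (length-4), `tau_pos`, `tau_neu` (length-5), `omega_pos`,
#'   `omega_neu` (5x5), and the realized `true_self_eval_bias`,
#'   `true_self_efficacy_bias`.
#' @export
draw_subject_parameters <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    purrr::map_dfr(seq_len(config$n_subjects), function(s) {
      draw_one_subject(config, s)
    })
  })
}

draw_one_subject <- function(config, s, max_retries = 100) {
  mu_s <- config$mu + rnorm(4, 0, config$mu_jitter)
  tau_s <- config$tau * exp(rnorm(5, 0, config$tau_jitter))

  for (try in seq_len(max_retries)) {
    om_neu <- jitter_correlation(config$omega_base, config$jitter_z,
      skip = rbind(c(3, 4), c(3, 5)))
    om_pos <- om_neu
    om_pos[3, 4] <- om_pos[4, 3] <- om_neu[3, 4] + config$self_eval_bias[s]
    om_pos[3, 5] <- om_pos[5, 3] <- om_neu[3, 5] + config$self_efficacy_bias[s]
    if (any(abs(om_pos) > 1)) next
    om_neu <- nearest_correlation(om_neu)
    om_pos <- nearest_correlation(om_pos)
    if (is_positive_definite(om_neu) && is_positive_definite(om_pos)) {
      return(tibble::tibble(
        subject_id = s,
        mu = list(stats::setNames(mu_s, c("y1", "y2", "y4", "y5"))),
        tau_pos = list(tau_s),
        tau_neu = list(tau_s),
        omega_pos = list(om_pos),
        omega_neu = list(om_neu),
        true_self_eval_bias = om_pos[3, 4] - om_neu[3, 4],
        true_self_efficacy_bias = om_pos[3, 5] - om_neu[3, 5]
      ))
    }
  }
  abort(sprintf(
    "Could not draw a positive-definite correlation pair for subject %d after %d retries.",
    s, max_retries
  ))
}

jitter_correlation <- function(om, sd_z, skip = NULL) {
  if (sd_z <= 0) {
    return(om)
  }
  p <- nrow(om)
  out <- om
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (!is.null(skip) &&
        any(skip[, 1] == i & skip[, 2] == j)) {
        next
      }
      z <- atanh(pmin(pmax(om[i, j], -0.999), 0.999)) + rnorm(1, 0, sd_z)
      out[i, j] <- out[j, i] <- tanh(z)
    }
  }
  out
}

#' Sample one subject's ratings conditional on the feedback schedule
#'
#' y3 values are taken from the schedule (they were experimenter-controlled),
#' and the remaining four scores are drawn from the 4-dimensional conditional
#' normal of the condition's covariance given y3 (Schur-complement
#' conditioning), with the y3 mean fixed at the per-condition schedule mean.
#'
#' @param params One row of [draw_subject_parameters()] output.
#' @param schedule A feedback schedule from [assign_feedback()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param discretize Clip to \[0, 10\] and round to the 0.1 VAS grid.
#' @param mu3 Named fixed y3 means (`neutral`, `positive`).
#' @return A tibble in long format: `item_id`, `score_type`, `value`.
#' @export
sample_ratings <- function(params, schedule, seed = NULL, discretize = FALSE,
                           mu3 = c(neutral = 5.05, positive = 8.25)) {
  assert_columns(schedule, c("item_id", "score", "condition"), "`schedule`")
  mu_free <- params$mu[[1]]
  with_seed(seed, {
    out <- vector("list", 2)
    for (k in seq_along(c("neutral", "positive"))) {
      cond <- c("neutral", "positive")[k]
      rows <- schedule[schedule$condition == cond, , drop = FALSE]
      if (nrow(rows) == 0) next
      om <- if (cond == "positive") params$omega_pos[[1]] else params$omega_neu[[1]]
      tau <- if (cond == "positive") params$tau_pos[[1]] else params$tau_neu[[1]]
      sig <- diag(tau) %*% om %*% diag(tau)
      free <- c(1, 2, 4, 5)
      mu_full <- c(mu_free[1], mu_free[2], mu3[[cond]], mu_free[3], mu_free[4])
      cond_cov <- sig[free, free] -
        tcrossprod(sig[free, 3]) / sig[3, 3]
      if (!is_positive_definite(cond_cov)) {
        abort("Conditional covariance is not positive definite.")
      }
      slope <- sig[free, 3] / sig[3, 3]
      n <- nrow(rows)
      centered <- rows$score - mu3[[cond]]
      mean_mat <- matrix(mu_full[free], n, 4, byrow = TRUE) +
        outer(centered, slope)
      draws <- mean_mat + matrix(rnorm(n * 4), n, 4) %*% chol(cond_cov)
      out[[k]] <- tibble::tibble(
        item_id = rep(rows$item_id, 5),
        score_type = rep(score_types(), each = n),
        value = c(draws[, 1], draws[, 2], as.numeric(rows$score),
          draws[, 3], draws[, 4])
      )
    }
    res <- dplyr::bind_rows(out)
    if (discretize) {
      keep_y3 <- res$score_type == "y3"
      res$value[!keep_y3] <-
        round_vas(pmin(pmax(res$value[!keep_y3], 0), 10), digits = 1)
    }
    dplyr::arrange(res, .data$item_id, .data$score_type)
  })
}

#' Simulate a full synthetic cohort with known ground truth
#'
#' Composes the feedback-assignment algorithm and the conditional rating
#' sampler over subjects. Each subject gets their own feedback schedule
#' (built from expected scores drawn around the subject's post-speech
#' self-evaluation mean) and a long ratings table with all five score types.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed; per-stage seeds are derived from it.
#' @return A list of class `fb_cohort` with elements `ratings` (long tibble:
#'   `subject_id`, `item_id`, `score_type`, `value`), `schedules` (tibble
#'   with `subject_id` plus schedule columns), `subjects` (the generating
#'   parameters with realized true biases), and `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 3, n_items = 20), seed = 1)
#' dplyr::count(coh$ratings, score_type)
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- draw_subject_parameters(config, seed = derive_seed(seed, 1))
  schedules <- vector("list", config$n_subjects)
  ratings <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    params <- subjects[s, , drop = FALSE]
    expected <- with_seed(derive_seed(seed, 100 + s), {
      pmin(pmax(rnorm(config$n_items, params$mu[[1]][["y2"]],
        config$tau[2]), 0), 10)
    })
    sched <- assign_feedback(expected, seed = derive_seed(seed, 200 + s))
    sched <- order_trials(sched, seed = derive_seed(seed, 300 + s))
    schedules[[s]] <- dplyr::bind_cols(
      tibble::tibble(subject_id = s), sched
    )
    r <- sample_ratings(params, sched,
      seed = derive_seed(seed, 400 + s),
      discretize = config$discretize, mu3 = config$mu3
    )
    ratings[[s]] <- dplyr::bind_cols(tibble::tibble(subject_id = s), r)
  }
  out <- list(
    ratings = dplyr::bind_rows(ratings),
    schedules = dplyr::bind_rows(schedules),
    subjects = subjects,
    config = config
  )
  class(out) <- "fb_cohort"
  out
}

#' @export
print.fb_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic speech-feedback cohort: %d subjects x %d items (%d rating rows)\n",
    x$config$n_subjects, x$config$n_items, nrow(x$ratings)
  ))
  cat(sprintf(
    "True bias ranges: self-evaluation [%.3f, %.3f], self-efficacy [%.3f, %.3f]\n",
    min(x$subjects$true_self_eval_bias), max(x$subjects$true_self_eval_bias),
    min(x$subjects$true_self_efficacy_bias),
    max(x$subjects$true_self_efficacy_bias)
  ))
  invisible(x)
}

#' Simulate questionnaire scale scores with a two-factor latent structure
#'
#' Generates the 12-scale battery (LSAS-SR, SPIN, BFNE, FPES, DPSOS self /
#' other, RSE, STAI, NEO neuroticism, BDI-II, SPSRQ reward / punishment)
#' from two latent factors -- "social sensitivity" and "self-negativity" --
#' plus scale-specific noise. The self-negativity factor is given a
#' configurable correlation with the supplied true update-bias values
#' (negative by default: more self-negative subjects update less positively),
#' and self-esteem (RSE) loads negatively on self-negativity. The SPSRQ
#' reward scale is left mostly unique, mimicking a battery in which one
#' scale forms its own residual component.
#'
#' @param true_bias Numeric vector, one true bias value per subject.
#' @param r_bias Target correlation between the self-negativity factor and
#'   `true_bias` (default -0.29).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A tibble: `subject_id` plus 12 scale columns.
#' @export
simulate_questionnaires <- function(true_bias, r_bias = -0.29, seed = NULL) {
  n <- length(true_bias)
  if (n < 3) abort("Need at least 3 subjects.")
  with_seed(seed, {
    b <- as.numeric(scale(true_bias))
    if (anyNA(b)) b <- rep(0, n) # constant bias: factor unrelated
    self_neg <- r_bias * b + sqrt(max(0, 1 - r_bias^2)) * rnorm(n)
    soc_sens <- rnorm(n)
    L <- questionnaire_loadings()
    f <- cbind(soc_sens, self_neg)
    uniq_sd <- sqrt(pmax(0.05, 1 - rowSums(L[, 1:2]^2)))
    z <- f %*% t(L[, 1:2]) +
      matrix(rnorm(n * nrow(L)), n) %*% diag(uniq_sd)
    raw <- sweep(sweep(z, 2, L$sd, `*`), 2, L$mean, `+`)
    colnames(raw) <- rownames(L)
    dplyr::bind_cols(
      tibble::tibble(subject_id = seq_len(n)),
      tibble::as_tibble(raw)
    )
  })
}

questionnaire_loadings <- function() {
  tab <- data.frame(
    row.names = c(
      "lsas", "spin", "bfne", "fpes", "dpsos_other", "dpsos_self",
      "rse", "stai", "neo_n", "bdi", "spsrq_punishment", "spsrq_reward"
    ),
    soc = c(0.80, 0.85, 0.75, 0.70, 0.60, 0.20,
      -0.10, 0.25, 0.30, 0.10, 0.35, 0.10),
    neg = c(0.15, 0.10, 0.25, 0.25, 0.20, 0.60,
      -0.75, 0.75, 0.70, 0.75, 0.55, 0.15),
    mean = c(55, 30, 46, 30, 12, 15, 19, 43, 25, 14, 12, 11),
    sd = c(22, 13, 9, 14, 6, 6, 5, 10, 8, 9, 5, 5)
  )
  tab
}

#' Reverse-code negatively valenced items
#'
#' Negatively valenced attributes are reverse-coded before analysis:
#' `value' = scale_max - value`. Positively valenced values pass through
#' unchanged. Applying the function twice restores the input.
#'
#' @param values Numeric vector in \[0, scale_max\].
#' @param valence Character vector (`"positive"`/`"negative"`), recycled.
#' @param scale_max Scale maximum (default 10).
#' @return The (partially) reflected values.
#' @export
#' @examples
#' reverse_code(c(0, 5, 10), "negative")
reverse_code <- function(values, valence = "negative", scale_max = 10) {
  if (anyNA(values) || any(values < 0 | values > scale_max)) {
    abort(sprintf("Values must lie in [0, %s].", scale_max))
  }
  valence <- rep_len(valence, length(values))
  ifelse(valence == "negative", scale_max - values, values)
}
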