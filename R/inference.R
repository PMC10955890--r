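#' Shortest-interval highest-density interval
#'
#' The HDI is computed as the shortest contiguous window on the sorted draws
#' containing the requested posterior mass.
#'
#' @param x Numeric vector of posterior draws.
#' @param level Posterior mass (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hdi_interval <- function(x, level = 0.95) {
  n <- length(x)
  if (n < 2) {
    return(c(lower = x[1], upper = x[1]))
  }
  xs <- sort(x)
  m <- ceiling(level * n)
  if (m >= n) {
    return(c(lower = xs[1], upper = xs[n]))
  }
  widths <- xs[(m):n] - xs[seq_len(n - m + 1)]
  i <- which.min(widths)
  c(lower = xs[i], upper = xs[i + m - 1])
}

#' Group-level bias assessment via the posterior of the across-subject median
#'
#' On each posterior draw the median of the per-subject bias values is taken
#' across subjects, giving a posterior distribution of the group median.
#' A group-level positive bias is established when the 95% HDI of that
#' distribution lies entirely above zero.
#'
#' @param fit An [fit_update_bias()] result, or a [extract_bias()] result.
#' @param which `"self_eval"` or `"self_efficacy"`.
#' @param level HDI mass (default 0.95).
#' @return A one-row tibble of class `hdi_result`: `which`, `point` (median
#'   of the group-median posterior), `hdi_low`, `hdi_high`, `level`,
#'   `decision` (`"positive_bias"`, `"negative_bias"`, `"not_established"`).
#'   The group-median draws are attached as attribute `"draws"`.
#' @export
group_bias_hdi <- function(fit, which = c("self_efficacy", "self_eval"),
                           level = 0.95) {
  which <- match.arg(which)
  bias <- if (inherits(fit, "bias_indices")) fit else extract_bias(fit)
  draws <- attr(bias, "draws")[[which]]
  med <- apply(draws, 1, stats::median)
  interval <- hdi_interval(med, level)
  decision <- if (interval[["lower"]] > 0) {
    "positive_bias"
  } else if (interval[["upper"]] < 0) {
    "negative_bias"
  } else {
    "not_established"
  }
  out <- tibble::tibble(
    which = which,
    point = stats::median(med),
    hdi_low = interval[["lower"]],
    hdi_high = interval[["upper"]],
    level = level,
    decision = decision
  )
  attr(out, "draws") <- med
  class(out) <- c("hdi_result", class(out))
  out
}

#' Empirical (non-model) update bias per subject
#'
#' The direct analogue of the model's bias index: the within-subject Pearson
#' correlation between the judges' score (y3) and the post-feedback rating
#' (y4 for self-evaluation, y5 for self-efficacy), computed separately under
#' positive and neutral feedback, differenced (positive minus neutral).
#'
#' @param ratings Long ratings table.
#' @param target `"y5"` (self-efficacy, default) or `"y4"`
#'   (self-evaluation).
#' @param positive_threshold Valence threshold (default 7).
#' @return A tibble: `subject_id`, `empirical_bias` (`NA` where a condition
#'   has fewer than 3 items or degenerate variance).
#' @export
empirical_bias <- function(ratings, target = c("y5", "y4"),
                           positive_threshold = 7) {
  target <- match.arg(target)
  wide <- ratings_to_wide(ratings)
  wide$condition <- ifelse(wide$y3 >= positive_threshold,
    "positive", "neutral")
  safe_cor <- function(x, y) {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(NA_real_)
    }
    stats::cor(x, y)
  }
  wide |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      empirical_bias =
        safe_cor(.data$y3[.data$condition == "positive"],
          .data[[target]][.data$condition == "positive"]) -
          safe_cor(.data$y3[.data$condition == "neutral"],
            .data[[target]][.data$condition == "neutral"]),
      .groups = "drop"
    )
}

#' Posterior predictive check: model bias vs. empirical correlation contrast
#'
#' Correlates the model-derived update-bias indices across subjects with the
#' corresponding empirical difference of Pearson correlations between
#' judges' scores and post-feedback ratings under positive vs. neutral
#' feedback.
#'
#' @param bias A [extract_bias()] result (or an `update_bias_fit`).
#' @param ratings The ratings the model was fitted to.
#' @param which `"self_efficacy"` (uses y5) or `"self_eval"` (uses y4).
#' @param positive_threshold Valence threshold.
#' @return A one-row tibble: `which`, `r`, `n`. The per-subject scatter data
#'   are attached as attribute `"data"`.
#' @export
ppc_bias_vs_empirical <- function(bias, ratings,
                                  which = c("self_efficacy", "self_eval"),
                                  positive_threshold = 7) {
  which <- match.arg(which)
  if (inherits(bias, "update_bias_fit")) bias <- extract_bias(bias)
  target <- if (which == "self_efficacy") "y5" else "y4"
  emp <- empirical_bias(ratings,
    target = target,
    positive_threshold = positive_threshold
  )
  col <- paste0(sub("self_eval$", "self_eval", which), "_bias")
  dat <- dplyr::inner_join(
    tibble::tibble(
      subject_id = bias$subject_id,
      model_bias = bias[[col]]
    ),
    emp,
    by = "subject_id"
  ) |>
    dplyr::filter(!is.na(.data$empirical_bias))
  if (nrow(dat) < 3) abort("Need at least 3 subjects with defined values.")
  out <- tibble::tibble(
    which = which,
    r = stats::cor(dat$model_bias, dat$empirical_bias),
    n = nrow(dat)
  )
  attr(out, "data") <- dat
  out
}

#' Posterior predictive check of all pairwise score correlations
#'
#' Simulates cohorts from randomly selected posterior draws (reusing the
#' synthetic-cohort conditional sampler with each subject's own feedback
#' schedule) and compares the across-subject mean within-subject Pearson
#' correlation of every score pair with the observed value.
#'
#' @param fit An [fit_update_bias()] result.
#' @param ratings The observed ratings.
#' @param schedules Tibble of per-subject schedules (`subject_id`,
#'   `item_id`, `score`, `condition`), e.g. `simulate_cohort()$schedules`.
#' @param n_sim Number of simulated datasets.
#' @param seed Integer seed.
#' @return A tibble with one row per score pair: `pair`, `observed`,
#'   `simulated_mean`, `sim_low`, `sim_high` (2.5% / 97.5% quantiles).
#' @export
ppc_correlation_table <- function(fit, ratings, schedules, n_sim = 50,
                                  seed = NULL) {
  stopifnot(inherits(fit, "update_bias_fit"))
  assert_columns(schedules, c("subject_id", "item_id", "score", "condition"),
    "`schedules`")
  obs <- mean_pairwise_correlations(ratings_to_wide(ratings))
  ndraw <- dim(fit$draws$mu)[1]
  mu3 <- c(neutral = fit$mu3[1], positive = fit$mu3[2])
  with_seed(seed, {
    sims <- matrix(NA_real_, n_sim, 10)
    for (i in seq_len(n_sim)) {
      d <- sample.int(ndraw, 1)
      rows <- vector("list", length(fit$subjects))
      for (si in seq_along(fit$subjects)) {
        s <- fit$subjects[si]
        params <- draw_to_params(fit, d, si)
        sched <- schedules[schedules$subject_id == s, , drop = FALSE]
        r <- sample_ratings(params, sched, mu3 = mu3)
        rows[[si]] <- dplyr::bind_cols(
          tibble::tibble(subject_id = s), r
        )
      }
      sims[i, ] <- mean_pairwise_correlations(
        ratings_to_wide(dplyr::bind_rows(rows))
      )
    }
    tibble::tibble(
      pair = names(obs),
      observed = as.numeric(obs),
      simulated_mean = colMeans(sims),
      sim_low = apply(sims, 2, stats::quantile, 0.025),
      sim_high = apply(sims, 2, stats::quantile, 0.975)
    )
  })
}

# Reconstruct a one-row parameter tibble (as draw_subject_parameters() emits)
# from one posterior draw for one subject.
draw_to_params <- function(fit, d, si) {
  pairs <- utils::combn(5, 2)
  unpack <- function(v) {
    om <- diag(5)
    for (u in seq_len(10)) {
      om[pairs[1, u], pairs[2, u]] <- om[pairs[2, u], pairs[1, u]] <- v[u]
    }
    om
  }
  mu <- fit$draws$mu[d, si, ]
  tibble::tibble(
    subject_id = fit$subjects[si],
    mu = list(stats::setNames(mu, c("y1", "y2", "y4", "y5"))),
    tau_pos = list(fit$draws$tau_pos[d, si, ]),
    tau_neu = list(fit$draws$tau_neu[d, si, ]),
    omega_pos = list(unpack(fit$draws$omega_pos[d, si, ])),
    omega_neu = list(unpack(fit$draws$omega_neu[d, si, ]))
  )
}

mean_pairwise_correlations <- function(wide) {
  pairs <- utils::combn(5, 2)
  labs <- apply(pairs, 2, function(p) {
    paste(score_types()[p[1]], score_types()[p[2]], sep = "-")
  })
  per_subject <- wide |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_map(function(g, key) {
      m <- stats::cor(as.matrix(g[score_types()]))
      m[cbind(pairs[1, ], pairs[2, ])]
    })
  out <- colMeans(do.call(rbind, per_subject))
  stats::setNames(out, labs)
}

#' Regress prediction-error imbalance out of bias values
#'
#' The design is unbalanced in prediction errors, so per-subject bias values
#' are adjusted by ordinary least squares on the subject's PE imbalance
#' `delta_pe` = mean(PE | positive) - mean(PE | neutral). The adjusted value
#' is the OLS residual plus the original mean (location preserved).
#'
#' @param bias Numeric vector of per-subject bias values.
#' @param delta_pe Numeric vector of per-subject PE imbalances.
#' @return Adjusted bias vector.
#' @export
residualize_on_pe <- function(bias, delta_pe) {
  if (length(bias) != length(delta_pe)) {
    abort("`bias` and `delta_pe` must have one value per subject each.")
  }
  if (stats::sd(delta_pe) == 0) {
    warn("`delta_pe` is constant; returning bias unchanged.")
    return(bias)
  }
  fit <- stats::lm(bias ~ delta_pe)
  as.numeric(stats::residuals(fit)) + mean(bias)
}

#' Principal component analysis with varimax rotation
#'
#' Standardizes the questionnaire scales, eigen-decomposes their correlation
#' matrix, retains components with eigenvalue > 1 (Kaiser criterion),
#' varimax-rotates the retained standardized loadings, and computes subject
#' component scores by the regression method.
#'
#' @param questionnaires Tibble with `subject_id` plus one numeric column
#'   per scale.
#' @return An object of class `component_profile`: list with `loadings`
#'   (scales x retained components, rotated), `eigenvalues` (all),
#'   `var_explained` (share per retained component, post-rotation),
#'   `scores` (tibble: `subject_id` + component scores), `retained`.
#' @export
pca_varimax <- function(questionnaires) {
  assert_columns(questionnaires, "subject_id", "`questionnaires`")
  scales <- dplyr::select(questionnaires, -"subject_id")
  if (!all(vapply(scales, is.numeric, TRUE))) {
    abort("All scale columns must be numeric.")
  }
  Z <- scale(as.matrix(scales))
  R <- stats::cor(as.matrix(scales))
  if (anyNA(R)) abort("Correlation matrix is undefined (constant scale?).")
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < 1e-10) {
    abort("Singular correlation matrix; remove redundant scales.")
  }
  retained <- kaiser_retained(e$values)
  if (retained == 0) {
    abort("No component has eigenvalue > 1.")
  }
  L <- e$vectors[, seq_len(retained), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(retained)]), retained)
  rot <- if (retained >= 2) {
    vm <- stats::varimax(L)
    L %*% vm$rotmat
  } else {
    L
  }
  # fix signs so each component loads positively on its dominant scale
  for (k in seq_len(retained)) {
    if (rot[which.max(abs(rot[, k])), k] < 0) rot[, k] <- -rot[, k]
  }
  rownames(rot) <- colnames(scales)
  colnames(rot) <- paste0("PC", seq_len(retained))
  scores <- Z %*% solve(R, rot) # regression method
  colnames(scores) <- colnames(rot)
  structure(
    list(
      loadings = rot,
      eigenvalues = e$values,
      var_explained = colSums(rot^2) / ncol(scales),
      scores = dplyr::bind_cols(
        tibble::tibble(subject_id = questionnaires$subject_id),
        tibble::as_tibble(scores)
      ),
      retained = retained
    ),
    class = "component_profile"
  )
}

#' Kaiser retention rule
#'
#' @param eigenvalues Numeric vector of correlation-matrix eigenvalues.
#' @return The number of components with eigenvalue strictly greater than 1.
#' @export
kaiser_retained <- function(eigenvalues) {
  sum(eigenvalues > 1)
}

#' @export
print.component_profile <- function(x, ...) {
  cat(sprintf(
    "Varimax component profile: %d of %d components retained (eigenvalue > 1)\n",
    x$retained, length(x$eigenvalues)
  ))
  cat("Variance explained:",
    paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.component_profile <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "scale") |>
    tidyr::pivot_longer(-"scale",
      names_to = "component",
      values_to = "loading"
    )
}

#' Correlate symptom components with update-bias indices
#'
#' Pearson correlations between each retained component score and each
#' update-bias index, after residualizing on the per-subject PE imbalance
#' (both variables by default, mirroring the nuisance-control procedure).
#' Raw two-tailed p-values are reported alongside Benjamini-Hochberg
#' adjusted values; decisions default to the raw values.
#'
#' @param profile A [pca_varimax()] result.
#' @param bias A [extract_bias()] result (columns `self_eval_bias`,
#'   `self_efficacy_bias`), aligned by `subject_id`.
#' @param delta_pe Tibble `subject_id`, `delta_pe`, or a numeric vector
#'   aligned with the profile's subjects; `NULL` skips residualization.
#' @param residualize Which variables to residualize on `delta_pe`.
#' @param conf_level Confidence level for the Fisher-z interval.
#' @return A tibble: `component`, `bias_type`, `r`, `conf.low`, `conf.high`,
#'   `p.value`, `p.adjusted`, `n`.
#' @export
correlate_components_with_bias <- function(profile, bias, delta_pe = NULL,
                                           residualize = c("both",
                                             "components", "bias", "none"),
                                           conf_level = 0.95) {
  residualize <- match.arg(residualize)
  stopifnot(inherits(profile, "component_profile"))
  scores <- profile$scores
  merged <- dplyr::inner_join(scores, bias, by = "subject_id")
  if (nrow(merged) < 4) abort("Need at least 4 aligned subjects.")
  if (!is.null(delta_pe)) {
    if (is.data.frame(delta_pe)) {
      merged <- dplyr::inner_join(merged, delta_pe, by = "subject_id")
    } else {
      merged$delta_pe <- delta_pe
    }
  } else {
    residualize <- "none"
  }
  comps <- setdiff(names(scores), "subject_id")
  bias_cols <- intersect(
    c("self_eval_bias", "self_efficacy_bias"), names(bias)
  )
  rows <- purrr::map_dfr(comps, function(cc) {
    purrr::map_dfr(bias_cols, function(bc) {
      x <- merged[[cc]]
      y <- merged[[bc]]
      if (residualize %in% c("both", "components")) {
        x <- residualize_on_pe(x, merged$delta_pe)
      }
      if (residualize %in% c("both", "bias")) {
        y <- residualize_on_pe(y, merged$delta_pe)
      }
      ct <- stats::cor.test(x, y, conf.level = conf_level)
      tibble::tibble(
        component = cc, bias_type = bc,
        r = unname(ct$estimate),
        conf.low = ct$conf.int[1], conf.high = ct$conf.int[2],
        p.value = ct$p.value, n = length(x)
      )
    })
  })
  rows$p.adjusted <- stats::p.adjust(rows$p.value, method = "BH")
  rows
}

#' Bootstrap mediation analysis
#'
#' Simple three-variable mediation: path `a` from the regression of the
#' mediator on the predictor, paths `b` and `c'` from the regression of the
#' outcome on predictor and mediator, total effect `c` from the outcome on
#' the predictor alone, and indirect effect `a * b`. The indirect-effect
#' confidence interval is a percentile interval over case-resampled
#' bootstrap replicates.
#'
#' @param x,m,y Aligned numeric vectors: predictor, mediator, outcome.
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param seed Integer seed.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble of class `mediation_result`: `a`, `b`, `c`,
#'   `c_prime`, `indirect`, `ci_low`, `ci_high`, `n_boot`, `significant`.
#'   Bootstrap indirect-effect replicates are attached as attribute
#'   `"boot"`.
#' @export
mediation_bootstrap <- function(x, m, y, n_boot = 5000, seed = NULL,
                                conf_level = 0.95) {
  n <- length(x)
  if (length(m) != n || length(y) != n) abort("x, m, y must be aligned.")
  if (n < 10) abort("Need at least 10 cases.")
  if (stats::sd(x) == 0 || stats::sd(m) == 0) {
    abort("Degenerate predictor or mediator (zero variance).")
  }
  paths <- function(xi, mi, yi) {
    a <- stats::coef(stats::lm(mi ~ xi))[2]
    bm <- stats::lm(yi ~ xi + mi)
    b <- stats::coef(bm)[3]
    c_prime <- stats::coef(bm)[2]
    c_tot <- stats::coef(stats::lm(yi ~ xi))[2]
    c(a = unname(a), b = unname(b), c = unname(c_tot),
      c_prime = unname(c_prime))
  }
  est <- paths(x, m, y)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      p <- paths(x[idx], m[idx], y[idx])
      p[["a"]] * p[["b"]]
    }, 0)
  })
  alpha <- (1 - conf_level) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
  out <- tibble::tibble(
    a = est[["a"]], b = est[["b"]], c = est[["c"]],
    c_prime = est[["c_prime"]],
    indirect = est[["a"]] * est[["b"]],
    ci_low = ci[1], ci_high = ci[2],
    n_boot = n_boot,
    significant = ci[1] > 0 || ci[2] < 0
  )
  attr(out, "boot") <- boot
  class(out) <- c("mediation_result", class(out))
  out
}
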