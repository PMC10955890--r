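#' Convert a long ratings table to wide form, validating the schema
#'
#' @param ratings Long tibble with columns `subject_id`, `item_id`,
#'   `score_type` (`y1`..`y5`), `value`.
#' @return A wide tibble: `subject_id`, `item_id`, `y1`..`y5`.
#' @keywords internal
ratings_to_wide <- function(ratings) {
  assert_columns(ratings, c("subject_id", "item_id", "score_type", "value"),
    "`ratings`")
  bad_type <- setdiff(unique(ratings$score_type), score_types())
  if (length(bad_type) > 0) {
    abort(sprintf("Unknown score_type value(s): %s",
      paste(bad_type, collapse = ", ")))
  }
  if (anyNA(ratings$value)) abort("`ratings` contains missing values.")
  dup <- ratings |>
    dplyr::count(.data$subject_id, .data$item_id, .data$score_type) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "Duplicate (subject_id, item_id, score_type) key(s), e.g. (%s, %s, %s).",
      dup$subject_id[1], dup$item_id[1], dup$score_type[1]
    ))
  }
  wide <- tidyr::pivot_wider(ratings,
    id_cols = c("subject_id", "item_id"),
    names_from = "score_type", values_from = "value"
  )
  missing_types <- setdiff(score_types(), names(wide))
  if (length(missing_types) > 0 || anyNA(wide[score_types()])) {
    abort("Every (subject, item) pair must have all five score types y1..y5.")
  }
  dplyr::arrange(wide, .data$subject_id, .data$item_id)
}

#' Label observations by feedback condition
#'
#' The valence split labels each (subject, item) observation `"positive"`
#' when the judges' score y3 is at or above the positive threshold (7 on the
#' 0--10 scale) and `"neutral"` below it. The prediction-error split labels
#' by the sign of PE = y3 - y2 (judges' score minus the participant's
#' expected score): `"positive"` for PE > 0, `"neutral"` for PE < 0, and
#' `"zero_pe"` when the feedback exactly matches the expectation.
#'
#' @param ratings Long ratings table (see [ratings_to_wide()]).
#' @param model `"valence"` or `"pe"`.
#' @param positive_threshold Valence-split threshold on y3 (default 7).
#' @return A tibble: `subject_id`, `item_id`, `condition`.
#' @export
partition_by_condition <- function(ratings, model = c("valence", "pe"),
                                   positive_threshold = 7) {
  model <- match.arg(model)
  wide <- ratings_to_wide(ratings)
  condition <- if (model == "valence") {
    ifelse(wide$y3 >= positive_threshold, "positive", "neutral")
  } else {
    pe <- wide$y3 - wide$y2
    dplyr::case_when(pe > 0 ~ "positive", pe < 0 ~ "neutral",
      TRUE ~ "zero_pe")
  }
  tibble::tibble(
    subject_id = wide$subject_id, item_id = wide$item_id,
    condition = condition
  )
}

#' Prior hyperparameters for the update-bias model
#'
#' Weakly informative conjugate priors. Subject-level precision matrices get
#' a Wishart prior with `nu0` degrees of freedom centred on the inverse of a
#' learned group-level covariance scale per condition (partial pooling);
#' the group scale itself gets a Wishart prior with `lambda_df` degrees of
#' freedom and expectation `lambda_scale` times the identity (on the 0--10
#' rating scale a prior score SD of 1.5 gives `lambda_scale = 2.25`).
#' Subject means are pooled toward group locations with normal hyperpriors
#' centred at `mu_loc` (scale midpoint region) with variance `mu_var`, and
#' the between-subject mean spread gets an inverse-gamma prior.
#'
#' @param nu0 Wishart degrees of freedom of the subject-precision prior
#'   (> 4; larger values pool subject covariances more strongly).
#' @param lambda_df,lambda_scale Group-scale Wishart prior.
#' @param mu_loc,mu_var Normal hyperprior on group-level means.
#' @param sigma_shape,sigma_rate Inverse-gamma prior on the between-subject
#'   variance of each free mean.
#' @return A list of class `bias_priors`.
#' @export
model_priors <- function(nu0 = 7, lambda_df = 7, lambda_scale = 2.25,
                         mu_loc = 5, mu_var = 25,
                         sigma_shape = 2, sigma_rate = 2) {
  stopifnot(nu0 > 4, lambda_df > 4, lambda_scale > 0, mu_var > 0,
    sigma_shape > 0, sigma_rate > 0)
  structure(
    list(
      nu0 = nu0, lambda_df = lambda_df, lambda_scale = lambda_scale,
      mu_loc = mu_loc, mu_var = mu_var,
      sigma_shape = sigma_shape, sigma_rate = sigma_rate
    ),
    class = "bias_priors"
  )
}

#' MCMC settings profiles
#'
#' The `"paper"` profile mirrors the original fitting configuration: four
#' chains, 1500 warmup iterations, 10,000 post-warmup iterations thinned by
#' 4 (10,000 retained draws in total). The `"ci"` profile is a reduced
#' configuration for routine testing: four chains, 500 warmup, 500 retained
#' per chain, no thinning.
#'
#' @param profile `"ci"` or `"paper"`.
#' @param chains,warmup,keep,thin Override individual settings.
#' @return A list with elements `chains`, `warmup`, `keep` (retained draws
#'   per chain), `thin`.
#' @export
mcmc_profile <- function(profile = c("ci", "paper"), chains = NULL,
                         warmup = NULL, keep = NULL, thin = NULL) {
  profile <- match.arg(profile)
  out <- if (profile == "paper") {
    list(chains = 4, warmup = 1500, keep = 2500, thin = 4)
  } else {
    list(chains = 4, warmup = 500, keep = 500, thin = 1)
  }
  out$chains <- chains %||% out$chains
  out$warmup <- warmup %||% out$warmup
  out$keep <- keep %||% out$keep
  out$thin <- thin %||% out$thin
  out$profile <- profile
  out
}

#' Fit the hierarchical Bayesian update-bias model
#'
#' Fits the five-score multivariate-normal model in which each (subject,
#' item) observation vector (y1 pre-speech self-efficacy, y2 post-speech
#' self-evaluation, y3 judges' feedback, y4 post-feedback self-evaluation,
#' y5 post-feedback self-efficacy) is drawn from a subject-level normal
#' whose covariance `Sigma_s = diag(tau_s) Omega_s diag(tau_s)` differs
#' between positive and neutral feedback. The y3 mean is fixed (the judges'
#' scores were experimenter-controlled): at the per-condition schedule means
#' 5.05 / 8.25 for the valence split, or at the per-label empirical y3 means
#' for the PE split. Subject means and covariances are partially pooled via
#' group-level hyperparameters. Sampling is by a fully conjugate Gibbs
#' sampler (exact full-conditional updates; no divergence or step-size
#' tuning concepts apply).
#'
#' For the PE-split model, zero-PE observations are modelled with a
#' covariance built from the element-wise average of the two conditions'
#' tau and Omega parameters.
#'
#' @param ratings Long ratings table (`subject_id`, `item_id`, `score_type`,
#'   `value`).
#' @param model `"valence"` (split by y3 >= 7) or `"pe"` (split by the sign
#'   of y3 - y2).
#' @param mcmc MCMC settings from [mcmc_profile()].
#' @param priors Prior hyperparameters from [model_priors()].
#' @param seed Integer seed (one per-chain seed is derived from it).
#' @param positive_threshold Valence threshold (default 7).
#' @param mu3 Fixed y3 means for the valence split, named `neutral`,
#'   `positive`.
#' @param compute_loglik Store the pointwise log-likelihood matrix
#'   (retained draws x observations) for the training data.
#' @param min_items_per_condition Identifiability floor: abort unless every
#'   subject has at least this many items under each condition label
#'   (default 2). PE-split labels are data-driven and can be sparse in
#'   small samples; lowering the floor lets the hierarchical prior carry
#'   sparse subject-conditions instead.
#' @param check `"warn"` (default) warns on convergence-rule violations
#'   (R-hat >= 1.1 or bulk ESS <= the `ess_min` implied by the profile);
#'   `"error"` aborts -- the behaviour required at full-scale settings;
#'   `"none"` skips the automatic check.
#' @return An object of class `update_bias_fit`.
#' @export
fit_update_bias <- function(ratings, model = c("valence", "pe"),
                            mcmc = mcmc_profile("ci"),
                            priors = model_priors(),
                            seed = NULL,
                            positive_threshold = 7,
                            mu3 = c(neutral = 5.05, positive = 8.25),
                            compute_loglik = FALSE,
                            min_items_per_condition = 2,
                            check = c("warn", "error", "none")) {
  model <- match.arg(model)
  check <- match.arg(check)
  wide <- ratings_to_wide(ratings)
  fit <- fit_core(wide,
    eval_wide = if (compute_loglik) wide else NULL,
    model = model, mcmc = mcmc, priors = priors, seed = seed,
    positive_threshold = positive_threshold, mu3 = mu3,
    min_items_per_condition = min_items_per_condition
  )
  fit$diagnostics <- compute_diagnostics(fit)
  enforce_convergence(fit, check, mcmc)
  fit
}

# Core fitting routine shared by fit_update_bias() and kfold_elpd().
# `wide`/`eval_wide` are wide ratings tables; eval points get pointwise
# log-likelihood values under each retained draw.
fit_core <- function(wide, eval_wide, model, mcmc, priors, seed,
                     positive_threshold, mu3, min_items_per_condition = 2) {
  lab_of <- function(w) {
    if (model == "valence") {
      ifelse(w$y3 >= positive_threshold, 1L, 0L)
    } else {
      pe <- w$y3 - w$y2
      ifelse(pe > 0, 1L, ifelse(pe < 0, 0L, 2L))
    }
  }
  lab <- lab_of(wide)
  if (model == "pe" && (sum(lab == 1) == 0 || sum(lab == 0) == 0)) {
    abort(paste(
      "Degenerate PE split: need at least one positive-PE and one",
      "negative-PE observation; the averaged zero-PE covariance is",
      "undefined otherwise."
    ))
  }
  subjects <- sort(unique(wide$subject_id))
  subj0 <- match(wide$subject_id, subjects) - 1L
  per <- table(factor(subj0, levels = seq_along(subjects) - 1L),
    factor(lab, levels = 0:1))
  if (any(per < min_items_per_condition)) {
    abort("Each subject needs at least 2 items per feedback condition.")
  }

  mu3_vec <- if (model == "valence") {
    c(mu3[["neutral"]], mu3[["positive"]], mean(wide$y3))
  } else {
    m_neu <- mean(wide$y3[lab == 0])
    m_pos <- mean(wide$y3[lab == 1])
    m_zero <- if (any(lab == 2)) mean(wide$y3[lab == 2]) else mean(wide$y3)
    c(m_neu, m_pos, m_zero)
  }

  Y <- as.matrix(wide[score_types()])
  if (is.null(eval_wide)) {
    Yeval <- matrix(0, 0, 5)
    subj_eval <- integer(0)
    lab_eval <- integer(0)
  } else {
    miss <- !(eval_wide$subject_id %in% subjects)
    if (any(miss)) {
      abort("Evaluation data contains subjects absent from the training data.")
    }
    Yeval <- as.matrix(eval_wide[score_types()])
    subj_eval <- match(eval_wide$subject_id, subjects) - 1L
    lab_eval <- lab_of(eval_wide)
  }

  B0 <- diag(priors$lambda_scale / priors$lambda_df, 5)
  chains <- lapply(seq_len(mcmc$chains), function(ch) {
    with_seed(derive_seed(seed, 1000 + ch) %||% NULL, {
      gibbs_chain_cpp(
        Y, subj0, lab, mu3_vec, length(subjects),
        mcmc$warmup, mcmc$keep, mcmc$thin,
        priors$nu0, priors$lambda_df, B0,
        rep(priors$mu_loc, 4), priors$mu_var,
        priors$sigma_shape, priors$sigma_rate,
        Yeval, subj_eval, lab_eval, !is.null(eval_wide)
      )
    })
  })

  bind_chains <- function(name) {
    arrs <- lapply(chains, `[[`, name)
    if (length(dim(arrs[[1]])) == 3) {
      out <- array(0, dim = c(
        sum(vapply(arrs, function(a) dim(a)[1], 0L)),
        dim(arrs[[1]])[2], dim(arrs[[1]])[3]
      ))
      at <- 1
      for (a in arrs) {
        out[at:(at + dim(a)[1] - 1), , ] <- a
        at <- at + dim(a)[1]
      }
      out
    } else {
      do.call(rbind, arrs)
    }
  }

  draws <- list(
    mu = bind_chains("mu"),
    tau_pos = bind_chains("tau_pos"), tau_neu = bind_chains("tau_neu"),
    omega_pos = bind_chains("omega_pos"), omega_neu = bind_chains("omega_neu"),
    eta = bind_chains("eta"), sigma2 = bind_chains("sigma2")
  )
  loglik <- if (!is.null(eval_wide)) bind_chains("loglik") else NULL

  structure(
    list(
      draws = draws,
      chain_id = rep(seq_len(mcmc$chains), each = mcmc$keep),
      subjects = subjects,
      labels = tibble::tibble(
        subject_id = wide$subject_id, item_id = wide$item_id,
        condition = c("neutral", "positive", "zero_pe")[lab + 1L]
      ),
      model = model, mu3 = mu3_vec, mcmc = mcmc, priors = priors,
      seed = seed,
      loglik = loglik,
      loglik_points = if (!is.null(eval_wide)) {
        eval_wide[, c("subject_id", "item_id")]
      } else {
        NULL
      },
      n_items = nrow(wide)
    ),
    class = "update_bias_fit"
  )
}

# Upper-triangle storage order of the 10 free correlation cells.
omega_cell_index <- function(i, j) {
  pairs <- utils::combn(5, 2)
  which(pairs[1, ] == min(i, j) & pairs[2, ] == max(i, j))
}

#' Extract per-subject positive-update-bias indices
#'
#' The self-evaluation update bias is `Omega_pos(y3, y4) - Omega_neu(y3, y4)`
#' and the self-efficacy update bias `Omega_pos(y3, y5) - Omega_neu(y3, y5)`:
#' the difference between the feedback-rating correlations under positive
#' and neutral feedback. Both are computed per posterior draw; the point
#' estimate is the posterior mean.
#'
#' @param fit An [fit_update_bias()] result.
#' @return A tibble of class `bias_indices` with columns `subject_id`,
#'   `self_eval_bias`, `self_efficacy_bias`. The full per-draw series are
#'   attached as attribute `"draws"` (a list of draws x subjects matrices).
#' @export
extract_bias <- function(fit) {
  stopifnot(inherits(fit, "update_bias_fit"))
  i34 <- omega_cell_index(3, 4)
  i35 <- omega_cell_index(3, 5)
  d_eval <- fit$draws$omega_pos[, , i34, drop = FALSE][, , 1] -
    fit$draws$omega_neu[, , i34, drop = FALSE][, , 1]
  d_eff <- fit$draws$omega_pos[, , i35, drop = FALSE][, , 1] -
    fit$draws$omega_neu[, , i35, drop = FALSE][, , 1]
  d_eval <- matrix(d_eval, nrow = dim(fit$draws$omega_pos)[1])
  d_eff <- matrix(d_eff, nrow = dim(fit$draws$omega_pos)[1])
  out <- tibble::tibble(
    subject_id = fit$subjects,
    self_eval_bias = colMeans(d_eval),
    self_efficacy_bias = colMeans(d_eff)
  )
  attr(out, "draws") <- list(self_eval = d_eval, self_efficacy = d_eff)
  class(out) <- c("bias_indices", class(out))
  out
}

# ---- convergence diagnostics ------------------------------------------------

#' Split-chain R-hat
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half (detects within-chain trends as well as between-chain disagreement).
#'
#' @param x Numeric vector of draws, ordered by chain.
#' @param chain_id Integer chain membership of each draw.
#' @return The split-R-hat value (1 indicates convergence).
#' @export
split_rhat <- function(x, chain_id) {
  cols <- split_chain_halves(x, chain_id)
  n <- min(lengths(cols))
  m <- vapply(cols, function(v) mean(v[seq_len(n)]), 0)
  v <- vapply(cols, function(v) stats::var(v[seq_len(n)]), 0)
  W <- mean(v)
  B <- n * stats::var(m)
  if (W == 0) {
    return(1)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

split_chain_halves <- function(x, chain_id) {
  out <- list()
  for (ch in unique(chain_id)) {
    v <- x[chain_id == ch]
    h <- floor(length(v) / 2)
    out <- c(out, list(v[seq_len(h)], v[(h + 1):(2 * h)]))
  }
  out
}

#' Effective sample size
#'
#' Multi-chain effective sample size using chain-averaged autocorrelations
#' (Geyer initial-positive-sequence truncation).
#'
#' @inheritParams split_rhat
#' @return The estimated effective number of independent draws.
#' @export
ess_draws <- function(x, chain_id) {
  cols <- split_chain_halves(x, chain_id)
  n <- min(lengths(cols))
  m <- length(cols)
  mat <- vapply(cols, function(v) v[seq_len(n)], numeric(n))
  chain_var <- apply(mat, 2, stats::var)
  W <- mean(chain_var)
  var_hat <- (n - 1) / n * W + n * stats::var(colMeans(mat)) / n
  if (W == 0 || var_hat == 0) {
    return(m * n)
  }
  max_lag <- min(n - 1, 200)
  acov <- vapply(seq_len(m), function(k) {
    a <- stats::acf(mat[, k], lag.max = max_lag, type = "covariance",
      plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(max_lag + 1))
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_hat
  # Geyer: sum consecutive pairs while positive
  s <- 0
  t <- 1 # rho[1] is lag 0 = contribution handled via 1 + 2*sum(lags>=1)
  lag <- 2
  while (lag + 1 <= length(rho)) {
    pair <- rho[lag] + rho[lag + 1]
    if (pair < 0) break
    s <- s + pair
    lag <- lag + 2
  }
  ess <- m * n / (1 + 2 * s)
  min(ess, m * n)
}

compute_diagnostics <- function(fit) {
  ndraw <- dim(fit$draws$mu)[1]
  S <- length(fit$subjects)
  series <- list()
  add <- function(name, x) series[[name]] <<- x
  pairs <- utils::combn(5, 2)
  for (s in seq_len(S)) {
    for (u in seq_len(10)) {
      nm <- sprintf("omega_pos[%d,%d%d]", s, pairs[1, u], pairs[2, u])
      add(nm, fit$draws$omega_pos[, s, u])
      nm <- sprintf("omega_neu[%d,%d%d]", s, pairs[1, u], pairs[2, u])
      add(nm, fit$draws$omega_neu[, s, u])
    }
    for (j in seq_len(5)) {
      add(sprintf("tau_pos[%d,%d]", s, j), fit$draws$tau_pos[, s, j])
      add(sprintf("tau_neu[%d,%d]", s, j), fit$draws$tau_neu[, s, j])
    }
    for (j in seq_len(4)) {
      add(sprintf("mu[%d,%d]", s, j), fit$draws$mu[, s, j])
    }
  }
  for (j in seq_len(4)) {
    add(sprintf("eta[%d]", j), fit$draws$eta[, j])
    add(sprintf("sigma2[%d]", j), fit$draws$sigma2[, j])
  }
  tibble::tibble(
    parameter = names(series),
    rhat = vapply(series, split_rhat, 0, chain_id = fit$chain_id),
    ess = vapply(series, ess_draws, 0, chain_id = fit$chain_id)
  )
}

#' Convergence report for a fitted model
#'
#' Applies the study's convergence rules: all R-hat values should be below
#' 1.1 and effective sample sizes above 1000 (the ESS rule is meaningful at
#' full-scale, 10,000-draw settings; at reduced settings the ESS floor is
#' scaled to half the retained draws).
#'
#' @param fit An [fit_update_bias()] result.
#' @param rhat_max R-hat threshold (default 1.1).
#' @param ess_min ESS threshold; default 1000 at full scale (>= 10,000
#'   retained draws), i.e. 10% of the retained draws, and the same 10%
#'   fraction at reduced settings.
#' @return A list with `max_rhat`, `min_ess`, `pass`, and the per-parameter
#'   `table`.
#' @export
check_convergence <- function(fit, rhat_max = 1.1, ess_min = NULL) {
  stopifnot(inherits(fit, "update_bias_fit"))
  diag <- fit$diagnostics %||% compute_diagnostics(fit)
  total <- dim(fit$draws$mu)[1]
  ess_min <- ess_min %||% if (total >= 10000) 1000 else total / 10
  list(
    max_rhat = max(diag$rhat),
    min_ess = min(diag$ess),
    rhat_max_allowed = rhat_max,
    ess_min_required = ess_min,
    pass = max(diag$rhat) < rhat_max && min(diag$ess) > ess_min,
    table = diag
  )
}

enforce_convergence <- function(fit, check, mcmc) {
  if (check == "none") {
    return(invisible(fit))
  }
  rep <- check_convergence(fit)
  if (!rep$pass) {
    msg <- sprintf(
      "Convergence rules violated: max R-hat = %.3f (< %.2f required), min ESS = %.0f (> %.0f required).",
      rep$max_rhat, rep$rhat_max_allowed, rep$min_ess, rep$ess_min_required
    )
    if (check == "error" || identical(mcmc$profile, "paper")) {
      abort(msg)
    }
    warn(msg)
  }
  invisible(fit)
}

# ---- methods ----------------------------------------------------------------

#' @export
print.update_bias_fit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical update-bias model (%s split)\n", x$model
  ))
  cat(sprintf(
    "  %d subjects, %d observations; %d chains x %d retained draws\n",
    length(x$subjects), x$n_items, x$mcmc$chains, x$mcmc$keep
  ))
  if (!is.null(x$diagnostics)) {
    cat(sprintf(
      "  max R-hat %.3f, min ESS %.0f\n",
      max(x$diagnostics$rhat), min(x$diagnostics$ess)
    ))
  }
  invisible(x)
}

#' Tidy per-subject bias summaries from a fitted model
#'
#' @param x An `update_bias_fit`.
#' @param conf_level Credible-interval mass (central quantiles).
#' @param ... Unused.
#' @return A tibble with one row per subject x bias type: `subject_id`,
#'   `term`, `estimate`, `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.update_bias_fit <- function(x, conf_level = 0.95, ...) {
  bias <- extract_bias(x)
  draws <- attr(bias, "draws")
  a <- (1 - conf_level) / 2
  purrr::map_dfr(
    c(self_eval_bias = "self_eval", self_efficacy_bias = "self_efficacy"),
    function(key) {
      d <- draws[[key]]
      tibble::tibble(
        subject_id = x$subjects,
        estimate = colMeans(d),
        std.error = apply(d, 2, stats::sd),
        conf.low = apply(d, 2, stats::quantile, probs = a),
        conf.high = apply(d, 2, stats::quantile, probs = 1 - a)
      )
    },
    .id = "term"
  ) |>
    dplyr::relocate("subject_id")
}

#' One-row model summary
#'
#' @param x An `update_bias_fit`.
#' @param ... Unused.
#' @return A one-row tibble with fit dimensions and diagnostics.
#' @export
glance.update_bias_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_subjects = length(x$subjects),
    n_obs = x$n_items,
    chains = x$mcmc$chains,
    n_draws = dim(x$draws$mu)[1],
    max_rhat = if (!is.null(x$diagnostics)) max(x$diagnostics$rhat) else NA_real_,
    min_ess = if (!is.null(x$diagnostics)) min(x$diagnostics$ess) else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
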