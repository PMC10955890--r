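# small cohort reused within this file
small_fit_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_subjects = 3, n_items = 20,
        self_efficacy_bias = 0.3)
      coh <- simulate_cohort(cfg, seed = 21)
      fit <- fit_update_bias(coh$ratings, "valence",
        mcmc = mcmc_profile("ci", chains = 2, warmup = 200, keep = 200),
        seed = 5, compute_loglik = TRUE, check = "none"
      )
      cache <<- list(cohort = coh, fit = fit)
    }
    cache
  }
})

test_that("condition labels follow the valence threshold and PE sign", {
  ratings <- tidyr::expand_grid(
    subject_id = 1, item_id = 1:4,
    score_type = c("y1", "y2", "y3", "y4", "y5")
  )
  y2 <- c(5, 7, 6.5, 3)
  y3 <- c(7, 6.99, 6.5, 9)
  ratings$value <- dplyr::case_when(
    ratings$score_type == "y2" ~ y2[ratings$item_id],
    ratings$score_type == "y3" ~ y3[ratings$item_id],
    TRUE ~ 5
  )
  val <- partition_by_condition(ratings, "valence")
  expect_equal(val$condition, c("positive", "neutral", "neutral", "positive"))
  pe <- partition_by_condition(ratings, "pe")
  expect_equal(pe$condition, c("positive", "neutral", "zero_pe", "positive"))
})

test_that("stored pointwise log-likelihood matches a direct density oracle", {
  skip_if_not_installed("mvtnorm")
  case <- small_fit_case()
  fit <- case$fit
  wide <- feedbackbias:::ratings_to_wide(case$cohort$ratings)
  lab <- ifelse(wide$y3 >= 7, 2L, 1L) # index into fit$mu3 (neu, pos, zero)
  set.seed(9)
  for (d in sample(dim(fit$draws$mu)[1], 5)) {
    for (i in sample(nrow(wide), 4)) {
      si <- match(wide$subject_id[i], fit$subjects)
      cond <- if (lab[i] == 2L) "pos" else "neu"
      sigma <- fit_draw_sigma(fit, d, si, cond)
      mu <- fit_draw_mu(fit, d, si, lab[i])
      y <- as.numeric(wide[i, c("y1", "y2", "y3", "y4", "y5")])
      ref <- mvtnorm::dmvnorm(y, mu, sigma, log = TRUE)
      expect_equal(fit$loglik[d, i], ref, tolerance = 1e-8)
    }
  }
})

test_that("posterior correlation draws are valid correlation matrices", {
  fit <- small_fit_case()$fit
  set.seed(2)
  for (d in sample(dim(fit$draws$mu)[1], 25)) {
    for (cond in c("pos", "neu")) {
      sig <- fit_draw_sigma(fit, d, 1, cond)
      om <- stats::cov2cor(sig)
      expect_true(all(abs(om) <= 1 + 1e-12))
      expect_true(all(eigen(om, only.values = TRUE)$values > 0))
    }
  }
  bias <- extract_bias(fit)
  draws <- attr(bias, "draws")
  expect_true(all(abs(draws$self_eval) <= 2))
  expect_true(all(abs(draws$self_efficacy) <= 2))
})

test_that("bias extraction is exact arithmetic on the correlation cells", {
  fit <- small_fit_case()$fit
  i34 <- feedbackbias:::omega_cell_index(3, 4)
  i35 <- feedbackbias:::omega_cell_index(3, 5)
  bias <- extract_bias(fit)
  draws <- attr(bias, "draws")
  set.seed(3)
  for (d in sample(dim(fit$draws$mu)[1], 10)) {
    for (s in seq_along(fit$subjects)) {
      expect_identical(
        draws$self_eval[d, s],
        fit$draws$omega_pos[d, s, i34] - fit$draws$omega_neu[d, s, i34]
      )
      expect_identical(
        draws$self_efficacy[d, s],
        fit$draws$omega_pos[d, s, i35] - fit$draws$omega_neu[d, s, i35]
      )
    }
  }
  expect_equal(bias$self_eval_bias, colMeans(draws$self_eval))
})

test_that("a single subject with many items recovers the generating gap", {
  om_pos <- omega_with(`3_5` = 0.6)
  om_neu <- omega_with(`3_5` = 0.2)
  params <- fixed_subject_params(om_pos, om_neu)
  comp <- feedback_composition(2000)
  sched <- tibble::tibble(
    item_id = seq_len(2000),
    score = as.integer(rep(comp$score, comp$n)),
    condition = rep(comp$condition, comp$n)
  )
  r <- sample_ratings(params, sched, seed = 14)
  ratings <- dplyr::bind_cols(tibble::tibble(subject_id = 1L), r)
  fit <- fit_update_bias(ratings, "valence",
    mcmc = mcmc_profile("ci", chains = 2, warmup = 200, keep = 300),
    seed = 6, check = "none"
  )
  i35 <- feedbackbias:::omega_cell_index(3, 5)
  expect_lt(abs(mean(fit$draws$omega_pos[, 1, i35]) - 0.6), 0.05)
  expect_lt(abs(mean(fit$draws$omega_neu[, 1, i35]) - 0.2), 0.05)
})

test_that("a null generator yields bias posteriors covering zero", {
  cfg <- cohort_config(n_subjects = 10, n_items = 40)
  coh <- simulate_cohort(cfg, seed = 17)
  fit <- fit_update_bias(coh$ratings, "valence",
    mcmc = mcmc_profile("ci", chains = 2, warmup = 300, keep = 400),
    seed = 3, check = "none"
  )
  td <- tidy(fit)
  eff <- td[td$term == "self_efficacy_bias", ]
  covered <- mean(eff$conf.low <= 0 & eff$conf.high >= 0)
  expect_gte(covered, 0.9)
})

test_that("PE and valence models agree when the labels coincide", {
  cfg <- cohort_config(n_subjects = 4, n_items = 40,
    self_efficacy_bias = 0.3)
  coh <- simulate_cohort(cfg, seed = 30)
  ratings <- coh$ratings |>
    tidyr::pivot_wider(names_from = "score_type", values_from = "value") |>
    dplyr::mutate(y2 = ifelse(.data$y3 >= 7, .data$y3 - 2, .data$y3 + 2) +
      withr::with_seed(55, runif(dplyr::n(), -1, 1))) |>
    tidyr::pivot_longer(dplyr::all_of(c("y1", "y2", "y3", "y4", "y5")),
      names_to = "score_type", values_to = "value"
    )
  lab_val <- partition_by_condition(ratings, "valence")
  lab_pe <- partition_by_condition(ratings, "pe")
  expect_identical(lab_val$condition, lab_pe$condition)

  mcmc <- mcmc_profile("ci", chains = 2, warmup = 300, keep = 300)
  fit_val <- fit_update_bias(ratings, "valence", mcmc = mcmc, seed = 8,
    check = "none")
  fit_pe <- fit_update_bias(ratings, "pe", mcmc = mcmc, seed = 9,
    check = "none")
  b_val <- extract_bias(fit_val)
  b_pe <- extract_bias(fit_pe)
  expect_equal(b_val$self_efficacy_bias, b_pe$self_efficacy_bias,
    tolerance = 0.15)
})

test_that("an all-zero-PE dataset is flagged as degenerate", {
  cfg <- cohort_config(n_subjects = 3, n_items = 20)
  coh <- simulate_cohort(cfg, seed = 12)
  ratings <- coh$ratings |>
    tidyr::pivot_wider(names_from = "score_type", values_from = "value") |>
    dplyr::mutate(y2 = .data$y3) |>
    tidyr::pivot_longer(dplyr::all_of(c("y1", "y2", "y3", "y4", "y5")),
      names_to = "score_type", values_to = "value"
    )
  expect_error(
    fit_update_bias(ratings, "pe", seed = 1, check = "none"),
    "[Dd]egenerate"
  )
})

test_that("fits require at least two items per condition per subject", {
  cfg <- cohort_config(n_subjects = 3, n_items = 20)
  coh <- simulate_cohort(cfg, seed = 13)
  # remove all but one neutral item for subject 2
  wide <- tidyr::pivot_wider(coh$ratings, names_from = "score_type",
    values_from = "value")
  drop <- wide$subject_id == 2 & wide$y3 < 7 &
    duplicated(wide$subject_id == 2 & wide$y3 < 7) &
    cumsum(wide$subject_id == 2 & wide$y3 < 7) > 1
  keep <- !(wide$subject_id == 2 & wide$y3 < 7 &
    seq_len(nrow(wide)) %in% which(wide$subject_id == 2 & wide$y3 < 7)[-1])
  long <- wide[keep, ] |>
    tidyr::pivot_longer(dplyr::all_of(c("y1", "y2", "y3", "y4", "y5")),
      names_to = "score_type", values_to = "value"
    )
  expect_error(
    fit_update_bias(long, "valence", seed = 1, check = "none"),
    "at least 2 items"
  )
})

test_that("split R-hat and ESS behave on analytic fixtures and match formulas", {
  skip_if_not_installed("coda")
  set.seed(77)
  # independent noise: rhat near 1, ESS near the number of draws
  x <- rnorm(2000)
  chain <- rep(1:4, each = 500)
  expect_lt(split_rhat(x, chain), 1.01)
  expect_gt(ess_draws(x, chain), 1200)

  # two chains at different levels: rhat far above 1
  y <- c(rnorm(500), rnorm(500) + 3)
  expect_gt(split_rhat(y, rep(1:2, each = 500)), 1.5)

  # identical chains: no between-chain variance
  z <- rep(rnorm(400), 2)
  expect_lt(split_rhat(z, rep(1:2, each = 400)), 1.001)

  # split-chain formula recount (independent implementation)
  v <- rnorm(800)
  cid <- rep(1:2, each = 400)
  halves <- list(v[1:200], v[201:400], v[401:600], v[601:800])
  n <- 200
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  ref <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(split_rhat(v, cid), ref, tolerance = 1e-6)

  # ESS comparable to coda on an AR(1) series
  ar <- as.numeric(arima.sim(list(ar = 0.7), 4000))
  ours <- ess_draws(ar, rep(1, 4000))
  ref_ess <- unname(coda::effectiveSize(ar))
  expect_lt(abs(ours - ref_ess) / ref_ess, 0.35)
})

test_that("convergence checking reports and enforces the study rules", {
  fit <- small_fit_case()$fit
  rep <- check_convergence(fit, ess_min = 30)
  expect_true(rep$pass)
  expect_lt(rep$max_rhat, 1.1)
  expect_true(all(c("parameter", "rhat", "ess") %in% names(rep$table)))
  # an absurd ESS requirement fails the report
  expect_false(check_convergence(fit, ess_min = 1e9)$pass)
})
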