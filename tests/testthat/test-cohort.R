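test_that("simulated cohorts have the full crossed structure and are reproducible", {
  cfg <- cohort_config(n_subjects = 6, n_items = 20)
  coh <- simulate_cohort(cfg, seed = 4)
  expect_equal(nrow(coh$ratings), 6 * 20 * 5)
  expect_equal(
    dplyr::count(coh$ratings, subject_id, item_id) |> dplyr::pull(n),
    rep(5, 6 * 20)
  )
  coh2 <- simulate_cohort(cfg, seed = 4)
  expect_identical(coh$ratings, coh2$ratings)
  coh3 <- simulate_cohort(cfg, seed = 5)
  expect_false(identical(coh$ratings$value, coh3$ratings$value))
})

test_that("subject parameters are valid correlation structures with exact truth", {
  cfg <- cohort_config(
    n_subjects = 20, self_eval_bias = 0.1,
    self_efficacy_bias = seq(-0.3, 0.5, length.out = 20)
  )
  pars <- draw_subject_parameters(cfg, seed = 2)
  for (s in seq_len(20)) {
    for (om in list(pars$omega_pos[[s]], pars$omega_neu[[s]])) {
      expect_equal(om, t(om))
      expect_equal(unname(diag(om)), rep(1, 5))
      expect_true(all(eigen(om, only.values = TRUE)$values > 0))
    }
    # stored truth equals the realized matrix difference exactly
    expect_identical(
      pars$true_self_efficacy_bias[s],
      pars$omega_pos[[s]][3, 5] - pars$omega_neu[[s]][3, 5]
    )
    expect_identical(
      pars$true_self_eval_bias[s],
      pars$omega_pos[[s]][3, 4] - pars$omega_neu[[s]][3, 4]
    )
  }
})

test_that("zero jitter makes all subjects share the population parameters", {
  cfg <- cohort_config(
    n_subjects = 4, jitter_z = 0, mu_jitter = 0, tau_jitter = 0,
    self_efficacy_bias = 0.4, self_eval_bias = 0
  )
  pars <- draw_subject_parameters(cfg, seed = 1)
  expect_equal(pars$omega_neu[[1]], pars$omega_neu[[4]])
  expect_equal(pars$omega_pos[[1]], pars$omega_pos[[4]])
  expect_equal(pars$true_self_efficacy_bias, rep(0.4, 4), tolerance = 1e-12)
  expect_equal(pars$omega_neu[[1]], default_omega_base())
})

test_that("conditional sampler matches a rejection-sampling oracle", {
  om_pos <- omega_with(`3_5` = 0.6)
  om_neu <- omega_with(`3_5` = 0.2)
  params <- fixed_subject_params(om_pos, om_neu)
  tau <- params$tau_pos[[1]]
  sig <- diag(tau) %*% om_pos %*% diag(tau)
  mu_full <- c(5.3, 5.0, 8.25, 5.6, 5.9)

  # oracle: unconditional 5-D draws, rejected onto a narrow y3 bin
  set.seed(71)
  L <- chol(sig)
  z <- matrix(rnorm(1.5e6 * 5), ncol = 5) %*% L
  y <- sweep(z, 2, mu_full, `+`)
  keep <- abs(y[, 3] - 8) < 0.05
  oracle_cov <- stats::cov(y[keep, c(1, 2, 4, 5)])

  # implementation: schedule pinning y3 = 8 on every (positive) item
  sched <- tibble::tibble(
    item_id = seq_len(50000), score = 8L, condition = "positive"
  )
  draws <- sample_ratings(params, sched, seed = 8)
  wide <- tidyr::pivot_wider(draws,
    names_from = "score_type", values_from = "value"
  )
  impl_cov <- stats::cov(as.matrix(wide[c("y1", "y2", "y4", "y5")]))

  scale_ref <- sqrt(diag(oracle_cov) %o% diag(oracle_cov))
  expect_true(all(abs(impl_cov - oracle_cov) / scale_ref < 0.02))
})

test_that("identity correlation makes ratings independent of the feedback", {
  params <- fixed_subject_params(diag(5), diag(5))
  sched <- tibble::tibble(
    item_id = 1:20000,
    score = rep(c(7L, 10L), 10000),
    condition = "positive"
  )
  draws <- sample_ratings(params, sched, seed = 3)
  wide <- tidyr::pivot_wider(draws, names_from = "score_type",
    values_from = "value")
  m_low <- colMeans(wide[wide$y3 == 7, c("y1", "y2", "y4", "y5")])
  m_high <- colMeans(wide[wide$y3 == 10, c("y1", "y2", "y4", "y5")])
  expect_true(all(abs(m_low - m_high) < 0.06))
  expect_true(all(abs(m_low - c(5.3, 5.0, 5.6, 5.9)) < 0.06))
})

test_that("near-unit feedback coupling makes y4 almost deterministic in y3", {
  om <- omega_with(`3_4` = 0.999, `2_3` = 0.1, `2_4` = 0.1, `1_4` = 0.1,
    `1_3` = 0.1, `4_5` = 0.1, `3_5` = 0.1)
  params <- fixed_subject_params(om, om)
  sched <- tibble::tibble(
    item_id = 1:5000,
    score = sample(rep(7:10, length.out = 5000)),
    condition = "positive"
  )
  draws <- sample_ratings(params, sched, seed = 12)
  wide <- tidyr::pivot_wider(draws, names_from = "score_type",
    values_from = "value")
  resid_sd <- stats::sd(stats::residuals(stats::lm(y4 ~ y3, data = wide)))
  tau4 <- params$tau_pos[[1]][4]
  expect_lte(resid_sd, tau4 * sqrt(1 - 0.999^2) * 1.1)
})

test_that("per-subject feedback correlations converge to the generating value", {
  om_pos <- omega_with(`3_5` = 0.6)
  params <- fixed_subject_params(om_pos, default_omega_base())
  comp <- feedback_composition(2000)
  sched <- tibble::tibble(
    item_id = seq_len(2000),
    score = as.integer(rep(comp$score, comp$n)),
    condition = rep(comp$condition, comp$n)
  )
  draws <- sample_ratings(params, sched, seed = 9)
  wide <- tidyr::pivot_wider(draws, names_from = "score_type",
    values_from = "value")
  pos <- wide[wide$y3 >= 7, ]
  expect_equal(stats::cor(pos$y3, pos$y5), 0.6, tolerance = 0.05)
})

test_that("discretization stays close to the continuous marginals", {
  cfg_c <- cohort_config(n_subjects = 4, n_items = 40,
    tau = rep(1.3, 5), discretize = FALSE)
  cfg_d <- cohort_config(n_subjects = 4, n_items = 40,
    tau = rep(1.3, 5), discretize = TRUE)
  cont <- simulate_cohort(cfg_c, seed = 33)$ratings
  disc <- simulate_cohort(cfg_d, seed = 33)$ratings
  for (st in c("y1", "y4", "y5")) {
    a <- cont$value[cont$score_type == st]
    b <- disc$value[disc$score_type == st]
    ks <- suppressWarnings(stats::ks.test(a, b)$statistic)
    expect_lte(unname(ks), 0.1)
  }
  expect_true(all(disc$value >= 0 & disc$value <= 10))
  expect_true(all(disc$value * 10 == round(disc$value * 10)))
})

test_that("reverse coding reflects the scale and is an involution", {
  expect_equal(reverse_code(0, "negative"), 10)
  expect_equal(reverse_code(5, "negative"), 5)
  expect_equal(reverse_code(7, "positive"), 7)
  v <- runif(20, 0, 10)
  expect_equal(reverse_code(reverse_code(v, "negative"), "negative"), v)
  expect_error(reverse_code(11, "negative"), "\\[0, 10\\]")
})

test_that("questionnaire generator plants the requested bias correlation", {
  set.seed(42)
  bias <- runif(500, -0.3, 0.5)
  q0 <- simulate_questionnaires(bias, r_bias = 0, seed = 5)
  z0 <- rowMeans(scale(as.matrix(q0[c("stai", "bdi", "neo_n")])))
  expect_lt(abs(stats::cor(z0, bias)), 0.1)

  q <- simulate_questionnaires(bias, r_bias = -0.29, seed = 5)
  prof <- pca_varimax(q)
  expect_gte(prof$retained, 2)
  expect_gt(prof$eigenvalues[2], 1)
  # identify the self-negativity component by its BDI loading
  k <- which.max(abs(prof$loadings["bdi", ]))
  r <- stats::cor(prof$scores[[paste0("PC", k)]], bias)
  # RSE loads opposite to the depression/anxiety block
  expect_lt(prof$loadings["rse", k] * prof$loadings["bdi", k], 0)
  expect_lt(abs(abs(r) - 0.29), 0.1)

  # rotated loadings recover the generating structure (congruence > 0.9)
  gen <- as.matrix(feedbackbias:::questionnaire_loadings()[, c("soc", "neg")])
  congruence <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  cg <- abs(outer(seq_len(2), seq_len(prof$retained), Vectorize(function(i, j) {
    congruence(gen[, i], prof$loadings[, j])
  })))
  expect_true(all(apply(cg, 1, max) > 0.9))
})
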