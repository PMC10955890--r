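test_that("the HDI equals a brute-force shortest-window search", {
  set.seed(101)
  for (i in 1:5) {
    x <- switch(i,
      rnorm(500),
      rexp(400),
      c(rnorm(300, -2), rnorm(200, 3)), # bimodal
      runif(250),
      rgamma(600, 2)
    )
    got <- hdi_interval(x, 0.95)
    ref <- hdi_oracle(x, 0.95)
    expect_equal(unname(got), ref)
  }
  # degenerate: all draws identical
  expect_equal(unname(hdi_interval(rep(1.5, 100))), c(1.5, 1.5))
})

test_that("group-level decisions follow the HDI position", {
  fake_bias <- function(draw_mat) {
    out <- tibble::tibble(
      subject_id = seq_len(ncol(draw_mat)),
      self_eval_bias = colMeans(draw_mat),
      self_efficacy_bias = colMeans(draw_mat)
    )
    attr(out, "draws") <- list(self_eval = draw_mat,
      self_efficacy = draw_mat)
    class(out) <- c("bias_indices", class(out))
    out
  }
  set.seed(5)
  pos <- fake_bias(matrix(rnorm(1000 * 9, 0.5, 0.1), 1000))
  res <- group_bias_hdi(pos, "self_efficacy")
  expect_equal(res$decision, "positive_bias")
  expect_true(res$hdi_low <= res$point && res$point <= res$hdi_high)

  null <- fake_bias(matrix(rnorm(1000 * 9, 0, 0.1), 1000))
  expect_equal(group_bias_hdi(null, "self_efficacy")$decision,
    "not_established")

  neg <- fake_bias(matrix(rnorm(1000 * 9, -0.5, 0.1), 1000))
  expect_equal(group_bias_hdi(neg, "self_efficacy")$decision,
    "negative_bias")

  const <- fake_bias(matrix(0.25, 200, 5))
  res_c <- group_bias_hdi(const, "self_eval")
  expect_equal(c(res_c$hdi_low, res_c$hdi_high), c(0.25, 0.25))
})

make_long <- function(wide) {
  tidyr::pivot_longer(wide, dplyr::all_of(c("y1", "y2", "y3", "y4", "y5")),
    names_to = "score_type", values_to = "value")
}

test_that("empirical bias reproduces textbook correlation differences", {
  set.seed(8)
  n <- 40
  y3 <- rep(c(4, 5, 6, 8, 9, 10), length.out = n)
  wide <- tibble::tibble(
    subject_id = 1, item_id = 1:n,
    y1 = rnorm(n, 5), y2 = rnorm(n, 5), y3 = y3,
    y4 = rnorm(n, 5), y5 = y3 + rnorm(n, 0, 0.01)
  )
  # y5 tracks y3 perfectly in both conditions: difference near 0
  res <- empirical_bias(make_long(wide), "y5")
  expect_lt(abs(res$empirical_bias), 0.1)

  # y5 = y3 under positive feedback only
  wide2 <- wide
  wide2$y5 <- ifelse(y3 >= 7, y3 + rnorm(n, 0, 0.001), rnorm(n, 5))
  # add spread to y3 within conditions so correlations are defined
  wide2$y3 <- rep(c(4, 5, 6, 8, 9, 10), length.out = n)
  wide2 <- dplyr::arrange(wide2, y3)
  wide2$y5 <- ifelse(wide2$y3 >= 7, wide2$y3 + rnorm(n, 0, 0.001),
    rnorm(n, 5))
  res2 <- empirical_bias(make_long(wide2), "y5")
  expect_gt(res2$empirical_bias, 0.8)

  # matches the direct formula
  pos <- wide2[wide2$y3 >= 7, ]
  neu <- wide2[wide2$y3 < 7, ]
  ref <- stats::cor(pos$y3, pos$y5) - stats::cor(neu$y3, neu$y5)
  expect_equal(res2$empirical_bias, ref)
})

test_that("the bias-vs-empirical check is exact for identical series", {
  set.seed(12)
  cfg <- cohort_config(n_subjects = 8, n_items = 20)
  coh <- simulate_cohort(cfg, seed = 44)
  emp <- empirical_bias(coh$ratings, "y5")
  fake <- tibble::tibble(
    subject_id = emp$subject_id,
    self_eval_bias = emp$empirical_bias,
    self_efficacy_bias = emp$empirical_bias
  )
  res <- ppc_bias_vs_empirical(fake, coh$ratings, "self_efficacy")
  expect_equal(res$r, 1, tolerance = 1e-12)
  # correlation invariant to affine rescaling of the model axis
  fake2 <- dplyr::mutate(fake,
    self_efficacy_bias = 3 * self_efficacy_bias - 0.2)
  expect_equal(ppc_bias_vs_empirical(fake2, coh$ratings, "self_efficacy")$r,
    1, tolerance = 1e-12)
})

test_that("simulating from the generator reproduces its correlation table", {
  case <- shared_recovery()
  sub <- case$cohort
  fit <- case$fit
  tab <- ppc_correlation_table(fit, sub$ratings, sub$schedules,
    n_sim = 15, seed = 9)
  expect_equal(nrow(tab), 10)
  # observed values fall inside (or near) the simulated intervals
  inside <- tab$observed >= tab$sim_low - 0.05 &
    tab$observed <= tab$sim_high + 0.05
  expect_gte(mean(inside), 0.9)
})

test_that("PE residualization has the right algebra", {
  set.seed(31)
  bias <- rnorm(30)
  # exactly orthogonal covariate: adjusted equals input
  dpe <- rnorm(30)
  dpe <- stats::residuals(stats::lm(dpe ~ bias))
  expect_equal(residualize_on_pe(bias, dpe), bias, tolerance = 1e-10)
  # bias an exact multiple of delta_pe: adjusted collapses to the mean
  dpe2 <- rnorm(30)
  expect_equal(residualize_on_pe(2 * dpe2, dpe2),
    rep(mean(2 * dpe2), 30), tolerance = 1e-10)
  # matches the normal equations
  dpe3 <- rnorm(30)
  beta <- solve(
    t(cbind(1, dpe3)) %*% cbind(1, dpe3),
    t(cbind(1, dpe3)) %*% bias
  )
  ref <- bias - cbind(1, dpe3) %*% beta + mean(bias)
  expect_equal(residualize_on_pe(bias, dpe3), as.numeric(ref),
    tolerance = 1e-10)
  expect_warning(residualize_on_pe(bias, rep(1, 30)), "constant")
})

test_that("PCA conserves trace, preserves communalities, recovers structure", {
  set.seed(13)
  bias <- runif(300, -0.3, 0.5)
  q <- simulate_questionnaires(bias, r_bias = -0.29, seed = 3)
  prof <- pca_varimax(q)
  expect_equal(sum(prof$eigenvalues), 12, tolerance = 1e-8)
  # communalities preserved by rotation
  R <- stats::cor(as.matrix(dplyr::select(q, -subject_id)))
  e <- eigen(R, symmetric = TRUE)
  L <- e$vectors[, seq_len(prof$retained)] %*%
    diag(sqrt(e$values[seq_len(prof$retained)]))
  expect_equal(unname(rowSums(prof$loadings^2)), rowSums(L^2),
    tolerance = 1e-8)
  # scores have zero mean; regression method reproduces R^-1 L weights
  expect_true(all(abs(colMeans(as.matrix(
    dplyr::select(prof$scores, -subject_id)))) < 1e-10))
})

test_that("the Kaiser rule retains exactly the eigenvalues above one", {
  expect_equal(kaiser_retained(c(6.86, 1.76, 1.08, 0.64, 0.4)), 3)
  expect_equal(kaiser_retained(c(0.9, 0.95)), 0)
  expect_equal(kaiser_retained(c(1 + 1e-9, 1)), 1)
})

test_that("independent scales give near-unit eigenvalues (boundary case)", {
  set.seed(21)
  q <- dplyr::bind_cols(
    tibble::tibble(subject_id = 1:10000),
    tibble::as_tibble(matrix(rnorm(120000), 10000,
      dimnames = list(NULL, paste0("s", 1:12))))
  )
  R <- stats::cor(as.matrix(dplyr::select(q, -subject_id)))
  ev <- eigen(R, only.values = TRUE)$values
  expect_lt(max(ev), 1.15)
  expect_gt(min(ev), 0.85)
})

test_that("component-bias correlations have Fisher intervals and BH control", {
  set.seed(3)
  bias <- runif(200, -0.3, 0.5)
  q <- simulate_questionnaires(bias, r_bias = -0.5, seed = 6)
  prof <- pca_varimax(q)
  b <- tibble::tibble(
    subject_id = prof$scores$subject_id,
    self_eval_bias = rnorm(200),
    self_efficacy_bias = bias
  )
  dpe <- tibble::tibble(subject_id = b$subject_id, delta_pe = rnorm(200))
  tab <- correlate_components_with_bias(prof, b, dpe)
  expect_equal(nrow(tab), 2 * prof$retained)
  # Fisher-z interval oracle
  for (i in seq_len(nrow(tab))) {
    z <- atanh(tab$r[i])
    ref <- tanh(z + c(-1, 1) * stats::qnorm(0.975) / sqrt(tab$n[i] - 3))
    expect_equal(c(tab$conf.low[i], tab$conf.high[i]), ref,
      tolerance = 1e-6)
  }
  expect_true(all(tab$p.adjusted >= tab$p.value - 1e-12))
  # a component equal to the bias itself gives r = 1
  prof2 <- prof
  prof2$scores$PC1 <- b$self_efficacy_bias
  tab2 <- correlate_components_with_bias(prof2, b, delta_pe = NULL)
  expect_equal(tab2$r[tab2$component == "PC1" &
    tab2$bias_type == "self_efficacy_bias"], 1, tolerance = 1e-12)
})

test_that("mediation recovers planted paths with exact OLS algebra", {
  set.seed(17)
  n <- 500
  x <- rnorm(n)
  m <- 0.5 * x + rnorm(n, 0, 0.8)
  y <- 0.6 * m + 0.2 * x + rnorm(n, 0, 0.8)
  res <- mediation_bootstrap(x, m, y, n_boot = 500, seed = 2)
  expect_lt(abs(res$indirect - 0.3), 0.1)
  expect_equal(res$c, res$c_prime + res$indirect, tolerance = 1e-8)
  expect_true(res$significant)

  # null b path: CI covers zero
  y0 <- 0.3 * x + rnorm(n)
  res0 <- mediation_bootstrap(x, m, y0, n_boot = 500, seed = 3)
  expect_true(res0$ci_low <= 0 && res0$ci_high >= 0)
})

test_that("mediation interval width shrinks like one over root n", {
  widths <- vapply(c(50, 200, 800), function(n) {
    set.seed(n)
    x <- rnorm(n)
    m <- 0.5 * x + rnorm(n, 0, 0.8)
    y <- 0.6 * m + 0.2 * x + rnorm(n, 0, 0.8)
    res <- mediation_bootstrap(x, m, y, n_boot = 400, seed = 1)
    res$ci_high - res$ci_low
  }, 0)
  expect_true(all(diff(widths) < 0))
  ratios <- widths[-3] / widths[-1] # each step quadruples n: expect ~2
  expect_true(all(ratios > 1.3 & ratios < 3.1))
})
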