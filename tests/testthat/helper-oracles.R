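# Independent oracles and small fixtures used across test files.

# Brute-force shortest interval containing >= level of the draws:
# O(n^2) search over all candidate (low, high) pairs of sorted draws.
hdi_oracle <- function(x, level = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  need <- ceiling(level * n)
  best <- c(xs[1], xs[n])
  best_w <- xs[n] - xs[1]
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 >= need && xs[j] - xs[i] < best_w) {
        best <- c(xs[i], xs[j])
        best_w <- xs[j] - xs[i]
      }
    }
  }
  best
}

# Manual schedule with arbitrary condition labels (for ordering tests etc.)
toy_schedule <- function(conditions, scores = NULL) {
  n <- length(conditions)
  tibble::tibble(
    item_id = seq_len(n),
    expected = rep(5, n),
    score = scores %||% ifelse(conditions == "positive", 8L, 5L),
    condition = conditions,
    pe = (scores %||% ifelse(conditions == "positive", 8L, 5L)) - 5
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Audit the greedy feedback assignment against its own recorded inventory:
# at every step, if an in-band (and null-cap-admissible) score was available
# in the remaining inventory, the chosen score must be in band; otherwise
# the choice must minimize the excess beyond the band, preferring the
# positive direction on ties.
audit_schedule_trace <- function(schedule) {
  trace <- attr(schedule, "trace")
  if (is.null(trace)) stop("schedule has no trace")
  for (st in trace) {
    pe_pool <- st$pool - st$expected_rounded
    admissible <- pe_pool >= -2 & pe_pool <= 4
    if (st$n_null_before >= 4) admissible <- admissible & pe_pool != 0
    chosen_pe <- st$chosen - st$expected_rounded
    if (any(admissible)) {
      if (!(chosen_pe >= -2 && chosen_pe <= 4)) {
        return(FALSE)
      }
      if (st$n_null_before >= 4 && chosen_pe == 0) {
        return(FALSE)
      }
    } else {
      excess <- pmax(0, -2 - pe_pool, pe_pool - 4)
      cand <- seq_along(st$pool)
      if (st$n_null_before >= 4) cand <- cand[pe_pool[cand] != 0]
      min_ex <- min(excess[cand])
      chosen_ex <- max(0, -2 - chosen_pe, chosen_pe - 4)
      if (chosen_ex > min_ex) {
        return(FALSE)
      }
      best <- cand[excess[cand] == min_ex]
      if (length(unique(sign(pe_pool[best]))) > 1 && chosen_pe < 0) {
        return(FALSE) # positive-direction tie-break violated
      }
    }
  }
  TRUE
}

# One-subject generating parameters as a tibble row, without jitter.
fixed_subject_params <- function(omega_pos, omega_neu,
                                 tau = c(1.3, 1.4, 0.9, 1.05, 1.3),
                                 mu = c(y1 = 5.3, y2 = 5.0, y4 = 5.6,
                                   y5 = 5.9)) {
  b34 <- omega_pos[3, 4] - omega_neu[3, 4]
  b35 <- omega_pos[3, 5] - omega_neu[3, 5]
  tibble::tibble(
    subject_id = 1L,
    mu = list(mu),
    tau_pos = list(tau), tau_neu = list(tau),
    omega_pos = list(omega_pos), omega_neu = list(omega_neu),
    true_self_eval_bias = b34,
    true_self_efficacy_bias = b35
  )
}

omega_with <- function(base = default_omega_base(), ...) {
  cells <- list(...)
  for (nm in names(cells)) {
    ij <- as.integer(strsplit(nm, "_")[[1]])
    base[ij[1], ij[2]] <- base[ij[2], ij[1]] <- cells[[nm]]
  }
  base
}

# All 720 permutations of 1:6 (row per permutation).
gtools_permutations_6 <- function() {
  rec <- function(v) {
    if (length(v) == 1) {
      return(matrix(v, 1, 1))
    }
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], rec(v[-i]))
    }))
  }
  rec(1:6)
}

# Direct multivariate-normal log density (reference path, via chol)
dmvnorm_log <- function(y, mu, sigma) {
  L <- chol(sigma)
  w <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(w^2))
}

# Reconstruct one draw's Sigma for a subject/condition from a fit object.
fit_draw_sigma <- function(fit, draw, subject_index, condition) {
  key_om <- paste0("omega_", condition)
  key_tau <- paste0("tau_", condition)
  pairs <- utils::combn(5, 2)
  om <- diag(5)
  v <- fit$draws[[key_om]][draw, subject_index, ]
  for (u in 1:10) {
    om[pairs[1, u], pairs[2, u]] <- om[pairs[2, u], pairs[1, u]] <- v[u]
  }
  tau <- fit$draws[[key_tau]][draw, subject_index, ]
  diag(tau) %*% om %*% diag(tau)
}

fit_draw_mu <- function(fit, draw, subject_index, label_index) {
  mu <- fit$draws$mu[draw, subject_index, ]
  c(mu[1], mu[2], fit$mu3[label_index], mu[3], mu[4])
}

# Cohort used by several expensive tests (built once per test run).
shared_cache <- new.env(parent = emptyenv())

shared_recovery <- function() {
  if (is.null(shared_cache$recovery)) {
    cfg <- cohort_config(
      n_subjects = 50, n_items = 40,
      self_efficacy_bias = seq(-0.3, 0.5, length.out = 50)
    )
    coh <- simulate_cohort(cfg, seed = 1)
    fit <- fit_update_bias(coh$ratings, "valence",
      mcmc = mcmc_profile("ci"), seed = 1, check = "none"
    )
    shared_cache$recovery <- list(cohort = coh, fit = fit)
  }
  shared_cache$recovery
}
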