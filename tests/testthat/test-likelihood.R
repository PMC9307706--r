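# Wiener first-passage density, variability integration and the mixture
# log-likelihood, checked against independent oracles.

test_that("choice probability: symmetry, dominant drift, simulator", {
  expect_identical(choice_probability(0, 2, 0.5), 0.5)
  expect_equal(choice_probability(0, 1.3, 0.3), 0.3)
  expect_lt(abs(choice_probability(10, 2, 0.5) - 1), 1e-6)

  set.seed(401)
  n <- 1e5
  sim <- simulate_trials(n, ddm_parameters(2.57, 1.78, 0), dt = 1e-4)
  phat <- mean(sim$upper, na.rm = TRUE)
  p <- choice_probability(2.57, 1.78, 0.5)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(phat - p), 2 * se + 5e-4)  # small allowance for Euler bias
})

test_that("density vanishes at nonpositive decision times", {
  expect_identical(wfpt_density(-0.1, "upper", 1, 2, 0.5), 0)
  expect_identical(wfpt_density(0, "lower", 1, 2, 0.5), 0)
})

test_that("density normalizes over boundaries and times", {
  grid <- list(c(2.57, 1.78, 0.5), c(0, 1, 0.3), c(1.78, 2.2, 0.5),
               c(-1, 0.8, 0.6))
  tt <- seq(1e-4, 30, length.out = 60000)
  dt <- tt[2] - tt[1]
  for (g in grid) {
    tot <- sum(wfpt_density(tt, "upper", g[1], g[2], g[3]) +
                 wfpt_density(tt, "lower", g[1], g[2], g[3])) * dt
    expect_lt(abs(tot - 1), 1e-3)
    # boundary split agrees with the closed-form absorption probability
    up <- sum(wfpt_density(tt, "upper", g[1], g[2], g[3])) * dt
    expect_lt(abs(up - choice_probability(g[1], g[2], g[3])), 1e-3)
  }
})

test_that("density matches a brute-force large-time series", {
  # independent oracle: the large-time representation truncated at 1000
  # terms, coded directly from the series formula
  oracle <- function(t, v, a, z) {
    k <- 1:1000
    (pi / a^2) * exp(-v * a * z - v^2 * t / 2) *
      sum(k * exp(-k^2 * pi^2 * t / (2 * a^2)) * sin(k * pi * z))
  }
  for (t0 in c(0.5, 1.0, 2.0)) {
    expect_lt(abs(wfpt_density(t0, "lower", 1, 2, 0.5) -
                    oracle(t0, 1, 2, 0.5)), 1e-6)
  }
  expect_lt(abs(wfpt_density(0.8, "lower", 2.57, 1.78, 0.4) -
                  oracle(0.8, 2.57, 1.78, 0.4)), 1e-6)
})

test_that("reflection symmetry holds to series tolerance", {
  tt <- c(0.2, 0.5, 1, 2, 4)
  for (g in list(c(1, 2, 0.4), c(2.57, 1.78, 0.5), c(-0.5, 1.2, 0.7))) {
    expect_equal(wfpt_density(tt, "lower", g[1], g[2], g[3]),
                 wfpt_density(tt, "upper", -g[1], g[2], 1 - g[3]),
                 tolerance = 1e-10)
  }
})

test_that("full density reduces to the shifted kernel without variability", {
  p <- ddm_parameters(2.57, 1.78, 0.3)
  rt <- seq(0.35, 3, by = 0.05)
  expect_equal(full_density(rt, "upper", p),
               wfpt_density(rt - 0.3, "upper", 2.57, 1.78, 0.5),
               tolerance = 1e-12)
  # no decision time available below ter - st/2
  p2 <- ddm_parameters(2, 1.5, 0.4, st = 0.2)
  expect_identical(full_density(0.29, "upper", p2), 0)
  expect_identical(full_density(-1, "upper", p2), 0)
})

test_that("drift-variability integration matches Monte Carlo", {
  set.seed(402)
  vs <- rnorm(1e5, 2, 0.5)
  mc <- mean(vapply(vs, function(v)
    wfpt_density(0.7, "upper", v, 1.5, 0.5), numeric(1)))
  an <- full_density(1.0, "upper", ddm_parameters(2, 1.5, 0.3, sv = 0.5))
  expect_lt(abs(mc - an), 1e-3)
})

test_that("simulator and integrated density agree in distribution", {
  # joint Kolmogorov-Smirnov distance on signed response times (errors
  # negative) at the default generating values for (set size 3, soft)
  set.seed(403)
  p <- ddm_parameters(2.57, 1.78, 0.58, z = 0.5, sv = 0.6, st = 0.1,
                      sz = 0.1)
  sim <- simulate_trials(1e5, p, dt = 1e-4)
  x <- ifelse(sim$upper, sim$rt, -sim$rt)
  x <- sort(x[!is.na(x)])

  tt <- seq(1e-3, 5, length.out = 5000)
  dtt <- tt[2] - tt[1]
  Fu <- cumsum(full_density(tt, "upper", p)) * dtt
  Fl <- cumsum(full_density(tt, "lower", p)) * dtt
  Fsigned <- function(q) {
    vapply(q, function(qq) {
      if (qq < 0) {
        i <- findInterval(-qq, tt)
        Fl[length(Fl)] - (if (i >= 1) Fl[i] else 0)
      } else {
        i <- findInterval(qq, tt)
        Fl[length(Fl)] + (if (i >= 1) Fu[i] else 0)
      }
    }, numeric(1))
  }
  n <- length(x)
  ks <- max(abs(Fsigned(x) - (seq_len(n) - 0.5) / n))
  expect_lt(ks, 0.01)
})

test_that("trial log-likelihood mixes the contaminant density", {
  p <- ddm_parameters(2.57, 1.78, 0.58, sv = 0.6, st = 0.1, sz = 0.1)
  trial <- list(rt = 0.9, correct = TRUE)
  f <- full_density(0.9, "upper", p)
  expect_equal(trial_loglik(trial, p, p_outlier = 0), log(f))
  expect_equal(trial_loglik(trial, p, p_outlier = 1,
                            config = likelihood_config(rt_ceiling = 5)),
               log(0.1))
  expect_equal(trial_loglik(trial, p, p_outlier = 0.05),
               log(0.95 * f + 0.05 * 0.1))
  expect_error(trial_loglik(list(rt = NA_real_, correct = TRUE), p),
               "no response time")
})

test_that("dataset log-likelihood is additive over trials", {
  set.seed(404)
  p <- ddm_parameters(2.2, 1.8, 0.5, sv = 0.6, st = 0.1, sz = 0.1)
  cells <- condition_cells()
  sim <- simulate_trials(10, p, dt = 1e-3)
  toy <- data.frame(set_size = rep(cells$set_size, length.out = 10),
                    spring = rep(cells$spring, length.out = 10),
                    rt = sim$rt, correct = sim$upper)
  cp <- setNames(rep(list(p), 4), paste(cells$set_size, cells$spring,
                                        sep = "."))
  total <- dataset_loglik(toy, cp)
  per_trial <- vapply(seq_len(10), function(i)
    trial_loglik(list(rt = toy$rt[i], correct = toy$correct[i]), p),
    numeric(1))
  expect_equal(total, sum(per_trial), tolerance = 1e-10)

  expect_identical(dataset_loglik(toy[0, ], cp), 0)
  expect_equal(dataset_loglik(toy[1:4, ], cp) + dataset_loglik(toy[5:10, ], cp),
               total, tolerance = 1e-10)
  expect_error(dataset_loglik(transform(toy, spring = "hard"), cp),
               "no parameters supplied")
})
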