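# Priors, the sampler machinery against conjugate closed forms, fit
# bookkeeping, diagnostics and posterior summaries.

test_that("default priors are proper and respect parameter support", {
  pr <- default_priors()
  # quadrature over each univariate prior density
  int1 <- function(f, lo, hi) {
    x <- seq(lo, hi, length.out = 20000)
    sum(f(x)) * (x[2] - x[1])
  }
  tn <- function(m, s, lower) function(x)
    exp(hbddm:::log_truncnormal(x, m, s, lower))
  hn <- function(scale) function(x) exp(hbddm:::log_halfnormal(x, scale))
  expect_lt(abs(int1(tn(2, 3, -Inf), -25, 25) - 1), 1e-3)
  expect_lt(abs(int1(tn(1.5, 1, 0), 0, 15) - 1), 1e-3)
  expect_lt(abs(int1(tn(0.4, 0.3, 0), 0, 5) - 1), 1e-3)
  expect_lt(abs(int1(hn(1), 0, 15) - 1), 1e-3)
  expect_lt(abs(int1(hn(0.2), 0, 4) - 1), 1e-3)
  expect_lt(abs(int1(hn(2), 0, 30) - 1), 1e-3)
  expect_lt(abs(int1(function(x) dbeta(x, 5, 5), 0, 1) - 1), 1e-3)
  # support: half-normals assign no mass below zero, truncation holds
  expect_identical(hn(1)(-0.5), 0)
  expect_identical(tn(1.5, 1, 0)(-0.1), 0)
})

test_that("prior-predictive response times are mostly plausible", {
  set.seed(701)
  n_draw <- 100
  ok <- logical(n_draw)
  for (i in seq_len(n_draw)) {
    v <- rnorm(1, 2, 3)
    a <- hbddm:::rtruncnorm1(1.5, 1, 0)
    ter <- hbddm:::rtruncnorm1(0.4, 0.3, 0)
    p <- tryCatch(ddm_parameters(v, max(a, 0.05), ter), error = function(e)
      NULL)
    if (is.null(p)) next
    sim <- simulate_trials(100, p, dt = 1e-3)
    med <- median(sim$rt, na.rm = TRUE)
    ok[i] <- is.finite(med) && med >= 0.2 && med <= 5
  }
  expect_gte(mean(ok), 0.5)
})

test_that("the Metropolis engine reproduces a conjugate normal posterior", {
  # y_i ~ N(theta, s^2) with known s, theta ~ N(m0, s0^2): closed form
  set.seed(702)
  y <- rnorm(40, 1.3, 0.8)
  s <- 0.8; m0 <- 0; s0 <- 2
  prec <- 1 / s0^2 + length(y) / s^2
  post_mean <- (m0 / s0^2 + sum(y) / s^2) / prec
  post_sd <- 1 / sqrt(prec)
  lt <- function(th) sum(dnorm(y, th, s, log = TRUE)) +
    dnorm(th, m0, s0, log = TRUE)
  draws <- hbddm:::amh_chain(lt, init = 0, n_iter = 22000, burn_in = 2000)
  ess <- hbddm:::ess_chain(draws)
  mc_se <- post_sd / sqrt(ess)
  expect_lt(abs(mean(draws) - post_mean), 3 * mc_se)
  expect_lt(abs(sd(draws) - post_sd), 0.05 * post_sd + 3 * mc_se)
})

test_that("the group-mean Gibbs draw matches the conjugate closed form", {
  set.seed(703)
  # repeated draws of the truncated-normal full conditional
  m <- 1.2; sd0 <- 0.4; lower <- 0
  draws <- replicate(20000, hbddm:::rtruncnorm1(m, sd0, lower))
  expect_gte(min(draws), lower)
  alpha <- (lower - m) / sd0
  tmean <- m + sd0 * dnorm(alpha) / pnorm(alpha, lower.tail = FALSE)
  expect_lt(abs(mean(draws) - tmean), 0.01)
  # untruncated case is plain normal
  d2 <- replicate(20000, hbddm:::rtruncnorm1(2, 0.5, -Inf))
  expect_lt(abs(mean(d2) - 2), 0.02)
  expect_lt(abs(sd(d2) - 0.5), 0.02)
})

test_that("fit bookkeeping: draw counts, node labels, determinism", {
  tf <- tiny_fit()
  f <- tf$fit
  expect_identical(nrow(f$draws), (250L - 100L) * 2L)
  # every node of the model's parameter_nodes appears in the draw matrix
  expect_true(all(parameter_nodes(f$spec)$node %in% colnames(f$draws)))
  expect_true(all(is.finite(f$deviance)))
  expect_identical(length(f$deviance), nrow(f$draws))

  f2 <- fit(tf$trials, build_model_space()[[4L]],
            mcmc = mcmc_config(iterations = 250L, burn_in = 100L,
                               chains = 2L, seed = 902L),
            likelihood = test_likelihood)
  expect_identical(f$draws, f2$draws)
  expect_identical(f$deviance, f2$deviance)
})

test_that("split R-hat and ESS behave on constructed chains", {
  set.seed(704)
  # constant draws: exact agreement
  cfit <- fake_fit(matrix(2.57, 4000, 1, dimnames = list(NULL, "v_ss3")))
  d <- diagnostics(cfit, "v_ss3")
  expect_identical(d$summary$rhat, 1.0)

  # iid standard normal: near-perfect mixing, ESS near nominal
  ifit <- fake_fit(matrix(rnorm(4000), 4000, 1,
                          dimnames = list(NULL, "v_ss3")))
  di <- diagnostics(ifit, "v_ss3")
  expect_lt(di$summary$rhat, 1.02)
  expect_gt(di$summary$ess, 0.8 * 4000)
  expect_lt(di$summary$ess, 1.2 * 4000)

  # chains offset by five SDs: diagnostic must flag them
  off <- c(rnorm(2000), rnorm(2000, 5))
  ofit <- fake_fit(matrix(off, 4000, 1, dimnames = list(NULL, "v_ss3")))
  do <- diagnostics(ofit, "v_ss3")
  expect_gt(do$summary$rhat, 1.5)

  # single chain: R-hat unavailable, not fabricated
  sfit <- fake_fit(matrix(rnorm(1000), 1000, 1,
                          dimnames = list(NULL, "v_ss3")),
                   chain = rep(1L, 1000))
  expect_true(is.na(diagnostics(sfit, "v_ss3")$summary$rhat))
})

test_that("posterior summaries report means and central intervals", {
  const <- fake_fit(matrix(2.57, 100, 1, dimnames = list(NULL, "v_ss3")))
  s <- summarize_fit(const)
  expect_equal(s$mean, 2.57)
  expect_equal(s$q97.5 - s$q2.5, 0)

  set.seed(705)
  norm <- fake_fit(matrix(rnorm(1e6), 1e6, 1,
                          dimnames = list(NULL, "v_ss3")))
  sn <- summarize_fit(norm)
  expect_lt(abs(sn$q2.5 - qnorm(0.025)), 0.01)
  expect_lt(abs(sn$q97.5 - qnorm(0.975)), 0.01)

  # completeness over a real fit: one row per node
  f <- tiny_fit()$fit
  sf <- summarize_fit(f, nodes = f$node_info$node)
  expect_identical(nrow(sf), nrow(parameter_nodes(f$spec)))
})

test_that("posterior predictive quantiles cover self-generated data", {
  tf <- tiny_fit()
  ppq <- posterior_predictive(tf$fit, tf$trials, n_rep = 30L, seed = 706L)
  expect_true(all(c("subject", "prob", "observed", "lo", "hi", "inside")
                  %in% names(ppq)))
  # envelopes are reproducible under a fixed seed
  ppq2 <- posterior_predictive(tf$fit, tf$trials, n_rep = 30L, seed = 706L)
  expect_identical(ppq, ppq2)
  # data were generated by the same process the model assumes: most
  # observed quantiles fall inside the replicate envelope
  cc <- ppq[ppq$type == "correct" & !is.na(ppq$inside), ]
  expect_gte(mean(cc$inside), 0.9)
  # cells without error trials are flagged absent, not zero
  ee <- ppq[ppq$type == "error", ]
  expect_true(all(is.na(ee$observed[is.na(ee$observed)])))
  expect_error(posterior_predictive(tf$fit, tf$trials, n_rep = 0L),
               "n_rep")
})
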