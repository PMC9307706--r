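# Shared fixtures. Fits are expensive, so they are built once per test run
# and memoized in this environment; every consumer states the seed it wants.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Experimental trials (practice removed, no-response dropped) plus ground
# truth, at the reduced recovery-study scale used by the test suite:
# 8 subjects, 100 experimental trials per condition cell.
recovery_data <- function(seed, group = default_group_parameters(),
                          n_subjects = 8L, epc = 100L) {
  memo(sprintf("data_%d_%s_%d_%d", seed, substr(config_key(group), 1, 10),
               n_subjects, epc), {
    set.seed(seed)
    ds <- generate_dataset(group, build_model_space()[[4L]],
                           n_subjects = n_subjects,
                           config = design_config(
                             experimental_per_condition = epc))
    tr <- remove_practice(ds$trials)
    list(trials = tr[!is.na(tr$rt), ], truth = ds$truth)
  })
}

config_key <- function(group) {
  paste0(signif(sum(group$means$v) + sum(group$means$a), 10), "_",
         group$sv)
}

test_mcmc <- function(seed, iterations = 2000L, burn_in = 600L) {
  mcmc_config(iterations = iterations, burn_in = burn_in, chains = 2L,
              seed = seed)
}

# Recovery fits use 3-node quadrature: at the st/sz magnitudes of the
# generating process it matches the 5-node default to well within
# posterior uncertainty at a fraction of the cost.
test_likelihood <- likelihood_config(quadrature_points = 3L)

# Model-`model_id` fit to model-4-generated data for one seed.
recovery_fit <- function(seed, model_id = 4L) {
  memo(sprintf("fit%d_%d", model_id, seed), {
    d <- recovery_data(seed)
    offset <- c(`1` = 200L, `4` = 100L, `9` = 300L)[as.character(model_id)]
    fit(d$trials, build_model_space()[[model_id]],
        mcmc = test_mcmc(seed + offset), likelihood = test_likelihood)
  })
}

# Model-recovery fits: BPIC discrimination between the generating model
# and its spring-split extension needs the full 600-trial per-subject
# design (the penalty gap scales with how well the extra subject-level
# nodes are identified), so this study uses 10 subjects x 150 trials per
# cell with 3000-iteration chains.
ranking_fits <- function(seed = 1L) {
  memo(sprintf("ranking_%d", seed), {
    set.seed(seed)
    ds <- generate_dataset(default_group_parameters(),
                           build_model_space()[[4L]], n_subjects = 10L,
                           config = design_config())
    tr <- remove_practice(ds$trials)
    tr <- tr[!is.na(tr$rt), ]
    mc <- function(s, it, bi) mcmc_config(iterations = it, burn_in = bi,
                                          chains = 2L, seed = s)
    list(
      trials = tr,
      f4 = fit(tr, build_model_space()[[4L]], mcmc = mc(101L, 3000L, 1000L),
               likelihood = test_likelihood),
      f1 = fit(tr, build_model_space()[[1L]], mcmc = mc(201L, 3000L, 1000L),
               likelihood = test_likelihood),
      f9 = fit(tr, build_model_space()[[9L]], mcmc = mc(301L, 1500L, 500L),
               likelihood = test_likelihood)
    )
  })
}

# Full-model fit to data generated with no spring effect on any parameter.
null_spring_fit <- function(seed = 61L) {
  memo(sprintf("fitnull_%d", seed), {
    d <- recovery_data(seed, group = null_spring_group_parameters())
    fit(d$trials, build_model_space()[[1L]], mcmc = test_mcmc(401L),
        likelihood = test_likelihood)
  })
}

# A fast throwaway fit for interface-level tests.
tiny_fit <- function() {
  memo("tiny", {
    d <- recovery_data(901L, n_subjects = 4L, epc = 24L)
    list(fit = fit(d$trials, build_model_space()[[4L]],
                   mcmc = mcmc_config(iterations = 250L, burn_in = 100L,
                                      chains = 2L, seed = 902L),
                   likelihood = test_likelihood),
         trials = d$trials, truth = d$truth)
  })
}

# Stand-in posterior object with known draws, for summary/overlap tests.
fake_fit <- function(draws, chain = rep(1:2, each = nrow(draws) / 2)) {
  spec <- build_model_space()[[4L]]
  list(draws = draws, chain = chain, spec = spec,
       node_info = parameter_nodes(spec))
}
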