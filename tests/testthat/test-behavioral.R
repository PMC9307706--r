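# Behavioral summaries, BIC-approximated Bayes factors and correlations.

cells_df <- function(values, subjects = sprintf("s%02d", seq_len(
  nrow(values) / 4))) {
  cells <- condition_cells()
  data.frame(subject = rep(subjects, each = 4L),
             set_size = rep(cells$set_size, length(subjects)),
             spring = rep(cells$spring, length(subjects)),
             accuracy = values$accuracy, mean_rt = values$mean_rt,
             stringsAsFactors = FALSE)
}

test_that("cell summaries compute accuracy and mean RT per cell", {
  tr <- data.frame(subject = "s01", block = 1L, trial_index = 1:4,
                   set_size = 3L, spring = "soft", match = TRUE,
                   response = "match",
                   correct = c(TRUE, TRUE, TRUE, FALSE),
                   rt = c(0.5, 0.6, 0.7, 0.8), is_practice = FALSE)
  cs <- suppressWarnings(cell_summary(tr))
  row <- cs[cs$set_size == 3 & cs$spring == "soft", ]
  expect_equal(row$accuracy, 0.75)
  expect_equal(row$mean_rt, 0.65)
  expect_identical(row$n_trials, 4L)
  # unobserved cells come back as NA rows with a warning
  expect_warning(cell_summary(tr), "empty cell")
  expect_true(all(is.na(cs$accuracy[cs$n_trials == 0])))

  tr$correct <- TRUE
  expect_equal(suppressWarnings(cell_summary(tr))$accuracy[
    cs$set_size == 3 & cs$spring == "soft"], 1.0)
})

test_that("cell summaries match a hand-computed table", {
  set.seed(810)
  cells <- condition_cells()
  tr <- do.call(rbind, lapply(1:4, function(cc) {
    data.frame(subject = "s01", block = 1L, trial_index = 1:5,
               set_size = cells$set_size[cc], spring = cells$spring[cc],
               match = TRUE, response = "match",
               correct = c(TRUE, TRUE, FALSE, TRUE, TRUE),
               rt = seq(0.4, 0.8, by = 0.1) + 0.01 * cc,
               is_practice = FALSE)
  }))
  cs <- cell_summary(tr)
  expect_equal(cs$accuracy, rep(0.8, 4))
  expect_equal(sort(cs$mean_rt), sort(0.6 + 0.01 * (1:4)))
})

test_that("Bayes factors detect strong effects and stay calibrated", {
  set.seed(811)
  n <- 24
  subj_int <- rnorm(n, 0.8, 0.1)
  # strong set-size effect: five group SDs
  eff <- 5 * 0.1
  vals <- data.frame(
    accuracy = rep(0.9, 4 * n),
    mean_rt = as.vector(vapply(seq_len(n), function(i) {
      base <- subj_int[i] + c(0, eff, 0, eff)  # set size 5 slower
      base + rnorm(4, 0, 0.05)
    }, numeric(4)))
  )
  d <- cells_df(vals)
  bf <- bf_model_comparison(d, "mean_rt")
  expect_gt(bf$table$bf[bf$table$model == "set_size"], 1e3)
  expect_gt(bf$inclusion[["set_size"]], 1e3)

  # null data: main-effect BFs favor the null in most replicates
  set.seed(812)
  hits <- replicate(100, {
    v0 <- data.frame(accuracy = rep(0.9, 4 * n),
                     mean_rt = rep(subj_int, each = 4) + rnorm(4 * n, 0, 0.05))
    b <- bf_model_comparison(cells_df(v0), "mean_rt")
    b$table$bf[b$table$model == "set_size"] < 1
  })
  expect_gt(mean(hits), 0.5)
})

test_that("Bayes factors are invariant to the RT unit", {
  set.seed(813)
  n <- 16
  vals <- data.frame(accuracy = rep(0.9, 4 * n),
                     mean_rt = rnorm(4 * n, 0.8, 0.2))
  d_s <- cells_df(vals)
  d_ms <- d_s
  d_ms$mean_rt <- d_ms$mean_rt * 1000
  bf_s <- bf_model_comparison(d_s, "mean_rt")
  bf_ms <- bf_model_comparison(d_ms, "mean_rt")
  expect_equal(bf_s$table$bf, bf_ms$table$bf, tolerance = 1e-8)
})

test_that("relative Bayes factors compose as ratios", {
  set.seed(814)
  n <- 12
  vals <- data.frame(accuracy = rep(0.9, 4 * n),
                     mean_rt = rnorm(4 * n, 0.8, 0.1))
  d <- cells_df(vals)
  bf <- bf_model_comparison(d, "mean_rt")$table
  bf_a <- bf$bf[bf$model == "both"]
  bf_b <- bf$bf[bf$model == "spring"]
  # BF(A vs null) / BF(B vs null) is BF(A vs B), recomputed from BIC
  dd <- d; dd$subject <- factor(dd$subject)
  bic_a <- BIC(lm(mean_rt ~ subject + spring + set_size, dd))
  bic_b <- BIC(lm(mean_rt ~ subject + spring, dd))
  expect_equal(bf_a / bf_b, exp((bic_b - bic_a) / 2), tolerance = 1e-8)

  expect_error(bf_model_comparison(d[-1, ], "mean_rt"), "unbalanced")
})

test_that("pearson_r handles exact and missing cases", {
  expect_equal(pearson_r(1:5, 1:5)$r, 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2))$r, -1.0)
  set.seed(815)
  x <- rnorm(10); y <- 0.5 * x + rnorm(10, 0, 0.3)
  x[3] <- NA
  pr <- pearson_r(x, y)
  expect_identical(pr$n_pairs, 9L)
  expect_equal(pr$r, cor(x[-3], y[-3]))
  expect_error(pearson_r(c(1, 2, NA), c(1, NA, 3)), "3 complete pairs")
})

test_that("correlation matrix is symmetric with unit diagonal", {
  set.seed(816)
  g <- default_group_parameters()
  spec <- build_model_space()[[4L]]
  subj <- sprintf("s%02d", 1:48)
  node_vals <- vapply(subj, function(s)
    draw_subject_params(g, spec)$node_values, numeric(10))
  pm <- data.frame(subject = subj, t(node_vals), stringsAsFactors = FALSE)
  truth <- list(subjects = setNames(
    lapply(subj, function(s) node_vals[, s]), subj))
  scores <- simulate_assessments(truth, noise_sd = 0.4)
  scores$sdmt_oral[1] <- NA  # missing values propagate, not crash
  m <- correlation_matrix(pm, scores)
  expect_equal(m, t(m), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(diag(m)), rep(1, ncol(m)))
  expect_match(attr(m, "caveat"), "caution")
  # assessments built as affine functions of true drift correlate strongly
  expect_gt(m["sdmt_oral", "v_ss3"], 0.5)
  expect_gt(m["sdmt_written", "v_ss5"], 0.5)
})

test_that("recovered subject drift tracks assessments built from truth", {
  tf <- tiny_fit()
  pm <- subject_parameter_means(tf$fit)
  set.seed(817)
  scores <- simulate_assessments(tf$truth, noise_sd = 0.2)
  m <- correlation_matrix(pm, scores)
  # only 4 subjects in the throwaway fit: direction, not magnitude
  expect_true(is.finite(m["sdmt_oral", "v_ss3"]))
  expect_identical(dim(m), c(13L, 13L))
})
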