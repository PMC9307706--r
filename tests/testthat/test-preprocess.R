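# Exclusion rules and the accounting report.

toy_trials <- function(subject, rt, correct = TRUE, set_size = 3L,
                       spring = "soft", is_practice = FALSE) {
  n <- max(lengths(list(rt, correct, set_size, spring)))
  data.frame(subject = subject, block = 1L, trial_index = seq_len(n),
             set_size = set_size, spring = spring, match = TRUE,
             response = "match", correct = correct, rt = rt,
             is_practice = is_practice, stringsAsFactors = FALSE)
}

test_that("practice removal keeps order and handles edge cases", {
  set.seed(601)
  g <- default_group_parameters()
  ds <- generate_dataset(g, n_subjects = 1L, config = design_config())
  out <- remove_practice(ds$trials)
  expect_identical(nrow(ds$trials), 648L)
  expect_identical(nrow(out), 600L)
  expect_false(any(out$is_practice))

  none <- toy_trials("s1", rt = c(0.5, 0.6))
  expect_identical(remove_practice(none), none)
  all_prac <- toy_trials("s1", rt = c(0.5, 0.6), is_practice = TRUE)
  expect_identical(nrow(remove_practice(all_prac)), 0L)
})

test_that("RT filtering applies the floor and the mean + 3 SD ceiling", {
  f1 <- filter_rts(toy_trials("s1", rt = c(0.1, 0.5, 0.55, 0.6)))
  expect_identical(f1$removed, 1L)
  expect_identical(f1$trials$rt, c(0.5, 0.55, 0.6))

  # 99 trials at 0.6 s and one at 5.0 s: the slow one exceeds mean + 3 SD
  rts <- c(rep(0.6, 99), 5.0)
  expect_gt(5.0, mean(rts) + 3 * sd(rts))  # oracle arithmetic
  f2 <- filter_rts(toy_trials("s2", rt = rts))
  expect_identical(f2$removed, 1L)
  expect_false(any(f2$trials$rt == 5.0))

  # compact spread: nothing removed
  set.seed(602)
  rts3 <- runif(50, 0.3, 0.8)
  f3 <- filter_rts(toy_trials("s3", rt = rts3))
  expect_identical(f3$removed, 0L)

  # thresholds are computed once, before any removal (single pass)
  again <- filter_rts(f2$trials)
  expect_lte(again$removed, 1L)
})

test_that("participant exclusions follow chance and group rules", {
  set.seed(603)
  mk_subj <- function(id, acc, rt_mean) {
    cells <- condition_cells()
    do.call(rbind, lapply(seq_len(4L), function(cc) {
      toy_trials(id, rt = rnorm(40, rt_mean, 0.05),
                 correct = runif(40) < acc[min(cc, length(acc))],
                 set_size = cells$set_size[cc], spring = cells$spring[cc])
    }))
  }
  base <- do.call(rbind, lapply(1:6, function(i)
    mk_subj(sprintf("s%02d", i), 0.95, 0.7)))

  chancey <- mk_subj("s99", c(0.40, 0.95, 0.95, 0.95), 0.7)
  e1 <- exclude_participants(rbind(base, chancey))
  expect_identical(e1$exclusions$reason[e1$exclusions$subject == "s99"],
                   "chance")

  # exactly 50% in one cell counts as at-or-below chance
  border <- mk_subj("s98", 0.95, 0.7)
  sel <- border$set_size == 3 & border$spring == "soft"
  border$correct[sel] <- rep(c(TRUE, FALSE), 20)
  e2 <- exclude_participants(rbind(base, border))
  expect_true("s98" %in% e2$exclusions$subject)

  slow <- mk_subj("s97", 0.95, 2.5)
  e3 <- exclude_participants(rbind(base, slow))
  expect_identical(e3$exclusions$reason[e3$exclusions$subject == "s97"],
                   "extreme_rt")

  # homogeneous cohort: nobody excluded
  e4 <- exclude_participants(base)
  expect_identical(nrow(e4$exclusions), 0L)

  expect_warning(exclude_participants(mk_subj("s1", 0.9, 0.7)),
                 "fewer than 3")
})

test_that("the pipeline reconciles its accounting", {
  set.seed(604)
  g <- default_group_parameters(p_outlier = 0)
  ds <- generate_dataset(g, n_subjects = 6L, config = design_config(
    experimental_per_condition = 50L))
  pp <- preprocess(ds$trials)
  r <- pp$report
  excluded_trials <- r$subject_trials_removed
  expect_identical(r$trials_out,
                   r$trials_in - r$practice_removed - excluded_trials -
                     r$rt_filtered)
  expect_identical(r$trials_out, nrow(pp$trials))
  # benign parameters, no contaminants: only the skewed diffusion tail is
  # trimmed, a small share of trials
  expect_lt(r$removed_fraction, 0.03)
  expect_gte(r$removed_fraction, 0)

  # deterministic given the data
  pp2 <- preprocess(ds$trials)
  expect_identical(pp$trials, pp2$trials)

  expect_error(preprocess(data.frame(subject = "s1")), "missing column")
})

test_that("removed fraction arithmetic matches the definition", {
  set.seed(605)
  tr <- toy_trials("s1", rt = c(rep(0.6, 596), rep(0.05, 4)))
  pp <- suppressWarnings(preprocess(tr))  # single subject: group rules skip
  expect_identical(pp$report$rt_filtered, 4L)
  expect_equal(pp$report$removed_fraction, 4 / 600, tolerance = 1e-12)

  empty <- toy_trials("s1", rt = 0.5)[0, ]
  ppe <- suppressWarnings(preprocess(empty))
  expect_identical(ppe$report$trials_in, 0L)
  expect_identical(ppe$report$trials_out, 0L)
  expect_identical(nrow(ppe$trials), 0L)
})
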