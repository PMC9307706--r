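# Behavioral condition summaries, approximate Bayes-factor model
# comparison, and convergent-validity correlations.

#' Per-subject condition-cell summaries
#'
#' Accuracy and mean response time per subject and condition cell.  The RT
#' mean is computed over all retained trials (correct and error) by
#' default.
#'
#' @param trials Preprocessed trial data frame.
#' @param correct_only Use correct trials only for the RT mean.
#' @return A data frame: `subject`, `set_size`, `spring`, `accuracy`,
#'   `mean_rt`, `n_trials`.  Empty cells yield a row of `NA`s with a
#'   warning.
#' @export
cell_summary <- function(trials, correct_only = FALSE) {
  cells <- condition_cells()
  subjects <- unique(trials$subject)
  rows <- list()
  for (s in subjects) {
    for (cc in seq_len(4L)) {
      sel <- trials$subject == s & trials$set_size == cells$set_size[cc] &
        trials$spring == cells$spring[cc]
      n <- sum(sel)
      if (n == 0L) {
        warning(sprintf("empty cell: subject %s, set size %d, %s", s,
                        cells$set_size[cc], cells$spring[cc]))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, set_size = cells$set_size[cc],
          spring = cells$spring[cc], accuracy = NA_real_,
          mean_rt = NA_real_, n_trials = 0L, stringsAsFactors = FALSE)
        next
      }
      rt <- trials$rt[sel]
      corr <- trials$correct[sel]
      if (correct_only) rt <- rt[corr %in% TRUE]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, set_size = cells$set_size[cc],
        spring = cells$spring[cc], accuracy = mean(corr, na.rm = TRUE),
        mean_rt = mean(rt, na.rm = TRUE), n_trials = n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Approximate Bayes factors for the 2x2 within-subject ANOVA models
#'
#' Compares the four candidate effect structures -- spring pressure only,
#' set size only, both main effects, both plus interaction -- against the
#' subject-only null on subject-by-cell means, using the BIC approximation
#' to the Bayes factor over repeated-measures linear models
#' (`BF = exp((BIC_null - BIC_model) / 2)`).  This approximates, rather
#' than replicates, default-Cauchy-prior ANOVA Bayes factors.  Inclusion
#' Bayes factors per effect compare the best model containing the effect
#' against its counterpart without it.
#'
#' @param cell_values Data frame from [cell_summary()] (or same shape).
#' @param dv `"accuracy"` or `"mean_rt"`.
#' @return A list with `table` (model, BF vs null) and `inclusion` (named
#'   BFs for `spring`, `set_size`, `interaction`).
#' @export
bf_model_comparison <- function(cell_values, dv = c("accuracy", "mean_rt")) {
  dv <- match.arg(dv)
  d <- cell_values[, c("subject", "set_size", "spring", dv)]
  names(d)[4] <- "y"
  if (anyNA(d$y)) {
    bad <- unique(d$subject[is.na(d$y)])
    stop("missing cells for subject(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(d$subject)
  if (any(counts != 4L))
    stop("unbalanced cells for subject(s): ",
         paste(names(counts)[counts != 4L], collapse = ", "), call. = FALSE)
  d$subject <- factor(d$subject)
  d$set_size <- factor(d$set_size)
  d$spring <- factor(d$spring)
  forms <- list(
    null = y ~ subject,
    spring = y ~ subject + spring,
    set_size = y ~ subject + set_size,
    both = y ~ subject + spring + set_size,
    interaction = y ~ subject + spring * set_size
  )
  bics <- vapply(forms, function(f) BIC(lm(f, data = d)), numeric(1))
  bf <- exp((bics[["null"]] - bics) / 2)
  inclusion <- c(
    spring = best_ratio(bf, with = c("spring", "both"),
                        drop = c("null", "set_size")),
    set_size = best_ratio(bf, with = c("set_size", "both"),
                          drop = c("null", "spring")),
    interaction = bf[["interaction"]] / bf[["both"]]
  )
  list(
    table = data.frame(model = names(forms)[-1], bf = unname(bf[-1]),
                       stringsAsFactors = FALSE),
    inclusion = inclusion
  )
}

# BF of the best model containing an effect over its counterpart without
# it; `with`/`drop` are aligned candidate pairs.
best_ratio <- function(bf, with, drop) {
  i <- which.max(bf[with])
  unname(bf[with][i] / bf[drop][i])
}

#' Pearson correlation with pairwise-complete handling
#'
#' @param x,y Numeric vectors of equal length; pairs with any missing value
#'   are dropped.  Fewer than 3 complete pairs is an error.
#' @return A list with `r` and `n_pairs`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  if (sum(ok) < 3L)
    stop("need at least 3 complete pairs", call. = FALSE)
  list(r = cor(x[ok], y[ok]), n_pairs = sum(ok))
}

#' Correlation matrix of assessments and subject parameter estimates
#'
#' Pearson correlations (pairwise-complete) over symbol-digit scores, peg-
#' test time and the subject-level posterior-mean DDM parameters, in the
#' layout assessments first, then drift, boundary and non-decision nodes.
#' Because the parameter estimates come from a hierarchical model, their
#' correlations are subject to shrinkage and should be interpreted with a
#' degree of caution (attached as the `"caveat"` attribute).
#'
#' @param param_means Data frame from [subject_parameter_means()].
#' @param scores Data frame with columns `subject`, `sdmt_oral`,
#'   `sdmt_written`, `nhpt_seconds`; missing scores propagate as missing.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(param_means, scores) {
  merged <- merge(scores, param_means, by = "subject", all = TRUE)
  vars <- c("sdmt_oral", "sdmt_written", "nhpt_seconds",
            setdiff(names(param_means), "subject"))
  m <- cor(as.matrix(merged[, vars]), use = "pairwise.complete.obs")
  attr(m, "caveat") <- paste(
    "Parameter estimates are derived from a hierarchical structure which",
    "may inaccurately estimate correlation strength; these values should",
    "be interpreted with a degree of caution.")
  m
}
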