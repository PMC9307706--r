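# Trial- and participant-level exclusion rules with a reconciled accounting
# report.

TRIAL_SCHEMA <- c("subject", "block", "trial_index", "set_size", "spring",
                  "match", "response", "correct", "rt", "is_practice")

check_trial_schema <- function(trials) {
  missing_cols <- setdiff(TRIAL_SCHEMA, names(trials))
  if (length(missing_cols) > 0L)
    stop("trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  invisible(trials)
}

#' Discard practice trials
#'
#' @param trials Trial data frame with an `is_practice` flag.
#' @return The experimental trials, order preserved.
#' @export
remove_practice <- function(trials) {
  out <- trials[!trials$is_practice, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Discard implausibly fast and slow response times
#'
#' Per participant, removes trials with `rt < 0.2` s and trials with `rt`
#' above the participant's mean plus three SDs.  Thresholds are computed
#' once, over all of that participant's retained experimental trials,
#' before any removal (single-pass semantics).  No-response trials (missing
#' `rt`) are also dropped and counted.  A participant with fewer than two
#' observed response times has no defined SD; only the 0.2 s floor applies.
#'
#' @param trials Experimental (practice-free) trial data frame.
#' @return A list with `trials` (the retained rows) and `removed` (count of
#'   dropped trials).
#' @export
filter_rts <- function(trials) {
  if (nrow(trials) == 0L) return(list(trials = trials, removed = 0L))
  keep <- rep(TRUE, nrow(trials))
  for (s in unique(trials$subject)) {
    idx <- which(trials$subject == s)
    rt <- trials$rt[idx]
    obs <- !is.na(rt)
    m <- mean(rt[obs])
    sdev <- if (sum(obs) >= 2L) sd(rt[obs]) else NA_real_
    ceiling_s <- if (is.na(sdev)) Inf else m + 3 * sdev
    keep[idx] <- obs & rt >= 0.2 & rt <= ceiling_s
  }
  out <- trials[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(trials = out, removed = sum(!keep))
}

#' Exclude participants by accuracy and overall response time
#'
#' Removes participants who performed at or below chance (accuracy <= 0.5,
#' the two-alternative chance level) in any single condition cell;
#' participants whose overall accuracy is at or below the group mean minus
#' two group SDs; and participants whose overall mean response time falls
#' outside the group mean plus or minus two group SDs.  Group statistics
#' are computed once over all participants before any exclusion.  With
#' fewer than three participants the group-level rules are skipped with a
#' warning.
#'
#' @param trials Experimental trial data frame.
#' @return A list with `trials` (rows of retained participants) and
#'   `exclusions` (data frame of `subject`, `reason` with reasons in
#'   `chance`, `low_accuracy`, `extreme_rt`).
#' @export
exclude_participants <- function(trials) {
  exclusions <- data.frame(subject = character(), reason = character(),
                           stringsAsFactors = FALSE)
  if (nrow(trials) == 0L) return(list(trials = trials, exclusions = exclusions))
  subjects <- unique(trials$subject)

  cell_acc <- aggregate(correct ~ subject + set_size + spring,
                        data = trials, FUN = mean, na.action = stats::na.omit)
  chance_subj <- unique(cell_acc$subject[cell_acc$correct <= 0.5])
  for (s in chance_subj) {
    exclusions <- rbind(exclusions,
                        data.frame(subject = s, reason = "chance"))
  }

  if (length(subjects) >= 3L) {
    overall_acc <- vapply(subjects, function(s)
      mean(trials$correct[trials$subject == s], na.rm = TRUE), numeric(1))
    overall_rt <- vapply(subjects, function(s)
      mean(trials$rt[trials$subject == s], na.rm = TRUE), numeric(1))
    acc_floor <- mean(overall_acc) - 2 * sd(overall_acc)
    rt_lo <- mean(overall_rt) - 2 * sd(overall_rt)
    rt_hi <- mean(overall_rt) + 2 * sd(overall_rt)
    for (i in seq_along(subjects)) {
      s <- subjects[i]
      if (overall_acc[i] <= acc_floor && !(s %in% exclusions$subject))
        exclusions <- rbind(exclusions,
                            data.frame(subject = s, reason = "low_accuracy"))
      if ((overall_rt[i] < rt_lo || overall_rt[i] > rt_hi) &&
          !(s %in% exclusions$subject))
        exclusions <- rbind(exclusions,
                            data.frame(subject = s, reason = "extreme_rt"))
    }
  } else {
    warning("fewer than 3 participants: group-level exclusion rules skipped")
  }
  out <- trials[!(trials$subject %in% exclusions$subject), , drop = FALSE]
  rownames(out) <- NULL
  list(trials = out, exclusions = exclusions)
}

#' Run the full preprocessing pipeline
#'
#' Applies, in order: practice removal, participant exclusions (chance-level
#' cells, low overall accuracy, extreme overall response times), then the
#' per-participant response-time trimming (0.2 s floor; mean + 3 SD
#' ceiling).  The report's counts always reconcile: `trials_out` equals
#' `trials_in` minus practice, minus excluded participants' experimental
#' trials, minus RT-filtered trials.
#'
#' @param trials Schema-valid trial data frame (see [generate_dataset()]).
#' @return A list with `trials` (clean data) and `report` (class
#'   `preprocess_report`): counts, `removed_fraction` (RT-filtered share of
#'   surviving experimental trials) and the exclusion table.
#' @export
preprocess <- function(trials) {
  check_trial_schema(trials)
  trials_in <- nrow(trials)
  expe <- remove_practice(trials)
  practice_removed <- trials_in - nrow(expe)
  excl <- exclude_participants(expe)
  subject_trials_removed <- nrow(expe) - nrow(excl$trials)
  filt <- filter_rts(excl$trials)
  report <- structure(
    list(trials_in = trials_in,
         practice_removed = practice_removed,
         excluded_subjects = excl$exclusions,
         subject_trials_removed = subject_trials_removed,
         rt_filtered = filt$removed,
         trials_out = nrow(filt$trials),
         removed_fraction = if (nrow(excl$trials) > 0L)
           filt$removed / nrow(excl$trials) else 0),
    class = "preprocess_report"
  )
  list(trials = filt$trials, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf(
    paste0("Preprocessing: %d trials in; %d practice removed; %d excluded-",
           "subject trials; %d RT-filtered (%.2f%%); %d retained\n"),
    x$trials_in, x$practice_removed, x$subject_trials_removed,
    x$rt_filtered, 100 * x$removed_fraction, x$trials_out))
  if (nrow(x$excluded_subjects) > 0L) {
    cat("Excluded participants:\n")
    print(x$excluded_subjects, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a preprocessing report as JSON
#'
#' @param report A `preprocess_report`.
#' @return A JSON string.
#' @export
report_to_json <- function(report) {
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, dataframe = "rows")
}
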