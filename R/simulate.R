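# Synthetic-data generator: experimental design scaffold and forward DDM
# simulation with hierarchical structure and uniform contaminants.

#' Configuration of the experimental design
#'
#' Defaults reproduce the string-comparison task structure: two
#' counterbalanced blocks (one per spring condition), 24 practice trials per
#' block, 150 experimental trials per condition cell (so 600 experimental
#' trials in total), a 5.0 s response window, a 0.5-3.0 s inter-trial
#' interval and 0.5 s feedback.
#'
#' @param n_blocks Number of blocks; must be 2 (one per spring condition).
#' @param practice_per_block Practice trials opening each block.
#' @param experimental_per_condition Experimental trials per condition cell.
#' @param response_window Response deadline, seconds.
#' @param iti_range Inter-trial-interval range, seconds (metadata only; the
#'   ITI does not enter the decision model).
#' @param feedback_duration Feedback display, seconds (metadata only).
#' @param counterbalance Alternate block order (soft-first / stiff-first)
#'   across subjects.
#' @return A list of class `design_config`.
#' @export
design_config <- function(n_blocks = 2L, practice_per_block = 24L,
                          experimental_per_condition = 150L,
                          response_window = 5.0, iti_range = c(0.5, 3.0),
                          feedback_duration = 0.5, counterbalance = TRUE) {
  stopifnot(n_blocks == 2L, practice_per_block > 0,
            practice_per_block %% 2L == 0L,
            experimental_per_condition > 0,
            experimental_per_condition %% 2L == 0L,
            response_window > 0, length(iti_range) == 2L,
            iti_range[1] <= iti_range[2])
  structure(
    list(n_blocks = 2L,
         practice_per_block = as.integer(practice_per_block),
         experimental_per_condition = as.integer(experimental_per_condition),
         response_window = response_window,
         iti_range = iti_range,
         feedback_duration = feedback_duration,
         counterbalance = isTRUE(counterbalance)),
    class = "design_config"
  )
}

#' Simulate trials by forward Euler-Maruyama diffusion
#'
#' Each trial draws its drift Normal(`v`, `sv`), start Uniform(`z` +/-
#' `sz/2`) and non-decision time Uniform(`ter` +/- `st/2`), then integrates
#' the diffusion path from `z * a` with time step `dt` until a boundary is
#' crossed or the response window (minus the drawn non-decision time) runs
#' out.  Uses R's global RNG, so `set.seed()` gives bit-identical output.
#'
#' @param n Number of trials.
#' @param params A [ddm_parameters()] object.
#' @param dt Integration step, seconds.
#' @param response_window Response deadline, seconds.
#' @return A data frame with columns `rt` (s; `NA` when no boundary was
#'   reached) and `upper` (logical boundary indicator; `NA` on no-response).
#' @export
simulate_trials <- function(n, params, dt = 1e-4, response_window = 5.0) {
  stopifnot(n >= 0, dt > 0, response_window > 0)
  validate_ddm_parameters(params)
  out <- .simulate_ddm_cpp(as.integer(n), params$v, params$a, params$ter,
                           params$z, params$sv, params$st, params$sz,
                           dt, response_window)
  data.frame(rt = out$rt, upper = out$upper)
}

#' @rdname simulate_trials
#' @return `simulate_trial()` returns a one-row data frame.
#' @export
simulate_trial <- function(params, dt = 1e-4, response_window = 5.0) {
  simulate_trials(1L, params, dt, response_window)
}

# Shuffle a segment's rows (practice or experimental) so set sizes are
# interleaved in randomized order.
shuffle_rows <- function(df) df[sample.int(nrow(df)), , drop = FALSE]

#' Generate the ordered trial scaffold for one subject
#'
#' Two blocks, one per spring condition.  Each block opens with the practice
#' trials (balanced across set sizes, match flag balanced within set size)
#' followed by the experimental trials: `experimental_per_condition` per set
#' size, half match / half no-match, in randomized interleaved order.
#'
#' @param config A [design_config()].
#' @param first_spring Spring condition of block 1 (`"soft"` or `"stiff"`).
#' @return A data frame with columns `block`, `trial_index`, `set_size`,
#'   `spring`, `match`, `is_practice`.
#' @export
generate_design <- function(config = design_config(),
                            first_spring = c("soft", "stiff")) {
  first_spring <- match.arg(first_spring)
  springs <- if (first_spring == "soft") c("soft", "stiff") else
    c("stiff", "soft")
  segment <- function(n_per_set, practice) {
    per_match <- n_per_set %/% 2L
    df <- expand.grid(set_size = SET_SIZES,
                      match = c(TRUE, FALSE), KEEP.OUT.ATTRS = FALSE)
    df <- df[rep(seq_len(nrow(df)), each = per_match), , drop = FALSE]
    df$is_practice <- practice
    shuffle_rows(df)
  }
  blocks <- lapply(1:2, function(b) {
    prac <- segment(config$practice_per_block %/% 2L, TRUE)
    expe <- segment(config$experimental_per_condition, FALSE)
    out <- rbind(prac, expe)
    out$block <- b
    out$spring <- springs[b]
    out$trial_index <- seq_len(nrow(out))
    out
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out[, c("block", "trial_index", "set_size", "spring", "match",
          "is_practice")]
}

#' Draw one subject's cell parameters from the group
#'
#' Subject-level `v`, `a` and `ter` are drawn Normal(group mean, between-SD)
#' per parameter node induced by the model specification (a node's group
#' mean is the average of the cell means it covers), redrawn until the
#' parameter-set invariants hold; group-only nuisance values are copied
#' verbatim.
#'
#' @param group A [group_parameters()] object.
#' @param spec A `ddm_model_spec` giving the node structure.
#' @return A list with `cell_params` (named list `"<set_size>.<spring>"` of
#'   [ddm_parameters()]) and `node_values` (named numeric of the drawn
#'   subject-level node values).
#' @export
draw_subject_params <- function(group, spec = build_model_space()[[1L]]) {
  stopifnot(inherits(group, "ddm_group_parameters"),
            inherits(spec, "ddm_model_spec"))
  cells <- condition_cells()
  gm <- group$means
  gm_key <- paste(gm$set_size, gm$spring)
  node_values <- c()
  cell_values <- list(v = numeric(4), a = numeric(4), ter = numeric(4))
  for (param in c("v", "a", "ter")) {
    node_of_cell <- cell_node_map(spec, param)
    for (node in unique(node_of_cell)) {
      in_node <- node_of_cell == node
      mu <- mean(gm[[param]][match(paste(cells$set_size, cells$spring)[in_node],
                                   gm_key)])
      val <- draw_truncated(param, mu, group$sds[[param]], group)
      node_values[node] <- val
      cell_values[[param]][in_node] <- val
    }
  }
  cp <- lapply(seq_len(4L), function(i) {
    ddm_parameters(v = cell_values$v[i], a = cell_values$a[i],
                   ter = cell_values$ter[i], z = group$z, sv = group$sv,
                   st = group$st, sz = group$sz)
  })
  names(cp) <- paste(cells$set_size, cells$spring, sep = ".")
  list(cell_params = cp, node_values = node_values)
}

# Normal draw redrawn until the parameter's support constraint holds
# (a > 0, ter >= st/2; drift unconstrained).  Falls back to the nearest
# admissible value if 100 redraws all land outside.
draw_truncated <- function(param, mu, sd, group) {
  lower <- switch(param, v = -Inf, a = 1e-6, ter = group$st / 2)
  if (sd == 0) return(max(mu, lower))
  for (i in 1:100) {
    val <- rnorm(1L, mu, sd)
    if (val >= lower) return(val)
  }
  lower
}

#' Generate a full synthetic dataset with ground truth
#'
#' For each subject a design scaffold is generated (block order alternating
#' across subjects when counterbalancing is on), subject parameters are
#' drawn from the group, and every trial is simulated from the subject's
#' cell parameters.  With probability `group$p_outlier` a trial becomes a
#' contaminant: its response time is replaced by a Uniform(0,
#' response window) draw and its response by a fair coin.  Contaminant flags
#' and the generating parameters are returned in a ground-truth ledger that
#' is never part of the trial table itself.
#'
#' @param group A [group_parameters()] object.
#' @param spec A `ddm_model_spec` describing the generating node structure.
#' @param n_subjects Number of subjects.
#' @param config A [design_config()].
#' @param dt Euler-Maruyama step for the simulator, seconds.
#' @return A list with `trials` (one row per trial: `subject`, `block`,
#'   `trial_index`, `set_size`, `spring`, `match`, `response`, `correct`,
#'   `rt`, `is_practice`) and `truth` (group parameters, model spec, per-
#'   subject node values, contaminant flags per trial row).
#' @export
generate_dataset <- function(group, spec = build_model_space()[[4L]],
                             n_subjects, config = design_config(),
                             dt = 1e-4) {
  stopifnot(n_subjects >= 1)
  subj_ids <- sprintf("s%02d", seq_len(n_subjects))
  all_trials <- vector("list", n_subjects)
  subj_truth <- vector("list", n_subjects)
  outlier_flags <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    first <- if (config$counterbalance && s %% 2L == 0L) "stiff" else "soft"
    design <- generate_design(config, first_spring = first)
    drawn <- draw_subject_params(group, spec)
    n <- nrow(design)
    rt <- rep(NA_real_, n)
    up <- rep(NA, n)
    key <- paste(design$set_size, design$spring, sep = ".")
    for (cell in unique(key)) {
      idx <- which(key == cell)
      sim <- simulate_trials(length(idx), drawn$cell_params[[cell]], dt,
                             config$response_window)
      rt[idx] <- sim$rt
      up[idx] <- sim$upper
    }
    is_out <- runif(n) < group$p_outlier
    n_out <- sum(is_out)
    if (n_out > 0L) {
      rt[is_out] <- runif(n_out, 0, config$response_window)
      up[is_out] <- runif(n_out) < 0.5
    }
    # accuracy coding: upper boundary is the correct response
    correct <- up
    response <- ifelse(is.na(correct), NA_character_,
                       ifelse(correct == design$match, "match", "no-match"))
    all_trials[[s]] <- data.frame(
      subject = subj_ids[s], design[, c("block", "trial_index", "set_size",
                                        "spring", "match")],
      response = response, correct = correct, rt = rt,
      is_practice = design$is_practice, stringsAsFactors = FALSE
    )
    subj_truth[[s]] <- drawn$node_values
    outlier_flags[[s]] <- is_out
  }
  trials <- do.call(rbind, all_trials)
  rownames(trials) <- NULL
  names(subj_truth) <- subj_ids
  list(
    trials = trials,
    truth = list(
      group = group, spec = spec, subjects = subj_truth,
      outliers = data.frame(subject = trials$subject,
                            block = trials$block,
                            trial_index = trials$trial_index,
                            is_outlier = unlist(outlier_flags))
    )
  )
}

#' Simulate assessment scores tied to the generating parameters
#'
#' Convenience generator for convergent-validity studies: symbol-digit
#' scores are affine in the subject's mean true drift rate and the peg-test
#' time is affine in the subject's mean true non-decision time, both plus
#' Gaussian noise.
#'
#' @param truth The `truth` element returned by [generate_dataset()].
#' @param noise_sd Residual SD on the standardized scale.
#' @return A data frame with columns `subject`, `sdmt_oral`,
#'   `sdmt_written`, `nhpt_seconds`.
#' @export
simulate_assessments <- function(truth, noise_sd = 0.5) {
  subj <- names(truth$subjects)
  vbar <- vapply(truth$subjects, function(x)
    mean(x[startsWith(names(x), "v")]), numeric(1))
  tbar <- vapply(truth$subjects, function(x)
    mean(x[startsWith(names(x), "ter")]), numeric(1))
  zv <- as.numeric(scale(vbar))
  zt <- as.numeric(scale(tbar))
  n <- length(subj)
  data.frame(
    subject = subj,
    sdmt_oral = round(pmax(55 + 8 * (zv + rnorm(n, 0, noise_sd)), 10)),
    sdmt_written = round(pmax(50 + 8 * (zv + rnorm(n, 0, noise_sd)), 10)),
    nhpt_seconds = pmax(18 + 2 * (zt + rnorm(n, 0, noise_sd)), 8),
    stringsAsFactors = FALSE
  )
}
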