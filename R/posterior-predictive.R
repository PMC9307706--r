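# Posterior-predictive response-time quantile checks.

PP_PROBS <- c(0.1, 0.3, 0.5, 0.7, 0.9)

pp_quantiles <- function(rt, correct) {
  q <- function(keep) {
    if (sum(keep, na.rm = TRUE) == 0L) rep(NA_real_, length(PP_PROBS))
    else quantile(rt[keep], probs = PP_PROBS, names = FALSE, na.rm = TRUE)
  }
  list(correct = q(correct %in% TRUE), error = q(correct %in% FALSE))
}

#' Posterior-predictive RT quantile check
#'
#' For each of `n_rep` retained posterior draws, simulates a replicate
#' dataset matching the observed design (same subjects, cells and trial
#' counts, the fitted contaminant mixture included) from that draw's
#' subject-level parameters, and computes the 10/30/50/70/90% RT quantiles
#' for correct and error responses per subject and condition.  Returns the
#' observed quantiles with the replicate [2.5, 97.5]% envelope.  Cells with
#' no error trials report `NA` quantiles (flagged absent, not zero).
#'
#' @param fit A `ddm_fit`.
#' @param trials The trial data the fit used.
#' @param n_rep Number of posterior replicates (>= 1).
#' @param seed Optional seed for the replicate simulation.
#' @param dt Euler step for replicate simulation, seconds.
#' @return A data frame with columns `subject`, `set_size`, `spring`,
#'   `type` (correct/error), `prob`, `observed`, `lo`, `hi`,
#'   `inside` (logical; `NA` where the observed quantile is absent).
#' @export
posterior_predictive <- function(fit, trials, n_rep = 50L, seed = NULL,
                                 dt = 1e-3) {
  if (n_rep < 1L) stop("n_rep must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  trials <- trials[!is.na(trials$rt), , drop = FALSE]
  cells <- condition_cells()
  subjects <- fit$subjects
  spec <- fit$spec
  vmap <- cell_node_map(spec, "v")
  amap <- cell_node_map(spec, "a")
  tmap <- cell_node_map(spec, "ter")
  draw_rows <- sample.int(nrow(fit$draws), n_rep, replace = n_rep >
                            nrow(fit$draws))

  obs <- list()
  reps <- list()
  for (s in subjects) {
    for (cc in seq_len(4L)) {
      sel <- trials$subject == s & trials$set_size == cells$set_size[cc] &
        trials$spring == cells$spring[cc]
      n_cell <- sum(sel)
      if (n_cell == 0L) next
      key <- paste(s, cc)
      obs[[key]] <- pp_quantiles(trials$rt[sel], trials$correct[sel])
      sim_c <- matrix(NA_real_, n_rep, length(PP_PROBS))
      sim_e <- matrix(NA_real_, n_rep, length(PP_PROBS))
      for (r in seq_len(n_rep)) {
        d <- fit$draws[draw_rows[r], ]
        pars <- ddm_parameters(
          v = d[[paste0(vmap[cc], ".", s)]],
          a = d[[paste0(amap[cc], ".", s)]],
          ter = d[[paste0(tmap[cc], ".", s)]],
          z = d[["z"]], sv = d[["sv"]], st = d[["st"]], sz = d[["sz"]]
        )
        sim <- simulate_trials(n_cell, pars, dt = dt,
                               response_window = fit$likelihood$rt_ceiling)
        is_out <- runif(n_cell) < fit$p_outlier
        sim$rt[is_out] <- runif(sum(is_out), 0, fit$likelihood$rt_ceiling)
        sim$upper[is_out] <- runif(sum(is_out)) < 0.5
        qq <- pp_quantiles(sim$rt, sim$upper)
        sim_c[r, ] <- qq$correct
        sim_e[r, ] <- qq$error
      }
      env <- function(m) {
        q1 <- function(x, p) {
          x <- x[!is.na(x)]
          if (length(x) == 0L) NA_real_ else
            quantile(x, probs = p, names = FALSE)
        }
        list(lo = apply(m, 2L, q1, p = 0.025),
             hi = apply(m, 2L, q1, p = 0.975))
      }
      reps[[key]] <- list(correct = env(sim_c), error = env(sim_e))
    }
  }

  rows <- list()
  for (s in subjects) {
    for (cc in seq_len(4L)) {
      key <- paste(s, cc)
      if (is.null(obs[[key]])) next
      for (type in c("correct", "error")) {
        o <- obs[[key]][[type]]
        e <- reps[[key]][[type]]
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, set_size = cells$set_size[cc],
          spring = cells$spring[cc], type = type, prob = PP_PROBS,
          observed = o, lo = e$lo, hi = e$hi,
          inside = ifelse(is.na(o), NA, o >= e$lo & o <= e$hi),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
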