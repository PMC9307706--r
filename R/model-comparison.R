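# Deviance-based model scoring (DIC / BPIC) and the credible-interval
# independence check.

#' Deviance components of a fit
#'
#' `Dbar` is the mean of the per-draw total deviances recorded during
#' sampling; `D_at_mean` is the deviance evaluated at the posterior means of
#' all nodes; `pD = Dbar - D_at_mean` is the effective number of parameters
#' (the classic plug-in definition).  By default the plug-in evaluates the
#' likelihood at subject-level posterior means (hierarchical DIC focused on
#' the subject-level likelihood); `plugin = "group"` replaces every
#' subject's values by the group-mean nodes instead.
#'
#' @param fit A `ddm_fit`.
#' @param trials The trial data the fit used (fingerprint-checked).
#' @param plugin `"subject"` (default) or `"group"`.
#' @return A list with `Dbar`, `D_at_mean`, `pD`.
#' @export
deviance_components <- function(fit, trials,
                                plugin = c("subject", "group")) {
  plugin <- match.arg(plugin)
  pd <- prep_fit_data(trials, fit$spec)
  if (!identical(pd$fingerprint, fit$data_fingerprint))
    stop("trial data do not match the data this model was fitted to",
         call. = FALSE)
  means <- colMeans(fit$draws)
  lik <- fit$likelihood
  vb <- ab <- tb <- numeric(pd$S * 4L)
  for (b in seq_len(pd$S * 4L)) {
    s <- pd$block_subj[b]
    cc <- pd$block_cell[b]
    node_at <- function(map) {
      nd <- pd$node_labels[map[cc]]
      if (plugin == "subject") means[[paste0(nd, ".", pd$subjects[s])]]
      else means[[nd]]
    }
    vb[b] <- node_at(pd$cellmap$v)
    ab[b] <- node_at(pd$cellmap$a)
    tb[b] <- node_at(pd$cellmap$ter)
  }
  ll <- .loglik_blocks_cpp(pd$all_rt, pd$all_up, pd$starts, pd$lens,
                           vb, ab, tb, means[["z"]], means[["sv"]],
                           means[["st"]], means[["sz"]], fit$p_outlier,
                           lik$rt_ceiling, lik$quadrature_points,
                           lik$series_tolerance)
  Dbar <- mean(fit$deviance)
  D_at_mean <- -2 * sum(ll)
  list(Dbar = Dbar, D_at_mean = D_at_mean, pD = Dbar - D_at_mean)
}

#' DIC and BPIC for one fit
#'
#' `DIC = Dbar + pD`; `BPIC = Dbar + 2 pD` (the doubled complexity penalty,
#' more stringent than DIC).  Lower is better.
#'
#' @inheritParams deviance_components
#' @return A one-row data frame with `model_id`, `Dbar`, `pD`, `DIC`,
#'   `BPIC`.
#' @export
bpic <- function(fit, trials, plugin = c("subject", "group")) {
  dc <- deviance_components(fit, trials, plugin)
  data.frame(model_id = fit$spec$model_id, Dbar = dc$Dbar, pD = dc$pD,
             DIC = dc$Dbar + dc$pD, BPIC = dc$Dbar + 2 * dc$pD)
}

#' Rank a set of fitted models by BPIC
#'
#' @param fits A list of `ddm_fit` objects fitted to identical trial data.
#' @param trials The shared trial data.
#' @param plugin Plug-in level, see [deviance_components()].
#' @return A data frame sorted by BPIC with `delta_bpic` relative to the
#'   best (lowest-BPIC) model.
#' @export
rank_models <- function(fits, trials, plugin = c("subject", "group")) {
  plugin <- match.arg(plugin)
  fps <- lapply(fits, `[[`, "data_fingerprint")
  if (length(unique(fps)) != 1L)
    stop("fits were not all estimated on the same data", call. = FALSE)
  tab <- do.call(rbind, lapply(fits, bpic, trials = trials, plugin = plugin))
  tab <- tab[order(tab$BPIC), , drop = FALSE]
  tab$delta_bpic <- tab$BPIC - min(tab$BPIC)
  rownames(tab) <- NULL
  tab
}

#' Mutual credible-interval containment between node pairs
#'
#' For each pair of nodes, reports whether the 95% credible interval of
#' each member contains the posterior mean of the other (the converging
#' check used to adjudicate whether two condition posteriors differ).
#'
#' @param fit A `ddm_fit`.
#' @param node_pairs A list of length-2 character vectors of node labels.
#' @return A data frame per pair: nodes, means, intervals, `a_contains_b`,
#'   `b_contains_a`, `mutual`.
#' @export
ci_overlap <- function(fit, node_pairs) {
  if (is.character(node_pairs)) node_pairs <- list(node_pairs)
  rows <- lapply(node_pairs, function(pair) {
    stopifnot(length(pair) == 2L)
    missing_nodes <- setdiff(pair, colnames(fit$draws))
    if (length(missing_nodes) > 0L)
      stop("unknown node(s): ", paste(missing_nodes, collapse = ", "),
           call. = FALSE)
    da <- fit$draws[, pair[1]]
    db <- fit$draws[, pair[2]]
    ia <- quantile(da, c(0.025, 0.975), names = FALSE)
    ib <- quantile(db, c(0.025, 0.975), names = FALSE)
    ma <- mean(da); mb <- mean(db)
    a_in_b <- mb >= ia[1] && mb <= ia[2]
    b_in_a <- ma >= ib[1] && ma <= ib[2]
    data.frame(node_a = pair[1], node_b = pair[2], mean_a = ma, mean_b = mb,
               a_lo = ia[1], a_hi = ia[2], b_lo = ib[1], b_hi = ib[2],
               a_contains_b = a_in_b, b_contains_a = b_in_a,
               mutual = a_in_b && b_in_a, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Soft-vs-stiff drift node pairs of a fitted model, if its drift structure
# has them; NULL otherwise (e.g. when drift varies by set size only).
spring_drift_pairs <- function(spec) {
  if (!("SPC" %in% spec$v_factors)) return(NULL)
  if ("SS" %in% spec$v_factors) {
    lapply(SET_SIZES, function(ss)
      paste0("v_ss", ss, "_", c("soft", "stiff")))
  } else {
    list(c("v_soft", "v_stiff"))
  }
}
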