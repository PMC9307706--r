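# Convergence diagnostics: split R-hat and effective sample size.

split_chains <- function(v, chain) {
  out <- list()
  for (ch in unique(chain)) {
    x <- v[chain == ch]
    h <- length(x) %/% 2L
    out <- c(out, list(x[seq_len(h)], x[h + seq_len(h)]))
  }
  out
}

rhat_split <- function(v, chain) {
  segs <- split_chains(v, chain)
  n <- min(lengths(segs))
  if (n < 2L) return(NA_real_)
  segs <- lapply(segs, function(x) x[seq_len(n)])
  m <- length(segs)
  means <- vapply(segs, mean, numeric(1))
  vars <- vapply(segs, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1.0)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Geyer initial-monotone-sequence ESS, averaged over chains.
ess_chain <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(n)
  rho <- as.numeric(acf(x, lag.max = min(n - 1L, 500L),
                        plot = FALSE)$acf)[-1]
  # sum adjacent pairs while positive
  s <- 0
  k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(n / (1 + 2 * s), 1)
}

#' Convergence diagnostics for a fit
#'
#' Split R-hat (each chain halved; values near 1 indicate agreement within
#' and between chains) and effective sample size per node, plus trace
#' extracts for plotting.
#'
#' @param fit A `ddm_fit` (or any list with `draws` matrix and `chain`
#'   vector).
#' @param nodes Node labels to report; default all.
#' @return A list with `summary` (data frame: node, rhat, ess) and `traces`
#'   (named list of per-chain draw vectors).
#' @export
diagnostics <- function(fit, nodes = colnames(fit$draws)) {
  chain <- fit$chain
  two_plus <- length(unique(chain)) >= 2L
  res <- data.frame(
    node = nodes,
    rhat = vapply(nodes, function(nd) {
      if (!two_plus) return(NA_real_)
      rhat_split(fit$draws[, nd], chain)
    }, numeric(1)),
    ess = vapply(nodes, function(nd) {
      sum(vapply(unique(chain), function(ch)
        ess_chain(fit$draws[chain == ch, nd]), numeric(1)))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  traces <- lapply(nodes, function(nd)
    split(fit$draws[, nd], chain))
  names(traces) <- nodes
  list(summary = res, traces = traces)
}

#' Posterior summary table
#'
#' Posterior mean and central [2.5, 97.5] percentile interval per node,
#' with the condition layout (parameter by set size by spring) attached for
#' the group-level condition nodes.
#'
#' @param fit A `ddm_fit`.
#' @param nodes Node labels; default all columns of the draw matrix.
#' @return A data frame with columns `node`, `parameter`, `set_size`,
#'   `spring`, `mean`, `q2.5`, `q97.5`.
#' @export
summarize_fit <- function(fit, nodes = colnames(fit$draws)) {
  stopifnot(nrow(fit$draws) >= 2L)
  qs <- t(apply(fit$draws[, nodes, drop = FALSE], 2L, quantile,
                probs = c(0.025, 0.975), names = FALSE))
  out <- data.frame(
    node = nodes,
    mean = colMeans(fit$draws[, nodes, drop = FALSE]),
    q2.5 = qs[, 1], q97.5 = qs[, 2],
    stringsAsFactors = FALSE
  )
  info <- fit$node_info
  m <- match(out$node, info$node)
  out$parameter <- info$parameter[m]
  out$set_size <- info$set_size[m]
  out$spring <- info$spring[m]
  rownames(out) <- NULL
  out[, c("node", "parameter", "set_size", "spring", "mean", "q2.5",
          "q97.5")]
}

#' Subject-level posterior means
#'
#' @param fit A `ddm_fit`.
#' @return A data frame with one row per subject and one column per
#'   condition node, holding that subject's posterior-mean parameter values.
#' @export
subject_parameter_means <- function(fit) {
  cond <- fit$node_info$node[fit$node_info$parameter %in% c("v", "a", "ter")]
  out <- data.frame(subject = fit$subjects, stringsAsFactors = FALSE)
  for (nd in cond) {
    cols <- paste0(nd, ".", fit$subjects)
    out[[nd]] <- colMeans(fit$draws[, cols, drop = FALSE])
  }
  out
}
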