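# Hierarchical Bayesian estimation by adaptive Metropolis-within-Gibbs.
#
# Structure: group means and between-subject SDs per condition node of v, a
# and ter; subject-level values per node; group-only z, sv, st, sz shared by
# all subjects.  Group means have truncated-normal full conditionals
# (conjugate Gibbs); everything else is single-site random-walk Metropolis
# with proposal scales adapted during burn-in.

#' MCMC configuration
#'
#' @param iterations Total iterations per chain.
#' @param burn_in Iterations discarded from the start of each chain.
#' @param chains Number of chains (two or more enable split-R-hat).
#' @param seed Integer root seed; chain `c` uses `seed + c - 1`.
#' @param adapt_window Iterations between proposal-scale adaptations
#'   (adaptation happens during burn-in only).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 5000L, burn_in = 1000L, chains = 2L,
                        seed = 1L, adapt_window = 50L, thin = 1L) {
  stopifnot(burn_in < iterations, chains >= 1, thin >= 1, adapt_window >= 10)
  structure(
    list(iterations = as.integer(iterations), burn_in = as.integer(burn_in),
         chains = as.integer(chains), seed = as.integer(seed),
         adapt_window = as.integer(adapt_window), thin = as.integer(thin)),
    class = "mcmc_config"
  )
}

# Assemble the per-subject, per-cell data blocks and node bookkeeping shared
# by fit() and deviance_components().
prep_fit_data <- function(trials, spec) {
  check_trial_schema(trials)
  trials <- trials[!is.na(trials$rt), , drop = FALSE]
  subjects <- sort(unique(trials$subject))
  S <- length(subjects)
  cells <- condition_cells()
  cell_of <- match(paste(trials$set_size, trials$spring),
                   paste(cells$set_size, cells$spring))
  subj_of <- match(trials$subject, subjects)

  nodes <- parameter_nodes(spec)
  cond_nodes <- nodes[nodes$parameter %in% c("v", "a", "ter"), , drop = FALSE]
  node_labels <- cond_nodes$node
  ncond <- length(node_labels)
  # column index of each cell's node, per parameter
  cellmap <- lapply(c(v = "v", a = "a", ter = "ter"), function(p) {
    match(cell_node_map(spec, p), node_labels)
  })

  block_rt <- vector("list", S * 4L)
  block_up <- vector("list", S * 4L)
  for (s in seq_len(S)) {
    for (cc in 1:4) {
      idx <- which(subj_of == s & cell_of == cc)
      if (length(idx) == 0L)
        stop(sprintf("subject %s has no trials in cell (set size %d, %s)",
                     subjects[s], cells$set_size[cc], cells$spring[cc]),
             call. = FALSE)
      b <- (s - 1L) * 4L + cc
      block_rt[[b]] <- as.numeric(trials$rt[idx])
      block_up[[b]] <- as.logical(trials$correct[idx])
    }
  }
  lens <- vapply(block_rt, length, integer(1))
  all_rt <- unlist(block_rt)
  all_up <- unlist(block_up)
  starts <- c(0L, cumsum(lens))[seq_len(S * 4L)]
  block_subj <- rep(seq_len(S), each = 4L)
  block_cell <- rep(1:4, times = S)

  # per (condition-node column, subject): concatenated data of the cells the
  # node covers, ready for a single likelihood call
  node_cells <- lapply(seq_len(ncond), function(j) {
    p <- cond_nodes$parameter[j]
    which(cellmap[[p]] == j)
  })
  pnode_data <- lapply(seq_len(ncond), function(j) {
    lapply(seq_len(S), function(s) {
      bs <- (s - 1L) * 4L + node_cells[[j]]
      rts <- unlist(block_rt[bs])
      ln <- lens[bs]
      list(rt = rts, up = unlist(block_up[bs]),
           starts = c(0L, cumsum(ln))[seq_along(bs)], lens = ln,
           cells = node_cells[[j]])
    })
  })

  fingerprint <- list(n = length(all_rt), sum_rt = round(sum(all_rt), 6),
                      n_correct = sum(all_up))
  list(subjects = subjects, S = S, cells = cells, cond_nodes = cond_nodes,
       node_labels = node_labels, ncond = ncond, cellmap = cellmap,
       node_cells = node_cells, pnode_data = pnode_data,
       block_rt = block_rt, block_up = block_up, lens = lens,
       all_rt = all_rt, all_up = all_up, starts = starts,
       block_subj = block_subj, block_cell = block_cell,
       fingerprint = fingerprint)
}

# Robust EZ-style moment estimates of (v, a, ter) from one cell's data.
ez_point <- function(rt, correct) {
  pc <- min(max(mean(correct), 0.55), 0.98)
  mrt <- mean(rt[correct])
  vrt <- var(rt[correct])
  if (!is.finite(mrt)) mrt <- mean(rt)
  if (!is.finite(vrt) || vrt <= 0) vrt <- max(var(rt), 0.01)
  L <- qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
  v <- sign(pc - 0.5) * x^(1 / 4)
  a <- L / v
  y <- -v * a
  mdt <- (a / (2 * v)) * (1 - exp(y)) / (1 + exp(y))
  ter <- mrt - mdt
  out <- c(v = v, a = a, ter = ter)
  if (!all(is.finite(out)) || a <= 0) out <- c(v = 2, a = 1.5, ter = 0.3)
  out["ter"] <- min(max(out[["ter"]], 0.05), max(min(rt) - 0.02, 0.05))
  out
}

#' Fit a hierarchical DDM by MCMC
#'
#' Samples the joint posterior of group means and between-subject SDs per
#' condition node of `v`, `a` and `ter`, subject-level node values, and
#' group-only `z`, `sv`, `st`, `sz`, under the uniform-contaminant mixture
#' likelihood with the contaminant fraction fixed (5% by default).  Group
#' means use truncated-normal conjugate Gibbs updates; all other nodes use
#' single-site random-walk Metropolis with proposal scales adapted toward a
#' 44% acceptance rate during burn-in.  The per-draw total deviance
#' (-2 log likelihood) is recorded for information-criterion comparison.
#'
#' @param trials Preprocessed trial data frame; every subject must have
#'   trials in all four condition cells.
#' @param spec A `ddm_model_spec`.
#' @param priors A [default_priors()] object.
#' @param mcmc A [mcmc_config()].
#' @param likelihood A [likelihood_config()]; the default uses 5 quadrature
#'   nodes per variability dimension, ample for the `st`/`sz` magnitudes
#'   this design produces (see the methods vignette).
#' @param p_outlier Fixed contaminant fraction.
#' @param init_retries Re-initialization attempts if the likelihood is not
#'   finite at the starting values.
#' @return An object of class `ddm_fit`: draw matrix (retained iterations
#'   stacked over chains), chain index, per-draw deviance, node metadata,
#'   model spec, configurations and a data fingerprint.
#' @export
fit <- function(trials, spec, priors = default_priors(spec),
                mcmc = mcmc_config(),
                likelihood = likelihood_config(quadrature_points = 5L),
                p_outlier = 0.05, init_retries = 20L) {
  pd <- prep_fit_data(trials, spec)
  chains <- lapply(seq_len(mcmc$chains), function(ch) {
    set.seed(mcmc$seed + ch - 1L)
    run_chain(pd, spec, priors, mcmc, likelihood, p_outlier, init_retries)
  })
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  deviance <- unlist(lapply(chains, `[[`, "deviance"))
  nkeep <- nrow(chains[[1]]$draws)
  structure(
    list(draws = draws,
         chain = rep(seq_len(mcmc$chains), each = nkeep),
         deviance = deviance,
         spec = spec,
         subjects = pd$subjects,
         node_info = parameter_nodes(spec),
         mcmc = mcmc, likelihood = likelihood, p_outlier = p_outlier,
         priors = priors,
         data_fingerprint = pd$fingerprint,
         accept_rates = chains[[length(chains)]]$accept_rates),
    class = "ddm_fit"
  )
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical DDM fit: model %d, %d subjects, %d draws (%d chains)\n",
    x$spec$model_id, length(x$subjects), nrow(x$draws), x$mcmc$chains))
  cat(sprintf("Mean deviance %.1f\n", mean(x$deviance)))
  invisible(x)
}

# One chain. Assumes the RNG is already seeded.
run_chain <- function(pd, spec, priors, mcmc, lik, p_outlier, init_retries) {
  S <- pd$S
  ncond <- pd$ncond
  param_of <- pd$cond_nodes$parameter
  nq <- lik$quadrature_points
  tol <- lik$series_tolerance
  ceil <- lik$rt_ceiling

  # --- initialization -------------------------------------------------
  ez_cells <- lapply(1:4, function(cc) {
    bs <- seq(cc, by = 4L, length.out = S)
    ez_point(unlist(pd$block_rt[bs]), unlist(pd$block_up[bs]))
  })
  init_state <- function(jitter) {
    mu <- numeric(ncond)
    for (j in seq_len(ncond)) {
      p <- param_of[j]
      mu[j] <- mean(vapply(pd$node_cells[[j]],
                           function(cc) ez_cells[[cc]][[p]], numeric(1)))
    }
    mu <- mu + rnorm(ncond, 0, jitter * c(v = 0.2, a = 0.1,
                                          ter = 0.02)[param_of])
    mu[param_of == "a"] <- pmax(mu[param_of == "a"], 0.3)
    mu[param_of == "ter"] <- pmax(mu[param_of == "ter"], 0.06)
    sigma <- c(v = 0.3, a = 0.25, ter = 0.05)[param_of]
    x <- matrix(rep(mu, each = S), nrow = S) +
      matrix(rnorm(S * ncond, 0, 0.5 * rep(sigma, each = S)), nrow = S)
    x[, param_of == "a"] <- pmax(x[, param_of == "a"], 0.2)
    x[, param_of == "ter"] <- pmax(x[, param_of == "ter"], 0.05)
    list(mu = mu, sigma = sigma, x = x, z = 0.5, sv = 0.5, st = 0.08,
         sz = 0.05)
  }

  blocks_ll <- function(x, z, sv, st, sz) {
    vb <- x[cbind(pd$block_subj, pd$cellmap$v[pd$block_cell])]
    ab <- x[cbind(pd$block_subj, pd$cellmap$a[pd$block_cell])]
    tb <- x[cbind(pd$block_subj, pd$cellmap$ter[pd$block_cell])]
    .loglik_blocks_cpp(pd$all_rt, pd$all_up, pd$starts, pd$lens, vb, ab, tb,
                       z, sv, st, sz, p_outlier, ceil, nq, tol)
  }

  st0 <- NULL
  for (try in seq_len(init_retries)) {
    st0 <- init_state(jitter = if (try == 1L) 1 else try)
    st0$x[, param_of == "ter"] <- pmax(st0$x[, param_of == "ter"],
                                       st0$st / 2 + 1e-4)
    ll <- blocks_ll(st0$x, st0$z, st0$sv, st0$st, st0$sz)
    if (all(is.finite(ll))) break
    if (try == init_retries)
      stop("likelihood not finite at initialization after ", init_retries,
           " retries", call. = FALSE)
  }
  mu <- st0$mu; sigma <- st0$sigma; x <- st0$x
  z <- st0$z; sv <- st0$sv; st <- st0$st; sz <- st0$sz
  ll_block <- matrix(ll, nrow = S, ncol = 4L, byrow = TRUE)

  # proposal scales (log scale for positive nodes)
  sc_sigma <- rep(0.3, ncond)
  sc_x <- c(v = 0.25, a = 0.15, ter = 0.02)[param_of]
  sc_nuis <- c(z = 0.15, sv = 0.2, st = 0.2, sz = 0.4, ridge = 0.08)
  acc <- list(sigma = numeric(ncond), x = numeric(ncond),
              nuis = numeric(5))
  cnt <- list(sigma = numeric(ncond), x = numeric(ncond),
              nuis = numeric(5))

  pm <- priors$mu
  prior_mean <- vapply(param_of, function(p) pm[[p]]$mean, numeric(1))
  prior_sd <- vapply(param_of, function(p) pm[[p]]$sd, numeric(1))
  prior_lower <- vapply(param_of, function(p) pm[[p]]$lower, numeric(1))
  sigma_scale <- priors$sigma_scale[param_of]
  ter_cols <- which(param_of == "ter")

  n_iter <- mcmc$iterations
  keep_idx <- seq(mcmc$burn_in + 1L, n_iter, by = mcmc$thin)
  nkeep <- length(keep_idx)
  subj_labels <- as.vector(outer(pd$subjects, pd$node_labels,
                                 function(s, n) paste0(n, ".", s)))
  colnames_out <- c(pd$node_labels, paste0("sigma_", pd$node_labels),
                    NUISANCE_NODES,
                    subj_labels)
  draws <- matrix(NA_real_, nkeep, length(colnames_out),
                  dimnames = list(NULL, colnames_out))
  deviance <- numeric(nkeep)
  krow <- 0L

  for (it in seq_len(n_iter)) {
    # group means: truncated-normal conjugate Gibbs
    for (j in seq_len(ncond)) {
      prec <- 1 / prior_sd[j]^2 + S / sigma[j]^2
      m <- (prior_mean[j] / prior_sd[j]^2 + sum(x[, j]) / sigma[j]^2) / prec
      mu[j] <- rtruncnorm1(m, 1 / sqrt(prec), prior_lower[j])
    }
    # group SDs: MH on log scale
    for (j in seq_len(ncond)) {
      prop <- sigma[j] * exp(sc_sigma[j] * rnorm(1L))
      lr <- sum(dnorm(x[, j], mu[j], prop, log = TRUE)) -
        sum(dnorm(x[, j], mu[j], sigma[j], log = TRUE)) +
        log_halfnormal(prop, sigma_scale[j]) -
        log_halfnormal(sigma[j], sigma_scale[j]) +
        log(prop) - log(sigma[j])
      cnt$sigma[j] <- cnt$sigma[j] + 1
      if (is.finite(lr) && log(runif(1L)) < lr) {
        sigma[j] <- prop
        acc$sigma[j] <- acc$sigma[j] + 1
      }
    }
    # subject-level nodes
    for (j in seq_len(ncond)) {
      p <- param_of[j]
      lower <- if (p == "a") 1e-3 else if (p == "ter") st / 2 else -Inf
      cells_j <- pd$node_cells[[j]]
      for (s in seq_len(S)) {
        cur <- x[s, j]
        prop <- cur + sc_x[j] * rnorm(1L)
        cnt$x[j] <- cnt$x[j] + 1
        if (prop < lower) next
        nd <- pd$pnode_data[[j]][[s]]
        vv <- x[s, pd$cellmap$v[cells_j]]
        aa <- x[s, pd$cellmap$a[cells_j]]
        tt <- x[s, pd$cellmap$ter[cells_j]]
        if (p == "v") vv[] <- prop
        else if (p == "a") aa[] <- prop
        else tt[] <- prop
        llp <- .loglik_blocks_cpp(nd$rt, nd$up, nd$starts, nd$lens,
                                  vv, aa, tt, z, sv, st, sz, p_outlier,
                                  ceil, nq, tol)
        lr <- sum(llp) - sum(ll_block[s, cells_j]) +
          dnorm(prop, mu[j], sigma[j], log = TRUE) -
          dnorm(cur, mu[j], sigma[j], log = TRUE)
        if (is.finite(lr) && log(runif(1L)) < lr) {
          x[s, j] <- prop
          ll_block[s, cells_j] <- llp
          acc$x[j] <- acc$x[j] + 1
        }
      }
    }
    # Full-data Metropolis moves: the bias node z is updated every
    # iteration (it is strongly anti-correlated with the drift/sv block and
    # limits mixing when starved), while sv, st, sz and a joint drift/sv
    # scaling move rotate round-robin.  Each proposal costs a full-data
    # likelihood pass.
    total_ll <- sum(ll_block)
    nuis_update <- function(k, prop_z, prop_sv, prop_st, prop_sz,
                            log_prior_diff, log_jac) {
      llp <- blocks_ll(x, prop_z, prop_sv, prop_st, prop_sz)
      sp <- sum(llp)
      lr <- sp - total_ll + log_prior_diff + log_jac
      cnt$nuis[k] <<- cnt$nuis[k] + 1
      if (is.finite(lr) && log(runif(1L)) < lr) {
        z <<- prop_z; sv <<- prop_sv; st <<- prop_st; sz <<- prop_sz
        ll_block <<- matrix(llp, nrow = S, ncol = 4L, byrow = TRUE)
        total_ll <<- sp
        acc$nuis[k] <<- acc$nuis[k] + 1
      }
    }
    # z (logit walk); its move also rescales the sz prior bound
    zl <- qlogis(z) + sc_nuis[1] * rnorm(1L)
    zp <- plogis(zl)
    szmax_p <- min(2 * zp, 2 * (1 - zp))
    if (sz < szmax_p && zp - sz / 2 > 0 && zp + sz / 2 < 1) {
      lpd <- dbeta(zp, priors$z_beta[1], priors$z_beta[2], log = TRUE) -
        dbeta(z, priors$z_beta[1], priors$z_beta[2], log = TRUE) -
        log(szmax_p) + log(min(2 * z, 2 * (1 - z)))
      jac <- log(zp * (1 - zp)) - log(z * (1 - z))
      nuis_update(1L, zp, sv, st, sz, lpd, jac)
    } else cnt$nuis[1] <- cnt$nuis[1] + 1
    total_ll <- sum(ll_block)
    nuis_k <- (it - 1L) %% 4L + 2L
    if (nuis_k == 2L) {
      # sv (log walk)
      svp <- sv * exp(sc_nuis[2] * rnorm(1L))
      nuis_update(2L, z, svp, st, sz,
                  log_halfnormal(svp, priors$sv_scale) -
                    log_halfnormal(sv, priors$sv_scale),
                  log(svp) - log(sv))
    } else if (nuis_k == 3L) {
      # st (log walk, capped by the smallest subject ter)
      stp <- st * exp(sc_nuis[3] * rnorm(1L))
      if (stp <= 2 * min(x[, ter_cols])) {
        nuis_update(3L, z, sv, stp, sz,
                    log_halfnormal(stp, priors$st_scale) -
                      log_halfnormal(st, priors$st_scale),
                    log(stp) - log(st))
      } else cnt$nuis[3] <- cnt$nuis[3] + 1
    } else if (nuis_k == 4L) {
      # sz (log walk, uniform prior on (0, min(2z, 2(1-z))))
      szp <- sz * exp(sc_nuis[4] * rnorm(1L))
      if (szp < min(2 * z, 2 * (1 - z))) {
        nuis_update(4L, z, sv, st, szp, 0, log(szp) - log(sz))
      } else cnt$nuis[4] <- cnt$nuis[4] + 1
    } else {
      # joint directional move along the posterior's slow manifold: sv,
      # sz and all drift-rate nodes (subject values, group means, group
      # SDs) rise together while the bias z falls -- choice accuracy
      # constrains mainly their combination, so single-site updates
      # traverse this direction slowly.  Scale the drift/sv/sz block by a
      # common factor and shift logit(z) against it, with the log-scale
      # and logit Jacobians.
      eps <- sc_nuis[5] * rnorm(1L)
      cf <- exp(eps)
      vcols <- which(param_of == "v")
      x_p <- x
      x_p[, vcols] <- x[, vcols] * cf
      mu_p <- mu[vcols] * cf
      sigma_p <- sigma[vcols] * cf
      sv_p <- sv * cf
      sz_p <- sz * cf
      z_p <- plogis(qlogis(z) - 0.12 * eps)
      ok <- sz_p < min(2 * z_p, 2 * (1 - z_p)) && z_p - sz_p / 2 > 0 &&
        z_p + sz_p / 2 < 1
      cnt$nuis[5] <- cnt$nuis[5] + 1
      if (ok) {
        llp <- blocks_ll(x_p, z_p, sv_p, st, sz_p)
        lp_prop <- log_halfnormal(sv_p, priors$sv_scale) +
          dbeta(z_p, priors$z_beta[1], priors$z_beta[2], log = TRUE) -
          log(min(2 * z_p, 2 * (1 - z_p)))
        lp_cur <- log_halfnormal(sv, priors$sv_scale) +
          dbeta(z, priors$z_beta[1], priors$z_beta[2], log = TRUE) -
          log(min(2 * z, 2 * (1 - z)))
        for (i in seq_along(vcols)) {
          j <- vcols[i]
          lp_prop <- lp_prop + dnorm(mu_p[i], prior_mean[j], prior_sd[j],
                                     log = TRUE) +
            log_halfnormal(sigma_p[i], sigma_scale[j]) +
            sum(dnorm(x_p[, j], mu_p[i], sigma_p[i], log = TRUE))
          lp_cur <- lp_cur + dnorm(mu[j], prior_mean[j], prior_sd[j],
                                   log = TRUE) +
            log_halfnormal(sigma[j], sigma_scale[j]) +
            sum(dnorm(x[, j], mu[j], sigma[j], log = TRUE))
        }
        n_scaled <- length(vcols) * (S + 2L) + 2L  # + sv and sz
        jac <- n_scaled * eps +
          log(z_p * (1 - z_p)) - log(z * (1 - z))
        lr <- sum(llp) - total_ll + lp_prop - lp_cur + jac
        if (is.finite(lr) && log(runif(1L)) < lr) {
          x <- x_p
          mu[vcols] <- mu_p
          sigma[vcols] <- sigma_p
          sv <- sv_p
          sz <- sz_p
          z <- z_p
          ll_block <- matrix(llp, nrow = S, ncol = 4L, byrow = TRUE)
          acc$nuis[5] <- acc$nuis[5] + 1
        }
      }
    }

    # proposal adaptation during burn-in
    if (it <= mcmc$burn_in && it %% mcmc$adapt_window == 0L) {
      adapt <- function(scales, a, n) {
        rate <- ifelse(n > 0, a / n, 0.44)
        scales * exp(pmin(pmax(rate - 0.44, -0.25), 0.25))
      }
      sc_sigma <- adapt(sc_sigma, acc$sigma, cnt$sigma)
      sc_x <- adapt(sc_x, acc$x, cnt$x)
      sc_nuis <- adapt(sc_nuis, acc$nuis, cnt$nuis)
      acc <- lapply(acc, function(v) v * 0)
      cnt <- lapply(cnt, function(v) v * 0)
    }

    if (it > mcmc$burn_in && (it - mcmc$burn_in - 1L) %% mcmc$thin == 0L) {
      krow <- krow + 1L
      draws[krow, ] <- c(mu, sigma, z, sv, st, sz, as.vector(x))
      deviance[krow] <- -2 * sum(ll_block)
    }
  }

  rates <- list(
    sigma = ifelse(cnt$sigma > 0, acc$sigma / cnt$sigma, NA_real_),
    x = ifelse(cnt$x > 0, acc$x / cnt$x, NA_real_),
    nuis = ifelse(cnt$nuis > 0, acc$nuis / cnt$nuis, NA_real_)
  )
  list(draws = draws[seq_len(krow), , drop = FALSE],
       deviance = deviance[seq_len(krow)], accept_rates = rates)
}

# Single adaptive random-walk Metropolis chain on a scalar log target; the
# same accept/adapt rules the hierarchical sampler uses.  Used for sampler
# verification against conjugate closed forms.
amh_chain <- function(log_target, init, n_iter, burn_in, scale = 1,
                      adapt_window = 50L) {
  x <- init
  lt <- log_target(x)
  out <- numeric(n_iter - burn_in)
  a <- 0L; n <- 0L
  for (it in seq_len(n_iter)) {
    prop <- x + scale * rnorm(1L)
    ltp <- log_target(prop)
    n <- n + 1L
    if (is.finite(ltp) && log(runif(1L)) < ltp - lt) {
      x <- prop; lt <- ltp; a <- a + 1L
    }
    if (it <= burn_in && it %% adapt_window == 0L) {
      scale <- scale * exp(min(max(a / n - 0.44, -0.25), 0.25))
      a <- 0L; n <- 0L
    }
    if (it > burn_in) out[it - burn_in] <- x
  }
  out
}
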