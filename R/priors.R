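# Weakly informative proper priors for the hierarchical DDM.

#' Default priors for hierarchical estimation
#'
#' Proper, weakly informative priors.  Group means: drift `v` ~ Normal(2, 3);
#' boundary `a` ~ Normal(1.5, 1) truncated positive; non-decision time `ter`
#' ~ Normal(0.4, 0.3) truncated nonnegative.  Between-subject SDs:
#' Half-Normal(1) for `v` and `a`, Half-Normal(0.2) for `ter`.  Group-only
#' nuisance parameters: `z` ~ Beta(5, 5); `sv` ~ Half-Normal(2); `st` ~
#' Half-Normal(0.3) jointly constrained so every subject-level `ter` keeps
#' `ter - st/2 >= 0`; `sz` ~ Uniform(0, min(2z, 2(1 - z))) jointly
#' constrained with `z`.
#'
#' @param spec A `ddm_model_spec` (the prior set is the same for every model
#'   in the space; the argument fixes the interface).
#' @return A list of class `ddm_priors`.
#' @export
default_priors <- function(spec = NULL) {
  structure(
    list(
      mu = list(
        v = list(mean = 2, sd = 3, lower = -Inf),
        a = list(mean = 1.5, sd = 1, lower = 0),
        ter = list(mean = 0.4, sd = 0.3, lower = 0)
      ),
      sigma_scale = c(v = 1, a = 1, ter = 0.2),
      z_beta = c(5, 5),
      sv_scale = 2,
      st_scale = 0.3
    ),
    class = "ddm_priors"
  )
}

# log density helpers ---------------------------------------------------

log_halfnormal <- function(x, scale) {
  ifelse(x < 0, -Inf, dnorm(x, 0, scale, log = TRUE) + log(2))
}

log_truncnormal <- function(x, mean, sd, lower) {
  ifelse(x < lower, -Inf,
         dnorm(x, mean, sd, log = TRUE) -
           pnorm(lower, mean, sd, lower.tail = FALSE, log.p = TRUE))
}

# Draw from Normal(mean, sd) truncated to [lower, Inf) by CDF inversion.
rtruncnorm1 <- function(mean, sd, lower) {
  if (!is.finite(lower)) return(rnorm(1L, mean, sd))
  plo <- pnorm(lower, mean, sd)
  u <- runif(1L, min(plo, 1 - 1e-12), 1)
  mean + sd * qnorm(u)
}
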