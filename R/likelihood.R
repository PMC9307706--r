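# Wiener first-passage-time likelihood: R surface over the C++ kernels.

#' Configuration of the likelihood evaluation
#'
#' @param series_tolerance Absolute truncation-error bound for the
#'   small-/large-time series of the normalized first-passage density.
#' @param quadrature_points Gauss-Legendre nodes per active across-trial
#'   variability dimension (`st`, `sz`); drift variability (`sv`) is
#'   integrated in closed form and needs no quadrature.
#' @param rt_ceiling Support (s) of the uniform contaminant distribution;
#'   defaults to the 5.0 s response window, the only principled bound in the
#'   design.
#' @return A list of class `likelihood_config`.
#' @export
likelihood_config <- function(series_tolerance = 1e-7, quadrature_points = 11L,
                              rt_ceiling = 5.0) {
  stopifnot(series_tolerance > 0, quadrature_points >= 1, rt_ceiling > 0)
  structure(
    list(series_tolerance = series_tolerance,
         quadrature_points = as.integer(quadrature_points),
         rt_ceiling = rt_ceiling),
    class = "likelihood_config"
  )
}

#' Probability of absorption at the upper boundary
#'
#' Classical two-barrier absorption probability for a Wiener process with
#' unit diffusion coefficient starting at `z * a`; equals `z` when the drift
#' is zero.
#'
#' @param v Drift rate.
#' @param a Boundary separation (> 0).
#' @param z Relative starting point in (0, 1).
#' @return Probability in `[0, 1]`.
#' @export
choice_probability <- function(v, a, z = 0.5) {
  if (!is.finite(a) || a <= 0 || z <= 0 || z >= 1)
    stop("invalid parameters: need a > 0 and 0 < z < 1", call. = FALSE)
  if (abs(v) < 1e-12) return(z)
  # (1 - exp(-2 v z a)) / (1 - exp(-2 v a)), guarded against overflow via
  # the expm1 form
  num <- -expm1(-2 * v * z * a)
  den <- -expm1(-2 * v * a)
  p <- num / den
  min(max(p, 0), 1)
}

#' Wiener first-passage-time density without across-trial variability
#'
#' Density (1/s) of first passage through the given boundary at decision
#' time `t` (non-decision time already subtracted).  Small-time and
#' large-time series representations are selected automatically so that the
#' truncation error is below `tol`.  Nonpositive `t` yields 0.
#'
#' @param t Decision time(s), seconds; vectorized.
#' @param boundary `"upper"` or `"lower"`.
#' @param v,a,z Drift rate, boundary separation, relative start.
#' @param tol Series truncation tolerance.
#' @return Density values, same length as `t`.
#' @export
wfpt_density <- function(t, boundary = c("upper", "lower"), v, a, z = 0.5,
                         tol = 1e-7) {
  boundary <- match.arg(boundary)
  if (!is.finite(a) || a <= 0 || z <= 0 || z >= 1 || tol <= 0)
    stop("invalid parameters", call. = FALSE)
  .wfpt_density_cpp(as.numeric(t), boundary == "upper", v, a, z, tol)
}

#' Full DDM density with across-trial variability
#'
#' Density of an observed response time (including non-decision time) at the
#' given boundary, with drift drawn Normal(`v`, `sv`) (integrated in closed
#' form), starting point Uniform(`z` +/- `sz/2`) and non-decision time
#' Uniform(`ter` +/- `st/2`) (both integrated by deterministic
#' Gauss-Legendre quadrature with `config$quadrature_points` nodes).
#' Inactive dimensions (parameter equal to 0) are skipped.  `rt` at or below
#' the smallest possible non-decision time yields 0.
#'
#' @param rt Observed response time(s), seconds; vectorized.
#' @param boundary `"upper"` or `"lower"`.
#' @param params A [ddm_parameters()] object.
#' @param config A [likelihood_config()].
#' @return Density values, same length as `rt`.
#' @export
full_density <- function(rt, boundary = c("upper", "lower"), params,
                         config = likelihood_config()) {
  boundary <- match.arg(boundary)
  validate_ddm_parameters(params)
  .full_density_cpp(as.numeric(rt), boundary == "upper", params$v, params$a,
                    params$ter, params$z, params$sv, params$st, params$sz,
                    config$quadrature_points, config$series_tolerance)
}

#' Per-trial mixture log-likelihood
#'
#' Log of `(1 - p_outlier) * full_density(rt, boundary) + p_outlier * u`
#' where `u = 1 / (2 * rt_ceiling)` is the uniform contaminant density with
#' its mass split over the two responses.
#'
#' @param trial A single-row trial record (needs `rt` and `correct`); under
#'   accuracy coding the upper boundary is the correct response.
#' @param params A [ddm_parameters()] object.
#' @param p_outlier Contaminant fraction in `[0, 1]`.
#' @param config A [likelihood_config()].
#' @return Log density (scalar).
#' @export
trial_loglik <- function(trial, params, p_outlier = 0.05,
                         config = likelihood_config()) {
  stopifnot(p_outlier >= 0, p_outlier <= 1)
  if (is.null(trial$rt) || length(trial$rt) != 1L || is.na(trial$rt))
    stop("trial has no response time; exclude no-response trials upstream",
         call. = FALSE)
  validate_ddm_parameters(params)
  as.numeric(.loglik_blocks_cpp(
    as.numeric(trial$rt), as.logical(trial$correct), 0L, 1L,
    params$v, params$a, params$ter, params$z, params$sv, params$st,
    params$sz, p_outlier, config$rt_ceiling, config$quadrature_points,
    config$series_tolerance
  ))
}

#' Summed log-likelihood of a trial table
#'
#' Resolves each trial's condition cell to its parameter node under the
#' supplied per-cell parameters and sums the per-trial mixture
#' log-likelihoods.  An empty table yields 0.
#'
#' @param trials Trial data frame with columns `set_size`, `spring`, `rt`,
#'   `correct`.
#' @param cell_params Named list mapping `"<set_size>.<spring>"` (e.g.
#'   `"3.soft"`) to a [ddm_parameters()] object; cells may share objects.
#' @param p_outlier Contaminant fraction.
#' @param config A [likelihood_config()].
#' @return Scalar log-likelihood.
#' @export
dataset_loglik <- function(trials, cell_params, p_outlier = 0.05,
                           config = likelihood_config()) {
  if (nrow(trials) == 0L) return(0)
  key <- paste(trials$set_size, trials$spring, sep = ".")
  missing_cells <- setdiff(unique(key), names(cell_params))
  if (length(missing_cells) > 0L)
    stop("no parameters supplied for cell(s): ",
         paste(missing_cells, collapse = ", "), call. = FALSE)
  total <- 0
  for (cell in unique(key)) {
    idx <- key == cell
    p <- cell_params[[cell]]
    validate_ddm_parameters(p)
    total <- total + sum(.loglik_blocks_cpp(
      as.numeric(trials$rt[idx]), as.logical(trials$correct[idx]),
      0L, sum(idx), p$v, p$a, p$ter, p$z, p$sv, p$st, p$sz,
      p_outlier, config$rt_ceiling, config$quadrature_points,
      config$series_tolerance
    ))
  }
  total
}
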