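# Parameter containers and validation.

#' Construct a validated DDM parameter set
#'
#' One accumulator's parameters under the scaling convention of a unit
#' diffusion coefficient.
#'
#' @param v Drift rate (evidence units/s); mean rate of evidence accumulation.
#' @param a Boundary separation (evidence units); must be positive.
#' @param ter Non-decision time (s); encoding plus motor execution.
#' @param z Relative starting point in (0, 1); 0.5 is unbiased.
#' @param sv Across-trial SD of drift (evidence units/s).
#' @param st Across-trial range of non-decision time (s); `ter` must leave
#'   `ter - st/2 >= 0`.
#' @param sz Across-trial range of the starting point; `z +/- sz/2` must stay
#'   inside (0, 1).
#' @return A named list of class `ddm_parameters`.
#' @export
ddm_parameters <- function(v, a, ter, z = 0.5, sv = 0, st = 0, sz = 0) {
  p <- list(v = v, a = a, ter = ter, z = z, sv = sv, st = st, sz = sz)
  validate_ddm_parameters(p)
  structure(p, class = "ddm_parameters")
}

validate_ddm_parameters <- function(p) {
  with(p, {
    if (!is.finite(a) || a <= 0) stop("a must be positive", call. = FALSE)
    if (!is.finite(z) || z <= 0 || z >= 1)
      stop("z must lie strictly between 0 and 1", call. = FALSE)
    if (ter < 0) stop("ter must be nonnegative", call. = FALSE)
    if (sv < 0 || st < 0 || sz < 0)
      stop("variability parameters must be nonnegative", call. = FALSE)
    if (ter - st / 2 < 0)
      stop("ter - st/2 must be nonnegative", call. = FALSE)
    if (z - sz / 2 <= 0 || z + sz / 2 >= 1)
      stop("z +/- sz/2 must stay inside (0, 1)", call. = FALSE)
  })
  invisible(p)
}

#' Group-level parameters for simulation
#'
#' Group means and between-subject SDs per condition cell for the parameters
#' that vary by subject (`v`, `a`, `ter`), plus group-only nuisance values
#' and the contaminant fraction.
#'
#' @param means A data frame with columns `set_size`, `spring`, `v`, `a`,
#'   `ter`: one row per condition cell (cells may share values where the
#'   generating model says they are identical).
#' @param sds Named numeric vector with entries `v`, `a`, `ter`: between-
#'   subject SDs (constant across cells).
#' @param z,sv,st,sz Group-only nuisance values shared by all subjects.
#' @param p_outlier Contaminant fraction in `[0, 1]`: probability a trial's
#'   response time is replaced by a uniform draw over the response window and
#'   its response by a fair coin.
#' @return An object of class `ddm_group_parameters`.
#' @seealso [default_group_parameters()]
#' @export
group_parameters <- function(means, sds = c(v = 0.3, a = 0.25, ter = 0.05),
                             z = 0.5, sv = 0.6, st = 0.1, sz = 0.1,
                             p_outlier = 0.05) {
  stopifnot(is.data.frame(means),
            all(c("set_size", "spring", "v", "a", "ter") %in% names(means)),
            all(c("v", "a", "ter") %in% names(sds)),
            all(sds >= 0), p_outlier >= 0, p_outlier <= 1)
  cells <- condition_cells()
  key <- paste(cells$set_size, cells$spring)
  if (!all(key %in% paste(means$set_size, means$spring)))
    stop("`means` must cover all four condition cells", call. = FALSE)
  for (i in seq_len(nrow(means))) {
    validate_ddm_parameters(list(
      v = means$v[i], a = means$a[i], ter = means$ter[i],
      z = z, sv = sv, st = st, sz = sz
    ))
  }
  structure(
    list(means = means, sds = sds[c("v", "a", "ter")], z = z, sv = sv,
         st = st, sz = sz, p_outlier = p_outlier),
    class = "ddm_group_parameters"
  )
}

#' Default generating parameters for recovery studies
#'
#' Group means follow the fitted group posterior means of the restricted
#' model in which drift rate varies by set size only while boundary
#' separation and non-decision time vary by both set size and spring
#' pressure (the best-fitting model for the letter-comparison task): drift
#' 2.57 / 1.78 for set sizes 3 / 5; boundary separation 1.78, 2.01 (soft)
#' and 2.14, 2.20 (stiff); non-decision time 0.58, 0.70 s (soft) and 0.62,
#' 0.80 s (stiff).  Between-subject SDs and group-only nuisance values are
#' documented package defaults (see the methods vignette).
#'
#' @param ... Overrides passed on to [group_parameters()].
#' @return An object of class `ddm_group_parameters`.
#' @export
default_group_parameters <- function(...) {
  means <- data.frame(
    set_size = c(3L, 5L, 3L, 5L),
    spring = c("soft", "soft", "stiff", "stiff"),
    v = c(2.57, 1.78, 2.57, 1.78),
    a = c(1.78, 2.01, 2.14, 2.20),
    ter = c(0.58, 0.70, 0.62, 0.80),
    stringsAsFactors = FALSE
  )
  group_parameters(means, ...)
}

#' Generating parameters with the spring-pressure effect removed
#'
#' Averages each parameter's group means over the spring factor within set
#' size, yielding a generating process with no motor-speed effect; used for
#' independence-check studies (does the fitted full model's soft/stiff drift
#' posteriors mutually cover each other's means when no effect exists?).
#'
#' @param base Group parameters to neutralize.
#' @return An object of class `ddm_group_parameters`.
#' @export
null_spring_group_parameters <- function(base = default_group_parameters()) {
  m <- base$means
  for (p in c("v", "a", "ter")) {
    m[[p]] <- stats::ave(m[[p]], m$set_size)
  }
  group_parameters(m, sds = base$sds, z = base$z, sv = base$sv, st = base$st,
                   sz = base$sz, p_outlier = base$p_outlier)
}
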