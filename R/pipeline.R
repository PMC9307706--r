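# Pipeline configuration, file I/O and the stage entry points
# (simulate / preprocess / fit / compare / behave) used by the thin CLI
# wrapper in inst/cli.

#' Read / write trial tables
#'
#' The on-disk schema is tab-separated with columns `subject`, `block`,
#' `trial`, `set_size`, `spring`, `match`, `response`, `rt_seconds`,
#' `is_practice`.  On read, the derived `correct` flag (response agrees
#' with the match status) and internal column names are added.
#'
#' @param path File path.
#' @return `read_trials()` returns the internal trial data frame.
#' @export
read_trials <- function(path) {
  raw <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
  needed <- c("subject", "block", "trial", "set_size", "spring", "match",
              "response", "rt_seconds", "is_practice")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L)
    stop("trial file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  data.frame(
    subject = as.character(raw$subject),
    block = as.integer(raw$block),
    trial_index = as.integer(raw$trial),
    set_size = as.integer(raw$set_size),
    spring = as.character(raw$spring),
    match = as.logical(raw$match),
    response = as.character(raw$response),
    correct = ifelse(is.na(raw$response), NA,
                     (raw$response == "match") == as.logical(raw$match)),
    rt = as.numeric(raw$rt_seconds),
    is_practice = as.logical(raw$is_practice),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_trials
#' @param trials Internal trial data frame.
#' @export
write_trials <- function(trials, path) {
  check_trial_schema(trials)
  out <- data.frame(
    subject = trials$subject, block = trials$block,
    trial = trials$trial_index, set_size = trials$set_size,
    spring = trials$spring, match = trials$match,
    response = trials$response, rt_seconds = trials$rt,
    is_practice = trials$is_practice, stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an assessments table
#'
#' Tab-separated columns `subject`, `sdmt_oral`, `sdmt_written`,
#' `nhpt_seconds`; missing values permitted.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_assessments <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = c("NA", ""))
}

#' Pipeline configuration
#'
#' One document holding the stage settings; can be read from a YAML file.
#' All randomness flows from the single `seed`.
#'
#' @param seed Root seed.
#' @param out_dir Output directory.
#' @param trials_path,assessments_path Input files (non-simulation mode).
#' @param n_subjects Subjects to simulate.
#' @param design A [design_config()].
#' @param group A [group_parameters()] object (simulation mode).
#' @param spec_ids Model ids (1-9) to fit.
#' @param mcmc A [mcmc_config()] (its `seed` is overridden by the pipeline
#'   seed).
#' @param likelihood A [likelihood_config()] used by the fits.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = ".", trials_path = NULL,
                            assessments_path = NULL, n_subjects = 48L,
                            design = design_config(),
                            group = default_group_parameters(),
                            spec_ids = c(1L, 4L, 9L),
                            mcmc = mcmc_config(),
                            likelihood = likelihood_config(
                              quadrature_points = 5L)) {
  mcmc$seed <- as.integer(seed) + 1000L
  structure(
    list(seed = as.integer(seed), out_dir = out_dir,
         trials_path = trials_path, assessments_path = assessments_path,
         n_subjects = as.integer(n_subjects), design = design,
         group = group, spec_ids = as.integer(spec_ids), mcmc = mcmc,
         likelihood = likelihood),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] arguments; scalar design
#' and MCMC settings may be given under `design:` and `mcmc:` mappings.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  design <- do.call(design_config, y$design %||% list())
  mcmc <- do.call(mcmc_config, y$mcmc %||% list())
  pipeline_config(
    seed = y$seed %||% 1L, out_dir = y$out_dir %||% ".",
    trials_path = y$trials_path, assessments_path = y$assessments_path,
    n_subjects = y$n_subjects %||% 48L, design = design,
    spec_ids = y$spec_ids %||% c(1L, 4L, 9L), mcmc = mcmc
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  # order-stable polynomial rolling hash over the serialized configuration
  s <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 17
  for (ch in s) h <- (h * 31 + ch) %% 2^28
  sprintf("%08x", as.integer(h))
}

sidecar <- function(config, extra = list()) {
  c(list(seed = config$seed, config_hash = config_hash(unclass(config)),
         package_version = as.character(utils::packageVersion("hbddm"))),
    extra)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Simulation stage: write a synthetic dataset and its ground truth
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the list of written file paths.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  ds <- generate_dataset(config$group, spec = build_model_space()[[4L]],
                         n_subjects = config$n_subjects,
                         config = config$design)
  paths <- list(
    trials = file.path(config$out_dir, "trials.tsv"),
    ledger = file.path(config$out_dir, "ground_truth.json"),
    meta = file.path(config$out_dir, "simulate_meta.json")
  )
  write_trials(ds$trials, paths$trials)
  write_json_file(
    list(group_means = ds$truth$group$means,
         group_sds = as.list(ds$truth$group$sds),
         nuisance = ds$truth$group[c("z", "sv", "st", "sz", "p_outlier")],
         model_spec = jsonlite::fromJSON(model_spec_to_json(ds$truth$spec)),
         subjects = lapply(ds$truth$subjects, as.list),
         n_contaminants = sum(ds$truth$outliers$is_outlier)),
    paths$ledger)
  write_json_file(sidecar(config), paths$meta)
  invisible(paths)
}

#' Fitting stage: preprocess, fit the requested models, write summaries
#'
#' Writes, per model, the draw matrix (gzipped TSV), a JSON sidecar with
#' node labels and configuration, a posterior summary table in the
#' parameter-by-condition layout, and convergence diagnostics.  Emits a
#' prominent warning (not silent success) when any node's split R-hat
#' exceeds 1.1.
#'
#' @param config A [pipeline_config()].
#' @param trials Optional in-memory trial table; defaults to
#'   `config$trials_path`.
#' @return Invisibly, a list with the fits and the preprocessing report.
#' @export
cmd_fit <- function(config, trials = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(trials)) {
    if (is.null(config$trials_path) || !file.exists(config$trials_path))
      stop("no trial data: set trials_path or pass `trials`", call. = FALSE)
    trials <- read_trials(config$trials_path)
  }
  pp <- preprocess(trials)
  writeLines(report_to_json(pp$report),
             file.path(config$out_dir, "preprocess_report.json"))
  space <- build_model_space()
  fits <- list()
  for (id in config$spec_ids) {
    f <- fit(pp$trials, space[[id]], mcmc = config$mcmc,
             likelihood = config$likelihood)
    dg <- diagnostics(f)
    bad <- dg$summary$node[!is.na(dg$summary$rhat) & dg$summary$rhat > 1.1]
    if (length(bad) > 0L)
      warning(sprintf("model %d: split R-hat > 1.1 on %d node(s): %s", id,
                      length(bad), paste(head(bad, 5L), collapse = ", ")),
              call. = FALSE)
    tag <- sprintf("model%d", id)
    con <- gzfile(file.path(config$out_dir, paste0(tag, "_draws.tsv.gz")),
                  "w")
    write.table(cbind(chain = f$chain, f$draws, deviance = f$deviance),
                con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    write_json_file(
      sidecar(config, list(
        model_spec = jsonlite::fromJSON(model_spec_to_json(f$spec)),
        nodes = colnames(f$draws), subjects = f$subjects,
        data_fingerprint = f$data_fingerprint,
        mcmc = unclass(f$mcmc))),
      file.path(config$out_dir, paste0(tag, "_fit.json")))
    write.table(summarize_fit(f, nodes = c(f$node_info$node)),
                file.path(config$out_dir, paste0(tag, "_summary.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(dg$summary,
                file.path(config$out_dir, paste0(tag, "_diagnostics.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    fits[[tag]] <- f
  }
  invisible(list(fits = fits, preprocess = pp))
}

#' Comparison stage: BPIC table, independence check, predictive quantiles
#'
#' @param config A [pipeline_config()].
#' @param fits Named list of `ddm_fit` objects (from [cmd_fit()]).
#' @param trials The preprocessed trials the fits used.
#' @param n_rep Posterior-predictive replicates for the quantile data.
#' @return Invisibly, a list with the comparison table, the overlap report
#'   (or the string "not applicable" where the best model has no spring
#'   drift nodes) and the predictive quantile data.
#' @export
cmd_compare <- function(config, fits, trials, n_rep = 50L) {
  stopifnot(inherits(config, "pipeline_config"), length(fits) >= 1L)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- rank_models(fits, trials)
  space_info <- do.call(rbind, lapply(fits, function(f) data.frame(
    model_id = f$spec$model_id,
    v = paste(f$spec$v_factors, collapse = "+"),
    a = paste(f$spec$a_factors, collapse = "+"),
    ter = paste(f$spec$ter_factors, collapse = "+"),
    stringsAsFactors = FALSE)))
  tab <- merge(space_info, tab, by = "model_id")
  tab <- tab[order(tab$BPIC), , drop = FALSE]
  write.table(tab, file.path(config$out_dir, "model_comparison.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  best <- fits[[which.max(vapply(fits, function(f)
    f$spec$model_id == tab$model_id[1], logical(1)))]]
  pairs <- spring_drift_pairs(best$spec)
  overlap <- if (is.null(pairs)) "not applicable" else ci_overlap(best, pairs)
  write_json_file(list(best_model = tab$model_id[1], overlap = overlap),
                  file.path(config$out_dir, "independence_check.json"))

  set.seed(config$seed + 2000L)
  ppq <- posterior_predictive(best, trials, n_rep = n_rep)
  write.table(ppq, file.path(config$out_dir, "predictive_quantiles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_json_file(sidecar(config), file.path(config$out_dir,
                                             "compare_meta.json"))
  invisible(list(comparison = tab, overlap = overlap, predictive = ppq))
}

#' Behavioral stage: cell summaries, Bayes factors, correlations
#'
#' @param config A [pipeline_config()].
#' @param trials Preprocessed trials.
#' @param fit Optional model fit supplying subject-level parameter means.
#' @param scores Optional assessments data frame.
#' @return Invisibly, the computed tables.
#' @export
cmd_behave <- function(config, trials, fit = NULL, scores = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cs <- cell_summary(trials)
  write.table(cs, file.path(config$out_dir, "cell_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  bf_acc <- bf_model_comparison(cs, "accuracy")
  bf_rt <- bf_model_comparison(cs, "mean_rt")
  bf_tab <- rbind(
    cbind(dv = "accuracy", bf_acc$table),
    cbind(dv = "mean_rt", bf_rt$table)
  )
  write.table(bf_tab, file.path(config$out_dir, "bayes_factors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  out <- list(cells = cs, bf = bf_tab)
  if (!is.null(fit) && !is.null(scores)) {
    cm <- correlation_matrix(subject_parameter_means(fit), scores)
    write.table(round(cm, 3),
                file.path(config$out_dir, "correlation_matrix.tsv"),
                sep = "\t", quote = FALSE, row.names = TRUE)
    out$correlations <- cm
  }
  invisible(out)
}
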