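# JSON serialization helpers for result objects.

result_to_list <- function(x) UseMethod("result_to_list")

#' @export
result_to_list.lsd_fit <- function(x) {
  list(name = x$name, terms = x$terms, intercept = x$intercept,
       se_intercept = x$se_intercept, betas = as.list(x$betas),
       ses = as.list(x$ses), logL = x$logL, K = x$K, n_used = x$n_used,
       converged = x$converged, separation_flag = x$separation_flag)
}

#' @export
result_to_list.occupancy_fit <- function(x) {
  list(model = x$spec$name, psi_terms = x$spec$psi_terms,
       p_terms = x$spec$p_terms,
       beta_psi = as.list(x$beta_psi), alpha_p = as.list(x$alpha_p),
       alpha_p_std = as.list(x$alpha_p_std), ses = as.list(x$ses),
       logL = x$logL, minus2LL = x$minus2LL, K = x$K,
       n_sites = x$n_sites, converged = x$converged,
       boundary_flag = x$boundary_flag,
       condition_number = x$condition_number)
}

#' @export
result_to_list.gof_result <- function(x) {
  list(chi2_obs = x$chi2_obs, boot_stats = as.list(x$boot_stats),
       p_value = x$p_value, c_hat = x$c_hat, nboot = x$nboot,
       n_failed = x$n_failed, unreliable = x$unreliable, seed = x$seed)
}

#' @export
result_to_list.screening_report <- function(x) {
  list(correlations = x$correlations, dropped = x$dropped,
       retained = x$retained, univariate_aicc = as.list(x$univariate_aicc),
       constant = x$constant, threshold = x$threshold)
}

#' @export
result_to_list.rank_table <- function(x) {
  list(table = as.data.frame(x), n_used = attr(x, "n_used"),
       excluded = attr(x, "excluded"))
}

#' @export
result_to_list.default <- function(x) x

#' Write a result object to JSON
#'
#' @param x a fit, rank table, screening report or GoF result.
#' @param path output file.
#' @param meta optional named list merged into the output (seed, version...).
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path, meta = NULL) {
  out <- result_to_list(x)
  if (!is.null(meta)) out <- c(meta, out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[persistLSD] ", fmt), ...))
}

#' Run the full persistence analysis pipeline
#'
#' Chains the four analysis stages over one dataset:
#' \enumerate{
#'   \item Rank the 13 a-priori persistence structures as LSD logistic fits
#'     (detection ignored).
#'   \item Carry the top structures (delta-AICc within `delta_cutoff`,
#'     at most `max_carry` models, null excluded) into the
#'     detection-corrected likelihood, crossed with `p(.)`, `p(Rush)`,
#'     `p(Date)`, `p(Rush+Date)`, and re-rank.
#'   \item Parametric-bootstrap goodness of fit on the global detection
#'     model (the largest carried psi structure with `p(Rush+Date)`).
#'   \item If an alternative score vector is supplied (e.g. occupancy
#'     predictions from an external model), correlate it with the top
#'     model's predicted persistence.
#' }
#' All tables are written as CSV and all result objects as JSON under
#' `out_dir`; every artifact embeds the package version, seed and a config
#' hash.  Timestamps appear only in log messages so outputs are diffable.
#'
#' @param histories a [detection_history].
#' @param bundle a [covariate_bundle].
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed (used by the GoF bootstrap; recorded everywhere).
#' @param nboot GoF bootstrap replicates.
#' @param n_effective effective sample size for AICc (default: sites).
#' @param alt_scores optional numeric vector of external per-site scores.
#' @param delta_cutoff,max_carry stage-1-to-stage-2 carry-over rule.
#' @param verbose log progress to stderr.
#' @return Invisibly, a list with `stage1`, `stage2`, `gof`, `comparison`
#'   and the artifact paths.
#' @export
run_full_analysis <- function(histories, bundle, out_dir, seed = 1,
                              nboot = 1000, n_effective = n_sites(histories),
                              alt_scores = NULL, delta_cutoff = 4,
                              max_carry = 4, verbose = TRUE) {
  stopifnot(inherits(histories, "detection_history"),
            inherits(bundle, "covariate_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(package = "persistLSD",
               version = as.character(utils::packageVersion("persistLSD")),
               seed = seed,
               config_hash = config_hash(list(
                 n = n_sites(histories), K = n_occasions(histories),
                 n_effective = n_effective, nboot = nboot, seed = seed,
                 delta_cutoff = delta_cutoff, max_carry = max_carry)))
  paths <- list()

  stage_fail <- function(stage, e) {
    stopf("pipeline stage '%s' failed: %s (partial artifacts kept in %s)",
          stage, conditionMessage(e), out_dir)
  }

  # Stage 1: LSD ranking of the a-priori persistence structures
  pipeline_log(verbose, "stage 1: LSD ranking of 13 persistence structures")
  stage1 <- tryCatch({
    labels <- suppressWarnings(labels_from_histories(histories))
    specs <- build_candidate_set("persistence")
    fits <- lapply(specs, function(s) {
      tryCatch(suppressWarnings(fit_lsd(labels, bundle, s$psi_terms)),
               error = function(e) NULL)
    })
    fits <- Filter(Negate(is.null), fits)
    rank_models(fits, n_effective)
  }, error = function(e) stage_fail("lsd-rank", e))
  paths$stage1 <- file.path(out_dir, "stage1_lsd_rank.csv")
  write_rank_csv(stage1, paths$stage1)
  write_result_json(stage1, file.path(out_dir, "stage1_lsd_rank.json"), meta)

  # Stage 2: detection-corrected refits of the top structures
  top <- utils::head(stage1[stage1$dAICc <= delta_cutoff &
                              stage1$model != "Null", ], max_carry)
  psi_structures <- lapply(strsplit(top$model, " \\+ "), trimws)
  pipeline_log(verbose, "stage 2: %d psi structures x 4 detection structures",
               length(psi_structures))
  stage2 <- tryCatch({
    specs <- build_candidate_set("detection", psi_structures)
    fits <- lapply(specs, function(s) {
      tryCatch(suppressWarnings(fit_occupancy(histories, bundle, s)),
               error = function(e) NULL)
    })
    fits <- Filter(Negate(is.null), fits)
    rank_models(fits, n_effective)
  }, error = function(e) stage_fail("detection-rank", e))
  paths$stage2 <- file.path(out_dir, "stage2_detection_rank.csv")
  write_rank_csv(stage2, paths$stage2)
  write_result_json(stage2, file.path(out_dir, "stage2_detection_rank.json"),
                    meta)

  # Stage 3: GoF on the global detection model
  sizes <- vapply(psi_structures, length, 0L)
  global_spec <- model_spec(psi_structures[[which.max(sizes)]],
                            c("Rush", "Date"))
  pipeline_log(verbose, "stage 3: GoF bootstrap (%d reps) on %s", nboot,
               global_spec$name)
  gof <- tryCatch({
    gfit <- suppressWarnings(fit_occupancy(histories, bundle, global_spec))
    if (!gfit$converged) {
      warnf("global detection model did not converge; GoF skipped")
      NULL
    } else {
      gof_test(gfit, histories, bundle, nboot = nboot, seed = seed)
    }
  }, error = function(e) stage_fail("gof", e))
  if (!is.null(gof)) {
    paths$gof <- file.path(out_dir, "gof.json")
    write_result_json(gof, paths$gof, meta)
  }

  # Stage 4: comparison against an external score vector
  comparison <- NULL
  top2_name <- stage2$model[1L]
  top2_spec <- Find(function(s) s$name == top2_name,
                    build_candidate_set("detection", psi_structures))
  top_fit <- suppressWarnings(fit_occupancy(histories, bundle, top2_spec))
  if (!is.null(alt_scores)) {
    pipeline_log(verbose, "stage 4: correlating top-model psi with external scores")
    comparison <- tryCatch(
      compare_predictions(predict_psi(top_fit, bundle), alt_scores),
      error = function(e) stage_fail("compare", e))
    paths$comparison <- file.path(out_dir, "comparison.json")
    write_result_json(comparison, paths$comparison, meta)
  }
  write_result_json(top_fit, file.path(out_dir, "top_model_fit.json"), meta)
  write_result_json(meta, file.path(out_dir, "run.json"))

  invisible(list(stage1 = stage1, stage2 = stage2, gof = gof,
                 comparison = comparison, top_fit = top_fit, paths = paths,
                 meta = meta))
}

# Stable short hash of the run configuration (md5 of its canonical JSON).
config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}
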