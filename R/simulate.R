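#' Simulation configuration
#'
#' Describes a synthetic repeat-survey study: covariate distributions, the
#' true persistence and detection coefficient vectors (logit scale), the
#' missing-visit rate and the RNG seed.  The generative model matches the
#' fitted one: `z_i ~ Bern(logistic(x_i' beta))`,
#' `y_ij ~ z_i * Bern(logistic(v_ij' alpha))` on surveyed occasions, with
#' occasions masked missing-completely-at-random.  No false positives.
#'
#' @param n_sites number of sites.
#' @param K number of survey occasions.
#' @param covariates named list; each element is
#'   `list(level = "site"|"occasion", dist = <name>, pars = <numeric>)`
#'   with `dist` one of `"normal" (mu, sd)`, `"uniform" (a, b)`,
#'   `"beta" (a, b)`, `"poisson" (lambda)`, `"bernoulli" (q)`.
#' @param true_beta_psi named numeric: element `"(Intercept)"` plus one
#'   coefficient per site covariate entering psi.
#' @param true_alpha_p named numeric: element `"(Intercept)"` plus one
#'   coefficient per (site or occasion) covariate entering p.
#' @param missing_rate probability an occasion is unsurveyed.
#' @param seed default RNG seed for [simulate_dataset].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_sites, K, covariates = list(),
                       true_beta_psi = c("(Intercept)" = 0),
                       true_alpha_p = c("(Intercept)" = 0),
                       missing_rate = 0, seed = 1) {
  if (n_sites < 1L || K < 1L) stopf("need n_sites >= 1 and K >= 1")
  if (missing_rate < 0 || missing_rate >= 1) {
    stopf("missing_rate must be in [0, 1)")
  }
  dists <- c(normal = 2L, uniform = 2L, beta = 2L, poisson = 1L,
             bernoulli = 1L)
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    if (!cv$level %in% c("site", "occasion")) {
      stopf("covariate '%s': level must be 'site' or 'occasion'", nm)
    }
    if (!cv$dist %in% names(dists)) {
      stopf("covariate '%s': unknown distribution '%s'", nm, cv$dist)
    }
    if (length(cv$pars) != dists[[cv$dist]]) {
      stopf("covariate '%s': %s needs %d parameter(s)", nm, cv$dist,
            dists[[cv$dist]])
    }
    bad <- switch(cv$dist,
      normal = cv$pars[2L] < 0,
      uniform = cv$pars[2L] < cv$pars[1L],
      beta = any(cv$pars <= 0),
      poisson = cv$pars[1L] < 0,
      bernoulli = cv$pars[1L] < 0 || cv$pars[1L] > 1)
    if (bad) stopf("covariate '%s': invalid %s parameters", nm, cv$dist)
  }
  check_coef <- function(co, label, levels_ok) {
    if (!"(Intercept)" %in% names(co)) {
      stopf("%s must contain an '(Intercept)' element", label)
    }
    for (nm in setdiff(names(co), "(Intercept)")) {
      if (!nm %in% names(covariates)) {
        stopf("%s references undeclared covariate '%s'", label, nm)
      }
      if (!covariates[[nm]]$level %in% levels_ok) {
        stopf("%s: covariate '%s' has the wrong level", label, nm)
      }
    }
  }
  check_coef(true_beta_psi, "true_beta_psi", "site")
  check_coef(true_alpha_p, "true_alpha_p", c("site", "occasion"))
  structure(list(n_sites = as.integer(n_sites), K = as.integer(K),
                 covariates = covariates, true_beta_psi = true_beta_psi,
                 true_alpha_p = true_alpha_p, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default lake-survey configuration
#'
#' A 43-site, 3-visit design emulating a boreal/parkland waterbird lake
#' survey: proportion covariates for development, forest and shoreline
#' bulrush (plus buffer bulrush), a fish-species count, shoreline length,
#' and a Julian survey date per visit.  True persistence is about 0.6 and
#' per-visit detection about 0.7, with development and bulrush favouring
#' persistence, forest disfavouring it, and shoreline bulrush reducing
#' detection.  Shore, Fish and RushBuf are drawn but have no true effect.
#'
#' @param n_sites,K,missing_rate,seed overrides of the default design.
#' @return A [sim_config].
#' @export
grebe_sim_config <- function(n_sites = 43, K = 3, missing_rate = 0.1,
                             seed = 1) {
  sim_config(
    n_sites = n_sites, K = K,
    covariates = list(
      Develop = list(level = "site", dist = "beta", pars = c(1, 6)),
      Forest  = list(level = "site", dist = "beta", pars = c(3, 3)),
      Rush    = list(level = "site", dist = "beta", pars = c(1.5, 6)),
      RushBuf = list(level = "site", dist = "beta", pars = c(1.5, 6)),
      Fish    = list(level = "site", dist = "poisson", pars = 6),
      Shore   = list(level = "site", dist = "uniform", pars = c(9, 120)),
      Date    = list(level = "occasion", dist = "uniform", pars = c(140, 235))
    ),
    true_beta_psi = c("(Intercept)" = 0.2, Develop = 2.5, Rush = 3,
                      Forest = -1.5),
    true_alpha_p = c("(Intercept)" = 1.2, Rush = -1.9),
    missing_rate = missing_rate, seed = seed
  )
}

draw_covariate <- function(cv, n) {
  switch(cv$dist,
    normal = rnorm(n, cv$pars[1L], cv$pars[2L]),
    uniform = runif(n, cv$pars[1L], cv$pars[2L]),
    beta = rbeta(n, cv$pars[1L], cv$pars[2L]),
    poisson = as.numeric(rpois(n, cv$pars[1L])),
    bernoulli = as.numeric(rbinom(n, 1L, cv$pars[1L])))
}

#' Simulate a detection-history dataset
#'
#' Draws covariates, latent persistence states and detection histories from
#' a [sim_config], fully reproducibly from the seed.  Conditional on
#' `z_i = 0` every surveyed outcome is 0 (no false positives).
#'
#' @param cfg a [sim_config].
#' @param seed RNG seed; defaults to `cfg$seed`.
#' @return A list with `histories` ([detection_history]), `bundle`
#'   ([covariate_bundle]), `z` (true persistence states) and `config`.
#' @export
simulate_dataset <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_sites; K <- cfg$K
  with_rng_seed(seed, {
    site_covs <- list(); occ_covs <- list()
    for (nm in names(cfg$covariates)) {
      cv <- cfg$covariates[[nm]]
      if (cv$level == "site") {
        site_covs[[nm]] <- draw_covariate(cv, n)
      } else {
        occ_covs[[nm]] <- matrix(draw_covariate(cv, n * K), n, K)
      }
    }
    eta_psi <- rep(cfg$true_beta_psi[["(Intercept)"]], n)
    for (nm in setdiff(names(cfg$true_beta_psi), "(Intercept)")) {
      eta_psi <- eta_psi + cfg$true_beta_psi[[nm]] * site_covs[[nm]]
    }
    z <- rbinom(n, 1L, plogis(eta_psi))
    eta_p <- matrix(cfg$true_alpha_p[["(Intercept)"]], n, K)
    for (nm in setdiff(names(cfg$true_alpha_p), "(Intercept)")) {
      cv <- cfg$covariates[[nm]]
      v <- if (cv$level == "site") matrix(site_covs[[nm]], n, K) else occ_covs[[nm]]
      eta_p <- eta_p + cfg$true_alpha_p[[nm]] * v
    }
    y <- matrix(rbinom(n * K, 1L, plogis(eta_p)), n, K) * z
    if (cfg$missing_rate > 0) {
      y[matrix(runif(n * K) < cfg$missing_rate, n, K)] <- NA_integer_
    }
    ids <- sprintf("lake%02d", seq_len(n))
    list(histories = suppressWarnings(detection_history(y, ids)),
         bundle = covariate_bundle(site_covs, occ_covs, ids),
         z = z, config = cfg)
  })
}

#' Parameter-recovery experiment
#'
#' Repeats simulate-then-fit and summarizes, per true parameter, the mean
#' bias, RMSE and coverage of 95% Wald intervals — the calibration harness
#' for the fitting machinery.  The fitted model structure is exactly the
#' generating one (the covariates with declared true coefficients).
#'
#' @param cfg a [sim_config].
#' @param n_reps number of replicates (>= 2).
#' @param seed seed controlling the per-replicate seeds.
#' @return A data frame with one row per parameter (`param`, `truth`,
#'   `bias`, `rmse`, `coverage`, `n_ok`) and attribute `n_failed`.
#' @export
recovery_experiment <- function(cfg, n_reps, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_reps < 2L) stopf("need n_reps >= 2")
  spec <- model_spec(setdiff(names(cfg$true_beta_psi), "(Intercept)"),
                     setdiff(names(cfg$true_alpha_p), "(Intercept)"))
  truth <- c(setNames(cfg$true_beta_psi,
                      paste0("psi.", names(cfg$true_beta_psi))),
             setNames(cfg$true_alpha_p,
                      paste0("p.", names(cfg$true_alpha_p))))
  seeds <- with_rng_seed(seed, sample.int(.Machine$integer.max, n_reps))
  est <- se <- matrix(NA_real_, n_reps, length(truth),
                      dimnames = list(NULL, names(truth)))
  for (r in seq_len(n_reps)) {
    dat <- simulate_dataset(cfg, seeds[r])
    fit <- tryCatch(
      suppressWarnings(fit_occupancy(dat$histories, dat$bundle, spec)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    v <- c(setNames(fit$beta_psi, paste0("psi.", names(fit$beta_psi))),
           setNames(fit$alpha_p, paste0("p.", names(fit$alpha_p))))
    est[r, names(truth)] <- v[names(truth)]
    se[r, names(truth)] <- fit$ses[names(truth)]
  }
  ok <- !is.na(est[, 1L])
  if (!any(ok)) stopf("all replicates failed to fit")
  out <- data.frame(
    param = names(truth), truth = unname(truth),
    bias = colMeans(est[ok, , drop = FALSE]) - truth,
    rmse = sqrt(colMeans((est[ok, , drop = FALSE] -
                            matrix(truth, sum(ok), length(truth),
                                   byrow = TRUE))^2)),
    coverage = colMeans(abs(est[ok, , drop = FALSE] -
                              matrix(truth, sum(ok), length(truth),
                                     byrow = TRUE)) <=
                          1.96 * se[ok, , drop = FALSE]),
    n_ok = sum(ok), row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_failed") <- sum(!ok)
  out
}
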