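#' Expected detection-history counts under a fitted model
#'
#' Sites are grouped into cohorts by their pattern of surveyed occasions
#' (missingness pattern).  Within a cohort, every possible 0/1 history over
#' the surveyed occasions gets an expected count: the sum over cohort sites
#' of the probability of that history under the fitted `psi_i`, `p_ij`.
#' Expected counts in a cohort sum exactly to the cohort size.
#'
#' @param fit an [fit_occupancy] result.
#' @param h the [detection_history] the fit was made on (or compatible).
#' @param bundle the matching [covariate_bundle].
#' @return A list of cohorts, each with `occasions` (surveyed occasion
#'   indices), `sites` (row indices), `patterns` (history strings),
#'   `observed` and `expected` count vectors.
#' @export
expected_history_counts <- function(fit, h, bundle) {
  stopifnot(inherits(fit, "occupancy_fit"), inherits(h, "detection_history"))
  psi <- predict_psi(fit, bundle)
  p <- predict_p(fit, bundle, K = n_occasions(h))
  obs <- !is.na(h$y)
  keys <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  cohorts <- list()
  for (key in unique(keys)) {
    sites <- which(keys == key)
    S <- which(obs[sites[1L], ])
    m <- length(S)
    if (m == 0L) {
      cohorts[[key]] <- list(occasions = integer(), sites = sites,
                             patterns = "", observed = length(sites),
                             expected = length(sites))
      next
    }
    grid <- as.matrix(expand.grid(rep(list(0:1), m)))[, m:1, drop = FALSE]
    patterns <- apply(grid, 1L, paste, collapse = "")
    expected <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      w <- grid[g, ]
      nondet <- all(w == 0)
      tot <- 0
      for (i in sites) {
        pj <- p[i, S]
        cond <- prod(pj^w * (1 - pj)^(1 - w))
        tot <- tot + psi[i] * cond + (1 - psi[i]) * nondet
      }
      expected[g] <- tot
    }
    ostr <- apply(h$y[sites, S, drop = FALSE], 1L, paste, collapse = "")
    observed <- as.numeric(table(factor(ostr, levels = patterns)))
    cohorts[[key]] <- list(occasions = S, sites = sites, patterns = patterns,
                           observed = observed, expected = expected)
  }
  cohorts
}

#' Pearson chi-square over pooled history cells
#'
#' `sum (O - E)^2 / E` after pooling: cells with expected count below
#' `pool_below` are merged into a single "other" cell, which stabilizes the
#' statistic at the ~40-site scale this model family is used at.
#'
#' @param observed,expected matching count vectors.
#' @param pool_below expected-count threshold below which cells are pooled.
#' @return The chi-square contribution (a nonnegative number).
#' @export
pearson_chi2 <- function(observed, expected, pool_below = 0.5) {
  if (length(observed) != length(expected)) {
    stopf("observed and expected differ in length")
  }
  keep <- expected >= pool_below
  O <- observed[keep]
  E <- expected[keep]
  if (any(!keep)) {
    Ep <- sum(expected[!keep])
    if (Ep > 0) {
      O <- c(O, sum(observed[!keep]))
      E <- c(E, Ep)
    }
  }
  if (!length(E) || all(E == 0)) {
    stopf("degenerate statistic: all cells pooled away")
  }
  sum((O - E)^2 / E)
}

# Observed Pearson statistic of a fit over its detection histories.
gof_statistic <- function(fit, h, bundle, pool_below = 0.5) {
  cohorts <- expected_history_counts(fit, h, bundle)
  tot <- 0
  for (co in cohorts) {
    if (!length(co$occasions)) next  # all-missing cohort: no information
    tot <- tot + pearson_chi2(co$observed, co$expected, pool_below)
  }
  tot
}

#' Parametric-bootstrap goodness of fit (c-hat)
#'
#' MacKenzie–Bailey-style test: the observed Pearson statistic over
#' detection-history frequencies is referred to its distribution under the
#' fitted model, obtained by simulating histories from `psi_hat_i`,
#' `p_hat_ij` (preserving each site's missingness pattern), refitting the
#' same model structure, and recomputing the statistic.  The p-value is the
#' proportion of bootstrap statistics at least as large as the observed
#' one; the overdispersion ratio is `c_hat = chi2_obs / mean(boot)`.
#'
#' Bootstrap refits start from the original estimates for speed and
#' convergence stability; replicates whose refit fails are dropped and
#' counted, with a warning if more than 20% fail.
#'
#' @param fit an [fit_occupancy] result (converged).
#' @param h the fitted [detection_history].
#' @param bundle the matching [covariate_bundle].
#' @param nboot number of bootstrap replicates (>= 100 recommended).
#' @param seed integer RNG seed; the result is bit-reproducible given it.
#' @param pool_below pooling threshold passed to [pearson_chi2].
#' @return An object of class `gof_result`: `chi2_obs`, `boot_stats`
#'   (mean and quantiles), `boot` (the replicate statistics), `p_value`,
#'   `c_hat`, `nboot`, `n_failed`, `unreliable`, `seed`.
#' @export
gof_test <- function(fit, h, bundle, nboot = 1000, seed = 1,
                     pool_below = 0.5) {
  stopifnot(inherits(fit, "occupancy_fit"))
  if (!fit$converged) stopf("goodness of fit requires a converged fit")
  chi2_obs <- gof_statistic(fit, h, bundle, pool_below)
  psi <- predict_psi(fit, bundle)
  p <- predict_p(fit, bundle, K = n_occasions(h))
  obs <- !is.na(h$y)
  n <- n_sites(h); K <- n_occasions(h)
  boot <- rep(NA_real_, nboot)
  with_rng_seed(seed, {
    for (b in seq_len(nboot)) {
      z <- rbinom(n, 1L, psi)
      yb <- matrix(rbinom(n * K, 1L, p), n, K) * z
      yb[!obs] <- NA_integer_
      hb <- suppressWarnings(detection_history(yb, h$site_ids))
      refit <- tryCatch(
        suppressWarnings(fit_occupancy(hb, bundle, fit$spec,
                                       start = fit$par_internal,
                                       restarts = 2L)),
        error = function(e) NULL)
      if (is.null(refit) || !refit$converged) next
      boot[b] <- tryCatch(gof_statistic(refit, hb, bundle, pool_below),
                          error = function(e) NA_real_)
    }
  })
  ok <- !is.na(boot)
  n_failed <- sum(!ok)
  unreliable <- n_failed > 0.2 * nboot
  if (unreliable) {
    warnf("goodness-of-fit bootstrap: %d of %d replicates failed; result unreliable",
          n_failed, nboot)
  }
  if (!any(ok)) stopf("all bootstrap replicates failed")
  bs <- boot[ok]
  structure(list(
    chi2_obs = chi2_obs,
    boot_stats = c(mean = mean(bs),
                   quantile(bs, c(0.05, 0.25, 0.5, 0.75, 0.95))),
    boot = bs,
    p_value = mean(bs >= chi2_obs),
    c_hat = chi2_obs / mean(bs),
    nboot = nboot, n_failed = n_failed, unreliable = unreliable,
    seed = seed
  ), class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("Parametric-bootstrap GoF (%d replicates, %d failed):\n",
              x$nboot, x$n_failed))
  cat(sprintf("  test statistic = %.4g, c-hat = %.3f, P = %.3f%s\n",
              x$chi2_obs, x$c_hat, x$p_value,
              if (x$unreliable) " [UNRELIABLE]" else ""))
  invisible(x)
}
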