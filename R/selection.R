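#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logL + 2K + 2K(K+1)/(n - K - 1)`.  The effective sample size
#' `n` is the number of sites, the dominant convention for single-season
#' occupancy models.
#'
#' @param logL maximized log-likelihood.
#' @param K number of estimated parameters.
#' @param n effective sample size; must exceed `K + 1`.
#' @return The AICc value.
#' @examples
#' aicc(-20, 2, 43)  # 44.3
#' @export
aicc <- function(logL, K, n) {
  if (any(n <= K + 1)) {
    stopf("AICc undefined: need n > K + 1 (got n = %s, K = %s)",
          paste(n, collapse = ","), paste(K, collapse = ","))
  }
  -2 * logL + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

# Uniform view over lsd_fit and occupancy_fit for ranking.
fit_info <- function(fit) UseMethod("fit_info")

#' @export
fit_info.lsd_fit <- function(fit) {
  list(name = fit$name, logL = fit$logL, K = fit$K,
       converged = fit$converged, condition_number = NA_real_)
}

#' @export
fit_info.occupancy_fit <- function(fit) {
  list(name = fit$spec$name, logL = fit$logL, K = fit$K,
       converged = fit$converged, condition_number = fit$condition_number)
}

#' Rank candidate models by AICc
#'
#' Computes AICc, delta-AICc against the best model, the model likelihood
#' `exp(-dAICc/2)` and Akaike weights (model likelihoods normalized over
#' the included candidate set) for a list of fitted models.  Fits that did
#' not converge, or whose Hessian condition number exceeds
#' `max_condition`, are excluded with a logged reason — mirroring the
#' exclusion of ill-behaved covariate structures from a published candidate
#' set rather than letting them distort the weights.
#'
#' Exact AICc ties are broken by smaller `K`, then model name.
#'
#' @param fits list of [fit_lsd] or [fit_occupancy] results.
#' @param n effective sample size (number of sites).
#' @param max_condition Hessian condition-number ceiling for inclusion.
#' @return An object of class `rank_table`: a data frame with columns
#'   `model, K, AICc, dAICc, model_likelihood, weight, minus2LL` sorted by
#'   AICc, with attributes `n_used` and `excluded` (data frame of
#'   model/reason).
#' @export
rank_models <- function(fits, n, max_condition = 1e8) {
  if (!length(fits)) stopf("no fits supplied")
  info <- lapply(fits, fit_info)
  excluded <- data.frame(model = character(), reason = character(),
                         stringsAsFactors = FALSE)
  keep <- logical(length(info))
  for (i in seq_along(info)) {
    f <- info[[i]]
    if (!isTRUE(f$converged)) {
      excluded <- rbind(excluded, data.frame(model = f$name,
                                             reason = "non-convergence",
                                             stringsAsFactors = FALSE))
    } else if (is.finite(f$condition_number) &&
               f$condition_number > max_condition) {
      excluded <- rbind(excluded,
                        data.frame(model = f$name,
                                   reason = sprintf("ill-conditioned (kappa = %.3g)",
                                                    f$condition_number),
                                   stringsAsFactors = FALSE))
    } else {
      keep[i] <- TRUE
    }
  }
  if (!any(keep)) stopf("all candidate models were excluded from ranking")
  if (nrow(excluded)) {
    message(sprintf("rank_models: excluded %d model(s): %s", nrow(excluded),
                    paste(excluded$model, collapse = "; ")))
  }
  info <- info[keep]
  tab <- data.frame(
    model = vapply(info, `[[`, "", "name"),
    K = vapply(info, `[[`, 0L, "K"),
    AICc = vapply(info, function(f) aicc(f$logL, f$K, n), 0),
    minus2LL = vapply(info, function(f) -2 * f$logL, 0),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$AICc, tab$K, tab$model), , drop = FALSE]
  tab$dAICc <- tab$AICc - tab$AICc[1L]
  tab$model_likelihood <- exp(-tab$dAICc / 2)
  tab$weight <- tab$model_likelihood / sum(tab$model_likelihood)
  tab <- tab[, c("model", "K", "AICc", "dAICc", "model_likelihood",
                 "weight", "minus2LL")]
  rownames(tab) <- NULL
  structure(tab, class = c("rank_table", "data.frame"),
            n_used = n, excluded = excluded)
}

#' @export
print.rank_table <- function(x, digits = 3, ...) {
  cat(sprintf("Model ranking (AICc, n = %d):\n", attr(x, "n_used")))
  print.data.frame(x, digits = digits, row.names = TRUE)
  ex <- attr(x, "excluded")
  if (nrow(ex)) {
    cat("Excluded:\n")
    print.data.frame(ex, row.names = FALSE)
  }
  invisible(x)
}

#' Write a rank table to CSV
#'
#' @param tab a [rank_models] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rank_csv <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' A-priori candidate model sets
#'
#' `stage = "persistence"` returns the 13 a-priori persistence structures
#' (lake morphometry, prey, vegetation and development main effects and
#' combinations, a global model, and a null), all with constant detection.
#' The two bulrush covariates are distinct: `Rush` is shoreline bulrush and
#' `RushBuf` bulrush within the 500-m buffer.
#'
#' `stage = "detection"` crosses the supplied psi structures with the four
#' detection structures `p(.)`, `p(Rush)`, `p(Date)` and `p(Rush+Date)`.
#'
#' @param stage `"persistence"` or `"detection"`.
#' @param psi_structures for the detection stage: a list of character
#'   vectors of psi terms (e.g. the top structures of the persistence
#'   stage).
#' @param p_covariates detection covariates used in the crossing.
#' @return A list of [model_spec] objects with unique names.
#' @export
build_candidate_set <- function(stage = c("persistence", "detection"),
                                psi_structures = NULL,
                                p_covariates = c("Rush", "Date")) {
  stage <- match.arg(stage)
  if (stage == "persistence") {
    structures <- list(
      "Shore",
      "Fish",
      c("Shore", "Fish"),
      "Rush",
      "Develop",
      "RushBuf",
      c("Develop", "Forest"),
      c("Shore", "Fish", "Rush"),
      c("Shore", "Fish", "Develop"),
      c("Shore", "Fish", "Forest"),
      c("Rush", "Forest", "Develop"),
      c("Shore", "Fish", "Rush", "Forest", "Develop"),
      character()
    )
    return(lapply(structures, function(s) model_spec(s, character())))
  }
  if (is.null(psi_structures) || !length(psi_structures)) {
    stopf("detection stage needs a list of psi structures")
  }
  p_structures <- list(character(), p_covariates[1L], p_covariates[2L],
                       p_covariates)
  specs <- list()
  for (ps in psi_structures) {
    for (pp in p_structures) {
      specs[[length(specs) + 1L]] <- model_spec(ps, pp)
    }
  }
  names(specs) <- NULL
  nm <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nm)) stopf("duplicate model names in candidate set")
  specs
}

#' Correlate two site-score vectors
#'
#' Pearson correlation with the t-based two-sided p-value on `n - 2`
#' degrees of freedom — used to compare the relative persistence scores of
#' the top model against an external occupancy (or other) prediction over
#' the same sites.
#'
#' @param a,b equal-length numeric vectors (length >= 3, nonzero variance).
#' @return A list with elements `r`, `p_value`, `t`, `df`, `n`.
#' @export
compare_predictions <- function(a, b) {
  if (length(a) != length(b)) stopf("score vectors differ in length")
  if (length(a) < 3L) stopf("need at least 3 paired scores")
  if (any(!is.finite(a)) || any(!is.finite(b))) stopf("scores must be finite")
  if (sd(a) == 0 || sd(b) == 0) stopf("zero variance in a score vector")
  ct <- cor.test(a, b, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       t = unname(ct$statistic), df = unname(ct$parameter), n = length(a))
}
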