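#' Prepare covariates: natural-log transform
#'
#' Skewed non-negative covariates (proportions, counts) are log-transformed
#' toward approximate normality before modelling.  Because zeros occur (e.g.
#' lakes with no development), each listed covariate `x` is replaced by
#' `log(x + c)` where `c` is half the smallest positive observed value of
#' `x`, or 1 if `x` is identically zero.  The offset is recorded in the
#' bundle's `log_offsets` attribute so the transform is invertible.
#'
#' @param bundle a [covariate_bundle].
#' @param log_transform character names of site-level covariates to transform.
#' @return The bundle with listed covariates replaced; attribute
#'   `log_offsets` maps each transformed name to its offset `c`.
#' @export
prepare_covariates <- function(bundle, log_transform = character()) {
  offsets <- attr(bundle, "log_offsets") %||% numeric()
  for (nm in log_transform) {
    v <- get_covariate(bundle, nm, level = "site")$value
    if (any(v < 0, na.rm = TRUE)) {
      stopf("covariate '%s' has negative values; log transform undefined", nm)
    }
    pos <- v[!is.na(v) & v > 0]
    c0 <- if (length(pos)) min(pos) / 2 else 1
    bundle$site_covs[[nm]] <- log(v + c0)
    offsets[[nm]] <- c0
  }
  attr(bundle, "log_offsets") <- offsets
  bundle
}

#' Invert a recorded log transform
#'
#' @param bundle a bundle produced by [prepare_covariates].
#' @param name a transformed covariate name.
#' @return The covariate on its original scale.
#' @export
unprepare_covariate <- function(bundle, name) {
  offsets <- attr(bundle, "log_offsets")
  if (is.null(offsets) || !(name %in% names(offsets))) {
    stopf("no recorded log transform for '%s'", name)
  }
  exp(bundle$site_covs[[name]]) - offsets[[name]]
}

#' Collinearity screening with univariate tie-breaking
#'
#' Computes Pearson correlations over all candidate site covariates.  For
#' each pair with `|r|` strictly greater than `threshold`, the member with
#' the weaker single-covariate predictive ability — the higher AICc of the
#' one-covariate logistic persistence fit — is dropped.  Dropping is greedy
#' from the largest `|r|` down; a pair is skipped if either member was
#' already dropped.  Pairs with `|r|` exactly at the threshold keep both
#' members (strict inequality).  Ties in AICc are broken alphabetically
#' (the alphabetically first name is kept).
#'
#' @param bundle a [covariate_bundle].
#' @param candidates character names of site-level candidate covariates.
#' @param labels a [persistence_labels] used for the univariate fits.
#' @param threshold correlation magnitude above which a pair is collinear.
#' @return An object of class `screening_report`: the correlation matrix,
#'   a data frame of `(dropped, kept, abs_r)`, the retained covariate list,
#'   per-candidate univariate AICc scores, and any constant covariates that
#'   were flagged and excluded from the correlation screen.
#' @export
screen_collinearity <- function(bundle, candidates, labels, threshold = 0.65) {
  if (length(candidates) < 2L) stopf("need >= 2 candidate covariates")
  x <- sapply(candidates, function(nm) get_covariate(bundle, nm, "site")$value)
  sds <- apply(x, 2L, sd)
  constant <- candidates[sds == 0]
  if (length(constant)) {
    warnf("constant covariate(s) excluded from correlation screen: %s",
          paste(constant, collapse = ", "))
  }
  active <- setdiff(candidates, constant)
  n <- length(labels$z)
  uni <- vapply(candidates, function(nm) {
    if (nm %in% constant) return(NA_real_)
    f <- fit_lsd(labels, bundle, nm)
    aicc(f$logL, f$K, n)
  }, numeric(1))

  C <- cor(x[, active, drop = FALSE])
  pairs <- which(upper.tri(C) & abs(C) > threshold, arr.ind = TRUE)
  ord <- order(-abs(C[pairs]),
               rownames(C)[pairs[, 1L]], colnames(C)[pairs[, 2L]])
  pairs <- pairs[ord, , drop = FALSE]

  retained <- candidates
  dropped <- data.frame(dropped = character(), kept = character(),
                        abs_r = numeric(), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(pairs))) {
    a <- rownames(C)[pairs[k, 1L]]
    b <- colnames(C)[pairs[k, 2L]]
    if (!(a %in% retained) || !(b %in% retained)) next
    # lower AICc (or alphabetically first on an exact tie) is kept
    keep <- if (uni[[a]] < uni[[b]] ||
                (uni[[a]] == uni[[b]] && a < b)) a else b
    drop <- if (keep == a) b else a
    retained <- setdiff(retained, drop)
    dropped <- rbind(dropped, data.frame(dropped = drop, kept = keep,
                                         abs_r = abs(C[a, b]),
                                         stringsAsFactors = FALSE))
  }
  structure(list(correlations = C, dropped = dropped, retained = retained,
                 univariate_aicc = uni, constant = constant,
                 threshold = threshold),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Collinearity screen (|r| > %.2f): %d candidate(s), %d dropped\n",
              x$threshold, length(x$univariate_aicc), nrow(x$dropped)))
  if (nrow(x$dropped)) print(x$dropped)
  cat("Retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Fit the latent-selection-difference (LSD) model
#'
#' Logistic regression of the persisted/extirpated site labels on site
#' covariates.  The LSD contrasts two sets of already-selected resource
#' units, so only the coefficients are interpretable — the fitted intercept
#' calibrates the contrast to the sample and is excluded from [lsd_score],
#' which is a relative, not absolute, persistence measure.
#'
#' A fit where any `|coefficient|` exceeds 15 on the logit scale is flagged
#' as (quasi-)separated: odds ratios beyond `e^15` are numerically
#' indistinguishable from infinity at this scale of data.
#'
#' @param labels a [persistence_labels].
#' @param bundle a [covariate_bundle] with the site covariates.
#' @param terms character names of site covariates (empty = null model).
#' @param name model label; defaults to the terms joined by `" + "`, or
#'   `"Null"`.
#' @return An object of class `lsd_fit`: `intercept`, `betas`, `ses`,
#'   `se_intercept`, `logL`, `K` (number of estimated parameters including
#'   the intercept), `n_used`, `converged`, `separation_flag`.
#' @export
fit_lsd <- function(labels, bundle, terms = character(), name = NULL) {
  z <- labels$z
  if (length(unique(z)) < 2L) {
    stopf("persistence labels are all %d: no contrast to estimate", z[1L])
  }
  terms <- as.character(terms)
  dat <- data.frame(.z = z)
  for (t in terms) dat[[t]] <- get_covariate(bundle, t, "site")$value
  fit <- suppressWarnings(glm(.z ~ ., data = dat, family = binomial()))
  co <- coef(fit)
  se <- suppressWarnings(sqrt(diag(vcov(fit))))
  # the intercept is excluded: its magnitude tracks covariate location
  separation <- any(abs(co[-1L]) > 15) || !fit$converged
  if (separation) {
    warnf("possible (quasi-)separation in LSD fit '%s': |beta| > 15 or glm non-convergence",
          name %||% paste(terms, collapse = " + "))
  }
  if (is.null(name)) {
    name <- if (length(terms)) paste(terms, collapse = " + ") else "Null"
  }
  structure(list(
    name = name, terms = terms,
    intercept = unname(co[1L]), se_intercept = unname(se[1L]),
    betas = co[-1L], ses = se[-1L],
    logL = as.numeric(logLik(fit)), K = length(co),
    n_used = length(z),
    converged = fit$converged && !separation,
    separation_flag = separation
  ), class = "lsd_fit")
}

#' @export
print.lsd_fit <- function(x, ...) {
  cat(sprintf("LSD fit '%s': logL = %.3f, K = %d, n = %d%s\n", x$name, x$logL,
              x$K, x$n_used, if (x$separation_flag) " [separation]" else ""))
  if (length(x$betas)) {
    print(data.frame(estimate = x$betas, se = x$ses))
  }
  invisible(x)
}

#' Relative persistence score from an LSD fit
#'
#' The exponential form of the latent selection difference:
#' `w(x) = exp(sum_k beta_k x_k)`, with the intercept excluded.  Scores are
#' proportional to — not equal to — persistence probability; only ratios
#' between sites are meaningful.
#'
#' @param fit an [fit_lsd] result.
#' @param x a named numeric vector (one site), a data frame, or a
#'   [covariate_bundle]; must supply every term in the fit.
#' @return Numeric vector of positive scores.
#' @export
lsd_score <- function(fit, x) {
  stopifnot(inherits(fit, "lsd_fit"))
  terms <- fit$terms
  if (!length(terms)) {
    nsite <- if (inherits(x, "covariate_bundle")) length(x$site_ids)
             else if (is.data.frame(x)) nrow(x) else 1L
    return(rep(1, nsite))
  }
  if (inherits(x, "covariate_bundle")) {
    m <- sapply(terms, function(t) get_covariate(x, t, "site")$value)
  } else if (is.data.frame(x) || is.matrix(x)) {
    miss <- setdiff(terms, colnames(x))
    if (length(miss)) stopf("missing term value(s): %s", paste(miss, collapse = ", "))
    m <- as.matrix(x[, terms, drop = FALSE])
  } else {
    miss <- setdiff(terms, names(x))
    if (length(miss)) stopf("missing term value(s): %s", paste(miss, collapse = ", "))
    m <- matrix(x[terms], nrow = 1L, dimnames = list(NULL, terms))
  }
  beta <- fit$betas[paste0(terms)]
  # glm names coefficients exactly after the data columns
  names(beta) <- terms
  as.numeric(exp(m %*% beta))
}
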