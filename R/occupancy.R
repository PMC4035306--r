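#' Single-site likelihood of a detection history
#'
#' The single-season occupancy likelihood of one site's history given its
#' persistence probability `psi` and per-occasion detection probabilities
#' `p`:
#' \deqn{L = \psi \prod_{j \in surveyed} p_j^{y_j} (1-p_j)^{1-y_j}
#'       + (1-\psi)\,I[\text{no detection among surveyed occasions}]}
#' Unsurveyed (missing) occasions contribute a factor 1; an all-missing
#' history has likelihood 1 for any parameters.  There are no false
#' positives: a detection is only possible at an occupied site.
#'
#' @param psi persistence (occupancy) probability in `[0, 1]`.
#' @param p numeric vector of `K` detection probabilities in `[0, 1]`.
#' @param history integer vector of `K` entries in `{0, 1, NA}`.
#' @return The likelihood, a value in `[0, 1]`.  Zero is possible (e.g. a
#'   detection with `psi = 0`); callers taking logs must guard it.
#' @examples
#' site_likelihood(0.5, rep(0.5, 3), c(1, 0, 0))  # 0.0625
#' @export
site_likelihood <- function(psi, p, history) {
  stopifnot(length(p) == length(history),
            psi >= 0, psi <= 1, all(p >= 0 & p <= 1))
  obs <- !is.na(history)
  if (!any(obs)) return(1)
  y <- history[obs]
  pj <- p[obs]
  cond <- prod(pj^y * (1 - pj)^(1 - y))
  psi * cond + (1 - psi) * as.numeric(all(y == 0))
}

# Build the psi design matrix (n x (1 + #terms)) and the list of p design
# matrices (each n x K).  Occasion-level p covariates are standardized
# (mean 0, sd 1 over surveyed cells) for optimizer stability; the scaling is
# returned so coefficients can be reported on the raw scale too.
build_designs <- function(h, bundle, spec) {
  n <- n_sites(h); K <- n_occasions(h)
  obs <- !is.na(h$y)
  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  for (t in spec$psi_terms) {
    v <- get_covariate(bundle, t, level = "site")$value
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- t
  }
  V <- list()
  scaling <- data.frame(term = character(), mu = numeric(), sd = numeric(),
                        stringsAsFactors = FALSE)
  for (t in spec$p_terms) {
    cv <- get_covariate(bundle, t)
    if (cv$level == "site") {
      m <- matrix(cv$value, n, K)
    } else {
      m <- cv$value
      mu <- mean(m[obs]); s <- sd(m[obs])
      if (!is.finite(s) || s == 0) s <- 1
      m <- (m - mu) / s
      scaling <- rbind(scaling, data.frame(term = t, mu = mu, sd = s,
                                           stringsAsFactors = FALSE))
    }
    m[!obs] <- 0  # unused cells; zeroed so NA covariates there are harmless
    V[[t]] <- m
  }
  list(X = X, V = V, scaling = scaling)
}

# Negative log-likelihood factory over the stacked parameter vector
# c(beta_psi, alpha_p) (alpha on the standardized scale).
make_nll <- function(h, designs) {
  y <- h$y
  obs <- !is.na(y)
  y0 <- y; y0[!obs] <- 0L
  nondet <- as.numeric(rowSums(y0) == 0L)
  X <- designs$X
  V <- designs$V
  ppsi <- ncol(X)
  np <- 1L + length(V)
  n <- nrow(y); K <- ncol(y)
  obs_num <- obs * 1
  function(par) {
    bpsi <- par[seq_len(ppsi)]
    ap <- par[ppsi + seq_len(np)]
    psi <- clamp_prob(plogis(drop(X %*% bpsi)))
    eta <- matrix(ap[1L], n, K)
    for (i in seq_along(V)) eta <- eta + ap[1L + i] * V[[i]]
    p <- clamp_prob(plogis(eta))
    logf <- obs_num * (y0 * log(p) + (1 - y0) * log1p(-p))
    cond <- exp(rowSums(logf))
    lik <- psi * cond + (1 - psi) * nondet
    -sum(log(pmax(lik, 1e-300)))
  }
}

#' Fit the persistence model with imperfect detection
#'
#' Maximum-likelihood fit of the single-season occupancy likelihood over
#' detection histories with missing occasions: `psi_i = logistic(x_i' beta)`
#' from site covariates, `p_ij = logistic(v_ij' alpha)` from site- or
#' occasion-level covariates.  Estimation is quasi-Newton (BFGS) from a zero
#' start with up to `restarts` seeded jittered restarts on non-convergence;
#' standard errors come from the inverse observed-information matrix.
#'
#' Occasion-level detection covariates are standardized internally; the
#' returned `alpha_p` is on the raw covariate scale (with matching SEs) and
#' `alpha_p_std` on the standardized scale actually optimized.
#'
#' A fit is flagged `boundary_flag` when any fitted `psi_i` or surveyed
#' `p_ij` pins within `1e-6` of 0 or 1, and the Hessian's condition number
#' is reported so callers can screen ill-behaved models the way shoreline
#' covariates were screened out of the published candidate set of this
#' model family ("non-convergence and overdispersion").
#'
#' @param h a [detection_history].
#' @param bundle a [covariate_bundle].
#' @param spec a [model_spec]; occasion-level terms may enter `p` only.
#' @param p_fixed if `1`, detection is assumed perfect and the fit reduces
#'   to a logistic regression of the naive persistence labels (profile
#'   identity: the intercept-only `psi` estimate then equals
#'   [naive_estimate] exactly).  Default `NULL` (estimate detection).
#' @param start optional start values on the internal (standardized) scale.
#' @param restarts maximum jittered restarts after a failed optimization.
#' @return An object of class `occupancy_fit`; see Details.
#' @export
fit_occupancy <- function(h, bundle, spec, p_fixed = NULL, start = NULL,
                          restarts = 5L) {
  stopifnot(inherits(h, "detection_history"), inherits(spec, "model_spec"))
  n <- n_sites(h); K <- n_occasions(h)
  validate_spec_against(spec, bundle, h)
  for (t in spec$psi_terms) {
    if (!(t %in% names(bundle$site_covs))) {
      stopf("psi term '%s' must be a site-level covariate", t)
    }
  }
  if (!is.null(p_fixed)) {
    if (!identical(as.numeric(p_fixed), 1)) {
      stopf("p_fixed currently supports only the perfect-detection value 1")
    }
    return(fit_perfect_detection(h, bundle, spec))
  }
  if (K == 1L && !length(spec$psi_terms) && !length(spec$p_terms)) {
    stopf("psi and p are confounded with a single occasion and no covariates")
  }

  designs <- build_designs(h, bundle, spec)
  nll <- make_nll(h, designs)
  ppsi <- ncol(designs$X)
  np <- 1L + length(designs$V)
  npar <- ppsi + np

  par0 <- start %||% rep(0, npar)
  best <- NULL
  for (attempt in 0:restarts) {
    p_try <- if (attempt == 0L) par0 else {
      with_rng_seed(76210 + attempt, par0 + rnorm(npar, 0, 0.5))
    }
    res <- tryCatch(
      optim(p_try, nll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
    if (res$convergence == 0) { best <- if (res$value <= best$value) res else best; break }
  }
  if (is.null(best)) {
    best <- list(par = par0, value = nll(par0), convergence = 99L)
  }
  par <- best$par
  converged <- best$convergence == 0

  hess <- tryCatch(optimHess(par, nll), error = function(e) NULL)
  vcov_std <- if (!is.null(hess)) {
    tryCatch(solve(hess), error = function(e) NULL)
  } else NULL
  cond <- if (!is.null(hess)) tryCatch(kappa(hess, exact = TRUE),
                                       error = function(e) Inf) else Inf
  if (!is.null(vcov_std) && any(!is.finite(vcov_std) | diag(vcov_std) < 0)) {
    vcov_std <- NULL
  }

  # map standardized-scale parameters to the raw covariate scale
  L <- diag(npar)
  if (nrow(designs$scaling)) {
    for (r in seq_len(nrow(designs$scaling))) {
      t <- designs$scaling$term[r]
      j <- ppsi + 1L + match(t, names(designs$V))
      L[ppsi + 1L, j] <- -designs$scaling$mu[r] / designs$scaling$sd[r]
      L[j, j] <- 1 / designs$scaling$sd[r]
    }
  }
  par_raw <- drop(L %*% par)
  vcov_raw <- if (!is.null(vcov_std)) L %*% vcov_std %*% t(L) else NULL
  ses <- if (!is.null(vcov_raw)) sqrt(pmax(diag(vcov_raw), 0)) else rep(NA_real_, npar)

  pnames <- c(paste0("psi.", colnames(designs$X)),
              paste0("p.", c("(Intercept)", names(designs$V))))
  names(par_raw) <- pnames
  names(ses) <- pnames
  if (!is.null(vcov_raw)) dimnames(vcov_raw) <- list(pnames, pnames)

  beta_psi <- setNames(par_raw[seq_len(ppsi)], colnames(designs$X))
  alpha_p <- setNames(par_raw[ppsi + seq_len(np)],
                      c("(Intercept)", names(designs$V)))
  alpha_p_std <- setNames(par[ppsi + seq_len(np)],
                          c("(Intercept)", names(designs$V)))

  psi_hat <- plogis(drop(designs$X %*% par[seq_len(ppsi)]))
  eta <- matrix(par[ppsi + 1L], n, K)
  for (i in seq_along(designs$V)) eta <- eta + par[ppsi + 1L + i] * designs$V[[i]]
  p_hat <- plogis(eta)
  obs <- !is.na(h$y)
  boundary <- any(psi_hat < 1e-6 | psi_hat > 1 - 1e-6) ||
    (any(obs) && any(p_hat[obs] < 1e-6 | p_hat[obs] > 1 - 1e-6))

  structure(list(
    spec = spec, n_sites = n, K_occasions = K,
    beta_psi = beta_psi, alpha_p = alpha_p, alpha_p_std = alpha_p_std,
    scaling = designs$scaling,
    logL = -best$value, minus2LL = 2 * best$value,
    K = npar, vcov = vcov_raw, ses = ses,
    converged = converged && !is.null(vcov_raw),
    boundary_flag = boundary, condition_number = cond,
    par_internal = par,
    psi_hat = psi_hat, p_hat = p_hat
  ), class = "occupancy_fit")
}

# Perfect-detection reduction: the likelihood factorizes so the MLE of the
# psi structure is the logistic regression of the naive labels.
fit_perfect_detection <- function(h, bundle, spec) {
  z <- as.integer(rowSums(h$y == 1, na.rm = TRUE) > 0)
  n <- n_sites(h)
  if (length(spec$psi_terms)) {
    dat <- data.frame(.z = z)
    for (t in spec$psi_terms) dat[[t]] <- get_covariate(bundle, t, "site")$value
    g <- suppressWarnings(glm(.z ~ ., data = dat, family = binomial()))
    beta <- setNames(coef(g), c("(Intercept)", spec$psi_terms))
    logL <- as.numeric(logLik(g))
    psi_hat <- unname(g$fitted.values)
    ses <- setNames(sqrt(diag(vcov(g))), names(beta))
    converged <- g$converged
  } else {
    zbar <- mean(z)
    beta <- c("(Intercept)" = qlogis(clamp_prob(zbar)))
    logL <- if (zbar %in% c(0, 1)) 0 else
      sum(z) * log(zbar) + sum(1 - z) * log(1 - zbar)
    psi_hat <- rep(zbar, n)
    ses <- c("(Intercept)" = sqrt(1 / max(n * zbar * (1 - zbar), .Machine$double.eps)))
    converged <- TRUE
  }
  structure(list(
    spec = spec, n_sites = n, K_occasions = n_occasions(h),
    beta_psi = beta,
    alpha_p = c("(Intercept)" = Inf), alpha_p_std = c("(Intercept)" = Inf),
    scaling = data.frame(term = character(), mu = numeric(), sd = numeric()),
    logL = logL, minus2LL = -2 * logL,
    K = length(beta), vcov = NULL,
    ses = setNames(c(ses, NA_real_), c(paste0("psi.", names(beta)), "p.(Intercept)")),
    converged = converged, boundary_flag = TRUE,
    condition_number = NA_real_, par_internal = unname(beta),
    psi_hat = psi_hat,
    p_hat = matrix(1, n, n_occasions(h))
  ), class = "occupancy_fit")
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat(sprintf("Occupancy/persistence fit: %s\n", x$spec$name))
  cat(sprintf("  n = %d sites, K = %d params, logL = %.4f (-2LL = %.4f)%s%s\n",
              x$n_sites, x$K, x$logL, x$minus2LL,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$boundary_flag) " [boundary]" else ""))
  est <- c(x$beta_psi, x$alpha_p)
  nm <- c(paste0("psi.", names(x$beta_psi)), paste0("p.", names(x$alpha_p)))
  print(data.frame(estimate = est, se = x$ses[nm], row.names = nm))
  invisible(x)
}

#' Predicted persistence probabilities
#'
#' Per-site `psi` on the probability scale from a fitted model and a
#' covariate bundle (which may be new sites).
#'
#' @param fit an [fit_occupancy] result.
#' @param bundle a [covariate_bundle] supplying every psi term.
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
predict_psi <- function(fit, bundle) {
  stopifnot(inherits(fit, "occupancy_fit"))
  n <- length(bundle$site_ids)
  eta <- rep(fit$beta_psi[["(Intercept)"]], n)
  for (t in fit$spec$psi_terms) {
    eta <- eta + fit$beta_psi[[t]] * get_covariate(bundle, t, "site")$value
  }
  plogis(eta)
}

#' Predicted detection probabilities
#'
#' Per-(site, occasion) `p` on the probability scale, using the raw-scale
#' detection coefficients.
#'
#' @inheritParams predict_psi
#' @param K number of occasions (defaults to the fitted table's).
#' @return An `n x K` matrix of probabilities.
#' @export
predict_p <- function(fit, bundle, K = fit$K_occasions) {
  stopifnot(inherits(fit, "occupancy_fit"))
  n <- length(bundle$site_ids)
  if (is.infinite(fit$alpha_p[["(Intercept)"]])) return(matrix(1, n, K))
  eta <- matrix(fit$alpha_p[["(Intercept)"]], n, K)
  for (t in fit$spec$p_terms) {
    cv <- get_covariate(bundle, t)
    m <- if (cv$level == "site") matrix(cv$value, n, K) else cv$value
    eta <- eta + fit$alpha_p[[t]] * m
  }
  plogis(eta)
}

#' Naive persistence estimate
#'
#' The fraction of sites with at least one detection — the uncorrected
#' estimate that coincides with the detection-corrected one only when
#' detection is perfect.
#'
#' @param h a [detection_history].
#' @return A proportion in `[0, 1]`.
#' @examples
#' # 27 detected among 43 sites -> 0.6279 (prints as 63%)
#' @export
naive_estimate <- function(h) {
  stopifnot(inherits(h, "detection_history"))
  mean(rowSums(h$y == 1, na.rm = TRUE) > 0)
}
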