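# Shared fixture builders and independent oracles for the test suite.

# Detection history from a plain matrix without rownames ceremony.
make_history <- function(...) {
  suppressWarnings(detection_history(rbind(...)))
}

# Write a temporary CSV and return its path (cleaned up by the caller's
# test env via withr-free tempfile semantics — files live in tempdir()).
write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# Independent brute-force oracle for the intercept-only detection model:
# dense 2-D grid search over (psi, p) on the probability scale.  Relies only
# on the sufficient statistics (detections d_i, surveyed occasions K_i).
grid_occupancy_oracle <- function(h, step = 0.001) {
  d <- rowSums(h$y == 1, na.rm = TRUE)
  K <- rowSums(!is.na(h$y))
  keep <- K > 0
  counts <- table(d[keep], K[keep])
  psi <- seq(step, 1 - step, by = step)
  p <- seq(step, 1 - step, by = step)
  ll <- matrix(0, length(psi), length(p))
  for (ds in rownames(counts)) {
    for (Ks in colnames(counts)) {
      m <- counts[ds, Ks]
      if (m == 0) next
      di <- as.numeric(ds); Ki <- as.numeric(Ks)
      cond <- outer(psi, p^di * (1 - p)^(Ki - di))
      lik <- cond + if (di == 0) outer(1 - psi, rep(1, length(p))) else 0
      ll <- ll + m * log(lik)
    }
  }
  idx <- which(ll == max(ll), arr.ind = TRUE)[1L, ]
  c(psi = psi[idx[1L]], p = p[idx[2L]])
}

# Independent coarse-then-fine grid maximizer of the Bernoulli logistic
# log-likelihood with one covariate (intercept + slope), used to check
# fit_lsd without going through glm.
grid_lsd_oracle <- function(z, x, lim = 10, fine = 0.01) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(z * eta - log1p(exp(eta)))
  }
  search <- function(b0s, b1s) {
    best <- c(NA, NA, -Inf)
    for (b0 in b0s) for (b1 in b1s) {
      v <- ll(b0, b1)
      if (v > best[3L]) best <- c(b0, b1, v)
    }
    best
  }
  coarse <- search(seq(-lim, lim, by = 0.1), seq(-lim, lim, by = 0.1))
  fine_res <- search(seq(coarse[1L] - 0.1, coarse[1L] + 0.1, by = fine),
                     seq(coarse[2L] - 0.1, coarse[2L] + 0.1, by = fine))
  c(intercept = fine_res[1L], beta = fine_res[2L])
}

# Intercept-only occupancy_fit test double with known psi and p, for
# exercising expected_history_counts / predict_* without an optimizer run.
fake_intercept_fit <- function(psi, p, K) {
  structure(list(
    spec = model_spec(), n_sites = NA_integer_, K_occasions = K,
    beta_psi = c("(Intercept)" = qlogis(psi)),
    alpha_p = c("(Intercept)" = qlogis(p)),
    alpha_p_std = c("(Intercept)" = qlogis(p)),
    scaling = data.frame(term = character(), mu = numeric(), sd = numeric()),
    logL = NA_real_, minus2LL = NA_real_, K = 2L, vcov = NULL,
    ses = NULL, converged = TRUE, boundary_flag = FALSE,
    condition_number = 1, par_internal = c(qlogis(psi), qlogis(p)),
    psi_hat = NULL, p_hat = NULL), class = "occupancy_fit")
}

# A reproducible 40-site, 3-occasion intercept-only dataset used by the
# grid-oracle equivalence checks.
oracle_fixture <- function(seed = 42, n = 40) {
  cfg <- sim_config(n, 3,
                    true_beta_psi = c("(Intercept)" = qlogis(0.6)),
                    true_alpha_p = c("(Intercept)" = qlogis(0.7)),
                    seed = seed)
  simulate_dataset(cfg)
}
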