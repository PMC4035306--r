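# Shared 10-site covariate fixture with |r|(A,B) = 0.90, |r|(B,C) = 0.70,
# |r|(A,C) = 0.45 (constructed by exact rotation, values frozen).
screen_fixture <- function(z) {
  ids <- paste0("s", 1:10)
  b <- covariate_bundle(list(
    A = c(-1.59, 2.54, 1.95, 1.61, 2.27, 2.24, 0.24, 1.26, 0.94, -1.47),
    B = c(-1.60, 1.51, 1.12, 1.96, 1.72, 2.57, 1.19, 1.96, 1.42, -1.86),
    C = c(-1.19, 0.51, -0.28, 3.49, 0.23, 2.23, 1.01, 1.57, 2.78, -0.34)),
    site_ids = ids)
  lab <- structure(list(site_ids = ids, z = z,
                        all_missing = rep(FALSE, 10)),
                   class = "persistence_labels")
  list(bundle = b, labels = lab)
}

test_that("log transform uses half the minimum positive value as offset", {
  ids <- c("a", "b", "c")
  b <- covariate_bundle(list(x = c(1, exp(1) - 0.5, exp(2) - 0.5),
                             zero = c(0, 0, 0)), site_ids = ids)
  out <- prepare_covariates(b, "x")
  expect_equal(unname(out$site_covs$x), c(log(1.5), 1, 2))
  expect_equal(attr(out, "log_offsets")[["x"]], 0.5)

  out0 <- prepare_covariates(b, "zero")
  expect_equal(unname(out0$site_covs$zero), c(0, 0, 0))  # ln(0 + 1)

  # recorded offset makes the transform invertible
  b2 <- covariate_bundle(list(x = c(0.2, 3, 11)), site_ids = ids)
  tr <- prepare_covariates(b2, "x")
  expect_equal(unname(unprepare_covariate(tr, "x")), c(0.2, 3, 11))

  bneg <- covariate_bundle(list(x = c(-1, 2, 3)), site_ids = ids)
  expect_error(prepare_covariates(bneg, "x"), "negative")
})

test_that("collinearity screen applies the greedy largest-|r|-first rule", {
  # Case 1: A predicts best; (A,B) fires first and removes B, so the (B,C)
  # pair is moot and C survives.
  fx <- screen_fixture(c(0L, 1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L, 0L))
  rep1 <- screen_collinearity(fx$bundle, c("A", "B", "C"), fx$labels)
  expect_true(abs(rep1$correlations["A", "B"]) > 0.65)
  expect_true(abs(rep1$correlations["B", "C"]) > 0.65)
  expect_true(abs(rep1$correlations["A", "C"]) < 0.65)
  expect_true(rep1$univariate_aicc[["A"]] < rep1$univariate_aicc[["B"]])
  expect_equal(rep1$retained, c("A", "C"))
  expect_equal(rep1$dropped$dropped, "B")
  expect_equal(rep1$dropped$kept, "A")

  # Case 2: B predicts best; the cascade continues and drops both A and C.
  fx2 <- screen_fixture(c(0L, 0L, 1L, 0L, 1L, 1L, 1L, 1L, 0L, 0L))
  rep2 <- screen_collinearity(fx2$bundle, c("A", "B", "C"), fx2$labels)
  expect_true(rep2$univariate_aicc[["B"]] < rep2$univariate_aicc[["A"]])
  expect_equal(rep2$retained, "B")
  expect_equal(rep2$dropped$dropped, c("A", "C"))

  # orthogonal pair: both retained; exactly-at-threshold pairs also keep both
  expect_false("C" %in% rep1$dropped$dropped)
})

test_that("exactly proportional covariates keep the better univariate one", {
  fx <- screen_fixture(c(0L, 1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L, 0L))
  b <- fx$bundle
  b$site_covs$A2 <- 2 * b$site_covs$A + 1  # r = 1 with A
  rep <- screen_collinearity(b, c("A", "A2"), fx$labels)
  # identical discrimination => AICc tie => alphabetical keep
  expect_equal(rep$retained, "A")
  expect_equal(rep$dropped$dropped, "A2")
  expect_equal(rep$dropped$abs_r, 1)
})

test_that("constant covariates are flagged and excluded from the screen", {
  fx <- screen_fixture(c(0L, 1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L, 0L))
  b <- fx$bundle
  b$site_covs$const <- rep(2, 10)
  expect_warning(rep <- screen_collinearity(b, c("A", "B", "const"),
                                            fx$labels),
                 "constant")
  expect_true("const" %in% rep$constant)
  expect_true(is.na(rep$univariate_aicc[["const"]]))
})

test_that("fit_lsd matches the closed-form 2x2 log odds ratio", {
  # persisted 8/10 when x = 1, 2/10 when x = 0 => beta = ln(8*8/(2*2))
  z <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  x <- c(rep(1, 10), rep(0, 10))
  ids <- paste0("s", 1:20)
  b <- covariate_bundle(list(x = x), site_ids = ids)
  lab <- structure(list(site_ids = ids, z = z, all_missing = rep(FALSE, 20)),
                   class = "persistence_labels")
  fit <- fit_lsd(lab, b, "x")
  expect_equal(unname(fit$betas[["x"]]), log(16), tolerance = 1e-5)
  expect_true(fit$converged)
  expect_lt(fit$logL, 0)
})

test_that("fit_lsd agrees with an independent grid search of the likelihood", {
  fx <- screen_fixture(c(0L, 1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L, 0L))
  # 20-site fixture: duplicate the 10 sites for a better-conditioned surface
  z <- rep(fx$labels$z, 2)
  x <- rep(fx$bundle$site_covs$A, 2)
  ids <- paste0("s", 1:20)
  b <- covariate_bundle(list(A = unname(x)), site_ids = ids)
  lab <- structure(list(site_ids = ids, z = z, all_missing = rep(FALSE, 20)),
                   class = "persistence_labels")
  fit <- fit_lsd(lab, b, "A")
  oracle <- grid_lsd_oracle(z, unname(x))
  expect_equal(unname(fit$intercept), unname(oracle[["intercept"]]),
               tolerance = 0.02)
  expect_equal(unname(fit$betas[["A"]]), unname(oracle[["beta"]]),
               tolerance = 0.02)
})

test_that("degenerate label sets are rejected and separation is flagged", {
  ids <- paste0("s", 1:4)
  b <- covariate_bundle(list(x = c(1, 2, 3, 4)), site_ids = ids)
  lab1 <- structure(list(site_ids = ids, z = rep(1L, 4),
                         all_missing = rep(FALSE, 4)),
                    class = "persistence_labels")
  expect_error(fit_lsd(lab1, b, "x"), "no contrast")

  # perfectly separated covariate
  lab2 <- structure(list(site_ids = ids, z = c(0L, 0L, 1L, 1L),
                         all_missing = rep(FALSE, 4)),
                    class = "persistence_labels")
  expect_warning(fit2 <- fit_lsd(lab2, b, "x"), "separation")
  expect_true(fit2$separation_flag)
  expect_false(fit2$converged)
})

test_that("covariate shifts move only the intercept; scores shift-invariant", {
  fx <- screen_fixture(c(0L, 0L, 1L, 0L, 1L, 1L, 1L, 1L, 0L, 0L))
  fit <- fit_lsd(fx$labels, fx$bundle, c("A", "C"))
  shifted <- fx$bundle
  shifted$site_covs$A <- shifted$site_covs$A + 5
  fit2 <- fit_lsd(fx$labels, shifted, c("A", "C"))
  expect_equal(fit2$betas, fit$betas, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(fit2$intercept, fit$intercept)))

  s1 <- lsd_score(fit, fx$bundle)
  s2 <- lsd_score(fit2, shifted)
  expect_equal(s2 / s2[1L], s1 / s1[1L], tolerance = 1e-6)

  # score ratios invariant to site reordering
  perm <- sample(10)
  b3 <- covariate_bundle(lapply(fx$bundle$site_covs, function(v) v[perm]),
                         site_ids = fx$bundle$site_ids[perm])
  expect_equal(lsd_score(fit, b3), s1[perm], tolerance = 1e-12)
})

test_that("lsd_score is the interceptless exponential of the linear index", {
  fit <- structure(list(name = "toy", terms = c("u", "v"), intercept = 3,
                        betas = c(u = 2, v = -1), ses = c(u = 1, v = 1),
                        logL = -1, K = 3, n_used = 10, converged = TRUE,
                        separation_flag = FALSE), class = "lsd_fit")
  expect_equal(lsd_score(fit, c(u = 1, v = 2)), 1)  # exp(2 - 2)
  expect_equal(lsd_score(fit, c(u = 0, v = 0)), 1)
  x <- c(u = 0.7, v = 1.3)
  expect_equal(log(lsd_score(fit, 2 * x)), 2 * log(lsd_score(fit, x)))
  expect_error(lsd_score(fit, c(u = 1)), "missing term")

  null_fit <- fit; null_fit$terms <- character(); null_fit$betas <- numeric()
  expect_equal(lsd_score(null_fit, c(u = 1)), 1)
})

test_that("fit_lsd recovers known coefficients from simulated labels", {
  set.seed(2026)
  n <- 2000
  x <- rnorm(n)
  z <- rbinom(n, 1, plogis(-0.4 + 0.9 * x))
  ids <- paste0("s", seq_len(n))
  b <- covariate_bundle(list(x = x), site_ids = ids)
  lab <- structure(list(site_ids = ids, z = z, all_missing = rep(FALSE, n)),
                   class = "persistence_labels")
  fit <- fit_lsd(lab, b, "x")
  expect_lt(abs(fit$betas[["x"]] - 0.9), 0.1)
  expect_lt(abs(fit$intercept - (-0.4)), 0.1)
})
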