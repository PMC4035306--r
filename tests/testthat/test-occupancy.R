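test_that("site_likelihood matches hand arithmetic and handles missingness", {
  expect_equal(site_likelihood(0.5, rep(0.5, 3), c(1, 0, 0)), 0.0625)
  expect_equal(site_likelihood(0.5, rep(0.5, 3), c(0, 0, 0)), 0.5625)
  expect_equal(site_likelihood(0.3, c(0.9, 0.2), c(NA, NA)), 1)
  expect_equal(site_likelihood(0, c(0.5, 0.5), c(1, 0)), 0)  # impossible event
  # missing occasions contribute factor one
  expect_equal(site_likelihood(0.4, c(0.7, 0.9, 0.3), c(1, NA, 0)),
               0.4 * 0.7 * 0.7)
})

test_that("history probabilities sum to one over all 2^K patterns", {
  set.seed(11)
  for (K in 1:4) {
    for (rep in 1:5) {
      psi <- runif(1)
      p <- runif(K)
      grid <- as.matrix(expand.grid(rep(list(0:1), K)))
      tot <- sum(apply(grid, 1L, function(hst) site_likelihood(psi, p, hst)))
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

test_that("complete detection drives p to the boundary and psi to naive", {
  y <- rbind(matrix(1L, 6, 3), matrix(0L, 4, 3))
  h <- detection_history(y)
  b <- covariate_bundle(site_ids = h$site_ids)
  fit <- suppressWarnings(fit_occupancy(h, b, model_spec()))
  expect_true(fit$boundary_flag)
  expect_gt(plogis(fit$alpha_p[["(Intercept)"]]), 0.999)
  expect_equal(plogis(fit$beta_psi[["(Intercept)"]]), 0.6, tolerance = 1e-3)
})

test_that("intercept-only MLE matches the dense grid-search oracle", {
  dat <- oracle_fixture(seed = 42, n = 40)
  fit <- fit_occupancy(dat$histories, dat$bundle, model_spec())
  oracle <- grid_occupancy_oracle(dat$histories, step = 0.001)
  expect_equal(plogis(fit$beta_psi[["(Intercept)"]]), unname(oracle["psi"]),
               tolerance = 0.005)
  expect_equal(plogis(fit$alpha_p[["(Intercept)"]]), unname(oracle["p"]),
               tolerance = 0.005)
  expect_true(fit$converged)
  expect_equal(fit$minus2LL, -2 * fit$logL, tolerance = 1e-8)
})

test_that("maximized likelihood beats random parameter vectors", {
  dat <- oracle_fixture(seed = 9, n = 30)
  spec <- model_spec()
  fit <- fit_occupancy(dat$histories, dat$bundle, spec)
  y <- dat$histories$y
  loglik_at <- function(psi, p) {
    sum(log(vapply(seq_len(nrow(y)), function(i) {
      site_likelihood(psi, rep(p, ncol(y)), y[i, ])
    }, numeric(1))))
  }
  set.seed(4)
  for (i in 1:100) {
    expect_gte(fit$logL + 1e-8, loglik_at(runif(1), runif(1)))
  }
})

test_that("psi-hat recovers the simulation truth at n = 2000", {
  cfg <- sim_config(2000, 3,
                    true_beta_psi = c("(Intercept)" = qlogis(0.6)),
                    true_alpha_p = c("(Intercept)" = qlogis(0.7)),
                    seed = 13)
  dat <- simulate_dataset(cfg)
  fit <- fit_occupancy(dat$histories, dat$bundle, model_spec())
  mc_se <- sqrt(0.6 * 0.4 / 2000)
  expect_lt(abs(plogis(fit$beta_psi[["(Intercept)"]]) - 0.6), 3 * mc_se)
})

test_that("covariate structures estimate K = 2 + #psi + #p parameters", {
  dat <- simulate_dataset(grebe_sim_config(seed = 3))
  spec <- model_spec("Develop", c("Rush", "Date"))
  fit <- suppressWarnings(fit_occupancy(dat$histories, dat$bundle, spec))
  expect_equal(fit$K, 2L + 1L + 2L)
  expect_equal(length(fit$beta_psi), 2L)
  expect_equal(length(fit$alpha_p), 3L)
  # standardized and raw Date coefficients describe the same fit
  sc <- fit$scaling
  expect_equal(sc$term, "Date")
  expect_equal(fit$alpha_p[["Date"]],
               fit$alpha_p_std[["Date"]] / sc$sd, tolerance = 1e-10)
})

test_that("single-occasion intercept-only data are rejected as unidentifiable", {
  h <- make_history(1, 0, 1, 0)
  b <- covariate_bundle(site_ids = h$site_ids)
  expect_error(fit_occupancy(h, b, model_spec()), "confounded")
})

test_that("predict_psi is constant for null models and monotone in covariates", {
  dat <- simulate_dataset(grebe_sim_config(seed = 5))
  null_fit <- fit_occupancy(dat$histories, dat$bundle, model_spec())
  expect_equal(length(unique(predict_psi(null_fit, dat$bundle))), 1L)

  fake <- fake_intercept_fit(0.5, 0.5, 3)
  b1 <- covariate_bundle(site_ids = "s1")
  expect_equal(predict_psi(fake, b1), 0.5)  # logit^-1(0) at zero predictor

  fit <- suppressWarnings(fit_occupancy(dat$histories, dat$bundle,
                                        model_spec("Develop")))
  beta <- fit$beta_psi[["Develop"]]
  b2 <- dat$bundle
  b2$site_covs$Develop <- b2$site_covs$Develop + 0.1 * sign(beta)
  expect_true(all(predict_psi(fit, b2) >= predict_psi(fit, dat$bundle) - 1e-12))
})

test_that("naive estimate counts sites with any detection", {
  y <- matrix(0L, 43, 3); y[seq_len(27), 1] <- 1L
  expect_equal(naive_estimate(detection_history(y)), 27 / 43)
  expect_equal(naive_estimate(make_history(c(0, 0), c(0, 0))), 0)
})

test_that("profile identity: psi-hat equals the naive estimate when p = 1", {
  dat <- oracle_fixture(seed = 21, n = 25)
  fit <- fit_occupancy(dat$histories, dat$bundle, model_spec(), p_fixed = 1)
  expect_equal(plogis(fit$beta_psi[["(Intercept)"]]),
               naive_estimate(dat$histories), tolerance = 1e-10)
  expect_true(all(predict_p(fit, dat$bundle) == 1))
})
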