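test_that("detection CSV parsing normalizes missing dialects and validates cells", {
  path <- write_temp_csv(c("site,occ1,occ2,occ3", "A,1,0,.", "B,0,0,0"))
  h <- read_detection_csv(path)
  expect_equal(n_sites(h), 2L)
  expect_equal(n_occasions(h), 3L)
  expect_true(is.na(h$y["A", 3L]))
  expect_equal(unname(h$y["B", ]), c(0L, 0L, 0L))

  # all three missing dialects map to the same sentinel
  path2 <- write_temp_csv(c("site,occ1,occ2,occ3", "A,1,NA,.", "B,,0,1"))
  h2 <- read_detection_csv(path2)
  expect_equal(sum(is.na(h2$y)), 3L)

  bad <- write_temp_csv(c("site,occ1,occ2", "A,1,2"))
  expect_error(read_detection_csv(bad), "invalid cell.*'2'.*occ2")
  dup <- write_temp_csv(c("site,occ1", "A,1", "A,0"))
  expect_error(read_detection_csv(dup), "duplicate site ids")
})

test_that("detection CSV round-trips through the canonical missing token", {
  h <- make_history(c(1, 0, NA), c(0, NA, NA), c(1, 1, 1))
  path <- tempfile(fileext = ".csv")
  write_detection_csv(h, path)
  h2 <- read_detection_csv(path)
  expect_identical(h2$y, h$y)
  expect_identical(h2$site_ids, h$site_ids)
  # the written file uses "." and nothing else for missing occasions
  expect_false(any(grepl("NA", readLines(path))))
})

test_that("persistence labels follow the any-detection rule", {
  h <- make_history(c(1, 0, 0), c(0, 0, 0))
  z <- labels_from_histories(h)$z
  expect_equal(z, c(1L, 0L))

  expect_warning(
    labels_from_histories(make_history(c(1, 0, 0), c(NA, NA, NA))),
    "no surveyed occasions")

  # labels are invariant to occasion order
  h3 <- make_history(c(0, NA, 1), c(1, 1, 0), c(0, 0, 0))
  perm <- detection_history(h3$y[, c(3, 1, 2)], h3$site_ids)
  expect_equal(labels_from_histories(h3)$z, labels_from_histories(perm)$z)
})

test_that("a 43-site table with 27 detected sites yields 27 persisted (63%)", {
  y <- matrix(0L, 43, 3)
  y[seq_len(27), 2] <- 1L
  h <- detection_history(y)
  expect_equal(sum(labels_from_histories(h)$z), 27L)
  expect_equal(naive_estimate(h), 27 / 43)
  expect_equal(round(100 * naive_estimate(h)), 63)
})

test_that("covariate CSVs align to the history table's canonical site order", {
  h <- make_history(c(1, 0, 0), c(0, 0, 0))
  h$site_ids <- c("B", "A")
  rownames(h$y) <- c("B", "A")
  sp <- write_temp_csv(c("site,Develop,Forest", "A,0.1,0.5", "B,0.3,0.2",
                         "C,0.9,0.9"))
  expect_warning(b <- read_covariates_csv(sp, histories = h),
                 "not in the detection table.*C")
  expect_equal(length(b$site_covs$Develop), 2L)
  expect_equal(unname(b$site_covs$Develop), c(0.3, 0.1))  # B first

  op <- write_temp_csv(c("site,occasion,Date", "A,1,150", "A,3,210",
                         "B,1,155", "B,2,180", "B,3,212"))
  b2 <- suppressWarnings(read_covariates_csv(sp, op, h))
  expect_equal(dim(b2$occasion_covs$Date), c(2L, 3L))
  expect_true(is.na(b2$occasion_covs$Date["A", 2L]))
  expect_equal(b2$occasion_covs$Date["B", 2L], 180)

  missing_site <- write_temp_csv(c("site,Develop", "A,0.1"))
  expect_error(read_covariates_csv(missing_site, histories = h),
               "absent in covariates")
  nonnum <- write_temp_csv(c("site,Develop", "A,0.1", "B,oops"))
  expect_error(read_covariates_csv(nonnum, histories = h), "non-numeric")
})

test_that("model specs validate terms and serialize through JSON", {
  s <- model_spec(c("Develop", "Forest"), "Rush")
  expect_equal(s$name, "psi(Develop+Forest) p(Rush)")
  expect_equal(model_spec()$name, "psi(.) p(.)")
  expect_error(model_spec(c("A", "A")), "duplicate")

  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(name = "m1", psi = list("Develop"), p = list()),
                       path, auto_unbox = TRUE)
  s2 <- read_model_spec_json(path)
  expect_equal(s2$psi_terms, "Develop")
  expect_equal(s2$p_terms, character())
  expect_equal(s2$name, "m1")
})

test_that("invalid detection-history matrices are rejected", {
  expect_error(detection_history(rbind(c(1, 2, 0))), "invalid")
  expect_error(detection_history(rbind(c(1, 0)), c("A", "B")), "length")
  expect_error(detection_history(rbind(c(1, 0), c(0, 1)), c("A", "A")),
               "duplicate")
})
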