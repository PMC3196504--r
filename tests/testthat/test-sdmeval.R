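test_that("rank AUC matches the trapezoidal ROC oracle and its symmetries", {
  expect_equal(roc_auc(c(1, 1), c(0, 0)), 1)
  expect_equal(roc_auc(c(0.3, 0.7), c(0.3, 0.7)), 0.5)
  set.seed(9)
  for (i in 1:10) {
    pres <- rnorm(sample(5:40, 1), mean = 0.5)
    back <- rnorm(sample(5:40, 1))
    expect_equal(roc_auc(pres, back), auc_trapezoid_oracle(pres, back),
                 tolerance = 1e-10)
    # complement identity for tie-free scores
    expect_equal(roc_auc(pres, back) + roc_auc(back, pres), 1,
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(numeric(0), 1), class = "comdemog_domain_error")
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  pres <- runif(25); back <- runif(30)
  got <- roc_auc(pres, back)
  want <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 25), rep(0, 30)), predictor = c(pres, back),
    quiet = TRUE, direction = "<")))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("threshold selection lands between the classes and honours ties", {
  scores <- c(0.1, 0.4, 0.6, 0.9)
  labels <- c(0, 0, 1, 1)
  for (crit in c("equal_sens_spec", "max_sens_plus_spec")) {
    rep_ <- find_threshold(scores, labels, crit)
    expect_gt(rep_$threshold, 0.4)
    expect_lt(rep_$threshold, 0.6)
    expect_equal(rep_$sensitivity, 1)
    expect_equal(rep_$specificity, 1)
    expect_equal(rep_$n_predicted_presence, 2L)
  }
  # label swap + score negation preserves achieved sens + spec
  r1 <- find_threshold(scores, labels, "max_sens_plus_spec")
  r2 <- find_threshold(-scores, 1 - labels, "max_sens_plus_spec")
  expect_equal(r1$sensitivity + r1$specificity,
               r2$sensitivity + r2$specificity)
  expect_error(find_threshold(scores, c(1, 1, 1, 1)),
               class = "comdemog_domain_error")
})

test_that("Cohen's kappa follows its closed form", {
  expect_equal(cohens_kappa(40, 10, 10, 40), 0.6)
  expect_equal(cohens_kappa(10, 0, 0, 20), 1)
  # chance-level agreement with matching marginals is exactly zero
  expect_equal(cohens_kappa(15, 35, 15, 35), 0)
  expect_warning(k <- cohens_kappa(10, 0, 0, 0), "Degenerate")
  expect_true(is.na(k))
  expect_error(cohens_kappa(-1, 0, 0, 1), class = "comdemog_domain_error")
})

test_that("range-cell counts use strict exceedance and NODATA exclusion", {
  g <- ascii_grid(matrix(0.9, 10, 10))
  expect_equal(count_range_cells(g, 0.5), 100)
  expect_equal(count_range_cells(g, 1.0), 0)
  expect_equal(count_range_cells(g, 0.9), 0)  # strict ">"
  m <- matrix(c(0.2, 0.6, NA, 0.7), 2)
  expect_equal(count_range_cells(m, 0.5), 2)
  # monotone non-increasing in the threshold
  set.seed(12)
  mm <- matrix(runif(100), 10)
  counts <- vapply(seq(0, 1, 0.1), function(th) count_range_cells(mm, th),
                   numeric(1L))
  expect_true(all(diff(counts) <= 0))
})

test_that("non-analogue masking flags exactly the out-of-range cells", {
  set.seed(14)
  cur <- purrr::map(1:3, ~ matrix(rnorm(30), 5, 6))
  expect_true(all(!nonanalog_mask(cur, cur), na.rm = TRUE))

  past <- purrr::map(cur, identity)
  past[[2]][3, 4] <- max(cur[[2]]) + 5
  mask <- nonanalog_mask(cur, past)
  expect_true(mask[3, 4])
  expect_equal(sum(mask), 1)

  # exhaustive per-cell per-variable oracle on random stacks
  past_r <- purrr::map(cur, \(m) m + matrix(rnorm(30, sd = 2), 5, 6))
  got <- nonanalog_mask(cur, past_r)
  want <- matrix(FALSE, 5, 6)
  for (r in 1:5) for (cc in 1:6) for (v in 1:3) {
    if (past_r[[v]][r, cc] < min(cur[[v]]) ||
        past_r[[v]][r, cc] > max(cur[[v]])) want[r, cc] <- TRUE
  }
  expect_equal(got, want)
  # idempotent w.r.t. variable order
  expect_equal(nonanalog_mask(rev(cur), rev(past_r)), want)
  expect_error(nonanalog_mask(cur, past_r[1:2]),
               class = "comdemog_domain_error")
})

test_that("fossil validation scores hindcast surfaces", {
  m <- matrix(seq(0, 1, length.out = 25), 5, 5)
  fossil <- cbind(row = c(5, 5, 4, 4, 3), col = c(5, 4, 5, 4, 5))
  background <- cbind(row = c(1, 1, 2, 2, 3), col = c(1, 2, 1, 2, 1))
  res <- fossil_validation(m, fossil, background, threshold = 0.5)
  expect_equal(res$auc, 1)
  expect_equal(res$n_correct, sum(m[fossil] > 0.5))
  expect_equal(res$n_fossil, 5L)
  expect_error(fossil_validation(m, fossil, background[1:3, ], 0.5),
               class = "comdemog_domain_error")
})

test_that("ESRI ASCII grids round-trip including NODATA cells", {
  m <- matrix(runif(12), 3, 4)
  m[2, 3] <- NA
  g <- ascii_grid(m, xllcorner = -117.5, yllcorner = 34.25, cellsize = 0.25)
  p <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g, p)
  back <- read_ascii_grid(p)
  expect_equal(back$data, g$data, tolerance = 1e-12)
  expect_equal(back$cellsize, 0.25)
  expect_equal(back$xllcorner, -117.5)
  expect_true(grepl("NODATA_value", readLines(p)[6]))
})
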