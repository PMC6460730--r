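test_that("hat basis interpolates at nodes, midpoints and proportions", {
  knots <- c(0, 1, 2, 3)
  for (j in seq_along(knots)) {
    w <- hat_basis(knots[j], knots)
    expect_equal(w, as.numeric(seq_along(knots) == j), ignore_attr = TRUE)
  }
  expect_equal(unname(hat_basis(2.5, knots)), c(0, 0, 0.5, 0.5))
  expect_equal(unname(hat_basis(2.25, knots)), c(0, 0, 0.75, 0.25))
  expect_error(hat_basis(3.1, knots), "outside the knot span")
  expect_error(hat_basis(-0.1, knots), "outside the knot span")
})

test_that("hat basis is a partition of unity with at most two supports", {
  knots <- default_knots()
  set.seed(1)
  ages <- runif(500, 0, 5.5)
  B <- hat_basis_matrix(ages, knots)
  expect_lt(max(abs(rowSums(B) - 1)), 1e-12)
  expect_true(all(B >= 0))
  expect_true(all(rowSums(B > 0) <= 2))
  # the weighted combination reproduces piecewise-linear interpolation
  vals <- c(-0.6, -0.4, -0.4, 0.2, 0.1, -0.1, -0.2)
  expect_equal(drop(B %*% vals), approx(knots, vals, xout = ages)$y)
})

test_that("a mean curve with no random effects and no noise is recovered exactly", {
  knots <- c(0, 1, 3)
  mu <- c(0.5, -0.2, 0.4)
  set.seed(2)
  recs <- lapply(1:30, function(i) {
    ages <- sort(runif(5, 0, 3))
    data.frame(subject_id = i, age = ages,
               value = approx(knots, mu, xout = ages)$y)
  })
  long <- long_table(do.call(rbind, recs))
  fit <- fit_broken_stick(long, knots, force = TRUE, quiet = TRUE)
  expect_lt(max(abs(fit$beta - mu)), 1e-6)
  expect_lt(fit$sigma2, 1e-8)
})

test_that("estimates are invariant to subject ordering", {
  ch <- noiseless_cohort(n = 25, seed = 5)
  long <- ch$long
  set.seed(1)
  # noisy version so the fit is interior
  long$value <- long$value + rnorm(nrow(long), 0, 0.2)
  perm <- long[sample(nrow(long)), ]
  f1 <- fit_broken_stick(long, c(0, 1, 2, 4), quiet = TRUE, force = TRUE)
  f2 <- fit_broken_stick(long_table(perm), c(0, 1, 2, 4), quiet = TRUE,
                         force = TRUE)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$re_cov, f2$re_cov, tolerance = 1e-8)
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-8)
})

test_that("the EM engine agrees with lmer on a well-conditioned problem", {
  set.seed(9)
  knots <- c(0, 1, 2)
  n <- 120
  mu <- c(-0.3, 0.2, 0.1)
  G <- diag(c(0.5, 0.4, 0.45))
  recs <- lapply(seq_len(n), function(i) {
    b <- mu + rnorm(3, 0, sqrt(diag(G)))
    ages <- c(0, 0.4, 0.9, 1.3, 1.7, 2)
    B <- hat_basis_matrix(ages, knots)
    data.frame(subject_id = i, age = ages,
               value = drop(B %*% b) + rnorm(length(ages), 0, 0.3))
  })
  long <- long_table(do.call(rbind, recs))
  f_lmer <- fit_broken_stick(long, knots, engine = "lmer", method = "ml",
                             quiet = TRUE, force = TRUE)
  f_em <- fit_broken_stick(long, knots, engine = "em", quiet = TRUE,
                           force = TRUE)
  expect_equal(f_em$beta, f_lmer$beta, tolerance = 0.02)
  expect_equal(f_em$sigma2, f_lmer$sigma2, tolerance = 0.02)
  expect_equal(f_em$re_cov, f_lmer$re_cov, tolerance = 0.1)
  expect_identical(f_em$fit_info$engine, "em")
})

test_that("records outside the knot span are dropped with a count, never extrapolated", {
  long <- long_table(data.frame(subject_id = c(1, 1, 1, 2, 2),
                                age = c(0.5, 1.5, 9, 0.2, 1.8),
                                value = c(0, 0.5, 3, -0.2, 0.1)))
  expect_message(
    fit_broken_stick(long, c(0, 1, 2), force = TRUE),
    "dropped 1 record"
  )
  f <- suppressMessages(fit_broken_stick(long, c(0, 1, 2), force = TRUE))
  expect_identical(f$fit_info$n_dropped_records, 1L)
  expect_identical(f$fit_info$n_records, 4L)
})

test_that("noiseless BLUPs interpolate the observed knot values", {
  ch <- noiseless_cohort(n = 50, knots = c(0, 1, 2, 4), seed = 42)
  fit <- fit_broken_stick(ch$long, c(0, 1, 2, 4), quiet = TRUE, force = TRUE)
  wide <- predict_knot_values(fit, ch$long)
  idx <- match(wide$subject_ids, ch$truth$subject_ids)
  expect_lt(max(abs(wide$values - ch$truth$values[idx, ])), 1e-4)
})

test_that("a degenerate model with zero random effects predicts the population mean", {
  knots <- c(0, 1, 2)
  model <- structure(list(knots = knots,
                          beta = setNames(c(0.1, 0.4, -0.2), paste0("k", 1:3)),
                          re_cov = matrix(0, 3, 3), sigma2 = 0.2,
                          fit_info = list()), class = "broken_stick")
  long <- long_table(data.frame(subject_id = "new", age = c(0.3, 1.2),
                                value = c(5, -5)))
  wide <- predict_knot_values(model, long)
  expect_equal(drop(wide$values), unname(model$beta), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("prediction error shrinks as subjects are observed more often", {
  set.seed(31)
  knots <- c(0, 1, 2, 4)
  k <- 4
  mu <- c(-0.5, 0, 0.3, 0.1)
  n <- 150
  truth <- sweep(matrix(rnorm(n * k, 0, 0.7), n, k), 2, mu, "+")
  make_long <- function(n_visits) {
    recs <- lapply(seq_len(n), function(i) {
      ages <- sort(runif(n_visits, 0, 4))
      B <- hat_basis_matrix(ages, knots)
      data.frame(subject_id = sprintf("s%03d", i), age = ages,
                 value = drop(B %*% truth[i, ]) + rnorm(n_visits, 0, 0.3))
    })
    long_table(do.call(rbind, recs))
  }
  long2 <- make_long(2)
  long6 <- make_long(6)
  fit <- fit_broken_stick(long6, knots, quiet = TRUE, force = TRUE)
  mae <- function(long) {
    w <- predict_knot_values(fit, long)
    mean(abs(w$values - truth[match(w$subject_ids, sprintf("s%03d", 1:n)), ]))
  }
  expect_lt(mae(long6), mae(long2))
})

test_that("model JSON serialization round-trips", {
  ch <- noiseless_cohort(n = 20, seed = 3)
  set.seed(4)
  long <- ch$long
  long$value <- long$value + rnorm(nrow(long), 0, 0.15)
  fit <- fit_broken_stick(long, c(0, 1, 2, 4), quiet = TRUE, force = TRUE)
  f <- tempfile(fileext = ".json")
  write_broken_stick(fit, f)
  back <- read_broken_stick(f)
  expect_identical(back$knots, fit$knots)
  expect_identical(back$beta, fit$beta)
  expect_identical(back$re_cov, fit$re_cov)
  expect_identical(back$sigma2, fit$sigma2)
  # restored model predicts identically
  p1 <- predict_knot_values(fit, long)
  p2 <- predict_knot_values(back, long)
  expect_identical(p1$values, p2$values)
  unlink(f)
})

test_that("refitting identical input reproduces the wide matrix bitwise", {
  ch <- noiseless_cohort(n = 20, seed = 8)
  set.seed(9)
  long <- ch$long
  long$value <- long$value + rnorm(nrow(long), 0, 0.1)
  w1 <- predict_knot_values(fit_broken_stick(long, c(0, 1, 2, 4), quiet = TRUE,
                                             force = TRUE), long)
  w2 <- predict_knot_values(fit_broken_stick(long, c(0, 1, 2, 4), quiet = TRUE,
                                             force = TRUE), long)
  expect_identical(w1$values, w2$values)
})

test_that("wide matrix CSV round-trips and validates", {
  w <- rand_wide(8, 3, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_wide_matrix(w, f)
  back <- read_wide_matrix(f)
  expect_equal(back$values, w$values, ignore_attr = TRUE)
  expect_equal(back$knots, w$knots)
  unlink(f)
  expect_error(wide_matrix(c("a", "b"), c(0, 1), matrix(c(1, NA, 2, 3), 2)),
               "finite")
})
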