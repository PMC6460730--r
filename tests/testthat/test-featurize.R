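test_that("feat_all is the identity encoding in knot order", {
  w <- toy_wide()
  fs <- feat_all(w)
  expect_equal(unname(fs$X[1, ]), toy_row())
  expect_identical(fs$names, paste0("age_", format(default_knots(), trim = TRUE)))
  # CSV round-trip preserves X exactly
  f <- tempfile(fileext = ".csv")
  write_features(fs, f)
  expect_equal(read_features(f)$X, fs$X, ignore_attr = TRUE)
  unlink(f)
})

test_that("feat_single selects one knot column and validates the index", {
  w <- toy_wide()
  expect_equal(unname(feat_single(w, 7)$X[1, 1]), -0.2)  # 5.5-year column
  expect_equal(unname(feat_single(w, 1)$X[1, 1]), -0.6)  # birth column
  expect_error(feat_single(w, 0), "index")
  expect_error(feat_single(w, 8), "index")
})

test_that("feat_summary computes mean and max per subject", {
  w <- toy_wide()
  expect_equal(unname(feat_summary(w, "mean")$X[1, 1]), -0.2, tolerance = 1e-12)
  expect_equal(unname(feat_summary(w, "max")$X[1, 1]), 0.2)
  # constant row: mean = max = c
  wc <- wide_matrix("a", c(0, 1, 2), matrix(0.7, 1, 3))
  expect_equal(unname(feat_summary(wc, "mean")$X[1, 1]), 0.7)
  expect_equal(unname(feat_summary(wc, "max")$X[1, 1]), 0.7)
  # mean is invariant to column permutation
  w2 <- rand_wide(10, 4, seed = 3)
  perm <- wide_matrix(w2$subject_ids, w2$knots, w2$values[, c(3, 1, 4, 2)])
  expect_equal(feat_summary(perm, "mean")$X, feat_summary(w2, "mean")$X,
               ignore_attr = TRUE)
})

test_that("feat_change encodes first value plus successive differences", {
  w <- toy_wide()
  fs <- feat_change(w)
  expect_equal(unname(fs$X[1, ]), c(-0.6, 0.2, 0.0, 0.6, -0.1, -0.2, -0.1),
               tolerance = 1e-12)
  # cumulative summation inverts the coding
  w2 <- rand_wide(20, 5, seed = 4)
  d <- feat_change(w2)$X
  expect_equal(t(apply(d, 1, cumsum)), w2$values, ignore_attr = TRUE,
               tolerance = 1e-12)
  # rate variant divides by the elapsed time (3y -> 5.5y spans 2.5 years)
  r <- feat_change(w, rate = TRUE)
  expect_equal(unname(r$X[1, 7]), -0.1 / 2.5, tolerance = 1e-12)
  expect_equal(unname(r$X[1, 2]), 0.2 / 0.25, tolerance = 1e-12)
})

test_that("conditional features are residuals orthogonal to all earlier columns", {
  w <- rand_wide(80, 5, seed = 5)
  fit <- feat_conditional_fit(w)
  X <- fit$features$X
  expect_equal(unname(X[, 1]), unname(w$values[, 1]))
  for (j in 2:5) {
    for (l in seq_len(j - 1)) {
      expect_lt(abs(cor(X[, j], w$values[, l])), 1e-10)
    }
    expect_lt(abs(mean(X[, j])), 1e-12)  # intercept included
  }
})

test_that("an exactly dependent column yields an identically zero conditional feature", {
  set.seed(6)
  v <- cbind(rnorm(40), rnorm(40))
  v <- cbind(v, v[, 1] + v[, 2])
  w <- wide_matrix(sprintf("s%02d", 1:40), c(0, 1, 2), v)
  fit <- feat_conditional_fit(w)
  expect_lt(max(abs(fit$features$X[, 3])), 1e-10)
})

test_that("conditional fitting matches an independent normal-equations solve", {
  w <- rand_wide(200, 4, seed = 7)
  fit <- feat_conditional_fit(w)
  V <- w$values
  for (j in 2:4) {
    M <- cbind(1, V[, seq_len(j - 1), drop = FALSE])
    beta <- solve(crossprod(M), crossprod(M, V[, j]))
    resid <- V[, j] - drop(M %*% beta)
    expect_equal(unname(fit$features$X[, j]), unname(resid), tolerance = 1e-8)
  }
})

test_that("applying the transformer reproduces training features and handles new subjects", {
  w <- rand_wide(60, 4, seed = 8)
  fit <- feat_conditional_fit(w)
  applied <- feat_conditional_apply(fit$transformer, w)
  expect_equal(applied$X, fit$features$X, ignore_attr = TRUE, tolerance = 1e-12)

  # a new subject lying on the training regression surface gets ~0 conditionals:
  # build it by predicting each column from the previous ones via the stored fit
  newv <- numeric(4)
  newv[1] <- mean(w$values[, 1])
  for (j in 2:4) {
    cf <- fit$transformer$coef[[j]]
    newv[j] <- cf[1] + sum(cf[-1] * newv[fit$transformer$kept[[j]]])
  }
  wn <- wide_matrix("new", w$knots, matrix(newv, 1))
  out <- feat_conditional_apply(fit$transformer, wn)
  expect_lt(max(abs(out$X[1, -1])), 1e-10)

  # knot-grid mismatch is an error
  wk <- wide_matrix("x", c(0, 1, 2, 5), matrix(rnorm(4), 1))
  expect_error(feat_conditional_apply(fit$transformer, wk), "mismatch")
})

test_that("the conditional transformer round-trips through JSON bitwise", {
  w <- rand_wide(50, 4, seed = 9)
  fit <- feat_conditional_fit(w)
  f <- tempfile(fileext = ".json")
  write_conditional_transformer(fit$transformer, f)
  back <- read_conditional_transformer(f)
  out <- feat_conditional_apply(back, w)
  expect_identical(out$X, feat_conditional_apply(fit$transformer, w)$X)
  unlink(f)
})

test_that("growth-curve features: exact linear fit and constant subjects", {
  long <- long_table(data.frame(subject_id = "a", age = 0:3, value = 1:4))
  fs <- feat_growthcurve(long, degree = 1, include_se = TRUE)
  expect_equal(unname(fs$X[1, ]), c(2.5, 1, 0), tolerance = 1e-12)

  const <- long_table(data.frame(subject_id = "c", age = c(0, 1, 2, 4),
                                 value = rep(0.4, 4)))
  fc <- feat_growthcurve(const, degree = 2)
  expect_equal(unname(fc$X[1, ]), c(0.4, 0, 0), tolerance = 1e-12)
})

test_that("growth-curve fits match a least-squares oracle in the raw basis", {
  set.seed(10)
  ages <- c(0.1, 0.7, 1.3, 2.2, 3.4, 4.8, 5.5)
  # values from a known quadratic, plus a cubic-fit case with noise
  v2 <- 0.3 - 0.5 * ages + 0.08 * ages^2
  long <- long_table(data.frame(subject_id = "q", age = ages, value = v2))
  fs <- feat_growthcurve(long, degree = 2)
  expect_equal(unname(fs$X[1, ]), c(mean(v2), -0.5, 0.08), tolerance = 1e-8)

  vn <- v2 + rnorm(length(ages), 0, 0.1)
  ln <- long_table(data.frame(subject_id = "n", age = ages, value = vn))
  for (d in 1:3) {
    fsd <- feat_growthcurve(ln, degree = d, include_se = TRUE)
    o <- lm(vn ~ poly(ages, d, raw = TRUE))
    expect_equal(unname(fsd$X[1, 1 + seq_len(d)]), unname(coef(o)[-1]),
                 tolerance = 1e-8)
    expect_equal(unname(fsd$X[1, d + 2]),
                 summary(o)$coefficients[2, "Std. Error"], tolerance = 1e-8)
  }
})

test_that("growth-curve features are invariant to record order and saturated fits give se 0", {
  set.seed(11)
  d <- data.frame(subject_id = "s", age = c(0.2, 1.1, 2.5, 4, 5),
                  value = rnorm(5))
  f1 <- feat_growthcurve(long_table(d), degree = 2, include_se = TRUE)
  f2 <- feat_growthcurve(long_table(d[c(4, 1, 5, 3, 2), ]), degree = 2,
                         include_se = TRUE)
  expect_equal(f1$X, f2$X, ignore_attr = TRUE, tolerance = 1e-12)

  sat <- long_table(data.frame(subject_id = "t", age = c(0, 1, 2),
                               value = c(0.5, 0.1, 0.9)))
  fs <- feat_growthcurve(sat, degree = 2, include_se = TRUE)
  expect_identical(unname(fs$X[1, "se_slope"]), 0)

  expect_error(feat_growthcurve(sat, degree = 3), "distinct age")
  expect_warning(feat_growthcurve(sat, degree = 3, demote = TRUE), "demoted")
})

test_that("growth-curve features accept a wide matrix as knot-age observations", {
  w <- rand_wide(15, 5, seed = 12)
  fs <- feat_growthcurve(w, degree = 1)
  # oracle: per-row OLS of values on knot ages
  for (i in c(1, 7, 15)) {
    o <- lm(w$values[i, ] ~ w$knots)
    expect_equal(unname(fs$X[i, "b_age"]), unname(coef(o)[2]), tolerance = 1e-8)
    expect_equal(unname(fs$X[i, "mean"]), mean(w$values[i, ]), tolerance = 1e-12)
  }
})

test_that("residual-se variant reports the RMS residual of the subject curve", {
  set.seed(13)
  ages <- c(0, 0.5, 1.5, 3, 4.5, 5.5)
  vals <- 0.2 + 0.1 * ages + rnorm(6, 0, 0.3)
  long <- long_table(data.frame(subject_id = "r", age = ages, value = vals))
  fs <- feat_growthcurve(long, degree = 1, include_se = TRUE,
                         se_type = "residual")
  o <- lm(vals ~ ages)
  expect_equal(unname(fs$X[1, "se_slope"]), summary(o)$sigma, tolerance = 1e-8)
})
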