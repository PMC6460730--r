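# shared fixtures, all built in code

# the seven per-visit mean SDS values used as a convenient toy trajectory
toy_row <- function() c(-0.6, -0.4, -0.4, 0.2, 0.1, -0.1, -0.2)

toy_wide <- function() {
  wide_matrix("s1", default_knots(), matrix(toy_row(), nrow = 1))
}

rand_wide <- function(n, k, seed = 1) {
  set.seed(seed)
  wide_matrix(sprintf("s%03d", seq_len(n)), seq(0, k - 1),
              matrix(rnorm(n * k), n, k))
}

# small synthetic LMS reference on a coarse age grid (two sexes)
toy_lms_ref <- function() {
  ages <- c(0.1, 0.5, 1, 2, 4, 6, 11)
  build <- function(sex, m0) {
    data.frame(sex = sex, age = ages,
               L = seq(-1.6, -0.4, length.out = length(ages)),
               M = m0 + c(0, 3, 4, 3.5, 3, 2.8, 3.2),
               S = seq(0.08, 0.13, length.out = length(ages)))
  }
  lms_reference(rbind(build("male", 13.5), build("female", 13.2)))
}

# noiseless broken-stick cohort: subject lines observed at knots + midpoints,
# so the residual variance is identified at zero
noiseless_cohort <- function(n = 50, knots = c(0, 1, 2, 4), seed = 42,
                             sd_re = 0.7) {
  set.seed(seed)
  k <- length(knots)
  mu <- seq(-0.5, 0.4, length.out = k)
  truth <- sweep(matrix(rnorm(n * k, 0, sd_re), n, k), 2, mu, "+")
  mids <- (knots[-1] + knots[-k]) / 2
  ages <- c(knots, mids)
  recs <- lapply(seq_len(n), function(i) {
    B <- hat_basis_matrix(ages, knots)
    data.frame(subject_id = sprintf("s%03d", i), age = ages,
               value = drop(B %*% truth[i, ]))
  })
  list(long = long_table(do.call(rbind, recs)),
       truth = wide_matrix(sprintf("s%03d", seq_len(n)), knots, truth),
       mu = mu)
}
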