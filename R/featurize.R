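# Six encodings of a repeatedly measured predictor into a design matrix:
# all measurements, a single measurement, a mean/max summary, successive
# changes, conditional (residualised) measurements, and per-subject
# growth-curve parameters. The first, fourth and fifth are invertible affine
# recodings of the same columns, which is why models built on them have
# identical fitted values and discrimination.

#' Feature set: a named design matrix aligned to subjects
#'
#' @param subject_ids vector of subject identifiers, one per row of `X`.
#' @param X numeric design matrix (subjects x features), all entries finite.
#' @param names feature labels (default: column names of `X`).
#' @param state method-specific fitted state (e.g. a conditional transformer
#'   reference or per-subject curve summaries); empty list when stateless.
#' @return a `feature_set` object.
#' @export
feature_set <- function(subject_ids, X, names = colnames(X), state = list()) {
  X <- as.matrix(X)
  if (is.null(names)) names <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(subject_ids)) stop("feature_set: row/subject mismatch")
  if (length(names) != ncol(X)) stop("feature_set: names length != ncol(X)")
  if (any(!is.finite(X))) stop("feature_set: non-finite entries in X")
  colnames(X) <- names
  rownames(X) <- as.character(subject_ids)
  structure(list(subject_ids = subject_ids, names = names, X = X, state = state),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("Feature set: ", nrow(x$X), " subjects x ", ncol(x$X), " features (",
      paste(x$names, collapse = ", "), ")\n", sep = "")
  print(head(x$X, 4))
  if (nrow(x$X) > 4) cat("...\n")
  invisible(x)
}

#' @rdname feature_set
#' @param path CSV path (`subject_id` column + one column per feature).
#' @export
write_features <- function(x, path) {
  stopifnot(inherits(x, "feature_set"))
  write.csv(data.frame(subject_id = x$subject_ids, x$X, check.names = FALSE,
                       row.names = NULL),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname feature_set
#' @export
read_features <- function(path) {
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  feature_set(d$subject_id, as.matrix(d[, -1, drop = FALSE]))
}

knot_labels <- function(knots) paste0("age_", format(knots, trim = TRUE))

#' Method 1: all measurements as separate predictors
#'
#' The identity encoding: every knot column of the wide matrix enters the
#' model as its own predictor.
#'
#' @param wide a [wide_matrix()].
#' @return a [feature_set()] with one feature per knot, in knot order.
#' @export
feat_all <- function(wide) {
  stopifnot(inherits(wide, "wide_matrix"))
  feature_set(wide$subject_ids, wide$values, knot_labels(wide$knots))
}

#' Method 2: a single measurement
#'
#' Selects one knot column as the sole predictor. `feat_single()` takes a
#' fixed knot position; `select_single_best()` picks the knot whose
#' univariable model discriminates best on the training outcome (the "single
#' best measurement" rule — for child growth this is typically the latest
#' measurement).
#'
#' @param wide a [wide_matrix()].
#' @param index knot position, 1-based (`length(knots)` selects the last knot).
#' @return a single-column [feature_set()].
#' @export
feat_single <- function(wide, index) {
  stopifnot(inherits(wide, "wide_matrix"))
  k <- length(wide$knots)
  if (length(index) != 1 || is.na(index) || index < 1 || index > k) {
    stop("feat_single: index must be in 1..", k)
  }
  feature_set(wide$subject_ids, wide$values[, index, drop = FALSE],
              knot_labels(wide$knots)[index])
}

#' @rdname feat_single
#' @param y_binary binary training outcome used to score each candidate knot.
#' @return `select_single_best()` returns the selected knot position
#'   (1-based), with the per-knot AUCs as attribute `"auc"`.
#' @export
select_single_best <- function(wide, y_binary) {
  stopifnot(inherits(wide, "wide_matrix"))
  aucs <- vapply(seq_along(wide$knots), function(j) {
    m <- fit_predmodel(feat_single(wide, j), y_binary, family = "logistic")
    auc(m$fitted, y_binary)
  }, numeric(1))
  structure(which.max(aucs), auc = setNames(aucs, knot_labels(wide$knots)))
}

#' Method 3: summary measurement (mean or maximum)
#'
#' Collapses the trajectory into a single per-subject summary: its mean level
#' or its peak value.
#'
#' @param wide a [wide_matrix()].
#' @param stat `"mean"` or `"max"`.
#' @return a single-column [feature_set()].
#' @export
feat_summary <- function(wide, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  stopifnot(inherits(wide, "wide_matrix"))
  v <- switch(stat,
              mean = rowMeans(wide$values, na.rm = TRUE),
              max = apply(wide$values, 1, max, na.rm = TRUE))
  feature_set(wide$subject_ids, matrix(v, ncol = 1), stat)
}

#' Method 4: change between subsequent measurements
#'
#' Encodes the trajectory as its first value plus the successive differences
#' `y_j - y_{j-1}`; cumulative summation recovers the original columns, so
#' this is an invertible recoding. With `rate = TRUE` each difference is
#' divided by the elapsed time between the knots (change per year), a variant
#' that tolerates mildly irregular measurement timing.
#'
#' @param wide a [wide_matrix()].
#' @param rate divide each change by the covered period of time.
#' @return a [feature_set()] with `k` features: the first knot value and
#'   `k - 1` (rate-)changes.
#' @export
feat_change <- function(wide, rate = FALSE) {
  stopifnot(inherits(wide, "wide_matrix"))
  k <- length(wide$knots)
  if (k < 2) stop("feat_change: need at least 2 knots")
  lab <- format(wide$knots, trim = TRUE)
  d <- wide$values[, -1, drop = FALSE] - wide$values[, -k, drop = FALSE]
  nm <- paste0(if (rate) "rate_" else "chg_", lab[-1], "_", lab[-k])
  if (rate) d <- sweep(d, 2, diff(wide$knots), "/")
  feature_set(wide$subject_ids, cbind(wide$values[, 1, drop = FALSE], d),
              c(knot_labels(wide$knots)[1], nm))
}

#' Method 5: conditional (residualised) measurements
#'
#' For each time point `j >= 2`, the conditional measurement is the residual
#' of the measurement at `j` regressed (with intercept) on all earlier
#' measurements across the training subjects; the first measurement enters
#' untouched. By least-squares construction every conditional feature is
#' uncorrelated with all earlier raw measurements. The fitted regression
#' coefficients are returned as a transformer so new subjects can be encoded
#' with the training-set coefficients via [feat_conditional_apply()].
#'
#' @param wide a training [wide_matrix()] with more subjects than knots.
#' @return a list with elements `features` (a [feature_set()]) and
#'   `transformer` (a `conditional_transformer`).
#' @export
feat_conditional_fit <- function(wide) {
  stopifnot(inherits(wide, "wide_matrix"))
  k <- length(wide$knots)
  n <- nrow(wide$values)
  if (n <= k) stop("feat_conditional_fit: need more subjects than knots")
  labs <- knot_labels(wide$knots)
  coefs <- vector("list", k)
  kept_idx <- vector("list", k)
  X <- matrix(0, n, k)
  X[, 1] <- wide$values[, 1]
  for (j in 2:k) {
    prev <- wide$values[, seq_len(j - 1), drop = FALSE]
    da <- drop_aliased(prev, names = labs[seq_len(j - 1)])
    M <- cbind(1, da$X)
    fit <- stats::lm.fit(M, wide$values[, j])
    X[, j] <- fit$residuals
    coefs[[j]] <- setNames(fit$coefficients, c("(Intercept)", da$kept_names))
    kept_idx[[j]] <- match(da$kept_names, labs)
  }
  transformer <- structure(list(knots = wide$knots, coef = coefs,
                                kept = kept_idx, labels = labs),
                           class = "conditional_transformer")
  feats <- feature_set(wide$subject_ids, X,
                       c(labs[1], paste0("cond_", labs[-1])),
                       state = list(transformer = transformer))
  list(features = feats, transformer = transformer)
}

#' Apply a fitted conditional transformer to (new) subjects
#'
#' Residualises each time point with the coefficients stored at training
#' time (no refitting); applied to the training matrix it reproduces the
#' [feat_conditional_fit()] features exactly.
#'
#' @param transformer a `conditional_transformer`.
#' @param wide a [wide_matrix()] on the same knot grid.
#' @return a [feature_set()].
#' @export
feat_conditional_apply <- function(transformer, wide) {
  stopifnot(inherits(transformer, "conditional_transformer"),
            inherits(wide, "wide_matrix"))
  if (length(transformer$knots) != length(wide$knots) ||
      any(abs(transformer$knots - wide$knots) > 1e-8)) {
    stop("feat_conditional_apply: knot grid mismatch")
  }
  k <- length(wide$knots)
  n <- nrow(wide$values)
  X <- matrix(0, n, k)
  X[, 1] <- wide$values[, 1]
  for (j in 2:k) {
    cf <- transformer$coef[[j]]
    prev <- wide$values[, transformer$kept[[j]], drop = FALSE]
    X[, j] <- wide$values[, j] - (cf[1] + drop(prev %*% cf[-1]))
  }
  labs <- transformer$labels
  feature_set(wide$subject_ids, X, c(labs[1], paste0("cond_", labs[-1])),
              state = list(transformer = transformer))
}

#' Serialize / restore a conditional transformer as JSON
#'
#' @param transformer a `conditional_transformer`.
#' @param path JSON file path.
#' @export
write_conditional_transformer <- function(transformer, path) {
  stopifnot(inherits(transformer, "conditional_transformer"))
  obj <- list(knots = transformer$knots, labels = transformer$labels,
              coef = lapply(transformer$coef, function(cf) {
                if (is.null(cf)) NULL else list(names = names(cf), values = unname(cf))
              }),
              kept = transformer$kept)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_conditional_transformer
#' @export
read_conditional_transformer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  coefs <- lapply(obj$coef, function(cf) {
    if (is.null(cf) || length(cf) == 0) return(NULL)
    setNames(as.numeric(unlist(cf$values)), as.character(unlist(cf$names)))
  })
  kept <- lapply(obj$kept, function(x) if (length(x)) as.integer(unlist(x)) else NULL)
  structure(list(knots = as.numeric(unlist(obj$knots)), coef = coefs,
                 kept = kept, labels = as.character(unlist(obj$labels))),
            class = "conditional_transformer")
}

#' Method 6: growth-curve parameters
#'
#' Two-step encoding: first an ordinary least-squares polynomial of degree
#' `degree` is fitted to each subject's measurements with age as the
#' independent variable (per subject, in long format); then the subject's
#' summary features are the mean of their measurements plus the fitted curve
#' coefficients (`b_age`, and for higher degrees `b_age2`, `b_age3`),
#' optionally with the standard error of the (linear) slope coefficient as an
#' indication of how much the measurements fluctuate around the curve.
#'
#' Fitting centres each subject's ages at their mean internally for numerical
#' conditioning and maps the coefficients back to the raw-age basis, so the
#' reported `b_age` etc. are raw-basis values. The output is invariant to the
#' ordering of a subject's records.
#'
#' @param x a [long_table()] of SDS records, or a [wide_matrix()] (treated as
#'   observations at the knot ages).
#' @param degree polynomial degree, 1 (linear), 2 (quadratic) or 3 (cubic).
#' @param include_se add the slope standard error as a feature. Subjects with
#'   exactly `degree + 1` points have a saturated fit and `se = 0`.
#' @param se_type `"slope"` (standard error of the raw-basis linear-age
#'   coefficient, default) or `"residual"` (root mean squared residual of the
#'   subject's curve).
#' @param demote if `TRUE`, subjects with fewer than `degree + 1` distinct
#'   ages are fitted at the highest feasible degree, the missing higher-order
#'   coefficients set to 0, and a warning issued; if `FALSE` (default) such
#'   subjects are an error.
#' @return a [feature_set()] with features `mean`, `b_age`, (`b_age2`,
#'   `b_age3`,) and optionally `se_slope`; per-subject point counts are kept
#'   in `state$n_points`.
#' @export
feat_growthcurve <- function(x, degree = 1, include_se = FALSE,
                             se_type = c("slope", "residual"), demote = FALSE) {
  se_type <- match.arg(se_type)
  if (!degree %in% 1:3) stop("feat_growthcurve: degree must be 1, 2 or 3")
  if (inherits(x, "wide_matrix")) {
    long <- data.frame(
      subject_id = rep(x$subject_ids, each = length(x$knots)),
      age = rep(x$knots, times = length(x$subject_ids)),
      value = as.vector(t(x$values)))
  } else {
    long <- as.data.frame(long_table(x))
  }
  ids <- unique(long$subject_id)
  idx <- split(seq_len(nrow(long)), factor(long$subject_id, levels = ids))
  p <- degree
  feat <- matrix(0, length(ids), 1 + p + as.integer(include_se))
  n_points <- integer(length(ids))
  n_demoted <- 0L
  for (i in seq_along(ids)) {
    a <- long$age[idx[[i]]]
    v <- long$value[idx[[i]]]
    n_distinct <- length(unique(a))
    n_points[i] <- length(a)
    d_i <- degree
    if (n_distinct < degree + 1) {
      if (!demote) {
        stop("feat_growthcurve: subject ", ids[i], " has ", n_distinct,
             " distinct age(s); degree ", degree,
             " needs at least ", degree + 1, " (see demote =)")
      }
      d_i <- max(n_distinct - 1, 0)
      n_demoted <- n_demoted + 1L
    }
    cf <- poly_subject_fit(a, v, d_i, se_type)
    feat[i, 1] <- mean(v)
    if (d_i >= 1) feat[i, 1 + seq_len(d_i)] <- cf$coef[seq_len(d_i)]
    if (include_se) feat[i, ncol(feat)] <- cf$se
  }
  if (n_demoted > 0) {
    warning("feat_growthcurve: degree demoted for ", n_demoted, " subject(s)")
  }
  nms <- c("mean", c("b_age", "b_age2", "b_age3")[seq_len(p)],
           if (include_se) "se_slope")
  feature_set(ids, feat, nms, state = list(degree = degree,
                                           n_points = setNames(n_points, ids)))
}

# per-subject polynomial OLS with mean-age centring, mapped back to the raw
# basis; returns raw-basis coefficients for powers 1..d and the slope (or
# residual) standard error
poly_subject_fit <- function(a, v, d, se_type) {
  if (d == 0) return(list(coef = numeric(0), se = 0))
  m <- mean(a)
  ac <- a - m
  M <- outer(ac, 0:d, "^")
  qrM <- qr(M)
  cf <- qr.coef(qrM, v)
  res <- v - drop(M %*% cf)
  df <- length(a) - (d + 1)
  s2 <- if (df > 0) sum(res^2) / df else 0
  # raw-basis coefficients: b_q = sum_{r>=q} C(r,q) c_r (-m)^(r-q)
  raw <- vapply(1:d, function(q) {
    r <- q:d
    sum(choose(r, q) * cf[r + 1] * (-m)^(r - q))
  }, numeric(1))
  se <- if (se_type == "residual") {
    sqrt(s2)
  } else {
    # delta method for the raw linear coefficient b_1 = sum r c_r (-m)^(r-1)
    w <- c(0, vapply(1:d, function(r) r * (-m)^(r - 1), numeric(1)))
    XtXi <- solve_ridge(crossprod(M))
    sqrt(max(s2 * drop(t(w) %*% XtXi %*% w), 0))
  }
  list(coef = raw, se = se)
}
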