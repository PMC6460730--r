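# Logistic / linear prediction models on a feature set, with the automatic
# collinearity pruning regression software applies: columns numerically in
# the span of previously entered columns (plus the intercept) are removed
# before fitting.

#' Drop numerically aliased design columns
#'
#' Examines columns in entry order and drops any column that lies (to within
#' a relative tolerance) in the span of the intercept plus the columns kept so
#' far. This emulates the "removed from the model as a result of collinearity"
#' behaviour of standard regression software, with the entry-order convention
#' made explicit: when a set of columns is linearly dependent the
#' later-entered ones are dropped. The operation is idempotent.
#'
#' @param X numeric matrix with finite entries.
#' @param names column labels (default: `colnames(X)`).
#' @param tol relative tolerance: a column is aliased when its residual norm
#'   after projection is `<= tol` times its own norm (default 1e-8).
#' @return list with `X` (kept columns), `kept_names`, `dropped_names`.
#' @examples
#' X <- cbind(a = rnorm(10), b = rnorm(10))
#' drop_aliased(cbind(X, ab = X[, 1] + X[, 2]))$dropped_names  # "ab"
#' @export
drop_aliased <- function(X, names = colnames(X), tol = 1e-8) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("drop_aliased: non-finite entries")
  if (is.null(names)) names <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  basis <- matrix(1, n, 1)  # intercept is always in the span and never dropped
  keep <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    cj <- X[, j]
    r <- qr.resid(qr(basis), cj)
    if (sqrt(sum(r^2)) > tol * max(sqrt(sum(cj^2)), .Machine$double.eps)) {
      keep[j] <- TRUE
      basis <- cbind(basis, cj)
    }
  }
  if (!any(keep)) stop("drop_aliased: no informative predictors (all columns aliased with the constant)")
  list(X = X[, keep, drop = FALSE], kept_names = names[keep],
       dropped_names = names[!keep])
}

#' Fit a collinearity-pruned logistic or linear prediction model
#'
#' Prunes aliased columns with [drop_aliased()], then fits by maximum
#' likelihood (logistic, IRLS to a 1e-10 deviance tolerance) or ordinary least
#' squares (linear). The intercept is always included. Log-likelihoods of the
#' fitted and of the intercept-only model are stored for the R-squared
#' measures in [nagelkerke_r2()] and [adjusted_r2()].
#'
#' @param features a [feature_set()] or a plain numeric matrix with column
#'   names.
#' @param y outcome vector: 0/1 (or logical) for `family = "logistic"`,
#'   numeric for `family = "linear"`.
#' @param family `"logistic"` or `"linear"`.
#' @param tol aliasing tolerance passed to [drop_aliased()].
#' @param force return a non-converged logistic fit (flagged) instead of
#'   erroring.
#' @return a `predmodel` object: `family`, `coef` (intercept first),
#'   `kept_names`, `dropped_names`, `loglik`, `loglik_null`, `n`, `p`,
#'   `fitted` (training scores: probabilities or predictions), `r_squared`
#'   (linear only), `separation` flag (logistic only).
#' @export
fit_predmodel <- function(features, y, family = c("logistic", "linear"),
                          tol = 1e-8, force = FALSE) {
  family <- match.arg(family)
  X <- if (inherits(features, "feature_set")) features$X else as.matrix(features)
  if (nrow(X) != length(y)) stop("fit_predmodel: X/y length mismatch")
  if (any(is.na(y))) stop("fit_predmodel: missing outcome values")
  if (family == "logistic") {
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1))) stop("fit_predmodel: logistic outcome must be 0/1")
    if (length(unique(y)) < 2) stop("fit_predmodel: outcome has a single class")
  } else {
    y <- as.numeric(y)
  }
  pr <- drop_aliased(X, tol = tol)
  dat <- data.frame(.y = y, pr$X, check.names = FALSE)
  f <- stats::as.formula(paste0(".y ~ `", paste(pr$kept_names, collapse = "` + `"), "`"))
  separation <- FALSE
  if (family == "logistic") {
    withCallingHandlers(
      fit <- glm(f, data = dat, family = binomial(),
                 control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    if (!fit$converged && !force && !separation) {
      stop("fit_predmodel: IRLS did not converge")
    }
    if (separation) {
      warning("fit_predmodel: (quasi-)separation detected; coefficients from the capped iteration returned")
    }
    null_ll <- as.numeric(logLik(glm(y ~ 1, family = binomial())))
    scores <- as.numeric(fit$fitted.values)
    r2 <- NA_real_
  } else {
    fit <- lm(f, data = dat)
    null_ll <- as.numeric(logLik(lm(y ~ 1)))
    scores <- as.numeric(fit$fitted.values)
    r2 <- 1 - sum((y - scores)^2) / sum((y - mean(y))^2)
  }
  cf <- coef(fit)
  names(cf) <- c("(Intercept)", pr$kept_names)
  structure(list(
    family = family,
    coef = cf,
    kept_names = pr$kept_names,
    dropped_names = pr$dropped_names,
    loglik = as.numeric(logLik(fit)),
    loglik_null = null_ll,
    n = length(y),
    p = length(pr$kept_names),
    fitted = scores,
    r_squared = r2,
    separation = if (family == "logistic") separation else NA,
    converged = if (family == "logistic") fit$converged else TRUE
  ), class = "predmodel")
}

#' @export
print.predmodel <- function(x, ...) {
  cat("Prediction model (", x$family, "): n = ", x$n, ", predictors kept = ",
      x$p, "\n", sep = "")
  if (length(x$dropped_names)) {
    cat("  dropped (collinearity): ", paste(x$dropped_names, collapse = ", "), "\n", sep = "")
  }
  print(round(x$coef, 4))
  invisible(x)
}

#' Predict scores from a fitted prediction model
#'
#' @param object a `predmodel`.
#' @param features a [feature_set()] or matrix providing all kept features by
#'   name; features dropped at fit time are ignored.
#' @param ... unused.
#' @return numeric scores: probabilities in (0, 1) for logistic models,
#'   real-valued predictions for linear models.
#' @export
predict.predmodel <- function(object, features, ...) {
  X <- if (inherits(features, "feature_set")) features$X else as.matrix(features)
  miss <- setdiff(object$kept_names, colnames(X))
  if (length(miss)) {
    stop("predict.predmodel: missing kept feature(s): ", paste(miss, collapse = ", "))
  }
  eta <- unname(object$coef[1] +
                  drop(X[, object$kept_names, drop = FALSE] %*% object$coef[-1]))
  if (object$family == "logistic") stats::plogis(eta) else eta
}

#' Serialize / restore a prediction model as JSON
#'
#' @param model a `predmodel`.
#' @param path JSON file path.
#' @export
write_predmodel <- function(model, path) {
  stopifnot(inherits(model, "predmodel"))
  obj <- list(family = model$family,
              coef_names = names(model$coef), coef = unname(model$coef),
              kept_names = model$kept_names, dropped_names = model$dropped_names,
              loglik = model$loglik, loglik_null = model$loglik_null,
              n = model$n, p = model$p)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_predmodel
#' @export
read_predmodel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(family = obj$family,
                 coef = setNames(as.numeric(obj$coef), obj$coef_names),
                 kept_names = as.character(obj$kept_names),
                 dropped_names = as.character(obj$dropped_names),
                 loglik = obj$loglik, loglik_null = obj$loglik_null,
                 n = obj$n, p = obj$p, fitted = NULL,
                 r_squared = NA_real_, separation = NA, converged = TRUE),
            class = "predmodel")
}
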