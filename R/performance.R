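# Predictive-quality surface: AUC (Mann-Whitney estimate), adjusted
# Nagelkerke R-squared for logistic models, adjusted R-squared for linear
# models, and the DeLong test for comparing two correlated AUCs.

#' Area under the ROC curve (Mann-Whitney estimate)
#'
#' The probability that a randomly chosen case outscores a randomly chosen
#' control, with tied pairs counted 0.5. Computed via midranks, which is
#' exactly the normalised Mann-Whitney U statistic (and therefore agrees with
#' exhaustive pair counting).
#'
#' @param scores numeric scores, higher = more case-like.
#' @param labels binary labels (0/1 or logical); both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.8, 0.6, 0.7, 0.1), c(1, 1, 0, 0))  # 3 of 4 pairs -> 0.75
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("auc: length mismatch")
  if (!all(labels %in% c(0, 1))) stop("auc: labels must be binary")
  m <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (m == 0 || n0 == 0) stop("auc: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n0)
}

# midrank placement values: for each case, the fraction of controls it beats
# (ties 0.5), and for each control, the fraction of cases beating it
placement_values <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  m <- length(cases)
  n0 <- length(controls)
  r_all <- rank(c(cases, controls), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(cases, ties.method = "average")) / n0
  v01 <- 1 - (r_all[m + seq_len(n0)] - rank(controls, ties.method = "average")) / m
  list(v10 = v10, v01 = v01)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors evaluated on the same subjects via
#' the covariance of their placement-value (structural-component)
#' representations: `var_diff = var(auc1) + var(auc2) - 2 cov`, `z =
#' (auc1 - auc2) / sqrt(var_diff)`, two-sided normal p-value. No continuity
#' correction. Identical score vectors (or any strictly increasing transform
#' of one into the other) give `z = 0`, `p = 1`.
#'
#' @param scores1,scores2 score vectors aligned to the same subjects.
#' @param labels binary labels; both classes must be present.
#' @return a `delong_result`: `auc1`, `auc2`, `var_diff`, `z`, `p`.
#' @export
delong_test <- function(scores1, scores2, labels) {
  labels <- as.numeric(labels)
  if (length(scores1) != length(scores2) || length(scores1) != length(labels)) {
    stop("delong_test: length mismatch")
  }
  if (!all(labels %in% c(0, 1))) stop("delong_test: labels must be binary")
  m <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (m == 0 || n0 == 0) stop("delong_test: both classes must be present")
  p1 <- placement_values(scores1, labels)
  p2 <- placement_values(scores2, labels)
  auc1 <- mean(p1$v10)
  auc2 <- mean(p2$v10)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  S <- s10 / m + s01 / n0
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (var_diff < -1e-12) stop("delong_test: negative variance of the AUC difference")
  var_diff <- max(var_diff, 0)
  if (var_diff == 0) {
    if (abs(auc1 - auc2) > 1e-12) {
      stop("delong_test: zero variance with unequal AUCs")
    }
    z <- 0
  } else {
    z <- (auc1 - auc2) / sqrt(var_diff)
  }
  structure(list(auc1 = auc1, auc2 = auc2, var_diff = var_diff,
                 z = z, p = 2 * pnorm(-abs(z))),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat("DeLong test: AUC ", format(x$auc1, digits = 4), " vs ",
      format(x$auc2, digits = 4), "; z = ", format(x$z, digits = 4),
      ", p = ", format(x$p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Nagelkerke R-squared for a logistic model
#'
#' `R2_N = (1 - exp(-LR/n)) / (1 - exp(2*LL0/n))` with `LR = 2 (LL - LL0)`.
#' The adjusted version penalises the likelihood-ratio statistic by the model
#' degrees of freedom, replacing `LR` with `max(0, LR - p)`; this is an
#' interpretation of the "adjusted" label (an optimism-style correction by df)
#' and the unadjusted value is always available alongside, so either reading
#' can be inspected.
#'
#' @param model a logistic [fit_predmodel()] fit.
#' @param adjusted apply the degrees-of-freedom penalty (default `TRUE`).
#' @return R-squared value (`<= 1`; the adjusted value never exceeds the
#'   unadjusted one).
#' @export
nagelkerke_r2 <- function(model, adjusted = TRUE) {
  stopifnot(inherits(model, "predmodel"))
  if (model$family != "logistic") {
    stop("nagelkerke_r2: model is not logistic; use adjusted_r2() for linear models")
  }
  lr <- 2 * (model$loglik - model$loglik_null)
  if (adjusted) lr <- max(0, lr - model$p)
  (1 - exp(-lr / model$n)) / (1 - exp(2 * model$loglik_null / model$n))
}

#' Adjusted R-squared for a linear model
#'
#' `1 - (1 - R2) (n - 1) / (n - p - 1)`; may be negative for uninformative
#' models.
#'
#' @param model a linear [fit_predmodel()] fit.
#' @return adjusted R-squared.
#' @export
adjusted_r2 <- function(model) {
  stopifnot(inherits(model, "predmodel"))
  if (model$family != "linear") {
    stop("adjusted_r2: model is not linear; use nagelkerke_r2() for logistic models")
  }
  if (model$n <= model$p + 1) stop("adjusted_r2: n must exceed p + 1")
  1 - (1 - model$r_squared) * (model$n - 1) / (model$n - model$p - 1)
}

#' Evaluate a fitted prediction model into a performance report
#'
#' Fills one report row in the style of a model-comparison table: for a
#' logistic model, the adjusted Nagelkerke R-squared and the AUC of the
#' predicted risks; for a linear model, the adjusted R-squared and the AUC of
#' the predicted continuous values against the observed binary label (the
#' cross-use of a linear model's predictions for discrimination).
#'
#' @param model a [fit_predmodel()] fit.
#' @param features the [feature_set()] to score (typically the training set:
#'   apparent performance).
#' @param y_binary observed binary outcome (state variable for the AUC).
#' @param label method label carried into the report.
#' @return a `performance_report`: `method_label`, `family`, `r2_kind`,
#'   `r2_value`, `r2_unadjusted`, `auc`, `n`, `dropped_names`, `scores`.
#' @export
evaluate_model <- function(model, features, y_binary, label = "") {
  stopifnot(inherits(model, "predmodel"))
  scores <- predict(model, features)
  if (model$family == "logistic") {
    r2_kind <- "nagelkerke_adjusted"
    r2 <- nagelkerke_r2(model, adjusted = TRUE)
    r2_un <- nagelkerke_r2(model, adjusted = FALSE)
  } else {
    r2_kind <- "adjusted_r2"
    r2 <- adjusted_r2(model)
    r2_un <- model$r_squared
  }
  structure(list(method_label = label, family = model$family,
                 r2_kind = r2_kind, r2_value = r2, r2_unadjusted = r2_un,
                 auc = auc(scores, y_binary), n = model$n,
                 dropped_names = model$dropped_names, scores = scores),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(x$method_label, " [", x$family, "]: ", x$r2_kind, " = ",
      format(x$r2_value, digits = 3), ", AUC = ", format(x$auc, digits = 3),
      ", n = ", x$n, sep = "")
  if (length(x$dropped_names)) {
    cat(" (dropped: ", paste(x$dropped_names, collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @rdname evaluate_model
#' @param x a `performance_report`.
#' @param path JSON file path.
#' @export
write_performance_report <- function(x, path) {
  stopifnot(inherits(x, "performance_report"))
  obj <- x[c("method_label", "family", "r2_kind", "r2_value",
             "r2_unadjusted", "auc", "n")]
  obj$dropped_names <- as.list(x$dropped_names)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
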