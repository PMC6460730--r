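# Broken-stick model: a linear mixed model whose fixed and random effects are
# the values of a piecewise-linear trajectory at fixed knot ages. Fitting it to
# irregular visit data and taking each subject's BLUP at the knots turns a
# ragged long table into a complete subjects-by-knots matrix.

#' Default knot grid
#'
#' Seven knots at birth, 3 months, 6 months, 14 months, 2, 3, and 5.5 years
#' (decimal years; months convert as m/12), matching the scheduled ages of
#' preventive child health care visits.
#'
#' @return numeric vector of knot ages in years.
#' @export
default_knots <- function() c(0, 0.25, 0.5, 14 / 12, 2, 3, 5.5)

check_knots <- function(knots) {
  knots <- as.numeric(knots)
  if (length(knots) < 2 || any(!is.finite(knots)) || any(diff(knots) <= 0)) {
    stop("knots must be a strictly increasing numeric vector of length >= 2")
  }
  knots
}

#' Piecewise-linear (hat function) basis weights
#'
#' For an age inside the knot span, returns the vector of hat-function weights
#' such that the weighted sum of knot values is the piecewise-linear
#' interpolant at that age. At most two weights are non-zero, all weights are
#' non-negative, and they sum to one. Ages falling exactly on a knot put the
#' full weight on that knot (segments are left-closed, `[knot_j, knot_{j+1})`).
#'
#' @param age decimal age(s) in years, inside `[min(knots), max(knots)]`.
#' @param knots strictly increasing knot ages.
#' @return for scalar `age` a length-`k` weight vector; use
#'   [hat_basis_matrix()] for many ages at once.
#' @examples
#' hat_basis(2.5, c(0, 1, 2, 3))  # 0.5 / 0.5 on the last two knots
#' @export
hat_basis <- function(age, knots) {
  knots <- check_knots(knots)
  if (length(age) != 1) stop("hat_basis expects a scalar age; see hat_basis_matrix")
  drop(hat_basis_matrix(age, knots))
}

#' @rdname hat_basis
#' @export
hat_basis_matrix <- function(age, knots) {
  knots <- check_knots(knots)
  k <- length(knots)
  if (any(!is.finite(age)) || any(age < knots[1]) || any(age > knots[k])) {
    stop("hat_basis: age outside the knot span [", knots[1], ", ", knots[k], "]")
  }
  B <- matrix(0, length(age), k)
  j <- findInterval(age, knots)          # left-closed: age == knot_j -> j
  at_end <- j >= k
  if (any(at_end)) B[cbind(which(at_end), k)] <- 1
  if (any(!at_end)) {
    i <- which(!at_end)
    jj <- j[i]
    h <- (age[i] - knots[jj]) / (knots[jj + 1] - knots[jj])
    B[cbind(i, jj)] <- 1 - h
    B[cbind(i, jj + 1)] <- h
  }
  colnames(B) <- paste0("k", seq_len(k))
  B
}

#' Complete subjects-by-knots matrix
#'
#' Container for the output of [predict_knot_values()]: one row per subject,
#' one column per knot age, no missing entries.
#'
#' @param subject_ids vector of subject identifiers (one per row).
#' @param knots knot ages (one per column).
#' @param values numeric matrix, `length(subject_ids)` x `length(knots)`,
#'   all entries finite.
#' @return a `wide_matrix` object.
#' @export
wide_matrix <- function(subject_ids, knots, values) {
  knots <- check_knots(knots)
  values <- as.matrix(values)
  if (nrow(values) != length(subject_ids) || ncol(values) != length(knots)) {
    stop("wide_matrix: dimensions do not match subjects/knots")
  }
  if (any(!is.finite(values))) stop("wide_matrix: all entries must be finite")
  if (anyDuplicated(subject_ids)) stop("wide_matrix: duplicate subject ids")
  dimnames(values) <- list(as.character(subject_ids), paste0("age_", format(knots, trim = TRUE)))
  structure(list(subject_ids = subject_ids, knots = knots, values = values),
            class = "wide_matrix")
}

#' @export
print.wide_matrix <- function(x, ...) {
  cat("Wide matrix: ", length(x$subject_ids), " subjects x ",
      length(x$knots), " knots (ages ", paste(format(x$knots), collapse = ", "),
      ")\n", sep = "")
  print(head(x$values, 4))
  if (nrow(x$values) > 4) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.wide_matrix <- function(x, ...) {
  data.frame(subject_id = x$subject_ids, x$values, check.names = FALSE,
             row.names = NULL)
}

#' @rdname wide_matrix
#' @param path CSV path; columns `subject_id` then one column per knot age.
#' @param x a `wide_matrix`.
#' @export
write_wide_matrix <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname wide_matrix
#' @export
read_wide_matrix <- function(path) {
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  knots <- as.numeric(sub("^age_", "", names(d)[-1]))
  wide_matrix(d$subject_id, knots, as.matrix(d[, -1, drop = FALSE]))
}

# records outside the knot span are dropped (never extrapolated); returns the
# kept long table plus the count, messaging when anything is dropped
drop_out_of_span <- function(long, knots, quiet = FALSE) {
  keep <- long$age >= knots[1] & long$age <= knots[length(knots)]
  n_drop <- sum(!keep)
  if (n_drop > 0 && !quiet) {
    message("broken stick: dropped ", n_drop,
            " record(s) outside the knot span [", knots[1], ", ",
            knots[length(knots)], "]")
  }
  list(long = long[keep, , drop = FALSE], n_dropped = n_drop)
}

#' Fit the broken-stick linear mixed model
#'
#' Fits `value = B(age) %*% (beta + b_i) + e` to long-format SDS data, where
#' `B(age)` is the hat-function basis over `knots`, `beta` are the population
#' mean SDS values at the knots, `b_i ~ N(0, re_cov)` are subject-specific
#' deviations at the knots, and `e ~ N(0, sigma2)` is measurement noise.
#' Estimation uses (restricted) maximum likelihood via [lme4::lmer()]; if the
#' optimiser fails or does not converge, a closed-form EM estimator takes over
#' (maximum likelihood; reported in `fit_info$engine`).
#'
#' @param long a [long_table()] on the SDS scale. Records with ages outside
#'   the knot span are dropped with a message (the model never extrapolates).
#' @param knots knot ages; default [default_knots()].
#' @param method `"reml"` (default) or `"ml"`.
#' @param cov_structure `"unstructured"` (default), `"diagonal"`, or `"cs"`
#'   (compound symmetry). The unstructured 7-knot model estimates 28
#'   covariance parameters; the cheaper structures suit small cohorts.
#'   `"cs"` is fitted by the EM engine with a structured M-step.
#' @param engine `"auto"` (lmer, EM fallback), `"lmer"`, or `"em"`.
#' @param force if `TRUE`, a non-converged fit is returned (flagged in
#'   `fit_info`) instead of raising an error.
#' @param quiet suppress progress/drop messages.
#' @return A `broken_stick` model object with elements `knots`, `beta`
#'   (fixed effects at the knots), `re_cov` (random-effect covariance),
#'   `sigma2` (residual variance), and `fit_info` (log-likelihood, counts,
#'   convergence flag, engine).
#' @seealso [predict_knot_values()] to obtain the complete wide matrix.
#' @export
fit_broken_stick <- function(long, knots = default_knots(),
                             method = c("reml", "ml"),
                             cov_structure = c("unstructured", "diagonal", "cs"),
                             engine = c("auto", "lmer", "em"),
                             force = FALSE, quiet = FALSE) {
  method <- match.arg(method)
  cov_structure <- match.arg(cov_structure)
  engine <- match.arg(engine)
  knots <- check_knots(knots)
  long <- long_table(long)
  sp <- drop_out_of_span(long, knots, quiet = quiet)
  long <- sp$long
  if (nrow(long) == 0) stop("fit_broken_stick: no records inside the knot span")
  k <- length(knots)
  B <- hat_basis_matrix(long$age, knots)
  id <- factor(long$subject_id)

  if (cov_structure == "cs" && engine %in% c("auto", "lmer")) engine <- "em"

  fit <- NULL
  engine_used <- engine
  if (engine %in% c("auto", "lmer")) {
    fit <- tryCatch(
      fit_bs_lmer(long$value, B, id, method = method,
                  cov_structure = cov_structure),
      error = function(e) e
    )
    if (inherits(fit, "error") || !fit$converged) {
      if (engine == "lmer" && inherits(fit, "error")) stop(fit)
      if (engine == "auto" && (inherits(fit, "error") || !fit$converged)) {
        if (!quiet) {
          message("broken stick: lmer ",
                  if (inherits(fit, "error")) "failed" else "did not converge",
                  "; falling back to the EM estimator")
        }
        fit <- NULL
        engine_used <- "em"
      }
    } else {
      engine_used <- "lmer"
    }
    # a singular fit with collapsed residual variance sits on a degenerate
    # boundary where BLUPs cannot interpolate; the EM estimator handles it
    if (engine == "auto" && !is.null(fit) && !inherits(fit, "error") &&
        isTRUE(fit$singular) && fit$sigma2 < 1e-6) {
      if (!quiet) {
        message("broken stick: singular boundary fit with zero residual variance; refitting with the EM estimator")
      }
      fit <- NULL
      engine_used <- "em"
    }
  }
  if (is.null(fit) || engine_used == "em") {
    fit <- fit_bs_em(long$value, B, id, cov_structure = cov_structure)
    engine_used <- "em"
  }

  if (!fit$converged && !force) {
    stop("fit_broken_stick: estimation did not converge (use force = TRUE to keep the fit)")
  }

  beta <- setNames(as.numeric(fit$beta), colnames(B))
  re_cov <- (fit$G + t(fit$G)) / 2
  dimnames(re_cov) <- list(colnames(B), colnames(B))
  structure(list(
    knots = knots,
    beta = beta,
    re_cov = re_cov,
    sigma2 = max(fit$sigma2, 0),
    fit_info = list(loglik = fit$loglik, method = method,
                    cov_structure = cov_structure, engine = engine_used,
                    n_subjects = nlevels(id), n_records = nrow(long),
                    n_dropped_records = sp$n_dropped,
                    converged = fit$converged,
                    singular = isTRUE(fit$singular))
  ), class = "broken_stick")
}

# lmer backend: random coefficients on the hat basis, no intercept
fit_bs_lmer <- function(y, B, id, method, cov_structure) {
  dat <- data.frame(.y = y, .id = id)
  dat <- cbind(dat, as.data.frame(B))
  terms <- paste(colnames(B), collapse = " + ")
  bar <- if (cov_structure == "diagonal") "||" else "|"
  f <- stats::as.formula(paste0(".y ~ 0 + ", terms, " + (0 + ", terms, " ", bar, " .id)"))
  ctrl <- lme4::lmerControl(check.nobs.vs.nRE = "ignore",
                            check.nobs.vs.nlev = "ignore",
                            calc.derivs = FALSE)
  m <- suppressWarnings(suppressMessages(
    lme4::lmer(f, data = dat, REML = (method == "reml"), control = ctrl)))
  msgs <- unlist(m@optinfo$conv$lme4$messages)
  # a boundary (singular) fit is a valid REML estimate, not a failure
  singular <- lme4::isSingular(m, tol = 1e-6)
  msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
  conv <- length(msgs) == 0 && m@optinfo$conv$opt == 0
  vc <- lme4::VarCorr(m)
  G <- matrix(0, ncol(B), ncol(B))
  for (blk in vc) {
    nm <- match(rownames(blk), colnames(B))
    G[nm, nm] <- G[nm, nm] + as.matrix(blk)[seq_along(nm), seq_along(nm)]
  }
  list(beta = lme4::fixef(m)[colnames(B)], G = G,
       sigma2 = stats::sigma(m)^2, loglik = as.numeric(stats::logLik(m)),
       converged = conv, singular = singular)
}

# EM backend for the random-coefficient model; closed-form E and M steps.
# cov_structure constrains the M-step: "diagonal" keeps only the diagonal,
# "cs" projects onto compound symmetry (common variance, common covariance).
fit_bs_em <- function(y, B, id, cov_structure = "unstructured",
                      maxit = 1000, tol = 1e-7) {
  ids <- levels(id)
  n <- length(ids)
  k <- ncol(B)
  Xi <- split.data.frame(B, id)
  yi <- split(y, id)
  beta <- qr.solve(B, y)
  G <- diag(stats::var(y), k)
  s2 <- stats::var(y) / 2
  N <- length(y)
  loglik <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    SB <- matrix(0, k, k)
    XtX <- matrix(0, k, k)
    Xtr <- numeric(k)
    rss <- 0
    ll <- 0
    for (i in seq_len(n)) {
      X1 <- as.matrix(Xi[[i]]); y1 <- yi[[i]]
      V <- X1 %*% G %*% t(X1) + diag(s2, nrow(X1))
      Vi <- solve_ridge(V)
      r0 <- y1 - X1 %*% beta
      K <- G %*% t(X1) %*% Vi
      bi <- K %*% r0
      Ci <- G - K %*% X1 %*% G
      SB <- SB + bi %*% t(bi) + Ci
      r <- r0 - X1 %*% bi
      rss <- rss + sum(r^2) + sum(diag(X1 %*% Ci %*% t(X1)))
      XtX <- XtX + crossprod(X1)
      Xtr <- Xtr + crossprod(X1, y1 - X1 %*% bi)
      ll <- ll - 0.5 * (determinant(V)$modulus + drop(t(r0) %*% Vi %*% r0) +
                          nrow(X1) * log(2 * pi))
    }
    beta_new <- drop(solve_ridge(XtX) %*% Xtr)
    G_new <- SB / n
    G_new <- switch(cov_structure,
                    unstructured = G_new,
                    diagonal = diag(diag(G_new), k),
                    cs = {
                      v <- mean(diag(G_new))
                      c0 <- mean(G_new[upper.tri(G_new)])
                      m <- matrix(c0, k, k); diag(m) <- v; m
                    })
    s2_new <- max(rss / N, 1e-12)
    delta <- max(abs(beta_new - beta), abs(G_new - G), abs(s2_new - s2),
                 abs(ll - loglik) / (abs(ll) + 1))
    beta <- beta_new
    G <- (G_new + t(G_new)) / 2
    s2 <- s2_new
    loglik <- as.numeric(ll)
    if (delta < tol) { converged <- TRUE; break }
  }
  list(beta = beta, G = G, sigma2 = s2, loglik = loglik, converged = converged)
}

# BLUP of the random effects, b = G X' (X G X' + s2 I)^{-1} r, computed via
# the eigendecomposition of X G X'. Null-space components contribute exactly
# zero (X G X' u = 0 implies G X' u = 0 for PSD G) but amplify rounding noise
# by 1/s2 when s2 is near zero, so they are truncated; this keeps the
# noiseless limit (s2 -> 0 with fully observed subjects interpolates the
# observations) numerically exact.
blup_deviation <- function(X1, r, G, s2) {
  A <- X1 %*% G %*% t(X1)
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  keep <- e$values > max(e$values, 0) * 1e-13
  if (!any(keep)) return(numeric(ncol(X1)))
  U <- e$vectors[, keep, drop = FALSE]
  w <- drop(crossprod(U, r)) / (e$values[keep] + s2)
  drop(G %*% crossprod(X1, U %*% w))
}

# solve() with a ridge-regularised retry for (near-)singular matrices
solve_ridge <- function(V) {
  out <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(out)) {
    ridge <- 1e-8 * mean(diag(V)) + 1e-12
    out <- solve(V + diag(ridge, nrow(V)))
  }
  out
}

#' @export
print.broken_stick <- function(x, ...) {
  cat("Broken-stick model (", length(x$knots), " knots: ",
      paste(format(x$knots), collapse = ", "), " y)\n", sep = "")
  cat("  engine: ", x$fit_info$engine, " (", x$fit_info$method, ", ",
      x$fit_info$cov_structure, "), converged: ", x$fit_info$converged,
      "\n", sep = "")
  cat("  subjects: ", x$fit_info$n_subjects, ", records: ",
      x$fit_info$n_records, ", residual SD: ",
      format(sqrt(x$sigma2), digits = 4), "\n", sep = "")
  cat("  knot means (SDS):\n")
  print(round(x$beta, 3))
  invisible(x)
}

#' Predict subject-specific values at the knots (BLUP)
#'
#' For each subject, computes the best linear unbiased prediction of the
#' trajectory at the knot ages given that subject's observed records:
#' `beta + re_cov %*% t(B_i) %*% solve(V_i, y_i - B_i %*% beta)` with
#' `V_i = B_i re_cov B_i' + sigma2 I`. Subjects with many records are barely
#' shrunk towards the population curve; subjects with few records strongly so;
#' a subject with no usable records would be predicted at the population mean,
#' but is excluded here (with a warning) because the input table defines the
#' prediction set.
#'
#' @param model a fitted [fit_broken_stick()] model.
#' @param long a [long_table()] on the SDS scale; out-of-span records are
#'   dropped with a message.
#' @return a [wide_matrix()] of predicted knot values, one row per subject
#'   with at least one in-span record.
#' @export
predict_knot_values <- function(model, long) {
  stopifnot(inherits(model, "broken_stick"))
  long <- long_table(long)
  all_ids <- unique(long$subject_id)
  sp <- drop_out_of_span(long, model$knots)
  long <- sp$long
  kept_ids <- unique(long$subject_id)
  n_excluded <- length(setdiff(all_ids, kept_ids))
  if (n_excluded > 0) {
    warning("predict_knot_values: ", n_excluded,
            " subject(s) with no usable records excluded")
  }
  if (length(kept_ids) == 0) stop("predict_knot_values: no subjects with usable records")
  k <- length(model$knots)
  B <- hat_basis_matrix(long$age, model$knots)
  G <- model$re_cov
  s2 <- model$sigma2
  beta <- model$beta
  idx <- split(seq_len(nrow(long)), factor(long$subject_id, levels = kept_ids))
  vals <- matrix(NA_real_, length(kept_ids), k)
  for (i in seq_along(kept_ids)) {
    X1 <- B[idx[[i]], , drop = FALSE]
    y1 <- long$value[idx[[i]]]
    vals[i, ] <- beta + blup_deviation(X1, y1 - drop(X1 %*% beta), G, s2)
  }
  wide_matrix(kept_ids, model$knots, vals)
}

#' Serialize / restore a broken-stick model as JSON
#'
#' @param model a `broken_stick` object.
#' @param path JSON file path.
#' @return `read_broken_stick()` returns the restored model;
#'   `write_broken_stick()` returns `path` invisibly.
#' @export
write_broken_stick <- function(model, path) {
  stopifnot(inherits(model, "broken_stick"))
  obj <- list(knots = model$knots, beta = unname(model$beta),
              re_cov = as.numeric(t(model$re_cov)),  # row-major
              sigma2 = model$sigma2, fit_info = model$fit_info)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_broken_stick
#' @export
read_broken_stick <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- length(obj$knots)
  knots <- as.numeric(obj$knots)
  beta <- setNames(as.numeric(obj$beta), paste0("k", seq_len(k)))
  re_cov <- matrix(as.numeric(obj$re_cov), k, k, byrow = TRUE,
                   dimnames = list(names(beta), names(beta)))
  structure(list(knots = knots, beta = beta, re_cov = re_cov,
                 sigma2 = as.numeric(obj$sigma2),
                 fit_info = obj$fit_info),
            class = "broken_stick")
}
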