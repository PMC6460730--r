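# Workbench: ingest or simulate a cohort, regularise it onto the knot grid,
# run every predictor encoding through model fitting and evaluation, and emit
# a comparison table (one row per method x family) with DeLong tests against
# a reference method.

#' Select the outcome record per subject
#'
#' Within an age window, picks for each subject the record measured closest to
#' the target age; on an exact tie in distance the earlier record wins.
#' Subjects with no in-window record are excluded and counted.
#'
#' @param long a [long_table()] covering the outcome ages.
#' @param window length-2 numeric, the eligible age window (default 9-10.5 y).
#' @param target_age aimed outcome age (default 10 y).
#' @return data frame `subject_id`, `age`, `value` (one row per retained
#'   subject), with attribute `"n_excluded"`.
#' @export
select_outcome <- function(long, window = c(9, 10.5), target_age = 10) {
  long <- long_table(long)
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("select_outcome: window must be (min, max) with min < max")
  }
  inw <- long[long$age >= window[1] & long$age <= window[2], , drop = FALSE]
  all_ids <- unique(long$subject_id)
  if (nrow(inw) == 0) stop("select_outcome: no records inside the window")
  picks <- lapply(split(inw, factor(inw$subject_id)), function(d) {
    dist <- abs(d$age - target_age)
    # ties broken towards the earlier record (rows are age-sorted)
    d[which.min(dist), , drop = FALSE]
  })
  out <- do.call(rbind, picks)[, c("subject_id", "age", "value")]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- length(setdiff(all_ids, out$subject_id))
  out
}

#' Apply the minimum-visit inclusion rule
#'
#' Removes subjects with fewer than `min_visits` records inside the predictor
#' age span (the usual cohort rule: at least two measurements between birth
#' and the last knot age).
#'
#' @param long a [long_table()].
#' @param span length-2 numeric age span (default 0-5.5 y).
#' @param min_visits minimum number of in-span records (default 2).
#' @return the filtered [long_table()], with attributes `"n_excluded"`
#'   (subjects removed) and `"n_retained"`.
#' @export
apply_inclusion <- function(long, span = c(0, 5.5), min_visits = 2) {
  long <- long_table(long)
  if (length(span) != 2 || span[1] >= span[2]) stop("apply_inclusion: invalid span")
  inspan <- long$age >= span[1] & long$age <= span[2]
  counts <- table(long$subject_id[inspan])
  keep_ids <- names(counts)[counts >= min_visits]
  if (length(keep_ids) == 0) stop("apply_inclusion: no subjects satisfy the rule")
  out <- long[long$subject_id %in% keep_ids, , drop = FALSE]
  class(out) <- c("long_table", "data.frame")
  attr(out, "n_excluded") <- length(unique(long$subject_id)) - length(keep_ids)
  attr(out, "n_retained") <- length(keep_ids)
  out
}

default_methods <- function() {
  list(
    list(label = "all", type = "all"),
    list(label = "single_best", type = "single", index = NULL),
    list(label = "summary_mean", type = "summary", stat = "mean"),
    list(label = "summary_max", type = "summary", stat = "max"),
    list(label = "change", type = "change", rate = FALSE),
    list(label = "conditional", type = "conditional"),
    list(label = "growthcurve", type = "growthcurve", degree = 3,
         include_se = FALSE)
  )
}

#' Comparison specification
#'
#' Defines which encodings to run, for which model families, on which knot
#' grid, and which method anchors the DeLong AUC comparisons.
#'
#' @param methods list of method recipes (label + type + options); default:
#'   all measurements, single best, summary mean, summary max, changes,
#'   conditional, and cubic growth-curve parameters.
#' @param families `"both"`, `"logistic"`, or `"linear"`.
#' @param knots knot grid.
#' @param outcome_window eligible outcome age window.
#' @param reference_method label anchoring the DeLong comparisons.
#' @return a `comparison_spec`.
#' @export
comparison_spec <- function(methods = default_methods(),
                            families = c("both", "logistic", "linear"),
                            knots = default_knots(),
                            outcome_window = c(9, 10.5),
                            reference_method = "all") {
  families <- match.arg(families)
  labels <- vapply(methods, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("comparison_spec: method labels must be unique")
  if (!reference_method %in% labels) {
    stop("comparison_spec: reference method '", reference_method, "' not among the methods")
  }
  structure(list(methods = methods, families = families,
                 knots = check_knots(knots), outcome_window = outcome_window,
                 reference_method = reference_method),
            class = "comparison_spec")
}

build_features <- function(recipe, wide, long, y_bin, demote = TRUE) {
  switch(recipe$type,
    all = feat_all(wide),
    single = {
      idx <- recipe$index
      if (is.null(idx)) idx <- as.integer(select_single_best(wide, y_bin))
      feat_single(wide, idx)
    },
    summary = feat_summary(wide, recipe$stat),
    change = feat_change(wide, rate = isTRUE(recipe$rate)),
    conditional = feat_conditional_fit(wide)$features,
    growthcurve = {
      src <- if (!is.null(long)) long else wide
      deg <- if (is.null(recipe$degree)) 3 else recipe$degree
      feat_growthcurve(src, degree = deg,
                       include_se = isTRUE(recipe$include_se),
                       demote = demote)
    },
    stop("unknown method type '", recipe$type, "'")
  )
}

describe_recipe <- function(recipe, knots) {
  ages <- paste(format(knots, trim = TRUE), collapse = ", ")
  switch(recipe$type,
    all = paste0("SDS at ages ", ages),
    single = "SDS at a single (best) age",
    summary = paste0(recipe$stat, " of SDS at ages ", ages),
    change = paste0(if (isTRUE(recipe$rate)) "first SDS and rate of change"
                    else "first SDS and changes between subsequent ages"),
    conditional = "first SDS and conditional SDS at later ages",
    growthcurve = paste0("mean and growth-curve coefficients (degree ",
                         if (is.null(recipe$degree)) 3 else recipe$degree, ")"),
    recipe$type)
}

#' Run the full method comparison
#'
#' Executes the pipeline: broken-stick regularisation of the long data onto
#' the knot grid (skipped when a complete `wide` matrix is supplied), each
#' featurisation recipe, pruned model fitting, evaluation, and a DeLong test
#' of each method's AUC against the reference method on the shared subjects.
#' All performance is apparent (models are fitted and evaluated on the same
#' cohort).
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()], or `NULL` when
#'   `long`/`outcomes` are given directly.
#' @param spec a [comparison_spec()].
#' @param long a [long_table()] of SDS records (ignored when `cohort` given).
#' @param outcomes data frame with `subject_id`, `y_bin`, and (for the linear
#'   family) `y_cont`.
#' @param wide optional precomputed [wide_matrix()]; when `NULL`, a
#'   broken-stick model is fitted to `long`.
#' @param demote passed to [feat_growthcurve()] so subjects with few visits
#'   are fitted at a reduced degree instead of erroring.
#' @param quiet suppress progress messages.
#' @return a `comparison_report`: `rows` (data frame, one row per method x
#'   family with r2, AUC, dropped columns and DeLong p vs reference),
#'   `scores` (per method/family), `broken_stick` (the fitted model or
#'   `NULL`), `spec`, and `provenance`.
#' @export
run_comparison <- function(cohort = NULL, spec = comparison_spec(),
                           long = NULL, outcomes = NULL, wide = NULL,
                           demote = TRUE, quiet = FALSE) {
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "sim_cohort"))
    long <- cohort$long
    outcomes <- cohort$outcomes
  }
  if (is.null(outcomes)) stop("run_comparison: outcomes are required")
  bs_model <- NULL
  if (is.null(wide)) {
    if (is.null(long)) stop("run_comparison: need long data or a wide matrix")
    if (!quiet) message("run_comparison: fitting the broken-stick model")
    bs_model <- fit_broken_stick(long, spec$knots, quiet = quiet)
    wide <- predict_knot_values(bs_model, long)
  }
  ids <- intersect(wide$subject_ids, outcomes$subject_id)
  if (length(ids) == 0) stop("run_comparison: no subjects shared between predictors and outcomes")
  wsel <- match(ids, wide$subject_ids)
  wide <- wide_matrix(ids, wide$knots, wide$values[wsel, , drop = FALSE])
  osel <- match(ids, outcomes$subject_id)
  y_bin <- outcomes$y_bin[osel]
  y_cont <- if ("y_cont" %in% names(outcomes)) outcomes$y_cont[osel] else NULL
  families <- switch(spec$families, both = c("logistic", "linear"),
                     spec$families)
  if ("linear" %in% families && is.null(y_cont)) {
    stop("run_comparison: linear family requested but outcomes lack y_cont")
  }

  rows <- list()
  scores <- list()
  for (recipe in spec$methods) {
    feats <- build_features(recipe, wide, long, y_bin, demote = demote)
    # align feature rows (growth-curve features come from the long table)
    fsel <- match(ids, feats$subject_ids)
    if (any(is.na(fsel))) stop("run_comparison: method '", recipe$label,
                               "' lacks features for some subjects")
    feats <- feature_set(ids, feats$X[fsel, , drop = FALSE], feats$names,
                         feats$state)
    for (fam in families) {
      y <- if (fam == "logistic") y_bin else y_cont
      model <- fit_predmodel(feats, y, family = fam)
      rep1 <- evaluate_model(model, feats, y_bin, label = recipe$label)
      key <- paste(recipe$label, fam, sep = ".")
      scores[[key]] <- rep1$scores
      rows[[key]] <- data.frame(
        method = recipe$label,
        model_includes = describe_recipe(recipe, spec$knots),
        family = fam, r2_kind = rep1$r2_kind, r2 = rep1$r2_value,
        r2_unadjusted = rep1$r2_unadjusted, auc = rep1$auc, n = rep1$n,
        dropped = paste(rep1$dropped_names, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL

  rows$delong_p_vs_reference <- NA_real_
  delong <- list()
  for (fam in families) {
    ref_key <- paste(spec$reference_method, fam, sep = ".")
    for (recipe in spec$methods) {
      key <- paste(recipe$label, fam, sep = ".")
      dl <- delong_test(scores[[key]], scores[[ref_key]], y_bin)
      delong[[key]] <- dl
      rows$delong_p_vs_reference[rows$method == recipe$label &
                                   rows$family == fam] <- dl$p
    }
  }

  structure(list(rows = rows, scores = scores, delong = delong,
                 broken_stick = bs_model, spec = spec,
                 provenance = list(n_subjects = length(ids),
                                   knots = spec$knots,
                                   reference_method = spec$reference_method)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 3, ...) {
  cat("Method comparison (", x$provenance$n_subjects, " subjects, reference: ",
      x$spec$reference_method, ")\n\n", sep = "")
  out <- x$rows[, c("method", "family", "r2", "auc", "dropped",
                    "delong_p_vs_reference")]
  out$r2 <- round(out$r2, digits)
  out$auc <- round(out$auc, digits)
  out$delong_p_vs_reference <- signif(out$delong_p_vs_reference, 2)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Write the comparison table as CSV
#'
#' Columns: `method, model_includes, family, r2_kind, r2, auc, dropped,
#' delong_p_vs_reference` — the machine-readable twin of a
#' methods-comparison table.
#'
#' @param report a `comparison_report`.
#' @param path CSV path.
#' @export
write_comparison_table <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  write.csv(report$rows[, c("method", "model_includes", "family", "r2_kind",
                            "r2", "r2_unadjusted", "auc", "n", "dropped",
                            "delong_p_vs_reference")],
            path, row.names = FALSE)
  invisible(path)
}
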