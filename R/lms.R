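# LMS z-score conversion: a growth reference is summarised per age by a
# skewness parameter L, median M and coefficient of variation S, and a raw
# measurement y becomes z = ((y/M)^L - 1)/(L*S), with the limit
# z = log(y/M)/S as L -> 0.

#' LMS growth reference table
#'
#' Validates a per-sex age grid of LMS parameters (skewness `L`, median `M`,
#' coefficient of variation `S`) used to convert raw measurements into age- and
#' sex-specific standard deviation scores.
#'
#' @param data data frame with columns `sex`, `age` (or `age_years`), `L`,
#'   `M`, `S`.
#' @return An `lms_reference`: the validated data frame, sorted by sex and age.
#' @details Invariants: within each sex ages are strictly increasing, with at
#'   least two rows (interpolation and lower-boundary extrapolation both need
#'   two support points); `M > 0` and `S > 0` everywhere.
#' @export
lms_reference <- function(data) {
  data <- as.data.frame(data)
  if ("age_years" %in% names(data) && !"age" %in% names(data)) {
    names(data)[names(data) == "age_years"] <- "age"
  }
  need <- c("sex", "age", "L", "M", "S")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("lms_reference: missing column(s): ", paste(miss, collapse = ", "))
  }
  data <- data[, need]
  for (cl in c("age", "L", "M", "S")) data[[cl]] <- as.numeric(data[[cl]])
  if (any(!is.finite(as.matrix(data[, c("age", "L", "M", "S")])))) {
    stop("lms_reference: non-finite entries")
  }
  if (any(data$M <= 0) || any(data$S <= 0)) {
    stop("lms_reference: M and S must be positive")
  }
  data <- data[order(data$sex, data$age), , drop = FALSE]
  for (sx in unique(data$sex)) {
    a <- data$age[data$sex == sx]
    if (length(a) < 2) stop("lms_reference: need >= 2 rows for sex '", sx, "'")
    if (any(diff(a) <= 0)) {
      stop("lms_reference: ages must be strictly increasing within sex '", sx, "'")
    }
  }
  rownames(data) <- NULL
  class(data) <- c("lms_reference", "data.frame")
  data
}

#' @rdname lms_reference
#' @param path CSV file with columns `sex, age_years, L, M, S` and a header.
#' @export
read_lms_reference <- function(path) {
  lms_reference(read.csv(path, stringsAsFactors = FALSE))
}

#' Interpolate LMS parameters at arbitrary ages
#'
#' Looks up `(L, M, S)` for one sex at the requested ages. Within the
#' reference age range each parameter is interpolated on the age axis
#' (linearly by default); below the first reference age the parameters are
#' linearly extrapolated from the first two rows, mirroring the common
#' practice of extending an infant reference that starts at 1-2 weeks down to
#' birth. Ages above the last reference age are an error: upper extrapolation
#' is never performed.
#'
#' @param ref an [lms_reference()].
#' @param sex sex level present in `ref`.
#' @param age numeric vector of decimal ages (years).
#' @param method `"linear"` (default) or `"spline"` (natural cubic spline)
#'   for interior interpolation; boundary extrapolation is always linear.
#' @return data frame with columns `L`, `M`, `S`, one row per age.
#' @examples
#' ref <- lms_reference(data.frame(sex = "f", age = 1:3,
#'                                 L = c(-1, -1, -1), M = c(3.5, 3.6, 3.8),
#'                                 S = c(0.1, 0.12, 0.14)))
#' lms_interpolate(ref, "f", c(0, 1.5, 3))
#' @export
lms_interpolate <- function(ref, sex, age, method = c("linear", "spline")) {
  method <- match.arg(method)
  stopifnot(inherits(ref, "lms_reference"))
  sub <- ref[ref$sex == sex, , drop = FALSE]
  if (nrow(sub) == 0) stop("lms_interpolate: unknown sex '", sex, "'")
  if (any(!is.finite(age))) stop("lms_interpolate: non-finite age")
  if (any(age > sub$age[nrow(sub)] + 1e-12)) {
    stop("lms_interpolate: age above last reference age (",
         sub$age[nrow(sub)], " y); upper extrapolation is not supported")
  }
  one <- function(param) {
    v <- sub[[param]]
    out <- numeric(length(age))
    below <- age < sub$age[1]
    if (any(below)) {
      # linear extrapolation through the first two reference rows
      slope <- (v[2] - v[1]) / (sub$age[2] - sub$age[1])
      out[below] <- v[1] + slope * (age[below] - sub$age[1])
    }
    if (any(!below)) {
      out[!below] <- if (method == "linear") {
        approx(sub$age, v, xout = age[!below], rule = 1)$y
      } else {
        spline(sub$age, v, xout = age[!below], method = "natural")$y
      }
    }
    out
  }
  data.frame(L = one("L"), M = one("M"), S = one("S"))
}

#' Convert a measurement to an LMS standard deviation score
#'
#' `z = ((y/M)^L - 1) / (L * S)`, with the logarithmic limit
#' `z = log(y/M) / S` used when `|L|` falls below `l_eps` (the two forms agree
#' to first order; the switch avoids 0/0).
#'
#' @param value positive measurement(s).
#' @param L,M,S LMS parameters (recycled against `value`); `M > 0`, `S > 0`.
#' @param l_eps threshold below which `|L|` is treated as zero (default 1e-7).
#' @return numeric SDS vector.
#' @examples
#' lms_zscore(17.6, L = 1, M = 16, S = 0.1)  # (17.6-16)/(16*0.1) = 1
#' @export
lms_zscore <- function(value, L, M, S, l_eps = 1e-7) {
  n <- max(length(value), length(L), length(M), length(S))
  value <- rep_len(value, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("lms_zscore: values must be positive and finite")
  }
  if (any(M <= 0) || any(S <= 0)) stop("lms_zscore: M and S must be positive")
  z <- ifelse(abs(L) < l_eps,
              log(value / M) / S,
              ((value / M)^L - 1) / (L * S))
  as.numeric(z)
}

#' Invert an LMS standard deviation score back to the measurement scale
#'
#' Exact inverse of [lms_zscore()]: `y = M * (1 + L*S*z)^(1/L)` (or
#' `M * exp(S*z)` in the `L -> 0` limit). Round-trip support for simulation
#' and testing.
#'
#' @inheritParams lms_zscore
#' @param z SDS value(s).
#' @return measurement-scale values.
#' @export
lms_inverse_zscore <- function(z, L, M, S, l_eps = 1e-7) {
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  if (any(M <= 0) || any(S <= 0)) stop("lms_inverse_zscore: M and S must be positive")
  base <- 1 + L * S * z
  bad <- abs(L) >= l_eps & base <= 0
  if (any(bad)) {
    stop("lms_inverse_zscore: z outside the invertible domain (1 + L*S*z <= 0)")
  }
  ifelse(abs(L) < l_eps, M * exp(S * z), M * base^(1 / L))
}

#' Convert a whole long table to standard deviation scores
#'
#' Applies [lms_interpolate()] and [lms_zscore()] record by record, keeping the
#' table shape: the returned `long_table` has `value` replaced by its SDS.
#'
#' @param long a [long_table()] of raw measurements with a usable `sex` column.
#' @param ref an [lms_reference()].
#' @param method interior interpolation method, see [lms_interpolate()].
#' @return a [long_table()] on the SDS scale.
#' @export
lms_convert <- function(long, ref, method = c("linear", "spline")) {
  method <- match.arg(method)
  long <- long_table(long)
  if (nrow(long) == 0) return(long)
  if (any(is.na(long$sex))) stop("lms_convert: sex is required for every record")
  out <- long
  for (sx in unique(long$sex)) {
    idx <- which(long$sex == sx)
    p <- tryCatch(
      lms_interpolate(ref, sx, long$age[idx], method = method),
      error = function(e) {
        stop("lms_convert: ", conditionMessage(e), " [first offending record: subject ",
             long$subject_id[idx[1]], "]", call. = FALSE)
      }
    )
    bad <- long$value[idx] <= 0
    if (any(bad)) {
      stop("lms_convert: non-positive measurement for subject ",
           long$subject_id[idx[which(bad)[1]]], " at age ",
           long$age[idx[which(bad)[1]]])
    }
    out$value[idx] <- lms_zscore(long$value[idx], p$L, p$M, p$S)
  }
  out
}
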