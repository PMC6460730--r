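#' Long-format growth records
#'
#' The universal input format: one row per measurement with a subject
#' identifier, sex, decimal age in years, and the measured value (raw units or
#' SDS). `long_table()` validates a data frame and stamps it with the
#' `"long_table"` class; downstream functions accept either a `long_table` or a
#' plain data frame with the same columns.
#'
#' @param data data frame with columns `subject_id`, `sex`, `age`, `value`
#'   (a column `age_years` is accepted as an alias for `age`). `sex` may be
#'   absent when no LMS conversion is needed; it is then filled with `NA`.
#' @return A `long_table`: a data frame with columns `subject_id`, `sex`,
#'   `age`, `value`, ordered by subject and age.
#' @details Invariants enforced: ages finite and non-negative; no duplicate
#'   (subject, age) pairs; values numeric. Records are sorted chronologically
#'   within subject, so each subject's rows read as successive visits.
#' @examples
#' long_table(data.frame(subject_id = 1, sex = "female", age = c(0, 1), value = c(13, 16)))
#' @export
long_table <- function(data) {
  data <- as.data.frame(data)
  if ("age_years" %in% names(data) && !"age" %in% names(data)) {
    names(data)[names(data) == "age_years"] <- "age"
  }
  need <- c("subject_id", "age", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("long_table: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"sex" %in% names(data)) data$sex <- NA_character_
  data <- data[, c("subject_id", "sex", "age", "value")]
  data$age <- as.numeric(data$age)
  data$value <- as.numeric(data$value)
  if (any(!is.finite(data$age)) || any(data$age < 0)) {
    stop("long_table: ages must be finite and non-negative")
  }
  key <- paste(data$subject_id, format(data$age, digits = 15))
  if (anyDuplicated(key)) {
    stop("long_table: duplicate (subject_id, age) pairs")
  }
  data <- data[order(data$subject_id, data$age), , drop = FALSE]
  rownames(data) <- NULL
  class(data) <- c("long_table", "data.frame")
  data
}

#' @export
print.long_table <- function(x, ...) {
  cat("Long-format growth table: ", nrow(x), " records, ",
      length(unique(x$subject_id)), " subjects, age range [",
      format(min(x$age)), ", ", format(max(x$age)), "]\n", sep = "")
  print(as.data.frame(head(x, 6)))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Read or write long-format growth records as CSV
#'
#' The CSV contract is `subject_id, sex, age_years, value` with a header row
#' (`sex` optional on read).
#'
#' @param path file path.
#' @param x a `long_table` (for writing).
#' @return `read_long_table()` returns a validated [long_table()];
#'   `write_long_table()` returns `path` invisibly.
#' @export
read_long_table <- function(path) {
  long_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_long_table
#' @export
write_long_table <- function(x, path) {
  out <- as.data.frame(x)
  names(out)[names(out) == "age"] <- "age_years"
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
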