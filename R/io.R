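#' Longitudinal CEL dataset
#'
#' The standard layout is one row per subject-month with columns `ID`
#' (subject label), `MONTH` (1-based consecutive integer), `DV`
#' (non-negative integer CEL count) and `STEROID` (0/1 dose flag).
#' `as_cel_dataset()` validates a data.frame and attaches the
#' `cel_dataset` class; violations are reported with row numbers.
#'
#' @param x A data.frame with the columns above (`STEROID` optional,
#'   defaults to 0).
#' @return A validated `cel_dataset` (a data.frame).
#' @export
as_cel_dataset <- function(x) {
  if (inherits(x, "cel_dataset")) return(x)
  if (!is.data.frame(x)) stop("dataset must be a data.frame", call. = FALSE)
  need <- c("ID", "MONTH", "DV")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"STEROID" %in% names(x)) x$STEROID <- 0L
  bad_dv <- which(!is.finite(x$DV) | x$DV < 0 | x$DV != floor(x$DV))
  if (length(bad_dv))
    stop("DV must be a non-negative integer; offending row(s): ",
         paste(utils::head(bad_dv, 5), collapse = ", "), call. = FALSE)
  bad_st <- which(!x$STEROID %in% c(0, 1))
  if (length(bad_st))
    stop("STEROID must be 0/1; offending row(s): ",
         paste(utils::head(bad_st, 5), collapse = ", "), call. = FALSE)
  for (id in unique(x$ID)) {
    m <- sort(x$MONTH[x$ID == id])
    if (length(m) == 0 || m[1] != 1 || !identical(as.integer(m),
                                                  seq_len(length(m))))
      stop("months of subject '", id,
           "' are not consecutive integers starting at 1", call. = FALSE)
  }
  x$DV <- as.integer(x$DV)
  x$MONTH <- as.integer(x$MONTH)
  x$STEROID <- as.integer(x$STEROID)
  class(x) <- c("cel_dataset", "data.frame")
  x
}

#' Read / write the standard dataset CSV
#'
#' Comma-separated, UTF-8, `.` decimal, header `ID,MONTH,DV,STEROID`.
#' `read_cel_dataset()` validates on load; the write/read round trip is the
#' identity.
#'
#' @param path File path.
#' @return `read_cel_dataset()`: a validated `cel_dataset`.
#' @export
read_cel_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as_cel_dataset(utils::read.csv(path))
}

#' @param x A `cel_dataset` (or coercible data.frame).
#' @rdname read_cel_dataset
#' @export
write_cel_dataset <- function(x, path) {
  x <- as_cel_dataset(x)
  utils::write.csv(as.data.frame(x)[, c("ID", "MONTH", "DV", "STEROID")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.cel_dataset <- function(x, ...) {
  cat("<cel_dataset>", length(unique(x$ID)), "subjects,",
      nrow(x), "subject-months,",
      sum(x$STEROID), "dose events\n")
  NextMethod()
}
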