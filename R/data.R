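# Small-data helpers: 2x2 tables, the bundled case-study tables, and CSV
# input/output for fitted results.

#' Build a 2x2 table as a grouped binary data set
#'
#' Returns a four-row data frame (one row per cell of the table) with an
#' outcome column, a 0/1 exposure column and a count column usable as
#' weights, so that a logistic fit on it is exactly the fit on the
#' record-level data.
#'
#' @param a exposed events, @param b exposed non-events,
#' @param c unexposed events, @param d unexposed non-events.
#' @param exposure name for the exposure column.
#' @return data frame with columns `outcome`, `<exposure>`, `n`.
#' @examples
#' two_by_two(2, 3, 12, 141)
#' @export
two_by_two <- function(a, b, c, d, exposure = "exposure") {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be nonnegative integers", call. = FALSE)
  if (sum(counts) == 0) stop("empty table", call. = FALSE)
  out <- data.frame(outcome = c(1, 0, 1, 0),
                    exposure = c(1, 1, 0, 0),
                    n = as.numeric(counts))
  names(out)[2] <- exposure
  out[out$n > 0, , drop = FALSE]
}

#' Bundled case-study tables
#'
#' `hydramnios_2x2()` is the unadjusted hydramnios / neonatal-death table
#' from a cohort of 2,992 births with 17 deaths: 1 death among 10
#' hydramnios pregnancies, 16 deaths among 2,982 without.
#' `vascular_2x2()` is the vascular disease / thromboembolic event
#' contingency table (2 events among 5 exposed, 12 among 153 unexposed).
#'
#' @return a grouped data frame as produced by [two_by_two()].
#' @export
hydramnios_2x2 <- function() two_by_two(1, 9, 16, 2966, "hydramnios")

#' @rdname hydramnios_2x2
#' @export
vascular_2x2 <- function() two_by_two(2, 3, 12, 141, "vascular")

#' Read a binary-outcome data set from CSV
#'
#' Expects a header row; the outcome column must be coded 0/1 and every
#' other retained column numeric.  An optional weight column is separated
#' out.  Covariates are used as given (no dummy coding or scaling):
#' multi-level factors should arrive as integer scores.
#'
#' @param file path to a CSV file.
#' @param outcome name of the 0/1 outcome column.
#' @param weight optional name of a nonnegative weight column.
#' @return data frame with attribute `"outcome"` (and `"weight"` if given).
#' @export
read_binary_csv <- function(file, outcome, weight = NULL) {
  d <- utils::read.csv(file, check.names = FALSE)
  if (!outcome %in% names(d))
    stop("outcome column '", outcome, "' not found", call. = FALSE)
  if (!is.null(weight) && !weight %in% names(d))
    stop("weight column '", weight, "' not found", call. = FALSE)
  if (!all(d[[outcome]] %in% c(0, 1)))
    stop("outcome column must be coded 0/1", call. = FALSE)
  num <- vapply(d, is.numeric, logical(1))
  if (!all(num)) stop("all columns must be numeric", call. = FALSE)
  attr(d, "outcome") <- outcome
  if (!is.null(weight)) attr(d, "weight") <- weight
  d
}

# One-row-per-term data frame used by the CSV/JSON writers.
sl_result_frame <- function(object) {
  cf <- coef(object)
  ci <- object$ci
  data.frame(method = object$method,
             term = names(cf),
             estimate = unname(cf),
             or = exp(unname(cf)),
             ci_low = unname(ci[, 1]),
             ci_high = unname(ci[, 2]),
             converged = object$converged,
             row.names = NULL)
}

#' Write fitted results to CSV or JSON
#'
#' Serializes one or more [sparselogit()] fits as a flat table (method,
#' term, estimate, OR, interval, convergence flag).  Infinite interval
#' bounds (open exact-method bounds) are kept as `Inf`/`-Inf`; in JSON they
#' are written as the strings `"inf"` / `"-inf"`.
#'
#' @param fits a `sparselogit` fit or list of fits.
#' @param file output path.
#' @param format `"csv"` or `"json"`.
#' @return the path, invisibly.
#' @export
write_fits <- function(fits, file, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(fits, "sparselogit")) fits <- list(fits)
  tab <- do.call(rbind, lapply(fits, sl_result_frame))
  if (format == "csv") {
    utils::write.csv(tab, file, row.names = FALSE)
  } else {
    for (col in c("ci_low", "ci_high")) {
      v <- tab[[col]]
      tab[[col]] <- ifelse(is.infinite(v), ifelse(v > 0, "inf", "-inf"), v)
    }
    jsonlite::write_json(tab, file, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(file)
}
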