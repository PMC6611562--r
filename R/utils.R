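#' Normalize an ICD-9-CM diagnosis code
#'
#' Codes are stored dot-less and upper-case internally; readers accept
#' either dialect, so `"282.42"` and `"28242"` normalize identically.
#'
#' @param x character vector of diagnosis codes (dotted or dot-less).
#' @return character vector of normalized codes.
#' @export
#' @examples
#' norm_dx(c("282.42", "28242", "v70.7"))
norm_dx <- function(x) {
  toupper(gsub(".", "", as.character(x), fixed = TRUE))
}

# ICD-9-CM shape: 3-5 alphanumeric characters, optional leading V/E
is_icd9_shape <- function(x) {
  n <- nchar(x)
  n >= 3L & n <= 5L & grepl("^[VE]?[0-9]+$", x)
}

#' Round half away from zero
#'
#' Matches the printed style of claims-study tables (29.65 -> 29.7), unlike
#' [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage at one decimal place
#'
#' `100 * n / d`, rounded half away from zero at 1 decimal -- the convention
#' used throughout the report module.
#'
#' @param n numerator count(s).
#' @param d denominator count.
#' @return numeric percentage(s); `NA` when `d == 0`.
#' @export
#' @examples
#' pct1(22631, 76154)  # 29.7
pct1 <- function(n, d) {
  if (length(d) == 1L && d == 0) return(rep(NA_real_, length(n)))
  round_half_up(100 * n / d, 1L)
}

#' Completed age in years at a reference date
#'
#' @param birth_date Date vector of birth dates.
#' @param on Date vector (recycled) of reference dates.
#' @return integer vector of completed years.
#' @export
age_at <- function(birth_date, on) {
  b <- as.POSIXlt(birth_date)
  o <- as.POSIXlt(on)
  age <- o$year - b$year
  before_birthday <- (o$mon < b$mon) | (o$mon == b$mon & o$mday < b$mday)
  as.integer(age - before_birthday)
}

# Coerce to Date, erroring with the field name on failure
as_date_field <- function(x, field) {
  if (inherits(x, "Date")) return(x)
  out <- tryCatch(as.Date(x), error = function(e) NA)
  if (anyNA(out)) stop("field '", field, "' is not a valid date: ",
                       paste(utils::head(x, 3), collapse = ", "),
                       call. = FALSE)
  out
}

# Merge intervals per id: two intervals merge when the next start is
# <= running episode end + tol (tol = 1 merges abutting day intervals;
# tol = gap + 1 reproduces the episode gap rule on a day grid).  Greedy
# running-end merging equals comparison against the per-id cummax of ends:
# whenever a break occurs at row i, e_i >= s_i > cummax_{<i}(e) + tol - tol,
# so from then on the cummax is carried by the new group.  Returns the
# sorted data.table with an integer `grp` column numbered within id.
interval_groups <- function(dt, id = "patient_id", start = "start",
                            end = "end", tol = 1L) {
  stopifnot(is.data.table(dt))
  if (nrow(dt) == 0L) {
    dt[, grp := integer(0)]
    return(dt[])
  }
  o <- order(dt[[id]], dt[[start]], dt[[end]])
  dt <- dt[o]
  s <- as.numeric(dt[[start]])
  e <- as.numeric(dt[[end]])
  idv <- dt[[id]]
  n <- length(s)
  new_id <- c(TRUE, idv[-1L] != idv[-n])
  cm <- cummax(e)
  # reset the running max at id boundaries
  if (any(new_id[-1L])) {
    # recompute cummax within id via group-offset trick
    first_of_id <- which(new_id)
    seg <- rep(seq_along(first_of_id), diff(c(first_of_id, n + 1L)))
    cm <- unlist(lapply(split(e, seg), cummax), use.names = FALSE)
  }
  prev_cm <- c(-Inf, cm[-n])
  brk <- new_id | s > prev_cm + tol
  g <- cumsum(brk)
  grp <- g - rep(g[new_id], diff(c(which(new_id), n + 1L))) + 1L
  dt[, grp := as.integer(grp)]
  dt[]
}
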