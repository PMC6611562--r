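#' Construct a diagnosis code set
#'
#' A code set is a named collection of ICD-9-CM codes plus a matching mode.
#' Codes are normalized (dot-less, upper case) and de-duplicated on
#' construction; matching is therefore dot-insensitive.  `prefix` mode
#' matches any code that begins with a listed code, which is how 3-digit
#' ICD-9 category codes (e.g. `"453"` for venous thrombosis) cover their
#' 4th/5th-digit children.
#'
#' @param name short identifier for the set.
#' @param codes character vector of ICD-9-CM codes, dotted or dot-less.
#' @param match_mode `"exact"` or `"prefix"`.
#' @return an object of class `codeset`.
#' @export
#' @examples
#' cs <- codeset("voc", c("282.42", "28262", "28264", "28269"))
#' code_matches("28242", cs)
codeset <- function(name, codes, match_mode = c("exact", "prefix")) {
  match_mode <- match.arg(match_mode)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("codeset name must be a non-empty string", call. = FALSE)
  codes <- unique(norm_dx(codes))
  if (length(codes) == 0L)
    stop("codeset '", name, "' is empty", call. = FALSE)
  bad <- codes[!is_icd9_shape(codes)]
  if (length(bad))
    stop("codeset '", name, "' has codes not shaped like ICD-9-CM: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(name = name, codes = codes, match_mode = match_mode),
            class = "codeset")
}

#' @export
print.codeset <- function(x, ...) {
  cat("<codeset>", x$name, sprintf("[%s]", x$match_mode),
      length(x$codes), "codes:",
      paste(utils::head(x$codes, 8), collapse = " "),
      if (length(x$codes) > 8) "..." else "", "\n")
  invisible(x)
}

#' Test diagnosis codes against a code set
#'
#' Dot-insensitive membership test, vectorized over `code`.  In `exact`
#' mode the normalized code must be in the set; in `prefix` mode it must
#' begin with a member.  Unmatched or empty codes return `FALSE`.
#'
#' @param code character vector of codes to test.
#' @param cs a [codeset()].
#' @return logical vector.
#' @export
code_matches <- function(code, cs) {
  stopifnot(inherits(cs, "codeset"))
  x <- norm_dx(code)
  if (cs$match_mode == "exact") {
    out <- x %in% cs$codes
  } else {
    out <- rep(FALSE, length(x))
    for (p in cs$codes) out <- out | startsWith(x, p)
  }
  out[is.na(code) | !nzchar(x)] <- FALSE
  out
}

#' Default SCD diagnosis code set
#'
#' Sickle cell disease: ICD-9-CM 282.41, 282.42 and the 282.60--282.69
#' range expanded literally to its ten codes (12 codes total).  Used for
#' index-date identification.
#'
#' @return a [codeset()] in exact mode.
#' @export
default_scd_codes <- function() {
  codeset("scd", c("28241", "28242", sprintf("2826%d", 0:9)))
}

#' Default VOC episode-definition code set
#'
#' Sickle cell crisis codes used to pick the claims that form VOC
#' episodes: 282.42, 282.62, 282.64, 282.69, matched in primary or
#' secondary position.
#'
#' @return a [codeset()] in exact mode.
#' @export
default_voc_episode_codes <- function() {
  codeset("voc_episode", c("28242", "28262", "28264", "28269"))
}

#' Default VOC primary-reason code set
#'
#' The broader SCD crisis list (282.41, 282.42, 282.60--282.69) used when
#' attributing the primary reason of an ER or inpatient visit from its
#' primary discharge diagnosis.  Deliberately distinct from
#' [default_voc_episode_codes()]; both lists are kept configurable.
#'
#' @return a [codeset()] in exact mode.
#' @export
default_voc_primary_reason_codes <- function() {
  codeset("voc_primary_reason", c("28241", "28242", sprintf("2826%d", 0:9)))
}

#' Default clinical-trial exclusion code set
#'
#' @return a [codeset()] holding V70.7 (examination of participant in
#'   clinical trial).
#' @export
default_trial_codes <- function() {
  codeset("trial_exclusion", "V707")
}

#' Construct a complication category
#'
#' @param label category label, unique within a configuration.
#' @param cs a [codeset()] defining the category.
#' @return an object of class `complication_category`.
#' @export
complication_category <- function(label, cs) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("category label must be a non-empty string", call. = FALSE)
  stopifnot(inherits(cs, "codeset"))
  structure(list(label = label, codeset = cs),
            class = "complication_category")
}

#' Illustrative SCD complication categories (synthetic default)
#'
#' The authoritative SCD complication code list used in claims studies is
#' not reproduced here; this default is a clearly-labelled *illustrative*
#' mapping of the six commonly-named categories to ICD-9 prefixes
#' (e.g. fever -> 780.6x, deep vein thrombosis -> 453.x).  It keeps the
#' pipeline runnable and testable; for a real study supply an
#' authoritative list via [load_config()] or [study_config()].
#'
#' @return named list of [complication_category()] objects.
#' @export
default_complication_categories <- function() {
  defs <- list(
    "infectious and parasitic diseases" =
      c("038", "041", "079", "590", "599"),
    "fever" = "7806",
    "pulmonary disorders" = c("486", "5173", "5184", "4168"),
    "cerebrovascular conditions" = sprintf("43%d", 0:8),
    "thrombosis/DVT" = "453",
    "aseptic (avascular) bone necrosis" = "7334"
  )
  out <- lapply(names(defs), function(lab) {
    complication_category(
      lab, codeset(gsub("[^a-z0-9]+", "_", tolower(lab)),
                   defs[[lab]], match_mode = "prefix"))
  })
  names(out) <- names(defs)
  out
}

# validate a list of complication categories: unique labels
check_categories <- function(categories) {
  if (!length(categories)) return(invisible(categories))
  ok <- vapply(categories, inherits, logical(1), "complication_category")
  if (!all(ok))
    stop("complication_categories must be complication_category objects",
         call. = FALSE)
  labs <- vapply(categories, `[[`, character(1), "label")
  if (anyDuplicated(labs))
    stop("duplicate complication category label: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "),
         call. = FALSE)
  invisible(categories)
}
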