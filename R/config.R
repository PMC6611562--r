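#' Study configuration
#'
#' Bundles every tunable study definition -- code sets, date windows, the
#' episode gap threshold, the place-of-service hierarchy, age and
#' enrollment requirements -- so that no clinical definition is hard-coded
#' in an algorithm.  Defaults reproduce a Medicaid SCD utilization study
#' design: study period 01 Jan 2009 -- 31 Dec 2013, identification window
#' 01 Jul 2009 -- 31 Dec 2012, 6-month (183-day) baseline, 12-month
#' (365-day) minimum follow-up, 3-day episode gap, hierarchy
#' inpatient > ER > outpatient > office > other, adults (18+).
#'
#' @param scd_codes [codeset()] identifying SCD diagnosis claims
#'   (index-date search).
#' @param voc_episode_codes [codeset()] of crisis codes defining VOC
#'   episode membership.
#' @param voc_primary_reason_codes [codeset()] of crisis codes used for
#'   visit primary-reason attribution.
#' @param complication_categories named list of
#'   [complication_category()] objects (labels must be unique).
#' @param trial_exclusion_codes [codeset()] flagging clinical-trial
#'   participation.
#' @param study_start,study_end Dates bounding the data period.
#' @param identification_start,identification_end Dates bounding the
#'   index-claim search window (must lie within the study period).
#' @param baseline_days positive integer, days of pre-index continuous
#'   enrollment required (default 183 = 6 months).
#' @param followup_min_days positive integer, days of post-index
#'   continuous enrollment required (default 365 = 12 months).
#' @param episode_gap_days non-negative integer; VOC claims whose start is
#'   more than this many days after the running episode end open a new
#'   episode (default 3).
#' @param setting_hierarchy character vector of place-of-service labels in
#'   priority order; must be unique and cover every value the pipeline can
#'   emit.
#' @param min_age minimum age in completed years at index (default 18).
#' @param rng_seed integer seed recorded in report provenance.
#' @return an object of class `study_config`.
#' @export
study_config <- function(scd_codes = default_scd_codes(),
                         voc_episode_codes = default_voc_episode_codes(),
                         voc_primary_reason_codes =
                           default_voc_primary_reason_codes(),
                         complication_categories =
                           default_complication_categories(),
                         trial_exclusion_codes = default_trial_codes(),
                         study_start = as.Date("2009-01-01"),
                         study_end = as.Date("2013-12-31"),
                         identification_start = as.Date("2009-07-01"),
                         identification_end = as.Date("2012-12-31"),
                         baseline_days = 183L,
                         followup_min_days = 365L,
                         episode_gap_days = 3L,
                         setting_hierarchy = c("inpatient", "ER",
                                               "outpatient", "office",
                                               "other"),
                         min_age = 18L,
                         rng_seed = 1L) {
  cfg <- list(
    scd_codes = scd_codes,
    voc_episode_codes = voc_episode_codes,
    voc_primary_reason_codes = voc_primary_reason_codes,
    complication_categories = complication_categories,
    trial_exclusion_codes = trial_exclusion_codes,
    study_start = as_date_field(study_start, "study_start"),
    study_end = as_date_field(study_end, "study_end"),
    identification_start = as_date_field(identification_start,
                                         "identification_start"),
    identification_end = as_date_field(identification_end,
                                       "identification_end"),
    baseline_days = as.integer(baseline_days),
    followup_min_days = as.integer(followup_min_days),
    episode_gap_days = as.integer(episode_gap_days),
    setting_hierarchy = as.character(setting_hierarchy),
    min_age = as.integer(min_age),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "study_config"
  validate_config(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n",
      " study period       ", format(x$study_start), "to",
      format(x$study_end), "\n",
      " identification     ", format(x$identification_start), "to",
      format(x$identification_end), "\n",
      " baseline/follow-up ", x$baseline_days, "/", x$followup_min_days,
      "days; gap", x$episode_gap_days, "days; min age", x$min_age, "\n",
      " hierarchy          ", paste(x$setting_hierarchy, collapse = " > "),
      "\n")
  invisible(x)
}

validate_config <- function(cfg) {
  for (f in c("scd_codes", "voc_episode_codes", "voc_primary_reason_codes",
              "trial_exclusion_codes"))
    if (!inherits(cfg[[f]], "codeset"))
      stop("config field '", f, "' must be a codeset", call. = FALSE)
  check_categories(cfg$complication_categories)
  if (cfg$identification_start < cfg$study_start ||
      cfg$identification_end > cfg$study_end ||
      cfg$identification_start > cfg$identification_end)
    stop("identification window must lie within the study period",
         call. = FALSE)
  if (cfg$baseline_days <= 0L)
    stop("baseline_days must be > 0", call. = FALSE)
  if (cfg$followup_min_days <= 0L)
    stop("followup_min_days must be > 0", call. = FALSE)
  if (cfg$episode_gap_days < 0L)
    stop("episode_gap_days must be >= 0", call. = FALSE)
  h <- cfg$setting_hierarchy
  if (length(h) == 0L || anyDuplicated(h))
    stop("setting_hierarchy must be non-empty with unique entries",
         call. = FALSE)
  if (cfg$min_age < 0L) stop("min_age must be >= 0", call. = FALSE)
  cfg
}

#' Load a study configuration from a JSON file
#'
#' The config dialect is JSON (YAML is not supported in this build; the
#' schema is flat and round-trips through `jsonlite`).  Every key is
#' optional; omitted fields take the [study_config()] defaults, which
#' reproduce the standard study definitions.  Schema:
#'
#' ```json
#' {
#'   "scd_codes":                ["28241", "282.42", ...],
#'   "voc_episode_codes":        ["28242", ...],
#'   "voc_primary_reason_codes": ["28241", ...],
#'   "trial_exclusion_codes":    ["V707"],
#'   "complication_categories": {
#'     "fever": {"codes": ["7806"], "match_mode": "prefix"}, ...
#'   },
#'   "study_start": "2009-01-01", "study_end": "2013-12-31",
#'   "identification_start": "2009-07-01",
#'   "identification_end": "2012-12-31",
#'   "baseline_days": 183, "followup_min_days": 365,
#'   "episode_gap_days": 3,
#'   "setting_hierarchy": ["inpatient","ER","outpatient","office","other"],
#'   "min_age": 18, "rng_seed": 1
#' }
#' ```
#'
#' An example ships at
#' `system.file("extdata", "study-config-example.json", package="vocepi")`.
#'
#' @param path path to a JSON config file.
#' @return a validated [study_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("config parse error in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a JSON object", call. = FALSE)
  allowed <- names(formals(study_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config key: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- list()
  for (f in c("scd_codes", "voc_episode_codes",
              "voc_primary_reason_codes", "trial_exclusion_codes"))
    if (!is.null(raw[[f]]))
      args[[f]] <- codeset(f, unlist(raw[[f]]))
  if (!is.null(raw$complication_categories)) {
    cc <- raw$complication_categories
    if (is.null(names(cc)) || any(!nzchar(names(cc))))
      stop("complication_categories entries must be named by label",
           call. = FALSE)
    if (anyDuplicated(names(cc)))
      stop("duplicate complication category label: ",
           paste(unique(names(cc)[duplicated(names(cc))]), collapse = ", "),
           call. = FALSE)
    args$complication_categories <- lapply(names(cc), function(lab) {
      entry <- cc[[lab]]
      codes <- if (is.list(entry)) unlist(entry$codes) else unlist(entry)
      mode <- if (is.list(entry) && !is.null(entry$match_mode))
        entry$match_mode else "exact"
      complication_category(
        lab, codeset(gsub("[^a-z0-9]+", "_", tolower(lab)), codes, mode))
    })
    names(args$complication_categories) <- names(cc)
  }
  for (f in c("study_start", "study_end", "identification_start",
              "identification_end"))
    if (!is.null(raw[[f]])) args[[f]] <- as_date_field(raw[[f]], f)
  for (f in c("baseline_days", "followup_min_days", "episode_gap_days",
              "min_age", "rng_seed"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  if (!is.null(raw$setting_hierarchy))
    args$setting_hierarchy <- unlist(raw$setting_hierarchy)
  do.call(study_config, args)
}
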