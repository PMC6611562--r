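#' Build SCD-related ER and inpatient visits for the first follow-up year
#'
#' Inpatient stays are maximal runs of overlapping/abutting inpatient
#' claims.  ER visits are same-day groups of ER claims, except that an ER
#' visit leading to an admission within `episode_gap_days` (or falling
#' inside a stay) is absorbed into the inpatient visit and not counted
#' separately.  Each visit's primary diagnosis is `dx1` of its anchor
#' claim -- the earliest member claim, ties broken by `claim_id` -- and
#' the reason is attributed from it: `VOC` if it matches
#' `voc_primary_reason_codes`, else `SCD_complication` if it matches a
#' complication category (the first matching category in configuration
#' order is recorded), else `other`.  Inpatient `los_days` is
#' `max(1, discharge - admit)`.
#'
#' @param claims claims table (all claims; the function windows each
#'   member's claims to their first `followup_min_days` follow-up days).
#' @param cohort cohort table from [select_cohort()].
#' @param config a [study_config()].
#' @param scd_related_only if `TRUE` (default) return only visits whose
#'   reason is `VOC` or `SCD_complication`, matching the study's
#'   SCD-related denominators; `FALSE` keeps `other` visits too.
#' @return data.table of visits: `patient_id`, `visit_type`
#'   (`"ER"`/`"inpatient"`), `admit`, `discharge`, `primary_dx`,
#'   `reason`, `reason_category`, `los_days` (`NA` for ER visits).
#' @export
build_visits <- function(claims, cohort, config = study_config(),
                         scd_related_only = TRUE) {
  cl <- as.data.table(claims)
  co <- as.data.table(cohort)
  empty <- data.table(patient_id = character(0), visit_type = character(0),
                      admit = as.Date(integer(0)),
                      discharge = as.Date(integer(0)),
                      primary_dx = character(0), reason = character(0),
                      reason_category = character(0),
                      los_days = numeric(0))
  if (nrow(cl) == 0L || nrow(co) == 0L) return(empty)
  w <- merge(cl, co[, .(patient_id, followup_start)], by = "patient_id")
  w <- w[service_start >= followup_start &
           as.numeric(service_start - followup_start) <
             config$followup_min_days]
  if (!"claim_id" %in% names(w)) w[, claim_id := as.character(.I)]

  ipc <- w[place_of_service == "inpatient"]
  stays <- NULL
  if (nrow(ipc)) {
    g <- interval_groups(ipc, start = "service_start",
                         end = "service_end", tol = 1L)
    setorder(g, patient_id, grp, service_start, claim_id)
    stays <- g[, .(admit = min(service_start),
                   discharge = max(service_end),
                   primary_dx = dx1[1L]), by = .(patient_id, grp)]
    stays[, `:=`(visit_type = "inpatient",
                 los_days = pmax(1, as.numeric(discharge - admit)),
                 grp = NULL)]
  }

  erc <- w[place_of_service == "ER"]
  ervis <- NULL
  if (nrow(erc)) {
    setorder(erc, patient_id, service_start, claim_id)
    ervis <- erc[, .(primary_dx = dx1[1L]),
                 by = .(patient_id, day = service_start)]
    if (!is.null(stays)) {
      ab <- stays[ervis, on = .(patient_id), allow.cartesian = TRUE,
                  nomatch = NULL][
        (day >= admit & day <= discharge) |
          (admit > day &
             as.numeric(admit - day) <= config$episode_gap_days)]
      absorbed_keys <- unique(ab[, .(patient_id, day)])
      ervis <- ervis[!absorbed_keys, on = c("patient_id", "day")]
    }
    if (nrow(ervis)) {
      ervis <- ervis[, .(patient_id, visit_type = "ER", admit = day,
                         discharge = day, primary_dx,
                         los_days = NA_real_)]
    } else ervis <- NULL
  }

  visits <- rbindlist(list(stays, ervis), use.names = TRUE, fill = TRUE)
  if (is.null(visits) || nrow(visits) == 0L) return(empty)

  cats <- config$complication_categories
  labs <- vapply(cats, `[[`, character(1), "label")
  is_voc <- code_matches(visits$primary_dx,
                         config$voc_primary_reason_codes)
  cat_lab <- rep(NA_character_, nrow(visits))
  for (j in rev(seq_along(cats)))
    cat_lab[code_matches(visits$primary_dx, cats[[j]]$codeset)] <- labs[j]
  visits[, reason := fifelse(is_voc, "VOC",
                             fifelse(!is.na(cat_lab), "SCD_complication",
                                     "other"))]
  visits[, reason_category := fifelse(reason == "SCD_complication",
                                      cat_lab, NA_character_)]
  if (scd_related_only) visits <- visits[reason != "other"]
  setorder(visits, patient_id, admit, visit_type)
  setcolorder(visits, c("patient_id", "visit_type", "admit", "discharge",
                        "primary_dx", "reason", "reason_category",
                        "los_days"))
  visits[]
}

#' Primary-reason breakdown of SCD-related visits
#'
#' For each visit type, counts and percentages (1 decimal, half away
#' from zero) of visits with VOC vs an SCD complication as the primary
#' reason, plus the category breakdown within complication-reason
#' visits.
#'
#' @param visits visit table from [build_visits()].
#' @return list with `by_type` (data.table: `visit_type`, `n_total`,
#'   `n_voc`, `n_complication`, `pct_voc`, `pct_complication`) and
#'   `categories` (data.table: `visit_type`, `reason_category`, `n`,
#'   `pct` within complication-reason visits of that type).
#' @export
reason_breakdown <- function(visits) {
  v <- as.data.table(visits)[reason %in% c("VOC", "SCD_complication")]
  if (nrow(v) == 0L)
    return(list(by_type = data.table(visit_type = character(0),
                                     n_total = integer(0),
                                     n_voc = integer(0),
                                     n_complication = integer(0),
                                     pct_voc = numeric(0),
                                     pct_complication = numeric(0)),
                categories = data.table(visit_type = character(0),
                                        reason_category = character(0),
                                        n = integer(0), pct = numeric(0))))
  by_type <- v[, .(n_total = .N, n_voc = sum(reason == "VOC"),
                   n_complication = sum(reason == "SCD_complication")),
               by = visit_type]
  by_type[, `:=`(pct_voc = pct1(n_voc, n_total[1L]),
                 pct_complication = pct1(n_complication, n_total[1L])),
          by = visit_type]
  categories <- v[reason == "SCD_complication",
                  .(n = .N), by = .(visit_type, reason_category)]
  categories[, pct := pct1(n, sum(n)), by = visit_type]
  setorder(categories, visit_type, -n, reason_category)
  list(by_type = by_type[order(visit_type)], categories = categories)
}

#' Length-of-stay summary by primary reason
#'
#' Inpatient visits only.  Per reason class: mean, sample SD (n-1
#' denominator; reported as 0 when n = 1, with `n` flagging the
#' singleton), median, and IQR = Q3 - Q1 under linear-interpolation
#' quantiles ([stats::quantile()] type 7).
#'
#' @param visits visit table from [build_visits()].
#' @return data.table with `reason`, `n`, `mean`, `sd`, `median`, `q1`,
#'   `q3`, `iqr`.
#' @export
los_summary <- function(visits) {
  v <- as.data.table(visits)[visit_type == "inpatient" &
                               !is.na(los_days)]
  if (nrow(v) == 0L)
    return(data.table(reason = character(0), n = integer(0),
                      mean = numeric(0), sd = numeric(0),
                      median = numeric(0), q1 = numeric(0),
                      q3 = numeric(0), iqr = numeric(0)))
  out <- v[, {
    q <- quantile(los_days, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    .(n = .N, mean = mean(los_days),
      sd = if (.N > 1L) sd(los_days) else 0,
      median = q[2L], q1 = q[1L], q3 = q[3L], iqr = q[3L] - q[1L])
  }, by = reason]
  setorder(out, reason)
  out[]
}
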