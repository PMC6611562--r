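#' Find a patient's index date
#'
#' The index date is the earliest `service_start` of a claim carrying an
#' SCD code in any diagnosis position within the identification window.
#'
#' @param claims data.table/data.frame of one patient's claims with
#'   `service_start` and `dx*` columns.
#' @param config a [study_config()].
#' @return a Date, or `NA` if no qualifying claim exists.
#' @export
find_index_date <- function(claims, config = study_config()) {
  cl <- as.data.table(claims)
  if (nrow(cl) == 0L) return(as.Date(NA))
  dxc <- grep("^dx", names(cl), value = TRUE)
  hit <- Reduce(`|`, lapply(dxc, function(cc)
    code_matches(cl[[cc]], config$scd_codes)))
  hit <- hit & cl$service_start >= config$identification_start &
    cl$service_start <= config$identification_end
  if (!any(hit)) return(as.Date(NA))
  min(cl$service_start[hit])
}

#' Continuous-enrollment check
#'
#' `TRUE` iff the union of this patient's enrollment spans that carry
#' both medical and pharmacy benefits covers every day of
#' `[interval_start, interval_end]`.  Adjacent spans abut with no day gap
#' (a span ending on day *d* joins one starting on day *d + 1*).
#'
#' @param spans data.table/data.frame of one patient's enrollment spans
#'   (`span_start`, `span_end`, `medical`, `pharmacy`).
#' @param interval_start,interval_end Dates bounding the required
#'   coverage interval (inclusive).
#' @return logical scalar.
#' @export
is_continuously_enrolled <- function(spans, interval_start, interval_end) {
  sp <- as.data.table(spans)
  sp <- sp[medical & pharmacy]
  if (nrow(sp) == 0L || interval_start > interval_end) {
    return(nrow(sp) > 0L && interval_start > interval_end)
  }
  sp[, patient_id := "x"]
  m <- interval_groups(sp, start = "span_start", end = "span_end",
                       tol = 1L)
  merged <- m[, .(start = min(span_start), end = max(span_end)), by = grp]
  any(merged$start <= interval_start & merged$end >= interval_end)
}

# merged medical+pharmacy coverage spans for all patients
merged_coverage <- function(enrollment) {
  e <- as.data.table(enrollment)[medical & pharmacy]
  if (nrow(e) == 0L)
    return(data.table(patient_id = character(0), start = as.Date(integer(0)),
                      end = as.Date(integer(0))))
  m <- interval_groups(e, start = "span_start", end = "span_end", tol = 1L)
  m[, .(start = min(span_start), end = max(span_end)),
    by = .(patient_id, grp)][, grp := NULL][]
}

# long table of (patient_id, code) over all dx positions, blanks dropped
dx_long <- function(claims) {
  cl <- as.data.table(claims)
  dxc <- grep("^dx", names(cl), value = TRUE)
  out <- rbindlist(lapply(dxc, function(cc)
    data.table(patient_id = cl$patient_id, code = cl[[cc]])))
  out[!is.na(code) & nzchar(code)]
}

# vectorized Charlson over many patients; returns patient_id, cci
charlson_scores_bulk <- function(codes_long) {
  if (nrow(codes_long) == 0L)
    return(data.table(patient_id = character(0), cci = integer(0)))
  x <- norm_dx(codes_long$code)
  m <- deyo_map()
  pats <- unique(codes_long$patient_id)
  pi <- match(codes_long$patient_id, pats)
  hitmat <- matrix(FALSE, length(pats), length(m),
                   dimnames = list(NULL, names(m)))
  for (j in seq_along(m)) {
    rowhit <- rep(FALSE, length(x))
    for (p in m[[j]]$p) rowhit <- rowhit | startsWith(x, p)
    if (any(rowhit))
      hitmat[unique(pi[rowhit]), j] <- TRUE
  }
  hitmat[hitmat[, "dm_compl"], "dm"] <- FALSE
  hitmat[hitmat[, "severe_liver"], "mild_liver"] <- FALSE
  hitmat[hitmat[, "mets"], "malignancy"] <- FALSE
  w <- vapply(m, `[[`, integer(1), "w")
  data.table(patient_id = pats,
             cci = as.integer(hitmat %*% w))
}

#' Baseline acute utilization for one patient
#'
#' ER visits are counted as one per patient per calendar day (same-day ER
#' claims collapse to a single visit); inpatient stays are maximal runs
#' of overlapping or abutting inpatient claims; length of stay per stay
#' is discharge minus admission in days, with same-day stays counted as
#' 1 day.
#'
#' @param claims data.table/data.frame of one patient's baseline-window
#'   claims (`service_start`, `service_end`, `place_of_service`).
#' @return list with `er_visits`, `ip_stays`, `ip_los_days`.
#' @export
baseline_utilization <- function(claims) {
  cl <- as.data.table(claims)
  er <- cl[place_of_service == "ER"]
  er_visits <- if (nrow(er)) uniqueN(er$service_start) else 0L
  ip <- cl[place_of_service == "inpatient"]
  if (nrow(ip) == 0L)
    return(list(er_visits = er_visits, ip_stays = 0L, ip_los_days = 0))
  ip[, patient_id := if ("patient_id" %in% names(cl))
    patient_id else "x"]
  g <- interval_groups(ip, start = "service_start", end = "service_end",
                       tol = 1L)
  stays <- g[, .(admit = min(service_start),
                 discharge = max(service_end)), by = .(patient_id, grp)]
  list(er_visits = er_visits,
       ip_stays = nrow(stays),
       ip_los_days = sum(pmax(1, as.numeric(stays$discharge -
                                              stays$admit))))
}

#' Select the study cohort and log exclusions
#'
#' Applies the selection rules in order: (1) an SCD claim in the
#' identification window fixes the index date; (2) age at index must
#' reach `min_age`; (3) continuous medical+pharmacy enrollment must cover
#' the baseline window `[index - baseline_days, index - 1]` and the first
#' `followup_min_days` of follow-up; (4) no clinical-trial code during
#' the study period; (5) never dual-eligible.  The logged reason is the
#' first rule violated, and every patient lands in exactly one of the two
#' output tables.  `followup_end` is the end of continuous post-index
#' enrollment, capped at `study_end`.
#'
#' Members are additionally characterized over the baseline window:
#' Charlson comorbidity index ([charlson_score()]) and baseline acute
#' utilization ([baseline_utilization()]).
#'
#' @param patients patients table (`patient_id`, `birth_date`, `sex`,
#'   `race`, `region`); `patient_id` must be unique.
#' @param enrollment enrollment-span table.
#' @param claims claims table.
#' @param config a [study_config()].
#' @return list with `cohort` and `exclusions` data.tables.
#' @export
select_cohort <- function(patients, enrollment, claims,
                          config = study_config()) {
  P <- as.data.table(patients)
  E <- as.data.table(enrollment)
  C <- as.data.table(claims)
  if (anyDuplicated(P$patient_id))
    stop("duplicate patient_id in patients table", call. = FALSE)

  dxc <- grep("^dx", names(C), value = TRUE)
  scd_hit <- Reduce(`|`, lapply(dxc, function(cc)
    code_matches(C[[cc]], config$scd_codes)))
  cand <- C[scd_hit & service_start >= config$identification_start &
              service_start <= config$identification_end,
            .(index_date = min(service_start)), by = patient_id]
  res <- merge(P, cand, by = "patient_id", all.x = TRUE)
  res[, age_at_index := age_at(birth_date, index_date)]

  cov <- merged_coverage(E)
  bl_lo <- res$index_date - config$baseline_days
  bl_hi <- res$index_date - 1L
  fu_hi <- res$index_date + config$followup_min_days - 1L
  ov <- cov[res[, .(patient_id, bl_lo, bl_hi, fu_hi,
                    index_date)], on = "patient_id",
            allow.cartesian = TRUE]
  covchk <- ov[, .(
    baseline_ok = any(!is.na(start) & start <= bl_lo & end >= bl_hi),
    followup_ok = any(!is.na(start) & start <= index_date & end >= fu_hi),
    fu_cont_end = {
      h <- !is.na(start) & start <= index_date & end >= index_date
      if (any(h)) max(end[h]) else as.Date(NA)
    }), by = patient_id]
  res <- merge(res, covchk, by = "patient_id", all.x = TRUE)
  res[is.na(baseline_ok), `:=`(baseline_ok = FALSE, followup_ok = FALSE)]

  trial_hit <- Reduce(`|`, lapply(dxc, function(cc)
    code_matches(C[[cc]], config$trial_exclusion_codes)))
  trial_pat <- unique(C$patient_id[
    trial_hit & C$service_start >= config$study_start &
      C$service_start <= config$study_end])
  dual_pat <- unique(E$patient_id[E$dual_eligible %in% TRUE])

  reason <- rep(NA_character_, nrow(res))
  reason[res$patient_id %in% dual_pat] <- "dual_eligible"
  reason[res$patient_id %in% trial_pat] <- "trial_code"
  reason[!res$followup_ok] <- "insufficient_followup"
  reason[!res$baseline_ok] <- "insufficient_baseline"
  reason[!is.na(res$age_at_index) &
           res$age_at_index < config$min_age] <- "under_age"
  reason[is.na(res$index_date)] <- "no_scd_claim_in_window"
  res[, excluded_reason := reason]

  exclusions <- res[!is.na(excluded_reason),
                    .(patient_id, excluded_reason,
                      detail = fifelse(is.na(index_date), "",
                                       paste0("index=",
                                              format(index_date))))]

  memb <- res[is.na(excluded_reason)]
  memb[, `:=`(
    baseline_start = index_date - config$baseline_days,
    followup_start = index_date,
    followup_end = pmin(fu_cont_end, config$study_end)
  )]

  # baseline characterization
  if (nrow(memb)) {
    blc <- merge(C, memb[, .(patient_id, bs = baseline_start,
                             be = index_date - 1L)],
                 by = "patient_id")
    blc <- blc[service_start >= bs & service_start <= be]
    cci <- charlson_scores_bulk(dx_long(blc))
    er <- blc[place_of_service == "ER",
              .(baseline_er_visits = uniqueN(service_start)),
              by = patient_id]
    ipc <- blc[place_of_service == "inpatient"]
    if (nrow(ipc)) {
      g <- interval_groups(ipc, start = "service_start",
                           end = "service_end", tol = 1L)
      ip <- g[, .(admit = min(service_start),
                  discharge = max(service_end)),
              by = .(patient_id, grp)][,
        .(baseline_ip_stays = .N,
          baseline_ip_los_days = sum(pmax(1, as.numeric(discharge -
                                                          admit)))),
        by = patient_id]
    } else {
      ip <- data.table(patient_id = character(0),
                       baseline_ip_stays = integer(0),
                       baseline_ip_los_days = numeric(0))
    }
    for (tb in list(cci, er, ip))
      memb <- merge(memb, tb, by = "patient_id", all.x = TRUE)
    memb[is.na(cci), cci := 0L]
    memb[is.na(baseline_er_visits), baseline_er_visits := 0L]
    memb[is.na(baseline_ip_stays), baseline_ip_stays := 0L]
    memb[is.na(baseline_ip_los_days), baseline_ip_los_days := 0]
  } else {
    memb[, `:=`(cci = integer(0), baseline_er_visits = integer(0),
                baseline_ip_stays = integer(0),
                baseline_ip_los_days = numeric(0))]
  }

  cohort <- memb[, .(patient_id, index_date, baseline_start,
                     followup_start, followup_end, age_at_index,
                     sex, race, region, cci, baseline_er_visits,
                     baseline_ip_stays, baseline_ip_los_days)]
  setorder(cohort, patient_id)
  setorder(exclusions, patient_id)
  list(cohort = cohort, exclusions = exclusions)
}
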