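#' Resolve an episode's setting through the place-of-service hierarchy
#'
#' Returns the highest-priority place of service present among the
#' member claims; the hierarchy's order is the priority order
#' (default inpatient > ER > outpatient > office > other).  The result is
#' invariant to claim order.
#'
#' @param places character vector of the member claims' places of
#'   service.
#' @param hierarchy character vector of place labels in priority order.
#' @return a single place-of-service label.
#' @export
#' @examples
#' assign_setting(c("ER", "inpatient"))  # "inpatient"
assign_setting <- function(places,
                           hierarchy = c("inpatient", "ER", "outpatient",
                                         "office", "other")) {
  if (length(places) == 0L)
    stop("assign_setting requires at least one claim", call. = FALSE)
  pr <- match(places, hierarchy)
  if (anyNA(pr))
    stop("place of service not in hierarchy: ",
         paste(unique(places[is.na(pr)]), collapse = ", "), call. = FALSE)
  hierarchy[min(pr)]
}

#' Build VOC episodes from one patient's follow-up claims
#'
#' Selects claims carrying a VOC episode code in any diagnosis position,
#' sorts them by service date, and greedily merges: a claim joins the
#' current episode iff its `service_start` minus the episode's running
#' end is at most `episode_gap_days`; otherwise it opens a new episode.
#' Episode start/end are the min/max service dates of member claims, and
#' the setting is resolved with [assign_setting()].  Ties on identical
#' start dates are ordered by `(service_start, service_end, claim_id)`
#' for determinism; the partition itself does not depend on tie order.
#'
#' @param claims data.table/data.frame of one patient's claims already
#'   filtered to the follow-up window.
#' @param config a [study_config()].
#' @return data.table of episodes (`episode_id`, `start`, `end`,
#'   `n_claims`, `setting`, `claim_ids` list column), chronological;
#'   zero rows when the patient has no VOC claims.
#' @export
build_episodes <- function(claims, config = study_config()) {
  cl <- as.data.table(claims)
  if (!"patient_id" %in% names(cl)) cl[, patient_id := "x"]
  if (length(unique(cl$patient_id)) > 1L)
    stop("build_episodes expects claims of a single patient; use ",
         "build_all_episodes for a multi-patient table", call. = FALSE)
  ep <- build_all_episodes(cl, config)
  ep[, patient_id := NULL]
  ep[]
}

#' Build VOC episodes for every patient in a claims table
#'
#' Vectorized multi-patient version of [build_episodes()]; identical
#' gap-merging rule, grouped by `patient_id`.
#'
#' @inheritParams build_episodes
#' @param claims claims table with `patient_id`.
#' @return data.table with `patient_id`, `episode_id` (sequential within
#'   patient), `start`, `end`, `n_claims`, `setting`, `claim_ids`.
#' @export
build_all_episodes <- function(claims, config = study_config()) {
  cl <- as.data.table(claims)
  empty <- data.table(patient_id = character(0), episode_id = integer(0),
                      start = as.Date(integer(0)),
                      end = as.Date(integer(0)), n_claims = integer(0),
                      setting = character(0), claim_ids = list())
  if (nrow(cl) == 0L) return(empty)
  dxc <- grep("^dx", names(cl), value = TRUE)
  voc <- Reduce(`|`, lapply(dxc, function(cc)
    code_matches(cl[[cc]], config$voc_episode_codes)))
  v <- cl[voc]
  if (nrow(v) == 0L) return(empty)
  if (!"claim_id" %in% names(v)) v[, claim_id := as.character(.I)]
  setorder(v, patient_id, service_start, service_end, claim_id)
  g <- interval_groups(v, start = "service_start", end = "service_end",
                       tol = config$episode_gap_days)
  bad <- setdiff(unique(g$place_of_service), config$setting_hierarchy)
  if (length(bad))
    stop("place of service not in hierarchy: ",
         paste(bad, collapse = ", "), call. = FALSE)
  ep <- g[, .(start = min(service_start), end = max(service_end),
              n_claims = .N,
              setting = assign_setting(place_of_service,
                                       config$setting_hierarchy),
              claim_ids = list(claim_id)),
          by = .(patient_id, grp)]
  setorder(ep, patient_id, start)
  ep[, episode_id := seq_len(.N), by = patient_id]
  ep[, grp := NULL]
  setcolorder(ep, c("patient_id", "episode_id", "start", "end",
                    "n_claims", "setting", "claim_ids"))
  ep[]
}

#' Classify episodes as complicated or uncomplicated
#'
#' Scans every claim (VOC-coded or not) whose service interval intersects
#' the episode interval `[start, end]`.  A complication category is in
#' `categories_any` if any such claim carries one of its codes in any
#' diagnosis position, and in `categories_primary` if the code sits in
#' position 1.  An episode is complicated iff `categories_any` is
#' non-empty.  Category labels are comma-joined in configuration order.
#'
#' @param episodes episode table from [build_all_episodes()] (needs
#'   `patient_id`, `start`, `end`).
#' @param claims full claims table for the same patients (not only VOC
#'   claims).
#' @param config a [study_config()]; supplies `complication_categories`.
#' @return the episode table with `complicated`, `categories_primary`,
#'   `categories_any` columns added.
#' @export
classify_episodes <- function(episodes, claims, config = study_config()) {
  ep <- copy(as.data.table(episodes))
  cl <- as.data.table(claims)
  cats <- config$complication_categories
  labs <- vapply(cats, `[[`, character(1), "label")
  ep[, `:=`(complicated = FALSE, categories_primary = "",
            categories_any = "")]
  if (nrow(ep) == 0L || nrow(cl) == 0L || length(cats) == 0L)
    return(ep[])
  dxc <- grep("^dx", names(cl), value = TRUE)
  anyc <- matrix(FALSE, nrow(cl), length(cats))
  prim <- matrix(FALSE, nrow(cl), length(cats))
  for (j in seq_along(cats)) {
    cs <- cats[[j]]$codeset
    hit <- Reduce(`|`, lapply(dxc, function(cc)
      code_matches(cl[[cc]], cs)))
    anyc[, j] <- hit
    prim[, j] <- code_matches(cl$dx1, cs)
  }
  rel <- which(rowSums(anyc) > 0)
  if (length(rel) == 0L) return(ep[])
  crel <- cl[rel, .(patient_id, cs = service_start, ce = service_end)]
  crel[, xid := rel]
  ep[, eid := .I]
  setkey(crel, patient_id, cs, ce)
  ov <- foverlaps(ep[, .(patient_id, start, end, eid)], crel,
                  by.x = c("patient_id", "start", "end"),
                  by.y = c("patient_id", "cs", "ce"), nomatch = NULL)
  if (nrow(ov)) {
    agg_any <- rowsum(anyc[ov$xid, , drop = FALSE] + 0L, ov$eid) > 0
    agg_prim <- rowsum(prim[ov$xid, , drop = FALSE] + 0L, ov$eid) > 0
    eids <- as.integer(rownames(agg_any))
    join_labels <- function(mrow) paste(labs[mrow], collapse = ",")
    ep[eids, categories_any := apply(agg_any, 1L, join_labels)]
    ep[eids, categories_primary := apply(agg_prim, 1L, join_labels)]
    ep[eids, complicated := rowSums(agg_any) > 0]
  }
  ep[, eid := NULL]
  ep[]
}

#' Episode rate summary over the cohort
#'
#' Computes (a) the overall episode rate per person-year, with
#' person-years the summed `followup_end - followup_start` over members
#' divided by 365.25; (b) first-year mean episode counts per patient,
#' overall and by setting (an episode belongs to year 1 iff its start
#' lies within the first 365 days of follow-up); (c) the per-patient
#' first-year count distribution binned 0 / 1 / 2 / >2; and (d) the
#' fraction of members with at least one episode over the full
#' follow-up.
#'
#' @param cohort cohort table from [select_cohort()].
#' @param episodes episode table attributed to those members.
#' @param config a [study_config()].
#' @return list with `total_episodes`, `person_years`, `rate_per_py`,
#'   `year1_mean`, `year1_mean_by_setting`, `year1_distribution`
#'   (counts and percentages for bins 0/1/2/>2), `pct_any_episode`.
#' @export
episode_rates <- function(cohort, episodes, config = study_config()) {
  co <- as.data.table(cohort)
  ep <- as.data.table(episodes)
  py <- sum(as.numeric(co$followup_end - co$followup_start)) / 365.25
  if (!is.finite(py) || py <= 0)
    stop("zero total person-time in cohort", call. = FALSE)
  n_mem <- nrow(co)
  total <- nrow(ep)
  epx <- merge(ep, co[, .(patient_id, followup_start)],
               by = "patient_id")
  epx[, in_y1 := as.numeric(start - followup_start) < 365]
  y1 <- epx[in_y1 == TRUE]
  y1_counts <- y1[, .N, by = patient_id]
  cnt <- merge(co[, .(patient_id)], y1_counts, by = "patient_id",
               all.x = TRUE)
  cnt[is.na(N), N := 0L]
  bins <- c(`0` = sum(cnt$N == 0L), `1` = sum(cnt$N == 1L),
            `2` = sum(cnt$N == 2L), `>2` = sum(cnt$N > 2L))
  by_setting <- sapply(config$setting_hierarchy, function(s)
    sum(y1$setting == s) / n_mem)
  list(
    total_episodes = total,
    person_years = py,
    rate_per_py = total / py,
    year1_mean = nrow(y1) / n_mem,
    year1_mean_by_setting = by_setting,
    year1_distribution = list(counts = bins,
                              pct = pct1(as.numeric(bins), n_mem)),
    pct_any_episode = pct1(uniqueN(ep$patient_id), n_mem)
  )
}
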