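#' Simulation parameters for the synthetic claims generator
#'
#' Defaults encode the study's published marginals: a negative-binomial
#' (gamma-mixed Poisson) VOC process with mean 3.31 episodes per
#' person-year and dispersion 0.24 (chosen analytically so that the
#' one-year zero fraction is 52.3%), per-episode settings proportional to
#' the published first-year per-patient means (1.06, 0.90, 0.51, 0.24,
#' 0.09 for inpatient/ER/outpatient/office/other), a complicated-episode
#' probability of 0.297, a primary-reason VOC share of 0.85 among acute
#' visits, and demographic margins matching the published baseline table.
#' Eligibility-noise probabilities default to 0 (a "clean" simulation in
#' which every patient is cohort-eligible); turn them up to exercise the
#' exclusion logic.
#'
#' @param n_patients positive integer.
#' @param voc_rate_mean mean VOC episodes per person-year (>= 0).
#' @param voc_rate_dispersion gamma shape for patient-level rate
#'   heterogeneity; smaller means more overdispersion.
#' @param setting_probs named probability vector over the five settings
#'   (must sum to 1 within 1e-9).
#' @param p_complicated probability an episode carries a complication
#'   diagnosis.
#' @param category_probs named probability vector over complication
#'   category labels (must sum to 1 and name configured categories).
#' @param episode_duration_days `list(dist = "poisson1", lambda = )`:
#'   non-inpatient episode span in days is 1 + Poisson(lambda), capped at
#'   `(claims - 1) * gap + 1` so within-episode gaps never exceed the
#'   merge threshold.
#' @param claims_per_episode `list(dist = "poisson1", lambda = )`: claims
#'   per episode is 1 + Poisson(lambda).
#' @param inpatient_los_days `list(dist = "lognormal", meanlog =, sdlog =)`
#'   for inpatient length of stay (days, rounded, min 1).
#' @param p_primary_reason_voc probability that an acute (ER/inpatient)
#'   episode's anchor claim has a VOC code as its primary diagnosis; must
#'   be >= 1 - p_complicated, since only complicated episodes can present
#'   with a complication as the primary diagnosis.
#' @param p_trial_code probability a patient gets a clinical-trial (V70.7)
#'   claim during the study period.
#' @param p_dual_eligible probability a patient's enrollment is flagged
#'   dual-eligible.
#' @param p_enrollment_gap probability of a 30--120 day coverage gap at a
#'   uniform position inside the enrollment span (may break the baseline,
#'   the first follow-up year, or merely truncate late follow-up).
#' @param p_early_disenroll probability enrollment ends before the study
#'   end (180--1500 days post-index) rather than running to it.
#' @param demographics list with `age_probs` (named over `"18-30"`,
#'   `"31-45"`, `"46-64"`, `"65+"`), `p_under_18`, `sex_probs`,
#'   `race_probs`, `region_probs`.
#' @param baseline list controlling baseline (pre-index) utilization
#'   noise: `er_mean`, `er_size` (negative-binomial ER visit count),
#'   `p_dup_er` (second same-day ER claim), `p_ip` (any inpatient stay),
#'   `ip_los_meanlog`, `ip_los_sdlog`, and comorbidity-injection
#'   probabilities `p_comorb1`, `p_comorb2`, `p_comorb6` (one Charlson
#'   condition of weight 1, 2, 6).
#' @param seed integer RNG seed; the generator is fully deterministic
#'   given `(params, config)`.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_patients = 1000L,
                       voc_rate_mean = 3.31,
                       voc_rate_dispersion = 0.24,
                       setting_probs = c(inpatient = 1.06, ER = 0.90,
                                         outpatient = 0.51, office = 0.24,
                                         other = 0.09) / 2.80,
                       p_complicated = 0.297,
                       category_probs = c(
                         "infectious and parasitic diseases" = 0.259,
                         "fever" = 0.218,
                         "pulmonary disorders" = 0.162,
                         "cerebrovascular conditions" = 0.085,
                         "thrombosis/DVT" = 0.082,
                         "aseptic (avascular) bone necrosis" = 0.194),
                       episode_duration_days = list(dist = "poisson1",
                                                    lambda = 0.8),
                       claims_per_episode = list(dist = "poisson1",
                                                 lambda = 0.7),
                       inpatient_los_days = list(dist = "lognormal",
                                                 meanlog = log(5),
                                                 sdlog = 0.82),
                       p_primary_reason_voc = 0.85,
                       p_trial_code = 0,
                       p_dual_eligible = 0,
                       p_enrollment_gap = 0,
                       p_early_disenroll = 0.1,
                       demographics = list(
                         age_probs = c("18-30" = 0.519, "31-45" = 0.296,
                                       "46-64" = 0.179, "65+" = 0.006),
                         p_under_18 = 0,
                         sex_probs = c(male = 0.327, female = 0.673),
                         race_probs = c(white = 0.063, black = 0.740,
                                        hispanic = 0.101, other = 0.029,
                                        unknown = 0.067),
                         region_probs = c(northeast = 0.446,
                                          north_central = 0.099,
                                          south = 0.266, west = 0.189)),
                       baseline = list(er_mean = 2.3, er_size = 0.4,
                                       p_dup_er = 0.1, p_ip = 0.298,
                                       ip_los_meanlog = log(3),
                                       ip_los_sdlog = 0.8,
                                       p_comorb1 = 0.25, p_comorb2 = 0.10,
                                       p_comorb6 = 0.03),
                       seed = 1L) {
  p <- list(n_patients = as.integer(n_patients),
            voc_rate_mean = voc_rate_mean,
            voc_rate_dispersion = voc_rate_dispersion,
            setting_probs = setting_probs,
            p_complicated = p_complicated,
            category_probs = category_probs,
            episode_duration_days = episode_duration_days,
            claims_per_episode = claims_per_episode,
            inpatient_los_days = inpatient_los_days,
            p_primary_reason_voc = p_primary_reason_voc,
            p_trial_code = p_trial_code,
            p_dual_eligible = p_dual_eligible,
            p_enrollment_gap = p_enrollment_gap,
            p_early_disenroll = p_early_disenroll,
            demographics = demographics,
            baseline = baseline,
            seed = as.integer(seed))
  class(p) <- "sim_params"
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  if (is.na(p$n_patients) || p$n_patients < 1L)
    stop("n_patients must be a positive integer", call. = FALSE)
  if (p$voc_rate_mean < 0) stop("voc_rate_mean must be >= 0", call. = FALSE)
  if (p$voc_rate_dispersion <= 0)
    stop("voc_rate_dispersion must be > 0", call. = FALSE)
  chk_probs <- function(v, nm) {
    if (length(v) == 0L || any(v < 0) || abs(sum(v) - 1) > 1e-9)
      stop(nm, " must be a non-empty probability vector summing to 1",
           call. = FALSE)
  }
  chk_probs(p$setting_probs, "setting_probs")
  chk_probs(p$category_probs, "category_probs")
  chk_probs(p$demographics$age_probs, "demographics$age_probs")
  chk_probs(p$demographics$sex_probs, "demographics$sex_probs")
  chk_probs(p$demographics$race_probs, "demographics$race_probs")
  chk_probs(p$demographics$region_probs, "demographics$region_probs")
  for (f in c("p_complicated", "p_primary_reason_voc", "p_trial_code",
              "p_dual_eligible", "p_enrollment_gap", "p_early_disenroll"))
    if (p[[f]] < 0 || p[[f]] > 1)
      stop(f, " must be in [0, 1]", call. = FALSE)
  if (p$p_primary_reason_voc < 1 - p$p_complicated - 1e-12)
    stop("p_primary_reason_voc must be >= 1 - p_complicated ",
         "(uncomplicated episodes always present as VOC)", call. = FALSE)
  for (f in c("episode_duration_days", "claims_per_episode"))
    if (!identical(p[[f]]$dist, "poisson1") || p[[f]]$lambda < 0)
      stop(f, " must be list(dist='poisson1', lambda >= 0)", call. = FALSE)
  if (!identical(p$inpatient_los_days$dist, "lognormal") ||
      p$inpatient_los_days$sdlog <= 0)
    stop("inpatient_los_days must be list(dist='lognormal', meanlog, ",
         "sdlog > 0)", call. = FALSE)
  p
}

# place-of-service label -> claim_type code
pos_to_type <- function(pos) {
  map <- c(inpatient = "IP", ER = "ER", outpatient = "OP",
           office = "OFF", other = "OTH")
  unname(map[pos])
}

# vectorized sampling of one concrete code per row from per-category pools
sample_cat_codes <- function(cat_idx, pools) {
  if (!length(cat_idx)) return(character(0))
  flat <- unlist(pools, use.names = FALSE)
  off <- cumsum(c(0L, lengths(pools)))[cat_idx]
  pick <- 1L + floor(runif(length(cat_idx)) * lengths(pools)[cat_idx])
  flat[off + pick]
}

#' Simulate a Medicaid-like claims database with known ground truth
#'
#' Generates patient, enrollment and claims tables together with the
#' ground truth they were drawn from (true episodes with setting,
#' complication status and category; true patient-level rates; an
#' eligibility flag with the first violated exclusion reason).  The
#' process is constructed so that the downstream pipeline can recover the
#' truth exactly on clean simulations:
#'
#' * patient-level episode counts are gamma-mixed Poisson (negative
#'   binomial) over each patient's true exposure;
#' * every VOC-coded claim belongs to exactly one true episode, within-
#'   episode claim gaps never exceed the merge threshold, and consecutive
#'   true episodes are separated by more than it;
#' * each episode's first ("anchor") claim carries the episode's true
#'   setting and every other claim a strictly lower-priority one, so the
#'   hierarchy resolves to the true setting;
#' * complication codes appear only on claims inside complicated
#'   episodes' intervals.
#'
#' @param params a [sim_params()] object.
#' @param config a [study_config()]; supplies code sets and study windows.
#' @return list with `patients`, `enrollment`, `claims` (data.tables) and
#'   `truth` (class `voc_ground_truth`: `$patients`, `$episodes`,
#'   `$claim_counts`).
#' @export
simulate_claims <- function(params, config = study_config()) {
  stopifnot(inherits(params, "sim_params"),
            inherits(config, "study_config"))
  if (!setequal(names(params$setting_probs), config$setting_hierarchy))
    stop("setting_probs names must match config$setting_hierarchy",
         call. = FALSE)
  cat_labels <- vapply(config$complication_categories, `[[`,
                       character(1), "label")
  if (!all(names(params$category_probs) %in% cat_labels))
    stop("category_probs names must be configured category labels",
         call. = FALSE)
  set.seed(params$seed)

  n <- params$n_patients
  d <- params$demographics
  gap <- config$episode_gap_days
  pid <- sprintf("P%06d", seq_len(n))

  ## ---- demographics -------------------------------------------------
  age_lo <- c("<18" = 8L, "18-30" = 18L, "31-45" = 31L, "46-64" = 46L,
              "65+" = 65L)
  age_hi <- c("<18" = 17L, "18-30" = 30L, "31-45" = 45L, "46-64" = 64L,
              "65+" = 80L)
  grp_p <- c("<18" = d$p_under_18, d$age_probs * (1 - d$p_under_18))
  grp <- names(grp_p)[sample.int(length(grp_p), n, TRUE, prob = grp_p)]
  age <- age_lo[grp] + floor(runif(n) * (age_hi[grp] - age_lo[grp] + 1L))
  sex <- names(d$sex_probs)[sample.int(length(d$sex_probs), n, TRUE,
                                       prob = d$sex_probs)]
  race <- names(d$race_probs)[sample.int(length(d$race_probs), n, TRUE,
                                         prob = d$race_probs)]
  region <- names(d$region_probs)[
    sample.int(length(d$region_probs), n, TRUE, prob = d$region_probs)]

  id_days <- as.integer(config$identification_end -
                          config$identification_start) + 1L
  idx <- config$identification_start + floor(runif(n) * id_days)
  birth <- idx - round(age * 365.25) - floor(runif(n) * 300)
  true_age <- age_at(birth, idx)

  ## ---- enrollment, eligibility noise --------------------------------
  enroll_start <- idx - config$baseline_days - (30L + floor(runif(n) * 91))
  early <- runif(n) < params$p_early_disenroll
  end_off <- 180L + floor(runif(n) * 1321)
  enroll_end <- fifelse(early, pmin(idx + end_off, config$study_end),
                        config$study_end)
  dual <- runif(n) < params$p_dual_eligible
  trial <- runif(n) < params$p_trial_code
  gap_flag <- runif(n) < params$p_enrollment_gap
  gap_len <- 30L + floor(runif(n) * 91)
  span_len <- as.integer(enroll_end - enroll_start) + 1L
  gap_flag <- gap_flag & span_len > gap_len + 20L
  gs_off <- 10L + floor(runif(n) * pmax(1, span_len - gap_len - 20L))
  gap_start <- enroll_start + gs_off
  gap_end <- gap_start + gap_len - 1L

  s1s <- enroll_start
  s1e <- fifelse(gap_flag, gap_start - 1L, enroll_end)
  s2s <- gap_end + 1L
  s2e <- enroll_end
  span_of <- function(day) {
    fifelse(day >= s1s & day <= s1e, 1L,
            fifelse(gap_flag & day >= s2s & day <= s2e, 2L, 0L))
  }
  bl_lo <- idx - config$baseline_days
  bl_hi <- idx - 1L
  sp_lo <- span_of(bl_lo); sp_hi <- span_of(bl_hi)
  baseline_ok <- sp_lo != 0L & sp_lo == sp_hi
  sp_idx <- span_of(idx)
  fu_cont_end <- fifelse(sp_idx == 1L, s1e,
                         fifelse(sp_idx == 2L, s2e, idx - 1L))
  fu_end <- pmin(fu_cont_end, config$study_end)
  followup_ok <- sp_idx != 0L &
    as.integer(fu_end - idx) >= config$followup_min_days - 1L

  reason <- rep(NA_character_, n)
  reason[dual] <- "dual_eligible"
  reason[trial] <- "trial_code"
  reason[!followup_ok] <- "insufficient_followup"
  reason[!baseline_ok] <- "insufficient_baseline"
  reason[true_age < config$min_age] <- "under_age"
  eligible <- is.na(reason)

  ## ---- true episode process -----------------------------------------
  t_days <- pmax(0L, as.integer(fu_end - idx))
  t_years <- t_days / 365.25
  k <- params$voc_rate_dispersion
  lam <- if (params$voc_rate_mean > 0)
    rgamma(n, shape = k, rate = k / params$voc_rate_mean)
  else rep(0, n)
  n_ep <- rpois(n, lam * t_years)

  m <- sum(n_ep)
  ep_p <- rep(seq_len(n), n_ep)
  hier <- config$setting_hierarchy
  sp <- params$setting_probs[hier]
  set_i <- sample.int(length(hier), m, TRUE, prob = sp)
  setting <- hier[set_i]
  complicated <- runif(m) < params$p_complicated
  x_voc <- if (params$p_complicated > 0)
    (params$p_primary_reason_voc - (1 - params$p_complicated)) /
      params$p_complicated else 1
  cat_primary <- complicated & (runif(m) < 1 - x_voc)
  cat_i <- sample.int(length(params$category_probs), m, TRUE,
                      prob = params$category_probs)
  cat_lab <- names(params$category_probs)[cat_i]
  cat_lab[!complicated] <- NA_character_
  ncl <- 1L + rpois(m, params$claims_per_episode$lambda)
  span_draw <- 1L + rpois(m, params$episode_duration_days$lambda)
  los <- pmax(1, round(rlnorm(m, params$inpatient_los_days$meanlog,
                              params$inpatient_los_days$sdlog)))
  is_ip <- setting == "inpatient"
  span <- fifelse(is_ip, los + 1L,
                  pmin(span_draw, (ncl - 1L) * pmax(gap, 1L) + 1L))
  avail <- t_days[ep_p]
  prop <- floor(runif(m) * pmax(1, avail - span + 2L))

  # sequential placement: episodes of a patient kept in proposed order,
  # pushed right so consecutive episodes are > gap days apart, dropped if
  # they no longer fit inside the follow-up window
  keep <- logical(m)
  st <- integer(m)
  if (m > 0L) {
    o <- order(ep_p, prop)
    pos <- 0L
    cur <- 0L
    for (ii in o) {
      p_i <- ep_p[ii]
      if (p_i != cur) { cur <- p_i; pos <- 0L }
      s <- max(prop[ii], pos)
      e <- s + span[ii] - 1L
      if (e <= t_days[p_i]) {
        keep[ii] <- TRUE
        st[ii] <- s
        pos <- e + gap + 1L
      }
    }
  }

  ep <- data.table(
    patient_id = pid[ep_p], pidx = ep_p, offset = st, span = span,
    setting = setting, complicated = complicated, category = cat_lab,
    cat_primary = cat_primary, n_claims = ncl, los = los
  )[keep == TRUE][order(pidx, offset)]
  ep[, start := idx[pidx] + offset]
  ep[, end := start + span - 1L]
  ep[, episode_id := seq_len(.N), by = patient_id]
  ep[, eid := .I]

  ## ---- claims -------------------------------------------------------
  voc_pool <- config$voc_episode_codes$codes
  cat_pools <- lapply(config$complication_categories, function(cc)
    cc$codeset$codes)
  names(cat_pools) <- cat_labels
  noise_pool <- c("78900", "7840", "4659", "V700")
  scd_pool <- setdiff(config$scd_codes$codes, voc_pool)

  mm <- nrow(ep)
  blank <- function(k) rep("", k)
  # anchor claims: one per episode, at the episode start, carrying the
  # episode's true setting
  cat_code <- rep("", mm)
  if (any(ep$complicated))
    cat_code[ep$complicated] <- sample_cat_codes(
      match(ep$category[ep$complicated], names(cat_pools)), cat_pools)
  voc_code <- voc_pool[1L + floor(runif(mm) * length(voc_pool))]
  anchor <- data.table(
    patient_id = ep$patient_id,
    service_start = ep$start,
    service_end = fifelse(ep$setting == "inpatient",
                          ep$start + ep$los, ep$start),
    place_of_service = ep$setting,
    dx1 = fifelse(ep$cat_primary, cat_code, voc_code),
    dx2 = fifelse(ep$cat_primary, voc_code,
                  fifelse(ep$complicated, cat_code, blank(mm))),
    dx3 = fifelse(runif(mm) < 0.15,
                  noise_pool[1L + floor(runif(mm) * length(noise_pool))],
                  blank(mm))
  )

  # extra claims: strictly lower-priority settings, spread over the
  # episode so consecutive within-episode gaps stay <= the threshold
  n_extra <- ep$n_claims - 1L
  xp <- rep(seq_len(mm), n_extra)
  extras <- NULL
  if (length(xp)) {
    j <- sequence(n_extra) + 1L
    e_span <- ep$span[xp]
    e_ncl <- ep$n_claims[xp]
    e_ip <- ep$setting[xp] == "inpatient"
    off <- integer(length(xp))
    off[e_ip] <- floor(runif(sum(e_ip)) * (ep$los[xp][e_ip] + 1L))
    ni <- !e_ip
    off[ni] <- round((j[ni] - 1L) * (e_span[ni] - 1L) /
                       pmax(1L, e_ncl[ni] - 1L))
    prio <- match(ep$setting[xp], hier)  # 1 = highest
    low <- length(hier)
    lower_pick <- prio + 1L + floor(runif(length(xp)) * (low - prio))
    lower_pick[prio >= low] <- low
    lower_pick[e_ip & lower_pick == match("ER", hier)] <-
      match("outpatient", hier)  # no stray ER claims inside IP episodes
    extras <- data.table(
      patient_id = ep$patient_id[xp],
      service_start = ep$start[xp] + off,
      service_end = ep$start[xp] + off,
      place_of_service = hier[lower_pick],
      dx1 = voc_pool[1L + floor(runif(length(xp)) * length(voc_pool))],
      dx2 = fifelse(runif(length(xp)) < 0.2,
                    noise_pool[1L + floor(runif(length(xp)) *
                                            length(noise_pool))],
                    blank(length(xp))),
      dx3 = blank(length(xp))
    )
  }

  # index claim: office visit with a non-crisis SCD code at the index date
  index_claims <- data.table(
    patient_id = pid,
    service_start = idx, service_end = idx,
    place_of_service = "office",
    dx1 = scd_pool[1L + floor(runif(n) * length(scd_pool))],
    dx2 = blank(n), dx3 = blank(n)
  )

  # clinical-trial marker claims
  trial_claims <- NULL
  if (any(trial)) {
    nt <- sum(trial)
    study_days <- as.integer(config$study_end - config$study_start) + 1L
    trial_claims <- data.table(
      patient_id = pid[trial],
      service_start = config$study_start + floor(runif(nt) * study_days),
      place_of_service = "other",
      dx1 = config$trial_exclusion_codes$codes[1L],
      dx2 = blank(nt), dx3 = blank(nt)
    )
    trial_claims[, service_end := service_start]
  }

  # baseline utilization noise: ER visits, an occasional inpatient stay,
  # and injected Charlson comorbidity codes -- none carry SCD/VOC codes
  b <- params$baseline
  er_cnt <- pmin(rnbinom(n, size = b$er_size, mu = b$er_mean),
                 config$baseline_days)
  er_rows <- which(er_cnt > 0L)
  er_claims <- NULL
  if (length(er_rows)) {
    er_days <- lapply(er_rows, function(i)
      sort(sample.int(config$baseline_days, er_cnt[i])) - 1L)
    er_p <- rep(er_rows, lengths(er_days))
    er_off <- unlist(er_days, use.names = FALSE)
    dup <- runif(length(er_p)) < b$p_dup_er
    er_p <- c(er_p, er_p[dup]); er_off <- c(er_off, er_off[dup])
    er_claims <- data.table(
      patient_id = pid[er_p],
      service_start = bl_lo[er_p] + er_off,
      place_of_service = "ER",
      dx1 = noise_pool[1L + floor(runif(length(er_p)) *
                                    length(noise_pool))],
      dx2 = blank(length(er_p)), dx3 = blank(length(er_p))
    )
    er_claims[, service_end := service_start]
  }
  ip_flag <- runif(n) < b$p_ip
  ip_claims <- NULL
  if (any(ip_flag)) {
    ni <- sum(ip_flag)
    ip_los <- pmin(pmax(1, round(rlnorm(ni, b$ip_los_meanlog,
                                        b$ip_los_sdlog))),
                   config$baseline_days - 2L)
    ip_off <- floor(runif(ni) * (config$baseline_days - ip_los))
    ip_claims <- data.table(
      patient_id = pid[ip_flag],
      service_start = bl_lo[ip_flag] + ip_off,
      place_of_service = "inpatient",
      dx1 = noise_pool[1L + floor(runif(ni) * length(noise_pool))],
      dx2 = blank(ni), dx3 = blank(ni)
    )
    ip_claims[, service_end := service_start + ip_los]
  }
  comorb_code <- c("4280", "5853", "0429")
  comorb_p <- c(b$p_comorb1, b$p_comorb2, b$p_comorb6)
  comorb_claims <- list()
  for (ci in seq_along(comorb_code)) {
    hitc <- runif(n) < comorb_p[ci]
    if (!any(hitc)) next
    nc <- sum(hitc)
    cc <- data.table(
      patient_id = pid[hitc],
      service_start = bl_lo[hitc] + floor(runif(nc) * config$baseline_days),
      place_of_service = "outpatient",
      dx1 = comorb_code[ci], dx2 = blank(nc), dx3 = blank(nc)
    )
    cc[, service_end := service_start]
    comorb_claims[[length(comorb_claims) + 1L]] <- cc
  }

  claims <- rbindlist(c(list(index_claims, anchor, extras, trial_claims,
                             er_claims, ip_claims), comorb_claims),
                      use.names = TRUE, fill = FALSE)
  setorder(claims, patient_id, service_start, service_end,
           place_of_service, dx1, dx2)
  claims[, claim_id := sprintf("C%08d", .I)]
  claims[, claim_type := pos_to_type(place_of_service)]
  setcolorder(claims, c("claim_id", "patient_id", "service_start",
                        "service_end", "place_of_service", "claim_type",
                        "dx1", "dx2", "dx3"))

  patients <- data.table(patient_id = pid, birth_date = birth,
                         sex = sex, race = race, region = region)
  enrollment <- rbindlist(list(
    data.table(patient_id = pid, span_start = s1s, span_end = s1e,
               medical = TRUE, pharmacy = TRUE, dual_eligible = dual),
    data.table(patient_id = pid[gap_flag], span_start = s2s[gap_flag],
               span_end = s2e[gap_flag], medical = TRUE, pharmacy = TRUE,
               dual_eligible = dual[gap_flag])
  ))
  setorder(enrollment, patient_id, span_start)

  truth_pat <- data.table(
    patient_id = pid, index_date = idx, followup_end = fu_end,
    exposure_years = t_years, true_rate = lam,
    true_n_episodes = tabulate(ep$pidx, nbins = n),
    eligible = eligible, reason = reason
  )
  truth <- structure(
    list(patients = truth_pat,
         episodes = ep[, .(patient_id, episode_id, start, end, setting,
                           complicated, category, cat_primary, n_claims)],
         claim_counts = list(index = n, episode = sum(ep$n_claims),
                             trial = sum(trial),
                             total = nrow(claims)),
         params = params),
    class = "voc_ground_truth")

  list(patients = patients, enrollment = enrollment, claims = claims,
       truth = truth)
}

#' Write simulated tables to CSV
#'
#' Writes `patients.csv`, `enrollment.csv` and `claims.csv` with the
#' documented headers; dates as ISO-8601, logicals as TRUE/FALSE.  The
#' files round-trip losslessly through [read_tables()].
#'
#' @param tables list with `patients`, `enrollment`, `claims` (as from
#'   [simulate_claims()]).
#' @param out_dir output directory (created if missing).
#' @return named character vector of file paths, invisibly.
#' @export
write_tables <- function(tables, out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  paths <- c(patients = file.path(out_dir, "patients.csv"),
             enrollment = file.path(out_dir, "enrollment.csv"),
             claims = file.path(out_dir, "claims.csv"))
  for (nm in names(paths))
    fwrite(tables[[nm]], paths[[nm]], dateTimeAs = "ISO")
  invisible(paths)
}

#' Read claims-database tables from CSV
#'
#' @param dir directory holding `patients.csv`, `enrollment.csv`,
#'   `claims.csv` as written by [write_tables()].
#' @return list of data.tables with parsed dates and logical flags.
#' @export
read_tables <- function(dir) {
  rd <- function(f, dates, logicals = character(0)) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing table: ", path, call. = FALSE)
    dt <- fread(path, colClasses = list(character = "patient_id"))
    for (cc in dates) set(dt, j = cc, value = as.Date(dt[[cc]]))
    for (cc in logicals) set(dt, j = cc, value = as.logical(dt[[cc]]))
    dt
  }
  claims <- rd("claims.csv", c("service_start", "service_end"))
  dxc <- grep("^dx", names(claims), value = TRUE)
  for (cc in dxc) {
    v <- claims[[cc]]
    if (!is.character(v)) v <- as.character(v)
    v[is.na(v)] <- ""
    set(claims, j = cc, value = v)
  }
  list(
    patients = rd("patients.csv", "birth_date"),
    enrollment = rd("enrollment.csv", c("span_start", "span_end"),
                    c("medical", "pharmacy", "dual_eligible")),
    claims = claims
  )
}
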