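cfg <- test_config()

test_that("find_index_date picks the first SCD claim inside the window", {
  one <- make_claims(0, dx1 = "28260", origin = as.Date("2010-03-05"))
  expect_identical(find_index_date(one, cfg), as.Date("2010-03-05"))

  # claim before the identification window is ignored
  two <- rbind(
    make_claims(0, dx1 = "28242", origin = as.Date("2009-06-15")),
    make_claims(0, dx1 = "28242", origin = as.Date("2009-08-01")))
  expect_identical(find_index_date(two, cfg), as.Date("2009-08-01"))

  # secondary-position SCD codes qualify
  sec <- make_claims(0, dx1 = "4659", dx2 = "28261",
                     origin = as.Date("2011-01-10"))
  expect_identical(find_index_date(sec, cfg), as.Date("2011-01-10"))

  none <- make_claims(0:2, dx1 = "4659", origin = as.Date("2010-01-01"))
  expect_true(is.na(find_index_date(none, cfg)))
})

test_that("is_continuously_enrolled handles covers, gaps and abutment", {
  origin <- as.Date("2010-01-01")
  exact <- make_spans(0, 99)
  expect_true(is_continuously_enrolled(exact, origin, origin + 99))
  # 1-day hole inside the interval
  hole <- make_spans(c(0, 51), c(49, 99))
  expect_false(is_continuously_enrolled(hole, origin, origin + 99))
  # abutting spans (end d, next start d + 1) cover
  abut <- make_spans(c(0, 50), c(49, 99))
  expect_true(is_continuously_enrolled(abut, origin, origin + 99))
  # spans without both benefits never count
  med_only <- make_spans(0, 99, pharmacy = FALSE)
  expect_false(is_continuously_enrolled(med_only, origin, origin + 99))
})

test_that("is_continuously_enrolled equals a day-by-day scan", {
  # randomized property test against the brute-force coverage oracle
  set.seed(424)
  origin <- as.Date("2010-01-01")
  for (i in 1:300) {
    k <- sample(1:4, 1)
    s <- sort(sample(0:40, k))
    e <- s + sample(0:15, k, replace = TRUE)
    sp <- make_spans(s, e,
                     medical = sample(c(TRUE, TRUE, FALSE), k, TRUE),
                     pharmacy = sample(c(TRUE, TRUE, FALSE), k, TRUE))
    a <- origin + sample(0:30, 1)
    b <- a + sample(0:20, 1)
    expect_identical(is_continuously_enrolled(sp, a, b),
                     covered_scan(sp, a, b),
                     label = sprintf("case %d", i))
  }
})

test_that("baseline_utilization counts visits, stays and LOS", {
  # two same-day ER claims are one visit
  er <- make_claims(c(5, 5), place = "ER", dx1 = "78900")
  u <- baseline_utilization(er)
  expect_identical(u$er_visits, 1L)
  # single stay: LOS = discharge - admission
  ip1 <- make_claims(0, end = 4, place = "inpatient", dx1 = "78900")
  u1 <- baseline_utilization(ip1)
  expect_identical(u1$ip_stays, 1L)
  expect_equal(u1$ip_los_days, 4)
  # overlapping/abutting IP claims merge into one stay (oracle: union)
  ip2 <- make_claims(c(0, 2), end = c(2, 5), place = "inpatient",
                     dx1 = "78900")
  u2 <- baseline_utilization(ip2)
  expect_identical(u2$ip_stays, 1L)
  expect_equal(u2$ip_los_days, 5)
  # same-day stay counts 1 day
  u3 <- baseline_utilization(make_claims(3, place = "inpatient",
                                         dx1 = "78900"))
  expect_equal(u3$ip_los_days, 1)
})

test_that("select_cohort applies exclusion rules in order", {
  db <- make_mini_db()
  sel <- select_cohort(db$patients, db$enrollment, db$claims, cfg)
  expect_identical(nrow(sel$cohort), 1L)
  expect_identical(nrow(sel$exclusions), 0L)
  expect_lte(sel$cohort$followup_end, as.Date("2013-12-31"))
  expect_identical(sel$cohort$index_date, as.Date("2010-03-01"))

  # trial code anywhere in the study period excludes
  db2 <- make_mini_db()
  db2$claims <- rbind(db2$claims,
                      make_claims(700, dx1 = "V707", place = "other",
                                  origin = as.Date("2010-03-01")))
  sel2 <- select_cohort(db2$patients, db2$enrollment, db2$claims, cfg)
  expect_identical(sel2$exclusions$excluded_reason, "trial_code")

  # dual eligibility on any span excludes
  db3 <- make_mini_db()
  db3$enrollment$dual_eligible <- TRUE
  sel3 <- select_cohort(db3$patients, db3$enrollment, db3$claims, cfg)
  expect_identical(sel3$exclusions$excluded_reason, "dual_eligible")

  # an under-age patient with a trial code logs the first violated rule
  db4 <- make_mini_db()
  db4$patients$birth_date <- as.Date("1995-01-01")
  db4$claims <- rbind(db4$claims,
                      make_claims(10, dx1 = "V707", place = "other",
                                  origin = as.Date("2010-03-01")))
  sel4 <- select_cohort(db4$patients, db4$enrollment, db4$claims, cfg)
  expect_identical(sel4$exclusions$excluded_reason, "under_age")

  # broken baseline enrollment
  db5 <- make_mini_db()
  db5$enrollment <- make_spans(c(-400, -50), c(-100, 1400),
                               origin = as.Date("2010-03-01"))
  sel5 <- select_cohort(db5$patients, db5$enrollment, db5$claims, cfg)
  expect_identical(sel5$exclusions$excluded_reason,
                   "insufficient_baseline")

  expect_error(
    select_cohort(rbind(db$patients, db$patients), db$enrollment,
                  db$claims, cfg),
    "duplicate")
})

test_that("cohort/exclusions partition the patient universe", {
  p <- sim_params(n_patients = 300, seed = 31, p_enrollment_gap = 0.2,
                  p_trial_code = 0.05, p_dual_eligible = 0.05)
  sim <- simulate_claims(p, cfg)
  sel <- select_cohort(sim$patients, sim$enrollment, sim$claims, cfg)
  expect_identical(nrow(sel$cohort) + nrow(sel$exclusions), 300L)
  expect_false(any(sel$cohort$patient_id %in% sel$exclusions$patient_id))
  # recovery: selection equals ground-truth eligibility, reasons included
  tp <- sim$truth$patients
  expect_setequal(sel$cohort$patient_id, tp[eligible == TRUE, patient_id])
  m <- merge(sel$exclusions, tp[, .(patient_id, reason)],
             by = "patient_id")
  expect_identical(m$excluded_reason, m$reason)
})

test_that("relaxing followup_min_days never shrinks the cohort", {
  p <- sim_params(n_patients = 200, seed = 17, p_enrollment_gap = 0.25,
                  p_early_disenroll = 0.4)
  sim <- simulate_claims(p, cfg)
  sizes <- vapply(c(540L, 365L, 180L, 90L), function(fu) {
    nrow(select_cohort(sim$patients, sim$enrollment, sim$claims,
                       study_config(followup_min_days = fu))$cohort)
  }, integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("members carry baseline characterization", {
  p <- sim_params(n_patients = 150, seed = 13)
  sim <- simulate_claims(p, cfg)
  sel <- select_cohort(sim$patients, sim$enrollment, sim$claims, cfg)
  co <- sel$cohort
  expect_true(all(co$age_at_index >= cfg$min_age))
  expect_true(all(co$cci >= 0))
  expect_true(all(co$baseline_ip_los_days[co$baseline_ip_stays == 0] == 0))
  # spot-check one member's CCI against the scalar scorer
  cl <- sim$claims[patient_id == co$patient_id[1]]
  bl <- cl[service_start >= co$baseline_start[1] &
             service_start < co$index_date[1]]
  codes <- unlist(bl[, .(dx1, dx2, dx3)])
  expect_identical(co$cci[1], charlson_score(codes))
})
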