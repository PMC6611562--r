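cfg <- test_config()

test_that("sim_params validates degenerate inputs", {
  expect_error(sim_params(n_patients = 0), "n_patients")
  expect_error(sim_params(setting_probs = c(inpatient = 0.5, ER = 0.4)),
               "summing to 1")
  expect_error(sim_params(voc_rate_dispersion = 0), "dispersion")
  expect_error(sim_params(p_complicated = 0.1,
                          p_primary_reason_voc = 0.5),
               "p_primary_reason_voc")
})

test_that("clean parameters produce an all-eligible population", {
  p <- sim_params(n_patients = 150, seed = 11, p_enrollment_gap = 0,
                  p_trial_code = 0, p_dual_eligible = 0,
                  p_early_disenroll = 0)
  sim <- simulate_claims(p, cfg)
  expect_true(all(sim$truth$patients$eligible))
  expect_true(all(is.na(sim$truth$patients$reason)))
})

test_that("a zero rate yields a null VOC process", {
  p <- sim_params(n_patients = 60, voc_rate_mean = 0, seed = 3)
  sim <- simulate_claims(p, cfg)
  expect_identical(nrow(sim$truth$episodes), 0L)
  expect_identical(sum(sim$truth$patients$true_n_episodes), 0L)
  dxc <- grep("^dx", names(sim$claims), value = TRUE)
  voc <- Reduce(`|`, lapply(dxc, function(cc)
    code_matches(sim$claims[[cc]], cfg$voc_episode_codes)))
  expect_identical(sum(voc), 0L)
})

test_that("the generator is byte-deterministic given the seed", {
  p <- sim_params(n_patients = 80, seed = 99, p_enrollment_gap = 0.1,
                  p_trial_code = 0.05)
  s1 <- simulate_claims(p, cfg)
  s2 <- simulate_claims(p, cfg)
  expect_identical(s1$claims, s2$claims)
  expect_identical(s1$enrollment, s2$enrollment)
  expect_identical(s1$patients, s2$patients)
  expect_identical(s1$truth$episodes, s2$truth$episodes)
  s3 <- simulate_claims(sim_params(n_patients = 80, seed = 100), cfg)
  expect_false(identical(s1$claims, s3$claims))
})

test_that("ground-truth structural invariants hold", {
  p <- sim_params(n_patients = 120, seed = 5)
  sim <- simulate_claims(p, cfg)
  ep <- sim$truth$episodes
  # consecutive true episodes separated by more than the gap threshold
  gaps <- ep[, as.numeric(start[-1L] - end[-.N]), by = patient_id]$V1
  expect_true(all(gaps > cfg$episode_gap_days))
  # every VOC-coded claim lies inside exactly one true episode interval
  dxc <- grep("^dx", names(sim$claims), value = TRUE)
  voc <- Reduce(`|`, lapply(dxc, function(cc)
    code_matches(sim$claims[[cc]], cfg$voc_episode_codes)))
  vc <- sim$claims[voc]
  hits <- ep[vc, on = .(patient_id, start <= service_start,
                        end >= service_start), nomatch = NULL, .N]
  expect_identical(hits, nrow(vc))
  # within-episode claim gaps never exceed the threshold (recoverability)
  expect_identical(sum(ep$n_claims), nrow(vc))
})

test_that("write_tables/read_tables round-trip losslessly", {
  p <- sim_params(n_patients = 40, seed = 8, p_enrollment_gap = 0.2)
  sim <- simulate_claims(p, cfg)
  dir <- withr::local_tempdir()
  paths <- write_tables(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_tables(dir)
  expect_equal(as.data.frame(back$patients), as.data.frame(sim$patients))
  expect_equal(as.data.frame(back$enrollment),
               as.data.frame(sim$enrollment))
  expect_equal(as.data.frame(back$claims), as.data.frame(sim$claims))
  # claims file row count equals the generator's claim bookkeeping
  expect_identical(nrow(back$claims), sim$truth$claim_counts$total)

  # empty claims table still writes a valid header-only CSV
  sim0 <- simulate_claims(sim_params(n_patients = 5, voc_rate_mean = 0,
                                     seed = 1), cfg)
  sim0$claims <- sim0$claims[0L]
  write_tables(sim0, dir)
  expect_identical(nrow(read_tables(dir)$claims), 0L)
})

test_that("patient-level counts are calibrated to the stated process", {
  # Monte-Carlo check against the generator's own stated process:
  # mean count = rate * exposure; SE from the NB variance mu + mu^2/k
  p <- sim_params(n_patients = 2000, seed = 21, p_early_disenroll = 0)
  sim <- simulate_claims(p, cfg)
  tp <- sim$truth$patients
  mu_i <- p$voc_rate_mean * tp$exposure_years
  se <- sqrt(sum(mu_i + mu_i^2 / p$voc_rate_dispersion)) /
    sum(tp$exposure_years)
  rate_hat <- sum(tp$true_n_episodes) / sum(tp$exposure_years)
  expect_lt(abs(rate_hat - p$voc_rate_mean), 3 * se)
})

test_that("episode settings are distributed as configured", {
  # chi-square goodness of fit at alpha = 0.01 on >= 5000 episodes,
  # across 20 fixed seeds (at most one rejection tolerated)
  probs <- c(inpatient = 1.06, ER = 0.90, outpatient = 0.51,
             office = 0.24, other = 0.09) / 2.80
  rejected <- 0L
  for (seed in 1:20) {
    p <- sim_params(n_patients = 700, seed = seed)
    ep <- simulate_claims(p, cfg)$truth$episodes
    expect_gt(nrow(ep), 5000)
    obs <- table(factor(ep$setting, names(probs)))
    pv <- suppressWarnings(
      stats::chisq.test(obs, p = probs)$p.value)
    if (pv < 0.01) rejected <- rejected + 1L
  }
  expect_lte(rejected, 1L)
})
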