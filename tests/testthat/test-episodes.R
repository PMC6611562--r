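cfg <- test_config()

test_that("gap merging follows the 3-day rule", {
  # claims on days 0, 2, 4: neighbour gaps <= 3 -> one episode over 0..4
  ep <- build_episodes(make_claims(c(0, 2, 4)), cfg)
  expect_identical(nrow(ep), 1L)
  expect_identical(as.integer(ep$end - ep$start), 4L)
  expect_identical(ep$n_claims, 3L)

  # day 0 and day 10: two episodes
  ep2 <- build_episodes(make_claims(c(0, 10)), cfg)
  expect_identical(nrow(ep2), 2L)

  # a 3-day gap merges, a 4-day gap splits
  expect_identical(nrow(build_episodes(make_claims(c(0, 3)), cfg)), 1L)
  expect_identical(nrow(build_episodes(make_claims(c(0, 4)), cfg)), 2L)

  # multi-day claims extend the running end
  long <- make_claims(c(0, 6), end = c(5, 6))
  expect_identical(nrow(build_episodes(long, cfg)), 1L)

  # non-VOC claims are ignored; no VOC claims -> empty result
  noise <- make_claims(c(0, 1), dx1 = "4659")
  expect_identical(nrow(build_episodes(noise, cfg)), 0L)
})

test_that("greedy merging equals transitive-closure clustering", {
  # oracle-equivalence property on 1000 random small claim sets
  set.seed(77)
  for (i in 1:1000) {
    k <- sample(1:8, 1)
    s <- sample(0:25, k, replace = TRUE)
    e <- s + sample(0:4, k, replace = TRUE)
    gap <- sample(0:4, 1)
    claims <- make_claims(s, end = e)
    ep <- build_episodes(claims, study_config(episode_gap_days = gap))
    want <- oracle_cluster(s, e, gap)
    # compare partitions of claim ids (canonical: sorted members,
    # parts ordered by their first member)
    got <- integer(k)
    for (g in seq_len(nrow(ep)))
      got[match(ep$claim_ids[[g]], claims$claim_id)] <- g
    canon <- function(grp) {
      parts <- lapply(split(claims$claim_id, grp), sort)
      unname(parts[order(vapply(parts, `[`, character(1), 1L))])
    }
    expect_identical(canon(got), canon(want),
                     label = sprintf("case %d", i))
  }
})

test_that("increasing the gap threshold never increases episode count", {
  set.seed(99)
  for (i in 1:50) {
    s <- sample(0:60, sample(2:10, 1), replace = TRUE)
    claims <- make_claims(s)
    n_ep <- vapply(0:6, function(g)
      nrow(build_episodes(claims, study_config(episode_gap_days = g))),
      integer(1))
    expect_true(all(diff(n_ep) <= 0))
  }
})

test_that("assign_setting resolves the hierarchy, order-invariantly", {
  expect_identical(assign_setting(c("ER", "inpatient")), "inpatient")
  expect_identical(assign_setting("office"), "office")
  expect_error(assign_setting(c("ER", "ward")), "hierarchy")
  expect_error(assign_setting(character(0)), "at least one")

  # permutation property: exhaustive over all multisets of size <= 3
  hier <- c("inpatient", "ER", "outpatient", "office", "other")
  for (k in 1:3) {
    sets <- do.call(expand.grid,
                    c(rep(list(hier), k), stringsAsFactors = FALSE))
    for (r in seq_len(nrow(sets))) {
      places <- unlist(sets[r, ], use.names = FALSE)
      base <- assign_setting(places, hier)
      expect_identical(assign_setting(rev(places), hier), base)
      expect_identical(base, hier[min(match(places, hier))])
    }
  }
})

test_that("classification scans intersecting claims by dx position", {
  # concurrent claim with a fever code as dx1 -> complicated, both sets
  claims <- rbind(make_claims(c(0, 2)),
                  make_claims(1, dx1 = "78060", place = "office"))
  ep <- classify_episodes(build_all_episodes(claims, cfg), claims, cfg)
  expect_true(ep$complicated)
  expect_identical(ep$categories_primary, "fever")
  expect_identical(ep$categories_any, "fever")

  # complication code only in secondary position -> any, not primary
  claims2 <- rbind(make_claims(0, dx2 = "4534"), make_claims(2))
  ep2 <- classify_episodes(build_all_episodes(claims2, cfg), claims2, cfg)
  expect_true(ep2$complicated)
  expect_identical(ep2$categories_primary, "")
  expect_identical(ep2$categories_any, "thrombosis/DVT")

  # no intersecting complication claims -> uncomplicated
  claims3 <- rbind(make_claims(0),
                   make_claims(30, dx1 = "78060", place = "office"))
  ep3 <- classify_episodes(build_all_episodes(claims3, cfg), claims3, cfg)
  expect_false(ep3$complicated)
  expect_identical(ep3$categories_any, "")

  # a claim outside the episode but overlapping it by interval counts
  claims4 <- rbind(make_claims(c(5, 7)),
                   make_claims(0, end = 6, dx1 = "486",
                               place = "inpatient"))
  ep4 <- build_all_episodes(claims4, cfg)
  voc_only <- classify_episodes(ep4, claims4, cfg)
  expect_true(any(voc_only$complicated))
})

test_that("episode conservation and complication split hold", {
  p <- sim_params(n_patients = 250, seed = 61, p_early_disenroll = 0)
  sim <- simulate_claims(p, cfg)
  tp <- sim$truth$patients
  cl <- merge(sim$claims, tp[, .(patient_id, index_date, followup_end)],
              by = "patient_id")
  fu <- cl[service_start >= index_date & service_start <= followup_end]
  ep <- classify_episodes(build_all_episodes(fu, cfg), fu, cfg)
  dxc <- grep("^dx", names(fu), value = TRUE)
  voc_n <- sum(Reduce(`|`, lapply(dxc, function(cc)
    code_matches(fu[[cc]], cfg$voc_episode_codes))))
  expect_identical(sum(ep$n_claims), voc_n)
  expect_identical(sum(ep$complicated) + sum(!ep$complicated), nrow(ep))
  # complicated fraction within 3 binomial SEs of the generator parameter
  phat <- mean(ep$complicated)
  se <- sqrt(0.297 * 0.703 / nrow(ep))
  expect_lt(abs(phat - 0.297), 3 * se)
})

test_that("episode_rates computes person-year and year-1 summaries", {
  co <- data.table(patient_id = "P1",
                   followup_start = as.Date("2010-01-01"),
                   followup_end = as.Date("2012-01-01"))
  ep <- data.table(patient_id = "P1",
                   start = as.Date("2010-01-01") + c(10, 50, 100, 200,
                                                     400, 600),
                   setting = c("inpatient", "ER", "ER", "office",
                               "inpatient", "other"))
  r <- episode_rates(co, ep, cfg)
  expect_equal(r$rate_per_py, 6 / (730 / 365.25), tolerance = 1e-10)
  expect_equal(r$rate_per_py, 3.0, tolerance = 0.01)
  # episode starting on day 400 is out of year 1, still in overall rate
  expect_equal(r$year1_mean, 4)
  expect_equal(unname(r$year1_mean_by_setting["inpatient"]), 1)
  expect_equal(unname(r$year1_distribution$counts[">2"]), 1L)
  expect_equal(r$pct_any_episode, 100)

  expect_error(episode_rates(co[0L], ep, cfg), "person-time")
})
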