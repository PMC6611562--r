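# Independent oracles and tiny fixture builders used across the suite.
library(data.table)

# --- fixtures --------------------------------------------------------------

# quick claims table: one row per element of `day` (offsets from `origin`)
make_claims <- function(day, end = day, place = "outpatient",
                        dx1 = "28242", dx2 = "", dx3 = "",
                        patient_id = "P1",
                        origin = as.Date("2010-06-01")) {
  data.table(
    claim_id = sprintf("C%03d", seq_along(day)),
    patient_id = patient_id,
    service_start = origin + day,
    service_end = origin + end,
    place_of_service = place,
    claim_type = c(inpatient = "IP", ER = "ER", outpatient = "OP",
                   office = "OFF", other = "OTH")[place],
    dx1 = dx1, dx2 = dx2, dx3 = dx3
  )
}

make_spans <- function(start, end, medical = TRUE, pharmacy = TRUE,
                       dual = FALSE, patient_id = "P1",
                       origin = as.Date("2010-01-01")) {
  data.table(patient_id = patient_id,
             span_start = origin + start, span_end = origin + end,
             medical = medical, pharmacy = pharmacy,
             dual_eligible = dual)
}

# a one-patient mini-database that passes every selection rule
make_mini_db <- function(index_day = 0L, origin = as.Date("2010-03-01")) {
  idx <- origin + index_day
  list(
    patients = data.table(patient_id = "P1",
                          birth_date = as.Date("1980-05-15"),
                          sex = "female", race = "black",
                          region = "south"),
    enrollment = make_spans(-400, 1400, origin = idx),
    claims = make_claims(0, patient_id = "P1", place = "office",
                         dx1 = "28260", origin = idx)
  )
}

# --- oracles ---------------------------------------------------------------

# day-by-day brute-force coverage scan (continuous-enrollment oracle)
covered_scan <- function(spans, a, b) {
  if (a > b) return(TRUE)
  days <- seq(a, b, by = "day")
  ok <- spans$medical & spans$pharmacy
  all(vapply(days, function(d)
    any(ok & spans$span_start <= d & spans$span_end >= d), logical(1)))
}

# transitive-closure interval clustering under the closed-interval gap
# metric: claims i, j connect iff max(s_i - e_j, s_j - e_i) <= gap
oracle_cluster <- function(s, e, gap) {
  n <- length(s)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && max(s[i] - e[j], s[j] - e[i]) <= gap) {
        parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  # canonical labels: number components by first appearance in start order
  ord <- order(s, e)
  match(roots, unique(roots[ord]))
}

# partition of claim ids induced by build_episodes, as a canonical list
episode_partition <- function(ep) {
  if (nrow(ep) == 0L) return(list())
  lapply(ep$claim_ids, sort)
}

# default config/params shared across tests
test_config <- function(...) study_config(...)
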