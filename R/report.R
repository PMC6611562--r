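# deterministic hash of the configuration (md5 of its JSON serialization)
config_hash <- function(config) {
  strip <- function(x) {
    if (inherits(x, "Date")) return(format(x))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  ser <- jsonlite::toJSON(strip(config), auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(ser), tf)
  unname(tools::md5sum(tf))
}

count_pct <- function(x, levels, denom = length(x)) {
  n <- vapply(levels, function(l) sum(x == l), integer(1))
  list(n = as.list(n), pct = as.list(pct1(as.numeric(n), denom)))
}

#' Assemble the descriptive summary report
#'
#' Builds the study's descriptive outputs as one machine-readable
#' structure: cohort demographics and baseline characteristics, episode
#' totals with complicated/uncomplicated shares and person-year rates,
#' first-year means by setting and the first-year count distribution,
#' complication-category rankings (primary-only and any-position), the
#' visit reason breakdown with LOS summaries, and provenance (config
#' hash, seed, row counts).  Percentages are computed before rounding and
#' rounded half away from zero at 1 decimal.
#'
#' @param cohort cohort table from [select_cohort()].
#' @param episodes classified episode table ([classify_episodes()]).
#' @param visits visit table from [build_visits()].
#' @param config a [study_config()].
#' @return a list of class `voc_summary_report`.
#' @export
build_report <- function(cohort, episodes, visits,
                         config = study_config()) {
  co <- as.data.table(cohort)
  ep <- as.data.table(episodes)
  vi <- as.data.table(visits)
  if (nrow(ep) && length(setdiff(ep$patient_id, co$patient_id)))
    stop("episodes reference patients absent from cohort", call. = FALSE)
  if (nrow(vi) && length(setdiff(vi$patient_id, co$patient_id)))
    stop("visits reference patients absent from cohort", call. = FALSE)
  n <- nrow(co)

  age_groups <- cut(co$age_at_index, c(-Inf, 17, 30, 45, 64, Inf),
                    labels = c("<18", "18-30", "31-45", "46-64", "65+"))
  cci_groups <- cut(co$cci, c(-Inf, 0, 1, 3, Inf),
                    labels = c("0", "1", "2-3", "4+"))
  cohort_summary <- list(
    n = n,
    age = list(mean = mean(co$age_at_index), sd = sd(co$age_at_index),
               median = median(as.numeric(co$age_at_index))),
    age_group = count_pct(as.character(age_groups),
                          c("<18", "18-30", "31-45", "46-64", "65+"), n),
    sex = count_pct(co$sex, sort(unique(co$sex)), n),
    race = count_pct(co$race, sort(unique(co$race)), n),
    region = count_pct(co$region, sort(unique(co$region)), n),
    cci = list(mean = mean(co$cci),
               distribution = count_pct(as.character(cci_groups),
                                        c("0", "1", "2-3", "4+"), n)),
    baseline = list(
      mean_er_visits = mean(co$baseline_er_visits),
      mean_ip_los_days = mean(co$baseline_ip_los_days),
      any_er = list(n = sum(co$baseline_er_visits > 0),
                    pct = pct1(sum(co$baseline_er_visits > 0), n)),
      any_ip = list(n = sum(co$baseline_ip_stays > 0),
                    pct = pct1(sum(co$baseline_ip_stays > 0), n))
    )
  )

  total <- nrow(ep)
  if (total > 0L) {
    rates <- episode_rates(co, ep, config)
    n_comp <- sum(ep$complicated)
    comp_ep <- ep[complicated == TRUE]
    cat_rank <- function(col) {
      labs <- unlist(strsplit(comp_ep[[col]][nzchar(comp_ep[[col]])],
                              ",", fixed = TRUE))
      if (!length(labs))
        return(data.table(category = character(0), n = integer(0),
                          pct = numeric(0)))
      tb <- as.data.table(table(category = labs))
      setnames(tb, "N", "n")
      tb[, pct := pct1(as.numeric(n), nrow(comp_ep))]
      setorder(tb, -n, category)
      tb
    }
    episode_summary <- list(
      total = total,
      complicated = list(n = n_comp, pct = pct1(n_comp, total)),
      uncomplicated = list(n = total - n_comp,
                           pct = pct1(total - n_comp, total)),
      person_years = rates$person_years,
      rate_per_py = rates$rate_per_py,
      year1_mean = rates$year1_mean,
      year1_mean_by_setting = as.list(rates$year1_mean_by_setting),
      year1_distribution = list(
        counts = as.list(rates$year1_distribution$counts),
        pct = as.list(rates$year1_distribution$pct)),
      pct_any_episode = rates$pct_any_episode,
      top_categories_primary = cat_rank("categories_primary"),
      top_categories_any = cat_rank("categories_any")
    )
  } else {
    episode_summary <- list(total = 0L,
                            complicated = list(n = 0L, pct = NA_real_),
                            uncomplicated = list(n = 0L, pct = NA_real_),
                            person_years = sum(as.numeric(
                              co$followup_end - co$followup_start)) /
                              365.25,
                            rate_per_py = NA_real_, rate_undefined = TRUE,
                            year1_mean = 0, year1_mean_by_setting = NULL,
                            year1_distribution = NULL,
                            pct_any_episode = 0,
                            top_categories_primary = NULL,
                            top_categories_any = NULL)
  }

  visit_summary <- list(reasons = reason_breakdown(vi),
                        los = los_summary(vi))

  report <- list(
    cohort_summary = cohort_summary,
    episode_summary = episode_summary,
    visit_summary = visit_summary,
    provenance = list(config_hash = config_hash(config),
                      rng_seed = config$rng_seed,
                      n_cohort = n, n_episodes = total,
                      n_visits = nrow(vi))
  )
  class(report) <- "voc_summary_report"
  report
}

fmt1 <- function(x) formatC(round_half_up(x, 1L), format = "f", digits = 1)

#' Render a summary report to JSON and/or Markdown
#'
#' The JSON rendering is a faithful machine-readable serialization that
#' parses back to an equal report; the Markdown rendering is a
#' human-readable digest with one table per summary block, numbers at
#' 1-decimal precision.  Both renderings are byte-deterministic.
#'
#' @param report a `voc_summary_report` from [build_report()].
#' @param format `"json"` or `"markdown"`.
#' @param path optional output file; written atomically when given.
#' @return the rendered text, invisibly when `path` is given.
#' @export
render_report <- function(report, format = c("json", "markdown"),
                          path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(report, "voc_summary_report"))
  if (format == "json") {
    txt <- as.character(jsonlite::toJSON(unclass(report),
                                         auto_unbox = TRUE, digits = 10,
                                         pretty = TRUE, na = "null"))
  } else {
    cs <- report$cohort_summary
    es <- report$episode_summary
    vs <- report$visit_summary
    lines <- c(
      "# VOC burden summary", "",
      "## Cohort", "",
      "| measure | value |", "|---|---|",
      sprintf("| patients | %d |", cs$n),
      sprintf("| age mean (SD) | %s (%s) |", fmt1(cs$age$mean),
              fmt1(cs$age$sd)),
      sprintf("| age median | %s |", fmt1(cs$age$median)),
      sprintf("| CCI mean | %s |", fmt1(cs$cci$mean)),
      sprintf("| baseline any ER visit | %d (%s%%) |",
              cs$baseline$any_er$n, fmt1(cs$baseline$any_er$pct)),
      sprintf("| baseline any inpatient stay | %d (%s%%) |",
              cs$baseline$any_ip$n, fmt1(cs$baseline$any_ip$pct)),
      "", "## Episodes", "",
      "| measure | value |", "|---|---|",
      sprintf("| total VOC episodes | %d |", es$total),
      sprintf("| complicated | %d (%s%%) |", es$complicated$n,
              fmt1(es$complicated$pct)),
      sprintf("| uncomplicated | %d (%s%%) |", es$uncomplicated$n,
              fmt1(es$uncomplicated$pct)),
      sprintf("| rate per person-year | %s |",
              if (is.na(es$rate_per_py)) "undefined"
              else fmt1(es$rate_per_py)),
      sprintf("| year-1 mean per patient | %s |", fmt1(es$year1_mean)),
      "", "## Visits", "")
    bt <- vs$reasons$by_type
    lines <- c(lines,
               "| visit type | SCD-related | VOC primary | complication primary |",
               "|---|---|---|---|")
    if (nrow(bt)) {
      lines <- c(lines, sprintf(
        "| %s | %d | %d (%s%%) | %d (%s%%) |", bt$visit_type,
        bt$n_total, bt$n_voc, fmt1(bt$pct_voc), bt$n_complication,
        fmt1(bt$pct_complication)))
    }
    los <- vs$los
    lines <- c(lines, "",
               "| LOS by reason | n | mean | sd | median | IQR |",
               "|---|---|---|---|---|---|")
    if (nrow(los)) {
      lines <- c(lines, sprintf(
        "| %s | %d | %s | %s | %s | %s |", los$reason, los$n,
        fmt1(los$mean), fmt1(los$sd), fmt1(los$median), fmt1(los$iqr)))
    }
    lines <- c(lines, "",
               sprintf("provenance: config %s, seed %d, %d patients, %d episodes, %d visits",
                       report$provenance$config_hash,
                       report$provenance$rng_seed,
                       report$provenance$n_cohort,
                       report$provenance$n_episodes,
                       report$provenance$n_visits), "")
    txt <- paste(lines, collapse = "\n")
  }
  if (!is.null(path)) {
    con <- file(path, open = "wb")  # fixed EOL across platforms
    writeBin(charToRaw(txt), con)
    close(con)
    return(invisible(txt))
  }
  txt
}

#' Run the whole pipeline on a synthetic database
#'
#' Chains simulate -> write tables -> read tables -> select cohort ->
#' build + classify episodes -> build visits -> build report, writing
#' every intermediate table and both report renderings under `out_dir`.
#' Fully deterministic for a fixed `(params, config)`.
#'
#' @param params a [sim_params()].
#' @param config a [study_config()].
#' @param out_dir output directory.
#' @return (invisibly) list with the report object, the tables, and the
#'   output file paths.
#' @export
run_all <- function(params, config = study_config(), out_dir) {
  sim <- simulate_claims(params, config)
  paths <- write_tables(sim, out_dir)
  tabs <- read_tables(out_dir)
  sel <- select_cohort(tabs$patients, tabs$enrollment, tabs$claims,
                       config)
  fu <- merge(tabs$claims,
              sel$cohort[, .(patient_id, followup_start, followup_end)],
              by = "patient_id")
  fu <- fu[service_start >= followup_start &
             service_start <= followup_end]
  ep <- build_all_episodes(fu, config)
  ep <- classify_episodes(ep, fu, config)
  vis <- build_visits(tabs$claims, sel$cohort, config)
  report <- build_report(sel$cohort, ep, vis, config)

  epw <- copy(ep)
  epw[, claim_ids := vapply(claim_ids, paste, character(1),
                            collapse = ";")]
  outs <- c(cohort = file.path(out_dir, "cohort.csv"),
            exclusions = file.path(out_dir, "exclusions.csv"),
            episodes = file.path(out_dir, "episodes.csv"),
            visits = file.path(out_dir, "visits.csv"),
            report_json = file.path(out_dir, "report.json"),
            report_md = file.path(out_dir, "report.md"))
  fwrite(sel$cohort, outs["cohort"], dateTimeAs = "ISO")
  fwrite(sel$exclusions, outs["exclusions"], dateTimeAs = "ISO")
  fwrite(epw, outs["episodes"], dateTimeAs = "ISO")
  fwrite(vis, outs["visits"], dateTimeAs = "ISO")
  render_report(report, "json", outs["report_json"])
  render_report(report, "markdown", outs["report_md"])
  invisible(list(report = report, cohort = sel$cohort,
                 exclusions = sel$exclusions, episodes = ep,
                 visits = vis, truth = sim$truth,
                 paths = c(paths, outs)))
}
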