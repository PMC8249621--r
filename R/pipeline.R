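#' Descriptive summary of nightly quotas
#'
#' Mean (SD) of each quota per stratum. Clock-time variables are summarized
#' circularly (mean clock time, dispersion in hours); the nap column is
#' additionally cross-checked as mean(TTST) - mean(TST).
#'
#' @param quotas Nightly quota table ([cohort_quotas()] output).
#' @param strata Character vector of grouping columns (empty for an overall
#'   summary).
#' @return Tibble with one row per stratum and variable: `mean`, `sd`, `n`,
#'   formatted `label`; plus `nap_from_identity` rows giving
#'   mean(TTST) - mean(TST).
#' @export
summarize_quotas <- function(quotas, strata = character()) {
  vars <- intersect(c("sleep_onset_h", "sleep_end_h", "tib_h", "tst_h",
                      "ttst_h", "nap_h", "waso_h", "efficiency_pct",
                      "fragmentation"), names(quotas))
  groups <- if (length(strata)) quotas %>% group_by(across(all_of(strata))) else quotas
  keys <- if (length(strata)) {
    quotas %>% distinct(across(all_of(strata)))
  } else tibble(.rows = 1)
  summarise_one <- function(df) {
    rows <- map(vars, function(v) {
      x <- df[[v]]
      if (v %in% .CLOCK_VARS) {
        cs <- circular_time_stats(x)
        tibble(variable = v, mean = cs$mean_h, sd = cs$dispersion_min / 60,
               n = length(x),
               label = sprintf("%s (%s)", format_clock(cs$mean_h),
                               format_clock(cs$dispersion_min / 60)))
      } else {
        sdv <- if (length(x) > 1) sd(x) else 0
        tibble(variable = v, mean = mean(x), sd = sdv, n = length(x),
               label = sprintf("%.2f (%.2f)", mean(x), sdv))
      }
    })
    nap_id <- mean(df$ttst_h) - mean(df$tst_h)
    bind_rows(list_rbind(rows),
              tibble(variable = "nap_from_identity", mean = nap_id,
                     sd = NA_real_, n = nrow(df),
                     label = sprintf("%.2f", nap_id)))
  }
  if (!length(strata)) return(summarise_one(quotas))
  out <- quotas %>%
    group_by(across(all_of(strata))) %>%
    dplyr::group_modify(function(df, key) summarise_one(df)) %>%
    ungroup()
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate (or load) -> score -> summarize -> compare ->
#' mixed-model averaging -> functional comparison, writing CSV tables, a
#' JSON run manifest and a log to `output_dir`.
#'
#' @param config List (or YAML file path) with elements:
#'   `synthetic` (a [cohort_config()] or arguments for one) or `cohort` (a
#'   prebuilt [sleep_cohort()]); `scoring` (a [scoring_config()]);
#'   logical toggles `npcra`, `comparisons`, `lmm`, `flm`; `alpha`,
#'   `n_perm`, `seed`; `output_dir`.
#' @return Invisible list of the computed tables (also written to disk).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(npcra = TRUE, comparisons = TRUE, lmm = TRUE, flm = TRUE,
                   alpha = 0.05, n_perm = 500, seed = 1L,
                   output_dir = "pipeline-out")
  config <- utils::modifyList(defaults, config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$output_dir, "run.log")
  log_line <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = logf, append = TRUE)
    message(msg)
  }
  unlink(logf)

  if (!is.null(config$cohort)) {
    cohort <- config$cohort
    log_line("stage=input source=supplied series=%d", length(cohort$series))
  } else {
    cc <- config$synthetic
    if (!inherits(cc, "cohort_config")) {
      cc <- do.call(cohort_config, c(if (is.list(cc)) cc else list(),
                                     list(seed = config$seed)))
    }
    cohort <- generate_cohort(cc)
    log_line("stage=simulate seed=%d series=%d", cc$seed, length(cohort$series))
  }
  scoring <- if (is.null(config$scoring)) scoring_config() else config$scoring

  out <- list()
  quotas <- cohort_quotas(cohort, scoring)
  out$quotas <- quotas
  readr::write_csv(quotas %>% select(-"onset", -"end"),
                   file.path(config$output_dir, "nightly_quotas.csv"))
  log_line("stage=score nights=%d participants=%d",
           nrow(quotas), dplyr::n_distinct(quotas$participant_id))

  out$summary_overall <- summarize_quotas(quotas)
  out$summary_location <- summarize_quotas(quotas, "location")
  out$summary_gender_location <- summarize_quotas(quotas, c("location", "gender"))
  readr::write_csv(out$summary_overall, file.path(config$output_dir, "summary_overall.csv"))
  readr::write_csv(out$summary_location, file.path(config$output_dir, "summary_by_location.csv"))
  readr::write_csv(out$summary_gender_location,
                   file.path(config$output_dir, "summary_by_gender_location.csv"))

  if (isTRUE(config$npcra)) {
    np <- suppressMessages(cohort_npcra(cohort))
    out$npcra <- np
    if (!is.null(np) && nrow(np)) {
      readr::write_csv(np, file.path(config$output_dir, "npcra.csv"))
    }
    log_line("stage=npcra eligible_series=%d", if (is.null(np)) 0L else nrow(np))
  }

  if (isTRUE(config$comparisons)) {
    comp_vars <- c("tib_h", "tst_h", "ttst_h", "nap_h", "waso_h",
                   "efficiency_pct", "fragmentation")
    comps <- bind_rows(
      list_rbind(map(comp_vars, function(v) compare_groups(quotas, v, "location"))),
      compare_groups(quotas, "sleep_onset_h", "location"),
      compare_groups(quotas, "sleep_end_h", "location"),
      list_rbind(map(comp_vars, function(v) compare_groups(quotas, v, "gender")))
    )
    out$comparisons <- comps
    readr::write_csv(comps, file.path(config$output_dir, "comparisons.csv"))
    log_line("stage=comparisons contrasts=%d", nrow(comps))
  }

  if (isTRUE(config$lmm)) {
    fits <- map(
      setNames(c("tst_h", "ttst_h", "efficiency_pct", "fragmentation"),
               c("tst", "ttst", "efficiency", "fragmentation")),
      function(ocol) sleep_lmm_average(quotas, ocol)
    )
    out$lmm <- fits
    lmm_tab <- list_rbind(imap(fits, function(f, nm) {
      mutate(tidy(f), outcome = nm, .before = 1)
    }))
    readr::write_csv(lmm_tab, file.path(config$output_dir, "lmm_averaged.csv"))
    log_line("stage=lmm outcomes=%d", length(fits))
  }

  if (isTRUE(config$flm)) {
    for (grp in c("location", "gender")) {
      res <- suppressMessages(
        flm_compare(cohort, grp, alpha = config$alpha,
                    n_perm = config$n_perm, seed = config$seed))
      out[[paste0("flm_", grp)]] <- res
      readr::write_csv(tidy(res),
                       file.path(config$output_dir, paste0("flm_", grp, ".csv")))
      log_line("stage=flm grouping=%s significant_fraction=%.3f",
               grp, mean(res$table$significant))
    }
  }

  manifest <- list(
    seed = config$seed, alpha = config$alpha, n_perm = config$n_perm,
    n_series = length(cohort$series),
    n_participants = dplyr::n_distinct(
      list_rbind(map(cohort$series, series_meta))$participant_id),
    n_nights = nrow(quotas),
    n_nights_by_location = as.list(table(quotas$location)),
    stages = names(out)
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line("stage=done nights=%d", nrow(quotas))
  invisible(out)
}
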