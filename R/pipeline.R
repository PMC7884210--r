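#' Run the full evaluation pipeline and write its outputs
#'
#' Chains every stage on one synthetic dataset: trial generation,
#' per-patient costing with arm summaries, 28-day quality-of-life AUC
#' comparison, survival fractions and tests at 1/2/5 years, the
#' base-case Markov cost-effectiveness comparison, and the PSA with its
#' acceptability curve. All outputs are written as CSV/JSON (and figures
#' as files when `figures = TRUE`) under `out_dir`, together with a run
#' manifest recording the seed, package version and an MD5 checksum per
#' output, so a rerun with the same seed is verifiably identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for the trial draw and the PSA.
#' @param config A [trial_config()].
#' @param schedule A [unit_cost_schedule()].
#' @param value_set A `cea_value_set`.
#' @param spec A [markov_spec()].
#' @param n_iterations PSA iterations.
#' @param figures Also write KM, CE-plane and CEAC figures (PDF)?
#' @return Invisibly, the manifest as a tibble.
#' @export
run_pipeline <- function(out_dir, seed = 1, config = trial_config(),
                         schedule = unit_cost_schedule(),
                         value_set = uk_tto_value_set(),
                         spec = markov_spec(), n_iterations = 1000,
                         figures = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  outputs <- character()
  emit_csv <- function(x, f) {
    write.csv(x, path(f), row.names = FALSE)
    outputs <<- c(outputs, f)
  }
  emit_json <- function(x, f) {
    jsonlite::write_json(x, path(f), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    outputs <<- c(outputs, f)
  }

  trial <- generate_trial(config, seed = seed, value_set = value_set)
  emit_csv(trial, "trial.csv")

  costed <- cost_patients(trial, schedule)
  emit_csv(costed, "costs_per_patient.csv")
  hosp <- arm_cost_summary(costed, "cost_total_hospital")
  comm <- arm_cost_summary(costed, "cost_community")
  diff_h <- arm_difference(hosp[hosp$arm == "ERP", ],
                           hosp[hosp$arm == "STANDARD", ])
  emit_json(list(hospital = hosp, community = comm,
                 hospital_difference = diff_h), "cost_summary.json")

  scored <- patient_auc(trial, value_set)
  emit_csv(scored[, c("patient_id", "arm", "auc_28d")], "auc_per_patient.csv")
  auc_cmp <- arm_auc_comparison(scored)
  qaly <- annualized_qaly_gain(auc_cmp$median_auc_erp,
                               auc_cmp$median_auc_std)
  emit_json(list(comparison = auc_cmp, annualized = qaly), "qol_summary.json")

  surv <- purrr::map(c(1, 2, 5), function(h) {
    s <- survival_at(trial, h)
    tab <- cbind(alive = s$alive, dead = s$n - s$alive)
    bind_cols(horizon_years = h, s, compare_survival(tab))
  }) |> bind_rows()
  emit_csv(surv, "survival_summary.csv")
  km <- km_by_arm(trial)
  emit_csv(km, "km_curves.csv")

  res <- run_cea(spec)
  emit_json(list(arms = res$arms, incremental = res$incremental),
            "ce_base_case.json")
  emit_csv(bind_rows(ERP = res$traces$ERP, STANDARD = res$traces$STANDARD,
                     .id = "arm"), "markov_trace.csv")

  cloud <- run_psa(psa_config(spec, n_iterations = n_iterations,
                              seed = seed))
  emit_csv(cloud, "psa_cloud.csv")
  curve <- ceac(cloud)
  emit_csv(curve, "ceac.csv")
  emit_json(glance(cloud), "psa_summary.json")

  if (figures) {
    figs <- list(km = plot_km(km), ce_plane = plot_ce_plane(cloud),
                 ceac = plot_ceac(curve))
    for (nm in names(figs)) {
      f <- paste0("fig_", nm, ".pdf")
      ggplot2::ggsave(path(f), figs[[nm]], width = 6, height = 4)
      outputs <- c(outputs, f)
    }
  }

  manifest <- tibble(
    file = outputs,
    md5 = unname(tools::md5sum(file.path(out_dir, outputs)))
  )
  jsonlite::write_json(
    list(seed = seed, package_version = as.character(
      utils::packageVersion("erpcea")),
      n_iterations = n_iterations, outputs = manifest),
    path("manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Command-line entry point
#'
#' A thin argument parser over the package pipeline, also installed as
#' the `Rscript` front-end at `system.file("cli", "erpcea", package =
#' "erpcea")`. Subcommands: `simulate`, `cost`, `qol`, `survival`,
#' `model`, `psa`, `all`/`report`.
#'
#' @param args Character vector of arguments (default: the command line).
#' @return Exit status, invisibly (0 on success); raises a classed error
#'   on unknown subcommands or missing inputs.
#' @examples
#' \donttest{
#' td <- tempfile()
#' cea_cli(c("simulate", "--seed", "1", "--out", td))
#' }
#' @export
cea_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: erpcea <simulate|cost|qol|survival|model|psa|all|report>",
    "[--seed N] [--out DIR] [--in FILE] [--iterations N]",
    "[--horizon N] [--discount-rate X] [--unit-costs FILE]",
    "[--value-set FILE] [--wtp-max N] [--figures]")
  if (length(args) == 0) abort_config(paste0("missing subcommand\n", usage))
  cmd <- args[1]
  opts <- list(seed = 1, out = ".", `in` = NULL, iterations = 1000,
               horizon = 10, `discount-rate` = 0.03, `unit-costs` = NULL,
               `value-set` = NULL, `wtp-max` = 50000, figures = FALSE)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opts)) {
      abort_config(paste0("unknown option --", key, "\n", usage))
    }
    if (key == "figures") { opts$figures <- TRUE; i <- i + 1; next }
    if (i + 1 > length(args)) abort_config(paste0("--", key, " needs a value"))
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  seed <- as.integer(opts$seed)
  out <- opts$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  schedule <- if (!is.null(opts$`unit-costs`)) {
    read_unit_costs(opts$`unit-costs`)
  } else unit_cost_schedule()
  vs <- if (!is.null(opts$`value-set`)) read_value_set(opts$`value-set`)
    else uk_tto_value_set()
  need_in <- function() {
    f <- opts$`in`
    if (is.null(f)) abort_config("this subcommand needs --in <trial.csv>")
    if (!file.exists(f)) {
      rlang::abort(paste0("input file not found: ", f),
                   class = "erpcea_io_error")
    }
    trial <- read_trial_csv(f)
    required <- c("patient_id", "arm", "survival_years", "died")
    miss <- setdiff(required, names(trial))
    if (length(miss)) {
      rlang::abort(paste0("trial CSV is missing columns: ",
                          paste(miss, collapse = ", ")),
                   class = "erpcea_validation_error")
    }
    trial
  }
  spec <- markov_spec(horizon = as.integer(opts$horizon),
                      discount_rate_costs = as.numeric(opts$`discount-rate`),
                      discount_rate_effects = as.numeric(opts$`discount-rate`))
  switch(cmd,
    simulate = {
      trial <- generate_trial(trial_config(), seed = seed, value_set = vs)
      write_trial_csv(trial, file.path(out, "trial.csv"))
    },
    cost = {
      costed <- cost_patients(need_in(), schedule)
      write.csv(costed, file.path(out, "costs_per_patient.csv"),
                row.names = FALSE)
      jsonlite::write_json(
        list(hospital = arm_cost_summary(costed, "cost_total_hospital"),
             community = arm_cost_summary(costed, "cost_community")),
        file.path(out, "cost_summary.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    },
    qol = {
      scored <- patient_auc(need_in(), vs)
      cmp <- arm_auc_comparison(scored)
      jsonlite::write_json(
        list(comparison = cmp,
             annualized = annualized_qaly_gain(cmp$median_auc_erp,
                                               cmp$median_auc_std)),
        file.path(out, "qol_summary.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    },
    survival = {
      trial <- need_in()
      surv <- purrr::map(c(1, 2, 5), function(h) {
        s <- survival_at(trial, h)
        tab <- cbind(alive = s$alive, dead = s$n - s$alive)
        bind_cols(horizon_years = h, s, compare_survival(tab))
      }) |> bind_rows()
      write.csv(surv, file.path(out, "survival_summary.csv"),
                row.names = FALSE)
    },
    model = {
      res <- run_cea(spec)
      jsonlite::write_json(list(arms = res$arms,
                                incremental = res$incremental),
                           file.path(out, "ce_base_case.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    },
    psa = {
      cloud <- run_psa(psa_config(spec,
                                  n_iterations = as.integer(opts$iterations),
                                  seed = seed))
      write.csv(cloud, file.path(out, "psa_cloud.csv"), row.names = FALSE)
      write.csv(ceac(cloud, seq(0, as.numeric(opts$`wtp-max`), by = 1000)),
                file.path(out, "ceac.csv"), row.names = FALSE)
    },
    all = ,
    report = {
      run_pipeline(out, seed = seed, schedule = schedule, value_set = vs,
                   spec = spec, n_iterations = as.integer(opts$iterations),
                   figures = isTRUE(opts$figures))
    },
    abort_config(paste0("unknown subcommand '", cmd, "'\n", usage))
  )
  invisible(0L)
}

#' Render survival results in publication table style
#'
#' Formats per-arm survival as `"alive (percent)"` cells with the test
#' used at each horizon, the layout survival tables in surgical trials
#' usually print.
#'
#' @param surv Tibble from the pipeline's survival stage (columns
#'   `horizon_years`, `arm`, `alive`, `n`, `percent`, `test`, `p_value`).
#' @return Tibble, one row per horizon, one column per arm plus the test
#'   and p-value.
#' @export
render_survival_table <- function(surv) {
  if (nrow(surv) == 0 || any(surv$n == 0)) {
    abort_domain("survival table needs non-empty arms (n > 0)")
  }
  surv |>
    mutate(cell = sprintf("%d (%d)", .data$alive, .data$percent)) |>
    select("horizon_years", "arm", "cell", "test", "p_value") |>
    tidyr::pivot_wider(names_from = "arm", values_from = "cell") |>
    mutate(p_value = round(.data$p_value, 2))
}
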