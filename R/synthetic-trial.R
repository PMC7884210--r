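#' Configure a synthetic two-arm recovery-program trial
#'
#' Builds the parameter set for [generate_trial()]. Defaults emulate a
#' 91-patient randomized trial of an enhanced recovery program (ERP)
#' versus standard care for open liver resection: 46/45 patients per arm,
#' arm-shifted theatre times and lengths of stay (shorter in the ERP arm),
#' an ERP advantage in early post-operative EQ-5D, lower community
#' resource use after earlier discharge, and a 2-year survival advantage
#' that converges by 5 years. Lengths of stay are log-normal rounded to
#' half days; survival is drawn from a piecewise-constant hazard on the
#' intervals \[0,1), \[1,2), \[2,5) years whose default interval hazards
#' reproduce the trial's 1-, 2- and 5-year survival fractions in
#' expectation; EQ-5D states are observed at the trial's measurement days
#' 0 (pre-operative baseline), 2, 3, 5, 7, 10, 14 and 28.
#'
#' @param n_erp,n_std Patients per arm (each at least 2).
#' @param arms Named list with elements `ERP` and `STANDARD`, each a
#'   per-arm parameter list as produced by the defaults; override
#'   selectively via `modifyList()` semantics on each arm.
#' @return A `trial_config` list.
#' @examples
#' cfg <- trial_config()
#' cfg$arms$ERP$survival_fractions
#' @export
trial_config <- function(n_erp = 46, n_std = 45, arms = list()) {
  default_arm <- function(arm) {
    erp <- arm == "ERP"
    list(
      age_mean = if (erp) 64 else 67, age_sd = 11,
      p_male = if (erp) 31 / 46 else 23 / 45,
      # colorectal metastases / other metastases / benign
      p_diagnosis = if (erp) c(35, 10, 1) / 46 else c(26, 10, 9) / 45,
      anesthetic = list(meanlog = log(if (erp) 52 else 55),
                        sdlog = if (erp) 0.21 else 0.30),
      surgical = list(meanlog = log(if (erp) 189 else 207),
                      sdlog = if (erp) 0.27 else 0.39),
      icu = list(meanlog = log(if (erp) 1.5 else 2), sdlog = 0.5, shift = 0),
      hdu = list(meanlog = log(if (erp) 1.5 else 2.5), sdlog = 0.8,
                 shift = 0.5),
      ward = list(meanlog = log(if (erp) 2 else 3), sdlog = 0.35, shift = 0),
      p_readmission = 0.08, readmission_meanlog = log(4),
      supplement_mean = if (erp) 12 else 0,
      community_rates = c(
        gp_surgery_visits = if (erp) 15 / 46 else 38 / 45,
        gp_home_visits = if (erp) 0.01 else 1 / 45,
        practice_nurse_visits = if (erp) 33 / 46 else 48 / 45,
        nurse_home_visits = if (erp) 42 / 46 else 49 / 45,
        outpatient_visits = if (erp) 5 / 46 else 10 / 45,
        ed_attendances = if (erp) 2 / 46 else 0.005,
        friends_family_events = if (erp) 132 / 46 else 188 / 45
      ),
      eq5d = list(baseline_mean = 0.85, baseline_sd = 0.08,
                  dip = if (erp) 0.45 else 0.55,
                  tau = if (erp) 6 else 8, noise_sd = 0.05),
      survival_fractions = if (erp) c(45, 42, 24) / 46 else c(41, 33, 23) / 45,
      p_complication = if (erp) 0.20 else 0.40
    )
  }
  cfg <- list(
    n_per_arm = c(ERP = as.integer(n_erp), STANDARD = as.integer(n_std)),
    arms = list(
      ERP = utils::modifyList(default_arm("ERP"), arms$ERP %||% list()),
      STANDARD = utils::modifyList(default_arm("STANDARD"),
                                   arms$STANDARD %||% list())
    )
  )
  validate_trial_config(cfg)
  cfg
}

validate_trial_config <- function(cfg) {
  if (any(cfg$n_per_arm < 2)) abort_config("each arm needs at least 2 patients")
  for (arm in names(cfg$arms)) {
    p <- cfg$arms[[arm]]
    check_prob(c(p$p_male, p$p_diagnosis, p$p_readmission, p$p_complication),
               paste0(arm, " probabilities"))
    if (abs(sum(p$p_diagnosis) - 1) > 1e-8) {
      abort_config("diagnosis probabilities must sum to 1")
    }
    sc <- c(p$anesthetic$sdlog, p$surgical$sdlog, p$icu$sdlog, p$hdu$sdlog,
            p$ward$sdlog, p$eq5d$baseline_sd, p$eq5d$noise_sd, p$eq5d$tau)
    if (any(sc <= 0)) abort_config("scale parameters must be positive")
    s <- p$survival_fractions
    if (length(s) != 3 || any(s <= 0) || any(s > 1) || any(diff(s) > 0)) {
      abort_config(
        "survival_fractions must be non-increasing probabilities in (0, 1]")
    }
  }
  invisible(cfg)
}

#' EQ-5D measurement schedule used by the trial design
#'
#' Day 0 is the pre-operative baseline; the remaining days are
#' post-operative follow-up points.
#' @return Integer vector of measurement days.
#' @export
eq5d_days <- function() c(0L, 2L, 3L, 5L, 7L, 10L, 14L, 28L)

# representative EQ-5D-3L states spanning the utility range; synthetic
# trajectories snap a latent utility onto this ladder
eq5d_state_ladder <- function(vs) {
  states <- c("11111", "11211", "11112", "11121", "11221", "11122",
              "21122", "21222", "22222", "23222", "22223", "22322",
              "22332", "32333", "33333")
  u <- utility_index(states, vs)
  ord <- order(u, decreasing = TRUE)
  list(states = states[ord], utilities = u[ord])
}

# piecewise-constant-hazard survival draw on [0,1), [1,2), [2,5); values
# beyond 5 years are administratively alive at the 5-year horizon
draw_survival <- function(n, fractions) {
  s1 <- fractions[1]; s2 <- fractions[2]; s5 <- fractions[3]
  lam <- c(-log(s1), log(s1 / s2), log(s2 / s5) / 3)
  u <- runif(n)
  t <- numeric(n)
  i1 <- u > s1
  i2 <- !i1 & u > s2
  i3 <- !i1 & !i2 & u > s5
  t[i1] <- -log(u[i1]) / lam[1]
  t[i2] <- 1 + (log(s1) - log(u[i2])) / lam[2]
  t[i3] <- 2 + (log(s2) - log(u[i3])) / lam[3]
  alive <- u <= s5
  t[alive] <- 5
  tibble(survival_years = t, died = !alive)
}

#' Generate a synthetic patient-level trial dataset
#'
#' Draws one row per patient with arm assignment, demographics, theatre
#' minutes, lengths of stay by care level, readmission days, supplement
#' consumption, community resource-use counts, an EQ-5D-3L state at each
#' scheduled measurement day (wide columns `eq5d_d0` ... `eq5d_d28`), and
#' a 5-year survival outcome. Output is byte-identical for a fixed seed.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed controlling all randomness.
#' @param value_set Value set used to snap latent utilities onto EQ-5D
#'   states; defaults to [uk_tto_value_set()].
#' @return A tibble with one row per patient.
#' @examples
#' trial <- generate_trial(trial_config(), seed = 1)
#' dplyr::count(trial, arm)
#' @export
generate_trial <- function(config = trial_config(), seed = 1,
                           value_set = uk_tto_value_set()) {
  validate_trial_config(config)
  set.seed(as.integer(seed))
  ladder <- eq5d_state_ladder(value_set)
  days <- eq5d_days()
  arms <- purrr::map2(names(config$arms), config$n_per_arm[names(config$arms)],
    function(arm, n) {
      p <- config$arms[[arm]]
      los <- function(q) {
        round_half_day(pmax(0, rlnorm(n, q$meanlog, q$sdlog) - q$shift))
      }
      surv <- draw_survival(n, p$survival_fractions)
      comm <- purrr::map(p$community_rates, ~ rpois(n, .x))
      # latent utility: baseline, then exponential recovery from a
      # post-operative trough at day 2
      base <- pmin(1, rnorm(n, p$eq5d$baseline_mean, p$eq5d$baseline_sd))
      traj <- matrix("", nrow = n, ncol = length(days))
      for (j in seq_along(days)) {
        d <- days[j]
        target <- if (d == 0) base else
          base - p$eq5d$dip * exp(-(d - 2) / p$eq5d$tau)
        target <- target + rnorm(n, 0, p$eq5d$noise_sd)
        idx <- purrr::map_int(target,
                              ~ which.min(abs(ladder$utilities - .x)))
        traj[, j] <- ladder$states[idx]
      }
      colnames(traj) <- paste0("eq5d_d", days)
      readmit <- rbinom(n, 1, p$p_readmission) *
        round_half_day(rlnorm(n, p$readmission_meanlog, 0.5))
      tibble(
        patient_id = sprintf("%s-%03d", substr(arm, 1, 3), seq_len(n)),
        arm = arm,
        age = pmin(90, pmax(27, round(rnorm(n, p$age_mean, p$age_sd)))),
        sex = ifelse(runif(n) < p$p_male, "M", "F"),
        diagnosis = sample(c("colorectal_metastases", "other_metastases",
                             "benign"), n, replace = TRUE,
                           prob = p$p_diagnosis),
        anesthetic_minutes = round(rlnorm(n, p$anesthetic$meanlog,
                                          p$anesthetic$sdlog)),
        surgical_minutes = round(rlnorm(n, p$surgical$meanlog,
                                        p$surgical$sdlog)),
        icu_days = los(p$icu),
        hdu_days = los(p$hdu),
        ward_days = los(p$ward),
        readmission_days = readmit,
        supplement_bottles = rpois(n, p$supplement_mean),
        complication = runif(n) < p$p_complication
      ) |>
        bind_cols(as_tibble(comm), as_tibble(traj), surv)
    })
  bind_rows(arms)
}

#' Write / read a trial dataset as CSV
#'
#' Plain one-row-per-patient CSV with EQ-5D states as 5-digit character
#' codes; `read_trial_csv()` restores column types.
#'
#' @param trial A tibble from [generate_trial()] (or same schema).
#' @param path Output / input file path.
#' @return `write_trial_csv()` returns `path` invisibly;
#'   `read_trial_csv()` returns a tibble.
#' @export
write_trial_csv <- function(trial, path) {
  write.csv(trial, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- read.csv(path, colClasses = "character")
  num <- setdiff(names(df), c("patient_id", "arm", "sex", "diagnosis",
                              grep("^eq5d_d", names(df), value = TRUE),
                              "died", "complication"))
  df[num] <- lapply(df[num], as.numeric)
  for (cl in intersect(c("died", "complication"), names(df))) {
    df[[cl]] <- df[[cl]] == "TRUE"
  }
  as_tibble(df)
}
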