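#' Synthetic UK-style period life table
#'
#' A smooth Gompertz approximation to recent UK national period mortality
#' (annual death probability `qx` rising log-linearly with age, sex
#' specific). It is a synthetic stand-in for the national interim life
#' tables, which are an external resource; replace it with
#' [read_life_table()] for a real table when one is available. Accuracy
#' near the typical hepatobiliary-surgery cohort ages (55-85) is within
#' the range of recent UK tables.
#'
#' @param ages Integer vector of ages to tabulate.
#' @return Tibble with `age`, `sex` (`"M"`/`"F"`), `qx`.
#' @examples
#' lt <- uk_life_table()
#' lt[lt$age == 65, ]
#' @export
uk_life_table <- function(ages = 25:105) {
  grid <- expand.grid(age = ages, sex = c("M", "F"),
                      stringsAsFactors = FALSE)
  a <- ifelse(grid$sex == "M", -10.1, -10.7)
  b <- ifelse(grid$sex == "M", 0.093, 0.097)
  as_tibble(grid) |>
    mutate(qx = pmin(1, exp(a + b * .data$age))) |>
    arrange(.data$sex, .data$age)
}

#' Read a life table from a 3-column CSV
#'
#' Expects columns `age`, `sex` (`M`/`F`) and `qx` (annual death
#' probability).
#' @param path CSV file path.
#' @return Tibble with `age`, `sex`, `qx`.
#' @export
read_life_table <- function(path) {
  lt <- as_tibble(read.csv(path))
  if (!all(c("age", "sex", "qx") %in% names(lt))) {
    abort_config("life table CSV needs columns age, sex, qx")
  }
  check_prob(lt$qx, "qx")
  lt
}

#' Background mortality adjusted for high-risk surgical survivors
#'
#' Looks up the annual death probability for an age/sex and multiplies it
#' by a relative risk reflecting the excess long-term mortality of
#' survivors of major high-risk surgery, capped at 1.
#'
#' @param age Age in whole years (vectorised).
#' @param sex `"M"` or `"F"` (recycled).
#' @param life_table Tibble from [uk_life_table()] or [read_life_table()].
#' @param relative_risk Mortality multiplier (default 1).
#' @return Adjusted annual death probabilities.
#' @examples
#' adjusted_mortality(70, "M", relative_risk = 2)
#' @export
adjusted_mortality <- function(age, sex, life_table = uk_life_table(),
                               relative_risk = 1) {
  check_nonneg(relative_risk, "relative_risk")
  key <- paste(floor(age), rep_len(sex, length(age)))
  idx <- match(key, paste(life_table$age, life_table$sex))
  if (any(is.na(idx))) {
    abort_domain("age/sex combination outside the life table's coverage")
  }
  pmin(1, life_table$qx[idx] * relative_risk)
}

# sex-mixed cohort mortality at a given attained age
cohort_mortality <- function(age, p_male, life_table, relative_risk) {
  p_male * adjusted_mortality(age, "M", life_table, relative_risk) +
    (1 - p_male) * adjusted_mortality(age, "F", life_table, relative_risk)
}
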