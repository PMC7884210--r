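#' EQ-5D-3L value sets and utility scoring
#'
#' An EQ-5D-3L health state is a 5-digit code, one digit per dimension
#' (mobility, self-care, usual activities, pain/discomfort,
#' anxiety/depression), each at level 1 (no problems), 2 (some) or 3
#' (extreme). A value set maps states to a utility index anchored at 1 for
#' full health (11111) and 0 for dead, with negative values possible for
#' states worse than dead. The additive-decrement form used here has a
#' constant term applied once for any departure from full health,
#' per-dimension decrements for levels 2 and 3, and an extra "N3" term
#' applied once if any dimension is at level 3.
#'
#' `uk_tto_value_set()` returns the UK time-trade-off tariff in this form
#' (the standard national tariff used for NHS economic evaluation); its
#' minimum, for state 33333, is -0.594.
#'
#' @return A `cea_value_set`: a list with elements `name`, `constant`,
#'   `n3`, and `decrements` (a 5 x 2 matrix, rows = dimensions, columns =
#'   levels 2 and 3).
#' @examples
#' vs <- uk_tto_value_set()
#' utility_index("11111", vs)
#' utility_index("33333", vs)
#' @export
uk_tto_value_set <- function() {
  dec <- matrix(
    c(0.069, 0.314,
      0.104, 0.214,
      0.036, 0.094,
      0.123, 0.386,
      0.071, 0.236),
    nrow = 5, byrow = TRUE,
    dimnames = list(
      c("mobility", "self_care", "usual_activities", "pain", "anxiety"),
      c("level2", "level3")
    )
  )
  value_set(name = "UK TTO (EQ-5D-3L)", constant = 0.081, n3 = 0.269,
            decrements = dec)
}

#' Construct an additive-decrement EQ-5D-3L value set
#'
#' @param name Label for the tariff.
#' @param constant Decrement applied once for any state other than 11111.
#' @param n3 Extra decrement applied once if any dimension is at level 3.
#' @param decrements 5 x 2 numeric matrix of per-dimension decrements for
#'   levels 2 and 3 (rows in EQ-5D dimension order).
#' @return A `cea_value_set` object.
#' @export
value_set <- function(name, constant, n3, decrements) {
  decrements <- as.matrix(decrements)
  if (!identical(dim(decrements), c(5L, 2L))) {
    abort_config("`decrements` must be a 5 x 2 matrix")
  }
  check_nonneg(c(constant, n3, decrements), "value set decrements")
  structure(
    list(name = name, constant = constant, n3 = n3, decrements = decrements,
         min_utility = 1 - constant - n3 - sum(decrements[, 2])),
    class = "cea_value_set"
  )
}

#' Read a value set from a YAML or JSON file
#'
#' The file must contain `name`, `constant`, `n3` and a 5 x 2 `decrements`
#' table (list of two 5-vectors `level2`, `level3`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cea_value_set` object.
#' @export
read_value_set <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- cbind(level2 = as.numeric(x$decrements$level2),
               level3 = as.numeric(x$decrements$level3))
  rownames(dec) <- c("mobility", "self_care", "usual_activities", "pain",
                     "anxiety")
  value_set(x$name %||% basename(path), x$constant, x$n3, dec)
}

#' Score EQ-5D-3L states against a value set
#'
#' @param state Character vector of 5-digit state codes, digits in 1-3
#'   (e.g. `"11221"`).
#' @param vs A `cea_value_set`, e.g. [uk_tto_value_set()].
#' @return Numeric vector of utility indices; 1 for full health.
#' @examples
#' utility_index(c("11111", "21111", "33333"), uk_tto_value_set())
#' @export
utility_index <- function(state, vs = uk_tto_value_set()) {
  stopifnot(inherits(vs, "cea_value_set"))
  state <- as.character(state)
  if (any(is.na(state)) || any(!grepl("^[123]{5}$", state))) {
    abort_domain("EQ-5D states must be 5-digit codes with digits in {1,2,3}")
  }
  lv <- matrix(as.integer(unlist(strsplit(state, ""))), ncol = 5, byrow = TRUE)
  u <- rep(1, length(state))
  any_dys <- rowSums(lv > 1) > 0
  u[any_dys] <- u[any_dys] - vs$constant
  for (d in 1:5) {
    u <- u - ifelse(lv[, d] == 2, vs$decrements[d, 1],
                    ifelse(lv[, d] == 3, vs$decrements[d, 2], 0))
  }
  u - ifelse(rowSums(lv == 3) > 0, vs$n3, 0)
}
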