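# Typed containers, validation and CSV I/O for the three required inputs
# (cross-sectional population data, seroresponse parameter draws, noise
# parameters) and for estimate output tables.
#
# Column-name dialects: dotted and underscored forms (y.low / y_low) are both
# accepted, and header matching is case-insensitive; antigen_iso *values* are
# case-sensitive exact-match keys. The canonical internal time unit is days
# for the kinetics (t1, alpha, time since infection) and years for age.

# normalize a header name for dialect matching
.norm_name <- function(x) tolower(gsub(".", "_", x, fixed = TRUE))

# locate required columns by normalized name, honouring a user column_map
.match_columns <- function(df, required, column_map = NULL, what = "input") {
  nm <- names(df)
  column_map <- as.list(column_map)
  out <- character(0)
  for (col in names(required)) {
    candidates <- required[[col]]
    if (col %in% names(column_map)) {
      if (!column_map[[col]] %in% nm)
        stop("mapped column '", column_map[[col]], "' not found in ", what)
      out[col] <- column_map[[col]]
      next
    }
    hit <- nm[.norm_name(nm) %in% candidates]
    if (length(hit) == 0L)
      stop("required column '", col, "' not found")
    out[col] <- hit[1L]
  }
  out
}

.read_csv_checked <- function(source) {
  df <- utils::read.csv(source, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no data rows in '", source, "'")
  df
}

.check_numeric <- function(x, col) {
  if (is.character(x)) x <- suppressWarnings(as.numeric(x))
  bad <- which(!is.finite(x))
  if (length(bad))
    stop("non-numeric or missing ", col, " at row ", bad[1L])
  x
}

#' Construct a cross-sectional population dataset
#'
#' Validates a long-format cross-sectional antibody survey: one row per
#' subject and antigen-isotype, with the subject's age in years and the
#' quantitative antibody measurement. Any additional columns are retained and
#' usable as stratification covariates.
#'
#' @param df A data frame with columns `id`, `age`, `antigen_iso`, `value`
#'   (default names; override with `column_map`).
#' @param column_map Optional named character vector/list mapping the
#'   canonical names to the columns of `df`, for example
#'   `c(value = "result")`.
#' @return A `pop_data` tibble with canonical column names first and strata
#'   columns after; attribute `strata` lists the extra columns.
#' @details Ages must be positive, values non-negative, and each
#'   `(id, antigen_iso)` pair unique -- duplicates are an error rather than
#'   silently averaged.
#' @export
as_pop_data <- function(df, column_map = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  cols <- .match_columns(df, list(
    id = "id", age = "age", antigen_iso = "antigen_iso", value = "value"
  ), column_map, "population data")
  out <- data.frame(
    id = as.character(df[[cols["id"]]]),
    age = .check_numeric(df[[cols["age"]]], "age"),
    antigen_iso = as.character(df[[cols["antigen_iso"]]]),
    value = .check_numeric(df[[cols["value"]]], "value"),
    stringsAsFactors = FALSE
  )
  if (any(out$age <= 0))
    stop("age must be > 0 (row ", which(out$age <= 0)[1L], ")")
  if (any(out$value < 0))
    stop("value must be >= 0 (row ", which(out$value < 0)[1L], ")")
  key <- paste(out$id, out$antigen_iso, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(out$id[duplicated(key)])
    stop("duplicated (id, antigen_iso) pairs for id(s): ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  strata_cols <- setdiff(names(df), cols)
  for (sc in strata_cols) out[[sc]] <- df[[sc]]
  out <- tibble::as_tibble(out)
  attr(out, "strata") <- strata_cols
  class(out) <- c("pop_data", class(out))
  out
}

#' Read cross-sectional population data from a CSV file
#'
#' @param source Path to (or connection for) a CSV file with a header row.
#' @inheritParams as_pop_data
#' @return A validated `pop_data` tibble; see [as_pop_data()].
#' @export
read_pop_data <- function(source, column_map = NULL) {
  as_pop_data(.read_csv_checked(source), column_map = column_map)
}

#' Write population data back to CSV
#'
#' Canonical and strata columns are written so that
#' `read_pop_data(write_pop_data(x, f))` reproduces the records exactly.
#'
#' @param pop A `pop_data` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pop_data <- function(pop, path) {
  utils::write.csv(as.data.frame(pop), path, row.names = FALSE)
  invisible(path)
}

#' Construct a seroresponse parameter ensemble
#'
#' Validates posterior draws of the two-phase antibody kinetics parameters,
#' grouped by antigen-isotype: baseline `y0`, peak `y1`, time to peak `t1`
#' (days), decay rate `alpha` (concentration^(1-r)/day) and decay shape `r`.
#' Typically these are samples from the joint predictive posterior of a
#' hierarchical within-host model fitted to longitudinal data on confirmed
#' cases; that upstream fit is outside the scope of this package and the
#' draws are taken as given. Extra columns (for example a country or age
#' stratum label) are retained and matched against population strata during
#' stratified estimation.
#'
#' For R users with draws stored as RDS: export once with
#' `write.csv(readRDS("fit.rds"), "sr_params.csv", row.names = FALSE)`.
#'
#' @param df Data frame with columns `antigen_iso, y0, y1, t1, alpha, r`
#'   (dotted dialects such as `y.0` accepted).
#' @param time_unit Unit of `t1` and `alpha` in `df`: `"day"` (default) or
#'   `"year"`. Year-scale inputs are converted so that the stored unit is
#'   always days (`t1 * 365.25`, `alpha / 365.25`).
#' @return An `sr_params` tibble (internal unit: days).
#' @export
as_sr_params <- function(df, time_unit = c("day", "year")) {
  time_unit <- match.arg(time_unit)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  cols <- .match_columns(df, list(
    antigen_iso = "antigen_iso",
    y0 = c("y0", "y_0"), y1 = c("y1", "y_1"), t1 = c("t1", "t_1"),
    alpha = "alpha", r = "r"
  ), NULL, "seroresponse parameters")
  out <- data.frame(
    antigen_iso = as.character(df[[cols["antigen_iso"]]]),
    y0 = .check_numeric(df[[cols["y0"]]], "y0"),
    y1 = .check_numeric(df[[cols["y1"]]], "y1"),
    t1 = .check_numeric(df[[cols["t1"]]], "t1"),
    alpha = .check_numeric(df[[cols["alpha"]]], "alpha"),
    r = .check_numeric(df[[cols["r"]]], "r"),
    stringsAsFactors = FALSE
  )
  if (time_unit == "year") {
    out$t1 <- out$t1 * 365.25
    out$alpha <- out$alpha / 365.25
  }
  if (any(out$r < 1))
    stop("r must be ≥ 1 (draw ", which(out$r < 1)[1L], ")")
  if (any(out$y0 <= 0))
    stop("y0 must be > 0 (draw ", which(out$y0 <= 0)[1L], ")")
  if (any(out$y1 <= out$y0))
    stop("y1 must be > y0 (draw ", which(out$y1 <= out$y0)[1L], ")")
  if (any(out$t1 <= 0))
    stop("t1 must be > 0 (draw ", which(out$t1 <= 0)[1L], ")")
  if (any(out$alpha <= 0))
    stop("alpha must be > 0 (draw ", which(out$alpha <= 0)[1L], ")")
  extra <- setdiff(names(df), cols)
  for (sc in extra) out[[sc]] <- df[[sc]]
  out <- tibble::as_tibble(out)
  attr(out, "strata") <- extra
  class(out) <- c("sr_params", class(out))
  out
}

#' Read seroresponse parameter draws from a CSV file
#'
#' @inheritParams read_pop_data
#' @inheritParams as_sr_params
#' @return An `sr_params` tibble; see [as_sr_params()].
#' @export
read_sr_params <- function(source, time_unit = c("day", "year")) {
  as_sr_params(.read_csv_checked(source), time_unit = time_unit)
}

#' Construct noise parameters
#'
#' One row per antigen-isotype: the biologic noise level `nu` (the antibody
#' signal scale in never-exposed individuals, from non-specific binding and
#' cross-reactivity; concentration units), the measurement noise `eps`
#' (assay replicate coefficient of variation, dimensionless), and the lower
#' and upper limits of reliable quantification `y_low`, `y_high`
#' (concentration units). Observations at or outside the limits are treated
#' as censored during estimation.
#'
#' @param df Data frame with columns `antigen_iso, nu, eps, y.low, y.high`
#'   (or `y_low`/`y_high`).
#' @return A `noise_params` tibble.
#' @export
as_noise_params <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  cols <- .match_columns(df, list(
    antigen_iso = "antigen_iso", nu = "nu", eps = "eps",
    y_low = "y_low", y_high = "y_high"
  ), NULL, "noise parameters")
  out <- data.frame(
    antigen_iso = as.character(df[[cols["antigen_iso"]]]),
    nu = .check_numeric(df[[cols["nu"]]], "nu"),
    eps = .check_numeric(df[[cols["eps"]]], "eps"),
    y_low = .check_numeric(df[[cols["y_low"]]], "y_low"),
    y_high = .check_numeric(df[[cols["y_high"]]], "y_high"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$antigen_iso))
    stop("duplicate noise-parameter rows for antigen_iso: ",
         out$antigen_iso[duplicated(out$antigen_iso)][1L])
  if (any(out$nu <= 0)) stop("nu must be > 0")
  if (any(out$eps < 0)) stop("eps must be >= 0")
  if (any(out$y_low < 0)) stop("y_low must be >= 0")
  if (any(out$y_low >= out$y_high))
    stop("y_low must be < y_high (antigen_iso ",
         out$antigen_iso[which(out$y_low >= out$y_high)[1L]], ")")
  out <- tibble::as_tibble(out)
  class(out) <- c("noise_params", class(out))
  out
}

#' Read noise parameters from a CSV file
#'
#' @inheritParams read_pop_data
#' @return A `noise_params` tibble; see [as_noise_params()].
#' @export
read_noise_params <- function(source) {
  as_noise_params(.read_csv_checked(source))
}

#' Cross-check the three inputs for a set of antigen-isotypes
#'
#' Verifies that every requested antigen-isotype is present in the population
#' data, the seroresponse ensemble and the noise parameters, and counts
#' population values outside the quantification limits (these are not an
#' error: they will be treated as censored during estimation).
#'
#' @param pop A `pop_data` object.
#' @param sr_params An `sr_params` object.
#' @param noise_params A `noise_params` object.
#' @param antigen_isos Character vector of requested antigen-isotypes
#'   (default: all antigen-isotypes present in `pop`).
#' @return A `serosurvey_validation` object: a tibble with one row per
#'   requested antigen-isotype (presence flags, observation and censoring
#'   counts). Errors if any requested antigen-isotype is missing from any
#'   input, naming the input.
#' @export
validate_inputs <- function(pop, sr_params, noise_params,
                            antigen_isos = unique(pop$antigen_iso)) {
  miss_msg <- c(
    pop = "cross-sectional population data",
    sr = "seroresponse parameters",
    noise = "noise parameters"
  )
  rows <- lapply(antigen_isos, function(ai) {
    in_pop <- ai %in% pop$antigen_iso
    in_sr <- ai %in% sr_params$antigen_iso
    in_noise <- ai %in% noise_params$antigen_iso
    if (!in_pop) stop("'", ai, "' missing from ", miss_msg["pop"])
    if (!in_sr) stop("'", ai, "' missing from ", miss_msg["sr"])
    if (!in_noise) stop("'", ai, "' missing from ", miss_msg["noise"])
    np <- noise_params[noise_params$antigen_iso == ai, ]
    v <- pop$value[pop$antigen_iso == ai]
    tibble::tibble(
      antigen_iso = ai, in_pop = in_pop, in_sr = in_sr, in_noise = in_noise,
      n_obs = length(v), n_draws = sum(sr_params$antigen_iso == ai),
      n_censored_low = sum(v <= np$y_low),
      n_censored_high = sum(v >= np$y_high)
    )
  })
  out <- do.call(rbind, rows)
  n_cens <- sum(out$n_censored_low) + sum(out$n_censored_high)
  if (n_cens > 0)
    warning(n_cens, " observation(s) at or outside the quantification limits",
            " will be treated as censored", call. = FALSE)
  class(out) <- c("serosurvey_validation", class(out))
  out
}

#' @export
print.serosurvey_validation <- function(x, ...) {
  cat("Serosurvey input validation: all requested antigen-isotypes present\n")
  print(tibble::as_tibble(unclass(x)))
  invisible(x)
}

#' Write a table of seroincidence estimates to CSV
#'
#' Numbers are serialized with 6 significant digits.
#'
#' @param x A data frame, typically from [summary.seroincidence()] or
#'   [summary.seroincidence_by()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(x, path) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], signif, digits = 6L)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
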