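# Reading, validating, filtering and encoding crash-level records.
#
# A "crash table" is a data.frame with one row per vehicle involved in a
# fatal multivehicle crash, carrying the vehicle's decoded warning-system
# availability codes (FCWS and BSM), the crash location and year, and the
# driver / road / crash covariates of the model.  Missing values are NA.

#' Read a crash-level CSV into a validated crash table
#'
#' Reads a flat, pre-joined CSV of vehicle-in-fatal-crash records.  Cells
#' that are blank, `NA`, or (for categorical fields) not one of the declared
#' level tokens are set to missing (`NA`); they are counted and removed later
#' by [apply_filters()].  Row order and row count are preserved.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector mapping canonical field
#'   names (see [required_fields()]) to the file's column names.  Defaults to
#'   the identity map.
#' @return A `data.frame` of class `crash_table` with canonical columns.
#'   Categorical columns are character vectors of level tokens;
#'   `unknown` cell values are coerced to `NA` with a count recorded in
#'   `attr(x, "n_unparseable")`.
#' @export
read_crash_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("crash table file does not exist: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("crash table is empty (no data rows): ", path)
  fields <- required_fields()
  if (is.null(schema)) schema <- stats::setNames(fields, fields)
  missing_map <- setdiff(fields, names(schema))
  if (length(missing_map))
    schema[missing_map] <- missing_map
  absent <- setdiff(unname(schema[fields]), names(raw))
  if (length(absent))
    stop("crash table is missing mandatory column(s): ",
         paste(absent, collapse = ", "))
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in fields) out[[f]] <- raw[[schema[[f]]]]
  as_crash_table(out)
}

#' Coerce a data.frame to a validated crash table
#'
#' Applies the canonical typing rules: numeric fields are parsed with
#' unparseable cells set to `NA`; categorical cells outside their declared
#' level set become `NA`; binary flags accept 0/1 and a few common aliases.
#' Coordinate and year range violations raise errors, matching the record
#' invariants (year 2016-2020 is checked later by [code_temporal()]).
#'
#' @param df A data.frame containing the columns of [required_fields()].
#' @return The typed `crash_table` with an `n_unparseable` attribute.
#' @export
as_crash_table <- function(df) {
  vars <- crash_variables()
  n_unparseable <- 0L
  blank_to_na <- function(x) {
    x <- trimws(as.character(x))
    x[x %in% c("", "NA", "na", "Missing", "missing", "Unknown", "unknown",
               "Not Reported", "NotReported")] <- NA_character_
    x
  }
  for (f in setdiff(required_fields(), "crash_id")) {
    v <- vars[[f]]
    x <- blank_to_na(df[[f]])
    if (is.null(v) || v$type == "numeric") {
      was_na <- is.na(x)
      num <- suppressWarnings(as.numeric(x))
      n_unparseable <- n_unparseable + sum(is.na(num) & !was_na)
      df[[f]] <- num
    } else if (v$type == "binary") {
      x[x %in% c("1", "Yes", "yes", "TRUE", "true")] <- "1"
      x[x %in% c("0", "No", "no", "FALSE", "false")] <- "0"
      bad <- !is.na(x) & !x %in% c("0", "1")
      n_unparseable <- n_unparseable + sum(bad)
      x[bad] <- NA_character_
      df[[f]] <- x
    } else {
      # accept either the token or the display label
      lab_to_tok <- stats::setNames(names(v$labels), unname(v$labels))
      hit <- !is.na(x) & !(x %in% v$levels) & (x %in% names(lab_to_tok))
      x[hit] <- lab_to_tok[x[hit]]
      bad <- !is.na(x) & !(x %in% v$levels)
      n_unparseable <- n_unparseable + sum(bad)
      x[bad] <- NA_character_
      df[[f]] <- x
    }
  }
  df$crash_id <- as.character(df$crash_id)
  ok_lat <- is.na(df$latitude) | (df$latitude >= -90 & df$latitude <= 90)
  ok_lon <- is.na(df$longitude) | (df$longitude >= -180 & df$longitude <= 180)
  if (!all(ok_lat)) stop("latitude out of [-90, 90] in row(s): ",
                         paste(utils::head(which(!ok_lat)), collapse = ", "))
  if (!all(ok_lon)) stop("longitude out of [-180, 180] in row(s): ",
                         paste(utils::head(which(!ok_lon)), collapse = ", "))
  if (any(!is.na(df$n_vehicles) & df$n_vehicles < 1))
    stop("n_vehicles must be >= 1")
  attr(df, "n_unparseable") <- n_unparseable
  class(df) <- c("crash_table", "data.frame")
  df
}

#' Derive the ordinal warning-system count from availability codes
#'
#' Maps the decoded (FCWS, BSM) availability pair to the ordinal outcome:
#' 2 when both are factory-standard, 1 when exactly one is standard and the
#' other not available, 0 when neither is available.  A vehicle with an
#' "Optional" code (presence unknowable from the VIN) or a missing code is
#' excluded, returned as `NA`.
#'
#' @param fcws_code,bsm_code Character vectors with values `"Standard"`,
#'   `"Optional"`, `"NotAvailable"` or `NA`.  A `crash_table` may be given as
#'   the first argument instead.
#' @return Integer vector in `{0, 1, 2}` with `NA` for excluded vehicles.
#' @export
derive_dws_count <- function(fcws_code, bsm_code = NULL) {
  if (is.data.frame(fcws_code)) {
    bsm_code <- fcws_code$bsm_code
    fcws_code <- fcws_code$fcws_code
  }
  stopifnot(length(fcws_code) == length(bsm_code))
  std <- (fcws_code == "Standard") + (bsm_code == "Standard")
  na_ <- (fcws_code == "NotAvailable") + (bsm_code == "NotAvailable")
  out <- rep(NA_integer_, length(fcws_code))
  known <- !is.na(fcws_code) & !is.na(bsm_code) &
    fcws_code != "Optional" & bsm_code != "Optional"
  out[known & std == 2L] <- 2L
  out[known & std == 1L & na_ == 1L] <- 1L
  out[known & na_ == 2L] <- 0L
  out
}

#' Filter a crash table to the modelling sample
#'
#' Applies the sample-definition rules, in order of precedence per row:
#' single-vehicle crashes are removed (`n_vehicles < 2`); vehicles whose
#' FCWS or BSM code is "Optional" are removed (warning-system presence is
#' unknowable); rows with any missing model field are removed (listwise
#' deletion).  When more than `missing_warn` of the input rows carry a
#' missing value, a warning is emitted: listwise deletion is only defensible
#' for a small missing fraction.
#'
#' @param records A `crash_table`.
#' @param missing_warn Missing-fraction warning threshold (default 0.02).
#' @return A list with `records` (the retained rows, plus an integer
#'   `dws_count` outcome column) and `report`, a `filter_report` with fields
#'   `n_input`, `removed_single_vehicle`, `removed_optional_dws`,
#'   `removed_missing`, `removed_unknown`, `n_retained`, `missing_fraction`.
#' @export
apply_filters <- function(records, missing_warn = 0.02) {
  if (nrow(records) == 0L) stop("empty crash table")
  model_fields <- setdiff(required_fields(), "crash_id")
  n <- nrow(records)
  any_missing <- Reduce(`|`, lapply(model_fields, function(f) is.na(records[[f]])))
  optional <- (!is.na(records$fcws_code) & records$fcws_code == "Optional") |
    (!is.na(records$bsm_code) & records$bsm_code == "Optional")
  single <- !is.na(records$n_vehicles) & records$n_vehicles < 2

  # precedence: single vehicle, then optional code, then missing field
  removed_single <- single
  removed_optional <- optional & !removed_single
  removed_missing <- any_missing & !removed_single & !removed_optional
  keep <- !(removed_single | removed_optional | removed_missing)

  missing_fraction <- mean(any_missing)
  if (missing_fraction > missing_warn)
    warning(sprintf(
      "%.1f%% of rows have missing values (> %.0f%%); listwise deletion may bias estimates",
      100 * missing_fraction, 100 * missing_warn))
  if (!any(keep)) stop("all rows removed by filtering; empty analysis sample")

  out <- records[keep, , drop = FALSE]
  out$dws_count <- derive_dws_count(out$fcws_code, out$bsm_code)
  stopifnot(!anyNA(out$dws_count))
  report <- structure(list(
    n_input = n,
    removed_single_vehicle = sum(removed_single),
    removed_optional_dws = sum(removed_optional),
    removed_missing = sum(removed_missing),
    removed_unknown = attr(records, "n_unparseable") %||% 0L,
    n_retained = sum(keep),
    missing_fraction = missing_fraction), class = "filter_report")
  list(records = out, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.filter_report <- function(x, ...) {
  cat("Crash-table filter report\n")
  cat(sprintf("  input rows:              %d\n", x$n_input))
  cat(sprintf("  removed single-vehicle:  %d\n", x$removed_single_vehicle))
  cat(sprintf("  removed 'Optional' DWS:  %d\n", x$removed_optional_dws))
  cat(sprintf("  removed missing fields:  %d\n", x$removed_missing))
  cat(sprintf("  retained:                %d\n", x$n_retained))
  cat(sprintf("  missing fraction:        %.4f\n", x$missing_fraction))
  invisible(x)
}

#' Code the linear temporal trend
#'
#' Adds `year_index`, the linear time-elapsed code used to absorb temporal
#' heterogeneity: 1 for 2016 through 5 for 2020.
#'
#' @param records A `crash_table` (or any data.frame with a `year` column).
#' @return The input with a `year_index` column appended.
#' @export
code_temporal <- function(records) {
  y <- records$year
  if (any(is.na(y)) || any(y < 2016 | y > 2020))
    stop("year outside the study period 2016-2020")
  records$year_index <- as.numeric(y) - 2015
  records
}

# (variable.level) -> design column name for every non-reference level
design_dummy_map <- function() {
  list(
    area_type.Urban = "urban", gender.Female = "female",
    age_band.AgeLt24 = "age_lt24", age_band.Age40to65 = "age_40_65",
    age_band.AgeGt65 = "age_gt65",
    season.Winter = "season_Winter", season.Spring = "season_Spring",
    season.Fall = "season_Fall",
    time_of_day.T12am3am = "tod_12am_3am", time_of_day.T3am6am = "tod_3am_6am",
    time_of_day.T9am12pm = "tod_9am_12pm", time_of_day.T12pm3pm = "tod_12pm_3pm",
    time_of_day.T3pm6pm = "tod_3pm_6pm", time_of_day.T6pm9pm = "tod_6pm_9pm",
    time_of_day.T9pm12am = "tod_9pm_12am",
    manner_of_collision.HeadOn = "manner_HeadOn",
    manner_of_collision.RearEnd = "manner_RearEnd",
    manner_of_collision.SideswipeOpposite = "manner_SideswipeOpposite",
    manner_of_collision.SideswipeSame = "manner_SideswipeSame",
    n_lanes.NoTrafficwayAccess = "lanes_NoAccess",
    n_lanes.OneLane = "lanes_One", n_lanes.ThreeLanes = "lanes_Three",
    n_lanes.FourLanes = "lanes_Four", n_lanes.FiveLanes = "lanes_Five",
    n_lanes.SixLanes = "lanes_Six", n_lanes.SevenPlus = "lanes_SevenPlus",
    surface_condition.Wet = "surface_Wet",
    surface_condition.IceSnowEtc = "surface_IceSnow",
    pre_crash_stability.SkidLateral = "stability_SkidLateral",
    pre_crash_stability.SkidLongitudinal = "stability_SkidLongitudinal",
    pre_crash_stability.NotSpecific = "stability_NotSpecific",
    functional_class.Interstate = "funclass_Interstate",
    functional_class.FreewayExpressway = "funclass_Freeway",
    functional_class.MinorArterial = "funclass_MinorArterial",
    functional_class.MajorCollector = "funclass_MajorCollector",
    functional_class.MinorCollector = "funclass_MinorCollector",
    functional_class.Local = "funclass_Local",
    light_condition.Dark = "light_Dark", light_condition.Dawn = "light_Dawn",
    light_condition.Dusk = "light_Dusk",
    weather.Cloudy = "weather_Cloudy", weather.Rain = "weather_Rain",
    weather.SnowFogEtc = "weather_SnowFog")
}

#' Encode the model design matrix
#'
#' Dummy-codes the filtered crash table against the reference levels of
#' [crash_variables()], adds an intercept (`constant`) and the numeric
#' `year_index` column, derives driver age bands from `driver_age`, and tags
#' each column with a fixed or random role.
#'
#' @param records Filtered records from [apply_filters()], passed through
#'   [code_temporal()]; must carry `dws_count`.
#' @param random_columns Design columns whose coefficients are random
#'   (default [default_random_columns()]).
#' @return A `design_matrix` list: `X` (numeric matrix), `y` (integer
#'   outcome 0/1/2), `role` (named `"fixed"`/`"random"` per column),
#'   `reference_levels`, `n_rows`, `n_cols`.
#' @export
encode_design <- function(records, random_columns = default_random_columns()) {
  if (is.null(records$year_index)) records <- code_temporal(records)
  vars <- crash_variables()
  n <- nrow(records)
  records$age_band <- age_to_band(records$driver_age)
  cols <- list(constant = rep(1, n), year_index = records$year_index)

  dummy_name <- function(var, lev) design_dummy_map()[[paste(var, lev, sep = ".")]]

  reference_levels <- list()
  for (v in model_covariates()) {
    def <- vars[[v]]
    x <- records[[v]]
    if (anyNA(x)) stop("missing values in '", v, "'; run apply_filters() first")
    if (def$type == "binary") {
      cols[[v]] <- as.numeric(x == "1")
      reference_levels[[v]] <- "0"
    } else {
      reference_levels[[v]] <- def$reference
      for (lev in setdiff(def$levels, def$reference))
        cols[[dummy_name(v, lev)]] <- as.numeric(x == lev)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  y <- as.integer(records$dws_count)
  if (!all(y %in% 0:2)) stop("outcome must be in {0, 1, 2}")
  missing_rand <- setdiff(random_columns, colnames(X))
  if (length(missing_rand))
    stop("random-role column(s) absent from design: ",
         paste(missing_rand, collapse = ", "))
  const <- apply(X, 2, function(col) length(unique(col)) == 1L)
  const["constant"] <- FALSE
  if (any(const))
    warning("constant design column(s): ", paste(names(which(const)), collapse = ", "))
  role <- stats::setNames(rep("fixed", ncol(X)), colnames(X))
  role[random_columns] <- "random"
  structure(list(X = X, y = y, role = role,
                 reference_levels = reference_levels,
                 n_rows = nrow(X), n_cols = ncol(X)),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d rows, %d columns (%d random-role)\n",
              x$n_rows, x$n_cols, sum(x$role == "random")))
  cat("outcome shares:",
      paste(sprintf("%d: %.3f", 0:2, tabulate(x$y + 1L, 3) / x$n_rows),
            collapse = ", "), "\n")
  invisible(x)
}

# Percentage rounded to three decimals, the descriptive-table convention.
pct3 <- function(count, total) round(100 * count / total, 3)

#' Descriptive frequency table
#'
#' Tabulates the analysis sample by every model variable, including the
#' derived warning-system count, reporting the count and the percentage of
#' the sample (rounded to three decimals) per category.
#'
#' @param records Filtered records carrying `dws_count`.
#' @return A data.frame with columns `variable`, `category`, `count`,
#'   `percent`.  Within each variable the percentages sum to 100 (up to
#'   rounding of 0.01).
#' @export
descriptive_table <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop("empty input")
  vars <- crash_variables()
  n <- nrow(records)
  records$age_band <- age_to_band(records$driver_age)
  rows <- list()
  add <- function(variable, labels, counts) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, category = labels, count = as.integer(counts),
      percent = pct3(counts, n), stringsAsFactors = FALSE)
  }
  dws_labels <- c("No FCWS or BSM", "Either FCWS or BSM", "Both FCWS and BSM")
  if (!is.null(records$dws_count))
    add("DWSs", dws_labels, tabulate(records$dws_count + 1L, 3))
  for (v in model_covariates()) {
    def <- vars[[v]]
    x <- records[[v]]
    levs <- def$levels
    counts <- vapply(levs, function(l) sum(x == l, na.rm = TRUE), integer(1))
    add(v, unname(def$labels[levs]), counts)
  }
  do.call(rbind, rows)
}
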