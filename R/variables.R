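# Variable dictionary shared by the reader, encoder, descriptive table and
# synthetic generator.  Level tokens are the package's canonical serialized
# strings; `label` carries the human-readable category name used in
# descriptive output.

#' Canonical crash-record variable dictionary
#'
#' Returns the dictionary of crash-level variables understood by the package:
#' categorical variables with their full level sets and model reference
#' levels, binary flags, and numeric fields.  Reference levels are the
#' omitted categories of the default model specification (summer, the
#' 6 a.m.-9 a.m. band, angle collisions, two lanes, dry surface, tracking
#' vehicles, principal arterials, daylight, clear weather, male drivers,
#' drivers aged 24-40 and rural areas).
#'
#' @return A named list; each element describes one variable with fields
#'   `type` (`"categorical"`, `"binary"` or `"numeric"`), `levels`,
#'   `reference`, and `labels` (display names per level).
#' @export
crash_variables <- function() {
  cat_var <- function(levels, reference, labels = levels) {
    list(type = "categorical", levels = levels, reference = reference,
         labels = stats::setNames(labels, levels))
  }
  bin_var <- function(label1, label0) {
    list(type = "binary", levels = c("1", "0"), reference = "0",
         labels = stats::setNames(c(label1, label0), c("1", "0")))
  }
  list(
    gender = cat_var(c("Female", "Male"), reference = "Male"),
    drink_drive = bin_var("Drink and drive related", "Not related to drink and drive"),
    speeding = bin_var("Speeding", "Not speeding"),
    intersection = bin_var("Intersection", "Non-intersection"),
    work_zone = bin_var("Work zone", "No work zone"),
    area_type = cat_var(c("Urban", "Rural"), reference = "Rural"),
    functional_class = cat_var(
      c("Interstate", "FreewayExpressway", "PrincipalArterial", "MinorArterial",
        "MajorCollector", "MinorCollector", "Local"),
      reference = "PrincipalArterial",
      labels = c("Interstate", "Freeway or expressway", "Principal arterial",
                 "Minor arterial", "Major collector", "Minor collector", "Local")),
    n_lanes = cat_var(
      c("NoTrafficwayAccess", "OneLane", "TwoLanes", "ThreeLanes", "FourLanes",
        "FiveLanes", "SixLanes", "SevenPlus"),
      reference = "TwoLanes",
      labels = c("No trafficway access", "One lane", "Two lanes", "Three lanes",
                 "Four lanes", "Five lanes", "Six lanes", "Seven or more lanes")),
    light_condition = cat_var(c("Daylight", "Dark", "Dawn", "Dusk"),
                              reference = "Daylight"),
    surface_condition = cat_var(
      c("Dry", "Wet", "IceSnowEtc"), reference = "Dry",
      labels = c("Dry", "Wet", "Ice, snow, mud, dirt, oil, or water")),
    pre_crash_stability = cat_var(
      c("Tracking", "SkidLateral", "SkidLongitudinal", "NotSpecific"),
      reference = "Tracking",
      labels = c("Tracking", "Skidding laterally", "Skidding longitudinally",
                 "Not specific")),
    season = cat_var(c("Winter", "Spring", "Summer", "Fall"), reference = "Summer"),
    time_of_day = cat_var(
      c("T12am3am", "T3am6am", "T6am9am", "T9am12pm", "T12pm3pm", "T3pm6pm",
        "T6pm9pm", "T9pm12am"),
      reference = "T6am9am",
      labels = c("12 a.m.-3 a.m.", "3 a.m.-6 a.m.", "6 a.m.-9 a.m.",
                 "9 a.m.-12 p.m.", "12 p.m.-3 p.m.", "3 p.m.-6 p.m.",
                 "6 p.m.-9 p.m.", "9 p.m.-12 a.m.")),
    weather = cat_var(
      c("Clear", "Cloudy", "Rain", "SnowFogEtc"), reference = "Clear",
      labels = c("Clear", "Cloudy", "Rain",
                 "Snow, fog/smoke/smog, or other adverse condition")),
    manner_of_collision = cat_var(
      c("HeadOn", "RearEnd", "Angle", "SideswipeOpposite", "SideswipeSame"),
      reference = "Angle",
      labels = c("Head-on", "Rear-end", "Angle", "Sideswipe - opposite direction",
                 "Sideswipe - same direction")),
    age_band = cat_var(
      c("AgeLt24", "Age24to40", "Age40to65", "AgeGt65"), reference = "Age24to40",
      labels = c("Less than 24 years", "24 to 40 years", "40 to 65 years",
                 "Greater than 65 years")),
    driver_age = list(type = "numeric"),
    year = list(type = "numeric"),
    latitude = list(type = "numeric"),
    longitude = list(type = "numeric"),
    n_vehicles = list(type = "numeric"),
    fcws_code = cat_var(c("Standard", "Optional", "NotAvailable"),
                        reference = "NotAvailable",
                        labels = c("Standard", "Optional", "Not Available")),
    bsm_code = cat_var(c("Standard", "Optional", "NotAvailable"),
                       reference = "NotAvailable",
                       labels = c("Standard", "Optional", "Not Available"))
  )
}

# Categorical / binary covariates that enter the model (and the descriptive
# table), in reporting order.
model_covariates <- function() {
  c("age_band", "drink_drive", "gender", "area_type", "functional_class",
    "intersection", "n_lanes", "work_zone", "light_condition",
    "pre_crash_stability", "surface_condition", "season", "speeding",
    "time_of_day", "weather", "manner_of_collision")
}

# Raw fields that must be present (directly or derivably) on a crash record.
required_fields <- function() {
  c("crash_id", "year", "latitude", "longitude", "fcws_code", "bsm_code",
    "n_vehicles", "driver_age", "gender", "drink_drive", "speeding",
    "intersection", "work_zone", "area_type", "functional_class", "n_lanes",
    "light_condition", "surface_condition", "pre_crash_stability", "season",
    "time_of_day", "weather", "manner_of_collision")
}

#' Default driver-behaviour columns given random coefficients
#'
#' The five design columns whose coefficients are treated as correlated
#' random parameters by default: drink-and-drive involvement, female driver,
#' and the three non-reference driver age bands.
#'
#' @return Character vector of design-matrix column names.
#' @export
default_random_columns <- function() {
  c("drink_drive", "female", "age_lt24", "age_40_65", "age_gt65")
}

# Age in years -> age band token.  Bands: <24; [24,40]; (40,65]; >65.
age_to_band <- function(age) {
  ifelse(is.na(age), NA_character_,
  ifelse(age < 24, "AgeLt24",
  ifelse(age <= 40, "Age24to40",
  ifelse(age <= 65, "Age40to65", "AgeGt65"))))
}

# Representative uniform age ranges per band, used by the generator.
age_band_ranges <- function() {
  list(AgeLt24 = c(16, 23.99), Age24to40 = c(24, 40),
       Age40to65 = c(40.01, 65), AgeGt65 = c(65.01, 90))
}
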