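# Shared fixtures: a hand-built valid crash table and small scenario helpers.

valid_crash_row <- function() {
  list(crash_id = "C000001", year = 2018, latitude = 35.2, longitude = -80.8,
       fcws_code = "Standard", bsm_code = "NotAvailable", n_vehicles = 2,
       driver_age = 30, gender = "Male", drink_drive = "0", speeding = "0",
       intersection = "0", work_zone = "0", area_type = "Urban",
       functional_class = "PrincipalArterial", n_lanes = "TwoLanes",
       light_condition = "Daylight", surface_condition = "Dry",
       pre_crash_stability = "Tracking", season = "Summer",
       time_of_day = "T6am9am", weather = "Clear",
       manner_of_collision = "Angle")
}

# n copies of the valid row with per-column overrides (vectors recycled)
make_crash_df <- function(n = 4, ...) {
  row <- valid_crash_row()
  df <- as.data.frame(lapply(row, rep, length.out = n),
                      stringsAsFactors = FALSE)
  df$crash_id <- sprintf("C%06d", seq_len(n))
  df$latitude <- df$latitude + seq_len(n) * 0.01
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- rep(over[[nm]], length.out = n)
  df
}

make_crash_table <- function(n = 4, ...) as_crash_table(make_crash_df(n, ...))

write_crash_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# random-ish mixed crash table with injected contamination, deterministic
random_crash_df <- function(n = 50, seed = 11) {
  set.seed(seed)
  vars <- crash_variables()
  df <- make_crash_df(n)
  df$year <- sample(2016:2020, n, TRUE)
  df$n_vehicles <- sample(1:3, n, TRUE, prob = c(0.2, 0.6, 0.2))
  codes <- c("Standard", "Optional", "NotAvailable")
  df$fcws_code <- sample(codes, n, TRUE)
  df$bsm_code <- sample(codes, n, TRUE)
  df$driver_age <- sample(16:90, n, TRUE)
  for (v in c("gender", "area_type", "functional_class", "n_lanes",
              "light_condition", "surface_condition", "pre_crash_stability",
              "season", "time_of_day", "weather", "manner_of_collision"))
    df[[v]] <- sample(vars[[v]]$levels, n, TRUE)
  for (v in c("drink_drive", "speeding", "intersection", "work_zone"))
    df[[v]] <- sample(c("0", "1"), n, TRUE)
  # inject a few missing covariates
  df$gender[seq_len(min(3, n))] <- NA
  df
}

# small design matrix from the compact scenario, cached per session
compact_design <- local({
  cache <- new.env()
  function(n = 1500, seed = 21) {
    key <- paste0("d", n, "_", seed)
    if (is.null(cache[[key]])) {
      tab <- generate_crash_table(scenario_compact(n = n, seed = seed))
      flt <- apply_filters(tab)
      cache[[key]] <- encode_design(code_temporal(flt$records))
    }
    cache[[key]]
  }
})

# wrap a bare matrix/outcome as a design_matrix
make_design <- function(X, y, random_columns = character(0)) {
  role <- stats::setNames(rep("fixed", ncol(X)), colnames(X))
  role[random_columns] <- "random"
  structure(list(X = X, y = as.integer(y), role = role,
                 reference_levels = list(), n_rows = nrow(X),
                 n_cols = ncol(X)), class = "design_matrix")
}

# simulate a plain fixed-parameter ordered-logit dataset
sim_fixed_design <- function(n, beta, psi1, seed = 1) {
  set.seed(seed)
  X <- cbind(constant = 1,
             x1 = rnorm(n),
             x2 = as.numeric(runif(n) < 0.4))
  eta <- drop(X %*% beta)
  ystar <- eta + rlogis(n)
  y <- ifelse(ystar <= 0, 0L, ifelse(ystar <= psi1, 1L, 2L))
  make_design(X, y)
}

# brute-force all-pairs neighbour oracle (shared by spatial and acceptance tests)
knn_oracle <- function(cases, pool, k) {
  pool <- pool[order(pool$crash_id), ]
  do.call(rbind, lapply(seq_len(nrow(cases)), function(i) {
    d <- haversine_ft(cases$latitude[i], cases$longitude[i],
                      pool$latitude, pool$longitude)
    sel <- order(d)[seq_len(k)]
    data.frame(case_id = cases$crash_id[i], rank = seq_len(k),
               control_id = pool$crash_id[sel], distance_ft = d[sel])
  }))
}

rand_points <- function(n, seed, prefix = "P") {
  set.seed(seed)
  data.frame(crash_id = sprintf("%s%03d", prefix, seq_len(n)),
             latitude = runif(n, 25, 48), longitude = runif(n, -120, -70),
             stringsAsFactors = FALSE)
}
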