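test_that("a clean CSV round-trips with no missing fields", {
  df <- make_crash_df(3)
  path <- write_crash_csv(df)
  rec <- read_crash_table(path)
  expect_s3_class(rec, "crash_table")
  expect_equal(nrow(rec), 3)
  model_fields <- setdiff(names(df), "crash_id")
  expect_false(any(vapply(rec[model_fields], anyNA, logical(1))))
  expect_equal(rec$year, rep(2018, 3))
})

test_that("a missing mandatory column raises a schema error naming it", {
  df <- make_crash_df(3)
  df$latitude <- NULL
  path <- write_crash_csv(df)
  expect_error(read_crash_table(path), "latitude")
})

test_that("an empty file raises a distinct error", {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(make_crash_df(1)[0, ], path, row.names = FALSE)
  expect_error(read_crash_table(path), "empty")
})

test_that("a blank cell becomes missing while other fields stay intact", {
  df <- make_crash_df(3)
  df$gender[2] <- ""
  rec <- read_crash_table(write_crash_csv(df))
  expect_identical(rec$gender, c("Male", NA, "Male"))
  expect_identical(rec$season, rep("Summer", 3))
  # invalid tokens are also coerced to missing and counted
  df$weather[1] <- "Hail?"
  rec2 <- read_crash_table(write_crash_csv(df))
  expect_true(is.na(rec2$weather[1]))
  expect_gte(attr(rec2, "n_unparseable"), 1L)
})

test_that("warning-system count follows the decision table on all 16 code pairs", {
  codes <- c("Standard", "Optional", "NotAvailable", NA)
  grid <- expand.grid(fcws = codes, bsm = codes, stringsAsFactors = FALSE)
  # independent enumeration of the rule: 2 = both standard; 1 = one standard,
  # other absent; 0 = both absent; excluded (NA) if optional or missing
  expected <- mapply(function(f, b) {
    if (is.na(f) || is.na(b) || f == "Optional" || b == "Optional")
      return(NA_integer_)
    if (f == "Standard" && b == "Standard") return(2L)
    if (f == "NotAvailable" && b == "NotAvailable") return(0L)
    1L
  }, grid$fcws, grid$bsm)
  expect_identical(derive_dws_count(grid$fcws, grid$bsm), unname(expected))
})

test_that("filtering removes single-vehicle crashes and tallies rules", {
  tab <- make_crash_table(10, n_vehicles = c(1, 1, rep(2, 8)))
  res <- apply_filters(tab)
  expect_equal(res$report$removed_single_vehicle, 2)
  expect_equal(res$report$n_retained, 8)
  expect_equal(nrow(res$records), 8)
})

test_that("a missing fraction above 2% raises a warning", {
  df <- make_crash_df(100)
  df$gender[1:3] <- NA
  tab <- as_crash_table(df)
  expect_warning(apply_filters(tab), "missing")
  # at exactly 2% no warning
  df2 <- make_crash_df(100)
  df2$gender[1:2] <- NA
  expect_silent(apply_filters(as_crash_table(df2)))
})

test_that("filter report matches a brute-force per-rule recount", {
  tab <- as_crash_table(random_crash_df(50))
  res <- suppressWarnings(apply_filters(tab))
  # oracle: independent row-wise classification with the same precedence
  single <- opt <- miss <- 0L
  kept <- 0L
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    fields <- setdiff(names(tab), "crash_id")
    if (!is.na(r$n_vehicles) && r$n_vehicles < 2) single <- single + 1L
    else if ((!is.na(r$fcws_code) && r$fcws_code == "Optional") ||
             (!is.na(r$bsm_code) && r$bsm_code == "Optional")) opt <- opt + 1L
    else if (any(is.na(r[fields]))) miss <- miss + 1L
    else kept <- kept + 1L
  }
  expect_equal(res$report$removed_single_vehicle, single)
  expect_equal(res$report$removed_optional_dws, opt)
  expect_equal(res$report$removed_missing, miss)
  expect_equal(res$report$n_retained, kept)
})

test_that("filtering is idempotent", {
  tab <- as_crash_table(random_crash_df(60, seed = 5))
  res1 <- suppressWarnings(apply_filters(tab))
  res2 <- apply_filters(res1$records)
  expect_equal(res2$report$n_retained, res1$report$n_retained)
  expect_equal(res2$report$removed_single_vehicle +
                 res2$report$removed_optional_dws +
                 res2$report$removed_missing, 0)
})

test_that("temporal coding maps study years to 1..5 and rejects others", {
  tab <- make_crash_table(5, year = 2016:2020)
  expect_equal(code_temporal(tab)$year_index, 1:5)
  expect_error(code_temporal(make_crash_table(1, year = 2015)), "2016-2020")
  expect_error(code_temporal(make_crash_table(1, year = 2021)), "2016-2020")
})

test_that("design encoding honours reference levels and roles", {
  tab <- make_crash_table(3, gender = c("Male", "Female", "Female"),
                          driver_age = c(30, 70, 22),
                          season = "Summer")
  tab$dws_count <- c(0L, 1L, 2L)
  d <- suppressWarnings(encode_design(code_temporal(tab)))
  # Summer is the reference: all season dummies zero
  expect_true(all(d$X[, c("season_Winter", "season_Spring", "season_Fall")] == 0))
  # Female, age > 65: female and age_gt65 dummies set, other ages zero
  expect_equal(unname(d$X[2, c("female", "age_gt65", "age_lt24", "age_40_65")]),
               c(1, 1, 0, 0))
  expect_equal(unname(d$X[3, c("female", "age_lt24")]), c(1, 1))
  expect_equal(unname(d$role[default_random_columns()]),
               rep("random", 5))
  expect_equal(d$n_rows, 3)
})

test_that("design column sums equal brute-force category tallies", {
  tab <- as_crash_table(random_crash_df(80, seed = 9))
  flt <- suppressWarnings(apply_filters(tab))
  rec <- code_temporal(flt$records)
  d <- suppressWarnings(encode_design(rec))
  expect_equal(unname(colSums(d$X)["season_Winter"]),
               sum(rec$season == "Winter"))
  expect_equal(unname(colSums(d$X)["female"]), sum(rec$gender == "Female"))
  expect_equal(unname(colSums(d$X)["lanes_Four"]),
               sum(rec$n_lanes == "FourLanes"))
  expect_equal(unname(colSums(d$X)["age_gt65"]), sum(rec$driver_age > 65))
  # per-row dummies of one categorical sum to 0 or 1
  season_cols <- c("season_Winter", "season_Spring", "season_Fall")
  expect_true(all(rowSums(d$X[, season_cols]) %in% c(0, 1)))
  expect_error(encode_design(rec, random_columns = "nonexistent"), "absent")
})

test_that("descriptive percentages are exact and sum to 100 per variable", {
  tab <- as_crash_table(random_crash_df(70, seed = 13))
  flt <- suppressWarnings(apply_filters(tab))
  dt <- descriptive_table(flt$records)
  n <- nrow(flt$records)
  # oracle recount per category
  expect_equal(dt$count[dt$variable == "gender" & dt$category == "Female"],
               sum(flt$records$gender == "Female"))
  expect_equal(dt$percent, round(100 * dt$count / n, 3))
  sums <- tapply(dt$percent, dt$variable, sum)
  expect_true(all(abs(sums - 100) <= 0.01))
  expect_error(descriptive_table(flt$records[0, ]), "empty")
})
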