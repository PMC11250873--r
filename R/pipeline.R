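# End-to-end orchestration: describe, match, simulate, fit, effects,
# recover.  Each stage writes CSV artifacts with a provenance header
# (package version, data hash, stage parameters; no timestamps, so repeated
# runs are byte-identical).

pkg_version <- function() as.character(utils::packageVersion("crpolr"))

# md5 of a data.frame's serialized CSV text, for provenance headers
data_hash <- function(df) {
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  utils::write.csv(df, tf, row.names = FALSE)
  unname(tools::md5sum(tf))
}

write_output_csv <- function(df, path, provenance) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# crpolr %s | %s", pkg_version(), provenance), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a stage output CSV (skipping the provenance header)
#' @param path File written by a `run_*` stage.
#' @return data.frame.
#' @export
read_output_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

resolve_input <- function(input) {
  if (is.character(input)) input <- read_crash_table(input)
  if (inherits(input, "scenario_config")) input <- generate_crash_table(input)
  if (!is.data.frame(input)) stop("input must be a path, crash_table or scenario_config")
  input
}

#' Stage: descriptive statistics
#'
#' Filters the input and writes the frequency/percentage table.
#'
#' @param input Path to a crash CSV, a `crash_table`, or a
#'   `scenario_config` (simulated on the fly).
#' @param out_dir Output directory.
#' @return Invisibly, a list with `table`, `report` and the output path.
#' @export
run_describe <- function(input, out_dir = ".") {
  records <- resolve_input(input)
  flt <- apply_filters(records)
  tab <- descriptive_table(flt$records)
  path <- file.path(out_dir, "descriptive_table.csv")
  write_output_csv(tab, path,
                   sprintf("stage=describe data=%s n=%d",
                           data_hash(flt$records), nrow(flt$records)))
  message(sprintf("describe: %d rows retained of %d; table -> %s",
                  flt$report$n_retained, flt$report$n_input, path))
  invisible(list(table = tab, report = flt$report, path = path))
}

#' Stage: spatial control matching
#'
#' Splits the filtered sample into cases (outcome >= 1) and the control
#' pool (outcome 0), matches `k` nearest controls per case, and writes the
#' match list plus the k-profile of the maximum k-th neighbour distance.
#'
#' @inheritParams run_describe
#' @param k Neighbours per case (default 3).
#' @param k_max Largest k profiled.
#' @return Invisibly: `matches`, `profile`, `sample` (matched analysis
#'   table), paths.
#' @export
run_match <- function(input, out_dir = ".", k = 3, k_max = 10) {
  records <- resolve_input(input)
  flt <- apply_filters(records)
  rec <- flt$records
  cases <- rec[rec$dws_count >= 1L, , drop = FALSE]
  pool <- rec[rec$dws_count == 0L, , drop = FALSE]
  matches <- knn_controls(cases, pool, k = k)
  profile <- knn_profile(cases, pool, k_max = min(k_max, nrow(pool)))
  sample_ <- build_matched_sample(cases, pool, matches)
  prov <- sprintf("stage=match k=%d data=%s", k, data_hash(rec))
  p1 <- write_output_csv(matches, file.path(out_dir, "matches.csv"), prov)
  p2 <- write_output_csv(profile, file.path(out_dir, "knn_profile.csv"), prov)
  message(sprintf("match: %d cases, %d pool, max %d-th distance %.0f ft",
                  nrow(cases), nrow(pool), k, max_kth_distance(matches, k)))
  invisible(list(matches = matches, profile = profile, sample = sample_,
                 paths = c(p1, p2)))
}

#' Stage: simulate a synthetic crash table
#'
#' @param config A `scenario_config`.
#' @param out_dir Output directory.
#' @return Invisibly: the table and its path.
#' @export
run_simulate <- function(config, out_dir = ".") {
  tab <- generate_crash_table(config)
  path <- file.path(out_dir, "crash_table.csv")
  write_output_csv(as.data.frame(tab), path,
                   sprintf("stage=simulate n=%d seed=%d", config$n, config$seed))
  invisible(list(table = tab, path = path))
}

# Table-2-style layout: constant and fixed coefficients, means of random
# parameters, Cholesky diagonal, below-diagonal elements, threshold
crp_coef_layout <- function(fit) {
  tab <- coef_table(fit)
  nm <- tab$variable
  block <- ifelse(nm == "psi1", "Threshold",
           ifelse(grepl("^chol_.*\\..*$", nm), "Cholesky below-diagonal",
           ifelse(grepl("^chol_", nm), "Cholesky diagonal",
           ifelse(grepl("^mean_", nm), "Random parameter mean", "Fixed"))))
  cbind(block = block, tab)
}

#' Stage: model fitting and comparison
#'
#' Encodes the filtered input, fits the fixed-parameter model and (when
#' requested) the correlated random parameters model, and writes coefficient
#' tables, the marginal-effects table of the preferred model, and the fit
#' comparison.
#'
#' @inheritParams run_describe
#' @param model `"both"`, `"fixed"` or `"crp"`.
#' @param D Halton draws for the correlated model (default 900).
#' @param random_columns Random-role design columns.
#' @param discard,primes Draw configuration.
#' @param effects Also compute the marginal-effects table (default TRUE).
#' @return Invisibly: `fixed`, `crp`, `comparison`, `effects`, paths.
#' @export
run_fit <- function(input, out_dir = ".", model = c("both", "fixed", "crp"),
                    D = 900, random_columns = default_random_columns(),
                    discard = 10, primes = NULL, effects = TRUE) {
  model <- match.arg(model)
  records <- resolve_input(input)
  flt <- apply_filters(records)
  design <- encode_design(code_temporal(flt$records), random_columns)
  prov_base <- sprintf("data=%s n=%d", data_hash(flt$records), design$n_rows)
  paths <- character(0)
  fit_f <- fit_fixed(design)
  if (!fit_f$converged)
    stop("fixed-parameter model did not converge (gradient norm ",
         format(fit_f$grad_norm), ")")
  paths <- c(paths, write_output_csv(
    coef_table(fit_f), file.path(out_dir, "coefficients_fixed.csv"),
    sprintf("stage=fit model=fixed %s", prov_base)))
  fit_c <- NULL
  comparison <- NULL
  eff <- NULL
  if (model %in% c("both", "crp")) {
    fit_c <- fit_crp(design, crp_spec(random_columns, D = D,
                                      discard = discard, primes = primes),
                     fixed = fit_f)
    prov_c <- sprintf("stage=fit model=crp D=%d primes=%s discard=%d %s",
                      D, paste(fit_c$primes, collapse = ","), discard, prov_base)
    paths <- c(paths, write_output_csv(
      crp_coef_layout(fit_c), file.path(out_dir, "coefficients_crp.csv"), prov_c))
    comparison <- likelihood_ratio_test(fit_f, fit_c)
    paths <- c(paths, write_output_csv(
      as.data.frame(unclass(comparison)), file.path(out_dir, "comparison.csv"),
      prov_c))
  }
  if (effects) {
    pref <- if (is.null(fit_c)) fit_f else fit_c
    eff <- marginal_effects(pref, design)
    paths <- c(paths, write_output_csv(
      as.data.frame(eff), file.path(out_dir, "partial_effects.csv"),
      sprintf("stage=effects model=%s %s",
              if (is.null(fit_c)) "fixed" else "crp", prov_base)))
  }
  message(sprintf("fit: logLik fixed %.3f%s", fit_f$loglik,
                  if (!is.null(fit_c)) sprintf(", correlated %.3f", fit_c$loglik)
                  else ""))
  invisible(list(fixed = fit_f, crp = fit_c, comparison = comparison,
                 effects = eff, design = design, paths = paths))
}

#' Stage: parameter-recovery experiment
#'
#' @param config A `scenario_config` with a nonzero Cholesky factor.
#' @param out_dir Output directory.
#' @param replicates,D_fit Passed to [parameter_recovery_experiment()].
#' @return Invisibly: the `recovery_report` and paths.
#' @export
run_recover <- function(config, out_dir = ".", replicates = 20, D_fit = 200) {
  rep_ <- parameter_recovery_experiment(config, replicates = replicates,
                                        D_fit = D_fit)
  prov <- sprintf("stage=recover n=%d replicates=%d D=%d seed=%d",
                  config$n, replicates, D_fit, config$seed)
  p1 <- write_output_csv(rep_$estimates, file.path(out_dir, "recovery_estimates.csv"), prov)
  p2 <- write_output_csv(rep_$summary, file.path(out_dir, "recovery_summary.csv"), prov)
  invisible(list(report = rep_, paths = c(p1, p2)))
}
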