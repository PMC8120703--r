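# End-to-end report writers behind the command-line interface
# (inst/cli/aaa-cea). Each writes plain delimited text plus a manifest
# sufficient to re-run it.

resolve_inputs <- function(config = NULL, life_table_path = NULL) {
  params <- if (is.null(config)) aaa_parameters() else read_parameters(config)
  lt <- if (is.null(life_table_path)) iran_male_life_table()
        else read_life_table(life_table_path)
  list(params = params, life_table = lt,
       config_label = if (is.null(config)) "<bundled default>" else config,
       lt_label = if (is.null(life_table_path)) "<bundled synthetic Iranian male>"
                  else life_table_path)
}

write_manifest <- function(out_dir, command, inputs, seed = NA) {
  manifest <- list(
    command = command,
    config = inputs$config_label,
    life_table = inputs$lt_label,
    seed = seed,
    package_version = as.character(utils::packageVersion("aaascreen")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run and export the base-case analysis
#'
#' Writes the two-strategy results table (`results.csv`), the per-strategy
#' cohort traces, and a run manifest.
#'
#' @param config path to a YAML parameter configuration (`NULL` = bundled
#'   default reproducing the published inputs).
#' @param life_table path to a life-table file (`NULL` = bundled synthetic
#'   Iranian-male table).
#' @param out_dir output directory (created if missing).
#' @param discount optional discount-rate override.
#' @param ppp also report monetary columns in PPP dollars.
#' @return the `aaa_cea` fit, invisibly.
#' @export
report_base_case <- function(config = NULL, life_table = NULL, out_dir = ".",
                             discount = NULL, ppp = FALSE) {
  inputs <- resolve_inputs(config, life_table)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- aaa_cea(inputs$params, inputs$life_table, discount_rate = discount)
  export_results(fit, file.path(out_dir, "results.csv"), ppp = ppp)
  export_trace(fit$traces$no_screening, file.path(out_dir, "trace_no_screening.csv"))
  export_trace(fit$traces$screening, file.path(out_dir, "trace_screening.csv"))
  write_manifest(out_dir, "base-case", inputs)
  invisible(fit)
}

#' Run and export the one-way sensitivity analysis
#'
#' Writes the tornado-ordered one-way results (`tornado.csv`) and a
#' manifest.
#'
#' @inheritParams report_base_case
#' @param params optional character vector restricting which parameters are
#'   varied.
#' @return the `aaa_dsa` table, invisibly.
#' @export
report_dsa <- function(config = NULL, life_table = NULL, out_dir = ".",
                       params = NULL) {
  inputs <- resolve_inputs(config, life_table)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dsa <- run_dsa(inputs$params, inputs$life_table, param_names = params)
  export_tornado(dsa, file.path(out_dir, "tornado.csv"))
  write_manifest(out_dir, "dsa", inputs)
  invisible(dsa)
}

#' Run and export the probabilistic sensitivity analysis
#'
#' Writes the PSA samples (`psa_samples.csv`), the acceptability curve
#' (`ceac.csv`) and a manifest.
#'
#' @inheritParams report_base_case
#' @param n number of PSA draws.
#' @param seed integer seed (required).
#' @param thresholds willingness-to-pay grid for the CEAC.
#' @return the `aaa_psa` object, invisibly.
#' @export
report_psa <- function(config = NULL, life_table = NULL, out_dir = ".",
                       n = 1000, seed, thresholds = seq(0, 20000, by = 500)) {
  inputs <- resolve_inputs(config, life_table)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  psa <- run_psa(inputs$params, inputs$life_table, n = n, seed = seed)
  utils::write.csv(psa$samples, file.path(out_dir, "psa_samples.csv"),
                   row.names = FALSE)
  export_ceac(ceac(psa, thresholds), file.path(out_dir, "ceac.csv"))
  write_manifest(out_dir, "psa", inputs, seed = seed)
  invisible(psa)
}

#' Write the bundled fixtures to a directory
#'
#' Writes (a) the default parameter configuration reproducing the published
#' inputs, (b) a synthetic Gompertz-Makeham life table for ages 65-100 with
#' the generator's default parameters, and (c) the synthetic Iranian-male
#' life table used in the worked analyses.
#'
#' @param out_dir output directory (created if missing).
#' @return character vector of the files written, invisibly.
#' @export
write_fixtures <- function(out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    params = file.path(out_dir, "aaa_params.yaml"),
    gompertz = file.path(out_dir, "life_table_gompertz_synthetic.csv"),
    iran = file.path(out_dir, "life_table_iran_male_synthetic.csv")
  )
  write_parameters(aaa_parameters(), files[["params"]])
  lt <- synth_life_table()
  utils::write.csv(data.frame(age = lt$age, qx = signif(lt$qx, 10)),
                   files[["gompertz"]], row.names = FALSE)
  file.copy(system.file("extdata", "life_table_iran_male_synthetic.csv",
                        package = "aaascreen", mustWork = TRUE),
            files[["iran"]], overwrite = TRUE)
  invisible(files)
}
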