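#' Run configuration
#'
#' Gathers every tunable of a pipeline run so that the resolved
#' configuration can be echoed to `config.json` in the output directory
#' and a run is reproducible from its outputs alone.
#'
#' @param small_threshold Small-granule diameter threshold, um.
#' @param conf Confidence level for comparisons, in (0, 1).
#' @param aggregate Aggregate grains to plants (`TRUE`, default).
#' @param seed Master seed for anything stochastic.
#' @param fit A [fit_options()] list.
#' @export
run_config <- function(small_threshold = 10, conf = 0.95, aggregate = TRUE,
                       seed = 1L, fit = fit_options()) {
  if (!is.finite(conf) || conf <= 0 || conf >= 1)
    gf_invalid("conf must be in (0, 1)")
  if (!is.finite(small_threshold) || small_threshold <= 0)
    gf_invalid("small_threshold must be > 0")
  list(small_threshold = small_threshold, conf = conf,
       aggregate = aggregate, seed = as.integer(seed), fit = fit)
}

echo_config <- function(config, out_dir, extra = list()) {
  cfg <- c(config, extra)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Fit every trace of a sample sheet and build phenotype tables
#'
#' The fit stage of the pipeline: reads each trace, converts it to
#' percent-density, fits the bimodal log-normal mixture, computes the
#' number-weighted phenotypes (percent small granules via weighting
#' conversion, granules per mg from the sheet's prep columns), and
#' aggregates grain-level records to per-plant phenotype records.
#' Unreadable or unfittable traces are recorded in the run log and the
#' run continues with status `"partial"`.
#'
#' @param sheet_path Path to a sample sheet CSV ([read_sample_sheet()]).
#' @param out_dir Output directory; receives `fits.csv`,
#'   `phenotypes.csv`, `grain_phenotypes.csv`, `config.json`, `run.log`.
#' @param config A [run_config()].
#' @return Invisibly, a list with `status` (`"ok"`/`"partial"`), `fits`,
#'   `phenotypes`, `grain_phenotypes`, `errors`.
#' @export
cmd_fit <- function(sheet_path, out_dir, config = run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line(log_path, sprintf("cmd_fit start: sheet=%s", sheet_path))
  sheet <- read_sample_sheet(sheet_path)
  fits <- grains <- list()
  errors <- character()
  for (i in seq_len(nrow(sheet))) {
    row <- sheet[i, ]
    rec <- tryCatch({
      tp <- row$trace_path
      if (!file.exists(tp) && !is.null(sheet_path))
        tp <- file.path(dirname(sheet_path), row$trace_path)
      trace <- read_trace(tp)
      fit <- fit_bimodal(trace, config$fit)
      fr <- fit_row(fit, sample_id = row$sample_id)
      num <- convert_weighting(trace, "number")
      gpm <- if (!is.null(row$grain_mass_mg) && is.finite(row$grain_mass_mg) &&
                 !is.null(row$counted_granules) &&
                 is.finite(row$counted_granules)) {
        granules_per_mg(sample_prep(
          aliquot_volume_mL = row$aliquot_volume_mL %||% 1,
          total_volume_mL = row$total_volume_mL %||% 100,
          grain_mass_mg = row$grain_mass_mg,
          counted_granules = row$counted_granules))
      } else NA_real_
      list(fit = fr,
           grain = data.frame(sample_id = row$sample_id,
                              plant_id = paste(row$genotype, row$plant,
                                               sep = "_"),
                              genotype = row$genotype,
                              dpa = row$dpa %||% NA_real_,
                              converged = fr$converged,
                              granules_per_mg = gpm,
                              pct_small_by_number =
                                pct_small(num, config$small_threshold),
                              b_volume_percent = fr$b_volume_percent,
                              mean_diam_A_um = fr$mean_diam_A_um,
                              mean_diam_B_um = fr$mean_diam_B_um,
                              median_diam_A_um = fr$median_diam_A_um,
                              median_diam_B_um = fr$median_diam_B_um,
                              stringsAsFactors = FALSE))
    }, granulofit_error = function(e) {
      log_line(log_path, sprintf("ERROR sample %s: %s", row$sample_id,
                                 conditionMessage(e)))
      conditionMessage(e)
    })
    if (is.character(rec)) {
      errors <- c(errors, rec)
    } else {
      fits[[length(fits) + 1L]] <- rec$fit
      grains[[length(grains) + 1L]] <- rec$grain
    }
  }
  fits <- do.call(rbind, fits)
  grains <- do.call(rbind, grains)
  phenos <- NULL
  if (config$aggregate && !is.null(grains)) {
    phenos <- do.call(rbind, lapply(split(grains, grains$plant_id),
      function(g) {
        rec <- withCallingHandlers(
          summarize_plant(g, plant_id = g$plant_id[1],
                          genotype = g$genotype[1], dpa = g$dpa[1]),
          warning = function(w) {
            log_line(log_path, paste("WARNING:", conditionMessage(w)))
            invokeRestart("muffleWarning")
          })
        rec
      }))
    if (!is.null(phenos)) phenos <- phenos[order(phenos$plant_id), ]
  }
  write_output_table(fits %||% data.frame(), file.path(out_dir, "fits.csv"))
  write_output_table(grains %||% data.frame(),
                     file.path(out_dir, "grain_phenotypes.csv"))
  if (!is.null(phenos))
    write_output_table(phenos, file.path(out_dir, "phenotypes.csv"))
  echo_config(config, out_dir,
              extra = list(command = "fit", sheet = sheet_path,
                           n_samples = nrow(sheet),
                           n_errors = length(errors)))
  status <- if (length(errors)) "partial" else "ok"
  log_line(log_path, sprintf("cmd_fit done: %d fits, %d errors, status=%s",
                             NROW(fits), length(errors), status))
  invisible(list(status = status, fits = fits, phenotypes = phenos,
                 grain_phenotypes = grains, errors = errors))
}

#' Compare genotypes on a phenotype table
#'
#' The statistics stage: one-way ANOVA plus Tukey-adjusted pairwise
#' contrasts per phenotype (optionally per stratum, e.g. `dpa`), written
#' as a tidy comparison table and optional forest plot.
#'
#' @param phenotype_path Path to a phenotype table CSV (as written by
#'   [cmd_fit()]).
#' @param out_dir Output directory; receives `comparisons.csv` (+
#'   `comparisons.svg` with `plots = TRUE`), `config.json`, `run.log`.
#' @param phenotypes Phenotype columns to compare; default: the standard
#'   set intersected with the table.
#' @param group_col,stratum_col Grouping / stratification columns.
#' @param config A [run_config()].
#' @param plots Write a forest plot.
#' @return Invisibly, the comparison data frame.
#' @export
cmd_compare <- function(phenotype_path, out_dir, phenotypes = NULL,
                        group_col = "genotype", stratum_col = NULL,
                        config = run_config(), plots = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line(log_path, sprintf("cmd_compare start: table=%s", phenotype_path))
  tab <- utils::read.csv(phenotype_path, stringsAsFactors = FALSE)
  if (!group_col %in% names(tab))
    gf_invalid(sprintf("group column '%s' not in table; available: %s",
                       group_col, paste(names(tab), collapse = ", ")))
  if (length(unique(tab[[group_col]])) < 2)
    gf_invalid("need at least 2 groups to compare (did you pass one genotype?)")
  if (is.null(phenotypes))
    phenotypes <- intersect(c("granules_per_mg", "pct_small_by_number",
                              "b_volume_percent", "mean_diam_A_um",
                              "mean_diam_B_um"), names(tab))
  cmp <- withCallingHandlers(
    run_comparisons(tab, phenotypes, group_col = group_col,
                    stratum_col = stratum_col, conf = config$conf),
    warning = function(w) {
      log_line(log_path, paste("WARNING:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  write_output_table(cmp, file.path(out_dir, "comparisons.csv"))
  if (plots && nrow(cmp))
    plot_comparisons(cmp, file.path(out_dir, "comparisons.svg"))
  echo_config(config, out_dir,
              extra = list(command = "compare", table = phenotype_path,
                           phenotypes = phenotypes, group_col = group_col,
                           stratum_col = stratum_col))
  log_line(log_path, sprintf("cmd_compare done: %d rows", nrow(cmp)))
  invisible(cmp)
}

#' Simulate a mock dataset from a named design
#'
#' @param design `"genotype_panel"`, `"time_course"`, or a design data
#'   frame ([design_genotype_panel()]).
#' @param out_dir Output directory.
#' @param config A [run_config()]; its `seed` drives all randomness.
#' @param ... Passed to the design builder when `design` is a name.
#' @return Invisibly, the [simulate_experiment()] result.
#' @export
cmd_simulate <- function(design = "genotype_panel", out_dir,
                         config = run_config(), ...) {
  if (is.character(design)) {
    design <- switch(design,
                     genotype_panel = design_genotype_panel(...),
                     time_course = design_time_course(...),
                     gf_invalid(sprintf("unknown design '%s'", design)))
  }
  res <- simulate_experiment(design, out_dir, base_seed = config$seed)
  log_line(file.path(out_dir, "run.log"),
           sprintf("cmd_simulate done: %d traces, seed=%d", nrow(res$sheet),
                   config$seed))
  echo_config(config, out_dir,
              extra = list(command = "simulate", n_samples = nrow(res$sheet)))
  invisible(res)
}

#' Command-line entry point
#'
#' `granulofit_cli(c("simulate", "--out", dir, "--seed", "7"))` etc.
#' Subcommands: `simulate`, `fit`, `compare`. Flags: `--sample-sheet`,
#' `--table`, `--design`, `--out`, `--seed`, `--small-threshold`,
#' `--conf`, `--objective` (lsq|mle), `--no-aggregate`, `--plots`,
#' `--group-col`, `--stratum-col`.
#'
#' Run from a shell as
#' `Rscript -e 'granulofit::granulofit_cli()' simulate --out sim`.
#'
#' @param args Character vector of arguments; defaults to the command
#'   line.
#' @return Integer exit status, invisibly (0 ok, 1 failure, 2 partial).
#' @export
granulofit_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: granulofit <simulate|fit|compare> [--flags]")
    return(invisible(1L))
  }
  cmd <- args[1]
  status <- tryCatch({
    flags <- parse_flags(args[-1])
    config <- run_config(
      small_threshold = as.numeric(flags[["small-threshold"]] %||% 10),
      conf = as.numeric(flags[["conf"]] %||% 0.95),
      aggregate = !isTRUE(flags[["no-aggregate"]]),
      seed = as.integer(flags[["seed"]] %||% 1),
      fit = fit_options(objective = flags[["objective"]] %||% "lsq"))
    out <- flags[["out"]] %||% gf_invalid("--out is required")
    switch(cmd,
    simulate = {
      cmd_simulate(flags[["design"]] %||% "genotype_panel", out, config)
      0L
    },
    fit = {
      res <- cmd_fit(flags[["sample-sheet"]] %||%
                       gf_invalid("fit requires --sample-sheet"),
                     out, config)
      if (res$status == "ok") 0L else 2L
    },
    compare = {
      cmd_compare(flags[["table"]] %||% gf_invalid("compare requires --table"),
                  out,
                  group_col = flags[["group-col"]] %||% "genotype",
                  stratum_col = flags[["stratum-col"]],
                  config = config, plots = isTRUE(flags[["plots"]]))
      0L
    },
    gf_invalid(sprintf("unknown subcommand '%s'", cmd)))
  },
    granulofit_error = function(e) {
      message("error: ", conditionMessage(e))
      1L
    })
  invisible(status)
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  bool_flags <- c("no-aggregate", "plots")
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      gf_invalid(sprintf("unexpected argument '%s'", a))
    key <- substring(a, 3)
    if (key %in% bool_flags) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args))
        gf_invalid(sprintf("flag --%s needs a value", key))
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}
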