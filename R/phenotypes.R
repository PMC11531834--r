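#' Granules per milligram of grain
#'
#' Back-calculates the absolute granule count from the volumetric counting
#' scheme: the instrument counts `counted_granules` in an aliquot of
#' `aliquot_volume_mL` drawn from `total_volume_mL` of suspension prepared
#' from `grain_mass_mg` of grain, so
#' `count * (total / aliquot) / mass`. With the standard 1 mL of a 100 mL
#' preparation the dilution factor is 100.
#'
#' @param prep A [sample_prep()].
#' @return Granule count per mg grain.
#' @export
granules_per_mg <- function(prep) {
  stopifnot(inherits(prep, "sample_prep"))
  prep$counted_granules *
    (prep$total_volume_mL / prep$aliquot_volume_mL) / prep$grain_mass_mg
}

#' Percentage of small granules by number
#'
#' The fraction of granules strictly below `threshold` um (default 10, the
#' conventional B-type size boundary), on a number-weighted distribution.
#' A bin straddling the threshold contributes the fraction of its width
#' below the threshold *on the log scale* (granules assumed uniform in
#' log-diameter within a bin, consistent with logarithmic binning).
#'
#' @param dist Number-weighted `binned_distribution`, kind count or percent.
#' @param threshold Diameter threshold in micrometres.
#' @return Percentage in `[0, 100]`.
#' @export
pct_small <- function(dist, threshold = 10) {
  stopifnot(inherits(dist, "binned_distribution"))
  if (dist$weighting != "number")
    gf_contract("pct_small requires a number-weighted distribution; use convert_weighting() first")
  if (!dist$value_kind %in% c("count", "percent"))
    gf_contract("pct_small requires value_kind count or percent")
  if (!is.finite(threshold) || threshold <= 0)
    gf_invalid("threshold must be > 0")
  e <- dist$bin_edges
  lo <- e[-length(e)]
  hi <- e[-1]
  frac_below <- ifelse(hi <= threshold, 1,
                       ifelse(lo >= threshold, 0,
                              log(threshold / lo) / log(hi / lo)))
  total <- sum(dist$values)
  if (total <= 0) gf_empty("empty distribution")
  100 * sum(dist$values * frac_below) / total
}

#' Aggregate grain-level records into a per-plant phenotype record
#'
#' The experimental unit of the study design is the plant: several grains
#' are measured per plant and each phenotype is averaged over that plant's
#' grains. Records from unconverged fits are excluded (and counted); a
#' plant with no usable grain is reported as `NULL` with a warning.
#'
#' @param grain_records Data frame with one row per grain; must carry a
#'   logical `converged` column (missing means all usable) plus numeric
#'   phenotype columns.
#' @param plant_id,genotype,dpa Plant metadata copied onto the record.
#' @param phenotype_cols Columns to average; defaults to the standard set,
#'   intersected with what is present.
#' @return One-row data frame (a phenotype record) or `NULL`.
#' @export
summarize_plant <- function(grain_records, plant_id, genotype, dpa = NA,
                            phenotype_cols = c("granules_per_mg",
                                               "pct_small_by_number",
                                               "b_volume_percent",
                                               "mean_diam_A_um",
                                               "mean_diam_B_um",
                                               "median_diam_A_um",
                                               "median_diam_B_um")) {
  grain_records <- as.data.frame(grain_records)
  usable <- if ("converged" %in% names(grain_records))
    grain_records[isTRUE_vec(grain_records$converged), , drop = FALSE]
  else grain_records
  n_excluded <- nrow(grain_records) - nrow(usable)
  if (nrow(usable) == 0L) {
    warning(sprintf("plant %s: no converged grain-level records; excluded",
                    plant_id), call. = FALSE)
    return(NULL)
  }
  cols <- intersect(phenotype_cols, names(usable))
  out <- data.frame(plant_id = plant_id, genotype = genotype, dpa = dpa,
                    stringsAsFactors = FALSE)
  for (cl in cols) out[[cl]] <- mean(usable[[cl]], na.rm = TRUE)
  out$n_grains_averaged <- nrow(usable)
  out$n_grains_excluded <- n_excluded
  out
}

isTRUE_vec <- function(x) !is.na(x) & x
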