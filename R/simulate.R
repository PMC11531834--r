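#' Simulation specification for a granule population
#'
#' A two-component log-normal world calibrated to Triticeae endosperm
#' starch: A-type granules with (number-weighted) median diameter around
#' 18-25 um and B-type granules around 3-10 um. The mixing proportion is
#' given in exactly one of the two conventions — by number (probability
#' that a granule belongs to the B component) or by volume (share of total
#' granule volume held by the B component); the other is derived in closed
#' form from the components' third moments.
#'
#' Default dispersions sdlog_A = 0.25 and sdlog_B = 0.30 give component
#' widths on the densified trace comparable to published mature-grain
#' traces; they are recorded in every truth table and trivially overridable.
#'
#' @param n_granules Number of granules to draw.
#' @param median_diam_A_um,median_diam_B_um Component medians, um.
#' @param sdlog_A,sdlog_B Log-scale standard deviations.
#' @param f_B_volume,f_B_number Mixing fraction; supply exactly one.
#' @param seed Integer RNG seed; populations are bit-reproducible given it.
#' @param window Instrument measurement window c(min, max) um. Default
#'   1.4-42 um, i.e. 2%-60% of a 70 um aperture.
#' @param n_bins Number of logarithmic size bins across the window.
#' @export
sim_spec <- function(n_granules = 1e5,
                     median_diam_A_um = 22, sdlog_A = 0.25,
                     median_diam_B_um = 5, sdlog_B = 0.30,
                     f_B_volume = NULL, f_B_number = NULL,
                     seed = 1L,
                     window = c(1.4, 42), n_bins = 256L) {
  if (is.null(f_B_volume) == is.null(f_B_number))
    gf_invalid("supply exactly one of f_B_volume, f_B_number")
  f <- f_B_volume %||% f_B_number
  if (!is.finite(f) || f < 0 || f > 1)
    gf_invalid("mixing fraction must be in [0, 1]")
  if (median_diam_A_um <= 0 || median_diam_B_um <= 0 ||
      sdlog_A <= 0 || sdlog_B <= 0)
    gf_invalid("medians and sdlogs must be > 0")
  if (n_granules < 1) gf_invalid("n_granules must be positive")
  if (length(window) != 2L || window[1] <= 0 || window[2] <= window[1])
    gf_invalid("window must be c(min, max) with 0 < min < max")
  structure(list(n_granules = as.integer(n_granules),
                 median_diam_A_um = median_diam_A_um, sdlog_A = sdlog_A,
                 median_diam_B_um = median_diam_B_um, sdlog_B = sdlog_B,
                 f_B_volume = f_B_volume, f_B_number = f_B_number,
                 seed = as.integer(seed), window = window,
                 n_bins = as.integer(n_bins)),
            class = "sim_spec")
}

# Third moment of a log-normal about zero, parameterized by median and
# sdlog: E[D^3] = median^3 * exp(4.5 sdlog^2). The (pi/6) sphere factor
# cancels in every ratio we take.
lognormal_m3 <- function(median_um, sdlog) median_um^3 * exp(4.5 * sdlog^2)

#' Volume-weighted view of a number-weighted log-normal component
#'
#' Volumetric traces are d^3 size-biased: if diameters in a component are
#' LN(mu, sigma) by number, the component's share of *volume* along the
#' diameter axis is LN(mu + 3 sigma^2, sigma). A mixture fitted to a
#' volumetric density therefore estimates the volume-weighted component,
#' whose median is `median_um * exp(3 sdlog^2)` and whose arithmetic mean
#' is `median_um * exp(3.5 sdlog^2)`. Use this to turn a simulation spec's
#' number-weighted medians into the values a correct fit should recover.
#'
#' @param median_um Number-weighted component median, um.
#' @param sdlog Log-scale standard deviation (unchanged by the weighting).
#' @return List with `median_um` and `mean_um` of the volume-weighted
#'   component.
#' @export
volume_weighted_component <- function(median_um, sdlog) {
  list(median_um = median_um * exp(3 * sdlog^2),
       mean_um = median_um * exp(3.5 * sdlog^2))
}

#' Convert between number- and volume-based mixing fractions
#'
#' In a two-component log-normal population the share of granules *by
#' number* and the share of granule volume held by a component are linked
#' through the components' third moments m3 = median^3 exp(4.5 sdlog^2):
#' f_number = (f_volume / m3_B) / (f_volume / m3_B + (1 - f_volume) / m3_A)
#' and conversely
#' f_volume = f_number m3_B / (f_number m3_B + (1 - f_number) m3_A).
#' This is the quantitative bridge between "more than 90% of granules by
#' number" and "less than 30% by volume" style statements. The round trip
#' is the identity.
#'
#' @param spec A [sim_spec()] carrying `f_B_volume`.
#' @return The B-component number fraction in `[0, 1]`.
#' @export
number_fraction_from_volume_fraction <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (is.null(spec$f_B_volume))
    gf_invalid("spec has no f_B_volume; use volume_fraction_from_number_fraction")
  fv <- spec$f_B_volume
  m3A <- lognormal_m3(spec$median_diam_A_um, spec$sdlog_A)
  m3B <- lognormal_m3(spec$median_diam_B_um, spec$sdlog_B)
  (fv / m3B) / (fv / m3B + (1 - fv) / m3A)
}

#' @rdname number_fraction_from_volume_fraction
#' @export
volume_fraction_from_number_fraction <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (is.null(spec$f_B_number))
    gf_invalid("spec has no f_B_number; use number_fraction_from_volume_fraction")
  fn <- spec$f_B_number
  m3A <- lognormal_m3(spec$median_diam_A_um, spec$sdlog_A)
  m3B <- lognormal_m3(spec$median_diam_B_um, spec$sdlog_B)
  fn * m3B / (fn * m3B + (1 - fn) * m3A)
}

# Both conventions for a spec, whichever was given.
spec_fractions <- function(spec) {
  if (!is.null(spec$f_B_volume))
    list(f_B_volume = spec$f_B_volume,
         f_B_number = number_fraction_from_volume_fraction(spec))
  else
    list(f_B_volume = volume_fraction_from_number_fraction(spec),
         f_B_number = spec$f_B_number)
}

#' Draw a granule population from a simulation spec
#'
#' Component membership is Bernoulli with the spec's number fraction;
#' diameters are log-normal within component. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [sim_spec()].
#' @return A [granule_population()] with `"A"`/`"B"` labels.
#' @export
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  fr <- spec_fractions(spec)
  n <- spec$n_granules
  set.seed(spec$seed)
  isB <- stats::runif(n) < fr$f_B_number
  d <- numeric(n)
  nB <- sum(isB)
  if (nB) d[isB] <- stats::rlnorm(nB, log(spec$median_diam_B_um), spec$sdlog_B)
  if (nB < n) d[!isB] <- stats::rlnorm(n - nB, log(spec$median_diam_A_um),
                                       spec$sdlog_A)
  granule_population(d, ifelse(isB, "B", "A"))
}

#' Emulate a volumetric measurement of a population
#'
#' Granules outside the instrument window are truncated before binning
#' (the aperture cannot see them); the truncated number and volume are
#' reported in the `overflow` attribute. The in-window granules are binned
#' on logarithmic edges and expressed as per-bin volume percentages.
#' Optionally, counting noise is added by multinomially subsampling
#' `n_count` granules across the bins before computing volume percentages
#' (per-bin volumes then use the bin's geometric-mean sphere volume).
#'
#' @param pop A [granule_population()].
#' @param spec A [sim_spec()] (its `window` and `n_bins` are used).
#' @param n_count Optional number of granules in the counted aliquot.
#' @param meta Metadata list attached to the returned distribution.
#' @return Volume-weighted percent `binned_distribution` with an
#'   `overflow` attribute.
#' @export
simulate_measurement <- function(pop, spec, n_count = NULL, meta = list()) {
  stopifnot(inherits(pop, "granule_population"), inherits(spec, "sim_spec"))
  edges <- make_log_edges(spec$window[1], spec$window[2], spec$n_bins)
  if (is.null(n_count)) {
    out <- bin_population(pop, edges, "volume")
  } else {
    cnt <- bin_population(pop, edges, "number")
    sub <- as.numeric(stats::rmultinom(1, n_count,
                                       prob = pmax(cnt$values, 0)))
    dc3 <- (pi / 6) * bin_centers(cnt)^3
    vol <- sub * dc3
    out <- binned_distribution(edges, 100 * vol / sum(vol), "volume",
                               "percent")
    attr(out, "overflow") <- attr(cnt, "overflow")
  }
  out$meta <- meta
  out$meta$window_um <- spec$window
  out$meta$n_bins <- spec$n_bins
  out
}

# Deterministic per-sample seed from a base seed and cell labels, kept
# below 2^31 so it is a valid R integer. Adding samples to a design never
# perturbs the seeds of existing ones.
sample_seed <- function(base_seed, ...) {
  key <- paste(c(base_seed, ...), collapse = "|")
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% 2147483629
  as.integer(h + 1)
}

default_genotype_params <- function(genotype) {
  switch(genotype,
         WT = list(median_diam_A_um = 22, sdlog_A = 0.25,
                   median_diam_B_um = 5.0, sdlog_B = 0.30,
                   f_B_volume = 0.22),
         mutant = list(median_diam_A_um = 19.5, sdlog_A = 0.25,
                       median_diam_B_um = 5.5, sdlog_B = 0.30,
                       f_B_volume = 0.32),
         gf_invalid(sprintf("no default parameters for genotype '%s'",
                            genotype)))
}

# Developmental parameterization: A-type granules initiate early and grow;
# B-type granules appear around 15-20 dpa in the wild type but already by
# 10-14 dpa in the early-initiating mutant, whose A-type granules also
# grow more slowly (smaller A median at later dpa).
default_timecourse_params <- function(genotype, dpa) {
  grid <- list(
    WT = list(`8` = c(A = 9, fB = 0.00, B = 4.0),
              `14` = c(A = 17, fB = 0.00, B = 4.5),
              `20` = c(A = 21, fB = 0.10, B = 5.0),
              `30` = c(A = 22, fB = 0.25, B = 5.0)),
    mutant = list(`8` = c(A = 9, fB = 0.00, B = 4.0),
                  `14` = c(A = 15, fB = 0.10, B = 5.0),
                  `20` = c(A = 17, fB = 0.22, B = 5.5),
                  `30` = c(A = 19, fB = 0.32, B = 5.5)))
  g <- grid[[genotype]]
  if (is.null(g)) gf_invalid(sprintf("no time-course defaults for '%s'", genotype))
  p <- g[[as.character(dpa)]]
  if (is.null(p)) gf_invalid(sprintf("no time-course defaults for %s dpa", dpa))
  list(median_diam_A_um = unname(p["A"]), sdlog_A = 0.25,
       median_diam_B_um = unname(p["B"]), sdlog_B = 0.30,
       f_B_volume = unname(p["fB"]))
}

#' Experiment designs for the simulator
#'
#' `design_genotype_panel()` mirrors a mature-grain genotype comparison:
#' 2 genotypes x 9 plants x 3 grains by default. `design_time_course()`
#' mirrors a developing-grain series at 8/14/20/30 dpa with 3 plants per
#' genotype per time point. Each row is one measured grain and carries the
#' full generating parameter set, so any cell can be overridden before
#' passing the design to [simulate_experiment()].
#'
#' @param genotypes Genotype labels with built-in defaults (`"WT"`,
#'   `"mutant"`).
#' @param n_plants,n_grains Replicate structure.
#' @param n_granules Granules drawn per measurement.
#' @param grain_mass_mg Nominal single-grain mass (mg).
#' @return Data frame, one row per measurement.
#' @export
design_genotype_panel <- function(genotypes = c("WT", "mutant"),
                                  n_plants = 9, n_grains = 3,
                                  n_granules = 1e5, grain_mass_mg = 50) {
  if (n_plants < 1 || n_grains < 1) gf_invalid("need >= 1 plant and grain")
  rows <- expand.grid(grain = seq_len(n_grains), plant = seq_len(n_plants),
                      genotype = genotypes, stringsAsFactors = FALSE)
  par <- do.call(rbind, lapply(rows$genotype, function(g)
    as.data.frame(default_genotype_params(g))))
  out <- cbind(rows[c("genotype", "plant", "grain")], par)
  out$dpa <- NA_real_
  out$n_granules <- n_granules
  out$grain_mass_mg <- grain_mass_mg
  out$sample_id <- sprintf("%s_p%02d_g%d", out$genotype, out$plant, out$grain)
  out
}

#' @rdname design_genotype_panel
#' @param dpa Time points (days post-anthesis).
#' @export
design_time_course <- function(genotypes = c("WT", "mutant"),
                               dpa = c(8, 14, 20, 30),
                               n_plants = 3, n_grains = 3,
                               n_granules = 1e5, grain_mass_mg = 50) {
  if (n_plants < 1 || n_grains < 1) gf_invalid("need >= 1 plant and grain")
  rows <- expand.grid(grain = seq_len(n_grains), plant = seq_len(n_plants),
                      dpa = dpa, genotype = genotypes,
                      stringsAsFactors = FALSE)
  par <- do.call(rbind, Map(function(g, t)
    as.data.frame(default_timecourse_params(g, t)), rows$genotype, rows$dpa))
  out <- cbind(rows[c("genotype", "plant", "grain", "dpa")], par)
  out$n_granules <- n_granules
  out$grain_mass_mg <- grain_mass_mg
  out$sample_id <- sprintf("%s_d%02d_p%02d_g%d", out$genotype, out$dpa,
                           out$plant, out$grain)
  out
}

#' Simulate a full mock experiment to disk
#'
#' For every design row, draws a population, emulates the volumetric
#' measurement and writes the trace CSV; then writes the sample sheet and
#' a ground-truth table carrying the complete generating parameters plus
#' the B fraction in both conventions. Per-sample seeds are hashed from
#' `(base_seed, genotype, plant, grain, dpa)`, so outputs are a
#' deterministic function of (design, base_seed) and adding rows never
#' changes existing files.
#'
#' @param design Data frame from [design_genotype_panel()] /
#'   [design_time_course()] (or hand-built with the same columns).
#' @param out_dir Output directory (created).
#' @param base_seed Integer master seed.
#' @param window,n_bins Instrument window and bin count.
#' @return List with `sheet_path`, `truth_path`, `trace_dir`, `sheet`,
#'   `truth`.
#' @export
simulate_experiment <- function(design, out_dir, base_seed = 1L,
                                window = c(1.4, 42), n_bins = 256L) {
  design <- as.data.frame(design)
  need <- c("sample_id", "genotype", "plant", "grain", "median_diam_A_um",
            "sdlog_A", "median_diam_B_um", "sdlog_B", "f_B_volume",
            "n_granules", "grain_mass_mg")
  miss <- setdiff(need, names(design))
  if (length(miss))
    gf_invalid(sprintf("design is missing column(s): %s",
                       paste(miss, collapse = ", ")))
  if (!nrow(design)) gf_invalid("empty design")
  if (anyDuplicated(design$sample_id))
    gf_invalid("duplicate sample_id in design")
  if (is.null(design$dpa)) design$dpa <- NA_real_
  trace_dir <- file.path(out_dir, "traces")
  dir.create(trace_dir, recursive = TRUE, showWarnings = FALSE)
  sheet <- truth <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    seed <- sample_seed(base_seed, row$genotype, row$plant, row$grain,
                        row$dpa)
    spec <- sim_spec(n_granules = row$n_granules,
                     median_diam_A_um = row$median_diam_A_um,
                     sdlog_A = row$sdlog_A,
                     median_diam_B_um = row$median_diam_B_um,
                     sdlog_B = row$sdlog_B,
                     f_B_volume = row$f_B_volume,
                     seed = seed, window = window, n_bins = n_bins)
    pop <- simulate_population(spec)
    meas <- simulate_measurement(pop, spec,
                                 meta = list(sample_id = row$sample_id,
                                             genotype = row$genotype,
                                             plant = row$plant,
                                             dpa = row$dpa))
    trace_path <- file.path(trace_dir, paste0(row$sample_id, ".csv"))
    write_trace(meas, trace_path)
    ov <- attr(meas, "overflow")
    counted <- ov$n_total - ov$n_below - ov$n_above
    fr <- spec_fractions(spec)
    sheet[[i]] <- data.frame(sample_id = row$sample_id,
                             genotype = row$genotype, plant = row$plant,
                             grain = row$grain, dpa = row$dpa,
                             grain_mass_mg = row$grain_mass_mg,
                             aliquot_volume_mL = 1, total_volume_mL = 100,
                             counted_granules = counted,
                             trace_path = trace_path,
                             stringsAsFactors = FALSE)
    vwA <- volume_weighted_component(row$median_diam_A_um, row$sdlog_A)
    vwB <- volume_weighted_component(row$median_diam_B_um, row$sdlog_B)
    truth[[i]] <- cbind(row, seed = seed, f_B_number = fr$f_B_number,
                        f_B_volume_true = fr$f_B_volume,
                        vw_median_A_um = vwA$median_um,
                        vw_mean_A_um = vwA$mean_um,
                        vw_median_B_um = vwB$median_um,
                        vw_mean_B_um = vwB$mean_um,
                        window_min_um = window[1], window_max_um = window[2],
                        n_bins = n_bins,
                        n_truncated = ov$n_below + ov$n_above,
                        volume_truncated = ov$volume_below + ov$volume_above)
  }
  sheet <- do.call(rbind, sheet)
  truth <- do.call(rbind, truth)
  sheet_path <- file.path(out_dir, "sample_sheet.csv")
  truth_path <- file.path(out_dir, "truth.csv")
  write_sample_sheet(sheet, sheet_path)
  write_output_table(truth, truth_path)
  list(sheet_path = sheet_path, truth_path = truth_path,
       trace_dir = trace_dir, sheet = sheet, truth = truth)
}
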