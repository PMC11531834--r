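#' Binned granule-size distribution
#'
#' The central container of the package: particle diameters (equivalent
#' spherical diameter, micrometres) binned into contiguous intervals, with
#' one magnitude per bin. The `weighting` records whether magnitudes are
#' proportional to particle number or particle volume; `value_kind` records
#' whether they are raw counts, percentages (summing to 100), or percent
#' densities (percent per micrometre, integrating to 100). Coulter-class
#' instruments export log-binned volume percentages; the density form makes
#' traces with unequal bins comparable and is the target of the mixture fit.
#'
#' Distributions are immutable values: every transform returns a new object.
#'
#' @param bin_edges Numeric vector of n+1 strictly increasing positive bin
#'   boundaries, in micrometres.
#' @param values Numeric vector of n nonnegative finite per-bin magnitudes.
#' @param weighting `"number"` or `"volume"`.
#' @param value_kind `"count"`, `"percent"` or `"percent_density"`.
#' @param meta Named list of free-form sample annotations (e.g. `sample_id`,
#'   `genotype`, `plant`, `dpa`).
#' @return An object of class `binned_distribution`.
#' @export
binned_distribution <- function(bin_edges, values,
                                weighting = c("number", "volume"),
                                value_kind = c("count", "percent",
                                               "percent_density"),
                                meta = list()) {
  weighting <- match.arg(weighting)
  value_kind <- match.arg(value_kind)
  bin_edges <- as.numeric(bin_edges)
  values <- as.numeric(values)
  if (length(bin_edges) < 2L)
    gf_invalid("need at least 2 bin edges")
  if (length(values) != length(bin_edges) - 1L)
    gf_invalid(sprintf("values has length %d but %d bins are defined",
                       length(values), length(bin_edges) - 1L))
  if (any(!is.finite(bin_edges)) || any(bin_edges <= 0))
    gf_invalid("bin_edges must be finite and > 0")
  if (any(diff(bin_edges) <= 0))
    gf_invalid("bin_edges must be strictly increasing")
  if (any(!is.finite(values)) || any(values < 0))
    gf_invalid("values must be finite and >= 0")
  if (value_kind == "percent") {
    s <- sum(values)
    if (abs(s - 100) > 1e-6 * 100)
      gf_validate(sprintf("percent values sum to %.8g, not 100", s))
  }
  if (value_kind == "percent_density") {
    s <- sum(values * diff(bin_edges))
    if (abs(s - 100) > 1e-6 * 100)
      gf_validate(sprintf("percent_density integrates to %.8g, not 100", s))
  }
  structure(list(bin_edges = bin_edges, values = values,
                 weighting = weighting, value_kind = value_kind,
                 meta = meta),
            class = "binned_distribution")
}

#' @export
print.binned_distribution <- function(x, ...) {
  cat(sprintf("<binned_distribution> %d bins [%.3g, %.3g] um, %s-weighted %s\n",
              length(x$values), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)], x$weighting, x$value_kind))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Bin widths, in micrometres
#' @param dist A `binned_distribution`.
#' @export
bin_widths <- function(dist) diff(dist$bin_edges)

#' Representative bin diameters
#'
#' The geometric mean of each bin's edges. Bins are logarithmic, so the
#' geometric mean (the log-midpoint) is the representative diameter; an
#' arithmetic midpoint would bias the d^3 volume weighting.
#' @param dist A `binned_distribution`.
#' @export
bin_centers <- function(dist) {
  e <- dist$bin_edges
  sqrt(e[-length(e)] * e[-1])
}

#' Logarithmically spaced bin edges
#'
#' Geometric edge sequence emulating an instrument's logarithmic size
#' classes: `n_bins + 1` edges from `d_min` to `d_max` with a constant
#' ratio between consecutive edges.
#'
#' @param d_min,d_max Positive window limits in micrometres, `d_min < d_max`.
#' @param n_bins Number of bins (>= 1).
#' @return Numeric vector of `n_bins + 1` edges.
#' @examples
#' make_log_edges(1, 4, 2)   # 1 2 4
#' @export
make_log_edges <- function(d_min, d_max, n_bins) {
  if (!is.finite(d_min) || !is.finite(d_max) || d_min <= 0 || d_max <= d_min)
    gf_invalid("require 0 < d_min < d_max")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L)
    gf_invalid("n_bins must be a positive integer")
  e <- exp(seq(log(d_min), log(d_max), length.out = n_bins + 1L))
  e[1] <- d_min
  e[n_bins + 1L] <- d_max
  e
}

#' Convert a percent distribution to percent density
#'
#' Divides each bin's percentage by its width in micrometres. This is the
#' "even bin" transform: on a log-binned trace the raw percentages are not
#' comparable across bins of unequal width, whereas the density is, and the
#' integral of density over diameter is conserved at 100.
#'
#' @param dist A `binned_distribution` with `value_kind = "percent"`.
#' @return A `binned_distribution` with `value_kind = "percent_density"`.
#' @seealso [from_density()] for the exact inverse.
#' @export
to_density <- function(dist) {
  stopifnot(inherits(dist, "binned_distribution"))
  if (dist$value_kind != "percent")
    gf_contract(sprintf("to_density expects value_kind 'percent', got '%s'",
                        dist$value_kind))
  binned_distribution(dist$bin_edges, dist$values / diff(dist$bin_edges),
                      dist$weighting, "percent_density", dist$meta)
}

#' Convert a percent-density distribution back to percent
#' @param dist A `binned_distribution` with `value_kind = "percent_density"`.
#' @export
from_density <- function(dist) {
  stopifnot(inherits(dist, "binned_distribution"))
  if (dist$value_kind != "percent_density")
    gf_contract(sprintf(
      "from_density expects value_kind 'percent_density', got '%s'",
      dist$value_kind))
  binned_distribution(dist$bin_edges, dist$values * diff(dist$bin_edges),
                      dist$weighting, "percent", dist$meta)
}

#' Normalize counts to percentages
#' @param dist A `binned_distribution` with `value_kind = "count"`.
#' @export
counts_to_percent <- function(dist) {
  stopifnot(inherits(dist, "binned_distribution"))
  if (dist$value_kind != "count")
    gf_contract(sprintf("counts_to_percent expects value_kind 'count', got '%s'",
                        dist$value_kind))
  s <- sum(dist$values)
  if (s <= 0)
    gf_empty("all-zero counts: nothing to normalize")
  binned_distribution(dist$bin_edges, 100 * dist$values / s,
                      dist$weighting, "percent", dist$meta)
}

#' Convert between number- and volume-weighted distributions
#'
#' One volumetric trace carries both the number- and the volume-weighted
#' view of a sample: within a bin all particles are represented by the
#' sphere at the bin's geometric-mean diameter d_c, so the per-bin volume is
#' the per-bin number times (pi/6) d_c^3. Converting number -> volume
#' multiplies by that sphere volume; volume -> number divides. Percent
#' values are renormalized to sum to 100 afterwards. The operation is an
#' involution: converting there and back recovers the input.
#'
#' @param dist A `binned_distribution` with `value_kind` `"count"` or
#'   `"percent"` (densify after converting, not before).
#' @param target `"number"` or `"volume"`.
#' @export
convert_weighting <- function(dist, target = c("number", "volume")) {
  stopifnot(inherits(dist, "binned_distribution"))
  target <- match.arg(target)
  if (dist$value_kind == "percent_density")
    gf_contract("convert_weighting on percent_density: convert before densifying")
  if (target == dist$weighting) return(dist)
  sphere <- (pi / 6) * bin_centers(dist)^3
  v <- if (target == "volume") dist$values * sphere else dist$values / sphere
  if (dist$value_kind == "percent") v <- 100 * v / sum(v)
  binned_distribution(dist$bin_edges, v, target, dist$value_kind, dist$meta)
}

#' Granule population
#'
#' A simulated (or otherwise individually resolved) set of granules given by
#' their equivalent spherical diameters, optionally labelled by mixture
#' component (`"A"` large / `"B"` small).
#'
#' @param diameters Positive numeric vector, micrometres.
#' @param labels Optional character vector of the same length, values in
#'   `c("A", "B")`.
#' @export
granule_population <- function(diameters, labels = NULL) {
  diameters <- as.numeric(diameters)
  if (length(diameters) == 0L)
    gf_empty("empty granule population")
  if (any(!is.finite(diameters)) || any(diameters <= 0))
    gf_invalid("diameters must be finite and > 0")
  if (!is.null(labels)) {
    if (length(labels) != length(diameters))
      gf_invalid("labels must match diameters in length")
    if (!all(labels %in% c("A", "B")))
      gf_invalid("labels must be 'A' or 'B'")
  }
  structure(list(diameters = diameters, labels = labels),
            class = "granule_population")
}

#' @export
print.granule_population <- function(x, ...) {
  cat(sprintf("<granule_population> %d granules, median %.3g um\n",
              length(x$diameters), stats::median(x$diameters)))
  invisible(x)
}

#' Bin a granule population
#'
#' Bins are half-open `[low, high)` with the last bin closed. Granules
#' outside the edge window are never silently dropped: they are tallied in
#' the `overflow` attribute (counts and volumes below/above the window).
#'
#' @param pop A [granule_population()].
#' @param edges Strictly increasing positive bin edges.
#' @param weighting `"number"` (per-bin counts) or `"volume"` (per-bin volume
#'   share as percent of total in-window volume).
#' @return A `binned_distribution` with attribute `overflow`, a list with
#'   `n_below`, `n_above`, `volume_below`, `volume_above`, `n_total`.
#' @export
bin_population <- function(pop, edges, weighting = c("number", "volume")) {
  stopifnot(inherits(pop, "granule_population"))
  weighting <- match.arg(weighting)
  edges <- as.numeric(edges)
  if (any(diff(edges) <= 0) || any(edges <= 0))
    gf_invalid("edges must be positive and strictly increasing")
  d <- pop$diameters
  n_bins <- length(edges) - 1L
  idx <- findInterval(d, edges, rightmost.closed = TRUE)
  below <- idx == 0L
  above <- idx == n_bins + 1L
  vol <- (pi / 6) * d^3
  overflow <- list(n_below = sum(below), n_above = sum(above),
                   volume_below = sum(vol[below]),
                   volume_above = sum(vol[above]),
                   n_total = length(d))
  inw <- !(below | above)
  if (!any(inw))
    gf_empty("no granules inside the bin window")
  if (weighting == "number") {
    values <- tabulate(idx[inw], nbins = n_bins)
    kind <- "count"
  } else {
    tb <- tapply(vol[inw], factor(idx[inw], levels = seq_len(n_bins)), sum)
    values <- as.numeric(tb)
    values[is.na(values)] <- 0
    values <- 100 * values / sum(values)
    kind <- "percent"
  }
  out <- binned_distribution(edges, values, weighting, kind)
  attr(out, "overflow") <- overflow
  out
}

#' Sample preparation / dilution record
#'
#' Describes the volumetric counting scheme: a small starch aliquot is made
#' up to `total_volume_mL` of electrolyte and the instrument counts the
#' granules in `aliquot_volume_mL` of it, so absolute granule numbers can be
#' back-calculated to the starting grain mass.
#'
#' @param aliquot_volume_mL Measured volume (default 1 mL).
#' @param total_volume_mL Total preparation volume (default 100 mL).
#' @param grain_mass_mg Grain mass the starch came from, milligrams.
#' @param counted_granules Nonnegative integer count in the aliquot.
#' @export
sample_prep <- function(aliquot_volume_mL = 1, total_volume_mL = 100,
                        grain_mass_mg, counted_granules) {
  if (!all(is.finite(c(aliquot_volume_mL, total_volume_mL, grain_mass_mg))) ||
      aliquot_volume_mL <= 0 || total_volume_mL <= 0 || grain_mass_mg <= 0)
    gf_invalid("volumes and grain mass must be finite and > 0")
  if (aliquot_volume_mL > total_volume_mL)
    gf_invalid("aliquot volume cannot exceed total volume")
  if (!is.finite(counted_granules) || counted_granules < 0)
    gf_invalid("counted_granules must be a nonnegative count")
  structure(list(aliquot_volume_mL = aliquot_volume_mL,
                 total_volume_mL = total_volume_mL,
                 grain_mass_mg = grain_mass_mg,
                 counted_granules = counted_granules),
            class = "sample_prep")
}
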