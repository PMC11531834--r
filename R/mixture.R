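#' Two-component log-normal mixture of granule volumes
#'
#' The volumetric size distribution of Triticeae endosperm starch is
#' modelled as a mixture of two log-normal components: the large A-type
#' granules and the small B-type granules. Components are Gaussian on the
#' ln(diameter) axis, which is the same thing as log-normal in diameter.
#' The mixture weight `f_B` is the fraction of total granule *volume* in
#' the B component, because the model is fitted to a volume-weighted
#' density; 100 * f_B is the "B-type granule percentage volume" phenotype.
#'
#' @param f_B B-component volume fraction, in `[0, 1]`.
#' @param mu_A,mu_B Component means of ln(diameter / um); by labelling
#'   convention A is the larger-diameter component (`mu_A >= mu_B`).
#' @param sigma_A,sigma_B Component standard deviations of ln(diameter), > 0.
#' @return An object of class `mixture_model`.
#' @export
mixture_model <- function(f_B, mu_A, sigma_A, mu_B, sigma_B) {
  if (!is.finite(f_B) || f_B < 0 || f_B > 1)
    gf_invalid("f_B must be in [0, 1]")
  if (!all(is.finite(c(mu_A, mu_B, sigma_A, sigma_B))) ||
      sigma_A <= 0 || sigma_B <= 0)
    gf_invalid("mu must be finite, sigma > 0")
  if (mu_A < mu_B)
    gf_invalid("labelling convention requires exp(mu_A) >= exp(mu_B); relabel")
  structure(list(f_B = f_B, mu_A = mu_A, sigma_A = sigma_A,
                 mu_B = mu_B, sigma_B = sigma_B),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf(
    "<mixture_model> f_B=%.4f | A: exp(mu)=%.2f um sigma=%.3f | B: exp(mu)=%.2f um sigma=%.3f\n",
    x$f_B, exp(x$mu_A), x$sigma_A, exp(x$mu_B), x$sigma_B))
  invisible(x)
}

#' Mixture percent-density at given diameters
#'
#' Evaluates 100 * [f_B LN(d; mu_B, sigma_B) + (1 - f_B) LN(d; mu_A,
#' sigma_A)] with LN the log-normal pdf in d, so the curve integrates to
#' 100 over (0, Inf) and lives on the same percent-per-micrometre scale as
#' a densified trace.
#'
#' @param model A [mixture_model()].
#' @param d Diameters in micrometres, all > 0.
#' @export
model_density <- function(model, d) {
  stopifnot(inherits(model, "mixture_model"))
  if (any(!is.finite(d)) || any(d <= 0))
    gf_invalid("d must be finite and > 0")
  100 * (model$f_B * stats::dlnorm(d, model$mu_B, model$sigma_B) +
           (1 - model$f_B) * stats::dlnorm(d, model$mu_A, model$sigma_A))
}

#' Fitting options
#'
#' Bounds keep the optimizer inside the physically meaningful window:
#' component medians exp(mu) in `[1.5, 50]` um (granules smaller than the
#' instrument window or larger than any reported granule are not
#' identifiable from these traces), sigma in `[0.05, 1]` (a log-sd below
#' 0.05 is narrower than a single bin; above 1 the "component" is flatter
#' than the whole trace), f_B in `[0, 1]`.
#'
#' @param diam_bounds Bounds for exp(mu), micrometres.
#' @param sigma_bounds Bounds for sigma.
#' @param rel_tol Relative convergence tolerance of the optimizer.
#' @param max_iter Iteration cap.
#' @param objective `"lsq"` (default): unweighted least squares on the
#'   percent-density scale. `"mle"`: Poisson likelihood on per-bin counts
#'   (requires a count-kind input), offered for sensitivity checks.
#' @param fit_raw_percent If `TRUE`, fit the raw log-binned percentages
#'   instead of the even-binned density (sensitivity flag; the density is
#'   the documented default target).
#' @param modality_threshold Evidence threshold on AIC_1 - AIC_2 used by
#'   [classify_modality()].
#' @export
fit_options <- function(diam_bounds = c(1.5, 50), sigma_bounds = c(0.05, 1),
                        rel_tol = 1e-10, max_iter = 500,
                        objective = c("lsq", "mle"),
                        fit_raw_percent = FALSE,
                        modality_threshold = 10) {
  objective <- match.arg(objective)
  stopifnot(diam_bounds[1] > 0, diam_bounds[2] > diam_bounds[1],
            sigma_bounds[1] > 0, sigma_bounds[2] > sigma_bounds[1],
            max_iter >= 1)
  list(diam_bounds = diam_bounds, sigma_bounds = sigma_bounds,
       rel_tol = rel_tol, max_iter = max_iter, objective = objective,
       fit_raw_percent = fit_raw_percent,
       modality_threshold = modality_threshold)
}

# Volume-weighted percent-density view of any volume-weighted input kind.
as_volume_density <- function(dist) {
  stopifnot(inherits(dist, "binned_distribution"))
  if (dist$weighting != "volume")
    gf_contract("fit requires a volume-weighted distribution; use convert_weighting() first")
  if (dist$value_kind == "count") dist <- counts_to_percent(dist)
  if (dist$value_kind == "percent") dist <- to_density(dist)
  dist
}

# Valley diameter between the two largest well-separated local maxima of
# the (lightly smoothed) density, or NULL when the trace looks unimodal.
# Smoothing (5-bin running mean) suppresses counting-noise micro-peaks.
init_split <- function(dd) {
  y <- dd$values
  d <- bin_centers(dd)
  n <- length(y)
  ys <- if (n >= 7L)
    as.numeric(stats::filter(y, rep(1 / 5, 5), sides = 2))
  else y
  ys[is.na(ys)] <- y[is.na(ys)]
  peaks <- which(diff(sign(diff(c(-Inf, ys, -Inf)))) < 0)
  if (length(peaks) < 2L) return(NULL)
  ord <- peaks[order(ys[peaks], decreasing = TRUE)]
  p1 <- ord[1]
  sep <- ord[-1][abs(log(d[ord[-1]] / d[p1])) > log(1.5)]
  if (!length(sep)) return(NULL)
  p2 <- sep[1]
  lo <- min(p1, p2); hi <- max(p1, p2)
  if (hi > lo + 1L) d[lo + which.min(ys[(lo + 1):(hi - 1)])]
  else sqrt(d[lo] * d[hi])
}

#' Deterministic initial guess for the mixture fit
#'
#' Splits the diameter axis at the density minimum between the two largest
#' well-separated local maxima of the densified trace (components whose
#' modes differ by less than a factor 1.5 are not treated as separate
#' peaks). If the trace looks unimodal the split falls back to 10 um, the
#' conventional boundary between B- and A-type granules. Each side then
#' yields volume-weighted log-moment estimates of (mu, sigma) and f_B is
#' the B-side share of total volume.
#'
#' @param dist Volume-weighted `binned_distribution` (percent or density).
#' @param options A [fit_options()] list.
#' @return A [mixture_model()].
#' @export
init_params <- function(dist, options = fit_options()) {
  dd <- as_volume_density(dist)
  moment_init(dd, init_split(dd) %||% 10, options)
}

# Per-side volume-weighted log-moment estimates for a given split diameter.
moment_init <- function(dd, split_d, options = fit_options()) {
  y <- dd$values
  if (sum(y > 0) < 6L)
    gf_insuff("need at least 6 bins with positive values to initialize")
  d <- bin_centers(dd)
  w <- y * bin_widths(dd)           # volume mass per bin
  side_moments <- function(mask) {
    ww <- w[mask]; ld <- log(d[mask])
    if (sum(ww) <= 0) return(NULL)
    mu <- sum(ww * ld) / sum(ww)
    sg <- sqrt(sum(ww * (ld - mu)^2) / sum(ww))
    c(mu = mu, sigma = sg)
  }
  clamp <- function(x, b) min(max(x, b[1]), b[2])
  mu_bounds <- log(options$diam_bounds)
  b_side <- side_moments(d < split_d)
  a_side <- side_moments(d >= split_d)
  f_B <- sum(w[d < split_d]) / sum(w)
  # fall back to global moments shifted apart when one side is empty
  glob <- side_moments(rep(TRUE, length(d)))
  if (is.null(a_side)) a_side <- c(mu = glob[["mu"]] + 0.3, sigma = glob[["sigma"]])
  if (is.null(b_side)) b_side <- c(mu = glob[["mu"]] - 0.7, sigma = glob[["sigma"]])
  mixture_model(
    f_B = clamp(f_B, c(0.001, 0.999)),
    mu_A = clamp(a_side[["mu"]], mu_bounds),
    sigma_A = clamp(max(a_side[["sigma"]], 0.08), options$sigma_bounds),
    mu_B = clamp(min(b_side[["mu"]], a_side[["mu"]]), mu_bounds),
    sigma_B = clamp(max(b_side[["sigma"]], 0.08), options$sigma_bounds))
}

#' Fit the bimodal log-normal mixture to a volumetric trace
#'
#' Bounded nonlinear least squares: minimizes the sum over bins of
#' (observed density - model density at the bin's geometric-mean
#' diameter)^2 on the percent-density scale, starting from
#' [init_params()]. The optimization is deterministic given the input and
#' options. After convergence, components are relabelled so that A is the
#' larger-diameter one; parameters that finish on a bound are flagged, and
#' non-convergence is reported in the result rather than thrown.
#'
#' @param dist Volume-weighted `binned_distribution` (count, percent or
#'   percent_density).
#' @param options A [fit_options()] list.
#' @param init Optional numeric start vector `c(f_B, mu_A, sigma_A, mu_B,
#'   sigma_B)` overriding [init_params()]; component order in the start is
#'   irrelevant (the labels are fixed after the fit).
#' @return An object of class `fit_result`: `model`, `rss`, `converged`,
#'   `n_iter`, `b_volume_percent`, `mean_diam_A`, `mean_diam_B`,
#'   `median_diam_A`, `median_diam_B`, `boundary_flags`.
#' @export
fit_bimodal <- function(dist, options = fit_options(), init = NULL) {
  counts <- if (dist$value_kind == "count") dist$values else NULL
  dd <- as_volume_density(dist)
  d <- bin_centers(dd)
  widths <- bin_widths(dd)
  y <- if (options$fit_raw_percent) dd$values * widths else dd$values
  as_par <- function(m) c(m$f_B, m$mu_A, m$sigma_A, m$mu_B, m$sigma_B)
  starts <- if (!is.null(init)) {
    stopifnot(is.numeric(init), length(init) == 5L)
    list(init)
  } else {
    # deterministic multi-start: detected-valley split plus the plain
    # 10 um split, which rescues shoulder-like traces whose B component
    # has no separate peak
    s <- list(as_par(init_params(dd, options)),
              as_par(moment_init(dd, 10, options)))
    unique(s)
  }
  lower <- c(0, log(options$diam_bounds[1]), options$sigma_bounds[1],
             log(options$diam_bounds[1]), options$sigma_bounds[1])
  upper <- c(1, log(options$diam_bounds[2]), options$sigma_bounds[2],
             log(options$diam_bounds[2]), options$sigma_bounds[2])
  pred <- function(p) {
    dens <- 100 * (p[1] * stats::dlnorm(d, p[4], p[5]) +
                     (1 - p[1]) * stats::dlnorm(d, p[2], p[3]))
    if (options$fit_raw_percent) dens * widths else dens
  }
  obj <- if (options$objective == "lsq") {
    function(p) sum((y - pred(p))^2)
  } else {
    if (is.null(counts))
      gf_contract("objective 'mle' requires a count-kind distribution")
    # Poisson deviance on counts against in-window mixture bin masses
    e <- dd$bin_edges
    function(p) {
      pm <- p[1] * diff(stats::plnorm(e, p[4], p[5])) +
        (1 - p[1]) * diff(stats::plnorm(e, p[2], p[3]))
      pm <- pmax(pm / sum(pm), 1e-300)
      lam <- sum(counts) * pm
      2 * sum(lam - counts - ifelse(counts > 0, counts * log(lam / counts), 0))
    }
  }
  run_one <- function(p0) {
    p0 <- pmin(pmax(p0, lower), upper)
    ctl <- list(iter.max = options$max_iter,
                eval.max = 10 * options$max_iter,
                rel.tol = options$rel_tol)
    res <- stats::nlminb(p0, obj, lower = lower, upper = upper,
                         control = ctl)
    res$gf_converged <- res$convergence == 0
    if (res$convergence != 0) {
      # At very tight tolerances nlminb can stop with "false convergence"
      # at an (often near-perfect) optimum. Restart once; if the restart
      # cannot improve the objective beyond the tolerance the point is
      # stationary and counts as converged.
      res2 <- stats::nlminb(res$par, obj, lower = lower, upper = upper,
                            control = ctl)
      res2$iterations <- res2$iterations + res$iterations
      res2$gf_converged <- res2$convergence == 0 ||
        (res$objective - res2$objective) <=
          options$rel_tol * (abs(res$objective) + options$rel_tol)
      res <- res2
    }
    res
  }
  fits <- lapply(starts, run_one)
  res <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  p <- res$par
  if (p[2] < p[4]) p <- c(1 - p[1], p[4], p[5], p[2], p[3])  # relabel A large
  at_bound <- abs(p - lower) < 1e-8 | abs(upper - p) < 1e-8
  names(at_bound) <- c("f_B", "mu_A", "sigma_A", "mu_B", "sigma_B")
  model <- mixture_model(p[1], p[2], p[3], p[4], p[5])
  rss <- sum((dd$values - model_density(model, d))^2)
  structure(list(
    model = model,
    rss = rss,
    objective_value = res$objective,
    converged = isTRUE(res$gf_converged),
    message = res$message,
    n_iter = res$iterations,
    n_bins = length(d),
    boundary_flags = at_bound,
    b_volume_percent = 100 * model$f_B,
    mean_diam_A = exp(model$mu_A + model$sigma_A^2 / 2),
    mean_diam_B = exp(model$mu_B + model$sigma_B^2 / 2),
    median_diam_A = exp(model$mu_A),
    median_diam_B = exp(model$mu_B),
    options = options,
    meta = dd$meta), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> %s in %d iter, rss=%.4g | B-vol%%=%.2f, A=%.2f um, B=%.2f um%s\n",
    if (x$converged) "converged" else "NOT CONVERGED", x$n_iter, x$rss,
    x$b_volume_percent, x$mean_diam_A, x$mean_diam_B,
    if (any(x$boundary_flags))
      paste0(" [at bound: ",
             paste(names(x$boundary_flags)[x$boundary_flags], collapse = ","),
             "]") else ""))
  invisible(x)
}

#' Extract distribution phenotypes from a converged fit
#'
#' `b_volume_percent` is 100 * f_B. The "mean diameter" of a component is
#' the arithmetic mean of its fitted volume-weighted log-normal,
#' exp(mu + sigma^2 / 2); the median exp(mu) is reported alongside because
#' the two differ by a few percent at typical sigma and the field's usage
#' is ambiguous.
#'
#' @param fit A converged `fit_result`.
#' @return Named list: `b_volume_percent`, `mean_diam_A`, `mean_diam_B`,
#'   `median_diam_A`, `median_diam_B`.
#' @export
extract_phenotypes <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$converged)
    gf_contract(sprintf("fit did not converge (%s); refusing to extract phenotypes",
                        fit$message %||% "no diagnostic"))
  fit[c("b_volume_percent", "mean_diam_A", "mean_diam_B",
        "median_diam_A", "median_diam_B")]
}

#' Classify a trace as unimodal or bimodal
#'
#' Fits a single log-normal and the two-component mixture to the same
#' densified trace and compares AIC computed from the Gaussian-error RSS
#' (AIC = n log(RSS/n) + 2 k, with k the parameter count plus one for the
#' error variance). The trace is called bimodal when AIC_1 - AIC_2 exceeds
#' `options$modality_threshold` (default 10, a conventional "decisive"
#' evidence gap) and the fitted f_B is off its bounds within
#' `[0.01, 0.99]`. Deterministic; if neither fit converges the status is
#' `"indeterminate"`.
#'
#' @param dist Volume-weighted `binned_distribution`.
#' @param options A [fit_options()] list.
#' @return List: `modality` (`"unimodal"`, `"bimodal"` or
#'   `"indeterminate"`), `delta_aic`, `fit1`, `fit2`.
#' @export
classify_modality <- function(dist, options = fit_options()) {
  dd <- as_volume_density(dist)
  d <- bin_centers(dd)
  y <- dd$values
  n <- length(d)
  fit2 <- fit_bimodal(dd, options)
  lower <- c(log(options$diam_bounds[1]), options$sigma_bounds[1])
  upper <- c(log(options$diam_bounds[2]), options$sigma_bounds[2])
  w <- y * bin_widths(dd)
  mu0 <- sum(w * log(d)) / sum(w)
  sg0 <- sqrt(sum(w * (log(d) - mu0)^2) / sum(w))
  par0 <- pmin(pmax(c(mu0, max(sg0, 0.08)), lower), upper)
  res1 <- stats::nlminb(par0,
                        function(p) sum((y - 100 * stats::dlnorm(d, p[1], p[2]))^2),
                        lower = lower, upper = upper,
                        control = list(iter.max = options$max_iter,
                                       rel.tol = options$rel_tol))
  conv1 <- res1$convergence == 0
  if (!conv1 && !fit2$converged)
    return(list(modality = "indeterminate", delta_aic = NA_real_,
                fit1 = res1, fit2 = fit2))
  aic <- function(rss, k) n * log(rss / n) + 2 * (k + 1)
  delta <- aic(res1$objective, 2) - aic(fit2$rss, 5)
  f_B <- fit2$model$f_B
  bimodal <- fit2$converged && is.finite(delta) &&
    delta > options$modality_threshold &&
    f_B >= 0.01 && f_B <= 0.99
  list(modality = if (bimodal) "bimodal" else "unimodal",
       delta_aic = delta, fit1 = res1, fit2 = fit2)
}

#' Tidy one row of fit diagnostics
#'
#' Flattens a `fit_result` into the fit-table row used by the pipeline
#' outputs.
#' @param fit A `fit_result`.
#' @param sample_id Optional id column value.
#' @export
fit_row <- function(fit, sample_id = fit$meta$sample_id %||% NA_character_) {
  m <- fit$model
  data.frame(sample_id = sample_id, converged = fit$converged,
             n_iter = fit$n_iter, rss = fit$rss,
             f_B = m$f_B, mu_A = m$mu_A, sigma_A = m$sigma_A,
             mu_B = m$mu_B, sigma_B = m$sigma_B,
             b_volume_percent = fit$b_volume_percent,
             mean_diam_A_um = fit$mean_diam_A,
             mean_diam_B_um = fit$mean_diam_B,
             median_diam_A_um = fit$median_diam_A,
             median_diam_B_um = fit$median_diam_B,
             boundary_flags = paste(names(fit$boundary_flags)[fit$boundary_flags],
                                    collapse = ";"),
             stringsAsFactors = FALSE)
}
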