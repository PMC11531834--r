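#' One-way fixed-effects ANOVA
#'
#' Standard decomposition: F = MS_between / MS_within with df (k - 1,
#' N - k). With exactly constant data the F ratio is undefined (0/0) and is
#' reported as `NA` rather than thrown.
#'
#' @param values Numeric response.
#' @param groups Grouping factor (coerced).
#' @return List: `F`, `p`, `df_between`, `df_resid`, `mse`, `ss_between`,
#'   `ss_within`, `group_means`, `group_n`, `k`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2L) gf_invalid("need at least 2 groups")
  if (n - k < 1L) gf_invalid("zero residual degrees of freedom")
  gm <- tapply(values, groups, mean)
  gn <- tabulate(groups, nbins = k)
  grand <- mean(values)
  ss_b <- sum(gn * (gm - grand)^2)
  ss_w <- sum((values - gm[as.integer(groups)])^2)
  df_b <- k - 1L
  df_w <- n - k
  mse <- ss_w / df_w
  Fstat <- if (ss_w == 0 && ss_b == 0) NA_real_ else (ss_b / df_b) / mse
  p <- if (is.na(Fstat)) NA_real_ else
    stats::pf(Fstat, df_b, df_w, lower.tail = FALSE)
  list(F = Fstat, p = p, df_between = df_b, df_resid = df_w, mse = mse,
       ss_between = ss_b, ss_within = ss_w,
       group_means = gm, group_n = gn, k = k,
       levels = levels(groups))
}

#' Tukey-adjusted all-pairs comparisons
#'
#' For every unordered pair of groups, reports the difference of means with
#' a simultaneous confidence interval and a familywise-adjusted p-value
#' from the studentized range distribution (Tukey HSD, in the Tukey-Kramer
#' form for unbalanced groups):
#' CI = diff +/- q(conf; k, df) / sqrt(2) * sqrt(mse (1/n_a + 1/n_b)).
#'
#' With k = 2 this reduces exactly to the pooled-variance t procedure.
#'
#' @param values Numeric response.
#' @param groups Grouping factor.
#' @param conf Simultaneous confidence level, default 0.95.
#' @return Data frame with one row per pair: `group_a`, `group_b`,
#'   `diff_means` (a - b), `ci_low`, `ci_high`, `p_adjusted`, `df_resid`,
#'   `n_a`, `n_b`.
#' @export
tukey_pairwise <- function(values, groups, conf = 0.95) {
  if (!is.finite(conf) || conf <= 0 || conf >= 1)
    gf_invalid("conf must be in (0, 1)")
  a <- anova_oneway(values, groups)
  k <- a$k
  qcrit <- stats::qtukey(conf, k, a$df_resid) / sqrt(2)
  pairs <- utils::combn(a$levels, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    ga <- pairs[1, j]; gb <- pairs[2, j]
    na <- a$group_n[match(ga, a$levels)]
    nb <- a$group_n[match(gb, a$levels)]
    diff <- unname(a$group_means[ga] - a$group_means[gb])
    se <- sqrt(a$mse * (1 / na + 1 / nb))
    qobs <- abs(diff) / (se / sqrt(2))
    data.frame(group_a = ga, group_b = gb, diff_means = diff,
               ci_low = diff - qcrit * se, ci_high = diff + qcrit * se,
               p_adjusted = stats::ptukey(qobs, k, a$df_resid,
                                          lower.tail = FALSE),
               df_resid = a$df_resid, n_a = na, n_b = nb,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run genotype comparisons across phenotypes (and strata)
#'
#' For each phenotype column (optionally within each level of a stratum
#' column such as `dpa`), fits the one-way model and emits the ANOVA
#' summary alongside every Tukey-adjusted pairwise contrast as a tidy long
#' table. Each phenotype is analysed separately; p-values are adjusted only
#' within a phenotype's pairwise family, not across phenotypes.
#'
#' Rows must be one per experimental unit (plant). If a `plant_id` column
#' is present and duplicated within a group x stratum cell the call is
#' refused: aggregate grains to plants first ([summarize_plant()]).
#'
#' @param table Data frame of per-plant phenotypes.
#' @param phenotypes Character vector of phenotype column names.
#' @param group_col Grouping column name (default `"genotype"`).
#' @param stratum_col Optional stratification column name (e.g. `"dpa"`).
#' @param conf Confidence level.
#' @return Tidy data frame: `phenotype`, `stratum`, `group_a`, `group_b`,
#'   `diff_means`, `ci_low`, `ci_high`, `p_adjusted`, `F`, `p_anova`,
#'   `df_resid`, `n_a`, `n_b`.
#' @export
run_comparisons <- function(table, phenotypes, group_col = "genotype",
                            stratum_col = NULL, conf = 0.95) {
  table <- as.data.frame(table)
  if (!group_col %in% names(table))
    gf_invalid(sprintf("group column '%s' not found; available: %s",
                       group_col, paste(names(table), collapse = ", ")))
  missing_ph <- setdiff(phenotypes, names(table))
  if (length(missing_ph))
    gf_invalid(sprintf("phenotype column(s) %s not found; available: %s",
                       paste(missing_ph, collapse = ", "),
                       paste(names(table), collapse = ", ")))
  strata <- if (is.null(stratum_col)) list(all = table) else
    split(table, table[[stratum_col]])
  if ("plant_id" %in% names(table)) {
    for (s in names(strata)) {
      cells <- paste(strata[[s]][[group_col]], strata[[s]]$plant_id)
      if (anyDuplicated(cells))
        gf_contract(paste0("duplicated plant_id within a comparison cell",
                           " (grain-level rows?): aggregate to plants first"))
    }
  }
  rows <- list()
  for (s in names(strata)) {
    sub <- strata[[s]]
    stratum <- if (is.null(stratum_col)) NA else s
    for (ph in phenotypes) {
      v <- sub[[ph]]
      g <- sub[[group_col]]
      enough <- length(unique(g[is.finite(v)])) >= 2 &&
        sum(is.finite(v)) - length(unique(g[is.finite(v)])) >= 1
      if (!enough) {
        warning(sprintf("skipping phenotype '%s'%s: not enough data", ph,
                        if (is.na(stratum)) "" else
                          sprintf(" in stratum %s", stratum)), call. = FALSE)
        next
      }
      a <- anova_oneway(v, g)
      tk <- tukey_pairwise(v, g, conf)
      tk$phenotype <- ph
      tk$stratum <- stratum
      tk$F <- a$F
      tk$p_anova <- a$p
      rows[[length(rows) + 1L]] <- tk
    }
  }
  if (!length(rows))
    return(data.frame())
  out <- do.call(rbind, rows)
  out[, c("phenotype", "stratum", "group_a", "group_b", "diff_means",
          "ci_low", "ci_high", "p_adjusted", "F", "p_anova", "df_resid",
          "n_a", "n_b")]
}

#' Forest-style plot of pairwise differences
#'
#' Difference-of-means dots with 95% CI whiskers, one panel layout per
#' phenotype, emulating the right-hand comparison panels of granule
#' phenotype figures. Writes SVG.
#'
#' @param comparisons Output of [run_comparisons()].
#' @param path Output `.svg` path.
#' @export
plot_comparisons <- function(comparisons, path) {
  cmp <- as.data.frame(comparisons)
  if (!nrow(cmp)) gf_invalid("no comparisons to plot")
  grDevices::svg(path, width = 7, height = 1 + 0.5 * nrow(cmp))
  on.exit(grDevices::dev.off())
  lab <- paste0(cmp$phenotype,
                ifelse(is.na(cmp$stratum), "", paste0("@", cmp$stratum)),
                ": ", cmp$group_a, " - ", cmp$group_b)
  yy <- rev(seq_len(nrow(cmp)))
  xlim <- range(0, cmp$ci_low, cmp$ci_high)
  graphics::par(mar = c(4, 16, 1, 1))
  graphics::plot(cmp$diff_means, yy, xlim = xlim, yaxt = "n",
                 xlab = "difference in means (95% CI)", ylab = "",
                 pch = 16)
  graphics::segments(cmp$ci_low, yy, cmp$ci_high, yy)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = yy, labels = lab, las = 1, cex.axis = 0.7)
  invisible(path)
}
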