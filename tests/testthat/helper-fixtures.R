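# Shared fixture builders. Everything is generated in code; no stored data.

# A percent-kind volume distribution exactly representing a mixture model
# over the given window (per-bin mass from the mixture CDF, renormalized
# within the window).
model_trace <- function(model, window = c(1.4, 42), n_bins = 256) {
  e <- make_log_edges(window[1], window[2], n_bins)
  mass <- model$f_B * diff(stats::plnorm(e, model$mu_B, model$sigma_B)) +
    (1 - model$f_B) * diff(stats::plnorm(e, model$mu_A, model$sigma_A))
  binned_distribution(e, 100 * mass / sum(mass), "volume", "percent")
}

# Small well-formed trace file on disk; returns the path.
write_tiny_trace <- function(path = tempfile(fileext = ".csv")) {
  dist <- binned_distribution(c(1, 2, 4, 8), c(20, 30, 50),
                              "volume", "percent",
                              meta = list(sample_id = "s1", genotype = "WT",
                                          plant = 1))
  write_trace(dist, path)
  path
}

# Mean percent trace across a set of trace files sharing one binning.
mean_trace <- function(paths) {
  first <- read_trace(paths[1])
  vals <- vapply(paths, function(p) read_trace(p)$values,
                 numeric(length(first$values)))
  mv <- rowMeans(vals)
  binned_distribution(first$bin_edges, 100 * mv / sum(mv),
                      "volume", "percent")
}
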