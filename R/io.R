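#' Read and write binned size-distribution traces
#'
#' The interchange format is a delimited text file (comma for `.csv`, tab
#' for `.tsv`/`.txt`) with header columns `bin_low_um`, `bin_high_um`,
#' `value` and optional inline metadata columns `sample_id`, `genotype`,
#' `plant`, `dpa`, `weighting`, `value_kind`. Bins must be contiguous and
#' strictly increasing. This CSV is the bridge from instrument exports: no
#' public machine-readable raw-trace format exists for this class of data,
#' so the column contract here is the canonical one for the whole pipeline.
#'
#' Decimal commas are rejected, not silently coerced; pass
#' `decimal = "comma"` for exports from locales that use them.
#'
#' @param path File path; the extension selects the delimiter.
#' @param weighting,value_kind Defaults used when the file carries no
#'   `weighting` / `value_kind` columns.
#' @param decimal `"point"` (default) or `"comma"`.
#' @return A [binned_distribution()].
#' @examples
#' # a simulator-generated (synthetic) trace shipped with the package
#' tr <- read_trace(system.file("extdata", "example_trace_synthetic.csv",
#'                              package = "granulofit"))
#' tr
#' @export
read_trace <- function(path, weighting = "volume", value_kind = "percent",
                       decimal = c("point", "comma")) {
  decimal <- match.arg(decimal)
  if (!file.exists(path))
    gf_parse(sprintf("trace file not found: %s", path))
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = trace_sep(path),
                      dec = if (decimal == "comma") "," else ".",
                      stringsAsFactors = FALSE),
    error = function(e) gf_parse(sprintf("%s: cannot parse: %s",
                                         path, conditionMessage(e))))
  need <- c("bin_low_um", "bin_high_um", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    gf_parse(sprintf("%s: missing required column(s): %s",
                     path, paste(miss, collapse = ", ")))
  for (col in need) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1] %||% 1L
      gf_parse(sprintf(
        "%s: column '%s' is not numeric at row %d (decimal commas? use decimal = \"comma\")",
        path, col, bad))
    }
  }
  n <- nrow(df)
  if (n < 1L) gf_parse(sprintf("%s: no data rows", path))
  bad <- which(df$bin_high_um <= df$bin_low_um)
  if (length(bad))
    gf_parse(sprintf("%s: bin_high_um <= bin_low_um at row %d", path, bad[1]))
  if (n > 1L) {
    gap <- which(abs(df$bin_low_um[-1] - df$bin_high_um[-n]) >
                   1e-9 * df$bin_high_um[-n])
    if (length(gap))
      gf_parse(sprintf("%s: bins not contiguous/increasing at row %d",
                       path, gap[1] + 1L))
  }
  bad <- which(df$value < 0)
  if (length(bad))
    gf_parse(sprintf("%s: negative value at row %d", path, bad[1]))
  meta <- list()
  for (col in c("sample_id", "genotype", "plant", "dpa")) {
    if (col %in% names(df)) meta[[col]] <- df[[col]][1]
  }
  if ("weighting" %in% names(df)) weighting <- as.character(df$weighting[1])
  if ("value_kind" %in% names(df)) value_kind <- as.character(df$value_kind[1])
  withCallingHandlers(
    binned_distribution(c(df$bin_low_um, df$bin_high_um[n]), df$value,
                        weighting, value_kind, meta),
    granulofit_error = function(e)
      gf_parse(sprintf("%s: %s", path, conditionMessage(e))))
}

trace_sep <- function(path) {
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

#' @rdname read_trace
#' @param dist A `binned_distribution` to write.
#' @export
write_trace <- function(dist, path) {
  stopifnot(inherits(dist, "binned_distribution"))
  e <- dist$bin_edges
  n <- length(dist$values)
  df <- data.frame(bin_low_um = num17(e[-(n + 1L)]),
                   bin_high_um = num17(e[-1L]),
                   value = num17(dist$values),
                   weighting = dist$weighting,
                   value_kind = dist$value_kind,
                   stringsAsFactors = FALSE)
  for (col in c("sample_id", "genotype", "plant", "dpa")) {
    if (!is.null(dist$meta[[col]])) df[[col]] <- dist$meta[[col]]
  }
  write_delim_lf(df, path, trace_sep(path))
  invisible(path)
}

# 17 significant digits round-trip doubles exactly through text
num17 <- function(x) {
  out <- formatC(x, digits = 17, format = "g", mode = "double")
  gsub(" ", "", out)
}

# fixed column order, '.' decimal separator, LF line endings
write_delim_lf <- function(df, path, sep = ",") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = sep), con, sep = "\n")
  if (nrow(df))
    writeLines(do.call(paste, c(unname(as.list(df)), list(sep = sep))),
               con, sep = "\n")
  invisible(path)
}

#' Read a sample sheet
#'
#' One row per measurement. Required columns: `sample_id` (unique),
#' `genotype`, `plant`, `trace_path`. Optional: `grain`, `dpa`,
#' `grain_mass_mg`, `aliquot_volume_mL`, `total_volume_mL`,
#' `counted_granules`. A typical design is 9 plants per genotype with 3
#' grains measured per plant, i.e. 27 rows per genotype.
#'
#' @param path Delimited text file (extension selects the delimiter).
#' @param genotype_levels Optional declared factor levels; rows with other
#'   genotypes are rejected.
#' @return A data frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path, genotype_levels = NULL) {
  if (!file.exists(path))
    gf_parse(sprintf("sample sheet not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = trace_sep(path),
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "plant", "trace_path")
  miss <- setdiff(need, names(df))
  if (length(miss))
    gf_validate(sprintf("%s: missing required column(s): %s",
                        path, paste(miss, collapse = ", ")))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    gf_validate(sprintf("%s: duplicate sample_id: %s", path,
                        paste(unique(dup), collapse = ", ")))
  if (any(!nzchar(df$trace_path)))
    gf_validate(sprintf("%s: empty trace_path at row %d", path,
                        which(!nzchar(df$trace_path))[1]))
  if (!is.null(genotype_levels)) {
    unknown <- setdiff(unique(df$genotype), genotype_levels)
    if (length(unknown))
      gf_validate(sprintf("%s: unknown genotype level(s): %s", path,
                          paste(unknown, collapse = ", ")))
  }
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' @rdname read_sample_sheet
#' @param sheet Data frame to write.
#' @export
write_sample_sheet <- function(sheet, path) {
  df <- as.data.frame(sheet)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], num17)
  write_delim_lf(df, path, trace_sep(path))
  invisible(path)
}

#' Write a pipeline output table as CSV
#'
#' Stable column order, '.' decimals, LF endings; numeric columns at full
#' precision so reruns are byte-comparable.
#' @param df Data frame.
#' @param path Output path.
#' @export
write_output_table <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], num17)
  write_delim_lf(df, path, ",")
  invisible(path)
}

#' Append a timestamped line to a run log
#' @param log_path Log file path (created if needed); `NULL` is a no-op.
#' @param msg Message string.
#' @param echo Also print to the console.
#' @export
log_line <- function(log_path, msg, echo = FALSE) {
  stamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  line <- paste0(stamp, " ", msg)
  if (!is.null(log_path)) cat(line, "\n", sep = "", file = log_path,
                              append = TRUE)
  if (echo) message(line)
  invisible(line)
}
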