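#' Packaged two-method quantification table for ten candy samples
#'
#' Mean and standard deviation (n = 3, 95% confidence level) of the dye
#' concentration found in ten commercial candy samples (A1-A10) by the
#' reference UV-vis method and by the image-based method, as published. The
#' values are carried verbatim; note that some published per-sample F and
#' relative-error figures were derived from unrounded source data and do not
#' all recompute exactly from the rounded means/SDs (see
#' [table3_printed_statistics()] for the published statistics columns).
#'
#' @return A long tibble with columns `sample_id`, `method` (`"uvvis"` /
#'   `"dia"`), `mean`, `sd` (mg/mL) and `n`, ready for [compare_methods()].
#' @examples
#' compare_methods(table3_fixture())
#' @export
table3_fixture <- function() {
  raw <- table3_raw()
  dplyr::bind_rows(
    tibble(sample_id = raw$sample_id, method = "uvvis",
           mean = raw$mean_uvvis, sd = raw$sd_uvvis, n = raw$n),
    tibble(sample_id = raw$sample_id, method = "dia",
           mean = raw$mean_dia, sd = raw$sd_dia, n = raw$n))
}

#' @rdname table3_fixture
#' @return For `table3_printed_statistics()`: a tibble with the published
#'   per-sample `printed_f`, `printed_t`, their p-values and
#'   `printed_re_pct`.
#' @export
table3_printed_statistics <- function() {
  dplyr::select(table3_raw(), "sample_id", dplyr::starts_with("printed_"))
}

table3_raw <- function() {
  path <- system.file("extdata", "table3_method_comparison.csv",
                      package = "chromaquant", mustWork = TRUE)
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write extracted colour signals to CSV
#'
#' @param signals Signals tibble from [extract_signals()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signals_csv <- function(signals, path) {
  utils::write.csv(signals, path, row.names = FALSE)
  invisible(path)
}
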