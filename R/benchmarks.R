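#' Published benchmark metrics bundled with the package
#'
#' The raw hyperspectral imagery behind the original glyphosate-resistance
#' screening study is not deposited, so its headline model results cannot be
#' recomputed from data. What *is* reproducible at desk scale is the
#' arithmetic that connects the printed numbers: the cross-experiment
#' average of the single-experiment test-set metrics, and F1 scores as the
#' harmonic mean of the printed precision/recall of each reported result.
#' These two small tables carry those printed values.
#'
#' `benchmark_single_experiment()` holds the per-experiment, per-day
#' single-experiment SVM metrics (training and test sets); the `f1` column
#' is `NaN` where no positive prediction was made (undefined precision).
#' `benchmark_transfer_headlines()` holds the precision/recall/F1 triples of
#' four headline transfer results (the best direct-transfer SVM task, the
#' best TCA task, and the combined updating + TCA model at two days).
#'
#' @return A tibble.
#' @export
benchmark_single_experiment <- function() {
  path <- system.file("extdata", "benchmark_single_experiment.csv",
                      package = "spectransfer", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(dat = "character")))
}

#' @rdname benchmark_single_experiment
#' @export
benchmark_transfer_headlines <- function() {
  path <- system.file("extdata", "benchmark_transfer_headlines.csv",
                      package = "spectransfer", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
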