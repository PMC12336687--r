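#' Load the packaged extrusion case study
#'
#' Returns the in-package soy/wheat-gluten high-moisture extrusion study
#' that the package's worked examples and regression tests are built on: the
#' 15-run three-factor Box-Behnken design, the experimental scalarized
#' texture deviations from the chicken-breast reference computed with the
#' tensile-inclusive property subset (together with the published
#' response-surface and surrogate predictions at each run), and the
#' validation records measured at the predicted optima. Only the
#' tensile-inclusive response set is distributed; the compression/cutting-only
#' responses were never published at run level, so requesting that variant is
#' an error (its validation records are still available via
#' `validation_variant = "without_tensile"`).
#'
#' @param variant response-set variant; only `"with_tensile"` is available.
#' @param validation_variant which validation table to return.
#' @return List with elements `design` (bbd_design), `responses` (data frame
#'   `run`, `experimental`, `predicted_rsm`, `predicted_bo`), `dataset`
#'   (a [response_dataset()] of the experimental responses), and
#'   `validation` (data frame with condition columns, `experimental`,
#'   `model`, `predicted`, `error_pct_printed`).
#' @examples
#' cs <- load_case_study()
#' cs$dataset
#' @export
load_case_study <- function(variant = "with_tensile",
                            validation_variant = variant) {
  if (!identical(variant, "with_tensile"))
    stop("unknown variant '", variant, "': only the tensile-inclusive ",
         "response set is distributed at run level", call. = FALSE)
  ext <- function(f) system.file("extdata", f, package = "hmeopt",
                                 mustWork = TRUE)
  design <- read_design(ext("bbd_design.csv"))
  responses <- utils::read.csv(ext("responses_with_tensile.csv"))
  vfile <- switch(validation_variant,
                  with_tensile = "validation_with_tensile.csv",
                  without_tensile = "validation_without_tensile.csv",
                  stop("unknown validation variant '", validation_variant,
                       "'", call. = FALSE))
  validation <- utils::read.csv(vfile <- ext(vfile))
  list(design = design,
       responses = responses,
       dataset = response_dataset(design,
                                  data.frame(run = responses$run,
                                             response = responses$experimental)),
       validation = validation)
}
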