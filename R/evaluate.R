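#' Relative prediction error in percent
#'
#' \eqn{100\,|predicted - experimental| / experimental}. The experimental
#' value is the denominator -- the convention under which every validation
#' percentage in the packaged case study is an arithmetic identity of its
#' printed (predicted, experimental) pair.
#'
#' @param predicted numeric vector of model predictions.
#' @param experimental numeric vector of measured values, strictly positive.
#' @return Numeric vector of percentages.
#' @examples
#' prediction_error(5.67, 14.54)  # 61.0
#' @export
prediction_error <- function(predicted, experimental) {
  if (any(!is.finite(experimental)) || any(experimental <= 0))
    stop("invalid denominator: experimental values must be positive",
         call. = FALSE)
  100 * abs(predicted - experimental) / experimental
}

#' Side-by-side model validation report
#'
#' Tabulates validation records (one row per condition x model, with the
#' measured response and a model prediction), recomputes the percentage
#' error for each row, and summarizes min/max error per model, flagging the
#' model with the lowest worst-case error.
#'
#' @param records data frame with columns `model`, `experimental`,
#'   `predicted`, plus any condition columns carried through (e.g. `trial`,
#'   `bt_c`, ...).
#' @return An object of class `"validation_report"`: list with `records`
#'   (input plus `error_pct`), `summary` (per-model min/max/mean error and
#'   record count), `best_model` (lowest maximum error).
#' @examples
#' cs <- load_case_study()
#' build_comparison(cs$validation)
#' @export
build_comparison <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L)
    return(structure(list(records = records,
                          summary = data.frame(model = character(),
                                               n = integer(),
                                               min_error_pct = numeric(),
                                               max_error_pct = numeric(),
                                               mean_error_pct = numeric()),
                          best_model = NA_character_),
                     class = "validation_report"))
  need <- c("model", "experimental", "predicted")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("records lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  records$error_pct <- prediction_error(records$predicted,
                                        records$experimental)
  sm <- do.call(rbind, lapply(split(records, records$model), function(d)
    data.frame(model = d$model[1], n = nrow(d),
               min_error_pct = min(d$error_pct),
               max_error_pct = max(d$error_pct),
               mean_error_pct = mean(d$error_pct))))
  rownames(sm) <- NULL
  structure(list(records = records, summary = sm,
                 best_model = sm$model[which.min(sm$max_error_pct)]),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x$records) == 0L) {
    cat("Validation report: no records\n")
    return(invisible(x))
  }
  cat("Validation report (errors in % of the experimental value):\n")
  sm <- x$summary
  sm[, 3:5] <- round(sm[, 3:5], 2)
  print(sm, row.names = FALSE)
  cat(sprintf("Lowest worst-case error: %s\n", x$best_model))
  invisible(x)
}

#' @rdname build_comparison
#' @param report a `"validation_report"`.
#' @param path output file.
#' @export
write_comparison_csv <- function(report, path) {
  utils::write.csv(report$records, path, row.names = FALSE)
  invisible(path)
}
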