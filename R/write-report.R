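#' Write a result object to disk
#'
#' Serializes screening artifacts: `"json"` round-trips numeric content
#' losslessly (full double precision), `"csv"` writes tabular objects, and
#' `"text"` writes plain-text reports line by line.
#'
#' @param obj A tibble, `sembed_cfa`, `sembed_mi`, `sembed_report`, or any
#'   list of serializable pieces.
#' @param path Output path.
#' @param format One of `"json"`, `"csv"`, `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(obj, path, format = c("json", "csv", "text")) {
  if (!format[1] %in% c("json", "csv", "text")) {
    abort(paste0("unsupported format: ", format[1]))
  }
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report_payload(obj), path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null", pretty = TRUE)
  } else if (format == "csv") {
    if (!is.data.frame(obj)) abort("csv format needs a data frame")
    readr::write_csv(as.data.frame(obj), path, progress = FALSE)
  } else {
    if (inherits(obj, "sembed_report") || is.character(obj)) {
      writeLines(unclass(obj), path, useBytes = TRUE)
    } else {
      writeLines(utils::capture.output(print(obj)), path)
    }
  }
  invisible(path)
}

# flatten package objects into plain lists jsonlite can write faithfully
report_payload <- function(obj) {
  if (inherits(obj, "sembed_cfa")) {
    return(list(
      type = "cfa_fit",
      items = obj$model$item_ids,
      factors = obj$model$factor_ids,
      estimates = as.data.frame(tidy(obj)),
      f_ml = obj$f_ml, chisq = obj$chisq, df = obj$df,
      n_pseudo = obj$n_pseudo,
      baseline_chisq = obj$baseline_chisq, baseline_df = obj$baseline_df,
      cfi = obj$cfi, tli = obj$tli, srmr = obj$srmr, rmsea = obj$rmsea,
      converged = obj$converged, n_iter = obj$n_iter,
      grad_norm = obj$grad_norm, heywood = obj$heywood, ridge = obj$ridge
    ))
  }
  if (inherits(obj, "sembed_screen")) {
    df <- as.data.frame(obj[setdiff(names(obj), c("fit", "mi"))])
    mi <- lapply(obj$mi, function(m) if (is.null(m)) NULL else as.data.frame(m))
    return(list(type = "screen", results = df, modification_indices = mi))
  }
  if (inherits(obj, "sembed_verdict_agreement")) {
    return(list(
      type = "verdict_agreement",
      target_agreement = obj$target_agreement, n_reps = obj$n_reps,
      confusion = as.data.frame(obj$confusion),
      disagreement_rate = obj$disagreement_rate,
      sensitivity = obj$sensitivity, specificity = obj$specificity
    ))
  }
  if (is.data.frame(obj)) return(as.data.frame(obj))
  obj
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path Path to the JSON file.
#' @return A list mirroring the written payload.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
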