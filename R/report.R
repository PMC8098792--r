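# Report rendering shared by the R surface and the command-line script.

#' Render an analysis report
#'
#' Produces the two-block report (model terms with exponentiated effects
#' and CIs, then the RERI block) as text, or a machine-readable JSON
#' object with a provenance block recording reorientations and drop
#' counts.
#'
#' @param fit a `reri_fit` object.
#' @param format `"text"` or `"json"`.
#' @param file optional path; when missing the report is returned as a
#'   character string.
#' @param timestamp include a timestamp in the JSON provenance block
#'   (suppress for byte-identical reruns).
#' @return the rendered report, invisibly when written to `file`.
#' @export
reri_report <- function(fit, format = c("text", "json"), file = NULL,
                        timestamp = FALSE) {
  stopifnot(inherits(fit, "reri_fit"))
  format <- match.arg(format)
  if (format == "text") {
    out <- paste(utils::capture.output(print(fit)), collapse = "\n")
  } else {
    eff <- switch(as.character(fit$family), cox = "HR", binomial = "OR", "RR")
    obj <- list(
      factors = fit$factors,
      level = fit$level,
      terms = {
        ct <- coef_table(fit, digits = 10, eff = eff)
        names(ct)[4] <- "effect"
        ct$effect_measure <- eff
        ct
      },
      measures = fit$measures,
      grid = list(pattern = names(fit$grid$rr), rr = unname(fit$grid$rr)),
      provenance = c(list(source = fit$source,
                          n = fit$n, n_dropped = fit$n_dropped,
                          reoriented = as.list(fit$reoriented)),
                     if (timestamp) list(timestamp = format(Sys.time())) else NULL))
    out <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                            pretty = TRUE, dataframe = "rows")
  }
  if (!is.null(file)) {
    writeLines(as.character(out), file)
    return(invisible(out))
  }
  out
}

#' Render a simulation report
#'
#' @param report a `simulation_report` from [run_simulation_study()].
#' @inheritParams reri_report
#' @export
simulation_report_render <- function(report, format = c("text", "json"),
                                     file = NULL) {
  format <- match.arg(format)
  if (format == "text") {
    out <- paste(utils::capture.output(print(report)), collapse = "\n")
  } else {
    cfg <- attr(report, "config")
    obj <- list(results = as.data.frame(report),
                n_used = attr(report, "n_used"),
                n_dropped = attr(report, "n_dropped"),
                config = cfg[c("n_factors", "factors", "prevalence", "family",
                               "scheme", "baseline", "n_subjects",
                               "n_replicates", "seed")])
    out <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                            pretty = TRUE, dataframe = "rows")
  }
  if (!is.null(file)) {
    writeLines(as.character(out), file)
    return(invisible(out))
  }
  out
}
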