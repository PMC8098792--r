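# S3 methods for reri_fit objects.

#' @export
print.reri_fit <- function(x, digits = 2, ...) {
  n <- length(x$factors)
  eff <- switch(as.character(x$family),
                cox = "HR", binomial = "OR (~RR, rare outcome)", "RR")
  cat(sprintf("Multi-way additive interaction: %d factors (%s)\n",
              n, paste(x$factors, collapse = ", ")))
  if (!is.na(x$n)) {
    cat(sprintf("Estimated from %s records (%s pathway%s)\n",
                format(x$n, big.mark = ","), x$source,
                if (x$n_dropped > 0)
                  sprintf(", %d incomplete rows dropped", x$n_dropped) else ""))
  }
  if (!is.null(x$reoriented)) {
    cat("Reoriented protective factors:",
        paste(sprintf("%s -> %s", names(x$reoriented), x$reoriented),
              collapse = ", "), "\n")
  }
  cat("\nModel terms:\n")
  print(coef_table(x, digits = digits, eff = eff), row.names = FALSE)
  cat("\nRelative excess risk due to interaction:\n")
  m <- x$measures
  tab <- data.frame(measure = m$measure,
                    estimate = round(m$estimate, digits),
                    se = round(m$se, digits))
  if (any(!is.na(m$lower))) {
    tab[[sprintf("%g%% CI", 100 * x$level)]] <-
      ifelse(is.na(m$lower), "",
             sprintf("%.*f, %.*f", digits, m$lower, digits, m$upper))
  }
  print(tab, row.names = FALSE)
  invisible(x)
}

coef_table <- function(x, digits = 2, eff = "RR") {
  cs <- x$coefficients
  z <- stats::qnorm(1 - (1 - x$level) / 2)
  b <- cs$beta
  se <- if (!is.null(cs$vcov)) sqrt(diag(cs$vcov)) else rep(NA_real_, length(b))
  out <- data.frame(term = names(b), b = round(b, digits), se = round(se, digits))
  out[[eff]] <- round(exp(b), digits)
  if (!is.null(cs$vcov)) {
    out[[sprintf("%g%% CI", 100 * x$level)]] <-
      sprintf("%.*f, %.*f", digits, exp(b - z * se), digits, exp(b + z * se))
  }
  rownames(out) <- NULL
  out
}

#' Summarise a fitted multi-way interaction analysis
#'
#' Adds sign classification (super-/sub-/additive and whether the CI
#' excludes 0) to every RERI measure, reports the multiplicative
#' interaction index, and checks the decomposition identity (components sum
#' to the total RERI).
#'
#' @param object a `reri_fit`.
#' @param tolerance additive-classification tolerance, see [classify()].
#' @param ... unused.
#' @export
summary.reri_fit <- function(object, tolerance = 0, ...) {
  m <- object$measures
  cls <- vapply(object$measure_objects, function(mm) {
    if (grepl("^RERI|^TotRERI", mm$kind)) as.character(classify(mm, tolerance))
    else NA_character_
  }, character(1))
  excl <- vapply(object$measure_objects, function(mm) {
    if (grepl("^RERI|^TotRERI", mm$kind)) {
      e <- attr(classify(mm, tolerance), "ci_excludes_zero")
      if (is.null(e)) NA else e
    } else NA
  }, logical(1))
  m$classification <- cls
  m$ci_excludes_zero <- excl
  dec <- decompose(object$grid)
  mult <- multiplicative_index(object$grid)
  structure(list(fit = object, measures = m,
                 decomposition_total = attr(dec, "total"),
                 tot_reri = tot_reri(object$grid)$estimate,
                 mult_index = mult$estimate),
            class = "summary.reri_fit")
}

#' @export
print.summary.reri_fit <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("\nMultiplicative index I_%d: %s\n",
              length(x$fit$factors), format(round(x$mult_index, digits))))
  cat(sprintf("Decomposition check: components sum to %s (TotRERI = %s)\n",
              format(round(x$decomposition_total, digits)),
              format(round(x$tot_reri, digits))))
  cat("\nClassification:\n")
  print(x$measures[c("measure", "estimate", "classification", "ci_excludes_zero")],
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.reri_fit <- function(object, ...) object$coefficients$beta

#' @export
vcov.reri_fit <- function(object, ...) object$coefficients$vcov

#' @export
confint.reri_fit <- function(object, parm = c("measures", "coefficients"),
                             level = NULL, ...) {
  parm <- match.arg(parm)
  if (parm == "measures") {
    m <- object$measures
    out <- as.matrix(m[c("lower", "upper")])
    rownames(out) <- m$measure
    return(out)
  }
  cs <- object$coefficients
  if (is.null(cs$vcov)) .err("rerin_missing_variance", "no covariance matrix")
  if (is.null(level)) level <- object$level
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(cs$vcov))
  cbind(lower = cs$beta - z * se, upper = cs$beta + z * se)
}

#' Predicted relative risks for exposure patterns
#'
#' @param object a `reri_fit`.
#' @param patterns character vector of pattern strings (default: all).
#' @param level CI level (coefficient pathway only).
#' @param ... unused.
#' @return data frame of pattern, RR, and (when a covariance matrix is
#'   available) a log-scale Wald CI.
#' @export
predict.reri_fit <- function(object, patterns = names(object$grid$rr),
                             level = NULL, ...) {
  if (is.null(level)) level <- object$level
  n <- length(object$factors)
  for (p in patterns) validate_pattern(p, n)
  rr <- object$grid$rr[patterns]
  out <- data.frame(pattern = patterns, rr = unname(rr))
  if (!is.null(object$coefficients$vcov)) {
    lims <- t(vapply(patterns, function(p) {
      idx <- indices_from_pattern(p)
      if (!length(idx)) return(c(1, 1))
      m <- delta_ci(object$coefficients,
                    measure_spec("RR", object$factors[idx]), level)
      c(m$lower, m$upper)
    }, numeric(2)))
    out$lower <- lims[, 1]
    out$upper <- lims[, 2]
  }
  out
}

#' Forest-style plot of interaction measures
#'
#' @param x a `reri_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.reri_fit <- function(x, ...) {
  m <- x$measures
  k <- nrow(m)
  xlim <- range(c(0, m$estimate, m$lower, m$upper), na.rm = TRUE)
  graphics::plot(m$estimate, rev(seq_len(k)), xlim = xlim, ylim = c(0.5, k + 0.5),
                 pch = 19, yaxt = "n", xlab = "RERI", ylab = "",
                 main = "Additive-interaction measures", ...)
  if (any(!is.na(m$lower))) {
    graphics::segments(m$lower, rev(seq_len(k)), m$upper, rev(seq_len(k)))
  }
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = rev(seq_len(k)), labels = m$measure, las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

#' Simulate cohorts from a fitted interaction analysis
#'
#' Uses the fitted coefficients as the generating truth.  Exposure
#' prevalences are taken from the model data when available, otherwise
#' they must be supplied via `prevalence`.
#'
#' @param object a `reri_fit`.
#' @param nsim number of cohorts.
#' @param seed integer seed.
#' @param n_subjects cohort size (default: the fitted data size).
#' @param prevalence per-factor exposure prevalences.
#' @param ... passed to [scenario_config()].
#' @return a list of cohort data frames (length `nsim`).
#' @export
simulate.reri_fit <- function(object, nsim = 1, seed = 1, n_subjects = NULL,
                              prevalence = NULL, ...) {
  if (is.null(prevalence)) {
    if (is.null(object$model)) {
      .err("rerin_specification_error",
           "prevalence must be supplied when no model data are available")
    }
    mf <- stats::model.frame(object$model)
    prevalence <- vapply(object$factors, function(f) mean(mf[[f]]), numeric(1))
  }
  fam <- if (identical(object$family, "cox")) "cox" else "binomial"
  cfg <- scenario_config(n_factors = length(object$factors),
                         factors = object$factors,
                         prevalence = prevalence,
                         beta = object$coefficients$beta,
                         family = fam,
                         n_subjects = if (is.null(n_subjects)) object$n else n_subjects,
                         n_replicates = nsim, seed = seed, ...)
  lapply(seq_len(nsim), function(i) generate_cohort(cfg, i))
}

#' @export
residuals.reri_fit <- function(object, ...) {
  if (is.null(object$model)) {
    .err("rerin_specification_error",
         "residuals are only available for the model-fitting pathway")
  }
  stats::residuals(object$model, ...)
}
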