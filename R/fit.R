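# The modelling surface: one fitting function returning a classed object,
# plus constructors that reach the same class from exported coefficients or
# a contingency table.

#' Fit a saturated interaction model and compute all additive-interaction measures
#'
#' Fits a logistic or Cox proportional-hazards model containing *every*
#' product term among the binary exposures (a saturated exposure
#' parameterisation -- mandatory, since additive-interaction measures are
#' not computable when product terms are dropped), builds the implied
#' relative-risk grid, and computes all conditional lower-order RERIs, the
#' top-order RERI, and the total RERI, each with a delta-method standard
#' error and Wald confidence interval.
#'
#' @param formula model formula.  The exposures are taken from the
#'   highest-order interaction term (e.g. `y ~ A * B * C + age` makes `A`,
#'   `B`, `C` the exposures and `age` a covariate); with no interaction
#'   term every right-hand-side variable is treated as an exposure.  For
#'   `family = "cox"` the left-hand side must be a [survival::Surv()]
#'   object.  Whatever interaction terms the formula contains, the model is
#'   refitted with the full saturated set.
#' @param data data frame; rows with missing values in any used variable
#'   are dropped (complete-case analysis).
#' @param family `"binomial"` (logistic regression; exponentiated
#'   coefficients are odds ratios, which approximate relative risks for
#'   rare outcomes) or `"cox"` (proportional hazards, Efron ties).
#' @param level confidence level for all intervals.
#' @param reorient if `TRUE`, exposures flagged as protective (single-factor
#'   RR < 1) are recoded to their complement (`1 - x`, renamed with a
#'   `"no_"` prefix) and the model is refitted; if `FALSE` (default) a
#'   protective exposure is an error, because additive-interaction
#'   measures computed on it would be wrong.
#' @param strata which conditioning strata to report for lower-order
#'   RERIs: `"all"` (every assignment of the remaining factors, the
#'   worked-example layout) or `"absent"` (only the decomposition
#'   components).
#' @param exposures,covariates optional character vectors overriding the
#'   formula-derived split.
#'
#' @return An object of class `reri_fit`: a list with the saturated
#'   [coef_set()], the implied [rr_grid()], a `measures` data frame
#'   (estimate, se, CI per measure), the underlying fitted model, and
#'   bookkeeping fields.  Methods: [print.reri_fit()], [summary.reri_fit()],
#'   `coef`, `vcov`, `confint`, `predict`, `plot`, `simulate`, `residuals`.
#'
#' @examples
#' set.seed(1)
#' d <- data.frame(A = rbinom(5000, 1, 0.3), B = rbinom(5000, 1, 0.4))
#' p <- plogis(-2.2 + 0.5 * d$A + 0.4 * d$B + 0.3 * d$A * d$B)
#' d$y <- rbinom(5000, 1, p)
#' f <- reri(y ~ A * B, d, family = "binomial")
#' f
#' @export
reri <- function(formula, data, family = c("binomial", "cox"), level = 0.95,
                 reorient = FALSE, strata = c("all", "absent"),
                 exposures = NULL, covariates = NULL) {
  family <- match.arg(family)
  strata <- match.arg(strata)
  cl <- match.call()

  tt <- stats::terms(formula, data = data)
  labels <- attr(tt, "term.labels")
  order <- attr(tt, "order")
  if (is.null(exposures)) {
    exposures <- if (max(order) > 1L) {
      strsplit(labels[which.max(order)], ":", fixed = TRUE)[[1]]
    } else {
      labels
    }
  }
  rhs_vars <- unique(unlist(strsplit(labels[order == 1L], ":", fixed = TRUE)))
  if (is.null(covariates)) covariates <- setdiff(rhs_vars, exposures)

  resp <- formula[[2]]
  used_vars <- unique(c(all.vars(resp), exposures, covariates))
  missing_cols <- setdiff(used_vars, names(data))
  if (length(missing_cols)) {
    .err("rerin_column_error",
         paste0("column(s) not found in data: ", paste(missing_cols, collapse = ", ")))
  }

  fit_saturated_model(data, exposures = exposures, outcome = deparse(resp),
                      covariates = covariates, family = family, level = level,
                      reorient = reorient, strata = strata, call = cl)
}

#' Fit the saturated exposure model on cohort data
#'
#' Lower-level fitting entry point used by [reri()]: takes column names
#' rather than a formula.  For `family = "cox"`, `outcome` may be a
#' `Surv(time, event)` expression (as text) or `time`/`event` column names
#' may be given separately.
#'
#' @param data data frame of individual-level records.
#' @param exposures character vector of binary (0/1) exposure columns.
#' @param outcome outcome column (binomial) or a `Surv(...)` expression
#'   (cox).
#' @param time,event alternative way to name the survival columns.
#' @param covariates additional adjustment columns (kept out of the RR
#'   grid; the grid is covariate-conditional).
#' @inheritParams reri
#' @param call the call to record in the result.
#' @return a `reri_fit` object; see [reri()].
#' @export
fit_saturated_model <- function(data, exposures, outcome = NULL,
                                time = NULL, event = NULL,
                                covariates = character(0),
                                family = c("binomial", "cox"), level = 0.95,
                                reorient = FALSE, strata = c("all", "absent"),
                                call = sys.call()) {
  family <- match.arg(family)
  strata <- match.arg(strata)
  n <- length(exposures)
  if (n < 2L) .err("rerin_dimensionality_error", "need at least two exposures")
  if (n > 16L) .err("rerin_dimensionality_error", "at most 16 exposures supported")

  if (family == "cox" && !is.null(time)) {
    outcome <- sprintf("survival::Surv(%s, %s)", time, event)
  }
  if (is.null(outcome)) .err("rerin_column_error", "an outcome must be named")

  used <- unique(c(all.vars(stats::as.formula(paste("~", outcome))),
                   exposures, covariates))
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    .err("rerin_column_error",
         paste0("column(s) not found in data: ", paste(missing_cols, collapse = ", ")))
  }

  dat <- data[used]
  cc <- stats::complete.cases(dat)
  n_dropped <- sum(!cc)
  dat <- dat[cc, , drop = FALSE]

  for (e in exposures) {
    x <- dat[[e]]
    if (is.logical(x)) x <- as.integer(x)
    if (is.factor(x) && nlevels(x) == 2L) x <- as.integer(x) - 1L
    if (!is.numeric(x) || !all(x %in% c(0, 1))) {
      .err("rerin_type_error",
           sprintf("exposure '%s' is not binary 0/1", e))
    }
    dat[[e]] <- x
  }

  # every exposure pattern must be observed, with at least one event, for
  # the saturated model to be identifiable
  pat <- apply(dat[exposures], 1, paste, collapse = "")
  all_pats <- patterns_canonical(n)
  unseen <- setdiff(all_pats, unique(pat))
  if (length(unseen)) {
    .err("rerin_unidentifiable_cell", paste0(
      "no subjects observed in exposure pattern(s): ",
      paste(unseen, collapse = ", ")))
  }
  ev <- if (family == "binomial") dat[[outcome]] else {
    all.vars(stats::as.formula(paste("~", outcome)))  # time, event
  }
  if (family == "binomial") {
    if (!all(dat[[outcome]] %in% c(0, 1))) {
      .err("rerin_type_error", sprintf("outcome '%s' is not binary 0/1", outcome))
    }
    ev_by_pat <- tapply(dat[[outcome]], pat, sum)
  } else {
    event_col <- utils::tail(all.vars(stats::as.formula(paste("~", outcome))), 1)
    ev_by_pat <- tapply(dat[[event_col]], pat, sum)
  }
  no_events <- names(ev_by_pat)[ev_by_pat == 0]
  if (length(no_events)) {
    .err("rerin_unidentifiable_cell", paste0(
      "no events observed in exposure pattern(s): ",
      paste(no_events, collapse = ", "),
      "; the saturated model cannot estimate these cells"))
  }

  ff <- stats::as.formula(paste(
    outcome, "~", paste(exposures, collapse = " * "),
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""))

  fit <- if (family == "binomial") {
    stats::glm(ff, data = dat, family = stats::binomial())
  } else {
    survival::coxph(ff, data = dat, ties = "efron")
  }
  if (family == "binomial" && !fit$converged) {
    .err("rerin_fit_error", "logistic fit did not converge (possible separation)")
  }

  labs <- term_labels_canonical(exposures)
  cf <- stats::coef(fit)
  names(cf) <- normalize_terms(names(cf), exposures)
  if (!all(labs %in% names(cf)) || anyNA(cf[labs])) {
    .err("rerin_fit_error", "saturated exposure terms could not all be estimated")
  }
  if (any(abs(cf[labs]) > 15)) {
    .err("rerin_fit_error", paste0(
      "implausibly large coefficient(s) (|b| > 15) suggest separation: ",
      paste(labs[abs(cf[labs]) > 15], collapse = ", ")))
  }
  V <- stats::vcov(fit)
  dimnames(V) <- list(normalize_terms(rownames(V), exposures),
                      normalize_terms(colnames(V), exposures))
  cs <- coef_set(exposures, cf[labs], V[labs, labs])
  side <- cf[setdiff(names(cf), labs)]   # intercept + covariates

  grid <- rr_grid_from_coefficients(cs)
  flagged <- check_risk_orientation(grid)
  if (nrow(flagged)) {
    if (!reorient) {
      .err("rerin_protective_factor", paste0(
        "protective exposure(s) detected (single-factor RR < 1): ",
        paste(sprintf("%s (RR %.3f)", flagged$factor, flagged$rr), collapse = ", "),
        ". Additive-interaction measures would be wrong; recode or call with reorient = TRUE."))
    }
    message("reorienting protective exposure(s): ",
            paste(flagged$factor, collapse = ", "))
    for (f in flagged$factor) {
      newname <- if (startsWith(f, "no_")) sub("^no_", "", f) else paste0("no_", f)
      dat[[newname]] <- 1L - dat[[f]]
      exposures[exposures == f] <- newname
    }
    res <- fit_saturated_model(dat, exposures, outcome = outcome,
                               covariates = covariates, family = family,
                               level = level, reorient = FALSE, strata = strata,
                               call = call)
    res$reoriented <- stats::setNames(exposures[match(
      paste0("no_", flagged$factor), exposures)], flagged$factor)
    return(res)
  }

  build_reri_fit(cs, grid, level = level, strata = strata, family = family,
                 model = fit, side = side, n = nrow(dat), n_dropped = n_dropped,
                 source = "model", call = call)
}

# assemble the classed result shared by all pathways
build_reri_fit <- function(coefset, grid, level, strata = "all", family = NA,
                           model = NULL, side = NULL, n = NA_integer_,
                           n_dropped = 0L, source, call = NULL,
                           counts_grid = NULL) {
  has_var <- !is.null(coefset$vcov) || !is.null(attr(counts_grid, "logrr_vcov"))
  ms <- if (!is.null(counts_grid)) {
    specs <- measure_specs_for(grid$factors, strata)
    lapply(specs, function(sp) counts_delta_ci(counts_grid, sp, level))
  } else {
    interaction_measures(coefset, level = level, strata = strata)
  }
  measures <- do.call(rbind, lapply(ms, as.data.frame))
  structure(list(call = call, family = family, level = level,
                 factors = grid$factors, coefficients = coefset, grid = grid,
                 measures = measures, measure_objects = ms, model = model,
                 side_coefficients = side, n = n, n_dropped = n_dropped,
                 reoriented = NULL, source = source,
                 counts_grid = counts_grid),
            class = "reri_fit")
}

measure_specs_for <- function(factors, strata = c("all", "absent")) {
  strata <- match.arg(strata)
  n <- length(factors)
  specs <- list()
  if (n > 2L) {
    for (k in 2:(n - 1L)) {
      combos <- utils::combn(n, k, simplify = FALSE)
      n_rest <- n - k
      assigns <- if (strata == "absent") matrix(0, 1, n_rest) else {
        as.matrix(expand.grid(rep(list(0:1), n_rest)))
      }
      for (a in seq_len(nrow(assigns))) {
        for (S in combos) {
          rest <- setdiff(seq_len(n), S)
          z <- stats::setNames(as.numeric(assigns[a, ]), factors[rest])
          specs <- c(specs, list(measure_spec("RERI_conditional", factors[S], z)))
        }
      }
    }
  }
  c(specs, list(measure_spec("RERI_top"), measure_spec("TotRERI")))
}

#' Interaction measures from an exported coefficient set
#'
#' Builds the same fitted-object surface as [reri()] from a coefficient
#' vector (and optional covariance matrix) exported from a model fitted
#' elsewhere.
#'
#' @param beta a [coef_set()], or a named numeric vector of log
#'   coefficients (see [coef_set()] for naming).
#' @param vcov optional covariance matrix (ignored when `beta` is already a
#'   [coef_set()]).
#' @param factors factor names when `beta` is a bare vector.
#' @inheritParams reri
#' @return a `reri_fit` object.
#' @examples
#' b <- c(lowMD = 0.36, highBMI = 0.29, smoker = 0.41,
#'        "lowMD:highBMI" = -0.27, "lowMD:smoker" = -0.23,
#'        "highBMI:smoker" = -0.24, "lowMD:highBMI:smoker" = 0.92)
#' f <- reri_from_coefs(b, factors = c("lowMD", "highBMI", "smoker"))
#' f$measures
#' @export
reri_from_coefs <- function(beta, vcov = NULL, factors = NULL, level = 0.95,
                            strata = c("all", "absent")) {
  strata <- match.arg(strata)
  cs <- if (inherits(beta, "coef_set")) beta else {
    if (is.null(factors)) {
      if (is.null(names(beta))) {
        .err("rerin_naming_error", "factors must be given when beta is unnamed")
      }
      factors <- names(beta)[!grepl("[*:]", names(beta))]
    }
    coef_set(factors, beta, vcov)
  }
  grid <- rr_grid_from_coefficients(cs)
  flagged <- check_risk_orientation(grid)
  if (nrow(flagged)) {
    warning(paste0("protective factor(s) in coefficient set: ",
                   paste(flagged$factor, collapse = ", "),
                   "; additive-interaction measures may be misleading"),
            call. = FALSE)
  }
  build_reri_fit(cs, grid, level = level, strata = strata,
                 source = "coefficients", call = sys.call())
}

#' Interaction measures from a contingency table
#'
#' The model-free pathway: estimates the relative-risk grid and all
#' interaction measures (with delta-method intervals over the log RRs)
#' directly from per-pattern cases and denominators.
#'
#' @param table a [cohort_table()].
#' @inheritParams reri
#' @inheritParams rr_grid_from_counts
#' @return a `reri_fit` object.
#' @export
reri_from_counts <- function(table, level = 0.95, strata = c("all", "absent"),
                             correction = c("none", "add_half"),
                             effect = c("risk", "odds")) {
  strata <- match.arg(strata)
  grid <- rr_grid_from_counts(table, correction = correction, effect = effect)
  flagged <- check_risk_orientation(grid)
  if (nrow(flagged)) {
    warning(paste0("protective factor(s) in table: ",
                   paste(flagged$factor, collapse = ", "),
                   "; consider reorient()"), call. = FALSE)
  }
  bare <- rr_grid(grid$factors, grid$rr)
  cs <- coef_set(grid$factors,
                 stats::setNames(drop(qr.solve(incidence_matrix(length(grid$factors))[-1, ],
                                               log(grid$rr[-1]))),
                                 term_labels_canonical(grid$factors)))
  build_reri_fit(cs, bare, level = level, strata = strata, family = "counts",
                 n = sum(table$denominator), source = "counts",
                 call = sys.call(), counts_grid = grid)
}
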