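# Synthetic-cohort generator and replication harness: bias and CI coverage
# of all additive-interaction measures under known generating truth.

#' Describe a simulation scenario
#'
#' The default scenario emulates the structure of a mortality cohort of
#' three binary risk factors: exposure prevalences 0.34 / 0.39 / 0.19,
#' log-scale effects including all two- and three-way product terms, and a
#' rare outcome (roughly 8% events), analysed by Cox regression.  A
#' logistic mode is provided for speed: there the generating model is
#' logistic, so exponentiated coefficients are odds ratios and the measure
#' truth is computed on that same scale.
#'
#' @param n_factors number of binary exposures.
#' @param factors factor names.
#' @param prevalence per-factor exposure prevalence in (0, 1).
#' @param beta named log-scale coefficients for all \eqn{2^n - 1} exposure
#'   terms (see [coef_set()]); the generating truth.
#' @param family `"cox"` (exponential event times, Cox analysis) or
#'   `"binomial"` (binary outcome, logistic analysis).
#' @param scheme binary-outcome link: `"logistic"` (default;
#'   `P = plogis(qlogis(baseline) + lp)`) or `"log_binomial"`
#'   (`P = baseline * exp(lp)`, which errors when any pattern's risk
#'   exceeds 1).
#' @param baseline reference-pattern event probability (binomial) or
#'   baseline hazard per unit time (cox).  When `NULL` (default) it is
#'   calibrated so the marginal event fraction equals `target_events`.
#' @param target_events marginal event fraction used for calibration.
#' @param follow_up,dropout maximum follow-up time and the fraction of
#'   subjects with uniform early drop-out (cox only).
#' @param dependence optional correlation matrix for the latent Gaussian
#'   copula generating dependent exposures; `NULL` (default) draws
#'   exposures independently.
#' @param covariates include an age-like continuous and an education-like
#'   4-level categorical confounder.
#' @param covariate_effects list with elements `age` (log effect per year,
#'   centred) and `education` (4 log effects).
#' @param n_subjects,n_replicates,seed cohort size, number of replicates,
#'   and master seed (per-replicate substreams are derived by counter, so
#'   replicates are order-independent).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(n_factors = 3,
                            factors = NULL,
                            prevalence = NULL,
                            beta = NULL,
                            family = c("cox", "binomial"),
                            scheme = c("logistic", "log_binomial"),
                            baseline = NULL, target_events = 0.08,
                            follow_up = 15, dropout = 0,
                            dependence = NULL,
                            covariates = FALSE,
                            covariate_effects = list(age = 0.07,
                                                     education = c(0, -0.1, -0.2, -0.3)),
                            n_subjects = 15903, n_replicates = 500, seed = 1) {
  family <- match.arg(family)
  scheme <- match.arg(scheme)
  if (is.null(factors)) {
    factors <- if (n_factors == 3) c("lowMD", "highBMI", "smoker")
               else paste0("X", seq_len(n_factors))
  }
  if (is.null(prevalence)) {
    if (n_factors != 3) {
      .err("rerin_configuration_error",
           "default prevalences are defined for 3 factors; supply prevalence")
    }
    prevalence <- c(0.34, 0.39, 0.19)
  }
  stopifnot(length(factors) == n_factors, length(prevalence) == n_factors)
  if (any(prevalence <= 0 | prevalence >= 1)) {
    .err("rerin_configuration_error", "prevalences must lie in (0, 1)")
  }
  if (n_subjects < 1 || n_replicates < 1) {
    .err("rerin_configuration_error", "n_subjects and n_replicates must be >= 1")
  }
  if (is.null(beta)) {
    if (n_factors != 3) {
      .err("rerin_configuration_error",
           "default beta is defined for 3 factors; supply beta for other sizes")
    }
    beta <- stats::setNames(c(0.36, 0.29, 0.41, -0.27, -0.23, -0.24, 0.92),
                            term_labels_canonical(factors))
  }
  cs <- coef_set(factors, beta)
  if (!is.null(dependence)) {
    dependence <- as.matrix(dependence)
    stopifnot(nrow(dependence) == n_factors, isSymmetric(dependence))
  }
  cfg <- structure(list(n_factors = n_factors, factors = factors,
                        prevalence = prevalence, beta = cs$beta,
                        family = family, scheme = scheme,
                        baseline = baseline, target_events = target_events,
                        follow_up = follow_up, dropout = dropout,
                        dependence = dependence, covariates = covariates,
                        covariate_effects = covariate_effects,
                        n_subjects = as.integer(n_subjects),
                        n_replicates = as.integer(n_replicates),
                        seed = as.integer(seed)),
                   class = "scenario_config")
  if (is.null(cfg$baseline)) cfg$baseline <- calibrate_baseline(cfg)
  # validate log-binomial risks once baseline is known
  if (family == "binomial" && scheme == "log_binomial") {
    risks <- cfg$baseline * pattern_rr(cfg)
    if (any(risks > 1)) {
      .err("rerin_configuration_error", paste0(
        "log-binomial risk exceeds 1 for pattern(s): ",
        paste(names(risks)[risks > 1], collapse = ", ")))
    }
  }
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Simulation scenario: %d factors (%s), N = %s, %d replicate%s\n",
              x$n_factors, paste(x$factors, collapse = ", "),
              format(x$n_subjects, big.mark = ","), x$n_replicates,
              if (x$n_replicates > 1) "s" else ""))
  cat(sprintf("  family %s%s, baseline %.5g (target marginal events %.3g)\n",
              x$family, if (x$family == "binomial") paste0("/", x$scheme) else "",
              x$baseline, x$target_events))
  cat("  prevalences:", paste(format(x$prevalence), collapse = ", "), "\n")
  invisible(x)
}

# exp(linear predictor) for each pattern, canonical order
pattern_rr <- function(cfg) {
  M <- incidence_matrix(cfg$n_factors)
  stats::setNames(exp(drop(M %*% cfg$beta)), rownames(M))
}

# pattern probabilities: analytic under independence, fixed-seed Monte Carlo
# under the copula
pattern_probs <- function(cfg) {
  n <- cfg$n_factors
  pats <- patterns_canonical(n)
  if (is.null(cfg$dependence)) {
    pr <- vapply(pats, function(p) {
      bits <- as.integer(strsplit(p, "", fixed = TRUE)[[1]])
      prod(ifelse(bits == 1, cfg$prevalence, 1 - cfg$prevalence))
    }, numeric(1))
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(97531)
    X <- draw_exposures(cfg, 200000L)
    lab <- apply(X, 1, paste, collapse = "")
    pr <- vapply(pats, function(p) mean(lab == p), numeric(1))
  }
  stats::setNames(pr, pats)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# solve for the reference-level baseline giving the target marginal event rate
calibrate_baseline <- function(cfg) {
  pr <- pattern_probs(cfg)
  rr <- pattern_rr(cfg)
  target <- cfg$target_events
  if (cfg$family == "binomial") {
    if (cfg$scheme == "log_binomial") {
      f <- function(b) sum(pr * pmin(b * rr, 1)) - target
      return(stats::uniroot(f, c(1e-10, 1), tol = 1e-12)$root)
    }
    f <- function(lb) sum(pr * stats::plogis(lb + log(rr))) - target
    # log(rr) is the linear predictor; logistic truth treats beta as log odds ratios
    return(stats::plogis(stats::uniroot(f, c(-30, 10), tol = 1e-12)$root))
  }
  # cox: P(event) averaged over admin censoring at follow_up and uniform dropout
  tau <- cfg$follow_up
  d <- cfg$dropout
  p_event <- function(lam0) {
    mu <- lam0 * rr
    admin <- 1 - exp(-mu * tau)
    unif <- 1 - (1 - exp(-mu * tau)) / (mu * tau)
    sum(pr * ((1 - d) * admin + d * unif))
  }
  stats::uniroot(function(l) p_event(l) - target, c(1e-10, 100), tol = 1e-12)$root
}

draw_exposures <- function(cfg, N) {
  n <- cfg$n_factors
  if (is.null(cfg$dependence)) {
    X <- vapply(seq_len(n), function(i) stats::rbinom(N, 1L, cfg$prevalence[i]),
                integer(N))
  } else {
    L <- chol(cfg$dependence)
    Z <- matrix(stats::rnorm(N * n), N, n) %*% L
    X <- vapply(seq_len(n), function(i) {
      as.integer(Z[, i] < stats::qnorm(cfg$prevalence[i]))
    }, integer(N))
  }
  colnames(X) <- cfg$factors
  X
}

# per-replicate substream, exact in double arithmetic and below 2^31
replicate_seed <- function(seed, replicate) {
  as.integer(((seed %% 46340) * 46341 + replicate) %% 2147483647)
}

#' Generate one synthetic cohort
#'
#' Draws binary exposures (independent, or via the latent-Gaussian copula),
#' optional confounders, and outcomes from the scenario's generating model:
#' logistic or log-binomial event probabilities in binomial mode,
#' exponential event times with hazard `baseline * exp(lp)` under
#' administrative censoring (plus optional uniform drop-out) in Cox mode.
#' The master seed and the replicate index determine the stream: the same
#' pair always reproduces the same cohort, independent of generation order.
#'
#' @param config a [scenario_config()].
#' @param replicate replicate counter (>= 1).
#' @return data frame with one row per subject: exposure columns, optional
#'   `age`/`education`, and `y` (binomial) or `time`/`event` (cox).
#' @export
generate_cohort <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(replicate_seed(config$seed, replicate))
  N <- config$n_subjects
  X <- draw_exposures(config, N)
  M <- incidence_matrix(config$n_factors)
  pat <- apply(X, 1, paste, collapse = "")
  lp <- drop(M %*% config$beta)[pat]

  d <- as.data.frame(X)
  if (config$covariates) {
    d$age <- stats::rnorm(N, 53.4, 12.5)
    d$education <- factor(sample.int(4L, N, replace = TRUE,
                                     prob = c(0.26, 0.41, 0.18, 0.15)))
    lp <- lp + config$covariate_effects$age * (d$age - 53.4) +
      config$covariate_effects$education[as.integer(d$education)]
  }

  if (config$family == "binomial") {
    p <- if (config$scheme == "log_binomial") {
      r <- config$baseline * exp(lp)
      if (any(r > 1)) {
        .err("rerin_configuration_error", paste0(
          "log-binomial risk exceeds 1 for pattern(s): ",
          paste(unique(pat[r > 1]), collapse = ", ")))
      }
      r
    } else {
      stats::plogis(stats::qlogis(config$baseline) + lp)
    }
    d$y <- stats::rbinom(N, 1L, p)
  } else {
    t_event <- stats::rexp(N, rate = config$baseline * exp(lp))
    cens <- rep(config$follow_up, N)
    if (config$dropout > 0) {
      drop_out <- stats::runif(N) < config$dropout
      cens[drop_out] <- stats::runif(sum(drop_out), 0, config$follow_up)
    }
    d$time <- pmin(t_event, cens)
    d$event <- as.integer(t_event <= cens)
  }
  attr(d, "replicate") <- replicate
  d
}

#' True measure values implied by a scenario
#'
#' Evaluates every reported interaction measure on the grid implied by the
#' scenario's generating coefficients: the analytic truth the replication
#' harness compares against.
#'
#' @param config a [scenario_config()].
#' @param strata see [reri()].
#' @return named numeric vector of measure truths.
#' @export
simulation_truth <- function(config, strata = "all") {
  cs <- coef_set(config$factors, config$beta)
  specs <- measure_specs_for(config$factors, strata)
  ests <- vapply(specs, function(sp) measure_estimate(cs, sp), numeric(1))
  labs <- vapply(specs, function(sp) {
    S <- if (is.null(sp$subset)) config$factors else sp$subset
    kind <- if (sp$kind == "RERI_conditional" && length(S) == length(config$factors))
      "RERI_top" else sp$kind
    measure_label(interaction_measure(kind, S, sp$conditioning, estimate = 0))
  }, character(1))
  stats::setNames(ests, labs)
}

#' Run a bias / coverage simulation study
#'
#' For each replicate: generate a cohort, fit the saturated model, compute
#' every interaction measure with its delta-method confidence interval;
#' then aggregate, per measure, the bias against the analytic truth, the
#' empirical and mean model-based standard errors, and the CI coverage.
#' Replicates whose saturated model is unidentifiable (an empty or
#' event-free exposure cell) are dropped and counted; more than 20% dropped
#' aborts the scenario as infeasible.
#'
#' @param config a [scenario_config()].
#' @param level CI level.
#' @param strata see [reri()].
#' @param progress print a dot every 50 replicates.
#' @return a `simulation_report`: data frame with one row per measure
#'   (`truth`, `mean`, `bias`, `bias_mcse`, `empirical_se`, `mean_se`,
#'   `coverage`, `coverage_mcse`), with the configuration and drop count in
#'   attributes.
#' @export
run_simulation_study <- function(config, level = 0.95, strata = "all",
                                 progress = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  truth <- simulation_truth(config, strata)
  R <- config$n_replicates
  est <- se <- lo <- hi <- matrix(NA_real_, R, length(truth),
                                  dimnames = list(NULL, names(truth)))
  dropped <- 0L
  for (r in seq_len(R)) {
    d <- generate_cohort(config, r)
    fit <- tryCatch({
      if (config$family == "binomial") {
        fit_saturated_model(d, config$factors, outcome = "y",
                            covariates = if (config$covariates) c("age", "education") else character(0),
                            family = "binomial", level = level, strata = strata)
      } else {
        fit_saturated_model(d, config$factors, time = "time", event = "event",
                            covariates = if (config$covariates) c("age", "education") else character(0),
                            family = "cox", level = level, strata = strata)
      }
    }, rerin_error = function(e) NULL)
    if (is.null(fit)) {
      dropped <- dropped + 1L
      next
    }
    m <- fit$measures
    idx <- match(names(truth), m$measure)
    est[r, ] <- m$estimate[idx]
    se[r, ] <- m$se[idx]
    lo[r, ] <- m$lower[idx]
    hi[r, ] <- m$upper[idx]
    if (progress && r %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  if (dropped > 0.2 * R) {
    .err("rerin_scenario_infeasible", sprintf(
      "%d of %d replicates dropped (unidentifiable cells); scenario infeasible",
      dropped, R))
  }
  ok <- !is.na(est[, 1])
  K <- sum(ok)
  cover <- (lo <= matrix(truth, R, length(truth), byrow = TRUE)) &
           (hi >= matrix(truth, R, length(truth), byrow = TRUE))
  report <- data.frame(
    measure = names(truth),
    truth = unname(truth),
    mean = colMeans(est[ok, , drop = FALSE]),
    bias = colMeans(est[ok, , drop = FALSE]) - unname(truth),
    bias_mcse = apply(est[ok, , drop = FALSE], 2, stats::sd) / sqrt(K),
    empirical_se = apply(est[ok, , drop = FALSE], 2, stats::sd),
    mean_se = colMeans(se[ok, , drop = FALSE]),
    coverage = colMeans(cover[ok, , drop = FALSE]),
    stringsAsFactors = FALSE)
  report$coverage_mcse <- if (K > 1) {
    sqrt(report$coverage * (1 - report$coverage) / K)
  } else NA_real_
  rownames(report) <- NULL
  structure(report, class = c("simulation_report", "data.frame"),
            config = config, n_used = K, n_dropped = dropped, level = level)
}

#' @export
print.simulation_report <- function(x, digits = 3, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Simulation report: %d replicates used (%d dropped), N = %s, family %s\n",
              attr(x, "n_used"), attr(x, "n_dropped"),
              format(cfg$n_subjects, big.mark = ","), cfg$family))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Read a scenario description from a key = value text file
#'
#' Lines of the form `key = value`; vector values are comma-separated,
#' `beta` is given in canonical term order.  Unknown keys are an error.
#'
#' @param path file path.
#' @return a [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)))
  parse_val <- function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    if (!anyNA(nums)) nums else parts
  }
  args <- stats::setNames(lapply(vals, parse_val), keys)
  allowed <- setdiff(names(formals(scenario_config)), "covariate_effects")
  bad <- setdiff(names(args), allowed)
  if (length(bad)) {
    .err("rerin_configuration_error",
         paste0("unknown scenario key(s): ", paste(bad, collapse = ", ")))
  }
  do.call(scenario_config, args)
}
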