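# Model-free pathway: relative-risk grids and delta-method intervals
# straight from a 2^n contingency table of cases and denominators.

#' Construct a per-pattern cohort table
#'
#' One row per exposure pattern with the number of cases and the
#' denominator (number of subjects, or person-time at risk).
#'
#' @param factors character vector of factor names.
#' @param cases numeric vector of case counts, named by pattern strings or
#'   unnamed in canonical pattern order (all \eqn{2^n} patterns required).
#' @param denominator matching vector of subject counts or person-time.
#' @param denominator_kind `"subjects"` (cohort risks) or `"person_time"`
#'   (rates).
#' @return object of class `cohort_table`.
#' @export
cohort_table <- function(factors, cases, denominator,
                         denominator_kind = c("subjects", "person_time")) {
  denominator_kind <- match.arg(denominator_kind)
  n <- length(factors)
  pats <- patterns_canonical(n)
  align <- function(x, what) {
    if (is.null(names(x))) {
      if (length(x) != length(pats)) {
        .err("rerin_invalid_table", sprintf(
          "%s must cover all %d patterns (got %d)", what, length(pats), length(x)))
      }
      names(x) <- pats
    }
    missing <- setdiff(pats, names(x))
    if (length(missing)) {
      .err("rerin_invalid_table", paste0(
        what, " missing pattern(s): ", paste(missing, collapse = ", ")))
    }
    x[pats]
  }
  cases <- align(cases, "cases")
  denominator <- align(denominator, "denominator")
  if (any(cases < 0)) .err("rerin_invalid_table", "negative case counts")
  if (any(denominator <= 0)) {
    .err("rerin_invalid_table", "denominators must be strictly positive")
  }
  if (denominator_kind == "subjects" && any(cases > denominator)) {
    .err("rerin_invalid_table", "cases exceed subjects in some pattern")
  }
  if (cases[[1L]] < 1) {
    .err("rerin_invalid_table",
         "reference pattern has no cases; relative risks are undefined")
  }
  structure(list(factors = factors, cases = cases, denominator = denominator,
                 denominator_kind = denominator_kind),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort table: %d factors (%s), denominators are %s\n",
              length(x$factors), paste(x$factors, collapse = ", "),
              gsub("_", " ", x$denominator_kind)))
  print(data.frame(pattern = names(x$cases), cases = unname(x$cases),
                   denominator = unname(x$denominator)), row.names = FALSE)
  invisible(x)
}

#' Read a cohort table from delimited text
#'
#' Accepts either a `pattern` column (strings such as `"011"`) or one 0/1
#' indicator column per factor, plus `cases` and `denominator` columns.
#'
#' @param path file path (tab- or comma-delimited, header required).
#' @param factors factor names; required with a `pattern` column, inferred
#'   from the indicator columns otherwise.
#' @param denominator_kind passed to [cohort_table()].
#' @return a [cohort_table()].
#' @export
read_cohort_table <- function(path, factors = NULL,
                              denominator_kind = c("subjects", "person_time")) {
  denominator_kind <- match.arg(denominator_kind)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                         sep = if (grepl("\\.csv$", path)) "," else "\t")
  if (!all(c("cases", "denominator") %in% names(d))) {
    .err("rerin_io_error", "table needs 'cases' and 'denominator' columns")
  }
  d$cases <- as.numeric(d$cases)
  d$denominator <- as.numeric(d$denominator)
  if ("pattern" %in% names(d)) {
    pats <- d$pattern
    if (is.null(factors)) factors <- paste0("X", seq_len(nchar(pats[1])))
    if (any(nchar(pats) != length(factors))) {
      .err("rerin_io_error", "pattern strings do not match the number of factors")
    }
  } else {
    ind <- setdiff(names(d), c("cases", "denominator"))
    if (is.null(factors)) factors <- ind
    pats <- apply(d[factors], 1, paste, collapse = "")
  }
  cohort_table(factors, stats::setNames(d$cases, pats),
               stats::setNames(d$denominator, pats), denominator_kind)
}

#' Relative-risk grid and log-RR covariance from a cohort table
#'
#' Per-pattern risks (cases/denominator) or rates become relative risks
#' against the all-absent pattern.  Log-RR variances use the standard
#' large-sample forms: `1/a_p - 1/N_p + 1/a_0 - 1/N_0` for subject counts
#' and `1/a_p + 1/a_0` for person-time.  Cells are independent, but all log
#' RRs share the reference cell, so the covariance between two log RRs is
#' the reference-cell variance component; the returned covariance matrix
#' carries that term and feeds the downstream delta method.
#'
#' @param table a [cohort_table()].
#' @param correction `"none"` (default) or `"add_half"`: when any cell has
#'   zero cases, add 0.5 to every case count (and 1 to subject
#'   denominators) before estimation; always announced via a message.
#' @param effect `"risk"` (default) or `"odds"`: odds ratios support
#'   case-control-style input but approximate relative risks only for rare
#'   outcomes (a warning reminds of this).
#' @return an [rr_grid()] with attributes `logrr_vcov` (covariance matrix
#'   of the non-reference log RRs, canonical order) and `table`.
#' @examples
#' tab <- cohort_table(c("A", "B"), c("00" = 10, "10" = 20, "01" = 30, "11" = 60),
#'                     rep(100, 4))
#' g <- rr_grid_from_counts(tab)
#' reri2(g)  # 2
#' @export
rr_grid_from_counts <- function(table, correction = c("none", "add_half"),
                                effect = c("risk", "odds")) {
  stopifnot(inherits(table, "cohort_table"))
  correction <- match.arg(correction)
  effect <- match.arg(effect)
  a <- table$cases
  N <- table$denominator
  subjects <- table$denominator_kind == "subjects"
  if (effect == "odds" && !subjects) {
    .err("rerin_invalid_table", "odds ratios require subject-count denominators")
  }
  if (any(a == 0)) {
    if (correction == "add_half") {
      message("continuity correction applied: +0.5 to all case counts",
              if (subjects) " (+1 to denominators)" else "")
      a <- a + 0.5
      if (subjects) N <- N + 1
    } else {
      warning(paste0(
        "zero cases in pattern(s) ",
        paste(names(a)[a == 0], collapse = ", "),
        ": log-RR variance is infinite there; consider correction = \"add_half\""),
        call. = FALSE)
    }
  }
  if (effect == "odds") {
    warning("odds-ratio mode approximates relative risks for rare outcomes only",
            call. = FALSE)
    meas <- a / (N - a)
    vlog <- 1 / a + 1 / (N - a)
  } else if (subjects) {
    meas <- a / N
    vlog <- 1 / a - 1 / N
  } else {
    meas <- a / N
    vlog <- 1 / a
  }
  rr <- meas / meas[[1L]]
  grid <- rr_grid(table$factors, rr)
  nonref <- names(rr)[-1L]
  m <- length(nonref)
  V <- matrix(vlog[[1L]], m, m, dimnames = list(nonref, nonref))
  diag(V) <- vlog[nonref] + vlog[[1L]]
  attr(grid, "logrr_vcov") <- V
  attr(grid, "table") <- table
  attr(grid, "effect") <- effect
  grid
}

# Delta-method CI for a measure when the parameters are the non-reference
# log RRs (contingency pathway).  d RR_q / d l_q = RR_q, so the gradient of
# N/D in l-space is c_q RR_q / D - [q = p0] * estimate.
counts_delta_ci <- function(grid, spec, level = 0.95) {
  V <- attr(grid, "logrr_vcov")
  if (is.null(V)) {
    .err("rerin_missing_variance", "grid carries no log-RR covariance matrix")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  factors <- grid$factors
  n <- length(factors)
  S <- if (is.null(spec$subset)) seq_len(n) else resolve_subset(spec$subset, factors)
  nonref <- rownames(V)

  if (spec$kind %in% c("MultIndex", "RR")) {
    joint <- pattern_from_indices(S, n)
    x <- stats::setNames(numeric(length(nonref)), nonref)
    x[joint] <- 1
    if (spec$kind == "MultIndex") {
      for (i in S) x[pattern_from_indices(i, n)] <- x[pattern_from_indices(i, n)] - 1
    }
    est <- if (spec$kind == "MultIndex") {
      unname(multiplicative_index(grid, factors[S])$estimate)
    } else unname(grid$rr[[joint]])
    se_log <- sqrt(max(drop(t(x) %*% V %*% x), 0))
    return(interaction_measure(spec$kind, factors[S],
                               estimate = est, se = est * se_log,
                               lower = est * exp(-z * se_log),
                               upper = est * exp(z * se_log), level = level))
  }

  kind <- if (spec$kind %in% c("RERI_top", "TotRERI")) spec$kind
          else if (length(S) == n) "RERI_top" else "RERI_conditional"
  mc <- measure_coef(kind, factors, S, spec$conditioning)
  D <- if (is.null(mc$denom)) 1 else grid$rr[[mc$denom]]
  num <- sum(mc$c * grid$rr[names(mc$c)])
  est <- num / D
  g <- stats::setNames(numeric(length(nonref)), nonref)
  for (q in names(mc$c)) {
    if (q %in% nonref) g[q] <- g[q] + mc$c[[q]] * grid$rr[[q]] / D
  }
  if (!is.null(mc$denom) && mc$denom %in% nonref) {
    g[mc$denom] <- g[mc$denom] - est
  }
  se <- sqrt(max(drop(t(g) %*% V %*% g), 0))
  interaction_measure(kind, factors[S], spec$conditioning, estimate = est,
                      se = se, lower = est - z * se, upper = est + z * se,
                      level = level)
}
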