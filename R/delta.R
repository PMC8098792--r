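# Delta-method machinery: analytic gradients of every interaction measure
# with respect to the saturated model coefficients, and Wald intervals.
#
# With beta the 2^n - 1 term coefficients and X the pattern-by-term
# incidence matrix, RR(p) = exp(x_p' beta).  A RERI-type measure is
# N/D with N = sum_p c_p RR(p) and D = RR(p0) (D = 1 unconditionally), so
#   dN/dbeta_T = sum_p c_p RR(p) x_p[T],    dD/dbeta_T = D x_p0[T],
#   g = dN/D - (N/D) x_p0.
# The multiplicative index and single-pattern RRs are log-linear in beta and
# are handled on the log scale.

#' Describe one interaction measure for the delta method
#'
#' A light descriptor identifying an interaction measure (kind, interacting
#' subset, conditioning stratum) independently of any grid, used by
#' [measure_gradient()] and [delta_ci()].
#'
#' @param kind one of `"RERI_top"`, `"TotRERI"`, `"RERI_conditional"`,
#'   `"MultIndex"`, `"RR"`.
#' @param subset factor names interacting (for `"RR"`: the present factors
#'   of the pattern); `NULL` means all factors.
#' @param conditioning named 0/1 vector over the remaining factors
#'   (RERI_conditional only).
#' @return object of class `measure_spec`.
#' @export
measure_spec <- function(kind = c("RERI_top", "TotRERI", "RERI_conditional",
                                  "MultIndex", "RR"),
                         subset = NULL, conditioning = numeric(0)) {
  kind <- match.arg(kind)
  structure(list(kind = kind, subset = subset, conditioning = conditioning),
            class = "measure_spec")
}

# resolve a measure_spec against a coefficient set; returns evaluation pieces
.spec_pieces <- function(coefset, spec) {
  stopifnot(inherits(coefset, "coef_set"), inherits(spec, "measure_spec"))
  factors <- coefset$factors
  n <- length(factors)
  S <- if (is.null(spec$subset)) seq_len(n) else resolve_subset(spec$subset, factors)
  M <- incidence_matrix(n)
  rr <- exp(drop(M %*% coefset$beta))
  names(rr) <- rownames(M)
  list(factors = factors, n = n, S = S, M = M, rr = rr)
}

#' Point estimate of a measure from a coefficient set
#'
#' @param coefset a [coef_set()].
#' @param spec a [measure_spec()].
#' @return numeric estimate.
#' @export
measure_estimate <- function(coefset, spec) {
  p <- .spec_pieces(coefset, spec)
  if (spec$kind == "MultIndex") {
    subs <- subsets_canonical(p$n)
    s <- vapply(subs, function(t) all(t %in% p$S) && length(t) >= 2, logical(1))
    return(exp(sum(coefset$beta[s])))
  }
  if (spec$kind == "RR") {
    return(unname(p$rr[[pattern_from_indices(p$S, p$n)]]))
  }
  kind <- if (spec$kind %in% c("RERI_top", "TotRERI") ||
              length(p$S) == p$n) spec$kind else "RERI_conditional"
  if (kind == "RERI_top" || kind == "TotRERI") {
    if (length(p$S) != p$n) {
      .err("rerin_specification_error",
           "unconditional RERI/TotRERI cover all factors; use RERI_conditional for subsets")
    }
  }
  mc <- measure_coef(kind, p$factors, p$S, spec$conditioning)
  num <- sum(mc$c * p$rr[names(mc$c)])
  if (is.null(mc$denom)) unname(num) else unname(num / p$rr[[mc$denom]])
}

#' Analytic gradient of a measure with respect to the model coefficients
#'
#' First-order derivatives of the measure's point estimate with respect to
#' every saturated exposure coefficient, used for delta-method variance
#' propagation.  Agrees with central finite differences to first order.
#'
#' @inheritParams measure_estimate
#' @return named numeric vector over the \eqn{2^n - 1} terms.
#' @export
measure_gradient <- function(coefset, spec) {
  p <- .spec_pieces(coefset, spec)
  labs <- names(coefset$beta)
  if (spec$kind == "MultIndex") {
    subs <- subsets_canonical(p$n)
    s <- as.numeric(vapply(subs, function(t) all(t %in% p$S) && length(t) >= 2,
                           logical(1)))
    est <- exp(sum(coefset$beta * s))
    return(stats::setNames(est * s, labs))
  }
  if (spec$kind == "RR") {
    pat <- pattern_from_indices(p$S, p$n)
    x <- p$M[pat, ]
    return(stats::setNames(unname(p$rr[[pat]]) * x, labs))
  }
  kind <- if (spec$kind %in% c("RERI_top", "TotRERI")) spec$kind
          else if (length(p$S) == p$n) "RERI_top" else "RERI_conditional"
  mc <- measure_coef(kind, p$factors, p$S, spec$conditioning)
  cw <- mc$c * p$rr[names(mc$c)]                       # c_p RR(p)
  dN <- drop(crossprod(p$M[names(mc$c), , drop = FALSE], cw))
  N <- sum(cw)
  if (is.null(mc$denom)) {
    g <- dN
  } else {
    D <- p$rr[[mc$denom]]
    x0 <- p$M[mc$denom, ]
    g <- dN / D - (N / D) * x0
  }
  stats::setNames(unname(g), labs)
}

#' Delta-method standard error and Wald confidence interval
#'
#' Propagates the coefficient covariance matrix through the measure's
#' analytic gradient: `se = sqrt(g' V g)`.  RERI-type measures get a
#' symmetric Wald interval on the RERI scale; single-pattern RRs/HRs and
#' the multiplicative index are log-linear in the coefficients, so their
#' intervals are computed on the log scale and exponentiated.
#'
#' @inheritParams measure_estimate
#' @param level confidence level in (0, 1).
#' @return an [interaction_measure()] carrying `estimate`, `se`, and CI.
#' @export
delta_ci <- function(coefset, spec, level = 0.95) {
  stopifnot(inherits(coefset, "coef_set"), level > 0, level < 1)
  if (is.null(coefset$vcov)) {
    .err("rerin_missing_variance",
         "coefficient set has no covariance matrix; cannot compute standard errors")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  factors <- coefset$factors
  S <- if (is.null(spec$subset)) factors else spec$subset
  est <- measure_estimate(coefset, spec)

  if (spec$kind %in% c("MultIndex", "RR")) {
    # log-linear: work on the log scale
    idxS <- resolve_subset(S, factors)
    subs <- subsets_canonical(length(factors))
    x <- if (spec$kind == "MultIndex") {
      as.numeric(vapply(subs, function(t) all(t %in% idxS) && length(t) >= 2,
                        logical(1)))
    } else {
      as.numeric(vapply(subs, function(t) all(t %in% idxS), logical(1)))
    }
    v <- drop(t(x) %*% coefset$vcov %*% x)
    if (v < -1e-10) .err("rerin_numerical_variance", "negative variance quadratic form")
    se_log <- sqrt(max(v, 0))
    return(interaction_measure(spec$kind, S,
                               estimate = est, se = est * se_log,
                               lower = est * exp(-z * se_log),
                               upper = est * exp(z * se_log), level = level))
  }

  g <- measure_gradient(coefset, spec)
  v <- drop(t(g) %*% coefset$vcov %*% g)
  if (v < -1e-10) .err("rerin_numerical_variance", "negative variance quadratic form")
  se <- sqrt(max(v, 0))
  kind <- if (spec$kind %in% c("RERI_top", "TotRERI")) spec$kind
          else if (length(resolve_subset(S, factors)) == length(factors)) "RERI_top"
          else "RERI_conditional"
  interaction_measure(kind, S, spec$conditioning, estimate = est, se = se,
                      lower = est - z * se, upper = est + z * se, level = level)
}

# All Table-style measures for a coefficient set: conditional lower-order
# RERIs (every stratum when strata = "all", only all-absent strata when
# "absent"), then the top-order RERI and TotRERI.  With a vcov, each comes
# with delta-method se/CI.
interaction_measures <- function(coefset, level = 0.95,
                                 strata = c("all", "absent")) {
  strata <- match.arg(strata)
  factors <- coefset$factors
  n <- length(factors)
  specs <- list()
  if (n > 2L) {
    for (k in 2:(n - 1L)) {
      combos <- utils::combn(n, k, simplify = FALSE)
      rest_assigns <- function(rest) {
        if (strata == "absent") {
          list(stats::setNames(rep(0, length(rest)), factors[rest]))
        } else {
          grid <- expand.grid(rep(list(0:1), length(rest)))
          lapply(seq_len(nrow(grid)), function(i) {
            stats::setNames(as.numeric(grid[i, ]), factors[rest])
          })
        }
      }
      # enumerate absent strata first (Table-style ordering)
      assigns_by_S <- lapply(combos, function(S) rest_assigns(setdiff(seq_len(n), S)))
      n_assign <- length(assigns_by_S[[1]])
      for (a in seq_len(n_assign)) {
        for (j in seq_along(combos)) {
          z <- assigns_by_S[[j]][[a]]
          specs <- c(specs, list(measure_spec("RERI_conditional",
                                             factors[combos[[j]]], z)))
        }
      }
    }
  }
  specs <- c(specs, list(measure_spec("RERI_top"), measure_spec("TotRERI")))
  lapply(specs, function(sp) {
    if (is.null(coefset$vcov)) {
      S <- if (is.null(sp$subset)) factors else sp$subset
      kind <- if (sp$kind == "RERI_conditional" &&
                  length(S) == length(factors)) "RERI_top" else sp$kind
      interaction_measure(kind, S, sp$conditioning,
                          estimate = measure_estimate(coefset, sp), level = level)
    } else {
      delta_ci(coefset, sp, level = level)
    }
  })
}
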