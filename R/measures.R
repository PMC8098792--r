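# Additive-interaction measures as pure functions of a relative-risk grid.
#
# Every RERI-type measure is a signed sum of pattern RRs divided by a
# re-referencing RR:  estimate = sum_p c_p RR(p) / RR(p0).  The coefficient
# vector c and the denominator pattern p0 are built once per measure
# (measure_coef) and shared by the grid evaluators here and by the
# delta-method gradients in delta.R, so the two stay consistent by
# construction.

#' A single interaction measure
#'
#' Container for one computed interaction quantity: its kind, the factors
#' interacting, any conditioning stratum, the point estimate, and (when a
#' covariance pathway produced it) a standard error and Wald confidence
#' interval.
#'
#' @param kind one of `"RERI_conditional"`, `"RERI_top"`, `"TotRERI"`,
#'   `"MultIndex"`, `"RR"`.
#' @param subset character vector of the interacting factor names.
#' @param conditioning named 0/1 vector fixing the remaining factors (empty
#'   for unconditional measures).
#' @param estimate,se,lower,upper,level numeric scalars (`se`/CI optional).
#' @return object of class `interaction_measure`.
#' @export
interaction_measure <- function(kind, subset, conditioning = numeric(0),
                                estimate, se = NA_real_,
                                lower = NA_real_, upper = NA_real_,
                                level = 0.95) {
  if (grepl("^RERI", kind) && length(subset) < 2L) {
    .err("rerin_dimensionality_error",
         "RERI-type measures require at least two interacting factors")
  }
  if (length(conditioning) && any(names(conditioning) %in% subset)) {
    .err("rerin_specification_error",
         "conditioning factors must be disjoint from the interacting subset")
  }
  if (!is.na(lower) && !is.na(upper) &&
      (lower - estimate > 1e-8 || estimate - upper > 1e-8)) {
    .err("rerin_specification_error", "CI must bracket the estimate")
  }
  structure(list(kind = kind, subset = subset, conditioning = conditioning,
                 estimate = estimate, se = se, lower = lower, upper = upper,
                 level = level),
            class = "interaction_measure")
}

measure_label <- function(m) {
  k <- length(m$subset)
  base <- switch(m$kind,
    RERI_conditional = sprintf("RERI_%d", k),
    RERI_top         = sprintf("RERI_%d", k),
    TotRERI          = sprintf("TotRERI_%d", k),
    MultIndex        = sprintf("I_%d", k),
    RR               = "RR",
    m$kind)
  cond <- if (length(m$conditioning)) {
    paste0(" | ", paste(sprintf("%s=%d", names(m$conditioning),
                                as.integer(m$conditioning)), collapse = ", "))
  } else ""
  sprintf("%s(%s%s)", base, paste(m$subset, collapse = ", "), cond)
}

#' @export
print.interaction_measure <- function(x, digits = 4, ...) {
  cat(measure_label(x), "=", format(round(x$estimate, digits)))
  if (!is.na(x$se)) cat(sprintf("  (se %s)", format(round(x$se, digits))))
  if (!is.na(x$lower)) {
    cat(sprintf("  %g%% CI [%s, %s]", 100 * x$level,
                format(round(x$lower, digits)), format(round(x$upper, digits))))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.interaction_measure <- function(x, ...) {
  data.frame(measure = measure_label(x), kind = x$kind,
             estimate = x$estimate, se = x$se,
             lower = x$lower, upper = x$upper, level = x$level,
             stringsAsFactors = FALSE)
}

# ---- internal measure algebra ------------------------------------------------

# Resolve a subset given as names or indices to sorted indices.
resolve_subset <- function(subset, factors) {
  if (is.character(subset)) {
    idx <- match(subset, factors)
    if (anyNA(idx)) {
      .err("rerin_specification_error", paste0(
        "unknown factor(s): ", paste(subset[is.na(idx)], collapse = ", ")))
    }
  } else idx <- as.integer(subset)
  if (any(idx < 1) || any(idx > length(factors)) || anyDuplicated(idx)) {
    .err("rerin_specification_error", "invalid factor subset")
  }
  sort(idx)
}

# Coefficient vector c over patterns plus denominator pattern for one measure.
# `conditioning` is a named 0/1 vector over the factors outside `subset_idx`
# (names resolved against `factors`).
measure_coef <- function(kind, factors, subset_idx = seq_along(factors),
                         conditioning = numeric(0)) {
  n <- length(factors)
  c_pat <- numeric(0)
  denom <- NULL
  add <- function(cv, pattern, w) {
    cv[pattern] <- (if (pattern %in% names(cv)) cv[[pattern]] else 0) + w
    cv
  }
  if (kind == "TotRERI") {
    stopifnot(length(subset_idx) == n)
    c_pat <- add(c_pat, pattern_from_indices(seq_len(n), n), 1)
    for (i in seq_len(n)) c_pat <- add(c_pat, pattern_from_indices(i, n), -1)
    c_pat <- add(c_pat, strrep("0", n), n - 1)
  } else if (kind == "RERI_top") {
    stopifnot(length(subset_idx) == n)
    for (p in patterns_canonical(n)) {
      k <- length(indices_from_pattern(p))
      c_pat <- add(c_pat, p, (-1)^(n - k))
    }
  } else if (kind == "RERI_conditional") {
    S <- subset_idx
    rest <- setdiff(seq_len(n), S)
    z <- conditioning
    if (!setequal(names(z), factors[rest])) {
      .err("rerin_specification_error",
           "conditioning must assign 0/1 to exactly the factors outside the subset")
    }
    if (length(z) && any(!z %in% c(0, 1))) {
      .err("rerin_specification_error", "conditioning values must be 0 or 1")
    }
    base <- integer(n)
    base[match(names(z)[z == 1], factors)] <- 1L
    k <- length(S)
    for (j in 0:k) {
      for (s in (if (j == 0) list(integer(0)) else utils::combn(S, j, simplify = FALSE))) {
        bits <- base
        bits[s] <- 1L
        c_pat <- add(c_pat, paste(bits, collapse = ""), (-1)^(k - j))
      }
    }
    denom <- paste(base, collapse = "")
  } else {
    .err("rerin_specification_error", paste0("unknown measure kind: ", kind))
  }
  list(c = c_pat, denom = denom)
}

eval_measure <- function(grid, mc) {
  num <- sum(mc$c * grid$rr[names(mc$c)])
  if (is.null(mc$denom)) num else num / grid$rr[[mc$denom]]
}

# ---- exported measures -------------------------------------------------------

#' Two-way relative excess risk due to interaction
#'
#' For two binary risk factors, `RERI_2 = RR_11 - RR_10 - RR_01 + 1`:
#' positive values indicate super-additive joint effects, zero exact
#' additivity, negative sub-additive effects.
#'
#' @param grid an [rr_grid()] with exactly two factors.
#' @return an [interaction_measure()].
#' @examples
#' reri2(rr_grid(c("A", "B"), c("10" = 2, "01" = 3, "11" = 6)))  # 2
#' @export
reri2 <- function(grid) {
  stopifnot(inherits(grid, "rr_grid"))
  if (n_factors(grid) != 2L) {
    .err("rerin_dimensionality_error",
         "reri2() needs a 2-factor grid; use conditional_reri() or reri_top() for n > 2")
  }
  reri_top(grid)
}

#' Total relative excess risk due to interaction
#'
#' Contrasts the excess relative risk when all \eqn{n} factors act jointly
#' against the sum of each factor's individual excess relative risk:
#' `TotRERI_n = RR(all present) - sum_i RR(only i) + (n - 1)`.  It equals
#' the sum of the top-order interaction and all lower-order conditional
#' RERIs with the uninvolved factors absent (see [decompose()]).
#'
#' @param grid an [rr_grid()] with at least two factors.
#' @return an [interaction_measure()].
#' @export
tot_reri <- function(grid) {
  stopifnot(inherits(grid, "rr_grid"))
  n <- n_factors(grid)
  if (n < 2L) .err("rerin_dimensionality_error", "TotRERI needs n >= 2 factors")
  mc <- measure_coef("TotRERI", grid$factors)
  interaction_measure("TotRERI", grid$factors, estimate = eval_measure(grid, mc))
}

#' Top-order n-way relative excess risk due to interaction
#'
#' The \eqn{n}-way additive interaction net of all lower-order interactions:
#' the alternating inclusion--exclusion sum
#' \eqn{\sum_k (-1)^{n-k} \sum_{|pattern|=k} RR(pattern)} over all
#' \eqn{2^n} exposure patterns.  For \eqn{n = 2} this is the classical
#' RERI.
#'
#' @inheritParams tot_reri
#' @return an [interaction_measure()].
#' @export
reri_top <- function(grid) {
  stopifnot(inherits(grid, "rr_grid"))
  n <- n_factors(grid)
  if (n < 2L) .err("rerin_dimensionality_error", "RERI needs n >= 2 factors")
  mc <- measure_coef("RERI_top", grid$factors)
  interaction_measure("RERI_top", grid$factors, estimate = eval_measure(grid, mc))
}

#' Conditional lower-order RERI within a stratum
#'
#' The RERI of the factors in `subset`, computed within the stratum in which
#' the remaining factors are fixed by `conditioning`.  When a conditioning
#' factor is present, all RRs are re-referenced by dividing by the stratum's
#' baseline RR (the RR of the pattern with the subset absent and the
#' conditioning applied); with an all-absent conditioning this reduces to
#' the plain lower-order RERI.
#'
#' @param grid an [rr_grid()].
#' @param subset factor names (or indices) interacting; at least two.
#' @param conditioning named 0/1 vector over exactly the remaining factors
#'   (empty when `subset` covers all factors).
#' @return an [interaction_measure()].
#' @examples
#' g <- rr_grid(c("A", "B", "C"),
#'              c("100" = 2, "010" = 3, "001" = 1.5, "110" = 6,
#'                "101" = 3, "011" = 4.5, "111" = 9))
#' conditional_reri(g, c("A", "B"), c(C = 0))
#' conditional_reri(g, c("A", "B"), c(C = 1))
#' @export
conditional_reri <- function(grid, subset, conditioning = numeric(0)) {
  stopifnot(inherits(grid, "rr_grid"))
  S <- resolve_subset(subset, grid$factors)
  if (length(S) < 2L) {
    .err("rerin_dimensionality_error", "conditional RERI needs a subset of >= 2 factors")
  }
  kind <- if (length(S) == n_factors(grid)) "RERI_top" else "RERI_conditional"
  if (kind == "RERI_top" && length(conditioning)) {
    .err("rerin_specification_error", "no factors left to condition on")
  }
  mc <- measure_coef(if (kind == "RERI_top") "RERI_top" else "RERI_conditional",
                     grid$factors, S, conditioning)
  interaction_measure(kind, grid$factors[S], conditioning,
                      estimate = eval_measure(grid, mc))
}

#' Decompose the total RERI into interaction components
#'
#' Returns the top-order \eqn{n}-way RERI together with every lower-order
#' conditional RERI taken with the uninvolved factors absent.  These
#' components sum exactly to [tot_reri()]: the total departure from
#' additivity splits into the contribution of each factor combination.
#'
#' @inheritParams tot_reri
#' @return a list of [interaction_measure()] objects (class
#'   `reri_decomposition`), top-order first, with the component sum in
#'   attribute `"total"`.
#' @export
decompose <- function(grid) {
  stopifnot(inherits(grid, "rr_grid"))
  n <- n_factors(grid)
  if (n < 2L) .err("rerin_dimensionality_error", "decomposition needs n >= 2 factors")
  out <- list(reri_top(grid))
  if (n > 2L) {
    for (k in (n - 1L):2L) {
      for (S in utils::combn(n, k, simplify = FALSE)) {
        rest <- setdiff(seq_len(n), S)
        z <- stats::setNames(rep(0, length(rest)), grid$factors[rest])
        out <- c(out, list(conditional_reri(grid, S, z)))
      }
    }
  }
  structure(out, total = sum(vapply(out, `[[`, numeric(1), "estimate")),
            class = c("reri_decomposition", "list"))
}

#' @export
print.reri_decomposition <- function(x, digits = 4, ...) {
  for (m in x) print(m, digits = digits)
  cat(sprintf("Sum of components (= TotRERI): %s\n",
              format(round(attr(x, "total"), digits))))
  invisible(x)
}

#' Multiplicative interaction index
#'
#' The RR of the joint presence of the factors in `subset` (others absent)
#' divided by the product of their single-factor RRs; 1 means exactly
#' multiplicative joint effects.  For two factors this is the classical
#' index \eqn{I_2 = RR_{11} / (RR_{10} RR_{01})}; for larger subsets the
#' same ratio is the natural generalisation.
#'
#' @param grid an [rr_grid()].
#' @param subset factor names or indices, at least two; defaults to all.
#' @return an [interaction_measure()] of kind `"MultIndex"`.
#' @export
multiplicative_index <- function(grid, subset = grid$factors) {
  stopifnot(inherits(grid, "rr_grid"))
  S <- resolve_subset(subset, grid$factors)
  if (length(S) < 2L) {
    .err("rerin_dimensionality_error", "multiplicative index needs >= 2 factors")
  }
  n <- n_factors(grid)
  joint <- grid$rr[[pattern_from_indices(S, n)]]
  singles <- vapply(S, function(i) grid$rr[[pattern_from_indices(i, n)]], numeric(1))
  interaction_measure("MultIndex", grid$factors[S],
                      estimate = joint / prod(singles))
}

#' Classify a RERI measure by its sign
#'
#' Labels a RERI-type measure super-additive (estimate above `tolerance`),
#' sub-additive (below `-tolerance`) or additive, the default tolerance
#' being 0 so classification is by sign.  When a confidence interval is
#' attached the result also records whether the CI excludes 0.
#'
#' @param measure an [interaction_measure()] of a RERI kind.
#' @param tolerance non-negative numeric half-width treated as additive.
#' @return character label with attribute `ci_excludes_zero` (logical, `NA`
#'   when no CI is present).
#' @export
classify <- function(measure, tolerance = 0) {
  stopifnot(inherits(measure, "interaction_measure"), tolerance >= 0)
  if (!grepl("^RERI|^TotRERI", measure$kind)) {
    .err("rerin_kind_error",
         "classify() applies to RERI-type measures; the multiplicative index is compared to 1")
  }
  lab <- if (measure$estimate > tolerance) "super-additive"
         else if (measure$estimate < -tolerance) "sub-additive"
         else "additive"
  excl <- if (is.na(measure$lower) || is.na(measure$upper)) NA
          else (measure$lower > 0 || measure$upper < 0)
  structure(lab, ci_excludes_zero = excl)
}
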