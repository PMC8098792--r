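# Protective-factor detection and grid reorientation.
#
# Additive-interaction measures are only meaningful when every factor is a
# risk factor: a protective factor's RR lives in (0, 1) while a risk
# factor's lives in (1, Inf), and mixing the two breaks the additive
# contrast (two protective drugs with exactly additive effects would imply
# a negative joint RR).  Protective factors are therefore recoded to their
# risk-conferring complement before any RERI is computed.

#' Flag factors that look protective
#'
#' Returns every factor whose single-factor relative risk (that factor
#' present, all others absent) is below 1.  With `strict = TRUE` the
#' single-factor contrast is additionally checked within every stratum of
#' the remaining factors, and a warning is raised when a factor's direction
#' reverses across strata (qualitative interaction), in which case no
#' reorientation can make it uniformly risk-conferring.
#'
#' @param grid an [rr_grid()].
#' @param strict also check within-stratum contrasts.
#' @return data frame with columns `factor` and `rr` (the offending
#'   single-factor RR); zero rows when all factors are risk factors.
#' @examples
#' g <- rr_grid(c("drugA", "drugB"),
#'              c("10" = 0.25, "01" = 0.25, "11" = 0.1))
#' check_risk_orientation(g)
#' @export
check_risk_orientation <- function(grid, strict = FALSE) {
  stopifnot(inherits(grid, "rr_grid"))
  n <- n_factors(grid)
  single <- vapply(seq_len(n), function(i) grid$rr[[pattern_from_indices(i, n)]],
                   numeric(1))
  flagged <- which(single < 1)
  if (strict && n > 1L) {
    for (i in seq_len(n)) {
      rest <- setdiff(seq_len(n), i)
      dirs <- vapply(0:(2^length(rest) - 1L), function(code) {
        bits <- integer(n)
        bits[rest] <- as.integer(intToBits(code)[seq_along(rest)])
        with_i <- bits; with_i[i] <- 1L
        grid$rr[[paste(with_i, collapse = "")]] >= grid$rr[[paste(bits, collapse = "")]]
      }, logical(1))
      if (any(dirs) && !all(dirs)) {
        warning(sprintf(
          "factor '%s' changes direction across strata (qualitative interaction); reorientation cannot make it uniformly risk-conferring",
          grid$factors[i]), call. = FALSE)
      }
    }
  }
  data.frame(factor = grid$factors[flagged], rr = unname(single[flagged]),
             stringsAsFactors = FALSE)
}

#' Reorient protective factors in a grid
#'
#' Recodes each factor in `flip` to its complement (absence becomes the
#' exposure): every pattern has the corresponding bits inverted, the new
#' reference is the pattern that is all-absent after flipping, and every RR
#' is re-referenced by dividing by the old RR of that new reference.
#' Flipped factor names are toggled with a `"no_"` prefix so the recoded
#' meaning stays visible; flipping twice restores the original grid.
#'
#' @param grid an [rr_grid()].
#' @param flip factor names (or indices) to recode; empty is the identity.
#' @param rename toggle the `"no_"` prefix on flipped factor names.
#' @return a new [rr_grid()].
#' @examples
#' g <- rr_grid(c("drugA", "drugB"),
#'              c("10" = 0.25, "01" = 0.25, "11" = 0.1))
#' reorient(g, c("drugA", "drugB"))  # RRs 1, 2.5, 2.5, 10
#' @export
reorient <- function(grid, flip, rename = TRUE) {
  stopifnot(inherits(grid, "rr_grid"))
  if (!length(flip)) return(grid)
  n <- n_factors(grid)
  idx <- resolve_subset(flip, grid$factors)
  flip_bits <- integer(n)
  flip_bits[idx] <- 1L
  new_ref_old <- paste(flip_bits, collapse = "")   # old pattern that becomes reference
  ref_rr <- grid$rr[[new_ref_old]]
  old_pats <- names(grid$rr)
  new_pats <- vapply(old_pats, function(p) {
    bits <- as.integer(strsplit(p, "", fixed = TRUE)[[1]])
    bits[idx] <- 1L - bits[idx]
    paste(bits, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  new_rr <- stats::setNames(unname(grid$rr) / ref_rr, new_pats)
  new_factors <- grid$factors
  if (rename) {
    new_factors[idx] <- ifelse(startsWith(new_factors[idx], "no_"),
                               sub("^no_", "", new_factors[idx]),
                               paste0("no_", new_factors[idx]))
  }
  out <- rr_grid(new_factors, new_rr)
  still <- check_risk_orientation(out)
  if (nrow(still)) {
    warning(paste0(
      "after reorientation these factors still look protective: ",
      paste(still$factor, collapse = ", "),
      " (mixed orientation may be unavoidable)"), call. = FALSE)
  }
  out
}
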