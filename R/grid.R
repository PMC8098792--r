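#' Construct a relative-risk grid
#'
#' A relative-risk grid maps each of the \eqn{2^n} presence/absence patterns
#' of \eqn{n} binary factors to its relative risk (or rate/hazard/odds
#' ratio), referenced to the pattern in which every factor is absent.  All
#' additive-interaction measures in this package are pure functions of such
#' a grid.
#'
#' @param factors character vector of distinct factor names (1--16 factors).
#' @param rr numeric vector of relative risks.  Either named by pattern
#'   strings such as `"101"` (any order, the reference `"00...0"` may be
#'   omitted and is then implied to be 1), or unnamed and of length
#'   \eqn{2^n} in canonical pattern order (reference first, then patterns by
#'   increasing number of present factors).
#'
#' @return An object of class `rr_grid`: a list with elements `factors` and
#'   `rr` (named numeric vector over all \eqn{2^n} patterns, canonical
#'   order, reference value exactly 1).
#'
#' @details Every relative risk must be strictly positive; a protective or
#'   null *combination* is fine (RR in (0,1]), but see
#'   [check_risk_orientation()] for single factors whose RR is below 1,
#'   which invalidate additive-interaction measures until reoriented.
#'
#' @examples
#' g <- rr_grid(c("A", "B"), c("10" = 2, "01" = 3, "11" = 6))
#' reri2(g)
#' @seealso [reri2()], [tot_reri()], [reri_top()], [conditional_reri()],
#'   [decompose()], [multiplicative_index()]
#' @export
rr_grid <- function(factors, rr) {
  if (!is.character(factors) || length(factors) < 1L || length(factors) > 16L) {
    .err("rerin_naming_error", "between 1 and 16 factor names are required")
  }
  if (anyDuplicated(factors) || any(!nzchar(factors))) {
    .err("rerin_naming_error", "factor names must be distinct and non-empty")
  }
  n <- length(factors)
  pats <- patterns_canonical(n)
  ref <- pats[1L]
  if (!is.numeric(rr)) .err("rerin_invalid_risk", "rr must be numeric")

  if (is.null(names(rr))) {
    if (length(rr) != length(pats)) {
      .err("rerin_incomplete_grid", sprintf(
        "unnamed rr must have all %d entries in canonical order (got %d)",
        length(pats), length(rr)))
    }
    names(rr) <- pats
  } else {
    bad <- setdiff(names(rr), pats)
    if (length(bad)) {
      .err("rerin_incomplete_grid",
           paste0("unknown pattern name(s): ", paste(bad, collapse = ", ")))
    }
    if (anyDuplicated(names(rr))) {
      .err("rerin_incomplete_grid", "duplicated pattern names in rr")
    }
    if (!(ref %in% names(rr))) rr <- c(stats::setNames(1, ref), rr)
    missing <- setdiff(pats, names(rr))
    if (length(missing)) {
      .err("rerin_incomplete_grid", paste0(
        "incomplete grid: missing pattern(s) ", paste(missing, collapse = ", ")))
    }
    rr <- rr[pats]
  }
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    bad <- names(rr)[!is.finite(rr) | rr <= 0]
    .err("rerin_invalid_risk", paste0(
      "relative risks must be finite and > 0; offending pattern(s): ",
      paste(bad, collapse = ", ")))
  }
  if (abs(rr[[ref]] - 1) > 1e-12) {
    .err("rerin_invalid_risk", sprintf(
      "reference pattern %s must have RR = 1 (got %g)", ref, rr[[ref]]))
  }
  rr[[ref]] <- 1
  structure(list(factors = factors, rr = rr), class = "rr_grid")
}

n_factors <- function(grid) length(grid$factors)

# RR lookup with a classed error on unknown patterns
rr_of <- function(grid, pattern) {
  validate_pattern(pattern, n_factors(grid))
  grid$rr[[pattern]]
}

#' Excess relative risk of one exposure pattern
#'
#' The excess relative risk (ERR) is the relative risk minus 1: the risk
#' beyond the reference level, on the additive scale.
#'
#' @param grid an [rr_grid()].
#' @param pattern pattern string, e.g. `"110"`.
#' @return numeric ERR.
#' @examples
#' g <- rr_grid(c("A", "B"), c("10" = 2, "01" = 3, "11" = 6))
#' excess_rr(g, "11")  # 5
#' @export
excess_rr <- function(grid, pattern) {
  stopifnot(inherits(grid, "rr_grid"))
  rr_of(grid, pattern) - 1
}

#' @export
print.rr_grid <- function(x, digits = 4, ...) {
  n <- n_factors(x)
  cat(sprintf("Relative-risk grid: %d factor%s (%s), %d patterns\n",
              n, if (n > 1) "s" else "", paste(x$factors, collapse = ", "),
              length(x$rr)))
  print(data.frame(pattern = names(x$rr), rr = round(unname(x$rr), digits)),
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.rr_grid <- function(x, ...) {
  d <- data.frame(pattern = names(x$rr), rr = unname(x$rr),
                  stringsAsFactors = FALSE)
  bits <- do.call(rbind, strsplit(d$pattern, "", fixed = TRUE))
  bits <- apply(bits, 2, as.integer)
  if (is.null(dim(bits))) bits <- matrix(bits, ncol = n_factors(x))
  colnames(bits) <- x$factors
  cbind(d, as.data.frame(bits))
}

#' Read and write relative-risk grids
#'
#' Grids serialise to a tab-delimited text file whose first line carries the
#' factor names (`#factors<TAB>A<TAB>B...`), followed by a `pattern` /
#' `rr` header and one row per pattern; or to JSON with the same structure.
#'
#' @param grid an [rr_grid()].
#' @param path file path.
#' @param format `"tsv"` or `"json"`; inferred from the file extension when
#'   missing.
#' @return `read_rr_grid()` returns an [rr_grid()]; `write_rr_grid()`
#'   returns `path` invisibly.
#' @export
write_rr_grid <- function(grid, path, format = c("auto", "tsv", "json")) {
  stopifnot(inherits(grid, "rr_grid"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    jsonlite::write_json(list(factors = grid$factors, rr = as.list(grid$rr)),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("#factors", grid$factors), collapse = "\t"), con)
    writeLines("pattern\trr", con)
    writeLines(sprintf("%s\t%.17g", names(grid$rr), unname(grid$rr)), con)
  }
  invisible(path)
}

#' @rdname write_rr_grid
#' @export
read_rr_grid <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(rr_grid(obj$factors, unlist(obj$rr)))
  }
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#factors")) {
    .err("rerin_io_error", "grid file must start with a '#factors' line")
  }
  factors <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  body <- utils::read.delim(text = lines[-1], colClasses = c("character", "numeric"))
  rr_grid(factors, stats::setNames(body$rr, body$pattern))
}
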