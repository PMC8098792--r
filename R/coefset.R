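# Saturated exposure coefficient sets and their mapping to RR grids.

#' Construct a saturated coefficient set
#'
#' Holds log-scale model coefficients for a saturated exposure
#' parameterisation: one term per non-empty subset of the factors (main
#' effects for singletons, product terms for larger subsets), optionally
#' with a matching covariance matrix.  A saturated parameterisation is
#' required: additive-interaction measures cannot be computed when any
#' product term has been dropped from the model.
#'
#' @param factors character vector of factor names.
#' @param beta numeric vector of \eqn{2^n - 1} log coefficients, either
#'   named by term labels (`"A"`, `"A:B"`, `"A:B:C"`; `"*"` separators are
#'   accepted) or unnamed in canonical term order (singletons in factor
#'   order, then pairs, etc.).
#' @param vcov optional covariance matrix over the same terms, in the same
#'   order; must be symmetric (within 1e-8) with non-negative diagonal.
#' @return object of class `coef_set`.
#' @examples
#' cs <- coef_set(c("A", "B"), c(A = log(2), B = log(3), "A:B" = 0))
#' rr_grid_from_coefficients(cs)
#' @export
coef_set <- function(factors, beta, vcov = NULL) {
  if (anyDuplicated(factors)) .err("rerin_naming_error", "duplicate factor names")
  n <- length(factors)
  labs <- term_labels_canonical(factors)
  m <- length(labs)
  if (!is.null(names(beta))) {
    names(beta) <- normalize_terms(names(beta), factors)
    missing <- setdiff(labs, names(beta))
    if (length(missing)) {
      .err("rerin_incomplete_model", paste0(
        "saturated parameterisation requires every exposure term; missing: ",
        paste(missing, collapse = ", ")))
    }
    extra <- setdiff(names(beta), labs)
    if (length(extra)) {
      .err("rerin_incomplete_model",
           paste0("unknown term(s): ", paste(extra, collapse = ", ")))
    }
    beta <- beta[labs]
  } else if (length(beta) == m) {
    names(beta) <- labs
  } else {
    .err("rerin_incomplete_model", sprintf(
      "beta must have %d entries (2^%d - 1), got %d", m, n, length(beta)))
  }
  if (!is.null(vcov)) {
    vcov <- as.matrix(vcov)
    if (!all(dim(vcov) == m)) {
      .err("rerin_incomplete_model", "vcov dimension does not match beta")
    }
    if (max(abs(vcov - t(vcov))) > 1e-8) {
      .err("rerin_incomplete_model", "vcov is not symmetric")
    }
    if (any(diag(vcov) < 0)) {
      .err("rerin_incomplete_model", "vcov has negative diagonal entries")
    }
    vcov <- (vcov + t(vcov)) / 2
    dimnames(vcov) <- list(labs, labs)
  }
  structure(list(factors = factors, beta = beta, vcov = vcov),
            class = "coef_set")
}

# accept "A*B" or "A:B" (any factor order within a term) and canonicalise
normalize_terms <- function(terms, factors) {
  vapply(terms, function(t) {
    parts <- strsplit(t, "[*:]")[[1]]
    parts <- trimws(parts)
    idx <- match(parts, factors)
    if (anyNA(idx)) return(t)  # leave unknown; caught by caller
    paste(factors[sort(idx)], collapse = ":")
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.coef_set <- function(x, digits = 4, ...) {
  cat(sprintf("Saturated coefficient set: %d factors (%s), %d terms%s\n",
              length(x$factors), paste(x$factors, collapse = ", "),
              length(x$beta), if (is.null(x$vcov)) "" else ", with vcov"))
  print(round(x$beta, digits))
  invisible(x)
}

#' Relative-risk grid implied by a saturated coefficient set
#'
#' Exponentiates, for every exposure pattern, the sum of the coefficients of
#' all non-empty subsets of the pattern's present factors:
#' `RR(pattern) = exp(sum of beta over contained terms)`, with
#' `RR(all absent) = 1`.
#'
#' @param coefset a [coef_set()].
#' @return an [rr_grid()].
#' @export
rr_grid_from_coefficients <- function(coefset) {
  stopifnot(inherits(coefset, "coef_set"))
  n <- length(coefset$factors)
  M <- incidence_matrix(n)
  rr <- exp(drop(M %*% coefset$beta))
  rr_grid(coefset$factors, stats::setNames(rr, rownames(M)))
}

#' Read and write coefficient sets
#'
#' The coefficient file is tab-delimited with columns `term` (e.g. `"A"`,
#' `"A*B"`, `"A:B:C"`) and `estimate`; the optional covariance file is a
#' tab-delimited matrix with the same terms as header.  A JSON alternative
#' bundles both (`factors`, `beta`, `vcov`).
#'
#' @param coefset a [coef_set()].
#' @param path,coefs_file,vcov_file file paths.
#' @param factors optional factor names; inferred from the singleton terms
#'   (in order of appearance) when missing.
#' @return `read_coef_set()` returns a [coef_set()].
#' @export
write_coef_set <- function(coefset, path, vcov_file = NULL) {
  stopifnot(inherits(coefset, "coef_set"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(factors = coefset$factors, beta = as.list(coefset$beta))
    if (!is.null(coefset$vcov)) obj$vcov <- unname(apply(coefset$vcov, 1, as.list))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  utils::write.table(
    data.frame(term = names(coefset$beta), estimate = unname(coefset$beta)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(vcov_file) && !is.null(coefset$vcov)) {
    utils::write.table(coefset$vcov, vcov_file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' @rdname write_coef_set
#' @export
read_coef_set <- function(coefs_file, vcov_file = NULL, factors = NULL) {
  if (grepl("\\.json$", coefs_file, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(coefs_file, simplifyVector = TRUE)
    vc <- if (!is.null(obj$vcov)) do.call(rbind, lapply(obj$vcov, unlist)) else NULL
    return(coef_set(obj$factors, unlist(obj$beta), vc))
  }
  d <- utils::read.delim(coefs_file, stringsAsFactors = FALSE)
  if (!all(c("term", "estimate") %in% names(d))) {
    .err("rerin_io_error", "coefficient file needs columns 'term' and 'estimate'")
  }
  if (is.null(factors)) {
    factors <- d$term[!grepl("[*:]", d$term)]
  }
  beta <- stats::setNames(d$estimate, d$term)
  vc <- NULL
  if (!is.null(vcov_file)) {
    vc <- as.matrix(utils::read.delim(vcov_file, check.names = FALSE))
    labs <- normalize_terms(colnames(vc), factors)
    canon <- term_labels_canonical(factors)
    idx <- match(canon, labs)
    if (anyNA(idx)) {
      .err("rerin_io_error", "covariance matrix header does not cover all exposure terms")
    }
    vc <- vc[idx, idx, drop = FALSE]
  }
  coef_set(factors, beta, vc)
}
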