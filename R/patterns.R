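# Exposure-pattern bookkeeping.
#
# A pattern is a string of 0/1 characters, one per factor, aligned with the
# grid's factor order ("101" = first and third factors present).  The
# canonical enumeration is by increasing number of present factors, ties
# broken lexicographically on the index subsets, so that patterns line up
# with the canonical model-term order A, B, C, A:B, A:C, B:C, A:B:C.

# classed error helper so callers can test on condition class
.err <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "rerin_error")))
}

# all non-empty index subsets of 1..n, size ascending, lexicographic within size
subsets_canonical <- function(n) {
  out <- vector("list", 2L^n - 1L)
  i <- 0L
  for (k in seq_len(n)) {
    for (s in utils::combn(n, k, simplify = FALSE)) {
      i <- i + 1L
      out[[i]] <- s
    }
  }
  out
}

pattern_from_indices <- function(idx, n) {
  bits <- integer(n)
  bits[idx] <- 1L
  paste(bits, collapse = "")
}

indices_from_pattern <- function(pattern) {
  which(strsplit(pattern, "", fixed = TRUE)[[1]] == "1")
}

# all 2^n patterns in canonical order (reference first)
patterns_canonical <- function(n) {
  stopifnot(n >= 1, n <= 16)
  c(strrep("0", n),
    vapply(subsets_canonical(n), pattern_from_indices, character(1), n = n))
}

validate_pattern <- function(pattern, n) {
  if (!is.character(pattern) || length(pattern) != 1L ||
      nchar(pattern) != n || grepl("[^01]", pattern)) {
    .err("rerin_lookup_error",
         sprintf("'%s' is not a valid pattern of %d binary indicators", pattern, n))
  }
  pattern
}

# term label for an index subset, e.g. "A:B"
term_label <- function(idx, factors) paste(factors[idx], collapse = ":")

# canonical term labels for all 2^n - 1 non-empty subsets
term_labels_canonical <- function(factors) {
  n <- length(factors)
  vapply(subsets_canonical(n), term_label, character(1), factors = factors)
}

# incidence matrix over all 2^n patterns x (2^n - 1) terms:
# entry [p, T] is 1 iff subset T is contained in the present set of pattern p.
# log RR(pattern) = incidence %*% beta for a saturated parameterisation.
incidence_matrix <- function(n) {
  pats <- patterns_canonical(n)
  subs <- subsets_canonical(n)
  M <- matrix(0, nrow = length(pats), ncol = length(subs),
              dimnames = list(pats, NULL))
  for (j in seq_along(subs)) {
    for (i in seq_along(pats)) {
      present <- indices_from_pattern(pats[i])
      if (all(subs[[j]] %in% present)) M[i, j] <- 1
    }
  }
  M
}
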