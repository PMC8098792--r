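# Shared fixtures: the worked-example coefficient set and random-grid
# generators used by the property suites.

# printed Cox coefficients of the three-factor mortality example
table2_beta <- function() {
  stats::setNames(c(0.36, 0.29, 0.41, -0.27, -0.23, -0.24, 0.92),
                  c("lowMD", "highBMI", "smoker",
                    "lowMD:highBMI", "lowMD:smoker", "highBMI:smoker",
                    "lowMD:highBMI:smoker"))
}

table2_coefset <- function(vcov = NULL) {
  coef_set(c("lowMD", "highBMI", "smoker"), table2_beta(), vcov)
}

table2_grid <- function() rr_grid_from_coefficients(table2_coefset())

# random positive grid: log RRs drawn iid normal, reference fixed at 1
random_grid <- function(n, sd = 0.8) {
  pats <- c(strrep("0", n))
  rr <- exp(stats::rnorm(2^n - 1, 0, sd))
  g <- rr_grid(paste0("F", seq_len(n)),
               stats::setNames(c(1, rr), rerin:::patterns_canonical(n)))
  g
}

# exactly additive grid: RR(S) = 1 + sum of per-factor excesses
additive_grid <- function(e) {
  n <- length(e)
  pats <- rerin:::patterns_canonical(n)
  rr <- vapply(pats, function(p) {
    1 + sum(e[rerin:::indices_from_pattern(p)])
  }, numeric(1))
  rr_grid(paste0("F", seq_len(n)), rr)
}

# random coefficient set with a random PSD covariance matrix
random_coefset <- function(n, sd = 0.5) {
  m <- 2^n - 1
  A <- matrix(stats::rnorm(m * m, 0, 0.05), m, m)
  coef_set(paste0("F", seq_len(n)), stats::rnorm(m, 0, sd),
           crossprod(A) + diag(1e-4, m))
}

# independent central finite-difference gradient (oracle for the analytic one)
fd_gradient <- function(coefset, spec, h = 1e-6) {
  b <- coefset$beta
  vapply(seq_along(b), function(j) {
    bp <- b; bm <- b
    bp[j] <- bp[j] + h
    bm[j] <- bm[j] - h
    (measure_estimate(coef_set(coefset$factors, bp), spec) -
     measure_estimate(coef_set(coefset$factors, bm), spec)) / (2 * h)
  }, numeric(1))
}
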