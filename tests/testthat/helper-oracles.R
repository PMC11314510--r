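# Independent oracles used across the suite.

# Brute-force logistic MLE by coarse-to-fine grid search over the
# coefficient space. Independent of fit_logistic: evaluates the Bernoulli
# log-likelihood directly on a shrinking lattice.
grid_logistic_oracle <- function(y, X, resolution = 1e-3) {
  X <- cbind(intercept = 1, as.matrix(X))
  k <- ncol(X)
  loglik <- function(beta) {
    eta <- drop(X %*% beta)
    sum(y * eta - log1p(exp(eta)))
  }
  centers <- rep(0, k)
  half <- 6
  step <- 1
  repeat {
    grids <- lapply(seq_len(k), function(j)
      seq(centers[j] - half, centers[j] + half, by = step))
    pts <- as.matrix(expand.grid(grids))
    ll <- apply(pts, 1, loglik)
    centers <- as.numeric(pts[which.max(ll), ])
    if (step <= resolution / 2) break
    half <- 2 * step  # concave log-likelihood: optimum stays in this window
    step <- step / 5
  }
  stats::setNames(centers, colnames(X))
}

# Textbook Pearson chi-squared on a 2x2 table: sum (O - E)^2 / E.
chisq_textbook <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Small raw trait data frame with known structure, built in code.
toy_trait_data <- function() {
  data.frame(
    species = c("sp_a", "sp_b", "sp_c", "sp_d", "sp_e", "sp_f"),
    iucn_category = c("EN", "LC", "DD", "VU", "NT", "LC"),
    plant_sex = c("monoicous", "dioicous", "dioicous", "monoicous",
                  "dioicous", "monoicous"),
    sporophyte_presence = c(NA, "present", "present", NA, "present",
                            "present"),
    vegetative_reproduction = c(NA, "present", NA, NA, "present", NA),
    seta_length = c(NA, 14, 20, NA, 8, 27.32),
    substrate_breadth = c(1, 3, 2, 1, 2, 4),
    stringsAsFactors = FALSE
  )
}

# Expected counts from a binomial draw: tolerance of 3 Monte-Carlo SEs.
binom_band <- function(p, n, se_mult = 3) {
  se <- sqrt(p * (1 - p) / n)
  c(p - se_mult * se, p + se_mult * se)
}
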