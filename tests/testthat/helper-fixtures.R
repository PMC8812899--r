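# Shared fixtures and independent oracles used across test files.

# Build a valid summary_stats table; p-values recomputed from beta/se unless
# supplied, so fixtures never trigger the consistency warning.
make_stats <- function(snp_id, beta, se, eaf = 0.3, chrom = "1",
                       pos = seq_along(snp_id) * 1000 + 1e6,
                       ea = "A", nea = "G", n = 10000, pvalue = NULL,
                       trait_label = "fixture", trait_units = "SD") {
  if (is.null(pvalue)) pvalue <- 2 * pnorm(-abs(beta / se))
  summary_stats(data.frame(
    snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = rep_len(ea, length(snp_id)),
    other_allele = rep_len(nea, length(snp_id)),
    eaf = rep_len(eaf, length(snp_id)), beta = beta, se = se,
    pvalue = pmin(pmax(pvalue, 1e-300), 1), n = rep_len(n, length(snp_id)),
    stringsAsFactors = FALSE),
    trait_label = trait_label, trait_units = trait_units)
}

# Random PSD correlation matrix with weak-to-moderate off-diagonals.
random_corr <- function(j, scale = 0.3) {
  a <- matrix(rnorm(j * j), j)
  s <- crossprod(a) / j
  r <- stats::cov2cor(s)
  r <- scale * r + (1 - scale) * diag(j)
  dimnames(r) <- list(paste0("s", seq_len(j)), paste0("s", seq_len(j)))
  r
}

# Independent generalized-least-squares oracle for the correlated IVW model,
# by explicit matrix inversion (never the package's chol path).
gls_oracle <- function(bx, by, se_outcome, rho) {
  omega <- diag(se_outcome) %*% rho %*% diag(se_outcome)
  oi <- solve(omega)
  denom <- drop(t(bx) %*% oi %*% bx)
  theta <- drop(t(bx) %*% oi %*% by) / denom
  v <- 1 / denom
  j <- length(bx)
  resid <- by - theta * bx
  phi2 <- drop(t(resid) %*% oi %*% resid) / (j - 1)
  phi <- max(1, sqrt(phi2))
  list(theta = theta, se = sqrt(v) * phi, phi = phi)
}

# Textbook independent IVW: weighted least squares through the origin with
# weights 1/se_outcome^2.
independent_ivw_oracle <- function(bx, by, se_outcome) {
  w <- 1 / se_outcome^2
  theta <- sum(w * bx * by) / sum(w * bx^2)
  list(theta = theta, se_fixed = sqrt(1 / sum(w * bx^2)))
}

# Exhaustive enumeration of single-causal-variant configurations for the
# colocalization posteriors (trait-1 causal i, trait-2 causal j).
coloc_enum_oracle <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  bf1 <- exp(labf1)
  bf2 <- exp(labf2)
  m <- length(bf1)
  w <- c(H0 = 1, H1 = 0, H2 = 0, H3 = 0, H4 = 0)
  for (i in seq_len(m)) w["H1"] <- w["H1"] + p1 * bf1[i]
  for (j in seq_len(m)) w["H2"] <- w["H2"] + p2 * bf2[j]
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) w["H4"] <- w["H4"] + p12 * bf1[i] * bf2[j]
    else w["H3"] <- w["H3"] + p1 * p2 * bf1[i] * bf2[j]
  }
  w / sum(w)
}

# Exhaustive hypergeometric upper tail via binomial coefficients.
hyper_tail_oracle <- function(overlap, n_set, n_universe, n_hits) {
  t_max <- min(n_set, n_hits)
  if (overlap > t_max) return(0)
  sum(vapply(overlap:t_max, function(t) {
    choose(n_set, t) * choose(n_universe - n_set, n_hits - t)
  }, numeric(1))) / choose(n_universe, n_hits)
}

# Harmonized-pairs data frame from two aligned stats tables (test shortcut).
pairs_from <- function(bx, bxse, by, byse, ids = paste0("s", seq_along(bx))) {
  data.frame(snp_id = ids, beta_exposure = bx, se_exposure = bxse,
             beta_outcome = by, se_outcome = byse, stringsAsFactors = FALSE)
}

# Access the internal estimate constructor for formatting-level tests.
mr_estimate_for_test <- function(theta, se) ctmr:::mr_estimate(theta, se)
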