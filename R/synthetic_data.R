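# Synthetic genotype, cohort, regional and expression-panel generators with
# known ground truth, so every pipeline stage is testable without consortium
# downloads. Genotypes follow a Gaussian-copula model: a latent AR(1)
# multivariate normal is thresholded per variant at Hardy-Weinberg quantiles
# of its allele frequency, giving direct control of pairwise LD at desk scale
# (haplotype block structure is not modelled).

.snp_ids <- function(m) sprintf("snp_%02d", seq_len(m))

#' Study configuration for a simulated exposure-outcome cohort
#'
#' @param n cohort size.
#' @param m number of cis variants.
#' @param eafs per-variant effect-allele frequencies in (0, 1) (recycled).
#' @param ld_rho latent AR(1) correlation parameter in `[0, 1)`; adjacent
#'   variants have latent correlation `ld_rho`, decaying geometrically.
#' @param snp_effects per-variant joint effects on the exposure (recycled).
#' @param theta causal exposure-to-outcome effect on the log-odds scale.
#' @param case_fraction target proportion of cases in (0, 1).
#' @param seed integer seed; all generators are deterministic given it.
#' @return A `study_config` list.
#' @export
study_config <- function(n = 20000, m = 8, eafs = 0.3, ld_rho = 0.3,
                         snp_effects = 0.15, theta = 0.1,
                         case_fraction = 0.5, seed = 1) {
  eafs <- rep_len(eafs, m)
  snp_effects <- rep_len(snp_effects, m)
  stopifnot(all(eafs > 0 & eafs < 1), ld_rho >= 0, ld_rho < 1,
            case_fraction > 0, case_fraction < 1, n >= 10, m >= 1)
  structure(list(n = n, m = m, eafs = eafs, ld_rho = ld_rho,
                 snp_effects = snp_effects, theta = theta,
                 case_fraction = case_fraction, seed = as.integer(seed)),
            class = "study_config")
}

#' Simulate 0/1/2 genotype dosages with AR(1) linkage disequilibrium
#'
#' @param n number of individuals.
#' @param eafs per-variant effect-allele frequencies.
#' @param ld_rho latent AR(1) correlation parameter.
#' @param seed optional seed (`NULL` uses the current RNG state).
#' @return An `n x m` integer dosage matrix with variant ids as column names;
#'   marginal genotype frequencies follow Hardy-Weinberg proportions.
#' @export
simulate_genotypes_ld <- function(n, eafs, ld_rho = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(eafs)
  z <- matrix(stats::rnorm(n * m), n, m)
  if (ld_rho > 0 && m > 1) {
    sigma <- ld_rho^abs(outer(seq_len(m), seq_len(m), "-"))
    z <- z %*% chol(sigma)
  }
  p0 <- (1 - eafs)^2
  p1 <- 2 * eafs * (1 - eafs)
  t1 <- stats::qnorm(p0)
  t2 <- stats::qnorm(p0 + p1)
  g <- (sweep(z, 2, t1, ">") + sweep(z, 2, t2, ">"))
  storage.mode(g) <- "integer"
  colnames(g) <- .snp_ids(m)
  g
}

# Vectorized marginal simple-regression (with intercept) of y on each column
# of g; normal-approximation p-values, the GWAS convention.
.marginal_linear <- function(g, y) {
  n <- length(y)
  gc <- sweep(g, 2, colMeans(g))
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  beta <- colSums(gc * yc) / sxx
  rss <- sum(yc^2) - beta^2 * sxx
  se <- sqrt(rss / (n - 2) / sxx)
  list(beta = beta, se = se, p = .p_from_z(beta / se))
}

# Per-variant marginal logistic regression via glm.fit; unscaled covariance
# from the weighted QR at convergence.
.marginal_logistic <- function(g, y) {
  m <- ncol(g)
  beta <- se <- numeric(m)
  for (j in seq_len(m)) {
    x <- cbind(1, g[, j])
    fit <- suppressWarnings(
      stats::glm.fit(x, y, family = stats::binomial()))
    beta[j] <- fit$coefficients[2]
    cov <- chol2inv(qr.R(fit$qr))
    se[j] <- sqrt(cov[2, 2])
  }
  list(beta = beta, se = se, p = .p_from_z(beta / se))
}

.stats_table <- function(ids, pos, eaf, fit, n, trait_label, trait_units,
                         chrom = "1") {
  summary_stats(data.frame(
    snp_id = ids, chrom = chrom, pos = pos,
    effect_allele = "A", other_allele = "G",
    eaf = eaf, beta = fit$beta, se = fit$se,
    pvalue = pmin(pmax(fit$p, .Machine$double.xmin), 1), n = n,
    stringsAsFactors = FALSE),
    trait_label = trait_label, trait_units = trait_units)
}

#' Simulate an exposure GWAS and a case-control outcome GWAS
#'
#' The exposure is `X = G b + e` with the noise variance chosen so that
#' `Var(X) = 1`; case status follows a logistic model with log-odds
#' `alpha + theta X`, the intercept tuned by root-finding to hit the target
#' case fraction. Per-variant summary statistics are marginal regressions
#' (linear for the exposure, logistic for the outcome), matching what GWAS
#' consortia publish. By default the outcome GWAS uses the full simulated
#' cohort; `ascertain = TRUE` instead samples a balanced case-control subset
#' from a five-fold larger pool (for studying non-collapsibility under
#' outcome-dependent sampling).
#'
#' @param config a [study_config].
#' @param ascertain sample cases/controls rather than analysing the cohort.
#' @return List with `exposure` and `outcome` [summary_stats] tables, the
#'   empirical signed LD matrix `ld`, and `truth` (joint effects, implied
#'   marginal exposure effects, theta, intercept, case fraction realized).
#' @export
simulate_exposure_outcome_study <- function(config, ascertain = FALSE) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  n_pool <- if (ascertain) 5L * config$n else config$n
  g <- simulate_genotypes_ld(n_pool, config$eafs, config$ld_rho)
  gb <- drop(g %*% config$snp_effects)
  var_g <- stats::var(gb)
  if (var_g >= 1) stop("genetic variance exceeds 1; shrink snp_effects")
  x <- gb + stats::rnorm(n_pool, sd = sqrt(1 - var_g))
  alpha <- tryCatch(
    stats::uniroot(function(a) {
      mean(stats::plogis(a + config$theta * x)) - config$case_fraction
    }, c(-30, 30))$root,
    error = function(e) stop("case_fraction unreachable for this theta"))
  y <- stats::rbinom(n_pool, 1L, stats::plogis(alpha + config$theta * x))
  if (ascertain) {
    n_case <- round(config$case_fraction * config$n)
    cases <- which(y == 1L)
    controls <- which(y == 0L)
    if (length(cases) < n_case || length(controls) < config$n - n_case) {
      stop("case_fraction unreachable for this theta")
    }
    idx <- c(sample(cases, n_case), sample(controls, config$n - n_case))
    g <- g[idx, , drop = FALSE]
    x <- x[idx]
    y <- y[idx]
  }
  n <- nrow(g)
  pos <- 1e6 + (seq_len(config$m) - 1L) * 5000
  eaf_hat <- colMeans(g) / 2
  exposure <- .stats_table(colnames(g), pos, eaf_hat,
                           .marginal_linear(g, x), n,
                           "simulated exposure", "SD")
  outcome <- .stats_table(colnames(g), pos, eaf_hat,
                          .marginal_logistic(g, y), n,
                          "simulated outcome", "log-odds")
  ld <- if (config$m > 1) stats::cor(g) else matrix(1, 1, 1,
                                                    dimnames = list(colnames(g), colnames(g)))
  gc_ <- sweep(g, 2, colMeans(g))
  beta_marginal <- drop(crossprod(gc_, gc_ %*% config$snp_effects)) /
    colSums(gc_^2)
  truth <- list(snp_effects = config$snp_effects,
                beta_marginal = beta_marginal,
                theta = config$theta, alpha = alpha,
                case_fraction_realized = mean(y))
  list(exposure = exposure, outcome = outcome, ld = ld, truth = truth)
}

#' Simulate a pair of regional association profiles for colocalization tests
#'
#' Two independently drawn cohorts share the same variant panel. Scenarios:
#' `shared` — one causal variant drives both quantitative traits; `distinct`
#' — two causal variants, chosen far enough apart that their latent AR(1)
#' correlation is below 0.3, drive one trait each; `null` — no causal variant.
#'
#' @param scenario `"shared"`, `"distinct"` or `"null"`.
#' @param n_per_trait cohort size per trait (default 5000).
#' @param m number of variants in the region (>= 3 for `distinct`).
#' @param ld_rho latent AR(1) correlation parameter.
#' @param effect per-dosage causal effect size (trait SD units).
#' @param seed integer seed.
#' @param eafs optional frequencies (default drawn uniformly in 0.1-0.9).
#' @return List with `trait1`, `trait2` (regional [summary_stats]) and
#'   `truth` (causal indices per trait, or NA for null).
#' @export
simulate_coloc_region_pair <- function(scenario = c("shared", "distinct", "null"),
                                       n_per_trait = 5000, m = 50,
                                       ld_rho = 0.5, effect = 0.5, seed = 1,
                                       eafs = NULL) {
  scenario <- match.arg(scenario)
  if (scenario == "distinct" && m < 3L) stop("distinct scenario needs m >= 3")
  set.seed(seed)
  if (is.null(eafs)) eafs <- stats::runif(m, 0.1, 0.9)
  causal1 <- causal2 <- NA_integer_
  if (scenario == "shared") {
    causal1 <- causal2 <- sample.int(m, 1L)
  } else if (scenario == "distinct") {
    # Keep the two causal sites far enough apart for latent correlation < 0.3.
    min_gap <- if (ld_rho > 0) ceiling(log(0.3) / log(ld_rho)) else 1L
    if (min_gap >= m) min_gap <- m - 1L
    causal1 <- sample.int(m - min_gap, 1L)
    causal2 <- causal1 + min_gap
  }
  one_trait <- function(causal) {
    g <- simulate_genotypes_ld(n_per_trait, eafs, ld_rho)
    y <- stats::rnorm(n_per_trait)
    if (!is.na(causal)) y <- y + effect * g[, causal]
    .stats_table(colnames(g), 1e6 + (seq_len(m) - 1L) * 2000,
                 colMeans(g) / 2, .marginal_linear(g, y), n_per_trait,
                 "simulated regional trait", "SD")
  }
  list(trait1 = one_trait(causal1), trait2 = one_trait(causal2),
       truth = list(scenario = scenario, causal1 = causal1, causal2 = causal2))
}

# Rank-based inverse normal transform (Blom offset).
.inverse_normal <- function(x) {
  stats::qnorm((rank(x) - 3 / 8) / (length(x) + 1 / 4))
}

#' Simulate a genotype + expression panel driven by a weighted score
#'
#' Dosages come from [simulate_genotypes_ld]; the true score is the weighted
#' dosage sum, standardized. Each gene's expression is
#' `gene_effect * score + covariate contributions + noise`, with the noise
#' variance set so the pre-transform variance is 1, then inverse-normal
#' transformed per gene (so planted effects are approximately preserved for
#' Gaussian data).
#'
#' @param n number of samples (default 445).
#' @param weights per-variant score weights (length = number of variants).
#' @param gene_effects per-gene effect of the standardized score (length =
#'   number of genes; zero means a null gene).
#' @param n_covariates number of nuisance covariates (first is binary,
#'   remainder standard normal).
#' @param covariate_effects optional `n_covariates x n_genes` matrix (default
#'   modest effects drawn once from N(0, 0.2)).
#' @param eafs per-variant frequencies (default 0.3).
#' @param ld_rho latent AR(1) correlation (default 0.2).
#' @param seed integer seed.
#' @return An `expression_panel`: list with `dosage` (n x m), `expression`
#'   (n x G, inverse-normal transformed), `covariates` (n x C), and `truth`
#'   (standardized score, gene effects).
#' @export
simulate_expression_panel <- function(n = 445, weights, gene_effects,
                                      n_covariates = 4,
                                      covariate_effects = NULL,
                                      eafs = 0.3, ld_rho = 0.2, seed = 1) {
  set.seed(seed)
  m <- length(weights)
  eafs <- rep_len(eafs, m)
  g <- simulate_genotypes_ld(n, eafs, ld_rho)
  raw <- drop(g %*% weights)
  if (stats::sd(raw) == 0) stop("weighted score has zero variance")
  score <- as.vector(scale(raw))
  n_genes <- length(gene_effects)
  covars <- cbind(stats::rbinom(n, 1L, 0.5),
                  matrix(stats::rnorm(n * (n_covariates - 1L)), n))
  colnames(covars) <- paste0("cov", seq_len(n_covariates))
  if (is.null(covariate_effects)) {
    covariate_effects <- matrix(stats::rnorm(n_covariates * n_genes, sd = 0.2),
                                n_covariates, n_genes)
  }
  signal <- outer(score, gene_effects) + covars %*% covariate_effects
  noise_sd <- sqrt(pmax(1 - gene_effects^2 - colSums(covariate_effects^2), 0.05))
  expr <- signal + sweep(matrix(stats::rnorm(n * n_genes), n), 2, noise_sd, "*")
  expr <- apply(expr, 2, .inverse_normal)
  colnames(expr) <- sprintf("gene_%05d", seq_len(n_genes))
  structure(list(dosage = g, expression = expr, covariates = covars,
                 truth = list(score = score, gene_effects = gene_effects,
                              weights = weights)),
            class = "expression_panel")
}
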