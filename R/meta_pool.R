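# Fixed-effects pooling of two GWAS of the same trait, plus the
# direction-concordance filter used when building instruments.

# Two-sided normal p computed on the log scale so that |z| ~ 31 (p ~ 1e-213)
# and beyond do not underflow prematurely.
.p_from_z <- function(z) {
  p <- exp(log(2) + stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE))
  # clamp to the smallest normal double so p stays inside (0, 1]
  pmax(p, .Machine$double.xmin)
}

#' Pool two harmonized GWAS by inverse-variance weighted fixed effects
#'
#' Variants are matched on `snp_id`; both tables must already be aligned to
#' the same effect allele per variant (see [harmonize_pair]). Weights are
#' `1/se^2`; the pooled estimate is the weighted mean and the pooled standard
#' error `(sum w)^(-1/2)`, with a two-sided normal p-value. Sample sizes add.
#'
#' @param a,b [summary_stats] tables of the same trait.
#' @return A `pooled_stats` table (also a valid [summary_stats]) restricted to
#'   the shared variants, with extra columns `beta1`, `beta2`, `concordant`
#'   (same nonzero effect sign in both inputs).
#' @export
pool_fixed_effects <- function(a, b) {
  stopifnot(inherits(a, "summary_stats"), inherits(b, "summary_stats"))
  idx <- match(a$snp_id, b$snp_id)
  keep <- which(!is.na(idx))
  if (length(keep) == 0L) stop("no shared variants to pool")
  a <- a[keep, ]
  b <- b[idx[keep], ]
  mism <- a$effect_allele != b$effect_allele | a$other_allele != b$other_allele
  if (any(mism)) {
    stop("allele mismatch between inputs (harmonize first): ",
         paste(utils::head(a$snp_id[mism], 5L), collapse = ", "))
  }
  w1 <- 1 / a$se^2
  w2 <- 1 / b$se^2
  beta <- (w1 * a$beta + w2 * b$beta) / (w1 + w2)
  se <- 1 / sqrt(w1 + w2)
  eaf <- (w1 * a$eaf + w2 * b$eaf) / (w1 + w2)
  out <- data.frame(
    snp_id = a$snp_id, chrom = a$chrom, pos = a$pos,
    effect_allele = a$effect_allele, other_allele = a$other_allele,
    eaf = eaf, beta = beta, se = se,
    pvalue = .p_from_z(beta / se), n = a$n + b$n,
    beta1 = a$beta, beta2 = b$beta,
    concordant = sign(a$beta) == sign(b$beta) & a$beta != 0 & b$beta != 0,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out,
            trait_label = attr(a, "trait_label"),
            trait_units = attr(a, "trait_units"),
            class = c("pooled_stats", "summary_stats", "data.frame"))
}

#' Retain pooled variants with concordant direction and genome-wide significance
#'
#' @param pooled a `pooled_stats` table from [pool_fixed_effects].
#' @param gws_threshold significance threshold on the pooled p-value
#'   (default 5e-8). Retention requires `pvalue < gws_threshold` (strict) and
#'   the same nonzero effect sign in both contributing GWAS; a beta of exactly
#'   zero in either input fails the concordance test.
#' @return The retained subset (possibly empty), same class as `pooled`.
#' @export
concordance_filter <- function(pooled, gws_threshold = 5e-8) {
  stopifnot(inherits(pooled, "pooled_stats"))
  keep <- pooled$concordant & pooled$pvalue < gws_threshold
  out <- pooled[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
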