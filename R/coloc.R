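# Bayesian colocalization of two traits in a region via per-variant
# approximate Bayes factors and enumeration of causal configurations.

#' Extract the regional window around a top variant
#'
#' Retains variants whose position lies within `window_bp` of the top
#' variant's position (closed interval); the top variant is always included.
#'
#' @param stats a [summary_stats] table.
#' @param top_snp id of the anchoring variant (e.g. the instrument's lead SNP).
#' @param window_bp half-width of the window in base pairs (default 300000,
#'   i.e. +/-300 kb).
#' @return The regional subset with attributes `top_snp` and `bounds`.
#' @export
define_region <- function(stats, top_snp, window_bp = 3e5) {
  stopifnot(inherits(stats, "summary_stats"))
  hit <- which(stats$snp_id == top_snp)
  if (length(hit) == 0L) stop("top_snp not found in table: ", top_snp)
  center <- stats$pos[hit[1]]
  keep <- stats$chrom == stats$chrom[hit[1]] &
    abs(stats$pos - center) <= window_bp
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "top_snp") <- top_snp
  attr(out, "bounds") <- c(center - window_bp, center + window_bp)
  out
}

#' Wakefield-style log approximate Bayes factor
#'
#' With `V = se^2`, `W = prior_sd^2`, shrinkage `r = W / (V + W)` and
#' `z = beta / se`: `log ABF = 0.5 log(1 - r) + r z^2 / 2`. A zero prior SD
#' gives log ABF = 0 (point-null prior).
#'
#' @param beta estimated effect.
#' @param se its standard error (> 0).
#' @param prior_sd standard deviation of the effect-scale prior (typical
#'   defaults: 0.15 for quantitative traits, 0.20 for log-odds).
#' @return Vector of log approximate Bayes factors.
#' @export
log_abf <- function(beta, se, prior_sd) {
  stopifnot(all(se > 0), all(prior_sd >= 0))
  v <- se^2
  w <- prior_sd^2
  r <- w / (v + w)
  z <- beta / se
  0.5 * log1p(-r) + r * z^2 / 2
}

.logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, -Inf if the difference vanishes.
.logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Posterior probabilities of colocalization hypotheses H0-H4
#'
#' Enumerates single-causal-variant configurations over the variants shared by
#' the two traits. With per-variant prior probabilities `p1` (causal for trait
#' 1 only), `p2` (trait 2 only) and `p12` (shared causal variant), the
#' unnormalized hypothesis weights are `L0 = 1`, `L1 = p1 sum BF1`,
#' `L2 = p2 sum BF2`, `L3 = p1 p2 (sum BF1 sum BF2 - sum BF1 BF2)`,
#' `L4 = p12 sum BF1 BF2`, all computed in log space.
#'
#' @param trait1,trait2 regional [summary_stats] (see [define_region]) or data
#'   frames with `snp_id`, `beta`, `se`.
#' @param p1,p2,p12 per-variant prior probabilities (defaults 1e-4, 1e-4,
#'   1e-5, the conventional colocalization defaults).
#' @param prior_sd1,prior_sd2 effect-scale prior SDs; defaults chosen by
#'   `trait1_type`/`trait2_type` (0.15 quantitative, 0.20 case-control).
#' @param trait1_type,trait2_type `"quantitative"` or `"case_control"`.
#' @return A `coloc_result`: list with `pp` (named posterior vector H0..H4
#'   summing to 1), `priors`, `n_snps`, `snp_ids`, `labf1`, `labf2`.
#' @export
coloc_posteriors <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4,
                             p12 = 1e-5, prior_sd1 = NULL, prior_sd2 = NULL,
                             trait1_type = c("quantitative", "case_control"),
                             trait2_type = c("quantitative", "case_control")) {
  trait1_type <- match.arg(trait1_type)
  trait2_type <- match.arg(trait2_type)
  if (is.null(prior_sd1)) prior_sd1 <- if (trait1_type == "quantitative") 0.15 else 0.20
  if (is.null(prior_sd2)) prior_sd2 <- if (trait2_type == "quantitative") 0.15 else 0.20
  shared <- intersect(trait1$snp_id, trait2$snp_id)
  if (length(shared) == 0L) stop("traits share no variants in the region")
  n_only <- nrow(trait1) + nrow(trait2) - 2L * length(shared)
  if (n_only > 0L) {
    message(n_only, " variant(s) present in only one trait dropped")
  }
  i1 <- match(shared, trait1$snp_id)
  i2 <- match(shared, trait2$snp_id)
  l1 <- log_abf(trait1$beta[i1], trait1$se[i1], prior_sd1)
  l2 <- log_abf(trait2$beta[i2], trait2$se[i2], prior_sd2)
  ls1 <- .logsumexp(l1)
  ls2 <- .logsumexp(l2)
  ls12 <- .logsumexp(l1 + l2)
  logw <- c(
    H0 = 0,
    H1 = log(p1) + ls1,
    H2 = log(p2) + ls2,
    H3 = log(p1) + log(p2) + .logdiffexp(ls1 + ls2, ls12),
    H4 = log(p12) + ls12)
  pp <- exp(logw - .logsumexp(logw))
  pp <- pp / sum(pp)
  structure(list(pp = pp,
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 prior_sd = c(trait1 = prior_sd1, trait2 = prior_sd2),
                 n_snps = length(shared), snp_ids = shared,
                 labf1 = l1, labf2 = l2),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization over", x$n_snps, "shared variants\n")
  print(round(x$pp, 4))
  invisible(x)
}

#' Sensitivity of the shared-variant posterior to the p12 prior
#'
#' @inheritParams coloc_posteriors
#' @param p12_grid vector of shared-causal prior probabilities to sweep.
#' @return Data frame `p12`, `pp_h3`, `pp_h4`.
#' @export
coloc_prior_sensitivity <- function(trait1, trait2, p12_grid, p1 = 1e-4,
                                    p2 = 1e-4, ...) {
  rows <- lapply(p12_grid, function(p12) {
    res <- coloc_posteriors(trait1, trait2, p1 = p1, p2 = p2, p12 = p12, ...)
    data.frame(p12 = p12, pp_h3 = unname(res$pp["H3"]),
               pp_h4 = unname(res$pp["H4"]))
  })
  do.call(rbind, rows)
}
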