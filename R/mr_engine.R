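# Causal-effect estimation from harmonized summary data: Wald ratio,
# LD-adjusted IVW with a multiplicative random-effects dispersion floor,
# rescaling, leave-one-out, multivariable extension, multiplicity tiers.

.Z95 <- stats::qnorm(0.975)

# Inference uses the normal distribution throughout, the summary-MR
# convention for consortium-scale sample sizes.
mr_estimate <- function(theta, se_theta, phi = 1, j = 1L, method = "wald",
                        orientation = "per_unit_higher_exposure") {
  structure(list(theta = theta, se_theta = se_theta,
                 pvalue = .p_from_z(theta / se_theta),
                 odds_ratio = exp(theta),
                 ci_low = exp(theta - .Z95 * se_theta),
                 ci_high = exp(theta + .Z95 * se_theta),
                 phi = phi, j = as.integer(j), method = method,
                 orientation = orientation),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate (%s, j = %d, %s)\n", x$method, x$j, x$orientation))
  cat(sprintf("  theta = %.4g (SE %.4g), OR = %s, p = %.3g, phi = %.3g\n",
              x$theta, x$se_theta,
              format_or_ci(x$theta, x$se_theta), x$pvalue, x$phi))
  invisible(x)
}

# Accept a harmonized_pairs object or a bare data frame with the beta/se columns.
.as_pairs_df <- function(pairs) {
  if (inherits(pairs, "harmonized_pairs")) pairs <- pairs$pairs
  needed <- c("beta_exposure", "beta_outcome", "se_outcome")
  missing <- setdiff(needed, names(pairs))
  if (length(missing) > 0L) {
    stop("pairs lack column(s): ", paste(missing, collapse = ", "))
  }
  if (any(pairs$se_outcome <= 0)) stop("se_outcome must be > 0")
  if (!is.null(pairs$se_exposure) && any(pairs$se_exposure <= 0)) {
    stop("se_exposure must be > 0")
  }
  pairs
}

.orient <- function(est, orientation) {
  if (orientation == "per_unit_lower_exposure") {
    est <- mr_estimate(-est$theta, est$se_theta, est$phi, est$j, est$method,
                       orientation)
  }
  est
}

#' Single-variant Wald ratio estimate
#'
#' `theta = beta_outcome / beta_exposure` with first-order delta-method
#' standard error `se_outcome / |beta_exposure|`.
#'
#' @param pairs a single harmonized pair (one-row data frame or
#'   `harmonized_pairs` with one variant).
#' @param orientation `"per_unit_higher_exposure"` (internal default) or
#'   `"per_unit_lower_exposure"`, which negates theta at reporting to match
#'   the inhibition/trait-lowering framing.
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(pairs, orientation = "per_unit_higher_exposure") {
  pairs <- .as_pairs_df(pairs)
  stopifnot(nrow(pairs) == 1L)
  if (pairs$beta_exposure == 0) stop("undefined ratio: beta_exposure is 0")
  est <- mr_estimate(pairs$beta_outcome / pairs$beta_exposure,
                     pairs$se_outcome / abs(pairs$beta_exposure),
                     phi = 1, j = 1L, method = "wald")
  .orient(est, orientation)
}

# Weighting matrix Omega = D rho D with D = diag(outcome SEs).
.omega <- function(se_outcome, ld) {
  if (is.null(ld)) ld <- diag(length(se_outcome))
  if (nrow(ld) != length(se_outcome)) {
    stop("LD dimension does not match number of pairs")
  }
  ld * tcrossprod(se_outcome)
}

.solve_omega <- function(omega, x) {
  ch <- tryCatch(chol(omega), error = function(e) {
    stop("weighting matrix is singular after PSD repair")
  })
  backsolve(ch, backsolve(ch, x, transpose = TRUE))
}

#' Inverse-variance weighted estimate adjusted for correlated variants
#'
#' Generalized weighted regression of outcome on exposure associations through
#' the origin, with weighting matrix `Omega = D rho D` built from the outcome
#' standard errors `D` and the signed LD correlation matrix `rho`. The
#' residual dispersion is handled multiplicatively: `phi_hat^2` is the
#' Omega-weighted residual mean square on `j - 1` degrees of freedom, floored
#' at 1, so over-dispersion inflates the standard error while under-dispersion
#' leaves the fixed-effect standard error untouched. With identity LD this
#' reproduces the classical independent IVW estimator; with a single variant
#' it reduces to the Wald ratio.
#'
#' @param pairs harmonized pairs (see [harmonize_pair]) or a data frame with
#'   `beta_exposure`, `beta_outcome`, `se_outcome`.
#' @param ld signed correlation matrix aligned to `pairs` (r, not r-squared;
#'   signs matter materially). `NULL` means independent variants.
#' @inheritParams wald_ratio
#' @return An `mr_estimate` with `method = "ivw_correlated"` (or `"wald"` for
#'   a single variant).
#' @export
ivw_correlated <- function(pairs, ld = NULL,
                           orientation = "per_unit_higher_exposure") {
  pairs <- .as_pairs_df(pairs)
  j <- nrow(pairs)
  if (j == 0L) stop("no pairs supplied")
  if (j == 1L) return(wald_ratio(pairs, orientation))
  if (!is.null(ld) && !is.null(pairs$snp_id) && !is.null(rownames(ld))) {
    ld <- ld[pairs$snp_id, pairs$snp_id, drop = FALSE]
  }
  bx <- pairs$beta_exposure
  by <- pairs$beta_outcome
  omega <- .omega(pairs$se_outcome, ld)
  oi_bx <- .solve_omega(omega, bx)
  denom <- drop(crossprod(bx, oi_bx))
  theta <- drop(crossprod(by, oi_bx)) / denom
  v <- 1 / denom
  resid <- by - theta * bx
  phi2 <- drop(crossprod(resid, .solve_omega(omega, resid))) / (j - 1)
  phi <- max(1, sqrt(phi2))
  est <- mr_estimate(theta, sqrt(v) * phi, phi = phi, j = j,
                     method = "ivw_correlated")
  .orient(est, orientation)
}

#' Rescale a causal estimate to a larger exposure change
#'
#' Multiplies theta, its standard error and the CI bounds by `scale` on the
#' log-odds scale, e.g. converting a per-1-mm-Hg estimate to the 8-mm-Hg
#' blood-pressure lowering typical of clinical trials.
#'
#' @param estimate an `mr_estimate`.
#' @param scale positive exposure-unit multiple.
#' @return The rescaled `mr_estimate`.
#' @export
scale_odds_ratio <- function(estimate, scale) {
  stopifnot(inherits(estimate, "mr_estimate"), scale > 0)
  mr_estimate(estimate$theta * scale, estimate$se_theta * scale,
              phi = estimate$phi, j = estimate$j, method = estimate$method,
              orientation = estimate$orientation)
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the correlated IVW estimate `j` times, each time excluding one
#' variant (with the LD sub-matrix extracted consistently), to flag findings
#' driven by a single influential variant.
#'
#' @inheritParams ivw_correlated
#' @return A data frame with one row per excluded variant: `excluded_snp`,
#'   `theta`, `se_theta`, `odds_ratio`, `ci_low`, `ci_high`, `pvalue`, `phi`.
#' @export
leave_one_out <- function(pairs, ld = NULL,
                          orientation = "per_unit_higher_exposure") {
  pairs <- .as_pairs_df(pairs)
  j <- nrow(pairs)
  if (j < 2L) stop("nothing to leave out: need at least 2 variants")
  ids <- if (!is.null(pairs$snp_id)) pairs$snp_id else as.character(seq_len(j))
  rows <- lapply(seq_len(j), function(i) {
    sub_ld <- if (is.null(ld)) NULL else ld[-i, -i, drop = FALSE]
    est <- ivw_correlated(pairs[-i, , drop = FALSE], sub_ld, orientation)
    data.frame(excluded_snp = ids[i], theta = est$theta,
               se_theta = est$se_theta, odds_ratio = est$odds_ratio,
               ci_low = est$ci_low, ci_high = est$ci_high,
               pvalue = est$pvalue, phi = est$phi, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Multivariable MR with correlated variants
#'
#' Joint generalized-least-squares estimation of several exposures' effects
#' from the same variant set: `theta = (B' Omega^-1 B)^-1 B' Omega^-1 by`,
#' with per-exposure standard errors from the diagonal of
#' `(B' Omega^-1 B)^-1` scaled by the dispersion floor `phi = max(1, phi_hat)`
#' on `j - E` residual degrees of freedom.
#'
#' @param bx_matrix j x E matrix of per-variant exposure betas (columns are
#'   exposures; column names label the output).
#' @param by per-variant outcome betas.
#' @param se_outcome per-variant outcome standard errors.
#' @param ld signed LD correlation matrix (`NULL` = identity).
#' @return A data frame with one row per exposure: `exposure`, `theta`,
#'   `se_theta`, `odds_ratio`, `ci_low`, `ci_high`, `pvalue`; attributes
#'   `phi` and `j`.
#' @export
mvmr_correlated <- function(bx_matrix, by, se_outcome, ld = NULL) {
  bx_matrix <- as.matrix(bx_matrix)
  j <- nrow(bx_matrix)
  e <- ncol(bx_matrix)
  stopifnot(e >= 2L, length(by) == j, length(se_outcome) == j)
  if (j <= e) stop("need more variants than exposures (j > E)")
  if (qr(bx_matrix)$rank < e) stop("collinear exposures: bx_matrix is rank deficient")
  omega <- .omega(se_outcome, ld)
  oi_b <- .solve_omega(omega, bx_matrix)
  xtx <- crossprod(bx_matrix, oi_b)
  xtx_inv <- solve(xtx)
  theta <- drop(xtx_inv %*% crossprod(oi_b, by))
  resid <- by - drop(bx_matrix %*% theta)
  phi2 <- drop(crossprod(resid, .solve_omega(omega, resid))) / (j - e)
  phi <- max(1, sqrt(phi2))
  se <- sqrt(diag(xtx_inv)) * phi
  labels <- colnames(bx_matrix)
  if (is.null(labels)) labels <- paste0("exposure", seq_len(e))
  out <- data.frame(exposure = labels, theta = theta, se_theta = se,
                    odds_ratio = exp(theta),
                    ci_low = exp(theta - .Z95 * se),
                    ci_high = exp(theta + .Z95 * se),
                    pvalue = .p_from_z(theta / se),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "phi") <- phi
  attr(out, "j") <- j
  out
}

#' Assign evidence tiers under a Bonferroni family correction
#'
#' The strong-evidence threshold is `alpha / number of tests`; p-values between
#' that threshold and `weak_p` are labelled "weak", everything else "little".
#'
#' @param pvalues numeric vector of p-values.
#' @param labels optional test labels (default: names of `pvalues` or indices).
#' @param alpha family-wise error rate (default 0.05).
#' @param weak_p upper bound of the weak-evidence band (default 0.20).
#' @return A data frame `label`, `pvalue`, `tier` with attribute `threshold`.
#' @export
apply_multiplicity <- function(pvalues, labels = NULL, alpha = 0.05,
                               weak_p = 0.20) {
  stopifnot(length(pvalues) > 0L)
  if (is.null(labels)) {
    labels <- if (!is.null(names(pvalues))) names(pvalues)
              else as.character(seq_along(pvalues))
  }
  threshold <- alpha / length(pvalues)
  tier <- ifelse(pvalues < threshold, "strong",
                 ifelse(pvalues < weak_p, "weak", "little"))
  out <- data.frame(label = labels, pvalue = unname(pvalues), tier = tier,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  out
}

#' Format an estimate as "OR (low-high)" at two decimals
#'
#' @param theta log-odds effect.
#' @param se_theta its standard error.
#' @return Character string, e.g. `"1.13 (1.05–1.21)"`.
#' @export
format_or_ci <- function(theta, se_theta) {
  sprintf("%.2f (%.2f–%.2f)", exp(theta),
          exp(theta - .Z95 * se_theta), exp(theta + .Z95 * se_theta))
}
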