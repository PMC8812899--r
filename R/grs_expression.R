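# Weighted genetic risk scores, transcriptome-wide association scans against
# the score with covariate adjustment, and gene-set over-representation.

#' Build a weighted genetic risk score
#'
#' `score_i = sum_j w_j dosage_ij`. Missing dosages are mean-imputed per
#' variant before scoring.
#'
#' @param dosage samples x variants dosage matrix (values in `[0, 2]`) with
#'   variant ids as column names.
#' @param weights per-allele effect weights, named by variant id (or in
#'   `dosage` column order if unnamed); at least one must be nonzero for a
#'   standardized score.
#' @param standardize center and scale the score to unit SD (default TRUE),
#'   matching the convention of regressing expression on the standardized
#'   score.
#' @return Numeric per-sample score vector.
#' @export
build_wgrs <- function(dosage, weights, standardize = TRUE) {
  dosage <- as.matrix(dosage)
  if (!is.null(names(weights))) {
    missing <- setdiff(names(weights), colnames(dosage))
    if (length(missing) > 0L) {
      stop("weight variant(s) absent from dosage matrix: ",
           paste(missing, collapse = ", "))
    }
    dosage <- dosage[, names(weights), drop = FALSE]
  } else if (length(weights) != ncol(dosage)) {
    stop("unnamed weights must match the dosage column count")
  }
  if (anyNA(dosage)) {
    for (j in which(colSums(is.na(dosage)) > 0L)) {
      nas <- is.na(dosage[, j])
      dosage[nas, j] <- mean(dosage[, j], na.rm = TRUE)
    }
  }
  score <- drop(dosage %*% weights)
  if (standardize) {
    if (stats::sd(score) == 0) stop("raw score has zero variance; cannot standardize")
    score <- as.vector(scale(score))
  }
  score
}

#' Transcriptome-wide association scan of expression on a genetic score
#'
#' Fits, per gene, an ordinary least-squares regression of expression on the
#' score plus covariates, and reports the score coefficient (per SD of score
#' when the score is standardized), its standard error, a two-sided p-value
#' (t-distribution on the residual degrees of freedom), and a Bonferroni
#' significance flag at `alpha / G`.
#'
#' @param expression samples x genes matrix (e.g. inverse-normal transformed
#'   abundances).
#' @param score per-sample genetic score (see [build_wgrs]).
#' @param covariates optional samples x C matrix of adjustment covariates
#'   (sex, ancestry PCs, batch, hidden expression factors, ...). Must be full
#'   rank together with the intercept and score.
#' @param alpha family-wise error rate for the Bonferroni flag (default 0.05).
#' @return A `twas_result` data frame: `gene`, `beta`, `se`, `pvalue`,
#'   `significant`; attribute `threshold = alpha / G`.
#' @export
twas_scan <- function(expression, score, covariates = NULL, alpha = 0.05) {
  expression <- as.matrix(expression)
  n <- nrow(expression)
  stopifnot(length(score) == n)
  x <- cbind(`(Intercept)` = 1, score = score)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    }
    x <- cbind(x, covariates)
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  coef <- qr.coef(qx, expression)
  fitted <- qr.fitted(qx, expression)
  df <- n - ncol(x)
  rss <- colSums((expression - fitted)^2)
  xtx_inv_score <- chol2inv(qr.R(qx))[2, 2]
  beta <- coef["score", ]
  se <- sqrt(rss / df * xtx_inv_score)
  pvalue <- 2 * stats::pt(abs(beta / se), df, lower.tail = FALSE)
  g <- ncol(expression)
  genes <- colnames(expression)
  if (is.null(genes)) genes <- sprintf("gene_%05d", seq_len(g))
  out <- data.frame(gene = genes, beta = unname(beta), se = unname(se),
                    pvalue = unname(pvalue),
                    significant = unname(pvalue) < alpha / g,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "threshold") <- alpha / g
  class(out) <- c("twas_result", "data.frame")
  out
}

#' Hypergeometric over-representation of hits in an annotated gene set
#'
#' Upper-tail probability of observing at least the realized overlap between
#' the hit list and the gene set when hits are drawn without replacement from
#' the universe.
#'
#' @param hits character vector of hit genes (must lie in `universe`).
#' @param gene_set character vector of annotated genes (subset of `universe`).
#' @param universe all testable genes (non-empty).
#' @return List with `overlap`, `expected`, and the upper-tail `p`.
#' @export
hypergeometric_enrichment <- function(hits, gene_set, universe) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  hits <- unique(hits)
  gene_set <- unique(intersect(gene_set, universe))
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  overlap <- length(intersect(hits, gene_set))
  p <- stats::phyper(overlap - 1L, length(gene_set),
                     length(universe) - length(gene_set),
                     length(hits), lower.tail = FALSE)
  list(overlap = overlap,
       expected = length(hits) * length(gene_set) / length(universe),
       p = min(p, 1))
}

#' Over-representation scan across multiple gene sets
#'
#' @inheritParams hypergeometric_enrichment
#' @param gene_sets named list of gene sets (e.g. from [read_gmt]).
#' @param adjust apply a Bonferroni adjustment across sets (default TRUE).
#' @return Data frame `set`, `n_set`, `overlap`, `p` (and `p_adjusted`).
#' @export
enrichment_scan <- function(hits, gene_sets, universe, adjust = TRUE) {
  rows <- lapply(names(gene_sets), function(nm) {
    res <- hypergeometric_enrichment(hits, gene_sets[[nm]], universe)
    data.frame(set = nm,
               n_set = length(intersect(gene_sets[[nm]], universe)),
               overlap = res$overlap, p = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p, method = "bonferroni")
  out[order(out$p), , drop = FALSE]
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path (set name, description, member genes per line).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    stop("reading GMT files requires the 'fgsea' package")
  }
  fgsea::gmtPathways(path)
}
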