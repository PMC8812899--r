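# Cis instrument construction: candidate selection around a target gene,
# greedy LD pruning, and instrument-strength diagnostics (r2, F).

#' Define a gene region with a cis flank
#'
#' @param gene_symbol gene name (e.g. "ACE").
#' @param chrom chromosome label.
#' @param start,end 1-based gene coordinates, `start <= end`.
#' @param window_bp flank added on both sides when selecting cis candidates
#'   (default 100000, i.e. +/-100 kb).
#' @return A `gene_region` object.
#' @export
gene_region <- function(gene_symbol, chrom, start, end, window_bp = 1e5) {
  stopifnot(start <= end, window_bp >= 0)
  structure(list(gene_symbol = gene_symbol, chrom = as.character(chrom),
                 start = as.numeric(start), end = as.numeric(end),
                 window_bp = as.numeric(window_bp)),
            class = "gene_region")
}

#' Read gene regions from BED-like tab-delimited text
#'
#' Columns: chrom, start, end, gene_symbol. Coordinates may be 0-based
#' half-open (BED convention, `zero_based = TRUE`) or 1-based closed.
#'
#' @param path file path.
#' @param zero_based whether start coordinates follow the 0-based BED
#'   convention (default FALSE).
#' @param window_bp flank applied to every region.
#' @return A list of [gene_region] objects named by gene symbol.
#' @export
read_gene_regions <- function(path, zero_based = FALSE, window_bp = 1e5) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "gene"))
  if (zero_based) tab$start <- tab$start + 1L
  regions <- lapply(seq_len(nrow(tab)), function(i) {
    gene_region(tab$gene[i], tab$chrom[i], tab$start[i], tab$end[i], window_bp)
  })
  stats::setNames(regions, tab$gene)
}

# Deterministic candidate ordering: ascending p, then smaller se, then snp_id.
.order_candidates <- function(x) {
  x[order(x$pvalue, x$se, x$snp_id), , drop = FALSE]
}

#' Select genome-wide-significant cis candidates for a gene region
#'
#' Retains variants on the region's chromosome whose position lies in the
#' closed interval `[start - window_bp, end + window_bp]` with
#' `pvalue < p_threshold` (strict), sorted by ascending p-value
#' (ties: smaller SE, then snp_id).
#'
#' @param stats a [summary_stats] table on the same genome build as `region`.
#' @param region a [gene_region].
#' @param p_threshold significance threshold (default 5e-8).
#' @return The retained subset of `stats`, ordered by significance.
#' @export
select_cis_candidates <- function(stats, region, p_threshold = 5e-8) {
  stopifnot(inherits(stats, "summary_stats"), inherits(region, "gene_region"))
  if (!region$chrom %in% stats$chrom) {
    warning("no variants on chromosome ", region$chrom, " in input table")
    return(stats[integer(0), , drop = FALSE])
  }
  lo <- region$start - region$window_bp
  hi <- region$end + region$window_bp
  keep <- stats$chrom == region$chrom & stats$pos >= lo & stats$pos <= hi &
    stats$pvalue < p_threshold
  out <- .order_candidates(stats[keep, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Greedy LD pruning of ranked candidates
#'
#' Sweeps candidates in order of ascending p-value and accepts a variant only
#' if its squared correlation with every already-accepted variant is strictly
#' below `r2_max`. Deterministic given the input; the most significant
#' candidate is always retained.
#'
#' @param candidates candidate table from [select_cis_candidates] (re-sorted
#'   defensively with the same tie-break).
#' @param ld signed correlation matrix covering all candidates (see
#'   [as_ld_matrix]).
#' @param r2_max pruning threshold on r-squared (default 0.10); a pair at
#'   exactly `r2_max` is pruned.
#' @return The retained subset of `candidates`, in acceptance order.
#' @export
ld_prune_greedy <- function(candidates, ld, r2_max = 0.10) {
  if (nrow(candidates) == 0L) return(candidates)
  candidates <- .order_candidates(candidates)
  missing <- setdiff(candidates$snp_id, rownames(ld))
  if (length(missing) > 0L) {
    stop("candidates absent from LD matrix: ", paste(missing, collapse = ", "))
  }
  accepted <- character(0)
  for (id in candidates$snp_id) {
    if (length(accepted) == 0L ||
        all(ld[id, accepted]^2 < r2_max)) {
      accepted <- c(accepted, id)
    }
  }
  out <- candidates[match(accepted, candidates$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Proportion of trait variance explained by a variant
#'
#' Two estimators: `eaf_beta` uses the per-allele effect on a standardized
#' (unit-variance) trait, `r2 = 2 f (1 - f) beta^2`; `z_n` converts a p-value
#' (or beta/se) and sample size through the univariable-regression identity
#' `r2 = z^2 / (z^2 + n - 2)`.
#'
#' @param beta per-allele effect (eaf_beta mode; also used for z when se given).
#' @param eaf effect-allele frequency (eaf_beta mode).
#' @param pvalue two-sided p-value (z_n mode).
#' @param se standard error; with `beta`, an alternative source of z in z_n mode.
#' @param n sample size (z_n mode), must exceed 2.
#' @param mode `"eaf_beta"` or `"z_n"`.
#' @return Vector of variance proportions in `[0, 1)`.
#' @export
variance_explained <- function(beta = NULL, eaf = NULL, pvalue = NULL,
                               se = NULL, n = NULL,
                               mode = c("z_n", "eaf_beta")) {
  mode <- match.arg(mode)
  if (mode == "eaf_beta") {
    if (is.null(beta) || is.null(eaf)) stop("eaf_beta mode needs beta and eaf")
    return(2 * eaf * (1 - eaf) * beta^2)
  }
  if (is.null(n)) stop("z_n mode needs n")
  if (any(n <= 2)) stop("z_n mode needs n > 2")
  z <- if (!is.null(pvalue)) {
    stats::qnorm(pvalue / 2, lower.tail = FALSE)
  } else if (!is.null(beta) && !is.null(se)) {
    abs(beta / se)
  } else {
    stop("z_n mode needs pvalue, or beta and se")
  }
  z^2 / (z^2 + n - 2)
}

#' Instrument-strength F-statistic
#'
#' `F = r2 (n - k - 1) / ((1 - r2) k)`. For a single variant this equals the
#' squared z-statistic up to the `n - 2` vs `n - k - 1` convention. An F of at
#' least 10 is the conventional indicator of minimal weak-instrument bias.
#'
#' @param r2_total proportion of exposure variance explained, in `[0, 1)`.
#' @param n sample size of the exposure GWAS (must exceed `k + 1`).
#' @param k number of variants in the instrument.
#' @return F-statistic (>= 0).
#' @export
f_statistic <- function(r2_total, n, k) {
  if (any(r2_total < 0 | r2_total >= 1)) stop("r2_total must lie in [0, 1)")
  stopifnot(k >= 1, n > k + 1)
  r2_total * (n - k - 1) / ((1 - r2_total) * k)
}

# Per-variant r2 contributions used for instrument diagnostics.
.per_variant_r2 <- function(variants, n) {
  variance_explained(pvalue = variants$pvalue, n = n, mode = "z_n")
}

.instrument_diagnostics <- function(variants, ld, n, r2_method) {
  r2_j <- .per_variant_r2(variants, n)
  r2_total <- if (r2_method == "sum") {
    # Valid under weak LD post-pruning; approximate.
    sum(r2_j)
  } else {
    # LD-adjusted quadratic form on signed standardized effects.
    u <- sign(variants$beta) * sqrt(r2_j)
    drop(crossprod(u, solve(ld[variants$snp_id, variants$snp_id,
                                drop = FALSE], u)))
  }
  r2_total <- min(r2_total, 1 - 1e-12)
  list(r2_total = r2_total,
       f_stat = f_statistic(r2_total, n, nrow(variants)))
}

#' Build a pruned cis instrument for a drug-target gene
#'
#' Runs [select_cis_candidates] then [ld_prune_greedy], extracts the LD
#' sub-matrix, and computes strength diagnostics: the total variance explained
#' (sum of per-variant `z_n` contributions by default, or an LD-adjusted
#' quadratic form) and the F-statistic.
#'
#' @inheritParams select_cis_candidates
#' @inheritParams ld_prune_greedy
#' @param target label for the drug target (defaults to the region's gene).
#' @param exposure_label trait the instrument proxies.
#' @param n sample size for diagnostics (default: median `n` of retained
#'   variants).
#' @param r2_method `"sum"` or `"ld_adjusted"`.
#' @return An `instrument` object: list with `target`, `exposure_label`,
#'   `variants` (summary-stat rows), `ld`, `r2_total`, `f_stat`, `n_gwas`.
#' @export
build_instrument <- function(stats, region, ld, p_threshold = 5e-8,
                             r2_max = 0.10, target = region$gene_symbol,
                             exposure_label = attr(stats, "trait_label"),
                             n = NULL, r2_method = c("sum", "ld_adjusted")) {
  r2_method <- match.arg(r2_method)
  candidates <- select_cis_candidates(stats, region, p_threshold)
  if (nrow(candidates) == 0L) stop("no cis candidates for ", target)
  variants <- ld_prune_greedy(candidates, ld, r2_max)
  ld_sub <- as_ld_matrix(ld[variants$snp_id, variants$snp_id, drop = FALSE],
                         variants$snp_id)
  if (is.null(n)) n <- stats::median(variants$n)
  diag_ <- .instrument_diagnostics(variants, ld_sub, n, r2_method)
  structure(list(target = target,
                 exposure_label = if (is.null(exposure_label)) "" else exposure_label,
                 variants = variants, ld = ld_sub,
                 r2_total = diag_$r2_total, f_stat = diag_$f_stat,
                 n_gwas = n, r2_method = r2_method),
            class = "instrument")
}

#' Restrict an instrument to variants with eQTL support
#'
#' Keeps the intersection of the instrument's variants with `eqtl_ids` and
#' recomputes the LD sub-matrix and strength diagnostics.
#'
#' @param instrument an `instrument` from [build_instrument].
#' @param eqtl_ids non-empty character vector of eQTL variant ids.
#' @return The filtered `instrument`.
#' @export
restrict_to_eqtls <- function(instrument, eqtl_ids) {
  stopifnot(inherits(instrument, "instrument"), length(eqtl_ids) > 0L)
  keep <- instrument$variants$snp_id %in% eqtl_ids
  if (!any(keep)) stop("no eQTL-supported variants in instrument")
  variants <- instrument$variants[keep, , drop = FALSE]
  rownames(variants) <- NULL
  ld_sub <- as_ld_matrix(instrument$ld[variants$snp_id, variants$snp_id,
                                       drop = FALSE], variants$snp_id)
  diag_ <- .instrument_diagnostics(variants, ld_sub, instrument$n_gwas,
                                   instrument$r2_method)
  instrument$variants <- variants
  instrument$ld <- ld_sub
  instrument$r2_total <- diag_$r2_total
  instrument$f_stat <- diag_$f_stat
  instrument
}

#' @export
print.instrument <- function(x, ...) {
  cat("Cis instrument for", x$target,
      if (nzchar(x$exposure_label)) paste0("(", x$exposure_label, ")"), "\n")
  cat("  variants:", nrow(x$variants),
      " r2:", signif(x$r2_total, 3),
      " F:", signif(x$f_stat, 4),
      " n:", x$n_gwas, "\n")
  invisible(x)
}
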