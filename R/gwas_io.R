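# Summary-statistic containers, readers/writers, allele harmonization, LD input.

.canonical_cols <- c(
  snp_id = "SNP", chrom = "CHR", pos = "BP", effect_allele = "EA",
  other_allele = "NEA", eaf = "EAF", beta = "BETA", se = "SE",
  pvalue = "P", n = "N"
)

#' Construct a validated summary-statistics table
#'
#' A `summary_stats` object is a data frame with one row per variant and
#' columns `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pvalue`, `n`. Effects are per additional copy of the effect
#' allele, in the units of the trait (e.g. mm Hg for blood pressure, SD for a
#' serum protein, log-odds for a case-control outcome).
#'
#' @param x data frame with the columns above (any order).
#' @param trait_label human-readable trait name.
#' @param trait_units units of `beta` (e.g. "mmHg", "SD", "log-odds").
#' @return A `summary_stats` data frame; row order is preserved.
#' @export
summary_stats <- function(x, trait_label = "", trait_units = "") {
  required <- names(.canonical_cols)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  x <- as.data.frame(x)[required]
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    if (!is.numeric(x[[col]])) {
      coerced <- suppressWarnings(as.numeric(x[[col]]))
      bad <- which(is.na(coerced) & !is.na(x[[col]]))
      if (length(bad) > 0L) {
        stop("non-numeric value in column '", col, "' at row(s): ",
             paste(utils::head(bad, 5L), collapse = ", "))
      }
      x[[col]] <- coerced
    }
  }
  x$snp_id <- as.character(x$snp_id)
  x$chrom <- as.character(x$chrom)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  if (nrow(x) > 0L) {
    if (anyDuplicated(x$snp_id)) {
      stop("duplicate snp_id: ",
           paste(unique(x$snp_id[duplicated(x$snp_id)]), collapse = ", "))
    }
    if (any(x$se <= 0)) stop("se must be > 0")
    if (any(x$eaf < 0 | x$eaf > 1)) stop("eaf must lie in [0, 1]")
    if (any(x$pvalue <= 0 | x$pvalue > 1)) stop("pvalue must lie in (0, 1]")
    if (any(x$n < 1)) stop("n must be >= 1")
    if (any(x$effect_allele == x$other_allele)) {
      stop("effect_allele must differ from other_allele")
    }
    .check_p_consistency(x)
  }
  structure(x,
            trait_label = trait_label, trait_units = trait_units,
            class = c("summary_stats", "data.frame"))
}

# Published tables round beta and se; the implied p can legitimately move by
# several orders of magnitude at extreme z, so the tolerance scales with the
# recomputed magnitude (one order of magnitude, or 10%, whichever is larger).
.check_p_consistency <- function(x) {
  z <- abs(x$beta / x$se)
  log10p <- (log(2) + stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)) / log(10)
  off <- abs(log10(x$pvalue) - log10p) > pmax(1, 0.1 * abs(log10p))
  if (any(off)) {
    warning("reported p inconsistent with beta/se (>1 order of magnitude) for: ",
            paste(utils::head(x$snp_id[off], 5L), collapse = ", "))
  }
  invisible(x)
}

#' Read GWAS summary statistics from delimited text
#'
#' Expects a header with canonical columns `SNP CHR BP EA NEA EAF BETA SE P N`;
#' other column names can be remapped through `dialect`.
#'
#' @param path file path to a delimited text file with a header line.
#' @param dialect named character vector mapping canonical names (names) to the
#'   column names used in the file (values), e.g. `c(SNP = "rsid", P = "pval")`.
#'   Unmentioned columns are assumed canonical.
#' @param sep field separator (default tab).
#' @inheritParams summary_stats
#' @return A [summary_stats] table; a header-only file yields zero rows.
#' @export
read_summary_stats <- function(path, dialect = NULL, sep = "\t",
                               trait_label = "", trait_units = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = NA, comment.char = "")
  file_cols <- .canonical_cols
  if (!is.null(dialect)) {
    unknown <- setdiff(names(dialect), .canonical_cols)
    if (length(unknown) > 0L) {
      stop("dialect refers to unknown canonical column(s): ",
           paste(unknown, collapse = ", "))
    }
    file_cols[match(names(dialect), file_cols)] <- unname(dialect)
  }
  missing <- file_cols[!file_cols %in% names(raw)]
  if (length(missing) > 0L) {
    stop("input file lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- raw[unname(file_cols)]
  names(out) <- names(.canonical_cols)
  for (col in c("beta", "se")) {
    coerced <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(coerced) & !is.na(out[[col]]))
    if (length(bad) > 0L) {
      stop("non-numeric ", toupper(col), " at line(s): ",
           paste(bad + 1L, collapse = ", "))  # +1 for the header line
    }
    out[[col]] <- coerced
  }
  summary_stats(out, trait_label = trait_label, trait_units = trait_units)
}

#' Write summary statistics to tab-delimited text
#'
#' Numeric fields are written with 17 significant digits so that
#' write-then-read round-trips reproduce values exactly.
#'
#' @param x a [summary_stats] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  stopifnot(inherits(x, "summary_stats"))
  out <- as.data.frame(x)
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  names(out) <- unname(.canonical_cols)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(ea, nea) {
  !is.na(.complement[ea]) & .complement[ea] == nea
}

#' Harmonize exposure and outcome summary statistics to a common effect allele
#'
#' Variants are matched on `snp_id`. When the outcome's effect allele equals
#' the exposure's other allele, the outcome beta sign is flipped and its EAF
#' complemented. Strand flips (A<->T, C<->G) are attempted for non-palindromic
#' variants before an allele pair is declared incompatible. Palindromic
#' variants (A/T or C/G) whose outcome EAF lies within `0.5 +/-
#' palindrome_eaf_band` are dropped as strand-ambiguous; unambiguous
#' palindromic variants are oriented by comparing which side of 0.5 the two
#' EAFs fall on.
#'
#' @param exposure,outcome [summary_stats] tables for the two traits.
#' @param palindrome_eaf_band half-width of the ambiguity band around EAF 0.5
#'   (default 0.08).
#' @return A `harmonized_pairs` object: list with `pairs` (one row per aligned
#'   variant: exposure/outcome betas and SEs, shared alleles, `flipped` flag)
#'   and `dropped` (snp_id + reason: `missing_in_outcome`,
#'   `palindromic_ambiguous`, or `incompatible_alleles`).
#' @export
harmonize_pair <- function(exposure, outcome, palindrome_eaf_band = 0.08) {
  stopifnot(inherits(exposure, "summary_stats"), inherits(outcome, "summary_stats"))
  if (nrow(exposure) == 0L || nrow(outcome) == 0L) {
    stop("both tables must be non-empty")
  }
  idx <- match(exposure$snp_id, outcome$snp_id)
  dropped <- data.frame(snp_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  if (anyNA(idx)) {
    dropped <- rbind(dropped, data.frame(
      snp_id = exposure$snp_id[is.na(idx)], reason = "missing_in_outcome",
      stringsAsFactors = FALSE))
  }
  keep <- which(!is.na(idx))
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    e <- exposure[keep[i], ]
    o <- outcome[idx[keep[i]], ]
    ea <- e$effect_allele; nea <- e$other_allele
    oea <- o$effect_allele; onea <- o$other_allele
    pal <- .is_palindromic(ea, nea)
    flip <- NA
    if (oea == ea && onea == nea) {
      flip <- FALSE
    } else if (oea == nea && onea == ea) {
      flip <- TRUE
    } else if (!pal && !is.na(.complement[oea]) && !is.na(.complement[onea])) {
      if (.complement[[oea]] == ea && .complement[[onea]] == nea) {
        flip <- FALSE
      } else if (.complement[[oea]] == nea && .complement[[onea]] == ea) {
        flip <- TRUE
      }
    }
    if (is.na(flip)) {
      dropped <- rbind(dropped, data.frame(
        snp_id = e$snp_id, reason = "incompatible_alleles",
        stringsAsFactors = FALSE))
      next
    }
    beta_o <- if (flip) -o$beta else o$beta
    eaf_o <- if (flip) 1 - o$eaf else o$eaf
    if (pal) {
      if (abs(o$eaf - 0.5) <= palindrome_eaf_band) {
        dropped <- rbind(dropped, data.frame(
          snp_id = e$snp_id, reason = "palindromic_ambiguous",
          stringsAsFactors = FALSE))
        next
      }
      # Letters cannot distinguish strands for palindromes: orient by frequency.
      if ((e$eaf - 0.5) * (eaf_o - 0.5) < 0) {
        flip <- !flip
        beta_o <- -beta_o
        eaf_o <- 1 - eaf_o
      }
    }
    rows[[i]] <- data.frame(
      snp_id = e$snp_id, chrom = e$chrom, pos = e$pos,
      effect_allele = ea, other_allele = nea,
      eaf_exposure = e$eaf, beta_exposure = e$beta, se_exposure = e$se,
      eaf_outcome = eaf_o, beta_outcome = beta_o, se_outcome = o$se,
      n_outcome = o$n, flipped = flip, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(pairs)) {
    pairs <- data.frame(snp_id = character(), beta_exposure = numeric(),
                        se_exposure = numeric(), beta_outcome = numeric(),
                        se_outcome = numeric(), flipped = logical(),
                        stringsAsFactors = FALSE)
  }
  rownames(pairs) <- NULL
  if (nrow(dropped) > 0L) {
    message(nrow(dropped), " variant(s) dropped during harmonization (",
            paste(sprintf("%s: %s", dropped$snp_id, dropped$reason),
                  collapse = "; "), ")")
  }
  structure(list(pairs = pairs, dropped = dropped),
            class = "harmonized_pairs")
}

#' @export
print.harmonized_pairs <- function(x, ...) {
  cat("Harmonized exposure-outcome pairs:", nrow(x$pairs), "aligned,",
      nrow(x$dropped), "dropped\n")
  if (nrow(x$pairs) > 0L) print(utils::head(x$pairs, 10L))
  invisible(x)
}

#' Repair a correlation matrix to positive semi-definiteness
#'
#' Negative eigenvalues below `-tol` trigger eigenvalue clipping at zero
#' followed by rescaling to unit diagonal.
#'
#' @param r symmetric correlation matrix.
#' @param tol eigenvalue tolerance (default 1e-8).
#' @return A PSD correlation matrix with unit diagonal.
#' @export
repair_psd <- function(r, tol = 1e-8) {
  eig <- eigen(r, symmetric = TRUE)
  if (min(eig$values) >= -tol) return(r)
  vals <- pmax(eig$values, 0)
  fixed <- eig$vectors %*% (vals * t(eig$vectors))
  d <- sqrt(diag(fixed))
  fixed <- fixed / tcrossprod(d)
  diag(fixed) <- 1
  dimnames(fixed) <- dimnames(r)
  message("LD matrix repaired by eigenvalue clipping (min eigenvalue was ",
          signif(min(eig$values), 3), ")")
  fixed
}

#' Coerce a matrix of signed LD correlations to a validated form
#'
#' Checks symmetry, unit diagonal and the [-1, 1] range, orders rows/columns
#' to `snp_ids`, and repairs PSD violations by eigenvalue clipping.
#'
#' @param r square numeric matrix of signed correlations with dimnames.
#' @param snp_ids required row/column order.
#' @param sym_tol maximum tolerated asymmetry (default 1e-6).
#' @return A validated matrix ordered to `snp_ids`.
#' @export
as_ld_matrix <- function(r, snp_ids, sym_tol = 1e-6) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square")
  if (max(abs(r - t(r))) > sym_tol) stop("LD matrix is not symmetric")
  r <- (r + t(r)) / 2
  missing <- setdiff(snp_ids, rownames(r))
  if (length(missing) > 0L) {
    stop("snp_id(s) absent from LD matrix: ", paste(missing, collapse = ", "))
  }
  r <- r[snp_ids, snp_ids, drop = FALSE]
  if (any(abs(diag(r) - 1) > 1e-6)) stop("LD matrix diagonal must be 1")
  diag(r) <- 1
  if (any(r < -1 - 1e-8 | r > 1 + 1e-8)) stop("LD entries must lie in [-1, 1]")
  repair_psd(r)
}

#' Read a signed LD matrix from text
#'
#' Accepts either a square tab-delimited matrix with an id header row and id
#' first column, or a long-format three-column file (`id1 id2 r`, header
#' optional). In long format, pairs not listed default to r = 0 with a warning.
#'
#' @param path file path.
#' @param snp_ids ordered variant ids the matrix must cover.
#' @return A validated signed correlation matrix ordered to `snp_ids`.
#' @export
read_ld_matrix <- function(path, snp_ids) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t|,| +")[[1]]
  long <- length(first) == 3L &&
    !is.na(suppressWarnings(as.numeric(first[3]))) ||
    (length(first) == 3L && tolower(first[3]) %in% c("r", "rho", "cor"))
  if (long) {
    tab <- utils::read.table(path, header = tolower(first[3]) %in% c("r", "rho", "cor"),
                             stringsAsFactors = FALSE)
    names(tab) <- c("id1", "id2", "r")
    m <- length(snp_ids)
    r <- diag(m)
    dimnames(r) <- list(snp_ids, snp_ids)
    known <- unique(c(tab$id1, tab$id2))
    missing <- setdiff(snp_ids, known)
    seen <- matrix(FALSE, m, m, dimnames = list(snp_ids, snp_ids))
    for (i in seq_len(nrow(tab))) {
      a <- tab$id1[i]; b <- tab$id2[i]
      if (!(a %in% snp_ids) || !(b %in% snp_ids)) next
      r[a, b] <- r[b, a] <- tab$r[i]
      seen[a, b] <- seen[b, a] <- TRUE
    }
    diag(seen) <- TRUE
    if (length(missing) > 0L || !all(seen)) {
      warning(sum(!seen[upper.tri(seen)]),
              " variant pair(s) absent from LD file; defaulting to r = 0")
    }
    as_ld_matrix(r, snp_ids)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, row.names = 1L)
    as_ld_matrix(as.matrix(tab), snp_ids)
  }
}

#' Write a signed LD matrix as square tab-delimited text
#' @param r matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(r, path) {
  out <- data.frame(SNP = rownames(r),
                    matrix(sprintf("%.17g", r), nrow(r),
                           dimnames = list(NULL, colnames(r))),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
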