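# Orchestration: run the full drug-target analysis from a single structured
# config (pool -> instrument -> harmonize -> MR -> coloc trigger -> tiers)
# and render machine-readable reports.

.default_thresholds <- list(window_kb = 100, p_threshold = 5e-8,
                            r2_max = 0.10, coloc_window_kb = 300,
                            coloc_support = 0.80, family_alpha = 0.05,
                            coloc_trigger_p = 0.05)

#' Assemble and validate an analysis configuration
#'
#' Either pass the fields directly or a path to a YAML file holding them.
#' Thresholds default to the conventional drug-target MR settings: +/-100 kb
#' cis windows, genome-wide significance 5e-8, LD pruning at r2 < 0.10,
#' +/-300 kb colocalization windows with a 0.80 support threshold, and a 0.05
#' family-wise alpha.
#'
#' @param targets list of target definitions, each with `gene_symbol`,
#'   `chrom`, `start`, `end`.
#' @param exposure_paths one or two exposure GWAS file paths (two are pooled
#'   by fixed effects with the concordance filter).
#' @param outcome_paths named list/vector of outcome GWAS file paths.
#' @param ld_path LD matrix file covering candidate variants.
#' @param thresholds named list overriding entries of the defaults.
#' @param orientation reporting orientation (default per-unit-lower exposure,
#'   the inhibition framing).
#' @param scale optional exposure-unit multiple applied to reported estimates.
#' @param seed integer recorded for provenance.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(targets, exposure_paths, outcome_paths, ld_path,
                            thresholds = list(),
                            orientation = "per_unit_lower_exposure",
                            scale = NULL, seed = 1L) {
  th <- utils::modifyList(.default_thresholds, thresholds)
  stopifnot(length(exposure_paths) %in% 1:2, length(outcome_paths) >= 1)
  if (is.null(names(outcome_paths))) {
    names(outcome_paths) <- paste0("outcome", seq_along(outcome_paths))
  }
  if (any(unlist(th) <= 0)) stop("thresholds must be positive")
  structure(list(targets = targets, exposure_paths = exposure_paths,
                 outcome_paths = outcome_paths, ld_path = ld_path,
                 thresholds = th, orientation = orientation, scale = scale,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#' @param path YAML file with the fields of [analysis_config].
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  analysis_config(
    targets = raw$targets,
    exposure_paths = unlist(raw$exposure_paths),
    outcome_paths = unlist(raw$outcome_paths),
    ld_path = raw$ld_path,
    thresholds = if (is.null(raw$thresholds)) list() else raw$thresholds,
    orientation = if (is.null(raw$orientation)) "per_unit_lower_exposure" else raw$orientation,
    scale = raw$scale,
    seed = if (is.null(raw$seed)) 1L else raw$seed)
}

#' Run the full drug-target MR pipeline
#'
#' Stages: pool the exposure GWAS (when two are given) and apply the
#' concordance filter; build a pruned cis instrument per target; harmonize
#' against each outcome; estimate the correlated IVW effect (leave-one-out
#' when at least two variants remain); run colocalization for any
#' target-outcome pair with nominal evidence (p below the trigger, default
#' 0.05); and assign Bonferroni evidence tiers across all tests. Every
#' filtering stage logs counts in/out.
#'
#' @param config an `analysis_config` or path to a YAML file.
#' @return An `analysis_report`: list with `instruments`, `results` (per
#'   target x outcome: estimate, leave-one-out table, optional coloc result),
#'   `tiers`, and a `provenance` block (config hash, seed, package version).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  paths <- c(unlist(config$exposure_paths), unlist(config$outcome_paths),
             config$ld_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  th <- config$thresholds
  set.seed(config$seed)

  exposures <- lapply(config$exposure_paths, read_summary_stats)
  exposure <- if (length(exposures) == 2L) {
    pooled <- pool_fixed_effects(exposures[[1]], exposures[[2]])
    kept <- concordance_filter(pooled, th$p_threshold)
    message("pooling: ", nrow(pooled), " shared variants, ",
            nrow(kept), " concordant genome-wide significant")
    kept
  } else {
    exposures[[1]]
  }

  instruments <- list()
  results <- list()
  for (tg in config$targets) {
    region <- gene_region(tg$gene_symbol, tg$chrom, tg$start, tg$end,
                          window_bp = th$window_kb * 1000)
    candidates <- select_cis_candidates(exposure, region, th$p_threshold)
    message(tg$gene_symbol, ": ", nrow(candidates), " cis candidates")
    if (nrow(candidates) == 0L) next
    ld <- read_ld_matrix(config$ld_path, candidates$snp_id)
    instrument <- build_instrument(exposure, region, ld,
                                   p_threshold = th$p_threshold,
                                   r2_max = th$r2_max)
    message(tg$gene_symbol, ": ", nrow(instrument$variants),
            " variants after LD pruning (r2 < ", th$r2_max, "), F = ",
            signif(instrument$f_stat, 4))
    instruments[[tg$gene_symbol]] <- instrument

    for (oc in names(config$outcome_paths)) {
      outcome <- read_summary_stats(config$outcome_paths[[oc]])
      harm <- harmonize_pair(instrument$variants, outcome)
      if (nrow(harm$pairs) == 0L) {
        warning("no harmonized variants for ", tg$gene_symbol, " x ", oc)
        next
      }
      ld_sub <- instrument$ld[harm$pairs$snp_id, harm$pairs$snp_id,
                              drop = FALSE]
      est <- ivw_correlated(harm$pairs, ld_sub,
                            orientation = config$orientation)
      if (!is.null(config$scale)) est <- scale_odds_ratio(est, config$scale)
      loo <- if (nrow(harm$pairs) >= 2L) {
        leave_one_out(harm$pairs, ld_sub, orientation = config$orientation)
      }
      coloc <- NULL
      if (est$pvalue < th$coloc_trigger_p) {
        top <- harm$pairs$snp_id[which.min(
          .p_from_z(harm$pairs$beta_exposure / harm$pairs$se_exposure))]
        reg1 <- define_region(exposure, top, th$coloc_window_kb * 1000)
        oc_region <- outcome[outcome$snp_id %in% reg1$snp_id, , drop = FALSE]
        if (nrow(oc_region) > 0L) {
          coloc <- coloc_posteriors(reg1, oc_region,
                                    trait2_type = "case_control")
          message(tg$gene_symbol, " x ", oc, ": coloc over ",
                  coloc$n_snps, " variants, PP.H4 = ",
                  signif(coloc$pp[["H4"]], 3))
        }
      }
      results[[paste(tg$gene_symbol, oc, sep = ".")]] <- list(
        target = tg$gene_symbol, outcome = oc, estimate = est,
        leave_one_out = loo, coloc = coloc,
        n_snps = nrow(harm$pairs), dropped = harm$dropped)
    }
  }
  if (length(results) == 0L) stop("pipeline produced no results")
  pvals <- vapply(results, function(r) r$estimate$pvalue, numeric(1))
  tiers <- apply_multiplicity(pvals, labels = names(results),
                              alpha = th$family_alpha)
  for (nm in names(results)) {
    results[[nm]]$tier <- tiers$tier[tiers$label == nm]
  }
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file))
  saveRDS(config, cfg_file)
  structure(list(instruments = instruments, results = results, tiers = tiers,
                 provenance = list(
                   config_hash = unname(tools::md5sum(cfg_file)),
                   seed = config$seed,
                   version = as.character(utils::packageVersion("ctmr")))),
            class = "analysis_report")
}

.report_table <- function(report) {
  rows <- lapply(report$results, function(r) {
    data.frame(target = r$target, outcome = r$outcome, n_snps = r$n_snps,
               or = r$estimate$odds_ratio,
               ci_low = r$estimate$ci_low, ci_high = r$estimate$ci_high,
               or_ci = format_or_ci(r$estimate$theta, r$estimate$se_theta),
               pvalue = r$estimate$pvalue, phi = r$estimate$phi,
               tier = r$tier,
               pp_h4 = if (is.null(r$coloc)) NA_real_ else unname(r$coloc$pp["H4"]),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(target = character(), outcome = character(),
                      n_snps = integer(), or = numeric(), ci_low = numeric(),
                      ci_high = numeric(), or_ci = character(),
                      pvalue = numeric(), phi = numeric(), tier = character(),
                      pp_h4 = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render an analysis report to TSV and/or lossless JSON
#'
#' The TSV mirrors the shape of a drug-target MR results table (target,
#' outcome, OR with 95% CI, p, dispersion, tier, shared-variant posterior);
#' the JSON serializes the full report.
#'
#' @param report an `analysis_report` from [run_pipeline].
#' @param dir output directory (created if needed).
#' @param formats subset of `c("tsv", "json")`.
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(report, dir, formats = c("tsv", "json")) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if ("tsv" %in% formats) {
    path <- file.path(dir, "mr_estimates.tsv")
    utils::write.table(.report_table(report), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- c(written, path)
  }
  if ("json" %in% formats) {
    path <- file.path(dir, "report.json")
    serializable <- report
    serializable$instruments <- lapply(report$instruments, function(ins) {
      list(target = ins$target, variants = ins$variants,
           ld = ins$ld, r2_total = ins$r2_total, f_stat = ins$f_stat,
           n_gwas = ins$n_gwas)
    })
    jsonlite::write_json(serializable, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE, pretty = TRUE)
    written <- c(written, path)
  }
  invisible(written)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Drug-target MR analysis report:", length(x$results), "target-outcome",
      "analyses,", length(x$instruments), "instrument(s)\n")
  print(.report_table(x))
  invisible(x)
}
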