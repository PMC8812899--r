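test_that("reading a published-table-style file preserves fields", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tBP\tEA\tNEA\tEAF\tBETA\tSE\tP\tN",
               "rs4343\t17\t61570422\tA\tG\t0.45\t-0.63\t0.02\t1.53e-213\t4174"),
             path)
  tab <- read_summary_stats(path)
  expect_s3_class(tab, "summary_stats")
  expect_equal(tab$beta, -0.63)
  expect_equal(tab$se, 0.02)
  expect_equal(tab$snp_id, "rs4343")
  expect_equal(tab$pvalue, 1.53e-213)
})

test_that("header-only input yields an empty table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("SNP\tCHR\tBP\tEA\tNEA\tEAF\tBETA\tSE\tP\tN", path)
  expect_equal(nrow(read_summary_stats(path)), 0L)
})

test_that("missing columns and non-numeric effects fail with clear errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tBP\tEA\tNEA\tEAF\tSE\tP\tN",
               "rs1\t1\t100\tA\tG\t0.4\t0.1\t0.5\t100"), path)
  expect_error(read_summary_stats(path), "BETA")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tBP\tEA\tNEA\tEAF\tBETA\tSE\tP\tN",
               "rs1\t1\t100\tA\tG\t0.4\t0.2\t0.1\t0.0455\t100",
               "rs2\t1\t200\tA\tG\t0.4\tlow\t0.1\t0.5\t100"), path2)
  expect_error(read_summary_stats(path2), "line.*3")
})

test_that("dialect remapping resolves nonstandard column names", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tCHR\tBP\tEA\tNEA\tEAF\tBETA\tSE\tpval\tN",
               "rs1\t1\t100\tA\tG\t0.4\t0.2\t0.1\t0.0455\t100"), path)
  tab <- read_summary_stats(path, dialect = c(SNP = "rsid", P = "pval"))
  expect_equal(tab$snp_id, "rs1")
  expect_equal(tab$pvalue, 0.0455)
})

test_that("write-then-read is the identity on a 14-record table", {
  set.seed(42)
  beta <- rnorm(14, -0.4, 0.2)
  se <- runif(14, 0.02, 0.09)
  tab <- make_stats(sprintf("rs%03d", 1:14), beta, se,
                    eaf = runif(14, 0.01, 0.97), n = 4174)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(tab, path)
  back <- read_summary_stats(path)
  for (col in names(tab)) expect_equal(back[[col]], tab[[col]], info = col)
})

test_that("allele swap flips the outcome beta and flags it", {
  exp_tab <- make_stats("rs1", -0.63, 0.02, eaf = 0.45, ea = "A", nea = "G")
  out_tab <- make_stats("rs1", 0.10, 0.05, eaf = 0.55, ea = "G", nea = "A")
  h <- harmonize_pair(exp_tab, out_tab)
  expect_equal(h$pairs$beta_outcome, -0.10)
  expect_true(h$pairs$flipped)
  expect_equal(h$pairs$eaf_outcome, 0.45)
})

test_that("ambiguous palindromic variants are dropped within the EAF band", {
  exp_tab <- make_stats("rs1", 0.3, 0.05, eaf = 0.2, ea = "C", nea = "G")
  out_tab <- make_stats("rs1", 0.1, 0.05, eaf = 0.50, ea = "C", nea = "G")
  h <- suppressMessages(harmonize_pair(exp_tab, out_tab,
                                       palindrome_eaf_band = 0.08))
  expect_equal(nrow(h$pairs), 0L)
  expect_equal(h$dropped$reason, "palindromic_ambiguous")
  # outside the band the variant is retained
  out_tab2 <- make_stats("rs1", 0.1, 0.05, eaf = 0.21, ea = "C", nea = "G")
  h2 <- harmonize_pair(exp_tab, out_tab2, palindrome_eaf_band = 0.08)
  expect_equal(nrow(h2$pairs), 1L)
})

test_that("variants missing from the outcome are reported as dropped", {
  exp_tab <- make_stats(sprintf("rs%02d", 1:14), rnorm(14, -0.3, 0.1),
                        runif(14, 0.02, 0.08))
  out_tab <- make_stats(sprintf("rs%02d", 1:13), rnorm(13, 0, 0.05),
                        runif(13, 0.02, 0.08))
  h <- suppressMessages(harmonize_pair(exp_tab, out_tab))
  expect_equal(nrow(h$pairs), 13L)
  expect_equal(h$dropped$snp_id, "rs14")
  expect_equal(h$dropped$reason, "missing_in_outcome")
})

test_that("strand complements align and incompatible alleles are flagged", {
  exp_tab <- make_stats("rs1", 0.3, 0.05, ea = "A", nea = "G")
  # T/C is the strand complement of A/G: aligned without flip
  out_tab <- make_stats("rs1", 0.2, 0.05, ea = "T", nea = "C")
  h <- harmonize_pair(exp_tab, out_tab)
  expect_equal(h$pairs$beta_outcome, 0.2)
  expect_false(h$pairs$flipped)
  # C/T matches neither orientation nor complement of A/G
  out_bad <- make_stats("rs1", 0.2, 0.05, ea = "A", nea = "C")
  h2 <- suppressMessages(harmonize_pair(exp_tab, out_bad))
  expect_equal(h2$dropped$reason, "incompatible_alleles")
})

test_that("harmonization is idempotent and anti-symmetric under allele flips", {
  set.seed(7)
  exp_tab <- make_stats(paste0("rs", 1:6), rnorm(6, -0.3, 0.1),
                        runif(6, 0.02, 0.08), eaf = runif(6, 0.1, 0.45))
  out_tab <- make_stats(paste0("rs", 1:6), rnorm(6, 0, 0.05),
                        runif(6, 0.02, 0.08), eaf = runif(6, 0.1, 0.45))
  h1 <- harmonize_pair(exp_tab, out_tab)
  # re-harmonize the already-aligned outcome: nothing changes
  realigned <- make_stats(h1$pairs$snp_id, h1$pairs$beta_outcome,
                          h1$pairs$se_outcome, eaf = h1$pairs$eaf_outcome,
                          ea = "A", nea = "G")
  h2 <- harmonize_pair(exp_tab, realigned)
  expect_equal(h2$pairs$beta_outcome, h1$pairs$beta_outcome)
  expect_false(any(h2$pairs$flipped))
  # pre-flipping outcome alleles and beta sign yields identical output
  flipped <- make_stats(out_tab$snp_id, -out_tab$beta, out_tab$se,
                        eaf = 1 - out_tab$eaf, ea = "G", nea = "A")
  h3 <- harmonize_pair(exp_tab, flipped)
  expect_equal(h3$pairs$beta_outcome, h1$pairs$beta_outcome)
  expect_equal(h3$pairs$eaf_outcome, h1$pairs$eaf_outcome)
})

test_that("long-format LD input completes symmetry and defaults missing pairs", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("id1\tid2\tr", "s1\ts2\t0.3"), path)
  r <- read_ld_matrix(path, c("s1", "s2"))
  expect_equal(unname(r), matrix(c(1, 0.3, 0.3, 1), 2))
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("id1\tid2\tr", "s1\ts2\t0.3"), path2)
  expect_warning(r3 <- read_ld_matrix(path2, c("s1", "s2", "s3")),
                 "defaulting to r = 0")
  expect_equal(r3["s1", "s3"], 0)
})

test_that("square LD input validates symmetry and id coverage", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\ts1\ts2", "s1\t1\t0.3", "s2\t0.2\t1"), path)
  expect_error(read_ld_matrix(path, c("s1", "s2")), "not symmetric")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\ts1\ts2", "s1\t1\t0.3", "s2\t0.3\t1"), path2)
  expect_error(read_ld_matrix(path2, c("s1", "s9")), "s9")
  r <- read_ld_matrix(path2, c("s2", "s1"))
  expect_equal(rownames(r), c("s2", "s1"))
  expect_equal(r["s2", "s1"], 0.3)
})

test_that("PSD repair clips negative eigenvalues with small elementwise change", {
  # 3x3 correlation matrix engineered to have smallest eigenvalue ~ -1e-3
  r <- matrix(c(1, 0.9, 0.8,
                0.9, 1, 0.444,
                0.8, 0.444, 1), 3)
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(min(ev), -1e-4)
  dimnames(r) <- list(paste0("s", 1:3), paste0("s", 1:3))
  fixed <- suppressMessages(as_ld_matrix(r, paste0("s", 1:3)))
  ev_fixed <- eigen(fixed, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev_fixed), -1e-10)
  expect_lt(max(abs(fixed - r)), 1e-2)
  expect_equal(diag(fixed), setNames(rep(1, 3), paste0("s", 1:3)))
})

test_that("roundtrip of a written LD matrix reproduces values", {
  set.seed(3)
  r <- random_corr(4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(r, path)
  back <- read_ld_matrix(path, rownames(r))
  expect_equal(back, r, tolerance = 1e-12)
})
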