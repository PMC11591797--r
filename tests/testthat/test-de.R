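# TMM normalization, dispersion estimation, NB exact test, BH, calls

null_counts <- function(n_genes, seed, phi = 0.1, n_rep = 3) {
  cfg <- sim_config(n_genomes = 5, n_focal_genes = n_genes,
                    n_planted_operons = 1, operon_size_range = c(2, 2),
                    planted_log2fc = 0, nb_dispersion = phi,
                    n_replicates = n_rep, rng_seed = seed)
  generate_counts(cfg, generate_pangenome(cfg)$truth)
}

test_that("TMM factors are 1 for identical or proportionally scaled samples", {
  set.seed(41)
  base <- rnbinom(400, mu = 150, size = 10) + 1L
  counts <- cbind(control_1 = base, control_2 = base,
                  treated_1 = base, treated_2 = 2L * base)
  rownames(counts) <- paste0("g", seq_along(base))
  cm <- count_matrix(counts, c(control_1 = "control", control_2 = "control",
                               treated_1 = "treated", treated_2 = "treated"))
  f <- tmm_factors(cm)
  # identical samples: all M-values zero; doubling is absorbed by the
  # library size, so every TMM factor is 1
  expect_equal(unname(f), rep(1, 4), tolerance = 1e-12)
})

test_that("TMM factors have geometric mean 1 and track edgeR on NB data", {
  cm <- null_counts(400, seed = 42)
  f <- tmm_factors(cm)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  skip_if_not_installed("edgeR")
  fe <- edgeR::calcNormFactors(edgeR::DGEList(cm$counts))$samples$norm.factors
  expect_equal(unname(f), fe, tolerance = 0.05)
})

test_that("all-zero samples are rejected", {
  counts <- matrix(0L, 5, 4,
                   dimnames = list(paste0("g", 1:5),
                                   c("control_1", "control_2",
                                     "treated_1", "treated_2")))
  counts[, 1:3] <- 5L
  cond <- c(control_1 = "control", control_2 = "control",
            treated_1 = "treated", treated_2 = "treated")
  expect_error(tmm_factors(count_matrix(counts, cond)), "all-zero")
})

test_that("common dispersion recovers the simulation truth", {
  # NB truth phi = 0.1 at 500 genes, 3 + 3
  cm <- null_counts(500, seed = 43)
  phi_hat <- estimate_common_dispersion(cm)
  expect_gte(phi_hat, 0.07)
  expect_lte(phi_hat, 0.13)
  # Poisson data: estimate collapses to (near) zero
  cm0 <- null_counts(500, seed = 44, phi = 0)
  expect_lt(estimate_common_dispersion(cm0), 0.01)
})

test_that("dispersion estimation matches edgeR's qCML estimate closely", {
  skip_if_not_installed("edgeR")
  cm <- null_counts(500, seed = 45)
  phi_hat <- estimate_common_dispersion(cm)
  d <- edgeR::DGEList(cm$counts, group = cm$condition)
  d <- edgeR::calcNormFactors(d)
  d <- edgeR::estimateCommonDisp(d)
  expect_equal(phi_hat, d$common.dispersion, tolerance = 0.05)
})

test_that("single-replicate conditions are rejected with advice", {
  counts <- matrix(rpois(40, 50), 20, 2,
                   dimnames = list(paste0("g", 1:20),
                                   c("control_1", "treated_1")))
  storage.mode(counts) <- "integer"
  cm <- count_matrix(counts, c(control_1 = "control", treated_1 = "treated"))
  expect_error(estimate_common_dispersion(cm), "single\\s+replicate|single +replicate")
})

test_that("exact test gives p = 1 for perfectly balanced genes", {
  counts <- matrix(20L, 4, 6)
  dimnames(counts) <- list(paste0("g", 1:4),
                           c(paste0("control_", 1:3), paste0("treated_", 1:3)))
  cond <- structure(rep(c("control", "treated"), each = 3),
                    names = colnames(counts))
  cm <- count_matrix(counts, cond)
  f <- structure(rep(1, 6), names = colnames(counts))
  res <- nb_exact_test(cm, f, phi = 0.1)
  expect_true(all(res$pvalue == 1))
  expect_true(all(res$log2fc == 0))
  # phi = 0 reduces to the binomial split test; a 10/10 split of 20
  # with equal libraries sits at the centre: p = 1
  res0 <- nb_exact_test(cm, f, phi = 0)
  expect_true(all(res0$pvalue == 1))
})

test_that("exact-test p-values and fold changes track edgeR's exact test", {
  skip_if_not_installed("edgeR")
  cfg <- sim_config(n_genomes = 5, n_focal_genes = 300, n_planted_operons = 5,
                    rng_seed = 46)
  cm <- generate_counts(cfg, generate_pangenome(cfg)$truth)
  f <- tmm_factors(cm)
  res <- nb_exact_test(cm, f, estimate_common_dispersion(cm, f))
  d <- edgeR::DGEList(cm$counts,
                      group = factor(cm$condition,
                                     levels = c("control", "treated")))
  d <- edgeR::calcNormFactors(d)
  d <- edgeR::estimateCommonDisp(d)
  et <- edgeR::exactTest(d)$table
  expect_gt(cor(-log10(res$pvalue), -log10(et$PValue), method = "spearman"),
            0.99)
  expect_gt(cor(res$log2fc, et$logFC), 0.999)
})

test_that("null simulations are calibrated at the 5% level", {
  cm <- null_counts(2000, seed = 47)
  f <- tmm_factors(cm)
  res <- nb_exact_test(cm, f, estimate_common_dispersion(cm, f))
  frac <- mean(res$pvalue < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("bh_adjust equals the literal step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(48)
  p <- runif(1000)
  expect_equal(bh_adjust(p), oracle_bh(p))
  # monotone: larger raw p never gets a smaller adjusted p
  o <- order(p)
  expect_true(all(diff(bh_adjust(p)[o]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG calls respect the strict threshold semantics", {
  th2 <- de_thresholds(2, 0.05)
  th15 <- de_thresholds(1.5, 0.05)
  rec <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(1.1, -0.9, 1.1, 1),
                    pvalue = c(0.001, 0.001, 0.05, 0.001),
                    fdr = c(0.01, 0.01, 0.05, 0.01))
  out2 <- call_degs(rec, th2)
  expect_identical(out2$call, c("UP", "NS", "NS", "NS"))
  # |log2fc| = 0.9 exceeds log2(1.5) ~ 0.585: DOWN under the 1.5 variant
  out15 <- call_degs(rec, th15)
  expect_identical(out15$call[2], "DOWN")
  # FDR exactly at the cutoff is NS ("less than"), |FC| exactly 2 is NS
  expect_identical(out2$call[3], "NS")
  expect_identical(out2$call[4], "NS")
  # fc_signed and log2fc are mutually consistent
  expect_equal(abs(out2$fc_signed), 2^abs(out2$log2fc))
  expect_equal(sign(out2$fc_signed), sign(out2$log2fc))
})

test_that("planted four-fold effects are recovered with high power", {
  hits <- 0L; total <- 0L
  for (s in 1:5) {
    cfg <- sim_config(n_genomes = 5, n_focal_genes = 200,
                      n_planted_operons = 4, rng_seed = 60 + s)
    pg <- generate_pangenome(cfg)
    cm <- generate_counts(cfg, pg$truth)
    fit <- de_exact_test(cm)
    tab <- as.data.frame(fit)
    planted <- names(pg$truth$operon_membership)[
      !is.na(pg$truth$operon_membership)]
    expected_dir <- ifelse(pg$truth$gene_log2fc_true[planted] > 0, "UP", "DOWN")
    got <- tab$call[match(planted, tab$gene_id)]
    hits <- hits + sum(got == expected_dir)
    total <- total + length(planted)
  }
  expect_gte(hits / total, 0.9)
})

test_that("read_de_table parses, recomputes calls, and locates bad cells", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlog2FC\tPValue\tFDR",
               "g1\t2.5\t0.0001\t0.001",
               "g2\t-0.2\t0.6\t0.8"), path)
  de <- read_de_table(path)
  expect_identical(de$call, c("UP", "NS"))
  # alias logFC accepted
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tlogFC\tPValue\tFDR", "g1\t-3\t0.001\t0.01"), path2)
  expect_identical(read_de_table(path2)$call, "DOWN")
  # non-numeric cell located
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlog2FC\tPValue\tFDR", "g1\toops\t0.1\t0.2"), path3)
  expect_error(read_de_table(path3), "row 1")
  path4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlog2FC\tPValue", "g1\t1\t0.1"), path4)
  expect_error(read_de_table(path4), "missing column")
})

test_that("de_fit methods expose the fit", {
  st <- make_small_study(seed = 49)
  fit <- de_exact_test(st$cm)
  expect_s3_class(fit, "de_fit")
  expect_named(coef(fit), st$ann$gene_id, ignore.order = TRUE)
  expect_output(print(fit), "common dispersion")
  expect_output(summary(fit), "TMM factors")
  tab <- as.data.frame(fit)
  expect_true(all(c("gene_id", "log2fc", "fc_signed", "pvalue", "fdr",
                    "call") %in% names(tab)))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})
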