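#' Construct a validated count matrix with condition labels
#'
#' @param counts non-negative integer matrix, genes x samples, with
#'   unique row names (gene IDs) and column names (sample IDs).
#' @param condition named character vector (or factor) mapping each
#'   sample to `"control"` or `"treated"`.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` and `condition`.
#' @export
count_matrix <- function(counts, condition) {
  if (!is.matrix(counts))
    stopf("count_matrix: 'counts' must be a matrix")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stopf("count_matrix: 'counts' must carry unique gene ids as row names")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stopf("count_matrix: 'counts' must carry unique sample ids as column names")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stopf("count_matrix: counts must be non-negative integers")
  condition <- as.character(condition)[match(colnames(counts),
                                             names(condition))]
  if (any(is.na(condition)))
    stopf("count_matrix: every sample needs a condition label")
  if (!all(condition %in% c("control", "treated")))
    stopf("count_matrix: condition labels must be 'control' or 'treated'")
  if (length(unique(condition)) != 2L)
    stopf("count_matrix: both conditions must be present")
  storage.mode(counts) <- "integer"
  names(condition) <- colnames(counts)
  structure(list(counts = counts, condition = condition),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Count matrix: %d genes x %d samples (%d control, %d treated)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$condition == "control"), sum(x$condition == "treated")))
  invisible(x)
}

#' Read a count matrix and its condition map from TSV files
#'
#' @param counts_path TSV whose first column is `gene_id` followed by
#'   one integer column per sample.
#' @param conditions_path TSV with columns `sample_id` and `condition`.
#' @return A [count_matrix()] object.
#' @export
read_counts <- function(counts_path, conditions_path) {
  tab <- read.delim(counts_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L || !"gene_id" %in% names(tab)[1])
    stopf("read_counts: '%s' must have a leading 'gene_id' column", counts_path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  cond <- read.delim(conditions_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(cond)))
    stopf("read_counts: '%s' must have 'sample_id' and 'condition' columns",
          conditions_path)
  count_matrix(m, structure(cond$condition, names = cond$sample_id))
}

#' Write a count matrix and condition map as TSV
#' @param cm a [count_matrix()] object.
#' @param counts_path,conditions_path output paths.
#' @return `counts_path`, invisibly.
#' @export
write_counts <- function(cm, counts_path, conditions_path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = names(cm$condition),
                         condition = unname(cm$condition)),
              conditions_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values scaling factors against a reference
#' sample (the one whose 75th count-fraction percentile is closest to
#' the mean across samples).  Genes with a zero count in either sample
#' of a comparison are excluded; log-ratios (M) are trimmed 30% from
#' each tail and average log-abundances (A) 5% from each tail.  Factors
#' are rescaled to have geometric mean 1, so effective library sizes are
#' `colSums(counts) * factors`.
#'
#' @param cm a [count_matrix()] object.
#' @return Named numeric vector of positive factors, one per sample.
#' @export
tmm_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  y <- cm$counts
  lib <- colSums(y)
  if (any(lib == 0))
    stopf("tmm_factors: sample(s) with all-zero counts: %s",
          paste(colnames(y)[lib == 0], collapse = ", "))

  uq <- apply(sweep(y, 2, lib, "/"), 2, quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))

  f <- vapply(seq_len(ncol(y)), function(j) {
    if (j == ref) return(1)
    keep <- y[, j] > 0 & y[, ref] > 0
    if (sum(keep) < 10L) return(1)
    pj <- y[keep, j] / lib[j]
    pr <- y[keep, ref] / lib[ref]
    M <- log2(pj / pr)
    A <- 0.5 * log2(pj * pr)
    lo_m <- quantile(M, 0.3); hi_m <- quantile(M, 0.7)
    lo_a <- quantile(A, 0.05); hi_a <- quantile(A, 0.95)
    keep2 <- M >= lo_m & M <= hi_m & A >= lo_a & A <= hi_a
    if (!any(keep2)) return(1)
    2^mean(M[keep2])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(y)
  f
}

## counts rescaled to a common effective library size (the geometric
## mean of the per-sample effective sizes); shared by the dispersion
## estimator and the exact test
pseudo_counts <- function(cm, factors) {
  eff <- colSums(cm$counts) * factors[colnames(cm$counts)]
  common <- exp(mean(log(eff)))
  sweep(cm$counts, 2, common / eff, "*")
}

#' Estimate a common negative-binomial dispersion
#'
#' Maximises the conditional log-likelihood of the dispersion given the
#' per-condition totals of library-size-adjusted counts (the classic
#' small-sample-safe approach for NB counts with few replicates, which
#' removes the per-gene mean nuisance parameters by conditioning).  The
#' search scans a log-spaced grid over `[1e-4, 4]` and refines the best
#' bracket by golden-section/parabolic search.
#'
#' @param cm a [count_matrix()] object with >= 2 replicates in each
#'   condition.
#' @param factors TMM factors from [tmm_factors()].
#' @return The dispersion estimate `phi >= 0` (variance = mu + phi mu^2).
#' @export
estimate_common_dispersion <- function(cm, factors = tmm_factors(cm)) {
  stopifnot(inherits(cm, "count_matrix"))
  n_per <- table(cm$condition)
  if (any(n_per < 2L))
    stopf(paste0("estimate_common_dispersion: condition(s) with a single ",
                 "replicate (%s); supply a known dispersion to nb_exact_test() ",
                 "instead"),
          paste(names(n_per)[n_per < 2L], collapse = ", "))
  pc <- pseudo_counts(cm, factors)

  groups <- lapply(c("control", "treated"), function(cond)
    pc[, cm$condition == cond, drop = FALSE])
  ## drop gene/condition blocks with zero totals (no information)
  blocks <- list()
  for (g in groups) {
    tot <- rowSums(g)
    blocks[[length(blocks) + 1L]] <- g[tot > 0, , drop = FALSE]
  }

  cond_loglik <- function(phi) {
    if (phi <= 0) phi <- 1e-8
    r <- 1 / phi
    ll <- 0
    for (b in blocks) {
      n <- ncol(b)
      z <- rowSums(b)
      ll <- ll + sum(rowSums(lgamma(b + r)) - n * lgamma(r) +
                       lgamma(n * r) - lgamma(z + n * r))
    }
    ll
  }

  grid <- exp(seq(log(1e-4), log(4), length.out = 25))
  ll <- vapply(grid, cond_loglik, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(function(lp) cond_loglik(exp(lp)),
                  interval = c(log(lo), log(hi)), maximum = TRUE,
                  tol = 1e-6)
  phi <- exp(opt$maximum)
  ## likelihood maximised at (or below) the lower search bound means
  ## the data are Poisson-like
  if (i == 1L && ll[1] >= opt$objective) phi <- grid[1]
  phi
}

#' Negative-binomial exact test for a two-condition comparison
#'
#' For each gene, counts are rescaled to a common effective library size
#' (geometric mean) and summed per condition; the p-value is the exact
#' two-sided probability, under a negative binomial with the given
#' common dispersion and conditional on the gene's total, of a
#' per-condition split at least as extreme as the one observed
#' (the smaller tail is doubled and capped at 1).  With `phi = 0` the
#' conditional distribution is binomial.  Log2 fold changes (treated vs
#' control) use normalized per-condition means with a prior count of
#' 0.125 per sample to avoid log of zero.
#'
#' @param cm a [count_matrix()] object.
#' @param factors TMM factors from [tmm_factors()].
#' @param phi common NB dispersion (>= 0), e.g. from
#'   [estimate_common_dispersion()].
#' @param prior_count prior count added per sample for fold-change
#'   stabilisation (default 0.125).
#' @return A data frame with columns `gene_id`, `log2fc`, `pvalue`.
#' @export
nb_exact_test <- function(cm, factors = tmm_factors(cm), phi,
                          prior_count = 0.125) {
  stopifnot(inherits(cm, "count_matrix"))
  if (length(phi) != 1L || is.na(phi) || phi < 0)
    stopf("nb_exact_test: 'phi' must be a single non-negative number")
  pc <- pseudo_counts(cm, factors)
  is_t <- cm$condition == "treated"
  n1 <- sum(!is_t); n2 <- sum(is_t)
  s_ctrl <- rowSums(pc[, !is_t, drop = FALSE])
  s_trt <- rowSums(pc[, is_t, drop = FALSE])

  log2fc <- log2((s_trt + prior_count * n2) / n2) -
    log2((s_ctrl + prior_count * n1) / n1)

  pvalue <- vapply(seq_len(nrow(pc)), function(g) {
    exact_split_pvalue(round(s_ctrl[g]), round(s_trt[g]), n1, n2, phi)
  }, numeric(1))

  data.frame(gene_id = rownames(cm$counts), log2fc = log2fc,
             pvalue = pvalue, row.names = NULL, stringsAsFactors = FALSE)
}

## two-sided exact p-value for the split (s1, s2) of t = s1 + s2
## between n1 and n2 samples with common per-sample mean, NB dispersion
## phi; conditional distribution of S1 | t computed explicitly
exact_split_pvalue <- function(s1, s2, n1, n2, phi) {
  t <- s1 + s2
  if (t == 0) return(1)
  s <- 0:t
  if (phi == 0) {
    logp <- dbinom(s, t, n1 / (n1 + n2), log = TRUE)
  } else {
    r <- t / (n1 + n2)  # common per-sample mean under the null
    size1 <- n1 / phi; size2 <- n2 / phi
    logp <- dnbinom(s, size = size1, mu = n1 * r, log = TRUE) +
      dnbinom(t - s, size = size2, mu = n2 * r, log = TRUE)
    logp <- logp - logsumexp(logp)
  }
  p <- exp(logp)
  lower <- sum(p[s <= s1])
  upper <- sum(p[s >= s1])
  min(1, 2 * min(lower, upper))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment (sort ascending, `q_i = min_{j >= i} p_j m / j`,
#' capped at 1, returned in input order), delegated to
#' [stats::p.adjust()] after validating the inputs.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (FDR), same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stopf("bh_adjust: p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Differential-expression thresholds
#'
#' @param min_abs_fc minimum absolute linear fold change; a gene is
#'   called only if its |FC| strictly exceeds this (default 2; 1.5 is
#'   the common sensitive variant).
#' @param max_fdr FDR must be strictly below this (default 0.05).
#' @return An object of class `de_thresholds`.
#' @export
de_thresholds <- function(min_abs_fc = 2, max_fdr = 0.05) {
  if (!is.numeric(min_abs_fc) || min_abs_fc <= 1)
    stopf("de_thresholds: 'min_abs_fc' must be > 1")
  if (!is.numeric(max_fdr) || max_fdr <= 0 || max_fdr >= 1)
    stopf("de_thresholds: 'max_fdr' must lie in (0, 1)")
  structure(list(min_abs_fc = min_abs_fc, max_fdr = max_fdr),
            class = "de_thresholds")
}

#' Call differentially expressed genes
#'
#' Adds BH-adjusted FDR (if absent), the signed linear fold change
#' `fc_signed = sign(log2fc) * 2^|log2fc|`, and the call: `UP` if
#' `log2fc > log2(min_abs_fc)` and `fdr < max_fdr`, `DOWN` if
#' `log2fc < -log2(min_abs_fc)` and `fdr < max_fdr`, otherwise `NS`.
#' Both cutoffs are strict ("exceeding" the fold change, FDR "less
#' than"), so boundary values are `NS`.
#'
#' @param records data frame with columns `gene_id`, `log2fc`, `pvalue`
#'   (and optionally `fdr`).
#' @param thresholds a [de_thresholds()] object.
#' @return A data frame of DE records: `gene_id`, `log2fc`, `fc_signed`,
#'   `pvalue`, `fdr`, `call`.
#' @export
call_degs <- function(records, thresholds = de_thresholds()) {
  stopifnot(inherits(thresholds, "de_thresholds"))
  need <- c("gene_id", "log2fc", "pvalue")
  if (!all(need %in% names(records)))
    stopf("call_degs: records need columns %s", paste(need, collapse = ", "))
  fdr <- if ("fdr" %in% names(records)) records$fdr else bh_adjust(records$pvalue)
  lfc_cut <- log2(thresholds$min_abs_fc)
  call <- rep("NS", nrow(records))
  sig <- fdr < thresholds$max_fdr
  call[sig & records$log2fc > lfc_cut] <- "UP"
  call[sig & records$log2fc < -lfc_cut] <- "DOWN"
  data.frame(gene_id = records$gene_id,
             log2fc = records$log2fc,
             fc_signed = sign(records$log2fc) * 2^abs(records$log2fc),
             pvalue = records$pvalue,
             fdr = fdr,
             call = call,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the full differential-expression stage
#'
#' One-call wrapper: TMM normalization, common-dispersion estimation
#' (unless supplied), the NB exact test, BH adjustment, and threshold
#' calls.  Returns a classed fit with `print`, `summary`, `coef`,
#' `plot`, and `as.data.frame` methods.
#'
#' @param cm a [count_matrix()] object.
#' @param thresholds a [de_thresholds()] object.
#' @param dispersion optional known common dispersion; estimated from
#'   the data when `NULL`.
#' @return An object of class `de_fit` with elements `table` (the DE
#'   records), `factors`, `dispersion`, `thresholds`.
#' @examples
#' cfg <- sim_config(n_genomes = 20, n_focal_genes = 120,
#'                   n_planted_operons = 4, rng_seed = 11)
#' pg <- generate_pangenome(cfg)
#' fit <- de_exact_test(generate_counts(cfg, pg$truth))
#' summary(fit)
#' @export
de_exact_test <- function(cm, thresholds = de_thresholds(),
                          dispersion = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  factors <- tmm_factors(cm)
  if (is.null(dispersion))
    dispersion <- estimate_common_dispersion(cm, factors)
  res <- nb_exact_test(cm, factors, dispersion)
  tab <- call_degs(res, thresholds)
  structure(list(table = tab, factors = factors, dispersion = dispersion,
                 thresholds = thresholds,
                 n_samples = table(cm$condition)),
            class = "de_fit")
}

#' @export
print.de_fit <- function(x, ...) {
  cat(sprintf("NB exact-test differential expression fit (%d genes)\n",
              nrow(x$table)))
  cat(sprintf("  common dispersion: %.4g\n", x$dispersion))
  cat(sprintf("  thresholds: |FC| > %g, FDR < %g\n",
              x$thresholds$min_abs_fc, x$thresholds$max_fdr))
  tab <- table(factor(x$table$call, levels = c("UP", "DOWN", "NS")))
  cat(sprintf("  calls: %d UP, %d DOWN, %d NS\n",
              tab["UP"], tab["DOWN"], tab["NS"]))
  invisible(x)
}

#' @export
summary.de_fit <- function(object, ...) {
  print(object)
  cat("  TMM factors:\n")
  print(round(object$factors, 4))
  invisible(object)
}

#' @export
coef.de_fit <- function(object, ...) {
  structure(object$table$log2fc, names = object$table$gene_id)
}

#' @export
as.data.frame.de_fit <- function(x, ...) x$table

#' Volcano plot of a differential-expression fit
#' @param x a `de_fit` object.
#' @param ... passed to [plot()].
#' @export
plot.de_fit <- function(x, ...) {
  tab <- x$table
  col <- c(UP = "firebrick", DOWN = "steelblue", NS = "grey70")[tab$call]
  plot(tab$log2fc, -log10(pmax(tab$fdr, 1e-300)), col = col, pch = 16,
       cex = 0.6, xlab = "log2 fold change (treated vs control)",
       ylab = "-log10 FDR", ...)
  abline(v = c(-1, 1) * log2(x$thresholds$min_abs_fc), lty = 2, col = "grey50")
  abline(h = -log10(x$thresholds$max_fdr), lty = 2, col = "grey50")
  invisible(x)
}

#' Read a precomputed differential-expression table
#'
#' Accepts a TSV with columns `gene_id` (or `gene`), `log2FC` (or
#' `logFC`/`log2fc`), `PValue` (or `pvalue`), and `FDR` (or `fdr`),
#' e.g. an edgeR `topTags` export.  Calls are recomputed from the given
#' thresholds, never trusted from the file.
#'
#' @param path path to the table.
#' @param thresholds a [de_thresholds()] object.
#' @return A data frame of DE records as from [call_degs()].
#' @export
read_de_table <- function(path, thresholds = de_thresholds()) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(aliases) {
    hit <- intersect(aliases, names(tab))
    if (length(hit) == 0L)
      stopf("read_de_table: missing column; expected one of: %s",
            paste(aliases, collapse = ", "))
    hit[1]
  }
  gene_col <- pick(c("gene_id", "gene"))
  lfc_col <- pick(c("log2FC", "logFC", "log2fc"))
  p_col <- pick(c("PValue", "pvalue", "p"))
  fdr_col <- pick(c("FDR", "fdr"))
  num <- function(colname) {
    v <- suppressWarnings(as.numeric(tab[[colname]]))
    bad <- which(is.na(v) & !is.na(tab[[colname]]))
    if (length(bad) > 0L)
      stopf("read_de_table: non-numeric value '%s' in column '%s', row %d",
            tab[[colname]][bad[1]], colname, bad[1])
    v
  }
  call_degs(data.frame(gene_id = as.character(tab[[gene_col]]),
                       log2fc = num(lfc_col), pvalue = num(p_col),
                       fdr = num(fdr_col), stringsAsFactors = FALSE),
            thresholds)
}

#' Write differential-expression records as TSV
#' @param de DE record data frame ([call_degs()] / `as.data.frame(de_fit)`).
#' @param path output path; columns are `gene_id`, `log2FC`,
#'   `FC_signed`, `PValue`, `FDR`, `call`.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  out <- data.frame(gene_id = de$gene_id, log2FC = de$log2fc,
                    FC_signed = de$fc_signed, PValue = de$pvalue,
                    FDR = de$fdr, call = de$call)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
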