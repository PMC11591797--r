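#' Configuration for a synthetic phylogenetic-profiling study
#'
#' Bundles every tunable of the synthetic-data generators into one
#' validated object.  The defaults describe a desk-scale study: a panel
#' of 40 genomes, a 500-gene focal genome carrying 12 planted operons of
#' 2--6 genes each, negative-binomial expression counts in triplicate
#' per condition, and planted four-fold (|log2 FC| = 2) expression
#' shifts shared by all genes of an operon.
#'
#' @param n_genomes number of genomes in the panel (the focal genome is
#'   the first).  Larger panels (e.g. 163) are supported.
#' @param n_focal_genes number of genes annotated on the focal genome.
#' @param n_planted_operons number of ground-truth operons planted among
#'   the focal genes.
#' @param operon_size_range integer pair; operon sizes are drawn
#'   uniformly from this range (minimum 2).
#' @param planted_log2fc absolute log2 fold-change planted on every gene
#'   of an operon; the sign is drawn per operon.
#' @param nb_dispersion negative-binomial dispersion phi of the count
#'   generator (variance = mu + phi mu^2); 0 gives Poisson counts.
#' @param mean_expression median of the log-normal distribution of
#'   per-gene baseline mean counts.
#' @param mean_expression_sdlog log-scale standard deviation of baseline
#'   means (spread of expression levels across genes).
#' @param n_replicates biological replicates per condition.
#' @param intergenic_gap_bp gap in bp between the end of one gene and
#'   the start of the next; must stay below the 10,000 bp proximity
#'   window so planted operons satisfy the proximity criterion by
#'   construction.
#' @param gene_length_bp length of every simulated gene, bp.
#' @param profile_noise_flips number of random bit flips applied to each
#'   planted gene's phylogenetic profile (0 = perfectly inherited).
#' @param ct_noise_sd Gaussian noise on simulated qPCR Ct values, cycles.
#' @param qpcr_efficiency per-cycle amplification factor of the
#'   simulated assays (2 = perfect doubling).
#' @param rng_seed integer seed; every generator derives its stream from
#'   it, so a fixed seed gives byte-identical outputs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genomes = 20, n_focal_genes = 100,
#'                   n_planted_operons = 4, rng_seed = 7)
#' cfg
#' @export
sim_config <- function(n_genomes = 40L,
                       n_focal_genes = 500L,
                       n_planted_operons = 12L,
                       operon_size_range = c(2L, 6L),
                       planted_log2fc = 2,
                       nb_dispersion = 0.1,
                       mean_expression = 200,
                       mean_expression_sdlog = 1,
                       n_replicates = 3L,
                       intergenic_gap_bp = 200L,
                       gene_length_bp = 900L,
                       profile_noise_flips = 0L,
                       ct_noise_sd = 0.15,
                       qpcr_efficiency = 2,
                       rng_seed = 1L) {
  cfg <- list(
    n_genomes = as.integer(n_genomes),
    n_focal_genes = as.integer(n_focal_genes),
    n_planted_operons = as.integer(n_planted_operons),
    operon_size_range = as.integer(operon_size_range),
    planted_log2fc = as.numeric(planted_log2fc),
    nb_dispersion = as.numeric(nb_dispersion),
    mean_expression = as.numeric(mean_expression),
    mean_expression_sdlog = as.numeric(mean_expression_sdlog),
    n_replicates = as.integer(n_replicates),
    intergenic_gap_bp = as.integer(intergenic_gap_bp),
    gene_length_bp = as.integer(gene_length_bp),
    profile_noise_flips = as.integer(profile_noise_flips),
    ct_noise_sd = as.numeric(ct_noise_sd),
    qpcr_efficiency = as.numeric(qpcr_efficiency),
    rng_seed = as.integer(rng_seed)
  )
  counts <- c("n_genomes", "n_focal_genes", "n_planted_operons",
              "n_replicates", "gene_length_bp")
  for (nm in counts)
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stopf("sim_config: '%s' must be a positive count", nm)
  if (cfg$n_genomes < 2L)
    stopf("sim_config: 'n_genomes' must be at least 2 (focal genome plus panel)")
  if (length(cfg$operon_size_range) != 2L ||
      any(is.na(cfg$operon_size_range)) ||
      cfg$operon_size_range[1] < 2L ||
      cfg$operon_size_range[1] > cfg$operon_size_range[2])
    stopf("sim_config: 'operon_size_range' must be an increasing pair with minimum >= 2")
  if (is.na(cfg$intergenic_gap_bp) || cfg$intergenic_gap_bp < 1L)
    stopf("sim_config: 'intergenic_gap_bp' must be >= 1 (genes may not overlap)")
  if (cfg$intergenic_gap_bp >= 10000L)
    stopf(paste0("sim_config: 'intergenic_gap_bp' (%d) must be below the 10,000 bp ",
                 "proximity window so planted operons satisfy proximity by construction"),
          cfg$intergenic_gap_bp)
  if (cfg$nb_dispersion < 0) stopf("sim_config: 'nb_dispersion' must be >= 0")
  if (cfg$mean_expression <= 0) stopf("sim_config: 'mean_expression' must be > 0")
  if (cfg$profile_noise_flips < 0L || cfg$profile_noise_flips > cfg$n_genomes - 1L)
    stopf("sim_config: 'profile_noise_flips' must lie in [0, n_genomes - 1]")
  if (cfg$qpcr_efficiency <= 1 || cfg$qpcr_efficiency > 2.2)
    stopf("sim_config: 'qpcr_efficiency' must lie in (1, 2.2]")
  ## the layout must fit: every planted operon is separated from the
  ## next by at least one background gene
  max_operon_genes <- cfg$n_planted_operons * cfg$operon_size_range[2]
  if (max_operon_genes + cfg$n_planted_operons + 1L > cfg$n_focal_genes)
    stopf(paste0("sim_config: %d operons of up to %d genes do not fit among ",
                 "%d focal genes with background separators"),
          cfg$n_planted_operons, cfg$operon_size_range[2], cfg$n_focal_genes)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  genome panel:     %d genomes (focal = first)\n", x$n_genomes))
  cat(sprintf("  focal genes:      %d, %d planted operons of %d-%d genes\n",
              x$n_focal_genes, x$n_planted_operons,
              x$operon_size_range[1], x$operon_size_range[2]))
  cat(sprintf("  planted effect:   |log2FC| = %g, NB dispersion = %g, %d+%d replicates\n",
              x$planted_log2fc, x$nb_dispersion, x$n_replicates, x$n_replicates))
  cat(sprintf("  gene layout:      %d bp genes, %d bp gaps, %d profile bit flips\n",
              x$gene_length_bp, x$intergenic_gap_bp, x$profile_noise_flips))
  cat(sprintf("  rng seed:         %d\n", x$rng_seed))
  invisible(x)
}

## derive a sub-seed for one generator stage from the master seed;
## keeps the four generators' streams decoupled but fully determined
stage_seed <- function(cfg, offset) (cfg$rng_seed + offset) %% .Machine$integer.max

#' Generate a synthetic genome panel with planted identically-inherited
#' gene groups
#'
#' Creates one orthogroup per focal gene over a panel of genomes.  Genes
#' of the same planted operon receive identical presence/absence
#' patterns across the panel (before optional noise flips); background
#' genes receive independent random patterns with presence probability
#' 0.5.  Every orthogroup is present in the focal genome, mirroring the
#' fact that profiles are built for focal-strain genes.
#'
#' @param cfg a [sim_config()] object.
#' @return A list with elements
#'   \describe{
#'     \item{orthogroups}{named list orthogroup -> (genome -> character
#'       vector of member gene IDs), the in-memory form of an
#'       OrthoFinder `Orthogroups.tsv` table (see [write_orthogroups()]).}
#'     \item{presence}{integer 0/1 matrix, orthogroups x genomes.}
#'     \item{gene_orthogroup}{named character vector mapping each focal
#'       gene to its orthogroup.}
#'     \item{panel}{ordered genome identifiers; `focal_genome` names the
#'       focal one.}
#'     \item{truth}{a `ground_truth` object: `operon_membership` (named
#'       vector, `NA` for background genes), `gene_log2fc_true`,
#'       `operons` (list operon -> ordered member genes), and
#'       `gene_order` (genomic order used by [generate_annotation()]).}
#'   }
#' @export
generate_pangenome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg, 0L))

  panel <- sprintf("G%03d", seq_len(cfg$n_genomes))
  focal <- panel[1]
  genes <- sprintf("gene%04d", seq_len(cfg$n_focal_genes))

  size_span <- cfg$operon_size_range[2] - cfg$operon_size_range[1] + 1L
  sizes <- cfg$operon_size_range[1] +
    sample.int(size_span, cfg$n_planted_operons, replace = TRUE) - 1L
  n_op_genes <- sum(sizes)
  n_bg <- cfg$n_focal_genes - n_op_genes
  k <- cfg$n_planted_operons

  ## distribute background genes into k + 1 slots around the operon
  ## blocks; interior slots get at least one separator gene
  extra <- n_bg - (k - 1L)
  alloc <- as.integer(rmultinom_one(extra, k + 1L))
  slot_bg <- alloc + c(0L, rep(1L, k - 1L), 0L)

  operon_id <- rep(NA_character_, cfg$n_focal_genes)
  pos <- 0L
  for (i in seq_len(k)) {
    pos <- pos + slot_bg[i]
    operon_id[(pos + 1L):(pos + sizes[i])] <- sprintf("operon%02d", i)
    pos <- pos + sizes[i]
  }
  names(operon_id) <- genes

  ## planted fold changes: one sign per operon, shared by its members
  op_names <- sprintf("operon%02d", seq_len(k))
  op_sign <- sample(c(-1, 1), k, replace = TRUE)
  names(op_sign) <- op_names
  lfc <- ifelse(is.na(operon_id), 0, cfg$planted_log2fc * op_sign[operon_id])
  names(lfc) <- genes

  ## presence patterns: focal bit always 1; one shared pattern per
  ## planted operon, independent patterns for background genes
  pres <- matrix(0L, nrow = cfg$n_focal_genes, ncol = cfg$n_genomes,
                 dimnames = list(genes, panel))
  pres[, 1] <- 1L
  op_pattern <- lapply(op_names, function(o)
    as.integer(runif(cfg$n_genomes - 1L) < 0.5))
  names(op_pattern) <- op_names
  for (g in seq_along(genes)) {
    if (is.na(operon_id[g])) {
      pres[g, -1] <- as.integer(runif(cfg$n_genomes - 1L) < 0.5)
    } else {
      pres[g, -1] <- op_pattern[[operon_id[g]]]
    }
  }
  if (cfg$profile_noise_flips > 0L) {
    planted <- which(!is.na(operon_id))
    for (g in planted) {
      fl <- sample(cfg$n_genomes - 1L, cfg$profile_noise_flips)
      pres[g, 1L + fl] <- 1L - pres[g, 1L + fl]
    }
  }

  og_ids <- sprintf("OG%07d", seq_along(genes))
  gene_orthogroup <- structure(og_ids, names = genes)
  orthogroups <- vector("list", length(genes))
  names(orthogroups) <- og_ids
  for (g in seq_along(genes)) {
    members <- lapply(panel, function(gg) character(0))
    names(members) <- panel
    present_in <- panel[pres[g, ] == 1L]
    for (gg in present_in) {
      members[[gg]] <- if (gg == focal) genes[g] else paste0(genes[g], "_", gg)
    }
    orthogroups[[g]] <- members
  }
  rownames(pres) <- og_ids

  operons <- split(genes[!is.na(operon_id)], operon_id[!is.na(operon_id)])
  truth <- structure(
    list(operon_membership = operon_id,
         gene_log2fc_true = lfc,
         operons = operons[op_names],
         gene_order = genes),
    class = "ground_truth")

  list(orthogroups = structure(orthogroups, panel = panel, class = "orthogroups"),
       presence = pres,
       gene_orthogroup = gene_orthogroup,
       panel = panel,
       focal_genome = focal,
       truth = truth)
}

## draw one multinomial allocation of n items into k equiprobable slots
rmultinom_one <- function(n, k) {
  if (n == 0L) return(integer(k))
  tabulate(sample.int(k, n, replace = TRUE), nbins = k)
}

#' Generate a GFF3 gene annotation for the synthetic focal genome
#'
#' Lays the focal genes left-to-right on a single contig in the order
#' fixed by [generate_pangenome()], with configured gene lengths and
#' intergenic gaps.  All genes of a planted operon are contiguous and on
#' one randomly chosen strand; background genes get random strands.
#' Because the intergenic gap is below the 10,000 bp proximity window,
#' every planted operon satisfies the proximity criterion by
#' construction.
#'
#' @param cfg a [sim_config()] object.
#' @param truth the `truth` element returned by [generate_pangenome()].
#' @return A data frame of gene features (`gene_id`, `contig`, `start`,
#'   `end`, `strand`) with 1-based inclusive coordinates, in genomic
#'   order; serialise with [write_gff3()].
#' @export
generate_annotation <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "ground_truth"))
  set.seed(stage_seed(cfg, 1L))

  genes <- truth$gene_order
  n <- length(genes)
  membership <- truth$operon_membership[genes]

  op_names <- names(truth$operons)
  op_strand <- sample(c("+", "-"), length(op_names), replace = TRUE)
  names(op_strand) <- op_names
  strand <- ifelse(is.na(membership),
                   sample(c("+", "-"), n, replace = TRUE),
                   op_strand[membership])

  step <- cfg$gene_length_bp + cfg$intergenic_gap_bp
  start <- 1L + (seq_len(n) - 1L) * step
  end <- start + cfg$gene_length_bp - 1L
  if (max(end) > .Machine$integer.max)
    stopf("generate_annotation: layout overflows integer coordinates; reduce gene count or lengths")

  data.frame(gene_id = genes, contig = "contig_1",
             start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Generate a negative-binomial count matrix with planted fold changes
#'
#' Per-gene baseline means are log-normal around `mean_expression`;
#' treated-condition means are multiplied by `2^log2fc_true`.  Counts
#' are drawn independently per gene and sample from a negative binomial
#' with dispersion `nb_dispersion` (Poisson when 0).
#'
#' @param cfg a [sim_config()] object.
#' @param truth the `truth` element returned by [generate_pangenome()].
#' @return A [count_matrix()] object with samples `control_1..n` and
#'   `treated_1..n`.
#' @export
generate_counts <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "ground_truth"))
  set.seed(stage_seed(cfg, 2L))

  genes <- truth$gene_order
  n <- length(genes)
  mu0 <- rlnorm(n, meanlog = log(cfg$mean_expression),
                sdlog = cfg$mean_expression_sdlog)
  lfc <- truth$gene_log2fc_true[genes]

  samples <- c(paste0("control_", seq_len(cfg$n_replicates)),
               paste0("treated_", seq_len(cfg$n_replicates)))
  condition <- structure(rep(c("control", "treated"), each = cfg$n_replicates),
                         names = samples)
  mu <- mu0 * 2^outer(lfc, as.numeric(condition == "treated"))
  counts <- matrix(0L, n, length(samples), dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    counts[, j] <- if (cfg$nb_dispersion == 0) {
      rpois(n, mu[, j])
    } else {
      rnbinom(n, mu = mu[, j], size = 1 / cfg$nb_dispersion)
    }
  }
  count_matrix(counts, condition)
}

#' Generate a synthetic qPCR Ct table
#'
#' Simulates threshold-cycle measurements under the standard
#' exponential-amplification model: `Ct = intercept - log_E(expression)
#' + noise`, where `E` is the per-gene amplification efficiency.  A
#' planted log2 fold change of `x` with `E = 2` therefore shifts the
#' treated-condition Ct by exactly `-x` cycles.  Control (reference)
#' genes must have a true fold change of zero.
#'
#' @param cfg a [sim_config()] object (`ct_noise_sd` and
#'   `qpcr_efficiency` are used here).
#' @param truth the `truth` element returned by [generate_pangenome()].
#' @param control_genes character vector of reference gene IDs with true
#'   log2 fold change 0; at least one required, two or more recommended.
#' @param target_genes genes to assay; defaults to the first gene of up
#'   to five planted operons.
#' @return A [ct_table()] object.
#' @export
generate_qpcr <- function(cfg, truth, control_genes, target_genes = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "ground_truth"))
  set.seed(stage_seed(cfg, 3L))

  lfc <- truth$gene_log2fc_true
  if (length(control_genes) < 1L)
    stopf("generate_qpcr: at least one control gene is required")
  if (any(!control_genes %in% names(lfc)))
    stopf("generate_qpcr: unknown control gene(s): %s",
          paste(setdiff(control_genes, names(lfc)), collapse = ", "))
  if (any(lfc[control_genes] != 0))
    stopf("generate_qpcr: control genes must have true log2 fold change 0")
  if (is.null(target_genes)) {
    target_genes <- vapply(truth$operons[seq_len(min(5L, length(truth$operons)))],
                           `[`, character(1), 1L)
  }
  genes <- unique(c(target_genes, control_genes))

  ## per-gene baseline Ct offset: assays differ in abundance and primer
  ## placement, so intercepts vary by a few cycles
  base_ct <- 30 + rnorm(length(genes), 0, 1.5)
  names(base_ct) <- genes
  E <- cfg$qpcr_efficiency

  rows <- expand.grid(gene_id = genes,
                      replicate = seq_len(cfg$n_replicates),
                      condition = c("control", "treated"),
                      stringsAsFactors = FALSE)
  rel <- 2^(lfc[rows$gene_id] * (rows$condition == "treated"))
  ct <- base_ct[rows$gene_id] - log(rel) / log(E) +
    rnorm(nrow(rows), 0, cfg$ct_noise_sd)
  tbl <- data.frame(gene_id = rows$gene_id,
                    sample_id = paste0(rows$condition, "_", rows$replicate),
                    condition = rows$condition,
                    ct = as.numeric(ct),
                    efficiency = E,
                    stringsAsFactors = FALSE)
  ct_table(tbl, control_genes)
}

#' Simulate a complete study and write its files to a directory
#'
#' Runs all four generators and serialises their outputs in the formats
#' the reader functions consume: `orthogroups.tsv`, `genes.gff3`,
#' `counts.tsv`, `conditions.tsv`, `qpcr.tsv`, and `truth.json` (the
#' planted ground truth).
#'
#' @param cfg a [sim_config()] object.
#' @param outdir output directory, created if needed.
#' @param control_genes reference genes for the qPCR table; defaults to
#'   the first two background (non-operon) genes.
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
simulate_study <- function(cfg, outdir, control_genes = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  pg <- generate_pangenome(cfg)
  truth <- pg$truth
  ann <- generate_annotation(cfg, truth)
  cm <- generate_counts(cfg, truth)
  if (is.null(control_genes)) {
    bg <- names(truth$operon_membership)[is.na(truth$operon_membership)]
    control_genes <- bg[1:2]
  }
  qp <- generate_qpcr(cfg, truth, control_genes)

  paths <- list(
    orthogroups = file.path(outdir, "orthogroups.tsv"),
    gff = file.path(outdir, "genes.gff3"),
    counts = file.path(outdir, "counts.tsv"),
    conditions = file.path(outdir, "conditions.tsv"),
    qpcr = file.path(outdir, "qpcr.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  write_orthogroups(pg$orthogroups, paths$orthogroups)
  write_gff3(ann, paths$gff)
  write_counts(cm, paths$counts, paths$conditions)
  write_ct_table(qp, paths$qpcr)
  truth_json <- list(
    operon_membership = as.list(ifelse(is.na(truth$operon_membership),
                                       NA, truth$operon_membership)),
    gene_log2fc_true = as.list(truth$gene_log2fc_true),
    operons = truth$operons,
    control_genes = control_genes
  )
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)

  invisible(list(config = cfg, pangenome = pg, truth = truth,
                 annotation = ann, counts = cm, qpcr = qp,
                 control_genes = control_genes, paths = paths))
}
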