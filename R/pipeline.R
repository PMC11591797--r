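## key checksum vectors by file name, not by (temporary) full path
basename_keys <- function(x) {
  names(x) <- basename(names(x))
  x
}

#' Run the full operon-inference pipeline from a configuration
#'
#' Executes the stages in order — phylogenetic profiles and distance
#' matrix, differential expression (computed from counts or ingested
#' from a precomputed table), operon inference, and the optional COG
#' and qPCR summaries — writing every artifact plus a `manifest.json`
#' recording package version, parameters, seed, and MD5 checksums of
#' all inputs and outputs.  Any stage failure aborts with a
#' stage-named error and removes the partial outputs of this run.
#'
#' @param config path to a YAML file, or an equivalent named list, with
#'   fields:
#'   \describe{
#'     \item{orthogroups}{path to an `Orthogroups.tsv`-dialect table.}
#'     \item{gff}{path to the focal genome's GFF3 annotation.}
#'     \item{focal_genome}{name of the focal genome column.}
#'     \item{counts, conditions}{count matrix and condition map TSVs
#'       (either these or `de_table`).}
#'     \item{de_table}{precomputed DE table (alternative to counts).}
#'     \item{cog_map}{optional gene-to-COG TSV.}
#'     \item{qpcr, control_genes}{optional Ct table and its reference
#'       genes.}
#'     \item{outdir}{output directory.}
#'     \item{params}{optional: `distance_cutoff`, `window_bp`,
#'       `min_abs_fc`, `max_fdr`, `require_significance`,
#'       `exclude_focal`.}
#'     \item{seed}{optional integer seed recorded in the manifest (the
#'       analysis itself is deterministic).}
#'   }
#' @return Invisibly, a list with the fitted objects (`profiles`,
#'   `distances`, `de`, `operons`, `cog`, `qpcr`), output `paths`, and
#'   the `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stopf("run_pipeline: config file '%s' does not exist", config)
    config <- yaml::read_yaml(config)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("run_pipeline: stage '%s' failed: %s", name, conditionMessage(e)))
  }
  need_input <- function(field) {
    p <- config[[field]]
    if (is.null(p))
      stopf("run_pipeline: stage 'config' failed: required input '%s' missing",
            field)
    if (!file.exists(p))
      stopf("run_pipeline: stage 'config' failed: input '%s' path '%s' does not exist",
            field, p)
    p
  }

  og_path <- need_input("orthogroups")
  gff_path <- need_input("gff")
  if (is.null(config$focal_genome))
    stopf("run_pipeline: stage 'config' failed: 'focal_genome' missing")
  if (is.null(config$outdir))
    stopf("run_pipeline: stage 'config' failed: 'outdir' missing")
  use_counts <- !is.null(config$counts)
  if (use_counts) {
    counts_path <- need_input("counts")
    cond_path <- need_input("conditions")
  } else {
    de_path <- need_input("de_table")
  }

  p <- config$params
  thresholds <- de_thresholds(
    min_abs_fc = if (is.null(p$min_abs_fc)) 2 else p$min_abs_fc,
    max_fdr = if (is.null(p$max_fdr)) 0.05 else p$max_fdr)
  params <- operon_params(
    distance_cutoff = if (is.null(p$distance_cutoff)) 0.001 else p$distance_cutoff,
    window_bp = if (is.null(p$window_bp)) 10000 else p$window_bp,
    de_thresholds = thresholds,
    require_significance = if (is.null(p$require_significance)) TRUE
                           else p$require_significance)
  seed <- if (is.null(config$seed)) NA_integer_ else as.integer(config$seed)
  if (!is.na(seed)) set.seed(seed)

  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok && length(written) > 0L) unlink(written), add = TRUE)
  reg <- function(path) { written <<- c(written, path); path }

  ## --- profiles ---
  gff <- stage("profiles", read_gff3(gff_path))
  og <- stage("profiles", read_orthogroups(og_path))
  prof <- stage("profiles", build_profiles(
    og, focal_genome = config$focal_genome, genes = gff$gene_id))
  dm <- stage("profiles", profile_distance_matrix(
    prof, exclude_focal = isTRUE(p$exclude_focal)))
  stage("profiles", write_matrix_tsv(prof, reg(file.path(outdir, "profiles.tsv"))))
  stage("profiles", write_matrix_tsv(dm, reg(file.path(outdir, "distances.tsv"))))

  ## --- differential expression ---
  if (use_counts) {
    cm <- stage("de", read_counts(counts_path, cond_path))
    fit <- stage("de", de_exact_test(cm, thresholds))
    de <- as.data.frame(fit)
  } else {
    fit <- NULL
    de <- stage("de", read_de_table(de_path, thresholds))
  }
  stage("de", write_de_table(de, reg(file.path(outdir, "de_results.tsv"))))

  ## --- operons ---
  operons <- stage("operons", infer_operons(dm, gff, de, params))
  stage("operons", write_operons(operons, reg(file.path(outdir, "operons.tsv"))))
  reg(file.path(outdir, "operons.json"))

  ## --- cog (optional) ---
  cog_summary <- NULL
  if (!is.null(config$cog_map)) {
    cog <- stage("cog", read_cog_map(need_input("cog_map")))
    cog_summary <- stage("cog", summarize_by_category(de, cog))
    stage("cog", write.table(cog_summary,
                             reg(file.path(outdir, "cog_summary.tsv")),
                             sep = "\t", quote = FALSE, row.names = FALSE))
  }

  ## --- qpcr (optional) ---
  qpcr_results <- NULL
  if (!is.null(config$qpcr)) {
    if (is.null(config$control_genes))
      stopf("run_pipeline: stage 'qpcr' failed: 'control_genes' missing")
    ct <- stage("qpcr", read_ct_table(need_input("qpcr"),
                                      config$control_genes))
    qpcr_results <- stage("qpcr", compare_to_rnaseq(ddct_all(ct), de))
    stage("qpcr", write.table(qpcr_results,
                              reg(file.path(outdir, "qpcr_results.tsv")),
                              sep = "\t", quote = FALSE, row.names = FALSE))
  }

  ## --- manifest ---
  inputs <- c(orthogroups = og_path, gff = gff_path,
              if (use_counts) c(counts = counts_path, conditions = cond_path)
              else c(de_table = de_path),
              if (!is.null(config$cog_map)) c(cog_map = config$cog_map),
              if (!is.null(config$qpcr)) c(qpcr = config$qpcr))
  manifest <- list(
    package = "ppoperon",
    version = as.character(packageVersion("ppoperon")),
    r_version = R.version.string,
    seed = seed,
    parameters = list(distance_cutoff = params$distance_cutoff,
                      window_bp = params$window_bp,
                      min_abs_fc = thresholds$min_abs_fc,
                      max_fdr = thresholds$max_fdr,
                      require_significance = params$require_significance),
    input_checksums = as.list(basename_keys(tools::md5sum(unname(inputs)))),
    output_checksums = as.list(basename_keys(
      tools::md5sum(written[file.exists(written)])))
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  ok <- TRUE
  invisible(list(profiles = prof, distances = dm, de = de, de_fit = fit,
                 operons = operons, cog = cog_summary, qpcr = qpcr_results,
                 paths = c(written, manifest_path), manifest = manifest))
}
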