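# GFF3 reading and the operon-inference core

toy_gff_lines <- function() c(
  "##gff-version 3",
  "ctg1\tsim\tgene\t100\t400\t.\t+\t.\tID=g1",
  "ctg1\tsim\tgene\t600\t900\t.\t+\t.\tID=g2",
  "ctg1\tsim\tgene\t1100\t1400\t.\t+\t.\tID=g3")

test_that("read_gff3 parses gene features in coordinate order", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(rev(toy_gff_lines())[c(2, 1, 3, 4)], path)  # shuffled body
  feats <- read_gff3(path)
  expect_identical(feats$gene_id, c("g1", "g2", "g3"))
  expect_identical(feats$start, c(100L, 600L, 1100L))
  expect_identical(feats$strand, rep("+", 3))
})

test_that("read_gff3 accepts CRLF and rejects malformed features", {
  crlf <- withr::local_tempfile(fileext = ".gff3")
  writeBin(charToRaw(paste0(paste(toy_gff_lines(), collapse = "\r\n"), "\r\n")),
           crlf)
  expect_identical(read_gff3(crlf)$gene_id, c("g1", "g2", "g3"))

  nostrand <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "ctg1\tsim\tgene\t1\t10\t.\t.\t.\tID=g1"), nostrand)
  expect_error(read_gff3(nostrand), "line 2.*strand")

  noid <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("ctg1\tsim\tgene\t1\t10\t.\t+\t.\tName=g1"), noid)
  expect_error(read_gff3(noid), "line 1.*ID")

  badcoord <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("ctg1\tsim\tgene\t50\t10\t.\t+\t.\tID=g1"), badcoord)
  expect_error(read_gff3(badcoord), "line 1.*coordinates")
})

test_that("read_gff3 agrees with rtracklayer on simulated annotations", {
  skip_if_not_installed("rtracklayer")
  cfg <- sim_config(n_genomes = 8, n_focal_genes = 40, n_planted_operons = 2,
                    rng_seed = 71)
  ann <- generate_annotation(cfg, generate_pangenome(cfg)$truth)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, path)
  ours <- read_gff3(path)
  gr <- rtracklayer::import(path)
  idx <- match(ours$gene_id, gr$ID)
  expect_identical(ours$start, BiocGenerics::start(gr)[idx])
  expect_identical(ours$end, BiocGenerics::end(gr)[idx])
  expect_identical(ours$strand, as.character(BiocGenerics::strand(gr))[idx])
})

# hand-built instance: three contiguous same-strand genes with
# identical profiles, all called DOWN
toy_instance <- function(strand = c("+", "+", "+"),
                         call = c("DOWN", "DOWN", "DOWN"),
                         starts = c(100L, 1300L, 2500L)) {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), contig = "ctg1",
                      start = starts, end = starts + 900L,
                      strand = strand, stringsAsFactors = FALSE)
  prof <- matrix(rep(c(1L, 0L, 1L, 1L, 0L), 3), 3, byrow = TRUE,
                 dimnames = list(genes$gene_id, paste0("G", 1:5)))
  dm <- profile_distance_matrix(prof)
  de <- data.frame(gene_id = genes$gene_id,
                   log2fc = ifelse(call == "UP", 2, ifelse(call == "DOWN", -2, 0.1)),
                   fc_signed = ifelse(call == "UP", 4, ifelse(call == "DOWN", -4, 1.07)),
                   pvalue = ifelse(call == "NS", 0.9, 1e-5),
                   fdr = ifelse(call == "NS", 0.9, 1e-4),
                   call = call, stringsAsFactors = FALSE)
  list(dm = dm, genes = genes, de = de)
}

test_that("all three criteria together yield one candidate", {
  ti <- toy_instance()
  os <- infer_operons(ti$dm, ti$genes, ti$de)
  expect_length(os$candidates, 1)
  cand <- os$candidates[[1]]
  expect_identical(cand$member_genes, c("g1", "g2", "g3"))
  expect_identical(cand$direction, "DOWN")
  expect_identical(cand$strand, "+")
  expect_equal(cand$max_internal_distance, 0)
  expect_identical(cand$max_gap_bp, 299L)
})

test_that("a middle gene on the opposite strand breaks it into the flanking pair", {
  ti <- toy_instance(strand = c("+", "-", "+"))
  os <- infer_operons(ti$dm, ti$genes, ti$de)
  # adjacency is geometric: g1 and g3 are 1499 bp apart edge-to-edge,
  # well inside the window, so they still pair
  expect_length(os$candidates, 1)
  expect_identical(os$candidates[[1]]$member_genes, c("g1", "g3"))
})

test_that("a non-significant middle gene is excluded but flanks still pair", {
  ti <- toy_instance(call = c("DOWN", "NS", "DOWN"))
  os <- infer_operons(ti$dm, ti$genes, ti$de)
  expect_length(os$candidates, 1)
  expect_identical(os$candidates[[1]]$member_genes, c("g1", "g3"))
})

test_that("discordant directions never share a candidate", {
  ti <- toy_instance(call = c("DOWN", "UP", "DOWN"))
  os <- infer_operons(ti$dm, ti$genes, ti$de)
  expect_length(os$candidates, 1)
  expect_identical(os$candidates[[1]]$member_genes, c("g1", "g3"))
  ti2 <- toy_instance(call = c("DOWN", "UP", "UP"))
  os2 <- infer_operons(ti2$dm, ti2$genes, ti2$de)
  expect_length(os2$candidates, 1)
  expect_identical(os2$candidates[[1]]$member_genes, c("g2", "g3"))
})

test_that("genes beyond the proximity window never chain", {
  ti <- toy_instance(starts = c(100L, 1300L, 30000L))
  os <- infer_operons(ti$dm, ti$genes, ti$de)
  expect_length(os$candidates, 1)
  expect_identical(os$candidates[[1]]$member_genes, c("g1", "g2"))
})

test_that("sign concordance without significance joins genes only when allowed", {
  ti <- toy_instance(call = c("DOWN", "NS", "DOWN"))
  ti$de$log2fc[2] <- -0.4  # same sign, not significant
  p <- operon_params(require_significance = FALSE)
  os <- infer_operons(ti$dm, ti$genes, ti$de, p)
  expect_identical(os$candidates[[1]]$member_genes, c("g1", "g2", "g3"))
})

test_that("candidates always satisfy their structural invariants", {
  for (seed in c(81, 82, 83)) {
    st <- make_small_study(seed = seed)
    fit <- de_exact_test(st$cm)
    os <- infer_operons(st$dm, st$ann, as.data.frame(fit))
    de <- as.data.frame(fit)
    for (cand in os$candidates) {
      rows <- st$ann[match(cand$member_genes, st$ann$gene_id), ]
      expect_gte(length(cand$member_genes), 2)
      expect_length(unique(rows$contig), 1)
      expect_length(unique(rows$strand), 1)
      expect_false(is.unsorted(rows$start))
      dsub <- st$dm[cand$member_genes, cand$member_genes]
      expect_true(all(dsub[upper.tri(dsub)] < os$params$distance_cutoff))
      gaps <- rows$start[-1] - rows$end[-nrow(rows)] - 1L
      expect_true(all(gaps <= os$params$window_bp))
      calls <- de$call[match(cand$member_genes, de$gene_id)]
      expect_true(all(calls == cand$direction))
    }
  }
})

test_that("inference matches exhaustive enumeration on small instances", {
  for (seed in c(91, 92, 93, 94)) {
    st <- make_small_study(seed = seed)
    fit <- de_exact_test(st$cm)
    de <- as.data.frame(fit)
    n_de <- sum(de$call != "NS")
    skip_if(n_de > 25, "instance too large for the enumeration oracle")
    params <- operon_params()
    os <- infer_operons(st$dm, st$ann, de, params)
    expected <- oracle_enumerate_operons(st$dm, st$ann, de, params)
    expected <- expected[order(vapply(expected, paste, "", collapse = ","))]
    expect_identical(candidate_sets(os), expected)
  }
})

test_that("coverage is monotone in the distance cutoff and the window", {
  for (seed in 101:105) {
    st <- make_small_study(seed = seed)
    fit <- de_exact_test(st$cm)
    de <- as.data.frame(fit)
    coverage <- function(cutoff, window) {
      os <- infer_operons(st$dm, st$ann, de,
                          operon_params(distance_cutoff = cutoff,
                                        window_bp = window))
      sum(vapply(os$candidates, function(c) length(c$member_genes), 1L))
    }
    base <- coverage(0.001, 10000)
    expect_gte(coverage(0.01, 10000), base)
    expect_gte(coverage(0.001, 20000), base)
  }
})

test_that("operon tables round-trip through TSV and JSON mirrors exist", {
  st <- make_small_study(seed = 111)
  fit <- de_exact_test(st$cm)
  os <- infer_operons(st$dm, st$ann, as.data.frame(fit))
  path <- file.path(withr::local_tempdir(), "operons.tsv")
  write_operons(os, path)
  expect_true(file.exists(sub("\\.tsv$", ".json", path)))
  back <- read_operons(path)
  expect_equal(back, as.data.frame(os), ignore_attr = TRUE)

  # empty set: header-only TSV
  empty <- infer_operons(st$dm, st$ann,
                         data.frame(gene_id = st$ann$gene_id, log2fc = 0,
                                    fc_signed = 1, pvalue = 1, fdr = 1,
                                    call = "NS", stringsAsFactors = FALSE))
  expect_length(empty$candidates, 0)
  path2 <- file.path(withr::local_tempdir(), "empty.tsv")
  write_operons(empty, path2)
  expect_identical(nrow(read_operons(path2)), 0L)
})
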