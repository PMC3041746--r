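test_that("configuration invariants are enforced", {
  expect_error(sim_config(snp_rate = 1.5), "must lie in")
  expect_error(sim_config(depth_lambda = 0), "depth_lambda")
  expect_error(sim_config(expression_ratio = c(0.7, 0.2)), "sum to 1")
  expect_error(sim_config(n_subgenome_copies = 4), "1, 2 or 3")
  expect_error(sim_config(read_length = 0), "read_length")
  expect_s3_class(sim_config(seed = 9), "sim_config")
})

test_that("no variation planted means empty ground truth", {
  cfg <- sim_config(n_gene_families = 10, homoeolog_divergence = 0,
                    snp_rate = 0, base_error = 0,
                    homopolymer_indel_rate = 0, seed = 5)
  sim <- simulate_transcriptomes(cfg)
  expect_equal(nrow(sim$truth), 0L)
  vt <- simulate_variant_tables(cfg)
  expect_true(all(vapply(vt$tables, nrow, 1L) == 0L))
})

test_that("identical config gives identical outputs", {
  cfg <- sim_config(n_gene_families = 8, seed = 11)
  a <- simulate_transcriptomes(cfg)
  b <- simulate_transcriptomes(cfg)
  expect_identical(as.character(a$reference), as.character(b$reference))
  expect_identical(a$truth, b$truth)
  va <- simulate_variant_tables(cfg)
  vb <- simulate_variant_tables(cfg)
  expect_identical(va$tables, vb$tables)
  ra <- simulate_reads(a)
  rb <- simulate_reads(b)
  expect_identical(unclass(ra), unclass(rb))
})

test_that("planted SNP count follows the binomial law", {
  cfg <- sim_config(n_gene_families = 40, n_subgenome_copies = 1,
                    gene_length = 500, snp_rate = 0.01,
                    homoeolog_divergence = 0, collapse_prob = 0,
                    base_error = 0, seed = 21)
  sim <- simulate_transcriptomes(cfg)
  L <- 40 * 500
  n_planted <- sum(sim$truth$label == "allelic_snp")
  expect_gte(n_planted, qbinom(0.005, L, 0.01))
  expect_lte(n_planted, qbinom(0.995, L, 0.01))
  # positions lie within their contigs
  w <- Biostrings::width(sim$reference)[match(sim$truth$contig_id,
                                              names(sim$reference))]
  expect_true(all(sim$truth$pos >= 1 & sim$truth$pos <= w))
})

test_that("error-free reads are exact substrings with the right coverage", {
  cfg <- sim_config(n_gene_families = 1, n_subgenome_copies = 1,
                    gene_length = 1000, read_length = 100,
                    depth_lambda = 50, snp_rate = 0, base_error = 0,
                    homopolymer_indel_rate = 0, n_genotypes = 2,
                    seed = 31)
  sim <- simulate_transcriptomes(cfg)
  reads <- simulate_reads(sim)
  src <- as.character(sim$transcripts$REF)[[1]]
  for (rd in reads$REF) expect_true(grepl(rd, src, fixed = TRUE))
  cov <- sum(nchar(reads$REF)) / 1000
  expect_gte(cov, 45)
  expect_lte(cov, 55)
})

test_that("expression ratio (1, 0) sources all collapsed reads from copy 1", {
  cfg <- sim_config(n_gene_families = 4, n_subgenome_copies = 2,
                    collapse_prob = 1, expression_ratio = c(1, 0),
                    homoeolog_divergence = 0.05, snp_rate = 0,
                    base_error = 0, homopolymer_indel_rate = 0,
                    gene_length = 300, read_length = 80,
                    depth_lambda = 10, n_genotypes = 2, seed = 41)
  sim <- simulate_transcriptomes(cfg)
  reads <- simulate_reads(sim)
  srcs <- sub("^[^|]+\\|([^|]+)\\|.*$", "\\1", names(reads$REF))
  expect_true(all(grepl("\\.h1$", srcs)))
})

test_that("zero-length sequences are rejected by the read simulator", {
  cfg <- sim_config(n_gene_families = 2, n_genotypes = 2, seed = 3)
  sim <- simulate_transcriptomes(cfg)
  sim$transcripts$REF <- c(sim$transcripts$REF,
                           Biostrings::DNAStringSet(c(bad = "")))
  expect_error(simulate_reads(sim), "zero-length")
})

test_that("fixed planted SNPs carry frequency exactly 100 without error", {
  cfg <- sim_config(n_gene_families = 15, snp_rate = 0.01,
                    base_error = 0, homopolymer_indel_rate = 0,
                    depth_lambda = 10, seed = 51)
  vt <- simulate_variant_tables(cfg)
  truth_allelic <- vt$truth[vt$truth$label == "allelic_snp", ]
  tk <- paste(truth_allelic$contig_id, truth_allelic$pos,
              truth_allelic$alt)
  for (g in names(vt$tables)) {
    tab <- vt$tables[[g]]
    hit <- paste(tab$contig_id, tab$start, tab$var) %in% tk
    if (any(hit)) expect_true(all(tab$freq_pct[hit] == 100))
  }
})

test_that("balanced collapsed homoeolog sites sample frequency near 50", {
  cfg <- sim_config(n_gene_families = 10, n_subgenome_copies = 2,
                    collapse_prob = 1, expression_ratio = c(0.5, 0.5),
                    homoeolog_divergence = 0.05, snp_rate = 0,
                    base_error = 0, depth_lambda = 50, seed = 61)
  vt <- simulate_variant_tables(cfg)
  recs <- do.call(rbind, vt$tables)
  expect_gt(nrow(recs), 100)
  expect_true(all(recs$freq_pct < 100))
  expect_gt(mean(recs$freq_pct), 40)
  expect_lt(mean(recs$freq_pct), 60)
})

test_that("no collapse means no pseudo-SNP truth entries", {
  cfg <- sim_config(n_gene_families = 10, collapse_prob = 0,
                    homoeolog_divergence = 0.05, seed = 71)
  vt <- simulate_variant_tables(cfg)
  expect_false(any(vt$truth$label == "homoeolog_pseudo_snp"))
})

test_that("every emitted record is explained by the ground truth", {
  cfg <- sim_config(n_gene_families = 12, base_error = 0.01, seed = 81)
  vt <- simulate_variant_tables(cfg)
  tk <- paste(vt$truth$contig_id, vt$truth$pos, vt$truth$alt)
  for (g in names(vt$tables)) {
    tab <- vt$tables[[g]]
    if (!nrow(tab)) next
    expect_true(all(paste(tab$contig_id, tab$start, tab$var) %in% tk))
  }
})

test_that("RIL call simulation hits requested rates", {
  calls <- simulate_ril_calls(50, 200, het_rate = 0.1,
                              missing_rate = 0.05, seed = 91)
  expect_equal(dim(calls), c(50, 200))
  tab <- table(calls, useNA = "always")
  expect_gt(tab[["H"]], 500)
  expect_gt(sum(is.na(calls)), 200)
})
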