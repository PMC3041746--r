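make_ref <- function(ids, len = 200, with_n = character()) {
  set.seed(7)
  seqs <- vapply(ids, function(id) {
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  }, "")
  for (id in with_n) {
    substr(seqs[[id]], 50, 50) <- "N"
  }
  Biostrings::DNAStringSet(seqs)
}

test_that("a clean reference passes the self-screen untouched", {
  ref <- make_ref(paste0("c", 1:4))
  res <- screen_reference(ref, make_rec()[0, ])
  expect_equal(length(res$retained), 4L)
  expect_equal(res$report$removed, c(0L, 0L))
})

test_that("self-screen removes indel then ambiguous contigs against the initial count", {
  ref <- make_ref(paste0("c", 1:10), with_n = c("c3", "c4", "c5"))
  sv <- rbind(make_rec(contig = "c1", var = "-", genotype = "REF"),
              make_rec(contig = "c2", ref = "AT", var = "GC",
                       genotype = "REF"))
  res <- screen_reference(ref, sv)
  expect_equal(res$report$removed, c(2L, 3L))
  expect_equal(res$report$percent, c("20", "30"))
  expect_equal(res$report$remaining, c(8L, 5L))
  expect_setequal(names(res$retained), paste0("c", 6:10))
})

test_that("a contig with both an indel and an N is counted once, as indel", {
  ref <- make_ref(paste0("c", 1:3), with_n = "c1")
  sv <- make_rec(contig = "c1", var = "-", genotype = "REF")
  res <- screen_reference(ref, sv)
  expect_equal(res$report$removed, c(1L, 0L))
})

test_that("self-variants on unknown contigs abort the screen", {
  ref <- make_ref("c1")
  expect_error(screen_reference(ref, make_rec(contig = "cX")),
               "unknown contig")
})

test_that("single records route to the documented filter stages", {
  retained <- "c1"
  pass <- filter_candidates(make_rec(freq = 100, depth = 5), retained)
  expect_equal(nrow(pass$passed), 1L)
  dep <- filter_candidates(make_rec(freq = 100, depth = 4), retained)
  expect_equal(dep$removed$removed_at, "low_depth")
  con <- filter_candidates(make_rec(freq = 99, depth = 20), retained)
  expect_equal(con$removed$removed_at, "not_conserved")
})

test_that("the eight-record worked example attrits (3, 1, 2) leaving 2", {
  res <- filter_candidates(filter_batch(), "c1")
  expect_equal(res$report$removed, c(3L, 1L, 2L))
  expect_equal(nrow(res$passed), 2L)
  expect_equal(res$report$remaining, c(5L, 4L, 2L))
  # removed + remaining conserves the stage input at every stage
  input <- c(res$report$denominator[1], res$report$remaining[-3])
  expect_equal(res$report$removed + res$report$remaining, input)
})

test_that("the filter is idempotent", {
  res <- filter_candidates(filter_batch(), "c1")
  again <- filter_candidates(res$passed, "c1")
  expect_equal(again$report$removed, c(0L, 0L, 0L))
  expect_equal(again$passed, res$passed, ignore_attr = TRUE)
})

test_that("filter decisions match a brute-force oracle on 10,000 records", {
  recs <- random_records(10000, seed = 99)
  retained <- sprintf("c%02d", 1:15)   # c16-c20 silently dropped
  res <- filter_candidates(recs, retained)
  oracle <- filter_oracle(recs, retained)
  expect_equal(nrow(res$passed), sum(oracle$pass))
  expect_setequal(
    paste(res$passed$contig_id, res$passed$start, res$passed$var,
          res$passed$genotype),
    paste(recs$contig_id, recs$start, recs$var,
          recs$genotype)[oracle$pass])
  # stage attribution agrees record by record
  in_scope <- recs$contig_id %in% retained
  rem <- recs[in_scope & !oracle$pass[seq_len(nrow(recs))], ]
  okey <- paste(rem$contig_id, rem$start, rem$ref, rem$var,
                rem$genotype, rem$freq_pct, rem$depth)
  ostage <- filter_oracle(rem, retained)$stage
  rkey <- paste(res$removed$contig_id, res$removed$start,
                res$removed$ref, res$removed$var, res$removed$genotype,
                res$removed$freq_pct, res$removed$depth)
  expect_equal(res$removed$removed_at[match(okey, rkey)], ostage)
})

test_that("classification groups by allele identity and counts sharing", {
  one <- classify_candidates(make_rec(genotype = "Ogle"))
  expect_equal(one$sharing_class, 1L)

  three <- classify_candidates(rbind(
    make_rec(genotype = "Ogle"), make_rec(genotype = "Gem", depth = 7),
    make_rec(genotype = "HiFi", depth = 9)))
  expect_equal(nrow(three), 1L)
  expect_equal(three$sharing_class, 3L)
  expect_equal(three$genotypes, "Gem,HiFi,Ogle")
  expect_equal(three$depth_total, 26L)

  split_alt <- suppressMessages(classify_candidates(rbind(
    make_rec(genotype = "Ogle", var = "G"),
    make_rec(genotype = "Gem", var = "T"))))
  expect_equal(nrow(split_alt), 2L)
  expect_equal(split_alt$sharing_class, c(1L, 1L))
})

test_that("within-genotype conflicting alleles are flagged, not dropped", {
  recs <- rbind(make_rec(genotype = "Ogle", var = "G"),
                make_rec(genotype = "Ogle", var = "T"))
  expect_message(out <- classify_candidates(recs), "conflict")
  expect_equal(nrow(out), 2L)
  expect_length(attr(out, "conflicts"), 1L)
})

test_that("class counts always partition the candidate total", {
  recs <- random_records(2000, seed = 7)
  res <- filter_candidates(recs, sprintf("c%02d", 1:20))
  cand <- suppressMessages(classify_candidates(res$passed))
  expect_equal(sum(table(cand$sharing_class)), nrow(cand))
  expect_equal(sum(cand$sharing_class >= 1), nrow(cand))
})

test_that("the crowded-target window rule is strict at the boundary", {
  base <- suppressMessages(classify_candidates(rbind(
    make_rec(contig = "cFar", start = 100),
    make_rec(contig = "cFar", start = 250, ref = "C", var = "T"),
    make_rec(contig = "cNear", start = 100),
    make_rec(contig = "cNear", start = 150, ref = "C", var = "T"),
    make_rec(contig = "cEdge", start = 100),
    make_rec(contig = "cEdge", start = 200, ref = "C", var = "T"))))
  res <- select_assay_targets(base, window_bp = 100)
  expect_equal(res$eliminated_contigs, "cNear")
  expect_setequal(unique(res$eligible$contig_id), c("cFar", "cEdge"))
})

test_that("masking writes the right IUPAC code and truncation flag", {
  ref <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 50)))
  # position 101 in ACGT repeats is "A"
  cand <- classify_candidates(make_rec(contig = "c1", start = 101,
                                       ref = "A", var = "G"))
  tgt <- mask_snp_fasta(cand, ref, flank_bp = 50)
  expect_equal(tgt$iupac, "R")
  expect_false(tgt$truncated)
  expect_equal(nchar(tgt$seq), 101L)
  expect_equal(substr(tgt$seq, 51, 51), "R")

  ct <- classify_candidates(make_rec(contig = "c1", start = 5,
                                     ref = "A", var = "T"))
  tt <- mask_snp_fasta(ct, ref, flank_bp = 50)
  expect_true(tt$truncated)
  expect_equal(tt$window_start, 1L)
  expect_equal(nchar(tt$seq), 4L + 1L + 50L)
  expect_equal(tt$iupac, "W")

  cy <- classify_candidates(make_rec(contig = "c1", start = 102,
                                     ref = "C", var = "T"))
  expect_equal(mask_snp_fasta(cy, ref)$iupac, "Y")
})

test_that("masked targets serialize as dbSNP-style FASTA", {
  ref <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 50)))
  cand <- classify_candidates(make_rec(contig = "c1", start = 101,
                                       ref = "A", var = "G"))
  tgt <- mask_snp_fasta(cand, ref)
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_masked_fasta(tgt, tmp)
  lines <- readLines(tmp)
  expect_match(lines[1], "^>c1_101 alleles=A/G pos=51 product=90\\+/-30")
  expect_match(paste(lines[-1], collapse = ""), "R")
})
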