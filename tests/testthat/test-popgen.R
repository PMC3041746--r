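ril_row <- function(n_a, n_b, n_h = 0, n_na = 0) {
  matrix(c(rep("A", n_a), rep("B", n_b), rep("H", n_h),
           rep(NA_character_, n_na)),
         nrow = 1, dimnames = list("m1", NULL))
}

test_that("segregation ratios and the 1:1 test behave on worked examples", {
  even <- score_segregation(ril_row(50, 50))
  expect_equal(even$sr, 1)
  expect_equal(even$chi_square, 0)
  expect_false(even$distorted)

  skewed <- score_segregation(ril_row(45, 50))
  expect_equal(skewed$sr, 0.9)
  expect_equal(skewed$chi_square, 25 / 95)
  expect_equal(skewed$p_value,
               stats::chisq.test(c(45, 50), correct = FALSE)$p.value)

  hets <- score_segregation(ril_row(30, 30, 60))
  expect_equal(hets$het_fraction, 0.5)
  expect_true(hets$het_excess)
  expect_false(score_segregation(ril_row(40, 40, 20))$het_excess)

  none_b <- score_segregation(ril_row(30, 0))
  expect_true(is.na(none_b$sr))
})

test_that("missing calls are counted, not scored", {
  res <- score_segregation(ril_row(40, 50, 5, 5))
  expect_equal(res$n_missing, 5L)
  expect_equal(res$sr, 0.8)
})

test_that("distortion flags fire near the nominal rate under 1:1", {
  calls <- simulate_ril_calls(300, 136, seed = 13)
  seg <- score_segregation(calls)
  expect_gt(mean(seg$distorted), 0.01)
  expect_lt(mean(seg$distorted), 0.12)
})

test_that("binary coding makes one column per observed state", {
  calls <- matrix(c("X", "Y", "X",
                    "A", "G", "Null"),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("m1", "m2"), c("i1", "i2", "i3")))
  b <- code_binary(calls)
  expect_equal(colnames(b), c("m1.X", "m1.Y", "m2.A", "m2.G"))
  expect_equal(unname(b["i1", c("m1.X", "m1.Y")]), c(1, 0))
  expect_equal(unname(b["i3", c("m2.A", "m2.G")]), c(0, 0))  # Null

  wide <- matrix(c("A", "G", "A", "G",
                   "A", "G", "T", "A",
                   "A", "G", "T", "C"),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(paste0("m", 1:3), paste0("i", 1:4)))
  expect_equal(ncol(code_binary(wide)), 9L)   # 2 + 3 + 4 states
})

test_that("heterozygote coding modes differ as documented", {
  calls <- matrix(c("A", "G", "Het"), nrow = 1,
                  dimnames = list("m1", c("i1", "i2", "i3")))
  own <- code_binary(calls, het_mode = "state")
  expect_true("m1.Het" %in% colnames(own))
  expect_equal(unname(own["i3", ]), c(0, 0, 1))
  exp <- code_binary(calls, het_mode = "expand")
  expect_equal(colnames(exp), c("m1.A", "m1.G"))
  expect_equal(unname(exp["i3", ]), c(1, 1))
})

test_that("missing calls propagate as NA for pairwise handling", {
  calls <- matrix(c("A", NA, "G"), nrow = 1,
                  dimnames = list("m1", c("i1", "i2", "i3")))
  b <- code_binary(calls)
  expect_true(all(is.na(b["i2", ])))
})

test_that("Dice similarity matches its worked examples", {
  expect_equal(dice_similarity(rbind(x = c(1, 1, 0), y = c(1, 1, 0)))["x", "y"], 1)
  expect_equal(dice_similarity(rbind(x = c(1, 1, 0, 0), y = c(0, 0, 1, 1)))["x", "y"], 0)
  expect_equal(dice_similarity(rbind(x = c(1, 1, 0), y = c(1, 0, 1)))["x", "y"], 0.5)
})

test_that("Dice equals the set-overlap oracle on every 6-bit pair", {
  vecs <- as.matrix(expand.grid(rep(list(0:1), 6)))
  for (i in seq_len(nrow(vecs))) {
    for (j in seq_len(nrow(vecs))) {
      s <- dice_similarity(rbind(a = vecs[i, ], b = vecs[j, ]))
      expect_identical(s["a", "b"], s["b", "a"])
      expect_equal(s["a", "b"], dice_oracle(vecs[i, ], vecs[j, ]))
    }
  }
})

test_that("Dice is symmetric with unit diagonal on random matrices", {
  set.seed(5)
  m <- matrix(rbinom(60, 1, 0.5), nrow = 6,
              dimnames = list(paste0("i", 1:6), NULL))
  m[2, 3] <- NA
  s <- dice_similarity(m)
  expect_equal(s, t(s))
  expect_true(all(s >= 0 & s <= 1))
  has_presence <- rowSums(m > 0, na.rm = TRUE) > 0
  expect_true(all(diag(s)[has_presence] == 1))
})

test_that("missing columns are dropped pairwise in Dice", {
  m <- rbind(x = c(1, 1, NA), y = c(1, 0, 1))
  # only the first two columns are complete: a=1, b=1, c=0
  expect_equal(dice_similarity(m)["x", "y"], 2 / 3)
})

test_that("two taxa merge at half their distance", {
  s <- matrix(c(1, 0.6, 0.6, 1), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  tree <- upgma(s)
  expect_equal(tree$heights, 0.2)
  expect_equal(tree$newick, "(a:0.2,b:0.2);")
  expect_equal(tree$cophenetic["a", "b"], 0.4)

  zero <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(upgma(zero)$heights, 0)
})

test_that("UPGMA reproduces a hand-worked four-taxon merge sequence", {
  d <- matrix(c(0, 0.2, 0.6, 0.6,
                0.2, 0, 0.6, 0.6,
                0.6, 0.6, 0, 0.4,
                0.6, 0.6, 0.4, 0), 4, byrow = TRUE,
              dimnames = list(letters[1:4], letters[1:4]))
  tree <- upgma(1 - d)   # similarity input
  # merges: (a,b) at 0.1; (c,d) at 0.2; root at 0.3
  expect_equal(tree$heights, c(0.1, 0.2, 0.3))
  expect_equal(tree$cophenetic["a", "b"], 0.2)
  expect_equal(tree$cophenetic["c", "d"], 0.4)
  expect_equal(tree$cophenetic["a", "c"], 0.6)
})

test_that("UPGMA equals the definitional oracle on random small matrices", {
  for (seed in 1:12) {
    n <- 3 + seed %% 3   # 3, 4, 5 taxa
    s <- random_similarity(n, seed)
    tree <- upgma(s)
    oracle <- upgma_oracle_cophenetic(1 - s)
    expect_equal(tree$cophenetic, oracle, tolerance = 1e-9)
    expect_true(all(diff(tree$heights) >= -1e-12))   # ultrametric
  }
})

test_that("UPGMA agrees with average-linkage hclust cophenetics", {
  s <- random_similarity(8, 42)
  tree <- upgma(s)
  hc <- stats::hclust(stats::as.dist(1 - s), method = "average")
  ch <- as.matrix(stats::cophenetic(hc))
  expect_equal(tree$cophenetic[rownames(ch), colnames(ch)], ch,
               tolerance = 1e-9)
})

test_that("Newick round trip preserves topology and heights", {
  s <- random_similarity(7, 3)
  tree <- upgma(s)
  phy <- as_phylo(tree)
  coph <- as.matrix(stats::cophenetic(phy))
  expect_equal(coph[tree$labels, tree$labels], tree$cophenetic,
               tolerance = 1e-9)
})

test_that("non-symmetric similarity input is a hard error", {
  s <- random_similarity(4, 1)
  s[1, 2] <- s[1, 2] + 0.1
  expect_error(upgma(s), "symmetric")
})

test_that("allele accounting partitions SNP and supplementary states", {
  simple <- matrix(c("A", "G"), 1, dimnames = list("m1", c("i1", "i2")))
  s <- allele_summary(simple)
  expect_equal(s$total_alleles, 2L)
  expect_equal(s$mean_alleles, 2)

  panel <- synthetic_diversity_panel()
  ps <- allele_summary(panel)
  expect_equal(ps$n_markers, 36L)
  expect_equal(ps$total_alleles, 140L)
  expect_equal(ps$mean_alleles, 3.89)
  expect_equal(ps$n_snp_alleles, 73L)
  expect_equal(ps$n_supplementary, 67L)
  expect_equal(ps$n_indel, 51L)
  expect_equal(ps$n_het, 6L)
  expect_equal(ps$n_null, 10L)
})

test_that("marker tables round-trip through TSV", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  calls <- synthetic_diversity_panel()[1:5, 1:6]
  calls[2, 3] <- NA
  write_marker_table(calls, tmp)
  back <- read_marker_table(tmp)
  expect_identical(back, calls)
})
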