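# shared fixtures and independent oracles

make_rec <- function(contig = "c1", start = 10L, end = start, ref = "A",
                     var = "G", freq = 100, depth = 10L,
                     genotype = "G1") {
  data.frame(contig_id = contig, start = as.integer(start),
             end = as.integer(end), ref = ref, var = var,
             freq_pct = freq, depth = as.integer(depth),
             genotype = genotype, stringsAsFactors = FALSE)
}

# the 8-record worked example exercising every filter rule
filter_batch <- function() {
  rbind(
    make_rec(var = "G", freq = 100, depth = 5),     # pass
    make_rec(var = "-", freq = 100, depth = 9),     # indel
    make_rec(ref = "AT", var = "GC", freq = 100, depth = 9),  # multibase
    make_rec(var = "N", freq = 100, depth = 9),     # ambiguous
    make_rec(var = "G", freq = 50, depth = 50),     # conservation
    make_rec(var = "G", freq = 100, depth = 4),     # depth
    make_rec(ref = "C", var = "T", freq = 100, depth = 30),   # pass
    make_rec(ref = "G", var = "C", freq = 99.9, depth = 100)  # conservation
  )
}

# random but valid variant records, vectorized
random_records <- function(n, seed = 1) {
  set.seed(seed)
  alleles <- c("A", "C", "G", "T", "N", "-", "AT", "GC", "AAC")
  ref <- sample(alleles, n, replace = TRUE)
  var <- sample(alleles, n, replace = TRUE)
  clash <- ref == var
  var[clash] <- ifelse(ref[clash] == "A", "G", "A")
  data.frame(
    contig_id = sample(sprintf("c%02d", 1:20), n, replace = TRUE),
    start = s <- sample.int(500, n, replace = TRUE),
    end = s,
    ref = ref, var = var,
    freq_pct = round(sample(c(100, 100, 99.9, 87.5, 50, 25.1, 100),
                            n, replace = TRUE) , 1),
    depth = sample.int(30, n, replace = TRUE),
    genotype = sample(c("G1", "G2", "G3"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# direct re-evaluation of the four removal rules on a single record
filter_oracle <- function(rec, retained, depth_min = 5) {
  in_scope <- rec$contig_id %in% retained
  bad <- function(a) grepl("[-N]", a) | nchar(a) > 1
  s1 <- bad(rec$ref) | bad(rec$var)
  s2 <- rec$depth <= depth_min - 1
  s3 <- abs(rec$freq_pct - 100) > 1e-9
  list(pass = in_scope & !s1 & !s2 & !s3,
       stage = ifelse(s1, "indel_or_ambiguous",
                ifelse(s2, "low_depth",
                 ifelse(s3, "not_conserved", NA))))
}

# Dice via explicit set overlap of presence index sets
dice_oracle <- function(x, y) {
  a <- length(intersect(which(x == 1), which(y == 1)))
  b <- length(setdiff(which(x == 1), which(y == 1)))
  cc <- length(setdiff(which(y == 1), which(x == 1)))
  if (2 * a + b + cc == 0) 0 else 2 * a / (2 * a + b + cc)
}

# definitional UPGMA: cluster distance is the mean of ALL original
# member-pair distances (no Lance-Williams update); same tie-break rule
upgma_oracle_cophenetic <- function(d) {
  labels <- rownames(d)
  clusters <- lapply(labels, identity)
  coph <- matrix(0, nrow(d), nrow(d), dimnames = dimnames(d))
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = dij, key = key)
        }
      }
    }
    for (a in clusters[[best$i]]) for (b in clusters[[best$j]]) {
      coph[a, b] <- coph[b, a] <- best$d
    }
    clusters[[best$i]] <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters[[best$j]] <- NULL
  }
  coph
}

random_similarity <- function(n, seed) {
  set.seed(seed)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 0.95)
  d <- d + t(d)
  labels <- paste0("t", seq_len(n))
  dimnames(d) <- list(labels, labels)
  1 - d
}
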