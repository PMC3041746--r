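#' Configuration for the synthetic polyploid transcriptome generator
#'
#' Builds and validates the parameter set that drives all simulation
#' entry points ([simulate_transcriptomes()], [simulate_reads()],
#' [simulate_variant_tables()]). The generator emulates an EST survey of a
#' polyploid crop: gene families with 1-3 diverged subgenome (homoeologous)
#' copies, a fraction of families whose copies co-assemble into a single
#' "collapsed" reference contig (the source of pseudo-SNPs), true allelic
#' SNPs planted between genotypes, and 454-style sequencing noise
#' (uniform base miscalls plus homopolymer-run indels).
#'
#' Defaults describe a four-genotype hexaploid-like survey: ~580 bp genes,
#' mean per-transcript coverage 4x, 350 bp reads, 2 subgenome copies per
#' family diverging at 2% of bases, equal homoeolog expression, and mild
#' 454-style noise. One genotype (the first) acts as the reference
#' assembly genotype; planted allelic SNPs distinguish the remaining
#' genotypes from it.
#'
#' @param n_gene_families Number of gene families to simulate.
#' @param n_subgenome_copies Homoeologous copies per family (1-3).
#' @param homoeolog_divergence Per-base substitution probability between a
#'   non-reference copy and the family's first copy.
#' @param snp_rate Per-base probability that a true inter-genotype allelic
#'   SNP is planted at a reference position.
#' @param collapse_prob Probability that a family's copies assemble into
#'   one collapsed reference contig.
#' @param expression_ratio Relative read contribution of each homoeolog in
#'   a collapsed contig; non-negative, summing to 1, length
#'   `n_subgenome_copies`. Default: equal shares.
#' @param gene_length Length (bp) of each simulated gene copy.
#' @param read_length Read length in bases.
#' @param depth_lambda Mean per-base coverage (Poisson).
#' @param base_error Per-base miscall probability.
#' @param homopolymer_indel_rate Per homopolymer run (length >= 3)
#'   probability of a single-base insertion or deletion in a read.
#' @param n_genotypes Number of genotypes including the reference (>= 2).
#' @param genotype_names Optional character vector of genotype labels; the
#'   first is the reference-assembly genotype.
#' @param sharing_probs Probabilities that a planted SNP is shared by 1, 2
#'   or 3 non-reference genotypes. Default mirrors the heavy skew toward
#'   single-genotype variants seen in real polyploid EST surveys.
#' @param seed Single integer seed; every stochastic draw flows from it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_gene_families = 5, seed = 42)
#' @export
sim_config <- function(n_gene_families = 50L,
                       n_subgenome_copies = 2L,
                       homoeolog_divergence = 0.02,
                       snp_rate = 0.002,
                       collapse_prob = 0.3,
                       expression_ratio = NULL,
                       gene_length = 580L,
                       read_length = 350L,
                       depth_lambda = 4,
                       base_error = 0.005,
                       homopolymer_indel_rate = 0.005,
                       n_genotypes = 4L,
                       genotype_names = NULL,
                       sharing_probs = c(0.89, 0.10, 0.01),
                       seed = 1L) {
  cfg <- list(
    n_gene_families = as.integer(n_gene_families),
    n_subgenome_copies = as.integer(n_subgenome_copies),
    homoeolog_divergence = homoeolog_divergence,
    snp_rate = snp_rate,
    collapse_prob = collapse_prob,
    expression_ratio = expression_ratio,
    gene_length = as.integer(gene_length),
    read_length = as.integer(read_length),
    depth_lambda = depth_lambda,
    base_error = base_error,
    homopolymer_indel_rate = homopolymer_indel_rate,
    n_genotypes = as.integer(n_genotypes),
    genotype_names = genotype_names,
    sharing_probs = sharing_probs,
    seed = as.integer(seed)
  )
  if (is.null(cfg$expression_ratio)) {
    cfg$expression_ratio <- rep(1 / cfg$n_subgenome_copies,
                                cfg$n_subgenome_copies)
  }
  if (is.null(cfg$genotype_names)) {
    cfg$genotype_names <- c("REF", paste0("G", seq_len(cfg$n_genotypes - 1L)))
  }
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  probs <- c(homoeolog_divergence = cfg$homoeolog_divergence,
             snp_rate = cfg$snp_rate,
             collapse_prob = cfg$collapse_prob,
             base_error = cfg$base_error,
             homopolymer_indel_rate = cfg$homopolymer_indel_rate)
  bad <- probs < 0 | probs > 1 | !is.finite(probs)
  if (any(bad)) {
    stop_cfg(paste(names(probs)[bad], collapse = ", "),
             " must lie in [0, 1]")
  }
  if (cfg$n_gene_families < 1L) stop_cfg("n_gene_families must be >= 1")
  if (cfg$n_subgenome_copies < 1L || cfg$n_subgenome_copies > 3L) {
    stop_cfg("n_subgenome_copies must be 1, 2 or 3")
  }
  if (!is.finite(cfg$depth_lambda) || cfg$depth_lambda <= 0) {
    stop_cfg("depth_lambda must be > 0")
  }
  if (cfg$read_length < 1L) stop_cfg("read_length must be >= 1")
  if (cfg$gene_length < 1L) stop_cfg("gene_length must be >= 1")
  if (cfg$n_genotypes < 2L) stop_cfg("n_genotypes must be >= 2")
  er <- cfg$expression_ratio
  if (length(er) != cfg$n_subgenome_copies || any(er < 0) || any(er > 1)) {
    stop_cfg("expression_ratio must have one entry in [0,1] per copy")
  }
  if (abs(sum(er) - 1) > 1e-9) {
    stop_cfg("expression_ratio entries must sum to 1")
  }
  if (length(cfg$genotype_names) != cfg$n_genotypes) {
    stop_cfg("genotype_names must have length n_genotypes")
  }
  if (length(cfg$sharing_probs) != 3L || any(cfg$sharing_probs < 0)) {
    stop_cfg("sharing_probs must be 3 non-negative weights")
  }
  invisible(cfg)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

# substitute bases at given positions with a random different base
mutate_positions <- function(chars, pos) {
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  chars
}

empty_truth <- function() {
  data.frame(contig_id = character(), pos = integer(),
             ref = character(), alt = character(),
             genotypes = character(), label = character(),
             stringsAsFactors = FALSE)
}

#' Simulate genotype transcriptomes with a collapsed-assembly reference
#'
#' Generates, per gene family, `n_subgenome_copies` homoeologous gene
#' copies diverged from a common ancestor, decides whether the family
#' co-assembles into a single collapsed reference contig, plants true
#' allelic SNPs in non-reference genotypes, and records ground truth for
#' every site of variation. Positions where collapsed homoeologs differ
#' are labelled `homoeolog_pseudo_snp` (they masquerade as within-genotype
#' polymorphism in every genotype); planted genotype differences are
#' labelled `allelic_snp` and are fixed within their carrier genotypes
#' (applied to all copies of the family), so an error-free caller sees
#' them at 100% frequency.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_transcriptomes`: a list with elements
#'   `reference` (named [Biostrings::DNAStringSet] of reference contigs),
#'   `transcripts` (per-genotype named `DNAStringSet`s of gene-copy
#'   transcripts), `transcript_map` (data.frame mapping transcript id to
#'   contig id, copy index and expression weight), `truth` (data.frame:
#'   contig_id, pos, ref, alt, genotypes, label) and `config`.
#' @seealso [simulate_reads()], [simulate_variant_tables()]
#' @export
simulate_transcriptomes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  genos <- config$genotype_names
  ref_geno <- genos[1L]
  alt_genos <- genos[-1L]
  k <- config$n_subgenome_copies

  ref_seqs <- character()
  tx_map <- list()
  truth <- list()
  # per-genotype list of transcript character vectors
  tx <- stats::setNames(vector("list", length(genos)), genos)
  for (g in genos) tx[[g]] <- character()

  max_share <- min(3L, length(alt_genos))
  share_probs <- config$sharing_probs[seq_len(max_share)]
  share_probs <- share_probs / sum(share_probs)

  for (f in seq_len(config$n_gene_families)) {
    ancestor <- strsplit(random_dna(config$gene_length), "")[[1]]
    copies <- vector("list", k)
    copies[[1L]] <- ancestor
    if (k > 1L) {
      for (j in 2:k) {
        hits <- which(stats::runif(config$gene_length) <
                        config$homoeolog_divergence)
        copies[[j]] <- mutate_positions(ancestor, hits)
      }
    }
    collapsed <- k > 1L && stats::runif(1) < config$collapse_prob

    if (collapsed) {
      contig_id <- sprintf("c%04d", f)
      consensus <- copies[[1L]]
      ref_seqs[contig_id] <- paste(consensus, collapse = "")
      # positions where any further copy differs from the consensus
      pseudo_pos <- integer()
      for (j in 2:k) {
        diffs <- which(copies[[j]] != consensus)
        pseudo_pos <- union(pseudo_pos, diffs)
        for (p in diffs) {
          truth[[length(truth) + 1L]] <- data.frame(
            contig_id = contig_id, pos = p,
            ref = consensus[p], alt = copies[[j]][p],
            genotypes = paste(genos, collapse = ","),
            label = "homoeolog_pseudo_snp", stringsAsFactors = FALSE)
        }
      }
      # plant allelic SNPs at positions not already segregating homoeologs
      eligible <- setdiff(seq_len(config$gene_length), pseudo_pos)
      hits <- eligible[stats::runif(length(eligible)) < config$snp_rate]
      planted <- list()
      for (p in hits) {
        n_share <- sample.int(max_share, 1L, prob = share_probs)
        carriers <- sample(alt_genos, n_share)
        alt <- sample(setdiff(DNA_BASES, consensus[p]), 1L)
        planted[[length(planted) + 1L]] <-
          list(pos = p, alt = alt, carriers = carriers)
        truth[[length(truth) + 1L]] <- data.frame(
          contig_id = contig_id, pos = p,
          ref = consensus[p], alt = alt,
          genotypes = paste(sort(carriers), collapse = ","),
          label = "allelic_snp", stringsAsFactors = FALSE)
      }
      for (j in seq_len(k)) {
        tid <- sprintf("%s.h%d", contig_id, j)
        tx_map[[length(tx_map) + 1L]] <- data.frame(
          transcript_id = tid, contig_id = contig_id, copy = j,
          weight = config$expression_ratio[j], stringsAsFactors = FALSE)
        for (g in genos) {
          seq_g <- copies[[j]]
          for (pl in planted) {          # fixed within carrier genotypes
            if (g %in% pl$carriers && seq_g[pl$pos] != pl$alt) {
              seq_g[pl$pos] <- pl$alt
            }
          }
          tx[[g]][tid] <- paste(seq_g, collapse = "")
        }
      }
    } else {
      for (j in seq_len(k)) {
        contig_id <- if (k == 1L) sprintf("c%04d", f) else
          sprintf("c%04d_%d", f, j)
        ref_seqs[contig_id] <- paste(copies[[j]], collapse = "")
        hits <- which(stats::runif(config$gene_length) < config$snp_rate)
        planted <- list()
        for (p in hits) {
          n_share <- sample.int(max_share, 1L, prob = share_probs)
          carriers <- sample(alt_genos, n_share)
          alt <- sample(setdiff(DNA_BASES, copies[[j]][p]), 1L)
          planted[[length(planted) + 1L]] <-
            list(pos = p, alt = alt, carriers = carriers)
          truth[[length(truth) + 1L]] <- data.frame(
            contig_id = contig_id, pos = p,
            ref = copies[[j]][p], alt = alt,
            genotypes = paste(sort(carriers), collapse = ","),
            label = "allelic_snp", stringsAsFactors = FALSE)
        }
        tid <- contig_id
        tx_map[[length(tx_map) + 1L]] <- data.frame(
          transcript_id = tid, contig_id = contig_id, copy = j,
          weight = 1, stringsAsFactors = FALSE)
        for (g in genos) {
          seq_g <- copies[[j]]
          for (pl in planted) {
            if (g %in% pl$carriers) seq_g[pl$pos] <- pl$alt
          }
          tx[[g]][tid] <- paste(seq_g, collapse = "")
        }
      }
    }
  }

  truth_df <- if (length(truth)) do.call(rbind, truth) else empty_truth()
  out <- list(
    reference = Biostrings::DNAStringSet(ref_seqs),
    transcripts = lapply(tx, Biostrings::DNAStringSet),
    transcript_map = do.call(rbind, tx_map),
    truth = truth_df,
    config = config
  )
  class(out) <- "sim_transcriptomes"
  out
}

#' @export
print.sim_transcriptomes <- function(x, ...) {
  cat(sprintf(
    "sim_transcriptomes: %d reference contigs, %d genotypes, %d truth sites\n",
    length(x$reference), length(x$transcripts), nrow(x$truth)))
  invisible(x)
}

# introduce one-base indels in homopolymer runs of length >= 3
apply_homopolymer_indels <- function(read, rate) {
  if (rate <= 0) return(read)
  chars <- strsplit(read, "")[[1]]
  r <- rle(chars)
  runs <- which(r$lengths >= 3L)
  if (!length(runs)) return(read)
  hit <- runs[stats::runif(length(runs)) < rate]
  if (!length(hit)) return(read)
  # adjust run lengths: +1 (insertion) or -1 (deletion), one base per run
  delta <- sample(c(-1L, 1L), length(hit), replace = TRUE)
  r$lengths[hit] <- r$lengths[hit] + delta
  paste(inverse.rle(r), collapse = "")
}

apply_base_errors <- function(read, rate) {
  if (rate <= 0) return(read)
  chars <- strsplit(read, "")[[1]]
  hits <- which(stats::runif(length(chars)) < rate)
  if (!length(hits)) return(read)
  paste(mutate_positions(chars, hits), collapse = "")
}

#' Simulate 454-style reads from synthetic transcriptomes
#'
#' Draws reads with Poisson per-transcript counts and uniform start
#' positions so that the expected per-base coverage of each transcript is
#' `depth_lambda` times its expression weight (collapsed families share
#' the family's coverage across homoeologs according to
#' `expression_ratio`; independent contigs have weight 1). Sequencing
#' noise is applied per read: homopolymer-run indels first, then uniform
#' base miscalls. Qualities are constant.
#'
#' @param sim A `sim_transcriptomes` object.
#' @param config Optional [sim_config()]; defaults to `sim$config`.
#' @return Object of class `sim_reads`: named list per genotype, each a
#'   named character vector of read sequences. Read names encode the
#'   source transcript. Write to FASTQ with [write_fastq()].
#' @export
simulate_reads <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "sim_transcriptomes"))
  validate_sim_config(config)
  if (any(vapply(sim$transcripts, length, 1L) == 0L)) {
    stop("simulate_reads: empty sequence set", call. = FALSE)
  }
  set.seed(config$seed + 1L)
  map <- sim$transcript_map
  out <- list()
  for (g in names(sim$transcripts)) {
    seqs <- as.character(sim$transcripts[[g]])
    if (any(nchar(seqs) == 0L)) {
      stop("simulate_reads: zero-length sequence for genotype ", g,
           call. = FALSE)
    }
    reads <- character()
    for (tid in names(seqs)) {
      s <- seqs[[tid]]
      len <- nchar(s)
      w <- map$weight[match(tid, map$transcript_id)]
      rl <- min(config$read_length, len)
      n <- stats::rpois(1L, config$depth_lambda * w * len / rl)
      if (n == 0L) next
      starts <- sample.int(len - rl + 1L, n, replace = TRUE)
      rd <- substring(s, starts, starts + rl - 1L)
      rd <- vapply(rd, apply_homopolymer_indels, "",
                   rate = config$homopolymer_indel_rate, USE.NAMES = FALSE)
      rd <- vapply(rd, apply_base_errors, "",
                   rate = config$base_error, USE.NAMES = FALSE)
      names(rd) <- sprintf("%s|%s|r%05d", g, tid, seq_len(n))
      reads <- c(reads, rd)
    }
    out[[g]] <- reads
  }
  structure(out, class = "sim_reads")
}

#' Write simulated reads to FASTQ files
#'
#' One `<genotype>.fastq` per genotype, constant quality `I` (Q40).
#'
#' @param reads A `sim_reads` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_fastq <- function(reads, dir) {
  stopifnot(inherits(reads, "sim_reads"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (g in names(reads)) {
    dss <- Biostrings::DNAStringSet(reads[[g]])
    qual <- Biostrings::BStringSet(strrep("I", nchar(reads[[g]])))
    x <- Biostrings::QualityScaledDNAStringSet(
      dss, Biostrings::PhredQuality(qual))
    path <- file.path(dir, paste0(g, ".fastq"))
    Biostrings::writeQualityScaledXStringSet(x, path)
    paths[g] <- path
  }
  invisible(paths)
}

#' Simulate mapper-style candidate variant tables directly
#'
#' Record-level shortcut past alignment: for every ground-truth site it
#' draws the per-genotype read depth (Poisson `depth_lambda`) and the
#' non-reference allele count implied by the site's nature, then emits
#' one candidate [variant record][read_variant_table] per genotype that
#' observed the allele. Planted allelic SNPs are fixed within their
#' carrier genotypes, so with `base_error = 0` their records carry
#' frequency exactly 100; collapsed homoeolog sites draw their allele
#' count binomially from the expression ratio, so their frequency is
#' typically well below 100 — the signature the conservation filter
#' exploits. Spurious single-read records are added at rate
#' `base_error` per base per genotype and labelled `error` in the truth.
#'
#' @param config A [sim_config()].
#' @param sim Optional pre-built `sim_transcriptomes` (must share the
#'   config); by default one is generated.
#' @return Object of class `sim_variant_tables`: list with `tables`
#'   (named list of per-genotype variant-record data.frames, reference
#'   genotype first), `reference` (DNAStringSet), `truth` (ground truth
#'   incl. error records) and `config`.
#' @export
simulate_variant_tables <- function(config, sim = NULL) {
  validate_sim_config(config)
  if (is.null(sim)) sim <- simulate_transcriptomes(config)
  set.seed(config$seed + 2L)
  genos <- config$genotype_names
  map <- sim$transcript_map
  truth <- sim$truth
  tables <- stats::setNames(
    replicate(length(genos), list(), simplify = FALSE), genos)
  err_truth <- list()

  rec <- function(contig, pos, ref, var, k, d, g) {
    data.frame(contig_id = contig, start = pos, end = pos,
               ref = ref, var = var,
               freq_pct = round(100 * k / d, 1), depth = d,
               genotype = g, stringsAsFactors = FALSE)
  }

  if (nrow(truth)) {
    for (i in seq_len(nrow(truth))) {
      site <- truth[i, ]
      carriers <- strsplit(site$genotypes, ",", fixed = TRUE)[[1]]
      if (site$label == "homoeolog_pseudo_snp") {
        # alt allele share = summed expression of copies carrying it
        copies <- map[map$contig_id == site$contig_id, ]
        p_alt <- 0
        for (j in seq_len(nrow(copies))) {
          tseq <- sim$transcripts[[genos[1L]]][[copies$transcript_id[j]]]
          base <- as.character(Biostrings::subseq(tseq, site$pos, site$pos))
          if (base == site$alt) p_alt <- p_alt + copies$weight[j]
        }
        for (g in genos) {
          d <- stats::rpois(1L, config$depth_lambda)
          if (d < 1L) next
          k <- stats::rbinom(1L, d, p_alt)
          if (k < 1L) next
          tables[[g]][[length(tables[[g]]) + 1L]] <-
            rec(site$contig_id, site$pos, site$ref, site$alt, k, d, g)
        }
      } else {                                 # allelic_snp
        for (g in carriers) {
          d <- stats::rpois(1L, config$depth_lambda)
          if (d < 1L) next
          k <- stats::rbinom(1L, d, 1 - config$base_error)
          if (k < 1L) next
          tables[[g]][[length(tables[[g]]) + 1L]] <-
            rec(site$contig_id, site$pos, site$ref, site$alt, k, d, g)
        }
      }
    }
  }

  # spurious error records at unoccupied positions
  if (config$base_error > 0) {
    ref_chr <- as.character(sim$reference)
    occupied <- paste(truth$contig_id, truth$pos)
    for (g in genos) {
      for (contig in names(ref_chr)) {
        len <- nchar(ref_chr[[contig]])
        n_err <- stats::rpois(1L, len * config$base_error)
        if (n_err < 1L) next
        pos <- sample.int(len, min(n_err, len))
        pos <- pos[!(paste(contig, pos) %in% occupied)]
        for (p in pos) {
          d <- stats::rpois(1L, config$depth_lambda)
          if (d < 1L) next
          ref <- substr(ref_chr[[contig]], p, p)
          alt <- sample(setdiff(DNA_BASES, ref), 1L)
          tables[[g]][[length(tables[[g]]) + 1L]] <-
            rec(contig, p, ref, alt, 1L, d, g)
          err_truth[[length(err_truth) + 1L]] <- data.frame(
            contig_id = contig, pos = p, ref = ref, alt = alt,
            genotypes = g, label = "error", stringsAsFactors = FALSE)
        }
      }
    }
  }

  tables <- lapply(tables, function(x) {
    if (length(x)) do.call(rbind, x) else empty_variant_df()
  })
  truth_all <- rbind(truth,
                     if (length(err_truth)) do.call(rbind, err_truth)
                     else empty_truth())
  out <- list(tables = tables, reference = sim$reference,
              truth = truth_all, config = config)
  class(out) <- "sim_variant_tables"
  out
}

#' Simulate recombinant-inbred marker calls under 1:1 segregation
#'
#' Produces a RIL-mode marker call table (markers x individuals) with
#' calls drawn independently: parent-A allele with probability `p_a`,
#' heterozygous with probability `het_rate`, missing with probability
#' `missing_rate`, parent-B otherwise. Used to calibrate the segregation
#' distortion test under the null of single Mendelian loci.
#'
#' @param n_markers,n_individuals Table dimensions (default 136
#'   individuals, the size of a typical F6 RIL mapping population).
#' @param p_a Probability of the parent-A call among non-het, non-missing
#'   calls.
#' @param het_rate,missing_rate Per-cell rates of `H` and missing calls.
#' @param seed Integer seed.
#' @return Character matrix with marker row names and individual column
#'   names; calls in `A`, `B`, `H`, `NA`.
#' @export
simulate_ril_calls <- function(n_markers, n_individuals = 136L, p_a = 0.5,
                               het_rate = 0, missing_rate = 0, seed = 1L) {
  set.seed(seed)
  n <- n_markers * n_individuals
  u <- stats::runif(n)
  calls <- ifelse(u < missing_rate, NA_character_,
           ifelse(u < missing_rate + het_rate, "H",
           ifelse(stats::runif(n) < p_a, "A", "B")))
  matrix(calls, nrow = n_markers,
         dimnames = list(sprintf("m%04d", seq_len(n_markers)),
                         sprintf("i%03d", seq_len(n_individuals))))
}

#' Deterministic synthetic diversity panel
#'
#' A worked-example high-resolution-melting (HRM) call table, built to the
#' allele-richness structure reported for diverse oat germplasm panels: 36
#' markers scored across 34 lines, carrying 140 distinct allele states in
#' total (mean 3.89 per marker) of which 73 are SNP alleles and 67 are
#' supplementary states — 51 insertion/deletion alleles, 6 probable
#' heterozygotes and 10 null (no-amplification) alleles. The table is
#' synthetic: states are distributed deterministically so that every
#' state is observed in at least one line. It exercises
#' [allele_summary()], [code_binary()], [dice_similarity()] and [upgma()]
#' end to end without any external data.
#'
#' @return Character matrix (36 markers x 34 individuals) of
#'   diversity-mode calls.
#' @export
synthetic_diversity_panel <- function() {
  n_markers <- 36L
  n_ind <- 34L
  states <- vector("list", n_markers)
  snp_pairs <- list(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"),
                    c("A", "T"), c("C", "G"))
  for (m in seq_len(n_markers)) {
    states[[m]] <- snp_pairs[[(m - 1L) %% 6L + 1L]]
  }
  states[[1L]] <- c(states[[1L]], "T")       # one tri-allelic SNP locus: 73
  # 51 indel alleles: markers 1-15 get In+Del, 16-30 get In, 31-36 get Del
  for (m in 1:15) states[[m]] <- c(states[[m]], "In1", "Del1")
  for (m in 16:30) states[[m]] <- c(states[[m]], "In1")
  for (m in 31:36) states[[m]] <- c(states[[m]], "Del1")
  for (m in 1:6) states[[m]] <- c(states[[m]], "Het")     # 6 heterozygotes
  for (m in 7:16) states[[m]] <- c(states[[m]], "Null")   # 10 null alleles
  calls <- matrix(NA_character_, n_markers, n_ind,
                  dimnames = list(sprintf("m%02d", seq_len(n_markers)),
                                  sprintf("line%02d", seq_len(n_ind))))
  for (m in seq_len(n_markers)) {
    st <- states[[m]]
    # cycle states across lines so each is observed at least once
    calls[m, ] <- st[((seq_len(n_ind) - 1L + m) %% length(st)) + 1L]
  }
  calls
}

#' Evaluate filter performance against simulation ground truth
#'
#' Joins a [filter_candidates()] result back onto the ground truth of a
#' [simulate_variant_tables()] object and measures the two quantities
#' that define pipeline success: the percentage of collapsed-homoeolog
#' pseudo-SNP sites eliminated at the conservation stage, and the
#' percentage of planted fixed allelic SNP records (with passing depth)
#' that survive the whole cascade.
#'
#' A pseudo-SNP site counts as removed at the conservation stage when
#' none of its records pass and at least one was removed as
#' `not_conserved`. An allelic record is eligible when its depth meets
#' the filter's minimum.
#'
#' @param sim A `sim_variant_tables` object.
#' @param filtered Result list of [filter_candidates()] run on the
#'   non-reference genotype tables of `sim`.
#' @param depth_min Depth threshold used in the filter (default 5).
#' @return List: `pseudo_sites` (number of pseudo sites with at least
#'   one record), `pct_pseudo_removed_conservation`,
#'   `allelic_records` (eligible planted-record count),
#'   `pct_allelic_survived`.
#' @export
evaluate_recovery <- function(sim, filtered, depth_min = 5L) {
  stopifnot(inherits(sim, "sim_variant_tables"))
  truth <- sim$truth
  key <- function(df, pos_col = "pos") {
    paste(df$contig_id, df[[pos_col]], sep = "|")
  }
  pass_keys <- paste(filtered$passed$contig_id, filtered$passed$start,
                     filtered$passed$var, sep = "|")
  rem <- filtered$removed
  rem_keys <- paste(rem$contig_id, rem$start, rem$var, sep = "|")
  all_keys <- c(pass_keys, rem_keys)

  pseudo <- unique(truth[truth$label == "homoeolog_pseudo_snp",
                         c("contig_id", "pos", "alt")])
  if (nrow(pseudo)) {
    pk <- paste(pseudo$contig_id, pseudo$pos, pseudo$alt, sep = "|")
    seen <- pk %in% all_keys
    removed_cons <- vapply(pk, function(k) {
      !(k %in% pass_keys) &&
        any(rem_keys == k & rem$removed_at == "not_conserved")
    }, logical(1))
    n_seen <- sum(seen)
    pct_pseudo <- if (n_seen) 100 * sum(removed_cons[seen]) / n_seen
                  else NA_real_
  } else {
    n_seen <- 0L
    pct_pseudo <- NA_real_
  }

  allelic <- truth[truth$label == "allelic_snp", , drop = FALSE]
  n_elig <- 0L
  n_surv <- 0L
  if (nrow(allelic)) {
    recs <- rbind(filtered$passed,
                  rem[names(filtered$passed)])
    rk <- paste(recs$contig_id, recs$start, recs$var, recs$genotype,
                sep = "|")
    surv_k <- paste(filtered$passed$contig_id, filtered$passed$start,
                    filtered$passed$var, filtered$passed$genotype,
                    sep = "|")
    for (i in seq_len(nrow(allelic))) {
      carriers <- strsplit(allelic$genotypes[i], ",", fixed = TRUE)[[1]]
      for (g in carriers) {
        k <- paste(allelic$contig_id[i], allelic$pos[i], allelic$alt[i],
                   g, sep = "|")
        hit <- which(rk == k)
        if (!length(hit) || all(recs$depth[hit] < depth_min)) next
        n_elig <- n_elig + 1L
        if (k %in% surv_k) n_surv <- n_surv + 1L
      }
    }
  }
  list(pseudo_sites = n_seen,
       pct_pseudo_removed_conservation = pct_pseudo,
       allelic_records = n_elig,
       pct_allelic_survived = if (n_elig) 100 * n_surv / n_elig
                              else NA_real_)
}
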