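#' Screen the reference assembly against its own re-mapped variants
#'
#' Before candidate SNPs from other genotypes are considered, contigs of
#' the reference assembly whose own reads re-map with problems are
#' eliminated: polymorphism within the reference genotype can only be a
#' sequencing artifact or a collapsed-copy assembly artifact, and would
#' confound candidate calls. Two stages, in order:
#'
#' 1. `self_indel` — drop contigs with at least one self-variant whose
#'    reference or variant allele contains `-` or spans more than one
#'    base (insertion/deletion or multi-base polymorphism);
#' 2. `self_ambiguous_N` — from the survivors, drop contigs whose
#'    consensus contains an `N`, or with a self-variant calling an `N`.
#'
#' A contig hit by both problems is counted once, in the indel stage.
#' Both percentages are reported relative to the initial contig count.
#'
#' @param reference Named [Biostrings::DNAStringSet] of reference
#'   contigs.
#' @param self_variants Variant-record data.frame from re-mapping the
#'   reference genotype's own reads (may be zero-row).
#' @return List with `retained` (the surviving `DNAStringSet`) and
#'   `report` (an [attrition_report()]).
#' @export
screen_reference <- function(reference, self_variants) {
  n0 <- length(reference)
  stopifnot(n0 >= 1L)
  sv <- self_variants
  unknown <- setdiff(unique(sv$contig_id), names(reference))
  if (length(unknown)) {
    stop("self-variants reference unknown contig(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  is_indel <- grepl("-", sv$ref, fixed = TRUE) |
    grepl("-", sv$var, fixed = TRUE) |
    nchar(sv$ref) > 1L | nchar(sv$var) > 1L
  indel_contigs <- unique(sv$contig_id[is_indel])
  survivors1 <- setdiff(names(reference), indel_contigs)

  has_n_seq <- vapply(survivors1, function(cid) {
    Biostrings::countPattern("N", reference[[cid]]) > 0L
  }, logical(1))
  n_call <- grepl("N", sv$ref, fixed = TRUE) |
    grepl("N", sv$var, fixed = TRUE)
  n_contigs <- union(survivors1[has_n_seq],
                     intersect(unique(sv$contig_id[!is_indel & n_call]),
                               survivors1))
  retained_ids <- setdiff(survivors1, n_contigs)

  report <- attrition_report(
    stage = c("self_indel", "self_ambiguous_N"),
    denominator = c(n0, n0),
    removed = c(length(indel_contigs), length(n_contigs)),
    remaining = c(length(survivors1), length(retained_ids)))
  list(retained = reference[retained_ids], report = report)
}

#' Apply the four-rule pseudo-SNP filter cascade
#'
#' The polyploidy screen at the heart of the pipeline. Candidate records
#' on contigs that failed the reference self-screen are dropped silently
#' first; the survivors then pass through three reported stages, in the
#' order the attrition is conventionally narrated:
#'
#' 1. `indel_or_ambiguous` — variations longer than one base, or calling
#'    `-` (indel) or `N` (non-uniform polymorphism), are removed;
#' 2. `low_depth` — records with read depth `<= depth_min - 1`
#'    (default: depth of 4 or less) are removed;
#' 3. `not_conserved` — records whose frequency is below 100% within
#'    their genotype are removed. Passing requires exact equality to 100
#'    (tolerance 1e-9 on the percent scale): a variant seen in anything
#'    less than all of a genotype's reads at a position is most simply
#'    explained by collapsed homoeologous or paralogous copies, not by
#'    an allele, so this stage is the pseudo-SNP trap.
#'
#' Every stage's percentage is reported against the count entering the
#' cascade. Survivors are single-base, fully conserved, well-covered
#' candidate SNP observations.
#'
#' @param records Variant-record data.frame, or a named list of them
#'   (one per genotype) which is row-bound.
#' @param retained_contigs Character vector of contig ids that survived
#'   [screen_reference()] (or a `DNAStringSet`, whose names are used).
#' @param depth_min Minimum read depth to pass (default 5).
#' @param freq_required Required within-genotype frequency (default 100).
#' @param tol Tolerance on the percent scale for the conservation test.
#' @return List with `passed` (surviving records), `removed` (dropped
#'   records with a `removed_at` column naming the stage) and `report`
#'   (an [attrition_report()]).
#' @export
filter_candidates <- function(records, retained_contigs, depth_min = 5L,
                              freq_required = 100, tol = 1e-9) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, records)
  }
  if (is.null(records) || nrow(records) == 0L) records <- empty_variant_df()
  if (!is.character(retained_contigs)) {
    retained_contigs <- names(retained_contigs)
  }
  stopifnot(length(retained_contigs) >= 1L)
  rec <- records[records$contig_id %in% retained_contigs, , drop = FALSE]
  n0 <- nrow(rec)

  bad_allele <- function(a) grepl("[-N]", a) | nchar(a) > 1L
  stage1 <- bad_allele(rec$ref) | bad_allele(rec$var)
  stage2 <- !stage1 & rec$depth <= depth_min - 1L
  stage3 <- !stage1 & !stage2 &
    abs(rec$freq_pct - freq_required) > tol
  pass <- !stage1 & !stage2 & !stage3

  removed <- rec[!pass, , drop = FALSE]
  removed$removed_at <- ifelse(stage1[!pass], "indel_or_ambiguous",
                        ifelse(stage2[!pass], "low_depth",
                               "not_conserved"))
  r1 <- sum(stage1); r2 <- sum(stage2); r3 <- sum(stage3)
  report <- attrition_report(
    stage = c("indel_or_ambiguous", "low_depth", "not_conserved"),
    denominator = rep(n0, 3L),
    removed = c(r1, r2, r3),
    remaining = c(n0 - r1, n0 - r1 - r2, n0 - r1 - r2 - r3))
  list(passed = rec[pass, , drop = FALSE], removed = removed,
       report = report)
}

#' Classify candidate SNPs by genotype sharing
#'
#' Groups filtered records by (contig, position, variant allele): each
#' group becomes one candidate SNP whose supporting genotype set is the
#' group's genotypes and whose sharing class is the set size — class 1
#' interrogates variation between a single genotype and the reference
#' assembly, classes 2 and 3 between the reference and two or three
#' genotypes. Sharing requires an identical variant allele at an
#' identical coordinate; groups at the same position with different
#' alleles remain distinct candidates. Two records from the same
#' genotype at one position with different alleles are kept in their
#' groups and flagged as a within-genotype conflict.
#'
#' @param passed Filtered variant records (the `passed` element of
#'   [filter_candidates()]).
#' @return Object of class `candidate_snps`: data.frame with columns
#'   `contig_id`, `pos`, `ref`, `alt`, `sharing_class`, `genotypes`
#'   (comma-separated, sorted), `depth_total`, `support`
#'   (`genotype:freq/depth`, semicolon-separated). Attribute
#'   `conflicts` lists within-genotype conflicting (contig, pos) keys.
#' @export
classify_candidates <- function(passed) {
  if (nrow(passed) == 0L) {
    out <- data.frame(contig_id = character(), pos = integer(),
                      ref = character(), alt = character(),
                      sharing_class = integer(), genotypes = character(),
                      depth_total = integer(), support = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("candidate_snps", "data.frame")
    attr(out, "conflicts") <- character()
    return(out)
  }
  stopifnot(all(passed$start == passed$end))
  key <- paste(passed$contig_id, passed$start, passed$var, sep = "|")
  groups <- split(seq_len(nrow(passed)), key)
  rows <- lapply(groups, function(idx) {
    g <- passed[idx, ]
    g <- g[order(g$genotype), ]
    data.frame(
      contig_id = g$contig_id[1], pos = g$start[1],
      ref = g$ref[1], alt = g$var[1],
      sharing_class = length(unique(g$genotype)),
      genotypes = paste(unique(g$genotype), collapse = ","),
      depth_total = sum(g$depth),
      support = paste(sprintf("%s:%.1f/%d", g$genotype, g$freq_pct,
                              g$depth), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$contig_id, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL

  gkey <- paste(passed$contig_id, passed$start, passed$genotype, sep = "|")
  nalt <- vapply(split(passed$var, gkey),
                 function(v) length(unique(v)), 1L)
  conflicts <- names(nalt)[nalt > 1L]
  if (length(conflicts)) {
    message("within-genotype conflicting alleles at: ",
            paste(conflicts, collapse = ", "))
  }
  class(out) <- c("candidate_snps", "data.frame")
  attr(out, "conflicts") <- conflicts
  out
}

#' Exclude contigs with crowded assay targets
#'
#' A contig is eliminated from the assay set when any two of its
#' candidate positions lie strictly less than `window_bp` apart —
#' multiple melting targets within one amplicon window confound
#' melt-curve genotyping. Elimination is contig-level and affects only
#' assay output: the contig's candidates stay in the catalog.
#'
#' @param candidates A `candidate_snps` data.frame.
#' @param window_bp Window size in bp (default 100). Candidates exactly
#'   `window_bp` apart are retained (strict inequality).
#' @return List with `eligible` (candidates on retained contigs) and
#'   `eliminated_contigs` (character vector of contig ids).
#' @export
select_assay_targets <- function(candidates, window_bp = 100L) {
  crowded <- vapply(split(candidates$pos, candidates$contig_id),
                    function(p) {
                      p <- sort(p)
                      length(p) > 1L && any(diff(p) < window_bp)
                    }, logical(1))
  eliminated <- names(crowded)[crowded]
  list(eligible = candidates[!(candidates$contig_id %in% eliminated), ,
                             drop = FALSE],
       eliminated_contigs = eliminated)
}

# two-base IUPAC ambiguity codes (A/G -> R, C/T -> Y, ...)
iupac_code <- function(ref, alt) {
  as.character(Biostrings::mergeIUPACLetters(
    paste(sort(c(ref, alt)), collapse = "")))
}

#' Build IUPAC-masked assay target windows
#'
#' For each candidate SNP, extracts a window of up to `flank_bp` bases
#' either side of the SNP on its reference contig and replaces the SNP
#' base with the two-base IUPAC ambiguity code for {ref, alt}
#' (dbSNP-style masking for primer-design software). Windows running
#' into a contig end are truncated and flagged, never an error. Each
#' target carries the amplicon product-size constraint handed to primer
#' design (optimum 90 bp, tolerance +/- 30).
#'
#' @param candidates A `candidate_snps` data.frame (typically the
#'   `eligible` set from [select_assay_targets()]).
#' @param reference Named [Biostrings::DNAStringSet]; every candidate's
#'   contig and position must lie within it.
#' @param flank_bp Flank length per side (default 50).
#' @param product_size,product_tol Product-size constraint annotation
#'   (defaults 90 and 30).
#' @return Object of class `masked_targets`: data.frame with columns
#'   `name`, `contig_id`, `pos`, `ref`, `alt`, `iupac`, `window_start`,
#'   `window_end`, `truncated`, `seq`, `product_size`, `product_tol`.
#' @export
mask_snp_fasta <- function(candidates, reference, flank_bp = 50L,
                           product_size = 90L, product_tol = 30L) {
  unknown <- setdiff(unique(candidates$contig_id), names(reference))
  if (length(unknown)) {
    stop("candidates reference unknown contig(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- nrow(candidates)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cd <- candidates[i, ]
    contig <- reference[[cd$contig_id]]
    len <- length(contig)
    if (cd$pos < 1L || cd$pos > len) {
      stop("candidate position ", cd$pos, " outside contig ",
           cd$contig_id, call. = FALSE)
    }
    ws <- max(1L, cd$pos - flank_bp)
    we <- min(len, cd$pos + flank_bp)
    win <- strsplit(as.character(
      Biostrings::subseq(contig, ws, we)), "")[[1]]
    win[cd$pos - ws + 1L] <- iupac_code(cd$ref, cd$alt)
    rows[[i]] <- data.frame(
      name = sprintf("%s_%d", cd$contig_id, cd$pos),
      contig_id = cd$contig_id, pos = cd$pos,
      ref = cd$ref, alt = cd$alt, iupac = win[cd$pos - ws + 1L],
      window_start = ws, window_end = we,
      truncated = (cd$pos - ws < flank_bp) || (we - cd$pos < flank_bp),
      seq = paste(win, collapse = ""),
      product_size = product_size, product_tol = product_tol,
      stringsAsFactors = FALSE)
  }
  out <- if (n) do.call(rbind, rows) else
    data.frame(name = character(), contig_id = character(),
               pos = integer(), ref = character(), alt = character(),
               iupac = character(), window_start = integer(),
               window_end = integer(), truncated = logical(),
               seq = character(), product_size = integer(),
               product_tol = integer(), stringsAsFactors = FALSE)
  class(out) <- c("masked_targets", "data.frame")
  out
}

#' Write masked assay targets as dbSNP-style FASTA
#'
#' Headers carry the allele pair, SNP position within the window, and
#' the product-size constraint, e.g.
#' `>c0001_120 alleles=A/G pos=51 product=90+/-30`.
#'
#' @param targets A `masked_targets` data.frame from [mask_snp_fasta()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_masked_fasta <- function(targets, path) {
  stopifnot(inherits(targets, "masked_targets"))
  seqs <- Biostrings::DNAStringSet(targets$seq)
  names(seqs) <- sprintf("%s alleles=%s/%s pos=%d product=%d+/-%d",
                         targets$name, targets$ref, targets$alt,
                         targets$pos - targets$window_start + 1L,
                         targets$product_size, targets$product_tol)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
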