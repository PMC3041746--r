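#' Place reads on a reference contig assembly
#'
#' A minimal deterministic stand-in for a 454-era reference mapper: each
#' read is aligned globally (read) to a local window of every contig
#' with [Biostrings::pairwiseAlignment()] under unit edit costs, and
#' assigned to its best-scoring placement. A read is reported unplaced
#' when its best alignment needs more edits than the band allows
#' (default 10% of the read length). Equal-scoring placements are broken
#' deterministically by (contig id, offset) lexicographic order.
#'
#' ESTs are contiguous, so no split or chimeric placements are
#' attempted, and only the transcript (forward) strand is searched.
#'
#' @param reads Named character vector of read sequences, or a
#'   `sim_reads` genotype element.
#' @param reference Named [Biostrings::DNAStringSet] of contigs.
#' @param band_frac Maximum edit distance as a fraction of read length.
#' @return Object of class `read_placements`: data.frame with one row
#'   per read (`read_id`, `contig_id`, `start`, `edits`, `placed`) plus
#'   attributes `aligned_read` / `aligned_ref` holding the gapped
#'   alignment strings for placed reads.
#' @export
align_reads <- function(reads, reference, band_frac = 0.1) {
  stopifnot(length(reads) >= 1L, length(reference) >= 1L)
  if (is.null(names(reads))) names(reads) <- sprintf("r%05d",
                                                     seq_along(reads))
  contig_order <- sort(names(reference))
  n <- length(reads)
  res <- data.frame(read_id = names(reads),
                    contig_id = NA_character_, start = NA_integer_,
                    edits = NA_integer_, placed = FALSE,
                    stringsAsFactors = FALSE)
  aligned_read <- character(n)
  aligned_ref <- character(n)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1)
  for (i in seq_len(n)) {
    rd <- reads[[i]]
    band <- floor(band_frac * nchar(rd))
    best <- NULL
    for (cid in contig_order) {
      # a small gap-opening cost breaks mismatch-vs-indel ties toward
      # the mismatch, so substitutions are never reported as indels
      aln <- Biostrings::pairwiseAlignment(
        pattern = rd, subject = reference[[cid]],
        type = "global-local", substitutionMatrix = submat,
        gapOpening = 0.5, gapExtension = 1)
      edits <- ceiling(-Biostrings::score(aln) - 1e-9)
      start <- Biostrings::start(Biostrings::subject(aln))
      cand <- list(contig = cid, start = start, edits = edits,
                   pat = as.character(Biostrings::alignedPattern(aln)),
                   sub = as.character(Biostrings::alignedSubject(aln)))
      if (is.null(best) || cand$edits < best$edits ||
          (cand$edits == best$edits &&
           (cand$contig < best$contig ||
            (cand$contig == best$contig && cand$start < best$start)))) {
        best <- cand
      }
    }
    if (!is.null(best) && best$edits <= band) {
      res$contig_id[i] <- best$contig
      res$start[i] <- best$start
      res$edits[i] <- best$edits
      res$placed[i] <- TRUE
      aligned_read[i] <- best$pat
      aligned_ref[i] <- best$sub
    }
  }
  structure(res, aligned_read = aligned_read, aligned_ref = aligned_ref,
            class = c("read_placements", "data.frame"))
}

# accumulate per-column allele counts from gapped alignment strings;
# returns a list keyed "contig|pos" of list(ref, counts) where an
# insertion relative to the reference is keyed at the preceding
# reference position with ref "-"
build_pileup <- function(placements) {
  stopifnot(inherits(placements, "read_placements"))
  pat <- attr(placements, "aligned_read")
  sub <- attr(placements, "aligned_ref")
  pile <- new.env(parent = emptyenv())
  bump <- function(contig, pos, ref, allele) {
    key <- paste0(contig, "|", pos, "|", ref)
    cur <- if (!is.null(pile[[key]])) pile[[key]] else integer()
    cur[allele] <- (if (allele %in% names(cur)) cur[[allele]] else 0L) + 1L
    pile[[key]] <- cur
  }
  for (i in which(placements$placed)) {
    p <- strsplit(pat[i], "")[[1]]
    s <- strsplit(sub[i], "")[[1]]
    refpos <- placements$start[i] - 1L
    contig <- placements$contig_id[i]
    for (j in seq_along(s)) {
      if (s[j] != "-") {
        refpos <- refpos + 1L
        bump(contig, refpos, s[j], p[j])      # match/mismatch/deletion "-"
      } else {
        bump(contig, refpos, "-", p[j])       # insertion in the read
      }
    }
  }
  pile
}

#' Call candidate variants from read placements
#'
#' Reproduces the mapper behaviour of reporting every sequence
#' difference against the reference: for each reference column covered
#' by at least one placed read, one record is emitted per observed
#' non-reference allele, with `freq_pct = 100 * allele reads / depth`
#' (one decimal) and `depth` the column read depth. Read deletions are
#' emitted with `-` as the variant allele; read insertions with `-` as
#' the reference allele (anchored at the preceding reference position).
#' `N` in reads counts toward depth and forms its own allele class.
#' Columns with no coverage never emit records.
#'
#' @param placements A `read_placements` object from [align_reads()].
#' @param reference Named [Biostrings::DNAStringSet] of contigs.
#' @param genotype Genotype label written on every record.
#' @return Variant-record data.frame (see [variant_table]).
#' @export
call_variants <- function(placements, reference, genotype) {
  unknown <- setdiff(stats::na.omit(unique(placements$contig_id)),
                     names(reference))
  if (length(unknown)) {
    stop("placements reference unknown contig(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pile <- build_pileup(placements)
  keys <- ls(pile)
  recs <- list()
  for (key in keys) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    contig <- parts[1]
    pos <- as.integer(parts[2])
    ref <- parts[3]
    counts <- pile[[key]]
    depth <- sum(counts)
    if (depth < 1L) next
    for (allele in sort(names(counts))) {
      if (allele == ref) next
      recs[[length(recs) + 1L]] <- data.frame(
        contig_id = contig, start = pos, end = pos,
        ref = ref, var = allele,
        freq_pct = round(100 * counts[[allele]] / depth, 1),
        depth = depth, genotype = genotype, stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) return(empty_variant_df())
  out <- do.call(rbind, recs)
  out[order(out$contig_id, out$start, out$var), , drop = FALSE]
}
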