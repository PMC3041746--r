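#' @title Variant-table dialect and core record schema
#' @description
#' The pipeline's candidate variants travel in a fixed tab-separated
#' dialect that mirrors the "header report" a 454-era reference mapper
#' emits for each sequence difference against the reference assembly:
#' contig name, 1-based start and end position (both inclusive), the
#' reference and polymorphic base, the variation frequency as a percent,
#' the sample read depth, and the source genotype.
#'
#' Header (tab separated):
#' `contig_id  start  end  ref  var  freq_pct  depth  genotype`
#'
#' `-` denotes a gap allele (insertion/deletion); frequency is printed
#' with one decimal. Coordinates are transcript-strand, 1-based,
#' inclusive of both ends.
#' @name variant_table
NULL

VARIANT_COLS <- c("contig_id", "start", "end", "ref", "var",
                  "freq_pct", "depth", "genotype")

empty_variant_df <- function() {
  data.frame(contig_id = character(), start = integer(), end = integer(),
             ref = character(), var = character(), freq_pct = numeric(),
             depth = integer(), genotype = character(),
             stringsAsFactors = FALSE)
}

# per-row invariant checks; returns character vector of failure messages
# (empty when the row is valid)
validate_variant_row <- function(row) {
  msgs <- character()
  allele_re <- "^[ACGTN-]+$"
  if (is.na(row$start) || is.na(row$end) || row$start > row$end)
    msgs <- c(msgs, "start must be <= end")
  if (is.na(row$depth) || row$depth < 1)
    msgs <- c(msgs, "depth >= 1 violated")
  if (is.na(row$freq_pct) || row$freq_pct <= 0 || row$freq_pct > 100)
    msgs <- c(msgs, "freq_pct must lie in (0, 100]")
  if (!grepl(allele_re, row$ref) || !grepl(allele_re, row$var))
    msgs <- c(msgs, "alleles restricted to A,C,G,T,N,-")
  if (identical(row$ref, row$var))
    msgs <- c(msgs, "ref and var alleles must differ")
  msgs
}

#' Read a candidate variant table
#'
#' Parses the tab-separated [variant_table] dialect, validating every row
#' against the record invariants (1-based `start <= end`, `depth >= 1`,
#' frequency in (0, 100], alleles over `A,C,G,T,N,-`, `ref != var`).
#' Invalid rows abort the read with an error naming each offending line
#' and the violated invariant.
#'
#' @param path Path to a variant-table TSV with header.
#' @return A data.frame of validated variant records (possibly
#'   zero-row for a header-only file).
#' @examples
#' tmp <- tempfile(fileext = ".tsv")
#' df <- data.frame(contig_id = "c1", start = 10L, end = 10L,
#'                  ref = "A", var = "G", freq_pct = 100,
#'                  depth = 7L, genotype = "Ogle")
#' write_variant_table(df, tmp)
#' read_variant_table(tmp)
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) {
    stop("variant table not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(VARIANT_COLS %in% names(raw))) {
    stop("variant table ", path, " lacks required columns: ",
         paste(setdiff(VARIANT_COLS, names(raw)), collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[VARIANT_COLS]
  if (nrow(raw) == 0L) return(empty_variant_df())

  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  df <- data.frame(
    contig_id = raw$contig_id,
    start = as.integer(num_or_na(raw$start)),
    end = as.integer(num_or_na(raw$end)),
    ref = toupper(raw$ref),
    var = toupper(raw$var),
    freq_pct = num_or_na(raw$freq_pct),
    depth = as.integer(num_or_na(raw$depth)),
    genotype = raw$genotype,
    stringsAsFactors = FALSE
  )
  errs <- character()
  for (i in seq_len(nrow(df))) {
    msgs <- validate_variant_row(df[i, ])
    if (length(msgs)) {
      # +1 for the header line so the number matches the file
      errs <- c(errs, sprintf("line %d: %s", i + 1L,
                              paste(msgs, collapse = "; ")))
    }
  }
  if (length(errs)) {
    stop("invalid variant record(s) in ", path, ":\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  df
}

#' Write a candidate variant table
#'
#' Emits the tab-separated [variant_table] dialect with the frequency
#' printed to one decimal, so that write -> read -> write round-trips
#' byte-identically.
#'
#' @param records Variant-record data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_variant_table <- function(records, path) {
  stopifnot(all(VARIANT_COLS %in% names(records)))
  out <- records[VARIANT_COLS]
  out$freq_pct <- sprintf("%.1f", out$freq_pct)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Summarize per-genotype assemblies
#'
#' Computes, per genotype, the contig count, total length, mean/SD/min/max
#' contig length (SD by the population formula), and — when read counts
#' are supplied — the percent of reads assembled; then combines the rows
#' with [combine_assembly_stats()] into survey-level totals.
#'
#' @param contigs Named list (one element per genotype) of contig sets:
#'   [Biostrings::DNAStringSet] objects or numeric vectors of contig
#'   lengths.
#' @param reads Optional data.frame with columns `genotype`,
#'   `total_reads`, `assembled_reads`. When missing, read-derived fields
#'   are omitted with a warning.
#' @return List with `per_genotype` (data.frame of per-genotype rows) and
#'   `overall` (list of survey totals; see [combine_assembly_stats()]).
#' @examples
#' summarize_assembly(list(gA = c(100, 300)))
#' @export
summarize_assembly <- function(contigs, reads = NULL) {
  stopifnot(length(contigs) >= 1L)
  lens <- lapply(contigs, function(x) {
    if (methods::is(x, "XStringSet")) Biostrings::width(x) else as.numeric(x)
  })
  if (any(vapply(lens, length, 1L) == 0L)) {
    stop("each genotype needs at least one contig", call. = FALSE)
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  per <- data.frame(
    genotype = names(lens),
    n_contigs = vapply(lens, length, 1L),
    total_length_mb = vapply(lens, function(x) sum(x) / 1e6, 1),
    mean_len_bp = vapply(lens, mean, 1),
    sd_len_bp = vapply(lens, pop_sd, 1),
    min_len_bp = vapply(lens, min, 1),
    max_len_bp = vapply(lens, max, 1),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(reads)) {
    idx <- match(per$genotype, reads$genotype)
    per$total_reads <- reads$total_reads[idx]
    per$assembled_reads <- reads$assembled_reads[idx]
  } else {
    warning("no read counts supplied; read-derived fields omitted",
            call. = FALSE)
  }
  list(per_genotype = per, overall = combine_assembly_stats(per))
}

#' Combine per-genotype assembly statistics into survey totals
#'
#' The overall mean contig length is the contig-count-weighted mean of
#' the per-genotype means; the percent of reads assembled is rounded to
#' an integer. Works directly on a published-style per-genotype summary
#' table (columns `genotype`, `n_contigs`, `mean_len_bp`, optionally
#' `sd_len_bp`, `total_reads`, `assembled_reads`).
#'
#' @param per_genotype Data.frame of per-genotype statistics.
#' @return List with `total_contigs`, `mean_contigs_per_genotype`
#'   (rounded), `overall_mean_len_bp` (weighted, rounded), `mean_sd_bp`
#'   (rounded mean of per-genotype SDs, when present), and — when read
#'   counts are present — `total_reads`, `total_assembled_reads`,
#'   `pct_assembled` (rounded).
#' @export
combine_assembly_stats <- function(per_genotype) {
  stopifnot(all(c("n_contigs", "mean_len_bp") %in% names(per_genotype)))
  n <- per_genotype$n_contigs
  out <- list(
    total_contigs = sum(n),
    mean_contigs_per_genotype = round(sum(n) / nrow(per_genotype)),
    overall_mean_len_bp = round(sum(n * per_genotype$mean_len_bp) / sum(n))
  )
  if ("sd_len_bp" %in% names(per_genotype)) {
    out$mean_sd_bp <- round(mean(per_genotype$sd_len_bp))
  }
  if (all(c("total_reads", "assembled_reads") %in% names(per_genotype)) &&
      !anyNA(per_genotype$total_reads)) {
    out$total_reads <- sum(per_genotype$total_reads)
    out$total_assembled_reads <- sum(per_genotype$assembled_reads)
    out$pct_assembled <- round(100 * out$total_assembled_reads /
                                 out$total_reads)
  }
  out
}

#' Export classified candidate SNPs as VCF 4.2
#'
#' Writes one data line per candidate: `CHROM` = contig id, 1-based
#' `POS`, `REF`/`ALT` single bases, and an `INFO` field carrying the
#' summed read depth (`DP`), the genotype-sharing class (`SC`), the
#' supporting genotypes (`GTS`) and their per-genotype support strings
#' (`SUP`, `genotype:freq/depth`). Contig header lines carry lengths
#' taken from the reference. An empty candidate set yields a
#' header-only VCF.
#'
#' @param candidates A `candidate_snps` data.frame from
#'   [classify_candidates()].
#' @param reference Named [Biostrings::DNAStringSet] of reference
#'   contigs; every candidate's contig must be present.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_vcf <- function(candidates, reference, path) {
  unknown <- setdiff(unique(candidates$contig_id), names(reference))
  if (length(unknown)) {
    stop("candidates reference unknown contig(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=polysnp",
    paste0("##INFO=<ID=DP,Number=1,Type=Integer,",
           "Description=\"Summed supporting read depth\">"),
    paste0("##INFO=<ID=SC,Number=1,Type=Integer,",
           "Description=\"Genotype sharing class\">"),
    paste0("##INFO=<ID=GTS,Number=.,Type=String,",
           "Description=\"Supporting genotypes\">"),
    paste0("##INFO=<ID=SUP,Number=.,Type=String,",
           "Description=\"Per-genotype support genotype:freq/depth\">")
  )
  used <- sort(unique(candidates$contig_id))
  hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", used,
                        Biostrings::width(reference)[match(used,
                                                    names(reference))]))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", sep = "\t"))
  lines <- hdr
  if (nrow(candidates)) {
    ord <- order(candidates$contig_id, candidates$pos, candidates$alt)
    cd <- candidates[ord, ]
    info <- sprintf("DP=%d;SC=%d;GTS=%s;SUP=%s",
                    cd$depth_total, cd$sharing_class,
                    gsub(",", ",", cd$genotypes, fixed = TRUE),
                    cd$support)
    lines <- c(lines, sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                              cd$contig_id, cd$pos,
                              sprintf("%s_%d", cd$contig_id, cd$pos),
                              cd$ref, cd$alt, info))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read reference contigs from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that trims FASTA
#' descriptions to the first whitespace-delimited token so contig ids
#' match the variant tables.
#'
#' @param path FASTA path.
#' @return Named [Biostrings::DNAStringSet].
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}
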