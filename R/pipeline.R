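#' Configuration for the discovery pipeline
#'
#' Bundles inputs and thresholds for [run_pipeline()]. Inputs may be
#' file paths (reference FASTA, per-genotype variant-table TSVs) or
#' in-memory objects (a [Biostrings::DNAStringSet] and a named list of
#' variant-record data.frames). The first/first-named genotype whose
#' table equals `reference_genotype` supplies the self-variants for the
#' reference screen. Thresholds default to the pipeline's standard
#' values: depth at least 5, 100% within-genotype frequency, 100 bp
#' assay-target exclusion window, 50 bp masking flank, 90 +/- 30 bp
#' product size.
#'
#' @param reference Path to a reference FASTA or a `DNAStringSet`.
#' @param tables Named list (by genotype) of variant-table paths or
#'   data.frames; must include `reference_genotype`.
#' @param reference_genotype Name of the reference-assembly genotype.
#' @param out_dir Output directory for artifacts.
#' @param depth_min,freq_required,window_bp,flank_bp,product_size,product_tol
#'   Filter and assay-design thresholds.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(reference, tables, reference_genotype,
                            out_dir = NULL, depth_min = 5L,
                            freq_required = 100, window_bp = 100L,
                            flank_bp = 50L, product_size = 90L,
                            product_tol = 30L) {
  if (!reference_genotype %in% names(tables)) {
    stop("tables must include the reference genotype '",
         reference_genotype, "'", call. = FALSE)
  }
  stopifnot(depth_min >= 1L, freq_required > 0, freq_required <= 100,
            window_bp >= 1L, flank_bp >= 1L)
  structure(list(reference = reference, tables = tables,
                 reference_genotype = reference_genotype,
                 out_dir = out_dir, depth_min = as.integer(depth_min),
                 freq_required = freq_required,
                 window_bp = as.integer(window_bp),
                 flank_bp = as.integer(flank_bp),
                 product_size = as.integer(product_size),
                 product_tol = as.integer(product_tol)),
            class = "pipeline_config")
}

load_reference <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  read_reference_fasta(x)
}

load_table <- function(x) {
  if (is.data.frame(x)) return(x)
  read_variant_table(x)
}

#' Run the full SNP discovery pipeline
#'
#' Executes, in order: reference self-screen ([screen_reference()]),
#' the pseudo-SNP filter cascade over the non-reference genotypes'
#' records ([filter_candidates()]), genotype-sharing classification
#' ([classify_candidates()]), crowded-target exclusion
#' ([select_assay_targets()]) and IUPAC masking ([mask_snp_fasta()]).
#' When `config$out_dir` is set, artifacts are written there:
#' `candidates.tsv` (catalog), `assay_targets.fasta` (masked targets),
#' `candidates.vcf`, `attrition.tsv` and `attrition.txt` (the combined
#' screen + filter report in machine and narrative form). Identical
#' configuration yields byte-identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list: `retained_contigs`, `report` (combined
#'   [attrition_report()]), `passed`, `removed`, `candidates`,
#'   `assay` (list `eligible`/`eliminated_contigs`), `targets`
#'   (masked targets), `class_counts` (candidates per sharing class).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  reference <- load_reference(config$reference)
  tables <- lapply(config$tables, load_table)
  self_tab <- tables[[config$reference_genotype]]
  other_tabs <- tables[setdiff(names(tables), config$reference_genotype)]

  screened <- screen_reference(reference, self_tab)
  filtered <- filter_candidates(other_tabs, names(screened$retained),
                                depth_min = config$depth_min,
                                freq_required = config$freq_required)
  candidates <- classify_candidates(filtered$passed)
  assay <- select_assay_targets(candidates, config$window_bp)
  targets <- mask_snp_fasta(assay$eligible, reference,
                            flank_bp = config$flank_bp,
                            product_size = config$product_size,
                            product_tol = config$product_tol)
  combined <- rbind(screened$report, filtered$report)
  class(combined) <- c("attrition_report", "data.frame")

  class_counts <- table(factor(candidates$sharing_class,
                               levels = seq_len(max(1L,
                                 length(other_tabs)))))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$out_dir, f)
    utils::write.table(candidates, out("candidates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_masked_fasta(targets, out("assay_targets.fasta"))
    export_vcf(candidates, reference, out("candidates.vcf"))
    render_report(combined, "tsv", out("attrition.tsv"))
    render_report(combined, "text", out("attrition.txt"))
  }

  invisible(list(retained_contigs = names(screened$retained),
                 report = combined,
                 passed = filtered$passed, removed = filtered$removed,
                 candidates = candidates, assay = assay,
                 targets = targets,
                 class_counts = as.integer(class_counts)))
}
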