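#' Read or write a marker call table
#'
#' Marker call tables are TSV with marker ids in the first column
#' (`marker`) and one column per individual. RIL mode uses calls
#' `A`/`B`/`H` plus missing (empty or `-`); diversity mode uses named
#' allele states (e.g. `A`, `G`, `In1`, `Del1`, `Het`, `Null`).
#'
#' @param path File path.
#' @return Character matrix, markers in rows, individuals in columns;
#'   missing calls are `NA`.
#' @export
read_marker_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"marker" %in% names(df)) {
    stop("marker table must have a 'marker' column", call. = FALSE)
  }
  m <- as.matrix(df[setdiff(names(df), "marker")])
  rownames(m) <- df$marker
  m[m == "" | m == "-"] <- NA_character_
  m
}

#' @rdname read_marker_table
#' @param calls Character matrix of calls.
#' @export
write_marker_table <- function(calls, path) {
  df <- data.frame(marker = rownames(calls), calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df[is.na(df)] <- "-"
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Score marker segregation in a RIL population
#'
#' For each marker, counts the parental and heterozygous calls, reports
#' the segregation ratio `SR = n_A / n_B` (parent-A allele count over
#' parent-B; `NA` when `n_B = 0`), and tests the homozygous counts
#' against the 1:1 Mendelian expectation with a 1-df chi-square without
#' continuity correction. Markers with an excess of heterozygous calls
#' (fraction `>= het_threshold` of the called genotypes) are flagged:
#' in an inbred population a large heterozygous class usually signals a
#' mixture of alleles from two different loci rather than a marker.
#' The distortion flag is an extension beyond the plain ratio and is
#' labelled as such in output.
#'
#' @param calls Character matrix (markers x individuals) of RIL-mode
#'   calls.
#' @param parent_a,parent_b,het Call symbols (defaults `A`, `B`, `H`).
#' @param alpha Significance level for the distortion flag.
#' @param het_threshold Heterozygous-fraction threshold (default 0.4).
#' @return Data.frame with one row per marker: `marker`, `n_a`, `n_b`,
#'   `n_h`, `n_missing`, `sr`, `chi_square`, `p_value`, `distorted`,
#'   `het_fraction`, `het_excess`.
#' @examples
#' calls <- simulate_ril_calls(5, 100, seed = 7)
#' score_segregation(calls)
#' @export
score_segregation <- function(calls, parent_a = "A", parent_b = "B",
                              het = "H", alpha = 0.05,
                              het_threshold = 0.4) {
  stopifnot(is.matrix(calls))
  res <- lapply(seq_len(nrow(calls)), function(i) {
    x <- calls[i, ]
    n_a <- sum(x == parent_a, na.rm = TRUE)
    n_b <- sum(x == parent_b, na.rm = TRUE)
    n_h <- sum(x == het, na.rm = TRUE)
    n_missing <- length(x) - n_a - n_b - n_h
    n_hom <- n_a + n_b
    chi <- if (n_hom > 0) (n_a - n_b)^2 / n_hom else NA_real_
    p <- if (is.na(chi)) NA_real_ else
      stats::pchisq(chi, df = 1, lower.tail = FALSE)
    het_frac <- if (n_hom + n_h > 0) n_h / (n_hom + n_h) else NA_real_
    data.frame(
      marker = rownames(calls)[i],
      n_a = n_a, n_b = n_b, n_h = n_h, n_missing = n_missing,
      sr = if (n_b > 0) n_a / n_b else NA_real_,
      chi_square = chi, p_value = p,
      distorted = !is.na(p) && p < alpha,
      het_fraction = het_frac,
      het_excess = !is.na(het_frac) && het_frac >= het_threshold,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Code a diversity-mode call table as a binary matrix
#'
#' One indicator column is created per allele state observed at each
#' marker (columns named `marker.state`). `Null` (no amplification)
#' scores 0 in all of that marker's columns — absence of every allele.
#' Missing calls score `NA` across the marker's columns and are handled
#' pairwise-complete downstream. `Het` coding is configurable:
#' `"state"` (default) treats the heterozygous melt class as its own
#' allele state, as melt-curve genotyping resolves it; `"expand"` scores
#' 1 in both constituent SNP-allele columns when the marker has exactly
#' two single-base states, falling back to an own column otherwise.
#' Markers with no observed states are dropped with a warning.
#'
#' @param calls Character matrix (markers x individuals) of
#'   diversity-mode calls.
#' @param het_mode `"state"` or `"expand"`.
#' @param het,null Call symbols (defaults `Het`, `Null`).
#' @return Numeric matrix, individuals in rows, indicator columns;
#'   entries 0/1 or `NA`.
#' @export
code_binary <- function(calls, het_mode = c("state", "expand"),
                        het = "Het", null = "Null") {
  stopifnot(is.matrix(calls))
  het_mode <- match.arg(het_mode)
  inds <- colnames(calls)
  cols <- list()
  for (m in rownames(calls)) {
    x <- calls[m, ]
    states <- sort(unique(x[!is.na(x) & x != null]))
    expand_het <- FALSE
    if (het %in% states && het_mode == "expand") {
      snp_states <- setdiff(states, het)
      if (length(snp_states) == 2L && all(nchar(snp_states) == 1L)) {
        states <- snp_states
        expand_het <- TRUE
      }
    }
    if (!length(states)) {
      warning("marker ", m, " has no observed states; dropped",
              call. = FALSE)
      next
    }
    for (s in states) {
      v <- ifelse(is.na(x), NA_real_,
                  ifelse(x == s | (expand_het & x == het), 1, 0))
      cols[[paste(m, s, sep = ".")]] <- v
    }
  }
  if (!length(cols)) {
    return(matrix(numeric(), nrow = length(inds), ncol = 0L,
                  dimnames = list(inds, character())))
  }
  do.call(cbind, cols)
}

#' Dice similarity between binary profiles
#'
#' For individuals i and j, over the columns where both have data
#' (pairwise-complete), with `a` shared presences, `b` presences only in
#' i and `c` only in j: `S = 2a / (2a + b + c)`; defined as 0 when
#' `2a + b + c = 0`.
#'
#' @param m Binary matrix (individuals x indicator columns), entries
#'   0/1 or `NA`.
#' @return Symmetric similarity matrix over individuals.
#' @examples
#' dice_similarity(rbind(x = c(1, 1, 0), y = c(1, 0, 1)))
#' @export
dice_similarity <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  n <- nrow(m)
  s <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      xi <- m[i, ok] > 0
      xj <- m[j, ok] > 0
      a <- sum(xi & xj)
      b <- sum(xi & !xj)
      cc <- sum(!xi & xj)
      denom <- 2 * a + b + cc
      s[i, j] <- s[j, i] <- if (denom > 0) 2 * a / denom else 0
    }
  }
  s
}

#' UPGMA clustering of a similarity matrix
#'
#' Agglomerative unweighted pair-group clustering with arithmetic
#' averages on the distance `d = 1 - S`. At each step the closest pair
#' of clusters merges at height `d/2`; the distance from the merged
#' cluster to any other is the size-weighted mean of its members'
#' distances. Ties (within 1e-12) are broken by the lexicographically
#' smallest pair of minimum member labels, making the tree
#' deterministic. The result is ultrametric: merge heights never
#' decrease.
#'
#' @param s Square symmetric similarity matrix with labelled rows (or a
#'   distance matrix with `is_similarity = FALSE`).
#' @param is_similarity When `TRUE` (default) distances are `1 - s`.
#' @return Object of class `upgma_tree`: list with `newick` (with
#'   branch lengths), `heights` (merge heights, one per internal node),
#'   `labels`, and `cophenetic` (matrix of tree distances, `2 x` merge
#'   height for each leaf pair). Convert with [as_phylo()].
#' @examples
#' s <- diag(3); dimnames(s) <- list(letters[1:3], letters[1:3])
#' s[s == 0] <- 0.6
#' upgma(s)$newick
#' @export
upgma <- function(s, is_similarity = TRUE) {
  stopifnot(is.matrix(s), nrow(s) == ncol(s), nrow(s) >= 2L)
  if (max(abs(s - t(s))) > 1e-9) {
    stop("input matrix must be symmetric", call. = FALSE)
  }
  labels <- rownames(s)
  if (is.null(labels)) {
    labels <- paste0("t", seq_len(nrow(s)))
  }
  d <- if (is_similarity) 1 - s else s
  dimnames(d) <- list(labels, labels)

  clusters <- lapply(labels, function(l) {
    list(members = l, size = 1L, height = 0, newick = l)
  })
  coph <- matrix(0, length(labels), length(labels),
                 dimnames = list(labels, labels))
  heights <- numeric()
  active <- seq_along(clusters)
  dm <- d

  while (length(active) > 1L) {
    # find min-distance pair with deterministic tie-break
    best <- NULL
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        dij <- dm[i, j]
        key <- sort(c(min(clusters[[i]]$members),
                      min(clusters[[j]]$members)))
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = dij, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    ci <- clusters[[i]]; cj <- clusters[[j]]
    heights <- c(heights, h)
    for (a in ci$members) for (b in cj$members) {
      coph[a, b] <- coph[b, a] <- 2 * h
    }
    merged <- list(
      members = sort(c(ci$members, cj$members)),
      size = ci$size + cj$size,
      height = h,
      newick = sprintf("(%s:%.10g,%s:%.10g)",
                       ci$newick, h - ci$height,
                       cj$newick, h - cj$height))
    # size-weighted average-linkage update (equivalent to the mean of
    # all original member-pair distances)
    for (k in active) {
      if (k == i || k == j) next
      dm[i, k] <- dm[k, i] <-
        (ci$size * dm[i, k] + cj$size * dm[j, k]) / (ci$size + cj$size)
    }
    clusters[[i]] <- merged
    active <- setdiff(active, j)
  }
  root <- clusters[[active]]
  structure(list(newick = paste0(root$newick, ";"),
                 heights = heights, labels = labels,
                 cophenetic = coph),
            class = "upgma_tree")
}

#' Convert a UPGMA tree to an ape phylo object
#'
#' Parses the tree's Newick serialization with [ape::read.tree()].
#'
#' @param tree An `upgma_tree`.
#' @return An [ape] `phylo` object with branch lengths.
#' @export
as_phylo <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  ape::read.tree(text = tree$newick)
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree over", length(x$labels), "taxa\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' Write a UPGMA tree as Newick
#'
#' @param tree An `upgma_tree`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "upgma_tree"))
  writeLines(tree$newick, path)
  invisible(path)
}

#' Summarize allele richness of a diversity panel
#'
#' Counts the distinct allele states observed per marker (including
#' `Null` — a reproducible no-amplification class is an allele in
#' melt-curve genotyping), the total over markers, and the mean per
#' marker (two decimals). States are partitioned into SNP alleles and
#' supplementary alleles by prefix: states beginning `In`/`Ins`, `Del`,
#' `Het` or `Null` (case-insensitive) are insertions, deletions,
#' probable heterozygotes and nulls respectively; everything else
#' (single bases, or `X`/`Y` placeholders) counts as a SNP allele.
#'
#' @param calls Character matrix (markers x individuals) of
#'   diversity-mode calls.
#' @return List: `per_marker` (data.frame `marker`, `n_alleles`),
#'   `n_markers`, `total_alleles`, `mean_alleles` (2 dp),
#'   `n_snp_alleles`, `n_supplementary`, `n_indel`, `n_het`, `n_null`.
#' @examples
#' allele_summary(synthetic_diversity_panel())
#' @export
allele_summary <- function(calls) {
  stopifnot(is.matrix(calls))
  states <- lapply(seq_len(nrow(calls)), function(i) {
    x <- calls[i, ]
    sort(unique(x[!is.na(x)]))
  })
  n_alleles <- vapply(states, length, 1L)
  all_states <- unlist(states)
  kind <- function(s) {
    if (grepl("^ins?", s, ignore.case = TRUE)) "indel"
    else if (grepl("^del", s, ignore.case = TRUE)) "indel"
    else if (grepl("^het", s, ignore.case = TRUE)) "het"
    else if (grepl("^null", s, ignore.case = TRUE)) "null"
    else "snp"
  }
  kinds <- vapply(all_states, kind, "")
  list(
    per_marker = data.frame(marker = rownames(calls),
                            n_alleles = n_alleles,
                            stringsAsFactors = FALSE),
    n_markers = nrow(calls),
    total_alleles = sum(n_alleles),
    mean_alleles = round(sum(n_alleles) / nrow(calls), 2),
    n_snp_alleles = sum(kinds == "snp"),
    n_supplementary = sum(kinds != "snp"),
    n_indel = sum(kinds == "indel"),
    n_het = sum(kinds == "het"),
    n_null = sum(kinds == "null")
  )
}
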