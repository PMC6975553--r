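#' Filter homology hits by identity and alignment length
#'
#' Keeps hits with percent identity strictly greater than
#' \code{min_identity} and alignment length strictly greater than
#' \code{min_length} (both bounds can be relaxed to >= for sensitivity
#' analysis), then deduplicates to unique (query, subject) pairs keeping the
#' best (smallest) e-value.
#'
#' @param hits data.frame from \code{\link{read_homology_table}}.
#' @param min_identity percent identity lower bound, default 80.
#' @param min_length alignment length lower bound, default 70.
#' @param strict use strict inequalities (default TRUE).
#' @return Filtered, deduplicated data.frame.
#' @export
filter_homology_hits <- function(hits, min_identity = 80, min_length = 70,
                                 strict = TRUE) {
  keep <- if (strict)
    hits$percent_identity > min_identity & hits$alignment_length > min_length
  else
    hits$percent_identity >= min_identity & hits$alignment_length >= min_length
  out <- hits[keep, , drop = FALSE]
  if (nrow(out) == 0L) return(out)
  out <- out[order(out$query_gene, out$subject_gene, out$e_value,
                   -out$bit_score), , drop = FALSE]
  out <- out[!duplicated(out[, c("query_gene", "subject_gene")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map SNP markers to gene intervals
#'
#' Assigns each marker to every gene whose 1-based closed interval contains
#' its position; markers outside any gene are unmapped. A marker inside
#' overlapping genes is assigned to all of them.
#'
#' @param markers data.frame with columns \code{marker_id}, \code{chrom},
#'   \code{pos} (a genotype_matrix's \code{$markers} works directly).
#' @param annotation data.frame from \code{\link{read_gene_annotation}}.
#' @return data.frame with columns \code{gene_id}, \code{marker_id}, one row
#'   per containment.
#' @export
snp_to_gene <- function(markers, annotation) {
  if (inherits(markers, "genotype_matrix")) markers <- markers$markers
  if (nrow(markers) == 0L || nrow(annotation) == 0L)
    return(data.frame(gene_id = character(), marker_id = character()))
  snp <- GenomicRanges::GRanges(markers$chrom,
                                IRanges::IRanges(markers$pos, markers$pos))
  gene <- GenomicRanges::GRanges(annotation$chrom,
                                 IRanges::IRanges(annotation$start,
                                                  annotation$end))
  ov <- GenomicRanges::findOverlaps(snp, gene)
  out <- data.frame(
    gene_id = annotation$gene_id[S4Vectors::subjectHits(ov)],
    marker_id = markers$marker_id[S4Vectors::queryHits(ov)])
  out <- out[order(out$gene_id, out$marker_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the candidate marker set for epistasis analysis
#'
#' Union of the homology-derived markers and the GWAS-significant genic
#' markers, deduplicated by marker id, with per-marker provenance. The
#' inclusion-exclusion identity |union| = |A| + |B| - |A and B| is recorded
#' in the counts.
#'
#' @param homology_markers character vector of marker ids from the
#'   homology-filtered genes.
#' @param significant_markers character vector of GWAS-significant genic
#'   marker ids.
#' @return Object of class \code{"marker_set"}: list with
#'   \code{marker_ids}, \code{provenance} (factor: gwas_significant,
#'   homology_derived, both) and \code{counts} (named integer vector:
#'   n_gwas, n_homology, n_overlap, n_total).
#' @export
build_marker_set <- function(homology_markers, significant_markers) {
  a <- unique(as.character(homology_markers))
  b <- unique(as.character(significant_markers))
  ids <- union(a, b)
  prov <- ifelse(ids %in% a & ids %in% b, "both",
                 ifelse(ids %in% b, "gwas_significant", "homology_derived"))
  counts <- c(n_gwas = length(b), n_homology = length(a),
              n_overlap = length(intersect(a, b)), n_total = length(ids))
  stopifnot(counts[["n_total"]] ==
              counts[["n_gwas"]] + counts[["n_homology"]] -
              counts[["n_overlap"]])
  structure(list(marker_ids = ids,
                 provenance = factor(prov, levels = c("gwas_significant",
                                                      "homology_derived",
                                                      "both")),
                 counts = counts),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("marker_set:", x$counts[["n_total"]], "markers (",
      x$counts[["n_gwas"]], "GWAS-significant +",
      x$counts[["n_homology"]], "homology-derived, overlap",
      x$counts[["n_overlap"]], ")\n")
  invisible(x)
}

#' Marker-set accounting table
#'
#' Produces the gene/marker bookkeeping of the candidate set as a three-row
#' table (gwas, related, total). The related row reports counts net of the
#' overlap with the GWAS row, with the overlap itself in companion columns
#' (the "in parentheses" convention of the study's summary), so the total
#' row satisfies total = gwas + related - overlap in every column.
#'
#' @param gwas list with character-vector elements \code{source_genes},
#'   \code{corresponding_genes}, \code{array_genes}, \code{array_markers}
#'   for the GWAS-significant row.
#' @param related same structure for the trait-related (homology) row,
#'   before any overlap exclusion.
#' @return data.frame with rows gwas, related, total and columns
#'   \code{source_genes}, \code{corresponding_genes}, \code{array_genes},
#'   \code{array_markers}, plus \code{overlap_*} columns on the related row.
#' @export
summarize_counts <- function(gwas, related) {
  cats <- c("source_genes", "corresponding_genes", "array_genes",
            "array_markers")
  stopifnot(all(cats %in% names(gwas)), all(cats %in% names(related)))
  n_gwas <- vapply(gwas[cats], function(v) length(unique(v)), 0L)
  ov <- vapply(cats, function(cl)
    length(intersect(unique(related[[cl]]), unique(gwas[[cl]]))), 0L)
  n_rel_net <- vapply(related[cats], function(v) length(unique(v)), 0L) - ov
  out <- rbind(gwas = n_gwas, related = n_rel_net,
               total = n_gwas + n_rel_net)
  out <- as.data.frame(out)
  for (cl in cats) out[[paste0("overlap_", cl)]] <- c(0L, ov[[cl]], ov[[cl]])
  out
}
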