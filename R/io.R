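#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF 4.x file (plain or gzipped) and returns a
#' \code{\link{genotype_matrix}} of alternate-allele dosages. Only biallelic
#' SNP records are admitted; multiallelic or non-SNP sites are skipped with a
#' message (or rejected when \code{strict = TRUE}), mirroring the biallelic
#' design of SNP arrays.
#'
#' @param path VCF file.
#' @param missing_policy what to do with missing genotype calls:
#'   \code{"error"} (default), \code{"drop_marker"} (remove any marker with a
#'   missing call), or \code{"mode_impute"} (replace by the marker's most
#'   frequent dosage). The original study phased and imputed with external
#'   software; this loader makes the policy explicit instead.
#' @param strict if TRUE, multiallelic or non-SNP records raise an error
#'   instead of being skipped.
#' @return A \code{genotype_matrix}.
#' @export
read_genotypes <- function(path, missing_policy = c("error", "drop_marker",
                                                    "mode_impute"),
                           strict = FALSE) {
  missing_policy <- match.arg(missing_policy)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!snp)) {
    if (strict) stop(sum(!snp), " multiallelic or non-SNP record(s) in ", path)
    message("skipping ", sum(!snp), " multiallelic or non-SNP record(s)")
  }
  if (!any(snp)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  if (anyDuplicated(ids)) stop("duplicate marker ids in ", path)
  # dosage = count of "1" alleles in the GT field; phased or unphased
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dose <- (a1 == "1") + (a2 == "1")
  dose[a1 == "." | a2 == "." | is.na(gt)] <- NA_integer_
  dose <- t(dose)  # samples x markers
  colnames(dose) <- ids
  miss <- is.na(dose)
  if (any(miss)) {
    if (missing_policy == "error")
      stop(sum(miss), " missing genotype call(s); set missing_policy to ",
           "'drop_marker' or 'mode_impute' to proceed")
    if (missing_policy == "drop_marker") {
      keep <- colSums(miss) == 0L
      dose <- dose[, keep, drop = FALSE]
      fix <- fix[keep, , drop = FALSE]
      ids <- ids[keep]
      message("dropped ", sum(!keep), " marker(s) with missing calls")
    } else {
      for (j in which(colSums(miss) > 0L)) {
        tab <- tabulate(dose[, j] + 1L, 3L)
        dose[is.na(dose[, j]), j] <- which.max(tab) - 1L
      }
    }
  }
  markers <- data.frame(marker_id = ids, chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        ref = fix[, "REF"], alt = fix[, "ALT"],
                        row.names = NULL)
  genotype_matrix(dose, markers)
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits a minimal VCF 4.2 file with unphased GT fields, the exact inverse of
#' \code{\link{read_genotypes}} for complete data.
#'
#' @param g genotype_matrix.
#' @param path output file path (plain text).
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g$dosages)),
                     collapse = "\t")), con)
  gtcode <- c("0/0", "0/1", "1/1")
  m <- g$markers
  body <- matrix(gtcode[t(g$dosages) + 1L], nrow = nrow(m))
  lines <- paste(m$chrom, m$pos, m$marker_id, m$ref, m$alt, ".", "PASS", ".",
                 "GT", apply(body, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a quantitative phenotype table
#'
#' Reads a delimited text table of per-sample trait values (e.g. days to
#' flowering) and returns a named numeric vector in file order.
#'
#' @param path delimited text file with a header row.
#' @param id_column,value_column column names holding sample ids and values.
#' @param sep field separator (default tab).
#' @return Named numeric vector of phenotype values (names are sample ids).
#' @export
read_phenotypes <- function(path, id_column = "sample_id",
                            value_column = "value", sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (cl in c(id_column, value_column))
    if (!cl %in% names(tab)) stop("column '", cl, "' not found in ", path)
  ids <- as.character(tab[[id_column]])
  if (anyDuplicated(ids)) stop("duplicated sample id in ", path)
  vals <- tab[[value_column]]
  if (is.character(vals)) {
    suppressWarnings(num <- as.numeric(vals))
    if (anyNA(num) & !anyNA(vals)) stop("non-numeric phenotype value in ", path)
    vals <- num
  }
  if (anyNA(vals)) stop("missing or non-numeric phenotype value in ", path)
  stats::setNames(as.numeric(vals), ids)
}

#' Write a phenotype vector as a TSV table
#'
#' @param y named numeric vector (names are sample ids).
#' @param path output file.
#' @param value_column name for the value column.
#' @return \code{path}, invisibly.
#' @export
write_phenotypes <- function(y, path, value_column = "value") {
  tab <- data.frame(sample_id = names(y), value = unname(y))
  names(tab)[2] <- value_column
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene intervals from BED or GFF3
#'
#' Both formats are normalized to the package's internal convention of
#' 1-based, closed intervals (the convention in which the study reports bp
#' positions). BED input (0-based, half-open) is shifted on read.
#'
#' @param path a \code{.bed}, \code{.gff}, \code{.gff3} or \code{.gtf} file.
#'   Format is taken from the extension unless \code{format} is given.
#' @param format optional: \code{"bed"} or \code{"gff3"}.
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, sorted by (chrom, start).
#' @export
read_gene_annotation <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "bed") "bed" else "gff3"
  }
  format <- match.arg(format, c("bed", "gff3"))
  n_lines <- length(readLines(path, n = 1L))
  if (n_lines == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer()))
  gr <- if (format == "bed") rtracklayer::import(path, format = "BED")
        else rtracklayer::import(path, format = "GFF3")
  if (format == "gff3" && "type" %in% names(S4Vectors::mcols(gr)) &&
      any(S4Vectors::mcols(gr)$type == "gene"))
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(mc) && !all(is.na(mc$ID))) as.character(mc$ID)
         else if ("name" %in% names(mc)) as.character(mc$name)
         else if ("Name" %in% names(mc)) as.character(mc$Name)
         else paste0("gene", seq_along(gr))
  ann <- data.frame(gene_id = ids,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr))
  if (any(ann$start > ann$end)) stop("gene interval with start > end in ", path)
  ann <- ann[order(ann$chrom, ann$start, ann$gene_id), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Read homology hits in BLAST 12-column tabular format
#'
#' Parses BLAST outfmt-6 text (query, subject, percent identity, alignment
#' length, mismatches, gap opens, qstart, qend, sstart, send, e-value,
#' bit score). No filtering is applied at read time; see
#' \code{\link{filter_homology_hits}}.
#'
#' @param path tabular file.
#' @return data.frame with columns \code{query_gene}, \code{subject_gene},
#'   \code{percent_identity}, \code{alignment_length}, \code{e_value},
#'   \code{bit_score}.
#' @export
read_homology_table <- function(path) {
  cols <- c("query_gene", "subject_gene", "percent_identity",
            "alignment_length", "mismatches", "gap_opens", "q_start", "q_end",
            "s_start", "s_end", "e_value", "bit_score")
  empty <- stats::setNames(
    data.frame(character(), character(), numeric(), integer(), numeric(),
               numeric()),
    c(cols[1:4], cols[11:12]))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(empty)
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = cols, comment.char = "#")
  if (!is.numeric(tab$percent_identity) || !is.numeric(tab$alignment_length) ||
      !is.numeric(tab$e_value))
    stop("malformed homology row in ", path)
  if (any(tab$percent_identity < 0 | tab$percent_identity > 100))
    stop("percent identity outside [0, 100] in ", path)
  if (any(tab$alignment_length < 1)) stop("alignment length < 1 in ", path)
  tab$alignment_length <- as.integer(tab$alignment_length)
  tab[, c(cols[1:4], cols[11:12])]
}

#' Write pipeline result tables
#'
#' Writes association results, interaction groups and window statistics as
#' TSV files with a fixed column order, suitable as Manhattan/QQ plot source
#' tables.
#'
#' @param tables named list of data.frames. Names become file names
#'   (\code{<name>.tsv}).
#' @param out_dir output directory, created if absent.
#' @return Character vector of paths written, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
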