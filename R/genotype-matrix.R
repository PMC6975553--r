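#' Construct a genotype matrix
#'
#' The central data container of the package: a samples x markers matrix of
#' alternate-allele dosages (0, 1 or 2 for a diploid) together with marker
#' metadata. Markers are stored sorted by (chromosome, position) so that two
#' loads of the same data are always identical.
#'
#' @param dosages integer matrix, samples in rows, markers in columns, values
#'   in \{0, 1, 2\}. Row names are sample ids, column names marker ids.
#' @param markers data.frame with columns \code{marker_id}, \code{chrom},
#'   \code{pos} (1-based bp), \code{ref}, \code{alt}. One row per column of
#'   \code{dosages}, in the same order.
#' @return An object of class \code{"genotype_matrix"}: a list with elements
#'   \code{dosages} (integer matrix) and \code{markers} (data.frame).
#' @examples
#' g <- genotype_matrix(
#'   matrix(c(0L, 1L, 2L, 0L), 2, 2,
#'          dimnames = list(c("s1", "s2"), c("m1", "m2"))),
#'   data.frame(marker_id = c("m1", "m2"), chrom = "Gm01", pos = c(100L, 200L),
#'              ref = "A", alt = "G"))
#' dim(g$dosages)
#' @export
genotype_matrix <- function(dosages, markers) {
  stopifnot(is.matrix(dosages), is.data.frame(markers))
  required <- c("marker_id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols))
    stop("markers is missing columns: ", paste(missing_cols, collapse = ", "))
  if (ncol(dosages) != nrow(markers))
    stop("ncol(dosages) != nrow(markers)")
  storage.mode(dosages) <- "integer"
  if (anyNA(dosages) || !all(dosages %in% 0:2))
    stop("dosages must be 0, 1 or 2 with no missing values")
  sid <- rownames(dosages)
  if (is.null(sid) || anyDuplicated(sid))
    stop("dosages must have unique sample ids as row names")
  if (anyDuplicated(markers$marker_id))
    stop("duplicate marker ids")
  if (any(markers$pos < 1)) stop("marker positions must be >= 1")
  if (any(markers$ref == markers$alt)) stop("ref and alt allele must differ")
  bad <- !(markers$ref %in% c("A", "C", "G", "T")) |
    !(markers$alt %in% c("A", "C", "G", "T"))
  if (any(bad)) stop("alleles must be one of A, C, G, T")
  ord <- order(markers$chrom, markers$pos, markers$marker_id)
  markers <- markers[ord, , drop = FALSE]
  rownames(markers) <- NULL
  dosages <- dosages[, ord, drop = FALSE]
  colnames(dosages) <- markers$marker_id
  structure(list(dosages = dosages, markers = markers),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "markers on",
      length(unique(x$markers$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by samples and/or markers
#'
#' @param g genotype_matrix.
#' @param samples character or integer index of samples to keep (default all).
#' @param markers character (marker ids) or integer/logical index of markers
#'   to keep (default all).
#' @return A genotype_matrix restricted to the requested samples and markers.
#' @export
subset_genotypes <- function(g, samples = NULL, markers = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  m <- g$markers
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (!is.null(markers)) {
    if (is.character(markers)) markers <- match(markers, m$marker_id)
    d <- d[, markers, drop = FALSE]
    m <- m[markers, , drop = FALSE]
  }
  genotype_matrix(d, m)
}

#' Per-marker alternate-allele and minor-allele frequency
#'
#' @param g genotype_matrix.
#' @return data.frame with columns \code{marker_id}, \code{alt_freq},
#'   \code{maf}.
#' @export
allele_freqs <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  p <- colMeans(g$dosages) / 2
  data.frame(marker_id = g$markers$marker_id, alt_freq = p,
             maf = pmin(p, 1 - p), row.names = NULL)
}
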