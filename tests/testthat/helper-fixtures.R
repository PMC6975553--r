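# small in-code fixture builders shared across test files

# genotype_matrix from a dosage matrix with sensible metadata defaults
make_geno <- function(dosages, chrom = NULL, pos = NULL, ref = "A",
                      alt = "G") {
  m <- ncol(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("s", seq_len(nrow(dosages)))
  if (is.null(chrom)) chrom <- rep("Gm01", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  genotype_matrix(dosages,
                  data.frame(marker_id = paste0("mk", seq_len(m)),
                             chrom = chrom, pos = pos,
                             ref = rep_len(ref, m), alt = rep_len(alt, m)))
}

# minimal VCF text on disk; gts is a character matrix (markers x samples)
write_tiny_vcf <- function(path, gts, chrom = "Gm01",
                           pos = seq_len(nrow(gts)) * 100L,
                           ref = "A", alt = "G",
                           ids = paste0("v", seq_len(nrow(gts)))) {
  samples <- colnames(gts)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(gts)))
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (i in seq_len(nrow(gts)))
    lines <- c(lines, paste(c(rep_len(chrom, nrow(gts))[i], pos[i], ids[i],
                              rep_len(ref, nrow(gts))[i],
                              rep_len(alt, nrow(gts))[i],
                              ".", "PASS", ".", "GT", gts[i, ]),
                            collapse = "\t"))
  writeLines(lines, path)
  path
}

# distances between leaves of a phylo tree (patristic), as a plain matrix
tree_distances <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}
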