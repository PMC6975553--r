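#' Specification for the synthetic genotype/phenotype generator
#'
#' Describes a two-subgroup cultivated-soybean-like panel: two admixed
#' subgroups with small divergence (default Fst 0.0581, the improved-cultivar
#' vs landrace split), near-complete selfing (default inbreeding F 0.971),
#' local linkage disequilibrium decaying exponentially with physical
#' distance, and a days-to-flowering phenotype built from subgroup means
#' (defaults 42.16 and 45.86 days), additive QTL and planted multilocus
#' interaction effects.
#'
#' @param n_per_group integer vector of subgroup sizes, named
#'   \code{c(ic = ..., lr = ...)}.
#' @param n_markers total number of biallelic SNP markers.
#' @param n_chromosomes number of chromosomes markers are spread over.
#' @param chromosome_length chromosome length in bp.
#' @param target_fst Balding-Nichols divergence between the two subgroups.
#' @param target_inbreeding_f probability that a genotype call is a selfed
#'   (homozygous) draw rather than a Hardy-Weinberg draw.
#' @param ld_decay_scale bp scale of the exponential decay of adjacent-marker
#'   latent correlation.
#' @param maf_floor lower truncation of the ancestral allele-frequency
#'   spectrum.
#' @param phenotype_means subgroup phenotype means in days, named as
#'   \code{n_per_group}.
#' @param residual_sd residual standard deviation in days. The source study
#'   reports no DTF variance; 5 days is a fixture choice.
#' @param additive_qtl data.frame with columns \code{marker} (column index
#'   into the simulated genotype matrix) and \code{effect} (days per copy of
#'   the alternate allele), or NULL.
#' @param interaction_groups list of planted interactions, each a list with
#'   \code{markers} (integer vector of k column indices) and \code{effects}
#'   (numeric array with dim rep(3, k), days added for each joint genotype
#'   cell, indexed by dosage + 1), or NULL. See
#'   \code{\link{xor_cell_effects}}.
#' @param seed integer random seed.
#' @return A list of class \code{"simulation_spec"}.
#' @export
simulation_spec <- function(n_per_group = c(ic = 200L, lr = 200L),
                            n_markers = 2000L, n_chromosomes = 2L,
                            chromosome_length = 10000000L,
                            target_fst = 0.0581,
                            target_inbreeding_f = 0.971,
                            ld_decay_scale = 100000,
                            maf_floor = 0.05,
                            phenotype_means = c(ic = 42.16, lr = 45.86),
                            residual_sd = 5,
                            additive_qtl = NULL,
                            interaction_groups = NULL,
                            seed = 1L) {
  if (length(n_per_group) != 2L) stop("exactly two subgroups are simulated")
  if (is.null(names(n_per_group))) names(n_per_group) <- c("ic", "lr")
  if (is.null(names(phenotype_means)))
    names(phenotype_means) <- names(n_per_group)
  if (target_fst < 0 || target_fst >= 1) stop("target_fst must be in [0, 1)")
  if (target_inbreeding_f < 0 || target_inbreeding_f > 1)
    stop("target_inbreeding_f must be in [0, 1]")
  if (n_markers < 2L) stop("need at least 2 markers")
  if (maf_floor <= 0 || maf_floor >= 0.5) stop("maf_floor must be in (0, 0.5)")
  spec <- list(n_per_group = as.integer(n_per_group),
               n_markers = as.integer(n_markers),
               n_chromosomes = as.integer(n_chromosomes),
               chromosome_length = as.integer(chromosome_length),
               target_fst = target_fst,
               target_inbreeding_f = target_inbreeding_f,
               ld_decay_scale = ld_decay_scale, maf_floor = maf_floor,
               phenotype_means = phenotype_means, residual_sd = residual_sd,
               additive_qtl = additive_qtl,
               interaction_groups = interaction_groups,
               seed = as.integer(seed))
  names(spec$n_per_group) <- names(n_per_group)
  bad_idx <- function(i) any(i < 1L | i > spec$n_markers)
  if (!is.null(additive_qtl) && bad_idx(additive_qtl$marker))
    stop("additive_qtl marker index out of range")
  for (ig in spec$interaction_groups) {
    if (bad_idx(ig$markers)) stop("interaction marker index out of range")
    if (!all(dim(ig$effects) == 3L) ||
        length(dim(ig$effects)) != length(ig$markers))
      stop("interaction effects must be a 3^k array matching the marker count")
    if (any(!is.finite(ig$effects))) stop("interaction effects must be finite")
  }
  structure(spec, class = "simulation_spec")
}

#' XOR-like interaction effect table for a marker pair
#'
#' Builds the default planted two-locus epistatic pattern: \code{effect} days
#' are added when exactly one of the two markers carries the alternate allele
#' (dosage >= 1). Under balanced carrier frequencies this pattern has no
#' marginal additive component, so it is detectable only through the joint
#' genotype.
#'
#' @param effect cell effect in days.
#' @return 3 x 3 numeric matrix indexed by dosage + 1.
#' @export
xor_cell_effects <- function(effect) {
  carrier <- c(0, 1, 1)
  outer(carrier, carrier, function(a, b) effect * as.numeric(xor(a, b)))
}

# Latent Gaussian chains with exp(-distance/scale) AR(1) correlation along a
# chromosome; one row per haplotype.
.latent_chains <- function(n_hap, positions, scale) {
  m <- length(positions)
  z <- matrix(0, n_hap, m)
  z[, 1] <- stats::rnorm(n_hap)
  if (m > 1L) {
    rho <- exp(-diff(positions) / scale)
    for (j in 2:m)
      z[, j] <- rho[j - 1L] * z[, j - 1L] +
        sqrt(1 - rho[j - 1L]^2) * stats::rnorm(n_hap)
  }
  z
}

#' Simulate structured, inbred genotypes
#'
#' Draws ancestral allele frequencies from a truncated uniform spectrum,
#' derives subgroup frequencies from the Balding-Nichols beta distribution at
#' \code{target_fst}, and samples diploid genotypes with excess homozygosity:
#' with probability \code{target_inbreeding_f} a call is a selfed draw
#' (homozygous for a single sampled allele), otherwise two haplotype draws.
#' Haplotype draws come from per-individual latent Gaussian chains whose
#' correlation decays as \code{exp(-d / ld_decay_scale)}, giving local LD
#' that decays with distance.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return List with \code{genotypes} (a \code{\link{genotype_matrix}}),
#'   \code{groups} (factor of true subgroup labels per sample) and
#'   \code{group_freqs} (markers x 2 matrix of subgroup alternate-allele
#'   frequencies).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  m <- spec$n_markers
  per_chrom <- diff(round(seq(0, m, length.out = spec$n_chromosomes + 1L)))
  chrom <- rep(sprintf("Gm%02d", seq_len(spec$n_chromosomes)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k) {
    sort(sample.int(spec$chromosome_length, k))
  }), use.names = FALSE)
  p_anc <- stats::runif(m, spec$maf_floor, 1 - spec$maf_floor)
  fst <- spec$target_fst
  if (fst > 0) {
    shape_scale <- (1 - fst) / fst
    p_grp <- cbind(stats::rbeta(m, p_anc * shape_scale,
                                (1 - p_anc) * shape_scale),
                   stats::rbeta(m, p_anc * shape_scale,
                                (1 - p_anc) * shape_scale))
    # keep every marker's subgroup frequency inside the admitted spectrum
    p_grp <- pmin(pmax(p_grp, spec$maf_floor), 1 - spec$maf_floor)
  } else {
    p_grp <- cbind(p_anc, p_anc)
  }
  n <- sum(spec$n_per_group)
  grp <- rep(1:2, spec$n_per_group)
  dose <- matrix(0L, n, m)
  chrom_idx <- split(seq_len(m), chrom)
  for (ci in chrom_idx) {
    z1 <- .latent_chains(n, pos[ci], spec$ld_decay_scale)
    z2 <- .latent_chains(n, pos[ci], spec$ld_decay_scale)
    thr <- stats::qnorm(p_grp[ci, , drop = FALSE])  # markers x groups
    tmat <- t(thr[, grp, drop = FALSE])             # samples x markers
    a1 <- z1 < tmat
    a2 <- z2 < tmat
    selfed <- matrix(stats::runif(n * length(ci)) <
                       spec$target_inbreeding_f, n, length(ci))
    dose[, ci] <- ifelse(selfed, 2L * a1, a1 + a2)
  }
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), "")
  markers <- data.frame(marker_id = sprintf("AX%06d", seq_len(m)),
                        chrom = chrom, pos = pos, ref = ref, alt = unname(alt))
  sample_ids <- paste0(rep(toupper(names(spec$n_per_group)), spec$n_per_group),
                       unlist(lapply(spec$n_per_group, seq_len)))
  rownames(dose) <- sample_ids
  colnames(dose) <- markers$marker_id
  groups <- factor(rep(names(spec$n_per_group), spec$n_per_group),
                   levels = names(spec$n_per_group))
  names(groups) <- sample_ids
  colnames(p_grp) <- names(spec$n_per_group)
  list(genotypes = genotype_matrix(dose, markers), groups = groups,
       group_freqs = p_grp)
}

#' Simulate the quantitative phenotype over simulated genotypes
#'
#' Phenotype = subgroup mean + sum of additive QTL effects x dosage + sum of
#' planted interaction cell effects + Gaussian residual. The returned truth
#' record lists every planted locus and cell effect so recovery tests can
#' check detections against it.
#'
#' @param g a \code{\link{genotype_matrix}} from
#'   \code{\link{simulate_genotypes}}.
#' @param spec the \code{\link{simulation_spec}} used to generate \code{g}.
#' @param groups factor of subgroup labels per sample.
#' @return List with \code{phenotype} (named numeric vector, days) and
#'   \code{truth} (list: subgroup means, additive QTL, interaction groups
#'   with marker ids).
#' @export
simulate_phenotype <- function(g, spec, groups) {
  stopifnot(inherits(spec, "simulation_spec"),
            inherits(g, "genotype_matrix"))
  set.seed(spec$seed + 104729L)  # distinct stream from the genotype draw
  n <- nrow(g$dosages)
  y <- unname(spec$phenotype_means[as.character(groups)])
  truth <- list(group_means = spec$phenotype_means,
                residual_sd = spec$residual_sd,
                additive_qtl = NULL, interactions = list())
  if (!is.null(spec$additive_qtl)) {
    for (r in seq_len(nrow(spec$additive_qtl))) {
      j <- spec$additive_qtl$marker[r]
      y <- y + spec$additive_qtl$effect[r] * g$dosages[, j]
    }
    truth$additive_qtl <- data.frame(
      marker_id = g$markers$marker_id[spec$additive_qtl$marker],
      spec$additive_qtl)
  }
  for (ig in spec$interaction_groups) {
    cell <- g$dosages[, ig$markers, drop = FALSE] + 1L
    y <- y + ig$effects[cell]
    truth$interactions <- c(truth$interactions, list(list(
      marker_ids = g$markers$marker_id[ig$markers],
      markers = ig$markers, effects = ig$effects)))
  }
  if (spec$residual_sd > 0) y <- y + stats::rnorm(n, 0, spec$residual_sd)
  names(y) <- rownames(g$dosages)
  list(phenotype = y, truth = truth)
}

#' Write a complete synthetic fixture bundle
#'
#' Generates genotypes and phenotype from \code{spec} and writes everything a
#' pipeline run consumes: a plain-text VCF, a phenotype TSV, a BED file of
#' genes tiled across the chromosomes, a synthetic BLAST-style homology table
#' naming a subset of those genes as trait-related, the subgroup labels, and
#' a JSON truth record of every planted effect. Runs with the same spec are
#' byte-identical.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param out_dir output directory (created if needed).
#' @param gene_tile_bp width of the tiled gene intervals in bp.
#' @param related_gene_fraction fraction of tiled genes listed in the
#'   synthetic homology table as trait-related.
#' @return Named character vector of paths written, invisibly.
#' @export
make_fixture_bundle <- function(spec, out_dir, gene_tile_bp = 10000L,
                                related_gene_fraction = 0.25) {
  sim <- simulate_genotypes(spec)
  phe <- simulate_phenotype(sim$genotypes, spec, sim$groups)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             phenotype = file.path(out_dir, "phenotype.tsv"),
             genes = file.path(out_dir, "genes.bed"),
             homology = file.path(out_dir, "homology.tsv"),
             groups = file.path(out_dir, "groups.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_genotypes(sim$genotypes, paths[["vcf"]])
  write_phenotypes(phe$phenotype, paths[["phenotype"]], "days_to_flowering")
  chroms <- unique(sim$genotypes$markers$chrom)
  n_tiles <- ceiling(spec$chromosome_length / gene_tile_bp)
  bed <- do.call(rbind, lapply(chroms, function(ch) {
    data.frame(chrom = ch,
               start0 = (seq_len(n_tiles) - 1L) * gene_tile_bp,
               end = pmin(seq_len(n_tiles) * gene_tile_bp,
                          spec$chromosome_length),
               name = sprintf("%s.G%05d", ch, seq_len(n_tiles)))
  }))
  utils::write.table(bed, paths[["genes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  set.seed(spec$seed + 224737L)
  n_rel <- max(1L, round(related_gene_fraction * nrow(bed)))
  related <- sort(sample.int(nrow(bed), n_rel))
  hits <- data.frame(
    query = sprintf("AT1G%05d", seq_len(n_rel) * 10L),
    subject = bed$name[related],
    identity = round(stats::runif(n_rel, 81, 99), 2),
    length = sample(71:500, n_rel, replace = TRUE),
    mismatches = 0L, gap_opens = 0L, q_start = 1L, q_end = 100L,
    s_start = 1L, s_end = 100L,
    e_value = signif(10^stats::runif(n_rel, -50, -5), 3), bit_score = 200)
  # a few sub-threshold rows so filtering is exercised
  n_bad <- max(1L, round(n_rel * 0.1))
  bad <- hits[seq_len(n_bad), , drop = FALSE]
  bad$identity <- round(stats::runif(n_bad, 40, 80), 2)
  bad$length <- sample(20:70, n_bad, replace = TRUE)
  hits <- rbind(hits, bad)
  utils::write.table(hits, paths[["homology"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(sim$groups), group = as.character(sim$groups)),
    paths[["groups"]], sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- phe$truth
  truth$group_means <- as.list(truth$group_means)
  truth$interactions <- lapply(truth$interactions, function(ig) {
    ig$effects <- as.vector(ig$effects)
    ig
  })
  truth$related_genes <- bed$name[related]
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
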