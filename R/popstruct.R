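#' Identity-by-state similarity and distance
#'
#' IBS between two diploid samples is the mean, over markers, of the shared
#' allele fraction \code{(2 - |g_i - g_j|) / 2}. The companion distance is
#' \code{1 - IBS}.
#'
#' @param g genotype_matrix with at least 2 samples.
#' @return List with \code{similarity} and \code{distance}, both symmetric
#'   matrices with sample ids as dimnames.
#' @export
ibs_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (nrow(g$dosages) < 2L) stop("need at least 2 samples")
  if (ncol(g$dosages) == 0L) stop("no markers")
  manh <- as.matrix(stats::dist(g$dosages, method = "manhattan"))
  ibs <- 1 - manh / (2 * ncol(g$dosages))
  list(similarity = ibs, distance = 1 - ibs)
}

#' Kimura two-parameter distance between samples
#'
#' Pairs of samples are compared only at sites where both are homozygous,
#' each homozygote read as a haploid base call (heterozygotes are coded as
#' missing and excluded pairwise); in a panel that is ~97\% homozygous this
#' discards little data and avoids assigning a transition/transversion class
#' to ambiguous heterozygote differences. From the transition difference
#' fraction P and transversion fraction Q over the compared sites,
#' \code{d = -log((1 - 2P - Q) * sqrt(1 - 2Q)) / 2}. Saturated pairs (log
#' argument <= 0, or no comparable sites) are set to \code{cap} and flagged.
#'
#' @param g genotype_matrix.
#' @param cap distance assigned to saturated pairs.
#' @return Distance matrix with attribute \code{"saturated"}: a logical
#'   matrix marking capped pairs.
#' @export
k2p_distance <- function(g, cap = 5) {
  stopifnot(inherits(g, "genotype_matrix"))
  m <- g$markers
  base <- matrix("n", nrow(g$dosages), ncol(g$dosages),
                 dimnames = dimnames(g$dosages))
  refm <- matrix(tolower(m$ref), nrow(base), ncol(base), byrow = TRUE)
  altm <- matrix(tolower(m$alt), nrow(base), ncol(base), byrow = TRUE)
  base[g$dosages == 0L] <- refm[g$dosages == 0L]
  base[g$dosages == 2L] <- altm[g$dosages == 2L]
  dna <- ape::as.DNAbin(base)
  d <- suppressWarnings(
    ape::dist.dna(dna, model = "K80", pairwise.deletion = TRUE,
                  as.matrix = TRUE))
  sat <- !is.finite(d)
  d[sat] <- cap
  diag(d) <- 0
  diag(sat) <- FALSE
  attr(d, "saturated") <- sat
  d
}

#' Principal coordinates from a distance matrix
#'
#' Classical multidimensional scaling: the squared distances are
#' double-centered and spectrally decomposed; coordinates are eigenvectors
#' scaled by the square root of their (non-negative) eigenvalues, ordered by
#' eigenvalue. Explained proportions are relative to the sum of positive
#' eigenvalues.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param n_components number of coordinate axes requested. If it exceeds
#'   the number of positive eigenvalues the result is truncated with a
#'   warning.
#' @return List with \code{coordinates} (samples x components),
#'   \code{explained} (proportion per returned component) and
#'   \code{eigenvalues} (all of them, sorted decreasing).
#' @export
pca_from_distance <- function(d, n_components = 3L) {
  d <- as.matrix(d)
  stopifnot(isSymmetric(unname(d)), all(abs(diag(d)) < 1e-12))
  fit <- stats::cmdscale(d, k = min(n_components, nrow(d) - 1L), eig = TRUE)
  pos <- sum(fit$eig > 1e-9 * max(abs(fit$eig)))
  if (n_components > pos) {
    warning("only ", pos, " positive eigenvalue(s); truncating coordinates")
  }
  k <- min(n_components, pos)
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PC", seq_len(k))
  eig_pos <- pmax(fit$eig, 0)
  list(coordinates = coords,
       explained = eig_pos[seq_len(k)] / sum(eig_pos),
       eigenvalues = sort(fit$eig, decreasing = TRUE))
}

#' BIONJ phylogeny from a distance matrix
#'
#' Builds an unrooted tree with the variance-weighted BIONJ agglomeration.
#' Distance-estimation noise can produce negative branch lengths; by default
#' each negative branch is clamped to zero and its deficit transferred to the
#' adjacent (parental) branch so root-to-tip path lengths are approximately
#' preserved.
#'
#' @param d symmetric distance matrix over >= 3 taxa.
#' @param clamp_negative clamp negative branch lengths (default TRUE).
#' @return List with \code{newick} (tree text) and \code{tree} (an
#'   \code{ape::phylo} object).
#' @export
bionj_tree <- function(d, clamp_negative = TRUE) {
  d <- as.matrix(d)
  if (any(!is.finite(d))) stop("non-finite distances")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (n == 3L) {
    # exact three-point formulas
    len <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
             (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
             (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    tree <- list(edge = matrix(c(4L, 4L, 4L, 1L, 2L, 3L), 3, 2),
                 edge.length = len, tip.label = rownames(d), Nnode = 1L)
    class(tree) <- "phylo"
  } else {
    tree <- ape::bionj(d)
  }
  if (clamp_negative && any(tree$edge.length < 0)) {
    neg <- which(tree$edge.length < 0)
    for (e in neg) {
      deficit <- tree$edge.length[e]
      tree$edge.length[e] <- 0
      parent_edge <- which(tree$edge[, 2] == tree$edge[e, 1])
      if (length(parent_edge) == 1L)
        tree$edge.length[parent_edge] <-
          tree$edge.length[parent_edge] + deficit
    }
    tree$edge.length <- pmax(tree$edge.length, 0)
  }
  list(newick = ape::write.tree(tree), tree = tree)
}

#' Linkage-disequilibrium decay with distance
#'
#' For every intra-chromosomal marker pair separated by at most
#' \code{max_distance} bp, r-squared is the squared Pearson correlation of
#' the two dosage columns (a genotype-based composite measure; phase is not
#' required). Pairs are binned by distance; the curve reports the mean per
#' bin, and the summary means within 100 kb and within 500 kb are returned.
#'
#' @param g genotype_matrix (markers are stored position-sorted).
#' @param max_distance maximum pair separation in bp.
#' @param bin_width distance bin width in bp.
#' @return List of class \code{"ld_decay"}: \code{curve} (data.frame:
#'   \code{bin_lo}, \code{bin_hi} half-open, \code{mean_r2},
#'   \code{n_pairs}), \code{mean_r2_100kb}, \code{mean_r2_500kb},
#'   \code{n_monomorphic_skipped}.
#' @export
ld_decay <- function(g, max_distance = 500000L, bin_width = 10000L) {
  stopifnot(inherits(g, "genotype_matrix"))
  x <- g$dosages
  sds <- apply(x, 2, stats::sd)
  mono <- sds == 0
  xs <- scale(x[, , drop = FALSE])
  n <- nrow(x)
  pos <- g$markers$pos
  chrom <- g$markers$chrom
  dist_acc <- list()
  r2_acc <- list()
  skipped <- 0L
  for (ci in split(seq_along(pos), chrom)) {
    for (i in ci) {
      js <- ci[ci > i]
      js <- js[pos[js] - pos[i] <= max_distance]
      if (!length(js)) next
      poly <- !mono[js] & !mono[i]
      skipped <- skipped + sum(!poly)
      js <- js[poly]
      if (!length(js)) next
      r <- crossprod(xs[, i], xs[, js, drop = FALSE]) / (n - 1)
      dist_acc[[length(dist_acc) + 1L]] <- pos[js] - pos[i]
      r2_acc[[length(r2_acc) + 1L]] <- as.vector(r)^2
    }
  }
  dists <- unlist(dist_acc, use.names = FALSE)
  r2s <- unlist(r2_acc, use.names = FALSE)
  breaks <- seq(0, max_distance, by = bin_width)
  if (breaks[length(breaks)] < max_distance) breaks <- c(breaks, max_distance)
  bin <- findInterval(dists, breaks, left.open = TRUE, rightmost.closed = FALSE)
  curve <- data.frame(bin_lo = breaks[-length(breaks)],
                      bin_hi = breaks[-1],
                      mean_r2 = as.numeric(tapply(r2s, factor(bin,
                        levels = seq_len(length(breaks) - 1L)), mean)),
                      n_pairs = as.integer(table(factor(bin,
                        levels = seq_len(length(breaks) - 1L)))))
  structure(list(curve = curve,
                 mean_r2_100kb = mean(r2s[dists <= 100000]),
                 mean_r2_500kb = mean(r2s[dists <= 500000]),
                 n_monomorphic_skipped = skipped),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat("LD decay:", sum(x$curve$n_pairs), "pairs;",
      "mean r2 <=100kb:", signif(x$mean_r2_100kb, 4),
      "| <=500kb:", signif(x$mean_r2_500kb, 4), "\n")
  invisible(x)
}

# window starts over [1, chrom_len]: 1, 1+step, ... ; trailing windows that
# extend past the chromosome end are truncated and flagged
.windows <- function(chrom_len, window_size, window_step) {
  starts <- seq(1L, max(1L, chrom_len), by = window_step)
  starts <- starts[starts <= chrom_len]
  ends <- pmin(starts + window_size - 1L, chrom_len)
  data.frame(start = starts, end = ends,
             truncated = starts + window_size - 1L > chrom_len)
}

# sum of per-site values within each window via cumulative sums
.window_sums <- function(pos, val, wins) {
  ord <- order(pos)
  pos <- pos[ord]
  cs <- c(0, cumsum(val[ord]))
  cnt <- seq_along(pos)
  hi <- findInterval(wins$end, pos)
  lo <- findInterval(wins$start - 1L, pos)
  list(sum = cs[hi + 1L] - cs[lo + 1L], n = hi - lo)
}

#' Windowed nucleotide diversity
#'
#' Per-site diversity is the probability that two chromosomes drawn without
#' replacement carry different alleles: \code{c_ref * c_alt / choose(2n, 2)}
#' over the \code{2n} genotyped chromosomes. A window's value is the sum of
#' per-site diversity divided by the window length in bp, over windows of
#' \code{window_size} advancing by \code{window_step} from position 1.
#'
#' @param g genotype_matrix.
#' @param window_size,window_step window and slide size in bp.
#' @param chrom_lengths optional named vector of chromosome lengths; defaults
#'   to the last marker position per chromosome.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{value} (diversity per bp), \code{n_sites}, \code{truncated}.
#' @export
pi_windows <- function(g, window_size = 100000L, window_step = 10000L,
                       chrom_lengths = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  n2 <- 2L * nrow(g$dosages)
  c_alt <- colSums(g$dosages)
  pi_site <- c_alt * (n2 - c_alt) / choose(n2, 2)
  out <- lapply(split(seq_len(ncol(g$dosages)), g$markers$chrom),
                function(ci) {
    ch <- g$markers$chrom[ci[1]]
    clen <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]]
            else max(g$markers$pos[ci])
    wins <- .windows(clen, window_size, window_step)
    ws <- .window_sums(g$markers$pos[ci], pi_site[ci], wins)
    data.frame(chrom = ch, start = wins$start, end = wins$end,
               value = ws$sum / (wins$end - wins$start + 1L),
               n_sites = ws$n, truncated = wins$truncated)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Method-of-moments inbreeding coefficient per sample
#'
#' Compares each sample's observed homozygosity with the Hardy-Weinberg
#' expectation at the panel's allele frequencies:
#' \code{F = (O_hom - E_hom) / (L - E_hom)} over the L polymorphic sites,
#' with the per-site expected homozygosity
#' \code{1 - 2 p (1 - p) * 2n / (2n - 1)} (small-sample corrected).
#'
#' @param g genotype_matrix with >= 2 samples.
#' @return Named numeric vector of F per sample (NA where degenerate).
#' @export
inbreeding_f <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$dosages)
  if (n < 2L) stop("need at least 2 samples to estimate allele frequencies")
  p <- colMeans(g$dosages) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic sites")
  e_hom <- 1 - 2 * p[poly] * (1 - p[poly]) * (2 * n) / (2 * n - 1)
  e_sum <- sum(e_hom)
  l <- sum(poly)
  o_hom <- rowSums(g$dosages[, poly, drop = FALSE] != 1L)
  denom <- l - e_sum
  f <- if (abs(denom) < 1e-12) rep(NA_real_, n) else (o_hom - e_sum) / denom
  stats::setNames(f, rownames(g$dosages))
}

# Weir & Cockerham (1984) per-site variance components for two groups.
# Returns a data.frame of a, b, c per polymorphic site.
.wc_components <- function(g, groups) {
  gl <- split(seq_len(nrow(g$dosages)), groups)
  if (length(gl) != 2L) stop("exactly 2 groups required")
  if (any(lengths(gl) < 2L)) stop("each group needs >= 2 samples")
  r <- 2
  n_i <- lengths(gl)
  d <- g$dosages
  p_i <- rbind(colMeans(d[gl[[1]], , drop = FALSE]) / 2,
               colMeans(d[gl[[2]], , drop = FALSE]) / 2)
  h_i <- rbind(colMeans(d[gl[[1]], , drop = FALSE] == 1L),
               colMeans(d[gl[[2]], , drop = FALSE] == 1L))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n_i * p_i) / (r * nbar)
  s2 <- colSums(n_i * (sweep(p_i, 2, pbar))^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  poly <- pbar > 0 & pbar < 1
  data.frame(site = seq_len(ncol(d)), a = a, b = b, c = cc,
             polymorphic = poly)
}

#' Windowed and genome-wide Weir-Cockerham Fst between two groups
#'
#' Per-site variance components a (between groups), b (between individuals
#' within groups) and c (within individuals) follow Weir & Cockerham (1984);
#' a window's (and the genome's) Fst is the ratio of summed components
#' \code{sum(a) / sum(a + b + c)}, not the mean of per-site ratios. Sites
#' monomorphic over both groups are skipped.
#'
#' @param g genotype_matrix.
#' @param groups factor with two levels over the samples of \code{g}.
#' @param window_size,window_step window and slide size in bp.
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return List with \code{fst} (genome-wide weighted estimate),
#'   \code{windows} (data.frame like \code{\link{pi_windows}}) and
#'   \code{n_sites_used}.
#' @export
fst_windows <- function(g, groups, window_size = 100000L,
                        window_step = 10000L, chrom_lengths = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  groups <- factor(groups)
  comp <- .wc_components(g, groups)
  use <- comp$polymorphic
  fst <- sum(comp$a[use]) / sum((comp$a + comp$b + comp$c)[use])
  out <- lapply(split(which(use), g$markers$chrom[use]), function(ci) {
    if (!length(ci)) return(NULL)
    ch <- g$markers$chrom[ci[1]]
    clen <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]]
            else max(g$markers$pos[g$markers$chrom == ch])
    wins <- .windows(clen, window_size, window_step)
    wa <- .window_sums(g$markers$pos[ci], comp$a[ci], wins)
    wt <- .window_sums(g$markers$pos[ci],
                       (comp$a + comp$b + comp$c)[ci], wins)
    data.frame(chrom = ch, start = wins$start, end = wins$end,
               value = ifelse(wt$sum > 0, wa$sum / wt$sum, NA_real_),
               n_sites = wa$n, truncated = wins$truncated)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  list(fst = fst, windows = out, n_sites_used = sum(use))
}
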