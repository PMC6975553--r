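#' Filter markers by minor allele frequency
#'
#' Keeps markers whose minor allele frequency is strictly greater than the
#' threshold, the criterion used to reduce an array to common markers before
#' association testing.
#'
#' @param g genotype_matrix.
#' @param threshold MAF threshold (strict >), default 0.05.
#' @return List with \code{genotypes} (filtered genotype_matrix) and
#'   \code{removed} (data.frame of removed marker ids with their MAF).
#' @export
maf_filter <- function(g, threshold = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  af <- allele_freqs(g)
  keep <- af$maf > threshold
  removed <- data.frame(marker_id = af$marker_id[!keep],
                        maf = af$maf[!keep], row.names = NULL)
  if (!any(keep)) stop("no markers pass the MAF filter")
  list(genotypes = subset_genotypes(g, markers = which(keep)),
       removed = removed)
}

#' VanRaden kinship matrix
#'
#' Centered dosage cross-product scaled by \code{2 * sum(p * (1 - p))} over
#' the marker allele frequencies p: the standard genomic relationship matrix
#' used as the random-effect covariance of the mixed model.
#'
#' @param g genotype_matrix with at least one polymorphic marker.
#' @return Symmetric positive semi-definite matrix with sample ids as
#'   dimnames.
#' @export
kinship_vanraden <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  p <- colMeans(g$dosages) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers are monomorphic")
  z <- sweep(g$dosages[, poly, drop = FALSE], 2, 2 * p[poly])
  k <- tcrossprod(z) / (2 * sum(p[poly] * (1 - p[poly])))
  dimnames(k) <- list(rownames(g$dosages), rownames(g$dosages))
  k
}

# average-linkage compression of a kinship matrix into n_groups clusters;
# returns the n x n matrix whose (i, j) entry is the mean kinship between
# the clusters of i and j. n_groups = n reproduces K exactly.
.compress_kinship <- function(k, n_groups) {
  n <- nrow(k)
  if (n_groups >= n) return(k)
  d <- stats::as.dist(max(k) - k)
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = n_groups)
  idx <- split(seq_len(n), cl)
  kc <- k
  for (a in seq_along(idx)) for (b in seq_len(a)) {
    v <- mean(k[idx[[a]], idx[[b]], drop = FALSE])
    kc[idx[[a]], idx[[b]]] <- v
    kc[idx[[b]], idx[[a]]] <- v
  }
  kc
}

# restricted log-likelihood of the null model in the eigenspace of K,
# as a function of lambda = sigma_g^2 / sigma_e^2
.reml_ll <- function(log_lambda, yr, xr, dvals) {
  lambda <- exp(log_lambda)
  v <- lambda * dvals + 1
  w <- 1 / v
  a <- crossprod(xr, w * xr)
  b <- crossprod(xr, w * yr)
  beta <- solve(a, b)
  res <- yr - xr %*% beta
  rss <- sum(w * res^2)
  n <- length(yr)
  p <- ncol(xr)
  -0.5 * ((n - p) * log(rss) + sum(log(v)) + determinant(a)$modulus[1])
}

#' Compressed mixed-linear-model association scan
#'
#' Fits \code{y = marker * beta + PC covariates + u + e} with polygenic
#' effect \code{u ~ N(0, sigma_g^2 K)}. Variance components are estimated
#' once, under the null model, by REML on the spectral decomposition of K
#' (the P3D shortcut), then every marker is tested by generalized least
#' squares with a two-sided t-test on its coefficient. Optional compression
#' replaces K by the group-averaged kinship over clusters obtained by
#' average-linkage clustering; \code{compression_groups} equal to the sample
#' count (the default) reproduces the uncompressed model exactly.
#'
#' @param g genotype_matrix (typically MAF-filtered).
#' @param y named phenotype vector covering the samples of \code{g}.
#' @param k kinship matrix (default \code{\link{kinship_vanraden}} of
#'   \code{g}).
#' @param n_pcs number of genotype principal components used as fixed
#'   covariates (default 3).
#' @param compression_groups number of kinship compression groups (default:
#'   no compression).
#' @param lambda if supplied, fixes \code{sigma_g^2 / sigma_e^2} instead of
#'   estimating it (0 reduces the scan to ordinary least squares when K has
#'   no effect); default NULL (REML estimate).
#' @param significance_neglogp significance cut-off on the -log10 p scale
#'   (strict >), default 7.
#' @return Object of class \code{"cmlm_gwas"}: list with \code{results}
#'   (data.frame: marker_id, chrom, pos, maf, effect, se, p_value,
#'   neglog10_p, significant), \code{lambda}, \code{sigma_g2},
#'   \code{sigma_e2}, \code{n_samples}, \code{n_markers},
#'   \code{significance_neglogp}.
#' @export
cmlm_gwas <- function(g, y, k = NULL, n_pcs = 3L, compression_groups = NULL,
                      lambda = NULL, significance_neglogp = 7.0) {
  stopifnot(inherits(g, "genotype_matrix"))
  ids <- rownames(g$dosages)
  if (is.null(names(y)) || !all(ids %in% names(y)))
    stop("phenotype vector must be named and cover all genotyped samples")
  y <- y[ids]
  n <- length(y)
  if (is.null(k)) k <- kinship_vanraden(g)
  k <- k[ids, ids]
  if (!is.null(compression_groups))
    k <- .compress_kinship(k, compression_groups)
  ev <- eigen(k, symmetric = TRUE)
  if (min(ev$values) < -1e-6 * max(abs(ev$values)))
    stop("kinship matrix is not positive semi-definite")
  dvals <- pmax(ev$values, 0)
  u <- ev$vectors
  x0 <- matrix(1, n, 1)
  if (n_pcs > 0L) {
    z <- scale(g$dosages, scale = FALSE)
    pcs <- stats::prcomp(z, center = FALSE)$x[, seq_len(n_pcs), drop = FALSE]
    x0 <- cbind(x0, pcs)
  }
  yr <- crossprod(u, y)
  x0r <- crossprod(u, x0)
  if (is.null(lambda)) {
    opt <- stats::optimize(.reml_ll, interval = c(-12, 12), yr = yr, xr = x0r,
                           dvals = dvals, maximum = TRUE)
    lambda <- exp(opt$maximum)
    if (lambda < 1e-8) lambda <- 0
  }
  w <- 1 / (lambda * dvals + 1)
  p0 <- ncol(x0)
  res0 <- {
    a <- crossprod(x0r, w * x0r)
    beta <- solve(a, crossprod(x0r, w * yr))
    yr - x0r %*% beta
  }
  sigma_e2 <- sum(w * res0^2) / (n - p0)
  gr <- crossprod(u, g$dosages)  # rotated marker columns
  m <- ncol(gr)
  eff <- se <- pv <- rep(NA_real_, m)
  xw0 <- w * x0r
  a00 <- crossprod(x0r, xw0)
  b0 <- crossprod(xw0, yr)
  swy2 <- sum(w * yr^2)
  for (j in seq_len(m)) {
    gj <- gr[, j]
    if (stats::sd(g$dosages[, j]) == 0) next  # constant marker: singular
    a0g <- crossprod(xw0, gj)
    agg <- sum(w * gj^2)
    a <- rbind(cbind(a00, a0g), cbind(t(a0g), agg))
    b <- c(b0, sum(w * gj * yr))
    beta <- tryCatch(solve(a, b), error = function(e) NULL)
    if (is.null(beta)) next
    rss <- swy2 - sum(beta * b)
    df <- n - p0 - 1L
    s2 <- max(rss, 0) / df
    vlast <- solve(a)[p0 + 1L, p0 + 1L]
    eff[j] <- beta[p0 + 1L]
    se[j] <- sqrt(s2 * vlast)
    tstat <- eff[j] / se[j]
    pv[j] <- 2 * stats::pt(-abs(tstat), df)
  }
  af <- allele_freqs(g)
  results <- data.frame(marker_id = g$markers$marker_id,
                        chrom = g$markers$chrom, pos = g$markers$pos,
                        maf = af$maf, effect = eff, se = se, p_value = pv,
                        neglog10_p = -log10(pv),
                        significant = -log10(pv) > significance_neglogp,
                        row.names = NULL)
  structure(list(results = results, lambda = lambda,
                 sigma_g2 = lambda * sigma_e2, sigma_e2 = sigma_e2,
                 n_samples = n, n_markers = m,
                 significance_neglogp = significance_neglogp),
            class = "cmlm_gwas")
}

#' @export
print.cmlm_gwas <- function(x, ...) {
  cat("Compressed mixed-linear-model scan:", x$n_markers, "markers,",
      x$n_samples, "samples\n")
  cat(sprintf("  variance components: sigma_g2 = %.4g, sigma_e2 = %.4g (lambda = %.4g)\n",
              x$sigma_g2, x$sigma_e2, x$lambda))
  cat("  significant markers (-log10 p >", x$significance_neglogp, "):",
      sum(x$results$significant, na.rm = TRUE), "\n")
  invisible(x)
}

#' @export
summary.cmlm_gwas <- function(object, n_top = 10L, ...) {
  r <- object$results[order(object$results$p_value), ]
  cat("Top associations:\n")
  print(utils::head(r[, c("marker_id", "chrom", "pos", "effect", "se",
                          "neglog10_p", "significant")], n_top),
        row.names = FALSE)
  invisible(r)
}

#' Manhattan plot of a mixed-model scan
#'
#' @param x a \code{cmlm_gwas} object.
#' @param ... passed to \code{plot}.
#' @export
plot.cmlm_gwas <- function(x, ...) {
  r <- x$results[!is.na(x$results$p_value), ]
  chroms <- unique(r$chrom)
  offset <- 0
  xpos <- numeric(nrow(r))
  for (ch in chroms) {
    i <- r$chrom == ch
    xpos[i] <- r$pos[i] + offset
    offset <- offset + max(r$pos[i])
  }
  plot(xpos, r$neglog10_p, pch = 20, cex = 0.5,
       col = (match(r$chrom, chroms) %% 2) + 1,
       xlab = "genome position", ylab = expression(-log[10](p)), ...)
  graphics::abline(h = x$significance_neglogp, col = "red", lty = 2)
  invisible(x)
}

#' Bonferroni threshold on the -log10 p scale
#'
#' \code{-log10(alpha / n_tests)}: with 78,427 tests at alpha 0.05 this is
#' 6.2 to one decimal, the reference point below the study's adopted cut-off
#' of 7.
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error rate in (0, 1).
#' @return Threshold on the -log10 scale.
#' @export
bonferroni_neglog <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  -log10(alpha / n_tests)
}

#' Flag significant markers and their genic subset
#'
#' Markers with \code{-log10 p} strictly above the threshold are flagged;
#' the genic subset comprises flagged markers falling inside an annotated
#' gene interval (1-based closed containment), with gene ids attached.
#'
#' @param results data.frame of association results (as in
#'   \code{cmlm_gwas$results}).
#' @param threshold_neglogp significance cut-off (strict >), default 7.
#' @param annotation optional gene annotation data.frame from
#'   \code{\link{read_gene_annotation}}.
#' @return List with \code{significant} (flagged subset of \code{results})
#'   and, when annotation is given, \code{genic} (data.frame marker_id,
#'   gene_id for flagged genic markers).
#' @export
call_significant <- function(results, threshold_neglogp = 7.0,
                             annotation = NULL) {
  sig <- results[!is.na(results$neglog10_p) &
                   results$neglog10_p > threshold_neglogp, , drop = FALSE]
  out <- list(significant = sig)
  if (!is.null(annotation)) {
    map <- snp_to_gene(sig, annotation)
    out$genic <- map
  }
  out
}
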