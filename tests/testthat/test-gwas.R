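test_that("MAF filtering is strict at the boundary", {
  # marker frequencies: 0.000187-like rare, exactly 0.05, 0.5
  d <- matrix(0L, 40, 3)
  d[1, 1] <- 1L                 # maf 1/80 = 0.0125
  d[1:4, 2] <- 1L               # maf 4/80 = 0.05 exactly
  d[1:20, 3] <- 2L              # maf 0.5
  g <- make_geno(d)
  out <- maf_filter(g, 0.05)
  expect_equal(out$genotypes$markers$marker_id, "mk3")
  expect_setequal(out$removed$marker_id, c("mk1", "mk2"))
  expect_equal(sort(out$removed$maf), c(0.0125, 0.05))
})

test_that("VanRaden kinship matches the centered cross-product by hand", {
  d <- rbind(a = c(0L, 2L), b = c(1L, 1L), c = c(2L, 0L))
  g <- make_geno(d)
  p <- colMeans(d) / 2
  z <- sweep(d, 2, 2 * p)
  k_oracle <- tcrossprod(z) / (2 * sum(p * (1 - p)))
  expect_equal(kinship_vanraden(g), k_oracle, ignore_attr = TRUE)
  # duplicated samples give equal self- and cross-kinship
  d2 <- rbind(a = c(0L, 2L, 1L), b = c(0L, 2L, 1L), c = c(2L, 0L, 0L))
  k2 <- kinship_vanraden(make_geno(d2))
  expect_equal(k2["a", "a"], k2["a", "b"])
  expect_equal(k2["a", "b"], k2["b", "b"])
  # symmetric PSD on a random fixture
  set.seed(11)
  k3 <- kinship_vanraden(make_geno(matrix(sample(0:2, 10 * 50, TRUE), 10, 50)))
  expect_equal(k3, t(k3))
  expect_gte(min(eigen(k3, symmetric = TRUE)$values), -1e-8)
})

test_that("Bonferroni thresholds on the -log10 scale evaluate correctly", {
  expect_equal(round(bonferroni_neglog(78427, 0.05), 1), 6.2)
  expect_equal(bonferroni_neglog(1, 0.05), -log10(0.05), tolerance = 1e-12)
  expect_equal(bonferroni_neglog(20, 0.05), -log10(0.0025), tolerance = 1e-12)
  expect_error(bonferroni_neglog(10, 1.2), "alpha")
})

test_that("with no polygenic variance and identity kinship the scan is OLS", {
  set.seed(21)
  n <- 80
  g <- make_geno(matrix(sample(0:2, n * 30, TRUE), n, 30))
  y <- rnorm(n, 45, 5)
  names(y) <- rownames(g$dosages)
  k <- diag(n)
  dimnames(k) <- list(names(y), names(y))
  scan <- cmlm_gwas(g, y, k = k, n_pcs = 0, lambda = 0)
  for (j in c(1L, 7L, 30L)) {
    fit <- summary(lm(y ~ g$dosages[, j]))$coefficients
    expect_equal(scan$results$p_value[j], fit[2, 4], tolerance = 1e-8)
    expect_equal(scan$results$effect[j], fit[2, 1], tolerance = 1e-8)
  }
})

test_that("p-values are invariant to joint permutation, shift and scale", {
  set.seed(22)
  spec <- simulation_spec(n_per_group = c(ic = 40, lr = 40), n_markers = 60,
                          seed = 14)
  sim <- simulate_genotypes(spec)
  phe <- simulate_phenotype(sim$genotypes, spec, sim$groups)
  g <- maf_filter(sim$genotypes)$genotypes
  y <- phe$phenotype
  base <- cmlm_gwas(g, y, n_pcs = 2)
  # joint permutation of samples
  perm <- sample(rownames(g$dosages))
  g_p <- subset_genotypes(g, samples = perm)
  perm_scan <- cmlm_gwas(g_p, y, n_pcs = 2)
  expect_equal(perm_scan$results$p_value, base$results$p_value,
               tolerance = 1e-6)
  # shifting y changes nothing; scaling y scales effects but not p
  shift <- cmlm_gwas(g, y + 100, n_pcs = 2)
  expect_equal(shift$results$p_value, base$results$p_value, tolerance = 1e-8)
  scaled <- cmlm_gwas(g, y * 3, n_pcs = 2)
  expect_equal(scaled$results$p_value, base$results$p_value, tolerance = 1e-6)
  expect_equal(scaled$results$effect, base$results$effect * 3,
               tolerance = 1e-6)
})

test_that("kinship compression with one group per sample is exact", {
  spec <- simulation_spec(n_per_group = c(ic = 25, lr = 25), n_markers = 80,
                          seed = 15)
  sim <- simulate_genotypes(spec)
  phe <- simulate_phenotype(sim$genotypes, spec, sim$groups)
  g <- maf_filter(sim$genotypes)$genotypes
  a <- cmlm_gwas(g, phe$phenotype)
  b <- cmlm_gwas(g, phe$phenotype, compression_groups = nrow(g$dosages))
  expect_equal(a$results$p_value, b$results$p_value)
  # heavy compression still runs and returns finite p-values
  cc <- cmlm_gwas(g, phe$phenotype, compression_groups = 5)
  expect_true(all(is.finite(cc$results$p_value)))
})

test_that("a planted additive QTL is the top hit", {
  spec <- simulation_spec(n_per_group = c(ic = 150, lr = 150),
                          n_markers = 500,
                          additive_qtl = data.frame(marker = 250, effect = 7.5),
                          seed = 3)
  sim <- simulate_genotypes(spec)
  phe <- simulate_phenotype(sim$genotypes, spec, sim$groups)
  g <- maf_filter(sim$genotypes)$genotypes
  scan <- cmlm_gwas(g, phe$phenotype)
  r <- scan$results
  expect_equal(r$marker_id[which.min(r$p_value)], "AX000250")
})

test_that("significance calls use a strict threshold and genic containment", {
  res <- data.frame(marker_id = c("m1", "m2", "m3", "m4"),
                    chrom = "Gm06",
                    pos = c(150L, 250L, 350L, 700L),
                    p_value = 10^(-c(14.23, 9.75, 2.43, 7)),
                    neglog10_p = c(14.23, 9.75, 2.43, 7))
  ann <- data.frame(gene_id = c("geneA", "geneB"), chrom = "Gm06",
                    start = c(100L, 300L), end = c(200L, 400L))
  out <- call_significant(res, 7, ann)
  expect_setequal(out$significant$marker_id, c("m1", "m2"))  # 7 is not > 7
  expect_equal(out$genic$marker_id, "m1")
  expect_equal(out$genic$gene_id, "geneA")
})
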