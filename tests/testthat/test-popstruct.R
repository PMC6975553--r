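test_that("identity-by-state matches the shared-allele count", {
  g <- make_geno(rbind(s1 = c(0L, 2L, 1L, 1L),
                       s2 = c(0L, 0L, 1L, 2L),
                       s3 = c(2L, 0L, 1L, 1L)))
  ib <- ibs_matrix(g)
  # per-locus shared fractions for (s1, s2): 1, 0, 1, 0.5 -> mean 0.625
  expect_equal(ib$similarity["s1", "s2"], 0.625)
  expect_equal(diag(ib$similarity), c(s1 = 1, s2 = 1, s3 = 1))
  expect_equal(ib$distance, 1 - ib$similarity)
  # duplicated sample and fully opposite samples
  g2 <- make_geno(rbind(a = c(0L, 0L, 0L), b = c(0L, 0L, 0L),
                        c = c(2L, 2L, 2L)))
  ib2 <- ibs_matrix(g2)
  expect_equal(ib2$similarity["a", "b"], 1)
  expect_equal(ib2$similarity["a", "c"], 0)
})

test_that("IBS plus the normalized manhattan dosage distance is one", {
  set.seed(31)
  g <- make_geno(matrix(sample(0:2, 8 * 40, TRUE), 8, 40))
  ib <- ibs_matrix(g)
  manh <- as.matrix(dist(g$dosages, "manhattan")) / (2 * 40)
  expect_equal(ib$similarity + manh, matrix(1, 8, 8), ignore_attr = TRUE)
})

test_that("K2P distance matches its closed form on homozygous calls", {
  # 10 sites; transitions are A<->G, transversions A<->C etc.
  # pair (s1, s2): 1 transversion difference in 10 -> P = 0, Q = 0.1
  ref <- c(rep("A", 10))
  alt <- c("C", rep("G", 9))  # site 1 transversion, rest transitions
  d1 <- rep(0L, 10)
  d2 <- c(2L, rep(0L, 9))     # differs only at the transversion site
  d3 <- c(0L, 2L, rep(0L, 8)) # 1 transition difference from s1: P = 0.1
  g <- make_geno(rbind(s1 = d1, s2 = d2, s3 = d3), ref = ref, alt = alt)
  k <- k2p_distance(g)
  expect_equal(k["s1", "s2"], -0.5 * log(0.9 * sqrt(1 - 0.2)), tolerance = 1e-9)
  expect_equal(k["s1", "s3"], -0.5 * log((1 - 0.2) * sqrt(1)), tolerance = 1e-9)
  expect_equal(k["s1", "s1"], 0)
  # heterozygous sites are excluded pairwise: making site 1 het in s2
  # removes the only difference
  g2 <- make_geno(rbind(s1 = d1, s2 = c(1L, rep(0L, 9))),
                  ref = ref, alt = alt)
  expect_equal(k2p_distance(g2)["s1", "s2"], 0)
})

test_that("transition-only divergence follows -log(1 - 2P)/2", {
  # 20 sites, 1 transition difference -> P = 0.05, Q = 0
  ref <- rep("C", 20)
  alt <- rep("T", 20)
  g <- make_geno(rbind(s1 = rep(0L, 20), s2 = c(2L, rep(0L, 19))),
                 ref = ref, alt = alt)
  expect_equal(k2p_distance(g)["s1", "s2"], -0.5 * log(0.9),
               tolerance = 1e-9)
})

test_that("principal coordinates reproduce Euclidean geometry", {
  pts <- cbind(c(0, 3, 0, 5), c(0, 0, 4, 6))
  rownames(pts) <- paste0("s", 1:4)
  d <- as.matrix(dist(pts))
  pc <- pca_from_distance(d, 2)
  expect_equal(as.matrix(dist(pc$coordinates)), d, tolerance = 1e-9)
  expect_equal(sum(pc$explained), 1, tolerance = 1e-9)
  # identical samples land on identical coordinates
  d2 <- as.matrix(dist(pts[c(1, 1, 2, 3), ]))
  dimnames(d2) <- list(paste0("t", 1:4), paste0("t", 1:4))
  pc2 <- suppressWarnings(pca_from_distance(d2, 2))
  expect_equal(pc2$coordinates[1, ], pc2$coordinates[2, ])
  # asking for more axes than positive eigenvalues warns and truncates
  expect_warning(pca_from_distance(d, 4), "truncating")
})

test_that("three-taxon BIONJ branch lengths obey the three-point formulas", {
  d <- matrix(c(0, 5, 9,
                5, 0, 10,
                9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- bionj_tree(d)$tree
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(len[["a"]], (5 + 9 - 10) / 2)
  expect_equal(len[["b"]], (5 + 10 - 9) / 2)
  expect_equal(len[["c"]], (9 + 10 - 5) / 2)
})

test_that("BIONJ recovers an additive four-taxon tree exactly", {
  true <- ape::read.tree(text = "((a:1,b:2):1.5,(c:3,d:4):0.5);")
  d <- tree_distances(true)
  fit <- bionj_tree(d)
  expect_equal(tree_distances(fit$tree)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
  # topology: unrooted trees match
  expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(fit$tree))[1], 0)
  expect_match(fit$newick, "^\\(")
})

test_that("zero-distance taxa become siblings with zero pendant edges", {
  true <- ape::read.tree(text = "((a:0.0,b:0.0):1,(c:2,d:3):1);")
  d <- tree_distances(true)
  fit <- bionj_tree(d)$tree
  tips <- match(c("a", "b"), fit$tip.label)
  parents <- fit$edge[match(tips, fit$edge[, 2]), 1]
  expect_equal(parents[1], parents[2])
  expect_equal(fit$edge.length[match(tips, fit$edge[, 2])], c(0, 0))
})

test_that("LD r-squared equals squared Pearson correlation of dosages", {
  x1 <- c(0L, 0L, 1L, 2L, 2L)
  x2 <- c(0L, 1L, 1L, 2L, 0L)
  g <- make_geno(cbind(x1, x2, 2L - x1, x1),
                 pos = c(1000L, 2000L, 3000L, 4000L))
  ld <- ld_decay(g, max_distance = 10000L, bin_width = 1000L)
  r2 <- setNames(rep(NA_real_, 6), NULL)
  pairs <- ld$curve[ld$curve$n_pairs > 0, ]
  # manual two-pass correlation oracle
  expect_equal(sum(pairs$n_pairs), 6L)
  expect_equal(ld$mean_r2_500kb,
               mean(c(cor(x1, x2)^2, cor(x1, 2 - x1)^2, cor(x1, x1)^2,
                      cor(x2, 2 - x1)^2, cor(x2, x1)^2, cor(2 - x1, x1)^2)))
  # a copy and a mirrored copy are both in perfect LD
  expect_equal(cor(x1, 2 - x1)^2, 1)
})

test_that("monomorphic markers are excluded from LD with a count", {
  g <- make_geno(cbind(c(0L, 1L, 2L, 0L), c(1L, 1L, 1L, 1L),
                       c(2L, 1L, 0L, 2L)),
                 pos = c(1000L, 2000L, 3000L))
  ld <- ld_decay(g, max_distance = 10000L)
  expect_equal(ld$n_monomorphic_skipped, 2L)
  expect_equal(sum(ld$curve$n_pairs), 1L)
})

test_that("windowed nucleotide diversity follows the site formula", {
  # one site, 50 diploids, allele counts 50/50 over 100 chromosomes
  d <- matrix(0L, 50, 2)
  d[1:25, 1] <- 2L
  d[, 2] <- 0L; d[1, 2] <- 2L
  g <- make_geno(d, pos = c(5000L, 150000L))
  pw <- pi_windows(g, window_size = 100000L, window_step = 100000L)
  w1 <- pw[pw$start == 1, ]
  expect_equal(w1$value, (50 * 50 / choose(100, 2)) / 100000,
               tolerance = 1e-12)
  # doubling the window size halves the per-bp value of a single-site window
  pw2 <- pi_windows(subset_genotypes(g, markers = 1L),
                    window_size = 200000L, window_step = 200000L,
                    chrom_lengths = c(Gm01 = 200000L))
  expect_equal(pw2$value[1], w1$value / 2)
  # monomorphic window
  gm <- make_geno(matrix(2L, 10, 1), pos = 1000L)
  expect_equal(pi_windows(gm, 10000L, 10000L)$value, 0)
})

test_that("inbreeding F hits the textbook extremes and a hand-computed case", {
  # every sample homozygous at every polymorphic site -> F = 1
  g_hom <- make_geno(rbind(a = c(0L, 2L, 0L), b = c(2L, 0L, 0L),
                           c = c(0L, 2L, 2L)))
  expect_equal(unname(inbreeding_f(g_hom)), rep(1, 3))
  # heterozygous everywhere at p = 0.5 -> negative F
  g_het <- make_geno(rbind(a = c(1L, 1L), b = c(1L, 1L),
                           c = c(0L, 0L), d = c(2L, 2L)))
  expect_lt(inbreeding_f(g_het)[["a"]], 0)
  # spreadsheet-style oracle: n = 4 samples, 3 sites
  d <- rbind(a = c(0L, 1L, 2L), b = c(1L, 1L, 0L),
             c = c(2L, 0L, 0L), d = c(0L, 2L, 2L))
  g <- make_geno(d)
  p <- colMeans(d) / 2
  e_hom <- 1 - 2 * p * (1 - p) * 8 / 7
  o_hom <- rowSums(d != 1L)
  f_oracle <- (o_hom - sum(e_hom)) / (3 - sum(e_hom))
  expect_equal(unname(inbreeding_f(g)), unname(f_oracle))
})

test_that("Weir-Cockerham Fst is one at fixation and <= 0 for duplicated groups", {
  d <- rbind(a = c(0L, 0L), b = c(0L, 1L), c = c(2L, 0L), d = c(2L, 1L))
  g <- make_geno(d, pos = c(1000L, 2000L))
  grp <- factor(c("x", "x", "y", "y"))
  fw <- fst_windows(g, grp, window_size = 1500L, window_step = 1500L)
  # site 1 is fixed ref in x, fixed alt in y
  expect_equal(fw$windows$value[1], 1)
  # two groups that are copies of the same samples
  d2 <- rbind(d, d)
  rownames(d2) <- paste0("s", 1:8)
  g2 <- make_geno(d2, pos = c(1000L, 2000L))
  grp2 <- factor(rep(c("x", "y"), each = 4))
  expect_lte(fst_windows(g2, grp2)$fst, 0)
})

test_that("windowed Fst and pi values stay in range on random data", {
  set.seed(77)
  g <- make_geno(matrix(sample(0:2, 60 * 50, TRUE), 60, 50),
                 pos = sort(sample.int(500000L, 50)))
  grp <- factor(rep(c("x", "y"), each = 30))
  fw <- fst_windows(g, grp, 100000L, 50000L)
  vals <- fw$windows$value[!is.na(fw$windows$value)]
  expect_true(all(vals <= 1))
  pw <- pi_windows(g, 100000L, 50000L)
  expect_true(all(pw$value >= 0 & pw$value <= 1))
})
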