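test_that("Dirichlet-multinomial marginal matches closed-form small cases", {
  # one observation, uniform prior over 3 categories: predictive 1/3
  expect_equal(exp(dm_log_marginal(c(1, 0, 0), 1)), 1 / 3, tolerance = 1e-12)
  # counts (2,0,0) at uniform prior over 3: Gamma(3)/Gamma(5) * Gamma(3) = 1/6
  expect_equal(exp(dm_log_marginal(c(2, 0, 0), 1)), 1 / 6, tolerance = 1e-12)
  expect_error(dm_log_marginal(c(0, 0, 0)), "positive")
  expect_error(dm_log_marginal(c(1, 0), alpha = c(1, -1)), "positive")
})

test_that("the DM marginal is a probability over ordered sequences", {
  # sum over all ordered outcome sequences of length n with K categories = 1
  for (K in 2:3) for (n in 1:4) {
    seqs <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
    tot <- sum(apply(seqs, 1, function(s)
      exp(dm_log_marginal(tabulate(s, K), 1))))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("the Gaussian cell marginal matches its Student-t predictive", {
  pr <- gaussian_cell_prior(mu0 = 1, kappa0 = 2, alpha0 = 3, beta0 = 4)
  y <- 2.5
  # one observation: location-scale t with df 2*alpha0
  scale <- sqrt(pr$beta0 * (pr$kappa0 + 1) / (pr$alpha0 * pr$kappa0))
  dens <- dt((y - pr$mu0) / scale, df = 2 * pr$alpha0) / scale
  expect_equal(gaussian_log_marginal(list(y), pr), log(dens),
               tolerance = 1e-10)
  # independence across cells: two identical cells double the log marginal
  v <- c(0.3, -1.2, 0.8)
  expect_equal(gaussian_log_marginal(list(v, v), pr),
               2 * gaussian_log_marginal(list(v), pr), tolerance = 1e-12)
})

test_that("the Gaussian cell marginal agrees with numerical integration", {
  pr <- gaussian_cell_prior(mu0 = 0.5, kappa0 = 1, alpha0 = 2, beta0 = 1.5)
  v <- c(0.2, 1.1, -0.4)
  # integrate the NIG prior times the Gaussian likelihood over (mu, sigma2)
  inner <- function(s2) {
    vapply(s2, function(ss) {
      f <- function(mu)
        exp(sum(dnorm(v, mu, sqrt(ss), log = TRUE)) +
              dnorm(mu, pr$mu0, sqrt(ss / pr$kappa0), log = TRUE))
      integrate(Vectorize(f), -20, 20, rel.tol = 1e-10)$value *
        pr$beta0^pr$alpha0 / gamma(pr$alpha0) *
        ss^(-pr$alpha0 - 1) * exp(-pr$beta0 / ss)
    }, 0)
  }
  quad <- integrate(inner, 0.005, 300, rel.tol = 1e-8)$value
  expect_equal(gaussian_log_marginal(list(v), pr), log(quad),
               tolerance = 1e-4)
})

test_that("the partition score decomposes and is label-invariant", {
  set.seed(51)
  n <- 40
  d <- matrix(sample(0:2, n * 4, TRUE), n, 4)
  y <- rnorm(n)
  pr <- default_cell_prior(y)
  # all markers background: per-marker DM terms plus one global Gaussian cell
  s_bg <- partition_log_score(rep(0L, 4), d, y, pr)
  oracle <- gaussian_log_marginal(list(y), pr) +
    sum(vapply(1:4, function(j) dm_log_marginal(tabulate(d[, j] + 1, 3), 1),
               0))
  expect_equal(s_bg, oracle, tolerance = 1e-12)
  # relabeling dependency blocks changes nothing
  expect_equal(partition_log_score(c(2L, 2L, 3L, 3L), d, y, pr),
               partition_log_score(c(3L, 3L, 2L, 2L), d, y, pr))
  # marker order within a block changes nothing
  expect_equal(partition_log_score(c(1L, 1L, 0L, 0L), d, y, pr),
               partition_log_score(c(1L, 1L, 0L, 0L), d[, c(2, 1, 3, 4)],
                                   y, pr))
})

test_that("adding a null marker to the associated block lowers the score on average", {
  deltas <- vapply(1:20, function(s) {
    set.seed(600 + s)
    n <- 300
    d <- matrix(sample(0:2, n * 2, TRUE), n, 2)
    y <- rnorm(n)
    pr <- default_cell_prior(y)
    partition_log_score(c(1L, 0L), d, y, pr) -
      partition_log_score(c(0L, 0L), d, y, pr)
  }, 0)
  expect_lt(mean(deltas), 0)
})

test_that("the two-locus regression matches lm and handles degeneracy", {
  set.seed(52)
  n <- 200
  ga <- sample(0:2, n, TRUE)
  gb <- sample(0:2, n, TRUE)
  y <- 3 * ga * gb + rnorm(n, 0, 0.1)
  tl <- two_locus_test(cbind(ga, gb), y, 1, 2)
  fit <- summary(lm(y ~ ga * gb))$coefficients
  expect_equal(tl$p_value, fit["ga:gb", 4], tolerance = 1e-8)
  expect_equal(tl$coefficient, fit["ga:gb", 1], tolerance = 1e-8)
  expect_lt(tl$p_value, 1e-10)
  expect_true(tl$coefficient > 2.9 && tl$coefficient < 3.1)
  # random-fixture agreement with lm
  for (s in 1:5) {
    set.seed(700 + s)
    y2 <- rnorm(n)
    tl2 <- two_locus_test(cbind(ga, gb), y2, 1, 2)
    fit2 <- summary(lm(y2 ~ ga * gb))$coefficients
    expect_equal(tl2$p_value, fit2["ga:gb", 4], tolerance = 1e-8)
  }
  # constant phenotype
  tlc <- two_locus_test(cbind(ga, gb), rep(5, n), 1, 2)
  expect_equal(tlc$p_value, 1)
  expect_equal(tlc$coefficient, 0)
  # collinear design is flagged
  tld <- two_locus_test(cbind(ga, ga), y, 1, 2)
  expect_true(tld$degenerate)
  expect_true(is.na(tld$p_value))
})

test_that("purely additive phenotypes give uniform interaction p-values", {
  set.seed(53)
  ps <- replicate(200, {
    n <- 500
    ga <- sample(0:2, n, TRUE)
    gb <- sample(0:2, n, TRUE)
    y <- ga + gb + rnorm(n)
    two_locus_test(cbind(ga, gb), y, 1, 2)$p_value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("pairwise p-value ranges have the right shape", {
  set.seed(54)
  n <- 100
  d <- matrix(sample(0:2, n * 3, TRUE), n, 3)
  colnames(d) <- c("a", "b", "c")
  y <- rnorm(n)
  two <- pairwise_p_range(c(1, 2), d, y)
  expect_equal(two$min_p, two$max_p)   # single pair
  expect_equal(two$n_pairs, 1L)
  three <- pairwise_p_range(c(1, 2, 3), d, y)
  expect_equal(nrow(three$pairs), 3L)  # C(3,2)
  expect_lte(three$min_p, three$max_p)
})

test_that("the sampler matches the exact posterior on a three-marker toy", {
  set.seed(55)
  n <- 60
  d <- matrix(sample(0:2, n * 3, TRUE), n, 3)
  y <- rnorm(n) + 0.8 * d[, 1] * d[, 2]
  pr <- default_cell_prior(y)
  states <- partition_assignments(3)
  sc <- apply(states, 1, function(a) partition_log_score(a, d, y, pr))
  post <- exp(sc - max(sc))
  post <- post / sum(post)
  keys <- apply(states, 1, paste, collapse = "")
  es <- epistasis_scan(d, y, iterations = 220000, burnin = 20000, seed = 9,
                       track_states = TRUE)
  emp <- es$state_freq[keys]
  emp[is.na(emp)] <- 0
  expect_lt(0.5 * sum(abs(emp - post)), 0.02)  # total variation
})

test_that("planted interactions are recovered and the MAP matches enumeration", {
  spec <- simulation_spec(n_per_group = c(ic = 150, lr = 150), n_markers = 6,
                          target_fst = 0, phenotype_means = c(ic = 45, lr = 45),
                          interaction_groups = list(list(
                            markers = c(2L, 5L),
                            effects = xor_cell_effects(8))),
                          seed = 21)
  sim <- simulate_genotypes(spec)
  phe <- simulate_phenotype(sim$genotypes, spec, sim$groups)
  d <- sim$genotypes$dosages
  y <- phe$phenotype
  pr <- default_cell_prior(y)
  states <- partition_assignments(6, max_block_size = 5)
  sc <- apply(states, 1, function(a) partition_log_score(a, d, y, pr))
  enum_assoc <- which(states[which.max(sc), ] == 1L)
  es <- epistasis_scan(d, y, iterations = 60000, burnin = 10000, seed = 3)
  top_assoc <- es$sets[es$sets$kind == "associated", ]
  expect_equal(sort(top_assoc$markers[[1]]), sort(enum_assoc))
  expect_equal(es$map$score, max(sc), tolerance = 1e-8)
  expect_setequal(which(es$map$assignment == 1L), enum_assoc)
})
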