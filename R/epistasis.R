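#' Dirichlet-multinomial log marginal likelihood
#'
#' Log marginal probability of an unordered categorical sample after
#' integrating a Dirichlet prior over the category probabilities:
#' \code{log Gamma(A) - log Gamma(A + n) + sum_k [log Gamma(alpha_k + c_k) -
#' log Gamma(alpha_k)]} with \code{A = sum(alpha)}. This is the genotype
#' likelihood of each block in the Bayesian partition model.
#'
#' @param counts non-negative integer vector of category counts, at least
#'   one positive.
#' @param alpha Dirichlet concentration, a scalar (recycled over categories)
#'   or a vector matching \code{counts}; all > 0. Default 1 (uniform).
#' @return Log marginal likelihood (a scalar).
#' @export
dm_log_marginal <- function(counts, alpha = 1) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("at least one count must be positive")
  if (length(alpha) == 1L) alpha <- rep(alpha, length(counts))
  if (length(alpha) != length(counts))
    stop("alpha must be scalar or match counts")
  if (any(alpha <= 0)) stop("concentrations must be positive")
  a_tot <- sum(alpha)
  lgamma(a_tot) - lgamma(a_tot + sum(counts)) +
    sum(lgamma(alpha + counts) - lgamma(alpha))
}

#' Conjugate Gaussian cell prior
#'
#' Normal-Inverse-Gamma prior for the per-cell phenotype model of the
#' associated block: mean mu0 with strength kappa0 pseudo-observations,
#' variance with shape alpha0 and scale beta0. The package default centers
#' the prior on the sample (\code{mu0 = mean(y)}, \code{kappa0 = 1},
#' \code{alpha0 = 2}, \code{beta0 = var(y)}).
#'
#' @param mu0 prior mean.
#' @param kappa0 prior mean strength (> 0).
#' @param alpha0 inverse-gamma shape (> 0).
#' @param beta0 inverse-gamma scale (> 0).
#' @return List of class \code{"gaussian_cell_prior"}.
#' @export
gaussian_cell_prior <- function(mu0 = 0, kappa0 = 1, alpha0 = 2, beta0 = 1) {
  if (kappa0 <= 0 || alpha0 <= 0 || beta0 <= 0)
    stop("kappa0, alpha0 and beta0 must be positive")
  structure(list(mu0 = mu0, kappa0 = kappa0, alpha0 = alpha0, beta0 = beta0),
            class = "gaussian_cell_prior")
}

#' Default Gaussian cell prior derived from a phenotype vector
#'
#' @param y phenotype values.
#' @return A \code{\link{gaussian_cell_prior}} with \code{mu0 = mean(y)},
#'   \code{kappa0 = 1}, \code{alpha0 = 2}, \code{beta0 = var(y)}.
#' @export
default_cell_prior <- function(y) {
  gaussian_cell_prior(mu0 = mean(y), kappa0 = 1, alpha0 = 2,
                      beta0 = max(stats::var(y), 1e-12))
}

# vectorized NIG log marginal from per-cell sufficient statistics
.nig_log_marginal <- function(n, s, s2, prior) {
  ybar <- s / n
  ss <- pmax(s2 - s^2 / n, 0)
  kn <- prior$kappa0 + n
  an <- prior$alpha0 + n / 2
  bn <- prior$beta0 + ss / 2 +
    prior$kappa0 * n * (ybar - prior$mu0)^2 / (2 * kn)
  -(n / 2) * log(2 * pi) + 0.5 * (log(prior$kappa0) - log(kn)) +
    lgamma(an) - lgamma(prior$alpha0) +
    prior$alpha0 * log(prior$beta0) - an * log(bn)
}

#' Gaussian log marginal likelihood over phenotype cells
#'
#' Log marginal of the phenotype under the conjugate
#' Normal-Inverse-Gamma model, cell by cell and summed: each cell (a joint
#' genotype class of the associated block) has its own mean and variance
#' integrated out, giving a multivariate Student-t marginal per cell.
#' Empty cells contribute zero (marginal 1).
#'
#' @param values_by_cell list of numeric vectors, one per non-empty cell.
#' @param prior a \code{\link{gaussian_cell_prior}}.
#' @return Log marginal likelihood (a scalar).
#' @export
gaussian_log_marginal <- function(values_by_cell, prior) {
  stopifnot(inherits(prior, "gaussian_cell_prior"))
  if (!length(values_by_cell)) return(0)
  tot <- 0
  for (v in values_by_cell) {
    if (!length(v)) next
    tot <- tot + .nig_log_marginal(length(v), sum(v), sum(v^2), prior)
  }
  tot
}

# joint genotype code (1 .. 3^k) of a marker block
.joint_code <- function(d, idx) {
  k <- length(idx)
  as.integer(d[, idx, drop = FALSE] %*% (3^(seq_len(k) - 1L))) + 1L
}

# score of a dependency block: DM marginal over the 3^k joint genotype cells
.dep_score <- function(d, idx, alpha) {
  if (!length(idx)) return(0)
  code <- .joint_code(d, idx)
  dm_log_marginal(tabulate(code, 3^length(idx)), alpha)
}

# score of the associated block: DM marginal of its joint genotypes plus the
# Gaussian marginal of the phenotype split by joint genotype cell; an empty
# associated block leaves the phenotype in one global cell
.assoc_score <- function(d, idx, y, y2, alpha, prior) {
  if (!length(idx))
    return(.nig_log_marginal(length(y), sum(y), sum(y2), prior))
  code <- .joint_code(d, idx)
  cnt <- tabulate(code, 3^length(idx))
  sums <- rowsum(cbind(y, y2), code)
  ncell <- cnt[as.integer(rownames(sums))]
  dm_log_marginal(cnt, alpha) +
    sum(.nig_log_marginal(ncell, sums[, 1], sums[, 2], prior))
}

#' Log posterior score of a partition state
#'
#' The partition assigns every candidate marker to the phenotype-associated
#' block (label 1), a genotype-dependency block (labels >= 2) or the
#' independent background (label 0). The score is the log of
#' \code{P(Y | X_assoc) * prod_blocks P(X_block)} under the
#' Dirichlet-multinomial genotype model and the conjugate Gaussian phenotype
#' model, plus the log partition prior (uniform by default; a per-marker
#' block-size penalty is available to curb large-block artifacts). Every
#' block's genotypes, including the associated block's, carry a
#' Dirichlet-multinomial term, so scores are comparable across partitions.
#'
#' @param assignment integer vector over markers: 0 background, 1
#'   associated, >= 2 dependency block labels.
#' @param d integer dosage matrix (samples x candidate markers, values
#'   0/1/2).
#' @param y phenotype vector aligned to rows of \code{d}.
#' @param prior a \code{\link{gaussian_cell_prior}} (default derived from
#'   \code{y}).
#' @param dm_alpha Dirichlet concentration per joint-genotype cell.
#' @param size_penalty per-marker log-prior penalty for membership in a
#'   non-background block (0 = uniform prior).
#' @return Log posterior score (a scalar).
#' @export
partition_log_score <- function(assignment, d, y, prior = NULL,
                                dm_alpha = 1, size_penalty = 0) {
  if (ncol(d) == 0L) stop("empty candidate set")
  stopifnot(length(assignment) == ncol(d), length(y) == nrow(d))
  if (is.null(prior)) prior <- default_cell_prior(y)
  y2 <- y^2
  score <- .assoc_score(d, which(assignment == 1L), y, y2, dm_alpha, prior)
  for (j in which(assignment == 0L))
    score <- score + .dep_score(d, j, dm_alpha)
  for (l in unique(assignment[assignment >= 2L]))
    score <- score + .dep_score(d, which(assignment == l), dm_alpha)
  score - size_penalty * sum(assignment != 0L)
}

# canonical form of an assignment: dependency labels renumbered from 2 in
# order of first appearance
.canonical_assignment <- function(a) {
  dep <- a >= 2L
  if (any(dep)) {
    u <- unique(a[dep])
    a[dep] <- match(a[dep], u) + 1L
  }
  a
}

#' Enumerate all partition states of a small candidate set
#'
#' Generates every canonical assignment of \code{n_markers} markers to the
#' background, the associated block and any set of dependency blocks.
#' Intended as an exact oracle for small problems (the state count grows
#' super-exponentially).
#'
#' @param n_markers number of markers (<= 8 recommended).
#' @param max_block_size maximum markers per associated/dependency block.
#' @return Integer matrix, one row per canonical state.
#' @export
partition_assignments <- function(n_markers, max_block_size = n_markers) {
  states <- list(integer(0))
  for (m in seq_len(n_markers)) {
    nxt <- list()
    for (a in states) {
      labs <- c(0L, 1L, unique(a[a >= 2L]),
                if (length(a)) max(a, 1L) + 1L else 2L)
      labs <- unique(labs)
      for (l in labs) {
        if (l >= 1L && sum(a == l) + 1L > max_block_size) next
        nxt[[length(nxt) + 1L]] <- c(a, l)
      }
    }
    states <- nxt
  }
  out <- unique(t(vapply(states, .canonical_assignment,
                         integer(n_markers))))
  out
}

#' MCMC search for multilocus epistatic interactions
#'
#' Metropolis-Hastings over partition states: each sweep either relocates
#' one marker to another block (including opening a fresh dependency block
#' or emptying one, which dissolves it) or swaps two markers between blocks;
#' both proposals are symmetric. Samples retained after burn-in vote: the
#' posterior probability of a marker set is the fraction of retained samples
#' in which exactly that set forms a block, tracked separately for the
#' phenotype-associated block and for dependency blocks. Associated sets of
#' two or more markers at or above the posterior threshold are reported as
#' interaction groups; dependency blocks (inter-marker correlation without a
#' phenotype link, e.g. LD or shared population structure) remain available
#' in the full \code{sets} table.
#'
#' @param g genotype_matrix of the candidate markers (or a plain dosage
#'   matrix).
#' @param y named (or aligned) phenotype vector.
#' @param iterations total MCMC iterations.
#' @param burnin iterations discarded before tallying (< iterations).
#' @param seed integer random seed.
#' @param posterior_threshold minimum posterior for a reported group.
#' @param max_block_size maximum markers per block (guards the 3^k cell
#'   explosion), default 5.
#' @param dm_alpha Dirichlet concentration per joint-genotype cell.
#' @param prior a \code{\link{gaussian_cell_prior}}; default derived from
#'   \code{y}.
#' @param size_penalty per-marker log-prior penalty for non-background
#'   membership (0 = uniform partition prior).
#' @param track_states also tally full canonical states (for exact-posterior
#'   comparisons on toy problems).
#' @return Object of class \code{"epistasis_scan"}: list with \code{groups}
#'   (reported interaction groups), \code{sets} (all tallied marker sets
#'   with kind and posterior), \code{map} (best-scoring state visited),
#'   \code{acceptance_rate}, \code{n_retained}, \code{settings}, and
#'   \code{state_freq} when \code{track_states}.
#' @export
epistasis_scan <- function(g, y, iterations = 50000L, burnin = 45000L,
                           seed = 1L, posterior_threshold = 0.5,
                           max_block_size = 5L, dm_alpha = 1,
                           prior = NULL, size_penalty = 0,
                           track_states = FALSE) {
  if (inherits(g, "genotype_matrix")) {
    d <- g$dosages
    marker_ids <- g$markers$marker_id
  } else {
    d <- g
    marker_ids <- colnames(d)
    if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(ncol(d)))
  }
  m <- ncol(d)
  if (m < 2L) stop("need at least 2 candidate markers")
  if (burnin >= iterations) stop("burnin must be smaller than iterations")
  if (!is.null(names(y)) && !is.null(rownames(d))) y <- y[rownames(d)]
  stopifnot(length(y) == nrow(d))
  if (is.null(prior)) prior <- default_cell_prior(y)
  set.seed(seed)
  y2 <- y^2
  storage.mode(d) <- "integer"
  bg_score <- vapply(seq_len(m), function(j) .dep_score(d, j, dm_alpha), 0)

  # state: assignment a; cached contributions per label (index label + 1)
  a <- integer(m)                       # start with everything background
  cache <- rep(NA_real_, m + 2L)        # cache[l + 1] = contribution of l
  cache[1L] <- sum(bg_score)
  cache[2L] <- .assoc_score(d, integer(0), y, y2, dm_alpha, prior)
  total <- cache[1L] + cache[2L] - 0
  contrib <- function(l, av) {
    idx <- which(av == l)
    if (l == 1L) .assoc_score(d, idx, y, y2, dm_alpha, prior)
    else if (!length(idx)) NA_real_
    else .dep_score(d, idx, dm_alpha)
  }
  penalty <- function(av) size_penalty * sum(av != 0L)
  cur_pen <- 0
  best <- list(assignment = a, score = total)
  tally <- new.env(hash = TRUE, parent = emptyenv())
  states <- if (track_states) new.env(hash = TRUE, parent = emptyenv())
  n_retained <- iterations - burnin
  accepted <- 0L
  move_u <- stats::runif(iterations)
  u_accept <- stats::runif(iterations)

  for (it in seq_len(iterations)) {
    if (move_u[it] < 0.10) {
      # kind-switch: move the whole associated block to a fresh dependency
      # block, or (when the associated block is empty) promote one whole
      # dependency block to associated; the two directions are exact
      # reverses, with Hastings ratio 1/n_dep resp. n_dep
      ai <- which(a == 1L)
      dep_labs <- unique(a[a >= 2L])
      if (length(ai)) {
        fresh <- setdiff(2L:(m + 1L), dep_labs)[1L]
        a2 <- a
        a2[ai] <- fresh
        newc_dep <- .dep_score(d, ai, dm_alpha)
        newc_assoc <- .assoc_score(d, integer(0), y, y2, dm_alpha, prior)
        delta <- newc_dep + newc_assoc - cache[2L]
        n_dep_after <- length(dep_labs) + 1L
        if (u_accept[it] < exp(delta) / n_dep_after) {
          a <- a2
          cache[2L] <- newc_assoc
          cache[fresh + 1L] <- newc_dep
          total <- total + delta
          accepted <- accepted + 1L
        }
      } else if (length(dep_labs)) {
        l <- if (length(dep_labs) == 1L) dep_labs
             else dep_labs[sample.int(length(dep_labs), 1L)]
        di <- which(a == l)
        a2 <- a
        a2[di] <- 1L
        newc_assoc <- .assoc_score(d, di, y, y2, dm_alpha, prior)
        delta <- newc_assoc - cache[2L] - cache[l + 1L]
        if (u_accept[it] < exp(delta) * length(dep_labs)) {
          a <- a2
          cache[2L] <- newc_assoc
          cache[l + 1L] <- NA_real_
          total <- total + delta
          accepted <- accepted + 1L
        }
      }
    } else if (move_u[it] < 0.20) {
      # merge/split: fold an entire dependency block (size >= 2) into a
      # non-empty associated block, or split a subset (size 2..k-1) of the
      # associated block out into a fresh dependency block. The two are
      # exact inverses; sizes are restricted so neither overlaps with the
      # relocate or kind-switch moves, keeping proposal probabilities
      # attributable to a single move type.
      dep_labs <- unique(a[a >= 2L])
      ai <- which(a == 1L)
      k_assoc <- length(ai)
      do_merge <- move_u[it] < 0.15
      if (do_merge && length(dep_labs) && k_assoc >= 1L) {
        l <- if (length(dep_labs) == 1L) dep_labs
             else dep_labs[sample.int(length(dep_labs), 1L)]
        di <- which(a == l)
        if (length(di) >= 2L && k_assoc + length(di) <= max_block_size) {
          a2 <- a
          a2[di] <- 1L
          newc_assoc <- .assoc_score(d, c(ai, di), y, y2, dm_alpha, prior)
          delta <- newc_assoc - cache[2L] - cache[l + 1L]
          # reverse: split exactly this subset out of the merged block
          k2 <- k_assoc + length(di)
          n_subsets <- 2^k2 - k2 - 2L  # subsets of sizes 2..k2-1
          q_fwd <- 0.5 / length(dep_labs)
          q_rev <- 0.5 / n_subsets
          if (u_accept[it] < exp(delta) * q_rev / q_fwd) {
            a <- a2
            cache[2L] <- newc_assoc
            cache[l + 1L] <- NA_real_
            total <- total + delta
            accepted <- accepted + 1L
          }
        }
      } else if (!do_merge && k_assoc >= 3L) {
        n_subsets <- 2^k_assoc - k_assoc - 2L
        repeat {  # uniform subset of the associated block, size 2..k-1
          pick <- ai[stats::runif(k_assoc) < 0.5]
          if (length(pick) >= 2L && length(pick) < k_assoc) break
        }
        fresh <- setdiff(2L:(m + 1L), unique(a[a >= 2L]))[1L]
        a2 <- a
        a2[pick] <- fresh
        newc_assoc <- .assoc_score(d, setdiff(ai, pick), y, y2, dm_alpha,
                                   prior)
        newc_dep <- .dep_score(d, pick, dm_alpha)
        delta <- newc_assoc + newc_dep - cache[2L]
        n_dep_after <- length(unique(a[a >= 2L])) + 1L
        q_fwd <- 0.5 / n_subsets
        q_rev <- 0.5 / n_dep_after
        if (u_accept[it] < exp(delta) * q_rev / q_fwd) {
          a <- a2
          cache[2L] <- newc_assoc
          cache[fresh + 1L] <- newc_dep
          total <- total + delta
          accepted <- accepted + 1L
        }
      }
    } else if (move_u[it] < 0.30 && m >= 2L) {
      # pair toggle: move two markers jointly between the background and the
      # associated block (self-inverse on the same uniformly chosen pair, so
      # the proposal is symmetric); bridges the two-step valley a purely
      # epistatic pair has to cross to enter the associated block
      jk <- sample.int(m, 2L)
      both_bg <- all(a[jk] == 0L)
      both_assoc <- all(a[jk] == 1L)
      if (both_bg || both_assoc) {
        nl <- if (both_bg) 1L else 0L
        if (!(nl == 1L && sum(a == 1L) + 2L > max_block_size)) {
          a2 <- a
          a2[jk] <- nl
          newc_assoc <- .assoc_score(d, which(a2 == 1L), y, y2, dm_alpha,
                                     prior)
          newc_bg <- cache[1L] + (if (both_assoc) sum(bg_score[jk])
                                  else -sum(bg_score[jk]))
          delta <- (newc_assoc - cache[2L]) + (newc_bg - cache[1L])
          dpen <- size_penalty * (if (both_bg) 2L else -2L)
          if (u_accept[it] < exp(delta - dpen)) {
            a <- a2
            cache[1L] <- newc_bg
            cache[2L] <- newc_assoc
            total <- total + delta
            cur_pen <- cur_pen + dpen
            accepted <- accepted + 1L
          }
        }
      }
    } else if (move_u[it] < 0.35 && m >= 2L) {
      jk <- sample.int(m, 2L)
      j <- jk[1L]; k <- jk[2L]
      if (a[j] != a[k]) {
        a2 <- a
        a2[j] <- a[k]; a2[k] <- a[j]
        affected <- unique(c(a[j], a[k]))
        delta <- 0
        new_contribs <- numeric(length(affected))
        ok <- TRUE
        for (ii in seq_along(affected)) {
          l <- affected[ii]
          if (l == 0L) {
            newc <- cache[1L] +
              (if (a2[j] == 0L) bg_score[j] else 0) +
              (if (a2[k] == 0L) bg_score[k] else 0) -
              (if (a[j] == 0L) bg_score[j] else 0) -
              (if (a[k] == 0L) bg_score[k] else 0)
          } else {
            newc <- contrib(l, a2)
          }
          new_contribs[ii] <- newc
          oldc <- cache[l + 1L]
          delta <- delta +
            (if (is.na(newc)) 0 else newc) - (if (is.na(oldc)) 0 else oldc)
        }
        if (ok && u_accept[it] < exp(delta)) {  # swap keeps penalty constant
          a <- a2
          for (ii in seq_along(affected))
            cache[affected[ii] + 1L] <- new_contribs[ii]
          total <- total + delta
          accepted <- accepted + 1L
        }
      }
    } else {
      j <- sample.int(m, 1L)
      other_dep <- unique(a[-j][a[-j] >= 2L])
      # smallest unused dependency label among the other markers; labels
      # therefore stay within 2..(m + 1) and the cache stays bounded
      fresh <- setdiff(2L:(m + 1L), other_dep)[1L]
      opts <- c(0L, 1L, other_dep, fresh)
      cur_eff <- if (a[j] >= 2L && !(a[j] %in% other_dep)) fresh else a[j]
      # j alone in a dep block is the same choice as "fresh"
      opts <- setdiff(opts, cur_eff)
      nl <- if (length(opts) == 1L) opts else opts[sample.int(length(opts), 1L)]
      ol <- a[j]
      # block-size guard
      if (!(nl >= 1L && sum(a == nl) + 1L > max_block_size)) {
        a2 <- a
        a2[j] <- nl
        affected <- unique(c(ol, nl))
        delta <- 0
        new_contribs <- numeric(length(affected))
        for (ii in seq_along(affected)) {
          l <- affected[ii]
          if (l == 0L) {
            newc <- cache[1L] +
              (if (nl == 0L) bg_score[j] else 0) -
              (if (ol == 0L) bg_score[j] else 0)
          } else {
            newc <- contrib(l, a2)
          }
          new_contribs[ii] <- newc
          oldc <- cache[l + 1L]
          delta <- delta +
            (if (is.na(newc)) 0 else newc) - (if (is.na(oldc)) 0 else oldc)
        }
        new_pen <- penalty(a2)
        if (u_accept[it] < exp(delta - (new_pen - cur_pen))) {
          a <- a2
          for (ii in seq_along(affected))
            cache[affected[ii] + 1L] <- new_contribs[ii]
          total <- total + delta
          cur_pen <- new_pen
          accepted <- accepted + 1L
        }
      }
    }
    sc <- total - cur_pen
    if (sc > best$score) best <- list(assignment = a, score = sc)
    if (it > burnin) {
      ai <- which(a == 1L)
      if (length(ai)) {
        key <- paste0("A|", paste(ai, collapse = ","))
        tally[[key]] <- (if (is.null(tally[[key]])) 0L else tally[[key]]) + 1L
      }
      for (l in unique(a[a >= 2L])) {
        di <- which(a == l)
        if (length(di) >= 2L) {
          key <- paste0("D|", paste(di, collapse = ","))
          tally[[key]] <- (if (is.null(tally[[key]])) 0L else tally[[key]]) + 1L
        }
      }
      if (track_states) {
        key <- paste(.canonical_assignment(a), collapse = "")
        states[[key]] <-
          (if (is.null(states[[key]])) 0L else states[[key]]) + 1L
      }
    }
  }

  keys <- ls(tally)
  sets <- if (length(keys)) {
    idx_list <- lapply(strsplit(sub("^[AD]\\|", "", keys), ","), as.integer)
    data.frame(kind = ifelse(substr(keys, 1, 1) == "A", "associated",
                             "dependency"),
               markers = I(idx_list),
               marker_ids = I(lapply(idx_list, function(i) marker_ids[i])),
               size = lengths(idx_list),
               posterior = vapply(keys, function(k2) tally[[k2]], 0L) /
                 n_retained,
               row.names = NULL)
  } else {
    data.frame(kind = character(), markers = I(list()),
               marker_ids = I(list()), size = integer(),
               posterior = numeric())
  }
  sets <- sets[order(-sets$posterior), , drop = FALSE]
  rownames(sets) <- NULL
  groups <- sets[sets$kind == "associated" &
                   sets$posterior >= posterior_threshold & sets$size >= 2L, ,
                 drop = FALSE]
  rownames(groups) <- NULL
  best$assignment <- .canonical_assignment(best$assignment)
  out <- list(groups = groups, sets = sets, map = best,
              acceptance_rate = accepted / iterations,
              n_retained = n_retained,
              settings = list(iterations = iterations, burnin = burnin,
                              seed = seed,
                              posterior_threshold = posterior_threshold,
                              max_block_size = max_block_size,
                              dm_alpha = dm_alpha, prior = prior,
                              size_penalty = size_penalty),
              marker_ids = marker_ids)
  if (track_states) {
    sk <- ls(states)
    out$state_freq <- stats::setNames(
      vapply(sk, function(k2) states[[k2]], 0L) / n_retained, sk)
  }
  class(out) <- "epistasis_scan"
  out
}

#' @export
print.epistasis_scan <- function(x, ...) {
  cat("Bayesian partition scan over", length(x$marker_ids), "markers:",
      nrow(x$groups), "interaction group(s) at posterior >=",
      x$settings$posterior_threshold, "\n")
  if (nrow(x$groups)) {
    for (i in seq_len(nrow(x$groups)))
      cat(sprintf("  [%s] %s  posterior %.3f\n", x$groups$kind[i],
                  paste(x$groups$marker_ids[[i]], collapse = ", "),
                  x$groups$posterior[i]))
  }
  cat("  acceptance rate", sprintf("%.3f", x$acceptance_rate),
      "| retained", x$n_retained, "samples\n")
  invisible(x)
}

#' @export
summary.epistasis_scan <- function(object, n_top = 10L, ...) {
  cat("Top marker sets by posterior probability:\n")
  s <- utils::head(object$sets, n_top)
  if (nrow(s)) {
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %-10s %-30s %.3f\n", s$kind[i],
                  paste(s$marker_ids[[i]], collapse = ","), s$posterior[i]))
  }
  invisible(object$sets)
}

#' Two-locus epistasis test by fixed linear regression
#'
#' Ordinary least squares of the phenotype on
#' \code{[1, g_a, g_b, g_a * g_b]}; the reported p-value is the two-sided
#' t-test on the product term's coefficient, the classical fixed-regression
#' verification of a putative interaction.
#'
#' @param g genotype_matrix or dosage matrix.
#' @param y phenotype vector aligned to samples of \code{g}.
#' @param marker_a,marker_b marker ids (character) or column indices.
#' @return List with \code{coefficient} (interaction term, days),
#'   \code{se}, \code{t}, \code{p_value}, \code{df} and \code{degenerate}
#'   (TRUE when the design is collinear or residual variance vanishes with a
#'   non-zero coefficient; \code{p_value} is then NA).
#' @export
two_locus_test <- function(g, y, marker_a, marker_b) {
  if (inherits(g, "genotype_matrix")) {
    if (is.character(marker_a)) marker_a <- match(marker_a,
                                                  g$markers$marker_id)
    if (is.character(marker_b)) marker_b <- match(marker_b,
                                                  g$markers$marker_id)
    if (!is.null(names(y))) y <- y[rownames(g$dosages)]
    d <- g$dosages
  } else d <- g
  ga <- d[, marker_a]
  gb <- d[, marker_b]
  n <- length(y)
  if (n <= 5L) stop("need more than 5 samples")
  x <- cbind(1, ga, gb, ga * gb)
  qx <- qr(x)
  if (qx$rank < 4L)
    return(list(coefficient = NA_real_, se = NA_real_, t = NA_real_,
                p_value = NA_real_, df = n - qx$rank, degenerate = TRUE))
  xtx <- crossprod(x)
  xty <- crossprod(x, y)
  beta <- solve(xtx, xty)
  rss <- sum(y^2) - sum(beta * xty)
  df <- n - 4L
  s2 <- max(rss, 0) / df
  xtx_inv <- solve(xtx)
  coef_int <- beta[4L]
  if (s2 <= .Machine$double.eps * max(1, sum(y^2) / n)) {
    # residual variance is numerically zero
    if (abs(coef_int) < 1e-10)
      return(list(coefficient = 0, se = 0, t = 0, p_value = 1, df = df,
                  degenerate = FALSE))
    return(list(coefficient = coef_int, se = 0, t = Inf, p_value = NA_real_,
                df = df, degenerate = TRUE))
  }
  se <- sqrt(s2 * xtx_inv[4L, 4L])
  tstat <- coef_int / se
  list(coefficient = coef_int, se = se, t = tstat,
       p_value = 2 * stats::pt(-abs(tstat), df), df = df,
       degenerate = FALSE)
}

#' Pairwise two-locus p-value range of an interaction group
#'
#' Runs \code{\link{two_locus_test}} on every pair of markers in a group and
#' reports the minimum and maximum p-value, the pairwise verification that
#' accompanies each reported multilocus group. Degenerate pairs are excluded
#' with a warning. For a group of two markers the minimum equals the
#' maximum.
#'
#' @param markers marker ids (character) or column indices, length >= 2.
#' @param g genotype_matrix or dosage matrix.
#' @param y phenotype vector.
#' @return List with \code{min_p}, \code{max_p}, \code{n_pairs} (evaluated,
#'   non-degenerate) and \code{pairs} (data.frame of every tested pair).
#' @export
pairwise_p_range <- function(markers, g, y) {
  if (length(markers) < 2L) stop("a group needs at least 2 markers")
  cmb <- utils::combn(markers, 2L)
  res <- apply(cmb, 2L, function(pr) two_locus_test(g, y, pr[1L], pr[2L]))
  pairs <- data.frame(marker_a = as.character(cmb[1L, ]),
                      marker_b = as.character(cmb[2L, ]),
                      p_value = vapply(res, function(r) r$p_value, 0),
                      degenerate = vapply(res, function(r) r$degenerate,
                                          TRUE))
  if (any(pairs$degenerate))
    warning(sum(pairs$degenerate), " degenerate pair(s) excluded")
  ok <- pairs$p_value[!pairs$degenerate]
  list(min_p = if (length(ok)) min(ok) else NA_real_,
       max_p = if (length(ok)) max(ok) else NA_real_,
       n_pairs = length(ok), pairs = pairs)
}

#' Table of interaction groups with pairwise p-value ranges
#'
#' Formats an \code{\link{epistasis_scan}}'s reported groups with marker
#' coordinates, containing genes and the pairwise two-locus p-value range,
#' one row per marker, mirroring the study's interaction-group summary
#' layout.
#'
#' @param scan an \code{epistasis_scan}.
#' @param g genotype_matrix of the candidate markers.
#' @param y phenotype vector.
#' @param annotation optional gene annotation data.frame.
#' @return data.frame with columns \code{group}, \code{kind},
#'   \code{posterior}, \code{marker_id}, \code{chrom}, \code{pos},
#'   \code{gene_id}, \code{p_min}, \code{p_max}.
#' @export
interaction_table <- function(scan, g, y, annotation = NULL) {
  stopifnot(inherits(scan, "epistasis_scan"),
            inherits(g, "genotype_matrix"))
  rows <- list()
  for (i in seq_len(nrow(scan$groups))) {
    ids <- scan$groups$marker_ids[[i]]
    pr <- pairwise_p_range(ids, g, y)
    mi <- g$markers[match(ids, g$markers$marker_id), , drop = FALSE]
    gene <- rep(NA_character_, length(ids))
    if (!is.null(annotation)) {
      map <- snp_to_gene(mi, annotation)
      gene <- vapply(ids, function(id) {
        gg <- map$gene_id[map$marker_id == id]
        if (length(gg)) paste(gg, collapse = ";") else NA_character_
      }, "")
    }
    rows[[i]] <- data.frame(group = paste0("G", i),
                            kind = scan$groups$kind[i],
                            posterior = scan$groups$posterior[i],
                            marker_id = ids, chrom = mi$chrom, pos = mi$pos,
                            gene_id = gene, p_min = pr$min_p,
                            p_max = pr$max_p, row.names = NULL)
  }
  if (!length(rows))
    return(data.frame(group = character(), kind = character(),
                      posterior = numeric(), marker_id = character(),
                      chrom = character(), pos = integer(),
                      gene_id = character(), p_min = numeric(),
                      p_max = numeric()))
  do.call(rbind, rows)
}
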