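# Dissimilarity and permutation statistics: Bray-Curtis, classical-scaling
# PCoA, ANOSIM and PERMANOVA, each written from its defining formula.
# Permutation p-values include the observed statistic (+1/+1), so
# p >= 1/(B+1); exact = TRUE replaces Monte-Carlo permutations with
# exhaustive enumeration of all distinct labelings (small designs only).

#' Bray-Curtis dissimilarity on relative abundances
#'
#' d(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i) over OTUs, computed after
#' total-sum scaling of each sample, so entries lie in \[0, 1\].
#'
#' @param counts OTU x sample count matrix (every sample total > 0).
#' @return symmetric sample x sample distance matrix, zero diagonal.
#' @export
bray_curtis <- function(counts) {
  rel <- relative_abundance(counts)
  # on relative abundances the denominator is 2, so BC = Manhattan / 2
  d <- as.matrix(stats::dist(t(rel), method = "manhattan")) / 2
  diag(d) <- 0
  d
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers -d^2/2 and eigendecomposes it. Only axes with positive
#' eigenvalues carry coordinates; negative eigenvalues are reported.
#'
#' @param d symmetric distance matrix.
#' @param n_axes number of axes to return (default 2).
#' @return object of class `rhizonet_pcoa`: list with `coordinates`
#'   (sample x axis, centered), `eigenvalues` (all, non-increasing),
#'   `proportion_explained` (relative to the positive eigenvalue total)
#'   and `truncated` (TRUE when fewer positive axes exist than requested).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) {
    return(structure(list(coordinates = matrix(0, n, 0),
                          eigenvalues = numeric(0),
                          proportion_explained = numeric(0),
                          truncated = FALSE),
                     class = "rhizonet_pcoa"))
  }
  a <- -0.5 * d^2
  b <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen(b, symmetric = TRUE)
  eig <- e$values
  pos <- which(eig > max(eig[1], 0) * 1e-12 & eig > 0)
  k <- min(n_axes, length(pos))
  truncated <- n_axes > length(pos)
  coords <- if (k > 0) {
    e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
      diag(sqrt(eig[pos[seq_len(k)]]), k)
  } else matrix(0, n, 0)
  rownames(coords) <- rownames(d)
  if (k > 0) colnames(coords) <- paste0("PCo", seq_len(k))
  prop <- if (length(pos)) eig[pos[seq_len(k)]] / sum(eig[pos]) else numeric(0)
  structure(list(coordinates = coords, eigenvalues = eig,
                 proportion_explained = prop, truncated = truncated),
            class = "rhizonet_pcoa")
}

# pair index helpers ---------------------------------------------------

pair_indices <- function(n) {
  j <- rep(seq_len(n), each = n)
  i <- rep(seq_len(n), times = n)
  keep <- i < j
  list(i = i[keep], j = j[keep])
}

check_grouping <- function(d, grouping) {
  d <- as.matrix(d)
  if (nrow(d) != length(grouping)) {
    stopf("grouping length (%d) does not match distance matrix (%d)",
          length(grouping), nrow(d))
  }
  g <- as.character(grouping)
  sizes <- table(g)
  if (length(sizes) < 2) stopf("need at least 2 groups")
  if (any(sizes < 2)) {
    stopf("group(s) of size 1: %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  g
}

# All distinct arrangements of a label multiset, as a list of vectors.
multiset_permutations <- function(labels, max_n = 2e5) {
  counts <- table(labels)
  total <- factorial(length(labels)) / prod(factorial(counts))
  if (total > max_n) {
    stopf("exact enumeration infeasible: %g distinct labelings", total)
  }
  lev <- names(counts)
  recurse <- function(remaining) {
    if (sum(remaining) == 0) return(list(character(0)))
    out <- list()
    for (k in seq_along(lev)) {
      if (remaining[k] > 0) {
        rem <- remaining
        rem[k] <- rem[k] - 1
        for (tail in recurse(rem)) {
          out[[length(out) + 1L]] <- c(lev[k], tail)
        }
      }
    }
    out
  }
  recurse(as.vector(counts))
}

#' Analysis of similarities (ANOSIM)
#'
#' R = (mean rank of between-group distances - mean rank of within-group
#' distances) / (n(n-1)/4), with average ranks for ties. Significance by
#' label permutation: p = (1 + #\{permuted R >= observed\}) / (1 + B), or by
#' exhaustive enumeration of all distinct labelings when `exact = TRUE`
#' (then p is the exact proportion of labelings with R >= observed).
#'
#' @param d symmetric distance matrix.
#' @param grouping group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_permutations number of random permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param exact enumerate all distinct labelings instead of sampling.
#' @return object of class `rhizonet_anosim`: list(R, p, n_permutations).
#' @export
anosim <- function(d, grouping, n_permutations = 999, seed = 1,
                   exact = FALSE) {
  d <- as.matrix(d)
  g <- check_grouping(d, grouping)
  n <- nrow(d)
  px <- pair_indices(n)
  r <- rank(d[cbind(px$i, px$j)])
  denom <- n * (n - 1) / 4
  stat <- function(gg) {
    w <- gg[px$i] == gg[px$j]
    (mean(r[!w]) - mean(r[w])) / denom
  }
  R_obs <- stat(g)
  if (exact) {
    perms <- multiset_permutations(g)
    Rs <- vapply(perms, stat, numeric(1))
    p <- mean(Rs >= R_obs - 1e-12)
    n_perm <- length(perms)
  } else {
    R_perm <- with_seed(seed, vapply(seq_len(n_permutations), function(b) {
      stat(sample(g))
    }, numeric(1)))
    p <- (1 + sum(R_perm >= R_obs - 1e-12)) / (1 + n_permutations)
    n_perm <- n_permutations
  }
  structure(list(R = R_obs, p = p, n_permutations = n_perm, exact = exact),
            class = "rhizonet_anosim")
}

#' @export
print.rhizonet_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s, %d labelings)\n", x$R, x$p,
              if (x$exact) "exact" else "permutation", x$n_permutations))
  invisible(x)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor partitioning of a distance matrix: SS_total =
#' sum over pairs of d^2 / n, SS_within = sum over within-group pairs of
#' d^2 / n_g, pseudo-F = (SS_between/(a-1)) / (SS_within/(n-a)),
#' R^2 = SS_between / SS_total. Permutation p as in [anosim()] with
#' pseudo-F as the test statistic.
#'
#' @inheritParams anosim
#' @return object of class `rhizonet_permanova`:
#'   list(pseudo_F, R2, p, n_permutations).
#' @export
permanova <- function(d, grouping, n_permutations = 999, seed = 1,
                      exact = FALSE) {
  d <- as.matrix(d)
  g <- check_grouping(d, grouping)
  n <- nrow(d)
  a <- length(unique(g))
  px <- pair_indices(n)
  d2 <- d[cbind(px$i, px$j)]^2
  ss_total <- sum(d2) / n
  ss_within <- function(gg) {
    gi <- gg[px$i]
    w <- gi == gg[px$j]
    if (!any(w)) return(0)
    sums <- rowsum(d2[w], gi[w])
    sizes <- table(gg)[rownames(sums)]
    sum(sums[, 1] / as.vector(sizes))
  }
  stat <- function(gg) {
    ssw <- ss_within(gg)
    ssb <- ss_total - ssw
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  F_obs <- stat(g)
  ssw_obs <- ss_within(g)
  R2 <- (ss_total - ssw_obs) / ss_total
  if (exact) {
    perms <- multiset_permutations(g)
    Fs <- vapply(perms, stat, numeric(1))
    p <- mean(Fs >= F_obs - 1e-12)
    n_perm <- length(perms)
  } else {
    F_perm <- with_seed(seed, vapply(seq_len(n_permutations), function(b) {
      stat(sample(g))
    }, numeric(1)))
    p <- (1 + sum(F_perm >= F_obs - 1e-12)) / (1 + n_permutations)
    n_perm <- n_permutations
  }
  structure(list(pseudo_F = F_obs, R2 = R2, p = p,
                 n_permutations = n_perm, exact = exact),
            class = "rhizonet_permanova")
}

#' @export
print.rhizonet_permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4f, R2 = %.4f, p = %.4g (%s, %d labelings)\n",
    x$pseudo_F, x$R2, x$p,
    if (x$exact) "exact" else "permutation", x$n_permutations))
  invisible(x)
}

#' Per-factor community dissimilarity tests
#'
#' Runs ANOSIM and PERMANOVA on Bray-Curtis distances separately for each
#' design factor, mirroring a per-factor results table.
#'
#' @param counts OTU x sample count matrix.
#' @param metadata validated sample metadata.
#' @param factors metadata columns to test.
#' @param n_permutations permutations per test.
#' @param seed RNG seed.
#' @return data.frame: factor, anosim_R, anosim_p, permanova_F,
#'   permanova_R2, permanova_p.
#' @export
community_tests <- function(counts, metadata,
                            factors = c("treatment", "compartment", "stage"),
                            n_permutations = 999, seed = 1) {
  md <- metadata[match(colnames(counts), metadata$sample_id), ]
  d <- bray_curtis(counts)
  rows <- lapply(factors, function(f) {
    an <- anosim(d, md[[f]], n_permutations, seed)
    pm <- permanova(d, md[[f]], n_permutations, seed)
    data.frame(factor = f, anosim_R = an$R, anosim_p = an$p,
               permanova_F = pm$pseudo_F, permanova_R2 = pm$R2,
               permanova_p = pm$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
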