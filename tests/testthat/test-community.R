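# Bray-Curtis, PCoA, ANOSIM, PERMANOVA: closed-form examples, exhaustive
# enumeration against an independent oracle, and cross-checks with vegan.

test_that("bray_curtis matches its defining formula", {
  counts <- cbind(a = c(1L, 1L, 0L), b = c(0L, 1L, 1L), c = c(1L, 1L, 0L))
  rownames(counts) <- paste0("o", 1:3)
  d <- bray_curtis(counts)
  expect_equal(d["a", "c"], 0)            # identical samples
  expect_equal(d["a", "b"], 0.5)          # (1/3,1/3,0) vs (0,1/3,1/3)
  disjoint <- cbind(a = c(2L, 3L, 0L, 0L), b = c(0L, 0L, 1L, 5L))
  rownames(disjoint) <- paste0("o", 1:4)
  expect_equal(bray_curtis(disjoint)["a", "b"], 1)  # no shared OTUs
  zero <- cbind(a = c(1L, 1L), b = c(0L, 0L))
  rownames(zero) <- paste0("o", 1:2)
  expect_error(bray_curtis(zero), "b")
})

test_that("bray_curtis agrees with vegan::vegdist on random tables", {
  withr::with_seed(11, {
    counts <- matrix(rpois(20 * 8, 15), 20,
                     dimnames = list(paste0("o", 1:20), paste0("s", 1:8)))
    rel <- relative_abundance(counts)
    expect_equal(as.numeric(as.dist(bray_curtis(counts))),
                 as.numeric(vegan::vegdist(t(rel), method = "bray")),
                 tolerance = 1e-12)
  })
})

test_that("pcoa handles symmetric and degenerate inputs", {
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  ord <- pcoa(d3, n_axes = 2)
  pos <- ord$eigenvalues[ord$eigenvalues > 1e-10]
  expect_equal(pos[1], pos[2], tolerance = 1e-10)  # two equal axes
  cd <- as.matrix(dist(ord$coordinates))
  expect_equal(max(cd) - min(cd[cd > 0]), 0, tolerance = 1e-10)

  single <- matrix(0, 1, 1, dimnames = list("a", "a"))
  ord1 <- pcoa(single)
  expect_equal(ncol(ord1$coordinates), 0)
  expect_length(ord1$eigenvalues, 0)
})

test_that("pcoa recovers Euclidean configurations", {
  withr::with_seed(5, {
    pts <- matrix(rnorm(12 * 3), 12, 3)
    d <- as.matrix(dist(pts))
    ord <- pcoa(d, n_axes = 3)
    expect_equal(as.numeric(dist(ord$coordinates)), as.numeric(dist(pts)),
                 tolerance = 1e-9)
    expect_equal(unname(colMeans(ord$coordinates)), rep(0, 3),
                 tolerance = 1e-9)
    # 1-D configurations: first axis reproduces the line up to sign/scale
    line <- matrix(c(0, 1, 2, 5, 9), ncol = 1)
    orl <- pcoa(as.matrix(dist(line)), n_axes = 1)
    expect_equal(as.numeric(dist(orl$coordinates[, 1])),
                 as.numeric(dist(line)), tolerance = 1e-9)
    # agreement with classical scaling in base R
    cs <- cmdscale(d, k = 3, eig = TRUE)
    expect_equal(abs(ord$coordinates), abs(cs$points),
                 tolerance = 1e-8, ignore_attr = TRUE)
  })
})

test_that("anosim attains its extreme values", {
  d <- matrix(2, 6, 6) - 2 * diag(6)   # constant distances
  g <- rep(c("A", "B"), each = 3)
  res <- anosim(d, g, n_permutations = 99, seed = 1)
  expect_equal(res$R, 0)
  expect_equal(res$p, 1)

  # complete separation: every between-group distance > every within
  d2 <- matrix(5, 6, 6)
  d2[1:3, 1:3] <- 1; d2[4:6, 4:6] <- 1; diag(d2) <- 0
  expect_equal(anosim(d2, g, n_permutations = 99, seed = 1)$R, 1)

  expect_error(anosim(d, c("A", rep("B", 5)), seed = 1), "size 1")
})

test_that("anosim exact p equals exhaustive enumeration (vegan oracle)", {
  withr::with_seed(21, {
    pts <- matrix(rnorm(6 * 2), 6, 2)
    d <- as.matrix(dist(pts))
    g <- rep(c("A", "B"), each = 3)
    mine <- anosim(d, g, exact = TRUE)
    oracle <- enumeration_oracle(d, g, "anosim")
    expect_equal(mine$n_permutations, 20)
    expect_equal(mine$R, unname(oracle$obs), tolerance = 1e-12)
    expect_equal(mine$p, oracle$p)

    pts8 <- matrix(rnorm(8 * 2), 8, 2)
    d8 <- as.matrix(dist(pts8))
    g8 <- rep(c("A", "B"), each = 4)
    expect_equal(anosim(d8, g8, exact = TRUE)$p,
                 enumeration_oracle(d8, g8, "anosim")$p)
  })
})

test_that("permanova partitions sums of squares correctly", {
  # duplicated identical samples: within-group distances 0 -> R2 = 1
  d <- matrix(0, 6, 6)
  d[1:3, 4:6] <- 1; d[4:6, 1:3] <- 1
  g <- rep(c("A", "B"), each = 3)
  res <- permanova(d, g, n_permutations = 99, seed = 1)
  expect_equal(res$R2, 1)

  withr::with_seed(22, {
    pts <- matrix(rnorm(8 * 2), 8, 2)
    d8 <- as.matrix(dist(pts))
    g8 <- rep(c("A", "B"), each = 4)
    mine <- permanova(d8, g8, exact = TRUE)
    oracle <- enumeration_oracle(d8, g8, "permanova")
    expect_equal(mine$pseudo_F, oracle$obs, tolerance = 1e-10)
    expect_equal(mine$p, oracle$p)
    # statistic and R2 agree with vegan::adonis2
    ad <- vegan::adonis2(as.dist(d8) ~ gg, data = data.frame(gg = g8),
                         permutations = 99)
    expect_equal(mine$pseudo_F, as.numeric(ad$F[1]), tolerance = 1e-10)
    expect_equal(mine$R2, as.numeric(ad$R2[1]), tolerance = 1e-10)
  })
})

test_that("permanova on Euclidean distances equals the MANOVA trace F", {
  withr::with_seed(25, {
    pts <- matrix(rnorm(12 * 2), 12, 2)
    g <- rep(c("A", "B", "C"), each = 4)
    d <- as.matrix(dist(pts))
    mine <- permanova(d, g, n_permutations = 9, seed = 1)
    # classical one-way multivariate partitioning: traces of the
    # between- and within-group cross-product matrices
    grand <- colMeans(pts)
    ssb <- sum(vapply(unique(g), function(lv) {
      m <- colMeans(pts[g == lv, , drop = FALSE])
      sum(g == lv) * sum((m - grand)^2)
    }, numeric(1)))
    ssw <- sum(vapply(unique(g), function(lv) {
      x <- pts[g == lv, , drop = FALSE]
      sum(sweep(x, 2, colMeans(x))^2)
    }, numeric(1)))
    f_classical <- (ssb / 2) / (ssw / 9)
    expect_equal(mine$pseudo_F, f_classical, tolerance = 1e-10)
    expect_equal(mine$R2, ssb / (ssb + ssw), tolerance = 1e-10)
  })
})

test_that("anosim R is invariant to monotone transforms of distance", {
  withr::with_seed(23, {
    pts <- matrix(rnorm(10 * 2), 10, 2)
    d <- as.matrix(dist(pts))
    g <- rep(c("A", "B"), each = 5)
    r1 <- anosim(d, g, n_permutations = 49, seed = 2)$R
    r2 <- anosim(sqrt(d), g, n_permutations = 49, seed = 2)$R
    r3 <- anosim(d^3, g, n_permutations = 49, seed = 2)$R
    expect_equal(r1, r2)
    expect_equal(r1, r3)
  })
})

test_that("permutation p-values are valid and calibrated under the null", {
  withr::with_seed(24, {
    ps <- vapply(1:40, function(i) {
      pts <- matrix(rnorm(12 * 2), 12, 2)
      d <- as.matrix(dist(pts))
      g <- sample(rep(c("A", "B"), each = 6))
      permanova(d, g, n_permutations = 49, seed = i)$p
    }, numeric(1))
    expect_true(all(ps >= 1 / 50 & ps <= 1))
    # null p-values roughly uniform: rejection rate at 0.2 near 0.2
    expect_lt(abs(mean(ps <= 0.2) - 0.2), 0.17)
  })
})

test_that("community_tests detects planted treatment structure", {
  sim <- generate_otu_table(small_config(seed = 12))
  ct <- community_tests(sim$counts[, 1:120], sim$metadata[1:120, ],
                        factors = c("treatment", "compartment"),
                        n_permutations = 99, seed = 1)
  expect_equal(nrow(ct), 2)
  trt <- ct[ct$factor == "treatment", ]
  expect_lte(trt$anosim_p, 0.05)
  expect_lte(trt$permanova_p, 0.05)
  expect_true(all(ct$permanova_R2 > 0 & ct$permanova_R2 < 1))
})
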