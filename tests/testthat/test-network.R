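# Spearman matrices, BH adjustment, thresholded network construction,
# topology metrics and Erdos-Renyi null ensembles.

test_that("spearman_matrix reproduces rank-correlation closed forms", {
  x <- rbind(a = 1:5, b = c(2, 1, 4, 3, 5), c = 5:1)
  sp <- spearman_matrix(x)
  expect_equal(sp$rho["a", "b"], 0.8)          # 1 - 6*4/(5*24)
  expect_equal(sp$rho["a", "c"], -1)
  expect_equal(sp$rho["b", "b"], 1)
  # p from the t approximation, cross-checked against cor.test
  ct <- cor.test(x["a", ], x["b", ], method = "spearman")
  expect_equal(sp$p["a", "b"],
               2 * pt(-abs(0.8 * sqrt(3 / (1 - 0.64))), df = 3))
  expect_lt(abs(sp$p["a", "b"] - ct$p.value), 0.05)
})

test_that("constant OTUs are excluded and small n rejected", {
  x <- rbind(a = c(1, 2, 3, 4), b = rep(2, 4), c = c(4, 3, 2, 1))
  sp <- spearman_matrix(x)
  expect_equal(sp$excluded, "b")
  expect_equal(rownames(sp$rho), c("a", "c"))
  expect_error(spearman_matrix(x[, 1:3]), ">= 4 samples")
})

test_that("adjust_fdr performs BH step-up", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_fdr(0.05), 0.05)
  expect_length(adjust_fdr(numeric(0)), 0)
  withr::with_seed(41, {
    p <- runif(100)
    q <- adjust_fdr(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    # monotone after step-up smoothing
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  })
})

test_that("build_network equals a brute-force double loop on 50 OTUs", {
  withr::with_seed(42, {
    n <- 50
    x <- matrix(rnorm(n * 30), n, dimnames = list(paste0("o", 1:n), NULL))
    # plant a few strong pairs
    for (k in 1:5) x[2 * k, ] <- x[2 * k - 1, ] * (-1)^k + rnorm(30, 0, 0.3)
    sp <- spearman_matrix(x)
    tax <- data.frame(otu_id = rownames(sp$rho),
                      phylum = rep(c("P1", "P2"), length.out = n))
    net <- build_network(sp$rho, sp$p, tax, rho_min = 0.7, q_max = 0.05)

    # independent brute force: BH by hand over all pairs, double loop
    ids <- rownames(sp$rho)
    m <- choose(length(ids), 2)
    pv <- c(); pairs <- list()
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i < j) {
          pv <- c(pv, sp$p[i, j])
          pairs[[length(pairs) + 1]] <- c(i, j)
        }
      }
    }
    o <- order(pv)
    qv <- numeric(m)
    qv[o] <- rev(cummin(rev(pv[o] * m / seq_len(m))))
    expected <- character(0)
    for (k in seq_len(m)) {
      i <- pairs[[k]][1]; j <- pairs[[k]][2]
      if (abs(sp$rho[i, j]) > 0.7 && qv[k] < 0.05) {
        expected <- c(expected, paste(ids[i], ids[j]))
      }
    }
    el <- igraph::as_data_frame(net, what = "edges")
    ei <- match(el$from, ids); ej <- match(el$to, ids)
    got <- paste(ids[pmin(ei, ej)], ids[pmax(ei, ej)])
    expect_setequal(got, expected)
    expect_gt(length(expected), 0)
    # negative edges retained with their sign
    expect_true(any(el$sign == "negative"))
    expect_true(all((el$rho > 0) == (el$sign == "positive")))
  })
})

test_that("edge criterion is symmetric in OTU ordering", {
  withr::with_seed(43, {
    x <- matrix(rnorm(20 * 30), 20,
                dimnames = list(paste0("o", 1:20), NULL))
    x[2, ] <- x[1, ] + rnorm(30, 0, 0.2)
    tax <- data.frame(otu_id = rownames(x), phylum = "P1")
    sp <- spearman_matrix(x)
    net1 <- build_network(sp$rho, sp$p, tax)
    perm <- sample(20)
    sp2 <- spearman_matrix(x[perm, ])
    net2 <- build_network(sp2$rho, sp2$p, tax)
    e1 <- igraph::as_data_frame(net1); e2 <- igraph::as_data_frame(net2)
    key <- function(e) sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
    expect_equal(key(e1), key(e2))
  })
})

test_that("edge counts respond monotonically to both thresholds", {
  withr::with_seed(44, {
    x <- matrix(rnorm(30 * 30), 30,
                dimnames = list(paste0("o", 1:30), NULL))
    for (k in 1:8) x[k + 10, ] <- x[k, ] + rnorm(30, 0, k / 4)
    sp <- spearman_matrix(x)
    tax <- data.frame(otu_id = rownames(sp$rho), phylum = "P1")
    n_edges <- function(rho_min, q_max) {
      igraph::ecount(build_network(sp$rho, sp$p, tax, rho_min, q_max))
    }
    expect_gte(n_edges(0.5, 0.05), n_edges(0.7, 0.05))
    expect_gte(n_edges(0.7, 0.05), n_edges(0.9, 0.05))
    expect_lte(n_edges(0.7, 0.01), n_edges(0.7, 0.05))
    # all q = 1 -> empty network
    p1 <- sp$p; p1[] <- 1
    expect_equal(igraph::ecount(build_network(sp$rho, p1, tax)), 0)
    # missing taxonomy errors with the OTU named
    expect_error(build_network(sp$rho, sp$p, tax[-1, ]), tax$otu_id[1])
  })
})

test_that("topology matches closed forms on canonical graphs", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- letters[1:3]
  tp <- topology(tri)
  expect_equal(tp$avg_clustering, 1)
  expect_equal(tp$avg_path_length, 1)

  path3 <- igraph::make_graph(~ a - b, b - c)
  tp3 <- topology(path3)
  expect_equal(tp3$avg_clustering, 0)
  expect_equal(tp3$avg_path_length, 4 / 3)   # distances 1, 1, 2

  two_tri <- igraph::disjoint_union(igraph::make_full_graph(3),
                                    igraph::make_full_graph(3))
  igraph::V(two_tri)$name <- letters[1:6]
  expect_equal(topology(two_tri)$modularity, 0.5)  # 2 * (0.5 - 0.25)

  expect_error(topology(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})

test_that("random ensembles behave at the degenerate extremes", {
  rn <- random_network_ensemble(3, 3, n_reps = 20, seed = 1)
  expect_equal(unname(rn$sd), rep(0, 3))     # unique graph: the triangle
  expect_equal(unname(rn$mean[["avg_clustering"]]), 1)

  rn0 <- random_network_ensemble(5, 0, n_reps = 5, seed = 1)
  expect_true(rn0$degenerate)
  expect_true(is.na(rn0$mean[["avg_path_length"]]))
  expect_equal(unname(rn0$mean[["modularity"]]), 0)

  expect_error(random_network_ensemble(3, 5), "infeasible")
})

test_that("planted two-clique graphs exceed the random-modularity band", {
  cl <- igraph::disjoint_union(igraph::make_full_graph(10),
                               igraph::make_full_graph(10))
  cl <- igraph::add_edges(cl, c(1, 11))
  igraph::V(cl)$name <- paste0("n", 1:20)
  obs <- topology(cl)$modularity
  rn <- random_network_ensemble(20, igraph::ecount(cl), n_reps = 100,
                                seed = 7)
  expect_gt(obs, rn$mean[["modularity"]] + 2 * rn$sd[["modularity"]])
})

test_that("null synthetic data yields almost no edges (FDR control)", {
  fracs <- vapply(1:5, function(sd) {
    sim <- generate_otu_table(null_config(seed = sd))
    catalog <- build_selection_catalog(sim$counts, sim$metadata, seed = 1)
    cc <- catalog[catalog$treatment == "CK" & catalog$compartment == "B", ]
    sel <- cc$otu_id[cc$retained & (!is.na(cc$enriched_stage) |
                                      !is.na(cc$inhibited_stage))]
    md <- sim$metadata
    cols <- md$sample_id[md$treatment == "CK" & md$compartment == "B"]
    rel <- relative_abundance(sim$counts[, cols])
    sp <- spearman_matrix(rel[intersect(sel, rownames(rel)), ])
    net <- build_network(sp$rho, sp$p,
                         data.frame(otu_id = rownames(sp$rho),
                                    phylum = "P1"))
    igraph::ecount(net) / choose(nrow(sp$rho), 2)
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})
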