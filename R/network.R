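# Signed Spearman co-occurrence networks over selected sub-communities:
# rank correlation matrices with t-approximation p-values, BH edge FDR,
# thresholded graph construction and topology vs Erdos-Renyi null
# ensembles.

#' Spearman correlation matrix with p-values
#'
#' rho is Pearson correlation of average-ranked values per OTU across the
#' stratum's samples; the two-sided p-value uses the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom.
#' Constant OTUs have undefined rho and are excluded from the result.
#'
#' @param x OTU x sample matrix (counts or relative abundances) for the
#'   selected sub-community of one stratum; needs >= 4 samples.
#' @return list with `rho` and `p` matrices over the non-constant OTUs,
#'   and `excluded` (ids of constant OTUs).
#' @export
spearman_matrix <- function(x) {
  n <- ncol(x)
  if (n < 4) stopf("spearman_matrix: need >= 4 samples, got %d", n)
  keep <- apply(x, 1, function(v) length(unique(v)) > 1)
  excluded <- rownames(x)[!keep]
  x <- x[keep, , drop = FALSE]
  ranks <- t(apply(x, 1, rank))
  rho <- cor(t(ranks))
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[p > 1] <- 1
  p[p <= 0] <- .Machine$double.xmin
  diag(p) <- 1
  list(rho = rho, p = p, excluded = excluded)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment over a family of p-values
#' (all unique OTU pairs of a stratum when applied to a network).
#'
#' @param p vector of p-values in (0, 1\].
#' @return vector of q-values (monotone, <= 1).
#' @export
adjust_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  p.adjust(p, method = "BH")
}

#' Build a signed co-occurrence network
#'
#' Retains the edge (i, j) iff |rho_ij| > `rho_min` (or signed
#' rho_ij > rho_min when `abs_rho = FALSE`) and q_ij < `q_max`, where q is
#' the BH adjustment of all unique-pair p-values. Nodes with no retained
#' edge are dropped; each node carries its phylum.
#'
#' @param rho,p aligned square matrices from [spearman_matrix()].
#' @param taxonomy data.frame with otu_id and phylum covering all OTUs.
#' @param rho_min correlation threshold (default 0.7).
#' @param q_max FDR threshold (default 0.05).
#' @param abs_rho threshold |rho| (default TRUE) rather than signed rho.
#' @return igraph undirected graph; edge attributes rho, p, q, sign;
#'   node attributes name (otu_id), phylum.
#' @export
build_network <- function(rho, p, taxonomy, rho_min = 0.7, q_max = 0.05,
                          abs_rho = TRUE) {
  stopifnot(identical(dim(rho), dim(p)))
  ids <- rownames(rho)
  miss <- setdiff(ids, taxonomy$otu_id)
  if (length(miss)) {
    stopf("taxonomy is missing OTU(s): %s", paste(miss, collapse = ", "))
  }
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  pv <- p[ut]
  qv <- adjust_fdr(pv)
  rv <- rho[ut]
  keep <- if (abs_rho) abs(rv) > rho_min else rv > rho_min
  keep <- keep & qv < q_max
  edges <- data.frame(
    from = ids[ut[keep, 1]], to = ids[ut[keep, 2]],
    rho = rv[keep], p = pv[keep], q = qv[keep],
    sign = ifelse(rv[keep] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  igraph::V(g)$phylum <-
    taxonomy$phylum[match(nodes, taxonomy$otu_id)]
  g
}

#' Topology of a co-occurrence network
#'
#' Average local clustering coefficient (nodes of degree < 2 contribute
#' 0), average shortest-path length over unordered node pairs of the
#' largest connected component, and the modularity Q of
#' [detect_modules()]'s partition on the sign-blind unweighted skeleton.
#'
#' @param net nonempty igraph network.
#' @return list: avg_clustering, avg_path_length, modularity, n_nodes,
#'   n_edges.
#' @export
topology <- function(net) {
  if (igraph::vcount(net) == 0) stopf("topology: empty network")
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  comp <- igraph::components(net)
  giant <- igraph::induced_subgraph(
    net, which(comp$membership == which.max(comp$csize)))
  apl <- if (igraph::vcount(giant) > 1) {
    igraph::mean_distance(giant, directed = FALSE)
  } else NA_real_
  mods <- detect_modules(net)
  q <- igraph::modularity(net, mods)
  list(avg_clustering = mean(cc), avg_path_length = apl,
       modularity = q, n_nodes = igraph::vcount(net),
       n_edges = igraph::ecount(net))
}

#' Topology distribution of Erdos-Renyi random networks
#'
#' Draws `n_reps` G(n, m) graphs with the observed node and edge counts
#' and summarizes each topology metric by mean and sd.
#'
#' @param n_nodes,n_edges size of each random graph.
#' @param n_reps ensemble size (default 100).
#' @param seed RNG seed.
#' @return list: per-metric `mean` and `sd` (named vectors over
#'   avg_clustering, avg_path_length, modularity), plus `n_reps`; when
#'   n_edges = 0, path length is NA and flagged via `degenerate = TRUE`.
#' @export
random_network_ensemble <- function(n_nodes, n_edges, n_reps = 100,
                                    seed = 1) {
  if (n_edges > n_nodes * (n_nodes - 1) / 2 || n_edges < 0) {
    stopf("infeasible edge count %d for %d nodes", n_edges, n_nodes)
  }
  metrics <- with_seed(seed, {
    t(vapply(seq_len(n_reps), function(b) {
      g <- igraph::sample_gnm(n_nodes, n_edges)
      if (n_edges == 0) {
        c(avg_clustering = 0, avg_path_length = NA_real_, modularity = 0)
      } else {
        tp <- topology(g)
        c(avg_clustering = tp$avg_clustering,
          avg_path_length = tp$avg_path_length,
          modularity = tp$modularity)
      }
    }, numeric(3)))
  })
  list(mean = colMeans(metrics),
       sd = apply(metrics, 2, sd),
       n_reps = n_reps, degenerate = n_edges == 0)
}

#' Build the network for one (treatment, compartment) stratum
#'
#' Restricts the count table to the stratum's samples and its temporally
#' specifically-selected OTUs (retained, with an enriched or inhibited
#' stage), converts to relative abundances, and applies
#' [spearman_matrix()] + [build_network()].
#'
#' @param counts OTU x sample count matrix.
#' @param metadata validated sample metadata.
#' @param catalog selection catalog from [build_selection_catalog()].
#' @param taxonomy taxonomy data.frame.
#' @param treatment,compartment the stratum.
#' @inheritParams build_network
#' @return igraph network (possibly empty).
#' @export
stratum_network <- function(counts, metadata, catalog, taxonomy,
                            treatment, compartment, rho_min = 0.7,
                            q_max = 0.05, abs_rho = TRUE) {
  cc <- catalog[catalog$treatment == treatment &
                  catalog$compartment == compartment, ]
  sel <- cc$otu_id[cc$retained &
                     (!is.na(cc$enriched_stage) | !is.na(cc$inhibited_stage))]
  samples <- stratum_samples(metadata, treatment, compartment)
  rel <- relative_abundance(counts[, samples, drop = FALSE])
  sub <- rel[intersect(sel, rownames(rel)), , drop = FALSE]
  if (nrow(sub) < 2) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  sp <- spearman_matrix(sub)
  build_network(sp$rho, sp$p, taxonomy, rho_min, q_max, abs_rho)
}
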