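# Module detection, within-module degree z / among-module participation c
# (Guimera-Amaral roles), keystone calling, keystone sub-networks and
# inter-/intra-phylum negative-correlation proportions.

#' Detect network modules
#'
#' Greedy modularity maximization (fast-greedy agglomeration) on the
#' sign-blind, unweighted skeleton. Deterministic; singleton components
#' form their own modules.
#'
#' @param net nonempty igraph network.
#' @param seed unused (the greedy algorithm is deterministic); kept so
#'   callers can thread one seed through the pipeline.
#' @return named integer vector: node -> module id.
#' @export
detect_modules <- function(net, seed = 1) {
  if (igraph::vcount(net) == 0) stopf("detect_modules: empty network")
  # sign-blind unweighted skeleton: drop any weight attribute and
  # parallel edges before agglomeration
  skeleton <- igraph::simplify(net)
  if ("weight" %in% igraph::edge_attr_names(skeleton)) {
    skeleton <- igraph::delete_edge_attr(skeleton, "weight")
  }
  cl <- igraph::cluster_fast_greedy(skeleton)
  m <- setNames(as.integer(igraph::membership(cl)),
                igraph::V(skeleton)$name)
  # guard against floating-point ties in the greedy merge sequence: if
  # the connected-component partition scores at least as well, prefer it
  # (it is the coarsest optimum, e.g. one module per clique component)
  comp <- setNames(as.integer(igraph::components(skeleton)$membership),
                   igraph::V(skeleton)$name)
  if (igraph::modularity(skeleton, comp) >=
      igraph::modularity(skeleton, m) - 1e-12) {
    m <- comp
  }
  m
}

#' Within-module degree z and among-module participation c
#'
#' z_i = (k_i,within - mean(k_within over i's module)) / sd(...), with
#' z = 0 when the module sd is 0; c_i = 1 - sum_m (k_i,m / k_i)^2 over
#' modules m (participation coefficient). Isolated nodes get z = 0, c = 0.
#'
#' @param net igraph network.
#' @param modules named membership vector from [detect_modules()].
#' @return data.frame: otu_id, module, degree, z, c.
#' @export
node_roles <- function(net, modules) {
  nodes <- igraph::V(net)$name
  if (!all(nodes %in% names(modules))) {
    stopf("modules do not cover all network nodes")
  }
  mod <- modules[nodes]
  adj <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  adj <- (adj != 0) * 1
  deg <- rowSums(adj)
  mods <- sort(unique(mod))
  # k_i,m: edges from node i into module m
  k_im <- vapply(mods, function(m) {
    cols <- which(mod == m)
    rowSums(adj[, cols, drop = FALSE])
  }, numeric(length(nodes)))
  if (is.null(dim(k_im))) k_im <- matrix(k_im, nrow = length(nodes))
  k_within <- k_im[cbind(seq_along(nodes), match(mod, mods))]
  z <- numeric(length(nodes))
  for (m in mods) {
    idx <- which(mod == m)
    mu <- mean(k_within[idx])
    s <- sd(k_within[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (k_within[idx] - mu) / s
  }
  c_score <- ifelse(deg > 0, 1 - rowSums((k_im / pmax(deg, 1))^2), 0)
  data.frame(otu_id = nodes, module = as.integer(mod),
             degree = as.numeric(deg), z = z, c = as.numeric(c_score),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call keystone taxa from role scores
#'
#' A node is a keystone iff c > `c_threshold` OR z > `z_threshold`
#' (inclusive-or), or both when `require_both = TRUE`.
#'
#' @param scores data.frame from [node_roles()].
#' @param c_threshold participation threshold (default 0.6).
#' @param z_threshold within-module degree z threshold (default 2.5).
#' @param require_both demand both criteria (default FALSE).
#' @return character vector of keystone otu_ids.
#' @export
identify_keystones <- function(scores, c_threshold = 0.6,
                               z_threshold = 2.5, require_both = FALSE) {
  hit <- if (require_both) {
    scores$c > c_threshold & scores$z > z_threshold
  } else {
    scores$c > c_threshold | scores$z > z_threshold
  }
  scores$otu_id[hit]
}

#' Induced sub-network of keystone taxa
#'
#' @param net igraph network.
#' @param keystones node names (must be a subset of the network's nodes).
#' @return induced igraph subgraph (edge signs and node attributes kept);
#'   empty graph for an empty keystone set.
#' @export
keystone_subnetwork <- function(net, keystones) {
  if (length(keystones) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  miss <- setdiff(keystones, igraph::V(net)$name)
  if (length(miss)) {
    stopf("keystone(s) not in network: %s", paste(miss, collapse = ", "))
  }
  igraph::induced_subgraph(net, keystones)
}

#' Proportions of inter-/intra-phylum negative correlations
#'
#' Among all negative edges of the whole network, the proportion whose
#' endpoint phyla equal each unordered pair of keystone phyla (intra-phylum
#' when the two coincide). The denominator is the network's total negative
#' edge count, so proportions over keystone-phylum pairs sum to <= 1.
#'
#' @param net igraph network with node attribute phylum and edge attribute
#'   sign.
#' @param keystone_phyla phyla containing keystone taxa (nonempty).
#' @return data.frame: phylum_a, phylum_b (sorted within pair), n_edges,
#'   proportion; attribute `n_negative` carries the denominator, and
#'   `no_negative_edges` flags an all-zero result.
#' @export
negative_proportions <- function(net, keystone_phyla) {
  if (length(keystone_phyla) == 0) stopf("keystone_phyla is empty")
  keystone_phyla <- sort(unique(keystone_phyla))
  pairs <- expand.grid(a = keystone_phyla, b = keystone_phyla,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a <= pairs$b, ]
  neg_total <- 0
  cnt <- setNames(rep(0, nrow(pairs)), paste(pairs$a, pairs$b, sep = "\r"))
  if (igraph::ecount(net) > 0) {
    el <- igraph::as_data_frame(net, what = "edges")
    ph <- setNames(igraph::V(net)$phylum, igraph::V(net)$name)
    neg <- el[el$sign == "negative", , drop = FALSE]
    neg_total <- nrow(neg)
    if (neg_total > 0) {
      pa <- pmin(ph[neg$from], ph[neg$to])
      pb <- pmax(ph[neg$from], ph[neg$to])
      key <- paste(pa, pb, sep = "\r")
      tab <- table(key)
      hit <- intersect(names(tab), names(cnt))
      cnt[hit] <- as.numeric(tab[hit])
    }
  }
  out <- data.frame(phylum_a = pairs$a, phylum_b = pairs$b,
                    n_edges = unname(cnt),
                    proportion = if (neg_total > 0) unname(cnt) / neg_total
                    else rep(0, nrow(pairs)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_negative") <- neg_total
  attr(out, "no_negative_edges") <- neg_total == 0
  out
}

#' Full keystone analysis for one network
#'
#' @param net igraph network from [stratum_network()].
#' @param seed seed threaded to [detect_modules()].
#' @inheritParams identify_keystones
#' @return list: modules, scores (with is_keystone column), keystones,
#'   subnetwork, keystone_phyla.
#' @export
keystone_analysis <- function(net, seed = 1, c_threshold = 0.6,
                              z_threshold = 2.5, require_both = FALSE) {
  if (igraph::vcount(net) == 0) {
    return(list(modules = integer(0),
                scores = data.frame(otu_id = character(0),
                                    module = integer(0), degree = numeric(0),
                                    z = numeric(0), c = numeric(0),
                                    is_keystone = logical(0)),
                keystones = character(0),
                subnetwork = igraph::make_empty_graph(0, directed = FALSE),
                keystone_phyla = character(0)))
  }
  modules <- detect_modules(net, seed)
  scores <- node_roles(net, modules)
  keys <- identify_keystones(scores, c_threshold, z_threshold, require_both)
  scores$is_keystone <- scores$otu_id %in% keys
  ph <- setNames(igraph::V(net)$phylum, igraph::V(net)$name)
  list(modules = modules, scores = scores, keystones = keys,
       subnetwork = keystone_subnetwork(net, keys),
       keystone_phyla = sort(unique(unname(ph[keys]))))
}
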