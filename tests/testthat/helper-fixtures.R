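# Shared fixtures and independent oracles used across the suite.

# A small synthetic-study configuration: same design (5 x 2 x 5 x 6) at a
# community size that keeps the suite fast.
small_config <- function(seed = 1, ...) {
  synthetic_config(n_otus = 400, n_keystone = 6, n_enriched = 40,
                   n_inhibited = 40, seed = seed, ...)
}

# A configuration with no planted structure and no design effects.
null_config <- function(seed = 1, n_otus = 150) {
  synthetic_config(n_otus = n_otus, n_keystone = 0,
                   followers_per_group = 0, n_enriched = 0,
                   n_inhibited = 0, n_functional_drivers_per_gene = 0,
                   driven_genes = character(0), stage_effect = 0,
                   treatment_effect = 0, compartment_effect = 0,
                   keystone_coupling = 0, seed = seed)
}

# Tiny metadata table: t treatments x 1 compartment x s stages x r reps.
toy_metadata <- function(treatments = "CK", compartments = "B",
                         stages = paste0("S", 1:5), reps = 6) {
  g <- expand.grid(replicate = seq_len(reps), stage = stages,
                   compartment = compartments, treatment = treatments,
                   stringsAsFactors = FALSE)
  g$sample_id <- sprintf("%s_%s_%s_r%d", g$treatment, g$compartment,
                         g$stage, g$replicate)
  g[, c("sample_id", "treatment", "compartment", "stage", "replicate")]
}

# Independent exhaustive-enumeration oracle for two-group permutation
# tests: statistic computed by vegan, labelings enumerated via combn.
enumeration_oracle <- function(d, grouping, statistic = c("anosim",
                                                          "permanova")) {
  statistic <- match.arg(statistic)
  g <- as.character(grouping)
  lev <- unique(g)
  stopifnot(length(lev) == 2)
  n <- length(g)
  n1 <- sum(g == lev[1])
  stat_fun <- function(gg) {
    if (statistic == "anosim") {
      vegan::anosim(as.dist(d), gg, permutations = 0)$statistic
    } else {
      df <- data.frame(gg = gg)
      as.numeric(vegan::adonis2(as.dist(d) ~ gg, data = df,
                                permutations = 0)$F[1])
    }
  }
  obs <- stat_fun(g)
  combos <- combn(n, n1)
  stats <- apply(combos, 2, function(idx) {
    gg <- rep(lev[2], n)
    gg[idx] <- lev[1]
    stat_fun(gg)
  })
  list(obs = obs, stats = stats,
       p = mean(stats >= obs - 1e-12))
}

# Adjusted Rand index (for cluster-recovery checks), computed directly
# from the pair-counting definition.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Fraction of a network's negative-edge mass that falls on the planted
# phylum pairs (restricted to keystone phyla), plus keystone recall.
keystone_recovery <- function(sim, catalog, treatment, compartment) {
  net <- stratum_network(sim$counts, sim$metadata, catalog, sim$taxonomy,
                         treatment, compartment)
  ka <- keystone_analysis(net)
  recall <- if (length(sim$truth$planted_keystones)) {
    mean(sim$truth$planted_keystones %in% ka$keystones)
  } else NA_real_
  share <- NA_real_
  if (length(ka$keystone_phyla)) {
    np <- negative_proportions(net, ka$keystone_phyla)
    if (sum(np$proportion) > 0) {
      tp <- sim$truth$planted_negative_pairs
      planted_keys <- paste(pmin(tp$phylum_a, tp$phylum_b),
                            pmax(tp$phylum_a, tp$phylum_b))
      share <- sum(np$proportion[paste(np$phylum_a, np$phylum_b) %in%
                                   planted_keys]) / sum(np$proportion)
    }
  }
  list(recall = recall, share = share, network = net, analysis = ka)
}
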