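# Synthetic-study generator: a full-factorial soil-sampling design with
# planted, recoverable structure (stage-enriched/inhibited OTUs, coupled
# keystone hubs, gene-driver OTUs) used to validate every downstream stage.

# Internal latent-model constants (log scale). Baseline spread mimics the
# heavy-tailed rank-abundance of amplicon data; the OTU-level lognormal
# noise supplies NB-like overdispersion around the log-linear means.
.BASELINE_SD <- 1.5
# planted OTUs sit in the abundant tail: counts must stay clear of the
# 0-5 range across the latent swing or rank ties destroy the planted
# correlations; hubs get the highest baselines
.PLANTED_BASELINE_MEAN <- 2
.PLANTED_BASELINE_SD <- 0.4
.HUB_BASELINE_MEAN <- 4
.HUB_BASELINE_SD <- 0.3
# driver OTUs stay a small share of the community: a large summed driver
# mass would swing the compositional denominator and couple every other
# OTU to the gene signal
.DRIVER_BASELINE_MEAN <- 1
.DRIVER_BASELINE_SD <- 0.3
.LATENT_NOISE_SD <- 0.7
# stage-selected OTUs get extra sample-level noise: their planted signal
# lives in stage *means* (robust to per-sample noise across 6 replicates)
# while the noise suppresses spurious pairwise rank correlations between
# OTUs with aligned or opposed stage profiles
.SELECTED_NOISE_SD <- 1
# fraction of background OTUs responding to each design factor; sparse
# responses keep the community total stable across samples (large
# fluctuations of the compositional denominator would add shared noise
# to every relative abundance and erode the planted rank correlations)
.RESPONDER_FRAC <- 0.3
# planted gene-driver OTUs respond to the treatment x compartment x
# stage cell through a profile shared by the gene's driver set (what the
# gene follows, and what makes each driver individually predictive)
# plus an idiosyncratic per-driver part
.DRIVER_SHARED_SD <- 0.95
.DRIVER_IDIO_SD <- 0.3
# hub pairs are planted as near-perfect antagonists (|latent rho| at
# least 0.99, and never below the configured coupling): a high hub
# loading separates hub-follower correlations from follower-follower
# ones. Followers attach with two strengths: strongly coupled satellites
# (|rho| ~ 0.8 with the hubs, occasional edges among themselves) and
# weakly coupled ones (~0.73, edges essentially only to the hubs). The
# weak periphery keeps the module's mean degree low, so the hubs -- and
# only the hubs -- stand out in within-module degree z
.HUB_COUPLING_FLOOR <- 0.99
.FOLLOWER_LOADING_STRONG <- 0.8
.FOLLOWER_LOADING_WEAK <- 0.74
.TECH_REPS <- 3L

# Fixed per-assay baseline copy numbers (copies per g soil).
.GENE_BASELINE <- c(
  nifH = 2e6, AOB_amoA = 5e5, nxrA = 1e6, comamoA = 3e5,
  napA = 2e6, nirK = 3e6, qnorB = 1e6, nosZ = 2e6,
  hzsB = 2e5, Amx_16S = 4e5, nrfA = 1e6, TB_16S = 2e9)

# Phylum pairs carrying the planted negative couplings, cycled over hub
# groups.
.NEGATIVE_PAIRS <- list(
  c("Cyanobacteria", "Actinobacteria"),
  c("Cyanobacteria", "Proteobacteria"),
  c("Acidobacteria", "Gemmatimonadetes"),
  c("Proteobacteria", "Acidobacteria"),
  c("Actinobacteria", "Gemmatimonadetes"))

#' Generate the factorial sample design
#'
#' One row per soil sample over treatments x compartments x stages x
#' replicates. Deterministic given the configuration (no randomness).
#'
#' @param config a [synthetic_config()] object.
#' @return data.frame with columns sample_id, treatment, compartment,
#'   stage, replicate.
#' @export
generate_design <- function(config) {
  validate_config(config)
  g <- expand.grid(replicate = seq_len(config$replicates_per_cell),
                   stage = config$stages,
                   compartment = config$compartments,
                   treatment = config$treatments,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("treatment", "compartment", "stage", "replicate")]
  g$sample_id <- sprintf("%s_%s_%s_r%d", g$treatment, g$compartment,
                         g$stage, g$replicate)
  rownames(g) <- NULL
  g[, c("sample_id", "treatment", "compartment", "stage", "replicate")]
}

# Allocate OTU indices to planted roles. Hubs come in pairs; each pair and
# its followers share one latent factor and one negative phylum pair.
# Gene-driver OTUs are a dedicated role with idiosyncratic cell-level
# responses.
allocate_roles <- function(config) {
  n_groups <- config$n_keystone / 2
  n_group_otus <- n_groups * (2 + config$followers_per_group)
  n_driver <- length(config$driven_genes) *
    config$n_functional_drivers_per_gene
  n_planted <- n_group_otus + config$n_enriched + config$n_inhibited +
    n_driver
  if (n_planted > config$n_otus) {
    stopf("config plants %d OTUs but n_otus is only %d",
          n_planted, config$n_otus)
  }
  idx <- seq_len(config$n_otus)
  hubs <- if (n_groups > 0) seq_len(config$n_keystone) else integer(0)
  followers <- if (n_groups > 0 && config$followers_per_group > 0) {
    config$n_keystone + seq_len(n_groups * config$followers_per_group)
  } else integer(0)
  enriched <- if (config$n_enriched > 0) {
    n_group_otus + seq_len(config$n_enriched)
  } else integer(0)
  inhibited <- if (config$n_inhibited > 0) {
    n_group_otus + config$n_enriched + seq_len(config$n_inhibited)
  } else integer(0)
  drivers <- if (n_driver > 0) {
    n_group_otus + config$n_enriched + config$n_inhibited +
      seq_len(n_driver)
  } else integer(0)
  list(hubs = hubs, followers = followers, enriched = enriched,
       inhibited = inhibited, drivers = drivers, n_groups = n_groups,
       group_of_hub = if (n_groups > 0) rep(seq_len(n_groups), each = 2)
       else integer(0),
       group_of_follower = if (length(followers)) {
         rep(seq_len(n_groups), each = config$followers_per_group)
       } else integer(0),
       background = setdiff(idx, c(hubs, followers, enriched, inhibited,
                                   drivers)))
}

#' Generate an OTU count table with planted ground truth
#'
#' Counts follow a log-linear latent-abundance model: per-OTU baseline plus
#' stage, treatment and compartment effects plus lognormal OTU-level noise,
#' with planted structure layered on top. Stage-enriched (inhibited) OTUs
#' receive their maximum (minimum) stage effect at a planted stage with a
#' fixed log-scale margin. Keystone hub pairs load with opposite signs on a
#' shared standard-normal latent factor so that their latent correlation is
#' `-keystone_coupling`; weaker-loading follower OTUs in the same two phyla
#' correlate with the hubs but not with each other. Per-sample counts are a
#' multinomial draw at a log-normally distributed library size, so column
#' totals equal the drawn library sizes exactly.
#'
#' @param config a [synthetic_config()] object.
#' @return list with elements `counts` (integer matrix, OTU x sample),
#'   `taxonomy` (data.frame otu_id/kingdom/phylum/genus), `metadata` (the
#'   design, see [generate_design()]) and `truth` (planted ground truth:
#'   planted_enriched, planted_inhibited, planted_keystones,
#'   planted_followers, planted_negative_pairs, planted_drivers,
#'   planted_fold_changes).
#' @export
generate_otu_table <- function(config) {
  validate_config(config)
  design <- generate_design(config)
  roles <- allocate_roles(config)
  n <- config$n_otus
  n_samp <- nrow(design)
  otu_ids <- sprintf("OTU_%05d", seq_len(n))

  with_seed(config$seed, {
    # baselines: planted OTUs sit in the abundant tail so they are
    # detected in every replicate and survive the consensus filter
    baseline <- rnorm(n, 0, .BASELINE_SD)
    planted <- c(roles$hubs, roles$followers, roles$enriched,
                 roles$inhibited, roles$drivers)
    baseline[planted] <- rnorm(length(planted), .PLANTED_BASELINE_MEAN,
                               .PLANTED_BASELINE_SD)
    baseline[roles$hubs] <- rnorm(length(roles$hubs), .HUB_BASELINE_MEAN,
                                  .HUB_BASELINE_SD)
    baseline[roles$drivers] <- rnorm(length(roles$drivers),
                                     .DRIVER_BASELINE_MEAN,
                                     .DRIVER_BASELINE_SD)

    n_stage <- length(config$stages)
    resp <- function() rbinom(n, 1, .RESPONDER_FRAC)
    stage_eff <- resp() * matrix(rnorm(n * n_stage, 0, config$stage_effect),
                                 n, n_stage)
    treat_eff <- resp() * matrix(rnorm(n * length(config$treatments), 0,
                                       config$treatment_effect),
                                 n, length(config$treatments))
    comp_eff <- resp() * matrix(rnorm(n * length(config$compartments), 0,
                                      config$compartment_effect),
                                n, length(config$compartments))
    # enriched/inhibited OTUs always carry a full stage profile (that is
    # their planted role)
    sel_rows <- c(roles$enriched, roles$inhibited)
    if (length(sel_rows)) {
      stage_eff[sel_rows, ] <- matrix(
        rnorm(length(sel_rows) * n_stage, 0, config$stage_effect),
        length(sel_rows), n_stage)
    }
    group_members <- c(roles$hubs, roles$followers)
    # hub/follower OTUs carry no design effects: their variation is the
    # shared factor, so the planted coupling is not diluted
    stage_eff[group_members, ] <- 0
    treat_eff[group_members, ] <- 0
    comp_eff[group_members, ] <- 0
    # driver OTUs respond to the full treatment x compartment x stage
    # combination (idiosyncratic per driver), so the summed driver
    # abundance has a cell profile no other OTU shares -- what makes the
    # planted gene-driver relationship identifiable
    n_cells <- length(config$treatments) * length(config$compartments) *
      length(config$stages)
    driver_cell_eff <- NULL
    if (length(roles$drivers)) {
      stage_eff[roles$drivers, ] <- 0
      treat_eff[roles$drivers, ] <- 0
      comp_eff[roles$drivers, ] <- 0
      n_driven <- length(config$driven_genes)
      # every driver profile holds the SAME multiset of values in each
      # treatment, permuted independently per treatment: cell profiles
      # are idiosyncratic (identifiable), yet no treatment carries a
      # systematic level or spread difference, so the organic-vs-mineral
      # contrast of a gene comes from its planted fold change alone
      n_within <- length(config$compartments) * length(config$stages)
      n_trt <- length(config$treatments)
      n_stage <- length(config$stages)
      # per compartment, a base multiset of stage values rescaled to an
      # exact sample sd (so every gene's signal has guaranteed spread in
      # every compartment), permuted independently within each
      # (treatment, compartment) block
      permuted_profile <- function(sd_val) {
        out <- numeric(n_cells)
        for (ci in seq_along(config$compartments)) {
          base <- if (n_stage > 1) {
            as.vector(scale(rnorm(n_stage))) * sd_val
          } else {
            0
          }
          for (ti in seq_len(n_trt)) {
            idx <- (ti - 1) * n_within + (ci - 1) * n_stage +
              seq_len(n_stage)
            out[idx] <- base[sample.int(n_stage)]
          }
        }
        out
      }
      gene_of_driver <- rep(seq_len(n_driven),
                            each = config$n_functional_drivers_per_gene)
      shared <- t(vapply(seq_len(n_driven), function(g) {
        permuted_profile(.DRIVER_SHARED_SD)
      }, numeric(n_cells)))
      driver_cell_eff <- shared[gene_of_driver, , drop = FALSE] +
        t(vapply(seq_along(roles$drivers), function(i) {
          permuted_profile(.DRIVER_IDIO_SD)
        }, numeric(n_cells)))
    }

    planted_enriched <- character(0)
    if (length(roles$enriched)) {
      st <- sample(n_stage, length(roles$enriched), replace = TRUE)
      for (k in seq_along(roles$enriched)) {
        i <- roles$enriched[k]
        others <- stage_eff[i, -st[k]]
        stage_eff[i, st[k]] <- max(others) + config$enrichment_margin
      }
      planted_enriched <- setNames(config$stages[st],
                                   otu_ids[roles$enriched])
    }
    planted_inhibited <- character(0)
    if (length(roles$inhibited)) {
      st <- sample(n_stage, length(roles$inhibited), replace = TRUE)
      for (k in seq_along(roles$inhibited)) {
        i <- roles$inhibited[k]
        others <- stage_eff[i, -st[k]]
        stage_eff[i, st[k]] <- min(others) - config$enrichment_margin
      }
      planted_inhibited <- setNames(config$stages[st],
                                    otu_ids[roles$inhibited])
    }

    # latent noise / factor structure
    noise <- matrix(rnorm(n * n_samp, 0, .LATENT_NOISE_SD), n, n_samp)
    if (length(sel_rows)) {
      noise[sel_rows, ] <- matrix(
        rnorm(length(sel_rows) * n_samp, 0, .SELECTED_NOISE_SD),
        length(sel_rows), n_samp)
    }
    pair_used <- list()
    if (roles$n_groups > 0) {
      # hub-hub |latent rho| = a^2 = max(coupling, floor): the config
      # value is the guaranteed minimum magnitude
      a <- sqrt(max(config$keystone_coupling, .HUB_COUPLING_FLOOR))
      u <- matrix(rnorm(roles$n_groups * n_samp), roles$n_groups, n_samp)
      for (g in seq_len(roles$n_groups)) {
        hubs_g <- roles$hubs[roles$group_of_hub == g]
        fols_g <- roles$followers[roles$group_of_follower == g]
        members <- c(hubs_g, fols_g)
        # hubs load with opposite signs; followers alternate sign so the
        # group's total abundance is insensitive to the factor (an
        # unbalanced group would swing the compositional denominator and
        # wash out the planted negative correlations). Both hubs
        # correlate with every follower, keeping the group one module
        # with the hubs as its intra-module hubs; every negative edge
        # joins the planted phylum pair because sign determines phylum.
        signs <- c(1, -1,
                   if (length(fols_g))
                     rep_len(c(1, -1), length(fols_g)) else numeric(0))
        load <- c(a, a,
                  if (length(fols_g))
                    rep_len(c(.FOLLOWER_LOADING_STRONG,
                              .FOLLOWER_LOADING_STRONG,
                              .FOLLOWER_LOADING_WEAK,
                              .FOLLOWER_LOADING_WEAK),
                            length(fols_g)) else numeric(0))
        resid <- sqrt(pmax(0, 1 - load^2))
        noise[members, ] <- signs * load %o% u[g, ] +
          resid * matrix(rnorm(length(members) * n_samp),
                         length(members), n_samp)
        pair_used[[g]] <- sort(.NEGATIVE_PAIRS[[(g - 1) %%
                                                  length(.NEGATIVE_PAIRS) + 1]])
      }
    }

    # taxonomy: hub groups pinned to their negative pair's phyla,
    # everything else drawn with a Proteobacteria-heavy prior
    phyla <- config$phyla
    w <- setNames(rep(1, length(phyla)), phyla)
    w[intersect(names(w), c("Cyanobacteria", "Proteobacteria",
                            "Actinobacteria", "Acidobacteria",
                            "Gemmatimonadetes"))] <- 0
    w[c("Cyanobacteria", "Proteobacteria", "Actinobacteria",
        "Acidobacteria", "Gemmatimonadetes")] <- c(3, 32, 18, 14, 6)
    extra <- setdiff(phyla, c("Cyanobacteria", "Proteobacteria",
                              "Actinobacteria", "Acidobacteria",
                              "Gemmatimonadetes"))
    if (length(extra)) w[extra] <- 27 / length(extra)
    phylum <- sample(phyla, n, replace = TRUE, prob = w[phyla])
    if (roles$n_groups > 0) {
      for (g in seq_len(roles$n_groups)) {
        pr <- pair_used[[g]]
        hubs_g <- roles$hubs[roles$group_of_hub == g]
        fols_g <- roles$followers[roles$group_of_follower == g]
        members <- c(hubs_g, fols_g)
        signs <- c(1, -1,
                   if (length(fols_g))
                     rep_len(c(1, -1), length(fols_g)) else numeric(0))
        phylum[members] <- ifelse(signs > 0, pr[1], pr[2])
      }
    }
    genus <- paste0(phylum, "_gen", sample.int(40, n, replace = TRUE))

    # map the dedicated driver OTUs to their genes in allocation order
    planted_drivers <- list()
    if (length(roles$drivers)) {
      planted_drivers <- split(
        otu_ids[roles$drivers],
        rep(config$driven_genes,
            each = config$n_functional_drivers_per_gene))
      planted_drivers <- planted_drivers[config$driven_genes]
    }

    # counts: multinomial at log-normal library sizes
    meanlog <- log(config$library_size_mean) -
      config$library_size_dispersion^2 / 2
    lib <- pmax(1, round(rlnorm(n_samp, meanlog,
                                config$library_size_dispersion)))
    stage_i <- match(design$stage, config$stages)
    treat_i <- match(design$treatment, config$treatments)
    comp_i <- match(design$compartment, config$compartments)
    cell_i <- (treat_i - 1) * length(config$compartments) *
      length(config$stages) + (comp_i - 1) * length(config$stages) +
      stage_i
    counts <- matrix(0L, n, n_samp,
                     dimnames = list(otu_ids, design$sample_id))
    for (s in seq_len(n_samp)) {
      eta <- baseline + stage_eff[, stage_i[s]] + treat_eff[, treat_i[s]] +
        comp_eff[, comp_i[s]] + noise[, s]
      if (length(roles$drivers)) {
        eta[roles$drivers] <- eta[roles$drivers] +
          driver_cell_eff[, cell_i[s]]
      }
      p <- exp(eta - max(eta))
      counts[, s] <- rmultinom(1, lib[s], p)[, 1]
    }

    neg_pairs <- if (length(pair_used)) {
      unique(do.call(rbind, lapply(pair_used, function(p) {
        data.frame(phylum_a = p[1], phylum_b = p[2],
                   stringsAsFactors = FALSE)
      })))
    } else {
      data.frame(phylum_a = character(0), phylum_b = character(0))
    }
    rownames(neg_pairs) <- NULL

    truth <- list(
      planted_enriched = planted_enriched,
      planted_inhibited = planted_inhibited,
      planted_keystones = otu_ids[roles$hubs],
      planted_followers = otu_ids[roles$followers],
      planted_negative_pairs = neg_pairs,
      planted_drivers = planted_drivers,
      planted_fold_changes = config$fold_changes)
    taxonomy <- data.frame(otu_id = otu_ids, kingdom = "Bacteria",
                           phylum = phylum, genus = genus,
                           stringsAsFactors = FALSE)
    list(counts = counts, taxonomy = taxonomy, metadata = design,
         truth = truth)
  })
}

#' Generate a qPCR gene-abundance table driven by planted OTUs
#'
#' For each assay, log copy number in a pooled design cell (treatment x
#' compartment x stage) is a fixed baseline plus `driver_effect` times the
#' summed relative abundance of that gene's planted driver OTUs (averaged
#' over the cell's biological replicates, mirroring pooled-template qPCR),
#' plus the gene's log fold-change for organic treatments (labels starting
#' with "O"), plus independent Gaussian noise per technical replicate.
#'
#' @param config a [synthetic_config()] object.
#' @param otu_table counts matrix from [generate_otu_table()].
#' @param truth ground-truth list from the same call.
#' @param metadata the matching design data.frame.
#' @return data.frame with columns gene, treatment, compartment, stage,
#'   tech_rep, copies (copies per g soil).
#' @export
generate_gene_table <- function(config, otu_table, truth, metadata) {
  validate_config(config)
  missing_genes <- setdiff(config$driven_genes, names(truth$planted_drivers))
  if (length(missing_genes)) {
    stopf("ground truth is missing planted drivers for configured gene(s): %s",
          paste(missing_genes, collapse = ", "))
  }
  rel <- relative_abundance(otu_table)
  cell <- interaction(metadata$treatment, metadata$compartment,
                      metadata$stage, drop = FALSE, sep = "\r")
  cells <- expand.grid(stage = config$stages,
                       compartment = config$compartments,
                       treatment = config$treatments,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[, c("treatment", "compartment", "stage")]
  cell_key <- paste(cells$treatment, cells$compartment, cells$stage,
                    sep = "\r")
  organic <- grepl("^O", cells$treatment)

  gene_seed <- (config$seed + 104729L) %% .Machine$integer.max
  with_seed(gene_seed, {
    out <- lapply(gene_assays(), function(g) {
      fc <- config$fold_changes[[g]] %||% 1
      drv <- truth$planted_drivers[[g]]
      x <- if (length(drv)) {
        drv_sum <- colSums(rel[drv, , drop = FALSE])
        vapply(cell_key, function(k) mean(drv_sum[cell == k]), numeric(1))
      } else {
        rep(0, nrow(cells))
      }
      # slope derived so the driver term has log-scale sd driver_effect
      # across cells regardless of community size (the summed driver
      # relative abundance scales with 1/n_otus and its spread varies
      # with the planted fraction)
      beta <- if (sd(x) > 0) config$driver_effect / sd(x) else 0
      bx <- beta * x
      # express the driver term relative to each treatment's mean (on the
      # copy-number scale): the organic-vs-mineral contrast then comes
      # from the planted fold change alone, so treatment-group ratios of
      # cell means recover it exactly in the noise-free limit
      for (tr_lab in config$treatments) {
        cols <- which(cells$treatment == tr_lab)
        bx[cols] <- bx[cols] - log(mean(exp(bx[cols])))
      }
      log_mu <- log(.GENE_BASELINE[[g]]) + bx +
        log(fc) * organic
      reps <- lapply(seq_len(.TECH_REPS), function(r) {
        data.frame(gene = g, cells, tech_rep = r,
                   copies = exp(log_mu +
                                  rnorm(nrow(cells), 0,
                                        config$gene_noise_sd)),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, reps)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper around [generate_otu_table()] and
#' [generate_gene_table()].
#'
#' @param config a [synthetic_config()] object.
#' @return list with counts, taxonomy, metadata, genes, truth.
#' @export
simulate_study <- function(config) {
  sim <- generate_otu_table(config)
  genes <- generate_gene_table(config, sim$counts, sim$truth, sim$metadata)
  c(sim, list(genes = genes))
}
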