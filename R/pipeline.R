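# Pipeline orchestration: simulate -> filter -> diversity -> network ->
# keystone -> links -> funcgroups, each stage writing plain-table outputs
# plus a machine-readable run manifest.

.PIPELINE_STAGES <- c("simulate", "filter", "diversity", "network",
                      "keystone", "links", "funcgroups")

log_stage <- function(stage, msg, t0) {
  message(sprintf("[rhizonet] %-10s %s (%.1fs)", stage, msg,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' Executes the seven stages in order on a synthetic study (or on input
#' tables named in the config when `simulate: false`), writing each
#' stage's tables under `outdir` plus `manifest.json` (config hash, seed,
#' package version, per-stage status and shapes). Re-running with an
#' identical config reproduces every output.
#'
#' @param config path to a YAML/JSON config, or a [synthetic_config()]
#'   object.
#' @param outdir output directory (created if needed).
#' @param seed optional override of the config seed (required if the
#'   config file does not set one).
#' @param stages stages to run (default: all, in order).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir, seed = NULL,
                         stages = .PIPELINE_STAGES) {
  t0 <- as.numeric(Sys.time())
  opts <- list()
  if (is.character(config)) {
    raw <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
    if (is.null(raw$seed) && is.null(seed)) {
      stopf("config must set 'seed' (or pass seed explicitly)")
    }
    cfg <- read_config(config)
    opts <- attr(cfg, "pipeline_options") %||% list()
  } else {
    cfg <- config
    validate_config(cfg)
  }
  if (!is.null(seed)) cfg$seed <- seed
  stages <- match.arg(stages, .PIPELINE_STAGES, several.ok = TRUE)
  if (identical(opts$simulate, FALSE)) stages <- setdiff(stages, "simulate")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  rho_min <- opts$rho_min %||% 0.7
  q_max <- opts$q_max %||% 0.05
  abs_rho <- opts$abs_rho %||% TRUE
  c_thr <- opts$c_threshold %||% 0.6
  z_thr <- opts$z_threshold %||% 2.5
  n_perm <- opts$n_permutations %||% 999
  rf_trees <- opts$rf_trees %||% 500
  rf_perm <- opts$rf_permutations %||% 99
  kmeans_k <- opts$kmeans_k %||% 3

  manifest <- list(package = "rhizonet",
                   version = as.character(utils::packageVersion("rhizonet")),
                   seed = cfg$seed, stages = list())
  cfg_path <- file.path(outdir, "config_used.yaml")
  cfg_plain <- unclass(cfg)
  cfg_plain$fold_changes <- as.list(cfg_plain$fold_changes)
  yaml::write_yaml(cfg_plain, cfg_path)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))

  state <- new.env(parent = emptyenv())
  record <- function(stage, outputs, shapes = NULL) {
    manifest$stages[[stage]] <<- list(status = "completed",
                                      outputs = outputs,
                                      shapes = shapes,
                                      elapsed_s = round(
                                        as.numeric(Sys.time()) - t0, 1))
    log_stage(stage, paste("wrote", paste(outputs, collapse = ", ")), t0)
  }
  run_stage <- function(stage, fun) {
    if (!stage %in% stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      manifest$stages[[stage]] <<- list(status = "failed",
                                        error = conditionMessage(e))
      manifest$partial <<- TRUE
      jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }

  run_stage("simulate", function() {
    sim <- simulate_study(cfg)
    state$counts <- sim$counts; state$taxonomy <- sim$taxonomy
    state$metadata <- sim$metadata; state$genes <- sim$genes
    state$truth <- sim$truth
    write_otu_table(sim$counts, file.path(outdir, "otu_table.tsv"))
    write_tsv(sim$taxonomy, file.path(outdir, "taxonomy.tsv"))
    write_tsv(sim$metadata, file.path(outdir, "metadata.tsv"))
    write_tsv(sim$genes, file.path(outdir, "genes.tsv"))
    truth_json <- sim$truth
    truth_json$planted_enriched <- as.list(truth_json$planted_enriched)
    truth_json$planted_inhibited <- as.list(truth_json$planted_inhibited)
    truth_json$planted_fold_changes <-
      as.list(truth_json$planted_fold_changes)
    jsonlite::write_json(truth_json, file.path(outdir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    record("simulate",
           c("otu_table.tsv", "taxonomy.tsv", "metadata.tsv", "genes.tsv",
             "ground_truth.json"),
           list(otus = nrow(sim$counts), samples = ncol(sim$counts)))
  })
  if (!"simulate" %in% stages || identical(opts$simulate, FALSE)) {
    # load the inputs named in the config instead of simulating
    lv <- list(treatments = cfg$treatments, compartments = cfg$compartments,
               stages = cfg$stages)
    state$metadata <- read_metadata(opts$metadata %||%
                                      file.path(outdir, "metadata.tsv"), lv)
    state$counts <- read_otu_table(opts$otu_table %||%
                                     file.path(outdir, "otu_table.tsv"),
                                   state$metadata)
    state$taxonomy <- read_taxonomy(opts$taxonomy %||%
                                      file.path(outdir, "taxonomy.tsv"),
                                    rownames(state$counts))
    state$genes <- read_genes(opts$genes %||%
                                file.path(outdir, "genes.tsv"), lv)
  }
  manifest$samples <- list(n_input = ncol(state$counts),
                           n_used = ncol(state$counts), excluded = list())

  run_stage("filter", function() {
    state$catalog <- build_selection_catalog(state$counts, state$metadata,
                                             k = kmeans_k, seed = cfg$seed)
    write_tsv(state$catalog, file.path(outdir, "selection_catalog.tsv"))
    write_tsv(summarize_selection(state$catalog),
              file.path(outdir, "selection_summary.tsv"))
    write_tsv(compare_counts(state$catalog),
              file.path(outdir, "selection_count_tests.tsv"))
    record("filter", c("selection_catalog.tsv", "selection_summary.tsv",
                       "selection_count_tests.tsv"),
           list(retained = sum(state$catalog$retained)))
  })

  run_stage("diversity", function() {
    ct <- community_tests(state$counts, state$metadata,
                          n_permutations = n_perm, seed = cfg$seed)
    write_tsv(ct, file.path(outdir, "community_tests.tsv"))
    ord <- pcoa(bray_curtis(state$counts), n_axes = 2)
    coords <- data.frame(sample_id = rownames(ord$coordinates),
                         ord$coordinates, check.names = FALSE)
    write_tsv(coords, file.path(outdir, "pcoa_coordinates.tsv"))
    gt <- do.call(rbind, lapply(c("fertilization", "stage", "compartment"),
                                function(f) gene_group_tests(state$genes, f)))
    write_tsv(gt, file.path(outdir, "gene_tests.tsv"))
    record("diversity", c("community_tests.tsv", "pcoa_coordinates.tsv",
                          "gene_tests.tsv"))
  })

  run_stage("network", function() {
    strata <- unique(state$metadata[, c("treatment", "compartment")])
    nets <- list(); topo_rows <- list()
    for (s in seq_len(nrow(strata))) {
      tr <- strata$treatment[s]; cp <- strata$compartment[s]
      key <- paste(tr, cp, sep = "_")
      net <- stratum_network(state$counts, state$metadata, state$catalog,
                             state$taxonomy, tr, cp, rho_min, q_max,
                             abs_rho)
      nets[[key]] <- net
      write_network(net, file.path(outdir, paste0("network_", key, ".tsv")),
                    file.path(outdir, paste0("network_", key, ".graphml")))
      if (igraph::vcount(net) > 0 && igraph::ecount(net) > 0) {
        tp <- topology(net)
        rn <- random_network_ensemble(tp$n_nodes, tp$n_edges,
                                      n_reps = 100, seed = cfg$seed + s)
        topo_rows[[key]] <- data.frame(
          stratum = key, n_nodes = tp$n_nodes, n_edges = tp$n_edges,
          avg_clustering = tp$avg_clustering,
          avg_path_length = tp$avg_path_length, modularity = tp$modularity,
          random_clustering_mean = rn$mean[["avg_clustering"]],
          random_clustering_sd = rn$sd[["avg_clustering"]],
          random_path_mean = rn$mean[["avg_path_length"]],
          random_path_sd = rn$sd[["avg_path_length"]],
          random_modularity_mean = rn$mean[["modularity"]],
          random_modularity_sd = rn$sd[["modularity"]],
          stringsAsFactors = FALSE)
      }
    }
    state$networks <- nets
    topo <- if (length(topo_rows)) do.call(rbind, topo_rows) else
      data.frame(stratum = character(0))
    rownames(topo) <- NULL
    write_tsv(topo, file.path(outdir, "topology_summary.tsv"))
    record("network", c("network_<stratum>.tsv/.graphml",
                        "topology_summary.tsv"),
           list(strata = length(nets)))
  })

  run_stage("keystone", function() {
    keys_rows <- list(); neg_rows <- list()
    state$keystone <- list()
    for (key in names(state$networks)) {
      net <- state$networks[[key]]
      ka <- keystone_analysis(net, seed = cfg$seed, c_threshold = c_thr,
                              z_threshold = z_thr)
      state$keystone[[key]] <- ka
      if (nrow(ka$scores)) {
        keys_rows[[key]] <- cbind(stratum = key, ka$scores,
                                  phylum = igraph::V(net)$phylum[
                                    match(ka$scores$otu_id,
                                          igraph::V(net)$name)],
                                  stringsAsFactors = FALSE)
      }
      if (length(ka$keystone_phyla)) {
        np <- negative_proportions(net, ka$keystone_phyla)
        neg_rows[[key]] <- cbind(stratum = key, np,
                                 stringsAsFactors = FALSE)
      }
    }
    keys <- if (length(keys_rows)) do.call(rbind, keys_rows) else
      data.frame(stratum = character(0))
    neg <- if (length(neg_rows)) do.call(rbind, neg_rows) else
      data.frame(stratum = character(0))
    rownames(keys) <- rownames(neg) <- NULL
    write_tsv(keys, file.path(outdir, "keystone_scores.tsv"))
    write_tsv(neg, file.path(outdir, "negative_proportions.tsv"))
    record("keystone", c("keystone_scores.tsv", "negative_proportions.tsv"),
           list(keystones = sum(keys$is_keystone %||% 0)))
  })

  run_stage("links", function() {
    # key phyla = the (at most 5) phyla carrying the most keystone taxa;
    # a full phylum set would be compositionally collinear (sums to 1)
    ph_counts <- table(unlist(lapply(names(state$networks), function(nm) {
      net <- state$networks[[nm]]
      keys <- state$keystone[[nm]]$keystones
      unname(igraph::V(net)$phylum[match(keys, igraph::V(net)$name)])
    })))
    key_phyla <- names(sort(ph_counts, decreasing = TRUE))
    key_phyla <- sort(head(key_phyla, 5))
    if (length(key_phyla) < 2) {
      key_phyla <- c("Cyanobacteria", "Proteobacteria", "Actinobacteria",
                     "Acidobacteria", "Gemmatimonadetes")
    }
    pa <- aggregate_phyla(state$counts, state$taxonomy, key_phyla)
    fits <- pairwise_phylum_fits(pa, state$metadata)
    write_tsv(fits, file.path(outdir, "phylum_pairwise_fits.tsv"))
    x_cells <- pool_to_cells(pa, state$metadata)
    y_cells <- gene_cell_matrix(state$genes)
    y_cells <- y_cells[rownames(x_cells), , drop = FALSE]
    rd <- rda(y_cells, x_cells)
    expl <- data.frame(phylum = rownames(rd$explanatory_scores),
                       rd$explanatory_scores, check.names = FALSE)
    write_tsv(expl, file.path(outdir, "rda_explanatory_scores.tsv"))
    site <- data.frame(cell = rownames(rd$site_scores), rd$site_scores,
                       check.names = FALSE)
    write_tsv(site, file.path(outdir, "rda_site_scores.tsv"))
    state$rda <- rd
    record("links", c("phylum_pairwise_fits.tsv",
                      "rda_explanatory_scores.tsv", "rda_site_scores.tsv"),
           list(constrained_proportion =
                  round(rd$constrained_proportion, 4)))
  })

  run_stage("funcgroups", function() {
    imp_rows <- list(); grp_rows <- list(); spec_rows <- list()
    state$funcgroups <- list()
    for (cp in cfg$compartments) {
      fa <- rf_gene_analysis(state$counts, state$metadata, state$catalog,
                             state$genes, cp, n_trees = rf_trees,
                             n_permutations = rf_perm, seed = cfg$seed)
      state$funcgroups[[cp]] <- fa
      for (g in names(fa$importance)) {
        imp_rows[[paste(cp, g)]] <- data.frame(
          compartment = cp, gene = g, otu_id = names(fa$importance[[g]]),
          inc_mse = unname(fa$importance[[g]]),
          model_p = unname(fa$significance[[g]]),
          stringsAsFactors = FALSE)
        if (length(fa$groups$genes[[g]])) {
          grp_rows[[paste(cp, g)]] <- data.frame(
            compartment = cp, gene = g,
            process = unname(gene_processes()[g]),
            otu_id = fa$groups$genes[[g]], stringsAsFactors = FALSE)
        }
      }
      members <- sort(unique(unlist(fa$groups$genes)))
      if (length(members)) {
        sp <- selection_specificity(members, state$catalog, state$taxonomy)
        spec_rows[[cp]] <- sp[sp$compartment == cp, ]
      }
    }
    write_tsv(do.call(rbind, imp_rows),
              file.path(outdir, "rf_importance.tsv"))
    grp <- if (length(grp_rows)) do.call(rbind, grp_rows) else
      data.frame(compartment = character(0), gene = character(0),
                 process = character(0), otu_id = character(0))
    write_tsv(grp, file.path(outdir, "functional_groups.tsv"))
    spec <- if (length(spec_rows)) do.call(rbind, spec_rows) else
      data.frame(phylum = character(0))
    rownames(spec) <- NULL
    write_tsv(spec, file.path(outdir, "selection_specificity.tsv"))
    fc <- data.frame(
      gene = c("nifH", "Amx_16S"),
      fold_change_organic_vs_mineral = c(
        fold_change(state$genes, "nifH", c("O1", "O2"), c("N1", "N2")),
        fold_change(state$genes, "Amx_16S", c("O1", "O2"), c("N1", "N2"))),
      stringsAsFactors = FALSE)
    write_tsv(fc, file.path(outdir, "fold_changes.tsv"))
    record("funcgroups", c("rf_importance.tsv", "functional_groups.tsv",
                           "selection_specificity.tsv", "fold_changes.tsv"))
  })

  manifest$completed <- sum(vapply(manifest$stages, function(s) {
    identical(s$status, "completed")
  }, logical(1)))
  manifest$partial <- manifest$partial %||% FALSE
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
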