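#' Names of the twelve qPCR assays
#'
#' Eleven nitrogen-cycling marker genes plus the total-bacteria 16S rRNA
#' assay, grouped by process: nitrogen fixation (nifH), nitrification
#' (AOB_amoA, nxrA, comamoA), denitrification (napA, nirK, qnorB, nosZ),
#' anammox (hzsB, Amx_16S), DNRA (nrfA), and total bacteria (TB_16S).
#'
#' @return character vector of length 12.
#' @export
gene_assays <- function() {
  c("nifH", "AOB_amoA", "nxrA", "comamoA",
    "napA", "nirK", "qnorB", "nosZ",
    "hzsB", "Amx_16S", "nrfA", "TB_16S")
}

#' Map qPCR assays to nitrogen-cycling processes
#'
#' @return named character vector: assay -> process.
#' @export
gene_processes <- function() {
  c(nifH = "fixation",
    AOB_amoA = "nitrification", nxrA = "nitrification",
    comamoA = "nitrification",
    napA = "denitrification", nirK = "denitrification",
    qnorB = "denitrification", nosZ = "denitrification",
    hzsB = "anammox", Amx_16S = "anammox",
    nrfA = "DNRA", TB_16S = "total_bacteria")
}

default_phyla <- function(n_phyla) {
  core <- c("Cyanobacteria", "Proteobacteria", "Actinobacteria",
            "Acidobacteria", "Gemmatimonadetes")
  extra <- c("Bacteroidetes", "Chloroflexi", "Firmicutes",
             "Verrucomicrobia", "Planctomycetes", "Nitrospirae")
  if (n_phyla < length(core)) stopf("n_phyla must be >= %d", length(core))
  c(core, extra)[seq_len(n_phyla)]
}

default_fold_changes <- function() {
  fc <- setNames(rep(1, 12), gene_assays())
  # organic-vs-mineral effects echoing the study system: fixation and
  # anammox favoured by organic input, DNRA the opposite
  fc[["nifH"]] <- 2.6
  fc[["Amx_16S"]] <- 2.4
  fc[["hzsB"]] <- 2.0
  fc[["nrfA"]] <- 0.5
  fc
}

#' Configuration for the synthetic study generator
#'
#' Builds and validates the parameter set describing the emulated study: a
#' full-factorial design of `treatments` x `compartments` x `stages` x
#' `replicates_per_cell` soil samples, OTU counts drawn from a log-linear
#' latent-abundance model, and qPCR gene abundances driven by planted OTU
#' "driver" sets.
#'
#' @param n_otus number of OTUs to simulate.
#' @param n_phyla number of phyla (>= 5; the first five are always
#'   Cyanobacteria, Proteobacteria, Actinobacteria, Acidobacteria and
#'   Gemmatimonadetes).
#' @param treatments fertilization treatment labels (default CK, N1, N2,
#'   O1, O2: control, low/high urea, low/high manure).
#' @param compartments compartment labels (default B = bulk soil,
#'   R = rhizosphere).
#' @param stages developmental-stage labels (default S1..S5).
#' @param replicates_per_cell biological replicates per design cell.
#' @param library_size_mean mean sequencing depth per sample.
#' @param library_size_dispersion sd of log library size (log-normal).
#' @param stage_effect,treatment_effect,compartment_effect sd of the
#'   per-OTU log-scale effects for each design factor.
#' @param n_keystone number of planted keystone (hub) OTUs; must be even
#'   (hubs are planted in pairs with opposite-signed factor loadings, one
#'   per phylum of a planted negative phylum pair).
#' @param keystone_coupling target |Spearman rho| between paired planted
#'   hubs, in \[0, 1\].
#' @param followers_per_group number of satellite OTUs attached to each hub
#'   pair's latent factor with weaker loadings.
#' @param n_enriched,n_inhibited numbers of OTUs planted with a forced
#'   stage-specific maximum (resp. minimum) latent abundance.
#' @param enrichment_margin log-scale gap between the planted stage's
#'   effect and the most extreme other stage effect.
#' @param n_functional_drivers_per_gene planted driver OTUs per driven gene.
#' @param driver_effect log-scale magnitude (standard deviation across
#'   design cells) of the driver signal on gene copy numbers; the slope
#'   on the summed driver relative abundance is derived per gene as
#'   driver_effect / sd(summed driver abundance), keeping the planted
#'   signal comparable across community sizes.
#' @param gene_noise_sd sd of the log-scale noise on each qPCR observation.
#' @param fold_changes named vector of per-gene multiplicative organic
#'   (O1/O2) vs mineral (N1/N2) effects.
#' @param driven_genes genes that receive planted drivers (default: all
#'   assays except the total-bacteria 16S and the two fold-change
#'   showcase assays nifH and Amx_16S, so the planted organic-vs-mineral
#'   folds and the planted driver signals live on disjoint genes and
#'   each is cleanly measurable).
#' @param seed integer seed; every random draw in the generator flows from
#'   it.
#' @return object of class `rhizonet_config` (a validated list).
#' @export
synthetic_config <- function(n_otus = 1500,
                             n_phyla = 8,
                             treatments = c("CK", "N1", "N2", "O1", "O2"),
                             compartments = c("B", "R"),
                             stages = paste0("S", 1:5),
                             replicates_per_cell = 6,
                             library_size_mean = 37770,
                             library_size_dispersion = 0.2,
                             stage_effect = 1,
                             treatment_effect = 1,
                             compartment_effect = 0.5,
                             n_keystone = 10,
                             keystone_coupling = 0.9,
                             followers_per_group = 50,
                             n_enriched = 100,
                             n_inhibited = 100,
                             enrichment_margin = 1.5,
                             n_functional_drivers_per_gene = 5,
                             driver_effect = 2,
                             gene_noise_sd = 0.3,
                             fold_changes = default_fold_changes(),
                             driven_genes = setdiff(gene_assays(),
                                                    c("TB_16S", "nifH",
                                                      "Amx_16S")),
                             seed = 1) {
  cfg <- list(n_otus = n_otus, n_phyla = n_phyla,
              treatments = as.character(treatments),
              compartments = as.character(compartments),
              stages = as.character(stages),
              replicates_per_cell = replicates_per_cell,
              library_size_mean = library_size_mean,
              library_size_dispersion = library_size_dispersion,
              stage_effect = stage_effect,
              treatment_effect = treatment_effect,
              compartment_effect = compartment_effect,
              n_keystone = n_keystone,
              keystone_coupling = keystone_coupling,
              followers_per_group = followers_per_group,
              n_enriched = n_enriched, n_inhibited = n_inhibited,
              enrichment_margin = enrichment_margin,
              n_functional_drivers_per_gene = n_functional_drivers_per_gene,
              driver_effect = driver_effect,
              gene_noise_sd = gene_noise_sd,
              fold_changes = fold_changes,
              driven_genes = as.character(driven_genes),
              seed = seed)
  validate_config(cfg)
  cfg$phyla <- default_phyla(n_phyla)
  class(cfg) <- "rhizonet_config"
  cfg
}

validate_config <- function(cfg) {
  chk_count <- function(field, min = 1) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < min ||
        v != round(v)) {
      stopf("invalid config: '%s' must be an integer >= %d", field, min)
    }
  }
  chk_pos <- function(field, min = 0) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < min) {
      stopf("invalid config: '%s' must be a finite number >= %g", field, min)
    }
  }
  chk_count("n_otus"); chk_count("n_phyla", 5)
  chk_count("replicates_per_cell"); chk_count("seed", -2^31)
  chk_count("n_keystone", 0); chk_count("followers_per_group", 0)
  chk_count("n_enriched", 0); chk_count("n_inhibited", 0)
  chk_count("n_functional_drivers_per_gene", 0)
  chk_pos("library_size_mean", 1); chk_pos("library_size_dispersion")
  chk_pos("stage_effect"); chk_pos("treatment_effect")
  chk_pos("compartment_effect"); chk_pos("gene_noise_sd")
  chk_pos("enrichment_margin"); chk_pos("driver_effect")
  if (!is.numeric(cfg$keystone_coupling) ||
      cfg$keystone_coupling < 0 || cfg$keystone_coupling > 1) {
    stopf("invalid config: 'keystone_coupling' must lie in [0, 1]")
  }
  if (cfg$n_keystone %% 2 != 0) {
    stopf("invalid config: 'n_keystone' must be even (hubs are paired)")
  }
  if (cfg$n_keystone > cfg$n_otus) {
    stopf("invalid config: 'n_keystone' exceeds 'n_otus'")
  }
  for (f in c("treatments", "compartments", "stages")) {
    if (anyDuplicated(cfg[[f]]) || length(cfg[[f]]) < 1) {
      stopf("invalid config: '%s' must be distinct non-empty labels", f)
    }
  }
  if (!all(cfg$driven_genes %in% gene_assays())) {
    stopf("invalid config: unknown gene(s) in 'driven_genes': %s",
          paste(setdiff(cfg$driven_genes, gene_assays()), collapse = ", "))
  }
  if (is.null(names(cfg$fold_changes)) ||
      !all(names(cfg$fold_changes) %in% gene_assays()) ||
      any(!is.finite(cfg$fold_changes)) || any(cfg$fold_changes <= 0)) {
    stopf("invalid config: 'fold_changes' must be positive, named by assay")
  }
  invisible(TRUE)
}

#' Read a synthetic-data configuration from YAML or JSON
#'
#' Field names mirror the arguments of [synthetic_config()]; absent fields
#' take their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `rhizonet_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(synthetic_config))
  extra <- setdiff(names(raw), c(known, "simulate", "outdir",
                                 "rho_min", "q_max", "abs_rho",
                                 "c_threshold", "z_threshold",
                                 "n_permutations", "rf_trees",
                                 "rf_permutations", "kmeans_k"))
  if (length(extra)) {
    stopf("unknown config field(s): %s", paste(extra, collapse = ", "))
  }
  if (!is.null(raw$fold_changes)) raw$fold_changes <- unlist(raw$fold_changes)
  args <- raw[intersect(names(raw), known)]
  cfg <- do.call(synthetic_config, args)
  attr(cfg, "pipeline_options") <- raw[setdiff(names(raw), known)]
  cfg
}

#' @export
print.rhizonet_config <- function(x, ...) {
  n <- length(x$treatments) * length(x$compartments) * length(x$stages) *
    x$replicates_per_cell
  cat(sprintf(
    "rhizonet synthetic config: %d OTUs x %d samples (%d trt x %d comp x %d stages x %d reps), seed %d\n",
    x$n_otus, n, length(x$treatments), length(x$compartments),
    length(x$stages), x$replicates_per_cell, x$seed))
  invisible(x)
}
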