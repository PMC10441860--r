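# Gene-abundance group statistics, random-forest permutation importance of
# selected OTUs for nitrogen-cycling genes, model significance testing,
# functional-group definition and selection-specificity summaries.

#' Kruskal-Wallis tests of gene abundances by a design factor
#'
#' Per gene, a tie-corrected Kruskal-Wallis H test of copy numbers across
#' the factor's levels; BH adjustment across the genes of the factor's
#' family. Genes with a level holding fewer than 2 observations are
#' flagged and excluded from the BH family.
#'
#' @param genes gene-abundance data.frame (see [read_genes()]).
#' @param factor one of "fertilization", "stage", "compartment".
#' @return data.frame: gene, factor, H, p, q, flagged.
#' @export
gene_group_tests <- function(genes,
                             factor = c("fertilization", "stage",
                                        "compartment")) {
  factor <- match.arg(factor)
  col <- switch(factor, fertilization = "treatment", stage = "stage",
                compartment = "compartment")
  ids <- intersect(gene_assays(), unique(genes$gene))
  rows <- lapply(ids, function(g) {
    sub <- genes[genes$gene == g, ]
    sizes <- table(sub[[col]])
    if (length(sizes) < 2 || any(sizes < 2)) {
      return(data.frame(gene = g, factor = factor, H = NA_real_,
                        p = NA_real_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    if (length(unique(sub$copies)) == 1) {
      # all observations tied: no rank variation, H = 0 by convention
      return(data.frame(gene = g, factor = factor, H = 0, p = 1,
                        flagged = FALSE, stringsAsFactors = FALSE))
    }
    kt <- kruskal.test(sub$copies, as.factor(sub[[col]]))
    data.frame(gene = g, factor = factor,
               H = unname(kt$statistic), p = kt$p.value, flagged = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !out$flagged
  out$q[ok] <- adjust_fdr(out$p[ok])
  rownames(out) <- NULL
  out
}

#' Fold change of mean gene abundance between treatment groups
#'
#' @param genes gene-abundance data.frame.
#' @param gene_id assay name.
#' @param group_a,group_b treatment labels for numerator and denominator.
#' @return mean(copies in group_a) / mean(copies in group_b).
#' @export
fold_change <- function(genes, gene_id, group_a, group_b) {
  sub <- genes[genes$gene == gene_id, ]
  if (nrow(sub) == 0) stopf("no rows for gene %s", gene_id)
  ma <- mean(sub$copies[sub$treatment %in% group_a])
  mb <- mean(sub$copies[sub$treatment %in% group_b])
  if (!is.finite(mb) || mb == 0) stopf("zero/empty denominator group")
  if (!is.finite(ma)) stopf("empty numerator group")
  ma / mb
}

#' Random-forest permutation importance (%IncMSE)
#'
#' Regression random forest of a gene's cell-level abundance on
#' selected-OTU relative abundances; importance is the percent increase in
#' out-of-bag MSE when a predictor's OOB values are permuted.
#'
#' @param x observation x predictor matrix (>= 8 rows, >= 2 columns).
#' @param y numeric response (non-constant).
#' @param n_trees number of trees (default 500).
#' @param seed RNG seed (forest is deterministic given it).
#' @return named numeric vector of %IncMSE per predictor.
#' @export
rf_importance <- function(x, y, n_trees = 500, seed = 1) {
  x <- as.matrix(x)
  if (nrow(x) < 8) stopf("rf_importance: need >= 8 observations")
  if (ncol(x) < 2) stopf("rf_importance: need >= 2 predictors")
  if (sd(y) == 0) stopf("rf_importance: constant response")
  fit <- with_seed(seed, randomForest::randomForest(
    x = x, y = y, ntree = n_trees, mtry = ceiling(ncol(x) / 3),
    importance = TRUE))
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)
  # percent scale: mean OOB-MSE increase relative to the forest's OOB MSE
  setNames(100 * imp[, 1] / fit$mse[n_trees], rownames(imp))
}

#' Permutation test of random-forest predictive power
#'
#' Observed out-of-bag pseudo-R^2 (1 - OOB MSE / var(y)) compared with its
#' distribution over response permutations:
#' p = (1 + #\{permuted >= observed\}) / (1 + n_permutations).
#'
#' @inheritParams rf_importance
#' @param n_permutations number of response permutations (default 99).
#' @param n_trees trees per forest (default 100; the statistic is the
#'   model-level OOB fit, which stabilizes with far fewer trees than the
#'   per-predictor importances).
#' @return list: p, observed_r2, permuted_r2.
#' @export
rf_significance <- function(x, y, n_permutations = 99, seed = 1,
                            n_trees = 100) {
  x <- as.matrix(x)
  if (nrow(x) < 8) stopf("rf_significance: need >= 8 observations")
  if (ncol(x) < 2) stopf("rf_significance: need >= 2 predictors")
  if (sd(y) == 0) stopf("rf_significance: constant response")
  oob_r2 <- function(yy, s) {
    fit <- with_seed(s, randomForest::randomForest(
      x = x, y = yy, ntree = n_trees, mtry = ceiling(ncol(x) / 3)))
    fit$rsq[n_trees]
  }
  obs <- oob_r2(y, seed)
  perm <- with_seed(seed, {
    perms <- replicate(n_permutations, sample(y), simplify = FALSE)
    seeds <- sample.int(.Machine$integer.max - 1, n_permutations)
    vapply(seq_len(n_permutations), function(b) {
      oob_r2(perms[[b]], seeds[b])
    }, numeric(1))
  })
  list(p = (1 + sum(perm >= obs)) / (1 + n_permutations),
       observed_r2 = obs, permuted_r2 = perm)
}

#' Define functional groups from importance and model significance
#'
#' A gene's functional group is the set of OTUs with positive %IncMSE in a
#' random-forest model whose permutation p-value is below `alpha`; a
#' non-significant model yields an empty group. Process-level groups are
#' unions over each process's genes.
#'
#' @param importance named list: gene -> named %IncMSE vector.
#' @param significance named numeric vector: gene -> model p-value.
#' @param alpha significance level (default 0.05).
#' @return list with `genes` (gene -> otu ids) and `processes`
#'   (process -> otu ids).
#' @export
define_functional_groups <- function(importance, significance,
                                     alpha = 0.05) {
  genes <- names(importance)
  by_gene <- lapply(genes, function(g) {
    pg <- significance[[g]]
    if (is.null(pg) || is.na(pg) || pg >= alpha) return(character(0))
    imp <- importance[[g]]
    names(imp)[imp > 0]
  })
  names(by_gene) <- genes
  proc_map <- gene_processes()
  procs <- unique(unname(proc_map[genes]))
  by_proc <- lapply(procs, function(pr) {
    sort(unique(unlist(by_gene[genes[proc_map[genes] == pr]])))
  })
  names(by_proc) <- procs
  list(genes = by_gene, processes = by_proc)
}

#' Selection specificity of functional-group members
#'
#' Within each phylum and (treatment, compartment) stratum, the percentage
#' of functional-group member OTUs whose enriched (resp. inhibited) stage
#' equals each stage; percentages per direction sum to <= 100 (members
#' without that label form the remainder).
#'
#' @param members functional-group member otu_ids.
#' @param catalog selection catalog.
#' @param taxonomy taxonomy data.frame.
#' @param stages stage labels (output order).
#' @return data.frame: phylum, treatment, compartment, stage, direction,
#'   n, percent.
#' @export
selection_specificity <- function(members, catalog, taxonomy,
                                  stages = sort(unique(
                                    c(catalog$enriched_stage,
                                      catalog$inhibited_stage)))) {
  stages <- stages[!is.na(stages)]
  if (length(members) == 0) stopf("empty functional group")
  cc <- catalog[catalog$otu_id %in% members & catalog$retained, ]
  cc$phylum <- taxonomy$phylum[match(cc$otu_id, taxonomy$otu_id)]
  combos <- unique(cc[, c("phylum", "treatment", "compartment")])
  rows <- list()
  for (k in seq_len(nrow(combos))) {
    sub <- cc[cc$phylum == combos$phylum[k] &
                cc$treatment == combos$treatment[k] &
                cc$compartment == combos$compartment[k], ]
    n_mem <- nrow(sub)
    for (dir in c("enriched", "inhibited")) {
      col <- paste0(dir, "_stage")
      for (st in stages) {
        n <- sum(sub[[col]] == st, na.rm = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          phylum = combos$phylum[k], treatment = combos$treatment[k],
          compartment = combos$compartment[k], stage = st,
          direction = dir, n = n, percent = 100 * n / n_mem,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Random-forest gene analysis for one compartment
#'
#' Builds the RF design: predictors are the compartment's temporally
#' specifically-selected OTUs (union over its treatment strata), relative
#' abundances averaged over the biological replicates of each pooled
#' (treatment, compartment, stage) qPCR cell; each response is a gene's
#' mean ln(copies + 1) over technical replicates in those cells. Runs
#' [rf_importance()], [rf_significance()] and
#' [define_functional_groups()] per gene.
#'
#' @param counts OTU x sample count matrix.
#' @param metadata validated metadata.
#' @param catalog selection catalog.
#' @param genes gene-abundance data.frame.
#' @param compartment compartment label.
#' @param gene_ids assays to model (default: all 12).
#' @param n_trees,n_permutations,seed,alpha forwarded to the RF stages.
#' @return list: importance (gene -> named vector), significance
#'   (gene -> p), groups (see [define_functional_groups()]),
#'   predictors (otu ids used).
#' @export
rf_gene_analysis <- function(counts, metadata, catalog, genes, compartment,
                             gene_ids = gene_assays(), n_trees = 500,
                             n_permutations = 99, seed = 1, alpha = 0.05) {
  cc <- catalog[catalog$compartment == compartment & catalog$retained, ]
  sel <- sort(unique(cc$otu_id[!is.na(cc$enriched_stage) |
                                 !is.na(cc$inhibited_stage)]))
  if (length(sel) < 2) stopf("fewer than 2 selected OTUs in compartment %s",
                             compartment)
  md <- metadata[metadata$compartment == compartment, ]
  rel <- t(relative_abundance(counts)[sel, md$sample_id, drop = FALSE])
  x <- pool_to_cells(rel, md)
  y_all <- gene_cell_matrix(genes[genes$compartment == compartment, ])
  y_all <- y_all[rownames(x), , drop = FALSE]
  importance <- list(); signif <- numeric(0)
  for (g in intersect(gene_ids, colnames(y_all))) {
    y <- y_all[, g]
    importance[[g]] <- rf_importance(x, y, n_trees = n_trees, seed = seed)
    signif[[g]] <- rf_significance(x, y, n_permutations = n_permutations,
                                   seed = seed)$p
  }
  list(importance = importance, significance = signif,
       groups = define_functional_groups(importance, signif, alpha),
       predictors = sel)
}
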