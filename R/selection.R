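# Replicate-consensus presence calls, consistency filtering, temporal
# specific-selection (stage-wise enriched/inhibited OTUs) and kmeans
# abundance-pattern clustering, all within (treatment, compartment) strata.

#' Replicate-consensus presence call
#'
#' An OTU is `present` in a design cell when it is detected (count >= 1)
#' in more than half of the cell's replicates, `absent` when detected in
#' fewer than half, and `undefined` when detected in exactly half.
#'
#' @param counts vector of replicate counts for one OTU in one cell.
#' @return one of "present", "absent", "undefined".
#' @export
call_presence <- function(counts) {
  if (length(counts) == 0) stopf("call_presence: empty replicate vector")
  det <- sum(counts > 0)
  n <- length(counts)
  if (2 * det > n) "present" else if (2 * det < n) "absent" else "undefined"
}

stratum_samples <- function(metadata, treatment, compartment) {
  metadata$sample_id[metadata$treatment == treatment &
                       metadata$compartment == compartment]
}

# presence category codes per (OTU, stage) for one stratum:
# 1 present / 0 absent / NA undefined
stratum_presence <- function(counts, metadata, treatment, compartment) {
  md <- metadata[metadata$treatment == treatment &
                   metadata$compartment == compartment, ]
  stages <- sort(unique(metadata$stage))
  miss <- setdiff(stages, md$stage)
  if (length(miss)) {
    stopf("stratum %s/%s is missing stage(s): %s", treatment, compartment,
          paste(miss, collapse = ", "))
  }
  out <- vapply(stages, function(st) {
    cols <- md$sample_id[md$stage == st]
    x <- counts[, cols, drop = FALSE]
    det <- rowSums(x > 0)
    n <- length(cols)
    ifelse(2 * det > n, 1, ifelse(2 * det < n, 0, NA_real_))
  }, numeric(nrow(counts)))
  rownames(out) <- rownames(counts)
  out
}

#' Consistency filter within each (treatment, compartment) stratum
#'
#' Presence is called per stage cell over its replicates; an OTU is
#' retained in a stratum iff it is never `undefined` at any stage and is
#' `present` at one stage or more (consistently absent OTUs are dropped).
#'
#' @param counts OTU x sample count matrix.
#' @param metadata validated sample metadata covering the counts' samples.
#' @return data.frame: otu_id, treatment, compartment, retained (logical).
#' @export
filter_consistent <- function(counts, metadata) {
  strata <- unique(metadata[, c("treatment", "compartment")])
  rows <- lapply(seq_len(nrow(strata)), function(k) {
    pres <- stratum_presence(counts, metadata, strata$treatment[k],
                             strata$compartment[k])
    retained <- apply(pres, 1, function(v) !anyNA(v) && any(v == 1))
    data.frame(otu_id = rownames(counts),
               treatment = strata$treatment[k],
               compartment = strata$compartment[k],
               retained = unname(retained), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# OTU x stage matrix of stage-mean relative abundances for one stratum.
stage_mean_profiles <- function(counts, metadata, treatment, compartment,
                                otus = rownames(counts)) {
  md <- metadata[metadata$treatment == treatment &
                   metadata$compartment == compartment, ]
  rel <- relative_abundance(counts[, md$sample_id, drop = FALSE])
  prof <- group_col_means(rel, md$stage)
  prof[otus, , drop = FALSE]
}

#' Temporally specifically-selected OTUs in one stratum
#'
#' For each retained OTU, stage means of relative abundance (mean over the
#' stage's replicates of per-sample relative abundance) are computed; the
#' OTU is specifically enriched at the unique stage attaining the maximum
#' and specifically inhibited at the unique stage attaining the minimum.
#' Ties at an extremum withhold that label.
#'
#' @param counts OTU x sample count matrix.
#' @param metadata validated sample metadata.
#' @param treatment,compartment the stratum.
#' @param otus OTU ids to label (typically the stratum's retained set).
#' @return data.frame: otu_id, treatment, compartment, enriched_stage,
#'   inhibited_stage (NA when tied or all-zero).
#' @export
select_specific <- function(counts, metadata, treatment, compartment,
                            otus) {
  prof <- stage_mean_profiles(counts, metadata, treatment, compartment,
                              otus)
  stages <- colnames(prof)
  pick <- function(v, dir) {
    if (all(v == 0)) return(NA_character_)
    ext <- if (dir == "max") max(v) else min(v)
    hits <- which(v == ext)
    if (length(hits) != 1) NA_character_ else stages[hits]
  }
  data.frame(otu_id = rownames(prof), treatment = treatment,
             compartment = compartment,
             enriched_stage = apply(prof, 1, pick, dir = "max"),
             inhibited_stage = apply(prof, 1, pick, dir = "min"),
             stringsAsFactors = FALSE, row.names = NULL)
}

# k-means++ seeding (D^2-weighted), then Lloyd/Hartigan-Wong refinement.
kmeanspp <- function(x, k, restarts = 25) {
  n <- nrow(x)
  if (n < k) stopf("cluster_patterns: %d profiles but k = %d", n, k)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- matrix(NA_real_, k, ncol(x))
    centers[1, ] <- x[sample.int(n, 1), ]
    if (k > 1) {
      d2 <- colSums((t(x) - centers[1, ])^2)
      for (j in 2:k) {
        prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        centers[j, ] <- x[sample.int(n, 1, prob = prob), ]
        d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
      }
    }
    centers <- unique(centers)
    fit <- suppressWarnings(
      if (nrow(centers) < k) kmeans(x, k, nstart = 1, iter.max = 100)
      else kmeans(x, centers, iter.max = 100))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Cluster stage-abundance patterns
#'
#' Standardizes each OTU's stage-mean profile to zero mean / unit variance
#' (constant profiles become all-zero vectors) and clusters with k-means
#' (k-means++ initialization, 25 restarts, fixed seed).
#'
#' @param profiles OTU x stage matrix of stage-mean relative abundances.
#' @param k number of clusters (default 3).
#' @param seed RNG seed.
#' @return integer cluster label per OTU (named).
#' @export
cluster_patterns <- function(profiles, k = 3, seed = 1) {
  z <- t(apply(profiles, 1, function(v) {
    s <- sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  fit <- with_seed(seed, kmeanspp(z, k))
  setNames(fit$cluster, rownames(profiles))
}

#' Build the full selection catalog
#'
#' Runs [filter_consistent()], [select_specific()] and
#' [cluster_patterns()] for every (treatment, compartment) stratum.
#'
#' @param counts OTU x sample count matrix.
#' @param metadata validated sample metadata.
#' @param k kmeans cluster count (default 3).
#' @param seed RNG seed for clustering.
#' @return data.frame: otu_id, treatment, compartment, retained,
#'   enriched_stage, inhibited_stage, pattern_cluster (NA for
#'   non-retained OTUs).
#' @export
build_selection_catalog <- function(counts, metadata, k = 3, seed = 1) {
  filt <- filter_consistent(counts, metadata)
  strata <- unique(filt[, c("treatment", "compartment")])
  rows <- lapply(seq_len(nrow(strata)), function(s) {
    tr <- strata$treatment[s]; cp <- strata$compartment[s]
    f <- filt[filt$treatment == tr & filt$compartment == cp, ]
    f$enriched_stage <- NA_character_
    f$inhibited_stage <- NA_character_
    f$pattern_cluster <- NA_integer_
    keep <- f$otu_id[f$retained]
    if (length(keep)) {
      sel <- select_specific(counts, metadata, tr, cp, keep)
      i <- match(sel$otu_id, f$otu_id)
      f$enriched_stage[i] <- sel$enriched_stage
      f$inhibited_stage[i] <- sel$inhibited_stage
      if (length(keep) >= k) {
        prof <- stage_mean_profiles(counts, metadata, tr, cp, keep)
        cl <- cluster_patterns(prof, k, seed)
        f$pattern_cluster[match(names(cl), f$otu_id)] <- cl
      }
    }
    f
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-stage proportions of specifically-selected OTUs
#'
#' @param catalog a selection catalog from [build_selection_catalog()].
#' @param stages stage labels defining the output order.
#' @return data.frame: treatment, compartment, stage, direction
#'   (enriched/inhibited), n, proportion; proportions sum to 1 across
#'   stages within each (stratum, direction) with any labeled OTUs.
#' @export
summarize_selection <- function(catalog, stages = sort(unique(
  c(catalog$enriched_stage, catalog$inhibited_stage)))) {
  strata <- unique(catalog[, c("treatment", "compartment")])
  rows <- lapply(seq_len(nrow(strata)), function(s) {
    cc <- catalog[catalog$treatment == strata$treatment[s] &
                    catalog$compartment == strata$compartment[s], ]
    per_dir <- lapply(c(enriched = "enriched_stage",
                        inhibited = "inhibited_stage"), function(col) {
      n <- vapply(stages, function(st) sum(cc[[col]] == st, na.rm = TRUE),
                  numeric(1))
      tot <- sum(n)
      data.frame(stage = stages, n = unname(n),
                 proportion = if (tot > 0) unname(n) / tot else rep(0, length(n)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, Map(cbind,
                              direction = names(per_dir), per_dir,
                              stringsAsFactors = FALSE))
    cbind(treatment = strata$treatment[s],
          compartment = strata$compartment[s], out,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("treatment", "compartment", "stage", "direction", "n",
          "proportion")]
}

#' Compare enriched vs inhibited selection counts
#'
#' At each stage within a compartment, a two-sided Welch t-test compares
#' the per-treatment counts of specifically enriched OTUs against the
#' per-treatment counts of specifically inhibited OTUs.
#'
#' @param catalog a selection catalog.
#' @return data.frame: compartment, stage, mean_enriched, mean_inhibited,
#'   t, p, skipped (TRUE when < 2 treatments are available).
#' @export
compare_counts <- function(catalog) {
  comps <- sort(unique(catalog$compartment))
  stages <- sort(unique(c(catalog$enriched_stage,
                          catalog$inhibited_stage)))
  stages <- stages[!is.na(stages)]
  rows <- list()
  for (cp in comps) {
    cc <- catalog[catalog$compartment == cp, ]
    trts <- sort(unique(cc$treatment))
    for (st in stages) {
      enr <- vapply(trts, function(tr) {
        sum(cc$treatment == tr & cc$enriched_stage == st, na.rm = TRUE)
      }, numeric(1))
      inh <- vapply(trts, function(tr) {
        sum(cc$treatment == tr & cc$inhibited_stage == st, na.rm = TRUE)
      }, numeric(1))
      if (length(trts) < 2) {
        rows[[length(rows) + 1L]] <- data.frame(
          compartment = cp, stage = st, mean_enriched = mean(enr),
          mean_inhibited = mean(inh), t = NA_real_, p = NA_real_,
          skipped = TRUE, stringsAsFactors = FALSE)
        next
      }
      if (sd(enr) == 0 && sd(inh) == 0) {
        tt <- if (mean(enr) == mean(inh)) list(statistic = 0, p.value = 1)
        else list(statistic = sign(mean(enr) - mean(inh)) * Inf,
                  p.value = .Machine$double.xmin)
      } else {
        ht <- t.test(enr, inh, var.equal = FALSE)
        tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        compartment = cp, stage = st, mean_enriched = mean(enr),
        mean_inhibited = mean(inh), t = tt$statistic, p = tt$p.value,
        skipped = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
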