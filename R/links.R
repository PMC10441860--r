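# Phylum-level aggregation, pairwise linear associations between key
# phyla, and redundancy analysis (RDA) of ln(x+1) gene abundances on
# phylum abundances.

#' Aggregate relative abundances to phylum level
#'
#' Per-sample sums of OTU relative abundances over each phylum's OTUs.
#'
#' @param counts OTU x sample count matrix.
#' @param taxonomy data.frame with otu_id, phylum covering all OTUs.
#' @param key_phyla phyla to report (nonempty); typically the phyla
#'   containing keystone taxa.
#' @return sample x phylum matrix of relative abundances (row sums <= 1).
#' @export
aggregate_phyla <- function(counts, taxonomy, key_phyla) {
  if (length(key_phyla) == 0) stopf("key_phyla is empty")
  miss <- setdiff(rownames(counts), taxonomy$otu_id)
  if (length(miss)) {
    stopf("taxonomy is missing OTU(s): %s",
          paste(head(miss, 10), collapse = ", "))
  }
  rel <- relative_abundance(counts)
  ph <- taxonomy$phylum[match(rownames(rel), taxonomy$otu_id)]
  out <- vapply(key_phyla, function(p) {
    rows <- which(ph == p)
    if (length(rows) == 0) rep(0, ncol(rel))
    else colSums(rel[rows, , drop = FALSE])
  }, numeric(ncol(rel)))
  if (is.null(dim(out))) out <- matrix(out, ncol = length(key_phyla))
  dimnames(out) <- list(colnames(rel), key_phyla)
  out
}

#' Simple linear regression between two abundance vectors
#'
#' Ordinary least squares y ~ x with the two-sided slope t-test.
#'
#' @param x,y numeric vectors (n >= 3; x non-constant).
#' @return list: slope, intercept, r_squared, p.
#' @export
pairwise_lm <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  if (length(x) < 3) stopf("pairwise_lm: need n >= 3")
  if (sd(x) == 0) stopf("pairwise_lm: constant x")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  p <- if (sd(y) == 0) 1 else sm$coefficients["x", "Pr(>|t|)"]
  list(slope = unname(coef(fit)[["x"]]),
       intercept = unname(coef(fit)[["(Intercept)"]]),
       r_squared = if (sd(y) == 0) 0 else sm$r.squared,
       p = p)
}

#' Pairwise phylum-phylum linear fits
#'
#' Fits every unordered pair of key phyla, per (treatment, compartment)
#' stratum, with significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param phyla_abund sample x phylum matrix from [aggregate_phyla()].
#' @param metadata validated metadata matching the rows.
#' @return data.frame: treatment, compartment, phylum_x, phylum_y, slope,
#'   r2, p, stars.
#' @export
pairwise_phylum_fits <- function(phyla_abund, metadata) {
  md <- metadata[match(rownames(phyla_abund), metadata$sample_id), ]
  strata <- unique(md[, c("treatment", "compartment")])
  phyla <- colnames(phyla_abund)
  rows <- list()
  for (s in seq_len(nrow(strata))) {
    idx <- md$treatment == strata$treatment[s] &
      md$compartment == strata$compartment[s]
    for (a in seq_along(phyla)) {
      for (b in seq_along(phyla)) {
        if (a >= b) next
        x <- phyla_abund[idx, a]; y <- phyla_abund[idx, b]
        if (sd(x) == 0) next
        f <- pairwise_lm(x, y)
        stars <- if (f$p < 0.001) "***" else if (f$p < 0.01) "**"
        else if (f$p < 0.05) "*" else ""
        rows[[length(rows) + 1L]] <- data.frame(
          treatment = strata$treatment[s],
          compartment = strata$compartment[s],
          phylum_x = phyla[a], phylum_y = phyla[b],
          slope = f$slope, r2 = f$r_squared, p = f$p, stars = stars,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Redundancy analysis
#'
#' Centers the response and explanatory matrices, fits multivariate OLS of
#' the response on the explanatory variables, and takes RDA axes as the
#' principal components of the fitted values. The constrained proportion
#' is trace(fitted covariance) / trace(total covariance). Explanatory
#' scores are correlations of the explanatory variables with the site
#' scores (biplot arrows).
#'
#' @param response n x q numeric matrix (e.g. ln(x+1) gene abundances).
#' @param explanatory n x p numeric matrix (e.g. phylum abundances);
#'   must be full column rank after centering.
#' @param scale standardize explanatory columns to unit variance.
#' @return object of class `rhizonet_rda`: list(constrained_proportion,
#'   axis_eigenvalues, site_scores, response_scores, explanatory_scores).
#' @export
rda <- function(response, explanatory, scale = FALSE) {
  y <- as.matrix(response); x <- as.matrix(explanatory)
  if (nrow(y) != nrow(x)) stopf("rda: row mismatch")
  if (nrow(x) <= ncol(x)) {
    stopf("rda: need more observations (%d) than explanatory variables (%d)",
          nrow(x), ncol(x))
  }
  y <- scale(y, center = TRUE, scale = FALSE)
  x <- scale(x, center = TRUE, scale = scale)
  const <- apply(x, 2, function(v) all(abs(v) < 1e-12))
  if (any(const)) {
    stopf("rda: constant explanatory column(s): %s",
          paste(colnames(x)[const], collapse = ", "))
  }
  # columns live on very different scales (dominant vs rare phyla); rank
  # decisions must not drop a genuinely varying rare column
  qrx <- qr(scale(x), tol = 1e-8)
  if (qrx$rank < ncol(x)) {
    dep <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stopf("rda: collinear explanatory column(s): %s",
          paste(dep, collapse = ", "))
  }
  fitted <- qr.fitted(qrx, y)
  sv <- svd(fitted)
  keep <- which(sv$d > max(sv$d[1], 0) * 1e-10)
  eig <- sv$d[keep]^2 / (nrow(y) - 1)
  site <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))
  resp_scores <- sv$v[, keep, drop = FALSE]
  expl_scores <- if (length(keep) && ncol(x) > 0) {
    suppressWarnings(cor(x, site))
  } else matrix(0, ncol(x), 0)
  expl_scores[is.na(expl_scores)] <- 0
  axis_names <- paste0("RDA", seq_along(keep))
  dimnames(site) <- list(rownames(response), axis_names)
  dimnames(resp_scores) <- list(colnames(response), axis_names)
  if (length(keep)) colnames(expl_scores) <- axis_names
  rownames(expl_scores) <- colnames(explanatory)
  structure(list(
    constrained_proportion = sum(fitted^2) / sum(y^2),
    axis_eigenvalues = eig,
    site_scores = site,
    response_scores = resp_scores,
    explanatory_scores = expl_scores), class = "rhizonet_rda")
}

#' @export
print.rhizonet_rda <- function(x, ...) {
  cat(sprintf("RDA: %d constrained axes, constrained proportion = %.3f\n",
              length(x$axis_eigenvalues), x$constrained_proportion))
  invisible(x)
}

#' Average a sample-level matrix to pooled qPCR cells
#'
#' Means over the biological replicates of each (treatment, compartment,
#' stage) cell, mirroring the pooled-template qPCR design.
#'
#' @param x sample x variable matrix.
#' @param metadata validated metadata matching the rows.
#' @return cell x variable matrix with rownames "treatment_compartment_stage".
#' @export
pool_to_cells <- function(x, metadata) {
  md <- metadata[match(rownames(x), metadata$sample_id), ]
  key <- paste(md$treatment, md$compartment, md$stage, sep = "_")
  out <- rowsum(x, key) / as.vector(table(key)[sort(unique(key))])
  out[sort(unique(key)), , drop = FALSE]
}

#' Cell-level ln(x+1) gene matrix
#'
#' Averages ln(copies + 1) over technical replicates per (treatment,
#' compartment, stage) cell.
#'
#' @param genes gene-abundance data.frame (see [read_genes()]).
#' @return cell x gene matrix with rownames "treatment_compartment_stage".
#' @export
gene_cell_matrix <- function(genes) {
  key <- paste(genes$treatment, genes$compartment, genes$stage, sep = "_")
  lg <- log(genes$copies + 1)
  cells <- sort(unique(key))
  out <- vapply(gene_assays(), function(g) {
    sel <- genes$gene == g
    vapply(cells, function(k) mean(lg[sel & key == k]), numeric(1))
  }, numeric(length(cells)))
  rownames(out) <- cells
  out
}
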