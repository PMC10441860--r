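#' @importFrom stats coef cor cmdscale kmeans kruskal.test p.adjust pt
#'   rnorm rlnorm rmultinom sd t.test var lm quantile rbinom runif
#'   setNames
#' @importFrom utils write.table read.delim combn head
NULL

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

#' Convert a count matrix to per-sample relative abundances
#'
#' Total-sum scaling: each column (sample) is divided by its total count.
#'
#' @param counts numeric matrix, OTUs in rows, samples in columns.
#' @return matrix of the same shape with columns summing to 1.
#' @export
relative_abundance <- function(counts) {
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(counts)[totals <= 0], collapse = ", "))
  }
  sweep(counts, 2, totals, "/")
}

# Column means of `x` grouped by factor `g` (groups in levels order);
# returns matrix OTU x level.
group_col_means <- function(x, g) {
  g <- factor(g)
  out <- vapply(levels(g), function(lv) {
    cols <- which(g == lv)
    if (length(cols) == 1L) x[, cols] else rowMeans(x[, cols, drop = FALSE])
  }, numeric(nrow(x)))
  rownames(out) <- rownames(x)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
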