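# Plain-table IO: TSV interchange (UTF-8, header row, "." decimal) with
# validation against the sample metadata, plus GraphML export of networks.

.TREATMENT_LEVELS <- c("CK", "N1", "N2", "O1", "O2")
.COMPARTMENT_LEVELS <- c("B", "R")
.STAGE_LEVELS <- paste0("S", 1:5)

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, ...)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, colnames(df))
  if (length(miss)) {
    stopf("%s is missing column(s): %s", what, paste(miss, collapse = ", "))
  }
}

#' Read and validate a sample metadata table
#'
#' @param path TSV with columns sample_id, treatment, compartment, stage,
#'   replicate.
#' @param levels optional list overriding the factor enumerations
#'   (`treatments`, `compartments`, `stages`), e.g. from a custom design.
#' @return validated data.frame.
#' @export
read_metadata <- function(path, levels = NULL) {
  md <- read_tsv(path)
  validate_metadata(md, levels)
}

#' @rdname read_metadata
#' @param metadata a metadata data.frame to validate in place.
#' @export
validate_metadata <- function(metadata, levels = NULL) {
  require_cols(metadata, c("sample_id", "treatment", "compartment",
                           "stage", "replicate"), "metadata")
  if (anyDuplicated(metadata$sample_id)) {
    stopf("duplicate sample_id(s): %s",
          paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
                collapse = ", "))
  }
  lv <- list(treatments = levels$treatments %||% .TREATMENT_LEVELS,
             compartments = levels$compartments %||% .COMPARTMENT_LEVELS,
             stages = levels$stages %||% .STAGE_LEVELS)
  chk <- function(col, allowed) {
    bad <- setdiff(unique(metadata[[col]]), allowed)
    if (length(bad)) {
      stopf("metadata has unknown %s level(s): %s", col,
            paste(bad, collapse = ", "))
    }
  }
  chk("treatment", lv$treatments)
  chk("compartment", lv$compartments)
  chk("stage", lv$stages)
  if (!is.numeric(metadata$replicate) ||
      any(metadata$replicate != round(metadata$replicate)) ||
      any(metadata$replicate < 1)) {
    stopf("metadata replicate must be a positive integer")
  }
  metadata
}

#' Read and validate an OTU count table
#'
#' @param path TSV with first column `otu_id` and one column per sample.
#' @param metadata optional validated metadata; when given, every sample
#'   column must appear in it.
#' @return integer count matrix, OTUs in rows, samples in columns.
#' @export
read_otu_table <- function(path, metadata = NULL) {
  df <- read_tsv(path)
  require_cols(df, "otu_id", "OTU table")
  if (anyDuplicated(df$otu_id)) {
    stopf("duplicate otu_id(s): %s",
          paste(unique(df$otu_id[duplicated(df$otu_id)]), collapse = ", "))
  }
  m <- as.matrix(df[, setdiff(colnames(df), "otu_id"), drop = FALSE])
  rownames(m) <- df$otu_id
  if (!is.numeric(m) || any(!is.finite(m))) {
    stopf("OTU table counts must be finite numbers")
  }
  if (any(m < 0)) stopf("OTU table contains negative counts")
  storage.mode(m) <- "integer"
  if (!is.null(metadata)) {
    unknown <- setdiff(colnames(m), metadata$sample_id)
    if (length(unknown)) {
      stopf("OTU table references sample(s) absent from metadata: %s",
            paste(unknown, collapse = ", "))
    }
  }
  m
}

#' Write an OTU count table
#' @param counts OTU x sample matrix.
#' @param path output TSV path.
#' @export
write_otu_table <- function(counts, path) {
  df <- data.frame(otu_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read and validate a taxonomy table
#'
#' @param path TSV with columns otu_id, phylum, genus (other lineage
#'   columns are carried through).
#' @param otu_ids optional OTU ids that must all be present.
#' @return data.frame; empty phylum entries become "unclassified".
#' @export
read_taxonomy <- function(path, otu_ids = NULL) {
  tx <- read_tsv(path)
  require_cols(tx, c("otu_id", "phylum", "genus"), "taxonomy")
  if (anyDuplicated(tx$otu_id)) stopf("taxonomy has duplicate otu_id(s)")
  tx$phylum[is.na(tx$phylum) | tx$phylum == ""] <- "unclassified"
  if (!is.null(otu_ids)) {
    miss <- setdiff(otu_ids, tx$otu_id)
    if (length(miss)) {
      stopf("taxonomy is missing OTU(s): %s",
            paste(head(miss, 10), collapse = ", "))
    }
  }
  tx
}

#' Read and validate a qPCR gene-abundance table
#'
#' @param path TSV with columns gene, treatment, compartment, stage,
#'   tech_rep, copies.
#' @param levels optional factor-level overrides, as in [read_metadata()].
#' @return validated data.frame (copies strictly positive).
#' @export
read_genes <- function(path, levels = NULL) {
  gn <- read_tsv(path)
  require_cols(gn, c("gene", "treatment", "compartment", "stage",
                     "tech_rep", "copies"), "gene table")
  bad <- setdiff(unique(gn$gene), gene_assays())
  if (length(bad)) {
    stopf("gene table has unknown assay(s): %s", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(gn$copies)) || any(gn$copies <= 0)) {
    stopf("gene copies must be strictly positive")
  }
  lv <- list(treatments = levels$treatments %||% .TREATMENT_LEVELS,
             compartments = levels$compartments %||% .COMPARTMENT_LEVELS,
             stages = levels$stages %||% .STAGE_LEVELS)
  for (col in c("treatment", "compartment", "stage")) {
    allowed <- switch(col, treatment = lv$treatments,
                      compartment = lv$compartments, stage = lv$stages)
    badlv <- setdiff(unique(gn[[col]]), allowed)
    if (length(badlv)) {
      stopf("gene table has unknown %s level(s): %s", col,
            paste(badlv, collapse = ", "))
    }
  }
  tab <- table(gn$gene, paste(gn$treatment, gn$compartment, gn$stage))
  if (any(tab != tab[1, 1])) {
    stopf("gene table is unbalanced: unequal tech_rep counts per cell")
  }
  gn
}

#' Export a co-occurrence network
#'
#' Writes an edge-list TSV (source, target, rho, p, q, sign) and, when
#' `graphml` is given, a GraphML file preserving node attributes.
#'
#' @param net an igraph network from [build_network()].
#' @param edge_path output TSV path.
#' @param graphml optional output GraphML path.
#' @export
write_network <- function(net, edge_path, graphml = NULL) {
  if (igraph::ecount(net) > 0) {
    el <- igraph::as_data_frame(net, what = "edges")
    colnames(el)[1:2] <- c("source", "target")
  } else {
    el <- data.frame(source = character(0), target = character(0),
                     rho = numeric(0), p = numeric(0), q = numeric(0),
                     sign = character(0))
  }
  write_tsv(el, edge_path)
  if (!is.null(graphml)) igraph::write_graph(net, graphml, format = "graphml")
  invisible(edge_path)
}
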