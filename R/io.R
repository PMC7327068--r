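#' @include AllClasses.R AllGenerics.R
NULL

# Distinct, named validation errors: every reader failure carries a
# condition class prefixed "cernaTriad_" so callers can test for the exact
# failure mode rather than matching message text.
.err <- function(class, msg, call. = NULL) {
  stop(errorCondition(msg, class = c(paste0("cernaTriad_", class), "error",
                                     "condition")))
}

.readTsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "",
                    comment.char = "")
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
}

#' Read an expression matrix with its sample sheet
#'
#' Reads a features-by-samples TSV (first column: feature id; remaining
#' columns: one per sample) and a two-column sample sheet TSV
#' (\code{sample}, \code{group}), and returns a validated
#' \linkS4class{LayerExperiment}. Column order is taken from the matrix
#' file.
#'
#' Failure modes raise distinct condition classes:
#' \code{cernaTriad_duplicate_feature} (a feature id listed twice),
#' \code{cernaTriad_unassigned_sample} (a matrix column absent from the
#' sheet), and \code{cernaTriad_invalid_value} (negative, missing or
#' non-numeric abundance).
#'
#' @param path expression matrix TSV.
#' @param sampleSheetPath sample sheet TSV with columns sample, group.
#' @param layer one of \code{\link{RNA_LAYERS}}; declared, never inferred.
#' @return A \linkS4class{LayerExperiment}.
#' @export
readExpression <- function(path, sampleSheetPath, layer) {
  df <- .readTsv(path)
  if (ncol(df) < 2L)
    .err("invalid_value", "expression file needs a feature column and at least one sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    .err("duplicate_feature",
         paste("duplicate feature:",
               paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  sheet <- .readTsv(sampleSheetPath)
  if (!all(c("sample", "group") %in% colnames(sheet)))
    .err("invalid_value", "sample sheet must have columns 'sample' and 'group'")
  samples <- colnames(df)[-1L]
  missing <- setdiff(samples, sheet$sample)
  if (length(missing))
    .err("unassigned_sample",
         paste("unassigned sample:", paste(missing, collapse = ", ")))
  vals <- df[, -1L, drop = FALSE]
  num <- vapply(vals, function(col) suppressWarnings(as.numeric(col)),
                numeric(nrow(df)))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(ids, samples))
  if (anyNA(num) || any(!is.finite(num)))
    .err("invalid_value", "non-numeric or missing abundance value")
  if (any(num < 0))
    .err("invalid_value", "negative abundance value")
  LayerExperiment(num, setNames(as.character(sheet$group), sheet$sample),
                  layer)
}

#' Write an expression matrix and its sample sheet
#'
#' @param x a \linkS4class{LayerExperiment}.
#' @param path output TSV for the matrix (feature id column
#'   \code{feature_id}, one column per sample).
#' @param sampleSheetPath optional output TSV for the sample sheet.
#' @return invisibly, \code{path}.
#' @export
writeExpression <- function(x, path, sampleSheetPath = NULL) {
  m <- counts(x)
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTsv(df, path)
  if (!is.null(sampleSheetPath)) {
    g <- sampleGroups(x)
    .writeTsv(data.frame(sample = names(g), group = unname(g)),
              sampleSheetPath)
  }
  invisible(path)
}

#' Read a gene-set GMT file
#'
#' Standard GMT: one set per line, tab-separated
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}. A line with fewer
#' than three fields raises \code{cernaTriad_malformed_gmt} (an error, not
#' a skip). Duplicate genes within a set are collapsed.
#'
#' @param path GMT file.
#' @return A \linkS4class{PathwaySets}.
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    .err("malformed_gmt",
         paste("GMT line with fewer than 3 fields at line", bad[1L]))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  desc <- setNames(vapply(parts, `[[`, "", 2L), names(sets))
  PathwaySets(sets, desc)
}

#' Write a gene-set GMT file
#' @param x a \linkS4class{PathwaySets}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeGMT <- function(x, path) {
  lines <- vapply(names(x), function(nm)
    paste(c(nm, setDescriptions(x)[[nm]], geneSets(x)[[nm]]),
          collapse = "\t"), "")
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a miRNA target map TSV
#'
#' Expects columns \code{mirna_id}, \code{target_id}, \code{target_layer}
#' (the export format of sequence-based target prediction tables).
#' Duplicate pairs raise \code{cernaTriad_duplicate_pair}.
#'
#' @param path TSV file.
#' @return A \linkS4class{TargetMap}.
#' @export
readTargetMap <- function(path) {
  df <- .readTsv(path)
  need <- c("mirna_id", "target_id", "target_layer")
  if (!all(need %in% colnames(df)))
    .err("invalid_value",
         paste("target map needs columns", paste(need, collapse = ", ")))
  if (anyDuplicated(df[, c("mirna_id", "target_id")]))
    .err("duplicate_pair", "duplicate (mirna_id, target_id) pair")
  TargetMap(df[, need])
}

#' Write a miRNA target map TSV
#' @param x a \linkS4class{TargetMap}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeTargetMap <- function(x, path) {
  .writeTsv(targetPairs(x), path)
  invisible(path)
}

#' Export a network as Cytoscape-readable SIF plus an edge-attribute TSV
#'
#' Writes \code{<prefix>.sif} (\code{source<TAB>interaction<TAB>target},
#' zero data lines for an empty network) and \code{<prefix>_edges.tsv}
#' with columns source, target, interaction_type, r, p_adj, weight
#' (header-only when empty).
#'
#' @param network a \linkS4class{CernaNetwork}.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
writeEdgeList <- function(network, prefix) {
  e <- networkEdges(network)
  sif <- paste0(prefix, ".sif")
  attr <- paste0(prefix, "_edges.tsv")
  writeLines(if (nrow(e)) paste(e$source, e$interaction_type, e$target,
                                sep = "\t") else character(), sif)
  .writeTsv(e[, c("source", "target", "interaction_type", "r", "p_adj",
                  "weight")], attr)
  invisible(c(sif = sif, edges = attr))
}

#' Read back an edge-attribute TSV written by writeEdgeList
#' @param path the \code{_edges.tsv} file.
#' @return data.frame of edges.
#' @export
readEdgeList <- function(path) {
  df <- .readTsv(path)
  need <- c("source", "target", "interaction_type", "r", "p_adj", "weight")
  if (!all(need %in% colnames(df)))
    .err("invalid_value",
         paste("edge table needs columns", paste(need, collapse = ", ")))
  for (cn in c("r", "p_adj", "weight")) df[[cn]] <- as.numeric(df[[cn]])
  df
}

#' Write every artifact of a simulated dataset to a directory
#'
#' Emits, under \code{dir}: one expression TSV per layer plus a shared
#' sample sheet, the target map TSV, the pathway GMT, the glomerulus-grade
#' and injury TSVs, the Ct TSV, and the ground-truth manifest as JSON.
#'
#' @param sim a \linkS4class{SimulatedDataset}.
#' @param dir output directory (created if needed).
#' @return invisibly, named vector of the files written.
#' @export
writeDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeExpression(sim@mrna, p("mrna.tsv"), p("samples.tsv"))
  writeExpression(sim@mirna, p("mirna.tsv"))
  writeExpression(sim@lncrna, p("lncrna.tsv"))
  writeTargetMap(sim@targetMap, p("target_map.tsv"))
  writeGMT(sim@pathways, p("pathways.gmt"))
  .writeTsv(sim@glomeruli, p("glomeruli.tsv"))
  .writeTsv(sim@injury, p("injury.tsv"))
  .writeTsv(sim@ct, p("ct.tsv"))
  tr <- groundTruth(sim)
  jsonlite::write_json(list(
    de_features = tr@deFeatures, mirna_pairs = tr@mirnaPairs,
    sponge_triads = tr@spongeTriads,
    enriched_pathways = tr@enrichedPathways), p("manifest.json"),
    dataframe = "columns", digits = NA)
  files <- c("mrna.tsv", "samples.tsv", "mirna.tsv", "lncrna.tsv",
             "target_map.tsv", "pathways.gmt", "glomeruli.tsv",
             "injury.tsv", "ct.tsv", "manifest.json")
  invisible(setNames(file.path(dir, files), files))
}
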