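#' @include AllClasses.R AllGenerics.R simulate.R io.R scoring.R
#' @include differential.R enrichment.R networks.R
NULL

.checkThresholds <- function(th) {
  need <- c("fcUp", "fcDown", "pMax", "corr", "minOverlap", "adjP")
  if (!all(need %in% names(th)))
    .err("invalid_threshold",
         paste("missing threshold:", paste(setdiff(need, names(th)),
                                           collapse = ", ")))
  with(th, {
    if (!(fcDown < 1 && 1 < fcUp))
      .err("invalid_threshold", "need fcDown < 1 < fcUp")
    if (pMax <= 0 || pMax >= 1)
      .err("invalid_threshold", "pMax must lie in (0, 1)")
    if (corr <= 0 || corr > 1)
      .err("invalid_threshold", "corr must lie in (0, 1]")
    if (adjP <= 0 || adjP > 1)
      .err("invalid_threshold", "adjP must lie in (0, 1]")
    if (minOverlap < 0)
      .err("invalid_threshold", "minOverlap must be >= 0")
  })
  invisible(th)
}

#' Default analysis thresholds
#'
#' The thresholds of the published analysis: DEG fold change above 1.5 or
#' below 0.67 at t-test p < 0.05; coexpression |r| at or above 0.8 (signed
#' -0.8 for miRNA-target edges); pathway reporting at Fisher p < 0.05 with
#' at least 3 DEGs; network filtering at BH-adjusted p < 0.05.
#'
#' @param fcUp,fcDown,pMax DEG rule.
#' @param corr correlation threshold for all network legs.
#' @param minOverlap minimum DEGs for a reported pathway.
#' @param adjP adjusted-p cutoff for the filtered network view.
#' @return named list of thresholds (validated).
#' @export
pipelineThresholds <- function(fcUp = 1.5, fcDown = 0.67, pMax = 0.05,
                               corr = 0.8, minOverlap = 3, adjP = 0.05) {
  .checkThresholds(list(fcUp = fcUp, fcDown = fcDown, pMax = pMax,
                        corr = corr, minOverlap = minOverlap, adjP = adjP))
}

#' Run the full analysis end to end on a simulated dataset
#'
#' One reproducible run of simulate -> score -> differential expression ->
#' enrichment -> ceRNA network, returning (and optionally writing) every
#' table plus a machine-readable summary. Identical config and thresholds
#' give an identical summary.
#'
#' The summary records: DEG counts for every pairwise contrast (mRNA
#' layer), the NC-vs-OC DEG tables' up/down counts per layer, reported
#' pathways, edge counts by interaction type, triad counts before and
#' after the adjusted-p filter, group means of the glomerular sclerosis
#' and tubulointerstitial injury indices, the PC1-pathology correlation,
#' and - since the simulator's ground truth is at hand - recovery metrics
#' (fraction of planted DE features called with the correct direction,
#' fraction of planted sponge triads recovered, number of decoy triads,
#' and whether the planted pathway ranks first among reported pathways).
#'
#' @param config a \linkS4class{SimConfig} (or an already-simulated
#'   \linkS4class{SimulatedDataset}).
#' @param thresholds list from \code{\link{pipelineThresholds}}; validated
#'   before any computation.
#' @param outdir optional directory; when given, all input artifacts,
#'   result tables, network files (SIF + attributes) and
#'   \code{summary.json} are written there.
#' @return invisibly, a list: \code{summary} (the JSON-serialisable
#'   summary), \code{deg} (per-layer NC-vs-OC tables), \code{degCounts},
#'   \code{enrichment}, \code{network}, \code{filteredNetwork},
#'   \code{scores}, \code{dataset}.
#' @export
runPipeline <- function(config = SimConfig(),
                        thresholds = pipelineThresholds(),
                        outdir = NULL) {
  .checkThresholds(thresholds)
  sim <- if (is(config, "SimulatedDataset")) config
         else simulateDataset(config)
  cfg <- sim@config
  truth <- groundTruth(sim)

  # --- histopathology scores -------------------------------------------
  gradeCols <- grep("^g\\d+$", colnames(sim@glomeruli))
  gsiPerAnimal <- setNames(
    apply(sim@glomeruli[, gradeCols, drop = FALSE], 1,
          function(g) gsi(as.integer(g))),
    sim@glomeruli$animal)
  tiiPerAnimal <- setNames(tii(sim@injury$injury_percent),
                           sim@injury$animal)
  gsiSummary <- groupSummary(gsiPerAnimal, sim@glomeruli$group)
  tiiSummary <- groupSummary(as.numeric(tiiPerAnimal), sim@injury$group)
  rel <- ddct(sim@ct, referenceGene = .CT_REFERENCE,
              calibratorGroup = "NC")

  # --- differential expression -----------------------------------------
  degArgs <- list(fcUp = thresholds$fcUp, fcDown = thresholds$fcDown,
                  pMax = thresholds$pMax)
  deg <- lapply(c(mRNA = "mRNA", miRNA = "miRNA", lncRNA = "lncRNA"),
                function(ly) do.call(callDegs,
                  c(list(expressionLayer(sim, ly), "NC", "OC"), degArgs)))
  dcounts <- do.call(degCounts, c(list(sim@mrna), degArgs))

  # --- pathway enrichment ----------------------------------------------
  degIds <- deg$mRNA$feature[deg$mRNA$call != "ns"]
  enr <- enrich(degIds, rownames(sim@mrna), sim@pathways,
                minOverlap = thresholds$minOverlap, pMax = thresholds$pMax)

  # --- ceRNA network ----------------------------------------------------
  net <- buildCerna(sim@lncrna, sim@mirna, sim@mrna, sim@targetMap,
                    degTables = deg, threshold = thresholds$corr)
  fnet <- filterByAdjustedP(net, alpha = thresholds$adjP)

  # --- PC1 versus pathology --------------------------------------------
  pc1 <- pc1Pathology(sim@mrna, gsiPerAnimal)

  # --- recovery against the planted truth ------------------------------
  tab <- deg$mRNA[match(truth@deFeatures$feature_id, deg$mRNA$feature), ]
  deRecovery <- mean(tab$call == truth@deFeatures$direction)
  tr <- networkTriads(net)
  triadKey <- paste(tr$lncrna, tr$mirna, tr$mrna)
  plantedKey <- paste(truth@spongeTriads$lncrna_id,
                      truth@spongeTriads$mirna_id,
                      truth@spongeTriads$mrna_id)
  triadRecovery <- if (length(plantedKey))
    mean(plantedKey %in% triadKey) else NA_real_
  # triads built on a decoy (non-functional) target-map pair
  trueMg <- paste(truth@mirnaPairs$mirna_id, truth@mirnaPairs$target_id)
  decoyTriads <- sum(!paste(tr$mirna, tr$mrna) %in% trueMg)
  reported <- enr[enr$reported, ]
  plantedTop <- nrow(reported) > 0 &&
    reported$pathway[1L] %in% truth@enrichedPathways

  summary <- list(
    seed = cfg@seed,
    thresholds = thresholds,
    deg_counts = as.list(setNames(
      dcounts[upper.tri(dcounts)],
      outer(rownames(dcounts), colnames(dcounts),
            function(a, b) paste0(a, "_", b))[upper.tri(dcounts)])),
    degs_nc_oc = lapply(deg, function(d)
      list(up = sum(d$call == "up"), down = sum(d$call == "down"))),
    reported_pathways = reported$pathway,
    edge_counts = as.list(table(networkEdges(net)$interaction_type)),
    triads = nrow(tr),
    triads_adjusted = nrow(networkTriads(fnet)),
    gsi_group_mean = as.list(tapply(gsiPerAnimal, sim@glomeruli$group,
                                    mean)[TREATMENT_GROUPS]),
    tii_group_mean = as.list(tapply(as.numeric(tiiPerAnimal),
                                    sim@injury$group,
                                    mean)[TREATMENT_GROUPS]),
    pc1_pathology_r = pc1$r,
    recovery = list(de_direction = deRecovery,
                    sponge_triads = triadRecovery,
                    decoy_triads = decoyTriads,
                    planted_pathway_top = plantedTop))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeDataset(sim, file.path(outdir, "input"))
    p <- function(f) file.path(outdir, f)
    for (ly in names(deg))
      .writeTsv(deg[[ly]], p(sprintf("deg_%s_NC_vs_OC.tsv", ly)))
    .writeTsv(as.data.frame(dcounts), p("deg_counts.tsv"))
    .writeTsv(enr, p("enrichment.tsv"))
    .writeTsv(gsiSummary, p("gsi_summary.tsv"))
    .writeTsv(tiiSummary, p("tii_summary.tsv"))
    .writeTsv(rel, p("qpcr_rel_expr.tsv"))
    writeEdgeList(net, p("cerna"))
    writeEdgeList(fnet, p("cerna_filtered"))
    .writeTsv(networkTriads(net), p("triads.tsv"))
    jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(list(summary = summary, deg = deg, degCounts = dcounts,
                 enrichment = enr, network = net, filteredNetwork = fnet,
                 scores = list(gsi = gsiPerAnimal, tii = tiiPerAnimal,
                               gsiSummary = gsiSummary,
                               tiiSummary = tiiSummary, relExpr = rel),
                 pc1 = pc1, dataset = sim))
}
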