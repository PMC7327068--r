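#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats dbinom
NULL

#' Recognised RNA layers
#'
#' The three RNA layers the pipeline profiles jointly.
#' @export
RNA_LAYERS <- c("mRNA", "miRNA", "lncRNA")

#' Treatment group labels
#'
#' The five-arm design of the renal-interstitial-fibrosis experiment:
#' normal control (NC), operated model control (OC), low-dose treatment (LK),
#' high-dose treatment (HK), and losartan comparator (LOS).
#' @export
TREATMENT_GROUPS <- c("NC", "OC", "LK", "HK", "LOS")

#' LayerExperiment: one RNA layer with its sample design
#'
#' A \linkS4class{SummarizedExperiment} holding a features-by-samples
#' abundance matrix (assay \code{"counts"}) for a single RNA layer, with the
#' sample-to-group assignment in \code{colData(x)$group}.
#'
#' Validity requires unique feature and sample identifiers, finite
#' non-negative values, a group label for every sample, and a declared layer
#' from \code{\link{RNA_LAYERS}} (the layer is declared, never inferred from
#' identifiers).
#'
#' @slot layer character(1), one of \code{RNA_LAYERS}.
#' @export
setClass("LayerExperiment",
  contains = "SummarizedExperiment",
  slots = c(layer = "character")
)

setValidity("LayerExperiment", function(object) {
  msg <- character()
  if (length(object@layer) != 1L || !object@layer %in% RNA_LAYERS)
    msg <- c(msg, sprintf("'layer' must be one of %s",
                          paste(RNA_LAYERS, collapse = ", ")))
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
      msg <- c(msg, "duplicate or missing feature ids")
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
      msg <- c(msg, "duplicate or missing sample ids")
    if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0))
      msg <- c(msg, "abundance values must be finite and non-negative")
  }
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  else if (anyNA(SummarizedExperiment::colData(object)$group))
    msg <- c(msg, "every sample must have a group label")
  if (length(msg)) msg else TRUE
})

#' Construct a LayerExperiment
#'
#' @param counts numeric matrix, features x samples, with dimnames.
#' @param groups named character vector or factor mapping sample id to group
#'   label; names must cover all columns of \code{counts}. Unnamed vectors of
#'   length \code{ncol(counts)} are taken in column order.
#' @param layer one of \code{\link{RNA_LAYERS}}.
#' @return A \linkS4class{LayerExperiment}.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' le <- LayerExperiment(m, c(s1 = "NC", s2 = "OC"), "mRNA")
#' @export
LayerExperiment <- function(counts, groups, layer) {
  counts <- as.matrix(counts)
  if (is.null(names(groups))) {
    if (length(groups) != ncol(counts))
      stop("unnamed 'groups' must have one entry per sample")
    names(groups) <- colnames(counts)
  }
  missing <- setdiff(colnames(counts), names(groups))
  if (length(missing))
    stop("unassigned sample: no group for ", paste(missing, collapse = ", "))
  cd <- S4Vectors::DataFrame(
    group = as.character(groups[colnames(counts)]),
    row.names = colnames(counts)
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd
  )
  new("LayerExperiment", se, layer = layer)
}

#' TargetMap: predicted miRNA-target interaction pairs
#'
#' Holds (miRNA, target, target layer) triples such as those exported from
#' sequence-based target prediction databases. Pairs are unique; the target
#' layer is mRNA or lncRNA.
#'
#' @slot pairs data.frame with columns \code{mirna_id}, \code{target_id},
#'   \code{target_layer}.
#' @export
setClass("TargetMap", slots = c(pairs = "data.frame"))

setValidity("TargetMap", function(object) {
  p <- object@pairs
  need <- c("mirna_id", "target_id", "target_layer")
  if (!all(need %in% colnames(p)))
    return(sprintf("pairs must have columns %s", paste(need, collapse = ", ")))
  if (nrow(p) && anyDuplicated(p[, c("mirna_id", "target_id")]))
    return("duplicate (mirna_id, target_id) pair")
  if (nrow(p) && !all(p$target_layer %in% c("mRNA", "lncRNA")))
    return("target_layer must be 'mRNA' or 'lncRNA'")
  TRUE
})

#' @rdname TargetMap-class
#' @param pairs data.frame with columns \code{mirna_id}, \code{target_id},
#'   \code{target_layer}.
#' @export
TargetMap <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  new("TargetMap", pairs = pairs)
}

#' PathwaySets: named gene sets with descriptions
#'
#' In-memory form of a GMT file: named, non-empty gene sets (duplicates
#' within a set collapsed) with one description string per set.
#'
#' @slot sets named list of character vectors of gene ids.
#' @slot descriptions named character, same names as \code{sets}.
#' @export
setClass("PathwaySets",
  slots = c(sets = "list", descriptions = "character"))

setValidity("PathwaySets", function(object) {
  msg <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "sets must have unique names")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "gene sets must be non-empty")
  if (any(vapply(object@sets, anyDuplicated, 0L) > 0L))
    msg <- c(msg, "duplicate gene ids within a set")
  if (!identical(names(object@sets), names(object@descriptions)))
    msg <- c(msg, "descriptions must parallel sets")
  if (length(msg)) msg else TRUE
})

#' @rdname PathwaySets-class
#' @param sets named list of character vectors (duplicates collapsed).
#' @param descriptions optional named character; defaults to empty strings.
#' @export
PathwaySets <- function(sets, descriptions = NULL) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(sets)), names(sets))
  new("PathwaySets", sets = sets,
      descriptions = descriptions[names(sets)])
}

#' CernaNetwork: typed nodes, signed weighted edges, and ceRNA triads
#'
#' The joint network over mRNA, miRNA and lncRNA nodes. Edge types are
#' \code{coexpression}, \code{miRNA-target}, \code{lncRNA-miRNA} and
#' \code{lncRNA-mRNA}; each edge carries its Pearson r, BH-adjusted p and
#' weight \eqn{-\log_{10}(p_{adj})}. Triads record (lncRNA, miRNA, mRNA)
#' triples consistent with the sponge sign pattern; every triad's three
#' edges are present in the edge table.
#'
#' @slot nodes data.frame: \code{id}, \code{layer}, \code{regulation}.
#' @slot edges data.frame: \code{source}, \code{target},
#'   \code{interaction_type}, \code{r}, \code{p_adj}, \code{weight}.
#' @slot triads data.frame: \code{lncrna}, \code{mirna}, \code{mrna},
#'   \code{r_lm}, \code{r_mg}, \code{r_lg}, \code{min_p_adj}.
#' @export
setClass("CernaNetwork",
  slots = c(nodes = "data.frame", edges = "data.frame",
            triads = "data.frame"))

setValidity("CernaNetwork", function(object) {
  e <- object@edges
  msg <- character()
  need <- c("source", "target", "interaction_type", "r", "p_adj", "weight")
  if (!all(need %in% colnames(e)))
    return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
  if (nrow(e) && any(e$weight < 0, na.rm = TRUE))
    msg <- c(msg, "edge weights must be non-negative")
  tr <- object@triads
  if (nrow(tr)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    ek <- key(e$source, e$target)
    have <- key(tr$lncrna, tr$mirna) %in% ek &
            key(tr$mirna, tr$mrna) %in% ek &
            key(tr$lncrna, tr$mrna) %in% ek
    if (!all(have))
      msg <- c(msg, "every triad's three edges must be present in edges")
    if (any(tr$r_lm > 0) || any(tr$r_mg > 0))
      msg <- c(msg, "triad correlation signs violate the sponge pattern")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname CernaNetwork-class
#' @param nodes,edges,triads data.frames as described in the class slots;
#'   defaults are empty tables with the right columns.
#' @export
CernaNetwork <- function(nodes = NULL, edges = NULL, triads = NULL) {
  if (is.null(nodes))
    nodes <- data.frame(id = character(), layer = character(),
                        regulation = character())
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        interaction_type = character(), r = numeric(),
                        p_adj = numeric(), weight = numeric())
  if (is.null(triads))
    triads <- data.frame(lncrna = character(), mirna = character(),
                         mrna = character(), r_lm = numeric(),
                         r_mg = numeric(), r_lg = numeric(),
                         min_p_adj = numeric())
  rownames(nodes) <- rownames(edges) <- rownames(triads) <- NULL
  new("CernaNetwork", nodes = nodes, edges = edges, triads = triads)
}

#' CorrelationResult: pairwise Pearson correlations with p-values
#'
#' Pearson correlations between feature profiles across shared samples,
#' with two-sided p-values from the t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} and BH-adjusted p-values. For a single
#' input matrix the result is symmetric with unit diagonal and the BH family
#' is the strictly-upper triangle; for a cross-layer pair it is rows-of-x by
#' columns-of-y and the BH family is all entries.
#'
#' @slot r,p,padj numeric matrices of identical dimension.
#' @slot nSamples integer, samples used.
#' @slot symmetric logical, whether rows and columns index the same features.
#' @export
setClass("CorrelationResult",
  slots = c(r = "matrix", p = "matrix", padj = "matrix",
            nSamples = "integer", symmetric = "logical"))

setValidity("CorrelationResult", function(object) {
  msg <- character()
  if (!identical(dim(object@r), dim(object@p)) ||
      !identical(dim(object@r), dim(object@padj)))
    msg <- c(msg, "r, p, padj must share dimensions")
  if (any(abs(object@r) > 1 + 1e-8, na.rm = TRUE))
    msg <- c(msg, "|r| must not exceed 1")
  if (any(object@p < 0 | object@p > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (object@symmetric &&
      !isTRUE(all.equal(object@r, t(object@r), tolerance = 1e-12)))
    msg <- c(msg, "symmetric result must have a symmetric r matrix")
  if (length(msg)) msg else TRUE
})

#' SimConfig: parameters of the synthetic multi-omic generator
#'
#' All knobs of the five-group (NC, OC, LK, HK, LOS) negative-binomial
#' simulator. Counts for feature i in sample s are drawn
#' NB(mu_is, dispersion) with variance mu + dispersion * mu^2. Planted
#' differentially expressed mRNAs shift their group mean by
#' \code{effectLog2fc} scaled by the group's \code{doseProfile} entry;
#' planted miRNA-target pairs share a per-sample latent regulator with
#' opposite sign so their Pearson correlation concentrates near
#' \code{-sqrt(repressionCoupling)}; sponge lncRNAs load with the mRNA and
#' against the miRNA.
#'
#' @slot nPerGroup animals (= RNA samples) per group.
#' @slot nMrna,nMirna,nLncrna features per layer.
#' @slot baselineMean expected linear count for a null feature.
#' @slot nbDispersion negative-binomial dispersion.
#' @slot nDeMrna planted treatment-responsive mRNAs.
#' @slot effectLog2fc mean planted |log2 FC| of OC vs NC.
#' @slot doseProfile named per-group multiplier on the effect; NC must be 0.
#' @slot nTrueMirnaPairs planted miRNA-mRNA repression pairs.
#' @slot repressionCoupling fraction of target variance explained by its
#'   miRNA (0..1); controls the attainable |r|.
#' @slot latentSd SD (log2 scale) of the shared latent regulator.
#' @slot plantedDispersion NB dispersion of the latent-driven (pair and
#'   sponge) features; kept low so the regulator, not counting noise,
#'   dominates their profiles. Their baseline is pinned at
#'   \code{baselineMean}.
#' @slot nSpongeTriads planted lncRNA-miRNA-mRNA sponge triads.
#' @slot decoyTargetFraction fraction of target-map rows that are
#'   non-functional decoys.
#' @slot nPathways,pathwaySize,nPlantedEnriched pathway-set parameters.
#' @slot glomProbs groups x 5 matrix of glomerulus grade probabilities
#'   (grades 0..4), rows summing to 1.
#' @slot injuryMean,injurySd named per-group tubulointerstitial injured-area
#'   percentages (mean and SD of a truncated normal).
#' @slot seed master RNG seed; per-layer child streams are derived from it.
#' @export
setClass("SimConfig",
  slots = c(
    nPerGroup = "integer", nMrna = "integer", nMirna = "integer",
    nLncrna = "integer", baselineMean = "numeric", nbDispersion = "numeric",
    nDeMrna = "integer", effectLog2fc = "numeric", doseProfile = "numeric",
    nTrueMirnaPairs = "integer", repressionCoupling = "numeric",
    latentSd = "numeric", plantedDispersion = "numeric",
    nSpongeTriads = "integer",
    decoyTargetFraction = "numeric", nPathways = "integer",
    pathwaySize = "integer", nPlantedEnriched = "integer",
    glomProbs = "matrix", injuryMean = "numeric", injurySd = "numeric",
    seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  cnt <- c(nPerGroup = object@nPerGroup, nMrna = object@nMrna,
           nMirna = object@nMirna, nLncrna = object@nLncrna,
           nPathways = object@nPathways, pathwaySize = object@pathwaySize)
  if (any(cnt < 1L))
    msg <- c(msg, "all feature/sample/pathway counts must be >= 1")
  if (object@nbDispersion < 0 || object@plantedDispersion < 0)
    msg <- c(msg, "dispersion must be >= 0")
  if (object@repressionCoupling < 0 || object@repressionCoupling > 1)
    msg <- c(msg, "repressionCoupling must lie in [0, 1]")
  if (object@decoyTargetFraction < 0 || object@decoyTargetFraction >= 1)
    msg <- c(msg, "decoyTargetFraction must lie in [0, 1)")
  if (!identical(sort(names(object@doseProfile)), sort(TREATMENT_GROUPS)))
    msg <- c(msg, "doseProfile must name exactly the five treatment groups")
  else if (object@doseProfile[["NC"]] != 0)
    msg <- c(msg, "doseProfile['NC'] must be 0")
  if (object@nDeMrna + object@nTrueMirnaPairs + object@nSpongeTriads >
      object@nMrna)
    msg <- c(msg, "planted mRNA sets exceed nMrna")
  if (object@nTrueMirnaPairs + object@nSpongeTriads > object@nMirna)
    msg <- c(msg, "planted miRNA sets exceed nMirna")
  if (object@nSpongeTriads > object@nLncrna)
    msg <- c(msg, "planted sponge triads exceed nLncrna")
  if (object@nPlantedEnriched > object@nPathways)
    msg <- c(msg, "nPlantedEnriched exceeds nPathways")
  if (!identical(dim(object@glomProbs),
                 c(length(TREATMENT_GROUPS), 5L)) ||
      any(abs(rowSums(object@glomProbs) - 1) > 1e-8) ||
      any(object@glomProbs < 0))
    msg <- c(msg, "glomProbs must be a groups x 5 probability matrix with rows summing to 1")
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param nPerGroup,nMrna,nMirna,nLncrna,baselineMean,nbDispersion,nDeMrna
#'   see slots.
#' @param effectLog2fc,doseProfile,nTrueMirnaPairs,repressionCoupling see
#'   slots.
#' @param latentSd,nSpongeTriads,decoyTargetFraction see slots.
#' @param nPathways,pathwaySize,nPlantedEnriched see slots.
#' @param glomProbs,injuryMean,injurySd see slots; by default derived from
#'   \code{doseProfile} so that histological severity tracks the
#'   transcriptomic dose response (grade ~ Binomial(4, 0.02 + 0.88 dose),
#'   injured-area mean 5 + 75 dose percent).
#' @param seed master RNG seed.
#' @export
SimConfig <- function(nPerGroup = 3, nMrna = 2000, nMirna = 300,
                      nLncrna = 500, baselineMean = 500,
                      nbDispersion = 0.05, nDeMrna = 300,
                      effectLog2fc = 2,
                      doseProfile = c(NC = 0, OC = 1, LK = 0.7,
                                      HK = 0.2, LOS = 0.4),
                      nTrueMirnaPairs = 20, repressionCoupling = 0.99,
                      latentSd = 1, plantedDispersion = 0.002,
                      nSpongeTriads = 5,
                      decoyTargetFraction = 0.5, nPathways = 20,
                      pathwaySize = 15, nPlantedEnriched = 1,
                      glomProbs = NULL, injuryMean = NULL, injurySd = NULL,
                      seed = 1) {
  dose <- doseProfile[TREATMENT_GROUPS]
  if (is.null(glomProbs)) {
    p <- pmin(pmax(0.02 + 0.88 * dose, 0), 1)
    glomProbs <- t(vapply(p, function(pi) dbinom(0:4, 4, pi), numeric(5)))
    dimnames(glomProbs) <- list(TREATMENT_GROUPS, paste0("grade", 0:4))
  }
  if (is.null(injuryMean))
    injuryMean <- setNames(5 + 75 * dose, TREATMENT_GROUPS)
  if (is.null(injurySd))
    injurySd <- setNames(rep(5, length(dose)), TREATMENT_GROUPS)
  new("SimConfig",
      nPerGroup = as.integer(nPerGroup), nMrna = as.integer(nMrna),
      nMirna = as.integer(nMirna), nLncrna = as.integer(nLncrna),
      baselineMean = baselineMean, nbDispersion = nbDispersion,
      nDeMrna = as.integer(nDeMrna), effectLog2fc = effectLog2fc,
      doseProfile = dose, nTrueMirnaPairs = as.integer(nTrueMirnaPairs),
      repressionCoupling = repressionCoupling, latentSd = latentSd,
      plantedDispersion = plantedDispersion,
      nSpongeTriads = as.integer(nSpongeTriads),
      decoyTargetFraction = decoyTargetFraction,
      nPathways = as.integer(nPathways),
      pathwaySize = as.integer(pathwaySize),
      nPlantedEnriched = as.integer(nPlantedEnriched),
      glomProbs = glomProbs, injuryMean = injuryMean[TREATMENT_GROUPS],
      injurySd = injurySd[TREATMENT_GROUPS], seed = as.integer(seed))
}

#' GroundTruth: the generator's planted effects
#'
#' Test-oracle record of everything the simulator planted: responsive
#' features with their direction, true miRNA-target pairs, sponge triads,
#' enriched pathways, and the per-feature group means used for generation.
#' Used only for recovery testing, never by the analysis itself.
#'
#' @slot deFeatures data.frame: \code{feature_id}, \code{direction}
#'   (up/down for OC vs NC), \code{log2fc}.
#' @slot mirnaPairs data.frame: \code{mirna_id}, \code{target_id},
#'   \code{sponge} (logical: pair belongs to a planted triad).
#' @slot spongeTriads data.frame: \code{lncrna_id}, \code{mirna_id},
#'   \code{mrna_id}.
#' @slot enrichedPathways character vector of planted pathway ids.
#' @slot groupMeans named list (per layer) of features x groups mean
#'   matrices.
#' @export
setClass("GroundTruth",
  slots = c(deFeatures = "data.frame", mirnaPairs = "data.frame",
            spongeTriads = "data.frame", enrichedPathways = "character",
            groupMeans = "list"))

#' SimulatedDataset: everything one simulator run emits
#'
#' @slot mrna,mirna,lncrna \linkS4class{LayerExperiment} per layer.
#' @slot targetMap \linkS4class{TargetMap} (true pairs plus decoys).
#' @slot pathways \linkS4class{PathwaySets}.
#' @slot glomeruli data.frame: \code{animal}, \code{group}, 40 grade columns.
#' @slot injury data.frame: \code{animal}, \code{group},
#'   \code{injury_percent}.
#' @slot ct data.frame: \code{sample}, \code{group}, \code{gene}, \code{ct}.
#' @slot truth \linkS4class{GroundTruth}.
#' @slot config the \linkS4class{SimConfig} used.
#' @export
setClass("SimulatedDataset",
  slots = c(mrna = "LayerExperiment", mirna = "LayerExperiment",
            lncrna = "LayerExperiment", targetMap = "TargetMap",
            pathways = "PathwaySets", glomeruli = "data.frame",
            injury = "data.frame", ct = "data.frame",
            truth = "GroundTruth", config = "SimConfig"))

setValidity("SimulatedDataset", function(object) {
  tr <- object@truth
  msg <- character()
  if (!all(tr@deFeatures$feature_id %in% rownames(object@mrna)))
    msg <- c(msg, "manifest DE features missing from the mRNA matrix")
  tp <- tr@mirnaPairs
  if (nrow(tp)) {
    mk <- paste(object@targetMap@pairs$mirna_id,
                object@targetMap@pairs$target_id)
    if (!all(paste(tp$mirna_id, tp$target_id) %in% mk))
      msg <- c(msg, "true miRNA pairs must be a subset of the target map")
  }
  if (length(msg)) msg else TRUE
})
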