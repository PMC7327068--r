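#' @include AllClasses.R
NULL

#' Layer of an expression object
#' @param x a \linkS4class{LayerExperiment}.
#' @return character(1), one of \code{\link{RNA_LAYERS}}.
#' @export
setGeneric("rnaLayer", function(x) standardGeneric("rnaLayer"))

#' @rdname rnaLayer
#' @export
setMethod("rnaLayer", "LayerExperiment", function(x) x@layer)

#' Sample-to-group assignment
#' @param x a \linkS4class{LayerExperiment}.
#' @return named character vector, sample id -> group label.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "LayerExperiment", function(x) {
  setNames(as.character(SummarizedExperiment::colData(x)$group),
           colnames(x))
})

#' Raw abundance matrix of a LayerExperiment
#' @param object a \linkS4class{LayerExperiment}.
#' @param ... ignored.
#' @return numeric matrix, features x samples.
#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "LayerExperiment", function(object, ...) {
  SummarizedExperiment::assay(object, "counts")
})

#' Interaction pairs of a TargetMap
#' @param x a \linkS4class{TargetMap}.
#' @return data.frame with columns mirna_id, target_id, target_layer.
#' @export
setGeneric("targetPairs", function(x) standardGeneric("targetPairs"))

#' @rdname targetPairs
#' @export
setMethod("targetPairs", "TargetMap", function(x) x@pairs)

#' @describeIn TargetMap-class number of pairs.
#' @param x a TargetMap.
#' @export
setMethod("length", "TargetMap", function(x) nrow(x@pairs))

#' Gene sets of a PathwaySets object
#' @param x a \linkS4class{PathwaySets}.
#' @return named list of character vectors.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname geneSets
#' @export
setMethod("geneSets", "PathwaySets", function(x) x@sets)

#' Set descriptions of a PathwaySets object
#' @param x a \linkS4class{PathwaySets}.
#' @return named character vector.
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))

#' @rdname setDescriptions
#' @export
setMethod("setDescriptions", "PathwaySets", function(x) x@descriptions)

#' @describeIn PathwaySets-class set names.
#' @param x a PathwaySets.
#' @export
setMethod("names", "PathwaySets", function(x) names(x@sets))

#' @describeIn PathwaySets-class number of sets.
#' @export
setMethod("length", "PathwaySets", function(x) length(x@sets))

#' Node table of a network
#' @param x a \linkS4class{CernaNetwork}.
#' @return data.frame of nodes.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname networkNodes
#' @export
setMethod("networkNodes", "CernaNetwork", function(x) x@nodes)

#' Edge table of a network
#' @param x a \linkS4class{CernaNetwork}.
#' @return data.frame of edges.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname networkEdges
#' @export
setMethod("networkEdges", "CernaNetwork", function(x) x@edges)

#' Sponge-triad table of a network
#' @param x a \linkS4class{CernaNetwork}.
#' @return data.frame of (lncRNA, miRNA, mRNA) triads.
#' @export
setGeneric("networkTriads", function(x) standardGeneric("networkTriads"))

#' @rdname networkTriads
#' @export
setMethod("networkTriads", "CernaNetwork", function(x) x@triads)

#' Correlation, p-value and adjusted-p matrices
#' @param x a \linkS4class{CorrelationResult}.
#' @return numeric matrix.
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))

#' @rdname corValues
#' @export
setMethod("corValues", "CorrelationResult", function(x) x@r)

#' @rdname corValues
#' @export
setGeneric("corPvalues", function(x) standardGeneric("corPvalues"))

#' @rdname corValues
#' @export
setMethod("corPvalues", "CorrelationResult", function(x) x@p)

#' @rdname corValues
#' @export
setGeneric("corAdjPvalues", function(x) standardGeneric("corAdjPvalues"))

#' @rdname corValues
#' @export
setMethod("corAdjPvalues", "CorrelationResult", function(x) x@padj)

#' Ground-truth manifest of a simulated dataset
#' @param x a \linkS4class{SimulatedDataset}.
#' @return a \linkS4class{GroundTruth}.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "SimulatedDataset", function(x) x@truth)

#' One RNA layer of a simulated dataset
#' @param x a \linkS4class{SimulatedDataset}.
#' @param layer one of \code{\link{RNA_LAYERS}}.
#' @return a \linkS4class{LayerExperiment}.
#' @export
setGeneric("expressionLayer",
           function(x, layer) standardGeneric("expressionLayer"))

#' @rdname expressionLayer
#' @export
setMethod("expressionLayer", "SimulatedDataset", function(x, layer) {
  layer <- match.arg(layer, RNA_LAYERS)
  switch(layer, mRNA = x@mrna, miRNA = x@mirna, lncRNA = x@lncrna)
})

setMethod("show", "LayerExperiment", function(object) {
  cat(sprintf("LayerExperiment (%s): %d features x %d samples\n",
              object@layer, nrow(object), ncol(object)))
  g <- table(SummarizedExperiment::colData(object)$group)
  cat("groups:", paste(sprintf("%s(%d)", names(g), g), collapse = " "), "\n")
})

setMethod("show", "TargetMap", function(object) {
  cat(sprintf("TargetMap: %d pairs (%d miRNAs, %d targets)\n",
              nrow(object@pairs), length(unique(object@pairs$mirna_id)),
              length(unique(object@pairs$target_id))))
})

setMethod("show", "PathwaySets", function(object) {
  cat(sprintf("PathwaySets: %d sets, sizes %s\n", length(object@sets),
              paste(range(lengths(object@sets)), collapse = "-")))
})

setMethod("show", "CernaNetwork", function(object) {
  cat(sprintf("CernaNetwork: %d nodes, %d edges, %d triads\n",
              nrow(object@nodes), nrow(object@edges), nrow(object@triads)))
  if (nrow(object@edges))
    print(table(object@edges$interaction_type))
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("CorrelationResult: %d x %d (%s), n = %d samples\n",
              nrow(object@r), ncol(object@r),
              if (object@symmetric) "symmetric" else "cross-layer",
              object@nSamples))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:\n")
  cat(sprintf("  %d samples/group x 5 groups; features: %d mRNA, %d miRNA, %d lncRNA\n",
              object@nPerGroup, object@nMrna, object@nMirna, object@nLncrna))
  cat(sprintf("  NB(mean %.0f, dispersion %.3f); %d DE mRNAs at mean |log2FC| %.2f\n",
              object@baselineMean, object@nbDispersion, object@nDeMrna,
              object@effectLog2fc))
  cat(sprintf("  %d miRNA pairs (coupling %.2f), %d sponge triads; seed %d\n",
              object@nTrueMirnaPairs, object@repressionCoupling,
              object@nSpongeTriads, object@seed))
})

setMethod("show", "SimulatedDataset", function(object) {
  cat("SimulatedDataset\n")
  show(object@mrna); show(object@mirna); show(object@lncrna)
  show(object@targetMap)
  cat(sprintf("truth: %d DE features, %d pairs, %d triads, %d enriched pathway(s)\n",
              nrow(object@truth@deFeatures), nrow(object@truth@mirnaPairs),
              nrow(object@truth@spongeTriads),
              length(object@truth@enrichedPathways)))
})
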