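#' @include AllClasses.R AllGenerics.R io.R differential.R
NULL

.corInput <- function(x, pseudocount) {
  if (is(x, "LayerExperiment"))
    normalizeCPM(x, log = TRUE, pseudocount = pseudocount)
  else as.matrix(x)
}

# p-values for Pearson r via the t transform t = r sqrt((n-2)/(1-r^2)).
.corP <- function(r, n) {
  r2 <- pmin(r^2, 1)
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  p
}

#' Pairwise Pearson correlations with t-transform p-values
#'
#' Correlates feature profiles across samples. With one input the result
#' is the symmetric within-set correlation matrix (unit diagonal; BH
#' adjustment over the strictly-upper triangle); with two inputs it is the
#' cross-set matrix (BH over all entries). LayerExperiments are placed on
#' the log2-CPM scale first; plain matrices are used as given. Constant
#' feature profiles cannot be correlated: they are dropped with a warning
#' (an error if nothing remains).
#'
#' @param x a \linkS4class{LayerExperiment} or features-x-samples matrix.
#' @param y optional second object sharing x's samples.
#' @param pseudocount log-transform pseudocount for LayerExperiments.
#' @return A \linkS4class{CorrelationResult}.
#' @examples
#' m <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(6, 4, 2))
#' corValues(correlate(m))["a", "c"]  # -1
#' @export
correlate <- function(x, y = NULL, pseudocount = 1) {
  a <- .corInput(x, pseudocount)
  sym <- is.null(y)
  b <- if (sym) a else .corInput(y, pseudocount)
  shared <- intersect(colnames(a), colnames(b))
  if (is.null(colnames(a)) || is.null(colnames(b)))
    shared <- if (ncol(a) == ncol(b)) seq_len(ncol(a)) else character()
  if (length(shared) < 3L)
    .err("too_few_samples", "need >= 3 shared samples to correlate")
  a <- a[, shared, drop = FALSE]
  b <- b[, shared, drop = FALSE]
  dropConst <- function(m, label) {
    const <- apply(m, 1, function(v) stats::sd(v) == 0)
    if (any(const))
      warning(sum(const), " constant ", label,
              " feature(s) excluded from correlation")
    m[!const, , drop = FALSE]
  }
  a <- dropConst(a, "row")
  b <- if (sym) a else dropConst(b, "column")
  if (!nrow(a) || !nrow(b))
    .err("all_constant", "all features constant; nothing to correlate")
  n <- length(shared)
  r <- stats::cor(t(a), t(b))
  p <- .corP(r, n)
  if (sym) {
    diag(p) <- 0
    up <- upper.tri(p)
    padj <- p
    padj[up] <- stats::p.adjust(p[up], "BH")
    padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
    diag(padj) <- 0
  } else {
    padj <- matrix(stats::p.adjust(p, "BH"), nrow(p), ncol(p),
                   dimnames = dimnames(p))
  }
  new("CorrelationResult", r = r, p = p, padj = padj,
      nSamples = as.integer(n), symmetric = sym)
}

#' Coexpression edges from a thresholded Pearson-power adjacency
#'
#' Network adjacency between two features is the soft power of their
#' Pearson correlation, \eqn{a_{ij} = |r_{ij}|^\beta}; only the strongest
#' correlations, \eqn{|r| \ge} \code{threshold} (inclusive, default 0.8),
#' become edges. At the default \eqn{\beta = 1} the adjacency is plain
#' |r|; larger powers give WGCNA-style soft thresholding. The sign of r is
#' retained alongside.
#'
#' @param corr a \linkS4class{CorrelationResult}.
#' @param threshold |r| cutoff in (0, 1].
#' @param beta soft power applied to |r|.
#' @return data.frame: source, target, r, adjacency, sign, p, p_adj.
#' @export
coexpressionEdges <- function(corr, threshold = 0.8, beta = 1) {
  stopifnot(is(corr, "CorrelationResult"))
  if (threshold <= 0 || threshold > 1)
    .err("invalid_threshold", "threshold must lie in (0, 1]")
  r <- corValues(corr)
  keep <- abs(r) >= threshold
  if (corr@symmetric) keep <- keep & upper.tri(r)
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(
    source = rownames(r)[idx[, 1L]], target = colnames(r)[idx[, 2L]],
    r = r[keep], adjacency = abs(r[keep])^beta, sign = sign(r[keep]),
    p = corPvalues(corr)[keep], p_adj = corAdjPvalues(corr)[keep],
    stringsAsFactors = FALSE)
  out[order(-abs(out$r), out$source, out$target), , drop = FALSE]
}

#' Target-map-constrained negative miRNA-target edges
#'
#' Keeps a (miRNA, target) edge iff the pair is predicted in the target
#' map AND its signed Pearson correlation is at or below \code{rMax}
#' (default -0.8): predicted targeting must be corroborated by strong
#' negative coexpression. BH adjustment is over the family of tested
#' (expressed, mapped) pairs.
#'
#' @param mirna a \linkS4class{LayerExperiment} (miRNA layer).
#' @param target a \linkS4class{LayerExperiment} (mRNA or lncRNA layer).
#' @param targetMap a \linkS4class{TargetMap}.
#' @param rMax signed correlation ceiling for keeping an edge.
#' @param pseudocount log-transform pseudocount.
#' @return data.frame: mirna_id, target_id, r, p, p_adj. Empty (with a
#'   warning) when no mapped pair is expressed.
#' @export
mirnaTargetEdges <- function(mirna, target, targetMap, rMax = -0.8,
                             pseudocount = 1) {
  pairs <- targetPairs(targetMap)
  pairs <- pairs[pairs$target_layer == rnaLayer(target), , drop = FALSE]
  pairs <- pairs[pairs$mirna_id %in% rownames(mirna) &
                 pairs$target_id %in% rownames(target), , drop = FALSE]
  empty <- data.frame(mirna_id = character(), target_id = character(),
                      r = numeric(), p = numeric(), p_adj = numeric())
  if (!nrow(pairs)) {
    warning("no target-map pair overlaps the expressed features")
    return(empty)
  }
  # library sizes must come from the full layer, not the mapped subset
  lm <- normalizeCPM(mirna, log = TRUE, pseudocount = pseudocount)
  lg <- normalizeCPM(target, log = TRUE, pseudocount = pseudocount)
  cr <- correlate(lm[unique(pairs$mirna_id), , drop = FALSE],
                  lg[unique(pairs$target_id), , drop = FALSE])
  ij <- cbind(match(pairs$mirna_id, rownames(corValues(cr))),
              match(pairs$target_id, colnames(corValues(cr))))
  r <- corValues(cr)[ij]
  p <- corPvalues(cr)[ij]
  padj <- stats::p.adjust(p, "BH")
  keep <- !is.na(r) & r <= rMax
  out <- data.frame(mirna_id = pairs$mirna_id[keep],
                    target_id = pairs$target_id[keep],
                    r = r[keep], p = p[keep], p_adj = padj[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$r), , drop = FALSE]
}

.nodeRegulation <- function(ids, degTable) {
  if (is.null(degTable)) return(rep(NA_character_, length(ids)))
  degTable$call[match(ids, degTable$feature)]
}

.edgeWeight <- function(padj) -log10(pmax(padj, 1e-300))

#' Build the lncRNA-miRNA-mRNA ceRNA network
#'
#' Implements the sponge logic: a (lncRNA, miRNA, mRNA) triad is emitted
#' iff the lncRNA-miRNA correlation is at or below \code{-threshold}, the
#' miRNA-mRNA correlation is at or below \code{-threshold} with the pair
#' predicted in the target map, and (optionally, on by default) the
#' lncRNA-mRNA correlation is at or above \code{+threshold} - the sign
#' pattern under which an up-regulated lncRNA sequesters its miRNA and
#' thereby de-represses the miRNA's mRNA target. Edges carry Pearson r,
#' BH-adjusted p (adjusted within each edge-type family) and weight
#' \eqn{-\log_{10}(p_{adj})}; node regulation direction is annotated from
#' per-layer DEG tables when supplied. Use
#' \code{\link{filterByAdjustedP}} for the adjusted-p < 0.05 view.
#'
#' @param lncrna,mirna,mrna \linkS4class{LayerExperiment}s sharing the
#'   same samples (mismatch raises \code{cernaTriad_sample_mismatch}).
#' @param targetMap a \linkS4class{TargetMap} of predicted miRNA targets.
#' @param degTables optional named list (mRNA, miRNA, lncRNA) of
#'   \code{\link{callDegs}} tables used to annotate node regulation.
#' @param threshold absolute correlation threshold (default 0.8).
#' @param requireLncMrna require the positive lncRNA-mRNA leg (the
#'   inferred third side of the sponge pattern); when FALSE triads are
#'   defined by the two negative legs only, and the lncRNA-mRNA edge is
#'   still recorded for reference.
#' @param pseudocount log-transform pseudocount.
#' @return A \linkS4class{CernaNetwork}.
#' @export
buildCerna <- function(lncrna, mirna, mrna, targetMap, degTables = NULL,
                       threshold = 0.8, requireLncMrna = TRUE,
                       pseudocount = 1) {
  if (threshold <= 0 || threshold > 1)
    .err("invalid_threshold", "threshold must lie in (0, 1]")
  sm <- colnames(mrna)
  if (!setequal(sm, colnames(mirna)) || !setequal(sm, colnames(lncrna)))
    .err("sample_mismatch", "the three layers must share the same samples")

  # miRNA-target leg: map-constrained negative correlation
  mg <- mirnaTargetEdges(mirna, mrna, targetMap, rMax = -threshold,
                         pseudocount = pseudocount)

  # lncRNA-miRNA leg: correlation only (no lncRNA target map is assumed)
  crLM <- correlate(lncrna, mirna, pseudocount = pseudocount)
  lmIdx <- which(corValues(crLM) <= -threshold, arr.ind = TRUE)
  lm <- data.frame(
    lncrna_id = rownames(corValues(crLM))[lmIdx[, 1L]],
    mirna_id = colnames(corValues(crLM))[lmIdx[, 2L]],
    r = corValues(crLM)[lmIdx], p = corPvalues(crLM)[lmIdx],
    p_adj = corAdjPvalues(crLM)[lmIdx], stringsAsFactors = FALSE)

  crLG <- correlate(lncrna, mrna, pseudocount = pseudocount)

  # candidate triads: join the two negative legs, then test the third
  triads <- merge(lm, mg, by = "mirna_id",
                  suffixes = c("_lm", "_mg"))
  if (nrow(triads)) {
    rl <- corValues(crLG)[cbind(match(triads$lncrna_id,
                                      rownames(corValues(crLG))),
                                match(triads$target_id,
                                      colnames(corValues(crLG))))]
    pl <- corPvalues(crLG)[cbind(match(triads$lncrna_id,
                                       rownames(corValues(crLG))),
                                 match(triads$target_id,
                                       colnames(corValues(crLG))))]
    triads$r_lg <- rl
    triads$p_lg <- pl
    if (requireLncMrna)
      triads <- triads[!is.na(rl) & rl >= threshold, , drop = FALSE]
  } else {
    triads$r_lg <- numeric()
    triads$p_lg <- numeric()
  }

  # lncRNA-mRNA edges: one per surviving triad pair, BH within the family
  lg <- unique(triads[, c("lncrna_id", "target_id", "r_lg", "p_lg")])
  lg$p_adj <- if (nrow(lg)) stats::p.adjust(lg$p_lg, "BH") else numeric()

  edges <- rbind(
    if (nrow(lm)) data.frame(source = lm$lncrna_id, target = lm$mirna_id,
                             interaction_type = "lncRNA-miRNA", r = lm$r,
                             p_adj = lm$p_adj,
                             weight = .edgeWeight(lm$p_adj),
                             stringsAsFactors = FALSE),
    if (nrow(mg)) data.frame(source = mg$mirna_id, target = mg$target_id,
                             interaction_type = "miRNA-target", r = mg$r,
                             p_adj = mg$p_adj,
                             weight = .edgeWeight(mg$p_adj),
                             stringsAsFactors = FALSE),
    if (nrow(lg)) data.frame(source = lg$lncrna_id, target = lg$target_id,
                             interaction_type = "lncRNA-mRNA", r = lg$r_lg,
                             p_adj = lg$p_adj,
                             weight = .edgeWeight(lg$p_adj),
                             stringsAsFactors = FALSE))
  if (is.null(edges))
    return(CernaNetwork())

  ids <- unique(c(edges$source, edges$target))
  layerOf <- function(id) {
    if (id %in% rownames(lncrna)) "lncRNA"
    else if (id %in% rownames(mirna)) "miRNA" else "mRNA"
  }
  layers <- vapply(ids, layerOf, "")
  reg <- rep(NA_character_, length(ids))
  for (ly in unique(layers)) {
    sel <- layers == ly
    reg[sel] <- .nodeRegulation(ids[sel], degTables[[ly]])
  }
  nodes <- data.frame(id = ids, layer = unname(layers),
                      regulation = reg, stringsAsFactors = FALSE)

  triadTab <- if (nrow(triads)) {
    adjLG <- lg$p_adj[match(paste(triads$lncrna_id, triads$target_id),
                            paste(lg$lncrna_id, lg$target_id))]
    data.frame(
      lncrna = triads$lncrna_id, mirna = triads$mirna_id,
      mrna = triads$target_id, r_lm = triads$r_lm, r_mg = triads$r_mg,
      r_lg = triads$r_lg,
      min_p_adj = pmin(triads$p_adj_lm, triads$p_adj_mg, adjLG),
      stringsAsFactors = FALSE)
  } else NULL
  CernaNetwork(nodes = nodes, edges = edges, triads = triadTab)
}

#' Adjusted-p filtered view of a ceRNA network
#'
#' Keeps edges whose BH-adjusted p is below \code{alpha} (default 0.05)
#' and the triads whose three edges all survive; nodes touching no
#' surviving edge are dropped.
#'
#' @param network a \linkS4class{CernaNetwork}.
#' @param alpha adjusted-p cutoff.
#' @return A filtered \linkS4class{CernaNetwork}.
#' @export
filterByAdjustedP <- function(network, alpha = 0.05) {
  e <- networkEdges(network)
  keep <- e$p_adj < alpha
  e <- e[keep, , drop = FALSE]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ek <- key(e$source, e$target)
  tr <- networkTriads(network)
  if (nrow(tr))
    tr <- tr[key(tr$lncrna, tr$mirna) %in% ek &
             key(tr$mirna, tr$mrna) %in% ek &
             key(tr$lncrna, tr$mrna) %in% ek, , drop = FALSE]
  nodes <- networkNodes(network)
  nodes <- nodes[nodes$id %in% c(e$source, e$target), , drop = FALSE]
  rownames(e) <- rownames(tr) <- rownames(nodes) <- NULL
  CernaNetwork(nodes = nodes, edges = e, triads = tr)
}
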