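#' @include AllClasses.R AllGenerics.R io.R
NULL

.asCountsMatrix <- function(x) {
  if (is(x, "LayerExperiment")) counts(x) else as.matrix(x)
}

#' Counts-per-million normalisation
#'
#' Scales every sample column to a library size of one million; optionally
#' returns log2(CPM + pseudocount), the scale used for t-tests, clustering
#' and PCA (fold changes use linear CPM).
#'
#' @param x a \linkS4class{LayerExperiment} or counts matrix.
#' @param log if TRUE return log2(CPM + pseudocount).
#' @param pseudocount added before log transform.
#' @return numeric matrix of the same dimension.
#' @examples
#' m <- matrix(c(50, 50, 10, 30), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
#' normalizeCPM(m)["a", "s1"]  # 5e5
#' @export
normalizeCPM <- function(x, log = FALSE, pseudocount = 1) {
  m <- .asCountsMatrix(x)
  lib <- colSums(m)
  if (any(lib <= 0))
    .err("zero_library",
         paste("all-zero sample column:",
               paste(colnames(m)[lib <= 0], collapse = ", ")))
  cpm <- sweep(m, 2, lib, "/") * 1e6
  if (log) log2(cpm + pseudocount) else cpm
}

# Vectorised two-sided Welch t-test across the rows of two matrices;
# cross-checked against stats::t.test in the test suite. Rows where both
# groups are constant get p = 1 at zero difference (and p = 0 otherwise).
.rowWelch <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zero <- se2 == 0
  p[zero] <- ifelse(abs(mb - ma)[zero] == 0, 1, 0)
  list(p = unname(p), t = unname(t), df = unname(df))
}

#' Call differentially expressed features between two groups
#'
#' Fold change is the ratio of linear group-mean CPM (with a symmetric
#' pseudocount guarding zero counts); significance is a two-sided Welch
#' t-test on log2(CPM + pseudocount). A feature is called \code{up} when
#' fold change exceeds \code{fcUp} and p is below \code{pMax}, \code{down}
#' when fold change is below \code{fcDown} and p is below \code{pMax},
#' otherwise \code{ns}. The inequalities are strict: a fold change of
#' exactly 1.5 or 0.67 is not significant. A BH-adjusted column is emitted
#' for information only; the call uses the raw p.
#'
#' @param x a \linkS4class{LayerExperiment}.
#' @param groupA,groupB group labels; fold change is groupB over groupA,
#'   so \code{up} means higher in \code{groupB}.
#' @param fcUp,fcDown,pMax call thresholds (defaults 1.5, 0.67, 0.05).
#' @param pseudocount CPM pseudocount for both the ratio and the log scale.
#' @return data.frame (one row per feature): feature, mean_a, mean_b,
#'   fold_change, log2fc, p, p_adj, call; the contrast is attached as
#'   \code{attr(x, "contrast")}.
#' @export
callDegs <- function(x, groupA, groupB, fcUp = 1.5, fcDown = 0.67,
                     pMax = 0.05, pseudocount = 1) {
  g <- sampleGroups(x)
  for (gg in c(groupA, groupB))
    if (!gg %in% g) .err("missing_group", paste("group absent:", gg))
  if (sum(g == groupA) < 2L || sum(g == groupB) < 2L)
    .err("too_few_values", "need >= 2 samples per group")
  cpm <- normalizeCPM(x, log = FALSE, pseudocount = pseudocount)
  lcpm <- log2(cpm + pseudocount)
  ia <- which(g == groupA); ib <- which(g == groupB)
  meanA <- rowMeans(cpm[, ia, drop = FALSE])
  meanB <- rowMeans(cpm[, ib, drop = FALSE])
  fc <- (meanB + pseudocount) / (meanA + pseudocount)
  w <- .rowWelch(lcpm[, ia, drop = FALSE], lcpm[, ib, drop = FALSE])
  call <- rep("ns", nrow(cpm))
  call[fc > fcUp & w$p < pMax] <- "up"
  call[fc < fcDown & w$p < pMax] <- "down"
  out <- data.frame(
    feature = rownames(cpm), mean_a = unname(meanA), mean_b = unname(meanB),
    fold_change = unname(fc), log2fc = unname(log2(fc)), p = w$p,
    p_adj = stats::p.adjust(w$p, "BH"), call = call,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast") <- c(groupA, groupB)
  out
}

#' DEG counts for every pairwise group contrast
#'
#' Symmetric matrix of differentially-expressed-feature counts per
#' unordered group pair, under the same fold-change + t-test rule as
#' \code{\link{callDegs}}. In the planted five-arm design the NC-OC cell is
#' expected to be the largest and NC-HK the smallest of the NC contrasts
#' (the high-dose arm sits nearest the normal control).
#'
#' @param x a \linkS4class{LayerExperiment}.
#' @param groups group labels to cross (default: the five treatment arms).
#' @inheritParams callDegs
#' @return symmetric integer matrix with zero diagonal.
#' @export
degCounts <- function(x, groups = TREATMENT_GROUPS, fcUp = 1.5,
                      fcDown = 0.67, pMax = 0.05, pseudocount = 1) {
  have <- unique(sampleGroups(x))
  missing <- setdiff(groups, have)
  if (length(missing))
    .err("missing_group",
         paste("group absent:", paste(missing, collapse = ", ")))
  k <- length(groups)
  out <- matrix(0L, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    tab <- callDegs(x, groups[i], groups[j], fcUp = fcUp, fcDown = fcDown,
                    pMax = pMax, pseudocount = pseudocount)
    n <- sum(tab$call != "ns")
    out[i, j] <- out[j, i] <- n
  }
  out
}

#' Ward hierarchical clustering of samples
#'
#' Ward-criterion agglomerative clustering (hclust method
#' \code{"ward.D2"}, the Ward objective on Euclidean distances) of the
#' log2-CPM sample profiles. Deterministic for a given matrix; duplicate
#' samples merge first at height 0.
#'
#' @param x a \linkS4class{LayerExperiment} or counts matrix
#'   (>= 2 samples).
#' @param pseudocount log-transform pseudocount.
#' @return an \code{\link[stats]{hclust}} object over samples.
#' @export
wardCluster <- function(x, pseudocount = 1) {
  m <- .asCountsMatrix(x)
  if (ncol(m) < 2L) .err("too_few_values", "need >= 2 samples to cluster")
  lcpm <- normalizeCPM(m, log = TRUE, pseudocount = pseudocount)
  stats::hclust(stats::dist(t(lcpm)), method = "ward.D2")
}

#' First principal component versus pathology score
#'
#' Extracts PC1 of the centred log2-CPM sample profiles, fixes its sign so
#' that the OC-group mean coordinate is positive (PCA signs are otherwise
#' arbitrary), and correlates the per-sample coordinate with a pathology
#' score (e.g. the glomerular sclerosis index of the same animal).
#'
#' @param x a \linkS4class{LayerExperiment}.
#' @param scores named numeric, pathology score per sample; names must
#'   cover all samples. A constant score vector raises
#'   \code{cernaTriad_constant_scores}.
#' @param pseudocount log-transform pseudocount.
#' @return list: \code{pc1} (named coordinates), \code{r}, \code{p}
#'   (Pearson correlation and two-sided p-value).
#' @export
pc1Pathology <- function(x, scores, pseudocount = 1) {
  g <- sampleGroups(x)
  missing <- setdiff(names(g), names(scores))
  if (length(missing))
    .err("unassigned_sample",
         paste("no pathology score for:", paste(missing, collapse = ", ")))
  s <- scores[names(g)]
  if (stats::sd(s) == 0)
    .err("constant_scores",
         "pathology scores are constant; correlation undefined")
  lcpm <- normalizeCPM(x, log = TRUE, pseudocount = pseudocount)
  pc <- stats::prcomp(t(lcpm), center = TRUE, scale. = FALSE)
  pc1 <- pc$x[, 1L]
  if ("OC" %in% g && mean(pc1[g == "OC"]) < 0) pc1 <- -pc1
  ct <- stats::cor.test(pc1, s, method = "pearson")
  list(pc1 = pc1, r = unname(ct$estimate), p = ct$p.value)
}
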