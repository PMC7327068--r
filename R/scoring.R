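#' @include AllClasses.R
NULL

#' Glomerular sclerosis index
#'
#' Each of 40 glomeruli per animal is graded 0 (normal) to 4 (> 75 percent
#' cross-sectional sclerosis); the index is the weighted mean grade
#' \eqn{(N_1 + 2N_2 + 3N_3 + 4N_4)/40}, where \eqn{N_k} counts glomeruli
#' at grade k. Either the raw grade list or the per-grade counts may be
#' supplied.
#'
#' @param grades integer vector of exactly 40 grades in 0..4.
#' @param counts alternative input: vector of 5 counts for grades 0..4
#'   (named or in order), summing to 40.
#' @return numeric score in [0, 4].
#' @examples
#' gsi(rep(0, 40))                        # 0
#' gsi(counts = c(0, 10, 10, 10, 10))     # 2.5
#' @export
gsi <- function(grades = NULL, counts = NULL) {
  if (is.null(counts)) {
    if (is.null(grades)) stop("supply 'grades' or 'counts'")
    if (length(grades) != 40L)
      .err("invalid_grades", "exactly 40 glomerulus grades are required")
    if (any(is.na(grades)) || any(grades != as.integer(grades)) ||
        any(grades < 0L | grades > 4L))
      .err("invalid_grades", "grades must be integers in 0..4")
    counts <- tabulate(grades + 1L, nbins = 5L)
  } else {
    if (length(counts) != 5L || any(is.na(counts)) || any(counts < 0) ||
        sum(counts) != 40)
      .err("invalid_grades", "counts must be 5 non-negative values summing to 40")
  }
  sum(counts * 0:4) / 40
}

#' Tubulointerstitial injury index
#'
#' Grades the injured fraction of the tubulointerstitium on a 0..5 scale:
#' grade 0 for no morphological deformity (0 percent), then < 10, < 25,
#' < 50, < 75 percent, and grade 5 at 75 percent or higher. Bin edges
#' belong to the higher grade, as the top bin's "75 and higher" wording
#' dictates.
#'
#' @param injuryPercent numeric vector of injured-area percentages in
#'   [0, 100].
#' @return integer grades in 0..5.
#' @examples
#' tii(c(0, 5, 30, 80))  # 0 1 3 5
#' @export
tii <- function(injuryPercent) {
  if (any(is.na(injuryPercent)) ||
      any(injuryPercent < 0 | injuryPercent > 100))
    .err("invalid_percent", "injury percentage must lie in [0, 100]")
  g <- findInterval(injuryPercent, c(10, 25, 50, 75)) + 1L
  g[injuryPercent == 0] <- 0L
  g
}

#' Relative qPCR expression by the 2^-ddCt method
#'
#' For every sample and target gene: dCt = Ct(target) - Ct(reference gene);
#' ddCt = dCt - mean dCt of the calibrator group for that gene; relative
#' expression = 2^-ddCt. A calibrator-group sample whose dCt equals the
#' calibrator mean therefore has relative expression 1.
#'
#' @param ct data.frame with columns \code{sample}, \code{group},
#'   \code{gene}, \code{ct}.
#' @param referenceGene housekeeping gene used to normalise (every sample
#'   must carry a Ct for it; otherwise \code{cernaTriad_missing_reference}
#'   is raised).
#' @param calibratorGroup group whose mean dCt anchors ddCt.
#' @return data.frame: sample, group, gene, delta_ct, ddct, rel_expr
#'   (target genes only).
#' @export
ddct <- function(ct, referenceGene = "Gapdh", calibratorGroup = "NC") {
  need <- c("sample", "group", "gene", "ct")
  stopifnot(all(need %in% colnames(ct)))
  ref <- ct[ct$gene == referenceGene, ]
  refCt <- setNames(ref$ct, ref$sample)
  tgt <- ct[ct$gene != referenceGene, ]
  if (!all(tgt$sample %in% names(refCt)))
    .err("missing_reference",
         paste("no reference-gene Ct for sample:",
               paste(setdiff(tgt$sample, names(refCt)), collapse = ", ")))
  if (!any(tgt$group == calibratorGroup))
    .err("missing_reference", "calibrator group is empty")
  tgt$delta_ct <- tgt$ct - refCt[tgt$sample]
  calib <- tapply(tgt$delta_ct[tgt$group == calibratorGroup],
                  tgt$gene[tgt$group == calibratorGroup], mean)
  tgt$ddct <- as.numeric(tgt$delta_ct - calib[tgt$gene])
  tgt$rel_expr <- 2^(-tgt$ddct)
  rownames(tgt) <- NULL
  tgt[, c("sample", "group", "gene", "delta_ct", "ddct", "rel_expr")]
}

#' Group summary table with significance marks
#'
#' Mean and sample (n-1) SD per group, with Welch two-sample t-tests
#' against each reference group and tiered marks at p < 0.05, < 0.01 and
#' < 0.001 (one symbol repeated per tier: by convention \code{*} for the
#' model-control reference and \code{#} for the normal-control reference).
#'
#' @param values numeric vector of per-animal measurements.
#' @param groups group label per value.
#' @param referenceGroups groups each other group is tested against.
#' @param symbols one mark symbol per reference group.
#' @return data.frame: group, n, mean, sd, then p_vs_* and mark_vs_* per
#'   reference.
#' @export
groupSummary <- function(values, groups,
                         referenceGroups = c("OC", "NC"),
                         symbols = c("*", "#")) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  split_vals <- split(values, groups)
  if (any(lengths(split_vals) < 2L))
    .err("too_few_values", "every group needs at least 2 values")
  missing <- setdiff(referenceGroups, names(split_vals))
  if (length(missing))
    .err("missing_group",
         paste("reference group absent:", paste(missing, collapse = ", ")))
  glev <- unique(groups)
  out <- data.frame(
    group = glev,
    n = as.integer(lengths(split_vals)[glev]),
    mean = vapply(split_vals[glev], mean, 0),
    sd = vapply(split_vals[glev], stats::sd, 0),
    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_along(referenceGroups)) {
    ref <- referenceGroups[i]
    p <- vapply(glev, function(g) {
      if (g == ref) return(NA_real_)
      if (isTRUE(all.equal(sort(split_vals[[g]]), sort(split_vals[[ref]]))))
        return(1)
      tryCatch(stats::t.test(split_vals[[g]], split_vals[[ref]])$p.value,
               error = function(e) NA_real_)
    }, 0)
    tier <- ifelse(is.na(p), 0L, (p < 0.05) + (p < 0.01) + (p < 0.001))
    out[[paste0("p_vs_", ref)]] <- p
    out[[paste0("mark_vs_", ref)]] <-
      vapply(tier, function(k) paste(rep(symbols[i], k), collapse = ""), "")
  }
  out
}
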