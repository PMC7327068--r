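#' @include AllClasses.R AllGenerics.R io.R
NULL

#' Pathway over-representation by Fisher's exact test
#'
#' One-sided (upper-tail) Fisher's exact test of each pathway's overlap
#' with a differentially-expressed gene set, against the universe of all
#' features quantified in the layer. A pathway is \code{reported} when its
#' raw p is below \code{pMax} AND it contains at least \code{minOverlap}
#' DEGs; the BH-adjusted p is emitted alongside for information. Pathways
#' are intersected with the universe before counting and results are
#' sorted by p; pathways with no universe overlap are dropped.
#'
#' @param degSet character vector of DEG ids; must be a subset of
#'   \code{universe} (otherwise \code{cernaTriad_universe_mismatch} is
#'   raised, preventing silent universe inflation).
#' @param universe character vector of all measurable feature ids.
#' @param pathways a \linkS4class{PathwaySets}.
#' @param minOverlap minimum DEGs in a pathway for reporting (default 3).
#' @param pMax raw-p reporting threshold (default 0.05).
#' @return data.frame: pathway, k (DEGs in pathway), K (pathway size in
#'   universe), n (DEG count), N (universe size), p, p_bh, reported.
#' @export
enrich <- function(degSet, universe, pathways, minOverlap = 3,
                   pMax = 0.05) {
  universe <- unique(as.character(universe))
  degSet <- unique(as.character(degSet))
  stray <- setdiff(degSet, universe)
  if (length(stray))
    .err("universe_mismatch",
         paste("DEG not in universe:", paste(stray, collapse = ", ")))
  N <- length(universe)
  n <- length(degSet)
  rows <- lapply(names(pathways), function(nm) {
    set <- intersect(geneSets(pathways)[[nm]], universe)
    K <- length(set)
    if (K == 0L) return(NULL)
    k <- length(intersect(set, degSet))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(pathway = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_bh = numeric(), reported = logical()))
  out$p_bh <- stats::p.adjust(out$p, "BH")
  out$reported <- out$p < pMax & out$k >= minOverlap
  out <- out[order(out$p, out$pathway), ]
  rownames(out) <- NULL
  out
}

#' Exact hypergeometric upper-tail probability by direct summation
#'
#' Independent oracle for \code{\link{enrich}}: computes
#' \eqn{\sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}}
#' by direct log-space summation of the hypergeometric mass function,
#' without calling any distribution routine.
#'
#' @param k observed overlap (successes drawn).
#' @param K successes in the population (pathway size).
#' @param n draws (DEG count).
#' @param N population size (universe).
#' @return probability of an overlap of at least \code{k}.
#' @examples
#' hypergeomTail(0, 5, 5, 20)  # 1
#' @export
hypergeomTail <- function(k, K, n, N) {
  if (N < 0 || K < 0 || n < 0 || K > N || n > N || k < 0)
    .err("invalid_margins", "inconsistent hypergeometric margins")
  if (k > min(K, n)) return(0)
  i <- max(k, 0, n - (N - K)):min(K, n)
  logTerms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logTerms)
  exp(m) * sum(exp(logTerms - m))
}
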