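# Small configurations used across the suite; defaults elsewhere.
tinyConfig <- function(seed = 1, ...) {
  SimConfig(nMrna = 60, nMirna = 12, nLncrna = 12, nDeMrna = 8,
            nTrueMirnaPairs = 3, nSpongeTriads = 2, nPathways = 4,
            pathwaySize = 5, seed = seed, ...)
}

# no planted structure at all: null features only
nullConfig <- function(seed = 1, nMrna = 500, ...) {
  SimConfig(nMrna = nMrna, nMirna = 20, nLncrna = 20, nDeMrna = 1,
            effectLog2fc = 0, nTrueMirnaPairs = 1, nSpongeTriads = 1,
            repressionCoupling = 0, latentSd = 0, plantedDispersion = 0.05,
            nPathways = 2, pathwaySize = 5, seed = seed, ...)
}

# LayerExperiment from a literal matrix, with controlled library sizes
makeLayer <- function(values, groups, layer = "mRNA") {
  m <- as.matrix(values)
  if (is.null(rownames(m))) rownames(m) <- paste0("f", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  LayerExperiment(m, setNames(groups, colnames(m)), layer)
}

# adjusted Rand index between two labelings (contingency form)
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  sr <- sum(choose(rowSums(tab), 2)); sc <- sum(choose(colSums(tab), 2))
  si <- sum(choose(tab, 2)); n2 <- choose(sum(tab), 2)
  e <- sr * sc / n2
  (si - e) / ((sr + sc) / 2 - e)
}
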