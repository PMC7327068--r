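#' @include AllClasses.R AllGenerics.R
NULL

# Named child streams derived from one master seed, so that adding or
# re-ordering one layer's draws never perturbs another layer.
.SIM_STREAMS <- c("design", "latent", "mrna", "mirna", "lncrna",
                  "pathways", "targets", "histology", "ct")

.childSeed <- function(master, stream) {
  id <- match(stream, .SIM_STREAMS)
  if (is.na(id)) stop("unknown stream: ", stream)
  as.integer((as.numeric(master) * 48271 + id * 104729) %% 2147483647)
}

.withStream <- function(master, stream, fun) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.childSeed(master, stream))
  fun()
}

# NB draw with variance mu + dispersion * mu^2; dispersion 0 is Poisson.
# 'dispersion' may be scalar or per-draw.
.rnb <- function(n, mu, dispersion) {
  dispersion <- rep_len(dispersion, n)
  mu <- rep_len(mu, n)
  out <- numeric(n)
  pois <- dispersion <= 0
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) out[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                               size = 1 / dispersion[!pois])
  out
}

#' Simulate a five-group multi-layer expression dataset with known truth
#'
#' Draws negative-binomial counts for three RNA layers under the five-arm
#' treatment design (NC, OC, LK, HK, LOS), plants: (i) dose-responsive
#' mRNAs whose group means shift by a per-feature log2 fold change scaled by
#' the group's dose multiplier (so that the high-dose arm sits nearest the
#' normal control); (ii) miRNA-mRNA repression pairs that share a latent
#' per-sample regulator with opposite sign, concentrating their Pearson
#' correlation near \code{-sqrt(repressionCoupling)}; (iii) lncRNA sponge
#' triads in which the lncRNA loads with the mRNA and against the miRNA;
#' (iv) one or more pathways assembled from planted responsive genes; and
#' (v) decoy target-map entries with no functional coupling. Histology
#' grade tables and a qPCR Ct table are generated on the same dose profile.
#'
#' Identical config and seed give byte-identical output. Each component
#' draws from its own child RNG stream derived from the master seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A \linkS4class{SimulatedDataset}.
#' @examples
#' sim <- simulateDataset(SimConfig(nMrna = 50, nMirna = 10, nLncrna = 10,
#'                                  nDeMrna = 5, nTrueMirnaPairs = 2,
#'                                  nSpongeTriads = 1, nPathways = 3,
#'                                  pathwaySize = 4, seed = 7))
#' groundTruth(sim)
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "SimConfig"))
  methods::validObject(config)
  seed <- config@seed
  groups <- rep(TREATMENT_GROUPS, each = config@nPerGroup)
  samples <- paste0(groups, "_", seq_len(config@nPerGroup))
  names(groups) <- samples
  nS <- length(samples)
  dose <- config@doseProfile[groups]

  mrnaIds <- sprintf("mRNA_%04d", seq_len(config@nMrna))
  mirIds <- sprintf("miR_%03d", seq_len(config@nMirna))
  lncIds <- sprintf("lnc_%03d", seq_len(config@nLncrna))

  # --- design stream: which features carry which planted structure -------
  des <- .withStream(seed, "design", function() {
    deIdx <- sample.int(config@nMrna, config@nDeMrna)
    rest <- setdiff(seq_len(config@nMrna), deIdx)
    pairTgt <- rest[seq_len(config@nTrueMirnaPairs)]
    triadTgt <- rest[config@nTrueMirnaPairs + seq_len(config@nSpongeTriads)]
    pairMir <- seq_len(config@nTrueMirnaPairs)
    triadMir <- config@nTrueMirnaPairs + seq_len(config@nSpongeTriads)
    triadLnc <- seq_len(config@nSpongeTriads)
    dir <- rep_len(c(1, -1), config@nDeMrna)
    lfc <- config@effectLog2fc * stats::runif(config@nDeMrna, 0.75, 1.25)
    base <- list(
      mrna = config@baselineMean * 2^stats::rnorm(config@nMrna, 0, 1),
      mirna = config@baselineMean * 2^stats::rnorm(config@nMirna, 0, 1),
      lncrna = config@baselineMean * 2^stats::rnorm(config@nLncrna, 0, 1))
    # latent-driven features sit at the baseline mean with low dispersion,
    # so the shared regulator dominates their sample profiles
    base$mrna[c(pairTgt, triadTgt)] <- config@baselineMean
    base$mirna[c(pairMir, triadMir)] <- config@baselineMean
    base$lncrna[triadLnc] <- config@baselineMean
    list(deIdx = deIdx, dir = dir, lfc = lfc, pairTgt = pairTgt,
         triadTgt = triadTgt, pairMir = pairMir, triadMir = triadMir,
         triadLnc = triadLnc, base = base)
  })

  # --- latent stream: shared per-sample regulators for planted pairs -----
  nPlanted <- config@nTrueMirnaPairs + config@nSpongeTriads
  lat <- .withStream(seed, "latent", function() {
    list(z = matrix(stats::rnorm(nPlanted * nS), nPlanted, nS),
         eps = matrix(stats::rnorm(nPlanted * nS), nPlanted, nS))
  })
  cc <- config@repressionCoupling
  sd0 <- config@latentSd

  # Log2-scale per-sample mean offsets for latent-driven features.
  mirOffset <- sd0 * lat$z                       # miRNA tracks +z
  tgtOffset <- -sqrt(cc) * sd0 * lat$z + sqrt(1 - cc) * sd0 * lat$eps
  # Sponge lncRNA shares the target's full signal (regulon partner).
  lncOffset <- tgtOffset

  # --- group-mean construction ------------------------------------------
  log2meanMrna <- matrix(log2(des$base$mrna), config@nMrna, nS,
                         dimnames = list(mrnaIds, samples))
  for (i in seq_along(des$deIdx))
    log2meanMrna[des$deIdx[i], ] <- log2meanMrna[des$deIdx[i], ] +
      des$dir[i] * des$lfc[i] * dose
  if (nPlanted) {
    tgtRows <- c(des$pairTgt, des$triadTgt)
    log2meanMrna[tgtRows, ] <- log2meanMrna[tgtRows, ] + tgtOffset
  }
  log2meanMir <- matrix(log2(des$base$mirna), config@nMirna, nS,
                        dimnames = list(mirIds, samples))
  if (nPlanted) {
    mirRows <- c(des$pairMir, des$triadMir)
    log2meanMir[mirRows, ] <- log2meanMir[mirRows, ] + mirOffset
  }
  log2meanLnc <- matrix(log2(des$base$lncrna), config@nLncrna, nS,
                        dimnames = list(lncIds, samples))
  if (config@nSpongeTriads)
    log2meanLnc[des$triadLnc, ] <- log2meanLnc[des$triadLnc, ] +
      lncOffset[config@nTrueMirnaPairs + seq_len(config@nSpongeTriads), ,
                drop = FALSE]

  drawLayer <- function(stream, log2mean, latentRows) {
    disp <- rep(config@nbDispersion, nrow(log2mean))
    disp[latentRows] <- config@plantedDispersion
    .withStream(seed, stream, function() {
      m <- matrix(.rnb(length(log2mean), 2^as.vector(log2mean),
                       rep(disp, ncol(log2mean))),
                  nrow(log2mean), ncol(log2mean),
                  dimnames = dimnames(log2mean))
      storage.mode(m) <- "double"
      m
    })
  }
  mrna <- LayerExperiment(
    drawLayer("mrna", log2meanMrna, c(des$pairTgt, des$triadTgt)),
    groups, "mRNA")
  mirna <- LayerExperiment(
    drawLayer("mirna", log2meanMir, c(des$pairMir, des$triadMir)),
    groups, "miRNA")
  lncrna <- LayerExperiment(
    drawLayer("lncrna", log2meanLnc, des$triadLnc), groups, "lncRNA")

  # --- target map: true pairs, triad pairs, decoys ----------------------
  truePairs <- data.frame(
    mirna_id = mirIds[c(des$pairMir, des$triadMir)],
    target_id = mrnaIds[c(des$pairTgt, des$triadTgt)],
    target_layer = "mRNA", stringsAsFactors = FALSE)
  nullTgt <- setdiff(seq_len(config@nMrna),
                     c(des$deIdx, des$pairTgt, des$triadTgt))
  f <- config@decoyTargetFraction
  nDecoy <- round(f / (1 - f) * nrow(truePairs))
  nDecoy <- min(nDecoy, length(nullTgt))
  decoys <- .withStream(seed, "targets", function() {
    if (nDecoy == 0) return(truePairs[0, ])
    data.frame(
      mirna_id = sample(mirIds, nDecoy, replace = TRUE),
      target_id = mrnaIds[sample(nullTgt, nDecoy)],
      target_layer = "mRNA", stringsAsFactors = FALSE)
  })
  tmap <- TargetMap(rbind(truePairs, decoys))

  # --- pathway sets ------------------------------------------------------
  pw <- .withStream(seed, "pathways", function() {
    sets <- vector("list", config@nPathways)
    names(sets) <- sprintf("PW_%02d", seq_len(config@nPathways))
    for (i in seq_len(config@nPlantedEnriched))
      sets[[i]] <- mrnaIds[sample(des$deIdx,
                                  min(config@pathwaySize, length(des$deIdx)))]
    for (i in setdiff(seq_len(config@nPathways),
                      seq_len(config@nPlantedEnriched)))
      sets[[i]] <- mrnaIds[sample.int(config@nMrna, config@pathwaySize)]
    desc <- setNames(ifelse(seq_along(sets) <= config@nPlantedEnriched,
                            "planted responsive pathway",
                            "background pathway"), names(sets))
    PathwaySets(sets, desc)
  })

  hist <- simulateHistology(config)
  ct <- .simulateCt(config, samples, groups, dose)

  truth <- new("GroundTruth",
    deFeatures = data.frame(
      feature_id = mrnaIds[des$deIdx],
      direction = ifelse(des$dir > 0, "up", "down"),
      log2fc = des$dir * des$lfc, stringsAsFactors = FALSE),
    mirnaPairs = data.frame(
      mirna_id = truePairs$mirna_id, target_id = truePairs$target_id,
      sponge = c(rep(FALSE, config@nTrueMirnaPairs),
                 rep(TRUE, config@nSpongeTriads)),
      stringsAsFactors = FALSE),
    spongeTriads = data.frame(
      lncrna_id = lncIds[des$triadLnc],
      mirna_id = mirIds[des$triadMir],
      mrna_id = mrnaIds[des$triadTgt], stringsAsFactors = FALSE),
    enrichedPathways = names(geneSets(pw))[
      seq_len(config@nPlantedEnriched)],
    groupMeans = .expectedGroupMeans(config, des, mrnaIds, mirIds, lncIds))

  methods::validObject(out <- new("SimulatedDataset",
    mrna = mrna, mirna = mirna, lncrna = lncrna, targetMap = tmap,
    pathways = pw, glomeruli = hist$glomeruli, injury = hist$injury,
    ct = ct, truth = truth, config = config))
  out
}

# Expected linear group means (latent regulators average out on the log
# scale, so latent-driven features are recorded at their baseline).
.expectedGroupMeans <- function(config, des, mrnaIds, mirIds, lncIds) {
  g <- TREATMENT_GROUPS
  mm <- matrix(des$base$mrna, config@nMrna, length(g),
               dimnames = list(mrnaIds, g))
  for (i in seq_along(des$deIdx))
    mm[des$deIdx[i], ] <- mm[des$deIdx[i], ] *
      2^(des$dir[i] * des$lfc[i] * config@doseProfile[g])
  list(mRNA = mm,
       miRNA = matrix(des$base$mirna, config@nMirna, length(g),
                      dimnames = list(mirIds, g)),
       lncRNA = matrix(des$base$lncrna, config@nLncrna, length(g),
                       dimnames = list(lncIds, g)))
}

#' Simulate histopathology tables
#'
#' Per animal: 40 glomerulus grades (0..4) drawn from the group's grade
#' probability vector, and one tubulointerstitial injured-area percentage
#' drawn from a normal truncated to [0, 100]. Group severity follows the
#' config's dose profile, so the expected glomerular sclerosis index is
#' worst in OC and best in NC.
#'
#' @param config a \linkS4class{SimConfig}; its \code{glomProbs} rows must
#'   sum to 1.
#' @return list with data.frames \code{glomeruli} (animal, group,
#'   g01..g40) and \code{injury} (animal, group, injury_percent).
#' @export
simulateHistology <- function(config) {
  stopifnot(is(config, "SimConfig"))
  methods::validObject(config)
  .withStream(config@seed, "histology", function() {
    groups <- rep(TREATMENT_GROUPS, each = config@nPerGroup)
    animals <- paste0(groups, "_", seq_len(config@nPerGroup))
    grades <- t(vapply(groups, function(g)
      sample(0:4, 40, replace = TRUE, prob = config@glomProbs[g, ]),
      integer(40)))
    colnames(grades) <- sprintf("g%02d", 1:40)
    inj <- pmin(pmax(stats::rnorm(length(animals),
                                  config@injuryMean[groups],
                                  config@injurySd[groups]), 0), 100)
    list(
      glomeruli = data.frame(animal = animals, group = groups, grades,
                             stringsAsFactors = FALSE, row.names = NULL),
      injury = data.frame(animal = animals, group = groups,
                          injury_percent = inj, stringsAsFactors = FALSE))
  })
}

# qPCR Ct table on the same dose axis: fibrosis markers rise with disease
# burden, the anti-fibrotic marker falls, the reference gene is flat.
.CT_GENES <- c(Tgfb1 = 2, Col1a1 = 2, Smad3 = 1.5, Smad7 = -1)
.CT_REFERENCE <- "Gapdh"

.simulateCt <- function(config, samples, groups, dose) {
  .withStream(config@seed, "ct", function() {
    genes <- c(names(.CT_GENES), .CT_REFERENCE)
    out <- expand.grid(sample = samples, gene = genes,
                       stringsAsFactors = FALSE)
    out$group <- groups[out$sample]
    base <- c(setNames(rep(24, length(.CT_GENES)), names(.CT_GENES)),
              setNames(18, .CT_REFERENCE))
    eff <- c(.CT_GENES, setNames(0, .CT_REFERENCE))
    d <- config@doseProfile[out$group]
    out$ct <- base[out$gene] - eff[out$gene] * d +
      stats::rnorm(nrow(out), 0, 0.15)
    out[, c("sample", "group", "gene", "ct")]
  })
}
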