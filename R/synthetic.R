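#' Generate a synthetic multi-treatment ASV dataset
#'
#' Draws a taxa x samples count table with the statistical structure the
#' downstream analysis assumes: (1) per-taxon lognormal baseline abundances
#' (rank-abundance skew typical of ITS communities), (2) latent Gaussian
#' factors shared within each planted co-abundance module and scaled by the
#' (possibly per-group) `moduleStrength` loading, (3) per-group reweighting
#' of taxa so expected guild relative abundances follow the design's
#' `guildMix`, and (4) multinomial sampling of each sample at exactly
#' `sequencingDepth` reads. Latent and noise terms are mean-corrected on the
#' log scale so module membership does not bias expected abundance.
#'
#' A small fixed fraction (5%) of taxa carry an `g__unidentified` genus that
#' the generated guild reference does not cover, so downstream guild
#' assignment exercises the `Unassigned` path.
#'
#' @param design A [SimulationDesign-class] from [simulationDesign()].
#' @return A list with elements:
#'   \describe{
#'     \item{asv}{[AsvExperiment-class] with taxonomy and treatment metadata.}
#'     \item{taxonomy}{`data.frame(ASV_ID, lineage)`.}
#'     \item{metadata}{`data.frame(sample_id, treatment)`.}
#'     \item{guilds}{Guild reference `data.frame(pattern, guild)` mapping
#'       genus tokens to guild labels.}
#'     \item{truth}{Planted ground truth: per-taxon module membership
#'       (`0` = none) and guild assignment.}
#'   }
#' @export
#' @examples
#' d <- simulationDesign(nGroups = 2, replicatesPerGroup = 4, nTaxa = 20,
#'                       nModules = 2, moduleSize = 5, seed = 7)
#' sim <- generateDataset(d)
#' dim(asvCounts(sim$asv))
generateDataset <- function(design) {
  stopifnot(is(design, "SimulationDesign"))
  validObject(design)
  nT <- design@nTaxa
  nG <- design@nGroups
  nR <- design@replicatesPerGroup
  depth <- design@sequencingDepth
  groupNames <- rownames(design@guildMix)
  strength <- rep(design@moduleStrength, length.out = nG)
  names(strength) <- groupNames

  taxon_ids <- sprintf("ASV_%04d", seq_len(nT))
  module <- integer(nT)
  if (design@nModules > 0)
    module[seq_len(design@nModules * design@moduleSize)] <-
      rep(seq_len(design@nModules), each = design@moduleSize)

  # baseline abundances and guild assignment
  base <- withr::with_seed(.stageSeed(design@seed, "baseline"), {
    b <- rlnorm(nT, meanlog = 0, sdlog = 1.5)
    unassignedShare <- 0.05
    avgMix <- colMeans(design@guildMix)
    probs <- c(avgMix * (1 - unassignedShare), Unassigned = unassignedShare)
    guild <- sample(names(probs), nT, replace = TRUE, prob = probs)
    list(b = b, guild = guild)
  })
  guild <- base$guild
  b <- base$b

  # per-group weights so expected guild shares follow guildMix
  wt <- matrix(1, nT, nG, dimnames = list(taxon_ids, groupNames))
  for (g in seq_len(nG)) {
    for (gl in .GUILDS6) {
      in_gl <- guild == gl
      if (!any(in_gl)) next
      wt[in_gl, g] <- design@guildMix[g, gl] / sum(b[in_gl])
    }
    in_un <- guild == "Unassigned"
    if (any(in_un)) wt[in_un, g] <- 0.05 / sum(b[in_un])
  }

  nS <- nG * nR
  sample_ids <- paste0(rep(groupNames, each = nR), "_",
                       rep(seq_len(nR), times = nG))
  treatment <- rep(groupNames, each = nR)

  factors <- withr::with_seed(.stageSeed(design@seed, "factors"),
    matrix(rnorm(max(1, design@nModules) * nS), ncol = nS))
  noise <- withr::with_seed(.stageSeed(design@seed, "noise"),
    matrix(rnorm(nT * nS, sd = design@noiseDispersion), nrow = nT))

  counts <- withr::with_seed(.stageSeed(design@seed, "sampling"), {
    out <- matrix(0, nT, nS, dimnames = list(taxon_ids, sample_ids))
    for (i in seq_len(nS)) {
      g <- match(treatment[i], groupNames)
      lat <- rep(0, nT)
      if (design@nModules > 0) {
        s <- strength[g]
        has_mod <- module > 0
        # mean-corrected lognormal latent term (loading scale 2)
        lat[has_mod] <- 2 * s * factors[module[has_mod], i] - 2 * s^2
      }
      eps <- noise[, i] - design@noiseDispersion^2 / 2
      a <- b * wt[, g] * exp(lat + eps)
      out[, i] <- rmultinom(1, size = depth, prob = a / sum(a))
    }
    out
  })

  genus <- character(nT)
  abbr <- c(Saprotroph = "Sapro", Symbiotroph = "Symbio", Pathotroph = "Patho",
            `Pathotroph-Saprotroph` = "PatSap",
            `Saprotroph-Symbiotroph` = "SapSym",
            `Pathotroph-Saprotroph-Symbiotroph` = "PatSapSym",
            Unassigned = "unidentified")
  for (t in seq_len(nT)) {
    genus[t] <- if (guild[t] == "Unassigned") "unidentified"
                else sprintf("%s%03d", abbr[[guild[t]]], t)
  }
  lineage <- sprintf(
    "k__Fungi;p__Ascomycota;c__Sordariomycetes;o__Hypocreales;f__Nectriaceae;g__%s;s__%s_sp",
    genus, genus)
  taxonomy <- data.frame(ASV_ID = taxon_ids, lineage = lineage,
                         stringsAsFactors = FALSE)
  metadata <- data.frame(sample_id = sample_ids, treatment = treatment,
                         stringsAsFactors = FALSE)
  ref <- unique(data.frame(pattern = paste0("g__", genus[guild != "Unassigned"]),
                           guild = guild[guild != "Unassigned"],
                           stringsAsFactors = FALSE))
  asv <- AsvExperiment(counts, taxonomy = taxonomy, metadata = metadata)
  list(asv = asv, taxonomy = taxonomy, metadata = metadata, guilds = ref,
       truth = list(module = setNames(module, taxon_ids),
                    guild = setNames(guild, taxon_ids)))
}

#' Three-treatment fixture with contrasted planted network structure
#'
#' Builds a combined CK/CF/BF community in which the planted co-abundance
#' structure is densest for CF (two large blocks at high loading), moderate
#' for CK (three medium blocks), and sparse and fragmented for BF (six
#' small blocks at low loading). Each treatment's samples are drawn from
#' its own single-group design at elevated depth, then column-bound over a
#' shared taxon universe. This is the standard fixture for end-to-end
#' direction checks: treatment networks built from it should order
#' CF > CK > BF in connectivity.
#'
#' @param seed Master seed (per-group sub-seeds are derived from it).
#' @param replicates Samples per treatment.
#' @param nTaxa Taxa in the shared universe.
#' @return List with `asv` (an [AsvExperiment-class] with treatment
#'   metadata) and `designs` (the three per-group
#'   [SimulationDesign-class] objects).
#' @export
generateContrastFixture <- function(seed = 1L, replicates = 15L,
                                    nTaxa = 60L) {
  specs <- list(CK = list(nm = 3L, ms = 10L, st = 0.85, off = 0L),
                CF = list(nm = 2L, ms = 20L, st = 0.95, off = 100L),
                BF = list(nm = 6L, ms = 4L, st = 0.75, off = 200L))
  designs <- lapply(names(specs), function(g) {
    sp <- specs[[g]]
    simulationDesign(nGroups = 1L, replicatesPerGroup = replicates,
                     nTaxa = nTaxa, sequencingDepth = 30000L,
                     nModules = sp$nm, moduleSize = sp$ms,
                     moduleStrength = sp$st, noiseDispersion = 0.4,
                     groupNames = g, seed = as.integer(seed) + sp$off)
  })
  names(designs) <- names(specs)
  counts <- do.call(cbind, lapply(names(specs), function(g) {
    m <- asvCounts(generateDataset(designs[[g]])$asv)
    colnames(m) <- paste0(g, "_", seq_len(ncol(m)))
    m
  }))
  meta <- data.frame(sample_id = colnames(counts),
                     treatment = rep(names(specs), each = replicates),
                     stringsAsFactors = FALSE)
  list(asv = AsvExperiment(counts, metadata = meta), designs = designs)
}

#' Scale a guild's expected abundance within one treatment group
#'
#' Multiplies the sampling probability of every taxon mapped to `guild` by
#' `foldChange` for the samples of `group`, then redraws each affected
#' sample from a multinomial at its original total count. Other groups are
#' untouched; `foldChange = 1` or a guild with no matching taxa returns the
#' input unchanged.
#'
#' @param asv An [AsvExperiment-class] with treatment metadata.
#' @param group Treatment label to perturb.
#' @param guild Guild label whose taxa are scaled.
#' @param foldChange Positive scaling of the guild's expected relative
#'   abundance (e.g. `0.5` halves it, emulating a planted depletion).
#' @param mapping Named character vector taxon -> guild, e.g. from
#'   [assignGuilds()]; must cover the table's taxa.
#' @param seed Seed for the multinomial redraw.
#' @return A new [AsvExperiment-class].
#' @export
plantGroupEffect <- function(asv, group, guild, foldChange, mapping,
                             seed = 1L) {
  stopifnot(foldChange > 0)
  tr <- treatments(asv)
  if (is.null(tr)) stop("asv must carry treatment metadata")
  if (!group %in% tr) stop("unknown group: ", group)
  if (!guild %in% guildLabels()) stop("unknown guild label: ", guild)
  counts <- asvCounts(asv)
  mapping <- mapping[rownames(counts)]
  if (anyNA(mapping)) stop("mapping does not cover all taxa in the table")
  hit <- which(mapping == guild)
  cols <- which(tr == group)
  if (foldChange == 1 || length(hit) == 0 || sum(counts[hit, cols]) == 0)
    return(asv)
  newc <- counts
  withr::with_seed(.stageSeed(seed, "effect"), {
    for (j in cols) {
      pr <- counts[, j]
      pr[hit] <- pr[hit] * foldChange
      tot <- sum(counts[, j])
      newc[, j] <- rmultinom(1, size = tot, prob = pr / sum(pr))
    }
  })
  out <- asv
  assay(out, "counts") <- newc
  out
}
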