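#' Guild labels recognised by the pipeline
#'
#' The six trophic guild labels used throughout (decomposers, mutualists,
#' pathogens and their mixed-capability combinations), plus `"Unassigned"`
#' for taxa the reference cannot place.
#'
#' @return Character vector of the seven labels.
#' @export
#' @examples
#' guildLabels()
guildLabels <- function() {
  c("Saprotroph", "Symbiotroph", "Pathotroph",
    "Pathotroph-Saprotroph", "Saprotroph-Symbiotroph",
    "Pathotroph-Saprotroph-Symbiotroph", "Unassigned")
}

.GUILDS6 <- c("Saprotroph", "Symbiotroph", "Pathotroph",
              "Pathotroph-Saprotroph", "Saprotroph-Symbiotroph",
              "Pathotroph-Saprotroph-Symbiotroph")

#' AsvExperiment: an ASV count table with taxonomy and sample metadata
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' non-negative integer `counts` assay (taxa as rows, samples as columns),
#' optional taxonomic lineages in `rowData(x)$lineage` and a treatment label
#' in `colData(x)$treatment`.
#'
#' @export
setClass("AsvExperiment", contains = "SummarizedExperiment")

setValidity("AsvExperiment", function(object) {
  msg <- character()
  if (!("counts" %in% assayNames(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- assay(object, "counts")
    if (anyNA(m)) msg <- c(msg, "counts contain NA")
    else {
      if (any(m < 0)) msg <- c(msg, "counts contain negative values")
      if (any(m != round(m))) msg <- c(msg, "counts are not integers")
    }
    if (is.null(rownames(object)) || is.null(colnames(object)))
      msg <- c(msg, "taxon and sample identifiers are required as dimnames")
    else {
      if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate taxon identifiers")
      if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample identifiers")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AsvExperiment
#'
#' @param counts Non-negative integer matrix, taxa x samples, with row and
#'   column names.
#' @param taxonomy Optional `data.frame` with columns `ASV_ID` and `lineage`
#'   (semicolon-delimited ranked lineage, e.g. `"k__Fungi;...;g__Mortierella"`).
#' @param metadata Optional `data.frame` with columns `sample_id` and
#'   `treatment`; every sample column must appear exactly once.
#' @return An [AsvExperiment-class] object.
#' @export
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("ASV1", "ASV2"), paste0("S", 1:3)))
#' AsvExperiment(m)
AsvExperiment <- function(counts, taxonomy = NULL, metadata = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  rd <- S4Vectors::DataFrame(row.names = rownames(counts))
  if (!is.null(taxonomy)) {
    if (!all(c("ASV_ID", "lineage") %in% names(taxonomy)))
      stop("taxonomy must have columns 'ASV_ID' and 'lineage'")
    idx <- match(rownames(counts), taxonomy$ASV_ID)
    if (anyNA(idx))
      stop("taxonomy is missing lineages for: ",
           paste(utils::head(rownames(counts)[is.na(idx)], 5), collapse = ", "))
    rd$lineage <- taxonomy$lineage[idx]
  }
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(metadata)) {
    if (!all(c("sample_id", "treatment") %in% names(metadata)))
      stop("metadata must have columns 'sample_id' and 'treatment'")
    if (anyDuplicated(metadata$sample_id))
      stop("duplicate sample_id in metadata")
    idx <- match(colnames(counts), metadata$sample_id)
    if (anyNA(idx))
      stop("metadata is missing samples: ",
           paste(colnames(counts)[is.na(idx)], collapse = ", "))
    cd$treatment <- metadata$treatment[idx]
  }
  new("AsvExperiment",
      SummarizedExperiment(assays = list(counts = counts),
                           rowData = rd, colData = cd))
}

#' @describeIn AsvExperiment Extract the count matrix (taxa x samples).
#' @param x An `AsvExperiment`.
#' @export
asvCounts <- function(x) {
  if (is(x, "SummarizedExperiment")) assay(x, "counts") else as.matrix(x)
}

#' @describeIn AsvExperiment Treatment label per sample (or `NULL`).
#' @export
treatments <- function(x) {
  if (is(x, "SummarizedExperiment") && "treatment" %in% names(colData(x)))
    setNames(as.character(colData(x)$treatment), colnames(x))
  else NULL
}

#' SimulationDesign: parameters of the synthetic community generator
#'
#' Describes a multi-treatment ASV simulation: group and replicate counts,
#' community size, sequencing depth, planted co-abundance modules (latent
#' factor blocks), per-group guild composition, and dispersion of the
#' per-taxon lognormal noise.
#'
#' @slot nGroups Number of treatment groups.
#' @slot replicatesPerGroup Samples per group (>= 3).
#' @slot nTaxa Number of taxa.
#' @slot sequencingDepth Reads per sample (multinomial total).
#' @slot nModules Number of planted co-abundance blocks.
#' @slot moduleSize Taxa per block; `nModules * moduleSize <= nTaxa`.
#' @slot moduleStrength Latent-factor loading in \[0, 1\]; scalar or one value
#'   per group (stronger loading means denser planted correlation).
#' @slot guildMix Matrix (groups x 6 guilds) of guild proportions; rows sum
#'   to 1.
#' @slot noiseDispersion SD of per-taxon, per-sample lognormal noise.
#' @slot seed Master seed; per-stage substreams are derived from it.
#' @export
setClass("SimulationDesign",
  representation(nGroups = "integer", replicatesPerGroup = "integer",
                 nTaxa = "integer", sequencingDepth = "integer",
                 nModules = "integer", moduleSize = "integer",
                 moduleStrength = "numeric", guildMix = "matrix",
                 noiseDispersion = "numeric", seed = "integer"))

setValidity("SimulationDesign", function(object) {
  msg <- character()
  if (object@replicatesPerGroup < 3L)
    msg <- c(msg, "replicatesPerGroup must be >= 3")
  if (object@sequencingDepth <= 0L)
    msg <- c(msg, "sequencingDepth must be > 0")
  if (object@nModules * object@moduleSize > object@nTaxa)
    msg <- c(msg, "nModules * moduleSize must be <= nTaxa")
  if (any(object@moduleStrength < 0 | object@moduleStrength > 1))
    msg <- c(msg, "moduleStrength must lie in [0, 1]")
  if (!(length(object@moduleStrength) %in% c(1L, object@nGroups)))
    msg <- c(msg, "moduleStrength must have length 1 or nGroups")
  if (nrow(object@guildMix) != object@nGroups ||
      ncol(object@guildMix) != length(.GUILDS6))
    msg <- c(msg, "guildMix must be nGroups x 6")
  else if (any(abs(rowSums(object@guildMix) - 1) > 1e-9))
    msg <- c(msg, "guildMix rows must each sum to 1")
  if (object@noiseDispersion <= 0)
    msg <- c(msg, "noiseDispersion must be positive")
  if (length(msg)) msg else TRUE
})

#' Create a simulation design
#'
#' Defaults emulate a three-treatment rhizosphere ITS survey: 100 taxa with
#' lognormal rank-abundance skew, three planted 10-taxon co-abundance
#' modules, 10,000 reads per sample, and a saprotroph-dominated guild mix.
#' Replication defaults to 15 per group: with the |rho| > 0.8 plus
#' Bonferroni edge gate, smaller n cannot yield significant edges over
#' thousands of pairs.
#'
#' @param nGroups,replicatesPerGroup,nTaxa,sequencingDepth,nModules,moduleSize
#'   Integers; see [SimulationDesign-class].
#' @param moduleStrength Scalar or per-group loading in \[0, 1\].
#' @param guildMix Optional groups x 6 proportion matrix (columns in
#'   `guildLabels()[1:6]` order); defaults to one field-like mix per group.
#' @param noiseDispersion Lognormal noise SD.
#' @param groupNames Optional group labels; default `CK`, `CF`, `BF`, ...
#' @param seed Master seed.
#' @return A validated [SimulationDesign-class] object.
#' @export
#' @examples
#' simulationDesign(nGroups = 2, replicatesPerGroup = 5, nTaxa = 30, seed = 1)
simulationDesign <- function(nGroups = 3L, replicatesPerGroup = 15L,
                             nTaxa = 100L, sequencingDepth = 10000L,
                             nModules = 3L, moduleSize = 10L,
                             moduleStrength = 0.8, guildMix = NULL,
                             noiseDispersion = 0.5, groupNames = NULL,
                             seed = 1L) {
  if (is.null(groupNames)) {
    groupNames <- c("CK", "CF", "BF", paste0("G", seq_len(max(0, nGroups - 3))))
    groupNames <- groupNames[seq_len(nGroups)]
  }
  if (is.null(guildMix)) {
    guildMix <- matrix(rep(c(0.40, 0.15, 0.12, 0.12, 0.06, 0.15), nGroups),
                       nrow = nGroups, byrow = TRUE)
  }
  guildMix <- as.matrix(guildMix)
  colnames(guildMix) <- .GUILDS6
  rownames(guildMix) <- groupNames
  d <- new("SimulationDesign",
           nGroups = as.integer(nGroups),
           replicatesPerGroup = as.integer(replicatesPerGroup),
           nTaxa = as.integer(nTaxa),
           sequencingDepth = as.integer(sequencingDepth),
           nModules = as.integer(nModules), moduleSize = as.integer(moduleSize),
           moduleStrength = as.numeric(moduleStrength),
           guildMix = guildMix,
           noiseDispersion = as.numeric(noiseDispersion),
           seed = as.integer(seed))
  validObject(d)
  d
}

#' CorrelationResult: all-pairs Spearman correlations with Bonferroni gating
#'
#' @slot rho Symmetric correlation matrix (diagonal 1; NA for untestable
#'   pairs involving constant taxa).
#' @slot p Raw two-sided p-values (NA on the diagonal / untestable pairs).
#' @slot pAdjusted Bonferroni-adjusted p: `min(1, p * m)`.
#' @slot m Number of testable (non-constant) pairs used for the correction.
#' @slot nSamples Number of samples the correlations were computed across.
#' @export
setClass("CorrelationResult",
  representation(rho = "matrix", p = "matrix", pAdjusted = "matrix",
                 m = "integer", nSamples = "integer"))

setValidity("CorrelationResult", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@rho, t(object@rho), tolerance = 1e-8)))
    msg <- c(msg, "rho must be symmetric")
  if (any(diag(object@rho) != 1))
    msg <- c(msg, "rho diagonal must be 1")
  off <- object@p[upper.tri(object@p)]
  adj <- object@pAdjusted[upper.tri(object@pAdjusted)]
  ok <- !is.na(off)
  if (any(abs(adj[ok] - pmin(1, off[ok] * object@m)) > 1e-12))
    msg <- c(msg, "pAdjusted must equal min(1, p * m)")
  if (length(msg)) msg else TRUE
})

#' CoOccurrenceNetwork: a signed, correlation-weighted taxon graph
#'
#' Simple undirected graph over taxa; each edge passed the build-time gate
#' |rho| > `rhoThreshold` with Bonferroni-adjusted p < `alpha`. Isolated
#' taxa are not part of the node set.
#'
#' @slot graph An [igraph::igraph] object with edge attributes `rho` and
#'   `sign`.
#' @slot group Treatment label the network was built for.
#' @slot rhoThreshold,alpha The gate applied at build time.
#' @export
setClass("CoOccurrenceNetwork",
  representation(graph = "ANY", group = "character",
                 rhoThreshold = "numeric", alpha = "numeric"))

setValidity("CoOccurrenceNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  msg <- character()
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (any(igraph::which_loop(g))) msg <- c(msg, "self-loops are not allowed")
  if (any(igraph::which_multiple(g))) msg <- c(msg, "duplicate edges are not allowed")
  if (igraph::ecount(g) > 0) {
    rho <- igraph::E(g)$rho
    if (is.null(rho)) msg <- c(msg, "edges must carry a 'rho' attribute")
    else if (any(abs(rho) <= object@rhoThreshold))
      msg <- c(msg, "all edges must satisfy |rho| > rhoThreshold")
  }
  if (length(msg)) msg else TRUE
})

#' TopologySummary: the topology panel of a co-occurrence network
#'
#' @slot nodes,edges Connected-taxon and edge counts.
#' @slot averageDegree `2 * edges / nodes`.
#' @slot pathLength,diameter Unweighted shortest-path metrics on the largest
#'   connected component.
#' @slot pathLengthNormalized,diameterNormalized The same divided by the
#'   node count (the scale the reporting convention uses).
#' @slot density `2 * edges / (nodes * (nodes - 1))`.
#' @slot clusteringCoefficient Mean local clustering (0 for degree < 2).
#' @slot modularity Q of the deterministic greedy (CNM) partition.
#' @slot group Network group label.
#' @export
setClass("TopologySummary",
  representation(nodes = "integer", edges = "integer",
                 averageDegree = "numeric", pathLength = "numeric",
                 diameter = "numeric", pathLengthNormalized = "numeric",
                 diameterNormalized = "numeric", density = "numeric",
                 clusteringCoefficient = "numeric", modularity = "numeric",
                 group = "character"))

#' CohesionProfile: null-model cohesion and the stability ratio
#'
#' Per-taxon connectedness is the mean of the positive (resp. negative)
#' null-corrected pairwise correlations of that taxon; per-sample cohesion
#' weights connectedness by relative abundance. The stability ratio is
#' |negative cohesion| / positive cohesion.
#'
#' @slot connectednessPos,connectednessNeg Per-taxon means of positive /
#'   negative null-corrected correlations.
#' @slot cohesionPos,cohesionNeg Per-sample cohesion (pos >= 0, neg <= 0).
#' @slot nullIterations Number of taxon-shuffle randomisations.
#' @slot method Correlation method used (`pearson` or `spearman`).
#' @slot seed Seed the null shuffles were drawn from.
#' @export
setClass("CohesionProfile",
  representation(connectednessPos = "numeric", connectednessNeg = "numeric",
                 cohesionPos = "numeric", cohesionNeg = "numeric",
                 nullIterations = "integer", method = "character",
                 seed = "integer"))

setValidity("CohesionProfile", function(object) {
  msg <- character()
  if (any(object@cohesionPos < -1e-12)) msg <- c(msg, "cohesionPos must be >= 0")
  if (any(object@cohesionNeg > 1e-12)) msg <- c(msg, "cohesionNeg must be <= 0")
  if (length(msg)) msg else TRUE
})

#' RobustnessResult: connectivity after simulated node removal
#'
#' @slot mode `"random"` or `"targeted"` (descending degree, ties by node id).
#' @slot removalFraction Fraction of nodes removed, in \[0, 1).
#' @slot replicates Number of removal replicates (1 for targeted mode).
#' @slot metric `"giant_component_fraction"` (largest component size over
#'   surviving nodes) or `"natural_connectivity"` (post/pre ratio).
#' @slot values Per-replicate metric values.
#' @export
setClass("RobustnessResult",
  representation(mode = "character", removalFraction = "numeric",
                 replicates = "integer", metric = "character",
                 values = "numeric"))

setValidity("RobustnessResult", function(object) {
  msg <- character()
  if (object@mode == "targeted" && object@replicates != 1L)
    msg <- c(msg, "targeted mode is deterministic: replicates must be 1")
  if (object@metric == "giant_component_fraction" &&
      any(object@values < 0 | object@values > 1))
    msg <- c(msg, "giant_component_fraction values must lie in [0, 1]")
  if (object@removalFraction < 0 || object@removalFraction >= 1)
    msg <- c(msg, "removalFraction must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})
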