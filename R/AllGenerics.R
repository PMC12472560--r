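#' @name myconet-generics
#' @title Generics for myconet result classes
#' @description Accessor generics for the S4 result containers.
#' @param object A myconet S4 object.
#' @param ... Further arguments for methods.
NULL

#' Per-sample stability ratio |negative cohesion| / positive cohesion
#'
#' @param object A [CohesionProfile-class].
#' @param ... Unused.
#' @return Named numeric vector per sample; `NA` (with a warning) where
#'   positive cohesion is not strictly positive.
#' @export
setGeneric("stabilityRatio", function(object, ...) standardGeneric("stabilityRatio"))

#' @rdname stabilityRatio
#' @export
setMethod("stabilityRatio", "CohesionProfile", function(object, ...) {
  pos <- object@cohesionPos
  neg <- object@cohesionNeg
  out <- rep(NA_real_, length(pos))
  names(out) <- names(pos)
  ok <- pos > 0
  if (any(!ok))
    warning("stability ratio undefined for ", sum(!ok),
            " sample(s) with non-positive positive cohesion")
  out[ok] <- abs(neg[ok]) / pos[ok]
  out
})

#' Extract the igraph object of a network
#'
#' @param object A [CoOccurrenceNetwork-class].
#' @param ... Unused.
#' @export
setGeneric("networkGraph", function(object, ...) standardGeneric("networkGraph"))

#' @rdname networkGraph
#' @export
setMethod("networkGraph", "CoOccurrenceNetwork", function(object, ...) object@graph)

#' Edge table of a network
#'
#' @param object A [CoOccurrenceNetwork-class].
#' @param ... Unused.
#' @return `data.frame` with columns `source`, `target`, `rho`, `sign`,
#'   source < target lexicographically.
#' @export
setGeneric("networkEdges", function(object, ...) standardGeneric("networkEdges"))

#' @rdname networkEdges
#' @export
setMethod("networkEdges", "CoOccurrenceNetwork", function(object, ...) {
  g <- object@graph
  if (igraph::ecount(g) == 0)
    return(data.frame(source = character(), target = character(),
                      rho = numeric(), sign = character()))
  el <- igraph::as_edgelist(g)
  swap <- el[, 1] > el[, 2]
  tmp <- el[swap, 1]; el[swap, 1] <- el[swap, 2]; el[swap, 2] <- tmp
  out <- data.frame(source = el[, 1], target = el[, 2],
                    rho = igraph::E(g)$rho, sign = igraph::E(g)$sign)
  out[order(out$source, out$target), , drop = FALSE]
})

setMethod("show", "SimulationDesign", function(object) {
  cat("SimulationDesign:", object@nGroups, "group(s) x",
      object@replicatesPerGroup, "replicates,", object@nTaxa, "taxa\n")
  cat("  depth:", object@sequencingDepth, " modules:", object@nModules,
      "x", object@moduleSize, " strength:",
      paste(format(object@moduleStrength), collapse = "/"), "\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "CoOccurrenceNetwork", function(object) {
  g <- object@graph
  cat("CoOccurrenceNetwork [", object@group, "]: ",
      igraph::vcount(g), " nodes, ", igraph::ecount(g), " edges",
      " (|rho| > ", object@rhoThreshold, ", adj. p < ", object@alpha, ")\n",
      sep = "")
  if (igraph::ecount(g) > 0) {
    s <- igraph::E(g)$sign
    cat("  positive edges: ", sum(s == "+"), ", negative edges: ",
        sum(s == "-"), "\n", sep = "")
  }
})

setMethod("show", "CohesionProfile", function(object) {
  cat("CohesionProfile:", length(object@cohesionPos), "samples,",
      length(object@connectednessPos), "taxa,",
      object@nullIterations, "null iterations (", object@method, ")\n")
  r <- suppressWarnings(stabilityRatio(object))
  cat("  mean positive cohesion:", signif(mean(object@cohesionPos), 4),
      " mean negative cohesion:", signif(mean(object@cohesionNeg), 4), "\n")
  cat("  mean stability ratio:", signif(mean(r, na.rm = TRUE), 4), "\n")
})

setMethod("show", "RobustnessResult", function(object) {
  cat("RobustnessResult [", object@mode, "]: remove ",
      round(100 * object@removalFraction), "% of nodes, ",
      object@replicates, " replicate(s)\n", sep = "")
  cat("  ", object@metric, ": mean ", signif(mean(object@values), 4),
      " (sd ", signif(sd(object@values), 4), ")\n", sep = "")
})

setMethod("show", "TopologySummary", function(object) {
  print(as.data.frame(object))
})

#' Coerce a TopologySummary to a one-row data.frame
#' @param x A [TopologySummary-class].
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @export
as.data.frame.TopologySummary <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(group = x@group, nodes = x@nodes, edges = x@edges,
             averageDegree = x@averageDegree,
             pathLength = x@pathLength, diameter = x@diameter,
             pathLengthNormalized = x@pathLengthNormalized,
             diameterNormalized = x@diameterNormalized,
             density = x@density,
             clusteringCoefficient = x@clusteringCoefficient,
             modularity = x@modularity,
             stringsAsFactors = FALSE)
}

#' @rdname as.data.frame.TopologySummary
#' @export
setMethod("as.data.frame", "TopologySummary",
          function(x, row.names = NULL, optional = FALSE, ...)
            as.data.frame.TopologySummary(x, row.names, optional, ...))
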