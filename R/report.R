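#' Assemble and validate a pipeline configuration
#'
#' @param asvTable,taxonomy,metadata,guildReference Input file paths
#'   (TSV; see the `read*` functions), or `NULL` when passing in-memory
#'   objects to [runPipeline()].
#' @param rhoThreshold,alpha Network edge gate.
#' @param rarefactionDepth `"auto"` or an integer depth.
#' @param minPrevalence,minMeanRelabund Pre-network taxon filter.
#' @param nullIterations Cohesion null-model iterations.
#' @param removalFraction,replicates Robustness simulation settings.
#' @param nPerm PERMANOVA permutations.
#' @param control Control group label.
#' @param guildsOnRarefied Compute guild abundances on rarefied counts
#'   (default) or raw counts.
#' @param seed Master seed.
#' @return Validated named list.
#' @export
pipelineConfig <- function(asvTable = NULL, taxonomy = NULL, metadata = NULL,
                           guildReference = NULL, rhoThreshold = 0.8,
                           alpha = 0.05, rarefactionDepth = "auto",
                           minPrevalence = 0.5, minMeanRelabund = 1e-4,
                           nullIterations = 200L, removalFraction = 0.5,
                           replicates = 100L, nPerm = 999L, control = "CK",
                           guildsOnRarefied = TRUE, seed = 1L) {
  cfg <- list(asvTable = asvTable, taxonomy = taxonomy, metadata = metadata,
              guildReference = guildReference, rhoThreshold = rhoThreshold,
              alpha = alpha, rarefactionDepth = rarefactionDepth,
              minPrevalence = minPrevalence,
              minMeanRelabund = minMeanRelabund,
              nullIterations = as.integer(nullIterations),
              removalFraction = removalFraction,
              replicates = as.integer(replicates), nPerm = as.integer(nPerm),
              control = control, guildsOnRarefied = isTRUE(guildsOnRarefied),
              seed = as.integer(seed))
  stopifnot(cfg$rhoThreshold > 0, cfg$rhoThreshold < 1,
            cfg$alpha > 0, cfg$alpha <= 1,
            cfg$minPrevalence >= 0, cfg$minPrevalence <= 1,
            cfg$nullIterations > 0, cfg$removalFraction >= 0,
            cfg$removalFraction < 1, cfg$replicates > 0, cfg$nPerm > 0)
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipelineConfig()] arguments.
#' @return Validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full network-stability pipeline
#'
#' End-to-end orchestration: rarefaction, alpha diversity, Bray-Curtis +
#' PCoA + PERMANOVA, guild assignment and group tests, per-treatment
#' co-occurrence networks with topology summaries, cohesion / stability
#' ratio / robustness with group tests, guild-stability correlations, and
#' a run manifest. Deterministic given the config seed. When `outDir` is
#' given, every table is written as TSV (networks additionally as GraphML)
#' as it is produced, so partial output survives a failing stage.
#'
#' @param config From [pipelineConfig()] / [readPipelineConfig()].
#' @param asv Optional in-memory [AsvExperiment-class] (with taxonomy and
#'   metadata attached) overriding the config paths.
#' @param guildReference Optional in-memory guild reference `data.frame`.
#' @param outDir Optional output directory.
#' @return Invisible list bundle: `alpha`, `distance`, `pcoa`, `permanova`,
#'   `guildAbundance`, `guildTests`, `networks`, `topology`, `cohesion`,
#'   `stabilityTests`, `robustness`, `guildStability`, `manifest`.
#' @export
runPipeline <- function(config = pipelineConfig(), asv = NULL,
                        guildReference = NULL, outDir = NULL) {
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  emit <- function(name, df) {
    if (!is.null(outDir))
      write.table(df, file.path(outDir, paste0(name, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    df
  }
  bundle <- list()

  asv <- .stage("input", {
    if (is.null(asv)) {
      if (is.null(config$asvTable)) stop("no ASV table given")
      tab <- readAsvTable(config$asvTable)
      AsvExperiment(asvCounts(tab),
                    taxonomy = readTaxonomyTable(config$taxonomy),
                    metadata = readSampleMetadata(config$metadata))
    } else asv
  })
  guildReference <- .stage("input", {
    if (is.null(guildReference)) readGuildReference(config$guildReference)
    else guildReference
  })
  meta <- data.frame(sample_id = colnames(asv),
                     treatment = treatments(asv), stringsAsFactors = FALSE)

  rare <- .stage("rarefaction",
                 rarefy(asv, config$rarefactionDepth, seed = config$seed))
  bundle$alpha <- emit("alpha_diversity", .stage("alpha", {
    a <- alphaDiversity(rare)
    a$treatment <- treatments(rare)[a$sample_id]
    a
  }))
  bundle$distance <- .stage("beta", brayCurtis(rare))
  if (!is.null(outDir))
    write.table(data.frame(sample_id = rownames(bundle$distance),
                           bundle$distance, check.names = FALSE),
                file.path(outDir, "bray_curtis.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  bundle$pcoa <- .stage("pcoa", pcoa(bundle$distance,
                                     k = min(3, ncol(rare) - 1)))
  emit("pcoa_coordinates",
       data.frame(sample_id = rownames(bundle$pcoa$coordinates),
                  bundle$pcoa$coordinates))
  bundle$permanova <- .stage("permanova",
    permanova(bundle$distance, meta, nPerm = config$nPerm,
              seed = config$seed))
  emit("permanova", as.data.frame(bundle$permanova))

  mapping <- .stage("guilds", {
    lin <- rowData(asv)$lineage
    if (is.null(lin)) stop("ASV table lacks taxonomy lineages")
    assignGuilds(data.frame(ASV_ID = rownames(asv), lineage = lin,
                            stringsAsFactors = FALSE), guildReference)
  })
  gsrc <- if (config$guildsOnRarefied) rare else asv
  bundle$guildAbundance <- .stage("guilds",
    guildRelativeAbundance(gsrc, mapping[rownames(gsrc)]))
  emit("guild_abundance",
       data.frame(guild = rownames(bundle$guildAbundance),
                  bundle$guildAbundance, check.names = FALSE))
  bundle$guildTests <- emit("guild_tests", .stage("guilds",
    compareGuilds(bundle$guildAbundance, meta, control = config$control)))

  groups <- unique(meta$treatment)
  bundle$networks <- .stage("network", {
    nets <- lapply(groups, function(g)
      groupNetwork(rare, g, config$rhoThreshold, config$alpha,
                   config$minPrevalence, config$minMeanRelabund))
    names(nets) <- groups
    if (!is.null(outDir)) {
      for (g in groups) {
        writeNetwork(nets[[g]], file.path(outDir, paste0("network_", g,
                                                         ".graphml")))
        writeNetwork(nets[[g]], file.path(outDir, paste0("network_", g,
                                                         "_edges.csv")),
                     format = "edge_csv")
      }
    }
    nets
  })
  bundle$topology <- emit("topology", .stage("topology",
    compareTopology(lapply(bundle$networks, summarizeTopology),
                    control = config$control)))

  bundle$cohesion <- .stage("cohesion", {
    profs <- lapply(groups, function(g) {
      sub <- rare[, treatments(rare) == g]
      communityCohesion(filterTaxa(sub, config$minPrevalence,
                                   config$minMeanRelabund),
               nullIterations = config$nullIterations, seed = config$seed)
    })
    names(profs) <- groups
    profs
  })
  ratios <- lapply(bundle$cohesion, function(p)
    suppressWarnings(stabilityRatio(p)))
  emit("cohesion", do.call(rbind, lapply(groups, function(g) {
    p <- bundle$cohesion[[g]]
    data.frame(sample_id = names(p@cohesionPos), treatment = g,
               cohesion_pos = p@cohesionPos, cohesion_neg = p@cohesionNeg,
               stability_ratio = ratios[[g]], row.names = NULL)
  })))
  bundle$stabilityTests <- emit("stability_tests", .stage("stability",
    compareStability(ratios)))

  bundle$robustness <- .stage("robustness", {
    out <- list()
    for (g in groups) {
      if (igraph::vcount(networkGraph(bundle$networks[[g]])) == 0) {
        message("network for group '", g,
                "' is empty: robustness skipped")
        next
      }
      for (mode in c("random", "targeted")) {
        r <- robustness(bundle$networks[[g]], mode = mode,
                        removalFraction = config$removalFraction,
                        replicates = config$replicates, seed = config$seed)
        out[[paste(g, mode, sep = "_")]] <- r
      }
    }
    out
  })
  emit("robustness", do.call(rbind, lapply(names(bundle$robustness),
    function(nm) {
      r <- bundle$robustness[[nm]]
      data.frame(network = nm, mode = r@mode, metric = r@metric,
                 removal_fraction = r@removalFraction,
                 mean = mean(r@values), sd = sd(r@values),
                 replicates = r@replicates)
    })))

  bundle$guildStability <- emit("guild_stability", .stage("link", {
    s <- unlist(unname(ratios))
    correlateGuildStability(bundle$guildAbundance, s)
  }))

  bundle$manifest <- .stage("manifest", {
    man <- list(package = "myconet",
                version = as.character(packageVersion("myconet")),
                r_version = as.character(getRversion()),
                parameters = config[setdiff(names(config),
                                            c("asvTable", "taxonomy",
                                              "metadata", "guildReference"))],
                inputs = config[c("asvTable", "taxonomy", "metadata",
                                  "guildReference")],
                groups = groups)
    if (!is.null(outDir))
      jsonlite::write_json(man, file.path(outDir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    man
  })
  invisible(bundle)
}
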