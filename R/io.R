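# TSV dialect shared by all readers: tab-separated, UTF-8, lines starting
# with '#' ignored. Taxon/sample order is preserved exactly as read.

.readTsvLines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read an ASV count table from TSV
#'
#' Expects a header row of sample identifiers, a first column of taxon
#' identifiers (conventionally named `ASV_ID`), and integer cells. Lines
#' beginning with `#` are ignored. Ragged rows, duplicate identifiers and
#' negative or non-numeric cells are rejected with the offending line
#' number.
#'
#' @param path Path to the TSV file.
#' @return An [AsvExperiment-class] (counts only; attach taxonomy/metadata
#'   via [AsvExperiment()] if needed).
#' @export
readAsvTable <- function(path) {
  tsv <- .readTsvLines(path)
  if (length(tsv$lines) < 2) stop("empty ASV table: ", path)
  fields <- strsplit(tsv$lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncols <- length(header)
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers in header of ", path)
  body <- fields[-1]
  n <- length(body)
  taxa <- character(n)
  mat <- matrix(0, nrow = n, ncol = ncols - 1)
  for (i in seq_len(n)) {
    row <- body[[i]]
    if (length(row) != ncols)
      stop("ragged row at line ", tsv$lineno[i + 1], ": expected ", ncols,
           " fields, found ", length(row))
    taxa[i] <- row[1]
    vals <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1]
      stop("non-numeric cell at line ", tsv$lineno[i + 1], ", column '",
           sample_ids[bad], "': '", row[-1][bad], "'")
    }
    if (any(vals < 0)) {
      bad <- which(vals < 0)[1]
      stop("negative count at line ", tsv$lineno[i + 1], " (taxon '",
           row[1], "'), column '", sample_ids[bad], "'")
    }
    if (any(vals != round(vals))) {
      bad <- which(vals != round(vals))[1]
      stop("non-integer count at line ", tsv$lineno[i + 1], ", column '",
           sample_ids[bad], "'")
    }
    mat[i, ] <- vals
  }
  if (anyDuplicated(taxa))
    stop("duplicate taxon identifiers in ", path, ": ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  dimnames(mat) <- list(taxa, sample_ids)
  AsvExperiment(mat)
}

#' Write an ASV count table as TSV
#'
#' Taxa as rows, samples as columns, first column `ASV_ID`. Round-trips
#' bit-identically through [readAsvTable()].
#'
#' @param asv [AsvExperiment-class] or count matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAsvTable <- function(asv, path) {
  m <- asvCounts(asv)
  df <- data.frame(ASV_ID = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table (ASV_ID, lineage)
#'
#' @param path TSV with columns `ASV_ID` and `lineage`
#'   (semicolon-delimited 7-rank lineage).
#' @return `data.frame(ASV_ID, lineage)`.
#' @export
readTaxonomyTable <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("ASV_ID", "lineage") %in% names(df)))
    stop("taxonomy table must have columns 'ASV_ID' and 'lineage'")
  if (anyDuplicated(df$ASV_ID)) stop("duplicate ASV_ID in ", path)
  df[, c("ASV_ID", "lineage")]
}

#' Read sample metadata (sample_id, treatment)
#'
#' @param path TSV with columns `sample_id` and `treatment`.
#' @return `data.frame(sample_id, treatment)`.
#' @export
readSampleMetadata <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "treatment") %in% names(df)))
    stop("metadata must have columns 'sample_id' and 'treatment'")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in ", path)
  df[, c("sample_id", "treatment")]
}

#' Read a guild reference table (pattern, guild)
#'
#' @param path TSV with columns `pattern` (lineage fragment such as
#'   `g__Mortierella`) and `guild` (one of [guildLabels()]).
#' @return `data.frame(pattern, guild)`.
#' @export
readGuildReference <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("pattern", "guild") %in% names(df)))
    stop("guild reference must have columns 'pattern' and 'guild'")
  bad <- setdiff(unique(df$guild), guildLabels())
  if (length(bad))
    stop("unknown guild label(s): ", paste(bad, collapse = ", "))
  df[, c("pattern", "guild")]
}

#' Write a guild reference table
#' @param ref `data.frame(pattern, guild)`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGuildReference <- function(ref, path) {
  write.table(ref, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a co-occurrence network to GraphML or an edge list
#'
#' GraphML output (edge attributes `rho` and `sign`) is readable by Gephi
#' and igraph; `edge_csv` writes columns `source`, `target`, `rho`, `sign`.
#'
#' @param net A [CoOccurrenceNetwork-class].
#' @param path Output path.
#' @param format `"graphml"` or `"edge_csv"`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path, format = c("graphml", "edge_csv")) {
  format <- match.arg(format)
  stopifnot(is(net, "CoOccurrenceNetwork"))
  if (format == "graphml") {
    igraph::write_graph(net@graph, path, format = "graphml")
  } else {
    utils::write.csv(networkEdges(net), path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a GraphML network back into a CoOccurrenceNetwork
#'
#' @param path GraphML file written by [writeNetwork()].
#' @param group Group label to attach.
#' @param rhoThreshold,alpha Gate parameters to record (metadata only; the
#'   edges are taken as stored).
#' @return A [CoOccurrenceNetwork-class].
#' @export
readNetwork <- function(path, group = "NA", rhoThreshold = 0.8, alpha = 0.05) {
  g <- igraph::read_graph(path, format = "graphml")
  g <- igraph::as_undirected(g, mode = "collapse")
  if (!is.null(igraph::vertex_attr(g, "name")) &&
      is.null(igraph::V(g)$name)) igraph::V(g)$name <- igraph::vertex_attr(g, "name")
  new("CoOccurrenceNetwork", graph = g, group = group,
      rhoThreshold = rhoThreshold, alpha = alpha)
}
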