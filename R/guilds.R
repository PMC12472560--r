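#' Assign taxa to functional guilds by most-specific lineage match
#'
#' Lookup-table guild assignment: each taxon's semicolon-delimited ranked
#' lineage is scanned from the most specific rank (species, then genus,
#' family, order, class, phylum, kingdom); the first rank token with an
#' entry in the reference decides the guild. A genus-level entry therefore
#' always beats a conflicting family-level one. Unmatched or malformed
#' lineages become `Unassigned` (malformed ones with a warning).
#'
#' @param taxonomy `data.frame(ASV_ID, lineage)`.
#' @param reference Guild reference `data.frame(pattern, guild)`; patterns
#'   are rank tokens such as `"g__Mortierella"`.
#' @return Named character vector: taxon -> guild label.
#' @export
#' @examples
#' tax <- data.frame(ASV_ID = "ASV_1",
#'                   lineage = "k__Fungi;p__Mucoromycota;g__Mortierella")
#' ref <- data.frame(pattern = "g__Mortierella", guild = "Saprotroph")
#' assignGuilds(tax, ref)
assignGuilds <- function(taxonomy, reference) {
  bad <- setdiff(unique(reference$guild), guildLabels())
  if (length(bad)) stop("unknown guild label(s) in reference: ",
                        paste(bad, collapse = ", "))
  lookup <- setNames(reference$guild, reference$pattern)
  rankOrder <- c("s__", "g__", "f__", "o__", "c__", "p__", "k__")
  out <- setNames(rep("Unassigned", nrow(taxonomy)), taxonomy$ASV_ID)
  malformed <- character(0)
  for (i in seq_len(nrow(taxonomy))) {
    lin <- taxonomy$lineage[i]
    toks <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
    toks <- toks[nzchar(toks)]
    prefixed <- grepl("^[kpcofgs]__", toks)
    if (length(toks) == 0 || !any(prefixed)) {
      malformed <- c(malformed, taxonomy$ASV_ID[i])
      next
    }
    toks <- toks[prefixed]
    for (rk in rankOrder) {
      tok <- toks[startsWith(toks, rk)]
      tok <- tok[nzchar(sub(rk, "", tok))]
      if (length(tok) && tok[1] %in% names(lookup)) {
        out[i] <- lookup[[tok[1]]]
        break
      }
    }
  }
  if (length(malformed))
    warning("malformed lineage(s) set to Unassigned: ",
            paste(utils::head(malformed, 5), collapse = ", "))
  out
}

#' Per-sample guild relative abundances
#'
#' Sums counts per guild and divides by each sample's total; rows cover all
#' seven labels (including `Unassigned`), so columns sum to 1.
#'
#' @param asv [AsvExperiment-class] or count matrix.
#' @param mapping Named taxon -> guild vector from [assignGuilds()];
#'   must cover every taxon in the table.
#' @return Matrix (guild x sample) of proportions in \[0, 1\].
#' @export
guildRelativeAbundance <- function(asv, mapping) {
  m <- asvCounts(asv)
  mapping <- mapping[rownames(m)]
  if (anyNA(mapping)) stop("mapping does not cover all taxa in the table")
  cs <- colSums(m)
  if (any(cs == 0)) stop("zero-total sample(s): ",
                         paste(colnames(m)[cs == 0], collapse = ", "))
  agg <- rowsum(m, group = factor(mapping, levels = guildLabels()))
  out <- matrix(0, length(guildLabels()), ncol(m),
                dimnames = list(guildLabels(), colnames(m)))
  out[rownames(agg), ] <- agg
  sweep(out, 2, cs, "/")
}

#' Compare guild abundances between treatment groups
#'
#' Pairwise two-sided Wilcoxon rank-sum tests per guild between the control
#' group and each other group, plus the percent change of group means
#' relative to control. Exact p-values are used for small tie-free samples;
#' the tie-corrected normal approximation otherwise (the [stats::wilcox.test()]
#' convention).
#'
#' @param guildAbund Guild x sample proportion matrix from
#'   [guildRelativeAbundance()].
#' @param metadata `data.frame(sample_id, treatment)`.
#' @param control Control group label (default `"CK"`).
#' @return `data.frame(guild, group, meanControl, meanGroup, percentChange,
#'   W, p, stars)`.
#' @export
compareGuilds <- function(guildAbund, metadata, control = "CK") {
  idx <- match(colnames(guildAbund), metadata$sample_id)
  if (anyNA(idx)) stop("metadata is missing samples: ",
                       paste(colnames(guildAbund)[is.na(idx)], collapse = ", "))
  grp <- metadata$treatment[idx]
  tab <- table(grp)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 2)) stop("every group needs >= 2 samples")
  if (!control %in% grp) stop("control group '", control, "' not present")
  others <- setdiff(names(tab), control)
  res <- list()
  for (gl in rownames(guildAbund)) {
    x0 <- guildAbund[gl, grp == control]
    for (g in others) {
      x1 <- guildAbund[gl, grp == g]
      if (all(x0 == x0[1]) && all(x1 == x1[1]) && x0[1] == x1[1]) {
        w <- list(statistic = length(x0) * length(x1) / 2, p.value = 1)
      } else {
        w <- suppressWarnings(wilcox.test(x1, x0))
      }
      pc <- if (mean(x0) > 0) 100 * (mean(x1) - mean(x0)) / mean(x0) else NA_real_
      res[[length(res) + 1]] <- data.frame(
        guild = gl, group = g, meanControl = mean(x0), meanGroup = mean(x1),
        percentChange = pc, W = unname(w$statistic), p = w$p.value,
        stars = significanceStars(w$p.value), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
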