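#' Correlate guild relative abundance with per-sample network stability
#'
#' For each guild, Pearson (default) or Spearman correlation between the
#' guild's per-sample relative abundance and the per-sample stability ratio
#' (|negative cohesion| / positive cohesion), pooled over treatment groups.
#' Samples are aligned by identifier, never by position.
#'
#' @param guildAbund Guild x sample proportion matrix from
#'   [guildRelativeAbundance()].
#' @param stability Named numeric vector of per-sample stability ratios
#'   (names = sample ids), e.g. `stabilityRatio(communityCohesion(...))`.
#' @param method `"pearson"` (the reporting convention, with a fitted
#'   line) or `"spearman"`.
#' @return `data.frame(guild, R, p, n)`; guilds with zero variance get
#'   `R = NA` with a warning.
#' @export
correlateGuildStability <- function(guildAbund, stability,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stability <- stability[!is.na(stability)]
  shared <- intersect(colnames(guildAbund), names(stability))
  missing1 <- setdiff(colnames(guildAbund), names(stability))
  missing2 <- setdiff(names(stability), colnames(guildAbund))
  if (length(shared) < 3)
    stop("need >= 3 shared samples; missing from stability: ",
         paste(missing1, collapse = ", "), "; missing from guilds: ",
         paste(missing2, collapse = ", "))
  if (length(missing1) || length(missing2))
    stop("sample ids do not match; missing from stability: [",
         paste(missing1, collapse = ", "), "]; missing from guilds: [",
         paste(missing2, collapse = ", "), "]")
  s <- stability[shared]
  res <- lapply(rownames(guildAbund), function(gl) {
    x <- guildAbund[gl, shared]
    if (var(x) == 0 || var(s) == 0) {
      warning("zero variance for guild '", gl, "': correlation undefined")
      return(data.frame(guild = gl, R = NA_real_, p = NA_real_,
                        n = length(shared), stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(cor.test(x, s, method = method))
    data.frame(guild = gl, R = unname(ct$estimate), p = ct$p.value,
               n = length(shared), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
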