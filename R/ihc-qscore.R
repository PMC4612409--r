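# Semiquantitative immunohistochemistry Quick-score (Q-score) per tissue
# microarray core and per group.

#' Quick-score of a TMA core
#'
#' Percentage of positively stained cells (0-100) multiplied by the staining
#' intensity grade (0 none, 1 weak, 2 moderate, 3 strong), giving a score in
#' \[0, 300\].
#'
#' @param percent_positive percent positive cells in \[0, 100\].
#' @param intensity intensity grade in `{0, 1, 2, 3}`.
#' @return numeric Q-score(s) in \[0, 300\].
#' @examples
#' qscore(50, 2)   # 100
#' qscore(100, 3)  # 300
#' @export
qscore <- function(percent_positive, intensity) {
  if (!is.numeric(percent_positive) || anyNA(percent_positive) ||
      any(percent_positive < 0 | percent_positive > 100))
    .stopf("percent_positive must lie in [0, 100]")
  if (!is.numeric(intensity) || anyNA(intensity) ||
      !all(intensity %in% 0:3))
    .stopf("intensity must be one of 0, 1, 2, 3")
  percent_positive * intensity
}

#' Summarise Q-scores per group with a monotone-trend flag
#'
#' Group means and standard deviations of core-level Q-scores along the
#' stage order (NAT, AD, CRC), plus a flag for a strict monotone trend of
#' the means: `"decreasing"`, `"increasing"`, or `"none"`.
#'
#' @param records data.frame with columns `group` and either `qscore` or
#'   both `percent_positive` and `intensity`.
#' @param levels group order; defaults to `c("NAT", "AD", "CRC")`
#'   restricted to the groups present. Empty groups are excluded with a
#'   warning.
#' @return list with `summary` (data.frame: group, n, mean, sd) and
#'   `trend`.
#' @export
summarize_qscores <- function(records, levels = c("NAT", "AD", "CRC")) {
  if (!is.data.frame(records) || !"group" %in% names(records))
    .stopf("records must be a data.frame with a 'group' column")
  if (!"qscore" %in% names(records)) {
    if (!all(c("percent_positive", "intensity") %in% names(records)))
      .stopf("records need a 'qscore' column or percent_positive + intensity")
    records$qscore <- qscore(records$percent_positive, records$intensity)
  }
  grps <- unique(as.character(records$group))
  present <- if (is.factor(records$group)) levels(records$group) else
    c(levels[levels %in% grps], setdiff(grps, levels))
  empty <- present[!present %in% records$group]
  if (length(empty)) {
    .warnf("excluding empty group(s): %s", paste(empty, collapse = ", "))
    present <- setdiff(present, empty)
  }
  if (length(present) == 0L) .stopf("no non-empty groups")
  sm <- data.frame(
    group = present,
    n = vapply(present, function(g) sum(records$group == g), integer(1)),
    mean = vapply(present, function(g)
      mean(records$qscore[records$group == g]), numeric(1)),
    sd = vapply(present, function(g)
      stats::sd(records$qscore[records$group == g]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(sm) <- NULL
  trend <- "none"
  if (nrow(sm) >= 2L) {
    d <- diff(sm$mean)
    if (all(d < 0)) trend <- "decreasing"
    if (all(d > 0)) trend <- "increasing"
  }
  list(summary = sm, trend = trend)
}
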