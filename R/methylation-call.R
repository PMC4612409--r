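# Per-CpG methylation calling from passing alignments, assay-level
# summaries, group comparison with hyper/hypo classification, and
# hierarchical clustering of the marker x sample methylation matrix.

#' Summarise methylation evidence per CpG site
#'
#' Counts, over the passing reads of an alignment set, the methylation
#' evidence at each callable CpG site: `count_C` (methylated base),
#' `count_T` (unmethylated base), `count_other` (any other base, or a gap in
#' the read at that column). Sites inside primer masks are excluded.
#' The methylation fraction is `count_C / (count_C + count_T)`, undefined
#' (NA) at zero coverage. Reads that fail the score-fraction filter
#' contribute nothing.
#'
#' @param alignments a `bs_alignment_set` from [align_reads()].
#' @return a `cpg_call_table` data.frame with columns `template`, `site`
#'   (1-based plus-strand position of the CpG cytosine), `count_C`,
#'   `count_T`, `count_other`, `coverage` (= count_C + count_T), `fraction`.
#' @export
call_cpg_methylation <- function(alignments) {
  if (!inherits(alignments, "bs_alignment_set"))
    .stopf("alignments must be a bs_alignment_set")
  template <- alignments$template
  sites <- .callable_sites(template)
  pass <- alignments$table$pass
  if (is.null(pass)) .stopf("alignments must be filtered first (align_reads does this)")
  keep <- alignments$alignments[pass]
  if (length(sites) == 0L) {
    out <- data.frame(template = character(0), site = integer(0),
                      count_C = integer(0), count_T = integer(0),
                      count_other = integer(0), coverage = integer(0),
                      fraction = numeric(0))
    class(out) <- c("cpg_call_table", class(out))
    return(out)
  }
  if (length(keep)) {
    cm <- do.call(rbind, lapply(keep, `[[`, "cpg_calls"))
    count_C <- colSums(cm == "M", na.rm = TRUE)
    count_T <- colSums(cm == "U", na.rm = TRUE)
    count_other <- colSums(cm == "O", na.rm = TRUE)
  } else {
    count_C <- count_T <- count_other <- rep(0L, length(sites))
  }
  coverage <- count_C + count_T
  out <- data.frame(template = template$name, site = sites,
                    count_C = as.integer(count_C),
                    count_T = as.integer(count_T),
                    count_other = as.integer(count_other),
                    coverage = as.integer(coverage),
                    fraction = ifelse(coverage > 0, count_C / coverage,
                                      NA_real_),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cpg_call_table", class(out))
  out
}

#' Assay-level mean methylation percentage
#'
#' Unweighted mean of the defined per-site methylation fractions, times 100
#' (coverage weighting available via `coverage_weight = TRUE`). Mirrors a
#' per-assay "mean DNA methylation %" summary.
#'
#' @param table a `cpg_call_table` from [call_cpg_methylation()].
#' @param sites optional subset of site positions; default all.
#' @param coverage_weight weight sites by coverage instead of equally.
#' @return mean methylation percent in \[0, 100\], or NA if no site has a
#'   defined fraction.
#' @export
summarize_assay <- function(table, sites = NULL, coverage_weight = FALSE) {
  if (!is.data.frame(table) || !all(c("site", "fraction") %in% names(table)))
    .stopf("table must be a cpg_call_table")
  if (!is.null(sites)) {
    if (length(sites) == 0L) .stopf("empty site subset")
    miss <- setdiff(sites, table$site)
    if (length(miss))
      .stopf("site(s) not in table: %s", paste(miss, collapse = ", "))
    table <- table[table$site %in% sites, , drop = FALSE]
  }
  def <- !is.na(table$fraction)
  if (!any(def)) return(NA_real_)
  if (coverage_weight) {
    w <- table$coverage[def]
    return(100 * sum(table$fraction[def] * w) / sum(w))
  }
  100 * mean(table$fraction[def])
}

#' Compare methylation between lesion groups and a reference group
#'
#' Per assay (matrix row), two-sided pooled-variance t-tests of each lesion
#' group against the reference (first) group, plus the lesion-vs-lesion
#' comparison when three groups are present. Each lesion group is classified
#' against the reference as `"hypermethylated"` (higher mean, significant),
#' `"hypomethylated"` (lower mean, significant) or `"unchanged"`;
#' all-missing assays are `"not_evaluable"`. Missing cells are dropped
#' pairwise; a comparison with fewer than two non-missing values per group
#' yields NA. BH-adjusted p-values across assays are reported alongside;
#' classification uses the raw p by default (`adjust = TRUE` switches it to
#' the adjusted p).
#'
#' @param mat assays x samples matrix of methylation percentages (0-100,
#'   NA allowed).
#' @param groups per-sample group labels; a factor whose first level is the
#'   reference (e.g. NAT), or character labels among
#'   `c("NAT", "AD", "CRC")`.
#' @param alpha significance level (default 0.05).
#' @param adjust classify on BH-adjusted p-values instead of raw.
#' @return data.frame with per-group `mean_*` and `sd_*`, per-comparison
#'   `p_*` and `q_*`, and per-lesion `class_*` columns.
#' @export
compare_methylation_groups <- function(mat, groups, alpha = 0.05,
                                       adjust = FALSE) {
  if (is.data.frame(mat)) mat <- as.matrix(mat)
  if (!is.matrix(mat) || !is.numeric(mat)) .stopf("mat must be a numeric matrix")
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("assay_%d", seq_len(nrow(mat)))
  gf <- .stage_factor(groups, levels = c("NAT", "AD", "CRC"))
  if (length(gf) != ncol(mat)) .stopf("one group label per sample required")
  lv <- levels(gf)
  if (length(lv) < 2L) .stopf("need at least two groups")
  out <- data.frame(assay = rownames(mat), stringsAsFactors = FALSE)
  for (g in lv) {
    x <- mat[, gf == g, drop = FALSE]
    out[[paste0("mean_", g)]] <- rowMeans(x, na.rm = TRUE)
    out[[paste0("sd_", g)]] <- apply(x, 1L, stats::sd, na.rm = TRUE)
  }
  cmp <- lapply(seq_along(lv)[-1L], function(k) c(lv[1L], lv[k]))
  if (length(lv) == 3L) cmp <- c(cmp, list(c(lv[2L], lv[3L])))
  for (pair in cmp) {
    nm <- paste0(pair[1L], "_vs_", pair[2L])
    p <- vapply(seq_len(nrow(mat)), function(i) {
      x1 <- mat[i, gf == pair[1L]]; x1 <- x1[!is.na(x1)]
      x2 <- mat[i, gf == pair[2L]]; x2 <- x2[!is.na(x2)]
      if (length(x1) < 2L || length(x2) < 2L) return(NA_real_)
      .row_t_test(rbind(c(x1, x2)), seq_along(x1),
                  length(x1) + seq_along(x2))$p
    }, numeric(1))
    out[[paste0("p_", nm)]] <- p
    out[[paste0("q_", nm)]] <- bh_adjust(p)
  }
  all_missing <- apply(mat, 1L, function(x) all(is.na(x)))
  for (g in lv[-1L]) {
    nm <- paste0(lv[1L], "_vs_", g)
    p_use <- out[[paste0(if (adjust) "q_" else "p_", nm)]]
    dm <- out[[paste0("mean_", g)]] - out[[paste0("mean_", lv[1L])]]
    cls <- ifelse(is.na(p_use), "not_evaluable",
           ifelse(p_use < alpha & dm > 0, "hypermethylated",
           ifelse(p_use < alpha & dm < 0, "hypomethylated", "unchanged")))
    cls[all_missing] <- "not_evaluable"
    out[[paste0("class_", g)]] <- cls
  }
  out
}

#' Hierarchically cluster a methylation matrix
#'
#' Agglomerative clustering of assays (rows) and samples (columns) with
#' [stats::hclust()]. Missing cells are imputed with the row mean
#' (`impute = "mean"`, default) before computing distances; rows with no
#' observed value are excluded with a warning. The dendrogram and flat
#' partition are deterministic for a given matrix.
#'
#' @param mat assays x samples numeric matrix (NA allowed).
#' @param distance distance metric passed to [stats::dist()]
#'   (default "euclidean").
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default "average").
#' @param k optional number of flat row clusters to cut.
#' @param impute `"mean"` (row-mean imputation) or `"none"`.
#' @return list with `row_hclust`, `col_hclust`, `row_order`, `col_order`
#'   (labels in dendrogram order), `clusters` (named cluster ids when `k`
#'   given), and `excluded` (labels of all-missing rows).
#' @export
cluster_markers <- function(mat, distance = "euclidean", linkage = "average",
                            k = NULL, impute = c("mean", "none")) {
  impute <- match.arg(impute)
  if (is.data.frame(mat)) mat <- as.matrix(mat)
  if (!is.matrix(mat) || !is.numeric(mat)) .stopf("mat must be a numeric matrix")
  if (nrow(mat) < 2L) .stopf("need at least two rows to cluster")
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("assay_%d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("sample_%d", seq_len(ncol(mat)))
  all_missing <- apply(mat, 1L, function(x) all(is.na(x)))
  excluded <- rownames(mat)[all_missing]
  if (length(excluded)) {
    .warnf("excluding all-missing row(s): %s", paste(excluded, collapse = ", "))
    mat <- mat[!all_missing, , drop = FALSE]
  }
  if (nrow(mat) < 2L) .stopf("fewer than two rows with data")
  if (impute == "mean" && anyNA(mat)) {
    rm <- rowMeans(mat, na.rm = TRUE)
    ix <- which(is.na(mat), arr.ind = TRUE)
    mat[ix] <- rm[ix[, 1L]]
  }
  rh <- stats::hclust(stats::dist(mat, method = distance), method = linkage)
  ch <- if (ncol(mat) >= 2L)
    stats::hclust(stats::dist(t(mat), method = distance), method = linkage)
  else NULL
  out <- list(row_hclust = rh, col_hclust = ch,
              row_order = rownames(mat)[rh$order],
              col_order = if (is.null(ch)) colnames(mat)
                          else colnames(mat)[ch$order],
              excluded = excluded)
  if (!is.null(k)) {
    k <- .check_count(k, "k", min = 1L)
    out$clusters <- stats::cutree(rh, k = min(k, nrow(mat)))
  }
  out
}

#' Assemble a methylation matrix from per-sample assay summaries
#'
#' @param sample_values named list (one element per sample) of named numeric
#'   vectors (assay -> methylation percent).
#' @param groups per-sample group labels, same order as `sample_values`.
#' @return matrix assays x samples with a `groups` attribute (factor).
#' @export
methylation_matrix <- function(sample_values, groups) {
  if (!is.list(sample_values) || is.null(names(sample_values)))
    .stopf("sample_values must be a named list")
  if (length(groups) != length(sample_values))
    .stopf("one group label per sample required")
  assays <- unique(unlist(lapply(sample_values, names)))
  if (is.null(assays)) .stopf("sample value vectors must be named by assay")
  mat <- vapply(sample_values, function(v) {
    out <- rep(NA_real_, length(assays))
    names(out) <- assays
    out[names(v)] <- v
    out
  }, numeric(length(assays)))
  mat <- matrix(mat, nrow = length(assays),
                dimnames = list(assays, names(sample_values)))
  attr(mat, "groups") <- .stage_factor(groups, levels = c("NAT", "AD", "CRC"))
  mat
}

#' Heatmap of a methylation matrix
#'
#' Convenience wrapper: uses `pheatmap` when installed, otherwise
#' [stats::heatmap()]. Intended for interactive inspection; all clustering
#' statistics come from [cluster_markers()].
#'
#' @inheritParams cluster_markers
#' @param ... passed to the underlying heatmap function.
#' @export
methylation_heatmap <- function(mat, distance = "euclidean",
                                linkage = "average", ...) {
  if (is.data.frame(mat)) mat <- as.matrix(mat)
  if (anyNA(mat)) {
    rm <- rowMeans(mat, na.rm = TRUE)
    ix <- which(is.na(mat), arr.ind = TRUE)
    mat[ix] <- rm[ix[, 1L]]
  }
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(mat, clustering_distance_rows = distance,
                       clustering_distance_cols = distance,
                       clustering_method = linkage, ...)
  } else {
    stats::heatmap(mat, distfun = function(x) stats::dist(x, method = distance),
                   hclustfun = function(d) stats::hclust(d, method = linkage),
                   ...)
  }
}
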