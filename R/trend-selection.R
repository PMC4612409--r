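# Trend-based marker selection along the normal -> adenoma -> carcinoma
# sequence: Kendall tau-b against the ordinal stage code, pairwise
# pooled-variance t-tests with Benjamini-Hochberg correction, log2
# fold-change thresholds, and the two-way Venn categorisation.

#' Kendall rank correlation of expression against ordered stage
#'
#' Computes the tie-corrected Kendall tau-b between a vector of expression
#' values and an ordinal disease-stage code. Because the stage variable takes
#' only a few values (normal = 0, adenoma = 1, carcinoma = 2) it is massively
#' tied, so the tie-corrected tau-b variant is used. Tau is rank based, so any
#' strictly increasing recoding of the stages gives the same value.
#'
#' @param values numeric vector of per-sample expression (log2 scale).
#' @param stages per-sample stage labels: a factor (level order = stage
#'   order), integer codes, or character labels among
#'   `c("normal", "adenoma", "CRC")`.
#' @return tau in \[-1, 1\]. When `values` is constant the coefficient is
#'   undefined; 0 is returned with attribute `degenerate = TRUE`.
#' @examples
#' kendall_tau_trend(c(1, 2, 3), c(0, 1, 2))   #  1
#' kendall_tau_trend(c(3, 2, 1), c(0, 1, 2))   # -1
#' @export
kendall_tau_trend <- function(values, stages) {
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    .stopf("values must be finite numeric")
  st <- .stage_codes(stages)
  if (length(values) != length(st))
    .stopf("values and stages must have equal length")
  if (length(unique(st)) < 2L)
    .stopf("trend undefined: only one stage present")
  i <- .pair_index(length(values))
  dx <- sign(values[i$a] - values[i$b])
  dy <- sign(st[i$a] - st[i$b])
  n0 <- length(dx)
  n1 <- sum(dx == 0)
  n2 <- sum(dy == 0)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  sum(dx * dy) / den
}

# all unordered sample pairs a < b
.pair_index <- function(n) {
  cp <- utils::combn(n, 2L)
  list(a = cp[1L, ], b = cp[2L, ])
}

# vectorised tau-b for a genes x samples matrix against one stage vector
.row_kendall_tau <- function(mat, stages) {
  st <- .stage_codes(stages)
  n <- ncol(mat)
  i <- .pair_index(n)
  dy <- sign(st[i$a] - st[i$b])
  dx <- sign(mat[, i$a, drop = FALSE] - mat[, i$b, drop = FALSE])
  n0 <- length(dy)
  n1 <- rowSums(dx == 0)
  n2 <- sum(dy == 0)
  den <- sqrt((n0 - n1) * (n0 - n2))
  num <- as.vector(dx %*% dy)
  tau <- ifelse(den > 0, num / den, 0)
  list(tau = tau, degenerate = den == 0)
}

# Row-wise two-sample t-test between column sets idx1 and idx2.
# var_equal = TRUE gives the classical pooled-variance (Student) test;
# FALSE gives Welch. Degenerate rows follow t.test conventions where they
# exist and otherwise: both groups constant and equal -> p = 1; zero
# within-group variance with different means -> p = 0.
.row_t_test <- function(mat, idx1, idx2, var_equal = TRUE) {
  n1 <- length(idx1); n2 <- length(idx2)
  if (n1 < 2L || n2 < 2L) .stopf("each compared group needs >= 2 samples")
  x1 <- mat[, idx1, drop = FALSE]; x2 <- mat[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2); ss2 <- rowSums((x2 - m2)^2)
  if (var_equal) {
    df <- n1 + n2 - 2
    se <- sqrt((ss1 + ss2) / df * (1 / n1 + 1 / n2))
  } else {
    v1 <- ss1 / (n1 - 1) / n1
    v2 <- ss2 / (n2 - 1) / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tstat <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  zero_se <- se == 0
  if (any(zero_se)) {
    eq <- zero_se & (m1 == m2)
    tstat[eq] <- 0; p[eq] <- 1
    p[zero_se & !eq] <- 0
  }
  list(t = tstat, p = p, mean1 = m1, mean2 = m2, df = df)
}

#' Benjamini-Hochberg adjustment of a p-value vector
#'
#' Step-up false discovery rate adjustment: on the sorted p-values,
#' q(i) = min over j >= i of m * p(j) / j, capped at 1 and restored to the
#' input order (delegates to [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values, pointwise >= `p`, all in \[0, 1\].
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) .stopf("p must be numeric")
  if (any(!is.na(p) & (p < 0 | p > 1)))
    .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-gene difference of group mean intensities
#'
#' Log fold change on the log2 scale: `mean(group to) - mean(group from)`.
#' For the 5-Aza demethylation screen the same operation is applied to a
#' control/treated two-group design.
#'
#' @param mat genes x samples numeric matrix (log2 intensities).
#' @param groups per-sample group labels (factor or character).
#' @param from,to names of the baseline and comparison group.
#' @return named numeric vector of differences (one per gene).
#' @export
log_fold_change <- function(mat, groups, from, to) {
  mat <- .as_expr_matrix(mat)
  groups <- as.character(groups)
  i1 <- which(groups == from); i2 <- which(groups == to)
  if (length(i1) == 0L) .stopf("group '%s' is empty", from)
  if (length(i2) == 0L) .stopf("group '%s' is empty", to)
  rowMeans(mat[, i2, drop = FALSE]) - rowMeans(mat[, i1, drop = FALSE])
}

.as_expr_matrix <- function(mat) {
  if (is.data.frame(mat)) mat <- as.matrix(mat)
  if (!is.matrix(mat) || !is.numeric(mat)) .stopf("mat must be a numeric matrix")
  if (anyNA(mat) || any(!is.finite(mat))) .stopf("mat must be finite with no missing values")
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("gene_%04d", seq_len(nrow(mat)))
  mat
}

# the three canonical stage comparisons in (baseline, lesion) order
.stage_comparisons <- function(levels) {
  if (length(levels) != 3L)
    .stopf("expected exactly 3 stages, got: %s", paste(levels, collapse = ", "))
  list(n_ad  = c(levels[1L], levels[2L]),
       n_crc = c(levels[1L], levels[3L]),
       ad_crc = c(levels[2L], levels[3L]))
}

#' Pairwise group t-tests with per-comparison BH correction
#'
#' Two-sided pooled-variance t-tests per gene for each of the three stage
#' comparisons (normal vs adenoma, normal vs carcinoma, adenoma vs
#' carcinoma), with Benjamini-Hochberg adjustment applied across genes
#' separately within each comparison.
#'
#' @inheritParams log_fold_change
#' @param stages per-sample stage labels with three levels in stage order.
#' @param var_equal pooled-variance (Student) t when `TRUE` (default),
#'   Welch when `FALSE`.
#' @return data.frame with columns `gene`, and per comparison `p_*` and
#'   BH-adjusted `q_*` (`n_ad`, `n_crc`, `ad_crc` suffixes). A comparison
#'   whose groups have fewer than 2 samples is reported as `NA` with a
#'   message; the others are unaffected.
#' @export
pairwise_group_tests <- function(mat, stages, var_equal = TRUE) {
  mat <- .as_expr_matrix(mat)
  sf <- .stage_factor(stages)
  if (length(sf) != ncol(mat)) .stopf("one stage label per sample required")
  cmps <- .stage_comparisons(levels(sf))
  out <- data.frame(gene = rownames(mat), stringsAsFactors = FALSE)
  for (nm in names(cmps)) {
    i1 <- which(sf == cmps[[nm]][1L]); i2 <- which(sf == cmps[[nm]][2L])
    if (length(i1) < 2L || length(i2) < 2L) {
      message(sprintf("comparison %s not computable (group with < 2 samples)", nm))
      out[[paste0("p_", nm)]] <- NA_real_
      out[[paste0("q_", nm)]] <- NA_real_
      next
    }
    tt <- .row_t_test(mat, i1, i2, var_equal = var_equal)
    out[[paste0("p_", nm)]] <- tt$p
    out[[paste0("q_", nm)]] <- bh_adjust(tt$p)
  }
  out
}

#' Full trend analysis of a staged expression matrix
#'
#' Computes, per gene: Kendall tau-b against the stage order, pairwise
#' pooled-variance t-tests with BH correction, log2 fold changes for each
#' comparison, the selection flag of [select_markers()], and the Venn
#' category of [venn_categorize()].
#'
#' @inheritParams pairwise_group_tests
#' @param tau_min minimum |tau| for a gradual trend (default 0.5). Note the
#'   source selection interval is printed as `-0.5 <= tau <= 0.5`, which read
#'   literally keeps non-trending genes; this implementation uses the
#'   `|tau| >= tau_min` reading and exposes the threshold.
#' @param alpha significance level on BH-adjusted p-values (default 0.05).
#' @param logfc_min minimum |log2 fold change| (default 1).
#' @param var_equal pooled-variance t when `TRUE`, Welch when `FALSE`.
#' @return a `trend_result` data.frame with columns `gene`, `tau`,
#'   `degenerate`, `p_*`, `q_*`, `logfc_*` for the three comparisons,
#'   `direction` ("up"/"down"), `selected`, `venn`.
#' @export
trend_select <- function(mat, stages, tau_min = 0.5, alpha = 0.05,
                         logfc_min = 1, var_equal = TRUE) {
  mat <- .as_expr_matrix(mat)
  sf <- .stage_factor(stages)
  kt <- .row_kendall_tau(mat, sf)
  res <- pairwise_group_tests(mat, sf, var_equal = var_equal)
  res$tau <- kt$tau
  res$degenerate <- kt$degenerate
  cmps <- .stage_comparisons(levels(sf))
  for (nm in names(cmps))
    res[[paste0("logfc_", nm)]] <-
      log_fold_change(mat, sf, cmps[[nm]][1L], cmps[[nm]][2L])
  res$direction <- ifelse(res$tau >= 0, "up", "down")
  res <- select_markers(res, tau_min = tau_min, alpha = alpha,
                        logfc_min = logfc_min)
  res <- venn_categorize(res, alpha = alpha)
  class(res) <- c("trend_result", class(res))
  res
}

#' Apply the marker selection rule to a trend result
#'
#' A gene is selected iff `|tau| >= tau_min`, its BH-adjusted p is below
#' `alpha` in at least one normal-vs-lesion comparison, and `|logfc|`
#' exceeds `logfc_min` in that same comparison. Direction is the sign of
#' tau.
#'
#' @param result data.frame from [trend_select()] (or with the same
#'   `tau`, `q_n_ad`, `q_n_crc`, `logfc_n_ad`, `logfc_n_crc` columns).
#' @inheritParams trend_select
#' @return `result` with updated `direction` and logical `selected` columns.
#' @export
select_markers <- function(result, tau_min = 0.5, alpha = 0.05,
                           logfc_min = 1) {
  for (th in c(tau_min, alpha, logfc_min))
    if (!is.numeric(th) || length(th) != 1L || is.na(th) || th <= 0)
      .stopf("thresholds must be positive scalars")
  need <- c("tau", "q_n_ad", "q_n_crc", "logfc_n_ad", "logfc_n_crc")
  if (!all(need %in% names(result)))
    .stopf("result lacks required columns: %s",
           paste(setdiff(need, names(result)), collapse = ", "))
  hit_ad  <- !is.na(result$q_n_ad)  & result$q_n_ad  < alpha &
    abs(result$logfc_n_ad)  > logfc_min
  hit_crc <- !is.na(result$q_n_crc) & result$q_n_crc < alpha &
    abs(result$logfc_n_crc) > logfc_min
  result$direction <- ifelse(result$tau >= 0, "up", "down")
  result$selected <- abs(result$tau) >= tau_min & (hit_ad | hit_crc)
  result
}

#' Venn category of the two normal-vs-lesion comparisons
#'
#' Classifies each gene by the significance pattern of the normal-vs-adenoma
#' and normal-vs-carcinoma comparisons (BH-adjusted p below `alpha`):
#' `"both"`, `"AD_only"`, `"CRC_only"`, `"neither"`, or `"not_evaluable"`
#' when either adjusted p is missing.
#'
#' @inheritParams select_markers
#' @return `result` with a `venn` character column added.
#' @export
venn_categorize <- function(result, alpha = 0.05) {
  if (!all(c("q_n_ad", "q_n_crc") %in% names(result)))
    .stopf("result must contain q_n_ad and q_n_crc columns")
  sig_ad <- result$q_n_ad < alpha
  sig_crc <- result$q_n_crc < alpha
  venn <- ifelse(is.na(sig_ad) | is.na(sig_crc), "not_evaluable",
          ifelse(sig_ad & sig_crc, "both",
          ifelse(sig_ad, "AD_only",
          ifelse(sig_crc, "CRC_only", "neither"))))
  result$venn <- venn
  result
}

#' Two-condition demethylation (5-Aza) re-expression screen
#'
#' Special case of the differential-expression machinery for a
#' control/treated design: per-gene log2 fold change treated minus control,
#' a pooled-variance t-test when both groups have at least two samples, and
#' a re-expression flag `logfc > logfc_min` (genes re-expressed after
#' demethylating treatment are candidate methylation-silenced genes).
#'
#' @inheritParams log_fold_change
#' @param groups per-sample labels with exactly two distinct values.
#' @param control,treated group names; default the first/second distinct
#'   label in `groups`.
#' @param logfc_min re-expression threshold on the log2 scale (default 1).
#' @return data.frame with `gene`, `logfc`, `p` (NA when a group has < 2
#'   samples), and logical `reexpressed`.
#' @export
demethylation_screen <- function(mat, groups, control = NULL, treated = NULL,
                                 logfc_min = 1) {
  mat <- .as_expr_matrix(mat)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) .stopf("expected exactly two groups")
  if (is.null(control)) control <- lv[1L]
  if (is.null(treated)) treated <- lv[2L]
  lfc <- log_fold_change(mat, groups, from = control, to = treated)
  i1 <- which(groups == control); i2 <- which(groups == treated)
  p <- if (length(i1) >= 2L && length(i2) >= 2L)
    .row_t_test(mat, i1, i2)$p else rep(NA_real_, nrow(mat))
  data.frame(gene = rownames(mat), logfc = unname(lfc), p = unname(p),
             reexpressed = unname(lfc) > logfc_min,
             stringsAsFactors = FALSE)
}
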