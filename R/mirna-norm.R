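# miRNA qPCR Ct normalisation: inversion to an expression-like scale,
# interplate calibration, reference-miRNA normalisation, group comparison,
# and ranking of differential miRNAs by predicted targets in a gene set.

#' Invert raw Ct values to an expression-like scale
#'
#' Subtracts the raw Ct from the maximal qPCR cycle number, so that higher
#' values mean higher abundance. Missing values (undetected wells) stay
#' missing.
#'
#' @param raw_ct numeric vector of raw Ct values (NA allowed).
#' @param max_cycle maximal cycle number (default 45).
#' @return `max_cycle - raw_ct`.
#' @examples
#' invert_ct(30)  # 15
#' @export
invert_ct <- function(raw_ct, max_cycle = 45) {
  if (!is.numeric(raw_ct)) .stopf("raw_ct must be numeric")
  ok <- !is.na(raw_ct)
  if (any(raw_ct[ok] > max_cycle))
    .stopf("raw Ct above the maximal cycle number (%s)", max_cycle)
  if (any(raw_ct[ok] <= 0))
    .stopf("raw Ct must be positive")
  max_cycle - raw_ct
}

.check_plate_df <- function(plates, need = c("mirna", "sample", "plate",
                                             "ct", "is_calibrator")) {
  if (!is.data.frame(plates) || !all(need %in% names(plates)))
    .stopf("plate table must contain columns: %s", paste(need, collapse = ", "))
  plates
}

#' Remove plate-to-plate offsets with interplate calibrators
#'
#' Every plate must carry calibrator wells (`is_calibrator == TRUE`). The
#' per-plate calibrator mean is centred on the across-plate calibrator
#' mean, and each plate's deviation is subtracted from all wells of that
#' plate. Values are expected on the inverted (expression-like) scale; the
#' operation is offset-based so it works identically on raw Ct.
#'
#' @param plates data.frame with columns `mirna`, `sample`, `plate`, `ct`
#'   (or `value`), `is_calibrator`.
#' @param value_col column to calibrate (default `"value"` if present,
#'   else `"ct"`).
#' @return `plates` with the calibrated values in `value_col` and the
#'   applied per-plate deviations in attribute `plate_deviation`.
#' @export
calibrate_plates <- function(plates, value_col = NULL) {
  plates <- .check_plate_df(plates, c("mirna", "plate", "is_calibrator"))
  if (is.null(value_col)) value_col <- if ("value" %in% names(plates)) "value" else "ct"
  if (!value_col %in% names(plates)) .stopf("column '%s' not found", value_col)
  v <- plates[[value_col]]
  cal <- plates$is_calibrator & !is.na(v)
  plate_ids <- unique(plates$plate)
  no_cal <- setdiff(plate_ids, unique(plates$plate[cal]))
  if (length(no_cal))
    .stopf("plate(s) without calibrator measurement: %s",
           paste(no_cal, collapse = ", "))
  cal_mean <- tapply(v[cal], plates$plate[cal], mean)
  dev <- cal_mean - mean(cal_mean)
  plates[[value_col]] <- as.vector(v - dev[as.character(plates$plate)])
  attr(plates, "plate_deviation") <- dev
  plates
}

#' Normalise to a reference miRNA per sample
#'
#' Subtracts, per sample, the sample's reference-miRNA value (on the
#' inverted scale), the housekeeping-gene step of the normalisation.
#' Samples without a reference measurement are flagged and their values set
#' to NA so they drop out of comparisons.
#'
#' @inheritParams calibrate_plates
#' @param reference reference miRNA id (default `"hsa-miR-423-5p"`).
#' @return `plates` with normalised `value_col` and attribute
#'   `missing_reference_samples`.
#' @export
normalize_reference <- function(plates, reference = "hsa-miR-423-5p",
                                value_col = NULL) {
  plates <- .check_plate_df(plates, c("mirna", "sample", "is_calibrator"))
  if (is.null(value_col)) value_col <- if ("value" %in% names(plates)) "value" else "ct"
  if (!value_col %in% names(plates)) .stopf("column '%s' not found", value_col)
  v <- plates[[value_col]]
  is_ref <- !plates$is_calibrator & plates$mirna == reference & !is.na(v)
  if (!any(is_ref)) .stopf("reference miRNA '%s' not measured", reference)
  ref <- tapply(v[is_ref], plates$sample[is_ref], mean)
  samples <- unique(plates$sample[!plates$is_calibrator])
  missing_ref <- setdiff(samples, names(ref))
  if (length(missing_ref))
    .warnf("sample(s) without reference measurement flagged: %s",
           paste(missing_ref, collapse = ", "))
  idx <- match(as.character(plates$sample), names(ref))
  plates[[value_col]] <- as.vector(v - ref[idx])
  plates[[value_col]][plates$is_calibrator] <- NA_real_
  attr(plates, "missing_reference_samples") <- missing_ref
  plates
}

#' Full Ct normalisation pipeline
#'
#' Inversion to the expression-like scale (`max_cycle - Ct`), interplate
#' calibration, then reference-miRNA normalisation, in that order.
#'
#' @inheritParams calibrate_plates
#' @inheritParams normalize_reference
#' @param max_cycle maximal qPCR cycle number (default 45).
#' @return `plates` with a `value` column holding the final normalised
#'   values (NA for calibrator wells and samples lacking the reference).
#' @export
normalize_ct <- function(plates, reference = "hsa-miR-423-5p",
                         max_cycle = 45) {
  plates <- .check_plate_df(plates)
  plates$value <- invert_ct(plates$ct, max_cycle)
  plates <- calibrate_plates(plates, value_col = "value")
  normalize_reference(plates, reference = reference, value_col = "value")
}

#' Compare normalised miRNA values between groups
#'
#' Pooled-variance t-tests of each lesion group against the reference
#' (first) group per miRNA, with BH adjustment across miRNAs.
#'
#' @param plates normalised plate data.frame (from [normalize_ct()]) with
#'   columns `mirna`, `sample`, `group`, `value`, `is_calibrator`.
#' @param alpha significance level (default 0.05).
#' @param adjust flag significance on BH-adjusted p (default TRUE).
#' @return data.frame per miRNA and comparison: group means, difference,
#'   `p`, `q`, `direction` ("up"/"down" in the lesion), `significant`.
#' @export
compare_mirna_groups <- function(plates, alpha = 0.05, adjust = TRUE) {
  plates <- .check_plate_df(plates, c("mirna", "sample", "group", "value",
                                      "is_calibrator"))
  df <- plates[!plates$is_calibrator & !is.na(plates$value), , drop = FALSE]
  gf <- .stage_factor(df$group, levels = c("NAT", "AD", "CRC"))
  lv <- levels(gf)
  if (length(lv) < 2L) .stopf("need at least two groups")
  mirnas <- sort(unique(df$mirna))
  out <- list()
  for (g in lv[-1L]) {
    p <- m1 <- m2 <- rep(NA_real_, length(mirnas))
    for (i in seq_along(mirnas)) {
      x1 <- df$value[df$mirna == mirnas[i] & gf == lv[1L]]
      x2 <- df$value[df$mirna == mirnas[i] & gf == g]
      m1[i] <- mean(x1); m2[i] <- mean(x2)
      if (length(x1) >= 2L && length(x2) >= 2L)
        p[i] <- .row_t_test(rbind(c(x1, x2)), seq_along(x1),
                            length(x1) + seq_along(x2))$p
    }
    q <- bh_adjust(p)
    sig <- (if (adjust) q else p) < alpha
    out[[g]] <- data.frame(mirna = mirnas, comparison = paste0(lv[1L], "_vs_", g),
                           mean_ref = m1, mean_lesion = m2, diff = m2 - m1,
                           p = p, q = q,
                           direction = ifelse(m2 >= m1, "up", "down"),
                           significant = !is.na(sig) & sig,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank miRNAs by the number of selected genes they target
#'
#' Intersects each miRNA's predicted target genes (user-supplied prediction
#' table) with a gene set of interest and orders miRNAs by intersection
#' size (descending), ties broken by id (ascending).
#'
#' @param mirnas character vector of miRNA ids to rank (e.g. the
#'   differential ones); `NULL` ranks every miRNA in the table.
#' @param targets data.frame with columns `mirna` and `gene` (one predicted
#'   target pair per row).
#' @param gene_set non-empty character vector of genes of interest.
#' @return data.frame with `mirna`, `n_targets`, `targets`
#'   (comma-separated sorted gene list), ordered by count then id.
#' @export
rank_mirnas_by_targets <- function(mirnas = NULL, targets, gene_set) {
  if (!is.data.frame(targets) || !all(c("mirna", "gene") %in% names(targets))) {
    .warnf("empty or invalid prediction table; returning empty ranking")
    return(data.frame(mirna = character(0), n_targets = integer(0),
                      targets = character(0)))
  }
  if (length(gene_set) == 0L) .stopf("gene_set must be non-empty")
  if (nrow(targets) == 0L) {
    .warnf("empty prediction table; returning empty ranking")
    return(data.frame(mirna = character(0), n_targets = integer(0),
                      targets = character(0)))
  }
  if (is.null(mirnas)) mirnas <- unique(targets$mirna)
  hits <- lapply(mirnas, function(m)
    sort(intersect(unique(targets$gene[targets$mirna == m]), gene_set)))
  out <- data.frame(mirna = mirnas,
                    n_targets = vapply(hits, length, integer(1)),
                    targets = vapply(hits, paste, character(1), collapse = ","),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_targets, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}
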