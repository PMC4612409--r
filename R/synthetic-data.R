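# Synthetic-data generators with planted ground truth: staged expression
# matrices, bisulfite amplicon reads with a 454-style error model, miRNA
# qPCR Ct plates, and IHC Q-score core tables. All generators are
# deterministic given their seed and reproduce their parameters exactly at
# zero noise.

#' Generate a stage-labelled expression matrix with planted trends
#'
#' Emulates a normalised log2 microarray matrix over three ordered stages
#' (normal, adenoma, carcinoma). Planted trend genes have per-stage means
#' `baseline`, `baseline +/- step_effect`, `baseline +/- 2 * step_effect`
#' (sign by direction); null genes share one mean per gene. Gaussian noise
#' with standard deviation `noise_sd` is added throughout.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per stage (scalar or length 3).
#' @param n_trend_up,n_trend_down numbers of planted up/down trend genes
#'   (`n_trend_up + n_trend_down <= n_genes`).
#' @param step_effect per-stage mean shift in log2 units (default 1.5).
#' @param noise_sd Gaussian noise SD in log2 units (default 1).
#' @param seed RNG seed.
#' @param baseline_range range of per-gene baseline means (log2 scale).
#' @param context tissue context label attached to every sample
#'   ("biopsy", "LCM_epithelium" or "LCM_stroma").
#' @return list with `matrix` (genes x samples), `samples` (data.frame:
#'   sample, stage, context) and `truth` (list: `trend_genes` data.frame of
#'   gene + direction, `group_assignments`).
#' @export
gen_staged_expression <- function(n_genes, n_per_group, n_trend_up = 0,
                                  n_trend_down = 0, step_effect = 1.5,
                                  noise_sd = 1, seed = 1,
                                  baseline_range = c(4, 10),
                                  context = "biopsy") {
  n_genes <- .check_count(n_genes, "n_genes")
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 3L)
  if (length(n_per_group) != 3L) .stopf("n_per_group must have length 1 or 3")
  n_per_group <- vapply(n_per_group, .check_count, integer(1),
                        what = "n_per_group")
  n_trend_up <- .check_count(n_trend_up, "n_trend_up", min = 0L)
  n_trend_down <- .check_count(n_trend_down, "n_trend_down", min = 0L)
  if (n_trend_up + n_trend_down > n_genes)
    .stopf("n_trend_up + n_trend_down must not exceed n_genes")
  if (!is.numeric(noise_sd) || noise_sd < 0) .stopf("noise_sd must be >= 0")
  stages <- c("normal", "adenoma", "CRC")
  .with_seed(seed, {
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    planted <- sample(n_genes, n_trend_up + n_trend_down)
    dir <- integer(n_genes)
    dir[planted[seq_len(n_trend_up)]] <- 1L
    if (n_trend_down > 0)
      dir[planted[n_trend_up + seq_len(n_trend_down)]] <- -1L
    baseline <- stats::runif(n_genes, baseline_range[1L], baseline_range[2L])
    stage_vec <- rep(stages, times = n_per_group)
    sample_ids <- unlist(lapply(seq_along(stages), function(k)
      sprintf("%s_%02d", stages[k], seq_len(n_per_group[k]))))
    code <- rep(0:2, times = n_per_group)
    mu <- outer(dir * step_effect, code) + baseline
    noise <- matrix(stats::rnorm(n_genes * length(code), sd = noise_sd),
                    nrow = n_genes)
    mat <- mu + noise
    dimnames(mat) <- list(genes, sample_ids)
    truth <- list(
      trend_genes = data.frame(
        gene = genes[dir != 0],
        direction = ifelse(dir[dir != 0] > 0, "up", "down"),
        stringsAsFactors = FALSE),
      group_assignments = stats::setNames(stage_vec, sample_ids))
    list(matrix = mat,
         samples = data.frame(sample = sample_ids,
                              stage = factor(stage_vec, levels = stages),
                              context = context, stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Simulate bisulfite-converted amplicon reads with a 454-style error model
#'
#' Each read is the full-length plus-strand template after bisulfite
#' conversion: a CpG cytosine stays `C` with its site's methylation
#' probability (else reads `T`); every other cytosine converts to `T` with
#' probability `conversion_efficiency`. Sequencing errors are then applied:
#' substitutions at `sub_rate` per base, and indels at `indel_rate` per
#' base, multiplied by `homopolymer_multiplier` inside runs of three or
#' more identical bases (insertions duplicate the current base and
#' deletions drop it, mimicking homopolymer over/undercall).
#'
#' @param template an [amplicon_template()].
#' @param methylation per-CpG methylation probabilities, one per CpG site of
#'   the template.
#' @param n_reads number of reads.
#' @param conversion_efficiency probability a non-CpG cytosine converts.
#' @param sub_rate,indel_rate per-base error probabilities.
#' @param homopolymer_multiplier indel rate multiplier (>= 1) inside
#'   homopolymer runs (default 3).
#' @param seed RNG seed.
#' @return list with `reads` (named character vector) and `truth` (list:
#'   `site_states` reads x sites logical matrix of drawn methylation
#'   states, `site_c_counts` per-site methylated-read counts,
#'   `methylation` the input probabilities).
#' @export
gen_bisulfite_reads <- function(template, methylation, n_reads,
                                conversion_efficiency = 1, sub_rate = 0,
                                indel_rate = 0, homopolymer_multiplier = 3,
                                seed = 1) {
  if (!inherits(template, "amplicon_template"))
    .stopf("template must be an amplicon_template")
  n_sites <- length(template$cpg_pos)
  if (length(methylation) != n_sites)
    .stopf("methylation vector length (%d) must equal the number of CpG sites (%d)",
           length(methylation), n_sites)
  .check_prob(methylation, "methylation")
  .check_prob(conversion_efficiency, "conversion_efficiency")
  .check_prob(sub_rate, "sub_rate")
  .check_prob(indel_rate, "indel_rate")
  if (!is.numeric(homopolymer_multiplier) || homopolymer_multiplier < 1)
    .stopf("homopolymer_multiplier must be >= 1")
  n_reads <- .check_count(n_reads, "n_reads")
  ch <- strsplit(template$seq, "", fixed = TRUE)[[1L]]
  L <- length(ch)
  is_cpg_c <- rep(FALSE, L); is_cpg_c[template$cpg_pos] <- TRUE
  other_c <- which(ch == "C" & !is_cpg_c)
  bases <- c("A", "C", "G", "T")
  .with_seed(seed, {
    site_states <- matrix(FALSE, nrow = n_reads, ncol = n_sites)
    reads <- character(n_reads)
    for (r in seq_len(n_reads)) {
      rd <- ch
      if (n_sites > 0) {
        meth <- stats::runif(n_sites) < methylation
        site_states[r, ] <- meth
        rd[template$cpg_pos[!meth]] <- "T"
      }
      if (length(other_c))
        rd[other_c[stats::runif(length(other_c)) < conversion_efficiency]] <- "T"
      if (sub_rate > 0) {
        hit <- which(stats::runif(length(rd)) < sub_rate)
        if (length(hit))
          rd[hit] <- vapply(rd[hit], function(b)
            sample(setdiff(bases, b), 1L), character(1))
      }
      if (indel_rate > 0) {
        runs <- rle(rd)
        in_hp <- rep(runs$lengths >= 3L, runs$lengths)
        rate <- pmin(1, indel_rate * ifelse(in_hp, homopolymer_multiplier, 1))
        hit <- stats::runif(length(rd)) < rate
        type_ins <- stats::runif(length(rd)) < 0.5
        counts <- rep(1L, length(rd))
        counts[hit & type_ins] <- 2L   # duplicate the base
        counts[hit & !type_ins] <- 0L  # drop the base
        rd <- rep(rd, counts)
      }
      reads[r] <- paste(rd, collapse = "")
    }
    names(reads) <- sprintf("read_%04d", seq_len(n_reads))
    list(reads = reads,
         truth = list(site_states = site_states,
                      site_c_counts = if (n_sites > 0) colSums(site_states)
                                      else integer(0),
                      methylation = methylation))
  })
}

#' Generate miRNA qPCR Ct plates with planted group shifts
#'
#' Raw Ct = per-miRNA base + plate offset + planted group shift + Gaussian
#' noise. miRNAs are split across plates; every plate carries an interplate
#' calibrator well (base Ct 20) with the same plate offset. The reference
#' miRNA is always present, on the first plate, and must not carry a
#' planted shift.
#'
#' @param n_mirnas total number of miRNAs (including the reference).
#' @param groups named integer vector of samples per group, default
#'   `c(NAT = 3, AD = 3, CRC = 3)`.
#' @param plate_offsets numeric vector of per-plate Ct offsets (length =
#'   number of plates).
#' @param planted_shifts optional data.frame with columns `mirna`, `group`,
#'   `shift` (Ct units; negative = higher abundance).
#' @param noise_sd Gaussian Ct noise SD (default 0).
#' @param reference reference miRNA id (default `"hsa-miR-423-5p"`).
#' @param seed RNG seed.
#' @return list with `plates` (data.frame: mirna, sample, group, plate, ct,
#'   is_calibrator) and `truth` (differential_mirnas, plate_offsets,
#'   group_assignments).
#' @export
gen_ct_plates <- function(n_mirnas, groups = c(NAT = 3, AD = 3, CRC = 3),
                          plate_offsets = c(0, 0), planted_shifts = NULL,
                          noise_sd = 0, reference = "hsa-miR-423-5p",
                          seed = 1) {
  n_mirnas <- .check_count(n_mirnas, "n_mirnas", min = 2L)
  if (is.null(names(groups)) || any(groups < 1))
    .stopf("groups must be a named vector of positive counts")
  if (!is.null(planted_shifts)) {
    if (!is.data.frame(planted_shifts) ||
        !all(c("mirna", "group", "shift") %in% names(planted_shifts)))
      .stopf("planted_shifts must have columns mirna, group, shift")
    if (reference %in% planted_shifts$mirna)
      .stopf("the reference miRNA ('%s') must not carry a planted shift",
             reference)
    if (!all(planted_shifts$group %in% names(groups)))
      .stopf("planted_shifts refer to unknown group(s)")
  }
  mirnas <- c(reference, sprintf("mir_%03d", seq_len(n_mirnas - 1L)))
  n_plates <- length(plate_offsets)
  plate_of <- rep(seq_len(n_plates), length.out = n_mirnas)
  names(plate_of) <- mirnas
  sample_ids <- unlist(lapply(names(groups), function(g)
    sprintf("%s_%02d", g, seq_len(groups[[g]]))))
  group_of <- rep(names(groups), times = groups)
  names(group_of) <- sample_ids
  .with_seed(seed, {
    base_ct <- stats::setNames(stats::runif(n_mirnas, 22, 34), mirnas)
    wells <- expand.grid(mirna = mirnas, sample = sample_ids,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    wells$group <- group_of[wells$sample]
    wells$plate <- unname(plate_of[wells$mirna])
    shift <- numeric(nrow(wells))
    if (!is.null(planted_shifts)) {
      for (k in seq_len(nrow(planted_shifts))) {
        hit <- wells$mirna == planted_shifts$mirna[k] &
          wells$group == planted_shifts$group[k]
        shift[hit] <- shift[hit] + planted_shifts$shift[k]
      }
    }
    wells$ct <- base_ct[wells$mirna] + plate_offsets[wells$plate] + shift +
      stats::rnorm(nrow(wells), sd = noise_sd)
    wells$is_calibrator <- FALSE
    cal <- data.frame(mirna = "interplate_calibrator",
                      sample = sprintf("calibrator_plate_%d", seq_len(n_plates)),
                      group = NA_character_, plate = seq_len(n_plates),
                      ct = 20 + plate_offsets +
                        stats::rnorm(n_plates, sd = noise_sd),
                      is_calibrator = TRUE, stringsAsFactors = FALSE)
    plates <- rbind(wells, cal)
    rownames(plates) <- NULL
    list(plates = plates,
         truth = list(differential_mirnas = planted_shifts,
                      plate_offsets = plate_offsets,
                      group_assignments = group_of))
  })
}

#' Generate IHC Q-score core records around requested group means
#'
#' Per core, a target Q-score is drawn as `group mean + Gaussian noise`,
#' clipped to \[0, 300\], then decomposed into a single intensity grade
#' (`ceiling(target / 100)`, at most 3) and a percent-positive value so
#' that `percent * intensity` reproduces the target.
#'
#' @param group_means named numeric vector of per-group target Q-score
#'   means, each in \[0, 300\] (e.g. `c(NAT = 220, AD = 120, CRC = 40)`).
#' @param n_cores cores per group.
#' @param noise_sd Gaussian noise SD on the Q-score scale (default 0).
#' @param seed RNG seed.
#' @return data.frame with `core`, `group`, `percent_positive`,
#'   `intensity`, `qscore`.
#' @export
gen_qscore_cores <- function(group_means, n_cores = 10, noise_sd = 0,
                             seed = 1) {
  if (!is.numeric(group_means) || is.null(names(group_means)))
    .stopf("group_means must be a named numeric vector")
  if (any(group_means < 0 | group_means > 300))
    .stopf("group means must lie in [0, 300]")
  n_cores <- .check_count(n_cores, "n_cores")
  .with_seed(seed, {
    recs <- lapply(names(group_means), function(g) {
      target <- group_means[[g]] + stats::rnorm(n_cores, sd = noise_sd)
      target <- pmin(300, pmax(0, target))
      intensity <- pmin(3L, as.integer(ceiling(target / 100)))
      pct <- ifelse(intensity > 0, target / intensity, 0)
      data.frame(core = sprintf("%s_core_%02d", g, seq_len(n_cores)),
                 group = g, percent_positive = pct, intensity = intensity,
                 qscore = pct * intensity, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}

#' Construct a synthetic CpG-bearing amplicon
#'
#' Builds a random amplicon sequence with a requested number of CpG sites
#' (placed on an evenly spaced grid with CpG-free flanks), for exercising
#' the alignment and calling stages without external sequence data. The
#' non-CpG background is C-rich enough to make bisulfite conversion
#' consequential. Labelled synthetic; it stands in for a real promoter
#' amplicon.
#'
#' @param name template name.
#' @param length amplicon length in bases (default 80).
#' @param n_cpg number of CpG sites (default 3).
#' @param seed RNG seed.
#' @return an [amplicon_template()].
#' @export
synthetic_amplicon <- function(name = "synthetic_amplicon", length = 80,
                               n_cpg = 3, seed = 1) {
  length <- .check_count(length, "length", min = 20L)
  n_cpg <- .check_count(n_cpg, "n_cpg", min = 0L)
  .with_seed(seed, {
    repeat {
      ch <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                   prob = c(0.3, 0.25, 0.15, 0.3))
      # remove accidental CpGs, then plant the requested ones
      for (i in seq_len(length - 1L))
        if (ch[i] == "C" && ch[i + 1L] == "G") ch[i + 1L] <- "T"
      if (n_cpg > 0) {
        pos <- round(seq(10, length - 10, length.out = n_cpg))
        ch[pos] <- "C"; ch[pos + 1L] <- "G"
        # planting may have created adjacent CpGs; keep only planted ones
        ok <- TRUE
        for (i in seq_len(length - 1L))
          if (ch[i] == "C" && ch[i + 1L] == "G" && !(i %in% pos)) ok <- FALSE
        if (!ok) next
      }
      seq <- paste(ch, collapse = "")
      return(amplicon_template(name, seq))
    }
  })
}
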