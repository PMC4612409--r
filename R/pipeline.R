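# Configuration-driven orchestration of the full analysis: synthetic data
# generation, trend selection, CpG island prediction, bisulfite alignment
# and methylation calling/comparison/clustering, miRNA normalisation and
# target ranking, and IHC Q-score summaries. All randomness flows from one
# global seed through fixed per-stage offsets, and every artifact is a
# plain-text file, so a config + seed reproduces the bundle byte for byte.

.STAGES <- c("simulate", "trends", "islands", "methylation", "mirna", "qscore")

.stage_seed <- function(seed, offset) as.integer((seed + offset) %% 2147483647L)

#' Default pipeline configuration
#'
#' Returns the full configuration list with every stage enabled in
#' synthetic mode. Override any entry via [validate_config()] /
#' [run_pipeline()] (lists are merged recursively).
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "methmarker_out",
    stages = .STAGES,
    inputs = list(
      expression_matrix = NULL, expression_samples = NULL,
      promoters_fasta = NULL, templates_fasta = NULL,
      reads_manifest = NULL, ct_plates = NULL, targets = NULL,
      qscore_table = NULL),
    simulate = list(
      expression = list(n_genes = 500L, n_per_group = 10L,
                        n_trend_up = 15L, n_trend_down = 15L,
                        step_effect = 1.5, noise_sd = 1),
      amplicons = list(length = 80L, n_cpg = 3L),
      promoters = list(flank = 450L, core = 300L),
      reads = list(n_reads = 200L, n_per_group = 5L,
                   conversion_efficiency = 1, sub_rate = 0, indel_rate = 0,
                   homopolymer_multiplier = 3,
                   methylation = list(
                     hyper_assay = c(NAT = 0.05, AD = 0.35, CRC = 0.60),
                     hypo_assay = c(NAT = 0.90, AD = 0.80, CRC = 0.70))),
      ct = list(n_mirnas = 40L, n_per_group = 3L,
                plate_offsets = c(0, 1.5), noise_sd = 0.25,
                shifts = list(
                  list(mirna = "mir_001", group = "AD", shift = -2),
                  list(mirna = "mir_001", group = "CRC", shift = -3),
                  list(mirna = "mir_002", group = "CRC", shift = -2))),
      qscore = list(group_means = c(NAT = 220, AD = 120, CRC = 40),
                    n_cores = 10L, noise_sd = 15)),
    trends = list(tau_min = 0.5, alpha = 0.05, logfc_min = 1),
    islands = list(window = 100L, shift = 1L, min_len = 200L,
                   min_gc = 50, min_oe = 0.6),
    methylation = list(min_fraction = 0.8, alpha = 0.05,
                       scoring = list(match = 1, mismatch = -1,
                                      gap_open = -2, gap_extend = -1),
                       cluster_k = 2L),
    mirna = list(reference = "hsa-miR-423-5p", max_cycle = 45,
                 alpha = 0.05),
    qscore = list())
}

# recursive merge that treats unnamed lists (e.g. shift specs) atomically
.merge_config <- function(base, user) {
  if (!is.list(user)) return(user)
  if (!is.list(base) || is.null(names(user))) return(user)
  for (nm in names(user))
    base[[nm]] <- if (nm %in% names(base))
      .merge_config(base[[nm]], user[[nm]]) else user[[nm]]
  base
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a (possibly partial) configuration list,
#' merges it over [default_config()], and collects all validation errors
#' rather than failing on the first.
#'
#' @param config path to a YAML file, or a configuration list.
#' @return list with `config` (merged) and `errors` (character vector,
#'   empty when valid).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) .stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) .stopf("config must be a list or a YAML file path")
  errors <- character(0)
  unknown <- setdiff(names(config), names(default_config()))
  if (length(unknown))
    errors <- c(errors, sprintf("unknown config key(s): %s",
                                paste(unknown, collapse = ", ")))
  cfg <- if (length(config)) .merge_config(default_config(), config)
         else default_config()
  bad_stage <- setdiff(cfg$stages, .STAGES)
  if (length(bad_stage))
    errors <- c(errors, sprintf("unknown stage(s): %s",
                                paste(bad_stage, collapse = ", ")))
  chk_num <- function(x, nm, lo = -Inf, hi = Inf, lo_open = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        x < lo || x > hi || (lo_open && x <= lo))
      sprintf("%s must be a number in %s%s, %s]", nm,
              if (lo_open) "(" else "[", lo, hi)
    else character(0)
  }
  errors <- c(errors,
    chk_num(cfg$seed, "seed", 0, 2^31 - 1),
    chk_num(cfg$trends$tau_min, "trends$tau_min", 0, 1, lo_open = TRUE),
    chk_num(cfg$trends$alpha, "trends$alpha", 0, 1, lo_open = TRUE),
    chk_num(cfg$trends$logfc_min, "trends$logfc_min", 0, Inf, lo_open = TRUE),
    chk_num(cfg$methylation$min_fraction, "methylation$min_fraction", 0, 1,
            lo_open = TRUE),
    chk_num(cfg$methylation$alpha, "methylation$alpha", 0, 1, lo_open = TRUE),
    chk_num(cfg$mirna$alpha, "mirna$alpha", 0, 1, lo_open = TRUE),
    chk_num(cfg$mirna$max_cycle, "mirna$max_cycle", 1, Inf),
    chk_num(cfg$simulate$reads$sub_rate, "simulate$reads$sub_rate", 0, 1),
    chk_num(cfg$simulate$reads$indel_rate, "simulate$reads$indel_rate", 0, 1),
    chk_num(cfg$simulate$reads$conversion_efficiency,
            "simulate$reads$conversion_efficiency", 0, 1),
    chk_num(cfg$simulate$expression$noise_sd,
            "simulate$expression$noise_sd", 0, Inf))
  # enabled stages that skip simulation need their input files
  if (!"simulate" %in% cfg$stages) {
    need <- list(
      trends = c("expression_matrix", "expression_samples"),
      islands = "promoters_fasta",
      methylation = c("templates_fasta", "reads_manifest"),
      mirna = "ct_plates",
      qscore = "qscore_table")
    for (st in intersect(cfg$stages, names(need)))
      for (key in need[[st]]) {
        path <- cfg$inputs[[key]]
        if (is.null(path))
          errors <- c(errors,
                      sprintf("stage '%s' enabled without simulate: inputs$%s required",
                              st, key))
        else if (!file.exists(path))
          errors <- c(errors, sprintf("inputs$%s: file not found: %s", key, path))
      }
  }
  list(config = cfg, errors = errors)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order, writing per-stage
#' tab-separated tables (plus FASTA/BED where appropriate), a
#' machine-readable `summary.json`, and a `run_log.txt` recording the
#' package version, seed and parameters. Identical configuration and seed
#' produce byte-identical summaries.
#'
#' @param config YAML path or configuration list (see [default_config()]).
#' @param out_dir output directory; overrides `config$output_dir`.
#' @return (invisibly) the summary list, with attribute `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  vc <- validate_config(config)
  if (length(vc$errors))
    .stopf("invalid configuration:\n  - %s", paste(vc$errors, collapse = "\n  - "))
  cfg <- vc$config
  if (!is.null(out_dir)) cfg$output_dir <- out_dir
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  summary <- list(seed = seed, stages = as.list(cfg$stages))
  state <- new.env(parent = emptyenv())

  if ("simulate" %in% cfg$stages) .stage_simulate(cfg, seed, out, state, summary) -> summary
  if ("trends" %in% cfg$stages) .stage_trends(cfg, out, state, summary) -> summary
  if ("islands" %in% cfg$stages) .stage_islands(cfg, out, state, summary) -> summary
  if ("methylation" %in% cfg$stages) .stage_methylation(cfg, out, state, summary) -> summary
  if ("mirna" %in% cfg$stages) .stage_mirna(cfg, out, state, summary) -> summary
  if ("qscore" %in% cfg$stages) .stage_qscore(cfg, out, state, summary) -> summary

  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  log_lines <- c(
    sprintf("methmarker %s", as.character(utils::packageVersion("methmarker"))),
    sprintf("seed: %d", seed),
    sprintf("stages: %s", paste(cfg$stages, collapse = ", ")),
    "parameters:",
    strsplit(yaml::as.yaml(cfg), "\n")[[1L]])
  writeLines(log_lines, file.path(out, "run_log.txt"))
  attr(summary, "out_dir") <- out
  invisible(summary)
}

.stage_simulate <- function(cfg, seed, out, state, summary) {
  sim <- cfg$simulate
  expr <- do.call(gen_staged_expression,
                  c(sim$expression, list(seed = .stage_seed(seed, 101L))))
  write_expression_matrix(expr, file.path(out, "expression_matrix.tsv"),
                          file.path(out, "samples.tsv"))
  state$expr <- expr

  assays <- names(sim$reads$methylation)
  templates <- lapply(seq_along(assays), function(k)
    synthetic_amplicon(assays[k], length = sim$amplicons$length,
                       n_cpg = sim$amplicons$n_cpg,
                       seed = .stage_seed(seed, 200L + k)))
  names(templates) <- assays
  write_reads(stats::setNames(vapply(templates, `[[`, character(1), "seq"),
                              assays),
              file.path(out, "amplicons.fasta"))
  state$templates <- templates

  # promoter-scale sequences: AT-rich flanks around a GC/CpG-rich core
  promoters <- lapply(seq_along(assays), function(k)
    .with_seed(.stage_seed(seed, 300L + k), {
      flank1 <- paste(sample(c("A", "T"), sim$promoters$flank, TRUE), collapse = "")
      flank2 <- paste(sample(c("A", "T"), sim$promoters$flank, TRUE), collapse = "")
      core <- paste(sample(c("A", "C", "G", "T"), sim$promoters$core, TRUE,
                           prob = c(0.1, 0.4, 0.4, 0.1)), collapse = "")
      paste0(flank1, core, flank2)
    }))
  names(promoters) <- paste0(assays, "_promoter")
  write_reads(unlist(promoters), file.path(out, "promoters.fasta"))
  state$promoters <- promoters

  groups <- c("NAT", "AD", "CRC")
  n_pg <- sim$reads$n_per_group
  read_dir <- file.path(out, "reads")
  dir.create(read_dir, showWarnings = FALSE)
  state$read_sets <- list()
  state$read_groups <- character(0)
  meth_truth <- list()
  s_idx <- 0L
  for (g in groups) for (i in seq_len(n_pg)) {
    s_idx <- s_idx + 1L
    sample_id <- sprintf("%s_%02d", g, i)
    state$read_groups[sample_id] <- g
    for (k in seq_along(assays)) {
      a <- assays[k]
      p <- sim$reads$methylation[[a]][[g]]
      rs <- gen_bisulfite_reads(
        templates[[a]], rep(p, length(templates[[a]]$cpg_pos)),
        n_reads = sim$reads$n_reads,
        conversion_efficiency = sim$reads$conversion_efficiency,
        sub_rate = sim$reads$sub_rate, indel_rate = sim$reads$indel_rate,
        homopolymer_multiplier = sim$reads$homopolymer_multiplier,
        seed = .stage_seed(seed, 1000L + 37L * k + s_idx))
      state$read_sets[[a]][[sample_id]] <- rs$reads
      meth_truth[[a]][[sample_id]] <-
        100 * mean(rs$truth$site_c_counts / sim$reads$n_reads)
      write_reads(rs$reads,
                  file.path(read_dir, sprintf("%s_%s.fasta", a, sample_id)))
    }
  }
  state$meth_truth <- meth_truth

  shifts <- do.call(rbind, lapply(sim$ct$shifts, as.data.frame))
  ct <- gen_ct_plates(sim$ct$n_mirnas,
                      groups = stats::setNames(rep(sim$ct$n_per_group, 3),
                                               groups),
                      plate_offsets = sim$ct$plate_offsets,
                      planted_shifts = shifts,
                      noise_sd = sim$ct$noise_sd,
                      reference = cfg$mirna$reference,
                      seed = .stage_seed(seed, 400L))
  .write_tsv(ct$plates, file.path(out, "ct_plates.tsv"))
  state$ct <- ct

  cores <- gen_qscore_cores(unlist(sim$qscore$group_means),
                            n_cores = sim$qscore$n_cores,
                            noise_sd = sim$qscore$noise_sd,
                            seed = .stage_seed(seed, 500L))
  .write_tsv(cores, file.path(out, "qscore_cores.tsv"))
  state$cores <- cores

  # synthetic target-prediction table: planted miRNAs map to planted genes
  planted_mirnas <- unique(vapply(sim$ct$shifts, `[[`, character(1), "mirna"))
  planted_genes <- expr$truth$trend_genes$gene
  tgt <- list()
  for (j in seq_along(planted_mirnas)) {
    n_tg <- min(5L - (j - 1L) * 2L, length(planted_genes))
    if (n_tg > 0)
      tgt[[length(tgt) + 1L]] <-
        data.frame(mirna = planted_mirnas[j],
                   gene = planted_genes[seq_len(n_tg)],
                   source = "synthetic", stringsAsFactors = FALSE)
  }
  tgt[[length(tgt) + 1L]] <-
    data.frame(mirna = "mir_020", gene = "gene_absent",
               source = "synthetic", stringsAsFactors = FALSE)
  targets <- do.call(rbind, tgt)
  .write_tsv(targets, file.path(out, "targets.tsv"))
  state$targets <- targets

  truth <- list(
    trend_genes = expr$truth$trend_genes,
    methylation_percent = meth_truth,
    differential_mirnas = sim$ct$shifts,
    qscore_group_means = as.list(sim$qscore$group_means))
  jsonlite::write_json(truth, file.path(out, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  summary$truth <- truth
  summary
}

.stage_trends <- function(cfg, out, state, summary) {
  if (is.null(state$expr)) {
    io <- read_expression_matrix(cfg$inputs$expression_matrix,
                                 cfg$inputs$expression_samples)
    state$expr <- list(matrix = io$matrix,
                       samples = io$samples, truth = NULL)
  }
  res <- trend_select(state$expr$matrix, state$expr$samples$stage,
                      tau_min = cfg$trends$tau_min,
                      alpha = cfg$trends$alpha,
                      logfc_min = cfg$trends$logfc_min)
  .write_tsv(res, file.path(out, "trend_results.tsv"))
  sel <- res$gene[res$selected]
  state$selected_genes <- sel
  summary$trends <- list(
    n_genes = nrow(res), n_selected = length(sel),
    selected = as.list(sel),
    venn_counts = as.list(table(res$venn[res$selected])))
  summary
}

.stage_islands <- function(cfg, out, state, summary) {
  seqs <- if (!is.null(state$promoters)) {
    vapply(state$promoters, identity, character(1))
  } else {
    read_reads(cfg$inputs$promoters_fasta)
  }
  isl_summary <- list()
  all_rows <- list()
  for (nm in names(seqs)) {
    isl <- predict_islands(seqs[[nm]], window = cfg$islands$window,
                           shift = cfg$islands$shift,
                           min_len = cfg$islands$min_len,
                           min_gc = cfg$islands$min_gc,
                           min_oe = cfg$islands$min_oe)
    if (nrow(isl)) {
      write_islands_bed(isl, file.path(out, sprintf("islands_%s.bed", nm)),
                        name = nm)
      all_rows[[nm]] <- cbind(sequence = nm, isl)
    }
    isl_summary[[nm]] <- nrow(isl)
  }
  tab <- if (length(all_rows)) do.call(rbind, all_rows) else
    data.frame(sequence = character(0))
  rownames(tab) <- NULL
  .write_tsv(tab, file.path(out, "islands.tsv"))
  summary$islands <- isl_summary
  summary
}

.stage_methylation <- function(cfg, out, state, summary) {
  sc <- do.call(scoring_scheme, cfg$methylation$scoring)
  if (is.null(state$templates)) {
    seqs <- read_reads(cfg$inputs$templates_fasta)
    state$templates <- lapply(names(seqs), function(nm)
      amplicon_template(nm, seqs[[nm]]))
    names(state$templates) <- names(seqs)
    manifest <- .read_tsv(cfg$inputs$reads_manifest)
    state$read_sets <- list()
    state$read_groups <- character(0)
    for (r in seq_len(nrow(manifest))) {
      state$read_sets[[manifest$assay[r]]][[manifest$sample[r]]] <-
        read_reads(manifest$path[r])
      state$read_groups[manifest$sample[r]] <- manifest$group[r]
    }
  }
  sample_values <- list()
  call_rows <- list()
  filter_stats <- list()
  for (a in names(state$read_sets)) {
    for (s in names(state$read_sets[[a]])) {
      aln <- align_reads(state$read_sets[[a]][[s]], state$templates[[a]],
                         scoring = sc,
                         min_fraction = cfg$methylation$min_fraction)
      calls <- call_cpg_methylation(aln)
      sample_values[[s]][[a]] <- summarize_assay(calls)
      call_rows[[paste(a, s)]] <- cbind(sample = s, calls)
      cnt <- attr(aln, "counts")
      filter_stats[[a]] <- (filter_stats[[a]] %||% c(pass = 0, fail = 0)) + cnt
    }
  }
  calls_tab <- do.call(rbind, call_rows)
  rownames(calls_tab) <- NULL
  .write_tsv(calls_tab, file.path(out, "cpg_calls.tsv"))
  samples <- names(sample_values)
  mm <- methylation_matrix(
    lapply(sample_values, unlist),
    groups = unname(state$read_groups[samples]))
  mm_tab <- data.frame(assay = rownames(mm), mm, check.names = FALSE)
  .write_tsv(mm_tab, file.path(out, "methylation_matrix.tsv"))
  cmp <- compare_methylation_groups(mm, attr(mm, "groups"),
                                    alpha = cfg$methylation$alpha)
  .write_tsv(cmp, file.path(out, "methylation_comparisons.tsv"))
  cl <- if (nrow(mm) >= 2L)
    cluster_markers(mm, k = cfg$methylation$cluster_k) else NULL
  summary$methylation <- list(
    filter = lapply(filter_stats, as.list),
    classes = stats::setNames(
      lapply(seq_len(nrow(cmp)), function(i)
        list(AD = cmp$class_AD[i], CRC = cmp$class_CRC[i])),
      cmp$assay),
    cluster = if (!is.null(cl))
      list(row_order = as.list(cl$row_order),
           clusters = as.list(cl$clusters)) else NULL)
  summary
}

.stage_mirna <- function(cfg, out, state, summary) {
  plates <- if (!is.null(state$ct)) state$ct$plates else
    read_ct_plates(cfg$inputs$ct_plates)
  norm <- normalize_ct(plates, reference = cfg$mirna$reference,
                       max_cycle = cfg$mirna$max_cycle)
  .write_tsv(norm, file.path(out, "mirna_normalized.tsv"))
  cmp <- compare_mirna_groups(norm, alpha = cfg$mirna$alpha)
  .write_tsv(cmp, file.path(out, "mirna_comparisons.tsv"))
  diff_mirnas <- sort(unique(cmp$mirna[cmp$significant]))
  targets <- if (!is.null(state$targets)) state$targets else
    if (!is.null(cfg$inputs$targets)) read_targets_table(cfg$inputs$targets)
    else NULL
  ranking <- NULL
  if (!is.null(targets)) {
    gene_set <- state$selected_genes
    if (is.null(gene_set) || length(gene_set) == 0L)
      gene_set <- unique(targets$gene)
    ranking <- rank_mirnas_by_targets(diff_mirnas, targets, gene_set)
    .write_tsv(ranking, file.path(out, "mirna_target_ranking.tsv"))
  }
  summary$mirna <- list(
    differential = as.list(diff_mirnas),
    ranking = if (!is.null(ranking))
      stats::setNames(as.list(ranking$n_targets), ranking$mirna) else NULL)
  summary
}

.stage_qscore <- function(cfg, out, state, summary) {
  cores <- if (!is.null(state$cores)) state$cores else
    read_qscore_table(cfg$inputs$qscore_table)
  qs <- summarize_qscores(cores)
  .write_tsv(qs$summary, file.path(out, "qscore_summary.tsv"))
  summary$qscore <- list(
    trend = qs$trend,
    means = stats::setNames(as.list(qs$summary$mean), qs$summary$group),
    sds = stats::setNames(as.list(qs$summary$sd), qs$summary$group))
  summary
}
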