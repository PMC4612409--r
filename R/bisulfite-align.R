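# Bisulfite amplicon templates, converted references, affine-gap local
# alignment of reads against them, and the score-fraction read filter.

#' Bisulfite-convert a template sequence
#'
#' Models full bisulfite conversion of the plus strand: every cytosine reads
#' as thymine after conversion and PCR except a methylated CpG cytosine,
#' which stays cytosine. The forward converted reference therefore carries
#' `C -> T` at non-CpG positions and the wildcard `Y` (C or T) at CpG
#' positions. The reverse reference is the reverse complement treated
#' symmetrically: `G -> A` at non-CpG-derived positions and the wildcard `R`
#' (A or G) at positions mirroring a CpG cytosine.
#'
#' @param seq plus-strand DNA string.
#' @param cpg_pos 1-based positions of the C of each CpG; defaults to
#'   [list_cpg_sites()] of `seq`.
#' @return list with `forward` and `reverse` converted reference strings,
#'   both the same length as `seq`.
#' @examples
#' bisulfite_convert_template("CACGT")$forward  # "TAYGT"
#' @export
bisulfite_convert_template <- function(seq, cpg_pos = NULL) {
  s <- .check_dna(seq)
  if (is.null(cpg_pos)) cpg_pos <- list_cpg_sites(s)
  .check_cpg_pos(s, cpg_pos)
  L <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  fwd <- ch
  fwd[fwd == "C"] <- "T"
  fwd[cpg_pos] <- "Y"
  rc <- strsplit(.revcomp(s), "", fixed = TRUE)[[1L]]
  rev <- rc
  rev[rev == "G"] <- "A"
  if (length(cpg_pos)) rev[L + 1L - cpg_pos] <- "R"
  list(forward = paste(fwd, collapse = ""),
       reverse = paste(rev, collapse = ""))
}

.check_cpg_pos <- function(seq, cpg_pos) {
  if (length(cpg_pos) == 0L) return(invisible(TRUE))
  if (anyNA(cpg_pos) || any(cpg_pos < 1L) || any(cpg_pos >= nchar(seq)))
    .stopf("CpG positions out of range")
  if (is.unsorted(cpg_pos, strictly = TRUE))
    .stopf("CpG positions must be strictly increasing")
  bad <- substring(seq, cpg_pos, cpg_pos + 1L) != "CG"
  if (any(bad))
    .stopf("position(s) %s do not index a CG dinucleotide",
           paste(cpg_pos[bad], collapse = ", "))
  invisible(TRUE)
}

#' Construct an amplicon template
#'
#' Bundles a plus-strand amplicon sequence with its CpG site coordinates,
#' the forward/reverse bisulfite-converted references used for alignment,
#' and optional primer-region masks whose CpG sites are excluded from
#' methylation calling.
#'
#' @param name template name.
#' @param seq plus-strand DNA string.
#' @param cpg_pos 1-based CpG cytosine positions; autodetected when `NULL`.
#' @param primer_mask optional data.frame with 1-based closed `start`,`end`
#'   intervals to exclude from calling (typically the primer footprints).
#' @return object of class `amplicon_template`.
#' @export
amplicon_template <- function(name, seq, cpg_pos = NULL, primer_mask = NULL) {
  s <- .check_dna(seq)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    .stopf("name must be a non-empty string")
  if (is.null(cpg_pos)) cpg_pos <- list_cpg_sites(s)
  cpg_pos <- as.integer(cpg_pos)
  .check_cpg_pos(s, cpg_pos)
  if (!is.null(primer_mask)) {
    if (!is.data.frame(primer_mask) ||
        !all(c("start", "end") %in% names(primer_mask)))
      .stopf("primer_mask must be a data.frame with start and end columns")
    if (any(primer_mask$start < 1L) || any(primer_mask$end > nchar(s)) ||
        any(primer_mask$start > primer_mask$end))
      .stopf("primer_mask intervals out of range")
  }
  conv <- bisulfite_convert_template(s, cpg_pos)
  structure(list(name = name, seq = s, length = nchar(s),
                 cpg_pos = cpg_pos,
                 forward_ref = conv$forward, reverse_ref = conv$reverse,
                 primer_mask = primer_mask),
            class = "amplicon_template")
}

#' @export
print.amplicon_template <- function(x, ...) {
  cat(sprintf("amplicon_template '%s': %d bp, %d CpG site(s)%s\n",
              x$name, x$length, length(x$cpg_pos),
              if (is.null(x$primer_mask)) "" else
                sprintf(", %d masked interval(s)", nrow(x$primer_mask))))
  invisible(x)
}

# CpG sites retained for methylation calling (outside primer masks)
.callable_sites <- function(template) {
  sites <- template$cpg_pos
  pm <- template$primer_mask
  if (is.null(pm) || length(sites) == 0L) return(sites)
  masked <- rep(FALSE, length(sites))
  for (k in seq_len(nrow(pm)))
    masked <- masked | (sites >= pm$start[k] & sites <= pm$end[k])
  sites[!masked]
}

#' Alignment scoring scheme
#'
#' Match must be positive; mismatch, gap-open and gap-extend non-positive
#' with `gap_extend >= gap_open` (a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`). Reference wildcards `Y` (C/T) and `R`
#' (A/G) score as matches against either of their bases.
#'
#' @param match,mismatch,gap_open,gap_extend alignment scores.
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap_open = -2,
                           gap_extend = -1) {
  if (match <= 0) .stopf("match score must be positive")
  if (mismatch > 0 || gap_open > 0 || gap_extend > 0)
    .stopf("mismatch and gap scores must be <= 0")
  if (gap_extend < gap_open)
    .stopf("gap_extend must be >= gap_open")
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Maximum attainable alignment score of a read
#'
#' The score of a gapless full-length perfect match: `match * read_length`.
#' Score fractions are therefore read-length normalised.
#'
#' @param read_length read length in bases (>= 1).
#' @param scoring a [scoring_scheme()].
#' @return numeric score.
#' @export
max_attainable_score <- function(read_length, scoring = scoring_scheme()) {
  read_length <- .check_count(read_length, "read_length", min = 1L)
  scoring$match * read_length
}

#' Align one read against an amplicon template
#'
#' Best local alignment (Smith-Waterman with Gotoh's affine-gap three-state
#' recurrence) of the read against both the forward and the reverse
#' converted reference; the higher-scoring orientation is reported, ties
#' broken toward forward. Traceback is deterministic: diagonal preferred,
#' then up (gap in the reference), then left. Coordinates are 1-based on the
#' plus strand of the template.
#'
#' @param read read sequence (A/C/G/T/N).
#' @param template an [amplicon_template()].
#' @param scoring a [scoring_scheme()].
#' @param id read identifier.
#' @return object of class `bs_alignment`: a list with `read_id`,
#'   `template`, `orientation` ("forward"/"reverse"), `tmpl_start`,
#'   `tmpl_end` (plus-strand, 1-based closed), `score`, `max_score`,
#'   `score_fraction`, `unalignable`, and `cpg_calls` (per callable CpG
#'   site: "M" methylated, "U" unmethylated, "O" other base or gap, NA not
#'   covered).
#' @export
align_read <- function(read, template, scoring = scoring_scheme(),
                       id = "read") {
  r <- .check_dna(read, "read")
  if (nchar(r) == 0L) .stopf("empty read")
  if (!inherits(template, "amplicon_template"))
    .stopf("template must be an amplicon_template")
  fwd <- .sw_gotoh(r, template$forward_ref, scoring$match, scoring$mismatch,
                   scoring$gap_open, scoring$gap_extend)
  rev <- .sw_gotoh(r, template$reverse_ref, scoring$match, scoring$mismatch,
                   scoring$gap_open, scoring$gap_extend)
  orientation <- if (rev$score > fwd$score) "reverse" else "forward"
  aln <- if (orientation == "reverse") rev else fwd
  L <- template$length
  max_score <- max_attainable_score(nchar(r), scoring)
  unalignable <- aln$score <= 0
  if (unalignable) {
    tstart <- tend <- NA_integer_
    calls <- rep(NA_character_, length(.callable_sites(template)))
  } else if (orientation == "forward") {
    tstart <- aln$ref_start; tend <- aln$ref_end
    calls <- .cpg_calls_forward(r, aln, .callable_sites(template))
  } else {
    tstart <- L + 1L - aln$ref_end; tend <- L + 1L - aln$ref_start
    calls <- .cpg_calls_reverse(r, aln, .callable_sites(template), L)
  }
  names(calls) <- as.character(.callable_sites(template))
  structure(list(read_id = id, template = template$name,
                 orientation = orientation,
                 tmpl_start = tstart, tmpl_end = tend,
                 score = aln$score, max_score = max_score,
                 score_fraction = aln$score / max_score,
                 unalignable = unalignable, cpg_calls = calls),
            class = "bs_alignment")
}

# methylation evidence at plus-strand CpG positions from a forward-strand
# alignment: read C -> methylated, T -> unmethylated, other base or gap ->
# "O", site outside the aligned interval -> NA
.cpg_calls_forward <- function(read, aln, sites) {
  if (length(sites) == 0L) return(character(0))
  ix <- match(sites, aln$ref_idx)
  vapply(seq_along(sites), function(k) {
    j <- ix[k]
    if (is.na(j)) return(NA_character_)
    ri <- aln$read_idx[j]
    if (is.na(ri)) return("O")
    b <- substring(read, ri, ri)
    if (b == "C") "M" else if (b == "T") "U" else "O"
  }, character(1))
}

# on the reverse strand the informative base is the G complementary to the
# CpG cytosine: read G -> methylated, A -> unmethylated
.cpg_calls_reverse <- function(read, aln, sites, L) {
  if (length(sites) == 0L) return(character(0))
  ix <- match(L + 1L - sites, aln$ref_idx)
  vapply(seq_along(sites), function(k) {
    j <- ix[k]
    if (is.na(j)) return(NA_character_)
    ri <- aln$read_idx[j]
    if (is.na(ri)) return("O")
    b <- substring(read, ri, ri)
    if (b == "G") "M" else if (b == "A") "U" else "O"
  }, character(1))
}

#' Align a set of reads against a template
#'
#' @param reads named character vector or `Biostrings::DNAStringSet` of
#'   reads; unnamed reads get ids `read_1`, `read_2`, ...
#' @inheritParams align_read
#' @param min_fraction score-fraction pass threshold applied by
#'   [filter_reads()] (default 0.80, inclusive).
#' @return object of class `bs_alignment_set`: list with the `template`,
#'   per-read `alignments`, and a summary `table` (data.frame with read_id,
#'   template, orientation, tmpl_start, tmpl_end, score, max_score,
#'   score_fraction, pass).
#' @export
align_reads <- function(reads, template, scoring = scoring_scheme(),
                        min_fraction = 0.8) {
  if (methods::is(reads, "XStringSet")) {
    nm <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nm
  }
  if (!is.character(reads) || length(reads) == 0L)
    .stopf("reads must be a non-empty character vector or DNAStringSet")
  if (is.null(names(reads)))
    names(reads) <- sprintf("read_%d", seq_along(reads))
  alns <- lapply(seq_along(reads), function(k)
    align_read(reads[[k]], template, scoring, id = names(reads)[k]))
  tab <- data.frame(
    read_id = vapply(alns, `[[`, character(1), "read_id"),
    template = template$name,
    orientation = vapply(alns, `[[`, character(1), "orientation"),
    tmpl_start = vapply(alns, `[[`, integer(1), "tmpl_start"),
    tmpl_end = vapply(alns, `[[`, integer(1), "tmpl_end"),
    score = vapply(alns, `[[`, numeric(1), "score"),
    max_score = vapply(alns, `[[`, numeric(1), "max_score"),
    score_fraction = vapply(alns, `[[`, numeric(1), "score_fraction"),
    stringsAsFactors = FALSE)
  out <- structure(list(template = template, alignments = alns, table = tab,
                        min_fraction = min_fraction),
                   class = "bs_alignment_set")
  filter_reads(out, min_fraction)
}

#' Apply the score-fraction read filter
#'
#' A read passes iff its score fraction (alignment score divided by the
#' maximum attainable score for its length) is at least `min_fraction`;
#' the boundary is inclusive, so a fraction of exactly 0.80 passes at the
#' default threshold. Unalignable reads never pass.
#'
#' @param alignments a `bs_alignment_set` from [align_reads()], or a
#'   data.frame with a `score_fraction` column.
#' @param min_fraction threshold in (0, 1].
#' @return the input with an updated logical `pass` column in its table and
#'   an attribute `counts` (`c(pass = , fail = )`).
#' @export
filter_reads <- function(alignments, min_fraction = 0.8) {
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      is.na(min_fraction) || min_fraction <= 0 || min_fraction > 1)
    .stopf("min_fraction must lie in (0, 1]")
  if (is.data.frame(alignments)) {
    alignments$pass <- alignments$score_fraction >= min_fraction
    attr(alignments, "counts") <- c(pass = sum(alignments$pass),
                                    fail = sum(!alignments$pass))
    return(alignments)
  }
  if (!inherits(alignments, "bs_alignment_set"))
    .stopf("alignments must be a bs_alignment_set or data.frame")
  unal <- vapply(alignments$alignments, `[[`, logical(1), "unalignable")
  pass <- !unal & alignments$table$score_fraction >= min_fraction
  alignments$table$pass <- pass
  alignments$min_fraction <- min_fraction
  attr(alignments, "counts") <- c(pass = sum(pass), fail = sum(!pass))
  alignments
}

#' @export
print.bs_alignment_set <- function(x, ...) {
  n <- nrow(x$table)
  cat(sprintf("bs_alignment_set: %d read(s) vs template '%s' (%d passing at %.2f)\n",
              n, x$template$name, sum(x$table$pass %||% logical(0)),
              x$min_fraction))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
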