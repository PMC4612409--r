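# Sliding-window CpG island prediction (Gardiner-Garden & Frommer style
# GC% and observed/expected CpG statistics) for promoter and amplicon
# sequences, plus CpG site enumeration.

#' Observed/expected CpG ratio of a window
#'
#' `(number of CG dinucleotides * window length) / (C count * G count)`,
#' defined as 0 when the window contains no C or no G. N bases count toward
#' the window length but not toward any base or dinucleotide count.
#'
#' @param window DNA string (A/C/G/T/N), length >= 2.
#' @return non-negative ratio.
#' @examples
#' obs_exp_cpg("CGCG")  # 2
#' obs_exp_cpg("CCGG")  # 1
#' @export
obs_exp_cpg <- function(window) {
  s <- .check_dna(window, "window")
  n <- nchar(s)
  if (n < 2L) .stopf("window must have length >= 2")
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  nC <- sum(ch == "C"); nG <- sum(ch == "G")
  if (nC == 0L || nG == 0L) return(0)
  nCG <- sum(ch[-n] == "C" & ch[-1L] == "G")
  nCG * n / (nC * nG)
}

#' Positions of CpG dinucleotides
#'
#' @param seq DNA string.
#' @return strictly increasing 1-based positions `p` of the C of each CG
#'   dinucleotide (`substr(seq, p, p + 1) == "CG"`).
#' @examples
#' list_cpg_sites("CACGT")  # 3
#' list_cpg_sites("CGCG")   # 1 3
#' @export
list_cpg_sites <- function(seq) {
  s <- .check_dna(seq)
  if (nchar(s) < 2L) return(integer(0))
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  which(ch[-length(ch)] == "C" & ch[-1L] == "G")
}

#' Predict CpG islands by sliding-window scanning
#'
#' Slides a window of `window` bases by `shift` along the sequence, marks
#' windows with GC% above `min_gc` and observed/expected CpG ratio above
#' `min_oe`, merges overlapping or book-ended marked windows into spans, and
#' reports merged spans of at least `min_len` bases. The reported GC% and
#' obs/exp of a span are the means over its contributing marked windows, so
#' each reported span satisfies the thresholds by construction. Defaults
#' mirror the conventional island definition (100/1/200/50/0.6); none are
#' hard-coded.
#'
#' @param seq DNA string.
#' @param window window size in bases (>= 2).
#' @param shift step between successive windows.
#' @param min_len minimum merged-span length to report.
#' @param min_gc GC percentage threshold (exclusive).
#' @param min_oe observed/expected CpG threshold (exclusive).
#' @return data.frame with 1-based closed `start`, `end`, plus `length`,
#'   `gc_percent`, `obs_exp`; sorted by start, non-overlapping. A sequence
#'   shorter than the window yields an empty result with a warning.
#' @export
predict_islands <- function(seq, window = 100L, shift = 1L, min_len = 200L,
                            min_gc = 50, min_oe = 0.6) {
  s <- .check_dna(seq)
  window <- .check_count(window, "window", min = 2L)
  shift <- .check_count(shift, "shift", min = 1L)
  min_len <- .check_count(min_len, "min_len", min = 1L)
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), gc_percent = numeric(0),
                      obs_exp = numeric(0))
  L <- nchar(s)
  if (L < window) {
    .warnf("sequence length %d is shorter than the window (%d); no islands called",
           L, window)
    return(empty)
  }
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  isC <- ch == "C"; isG <- ch == "G"
  isCG <- c(isC[-L] & isG[-1L], FALSE)
  csC <- c(0, cumsum(isC)); csG <- c(0, cumsum(isG)); csCG <- c(0, cumsum(isCG))
  starts <- seq.int(1L, L - window + 1L, by = shift)
  ends <- starts + window - 1L
  nC <- csC[ends + 1L] - csC[starts]
  nG <- csG[ends + 1L] - csG[starts]
  nCG <- csCG[ends] - csCG[starts]  # CG must start at <= end - 1
  gc <- 100 * (nC + nG) / window
  oe <- ifelse(nC > 0 & nG > 0, nCG * window / (nC * nG), 0)
  marked <- which(gc > min_gc & oe > min_oe)
  if (length(marked) == 0L) return(empty)
  # merge marked windows whose spans overlap or touch
  brk <- which(starts[marked[-1L]] > ends[marked[-length(marked)]] + 1L)
  grp <- cumsum(c(1L, seq_along(marked)[-1L] %in% (brk + 1L)))
  spans <- lapply(split(marked, grp), function(ix) {
    data.frame(start = starts[ix[1L]], end = ends[ix[length(ix)]],
               gc_percent = mean(gc[ix]), obs_exp = mean(oe[ix]))
  })
  out <- do.call(rbind, spans)
  out$length <- out$end - out$start + 1L
  out <- out[out$length >= min_len, c("start", "end", "length",
                                      "gc_percent", "obs_exp")]
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}
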