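# Independent oracles written directly from definitions; used to check the
# package implementations, never the other way round.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Kendall tau-b by explicit enumeration of all sample pairs
oracle_tau <- function(x, y) {
  n <- length(x)
  conc <- disc <- tie_x <- tie_y <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0 && dy == 0) { tie_x <- tie_x + 1; tie_y <- tie_y + 1 }
    else if (dx == 0) tie_x <- tie_x + 1
    else if (dy == 0) tie_y <- tie_y + 1
    else if (sign(dx) == sign(dy)) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  den <- sqrt((n0 - tie_x) * (n0 - tie_y))
  if (den == 0) return(0)
  (conc - disc) / den
}

# step-up FDR adjustment from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# pooled-variance two-sample t-test p-value from the textbook formula
oracle_pooled_t_p <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  tstat <- (mean(x2) - mean(x1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(tstat), n1 + n2 - 2)
}

# Best local alignment score with affine gaps by exhaustive enumeration of
# aligned-column subsets: an alignment is a strictly increasing pairing of k
# read positions with k template positions (each column scoring
# match/mismatch), with one gap run per sequence between consecutive
# columns, costed gap_open + (L - 1) * gap_extend. Interleaving gap runs
# further can only cost more, so the maximum over this family equals the
# optimal local alignment score. The empty alignment scores 0.
oracle_local_align <- function(read, ref,
                               sc = list(match = 1, mismatch = -1,
                                         gap_open = -2, gap_extend = -1)) {
  pair_score <- function(r, t) {
    if (t == "Y") return(if (r %in% c("C", "T")) sc$match else sc$mismatch)
    if (t == "R") return(if (r %in% c("A", "G")) sc$match else sc$mismatch)
    if (r == "N" || t == "N") return(sc$mismatch)
    if (r == t) sc$match else sc$mismatch
  }
  gap_cost <- function(L) ifelse(L == 0, 0, sc$gap_open + (L - 1) * sc$gap_extend)
  rch <- strsplit(read, "")[[1]]
  tch <- strsplit(ref, "")[[1]]
  nr <- length(rch); nt <- length(tch)
  S <- matrix(0, nr, nt)
  for (i in seq_len(nr)) for (j in seq_len(nt)) S[i, j] <- pair_score(rch[i], tch[j])
  best <- 0
  for (k in seq_len(min(nr, nt))) {
    Ra <- utils::combn(nr, k)
    Ta <- utils::combn(nt, k)
    tg <- apply(Ta, 2L, function(tb) sum(gap_cost(diff(tb) - 1)))
    for (ca in seq_len(ncol(Ra))) {
      ra <- Ra[, ca]
      rg <- sum(gap_cost(diff(ra) - 1))
      col_scores <- matrix(S[cbind(rep(ra, ncol(Ta)), as.vector(Ta))], nrow = k)
      best <- max(best, max(colSums(col_scores) + tg + rg))
    }
  }
  best
}

# naive sliding-window island scan: returns the union coverage spans of the
# marked windows (window step 1)
oracle_marked_spans <- function(seq, window = 100, min_gc = 50, min_oe = 0.6) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  cov <- logical(L)
  for (i in seq_len(L - window + 1)) {
    w <- ch[i:(i + window - 1)]
    nC <- sum(w == "C"); nG <- sum(w == "G")
    nCG <- sum(w[-window] == "C" & w[-1] == "G")
    gc <- 100 * (nC + nG) / window
    oe <- if (nC > 0 && nG > 0) nCG * window / (nC * nG) else 0
    if (gc > min_gc && oe > min_oe) cov[i:(i + window - 1)] <- TRUE
  }
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

# small template used across alignment/calling tests: 60 bp, 3 CpG sites
fixture_template <- function() {
  amplicon_template(
    "fix",
    paste0("ATTACCGGATTCATCAGGAATCGAATCACCATTGGACTTACGTTAGGACA",
           "TCATTGGAAT"))
}
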