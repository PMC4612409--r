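# Template conversion, affine-gap local alignment against converted
# references, and the score-fraction read filter.

test_that("bisulfite conversion of templates follows the C/T rule", {
  expect_equal(bisulfite_convert_template("CACGT")$forward, "TAYGT")
  expect_equal(bisulfite_convert_template("CGCG")$forward, "YGYG")
  expect_equal(bisulfite_convert_template("ATTGA")$forward, "ATTGA")
  # reverse form: reverse complement with G -> A except mirrored CpG G -> R
  expect_equal(bisulfite_convert_template("CACGT")$reverse, "ACRTA")
  conv <- bisulfite_convert_template("ACGGATCG")
  expect_equal(nchar(conv$forward), 8)
  expect_equal(nchar(conv$reverse), 8)
  expect_error(bisulfite_convert_template("ACXGT"), "alphabet")
  expect_error(bisulfite_convert_template("ACGT", cpg_pos = 3), "CG dinucleotide")
})

test_that("amplicon_template validates CpG positions and masks", {
  t <- fixture_template()
  expect_true(all(substring(t$seq, t$cpg_pos, t$cpg_pos + 1) == "CG"))
  expect_error(amplicon_template("x", "ACGT", cpg_pos = c(1, 1)),
               "strictly increasing")
  tm <- amplicon_template("x", "ACGGATCGTA",
                          primer_mask = data.frame(start = 1, end = 3))
  expect_equal(methmarker:::.callable_sites(tm), 7L)
})

test_that("max_attainable_score is match x read length", {
  expect_equal(max_attainable_score(100), 100)
  expect_equal(max_attainable_score(1, scoring_scheme(match = 2)), 2)
})

test_that("scoring_scheme validates sign constraints", {
  expect_error(scoring_scheme(match = 0), "positive")
  expect_error(scoring_scheme(mismatch = 1), "<= 0")
  expect_error(scoring_scheme(gap_open = -1, gap_extend = -2), ">=")
})

test_that("a read identical to the converted template aligns perfectly", {
  t <- fixture_template()
  read <- gsub("Y", "C", t$forward_ref)  # fully methylated forward read
  a <- align_read(read, t)
  expect_equal(a$orientation, "forward")
  expect_equal(a$score, nchar(read))
  expect_equal(a$score_fraction, 1)
  expect_equal(a$tmpl_start, 1L)
  expect_equal(a$tmpl_end, t$length)
  expect_true(all(a$cpg_calls == "M"))
  # unmethylated forward read
  b <- align_read(gsub("Y", "T", t$forward_ref), t)
  expect_equal(b$score_fraction, 1)
  expect_true(all(b$cpg_calls == "U"))
})

test_that("minus-strand reads win the reverse orientation", {
  t <- fixture_template()
  read <- gsub("R", "G", t$reverse_ref)  # methylated minus-strand read
  a <- align_read(read, t)
  expect_equal(a$orientation, "reverse")
  expect_equal(a$score_fraction, 1)
  expect_true(all(a$cpg_calls == "M"))
  u <- align_read(gsub("R", "A", t$reverse_ref), t)
  expect_equal(u$orientation, "reverse")
  expect_true(all(u$cpg_calls == "U"))
})

test_that("DP score equals the exhaustive oracle on small random pairs", {
  set.seed(99)
  sc <- scoring_scheme()
  for (rep in 1:150) {
    read <- random_dna(sample(1:8, 1))
    ref <- random_dna(sample(1:8, 1))
    got <- methmarker:::.sw_gotoh(read, ref, sc$match, sc$mismatch,
                                  sc$gap_open, sc$gap_extend)$score
    expect_equal(got, oracle_local_align(read, ref), info = paste(read, ref))
  }
})

test_that("DP score matches Biostrings local alignment on clean instances", {
  set.seed(123)
  sc <- scoring_scheme(match = 1, mismatch = -1, gap_open = -2,
                       gap_extend = -1)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (rep in 1:25) {
    read <- random_dna(sample(10:40, 1))
    ref <- random_dna(sample(20:60, 1))
    got <- methmarker:::.sw_gotoh(read, ref, 1, -1, -2, -1)$score
    # Biostrings costs a gap of length L as gapOpening + L * gapExtension
    want <- Biostrings::pairwiseAlignment(read, ref, type = "local",
                                          substitutionMatrix = mat,
                                          gapOpening = 1, gapExtension = 1,
                                          scoreOnly = TRUE)
    expect_equal(got, want)
  }
})

test_that("score is invariant under joint reverse-complementation", {
  set.seed(55)
  for (rep in 1:20) {
    read <- random_dna(sample(5:20, 1))
    ref <- random_dna(sample(5:20, 1))
    a <- methmarker:::.sw_gotoh(read, ref, 1, -1, -2, -1)$score
    b <- methmarker:::.sw_gotoh(methmarker:::.revcomp(read),
                                methmarker:::.revcomp(ref), 1, -1, -2, -1)$score
    expect_equal(a, b)
  }
})

test_that("one extra mismatch in a perfect read lowers the score by match - mismatch", {
  t <- fixture_template()
  read <- gsub("Y", "C", t$forward_ref)
  base <- align_read(read, t)$score
  # corrupt an interior base to something matching nothing nearby
  pos <- 30
  ch <- strsplit(read, "")[[1]]
  orig <- ch[pos]
  repl <- setdiff(c("A", "C", "G", "T"), c(orig, "C", "T"))[1]
  ch[pos] <- repl
  mut <- paste(ch, collapse = "")
  got <- align_read(mut, t)$score
  expect_lte(got, base)
  expect_equal(got, base - (1 - (-1)))
})

test_that("filter boundary at 0.80 is inclusive and unalignable reads fail", {
  t <- fixture_template()
  df <- data.frame(score_fraction = c(0.80, 1.0, 0.799))
  out <- filter_reads(df, 0.80)
  expect_equal(out$pass, c(TRUE, TRUE, FALSE))
  nn <- align_read(strrep("N", 20), t)
  expect_true(nn$unalignable)
  aset <- align_reads(c(r1 = strrep("N", 20)), t)
  expect_false(aset$table$pass[1])
  expect_error(align_read("", t), "empty|string")
  expect_error(filter_reads(df, 0), "\\(0, 1\\]")
})

test_that("error-free simulated reads all pass; random reads rarely pass", {
  t <- fixture_template()
  sim <- gen_bisulfite_reads(t, rep(0.5, length(t$cpg_pos)), n_reads = 60,
                             seed = 17)
  aset <- align_reads(sim$reads, t)
  expect_true(all(aset$table$score_fraction == 1))
  expect_true(all(aset$table$pass))
  set.seed(71)
  rnd <- vapply(1:150, function(i) random_dna(t$length), character(1))
  rset <- align_reads(rnd, t)
  expect_lt(mean(rset$table$pass), 0.05)
})

test_that("pass rate is non-increasing in the substitution rate", {
  t <- fixture_template()
  rates <- c(0, 0.05, 0.15, 0.3)
  pr <- vapply(rates, function(r) {
    sim <- gen_bisulfite_reads(t, rep(0.5, length(t$cpg_pos)), n_reads = 40,
                               sub_rate = r, seed = 202)
    mean(align_reads(sim$reads, t)$table$pass)
  }, numeric(1))
  expect_true(all(diff(pr) <= 1e-9))
})
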