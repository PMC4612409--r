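# Per-CpG methylation calling, assay summaries, group comparison and
# clustering.

test_that("calls count C/T evidence and recover the simulator's draws", {
  t <- fixture_template()
  n_sites <- length(t$cpg_pos)
  sim <- gen_bisulfite_reads(t, rep(0.6, n_sites), n_reads = 200, seed = 5)
  calls <- call_cpg_methylation(align_reads(sim$reads, t))
  expect_equal(calls$count_C, unname(sim$truth$site_c_counts))
  expect_equal(calls$coverage, rep(200L, n_sites))
  expect_equal(calls$count_other, rep(0L, n_sites))
  expect_equal(calls$fraction, sim$truth$site_c_counts / 200)
  # the drawn states match an independent per-read count from the reads
  read_base <- substring(sim$reads, t$cpg_pos[1], t$cpg_pos[1])
  expect_equal(sum(read_base == "C"), sim$truth$site_c_counts[[1]])
})

test_that("zero coverage gives undefined fractions, not an error", {
  t <- fixture_template()
  aset <- align_reads(c(r = strrep("N", 30)), t)  # unalignable -> no pass
  calls <- call_cpg_methylation(aset)
  expect_equal(calls$coverage, rep(0L, length(t$cpg_pos)))
  expect_true(all(is.na(calls$fraction)))
})

test_that("counts at a site conserve the number of passing reads spanning it", {
  t <- fixture_template()
  sim <- gen_bisulfite_reads(t, rep(0.4, length(t$cpg_pos)), n_reads = 80,
                             sub_rate = 0.03, indel_rate = 0.02, seed = 23)
  aset <- align_reads(sim$reads, t)
  calls <- call_cpg_methylation(aset)
  tab <- aset$table
  for (k in seq_along(t$cpg_pos)) {
    p <- t$cpg_pos[k]
    spanning <- sum(tab$pass & !is.na(tab$tmpl_start) &
                      tab$tmpl_start <= p & tab$tmpl_end >= p)
    expect_equal(calls$count_C[k] + calls$count_T[k] + calls$count_other[k],
                 spanning)
  }
})

test_that("failing reads contribute nothing to the counts", {
  t <- fixture_template()
  sim <- gen_bisulfite_reads(t, rep(0.5, length(t$cpg_pos)), n_reads = 50,
                             seed = 7)
  aset <- align_reads(sim$reads, t)
  calls1 <- call_cpg_methylation(aset)
  junk <- vapply(1:30, function(i) random_dna(40), character(1))
  names(junk) <- sprintf("junk_%d", 1:30)
  aset2 <- align_reads(c(sim$reads, junk), t)
  expect_equal(sum(aset2$table$pass), 50)
  calls2 <- call_cpg_methylation(aset2)
  expect_equal(calls1$count_C, calls2$count_C)
  expect_equal(calls1$count_T, calls2$count_T)
})

test_that("primer-masked sites are excluded from calling", {
  seqs <- "ATACGGATTACCGGATTACGGA"
  tm <- amplicon_template("m", seqs,
                          primer_mask = data.frame(start = 1, end = 6))
  sites_all <- list_cpg_sites(seqs)
  expect_true(length(sites_all) > length(methmarker:::.callable_sites(tm)))
  sim <- gen_bisulfite_reads(tm, rep(1, length(sites_all)), n_reads = 10,
                             seed = 2)
  calls <- call_cpg_methylation(align_reads(sim$reads, tm))
  expect_false(any(calls$site <= 6))
})

test_that("summarize_assay averages defined sites on the percent scale", {
  tab <- data.frame(template = "x", site = c(5, 9, 20),
                    count_C = c(2, 4, 0), count_T = c(8, 6, 0),
                    count_other = 0L, coverage = c(10L, 10L, 0L),
                    fraction = c(0.2, 0.4, NA))
  expect_equal(summarize_assay(tab), 30)
  expect_equal(summarize_assay(tab, sites = c(5, 9)), 30)
  expect_equal(summarize_assay(tab, sites = 9), 40)
  expect_equal(summarize_assay(tab, coverage_weight = TRUE), 30)
  expect_error(summarize_assay(tab, sites = integer(0)), "empty")
  expect_error(summarize_assay(tab, sites = 99), "not in table")
  tab$fraction <- NA_real_
  expect_true(is.na(summarize_assay(tab)))
})

test_that("methylation parameter recovery across the truth grid", {
  t <- fixture_template()
  n_sites <- length(t$cpg_pos)
  for (p in c(0.1, 0.5, 0.9)) {
    sim <- gen_bisulfite_reads(t, rep(p, n_sites), n_reads = 300,
                               seed = 1000 + round(100 * p))
    calls <- call_cpg_methylation(align_reads(sim$reads, t))
    se <- sqrt(p * (1 - p) / 300)
    expect_true(all(abs(calls$fraction - p) < 3 * se + 1e-12))
  }
})

test_that("group comparison classifies hyper/hypo/unchanged", {
  set.seed(12)
  n <- 6
  mk <- function(m, s = 2) rnorm(n, m, s)
  mat <- rbind(hyper = c(mk(7), mk(15), mk(29)),
               hypo = c(mk(91), mk(86), mk(84)),
               flat = c(mk(50), mk(50), mk(50)))
  groups <- rep(c("NAT", "AD", "CRC"), each = n)
  cmp <- compare_methylation_groups(mat, groups)
  expect_equal(cmp$class_CRC[1], "hypermethylated")
  expect_equal(cmp$class_CRC[2], "hypomethylated")
  expect_equal(cmp$class_CRC[3], "unchanged")
  # identical groups -> unchanged with p = 1
  one <- matrix(50, nrow = 1, ncol = 3 * n,
                dimnames = list("const", NULL))
  cmp1 <- compare_methylation_groups(one, groups)
  expect_equal(cmp1$p_NAT_vs_CRC, 1)
  expect_equal(cmp1$class_CRC, "unchanged")
  # all-missing assay
  mat2 <- rbind(mat, missing = NA_real_)
  cmp2 <- compare_methylation_groups(mat2, groups)
  expect_equal(cmp2$class_CRC[4], "not_evaluable")
})

test_that("clustering merges identical rows first and recovers structure", {
  m <- rbind(a = c(0, 0, 0), b = c(0, 0, 0), c = c(9, 9, 9))
  cl <- cluster_markers(m, k = 2)
  expect_equal(cl$row_hclust$height[1], 0)
  expect_equal(unname(cl$clusters[c("a", "b")]), c(1, 1))
  expect_false(cl$clusters[["c"]] == cl$clusters[["a"]])
  # 1-D points {0, 1, 10}: {0,1} merge first under average linkage
  m2 <- rbind(x = 0, y = 1, z = 10)
  cl2 <- cluster_markers(m2)
  expect_equal(cl2$row_hclust$merge[1, ], c(-1, -2))
  expect_equal(cl2$row_hclust$height, c(1, 9.5))
})

test_that("clustering is invariant to row order and excludes all-NA rows", {
  set.seed(3)
  block <- matrix(rnorm(4 * 8, 80, 3), nrow = 4,
                  dimnames = list(paste0("hi", 1:4), NULL))
  rest <- matrix(rnorm(5 * 8, 10, 3), nrow = 5,
                 dimnames = list(paste0("lo", 1:5), NULL))
  m <- rbind(block, rest)
  cl <- cluster_markers(m, k = 2)
  perm <- sample(nrow(m))
  cl_p <- cluster_markers(m[perm, ], k = 2)
  # same partition up to label renaming
  part <- function(cl) split(names(cl$clusters), cl$clusters)
  norm <- function(p) unname(lapply(p[order(vapply(p, `[`, "", 1))], sort))
  expect_equal(norm(part(cl)), norm(part(cl_p)))
  # planted high block is separated at k = 2
  expect_equal(length(unique(cl$clusters[paste0("hi", 1:4)])), 1)
  expect_false(cl$clusters[["hi1"]] == cl$clusters[["lo1"]])
  m_na <- rbind(m, allna = NA_real_)
  expect_warning(cl_na <- cluster_markers(m_na, k = 2), "all-missing")
  expect_equal(cl_na$excluded, "allna")
})

test_that("methylation_matrix assembles per-sample assay values", {
  sv <- list(s1 = c(a = 10, b = 90), s2 = c(a = 12), s3 = c(a = 30, b = 70))
  mm <- methylation_matrix(sv, groups = c("NAT", "AD", "CRC"))
  expect_equal(dim(mm), c(2L, 3L))
  expect_true(is.na(mm["b", "s2"]))
  expect_equal(levels(attr(mm, "groups")), c("NAT", "AD", "CRC"))
})
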