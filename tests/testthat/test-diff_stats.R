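make_profiles <- function(n_control, n_case, edited_ctrl, edited_case,
                          site = list("chr1", 100L),
                          lib = NULL) {
  ids <- c(sprintf("c%02d", seq_len(n_control)),
           sprintf("p%02d", seq_len(n_case)))
  groups <- rep(c("control", "case"), c(n_control, n_case))
  if (is.null(lib)) lib <- rep(1e6, n_control + n_case)
  ed_ids <- c(ids[seq_len(edited_ctrl)],
              ids[n_control + seq_len(edited_case)])
  edited <- if (length(ed_ids))
    data.frame(sample_id = ed_ids, chrom = site[[1]],
               position = site[[2]])
  else data.frame(sample_id = character(), chrom = character(),
                  position = integer())
  sample_profiles(
    data.frame(sample_id = ids, group = groups, library_size = lib),
    edited)
}

test_that("contingency counts reflect per-sample edited status", {
  prof <- make_profiles(44L, 29L, 38L, 11L)
  expect_equal(build_contingency(prof, list("chr1", 100L)),
               c(k_control = 38L, n_control = 44L,
                 k_case = 11L, n_case = 29L))
  # absent site: zeros with full denominators
  expect_equal(build_contingency(prof, list("chr1", 999L)),
               c(k_control = 0L, n_control = 44L,
                 k_case = 0L, n_case = 29L))
  full <- make_profiles(4L, 3L, 4L, 3L)
  expect_equal(build_contingency(full, list("chr1", 100L)),
               c(k_control = 4L, n_control = 4L, k_case = 3L, n_case = 3L))
  expect_error(sample_profiles(
    data.frame(sample_id = "s1", group = "patient", library_size = 1),
    data.frame(sample_id = character(), chrom = character(),
               position = integer())), "group label")
})

test_that("Fisher two-sided p matches hand enumeration and edge cases", {
  # margins (2,2|2,2): point probs 1/6, 4/6, 1/6 -> two-sided p = 1/3
  expect_equal(fisher_exact_two_sided(2L, 2L, 0L, 2L), 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(5L, 10L, 5L, 10L), 1)
  expect_error(fisher_exact_two_sided(5L, 4L, 0L, 2L), "impossible")
  expect_error(fisher_exact_two_sided(-1L, 4L, 0L, 2L), "impossible")
})

test_that("Fisher agrees with exhaustive enumeration for all margins <= 12", {
  for (n1 in 1:11) for (n2 in 1:(12 - n1)) {
    for (k1 in 0:n1) for (k2 in 0:n2) {
      expect_equal(fisher_exact_two_sided(k1, n1, k2, n2),
                   oracle_fisher(k1, n1, k2, n2), tolerance = 1e-9,
                   label = sprintf("(%d/%d vs %d/%d)", k1, n1, k2, n2))
    }
  }
})

test_that("BH adjustment matches the step-up oracle and input contracts", {
  expect_equal(bh_adjust(0.5, m_total = 1L), 0.5)
  set.seed(99)
  for (rep in 1:5) {
    p <- runif(20)
    expect_equal(bh_adjust(p), oracle_bh(p, 20L), tolerance = 1e-12)
    # enlarged family: supplied values are the smallest m of the family
    small <- sort(p)[1:8]
    expect_equal(bh_adjust(small, m_total = 50L), oracle_bh(small, 50L),
                 tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, 0.2), m_total = 1L), "smaller")
  # monotone in raw-p order, never below raw p, never above 1
  p <- runif(30)
  adj <- bh_adjust(p, m_total = 60L)
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  # Bonferroni option
  expect_equal(bh_adjust(c(0.01, 0.4), m_total = 10L,
                         method = "bonferroni"), c(0.1, 1))
})

test_that("the BH family size reproduces published-style adjusted columns", {
  # six smallest p-values of a 160-site family
  p <- c(3.00e-5, 1.00e-4, 4.80e-4, 1.67e-3, 2.10e-3, 3.65e-3)
  adj <- bh_adjust(p, m_total = 160L)
  expect_equal(signif(adj, 3),
               c(4.80e-3, 8.00e-3, 2.56e-2, 6.68e-2, 6.72e-2, 9.73e-2))
})

test_that("differential tables order records and adjust over the family", {
  ids <- c(sprintf("c%02d", 1:10), sprintf("p%02d", 1:10))
  groups <- rep(c("control", "case"), each = 10L)
  edited <- rbind(
    data.frame(sample_id = ids[1:9], chrom = "chr1", position = 11L),
    data.frame(sample_id = ids[11:12], chrom = "chr1", position = 11L),
    data.frame(sample_id = ids[c(1:5, 11:15)], chrom = "chr1",
               position = 22L))
  prof <- sample_profiles(
    data.frame(sample_id = ids, group = groups, library_size = 1e6),
    edited)
  sites <- data.frame(chrom = "chr1", position = c(11L, 22L),
                      gene = c("gA", "gB"))
  dt <- differential_table(prof, sites)
  expect_s3_class(dt, "edit_diff")
  tab <- as.data.frame(dt)
  expect_equal(tab$position, c(11L, 22L))  # smaller p first
  expect_equal(tab$k_control, c(9L, 5L))
  expect_equal(tab$k_case, c(2L, 5L))
  expect_equal(tab$p_fisher,
               c(fisher_exact_two_sided(9L, 10L, 2L, 10L), 1))
  expect_equal(tab$p_adjusted, bh_adjust(tab$p_fisher, 2L))

  # single site: adjusted equals raw
  one <- differential_table(prof, sites[1L, ])
  expect_equal(as.data.frame(one)$p_adjusted,
               as.data.frame(one)$p_fisher)

  # identical proportions everywhere -> all p = 1
  same <- make_profiles(6L, 6L, 3L, 3L)
  flat <- differential_table(same, data.frame(chrom = "chr1",
                                              position = 100L))
  expect_equal(as.data.frame(flat)$p_fisher, 1)
  expect_equal(as.data.frame(flat)$p_adjusted, 1)

  expect_output(print(dt), "sites tested")
  s <- summary(dt)
  expect_equal(s$n_sites, 2L)
})

test_that("group-label symmetry leaves both tests unchanged", {
  set.seed(7)
  for (rep in 1:10) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    expect_equal(fisher_exact_two_sided(k1, n1, k2, n2),
                 fisher_exact_two_sided(k2, n2, k1, n1))
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(wilcoxon_rank_sum(x, y), wilcoxon_rank_sum(y, x))
  }
})

test_that("rank-sum test: exact enumeration, ties, and null calibration", {
  # C(6,3) = 20 assignments, 2 as extreme -> p = 0.1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)),
               oracle_ranksum(c(1, 2, 3), c(4, 5, 6)))
  set.seed(12)
  for (rep in 1:5) {
    x <- rnorm(4); y <- rnorm(5)
    expect_equal(wilcoxon_rank_sum(x, y), oracle_ranksum(x, y),
                 tolerance = 1e-9)
  }
  expect_equal(wilcoxon_rank_sum(c(2, 1, 3), c(3, 1, 2)), 1)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")

  # type-I error at alpha = 0.05 for 30 vs 30, inside binomial 99% bounds
  set.seed(2024)
  rej <- replicate(1000, {
    wilcoxon_rank_sum(rnorm(30), rnorm(30)) < 0.05
  })
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.05) / 1000
  expect_gte(mean(rej), bounds[1])
  expect_lte(mean(rej), bounds[2])
})

test_that("burden counts, normalization and comparison behave", {
  ids <- c("c1", "c2", "p1", "p2")
  samples <- data.frame(sample_id = ids,
                        group = c("control", "control", "case", "case"),
                        library_size = c(5e7, 2.5e7, 5e7, 2.5e7))
  edited <- data.frame(
    sample_id = c(rep("c1", 500), rep("c2", 500), rep("p1", 10)),
    chrom = "chr1", position = c(1:500, 1:500, 1:10))
  prof <- sample_profiles(samples, edited)
  b <- edit_burden(prof)
  per <- b$per_sample
  expect_equal(per[per$sample_id == "c1", ]$sites_per_million, 10)
  expect_equal(per[per$sample_id == "c2", ]$sites_per_million, 20)
  expect_equal(per[per$sample_id == "p2", ]$n_sites, 0L)
  expect_equal(per[per$sample_id == "p2", ]$sites_per_million, 0)
  expect_equal(b$medians$raw[["control"]], 500)
  expect_gt(b$medians$normalized[["control"]],
            b$medians$normalized[["case"]])
  expect_true(b$p_raw > 0 && b$p_raw <= 1)

  expect_error(sample_profiles(
    data.frame(sample_id = "s", group = "control", library_size = 0),
    edited[0, ]), "positive")
})
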