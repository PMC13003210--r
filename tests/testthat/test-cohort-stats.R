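# Cohort statistics: aggregation, exact nonparametric tests against
# enumeration oracles, BH adjustment and the standardized PCA.

mk_table <- function(vals, tp, pid = NULL) {
  n <- length(vals)
  if (is.null(pid)) pid <- sprintf("S%02d", seq_len(n))
  out <- data.frame(participant_id = pid,
                    group = ifelse(tp == "single", "control", "patient"),
                    time_point = tp)
  for (f in multimodal_feature_names()) out[[f]] <- vals
  out
}

test_that("cohort aggregation is the mean of the windowed series", {
  ts1 <- data.frame(window_start = c(0, 8), RR = c(10, 20), Ti = 1,
                    Te = 2, TeTi = 2, TiIBI = 1 / 3,
                    SI100_300_I = 0.7, SI300_500_I = 0.15,
                    SI500_800_I = 0.1, SI800_1000_I = 0.05,
                    SI100_300_E = 0.7, SI300_500_E = 0.15,
                    SI500_800_E = 0.1, SI800_1000_E = 0.05)
  man <- data.frame(id = "r1", participant_id = "P01",
                    group = "patient", time_point = "T1")
  tab <- aggregate_cohort(list(r1 = ts1), man)
  expect_equal(tab$RR, 15)
  expect_equal(nrow(tab), 1)

  man2 <- rbind(man, man)
  man2$id <- c("r1", "r2")
  expect_error(aggregate_cohort(list(r1 = ts1, r2 = ts1), man2),
               "duplicate")
})

test_that("paired signed-rank matches the enumeration oracle", {
  # all-positive differences 1..5: W = 15, exact two-sided p = 0.0625
  t1 <- c(11, 22, 33, 44, 55); t2 <- t1 - (1:5)
  tab <- rbind(mk_table(t1, rep("T1", 5), sprintf("P%d", 1:5)),
               mk_table(t2, rep("T2", 5), sprintf("P%d", 1:5)))
  res <- paired_wilcoxon(tab, features = "RR")
  or <- signed_rank_oracle(t1 - t2)
  expect_equal(res$W, 15)
  expect_equal(res$p, 0.0625)
  expect_equal(res$W, or$W)
  expect_equal(res$p, or$p)

  # antisymmetric differences: p = 1
  taba <- rbind(mk_table(c(5, 6), c("T1", "T1"), c("Pa", "Pb")),
                mk_table(c(6, 5), c("T2", "T2"), c("Pa", "Pb")))
  expect_equal(paired_wilcoxon(taba, features = "RR")$p, 1)

  # all-zero differences: W = 0, p = 1
  tabz <- rbind(mk_table(c(3, 3), c("T1", "T1"), c("Pa", "Pb")),
                mk_table(c(3, 3), c("T2", "T2"), c("Pa", "Pb")))
  rz <- paired_wilcoxon(tabz, features = "RR")
  expect_equal(rz$W, 0); expect_equal(rz$p, 1)

  # random configurations n <= 10 agree exactly with the oracle
  set.seed(21)
  for (n in c(4, 6, 8, 10)) {
    a <- stats::rnorm(n); b <- stats::rnorm(n)
    tt <- rbind(mk_table(a, rep("T1", n), sprintf("P%d", 1:n)),
                mk_table(b, rep("T2", n), sprintf("P%d", 1:n)))
    r <- paired_wilcoxon(tt, features = "Ti")
    o <- signed_rank_oracle(a - b)
    expect_equal(r$W, o$W)
    expect_equal(r$p, o$p, tolerance = 1e-12)
  }
})

test_that("rank-sum with BH matches oracles and hand-computed values", {
  tab <- rbind(mk_table(c(1, 2, 3), rep("T1", 3)),
               mk_table(c(4, 5, 6), rep("single", 3),
                        sprintf("C%d", 1:3)))
  res <- group_wilcoxon_bh(tab, features = "RR", time_points = "T1")
  expect_equal(res$p, 0.1)   # exact two-sided, most extreme at 3v3
  expect_equal(res$W, 6)     # rank sum of the first-named group

  # identical groups: p = 1 (tied ranks, z = 0), BH-adjusted 1
  tabi <- rbind(mk_table(c(1, 2, 3), rep("T1", 3)),
                mk_table(c(1, 2, 3), rep("single", 3),
                         sprintf("C%d", 1:3)))
  resi <- group_wilcoxon_bh(tabi, features = "RR", time_points = "T1")
  expect_equal(resi$p, 1); expect_equal(resi$p_adj, 1)

  # random configurations n1 + n2 <= 10 agree with enumeration
  set.seed(22)
  for (k in 1:4) {
    n1 <- sample(3:6, 1); n2 <- sample(3:4, 1)
    a <- stats::rnorm(n1); b <- stats::rnorm(n2)
    tt <- rbind(mk_table(a, rep("T1", n1)),
                mk_table(b, rep("single", n2), sprintf("C%d", 1:n2)))
    r <- group_wilcoxon_bh(tt, features = "Te", time_points = "T1")
    o <- rank_sum_oracle(a, b)
    expect_equal(r$W, o$W)
    expect_equal(r$p, o$p, tolerance = 1e-12)
  }

  # BH with m = 2: (0.01, 0.04) -> (0.02, 0.04)
  expect_equal(stats::p.adjust(c(0.01, 0.04), "BH"), c(0.02, 0.04))
  # BH invariants on the package output
  tab2 <- rbind(mk_table(c(1, 2, 3, 10), rep("T1", 4)),
                mk_table(c(4, 5, 6, 7), rep("T2", 4),
                         sprintf("Q%d", 1:4)),
                mk_table(c(2, 3, 4, 5), rep("single", 4),
                         sprintf("C%d", 1:4)))
  r2 <- group_wilcoxon_bh(tab2, features = c("RR", "Ti"))
  expect_true(all(r2$p_adj >= r2$p))
  expect_true(all(r2$p_adj <= 1))
})

test_that("PCA is standardized, oriented and correctly ranked", {
  # two perfectly correlated features: PC1 explains everything
  set.seed(23)
  v <- stats::rnorm(20)
  tab <- mk_table(v, rep("T1", 20), sprintf("P%d", 1:20))
  pca <- run_pca(tab, features = c("RR", "Ti"))
  expect_equal(pca$explained[1], 1, tolerance = 1e-12)
  expect_equal(abs(unname(pca$loadings[, 1])), rep(1 / sqrt(2), 2),
               tolerance = 1e-9)
  # sign convention: largest-|loading| coefficient positive
  expect_gt(pca$loadings[which.max(abs(pca$loadings[, 1])), 1], 0)

  # isotropic data: each PC explains ~ 1/13
  tab2 <- mk_table(stats::rnorm(200), rep("T1", 200),
                   sprintf("P%d", 1:200))
  for (f in multimodal_feature_names()) tab2[[f]] <- stats::rnorm(200)
  pca2 <- run_pca(tab2)
  expect_lt(pca2$explained[1], 2 / 13)
  expect_equal(sum(pca2$explained), 1, tolerance = 1e-12)
  expect_true(all(diff(pca2$explained) <= 1e-12))

  # scores invariant to feature ordering
  pca3 <- run_pca(tab2, features = rev(multimodal_feature_names()))
  expect_equal(abs(pca3$scores$PC1), abs(pca2$scores$PC1),
               tolerance = 1e-9)

  # zero-variance feature dropped with a warning
  tab3 <- tab2; tab3$TeTi <- 5
  expect_warning(pca4 <- run_pca(tab3), "zero-variance")
  expect_false("TeTi" %in% rownames(pca4$loadings))

  expect_error(run_pca(tab2[1:2, ]), "3 rows")
})

test_that("PC1 group comparison reduces to the rank-sum oracle", {
  tab <- rbind(mk_table(c(0, 1, 2), rep("T1", 3)),
               mk_table(c(10, 11, 12), rep("single", 3),
                        sprintf("C%d", 1:3)))
  for (f in multimodal_feature_names())
    tab[[f]] <- tab[[f]] + stats::rnorm(6, 0, 0.01)
  pca <- run_pca(tab)
  res <- compare_pc1_groups(pca, time_points = "T1")
  expect_equal(res$p, 0.1)  # 3 vs 3 fully separated
})
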