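test_that("CPM normalization scales columns to 1e6 and preserves proportions", {
  m <- cbind(s1 = c(A = 10, B = 90), s2 = c(A = 25, B = 25))
  norm <- normalize_counts(m)
  expect_equal(unname(norm[, "s1"]), c(1e5, 9e5))
  expect_equal(unname(colSums(norm)), c(1e6, 1e6))
  expect_equal(normalize_counts(2 * m), norm) # scale invariance

  bad <- cbind(s1 = c(A = 1, B = 2), s2 = c(A = 0, B = 0))
  expect_error(normalize_counts(bad), "s2")
})

test_that("ratios follow the pseudocount-then-normalize convention", {
  # equal raw counts and totals -> ratio 0
  m <- cbind(nuc = c(A = 50, B = 50), cyt = c(A = 50, B = 50))
  pairs <- data.frame(numerator = "nuc", denominator = "cyt")
  r <- compute_ratios(m, pairs, min_reads = 0)
  expect_equal(r$log2_ratio, c(0, 0))

  # nuc 0 / cyt 31 with equal post-pseudocount totals: log2(0.5/31.5)
  m <- cbind(nuc = c(A = 0, B = 31), cyt = c(A = 31, B = 0))
  r <- compute_ratios(m, pairs, min_reads = 0)
  expect_equal(r[r$tile_id == "A", ]$log2_ratio, log2(0.5 / 31.5),
               tolerance = 1e-12)

  # ratio strictly increases with the numerator count, all else fixed
  vals <- vapply(c(5, 10, 20, 40), function(n) {
    m <- cbind(nuc = c(A = n, B = 100 - n), cyt = c(A = 50, B = 50))
    compute_ratios(m, pairs, min_reads = 0)[tile_id == "A"]$log2_ratio
  }, numeric(1))
  expect_true(all(diff(vals) > 0))

  expect_error(compute_ratios(m, data.frame(numerator = "nuc",
                                            denominator = "missing")),
               "absent")
})

test_that("ratios are antisymmetric under swapping the fractions", {
  set.seed(5)
  m <- matrix(rpois(40, 100), nrow = 20,
              dimnames = list(paste0("t", 1:20), c("nuc", "cyt")))
  fwd <- compute_ratios(m, data.frame(numerator = "nuc", denominator = "cyt"),
                        min_reads = 0)
  rev <- compute_ratios(m, data.frame(numerator = "cyt", denominator = "nuc"),
                        min_reads = 0)
  expect_equal(fwd$log2_ratio, -rev$log2_ratio)
})

test_that("the min-reads filter requires both members of a pair", {
  m <- cbind(nuc = c(A = 25, B = 10), cyt = c(A = 30, B = 100))
  r <- compute_ratios(m, data.frame(numerator = "nuc", denominator = "cyt"),
                      min_reads = 20)
  expect_equal(r$tile_id, "A")
})

test_that("localization calls apply the joint threshold and alpha rule", {
  tab <- data.table::rbindlist(lapply(list(
    list(id = "cyto_tile", r = c(-0.9, -1.0, -1.1)),
    list(id = "weak_tile", r = c(-0.15, -0.2, -0.25)),
    list(id = "noisy_tile", r = c(2.5, 0.4, -0.2)),
    list(id = "nuc_tile", r = c(0.8, 0.9, 1.0))
  ), function(x) data.table::data.table(tile_id = x$id, replicate = 1:3,
                                        log2_ratio = x$r)))
  calls <- call_localized_tiles(tab, threshold = 0.3, alpha = 0.05)
  cls <- setNames(calls$class, calls$tile_id)

  # median -1.0 and one-sample t-test P ~ 0.0033
  expect_equal(unname(cls["cyto_tile"]), "cytoplasmic")
  expect_lt(calls[calls$tile_id == "cyto_tile", ]$p_value, 0.05)
  # median -0.2: inside the threshold band regardless of P
  expect_equal(unname(cls["weak_tile"]), "unclassified")
  expect_lt(calls[calls$tile_id == "weak_tile", ]$p_value, 0.05)
  # median beyond threshold but P > alpha
  expect_gt(calls[calls$tile_id == "noisy_tile", ]$median_log2_ratio, 0.3)
  expect_gt(calls[calls$tile_id == "noisy_tile", ]$p_value, 0.05)
  expect_equal(unname(cls["noisy_tile"]), "unclassified")
  expect_equal(unname(cls["nuc_tile"]), "nuclear")

  # single replicate: threshold only, P absent
  one <- call_localized_tiles(
    data.table::data.table(tile_id = "x", replicate = 1, log2_ratio = -0.8))
  expect_equal(one$class, "cytoplasmic")
  expect_true(is.na(one$p_value))
})

test_that("classification respects the joint rule on random tables", {
  set.seed(123)
  for (i in 1:20) {
    tab <- data.table::data.table(
      tile_id = rep(paste0("t", 1:15), each = 3),
      replicate = rep(1:3, 15),
      log2_ratio = rnorm(45, sd = 0.8))
    calls <- call_localized_tiles(tab)
    for (j in seq_len(nrow(calls))) {
      med <- calls$median_log2_ratio[j]; p <- calls$p_value[j]
      expected <- if (med < -0.3 && !is.na(p) && p < 0.05) "cytoplasmic"
        else if (med > 0.3 && !is.na(p) && p < 0.05) "nuclear"
        else "unclassified"
      expect_equal(calls$class[j], expected)
    }
  }
})

test_that("rank-sum comparison is exact for small untied groups", {
  same <- group_comparison(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$p_value, 1)

  sep <- group_comparison(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(sep$p_value, 0.1) # 2 of the C(6,3)=20 rankings are this extreme

  expect_error(group_comparison(1:3, rep("a", 3)), "two non-empty groups")
})

test_that("rank-sum P matches exhaustive enumeration at n1=n2=4", {
  set.seed(11)
  for (i in 1:15) {
    x <- sample(1:50, 4); y <- sample(51:100, 4) - sample(0:60, 4)
    vals <- c(x, y)
    if (anyDuplicated(vals)) next
    got <- group_comparison(vals, rep(c("a", "b"), each = 4))$p_value
    expect_equal(got, oracle_wilcoxon_p(x, y))
  }
})

test_that("gc_content counts G and C bases", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GATC"), 0.5)
  expect_error(gc_content(""), "empty")
})

test_that("context correlations are Spearman on shared tiles", {
  set.seed(9)
  a <- data.frame(tile_id = paste0("t", 1:20),
                  median_log2_ratio = rnorm(20))
  b <- data.frame(tile_id = paste0("t", 1:20),
                  median_log2_ratio = -a$median_log2_ratio)
  mat <- context_correlation(list(ctx1 = a, ctx1b = a, ctx2 = b))
  expect_equal(unname(diag(mat)), c(1, 1, 1))
  expect_equal(mat["ctx1", "ctx1b"], 1)
  expect_equal(mat["ctx1", "ctx2"], -1)
  expect_equal(mat, t(mat))

  # definitional oracle: rank then Pearson
  c2 <- data.frame(tile_id = paste0("t", 1:20),
                   median_log2_ratio = rnorm(20))
  m2 <- context_correlation(list(x = a, y = c2))
  expect_equal(m2["x", "y"],
               cor(rank(a$median_log2_ratio), rank(c2$median_log2_ratio)))

  few <- data.frame(tile_id = c("t1", "t2"), median_log2_ratio = c(0, 1))
  expect_message(m3 <- context_correlation(list(x = a, y = few)),
                 "shared tiles")
  expect_true(is.na(m3["x", "y"]))
})
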