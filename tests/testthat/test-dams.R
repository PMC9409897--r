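# DAM statistics: normalisation, tests, calls, summaries.

small_table <- function(values_by_sample, conditions, features = NULL) {
  x <- do.call(cbind, values_by_sample)
  rownames(x) <- if (is.null(features)) paste0("F", seq_len(nrow(x))) else features
  design <- tibble::tibble(
    sample = colnames(x), condition = conditions,
    replicate = ave(seq_along(conditions), conditions, FUN = seq_along)
  )
  feature_table(x, design)
}

test_that("median-scale normalisation is a fixed point on equal-median samples", {
  x <- matrix(c(1, 2, 3, 10, 1, 2, 3, 10), ncol = 2,
    dimnames = list(paste0("F", 1:4), c("s1", "s2")))
  ft <- feature_table(x, tibble::tibble(
    sample = c("s1", "s2"), condition = c("A", "B"), replicate = c(1L, 1L)
  ))
  out <- normalize_intensities(ft)
  expect_equal(out$intensities, x)
  expect_equal(unname(attr(out, "scale_factors")), c(1, 1))
})

test_that("a doubled sample recovers a scale factor of one half", {
  base <- c(5, 10, 20, 40)
  x <- cbind(s1 = base, s2 = base, s3 = 2 * base)
  rownames(x) <- paste0("F", 1:4)
  ft <- feature_table(x, tibble::tibble(
    sample = paste0("s", 1:3), condition = c("A", "A", "B"),
    replicate = c(1L, 2L, 1L)
  ))
  out <- normalize_intensities(ft)
  expect_equal(unname(attr(out, "scale_factors")["s3"]), 0.5)
  expect_equal(out$intensities[, "s3"], base, ignore_attr = TRUE)
})

test_that("an all-zero sample aborts normalisation by name", {
  x <- cbind(s1 = c(1, 2), s2 = c(0, 0))
  rownames(x) <- c("F1", "F2")
  ft <- feature_table(x, tibble::tibble(
    sample = c("s1", "s2"), condition = c("A", "B"), replicate = c(1L, 1L)
  ))
  expect_error(normalize_intensities(ft), "s2")
})

test_that("normalisation leaves planted log2 fold changes essentially unchanged", {
  ftt <- make_feature_table(n_features = 200, n_dams_per_pair = 20, seed = 21)
  raw <- call_significant(pairwise_dam_test(ftt$table, "C5", "C6"))
  norm <- call_significant(pairwise_dam_test(normalize_intensities(ftt$table), "C5", "C6"))
  expect_lt(max(abs(raw$log2_fold_change - norm$log2_fold_change)), 0.01 + 0.05)
  # and the planted effects are recovered near their nominal size
  truth <- ftt$truth[ftt$truth$comparison == "C5 vs C6" & ftt$truth$true_dam, ]
  est <- norm$log2_fold_change[match(truth$feature, norm$feature)]
  expect_lt(median(abs(est - truth$true_log2fc)), 0.35)
})

test_that("identical group values give FC 1 and p 1", {
  ft <- small_table(
    list(a1 = c(4, 8), a2 = c(4, 8), b1 = c(4, 8), b2 = c(4, 8)),
    c("A", "A", "B", "B")
  )
  res <- pairwise_dam_test(ft, "A", "B")
  expect_equal(res$fold_change, c(1, 1))
  expect_equal(res$log2_fold_change, c(0, 0))
  expect_equal(res$p_value, c(1, 1))
})

test_that("the Welch p-value matches the closed-form computation", {
  a <- c(29.1, 30.2, 30.7)
  b <- c(9.6, 10.1, 10.3)
  ft <- small_table(
    list(a1 = a[1], a2 = a[2], a3 = a[3], b1 = b[1], b2 = b[2], b3 = b[3]),
    c("A", "A", "A", "B", "B", "B"), features = "F1"
  )
  res <- pairwise_dam_test(ft, "A", "B")
  expect_equal(res$fold_change, mean(a) / mean(b), tolerance = 1e-12)
  expect_equal(res$log2_fold_change, log2(mean(a) / mean(b)), tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)
  # closed form on the log2 scale
  la <- log2(a)
  lb <- log2(b)
  s2a <- var(la) / 3
  s2b <- var(lb) / 3
  tstat <- (mean(la) - mean(lb)) / sqrt(s2a + s2b)
  df <- (s2a + s2b)^2 / (s2a^2 / 2 + s2b^2 / 2)
  expect_equal(res$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-12)
})

test_that("A-means 30 vs B-means 10 gives log2FC near 1.585", {
  set.seed(5)
  a <- 30 + rnorm(3, 0, 1e-3)
  b <- 10 + rnorm(3, 0, 1e-3)
  ft <- small_table(
    list(a1 = a[1], a2 = a[2], a3 = a[3], b1 = b[1], b2 = b[2], b3 = b[3]),
    c("A", "A", "A", "B", "B", "B"), features = "F1"
  )
  res <- pairwise_dam_test(ft, "A", "B")
  expect_equal(res$log2_fold_change, log2(3), tolerance = 1e-3)
  expect_lt(res$p_value, 1e-6)
})

test_that("swapping the comparison negates log2FC and preserves p", {
  ftt <- make_feature_table(n_features = 60, n_dams_per_pair = 10, seed = 8)
  ab <- pairwise_dam_test(ftt$table, "C5", "C6")
  ba <- pairwise_dam_test(ftt$table, "C6", "C5")
  expect_equal(ab$log2_fold_change, -ba$log2_fold_change, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  # direction antisymmetry of flagged counts
  sab <- summarize_dams(call_significant(ab))$comparisons
  sba <- summarize_dams(call_significant(ba))$comparisons
  expect_identical(sab$n_up, sba$n_down)
  expect_identical(sab$n_down, sba$n_up)
})

test_that("Welch p-values track a permutation oracle on moderate samples", {
  set.seed(33)
  n <- 6
  diffs <- numeric(10)
  for (k in 1:10) {
    a <- rnorm(n, ifelse(k <= 5, 0.8, 0), 1)
    b <- rnorm(n, 0, 1)
    vals <- setNames(as.list(2^c(a, b) * 1e4), paste0("s", 1:(2 * n)))
    ft <- small_table(vals, rep(c("A", "B"), each = n), features = "F1")
    res <- pairwise_dam_test(ft, "A", "B")
    la <- log2(2^a * 1e4)
    lb <- log2(2^b * 1e4)
    pooled <- c(la, lb)
    obs <- abs(mean(la) - mean(lb))
    perm <- replicate(2000, {
      idx <- sample(2 * n, n)
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    })
    p_perm <- (1 + sum(perm >= obs - 1e-12)) / 2001
    diffs[k] <- abs(res$p_value - p_perm)
  }
  expect_lt(mean(diffs), 0.06)
  expect_lt(max(diffs), 0.2)
})

test_that("significance thresholds are inclusive at the boundary", {
  dams <- tibble::tibble(
    feature = c("a", "b", "c", "d"),
    metabolite = feature, class = "unknown", comparison = "A vs B",
    log2_fold_change = c(0.5, 0.499, -0.5, 0),
    p_value = c(0.05, 0.01, 0.050001, 0.2),
    direction = c("up", "up", "down", "up")
  )
  out <- call_significant(dams)
  expect_identical(out$significant, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("raising thresholds never increases the significant count", {
  ftt <- make_feature_table(n_features = 150, n_dams_per_pair = 25, seed = 13)
  dams <- pairwise_dam_test(ftt$table, "C5", "C6")
  n_sig <- function(lfc, a) sum(call_significant(dams, lfc, a)$significant)
  base <- n_sig(0.5, 0.05)
  expect_lte(n_sig(1.0, 0.05), base)
  expect_lte(n_sig(0.5, 0.01), base)
  expect_lte(n_sig(2.0, 0.001), min(n_sig(2.0, 0.05), n_sig(0.5, 0.001)))
})

test_that("summaries count and percentage correctly and conserve totals", {
  dams <- tibble::tibble(
    feature = paste0("F", 1:10), metabolite = feature,
    class = c(rep("sphingolipids", 3), rep("unknown", 7)),
    comparison = "A vs B",
    log2_fold_change = c(2, 1, -1, 2, 2, 0.1, 0.1, -0.1, 0.2, 0),
    p_value = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.5, 0.5, 0.5, 0.5, 0.5),
    direction = ifelse(log2_fold_change < 0, "down", "up")
  )
  s <- summarize_dams(call_significant(dams))
  cmp <- s$comparisons
  expect_identical(cmp$n_significant, 5L)
  expect_identical(cmp$n_up + cmp$n_down, cmp$n_significant)
  expect_equal(cmp$percent_up, 80)
  expect_equal(cmp$percent_down, 20)
  expect_identical(sum(s$classes$n), 5L)
  # empty input gives zeros
  s0 <- summarize_dams(call_significant(dams[0, ]))
  expect_identical(s0$n_significant_total, 0L)
})

test_that("set comparison partitions common and specific members", {
  out <- compare_dam_sets(list(X = c("a", "b", "c"), Y = c("b", "c", "d")))
  expect_identical(out$counts$n[out$counts$region == "common"], 2L)
  expect_identical(out$counts$n[out$counts$region == "specific_X"], 1L)
  expect_identical(out$counts$n[out$counts$region == "specific_Y"], 1L)
  disj <- compare_dam_sets(list(X = c("a"), Y = c("b")))
  expect_false("common" %in% disj$counts$region)
})

test_that("identical rows merge first at height zero", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9), d = c(5, 1, 0))
  hc <- hierarchical_cluster(m)
  expect_equal(hc$height[1], 0)
  expect_setequal(abs(hc$merge[1, ]), c(1, 2)) # rows a and b
})

test_that("merge heights equal the brute-force agglomeration oracle", {
  set.seed(42)
  m <- matrix(rnorm(15), nrow = 5, dimnames = list(letters[1:5], NULL))
  hc <- hierarchical_cluster(m)
  expect_equal(hc$height, brute_force_average_linkage(m), tolerance = 1e-12)
})

test_that("clustering is invariant to column permutation and rejects NaN", {
  set.seed(4)
  m <- matrix(rnorm(18), nrow = 6, dimnames = list(paste0("r", 1:6), NULL))
  h1 <- hierarchical_cluster(m)
  h2 <- hierarchical_cluster(m[, c(3, 1, 2)])
  expect_equal(h1$height, h2$height)
  expect_identical(h1$merge, h2$merge)
  m[2, 2] <- NaN
  expect_error(hierarchical_cluster(m), "r2")
})

test_that("PCA separates planted condition clusters and canonicalises signs", {
  ftt <- make_feature_table(n_features = 120, n_dams_per_pair = 30, seed = 17)
  p <- pca_scores(ftt$table)
  expect_lte(sum(p$variance_explained), 1 + 1e-9)
  # silhouette of condition labels on the first two PCs is positive
  sc <- as.matrix(p$scores[, c("PC1", "PC2")])
  lab <- p$scores$condition
  d <- as.matrix(dist(sc))
  sil <- vapply(seq_along(lab), function(i) {
    a <- mean(d[i, lab == lab[i] & seq_along(lab) != i])
    b <- min(vapply(setdiff(unique(lab), lab[i]), function(l) mean(d[i, lab == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
  # sign convention: the largest-magnitude loading on each PC is positive
  for (j in 1:2) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
})

test_that("two well-separated clusters put most variance on component 1", {
  set.seed(3)
  x <- cbind(
    matrix(2^(16 + rnorm(40 * 3, 0, 0.1)), ncol = 3),
    matrix(2^(c(rep(20, 20), rep(12, 20)) + rnorm(40 * 3, 0, 0.1)), ncol = 3)
  )
  colnames(x) <- paste0("s", 1:6)
  rownames(x) <- paste0("F", 1:40)
  ft <- feature_table(x, tibble::tibble(
    sample = colnames(x), condition = rep(c("A", "B"), each = 3),
    replicate = rep(1:3, 2)
  ))
  p <- pca_scores(ft)
  expect_gt(p$variance_explained[["PC1"]], 0.5)
})

test_that("degenerate PCA input yields zero variance beyond the first component", {
  x <- matrix(rep(c(1e5, 2e5, 3e5), 4), ncol = 4,
    dimnames = list(paste0("F", 1:3), paste0("s", 1:4)))
  ft <- feature_table(x, tibble::tibble(
    sample = colnames(x), condition = rep("A", 4), replicate = 1:4
  ))
  p <- pca_scores(ft)
  expect_lt(sum(p$variance_explained, na.rm = TRUE), 1e-9 + 1)
  expect_true(all(abs(as.matrix(p$scores[, -(1:2)])) < 1e-9))
  expect_error(pca_scores(x[, 1:2, drop = FALSE]), "3 samples")
})

test_that("volcano coordinates conserve counts and cap extreme p-values", {
  ftt <- make_feature_table(n_features = 100, n_dams_per_pair = 20, seed = 19)
  dams <- call_significant(pairwise_dam_test(ftt$table, "C5", "C6"))
  vd <- volcano_data(dams)
  q <- attr(vd, "quadrant_counts")
  expect_identical(sum(q$n), nrow(dams))
  s <- summarize_dams(dams)$comparisons
  expect_identical(
    q$n[q$status == "significant-up"] %||% 0L, s$n_up
  )
  # p = 0 is capped
  dams$p_value[1] <- 0
  vd0 <- volcano_data(dams)
  expect_equal(max(vd0$neg_log10_p), 300)
})

test_that("ANOVA with identical groups gives F near 0 and p near 1", {
  # every condition sees the same three replicate values: group means are
  # equal, within-group variance is not
  reps <- c(0.9e5, 1.0e5, 1.3e5)
  vals <- as.list(rep(reps, times = 3))
  names(vals) <- paste0("s", 1:9)
  ft <- small_table(vals, rep(c("A", "B", "C"), each = 3), features = "F1")
  res <- anova_tukey(ft)
  expect_lt(max(res$f_statistic), 1e-20)
  expect_true(all(res$p_adjusted > 0.999))
})

test_that("a 5-sigma shifted group is flagged in both of its Tukey pairs", {
  set.seed(6)
  sigma <- 0.3
  mk <- function(shift) 2^(16 + shift + rnorm(1, 0, sigma))
  vals <- c(
    lapply(1:3, function(i) mk(5 * sigma)),
    lapply(1:3, function(i) mk(0)),
    lapply(1:3, function(i) mk(0))
  )
  vals <- lapply(vals, function(v) v) # one feature per sample row
  names(vals) <- paste0("s", 1:9)
  ft <- small_table(vals, rep(c("A", "B", "C"), each = 3), features = "F1")
  res <- anova_tukey(ft)
  pa <- res$p_adjusted[grepl("A", res$comparison)]
  pn <- res$p_adjusted[!grepl("A", res$comparison)]
  expect_true(all(pa < 0.05))
  expect_true(all(pn > 0.05))
})

test_that("Tukey adjusted p-values agree with a permutation oracle on a fixture", {
  set.seed(9)
  vals <- as.list(2^(16 + c(1.2, 1.4, 1.1, 0.1, -0.1, 0, 0.2, 0, -0.2)))
  names(vals) <- paste0("s", 1:9)
  grp <- rep(c("A", "B", "C"), each = 3)
  ft <- small_table(vals, grp, features = "F1")
  res <- anova_tukey(ft)
  # permutation oracle for the A-B contrast: max-t null over relabelings
  y <- log2(unlist(vals))
  obs <- abs(mean(y[grp == "A"]) - mean(y[grp == "B"]))
  perm <- replicate(4000, {
    g <- sample(grp)
    max(
      abs(mean(y[g == "A"]) - mean(y[g == "B"])),
      abs(mean(y[g == "A"]) - mean(y[g == "C"])),
      abs(mean(y[g == "B"]) - mean(y[g == "C"]))
    )
  })
  p_perm <- (1 + sum(perm >= obs - 1e-12)) / 4001
  p_tukey <- res$p_adjusted[res$comparison %in% c("B vs A", "A vs B")]
  expect_lt(abs(p_tukey - p_perm), 0.1)
})
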