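test_that("nrmsd is RMSD about the mean over the mean", {
  expect_equal(nrmsd(c(0.5, 0.5, 0.5)), 0)
  expect_equal(nrmsd(c(0, 1)), 1.0)
  expect_error(nrmsd(0.5), "at least 2")
  expect_error(nrmsd(c(0.1, NA)), "missing")
  ## population RMSD, not sample sd: (1,2,3) -> sqrt(2/3)/2
  expect_equal(nrmsd(c(1, 2, 3)), sqrt(2 / 3) / 2)
  ## scale invariance
  set.seed(4)
  x <- runif(10, 0.1, 1)
  expect_equal(nrmsd(3.7 * x), nrmsd(x))
  ## zero mean with spread is undefined
  expect_true(is.na(nrmsd(c(-1, 1))))
  ## range normalization alternative
  expect_equal(nrmsd(c(0, 1), normalizer = "range"), 0.5)
})

test_that("matrix scaling z-scores rows or columns with guards", {
  m <- rbind(a = c(1, 2, 3), b = c(10, 20, 30))
  expect_equal(unname(scale_matrix(m, "row")[1, ]), c(-1, 0, 1))
  expect_equal(unname(scale_matrix(m, "row")[2, ]), c(-1, 0, 1))
  ## idempotent up to numerical tolerance
  s <- scale_matrix(m, "row")
  expect_equal(scale_matrix(s, "row"), s, tolerance = 1e-12)
  ## constant rows map to zeros, with a warning
  m2 <- rbind(c(5, 5, 5), c(1, 2, 3))
  expect_warning(s2 <- scale_matrix(m2, "row"), "zero-variance")
  expect_equal(unname(s2[1, ]), c(0, 0, 0))
  ## column scaling
  expect_equal(unname(scale_matrix(m, "column")[, 1]),
               (c(1, 10) - 5.5) / sd(c(1, 10)))
})

test_that("PCA contributions sum to 100 and match an eigen oracle", {
  set.seed(12)
  m <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("x", "y", "z")))
  res <- pca_contributions(m, center = TRUE, scale = TRUE)
  expect_equal(unname(colSums(res$contributions)),
               rep(100, ncol(res$contributions)), tolerance = 1e-9)
  expect_equal(sum(res$explained_variance), 100, tolerance = 1e-9)
  ## oracle: eigendecomposition of the correlation matrix
  eig <- eigen(cor(m))
  expect_equal(abs(unname(res$loadings)), abs(eig$vectors),
               tolerance = 1e-8)
  expect_equal(res$explained_variance,
               100 * eig$values / sum(eig$values), tolerance = 1e-8)
  ## two perfectly correlated columns: PC1 explains everything
  m2 <- cbind(a = 1:5, b = 2 * (1:5) + 3)
  res2 <- pca_contributions(m2, center = TRUE, scale = TRUE)
  expect_equal(res2$explained_variance[1], 100, tolerance = 1e-9)
  ## constant column with scaling is an error naming the column
  m3 <- cbind(a = 1:4, flat = rep(2, 4))
  expect_error(pca_contributions(m3), "flat")
  ## missing values are imputed to column means
  m4 <- m; m4[2, 1] <- NA
  expect_message(pca_contributions(m4), "imputing")
})

test_that("Dunn z matches the hand-derived rank statistic", {
  res <- kruskal_dunn(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3))
  ## mean ranks 2 and 5; z = 3 / sqrt((6*7/12) * (2/3))
  expect_equal(abs(res$comparisons$z), 3 / sqrt((6 * 7 / 12) * (2 / 3)),
               tolerance = 1e-12)
  expect_equal(abs(res$comparisons$z), 1.964, tolerance = 1e-3)
  ## two identical groups: z = 0, p = 1
  res2 <- kruskal_dunn(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  expect_equal(res2$comparisons$z, 0)
  expect_equal(res2$comparisons$p, 1)
  ## all values tied across groups gives the degenerate H = 0 case
  res3 <- kruskal_dunn(rep(7, 6), rep(c("A", "B"), each = 3))
  expect_equal(res3$kw_statistic, 0)
  expect_equal(res3$comparisons$z, 0)
  expect_equal(res3$comparisons$p, 1)
  expect_error(kruskal_dunn(1:5, rep("A", 5)), "2 groups")
})

test_that("Dunn z is invariant under monotone transformations", {
  set.seed(77)
  for (i in 1:10) {
    x <- rnorm(30)
    g <- sample(c("a", "b", "c"), 30, replace = TRUE)
    if (length(unique(g)) < 3) next
    z1 <- kruskal_dunn(x, g)$comparisons$z
    z2 <- kruskal_dunn(exp(x), g)$comparisons$z
    expect_equal(z1, z2, tolerance = 1e-12)
  }
})

test_that("the tie correction follows the Dunn formula", {
  x <- c(1, 1, 2, 3, 3, 3, 4, 5)
  g <- rep(c("A", "B"), each = 4)
  res <- kruskal_dunn(x, g)
  N <- 8
  r <- rank(x)
  ties <- table(x)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  z_hand <- (mean(r[g == "A"]) - mean(r[g == "B"])) /
    sqrt((N * (N + 1) / 12 - Tcorr) * (1 / 4 + 1 / 4))
  expect_equal(res$comparisons$z, z_hand, tolerance = 1e-12)
  ## the omnibus H agrees with the base R implementation
  expect_equal(res$kw_statistic,
               unname(kruskal.test(x, factor(g))$statistic))
})

test_that("Holm adjustment is applied across the pairwise table", {
  set.seed(2)
  x <- c(rnorm(8), rnorm(8) + 3, rnorm(8))
  g <- rep(c("a", "b", "c"), each = 8)
  res <- kruskal_dunn(x, g, p_adjust = "holm")
  expect_equal(res$comparisons$p_adjusted,
               p.adjust(res$comparisons$p, "holm"))
  res_bh <- kruskal_dunn(x, g, p_adjust = "BH")
  expect_equal(res_bh$comparisons$p_adjusted,
               p.adjust(res_bh$comparisons$p, "BH"))
})

test_that("NRMSD matrices flag GANTC as the least variable motif", {
  p <- small_panel()
  freq <- methylation_frequency(
    p$truth, by = c("strain_id", "motif_label", "region"), complete = TRUE)
  nm <- nrmsd_matrix(freq, group = "region")
  expect_true(all(rowMeans(nm, na.rm = TRUE)["GANTC"] <=
                    rowMeans(nm, na.rm = TRUE)))
  expect_true(all(nm >= 0, na.rm = TRUE))
  expect_identical(attr(nm, "normalizer"), "mean")
})
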