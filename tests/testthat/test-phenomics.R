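make_panel <- function(nS = 6, nM = 3, seed = 13, noise = 1) {
  set.seed(seed)
  df <- expand.grid(strain = paste0("s", seq_len(nS)),
                    must = paste0("m", seq_len(nM)),
                    stringsAsFactors = FALSE)
  for (tr in c("lp", "v50_80", "co2max", "glycerol", "acetic_acid"))
    df[[tr]] <- rnorm(nrow(df), 10, noise) + 3 * (df$must == "m1")
  df
}

test_that("per-must normalization centers and scales each trait", {
  df <- make_panel()
  norm <- normalize_by_must(df, c("lp", "glycerol"))
  for (m in unique(norm$must)) {
    expect_equal(mean(norm$lp[norm$must == m]), 0, tolerance = 1e-9)
    expect_equal(sd(norm$lp[norm$must == m]), 1, tolerance = 1e-9)
  }
  expect_equal(normalize_by_must(norm, c("lp", "glycerol")), norm,
               tolerance = 1e-12)    # idempotent
  # the toy example {1,2,3} -> {-1,0,1}
  toy <- data.frame(must = "m", strain = letters[1:3], x = 1:3)
  expect_equal(normalize_by_must(toy, "x")$x, c(-1, 0, 1))
  dfz <- df; dfz$lp[dfz$must == "m1"] <- 4
  expect_error(normalize_by_must(dfz, "lp"), "zero variance.*m1")
})

test_that("Spearman correlations capture monotone association", {
  set.seed(2)
  x <- rnorm(30)
  df <- data.frame(a = x, b = 2 * x, c = rnorm(30))
  cm <- correlation_matrix(df)
  expect_equal(cm$rho["a", "b"], 1)
  expect_true(cm$significant["a", "b"])
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(unname(diag(cm$rho)), rep(1, 3))
  dfc <- df; dfc$c <- 5
  cmc <- correlation_matrix(dfc)
  expect_equal(cmc$flagged, "c")
  expect_true(is.na(cmc$rho["a", "c"]))
})

test_that("PCA axis variances equal correlation-matrix eigenvalues", {
  set.seed(3)
  x <- matrix(rnorm(24), 6, 4, dimnames = list(NULL, paste0("t", 1:4)))
  pca <- pca_phenotypes(as.data.frame(x))
  ev <- eigen(cor(x), symmetric = TRUE)$values   # independent eigensolver
  expect_equal(pca$sdev^2, ev, tolerance = 1e-9)
  expect_equal(sum(pca$percent_variance), 100, tolerance = 1e-9)
  # two perfectly correlated standardized variables: one axis carries all
  df2 <- data.frame(a = 1:6, b = 2 * (1:6) + 3)
  expect_equal(pca_phenotypes(df2)$percent_variance[1], 100)
  # permutation-invariance to observation order
  perm <- sample(6)
  pca2 <- pca_phenotypes(as.data.frame(x[perm, ]))
  expect_equal(pca2$percent_variance, pca$percent_variance)
  expect_error(pca_phenotypes(data.frame(a = 1:6, b = 1)), "zero-variance")
})

test_that("strain dispersion averages pairwise Euclidean distances", {
  df <- data.frame(strain = c("a", "b"), must = "m",
                   x = c(0, 3), y = c(0, 4))
  d <- strain_dispersion(df, list(k = c("x", "y")))
  expect_equal(d$mean_distance, 5)          # the 3-4-5 triangle
  dfi <- data.frame(strain = letters[1:4], must = "m", x = 1, y = 1)
  expect_equal(strain_dispersion(dfi, list(k = c("x", "y")))$mean_distance,
               0)
  # brute-force pair enumeration oracle
  set.seed(4)
  dfr <- data.frame(strain = letters[1:5], must = "m",
                    x = rnorm(5), y = rnorm(5), z = rnorm(5))
  d5 <- strain_dispersion(dfr, list(k = c("x", "y", "z")))
  pairs <- combn(5, 2)
  manual <- mean(apply(pairs, 2, function(ij)
    sqrt(sum((dfr[ij[1], 3:5] - dfr[ij[2], 3:5])^2))))
  expect_equal(d5$mean_distance, manual)
  expect_equal(d5$n_pairs, 10)
  expect_error(strain_dispersion(dfr, list(k = character(0))), "at least one")
})

test_that("rank matrices are per-trait permutations clustered sensibly", {
  df <- data.frame(strain = c("s1", "s2", "s3"), a = c(5, 2, 9),
                   b = c(1, 2, 3))
  rc <- suppressWarnings(rank_clustermap(df, c("a", "b")))
  expect_equal(unname(rc$ranks[, "a"]), c(2, 1, 3))
  expect_true(all(sort(rc$ranks[, "b"]) == 1:3))
  # two tight pairs: the dendrogram pairs them, heights match the naive
  # complete-linkage agglomeration
  df4 <- data.frame(strain = paste0("s", 1:4),
                    a = c(10, 11, 30, 31), b = c(5, 6, 20, 21),
                    c = c(4, 2, 9, 7))
  rc4 <- suppressWarnings(rank_clustermap(df4, c("a", "b", "c")))
  m <- rc4$hclust$merge
  expect_true(any(apply(m, 1, function(r) setequal(r, c(-1, -2)))))
  expect_true(any(apply(m, 1, function(r) setequal(r, c(-3, -4)))))
  expect_equal(sort(rc4$merge_heights),
               sort(complete_linkage_heights(rc4$ranks)))
  expect_error(rank_clustermap(df4[1, ], c("a", "b")), "at least 2")
})

test_that("redundant trait pairs trigger the collinearity warning", {
  df <- data.frame(strain = paste0("s", 1:6), a = 1:6, b = (1:6) * 2,
                   c = c(3, 1, 4, 1, 5, 9))
  expect_warning(rank_clustermap(df, c("a", "b", "c")), "correlated")
})

test_that("robustness splits strains into fluctuating quartile and robust rest", {
  set.seed(9)
  nS <- 8
  df <- expand.grid(strain = paste0("s", seq_len(nS)),
                    must = paste0("m", 1:4), stringsAsFactors = FALSE)
  df$x <- rnorm(nrow(df), 10, 0.2)
  df$x[df$strain == "s1"] <- c(5, 15, 8, 12)  # wildly must-dependent
  df$x[df$strain == "s2"] <- 10               # constant: perfectly robust
  df$y <- rnorm(nrow(df), 3, 0.3)
  rb <- robustness_analysis(df, c("x", "y"))
  expect_equal(rb$fluct_size, 2)              # round(0.25 * 8)
  expect_equal(unname(colSums(rb$fluctuating)), c(2, 2))
  expect_true(rb$fluctuating["s1", "x"])
  expect_false(rb$fluctuating["s2", "x"])
  expect_equal(unname(rb$variance["s2", "x"]), 0)
  # variance invariant to per-strain constant shifts, quadratic in scale
  df2 <- df; df2$x[df2$strain == "s3"] <- df2$x[df2$strain == "s3"] + 100
  rb2 <- robustness_analysis(df2, c("x", "y"))
  expect_equal(rb2$variance["s3", "x"], rb$variance["s3", "x"])
  df3 <- df; df3$x <- df3$x * 3
  rb3 <- robustness_analysis(df3, c("x", "y"))
  expect_equal(unname(rb3$variance[, "x"]), unname(9 * rb$variance[, "x"]))
  expect_error(robustness_analysis(df[df$must == "m1", ], c("x", "y")),
               "at least 2 musts")
})
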