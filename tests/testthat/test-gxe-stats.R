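test_that("a single-factor contrast gets 100% of the explained SS", {
  df <- random_balanced_table(nS = 2, nM = 2, nO = 2, reps = 2)
  df$value <- as.numeric(df$must == "m1")   # noise-free must contrast
  dec <- fit_lm1(df)
  expect_equal(dec$percent[dec$terms == "Must"], 100)
  expect_lt(max(abs(dec$percent[dec$terms != "Must"])), 1e-9)
})

test_that("sequential SS agree with the brute-force mean decomposition", {
  set.seed(101)
  for (i in 1:5) {
    df <- random_balanced_table(nS = sample(2:4, 1), nM = 2, nO = 2,
                                reps = sample(2:5, 1), effect = 0.5)
    dec <- fit_lm1(df)
    oracle <- lm1_oracle(df)
    expect_lt(max(abs(dec$percent - oracle[dec$terms])), 1e-9)
    expect_equal(sum(dec$percent), 100, tolerance = 1e-12)
  }
})

test_that("the decomposition matches anova(lm) and is order-invariant when balanced", {
  set.seed(7)
  df <- random_balanced_table(nS = 3, reps = 3, effect = 1)
  dec <- fit_lm1(df)
  df$mox <- factor(df$mox)
  a1 <- anova(lm(value ~ strain + must + mox + strain:must + strain:mox,
                 data = df))
  expect_equal(unname(dec$ss),
               unname(a1[c("strain", "must", "mox", "strain:must",
                           "strain:mox", "Residuals"), "Sum Sq"]),
               tolerance = 1e-10)
  # balanced: a different term order gives identical per-term SS
  a2 <- anova(lm(value ~ mox + must + strain + strain:mox + strain:must,
                 data = df))
  expect_equal(a1["strain", "Sum Sq"], a2["strain", "Sum Sq"])
  sm2 <- rownames(a2)[grepl("strain", rownames(a2)) &
                        grepl("must", rownames(a2))]
  expect_equal(a1["strain:must", "Sum Sq"], a2[sm2, "Sum Sq"])
})

test_that("degenerate trait tables are refused with informative errors", {
  df <- random_balanced_table()
  df1 <- df[!(df$strain == "s1" & df$must == "m2"), ]
  expect_error(fit_lm1(df1), "empty design cell.*s1.*m2")
  dfc <- df; dfc$value <- 1
  expect_error(fit_lm1(dfc), "zero total variance")
  dfu <- df[-1, ]
  expect_warning(fit_lm1(dfu), "unbalanced")
})

test_that("permutation p-values hit the floor for overwhelming effects", {
  df <- random_balanced_table(nS = 3, reps = 4)
  df$value <- df$value * 0.01 + 10 * (df$must == "m1")
  pv <- permutation_pvalues(df, n_perm = 200, seed = 31)
  expect_equal(pv$p_value[pv$term == "Must"], 1 / 201)
  pv2 <- permutation_pvalues(df, n_perm = 200, seed = 31)
  expect_identical(pv, pv2)     # same seed, same p
  expect_error(permutation_pvalues(df, n_perm = 100),
               "seed is required")
})

test_that("compact letter display separates what Tukey separates", {
  set.seed(5)
  v <- c(rnorm(6, 0, 0.01), rnorm(6, 0, 0.01), rnorm(6, 10, 0.01))
  g <- rep(c("g1", "g2", "g3"), each = 6)
  lt <- tukey_letters(v, g)
  expect_equal(unname(lt["g3"]), "a")      # highest mean gets "a"
  expect_equal(unname(lt["g1"]), unname(lt["g2"]))
  expect_false(lt["g3"] == lt["g1"])
  # identical groups share one letter
  lt0 <- tukey_letters(rep(c(1, 1, 1), each = 4), rep(c("a", "b", "c"),
                                                      each = 4))
  expect_true(all(lt0 == "a"))
})

test_that("letter sharing equals pairwise Tukey non-significance (graded groups)", {
  set.seed(8)
  for (rep in 1:3) {
    means <- cumsum(runif(4, 0.5, 2.5))
    v <- rnorm(40, rep(means, each = 10), 1)
    g <- rep(paste0("g", 1:4), each = 10)
    lt <- tukey_letters(v, g)
    oracle <- tukey_pairwise_oracle(v, g)
    share <- function(a, b)
      length(intersect(strsplit(lt[[a]], "")[[1]],
                       strsplit(lt[[b]], "")[[1]])) > 0
    for (nm in names(oracle)) {
      ab <- strsplit(nm, "|", fixed = TRUE)[[1]]
      expect_equal(share(ab[1], ab[2]), oracle[[nm]] > 0.05,
                   info = paste("pair", nm, "rep", rep))
    }
  }
})

test_that("Wilcoxon comparison behaves at the boundaries", {
  expect_equal(wilcoxon_compare(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  w <- wilcoxon_compare(1:10, 101:110)
  expect_lt(w$p_value, 0.001)
  expect_true(w$significant)
  # rank statistic invariant under monotone transforms of pooled data
  a <- rnorm(8); b <- rnorm(8) + 1
  expect_equal(wilcoxon_compare(a, b)$statistic,
               wilcoxon_compare(exp(a), exp(b))$statistic)
  # fully tied data carries no signal
  expect_equal(wilcoxon_compare(rep(2, 5), rep(2, 5))$p_value, 1)
})

test_that("CV tables measure relative replicate spread", {
  df <- data.frame(strain = rep(c("a", "b"), each = 6),
                   condition = rep(c("c1", "c2"), each = 3, times = 2),
                   t1 = c(9, 10, 11, 9, 10, 11, 5, 5, 5, 4, 4, 4))
  df$t2 <- df$t1 * 2
  cv <- cv_table(df, c("t1", "t2"))
  cell <- cv$per_cell
  a_c1 <- cell[cell$strain == "a" & cell$condition == "c1" &
                 cell$trait == "t1", ]
  expect_equal(a_c1$cv, 10)     # sd 1, mean 10
  b_cells <- cell[cell$strain == "b" & cell$trait == "t1", ]
  expect_true(all(b_cells$cv == 0))        # identical replicates
  # scale invariance: t2 = 2 * t1 has the same CVs
  expect_equal(cell$cv[cell$trait == "t1"], cell$cv[cell$trait == "t2"])
  # zero mean is flagged, not an error
  df$t3 <- rep(c(-1, 0, 1), 4)
  cv3 <- cv_table(df, "t3")
  expect_true(any(cv3$per_cell$flag == "ZERO_MEAN"))
})

test_that("exact CV example: replicates {9,10,11} give 10%", {
  df <- data.frame(strain = "a", condition = "c", val = c(9, 10, 11))
  cv <- cv_table(df, "val")
  expect_equal(cv$per_cell$cv, 10)
})
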