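# Shared fixtures and independent oracles used across the test files.

# a weighing record tracing a pure (lag-free) logistic CO2 curve
make_logistic_record <- function(A = 93.508, k = 0.1, tm = 40,
                                 times = seq(0, 100, by = 4),
                                 volume_ml = 5, noise_sd = 0,
                                 vial_id = "vx") {
  co2 <- A / (1 + exp(-k * (times - tm)))
  w <- 20 - co2 * volume_ml / 1000
  if (noise_sd > 0) w <- w + rnorm(length(w), 0, noise_sd)
  fermentation_record(vial_id, "S1", "M1", FALSE, volume_ml, 1L, times, w)
}

# closed-form kinetic traits of the pure logistic above
logistic_truth <- function(A = 93.508, k = 0.1, tm = 40, tco2max = A,
                           lag = 2) {
  inv <- function(c) tm - log(A / c - 1) / k
  lp <- inv(lag)
  list(lp = lp, t35 = inv(0.35 * tco2max) - lp,
       t50 = inv(0.50 * tco2max) - lp, t80 = inv(0.80 * tco2max) - lp,
       v50_80 = (0.30 * tco2max / 0.482) /
         (inv(0.80 * tco2max) - inv(0.50 * tco2max)))
}

# brute-force sequential-SS oracle for the two-way-interaction model on a
# BALANCED design: marginal/cell mean decomposition computed from scratch
lm1_oracle <- function(df, response = "value") {
  y <- df[[response]]
  g <- mean(y)
  mS <- tapply(y, df$strain, mean)[as.character(df$strain)]
  mM <- tapply(y, df$must, mean)[as.character(df$must)]
  mO <- tapply(y, df$mox, mean)[as.character(df$mox)]
  kSM <- interaction(df$strain, df$must)
  kSO <- interaction(df$strain, df$mox)
  mSM <- tapply(y, kSM, mean)[as.character(kSM)]
  mSO <- tapply(y, kSO, mean)[as.character(kSO)]
  ss <- c(Strain = sum((mS - g)^2),
          Must = sum((mM - g)^2),
          MicroOxygenation = sum((mO - g)^2),
          `Strain:Must` = sum((mSM - mS - mM + g)^2),
          `Strain:MicroOxygenation` = sum((mSO - mS - mO + g)^2))
  tot <- sum((y - g)^2)
  c(ss, Residual = tot - sum(ss)) / tot * 100
}

# a random balanced strain x must x mox trait table
random_balanced_table <- function(nS = 3, nM = 2, nO = 2, reps = 4,
                                  effect = 0) {
  df <- expand.grid(replicate = seq_len(reps),
                    mox = c(FALSE, TRUE)[seq_len(nO)],
                    must = paste0("m", seq_len(nM)),
                    strain = paste0("s", seq_len(nS)),
                    stringsAsFactors = FALSE)
  df$value <- rnorm(nrow(df)) +
    effect * (df$must == "m1") * as.integer(factor(df$strain))
  df
}

# pairwise Tukey HSD p-values computed from first principles (studentized
# range on the one-way fit), independent of stats::TukeyHSD
tukey_pairwise_oracle <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ni <- tapply(values, groups, length)
  mi <- tapply(values, groups, mean)
  dfres <- length(values) - k
  mse <- sum((values - mi[as.character(groups)])^2) / dfres
  out <- list()
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    se <- sqrt(mse / 2 * (1 / ni[i] + 1 / ni[j]))
    q <- abs(mi[i] - mi[j]) / se
    out[[paste(levels(groups)[i], levels(groups)[j], sep = "|")]] <-
      unname(ptukey(q, k, dfres, lower.tail = FALSE))
  }
  unlist(out)
}

# naive complete-linkage agglomeration: returns successive merge heights
complete_linkage_heights <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- 0L
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}
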