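#' @keywords internal
#' Validate an LM1 trait table and build the fixed design decomposition.
#' Returns the lm fit plus everything needed to recompute sequential SS
#' for arbitrary (permuted) responses through the same QR factorization.
.lm1_design <- function(data, response = "value") {
  need <- c("strain", "must", "mox")
  if (!"mox" %in% names(data) && "shaking" %in% names(data))
    data$mox <- data$shaking
  miss <- setdiff(c(need, response), names(data))
  if (length(miss))
    stop("trait table lacks column(s): ", paste(miss, collapse = ", "))
  df <- data.frame(strain = factor(data$strain), must = factor(data$must),
                   mox = factor(data$mox), y = as.numeric(data[[response]]))
  if (any(is.na(df$y))) stop("missing trait values are not allowed")
  for (f in need)
    if (nlevels(df[[f]]) < 2L)
      stop("factor '", f, "' needs at least 2 levels")
  for (pair in list(c("strain", "must"), c("strain", "mox"))) {
    tab <- table(df[[pair[1L]]], df[[pair[2L]]])
    if (any(tab == 0L)) {
      w <- which(tab == 0L, arr.ind = TRUE)[1L, ]
      stop("empty design cell: ", pair[1L], "=", rownames(tab)[w[1L]],
           ", ", pair[2L], "=", colnames(tab)[w[2L]])
    }
  }
  cell <- table(df$strain, df$must, df$mox)
  if (length(unique(as.vector(cell))) > 1L)
    warning("unbalanced design: sequential sums of squares depend on term order")
  fit <- stats::lm(y ~ strain + must + mox + strain:must + strain:mox,
                   data = df)
  qrx <- fit$qr
  p <- qrx$rank
  asgn <- fit$assign[qrx$pivot[seq_len(p)]]
  list(fit = fit, df = df, qr = qrx, p = p, asgn = asgn,
       n = nrow(df),
       term_labels = c("Strain", "Must", "MicroOxygenation",
                       "Strain:Must", "Strain:MicroOxygenation"))
}

# sequential SS (model terms + residual) for each column of the response
# matrix Y, through a fixed QR: identical to anova(lm(...)) term by term
.lm1_ss <- function(dsn, Y) {
  Y <- as.matrix(Y)
  qty <- qr.qty(dsn$qr, Y)
  head <- qty[seq_len(dsn$p), , drop = FALSE]
  keep <- dsn$asgn > 0            # drop the intercept component
  ssm <- rowsum((head[keep, , drop = FALSE])^2, dsn$asgn[keep])
  rss <- colSums(qty[-seq_len(dsn$p), , drop = FALSE]^2)
  list(terms = ssm, residual = rss)
}

#' Decompose a trait's variance into strain, must and oxygenation terms
#'
#' Fits the two-way-interaction linear model
#' `y = m + Strain + Must + MOX + Strain:Must + Strain:MOX + e`
#' to a vial-level trait table and reports each term's share of the total
#' sum of squares. Sequential (Type I) sums of squares are used; on the
#' balanced factorials this model is designed for they are independent of
#' term order (an unbalanced table triggers a warning). With `n_perm > 0`
#' the omnibus significance of every term is assessed by a permutation
#' test ([permutation_pvalues()]) rather than the normal-theory F test.
#'
#' @param data Data frame with columns `strain`, `must`, `mox` (or
#'   `shaking`) and the response.
#' @param response Name of the trait column. Default `"value"`.
#' @param n_perm Number of permutations for p-values; 0 (default) skips
#'   them.
#' @param seed Integer seed, required when `n_perm > 0`.
#' @param trait Optional trait name stored in the result.
#' @return An object of class `lm1_fit`: list with `trait`, `terms`
#'   (term labels incl. `Residual`), `ss`, `df`, `percent` (shares of
#'   total SS, summing to 100), `p_value` (NA-filled when `n_perm = 0`;
#'   the residual has no p-value), `n_perm`, `fit` (the underlying `lm`).
#' @examples
#' ex <- simulate_experiment(simulation_design(replicates = 3),
#'                           curves = FALSE)
#' fit_lm1(ex$traits, response = "glycerol")
#' @export
fit_lm1 <- function(data, response = "value", n_perm = 0, seed = NULL,
                    trait = response) {
  dsn <- .lm1_design(data, response)
  if (stats::var(dsn$df$y) == 0)
    stop("trait '", trait, "' has zero total variance")
  ss <- .lm1_ss(dsn, dsn$df$y)
  ss_terms <- as.vector(ss$terms)
  # terms absent from the pivoted range (rank-deficient) get zero SS
  ss_full <- numeric(5)
  ss_full[as.integer(rownames(ss$terms))] <- ss_terms
  total <- sum(ss_full) + ss$residual
  if (total <= 0) stop("trait '", trait, "' has zero total variance")
  df_terms <- table(factor(dsn$asgn[dsn$asgn > 0], levels = 1:5))
  df_res <- dsn$n - dsn$p
  pv <- rep(NA_real_, 5)
  if (n_perm > 0)
    pv <- permutation_pvalues(data, response = response, n_perm = n_perm,
                              seed = seed)$p_value
  structure(list(trait = trait,
                 terms = c(dsn$term_labels, "Residual"),
                 ss = c(ss_full, ss$residual),
                 df = c(as.vector(df_terms), df_res),
                 percent = 100 * c(ss_full, ss$residual) / total,
                 p_value = c(pv, NA_real_),
                 n_perm = n_perm, fit = dsn$fit),
            class = "lm1_fit")
}

#' Significance stars for p-values
#'
#' `***` below 0.001, `**` below 0.01, `*` below 0.05, `.` below 0.1.
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.1] <- "."
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out
}

#' @export
print.lm1_fit <- function(x, digits = 1, ...) {
  cat("Variance decomposition for trait '", x$trait, "'\n", sep = "")
  tab <- data.frame(term = x$terms, df = x$df,
                    percent = round(x$percent, digits),
                    p = signif(x$p_value, 3),
                    sig = significance_stars(x$p_value))
  print(tab, row.names = FALSE)
  if (x$n_perm > 0)
    cat("p-values from", x$n_perm, "response permutations\n")
  invisible(x)
}

#' @export
summary.lm1_fit <- function(object, ...) object

#' @export
coef.lm1_fit <- function(object, ...)
  stats::setNames(object$percent, object$terms)

#' Variance decomposition table across many traits
#'
#' Runs [fit_lm1()] for each trait column and assembles the familiar
#' ANOVA summary layout: one column per trait, one row per model term,
#' each cell a percent of total SS with a permutation significance star.
#'
#' @inheritParams fit_lm1
#' @param traits Character vector of trait column names.
#' @return List of class `lm1_table` with `percent` (terms x traits
#'   matrix), `p_value` (same shape), `stars`, `fits`.
#' @export
lm1_table <- function(data, traits, n_perm = 0, seed = NULL) {
  fits <- lapply(traits, function(tr)
    fit_lm1(data, response = tr, n_perm = n_perm,
            seed = if (is.null(seed)) NULL else seed, trait = tr))
  names(fits) <- traits
  pct <- sapply(fits, `[[`, "percent")
  pv <- sapply(fits, `[[`, "p_value")
  rownames(pct) <- rownames(pv) <- fits[[1L]]$terms
  structure(list(percent = pct, p_value = pv,
                 stars = apply(pv, 2, significance_stars), fits = fits),
            class = "lm1_table")
}

#' @export
print.lm1_table <- function(x, digits = 1, ...) {
  disp <- matrix(paste0(format(round(x$percent, digits)),
                        ifelse(x$stars == "", "",
                               paste0(" ", x$stars))),
                 nrow = nrow(x$percent), dimnames = dimnames(x$percent))
  print(as.data.frame(disp))
  invisible(x)
}

#' Permutation p-values for the LM1 terms
#'
#' For every term of the strain/must/oxygenation model, compares the
#' observed F statistic with its distribution under random permutation of
#' the response values across all vials:
#' `p = (1 + #{F_perm >= F_obs}) / (n_perm + 1)`. All permutations reuse
#' a single QR factorization of the fixed design, so the sequential sums
#' of squares are exactly those of the original fit.
#'
#' @inheritParams fit_lm1
#' @param n_perm Number of permutations. Default 5000.
#' @param seed Integer seed (required: permutation tests must be
#'   reproducible).
#' @return Data frame with `term`, `F`, `p_value`.
#' @export
permutation_pvalues <- function(data, response = "value", n_perm = 5000,
                                seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for permutation p-values")
  dsn <- .lm1_design(data, response)
  y <- dsn$df$y
  if (stats::var(y) == 0)
    stop("zero total variance: no permutation test possible")
  df_terms <- as.vector(table(factor(dsn$asgn[dsn$asgn > 0], levels = 1:5)))
  df_res <- dsn$n - dsn$p
  if (df_res <= 0) stop("no residual degrees of freedom")
  fstat <- function(ss) {
    ssm <- matrix(0, 5, ncol(ss$terms))
    ssm[as.integer(rownames(ss$terms)), ] <- ss$terms
    sweep(ssm / df_terms, 2, ss$residual / df_res, "/")
  }
  f_obs <- fstat(.lm1_ss(dsn, y))[, 1L]
  set.seed(as.integer(seed %% 2147483647))
  exceed <- numeric(5)
  block <- 500L
  done <- 0L
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    Y <- vapply(seq_len(b), function(i) y[sample.int(dsn$n)],
                numeric(dsn$n))
    f_perm <- fstat(.lm1_ss(dsn, Y))
    exceed <- exceed + rowSums(f_perm >= f_obs)
    done <- done + b
  }
  data.frame(term = dsn$term_labels, F = f_obs,
             p_value = (1 + exceed) / (n_perm + 1))
}

#' Compact letter display from Tukey's HSD
#'
#' All-pairs Tukey honest-significant-difference comparisons on a one-way
#' least-squares fit, summarized as a compact letter display: groups that
#' share a letter do not differ significantly at `alpha`. Letters are
#' built by the insert-and-absorb algorithm and assigned in order of
#' decreasing group mean (the highest mean gets "a").
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor).
#' @param alpha Familywise significance level. Default 0.05.
#' @return Named character vector: one letter string per group, named by
#'   group level, ordered by decreasing group mean. Attribute `"tukey"`
#'   carries the underlying pairwise table.
#' @examples
#' set.seed(1)
#' tukey_letters(c(rnorm(5), rnorm(5), rnorm(5) + 10),
#'               rep(c("g1", "g2", "g3"), each = 5))
#' @export
tukey_letters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("at least 2 groups are required")
  if (any(table(groups) < 1L)) stop("every group needs at least one value")
  if (length(values) - nlevels(groups) < 1L)
    stop("no residual degrees of freedom for Tukey's HSD")
  fit <- stats::aov(values ~ groups)
  hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  means <- sort(tapply(values, groups, mean), decreasing = TRUE)
  g <- names(means)
  k <- length(g)
  # significance lookup from the pairwise table
  pair_p <- function(a, b) {
    nm <- rownames(hsd)
    i <- match(paste(a, b, sep = "-"), nm)
    if (is.na(i)) i <- match(paste(b, a, sep = "-"), nm)
    hsd[i, "p adj"]
  }
  cols <- list(rep(TRUE, k))             # start: one letter for everyone
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    p_ij <- pair_p(g[i], g[j])
    if (is.na(p_ij) || p_ij > alpha) next   # NaN: no residual variance, no signal
    hit <- vapply(cols, function(cl) cl[i] && cl[j], logical(1))
    if (!any(hit)) next
    new <- list()
    for (ci in seq_along(cols)) {
      if (!hit[ci]) { new <- c(new, cols[ci]); next }
      a <- cols[[ci]]; a[i] <- FALSE
      b <- cols[[ci]]; b[j] <- FALSE
      new <- c(new, list(a, b))
    }
    # absorb: drop columns whose group set is contained in another's
    keep <- rep(TRUE, length(new))
    for (ci in seq_along(new)) for (cj in seq_along(new)) {
      if (ci == cj || !keep[ci]) next
      if (all(!new[[ci]] | new[[cj]]) &&
          (any(new[[cj]] & !new[[ci]]) || cj < ci))
        keep[ci] <- FALSE
    }
    cols <- new[keep]
  }
  ord <- order(vapply(cols, function(cl) which(cl)[1L], integer(1)))
  cols <- cols[ord]
  letters_out <- vapply(seq_len(k), function(gi)
    paste(letters[which(vapply(cols, `[`, logical(1), gi))], collapse = ""),
    character(1))
  names(letters_out) <- g
  attr(letters_out, "tukey") <- hsd
  letters_out
}

#' Wilcoxon-Mann-Whitney comparison of two samples
#'
#' Two-sided rank-sum test: exact null distribution for small samples
#' without ties, normal approximation with tie correction otherwise.
#' Samples that are completely tied across both groups carry no signal
#' and return p = 1 rather than an error.
#'
#' @param sample_a,sample_b Numeric vectors (non-empty).
#' @param alpha Significance level for the `significant` flag. Default
#'   0.05.
#' @return List with `statistic` (Mann-Whitney W), `p_value`,
#'   `significant`.
#' @export
wilcoxon_compare <- function(sample_a, sample_b, alpha = 0.05) {
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be non-empty")
  pooled <- c(sample_a, sample_b)
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = length(sample_a) * length(sample_b) / 2,
                p_value = 1, significant = FALSE))
  }
  wt <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       significant = wt$p.value <= alpha)
}

#' Replicate coefficient-of-variation table
#'
#' Measurement reliability audit: for every strain x condition x trait
#' cell, the coefficient of variation across replicates
#' (`CV% = 100 sd/mean`); per condition and trait, the CV averaged over
#' strains; and per condition the "cumulated CV" -- the per-trait average
#' CVs summed over traits, the height of the stacked reliability bar
#' chart.
#'
#' @param data Vial-level data frame.
#' @param traits Character vector of trait columns.
#' @param strain,condition Names of the strain and condition columns.
#'   Defaults `"strain"` and `"condition"`.
#' @return Object of class `cv_table`: list with `per_cell` (strain,
#'   condition, trait, n, mean, sd, cv; `cv` is `NA` with `flag
#'   "ZERO_MEAN"` where the cell mean is 0), `per_condition` (condition,
#'   trait, average cv) and `cumulated` (condition, summed cv).
#' @export
cv_table <- function(data, traits, strain = "strain",
                     condition = "condition") {
  miss <- setdiff(c(strain, condition, traits), names(data))
  if (length(miss))
    stop("data lacks column(s): ", paste(miss, collapse = ", "))
  key <- interaction(data[[strain]], data[[condition]], drop = TRUE)
  if (any(table(key) < 2L))
    stop("every strain x condition cell needs >= 2 replicates")
  rows <- do.call(rbind, lapply(traits, function(tr) {
    m <- tapply(data[[tr]], key, mean)
    s <- tapply(data[[tr]], key, stats::sd)
    n <- tapply(data[[tr]], key, length)
    ks <- strsplit(names(m), ".", fixed = TRUE)
    data.frame(strain = vapply(ks, `[`, "", 1L),
               condition = vapply(ks, `[`, "", 2L),
               trait = tr, n = as.vector(n), mean = as.vector(m),
               sd = as.vector(s),
               cv = ifelse(m == 0, NA_real_, 100 * as.vector(s) / abs(m)),
               flag = ifelse(m == 0, "ZERO_MEAN", ""),
               stringsAsFactors = FALSE)
  }))
  ok <- rows[!is.na(rows$cv), , drop = FALSE]
  if (nrow(ok)) {
    agg <- stats::aggregate(cv ~ condition + trait, data = ok, FUN = mean)
    cum <- stats::aggregate(cv ~ condition, data = agg, FUN = sum)
  } else {
    agg <- data.frame(condition = character(0), trait = character(0),
                      cv = numeric(0))
    cum <- data.frame(condition = character(0), cv = numeric(0))
  }
  names(cum)[2L] <- "cumulated_cv"
  structure(list(per_cell = rows, per_condition = agg, cumulated = cum),
            class = "cv_table")
}

#' @export
print.cv_table <- function(x, ...) {
  cat("Replicate CV summary (cumulated CV% per condition):\n")
  print(x$cumulated, row.names = FALSE)
  invisible(x)
}
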