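#' Center and scale traits within each must
#'
#' Removes the dominating must (medium) effect from a per-(strain, must)
#' phenotype table: within each must, every trait column is centered and
#' scaled to unit sample standard deviation, so strains are compared on
#' their relative behaviour in each environment. Note that this transform
#' deliberately hides strain-by-must interactions.
#'
#' @param data Data frame of per-(strain, must) trait values (typically
#'   replicate means), with a must column and trait columns.
#' @param traits Character vector of trait column names.
#' @param must Name of the must column. Default `"must"`.
#' @return `data` with the trait columns replaced by their within-must
#'   z-scores.
#' @export
normalize_by_must <- function(data, traits, must = "must") {
  miss <- setdiff(c(must, traits), names(data))
  if (length(miss))
    stop("data lacks column(s): ", paste(miss, collapse = ", "))
  out <- data
  for (m in unique(data[[must]])) {
    idx <- data[[must]] == m
    if (sum(idx) < 2L)
      stop("must ", m, " has fewer than 2 strains")
    for (tr in traits) {
      v <- data[[tr]][idx]
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0)
        stop("trait '", tr, "' has zero variance within must ", m)
      out[[tr]][idx] <- (v - mean(v)) / s
    }
  }
  out
}

#' Spearman correlation matrix with significance mask
#'
#' Pairwise Spearman rank correlations between traits (average ranks for
#' ties) with a significance mask from `cor.test` at the requested level.
#' Constant traits yield `NA` correlations and are reported in the
#' `flagged` field instead of erroring.
#'
#' @param data Data frame or matrix of observations x traits.
#' @param traits Optional character vector selecting trait columns;
#'   default: all numeric columns.
#' @param alpha Significance level for the mask. Default 0.05.
#' @return Object of class `trait_cor`: list with `rho` (symmetric, unit
#'   diagonal), `p_value`, `significant` (logical mask, diagonal `NA`),
#'   `alpha`, `n`, `flagged` (names of constant traits).
#' @export
correlation_matrix <- function(data, traits = NULL, alpha = 0.05) {
  if (is.null(traits))
    traits <- names(data)[vapply(data, is.numeric, logical(1))]
  x <- as.matrix(as.data.frame(data)[, traits, drop = FALSE])
  if (nrow(x) < 4L) stop("at least 4 observations are required")
  flagged <- traits[apply(x, 2, function(v) stats::sd(v) == 0)]
  k <- ncol(x)
  rho <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(rho) <- dimnames(p) <- list(traits, traits)
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    if (traits[i] %in% flagged || traits[j] %in% flagged) {
      rho[i, j] <- rho[j, i] <- NA_real_
      next
    }
    ct <- suppressWarnings(stats::cor.test(x[, i], x[, j],
                                           method = "spearman"))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  sig <- p <= alpha
  structure(list(rho = rho, p_value = p, significant = sig, alpha = alpha,
                 n = nrow(x), flagged = flagged),
            class = "trait_cor")
}

#' @export
print.trait_cor <- function(x, digits = 2, ...) {
  cat(sprintf("Spearman correlations over %d observations (alpha = %g)\n",
              x$n, x$alpha))
  disp <- round(x$rho, digits)
  disp[!is.na(x$significant) & !x$significant] <- NA
  print(disp, na.print = ".")
  if (length(x$flagged))
    cat("constant traits (no correlation defined):",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Principal component analysis of a phenotype table
#'
#' PCA on centered, unit-variance trait columns. Variable loadings are
#' reported as trait-axis correlations, the quantities drawn on a
#' correlation circle, and each axis's share of total variance sums to
#' 100.
#'
#' @param data Data frame or matrix of observations x traits.
#' @param traits Optional trait column selection (default: all numeric
#'   columns).
#' @return Object of class `pheno_pca`: `scores` (observations x axes),
#'   `loadings` (trait-axis correlations), `percent_variance`, `sdev` and
#'   the underlying `prcomp` fit.
#' @export
pca_phenotypes <- function(data, traits = NULL) {
  if (is.null(traits))
    traits <- names(data)[vapply(data, is.numeric, logical(1))]
  x <- as.matrix(as.data.frame(data)[, traits, drop = FALSE])
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("at least 2 observations and 2 traits are required")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance trait(s): ",
         paste(traits[sds == 0], collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  loadings <- stats::cor(scale(x), pc$x)
  structure(list(scores = pc$x, loadings = loadings,
                 percent_variance = pct, sdev = pc$sdev, prcomp = pc),
            class = "pheno_pca")
}

#' @export
print.pheno_pca <- function(x, ...) {
  cat("PCA of", nrow(x$scores), "observations x", nrow(x$loadings),
      "traits\n")
  cat("axis variance (%):",
      paste(sprintf("%.1f", x$percent_variance[seq_len(min(5,
        length(x$percent_variance)))]), collapse = ", "), "...\n")
  invisible(x)
}

#' @param x A `pheno_pca` object.
#' @param axes Two axes to draw. Default `c(1, 2)`.
#' @param groups Optional factor coloring the score points.
#' @param ... Further plot arguments.
#' @rdname pca_phenotypes
#' @export
plot.pheno_pca <- function(x, axes = c(1, 2), groups = NULL, ...) {
  sc <- x$scores[, axes, drop = FALSE]
  col <- if (is.null(groups)) "black" else as.integer(factor(groups))
  graphics::plot(sc, col = col, pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", axes[1L],
                                x$percent_variance[axes[1L]]),
                 ylab = sprintf("PC%d (%.1f%%)", axes[2L],
                                x$percent_variance[axes[2L]]), ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}

#' Within-must strain dispersion
#'
#' How well an environment separates strains: for each must and each
#' trait class (e.g. kinetic vs metabolic), the mean Euclidean distance
#' between all unordered pairs of strains in the standardized trait
#' subspace. Larger values mean the must spreads the strains further
#' apart, i.e. discriminates them better.
#'
#' @param data Per-(strain, must) table on the normalized layer (see
#'   [normalize_by_must()]).
#' @param trait_classes Named list of character vectors partitioning the
#'   trait columns into classes.
#' @param strain,must Column names. Defaults `"strain"`, `"must"`.
#' @return Data frame with `must`, `class`, `mean_distance`, `n_pairs`.
#' @export
strain_dispersion <- function(data, trait_classes, strain = "strain",
                              must = "must") {
  if (!length(trait_classes) || any(!lengths(trait_classes)))
    stop("every trait class must contain at least one trait")
  miss <- setdiff(c(strain, must, unlist(trait_classes)), names(data))
  if (length(miss))
    stop("data lacks column(s): ", paste(miss, collapse = ", "))
  out <- expand.grid(must = unique(data[[must]]),
                     class = names(trait_classes),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- t(apply(out, 1, function(row) {
    sub <- data[data[[must]] == row[["must"]],
                trait_classes[[row[["class"]]]], drop = FALSE]
    d <- stats::dist(as.matrix(sub))
    c(mean_distance = mean(d), n_pairs = length(d))
  }))
  cbind(out, as.data.frame(res))
}

#' Strain rank matrix with hierarchical clustering
#'
#' Ranks every strain 1..n within each trait (ascending, average ranks
#' for ties) and clusters strains on the rank matrix by complete-linkage
#' agglomeration with Euclidean distance -- each trait thereby gets equal
#' weight in the clustering regardless of scale. Strongly redundant
#' traits would double-weight one underlying axis, so pairwise Spearman
#' correlations above `redundancy_rho` trigger a warning suggesting a
#' trait subset.
#'
#' @param data Per-strain table (one row per strain, typically cross-must
#'   means of normalized values).
#' @param traits Trait columns to rank.
#' @param strain Strain column name. Default `"strain"`.
#' @param redundancy_rho Absolute Spearman correlation above which a
#'   trait pair is flagged as redundant. Default 0.8.
#' @return Object of class `rank_clustermap`: `ranks` (strains x traits),
#'   `hclust`, `order` (leaf order, strain labels), `merge_heights`.
#' @export
rank_clustermap <- function(data, traits, strain = "strain",
                            redundancy_rho = 0.8) {
  miss <- setdiff(c(strain, traits), names(data))
  if (length(miss))
    stop("data lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) < 2L) stop("at least 2 strains are required")
  if (anyDuplicated(data[[strain]]))
    stop("expected one row per strain")
  x <- as.matrix(data[, traits, drop = FALSE])
  rownames(x) <- data[[strain]]
  if (length(traits) > 1L) {
    rho <- stats::cor(x, method = "spearman")
    high <- abs(rho) > redundancy_rho & upper.tri(rho)
    if (any(high)) {
      w <- which(high, arr.ind = TRUE)
      warning("strongly correlated trait pair(s) in rank clustering: ",
              paste(traits[w[, 1]], traits[w[, 2]], sep = "~",
                    collapse = ", "))
    }
  }
  ranks <- apply(x, 2, rank, ties.method = "average")
  rownames(ranks) <- rownames(x)
  hc <- stats::hclust(stats::dist(ranks), method = "complete")
  structure(list(ranks = ranks, hclust = hc,
                 order = rownames(ranks)[hc$order],
                 merge_heights = hc$height),
            class = "rank_clustermap")
}

#' @export
print.rank_clustermap <- function(x, ...) {
  cat("Rank matrix:", nrow(x$ranks), "strains x", ncol(x$ranks),
      "traits; complete-linkage leaf order:\n")
  cat(" ", paste(x$order, collapse = ", "), "\n")
  invisible(x)
}

#' @param x A `rank_clustermap` object.
#' @param ... Further arguments to `image`.
#' @rdname rank_clustermap
#' @export
plot.rank_clustermap <- function(x, ...) {
  ord <- x$hclust$order
  m <- x$ranks[ord, , drop = FALSE]
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  col = grDevices::hcl.colors(32, "Blue-Yellow"),
                  axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(m)), rownames(m), las = 1, cex.axis = 0.6)
  invisible(x)
}

#' Cross-must robustness analysis of a strain panel
#'
#' Quantifies how stable each strain's phenotype is across environments:
#' for every strain and trait, the sample variance of the per-must mean
#' values (computed on the raw, non-normalized layer, so strain-by-must
#' interactions are retained). Per trait, the quarter of strains with the
#' highest variance form the "fluctuating" group, the rest the "robust"
#' group; per must, the two group means are contrasted with Tukey letters
#' across the must x group cells and a Wilcoxon rank-sum test per must.
#'
#' @param data Per-(strain, must) table of raw trait means.
#' @param traits Trait columns to analyze.
#' @param strain,must Column names. Defaults `"strain"`, `"must"`.
#' @param quartile Fraction of strains classed as fluctuating; the group
#'   size is `floor(quartile * n)` so it never exceeds the stated
#'   fraction (35 strains -> 8 fluctuating, 27 robust). Default 0.25.
#' @param alpha Significance level for the group contrasts. Default 0.05.
#' @param contrasts Compute the per-must group contrasts (Tukey letters
#'   and Wilcoxon tests)? Disable for speed in simulation studies that
#'   only need the quartile membership. Default TRUE.
#' @return Object of class `robustness_report`: `variance` (strains x
#'   traits), `scaled_variance` (column z-scores, the display layer),
#'   `fluctuating` (logical strains x traits), `fluct_size`,
#'   `group_means` (trait, must, group, mean, n, Tukey letter),
#'   `wilcoxon` (trait, must, p_value, significant), `hclust` (strain
#'   clustering on the scaled variance matrix).
#' @export
robustness_analysis <- function(data, traits, strain = "strain",
                                must = "must", quartile = 0.25,
                                alpha = 0.05, contrasts = TRUE) {
  miss <- setdiff(c(strain, must, traits), names(data))
  if (length(miss))
    stop("data lacks column(s): ", paste(miss, collapse = ", "))
  strains <- unique(data[[strain]])
  musts <- unique(data[[must]])
  if (length(musts) < 2L) stop("at least 2 musts are required")
  n <- length(strains)
  q <- floor(quartile * n)
  if (q < 1L || q >= n)
    stop("quartile size ", q, " is impossible with ", n, " strains")
  variance <- sapply(traits, function(tr) {
    vapply(strains, function(s)
      stats::var(data[[tr]][data[[strain]] == s]), numeric(1))
  })
  rownames(variance) <- strains
  fluct <- apply(variance, 2, function(v)
    rank(-v, ties.method = "first") <= q)
  rownames(fluct) <- strains
  scaled <- scale(variance)
  gm <- list(); wx <- list()
  for (tr in if (contrasts) traits else character(0)) {
    grp <- ifelse(fluct[match(data[[strain]], strains), tr],
                  "fluctuating", "robust")
    cells <- interaction(data[[must]], grp, sep = ":", drop = TRUE)
    lett <- tukey_letters(data[[tr]], cells, alpha = alpha)
    mtab <- stats::aggregate(data[[tr]],
                             list(must = data[[must]], group = grp),
                             FUN = mean)
    ntab <- stats::aggregate(data[[tr]],
                             list(must = data[[must]], group = grp),
                             FUN = length)
    key <- paste(mtab$must, mtab$group, sep = ":")
    gm[[tr]] <- data.frame(trait = tr, must = mtab$must, group = mtab$group,
                           mean = mtab$x, n = ntab$x,
                           letters = unname(lett[key]),
                           stringsAsFactors = FALSE)
    wx[[tr]] <- do.call(rbind, lapply(musts, function(m) {
      sel <- data[[must]] == m
      wc <- wilcoxon_compare(data[[tr]][sel & grp == "fluctuating"],
                             data[[tr]][sel & grp == "robust"],
                             alpha = alpha)
      data.frame(trait = tr, must = m, p_value = wc$p_value,
                 significant = wc$significant, stringsAsFactors = FALSE)
    }))
  }
  structure(list(variance = variance, scaled_variance = scaled,
                 fluctuating = fluct, fluct_size = q,
                 group_means = do.call(rbind, gm),
                 wilcoxon = do.call(rbind, wx),
                 hclust = stats::hclust(stats::dist(scaled),
                                        method = "complete")),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("Robustness report: %d strains x %d traits; %d fluctuating / %d robust per trait\n",
              nrow(x$variance), ncol(x$variance), x$fluct_size,
              nrow(x$variance) - x$fluct_size))
  sig <- x$wilcoxon[x$wilcoxon$significant, c("trait", "must", "p_value")]
  if (nrow(sig)) {
    cat("musts where fluctuating and robust groups differ (Wilcoxon):\n")
    print(sig, row.names = FALSE)
  }
  invisible(x)
}
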