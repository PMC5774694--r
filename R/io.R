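.sniff_sep <- function(path)
  if (grepl("\t", readLines(path, n = 1L))) "\t" else ","

#' Read a vial weighing log
#'
#' Long-format log of manual weighings: one row per weighing, columns
#' `vial_id`, `strain`, `must`, `shaking`, `volume_mL`, `replicate`,
#' `time_h`, `weight_g` (CSV or TSV, UTF-8, `.` decimal separator).
#' Rows are sorted by time within vial; a duplicated (vial, time) pair or
#' inconsistent design labels within a vial are data-entry errors and
#' abort with the offending vial named.
#'
#' @param path Path to the log file.
#' @return Named list of [fermentation_record()]s, one per vial.
#' @seealso [write_weighing_log()] for the inverse operation.
#' @export
read_weighing_log <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                          stringsAsFactors = FALSE)
  req <- c("vial_id", "strain", "must", "shaking", "volume_mL",
           "replicate", "time_h", "weight_g")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("weighing log lacks column(s): ", paste(miss, collapse = ", "))
  recs <- lapply(split(df, df$vial_id), function(v) {
    if (anyDuplicated(v$time_h))
      stop("vial ", v$vial_id[1L], ": duplicated weighing time(s) ",
           paste(unique(v$time_h[duplicated(v$time_h)]), collapse = ", "))
    for (lab in c("strain", "must", "shaking", "volume_mL", "replicate"))
      if (length(unique(v[[lab]])) > 1L)
        stop("vial ", v$vial_id[1L], ": inconsistent '", lab,
             "' labels within the vial")
    v <- v[order(v$time_h), ]
    fermentation_record(v$vial_id[1L], v$strain[1L], v$must[1L],
                        as.logical(v$shaking[1L]), v$volume_mL[1L],
                        v$replicate[1L], v$time_h, v$weight_g)
  })
  recs[order(names(recs))]
}

#' Write a vial weighing log
#'
#' @param records List of [fermentation_record()]s.
#' @param path Output path; `.tsv` extension selects tab separation,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_weighing_log <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(r)
    data.frame(vial_id = r$vial_id, strain = r$strain, must = r$must_code,
               shaking = r$shaking, volume_mL = r$volume_ml,
               replicate = r$replicate, time_h = r$time_h,
               weight_g = r$weight_g, stringsAsFactors = FALSE)))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(rows, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a vial-level trait table
#'
#' CSV/TSV with one row per vial: design columns (`vial_id`, `strain`,
#' `must`, and optionally `shaking`/`mox`, `replicate`) plus numeric
#' trait columns.
#'
#' @param path Path to the table.
#' @return A data frame.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                          stringsAsFactors = FALSE)
  if (!any(c("vial_id", "strain") %in% names(df)))
    stop("trait table needs a 'vial_id' or 'strain' column")
  df
}

#' Assemble and validate a pipeline configuration
#'
#' A configuration is a plain named list (or the path of a YAML file
#' holding one) with elements
#' \describe{
#'   \item{weighing_log}{path to the weighing log (required unless
#'     `trait_table` alone is analyzed).}
#'   \item{trait_table}{optional path to a vial-level end-point trait
#'     table merged with the kinetic parameters on `vial_id`.}
#'   \item{must_table}{path to the must composition table; defaults to
#'     the packaged five-must panel.}
#'   \item{kinetics}{list: `span` (0.45), `grid_step` (0.1),
#'     `lag_threshold` (2).}
#'   \item{stats}{list: `n_perm` (0), `seed`, `alpha` (0.05). A positive
#'     `n_perm` without a seed is refused -- stochastic stages must be
#'     reproducible.}
#'   \item{phenomics}{list: `quartile` (0.25), `trait_classes` (named
#'     list partitioning traits into e.g. kinetic/metabolic).}
#'   \item{output_dir}{directory for the tidy CSV artifacts and run log.}
#' }
#'
#' @param config Named list or YAML file path.
#' @return Validated config list of class `experiment_config`.
#' @export
experiment_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    must_table = system.file("extdata", "grape_musts.csv",
                             package = "fermphen"),
    kinetics = list(span = 0.45, grid_step = 0.1, lag_threshold = 2),
    stats = list(n_perm = 0, seed = NULL, alpha = 0.05),
    phenomics = list(quartile = 0.25, trait_classes = NULL),
    output_dir = "fermphen-out")
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      config[[nm]] <- utils::modifyList(defaults[[nm]], config[[nm]])
  }
  if (is.null(config$weighing_log) && is.null(config$trait_table))
    stop("config needs at least one of 'weighing_log' or 'trait_table'")
  for (f in c("weighing_log", "trait_table", "must_table"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("config file does not exist: ", config[[f]])
  if (config$stats$n_perm > 0 && is.null(config$stats$seed))
    stop("config requests n_perm > 0 but no seed; refusing an unseeded stochastic stage")
  structure(config, class = c("experiment_config", "list"))
}

#' Run the full phenomics pipeline
#'
#' Executes the analysis stages in order on the configured inputs --
#' kinetics (per-vial curve fitting and parameter extraction), trait
#' assembly (kinetic + end-point traits), G-by-E variance decomposition
#' (when the design has at least two strains, musts and oxygenation
#' levels), and the multivariate stage (per-must means, normalization,
#' PCA, correlations, dispersion, rank clustering and robustness, when at
#' least two musts are present) -- and writes each result as a tidy CSV
#' into the output directory together with a run log recording stage
#' order and seeds. Stages whose design requirements are not met are
#' skipped with a log entry. Deterministic stages are bit-reproducible
#' for a fixed config.
#'
#' @param config An [experiment_config()], a plain list, or a YAML path.
#' @return Invisibly, a named list of written artifact paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "experiment_config")) config
         else experiment_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$output_dir, "run.log")
  cat("", file = logf)
  note <- function(...) cat(format(Sys.time(), "%H:%M:%OS2"), " ", ...,
                            "\n", sep = "", file = logf, append = TRUE)
  paths <- list()
  emit <- function(obj, name) {
    p <- file.path(cfg$output_dir, paste0(name, ".csv"))
    utils::write.csv(obj, p, row.names = FALSE)
    paths[[name]] <<- p
    note("wrote ", p)
  }
  musts <- read_must_table(cfg$must_table)
  note("read ", length(musts), " must compositions from ", cfg$must_table)

  traits_df <- NULL
  if (!is.null(cfg$weighing_log)) {
    note("stage kinetics: reading ", cfg$weighing_log)
    recs <- read_weighing_log(cfg$weighing_log)
    kp <- fit_kinetics_batch(recs, musts = musts,
                             span = cfg$kinetics$span,
                             grid_step = cfg$kinetics$grid_step,
                             lag_threshold = cfg$kinetics$lag_threshold)
    emit(kp, "kinetic_params")
    traits_df <- kp[, c("vial_id", "strain", "must", "shaking",
                        "replicate", "lp", "t35", "t50", "t80", "v50_80",
                        "co2max")]
  }
  if (!is.null(cfg$trait_table)) {
    et <- read_trait_table(cfg$trait_table)
    traits_df <- if (is.null(traits_df)) et else
      merge(traits_df, et[, c("vial_id",
                              setdiff(names(et), names(traits_df)))],
            by = "vial_id")
    note("assembled trait table: ", nrow(traits_df), " vials")
  }
  emit(traits_df, "trait_table")
  design_cols <- c("vial_id", "strain", "must", "shaking", "replicate")
  trait_cols <- setdiff(names(traits_df)[vapply(traits_df, is.numeric,
                                                logical(1))],
                        c(design_cols, "tco2max"))
  complete <- trait_cols[colSums(is.na(traits_df[trait_cols])) == 0L]

  # G x E stage: needs >= 2 levels of strain, must and oxygenation
  nlev <- function(v) length(unique(v))
  if (!is.null(traits_df$shaking) && nlev(traits_df$strain) >= 2 &&
      nlev(traits_df$must) >= 2 && nlev(traits_df$shaking) >= 2) {
    note("stage gxe: LM1 decomposition of ",
         length(complete), " traits, n_perm=", cfg$stats$n_perm,
         if (cfg$stats$n_perm > 0) paste0(", seed=", cfg$stats$seed) else "")
    traits_df$mox <- traits_df$shaking
    lt <- lm1_table(traits_df, complete, n_perm = cfg$stats$n_perm,
                    seed = cfg$stats$seed)
    emit(data.frame(term = rownames(lt$percent), round(lt$percent, 4),
                    check.names = FALSE), "lm1_percent")
    emit(data.frame(term = rownames(lt$p_value), lt$p_value,
                    check.names = FALSE), "lm1_pvalues")
  } else note("stage gxe skipped: needs 2+ strains, musts and oxygenation levels")

  if (nlev(traits_df$must) >= 2 && nlev(traits_df$strain) >= 2) {
    note("stage phenomics")
    agg <- stats::aggregate(traits_df[complete],
                            list(strain = traits_df$strain,
                                 must = traits_df$must), mean)
    emit(agg, "per_must_means")
    norm <- normalize_by_must(agg, complete)
    emit(norm, "normalized_means")
    pca <- pca_phenotypes(norm, complete)
    emit(data.frame(strain = norm$strain, must = norm$must,
                    round(pca$scores, 6)), "pca_scores")
    emit(data.frame(trait = rownames(pca$loadings),
                    round(pca$loadings, 6)), "pca_loadings")
    emit(data.frame(axis = seq_along(pca$percent_variance),
                    percent = round(pca$percent_variance, 4)),
         "pca_variance")
    strain_means <- stats::aggregate(norm[complete],
                                     list(strain = norm$strain), mean)
    if (nrow(strain_means) >= 4) {
      cm <- correlation_matrix(strain_means, complete,
                               alpha = cfg$stats$alpha)
      emit(data.frame(trait = rownames(cm$rho), round(cm$rho, 4)),
           "correlations")
      emit(data.frame(trait = rownames(cm$p_value),
                      round(cm$p_value, 6)), "correlation_pvalues")
    }
    classes <- cfg$phenomics$trait_classes
    if (is.null(classes)) {
      kin <- intersect(c("lp", "t35", "t50", "t80", "v50_80", "co2max"),
                       complete)
      met <- setdiff(complete, kin)
      classes <- Filter(length, list(kinetic = kin, metabolic = met))
    }
    if (length(classes))
      emit(strain_dispersion(norm, classes), "dispersion")
    q <- floor(cfg$phenomics$quartile * nrow(strain_means))
    if (q >= 1 && q < nrow(strain_means)) {
      rb <- robustness_analysis(agg, complete,
                                quartile = cfg$phenomics$quartile,
                                alpha = cfg$stats$alpha)
      emit(data.frame(strain = rownames(rb$variance),
                      round(rb$variance, 6)), "robustness_variance")
      emit(data.frame(strain = rownames(rb$fluctuating),
                      rb$fluctuating), "robustness_fluctuating")
      emit(rb$group_means, "robustness_groups")
      emit(rb$wilcoxon, "robustness_wilcoxon")
    } else note("robustness skipped: too few strains for a quartile split")
  } else note("stage phenomics skipped: needs 2+ musts and 2+ strains")
  note("pipeline complete")
  paths$log <- logf
  invisible(paths)
}
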