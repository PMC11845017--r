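#' Validate a pipeline run configuration
#'
#' Reads a YAML configuration, applies defaults, and validates it
#' strictly: unknown keys are fatal. Recognized keys:
#' \describe{
#'   \item{inputs}{named paths: \code{trial} (replicate-level table),
#'     optional \code{fragments}, \code{deg_stats}, \code{qpcr}.}
#'   \item{control_label}{control group (default \code{"CK"}).}
#'   \item{alpha}{significance level in (0, 1) (default 0.05).}
#'   \item{lfc_min}{|log2FC| screen threshold (default 1).}
#'   \item{dispersion_mode}{\code{"se"} or \code{"sd"} (default
#'     \code{"se"}).}
#'   \item{decimals}{presentation decimals (default 2).}
#'   \item{seed}{integer seed (default 1).}
#'   \item{outdir}{output directory (default \code{"amftrial_report"}).}
#'   \item{qpcr_targets, qpcr_treatment, qpcr_control,
#'     reference_gene}{qPCR stage settings.}
#' }
#'
#' @param path path to a YAML file.
#' @return A validated config list of class \code{run_config}.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("configuration error: file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration error: not a YAML mapping")
  known <- c("inputs", "control_label", "alpha", "lfc_min",
             "dispersion_mode", "decimals", "seed", "outdir",
             "qpcr_targets", "qpcr_treatment", "qpcr_control",
             "reference_gene")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("configuration error: unknown key(s): ",
         paste(unknown, collapse = ", "))
  defaults <- list(control_label = "CK", alpha = 0.05, lfc_min = 1,
                   dispersion_mode = "se", decimals = 2, seed = 1L,
                   outdir = "amftrial_report", qpcr_targets = NULL,
                   qpcr_treatment = "Fm", qpcr_control = "CK",
                   reference_gene = "actin")
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[k] <- defaults[k]
  if (is.null(cfg$inputs) || is.null(cfg$inputs$trial))
    stop("configuration error: inputs.trial is required")
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("configuration error: alpha must lie in (0, 1)")
  if (!is.numeric(cfg$lfc_min) || cfg$lfc_min < 0)
    stop("configuration error: lfc_min must be >= 0")
  if (!cfg$dispersion_mode %in% c("se", "sd"))
    stop("configuration error: dispersion_mode must be 'se' or 'sd'")
  if (!is.numeric(cfg$decimals) || cfg$decimals < 0)
    stop("configuration error: decimals must be >= 0")
  for (p in unlist(cfg$inputs))
    if (!file.exists(p))
      stop("configuration error: input path does not exist: ", p)
  cfg$config_hash <- unname(tools::md5sum(path))
  class(cfg) <- "run_config"
  cfg
}

#' Run the full evaluation pipeline
#'
#' Executes the configured stages in order -- colonization indices (if a
#' fragment table is given), per-indicator group statistics with Tukey
#' letters, percent change versus control, the membership-function
#' evaluation and ranking, then the molecular stages (DEG screen, qPCR
#' 2^-ddCt) if their inputs are given -- and writes one TSV per stage
#' plus a JSON run manifest (package version, seed, config hash) into
#' \code{config$outdir}.
#'
#' @param config a \code{run_config} from [validate_config()], or a path
#'   to a YAML file.
#' @return Invisibly, a list with the per-stage results and the vector
#'   of files written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  if (!inherits(config, "run_config"))
    stop("configuration error: expected a run_config")
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  results <- list()
  emit <- function(df, name) {
    p <- file.path(outdir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    files <<- c(files, p)
    p
  }

  if (!is.null(config$inputs$fragments)) {
    frags <- read_fragments(config$inputs$fragments)
    col <- do.call(rbind, lapply(split(frags, frags$sample_id), function(d) {
      s <- colonization_summary(d)
      data.frame(sample_id = d$sample_id[1], n_fragments = s$n_fragments,
                 F = round_half_up(s$F, config$decimals),
                 M = round_half_up(s$M, config$decimals),
                 m = round_half_up(s$m, config$decimals),
                 a = round_half_up(s$a, config$decimals),
                 A = round_half_up(s$A, config$decimals))
    }))
    rownames(col) <- NULL
    results$colonization <- col
    emit(col, "colonization")
  }

  trial <- read_trial(config$inputs$trial,
                      control_label = config$control_label)
  summ <- summarize_groups(trial, dispersion = config$dispersion_mode)
  letters_by_ind <- lapply(unique(summ$indicator), function(ind) {
    anova_letters(trial, ind, alpha = config$alpha)$letters
  })
  names(letters_by_ind) <- unique(summ$indicator)
  summ$letters <- mapply(function(tr, ind) letters_by_ind[[ind]][[tr]],
                         summ$treatment, summ$indicator)
  results$summary <- summ
  p <- file.path(outdir, "summary.tsv")
  write_summary(summ, p, digits = config$decimals)
  files <- c(files, p)

  pc <- percent_change(summ, control = config$control_label,
                       digits = config$decimals)
  results$percent_change <- pc
  emit(pc, "percent_change")

  mm <- membership_matrix(summ)
  results$membership <- mm
  mtab <- data.frame(indicator = rep(rownames(mm$mu), ncol(mm$mu)),
                     treatment = rep(colnames(mm$mu),
                                     each = nrow(mm$mu)),
                     membership = round_half_up(as.vector(mm$mu),
                                                config$decimals))
  mtab <- rbind(mtab,
                data.frame(indicator = "average_value",
                           treatment = names(mm$column_mean),
                           membership = round_half_up(mm$column_mean,
                                                      config$decimals)),
                data.frame(indicator = "rank",
                           treatment = names(mm$rank),
                           membership = mm$rank))
  emit(mtab, "membership")

  if (!is.null(config$inputs$deg_stats)) {
    degs <- screen_degs(read_deg_stats(config$inputs$deg_stats),
                        alpha = config$alpha, lfc_min = config$lfc_min)
    results$deg <- degs
    emit(degs$records, "deg_status")
  }

  if (!is.null(config$inputs$qpcr) && length(config$qpcr_targets)) {
    plate <- read_qpcr(config$inputs$qpcr,
                       reference_gene = config$reference_gene)
    qp <- do.call(rbind, lapply(config$qpcr_targets, function(g) {
      r <- relative_expression(plate, g, config$qpcr_treatment,
                               config$qpcr_control)
      data.frame(gene = g,
                 fold_change = round_half_up(r$fold_change,
                                             config$decimals),
                 ddct = round_half_up(r$ddct, 4))
    }))
    results$qpcr <- qp
    emit(qp, "qpcr")
  }

  manifest <- list(
    package = "amftrial",
    version = as.character(utils::packageVersion("amftrial")),
    seed = config$seed,
    config_hash = config$config_hash,
    control_label = config$control_label,
    alpha = config$alpha,
    lfc_min = config$lfc_min,
    dispersion_mode = config$dispersion_mode,
    ranking = rank_treatments(mm),
    files = basename(files))
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, mp)

  invisible(c(results, list(files = files)))
}
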