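#' Read a replicate-level trial table
#'
#' Reads a long-format delimited text file with header columns
#' \code{treatment}, \code{replicate}, \code{indicator}, \code{value}
#' (comma- or tab-separated, autodetected from the header line) and
#' validates it against an indicator registry.
#'
#' @param path path to a CSV/TSV file.
#' @param registry an \code{amf_registry}; defaults to
#'   \code{\link{default_indicators}}.
#' @param control_label label of the control group (default \code{"CK"}).
#' @return A data frame of class \code{amf_trial} with columns
#'   \code{treatment}, \code{replicate}, \code{indicator}, \code{value}
#'   and attributes \code{registry} and \code{control_label}.
#' @export
read_trial <- function(path, registry = default_indicators(),
                       control_label = "CK") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sniff_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, encoding = "UTF-8",
                           colClasses = "character")
  need <- c("treatment", "replicate", "indicator", "value")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  val <- suppressWarnings(as.numeric(raw$value))
  if (anyNA(val))
    stop("parse error: non-numeric value at row(s) ",
         paste(which(is.na(val)), collapse = ", "))
  rep_id <- suppressWarnings(as.integer(raw$replicate))
  if (anyNA(rep_id))
    stop("parse error: non-integer replicate at row(s) ",
         paste(which(is.na(rep_id)), collapse = ", "))
  as_trial(data.frame(treatment = raw$treatment, replicate = rep_id,
                      indicator = raw$indicator, value = val,
                      stringsAsFactors = FALSE),
           registry = registry, control_label = control_label)
}

#' Assemble a trial dataset from a data frame
#'
#' Validates replicate-level records: indicators must exist in the registry
#' and (treatment, replicate, indicator) triples must be unique.
#'
#' @param df data frame with columns \code{treatment}, \code{replicate},
#'   \code{indicator}, \code{value}.
#' @inheritParams read_trial
#' @return An \code{amf_trial} data frame.
#' @export
as_trial <- function(df, registry = default_indicators(),
                     control_label = "CK") {
  stopifnot(is.data.frame(df))
  need <- c("treatment", "replicate", "indicator", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  unknown <- setdiff(unique(df$indicator), registry$name)
  if (length(unknown))
    stop("validation error: unknown indicator(s) not in registry: ",
         paste(unknown, collapse = ", "))
  key <- paste(df$treatment, df$replicate, df$indicator, sep = "\r")
  if (anyDuplicated(key))
    stop("validation error: duplicated (treatment, replicate, indicator) ",
         "at row(s) ", paste(which(duplicated(key)), collapse = ", "))
  if (!is.numeric(df$value)) stop("parse error: value column is not numeric")
  out <- df[, need]
  attr(out, "registry") <- registry
  attr(out, "control_label") <- control_label
  class(out) <- c("amf_trial", "data.frame")
  out
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  if (grepl("\t", header)) "\t" else ","
}

#' Write and re-read group summary tables
#'
#' `write_summary()` writes a summary table (one row per treatment and
#' indicator, as produced by [summarize_groups()] and [anova_letters()])
#' as delimited text; `read_summary()` reads it back.
#'
#' @param rows non-empty data frame with columns \code{treatment},
#'   \code{indicator}, \code{n}, \code{mean}, \code{dispersion} and
#'   optionally \code{letters}.
#' @param path output file path.
#' @param sep field separator, `"\t"` (default) or `","`.
#' @param digits decimals kept for numeric columns (half-up); default 2.
#' @return `write_summary()` returns `path` invisibly; `read_summary()`
#'   returns the summary data frame.
#' @export
write_summary <- function(rows, path, sep = "\t", digits = 2) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop("summary rows must be a non-empty data frame")
  need <- c("treatment", "indicator", "n", "mean", "dispersion")
  miss <- setdiff(need, names(rows))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- rows
  if (!"letters" %in% names(out)) out$letters <- ""
  out$mean <- round_half_up(out$mean, digits)
  out$dispersion <- round_half_up(out$dispersion, digits)
  out <- out[, c("treatment", "indicator", "n", "mean", "dispersion",
                 "letters")]
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  sep <- sniff_sep(path)
  out <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, encoding = "UTF-8",
                           colClasses = c(letters = "character"))
  out$letters[is.na(out$letters)] <- ""
  out
}

#' Published reference tables packaged as fixtures
#'
#' Returns one of the published result tables of the tobacco AMF screening
#' trial, exactly as printed:
#' \describe{
#'   \item{\code{"table2"}}{root colonization and soil spore density: mean,
#'     standard error (n = 3) and significance letter for 4 indicators x
#'     7 treatments.}
#'   \item{\code{"table3"}}{growth indicators (plant height, root length,
#'     leaf area, stem diameter, biomasses): mean, SE, letter for 7
#'     indicators x 7 treatments.}
#'   \item{\code{"table4"}}{membership-function values for all 19
#'     evaluation indicators x 7 treatments, plus the \code{average_value}
#'     and \code{rank} rows.}
#' }
#'
#' @param name one of \code{"table2"}, \code{"table3"}, \code{"table4"}.
#' @return A long-format data frame; tables 2 and 3 have columns
#'   \code{indicator}, \code{treatment}, \code{mean}, \code{se},
#'   \code{letter}; table 4 has \code{indicator}, \code{treatment},
#'   \code{value}.
#' @examples
#' t3 <- builtin_fixture("table3")
#' subset(t3, indicator == "plant_height" & treatment == "Fm")$mean  # 61.43
#' @export
builtin_fixture <- function(name = c("table2", "table3", "table4")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "amftrial",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Treatment-by-indicator means from a fixture or summary table
#'
#' Convenience accessor: converts a long table with \code{indicator},
#' \code{treatment} and a value column into the long means format consumed
#' by [membership_matrix()] and [percent_change()].
#'
#' @param tab long data frame (e.g. from [builtin_fixture()]).
#' @param value name of the value column (\code{"mean"} or \code{"value"}).
#' @return Data frame with columns \code{indicator}, \code{treatment},
#'   \code{value}.
#' @export
fixture_means <- function(tab, value = intersect(c("mean", "value"),
                                                 names(tab))[1]) {
  stopifnot(value %in% names(tab))
  data.frame(indicator = tab$indicator, treatment = tab$treatment,
             value = tab[[value]], stringsAsFactors = FALSE)
}

#' Synthetic default means for figure-only indicators
#'
#' The enzyme, hormone, pigment and osmolyte indicators of the panel are
#' published only as figures, so the simulator cannot take their group
#' means from a printed table. This table provides documented synthetic
#' defaults: each indicator is given a plausible physiological range and
#' the seven treatment means are placed inside that range by the published
#' membership values (inverted for MDA, the inverse-direction indicator).
#' The numbers are synthetic stand-ins, not measurements.
#'
#' @return Data frame with columns \code{indicator}, \code{treatment},
#'   \code{mean}, \code{se}.
#' @export
synthetic_defaults <- function() {
  path <- system.file("extdata", "synthetic_defaults.csv",
                      package = "amftrial", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
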