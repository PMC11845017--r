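#' Screen differentially expressed genes by fold change and p-value
#'
#' Classifies per-gene differential statistics with the standard screen:
#' a gene is \code{"up"} if \code{log2fc >= lfc_min} and
#' \code{pvalue < alpha}, \code{"down"} if \code{log2fc <= -lfc_min} and
#' \code{pvalue < alpha}, otherwise \code{"ns"}. Boundary semantics
#' follow the usual statement of the rule: the p-value cut is strict,
#' the fold-change cut is inclusive. No multiple-testing adjustment is
#' applied by default (the screen operates on the p-values it is given);
#' set \code{adjust = "BH"} to screen on Benjamini-Hochberg adjusted
#' values instead.
#'
#' @param stats data frame with columns \code{gene_id}, \code{log2fc},
#'   \code{pvalue}.
#' @param alpha p-value threshold (default 0.05, strict).
#' @param lfc_min |log2FC| threshold (default 1, inclusive).
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return A list of class \code{deg_screen} with elements
#'   \code{records} (the input plus a \code{status} column, input order
#'   preserved), \code{n_up}, \code{n_down}, \code{n_ns}.
#' @examples
#' screen_degs(data.frame(gene_id = c("g1", "g2", "g3"),
#'                        log2fc = c(0.5, 1.0, -1.0),
#'                        pvalue = c(0.001, 0.049, 0.049)))
#' @export
screen_degs <- function(stats, alpha = 0.05, lfc_min = 1,
                        adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  need <- c("gene_id", "log2fc", "pvalue")
  miss <- setdiff(need, names(stats))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  p <- stats$pvalue
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("validation error: pvalues must lie in [0, 1]")
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  sig <- p < alpha
  status <- rep("ns", nrow(stats))
  status[sig & stats$log2fc >= lfc_min] <- "up"
  status[sig & stats$log2fc <= -lfc_min] <- "down"
  records <- stats
  records$status <- status
  structure(list(records = records,
                 n_up = sum(status == "up"),
                 n_down = sum(status == "down"),
                 n_ns = sum(status == "ns"),
                 alpha = alpha, lfc_min = lfc_min, adjust = adjust),
            class = "deg_screen")
}

#' @export
print.deg_screen <- function(x, ...) {
  cat(sprintf(
    "DEG screen (p < %g%s, |log2FC| >= %g): %d up, %d down, %d ns of %d genes\n",
    x$alpha, if (x$adjust == "BH") " BH-adjusted" else "", x$lfc_min,
    x$n_up, x$n_down, x$n_ns, nrow(x$records)))
  invisible(x)
}

#' Auxiliary two-group Welch test per gene
#'
#' Computes per-gene log2 fold change and Welch t-test p-value from two
#' matrices of log2-scale expression, producing input for
#' [screen_degs()]. This is a convenience for exercising the screen on
#' simulated data; it is not a count-model differential-expression
#' procedure.
#'
#' @param treatment,control numeric matrices (genes x replicates) of
#'   log2-scale expression with matching row names.
#' @return Data frame with columns \code{gene_id}, \code{log2fc},
#'   \code{pvalue}.
#' @export
welch_deg_stats <- function(treatment, control) {
  stopifnot(is.matrix(treatment), is.matrix(control),
            nrow(treatment) == nrow(control))
  ids <- rownames(treatment)
  if (is.null(ids)) ids <- sprintf("gene_%04d", seq_len(nrow(treatment)))
  out <- data.frame(gene_id = ids, log2fc = NA_real_, pvalue = NA_real_,
                    stringsAsFactors = FALSE)
  for (g in seq_len(nrow(treatment))) {
    tt <- stats::t.test(treatment[g, ], control[g, ])
    out$log2fc[g] <- mean(treatment[g, ]) - mean(control[g, ])
    out$pvalue[g] <- tt$p.value
  }
  out
}

#' Livak 2^-ddCt relative expression
#'
#' Per replicate, \eqn{\Delta CT = CT_{target} - CT_{reference}};
#' \eqn{\Delta\Delta CT} is the difference of group-mean
#' \eqn{\Delta CT}s (treatment minus control) and the relative
#' expression is \eqn{2^{-\Delta\Delta CT}}. Per-replicate fold changes
#' (each treatment replicate's \eqn{\Delta CT} against the control mean)
#' are also returned, since conventions differ on the aggregation.
#'
#' @param plate data frame with columns \code{group}, \code{replicate},
#'   \code{gene}, \code{ct} (e.g. from [simulate_qpcr()] or
#'   [read_qpcr()]).
#' @param target target gene name.
#' @param treatment_group,control_group group labels.
#' @param reference_gene internal reference gene (default taken from the
#'   plate attribute, else \code{"actin"}).
#' @return A list of class \code{ddct_result} with elements
#'   \code{fold_change}, \code{ddct}, \code{dct_treatment},
#'   \code{dct_control} (per-replicate vectors) and
#'   \code{per_replicate_fc}.
#' @examples
#' plate <- simulate_qpcr(c(gh3 = 4), ct_noise_sd = 0)
#' relative_expression(plate, "gh3", "Fm", "CK")$fold_change  # 4
#' @export
relative_expression <- function(plate, target, treatment_group,
                                control_group,
                                reference_gene = NULL) {
  if (is.null(reference_gene))
    reference_gene <- attr(plate, "reference_gene")
  if (is.null(reference_gene)) reference_gene <- "actin"
  need <- c("group", "replicate", "gene", "ct")
  miss <- setdiff(need, names(plate))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(plate$ct <= 0)) stop("validation error: Ct values must be > 0")
  dct_group <- function(grp) {
    d <- plate[plate$group == grp, ]
    if (nrow(d) == 0L) stop("group '", grp, "' not present on plate")
    reps <- unique(d$replicate)
    vapply(reps, function(r) {
      tgt <- d$ct[d$replicate == r & d$gene == target]
      ref <- d$ct[d$replicate == r & d$gene == reference_gene]
      if (length(ref) != 1L)
        stop("validation error: reference gene '", reference_gene,
             "' missing (or duplicated) in group ", grp, " replicate ", r)
      if (length(tgt) != 1L)
        stop("validation error: target gene '", target,
             "' missing (or duplicated) in group ", grp, " replicate ", r)
      tgt - ref
    }, 0)
  }
  dct_t <- dct_group(treatment_group)
  dct_c <- dct_group(control_group)
  ddct <- mean(dct_t) - mean(dct_c)
  structure(list(fold_change = 2^(-ddct), ddct = ddct,
                 dct_treatment = dct_t, dct_control = dct_c,
                 per_replicate_fc = 2^(-(dct_t - mean(dct_c))),
                 target = target, reference_gene = reference_gene),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf(
    "2^-ddCt for %s (reference %s): fold change %.4g (ddCt = %.4g)\n",
    x$target, x$reference_gene, x$fold_change, x$ddct))
  invisible(x)
}

#' Read a qPCR plate table
#'
#' Delimited text with columns \code{group}, \code{replicate},
#' \code{gene}, \code{ct}.
#'
#' @param path path to CSV/TSV file.
#' @param reference_gene internal reference gene label (default
#'   \code{"actin"}).
#' @return A \code{qpcr_plate} data frame.
#' @export
read_qpcr <- function(path, reference_gene = "actin") {
  sep <- sniff_sep(path)
  out <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("group", "replicate", "gene", "ct")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  attr(out, "reference_gene") <- reference_gene
  class(out) <- c("qpcr_plate", "data.frame")
  out
}

#' Read a per-gene differential-statistics table
#'
#' Delimited text with columns \code{gene_id}, \code{log2fc},
#' \code{pvalue}.
#'
#' @param path path to CSV/TSV file.
#' @return Data frame of per-gene statistics.
#' @export
read_deg_stats <- function(path) {
  sep <- sniff_sep(path)
  out <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("gene_id", "log2fc", "pvalue")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  out
}
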