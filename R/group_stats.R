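#' Per-indicator group summaries
#'
#' One row per treatment with replicate count, mean and dispersion.
#' Dispersion can be reported as the sample standard deviation or the
#' standard error of the mean; the default is SE, matching the "mean
#' +/- standard error (n = 3)" convention of the reference tables.
#'
#' @param data an \code{amf_trial} data frame (see [as_trial()]).
#' @param indicator indicator name; if \code{NULL}, all indicators
#'   present are summarized.
#' @param dispersion \code{"se"} (default) or \code{"sd"}.
#' @return Data frame with columns \code{treatment}, \code{indicator},
#'   \code{n}, \code{mean}, \code{dispersion}.
#' @export
summarize_groups <- function(data, indicator = NULL,
                             dispersion = c("se", "sd")) {
  dispersion <- match.arg(dispersion)
  inds <- if (is.null(indicator)) unique(data$indicator) else indicator
  out <- do.call(rbind, lapply(inds, function(ind) {
    d <- data[data$indicator == ind, ]
    if (nrow(d) == 0L) stop("no records for indicator ", ind)
    cnt <- table(d$treatment)
    low <- names(cnt)[cnt < 2]
    if (length(low))
      stop("precondition error: fewer than 2 replicates for group(s) ",
           paste(low, collapse = ", "), " of indicator ", ind)
    agg <- do.call(rbind, lapply(unique(d$treatment), function(tr) {
      v <- d$value[d$treatment == tr]
      disp <- stats::sd(v)
      if (dispersion == "se") disp <- disp / sqrt(length(v))
      data.frame(treatment = tr, indicator = ind, n = length(v),
                 mean = mean(v), dispersion = disp,
                 stringsAsFactors = FALSE)
    }))
    agg
  }))
  rownames(out) <- NULL
  attr(out, "dispersion_mode") <- dispersion
  out
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Fits a one-way ANOVA for one indicator, runs all-pairs Tukey HSD
#' comparisons at level \code{alpha}, and assigns lowercase letters by
#' the insert-and-absorb algorithm so that two groups share at least one
#' letter exactly when their pairwise comparison is non-significant.
#' Letters are assigned in descending order of group means starting at
#' "a" (the convention of agronomy result tables).
#'
#' @param data an \code{amf_trial} data frame.
#' @param indicator indicator name.
#' @param alpha significance level (default 0.05).
#' @return A list of class \code{amf_letters} with elements
#'   \code{letters} (named character vector, one entry per treatment),
#'   \code{means}, \code{pairwise} (data frame of pairwise adjusted
#'   p-values), \code{alpha}, \code{anova_p}.
#' @export
anova_letters <- function(data, indicator, alpha = 0.05) {
  d <- data[data$indicator == indicator, ]
  if (nrow(d) == 0L) stop("no records for indicator ", indicator)
  cnt <- table(d$treatment)
  if (length(cnt) < 2) stop("precondition error: need >= 2 groups")
  if (any(cnt < 2))
    stop("precondition error: fewer than 2 replicates for group(s) ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  grp <- factor(d$treatment, levels = unique(d$treatment))
  means <- tapply(d$value, grp, mean)
  # degenerate: zero variance everywhere and all means equal
  if (all(tapply(d$value, grp, stats::sd) == 0) &&
      length(unique(means)) == 1L) {
    letters_out <- stats::setNames(rep("a", length(means)), names(means))
    pw <- all_pairs(names(means))
    pw$p_adj <- 1
    return(structure(list(letters = letters_out, means = means,
                          pairwise = pw, alpha = alpha, anova_p = NA_real_),
                     class = "amf_letters"))
  }
  fit <- stats::aov(value ~ grp, data = data.frame(value = d$value,
                                                   grp = grp))
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$grp
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  pw <- data.frame(g1 = vapply(cmp, `[`, "", 1),
                   g2 = vapply(cmp, `[`, "", 2),
                   p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(pw) <- NULL
  letters_out <- cld_insert_absorb(means, pw, alpha)
  structure(list(letters = letters_out, means = means, pairwise = pw,
                 alpha = alpha, anova_p = anova_p),
            class = "amf_letters")
}

all_pairs <- function(labels) {
  idx <- utils::combn(labels, 2)
  data.frame(g1 = idx[1, ], g2 = idx[2, ], stringsAsFactors = FALSE)
}

# Insert-and-absorb compact letter display (Piepho-style). `means` is a
# named vector; `pairwise` has columns g1, g2, p_adj. Returns a named
# character vector of letter strings, letters ordered by descending mean.
cld_insert_absorb <- function(means, pairwise, alpha) {
  labs <- names(sort(means, decreasing = TRUE))
  sig <- pairwise[pairwise$p_adj < alpha, , drop = FALSE]
  # columns: list of character vectors of member labels
  cols <- list(labs)
  for (k in seq_len(nrow(sig))) {
    a <- sig$g1[k]; b <- sig$g2[k]
    newcols <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        newcols <- c(newcols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        newcols <- c(newcols, list(col))
      }
    }
    # absorb: drop columns that are subsets of another column
    keep <- rep(TRUE, length(newcols))
    for (i in seq_along(newcols)) for (j in seq_along(newcols)) {
      if (i != j && keep[i] &&
          all(newcols[[i]] %in% newcols[[j]]) &&
          (length(newcols[[i]]) < length(newcols[[j]]) ||
           (length(newcols[[i]]) == length(newcols[[j]]) && i > j)))
        keep[i] <- FALSE
    }
    cols <- newcols[keep]
  }
  # order columns by the best (largest-mean) member so "a" goes to the top
  rank_of <- stats::setNames(seq_along(labs), labs)
  first <- vapply(cols, function(col) min(rank_of[col]), 0)
  cols <- cols[order(first)]
  out <- stats::setNames(rep("", length(labs)), labs)
  for (i in seq_along(cols)) {
    l <- letters[(i - 1) %% 26 + 1]
    if (i > 26) l <- paste0(l, (i - 1) %/% 26)
    for (g in cols[[i]]) out[g] <- paste0(out[g], l)
  }
  out[names(means)]
}

#' @export
print.amf_letters <- function(x, ...) {
  ord <- order(-x$means)
  cat(sprintf("One-way ANOVA p = %s; Tukey HSD letters at alpha = %g:\n",
              format.pval(x$anova_p), x$alpha))
  for (i in ord)
    cat(sprintf("  %-6s %10.4g  %s\n", names(x$means)[i], x$means[i],
                x$letters[[names(x$means)[i]]]))
  invisible(x)
}

#' Percent change of treatment means versus the control
#'
#' Signed percent change \eqn{100 (\bar x_t - \bar x_{CK})/\bar x_{CK}}
#' per non-control treatment and indicator, computed from unrounded means
#' and rounded half-up to \code{digits} decimals for presentation.
#'
#' @param summary data frame with columns \code{treatment},
#'   \code{indicator}, \code{mean} (e.g. from [summarize_groups()] or
#'   [builtin_fixture()]).
#' @param control control treatment label (default \code{"CK"}).
#' @param digits presentation decimals (default 2); use \code{NULL} for
#'   full precision.
#' @return Data frame with columns \code{treatment}, \code{indicator},
#'   \code{percent_change}.
#' @examples
#' t3 <- builtin_fixture("table3")
#' pc <- percent_change(t3)
#' subset(pc, treatment == "Fm" & indicator == "plant_height")  # 91.07
#' @export
percent_change <- function(summary, control = "CK", digits = 2) {
  need <- c("treatment", "indicator", "mean")
  miss <- setdiff(need, names(summary))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!control %in% summary$treatment)
    stop("control group '", control, "' not present")
  out <- do.call(rbind, lapply(unique(summary$indicator), function(ind) {
    d <- summary[summary$indicator == ind, ]
    m0 <- d$mean[d$treatment == control]
    if (length(m0) != 1L)
      stop("control mean missing or duplicated for indicator ", ind)
    if (m0 == 0)
      stop("undefined-change error: control mean is zero for indicator ",
           ind)
    d <- d[d$treatment != control, ]
    pc <- 100 * (d$mean - m0) / m0
    if (!is.null(digits)) pc <- round_half_up(pc, digits)
    data.frame(treatment = d$treatment, indicator = ind,
               percent_change = pc, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
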