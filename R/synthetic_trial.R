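#' Seeded synthetic generators for the pot-trial design
#'
#' The trial simulator emulates the screening design: seven treatment
#' groups (uninoculated control plus six AMF inoculants) measured on a
#' panel of indicators, with replicate-level Gaussian noise on the
#' measurement scale, truncated at zero for strictly non-negative traits.
#' Group means and dispersions default to the published tables for the
#' tabulated indicators and to the documented synthetic defaults for the
#' figure-only ones.
#'
#' @name synthetic_trial
NULL

# evaluate expr under a seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Build a trial simulation specification
#'
#' @param cells data frame with columns \code{treatment},
#'   \code{indicator}, \code{mean}, \code{sd}: the true group mean and
#'   per-observation standard deviation of every cell. Defaults to
#'   [default_sim_cells()].
#' @param n_replicates replicates per group (>= 2); default 3, matching
#'   the published summary tables (the full design grew 12 pots per
#'   group; both are valid choices).
#' @param registry indicator registry used for validation.
#' @param seed integer seed; each generator call uses a single RNG stream
#'   seeded from it.
#' @return A list of class \code{trial_sim_spec}.
#' @export
trial_sim_spec <- function(cells = default_sim_cells(), n_replicates = 3,
                           registry = default_indicators(), seed = 1L) {
  stopifnot(is.data.frame(cells))
  need <- c("treatment", "indicator", "mean", "sd")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("validation error: cells missing column(s) ",
         paste(miss, collapse = ", "))
  if (any(cells$sd < 0))
    stop("validation error: true dispersion must be >= 0")
  if (n_replicates < 2) stop("validation error: n_replicates must be >= 2")
  unknown <- setdiff(unique(cells$indicator), registry$name)
  if (length(unknown))
    stop("validation error: unknown indicator(s): ",
         paste(unknown, collapse = ", "))
  key <- paste(cells$treatment, cells$indicator)
  if (anyDuplicated(key))
    stop("validation error: duplicated (treatment, indicator) cells")
  structure(list(cells = cells[, need],
                 n_replicates = as.integer(n_replicates),
                 registry = registry, seed = as.integer(seed)),
            class = "trial_sim_spec")
}

#' Default simulation cells: published tables plus synthetic defaults
#'
#' Group means for the 19 evaluation indicators: the seven growth
#' indicators and the colonization panel come from the published summary
#' tables (standard errors at n = 3 converted to per-observation SDs by
#' multiplying by sqrt(3)); the figure-only indicators come from
#' [synthetic_defaults()].
#'
#' @param include_colonization also include the colonization indicators
#'   (infection rate/density, arbuscule abundance, spore density);
#'   default FALSE.
#' @return Data frame with columns \code{treatment}, \code{indicator},
#'   \code{mean}, \code{sd}.
#' @export
default_sim_cells <- function(include_colonization = FALSE) {
  t3 <- builtin_fixture("table3")
  syn <- synthetic_defaults()
  tabs <- list(t3, syn)
  if (include_colonization) tabs <- c(tabs, list(builtin_fixture("table2")))
  cells <- do.call(rbind, lapply(tabs, function(d)
    data.frame(treatment = d$treatment, indicator = d$indicator,
               mean = d$mean, sd = d$se * sqrt(3),
               stringsAsFactors = FALSE)))
  rownames(cells) <- NULL
  cells
}

#' Simulate a replicate-level trial dataset
#'
#' Draws \code{n_replicates} Gaussian observations per (treatment,
#' indicator) cell at the cell's true mean and SD, on the measurement
#' scale, truncating negative draws at zero (all panel indicators are
#' non-negative quantities); the number of truncated draws is attached as
#' attribute \code{n_truncated}. Deterministic given the spec's seed: one
#' RNG stream, cells visited in the spec's row order.
#'
#' @param spec a [trial_sim_spec()].
#' @return An \code{amf_trial} data frame.
#' @export
simulate_trial <- function(spec) {
  if (!inherits(spec, "trial_sim_spec"))
    stop("validation error: spec must be a trial_sim_spec")
  cells <- spec$cells
  n <- spec$n_replicates
  out <- with_seed(spec$seed, {
    vals <- unlist(lapply(seq_len(nrow(cells)), function(i)
      stats::rnorm(n, cells$mean[i], cells$sd[i])))
    vals
  })
  n_trunc <- sum(out < 0)
  out <- pmax(out, 0)
  df <- data.frame(
    treatment = rep(cells$treatment, each = n),
    replicate = rep(seq_len(n), times = nrow(cells)),
    indicator = rep(cells$indicator, each = n),
    value = out, stringsAsFactors = FALSE)
  trial <- as_trial(df, registry = spec$registry)
  attr(trial, "n_truncated") <- n_trunc
  trial
}

#' Simulate scored root fragments
#'
#' Each fragment is mycorrhizal with probability \code{target_F/100};
#' mycorrhizal fragments draw an intensity class 1--5 from
#' \code{class_mix} and an arbuscule class 1--3 from \code{arbuscule_mix}
#' (class A0 is allowed via a leading probability); non-mycorrhizal
#' fragments are class 0/A0.
#'
#' @param target_F expected colonization frequency in percent (0--100).
#' @param class_mix probabilities over intensity classes 1--5 (sums to 1).
#' @param arbuscule_mix probabilities over arbuscule classes A1--A3
#'   (sums to 1).
#' @param n_fragments number of fragments to score (default 30).
#' @param seed integer seed.
#' @return Data frame with columns \code{sample_id},
#'   \code{fragment_index}, \code{intensity_class},
#'   \code{arbuscule_class}.
#' @export
simulate_fragments <- function(target_F, class_mix = rep(0.2, 5),
                               arbuscule_mix = c(0.2, 0.3, 0.5),
                               n_fragments = 30, seed = 1L) {
  if (target_F < 0 || target_F > 100)
    stop("validation error: target_F must be in [0, 100]")
  if (length(class_mix) != 5 || abs(sum(class_mix) - 1) > 1e-9)
    stop("validation error: class_mix must give 5 probabilities summing to 1")
  if (length(arbuscule_mix) != 3 || abs(sum(arbuscule_mix) - 1) > 1e-9)
    stop("validation error: arbuscule_mix must give 3 probabilities ",
         "summing to 1")
  with_seed(seed, {
    myco <- stats::runif(n_fragments) < target_F / 100
    ic <- integer(n_fragments)
    ac <- integer(n_fragments)
    k <- sum(myco)
    if (k > 0) {
      ic[myco] <- sample.int(5, k, replace = TRUE, prob = class_mix)
      ac[myco] <- sample.int(3, k, replace = TRUE, prob = arbuscule_mix)
    }
    data.frame(sample_id = "sim", fragment_index = seq_len(n_fragments),
               intensity_class = ic, arbuscule_class = ac,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a qPCR plate with known fold changes
#'
#' Generates Ct values for target genes and a reference gene in a control
#' and a treatment group. The reference gene cycles at
#' \code{ct_reference} in every well; each target's control-group delta-Ct
#' (target minus reference) is fixed at \code{dct_control}, and its
#' treatment-group delta-Ct is \code{dct_control - log2(fold change)}, so
#' Livak 2^-ddCt recovers the requested fold change exactly at zero
#' noise. Gaussian noise of SD \code{ct_noise_sd} is added independently
#' to every Ct.
#'
#' @param true_fold_changes named numeric vector of positive fold changes
#'   (treatment over control), one per target gene.
#' @param ct_reference reference-gene Ct (default 20 cycles).
#' @param dct_control control-group delta-Ct of every target (default 3).
#' @param ct_noise_sd Gaussian noise SD on each Ct (default 0).
#' @param n_replicates biological replicates per group (default 4).
#' @param reference_gene reference gene label (default \code{"actin"}).
#' @param groups labels for control and treatment group.
#' @param seed integer seed.
#' @return Data frame of class \code{qpcr_plate} with columns
#'   \code{group}, \code{replicate}, \code{gene}, \code{ct}; attribute
#'   \code{reference_gene}.
#' @export
simulate_qpcr <- function(true_fold_changes, ct_reference = 20,
                          dct_control = 3, ct_noise_sd = 0,
                          n_replicates = 4, reference_gene = "actin",
                          groups = c(control = "CK", treatment = "Fm"),
                          seed = 1L) {
  if (is.null(names(true_fold_changes)) || any(!nzchar(names(true_fold_changes))))
    stop("validation error: fold changes must be a named vector")
  if (any(true_fold_changes <= 0))
    stop("validation error: fold changes must be positive")
  genes <- names(true_fold_changes)
  grid <- expand.grid(group = unname(groups),
                      replicate = seq_len(n_replicates),
                      gene = c(reference_gene, genes),
                      stringsAsFactors = FALSE)
  dct <- function(gene, group) {
    if (gene == reference_gene) return(0)
    d <- dct_control
    if (group == groups[["treatment"]])
      d <- d - log2(true_fold_changes[[gene]])
    d
  }
  ct0 <- ct_reference +
    mapply(dct, grid$gene, grid$group)
  ct <- with_seed(seed,
    ct0 + stats::rnorm(nrow(grid), 0, ct_noise_sd))
  plate <- data.frame(group = grid$group, replicate = grid$replicate,
                      gene = grid$gene, ct = ct,
                      stringsAsFactors = FALSE)
  attr(plate, "reference_gene") <- reference_gene
  class(plate) <- c("qpcr_plate", "data.frame")
  plate
}

#' Simulate a per-gene differential-statistics table with planted truth
#'
#' Null genes draw two groups of log2-scale expression from the same
#' Gaussian; differentially expressed (DE) genes receive an additive
#' log2-scale effect of magnitude centred at \code{effect_location}
#' (spread \code{effect_spread}), sign chosen equiprobably. Each gene's
#' log2 fold change is the group difference of log2 means and its p-value
#' comes from a two-group Welch t-test on the log2 values, so null
#' p-values are uniform by construction. Truth labels are retained in the
#' \code{truth} column for recovery tests.
#'
#' @param n_genes number of genes.
#' @param frac_de fraction of genes that are truly DE (0--1).
#' @param effect_location mean |log2FC| of DE genes (default 2).
#' @param effect_spread SD of the DE effect magnitude (default 0.25).
#' @param n_per_group replicates per group (default 4).
#' @param within_sd log2-scale within-group SD (default 0.5).
#' @param seed integer seed.
#' @return Data frame with columns \code{gene_id}, \code{log2fc},
#'   \code{pvalue}, \code{truth} (\code{"up"}, \code{"down"},
#'   \code{"ns"}).
#' @export
simulate_deg_table <- function(n_genes = 1000, frac_de = 0.1,
                               effect_location = 2, effect_spread = 0.25,
                               n_per_group = 4, within_sd = 0.5,
                               seed = 1L) {
  if (frac_de < 0 || frac_de > 1)
    stop("validation error: frac_de must be in [0, 1]")
  if (n_per_group < 2)
    stop("validation error: n_per_group must be >= 2")
  with_seed(seed, {
    n_de <- round(n_genes * frac_de)
    is_de <- c(rep(TRUE, n_de), rep(FALSE, n_genes - n_de))
    sgn <- ifelse(stats::runif(n_genes) < 0.5, 1, -1)
    eff <- ifelse(is_de,
                  sgn * abs(stats::rnorm(n_genes, effect_location,
                                         effect_spread)),
                  0)
    base <- stats::rnorm(n_genes, 8, 2)   # log2 baseline expression
    log2fc <- numeric(n_genes)
    pval <- numeric(n_genes)
    for (g in seq_len(n_genes)) {
      ctrl <- stats::rnorm(n_per_group, base[g], within_sd)
      trt <- stats::rnorm(n_per_group, base[g] + eff[g], within_sd)
      tt <- stats::t.test(trt, ctrl)
      log2fc[g] <- mean(trt) - mean(ctrl)
      pval[g] <- tt$p.value
    }
    truth <- ifelse(!is_de, "ns", ifelse(eff > 0, "up", "down"))
    data.frame(gene_id = sprintf("gene_%04d", seq_len(n_genes)),
               log2fc = log2fc, pvalue = pval, truth = truth,
               stringsAsFactors = FALSE)
  })
}
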