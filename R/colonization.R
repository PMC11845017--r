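#' Mycorrhizal colonization indices from scored root fragments
#'
#' Implements the five-class root-fragment scoring convention of the
#' Trouvelot method (as computed by the Mycocalc calculator). Each root
#' fragment receives an intensity class 0--5 (0 = no colonization, 5 =
#' more than 90\% of the cortex colonized) and an arbuscule class 0--3
#' (A0 = no arbuscules, A3 = abundant). From N scored fragments with
#' \eqn{n_k} fragments in intensity class k:
#' \deqn{F\% = 100\,(N - n_0)/N}
#' \deqn{M\% = (95 n_5 + 70 n_4 + 30 n_3 + 5 n_2 + n_1)/N}
#' \deqn{m\% = M \cdot N / (N - n_0)}
#' and with \eqn{mA_i} the intensity-weighted share of colonized fragments
#' carrying arbuscule class i (expressed as a percentage of m),
#' \deqn{a\% = (100\, mA_3 + 50\, mA_2 + 10\, mA_1)/100, \quad
#'       A\% = a \cdot M / 100.}
#' F is the colonization frequency, M the colonization intensity over the
#' whole root system, m the intensity within colonized fragments, a the
#' arbuscule abundance within colonized fragments and A the arbuscule
#' abundance over the whole root system. The class weights are pinned
#' constants of the convention but can be overridden for other schemes.
#'
#' @param scores data frame with integer columns \code{intensity_class}
#'   (0--5) and \code{arbuscule_class} (0--3); one row per fragment.
#' @param intensity_weights weights for intensity classes 1--5
#'   (default \code{c(1, 5, 30, 70, 95)}).
#' @param arbuscule_weights weights for arbuscule classes A1--A3
#'   (default \code{c(10, 50, 100)}).
#' @return A list of class \code{amf_colonization} with elements \code{F},
#'   \code{M}, \code{m}, \code{a}, \code{A} (all percentages, full
#'   precision) and \code{n_fragments}.
#' @examples
#' sc <- data.frame(intensity_class = c(0, 0, 0, 0, 0, 3, 3, 3, 5, 5),
#'                  arbuscule_class = c(0, 0, 0, 0, 0, 1, 1, 1, 3, 3))
#' colonization_summary(sc)  # F = 60, M = 28, m = 46.67, ...
#' @export
colonization_summary <- function(scores,
                                 intensity_weights = c(1, 5, 30, 70, 95),
                                 arbuscule_weights = c(10, 50, 100)) {
  validate_fragments(scores)
  ic <- as.integer(scores$intensity_class)
  ac <- as.integer(scores$arbuscule_class)
  N <- length(ic)
  w <- c(0, intensity_weights)[ic + 1L]          # per-fragment intensity weight
  ncol_ <- sum(ic > 0L)
  F_ <- 100 * ncol_ / N
  M_ <- sum(w) / N
  m_ <- if (ncol_ > 0L) M_ * N / ncol_ else 0
  if (ncol_ > 0L && m_ > 0) {
    # mA_i: intensity mass of colonized fragments with arbuscule class i,
    # as a percentage of m
    mA <- vapply(1:3, function(i) sum(w[ic > 0L & ac == i]) / ncol_, 0)
    mA <- 100 * mA / m_
    a_ <- sum(arbuscule_weights * mA) / 100
  } else {
    a_ <- 0
  }
  A_ <- a_ * M_ / 100
  structure(list(F = F_, M = M_, m = m_, a = a_, A = A_, n_fragments = N),
            class = "amf_colonization")
}

validate_fragments <- function(scores) {
  if (!is.data.frame(scores) || nrow(scores) == 0L)
    stop("precondition error: fragment score set is empty")
  need <- c("intensity_class", "arbuscule_class")
  miss <- setdiff(need, names(scores))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  ic <- scores$intensity_class; ac <- scores$arbuscule_class
  if (any(ic != round(ic)) || any(ic < 0 | ic > 5))
    stop("validation error: intensity_class must be an integer in 0..5")
  if (any(ac != round(ac)) || any(ac < 0 | ac > 3))
    stop("validation error: arbuscule_class must be an integer in 0..3")
  if (any(ic == 0 & ac > 0))
    stop("validation error: uncolonized fragments (class 0) cannot carry ",
         "arbuscules")
  invisible(TRUE)
}

#' @export
print.amf_colonization <- function(x, ...) {
  cat(sprintf(
    "Colonization indices over %d fragments:\n  F = %.2f%%  M = %.2f%%  m = %.2f%%  a = %.2f%%  A = %.2f%%\n",
    x$n_fragments, x$F, x$M, x$m, x$a, x$A))
  invisible(x)
}

#' Read a fragment score table
#'
#' Expects delimited text with columns \code{sample_id},
#' \code{fragment_index}, \code{intensity_class}, \code{arbuscule_class}.
#'
#' @param path path to CSV/TSV file.
#' @return Data frame of fragment scores (validated).
#' @export
read_fragments <- function(path) {
  sep <- sniff_sep(path)
  out <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_fragments(out)
  out
}

#' Spore density per 25 g of soil
#'
#' Converts a wet-sieve spore count from an arbitrary soil mass to the
#' conventional reporting basis of spores per 25 g of rhizosphere soil.
#'
#' @param spore_count non-negative spore count.
#' @param soil_mass soil mass in grams (> 0); default 25.
#' @return Spores per 25 g soil.
#' @examples
#' spore_density(686, 50)  # 343
#' @export
spore_density <- function(spore_count, soil_mass = 25) {
  if (any(soil_mass <= 0))
    stop("precondition error: soil_mass must be positive")
  if (any(spore_count < 0))
    stop("precondition error: spore_count must be non-negative")
  spore_count * 25 / soil_mass
}
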