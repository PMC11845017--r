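#' Membership-function value of a single observation
#'
#' Direction-aware min--max score used by the comprehensive evaluation:
#' for a positive-direction indicator
#' \deqn{F_1(x) = (x - x_{min})/(x_{max} - x_{min})}
#' and for an inverse-direction indicator (lower is better, e.g. MDA)
#' \deqn{F_2(x) = 1 - F_1(x).}
#'
#' @param x observed value, within \code{[xmin, xmax]}.
#' @param xmin,xmax extremes of the indicator across treatments
#'   (\code{xmax >= xmin}).
#' @param direction \code{"positive"} or \code{"inverse"}.
#' @return Membership value in \code{[0, 1]}.
#' @examples
#' membership_value(59.16, 32.15, 61.43, "positive")  # 0.92...
#' @export
membership_value <- function(x, xmin, xmax,
                             direction = c("positive", "inverse")) {
  direction <- match.arg(direction)
  if (xmax < xmin) stop("precondition error: xmax must be >= xmin")
  if (any(x < xmin - 1e-12) || any(x > xmax + 1e-12))
    stop("precondition error: x outside [xmin, xmax]")
  if (xmax == xmin)
    stop("undefined membership: indicator constant across treatments ",
         "(xmax == xmin)")
  f1 <- (x - xmin) / (xmax - xmin)
  if (direction == "inverse") 1 - f1 else f1
}

#' Membership matrix across treatments and indicators
#'
#' For every indicator, takes its minimum and maximum across treatments
#' and scores each treatment with \code{F1} (positive direction) or
#' \code{F2 = 1 - F1} (inverse direction, per the registry). Column
#' means are unweighted averages over indicators; ranks are assigned in
#' descending column-mean order (1 = strongest promotion), ties broken
#' by treatment input order.
#'
#' Indicators constant across treatments leave the score undefined; by
#' default they are excluded with a warning (set
#' \code{constant = "half"} to score them 0.5 instead).
#'
#' @param means long data frame with columns \code{indicator},
#'   \code{treatment} and a value column (\code{mean} or \code{value});
#'   every (indicator, treatment) cell must be present.
#' @param registry an \code{amf_registry} giving each indicator's
#'   direction.
#' @param constant how to handle constant indicators: \code{"drop"}
#'   (default) or \code{"half"}.
#' @return A list of class \code{membership_matrix} with elements
#'   \code{mu} (indicator x treatment matrix), \code{column_mean},
#'   \code{rank} (named integer vector), \code{treatments},
#'   \code{indicators}.
#' @examples
#' t3 <- builtin_fixture("table3")
#' mm <- membership_matrix(fixture_means(t3))
#' round(mm$mu["plant_height", ], 2)
#' @export
membership_matrix <- function(means, registry = default_indicators(),
                              constant = c("drop", "half")) {
  constant <- match.arg(constant)
  need <- c("indicator", "treatment")
  miss <- setdiff(need, names(means))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  valcol <- intersect(c("mean", "value"), names(means))[1]
  if (is.na(valcol)) stop("means must have a 'mean' or 'value' column")
  trts <- unique(means$treatment)
  inds <- unique(means$indicator)
  if (length(trts) < 2) stop("precondition error: need >= 2 treatments")
  M <- matrix(NA_real_, length(inds), length(trts),
              dimnames = list(inds, trts))
  M[cbind(match(means$indicator, inds), match(means$treatment, trts))] <-
    means[[valcol]]
  if (anyNA(M))
    stop("validation error: missing (indicator, treatment) cell(s)")
  dir <- indicator_direction(registry, inds)
  keep <- rep(TRUE, length(inds))
  mu <- M
  for (i in seq_along(inds)) {
    lo <- min(M[i, ]); hi <- max(M[i, ])
    if (hi == lo) {
      if (constant == "drop") {
        warning("indicator '", inds[i],
                "' constant across treatments; excluded from matrix")
        keep[i] <- FALSE
      } else {
        mu[i, ] <- 0.5
      }
      next
    }
    f1 <- (M[i, ] - lo) / (hi - lo)
    mu[i, ] <- if (dir[i] == "inverse") 1 - f1 else f1
  }
  mu <- mu[keep, , drop = FALSE]
  if (nrow(mu) == 0L) stop("no scorable indicators remain")
  col_mean <- colMeans(mu)
  ord <- order(-col_mean)            # stable: ties keep input order
  rk <- integer(length(trts)); rk[ord] <- seq_along(trts)
  names(rk) <- trts
  structure(list(mu = mu, column_mean = col_mean, rank = rk,
                 treatments = trts, indicators = rownames(mu)),
            class = "membership_matrix")
}

#' Treatment ranking from a membership matrix
#'
#' @param matrix a \code{membership_matrix}.
#' @return Treatment labels in descending column-mean order (rank 1
#'   first).
#' @examples
#' mm <- membership_matrix(fixture_means(builtin_fixture("table3")))
#' rank_treatments(mm)  # Fm first, CK last
#' @export
rank_treatments <- function(matrix) {
  if (!inherits(matrix, "membership_matrix"))
    stop("expected a membership_matrix")
  matrix$treatments[order(matrix$rank)]
}

#' @export
print.membership_matrix <- function(x, digits = 2, ...) {
  cat("Membership matrix (", nrow(x$mu), " indicators x ",
      ncol(x$mu), " treatments)\n", sep = "")
  tab <- rbind(round_half_up(x$mu, digits),
               average_value = round_half_up(x$column_mean, digits),
               rank = x$rank)
  print(tab)
  cat("Promotion ranking:", paste(rank_treatments(x), collapse = " > "),
      "\n")
  invisible(x)
}
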