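# Brute-force colonization oracle: direct per-fragment summation with the
# published class weights, written independently of the package's
# vectorized implementation.
oracle_colonization <- function(scores) {
  iw <- c(1, 5, 30, 70, 95)   # intensity classes 1..5
  aw <- c(10, 50, 100)        # arbuscule classes 1..3
  N <- nrow(scores)
  n_col <- 0
  msum <- 0
  masum <- c(0, 0, 0)
  for (k in seq_len(N)) {
    ic <- scores$intensity_class[k]
    ac <- scores$arbuscule_class[k]
    if (ic > 0) {
      n_col <- n_col + 1
      msum <- msum + iw[ic]
      if (ac > 0) masum[ac] <- masum[ac] + iw[ic]
    }
  }
  F <- 100 * n_col / N
  M <- msum / N
  m <- if (n_col > 0) msum / n_col else 0
  if (n_col > 0 && m > 0) {
    mA <- 100 * (masum / n_col) / m
    a <- sum(aw * mA) / 100
  } else a <- 0
  list(F = F, M = M, m = m, a = a, A = a * M / 100)
}

random_fragments <- function(n = 30) {
  ic <- sample(0:5, n, replace = TRUE)
  ac <- ifelse(ic == 0, 0L, sample(0:3, n, replace = TRUE))
  data.frame(intensity_class = ic, arbuscule_class = ac)
}

# small two-indicator trial for I/O tests
tiny_trial_df <- function() {
  data.frame(
    treatment = rep(c("CK", "Fm"), each = 6),
    replicate = rep(1:3, 4),
    indicator = rep(rep(c("plant_height", "root_length"), each = 3), 2),
    value = c(30, 32, 34, 25, 26, 27, 58, 60, 62, 35, 36, 37),
    stringsAsFactors = FALSE)
}

# random balanced multi-group dataset for letter-display tests
random_groups_trial <- function(means, sd = 1, n = 5,
                                indicator = "plant_height") {
  g <- names(means)
  as_trial(data.frame(
    treatment = rep(g, each = n),
    replicate = rep(seq_len(n), length(g)),
    indicator = indicator,
    value = stats::rnorm(length(g) * n, rep(unlist(means), each = n), sd),
    stringsAsFactors = FALSE))
}

# does a letter display encode "share a letter iff not significant"?
letters_encode <- function(letters_vec, pairwise, alpha) {
  for (k in seq_len(nrow(pairwise))) {
    a <- pairwise$g1[k]; b <- pairwise$g2[k]
    shared <- length(intersect(strsplit(letters_vec[[a]], "")[[1]],
                               strsplit(letters_vec[[b]], "")[[1]])) > 0
    signif <- pairwise$p_adj[k] < alpha
    if (shared == signif) return(FALSE)
  }
  TRUE
}
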