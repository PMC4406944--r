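## Independent oracles used across test files.

## Balanced one-way random-effects intraclass correlation, closed form:
## ICC = (MSB - MSW) / (MSB + (r - 1) MSW) on a strains x replicates matrix.
anova_icc <- function(y) {
  n <- nrow(y); r <- ncol(y)
  gm <- mean(y)
  sm <- rowMeans(y)
  msb <- r * sum((sm - gm)^2) / (n - 1)
  msw <- sum((y - sm)^2) / (n * (r - 1))
  (msb - msw) / (msb + (r - 1) * msw)
}

## Brute-force triad classifier: a triad is transitive iff some ordering
## (a, b, c) has a beating b and c, and b beating c.  Enumerates all six
## orderings -- independent of the out-degree shortcut in the package.
brute_transitive <- function(wins, i, j, k) {
  for (p in list(c(i, j, k), c(i, k, j), c(j, i, k),
                 c(j, k, i), c(k, i, j), c(k, j, i))) {
    if (wins[p[1], p[2]] == 1 && wins[p[1], p[3]] == 1 &&
        wins[p[2], p[3]] == 1)
      return(TRUE)
  }
  FALSE
}

## Brute-force p_t over all tie-free triads of a tournament object.
brute_pt <- function(trn) {
  n <- length(trn$strains)
  decided <- trn$wins + t(trn$wins)
  tot <- 0L; trans <- 0L
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    if (decided[i, j] == 1 && decided[i, k] == 1 && decided[j, k] == 1) {
      tot <- tot + 1L
      if (brute_transitive(trn$wins, i, j, k)) trans <- trans + 1L
    }
  }
  if (tot == 0L) return(NULL)
  list(p_t = trans / tot, n_triads = tot)
}

## Tournament object straight from a win-probability orientation matrix.
tournament_from_wins <- function(W) {
  n <- nrow(W)
  P <- matrix(0.5, n, n)
  P[W == 1] <- 0.9
  P[t(W) == 1] <- 0.1
  diag(P) <- NA
  rownames(P) <- colnames(P) <- sprintf("S%03d", seq_len(n))
  tournament(P)
}

## Small generative parameter set for fast tests.
small_params <- function(...) {
  trait_params(n_strains = 12L, n_reps = 3L, n_plated = 50L,
               n_counted = 200L, ...)
}
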