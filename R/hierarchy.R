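#' Pairwise chimeric representation and per-strain means
#'
#' Pools spore counts over replicates for each unordered strain pair
#' (weighting replicates by spores counted — the binomial maximum-likelihood
#' estimate) to give the proportion matrix `P[i, j]`: the estimated fraction
#' of strain i spores in an (i, j) chimera.  `P[j, i] = 1 - P[i, j]` by
#' construction.  The per-strain representation `C_i` is the unweighted mean
#' of `P[i, j]` over partners j.
#'
#' @param mixes mix-count table (`strain_a`, `strain_b`, `replicate`,
#'   `count_a`, `n_counted`); both or either orientation per pair accepted.
#' @return object of class `"chimrep"`: list with `P` (proportion matrix,
#'   NA diagonal and NA for unmixed pairs), `n` (pooled counts per pair),
#'   `C` (named per-strain mean representation), `strains`.
#' @export
chimeric_representation <- function(mixes) {
  .check_mixes(mixes)
  strains <- sort(unique(c(mixes$strain_a, mixes$strain_b)))
  ns <- length(strains)
  cnt <- tot <- matrix(0, ns, ns, dimnames = list(strains, strains))
  ia <- match(mixes$strain_a, strains)
  ib <- match(mixes$strain_b, strains)
  for (row in seq_len(nrow(mixes))) {
    cnt[ia[row], ib[row]] <- cnt[ia[row], ib[row]] + mixes$count_a[row]
    cnt[ib[row], ia[row]] <- cnt[ib[row], ia[row]] +
      mixes$n_counted[row] - mixes$count_a[row]
    tot[ia[row], ib[row]] <- tot[ia[row], ib[row]] + mixes$n_counted[row]
    tot[ib[row], ia[row]] <- tot[ib[row], ia[row]] + mixes$n_counted[row]
  }
  P <- cnt / tot        # 0/0 -> NaN for unmixed pairs
  P[tot == 0] <- NA_real_
  diag(P) <- NA_real_
  C <- rowMeans(P, na.rm = TRUE)
  if (anyNA(C) || any(is.nan(C)))
    stop("a strain has no mix observations", call. = FALSE)
  structure(list(P = P, n = tot, C = C, strains = strains),
            class = "chimrep")
}

#' @export
print.chimrep <- function(x, digits = 3, ...) {
  cat(sprintf("Chimeric representation for %d strains\n", length(x$strains)))
  cat("  mean representation C_i:\n")
  print(round(sort(x$C, decreasing = TRUE), digits))
  invisible(x)
}

#' Binary dominance tournament from pairwise proportions
#'
#' Strain i beats strain j iff `P[i, j] > 0.5 + tie_tol`; pairs with
#' `|P[i, j] - 0.5| <= tie_tol` (boundary inclusive) are recorded as ties
#' and excluded from triad counting.  Unmixed pairs are also treated as
#' undecided.
#'
#' @param x a `"chimrep"` object or a pairwise proportion matrix.
#' @param tie_tol half-width of the tie band around 0.5 (default 0: strict
#'   majority decides).
#' @return object of class `"tournament"`: list with `strains`, `wins`
#'   (binary matrix, `wins[i, j] = 1` iff i beats j), `ties` (two-column
#'   matrix of tied pairs).
#' @export
tournament <- function(x, tie_tol = 0) {
  P <- if (inherits(x, "chimrep")) x$P else as.matrix(x)
  stopifnot(nrow(P) == ncol(P), tie_tol >= 0)
  strains <- rownames(P)
  if (is.null(strains)) strains <- strain_ids(nrow(P))
  dimnames(P) <- list(strains, strains)
  wins <- (!is.na(P) & P > 0.5 + tie_tol) * 1L
  diag(wins) <- 0L
  undec <- upper.tri(P) & (is.na(P) | abs(P - 0.5) <= tie_tol)
  ties <- which(undec, arr.ind = TRUE)
  ties <- cbind(strains[ties[, 1]], strains[ties[, 2]])
  colnames(ties) <- c("strain_a", "strain_b")
  structure(list(strains = strains, wins = wins, ties = ties),
            class = "tournament")
}

#' @export
print.tournament <- function(x, ...) {
  cat(sprintf("Dominance tournament: %d strains, %d decided pairs, %d ties\n",
              length(x$strains), sum(x$wins), nrow(x$ties)))
  invisible(x)
}

## triads with all three pairs decided, as index triples + their pair codes
.complete_triads <- function(t) {
  n <- length(t$strains)
  if (n < 3L) return(NULL)
  decided <- t$wins + base::t(t$wins)   # 1 where pair decided
  tri <- utils::combn(n, 3L)
  ok <- decided[cbind(tri[1, ], tri[2, ])] == 1 &
    decided[cbind(tri[1, ], tri[3, ])] == 1 &
    decided[cbind(tri[2, ], tri[3, ])] == 1
  tri[, ok, drop = FALSE]
}

#' Triangle transitivity of a dominance tournament
#'
#' Enumerates all triads whose three pairs are decided (tie-free).  A triad
#' is transitive iff it is not a 3-cycle, i.e. iff some strain beats both
#' others.  With `p_t` the proportion of transitive triads,
#' `t_tri = 4 * (p_t - 0.75)`: 1 for a perfectly linear hierarchy, 0 at the
#' random-orientation expectation (each triad is cyclic with probability
#' 1/4), and -3 when every triad is cyclic.
#'
#' @param t a [tournament()] object.
#' @return object of class `"ttri"`: list with `p_t`, `t_tri`, `n_triads`
#'   (and `p_value = NA`; see [ttri_test()]).
#' @export
ttri <- function(t) {
  stopifnot(inherits(t, "tournament"))
  tri <- .complete_triads(t)
  if (is.null(tri) || ncol(tri) == 0L)
    stop("zero complete (tie-free) triads; cannot compute transitivity",
         call. = FALSE)
  W <- t$wins
  ## cyclic iff every member beats exactly one other member
  o1 <- W[cbind(tri[1, ], tri[2, ])] + W[cbind(tri[1, ], tri[3, ])]
  o2 <- W[cbind(tri[2, ], tri[1, ])] + W[cbind(tri[2, ], tri[3, ])]
  o3 <- W[cbind(tri[3, ], tri[1, ])] + W[cbind(tri[3, ], tri[2, ])]
  cyclic <- o1 == 1 & o2 == 1 & o3 == 1
  p_t <- 1 - mean(cyclic)
  structure(list(p_t = p_t, t_tri = 4 * (p_t - 0.75),
                 n_triads = ncol(tri), p_value = NA_real_,
                 n_perm = NA_integer_),
            class = "ttri")
}

#' Randomization test for hierarchy linearity
#'
#' Computes [ttri()] on the observed tournament and compares it with a null
#' in which the direction of every decided pair is re-drawn independently
#' with probability 0.5 (ties held fixed, so the triad set is unchanged).
#' The one-sided p-value for high transitivity uses the add-one permutation
#' correction: `p = (1 + #\{null t_tri >= observed\}) / (n_perm + 1)`.
#'
#' @param t a [tournament()] object.
#' @param n_perm number of random orientations (`0` gives `p = 1`).
#' @param seed integer seed.
#' @return a `"ttri"` object with `p_value`, `n_perm` and the null mean
#'   (`null_mean_t_tri`) filled in.
#' @export
ttri_test <- function(t, n_perm = 10000L, seed = 1L) {
  obs <- ttri(t)
  tri <- .complete_triads(t)
  n <- length(t$strains)
  ## orientation bit per unordered decided pair, indexed into a pair table
  pairs <- which(upper.tri(matrix(0, n, n)) &
                   (t$wins + base::t(t$wins)) == 1, arr.ind = TRUE)
  key <- function(i, j) (pmin(i, j) - 1) * n + pmax(i, j)
  pair_id <- stats::setNames(seq_len(nrow(pairs)), key(pairs[, 1], pairs[, 2]))
  e12 <- pair_id[as.character(key(tri[1, ], tri[2, ]))]
  e13 <- pair_id[as.character(key(tri[1, ], tri[3, ]))]
  e23 <- pair_id[as.character(key(tri[2, ], tri[3, ]))]
  set.seed(seed)
  n_perm <- as.integer(n_perm)
  stopifnot(n_perm >= 0)
  null_t <- numeric(n_perm)
  npair <- nrow(pairs)
  for (b in seq_len(n_perm)) {
    ## o[e] = TRUE iff lower-index strain beats higher-index strain
    o <- stats::runif(npair) < 0.5
    cyc <- (o[e12] & o[e23] & !o[e13]) | (!o[e12] & !o[e23] & o[e13])
    null_t[b] <- 4 * ((1 - mean(cyc)) - 0.75)
  }
  obs$p_value <- (1 + sum(null_t >= obs$t_tri)) / (n_perm + 1)
  obs$n_perm <- n_perm
  obs$null_mean_t_tri <- if (n_perm > 0) mean(null_t) else NA_real_
  obs
}

#' @export
print.ttri <- function(x, ...) {
  cat(sprintf("Triangle transitivity: t_tri = %.3f (p_t = %.3f over %d triads)\n",
              x$t_tri, x$p_t, x$n_triads))
  if (!is.na(x$p_value))
    cat(sprintf("  randomization p-value = %.4g (%d permutations)\n",
                x$p_value, x$n_perm))
  invisible(x)
}
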