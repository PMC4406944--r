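#' Prior specification for the multi-trait mixed model
#'
#' Conjugate priors: inverse-Wishart on the genetic covariance G, a scaled
#' inverse-chi-squared on each residual variance, and a diffuse normal on the
#' trait means.
#'
#' @param nu0 inverse-Wishart degrees of freedom for G (default: traits + 1).
#' @param psi0_scale inverse-Wishart scale is `psi0_scale * I`.
#' @param nuE,s2E residual-variance prior degrees of freedom and scale.
#' @param mu_var prior variance of each trait mean (flat-ish normal).
#' @return list of class `"mtmm_priors"`.
#' @export
mtmm_priors <- function(nu0 = 5, psi0_scale = 0.1, nuE = 1, s2E = 0.5,
                        mu_var = 1e8) {
  stopifnot(psi0_scale > 0, nuE > 0, s2E > 0, mu_var > 0)
  structure(list(nu0 = nu0, psi0_scale = psi0_scale, nuE = nuE, s2E = s2E,
                 mu_var = mu_var), class = "mtmm_priors")
}

#' Chain specification for the multi-trait mixed model
#'
#' @param iterations total Gibbs iterations.
#' @param burnin iterations discarded before storage.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @return list of class `"mtmm_chain"`.
#' @export
mtmm_chain <- function(iterations = 20000L, burnin = 5000L, thin = 10L) {
  iterations <- .check_count(iterations, "iterations")
  burnin <- as.integer(burnin)
  thin <- .check_count(thin, "thin")
  stopifnot(burnin >= 0, burnin < iterations)
  structure(list(iterations = iterations, burnin = burnin, thin = thin),
            class = "mtmm_chain")
}

#' Fit the multi-trait Bayesian mixed model by Gibbs sampling
#'
#' Fits the strain-level random-effect ("animal model without pedigree")
#' decomposition
#' \deqn{y_{itr} = \mu_t + g_{it} + e_{itr}, \quad g_i \sim N_k(0, G), \quad
#'       e_{itr} \sim N(0, E_t),}
#' where `i` indexes strains, `t` traits and `r` replicates.  Genetic
#' covariance between traits is carried entirely by the strain level; the
#' residual covariance is diagonal because each trait is assayed on separate
#' cells, so replicate-level covariances are not identifiable.
#'
#' The sampler is a conjugate Gibbs cycle: (1) strain effects from their
#' multivariate-normal full conditional (strains sharing a replicate-count
#' pattern are updated in one vectorized block); (2) G from an
#' inverse-Wishart; (3) each residual variance from a scaled
#' inverse-chi-squared; (4) trait means from normals.  Draws after burn-in
#' are thinned and stored.  The run is deterministic given `seed`.
#'
#' Convergence is screened by the split-chain potential scale reduction
#' factor (split-Rhat) on every genetic and residual variance; values above
#' 1.1 set `converged = FALSE` on the result (reported, not fatal).
#'
#' @param data long-format modelling-scale frame from [model_frame()]:
#'   columns `strain`, `trait`, `replicate`, `value`.
#' @param priors a [mtmm_priors()] object.
#' @param chain a [mtmm_chain()] object.
#' @param seed integer seed.
#' @return object of class `"mtmm"` with elements `draws` (list: `G` a
#'   k x k x m array, `E` and `mu` m x k matrices), `traits`, `strains`,
#'   `g_mean` (posterior-mean strain effects), `rhat`, `converged`, `chain`,
#'   `priors`, `seed`, `data`.
#' @seealso [heritability()], [gen_correlations()], [summary.mtmm()],
#'   [simulate.mtmm()]
#' @export
mtmm <- function(data, priors = mtmm_priors(), chain = mtmm_chain(),
                 seed = 1L) {
  stopifnot(inherits(priors, "mtmm_priors"), inherits(chain, "mtmm_chain"))
  need <- c("strain", "trait", "value")
  if (!all(need %in% names(data)))
    stop("'data' must have columns strain, trait, value", call. = FALSE)
  traits <- .traits[.traits %in% unique(data$trait)]
  if (length(traits) == 0L) stop("no recognized traits in data", call. = FALSE)
  strains <- sort(unique(data$strain))
  ns <- length(strains)
  if (ns < 3L) stop("need at least 3 strains", call. = FALSE)
  k <- length(traits)

  ## per-strain sufficient statistics
  si <- match(data$strain, strains)
  ti <- match(data$trait, traits)
  y <- data$value
  nmat <- matrix(0, ns, k)        # replicate counts
  smat <- matrix(0, ns, k)        # sums
  qmat <- matrix(0, ns, k)        # sums of squares
  idx <- cbind(si, ti)
  for (row in seq_along(y)) {
    nmat[si[row], ti[row]] <- nmat[si[row], ti[row]] + 1
    smat[si[row], ti[row]] <- smat[si[row], ti[row]] + y[row]
    qmat[si[row], ti[row]] <- qmat[si[row], ti[row]] + y[row]^2
  }
  if (any(colSums(nmat) == 0))
    stop("a trait has no observations", call. = FALSE)
  vart <- vapply(seq_len(k), function(t) stats::var(y[ti == t]), numeric(1))
  if (any(vart == 0))
    stop(sprintf("trait %s has zero variance; model is singular",
                 traits[which(vart == 0)[1]]), call. = FALSE)
  Ntot <- colSums(nmat)

  ## group strains by identical replicate-count pattern (balanced data: 1 group)
  pat <- apply(nmat, 1, paste, collapse = ",")
  groups <- split(seq_len(ns), pat)

  set.seed(seed)
  nu0 <- priors$nu0
  Psi0 <- diag(priors$psi0_scale, k)
  nuE <- priors$nuE; s2E <- priors$s2E
  Gc <- diag(pmax(vart / 2, 1e-6), k)
  Ev <- pmax(vart / 2, 1e-6)
  muv <- colSums(smat) / Ntot
  gmat <- matrix(0, ns, k)

  it_tot <- chain$iterations
  keep <- seq(chain$burnin + chain$thin, it_tot, by = chain$thin)
  m <- length(keep)
  if (m == 0L) stop("chain specification keeps no draws", call. = FALSE)
  Gd <- array(NA_real_, c(k, k, m), dimnames = list(traits, traits, NULL))
  Ed <- matrix(NA_real_, m, k, dimnames = list(NULL, traits))
  mud <- matrix(NA_real_, m, k, dimnames = list(NULL, traits))
  g_accum <- matrix(0, ns, k)
  ki <- 0L

  for (it in seq_len(it_tot)) {
    ## (1) strain effects | rest
    Ginv <- chol2inv(chol(Gc))
    B <- sweep(smat - sweep(nmat, 2, muv, "*"), 2, Ev, "/")
    for (grp in groups) {
      n_pat <- nmat[grp[1L], ]
      P <- Ginv + diag(n_pat / Ev, k)
      Pc <- chol(P)
      Bm <- B[grp, , drop = FALSE]
      Mn <- t(backsolve(Pc, backsolve(Pc, t(Bm), transpose = TRUE)))
      Z <- matrix(stats::rnorm(length(grp) * k), length(grp), k)
      gmat[grp, ] <- Mn + t(backsolve(Pc, t(Z)))
    }
    ## (2) trait means | rest
    for (t in seq_len(k)) {
      prec <- Ntot[t] / Ev[t] + 1 / priors$mu_var
      mn <- sum(smat[, t] - nmat[, t] * gmat[, t]) / Ev[t] / prec
      muv[t] <- stats::rnorm(1, mn, sqrt(1 / prec))
    }
    ## (3) G | g  (inverse-Wishart)
    Sg <- crossprod(gmat)
    W <- stats::rWishart(1, nu0 + ns, chol2inv(chol(Psi0 + Sg)))[, , 1]
    Gc <- chol2inv(chol(W))
    ## (4) residual variances | rest  (scaled inverse-chi-squared)
    for (t in seq_len(k)) {
      a <- muv[t] + gmat[, t]
      ss <- sum(qmat[, t] - 2 * a * smat[, t] + nmat[, t] * a^2)
      Ev[t] <- (nuE * s2E + ss) / stats::rchisq(1, nuE + Ntot[t])
    }
    if (ki < m && it == keep[ki + 1L]) {
      ki <- ki + 1L
      Gd[, , ki] <- Gc
      Ed[ki, ] <- Ev
      mud[ki, ] <- muv
      g_accum <- g_accum + gmat
    }
  }

  gdiag <- vapply(seq_len(k), function(t) Gd[t, t, ], numeric(m))
  if (m == 1L) gdiag <- matrix(gdiag, 1L, k)
  comps <- cbind(gdiag, Ed)
  colnames(comps) <- c(paste0("G_", traits), paste0("E_", traits))
  rhat <- apply(comps, 2, split_rhat)
  fit <- structure(list(
    draws = list(G = Gd, E = Ed, mu = mud),
    traits = traits, strains = strains,
    g_mean = {
      gm <- g_accum / m
      dimnames(gm) <- list(strains, traits)
      gm
    },
    rhat = rhat, converged = all(rhat <= 1.1, na.rm = TRUE),
    chain = chain, priors = priors, seed = as.integer(seed),
    n_obs = length(y), data = data[c("strain", "trait", "value")],
    call = match.call()), class = "mtmm")
  fit
}

#' Split-chain potential scale reduction factor
#'
#' Split-Rhat of a single chain: the chain is halved and the usual
#' between/within variance ratio computed over the two halves.  Values near
#' 1 indicate the two halves explore the same distribution.
#'
#' @param x numeric vector of draws.
#' @return Rhat (NA for constant or too-short chains).
#' @export
split_rhat <- function(x) {
  n <- length(x) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- list(x[seq_len(n)], x[n + seq_len(n)])
  W <- mean(vapply(halves, stats::var, numeric(1)))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * stats::var(vapply(halves, mean, numeric(1)))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Broad-sense heritability with credible intervals
#'
#' Per retained draw, `H2_t = G_tt / (G_tt + E_t)`; the point estimate is the
#' posterior mean and the interval the central 95% equal-tailed credible
#' interval.  Defined as a per-draw ratio, every draw (and hence the
#' interval) lies in `[0, 1]`.
#'
#' @param fit an [mtmm()] object.
#' @param trait optional subset of traits.
#' @return data.frame with columns `trait`, `point`, `lo`, `hi`.
#' @export
heritability <- function(fit, trait = NULL) {
  stopifnot(inherits(fit, "mtmm"))
  traits <- if (is.null(trait)) fit$traits else match.arg(trait, fit$traits,
                                                          several.ok = TRUE)
  out <- lapply(traits, function(t) {
    h2 <- fit$draws$G[t, t, ] / (fit$draws$G[t, t, ] + fit$draws$E[, t])
    q <- stats::quantile(h2, c(0.025, 0.975), names = FALSE)
    data.frame(trait = t, point = mean(h2), lo = q[1], hi = q[2])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Genetic correlations with credible intervals
#'
#' Per retained draw, `r_ij = G_ij / sqrt(G_ii G_jj)`; because every stored
#' G draw is positive definite, each per-draw correlation lies in `[-1, 1]`.
#' Point estimates are posterior means, intervals are central 95%
#' equal-tailed.
#'
#' @param fit an [mtmm()] object.
#' @return object of class `"mtmm_gencor"`: list with matrices `point`,
#'   `lo`, `hi` (unit diagonal) and a data.frame `pairs` (one row per
#'   unordered trait pair).
#' @export
gen_correlations <- function(fit) {
  stopifnot(inherits(fit, "mtmm"))
  traits <- fit$traits
  k <- length(traits)
  rd <- apply(fit$draws$G, 3, function(M) {
    d <- sqrt(diag(M))
    stats::cov2cor(M)[upper.tri(M)]
  })
  if (is.null(dim(rd))) rd <- matrix(rd, nrow = 1)
  pt <- lo <- hi <- diag(k)
  dimnames(pt) <- dimnames(lo) <- dimnames(hi) <- list(traits, traits)
  up <- which(upper.tri(pt), arr.ind = TRUE)
  pairs <- data.frame(pair = paste0(traits[up[, 1]], traits[up[, 2]]),
                      point = rowMeans(rd),
                      lo = apply(rd, 1, stats::quantile, 0.025, names = FALSE),
                      hi = apply(rd, 1, stats::quantile, 0.975, names = FALSE))
  for (j in seq_len(nrow(up))) {
    pt[up[j, 1], up[j, 2]] <- pt[up[j, 2], up[j, 1]] <- pairs$point[j]
    lo[up[j, 1], up[j, 2]] <- lo[up[j, 2], up[j, 1]] <- pairs$lo[j]
    hi[up[j, 1], up[j, 2]] <- hi[up[j, 2], up[j, 1]] <- pairs$hi[j]
  }
  structure(list(point = pt, lo = lo, hi = hi, pairs = pairs),
            class = "mtmm_gencor")
}

#' @export
print.mtmm_gencor <- function(x, digits = 2, ...) {
  cat("Genetic correlations (posterior mean, 95% CrI):\n")
  df <- x$pairs
  df$point <- round(df$point, digits)
  df$CrI <- sprintf("[%.*f, %.*f]", digits, df$lo, digits, df$hi)
  print(df[c("pair", "point", "CrI")], row.names = FALSE)
  invisible(x)
}

#' @export
print.mtmm <- function(x, ...) {
  cat(sprintf("Multi-trait Bayesian mixed model: %d traits (%s), %d strains, %d observations\n",
              length(x$traits), paste(x$traits, collapse = ", "),
              length(x$strains), x$n_obs))
  cat(sprintf("  %d stored draws (%d iterations, %d burn-in, thin %d); %s\n",
              dim(x$draws$G)[3], x$chain$iterations, x$chain$burnin,
              x$chain$thin,
              if (x$converged) "converged (all split-Rhat <= 1.1)"
              else "NOT converged (split-Rhat > 1.1 on a variance component)"))
  invisible(x)
}

#' Summarize an mtmm fit
#'
#' @param object an [mtmm()] object.
#' @param ... unused.
#' @return class `"summary.mtmm"`: heritability table, genetic-correlation
#'   summary, posterior-mean residual variances and trait means, Rhat.
#' @export
summary.mtmm <- function(object, ...) {
  structure(list(
    heritability = heritability(object),
    correlations = gen_correlations(object),
    E = colMeans(object$draws$E),
    mu = colMeans(object$draws$mu),
    rhat = object$rhat, converged = object$converged,
    n_strains = length(object$strains), n_obs = object$n_obs),
    class = "summary.mtmm")
}

#' @export
print.summary.mtmm <- function(x, digits = 2, ...) {
  cat(sprintf("Multi-trait mixed model: %d strains, %d observations\n\n",
              x$n_strains, x$n_obs))
  cat("Broad-sense heritabilities (posterior mean, 95% CrI):\n")
  h <- x$heritability
  h$point <- round(h$point, digits)
  h$CrI <- sprintf("[%.*f, %.*f]", digits, h$lo, digits, h$hi)
  print(h[c("trait", "point", "CrI")], row.names = FALSE)
  cat("\n")
  print(x$correlations, digits = digits)
  cat(sprintf("\nConvergence: max split-Rhat %.3f (%s)\n", max(x$rhat, na.rm = TRUE),
              if (x$converged) "ok" else "check chains"))
  invisible(x)
}

#' @export
coef.mtmm <- function(object, ...) colMeans(object$draws$mu)

#' Posterior-mean genetic covariance matrix
#' @param object an [mtmm()] object.
#' @param ... unused.
#' @return k x k posterior-mean G.
#' @export
vcov.mtmm <- function(object, ...) {
  apply(object$draws$G, c(1, 2), mean)
}

#' Posterior-mean strain genetic effects
#' @param fit an [mtmm()] object.
#' @return matrix (strains x traits).
#' @export
strain_effects <- function(fit) {
  stopifnot(inherits(fit, "mtmm"))
  fit$g_mean
}

#' @export
fitted.mtmm <- function(object, ...) {
  mu <- coef(object)
  unname(mu[object$data$trait] +
           object$g_mean[cbind(object$data$strain, object$data$trait)])
}

#' @export
residuals.mtmm <- function(object, ...) {
  object$data$value - fitted.mtmm(object)
}

#' Simulate strain genetic values from the posterior of G
#'
#' For each retained draw of G, samples `nsim` strain-level genetic values
#' from a zero-mean multivariate normal with that draw's covariance, pools
#' them, and standardizes each trait to SD units.  These posterior-simulated
#' strains visualize the estimated genetic correlation structure (the grey
#' point clouds of trait–trait scatter plots).
#'
#' @param object an [mtmm()] object.
#' @param nsim strains per retained draw (`0` gives an empty frame).
#' @param seed optional integer seed.
#' @param standardize z-score each trait over the pooled sample (default).
#' @param ... unused.
#' @return data.frame with column `draw` and one column per trait.
#' @export
simulate.mtmm <- function(object, nsim = 1, seed = NULL, standardize = TRUE,
                          ...) {
  if (!is.null(seed)) set.seed(seed)
  k <- length(object$traits)
  m <- dim(object$draws$G)[3]
  nsim <- as.integer(nsim)
  stopifnot(nsim >= 0)
  if (nsim == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0, k + 1))
    names(out) <- c("draw", object$traits)
    return(out)
  }
  vals <- matrix(NA_real_, m * nsim, k)
  for (j in seq_len(m)) {
    L <- chol(object$draws$G[, , j])
    vals[(j - 1) * nsim + seq_len(nsim), ] <-
      matrix(stats::rnorm(nsim * k), nsim, k) %*% L
  }
  if (standardize && nrow(vals) > 1L)
    vals <- scale(vals)
  out <- data.frame(draw = rep(seq_len(m), each = nsim), vals)
  names(out) <- c("draw", object$traits)
  out
}

#' Trace plots of per-draw heritabilities
#'
#' @param x an [mtmm()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mtmm <- function(x, ...) {
  traits <- x$traits
  old <- graphics::par(mfrow = c(length(traits), 1),
                       mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (t in traits) {
    h2 <- x$draws$G[t, t, ] / (x$draws$G[t, t, ] + x$draws$E[, t])
    graphics::plot(h2, type = "l", ylab = bquote(H^2 ~ .(t)),
                   xlab = "stored draw", ylim = c(0, 1), ...)
  }
  invisible(x)
}

#' Export posterior draws in long format
#'
#' One row per stored draw and scalar parameter (elements of G, E, mu),
#' suitable for writing as `posterior.csv`.
#'
#' @param fit an [mtmm()] object.
#' @return data.frame `iteration`, `parameter`, `value`.
#' @export
posterior_long <- function(fit) {
  stopifnot(inherits(fit, "mtmm"))
  traits <- fit$traits
  k <- length(traits)
  m <- dim(fit$draws$G)[3]
  iter <- fit$chain$burnin + fit$chain$thin * seq_len(m)
  blocks <- list()
  for (a in seq_len(k)) for (b in a:k)
    blocks[[paste0("G_", traits[a], traits[b])]] <- fit$draws$G[a, b, ]
  for (t in traits) blocks[[paste0("E_", t)]] <- fit$draws$E[, t]
  for (t in traits) blocks[[paste0("mu_", t)]] <- fit$draws$mu[, t]
  data.frame(
    iteration = rep(iter, times = length(blocks)),
    parameter = rep(names(blocks), each = m),
    value = unlist(blocks, use.names = FALSE))
}
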