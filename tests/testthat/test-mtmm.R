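## Direct construction of a one-trait modelling frame: y = g + e.
one_trait_frame <- function(n_strains, n_reps, h2, seed) {
  set.seed(seed)
  g <- rnorm(n_strains, 0, sqrt(h2))
  y <- g + matrix(rnorm(n_strains * n_reps, 0, sqrt(1 - h2)),
                  n_strains, n_reps)
  data.frame(strain = rep(sprintf("S%03d", 1:n_strains), n_reps),
             trait = "N",
             replicate = rep(1:n_reps, each = n_strains),
             value = as.vector(y))
}

test_that("one-trait posterior mean matches the closed-form ANOVA ICC", {
  mf <- one_trait_frame(200, 8, h2 = 0.5, seed = 31)
  y <- matrix(mf$value, 200)
  fit <- mtmm(mf, chain = mtmm_chain(4000, 1000, 4), seed = 2)
  h2_hat <- heritability(fit, "N")
  expect_equal(h2_hat$point, anova_icc(y), tolerance = 0.05)
  expect_true(h2_hat$lo <= h2_hat$point && h2_hat$point <= h2_hat$hi)
})

test_that("fixed seed and data give an identical draw sequence", {
  mf <- one_trait_frame(20, 4, h2 = 0.4, seed = 8)
  f1 <- mtmm(mf, chain = mtmm_chain(500, 100, 2), seed = 5)
  f2 <- mtmm(mf, chain = mtmm_chain(500, 100, 2), seed = 5)
  expect_identical(f1$draws, f2$draws)
  f3 <- mtmm(mf, chain = mtmm_chain(500, 100, 2), seed = 6)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("per-draw identities and chain bookkeeping hold", {
  p <- small_params()
  st <- simulate_study(p, seed = 13)
  fit <- mtmm(model_frame(st$phenotypes, st$mixes),
              chain = mtmm_chain(1200, 200, 4), seed = 3)
  m <- dim(fit$draws$G)[3]
  expect_equal(m, (1200 - 200) / 4)
  for (t in fit$traits) {
    h2 <- fit$draws$G[t, t, ] / (fit$draws$G[t, t, ] + fit$draws$E[, t])
    expect_true(all(h2 >= 0 & h2 <= 1))
  }
  ## every stored G draw is symmetric positive definite; correlations in [-1, 1]
  for (j in seq_len(m)) {
    G <- fit$draws$G[, , j]
    expect_true(isSymmetric(G, tol = 1e-10))
    expect_gt(min(eigen(G, symmetric = TRUE)$values), 0)
    r <- cov2cor(G)[upper.tri(G)]
    expect_true(all(abs(r) <= 1))
  }
  expect_true(all(fit$draws$E > 0))
  ## reported intervals contain the posterior mean
  h <- heritability(fit)
  expect_true(all(h$lo <= h$point & h$point <= h$hi))
  rr <- gen_correlations(fit)$pairs
  expect_true(all(rr$lo <= rr$point & rr$point <= rr$hi))
})

test_that("diagonal G is recovered at scale", {
  r0 <- setNames(rep(0, 6), c("NS", "SV", "NV", "NC", "SC", "VC"))
  p <- trait_params(h2 = rep(0.5, 4), r = r0, n_strains = 200L, n_reps = 8L)
  st <- simulate_study(p, seed = 23)
  fit <- mtmm(model_frame(st$phenotypes, st$mixes),
              chain = mtmm_chain(6000, 1000, 5), seed = 7)
  h <- heritability(fit)
  expect_lt(max(abs(h$point - 0.5)), 0.08)
  ## the posterior tracks the covariance realized in this finite strain
  ## sample, so compare correlations against the drawn effects
  realized <- cor(as.matrix(st$effects[, -1]))
  dimnames(realized) <- list(sporefit:::.traits, sporefit:::.traits)
  est <- gen_correlations(fit)$point
  for (a in rownames(est)) for (b in colnames(est))
    expect_lt(abs(est[a, b] - realized[a, b]), 0.1)
  expect_true(fit$converged)
})

test_that("all-diagonal G draws give zero correlations with zero-width CIs", {
  m <- 5
  fake <- structure(list(
    draws = list(G = array(rep(diag(c(1, 2, 3, 4)), m), c(4, 4, m),
                           dimnames = list(sporefit:::.traits,
                                           sporefit:::.traits, NULL))),
    traits = sporefit:::.traits), class = "mtmm")
  rr <- gen_correlations(fake)$pairs
  expect_equal(rr$point, rep(0, 6))
  expect_true(all(rr$lo == 0 & rr$hi == 0))
})

test_that("degenerate data are rejected with explicit errors", {
  mf <- one_trait_frame(10, 3, h2 = 0.4, seed = 2)
  mf$value <- 1
  expect_error(mtmm(mf), "zero variance")
  expect_error(mtmm(one_trait_frame(2, 3, 0.4, 1)), "at least 3 strains")
})

test_that("heritability limits are exact in the pure-variance cases", {
  ## fabricated draw sets exercise the algebra at its boundaries
  fake <- structure(list(
    draws = list(G = array(rep(diag(c(1, 0, 1, 1)), 3), c(4, 4, 3),
                           dimnames = list(sporefit:::.traits,
                                           sporefit:::.traits, NULL)),
                 E = matrix(c(0, 1, 1, 1), 3, 4, byrow = TRUE,
                            dimnames = list(NULL, sporefit:::.traits))),
    traits = sporefit:::.traits), class = "mtmm")
  h <- heritability(fake)
  expect_equal(h$point[h$trait == "N"], 1)  # E = 0 -> H2 = 1
  expect_equal(h$point[h$trait == "S"], 0)  # G = 0 -> H2 = 0
})

test_that("posterior-simulated strains mirror the G draws", {
  fake <- structure(list(
    draws = list(G = array(diag(4), c(4, 4, 1),
                           dimnames = list(sporefit:::.traits,
                                           sporefit:::.traits, NULL))),
    traits = sporefit:::.traits), class = "mtmm")
  sim <- simulate(fake, nsim = 10000, seed = 9)
  cm <- cor(sim[, -1])
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.05)
  ## pooled output is standardized to SD units
  expect_equal(unname(apply(sim[, -1], 2, sd)), rep(1, 4), tolerance = 1e-9)
  expect_equal(nrow(simulate(fake, nsim = 0)), 0)
})

test_that("model accessors are coherent", {
  p <- small_params()
  st <- simulate_study(p, seed = 19)
  mf <- model_frame(st$phenotypes, st$mixes)
  fit <- mtmm(mf, chain = mtmm_chain(800, 200, 4), seed = 3)
  expect_equal(dim(vcov(fit)), c(4, 4))
  expect_length(coef(fit), 4)
  expect_equal(length(residuals(fit)), nrow(mf))
  expect_equal(fitted(fit) + residuals(fit), mf$value)
  expect_equal(dim(strain_effects(fit)), c(12, 4))
  s <- summary(fit)
  expect_s3_class(s, "summary.mtmm")
  expect_equal(nrow(s$heritability), 4)
  pl <- posterior_long(fit)
  expect_equal(nrow(pl), 150 * (10 + 4 + 4))
  expect_true(all(c("iteration", "parameter", "value") %in% names(pl)))
})
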