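test_that("pairwise representation pools counts across replicates", {
  m <- data.frame(strain_a = "A", strain_b = "B", replicate = 1L,
                  count_a = 60L, n_counted = 100L)
  cr <- chimeric_representation(m)
  expect_equal(cr$P["A", "B"], 0.6)
  expect_equal(cr$P["B", "A"], 0.4)

  ## pooling weights replicates by spores counted (binomial MLE), not a
  ## mean of per-replicate proportions
  m2 <- data.frame(strain_a = c("A", "A"), strain_b = "B",
                   replicate = 1:2, count_a = c(60L, 10L),
                   n_counted = c(100L, 20L))
  cr2 <- chimeric_representation(m2)
  expect_equal(cr2$P["A", "B"], 70 / 120)

  ## exact 50:50 everywhere gives C_i = 0.5
  m3 <- expand.grid(strain_a = "A", strain_b = c("B", "C"),
                    replicate = 1:2, stringsAsFactors = FALSE)
  m3$count_a <- 50L; m3$n_counted <- 100L
  m3 <- rbind(m3, data.frame(strain_a = "B", strain_b = "C", replicate = 1L,
                             count_a = 50L, n_counted = 100L))
  expect_equal(unname(chimeric_representation(m3)$C), rep(0.5, 3))

  expect_error(chimeric_representation(
    data.frame(strain_a = "A", strain_b = "B", replicate = 1L,
               count_a = 0L, n_counted = 0L)), "n_counted")
})

test_that("per-strain representation equals brute-force pooled means", {
  set.seed(12)
  strains <- c("A", "B", "C")
  m <- expand.grid(a = 1:2, b = 2:3, replicate = 1:3)
  m <- m[m$a < m$b, ]
  mixes <- data.frame(strain_a = strains[m$a], strain_b = strains[m$b],
                      replicate = m$replicate,
                      count_a = rbinom(nrow(m), 100, 0.5),
                      n_counted = 100L)
  cr <- chimeric_representation(mixes)
  for (s in strains) {
    others <- setdiff(strains, s)
    props <- vapply(others, function(o) {
      fwd <- mixes$strain_a == s & mixes$strain_b == o
      rev <- mixes$strain_a == o & mixes$strain_b == s
      (sum(mixes$count_a[fwd]) +
         sum(mixes$n_counted[rev] - mixes$count_a[rev])) /
        (sum(mixes$n_counted[fwd]) + sum(mixes$n_counted[rev]))
    }, numeric(1))
    expect_equal(unname(cr$C[s]), mean(props))
  }
})

test_that("tournament binarization honours the tie tolerance", {
  P <- matrix(c(NA, 0.6, 0.4, NA), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  t0 <- tournament(P)
  expect_equal(t0$wins["A", "B"], 1L)
  expect_equal(t0$wins["B", "A"], 0L)
  expect_equal(nrow(t0$ties), 0L)

  P2 <- P; P2["A", "B"] <- 0.5; P2["B", "A"] <- 0.5
  expect_equal(nrow(tournament(P2)$ties), 1L)

  ## boundary is a tie: |0.65 - 0.5| <= 0.2 with tie_tol = 0.2
  P3 <- P; P3["A", "B"] <- 0.65; P3["B", "A"] <- 0.35
  t3 <- tournament(P3, tie_tol = 0.2)
  expect_equal(sum(t3$wins), 0L)
  expect_equal(nrow(t3$ties), 1L)
})

test_that("triangle transitivity formula is exact in the closed cases", {
  ## fully transitive 4-strain tournament
  W <- matrix(0L, 4, 4)
  W[upper.tri(W)] <- 1L
  tt <- ttri(tournament_from_wins(W))
  expect_equal(tt$p_t, 1)
  expect_equal(tt$t_tri, 1)
  expect_equal(tt$n_triads, 4L)

  ## single 3-cycle
  W3 <- matrix(0L, 3, 3)
  W3[1, 2] <- W3[2, 3] <- W3[3, 1] <- 1L
  tt3 <- ttri(tournament_from_wins(W3))
  expect_equal(tt3$p_t, 0)
  expect_equal(tt3$t_tri, -3)

  ## t_tri = 4 (p_t - 0.75) by definition
  expect_equal(tt$t_tri, 4 * (tt$p_t - 0.75))
})

test_that("triad classification agrees with exhaustive enumeration", {
  ## all 8 orientations of a 3-strain tournament
  for (bits in 0:7) {
    W <- matrix(0L, 3, 3)
    o <- as.integer(intToBits(bits))[1:3]
    if (o[1]) W[1, 2] <- 1L else W[2, 1] <- 1L
    if (o[2]) W[1, 3] <- 1L else W[3, 1] <- 1L
    if (o[3]) W[2, 3] <- 1L else W[3, 2] <- 1L
    trn <- tournament_from_wins(W)
    expect_equal(ttri(trn)$p_t, brute_pt(trn)$p_t)
  }
  ## random complete tournaments of every size up to 6
  set.seed(7)
  for (n in 3:6) for (rep in 1:20) {
    W <- matrix(0L, n, n)
    up <- which(upper.tri(W))
    W[up] <- as.integer(runif(length(up)) < 0.5)
    W[lower.tri(W)] <- (1L - t(W))[lower.tri(W)]
    diag(W) <- 0L
    trn <- tournament_from_wins(W)
    tt <- ttri(trn); bf <- brute_pt(trn)
    expect_equal(tt$p_t, bf$p_t)
    expect_equal(tt$n_triads, bf$n_triads)
    expect_true(tt$t_tri >= -3 && tt$t_tri <= 1)
  }
})

test_that("tournaments with ties exclude incomplete triads", {
  P <- matrix(NA_real_, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  P["a", "b"] <- 0.9; P["b", "a"] <- 0.1
  P["a", "c"] <- 0.8; P["c", "a"] <- 0.2
  P["b", "c"] <- 0.7; P["c", "b"] <- 0.3
  P["a", "d"] <- 0.5; P["d", "a"] <- 0.5   # tie: every d-triad incomplete
  P["b", "d"] <- 0.9; P["d", "b"] <- 0.1
  P["c", "d"] <- 0.9; P["d", "c"] <- 0.1
  tt <- ttri(tournament(P))
  expect_equal(tt$n_triads, 2L)  # abc and bcd only

  ## all ties: no complete triad
  P0 <- matrix(0.5, 3, 3); diag(P0) <- NA
  expect_error(ttri(tournament(P0)), "zero complete")
})

test_that("edge randomization null behaves as expected", {
  ## observed single cycle: every null orientation has t_tri >= -3, so p = 1
  W3 <- matrix(0L, 3, 3)
  W3[1, 2] <- W3[2, 3] <- W3[3, 1] <- 1L
  cyc <- tournament_from_wins(W3)
  res <- ttri_test(cyc, n_perm = 400, seed = 3)
  expect_gte(res$p_value, 0.5)
  expect_equal(res$p_value, 1)

  ## exact 3-strain null: a random orientation is cyclic with prob 1/4,
  ## so for observed t_tri = 1 the p-value converges to 3/4
  W <- matrix(0L, 3, 3); W[upper.tri(W)] <- 1L
  lin <- tournament_from_wins(W)
  res2 <- ttri_test(lin, n_perm = 4000, seed = 5)
  expect_equal(res2$p_value, 0.75, tolerance = 0.03)

  ## n_perm = 0: the add-one correction gives p = 1
  expect_equal(ttri_test(lin, n_perm = 0, seed = 1)$p_value, 1)

  ## E[p_t] = 0.75 under random orientation: mean null t_tri near 0
  set.seed(41)
  W8 <- matrix(0L, 8, 8)
  up <- which(upper.tri(W8))
  W8[up] <- as.integer(runif(length(up)) < 0.5)
  W8[lower.tri(W8)] <- (1L - t(W8))[lower.tri(W8)]
  diag(W8) <- 0L
  res3 <- ttri_test(tournament_from_wins(W8), n_perm = 10000, seed = 11)
  ## per-permutation SD of t_tri for 56 triads is below 0.6, so 3 SE of the
  ## mean over 1e4 permutations is below 0.02
  expect_lt(abs(res3$null_mean_t_tri), 0.02)
})
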