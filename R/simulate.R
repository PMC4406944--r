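#' Draw strain-level genetic effects from the G matrix
#'
#' Samples `n_strains` independent strains from a zero-mean multivariate
#' normal with covariance `params$G`.  A symmetric eigendecomposition square
#' root is used so positive *semi*-definite G (e.g. after PSD repair, or all
#' zero) is handled exactly.
#'
#' @param params a [trait_params()] object.
#' @param seed integer seed; defaults to the seed stored in `params`.
#' @return data.frame with column `strain` and one column per trait
#'   (`g_N`, `g_S`, `g_V`, `g_C`): latent genetic deviations from `mu`.
#' @export
simulate_strains <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "trait_params"))
  set.seed(seed)
  n <- params$n_strains
  ev <- eigen(params$G, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  rt <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))
  g <- matrix(stats::rnorm(n * 4L), n, 4L) %*% rt
  colnames(g) <- paste0("g_", .traits)
  data.frame(strain = strain_ids(n), g, stringsAsFactors = FALSE)
}

strain_ids <- function(n) sprintf("S%03d", seq_len(n))

.effects_matrix <- function(effects) {
  g <- as.matrix(effects[, paste0("g_", .traits)])
  rownames(g) <- effects$strain
  colnames(g) <- .traits
  g
}

#' Simulate replicate-level phenotype assays
#'
#' Emulates the three clonal assays, per strain and replicate:
#' * spore number: `round(exp(mu_N + g_N + e))` with round-half-to-even,
#'   truncated below at 0 (`e ~ N(0, E_N)`);
#' * spore size: `exp(mu_S + g_S + e)` in µm;
#' * viability: `hatched ~ Binomial(n_plated, plogis(mu_V + g_V + e))`,
#'   reported as a (hatched, n_plated) count pair.
#'
#' @param effects output of [simulate_strains()].
#' @param params the [trait_params()] object used to generate `effects`.
#' @param seed integer seed.
#' @return data.frame in long format with columns `strain`, `trait`
#'   (`"N"`, `"S"` or `"V"`), `replicate`, `value` (count, size in µm, or
#'   hatch fraction), `numerator`, `denominator` (NA except for viability).
#' @export
simulate_phenotypes <- function(effects, params, seed = params$seed + 1L) {
  stopifnot(inherits(params, "trait_params"))
  g <- .effects_matrix(effects)
  set.seed(seed)
  ns <- nrow(g)
  nr <- params$n_reps
  E <- params$E
  mu <- params$mu
  one <- function(trait) {
    e <- matrix(stats::rnorm(ns * nr, 0, sqrt(E[trait])), ns, nr)
    lat <- mu[trait] + g[, trait] + e
    switch(trait,
      N = {
        val <- pmax(round(exp(lat)), 0)
        data.frame(strain = rep(rownames(g), nr),
                   trait = "N",
                   replicate = rep(seq_len(nr), each = ns),
                   value = as.vector(val),
                   numerator = NA_integer_, denominator = NA_integer_,
                   stringsAsFactors = FALSE)
      },
      S = data.frame(strain = rep(rownames(g), nr),
                     trait = "S",
                     replicate = rep(seq_len(nr), each = ns),
                     value = as.vector(exp(lat)),
                     numerator = NA_integer_, denominator = NA_integer_,
                     stringsAsFactors = FALSE),
      V = {
        p <- stats::plogis(lat)
        hatched <- matrix(stats::rbinom(ns * nr, params$n_plated, p), ns, nr)
        data.frame(strain = rep(rownames(g), nr),
                   trait = "V",
                   replicate = rep(seq_len(nr), each = ns),
                   value = as.vector(hatched) / params$n_plated,
                   numerator = as.vector(hatched),
                   denominator = params$n_plated,
                   stringsAsFactors = FALSE)
      })
  }
  out <- rbind(one("N"), one("S"), one("V"))
  rownames(out) <- NULL
  out
}

#' Simulate 50:50 pairwise chimera spore counts
#'
#' For every unordered strain pair (i, j) and replicate, the number of focal
#' (strain i) spores among `n_counted` counted is drawn from a binomial with
#' success probability `plogis(eta_i - eta_j)` — a Bradley–Terry model on the
#' latent competitiveness scale, which makes the implied dominance hierarchy
#' probabilistically transitive.  `eta = mu_C + g_C + e`, where the replicate
#' noise `e ~ N(0, E_C)` is drawn once per strain and replicate (the strain's
#' competitive state in that replicate, shared across all its mixes), so the
#' replicate-level variance of competitiveness is identifiable downstream.
#'
#' Only the `strain_a < strain_b` orientation is stored; the reverse count is
#' `n_counted - count_a` by construction.
#'
#' @inheritParams simulate_phenotypes
#' @return data.frame with columns `strain_a`, `strain_b`, `replicate`,
#'   `count_a`, `n_counted`.
#' @export
simulate_mixes <- function(effects, params, seed = params$seed + 2L) {
  stopifnot(inherits(params, "trait_params"))
  g <- .effects_matrix(effects)
  ns <- nrow(g)
  if (ns < 2L) stop("need at least 2 strains to mix", call. = FALSE)
  set.seed(seed)
  nr <- params$n_reps
  ids <- rownames(g)
  pair <- utils::combn(ns, 2L)
  np <- ncol(pair)
  out <- vector("list", nr)
  for (r in seq_len(nr)) {
    eta <- params$mu["C"] + g[, "C"] +
      stats::rnorm(ns, 0, sqrt(params$E["C"]))
    p <- stats::plogis(eta[pair[1L, ]] - eta[pair[2L, ]])
    cnt <- stats::rbinom(np, params$n_counted, p)
    out[[r]] <- data.frame(strain_a = ids[pair[1L, ]],
                           strain_b = ids[pair[2L, ]],
                           replicate = r,
                           count_a = cnt,
                           n_counted = params$n_counted,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_strains()], [simulate_phenotypes()] and [simulate_mixes()]
#' with seeds derived deterministically from one base seed, and returns all
#' three tables plus the generating truth.
#'
#' @param params a [trait_params()] object.
#' @param seed base integer seed (default: the seed stored in `params`).
#' @return list with elements `effects`, `phenotypes`, `mixes`, `params`,
#'   `seed`, of class `"spore_study"`.
#' @export
simulate_study <- function(params = trait_params(), seed = params$seed) {
  seeds <- stage_seeds(seed)
  effects <- simulate_strains(params, seed = seeds[["strains"]])
  phen <- simulate_phenotypes(effects, params, seed = seeds[["phenotypes"]])
  mixes <- simulate_mixes(effects, params, seed = seeds[["mixes"]])
  structure(list(effects = effects, phenotypes = phen, mixes = mixes,
                 params = params, seed = as.integer(seed)),
            class = "spore_study")
}

#' Derive per-stage sub-seeds from one base seed
#'
#' Stages use distinct deterministic seeds so each stage can be re-run in
#' isolation.  `stage_seed = (97 * seed + offset) mod (2^31 - 1)`.
#'
#' @param seed base integer seed.
#' @return named integer vector of stage seeds.
#' @export
stage_seeds <- function(seed) {
  stages <- c(strains = 1L, phenotypes = 2L, mixes = 3L,
              fit = 4L, hierarchy = 5L, posterior = 6L)
  s <- (97 * as.double(seed) + stages) %% (2^31 - 1)
  stats::setNames(as.integer(s), names(stages))
}

#' @export
print.spore_study <- function(x, ...) {
  cat(sprintf("Synthetic spore study: %d strains, %d replicates/trait (seed %d)\n",
              x$params$n_strains, x$params$n_reps, x$seed))
  cat(sprintf("  phenotype rows: %d; mix rows: %d\n",
              nrow(x$phenotypes), nrow(x$mixes)))
  invisible(x)
}

#' Write / read study tables as CSV and the truth as JSON
#'
#' `write_study()` writes `phenotypes.csv`, `mixes.csv` and `truth.json`
#' (generative parameters plus true strain effects, for recovery tests) into
#' a directory.  Output is plain RFC-4180 CSV with a header row; identical
#' studies produce byte-identical files.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "spore_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(phenotypes = file.path(dir, "phenotypes.csv"),
             mixes = file.path(dir, "mixes.csv"),
             truth = file.path(dir, "truth.json"))
  .write_csv(study$phenotypes, paths[["phenotypes"]])
  .write_csv(study$mixes, paths[["mixes"]])
  truth <- list(schema_version = 1L,
                params = unclass(study$params),
                effects = study$effects,
                seed = study$seed)
  jsonlite::write_json(truth, paths[["truth"]], digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' @rdname write_study
#' @param path path to `truth.json`.
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- truth$params
  params <- trait_params(h2 = unlist(p$h2), mu = unlist(p$mu),
                         r = .r_from_matrix(matrix(unlist(p$R), 4, 4)),
                         n_strains = p$n_strains, n_reps = p$n_reps,
                         n_plated = p$n_plated, n_counted = p$n_counted,
                         seed = p$seed)
  list(params = params, effects = truth$effects, seed = truth$seed)
}

.r_from_matrix <- function(R) {
  dimnames(R) <- list(.traits, .traits)
  stats::setNames(vapply(.trait_pairs, function(pair)
    R[substr(pair, 1, 1), substr(pair, 2, 2)], numeric(1)), .trait_pairs)
}

.write_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
}
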