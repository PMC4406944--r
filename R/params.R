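#' Assemble generative parameters from heritability and correlation targets
#'
#' Builds the strain-level genetic covariance matrix G and replicate-level
#' residual variances E for the four traits — spore number (N), spore size
#' (S), spore viability (V) and competitiveness/chimeric representation (C) —
#' from target broad-sense heritabilities and pairwise genetic correlations.
#' Phenotypic variance is fixed at 1 per trait on the modelling scale (log
#' spore count, log spore size, logit viability, logit competitiveness), so
#' `G[t,t] = h2[t]` and `E[t] = 1 - h2[t]`.
#'
#' The correlation matrix assembled from `r` must be positive semi-definite.
#' If its smallest eigenvalue is negative but no smaller than `-0.05` the
#' matrix is repaired by eigenvalue clipping at zero followed by
#' re-normalization to unit diagonal (nearest-PSD projection); the repair is
#' recorded in the returned object.  A smallest eigenvalue below `-0.05` is an
#' error: printed pairwise estimates that far from joint validity are not
#' accepted.
#'
#' Defaults are the published estimates for the North Carolina
#' *D. discoideum* isolates: heritabilities (0.25, 0.59, 0.62, 0.35) and
#' genetic correlations (NS -0.72, SV 0.86, NV -0.54, NC 0.50, SC -0.55,
#' VC -0.69).  That correlation matrix is positive definite (smallest
#' eigenvalue 0.078), so no repair occurs for the defaults.
#'
#' @param h2 named numeric(4), broad-sense heritability per trait, each in
#'   `[0, 1)`; names `c("N","S","V","C")` (order enforced).
#' @param r named numeric(6), genetic correlations for the unordered trait
#'   pairs, names among `c("NS","SV","NV","NC","SC","VC")`, each in (-1, 1).
#' @param mu numeric(4), trait means on the modelling scale: log spore count,
#'   log spore size (µm), logit viability, logit competitiveness.
#' @param n_strains,n_reps number of strains and replicates per trait.
#' @param n_plated spores plated per viability assay replicate.
#' @param n_counted spores counted per chimera replicate.
#' @param seed default integer seed used by the simulators.
#' @return An object of class `"trait_params"`: a list with elements
#'   `mu`, `G`, `E`, `h2`, `R` (the possibly repaired correlation matrix),
#'   `n_strains`, `n_reps`, `n_plated`, `n_counted`, `seed`, and `psd_repair`
#'   (a list recording the smallest eigenvalue before repair and whether a
#'   repair was applied).
#' @seealso [simulate_strains()], [simulate_study()]
#' @examples
#' p <- trait_params()
#' p$G["N", "N"]   # 0.25: heritability of spore number
#' p$psd_repair$repaired
#' @export
trait_params <- function(h2 = c(N = 0.25, S = 0.59, V = 0.62, C = 0.35),
                         r = c(NS = -0.72, SV = 0.86, NV = -0.54,
                               NC = 0.50, SC = -0.55, VC = -0.69),
                         mu = c(N = log(2e5), S = log(6.5), V = 1.1, C = 0),
                         n_strains = 24L, n_reps = 4L,
                         n_plated = 100L, n_counted = 500L,
                         seed = 1L) {
  h2 <- .check_named4(h2, "h2")
  mu <- .check_named4(mu, "mu")
  if (any(h2 < 0 | h2 >= 1))
    stop("all heritabilities must lie in [0, 1)", call. = FALSE)
  if (any(!is.finite(mu)))
    stop("trait means must be finite", call. = FALSE)
  if (length(r) != 6L || is.null(names(r)) || !setequal(names(r), .trait_pairs))
    stop("'r' must be a named numeric(6) with names ",
         paste(.trait_pairs, collapse = ", "), call. = FALSE)
  if (any(abs(r) >= 1))
    stop("all genetic correlations must lie in (-1, 1)", call. = FALSE)
  n_strains <- .check_count(n_strains, "n_strains")
  n_reps <- .check_count(n_reps, "n_reps")
  n_plated <- .check_count(n_plated, "n_plated")
  n_counted <- .check_count(n_counted, "n_counted")

  R <- diag(4)
  dimnames(R) <- list(.traits, .traits)
  for (pair in .trait_pairs) {
    a <- substr(pair, 1, 1); b <- substr(pair, 2, 2)
    R[a, b] <- R[b, a] <- unname(r[pair])
  }
  rep_info <- psd_repair(R)
  R <- rep_info$matrix

  sd_g <- sqrt(h2)
  G <- R * (sd_g %o% sd_g)
  E <- 1 - h2

  structure(list(mu = mu, G = G, E = E, h2 = h2, R = R,
                 n_strains = n_strains, n_reps = n_reps,
                 n_plated = n_plated, n_counted = n_counted,
                 seed = as.integer(seed),
                 psd_repair = rep_info[c("min_eigenvalue", "repaired")]),
            class = "trait_params")
}

#' Nearest-PSD repair of a correlation matrix by eigenvalue clipping
#'
#' Checks a symmetric correlation matrix for positive semi-definiteness.  If
#' the smallest eigenvalue is in `(-0.05, 0)` the matrix is projected to the
#' nearest positive semi-definite matrix by clipping negative eigenvalues at
#' zero and re-normalizing to unit diagonal.  A smallest eigenvalue of
#' `-0.05` or below is an error.
#'
#' @param R symmetric correlation matrix (unit diagonal).
#' @param tol eigenvalues above `-tol` count as non-negative (no repair).
#' @return list with `matrix` (possibly repaired), `min_eigenvalue` (before
#'   repair) and `repaired` (logical).
#' @export
psd_repair <- function(R, tol = 1e-10) {
  if (!isSymmetric(unname(R), tol = 1e-8))
    stop("correlation matrix must be symmetric", call. = FALSE)
  ev <- eigen(R, symmetric = TRUE)
  min_ev <- min(ev$values)
  if (min_ev >= -tol)
    return(list(matrix = R, min_eigenvalue = min_ev, repaired = FALSE))
  if (min_ev < -0.05)
    stop(sprintf(paste0("correlation matrix is irreparably non-PSD ",
                        "(smallest eigenvalue %.4f < -0.05)"), min_ev),
         call. = FALSE)
  lam <- pmax(ev$values, 0)
  M <- ev$vectors %*% (lam * t(ev$vectors))
  d <- sqrt(diag(M))
  M <- M / (d %o% d)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  dimnames(M) <- dimnames(R)
  list(matrix = M, min_eigenvalue = min_ev, repaired = TRUE)
}

#' @export
print.trait_params <- function(x, ...) {
  cat("Generative trait parameters (traits N, S, V, C)\n")
  cat(sprintf("  %d strains, %d replicates/trait; %d plated, %d counted\n",
              x$n_strains, x$n_reps, x$n_plated, x$n_counted))
  cat("  heritabilities:", paste(sprintf("%s=%.2f", .traits, x$h2),
                                 collapse = " "), "\n")
  cat("  genetic correlations:\n")
  print(round(x$R, 3))
  if (isTRUE(x$psd_repair$repaired))
    cat(sprintf("  (correlation matrix repaired; smallest eigenvalue was %.4f)\n",
                x$psd_repair$min_eigenvalue))
  invisible(x)
}

.check_named4 <- function(x, what) {
  if (length(x) != 4L)
    stop(sprintf("'%s' must have length 4 (traits N, S, V, C)", what),
         call. = FALSE)
  if (is.null(names(x))) names(x) <- .traits
  if (!setequal(names(x), .traits))
    stop(sprintf("'%s' must be named with traits N, S, V, C", what),
         call. = FALSE)
  x[.traits]
}

.check_count <- function(x, what) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != round(x))
    stop(sprintf("'%s' must be a positive integer", what), call. = FALSE)
  as.integer(x)
}
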