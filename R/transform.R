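#' Empirical logit
#'
#' `log((x + 0.5) / (n - x + 0.5))` — finite at `x = 0` and `x = n`, unlike
#' the raw logit of a count fraction.
#'
#' @param x successes (numeric).
#' @param n trials (numeric).
#' @return numeric on the logit scale.
#' @export
emp_logit <- function(x, n) {
  stopifnot(all(x >= 0 & x <= n))
  log((x + 0.5) / (n - x + 0.5))
}

#' Per-replicate competitiveness phenotypes from mix counts
#'
#' Converts the pairwise chimera count table into a replicate-level
#' competitiveness observation per strain: the mean, over all partners mixed
#' with in that replicate, of the empirical logit of the focal spore
#' fraction.  Under the Bradley–Terry generative model this is, up to a
#' shared per-replicate constant, the strain's latent competitiveness
#' `mu_C + g_C + e` plus small counting noise, so it carries the trait onto
#' the same modelling scale as the other traits.
#'
#' @param mixes data.frame with columns `strain_a`, `strain_b`, `replicate`,
#'   `count_a`, `n_counted` (one orientation per pair is sufficient).
#' @return data.frame `strain`, `trait = "C"`, `replicate`, `value`,
#'   `numerator`, `denominator` (counts NA: the value is a partner mean).
#' @export
mix_phenotypes <- function(mixes) {
  .check_mixes(mixes)
  ela <- emp_logit(mixes$count_a, mixes$n_counted)
  long <- data.frame(
    strain = c(mixes$strain_a, mixes$strain_b),
    replicate = rep(mixes$replicate, 2L),
    el = c(ela, -ela))
  agg <- stats::aggregate(el ~ strain + replicate, data = long, FUN = mean)
  data.frame(strain = agg$strain, trait = "C", replicate = agg$replicate,
             value = agg$el,
             numerator = NA_integer_, denominator = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Assemble the modelling-scale phenotype frame
#'
#' Joins the clonal assay table and (optionally) the mix-count table into the
#' long-format frame consumed by [mtmm()] and [genotypic_means()], applying
#' the modelling transforms: log spore count, log spore size, empirical-logit
#' viability, and the mean empirical-logit representation from
#' [mix_phenotypes()].
#'
#' @param phenotypes data.frame as written by [simulate_phenotypes()] (raw
#'   assay scale: counts, µm, hatch count pairs).
#' @param mixes optional mix-count table; if supplied, competitiveness (C)
#'   is added as a fourth trait.
#' @return data.frame `strain`, `trait`, `replicate`, `value` with values on
#'   the modelling scale.
#' @export
model_frame <- function(phenotypes, mixes = NULL) {
  need <- c("strain", "trait", "replicate", "value")
  if (!all(need %in% names(phenotypes)))
    stop("'phenotypes' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ph <- phenotypes
  val <- ph$value
  tr <- ph$trait
  out <- ph[need]
  out$value[tr == "N"] <- log(pmax(val[tr == "N"], 0.5))  # guard zero counts
  out$value[tr == "S"] <- log(val[tr == "S"])
  isv <- tr == "V"
  if (any(isv)) {
    if (!all(c("numerator", "denominator") %in% names(ph)) ||
        anyNA(ph$numerator[isv]) || anyNA(ph$denominator[isv]))
      stop("viability rows need numerator/denominator counts", call. = FALSE)
    out$value[isv] <- emp_logit(ph$numerator[isv], ph$denominator[isv])
  }
  if (!is.null(mixes)) {
    cm <- mix_phenotypes(mixes)
    out <- rbind(out, cm[need])
  }
  if (any(!is.finite(out$value)))
    stop("non-finite values after transform", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Standardized per-strain genotypic means
#'
#' Averages replicates per strain and trait on the modelling scale, then
#' z-scores each trait across strains (mean 0, SD 1; `stats::sd`, n-1
#' divisor).  These are the red "genotypic mean" points of trait–trait
#' scatter plots, in standard deviation units.
#'
#' @param data modelling-scale frame from [model_frame()].
#' @return matrix (strains x traits) of standardized genotypic means.
#' @export
genotypic_means <- function(data) {
  traits <- sort(unique(data$trait))
  strains <- sort(unique(data$strain))
  if (length(strains) < 2L)
    stop("need at least 2 strains to standardize genotypic means",
         call. = FALSE)
  m <- matrix(NA_real_, length(strains), length(traits),
              dimnames = list(strains, traits))
  agg <- stats::aggregate(value ~ strain + trait, data = data, FUN = mean)
  m[cbind(agg$strain, agg$trait)] <- agg$value
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf("strain %s has no observations for trait %s",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]),
         call. = FALSE)
  }
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("a trait has zero variance across strains; cannot standardize",
         call. = FALSE)
  scale(m, center = TRUE, scale = sds)[, , drop = FALSE]
}

.check_mixes <- function(mixes) {
  need <- c("strain_a", "strain_b", "replicate", "count_a", "n_counted")
  if (!all(need %in% names(mixes)))
    stop("mix table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(mixes$strain_a == mixes$strain_b))
    stop("self-mixes (strain_a == strain_b) are not allowed", call. = FALSE)
  if (any(mixes$n_counted < 1))
    stop("every mix replicate must have n_counted >= 1", call. = FALSE)
  if (any(mixes$count_a < 0 | mixes$count_a > mixes$n_counted))
    stop("counts must satisfy 0 <= count_a <= n_counted", call. = FALSE)
  invisible(mixes)
}
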