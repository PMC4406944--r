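#' Pooled viability per strain
#'
#' Hatch fraction per strain, pooling counts over replicates (sum of hatched
#' over sum of plated — the binomial maximum-likelihood estimate).
#'
#' @param phenotypes assay table from [simulate_phenotypes()] (or any table
#'   with `strain`, `trait == "V"`, `numerator`, `denominator`).
#' @return named numeric vector of hatch fractions in `[0, 1]`.
#' @export
pooled_viability <- function(phenotypes) {
  v <- phenotypes[phenotypes$trait == "V", , drop = FALSE]
  if (nrow(v) == 0L) stop("no viability rows in phenotype table",
                          call. = FALSE)
  num <- tapply(v$numerator, v$strain, sum)
  den <- tapply(v$denominator, v$strain, sum)
  out <- num / den
  out[sort(names(out))]
}

#' Realized social fitness: representation times viability
#'
#' `w_i = C_i * V_i`, the proportional representation of a strain in the
#' chimeric sporehead discounted by the viability of the spores it makes.
#' A strain overrepresented in the sporehead gains nothing if its extra
#' spores do not hatch — `w` is the composite measure on which "cheating"
#' is actually selected.
#'
#' @param C named per-strain chimeric representation in `[0, 1]` (e.g. the
#'   `C` element of [chimeric_representation()]).
#' @param V named per-strain viability in `[0, 1]` (e.g.
#'   [pooled_viability()]).
#' @param traits optional matrix of standardized genotypic means
#'   ([genotypic_means()]); matched columns `N` and `S` are joined as
#'   `N_sd`, `S_sd`.
#' @return data.frame of class `"fitness_table"`: `strain`, `C`, `V`, `w`
#'   (plus `N_sd`, `S_sd` when `traits` is given).
#' @export
realized_fitness <- function(C, V, traits = NULL) {
  if (is.null(names(C)) || is.null(names(V)))
    stop("'C' and 'V' must be named by strain", call. = FALSE)
  if (!setequal(names(C), names(V)))
    stop("strain sets of 'C' and 'V' do not match", call. = FALSE)
  strains <- sort(names(C))
  C <- C[strains]; V <- V[strains]
  if (any(C < 0 | C > 1) || any(V < 0 | V > 1))
    stop("'C' and 'V' must lie in [0, 1]", call. = FALSE)
  out <- data.frame(strain = strains, C = unname(C), V = unname(V),
                    w = unname(C * V), stringsAsFactors = FALSE)
  if (!is.null(traits)) {
    if (!all(strains %in% rownames(traits)))
      stop("'traits' is missing strains present in C/V", call. = FALSE)
    for (t in intersect(c("N", "S"), colnames(traits)))
      out[[paste0(t, "_sd")]] <- traits[strains, t]
  }
  class(out) <- c("fitness_table", "data.frame")
  out
}

#' Polynomial selection-surface fit with confidence intervals
#'
#' Ordinary least squares of `y` on a raw polynomial basis in `x` of the
#' given degree, with 95% coefficient confidence intervals from the
#' t-distribution on residual degrees of freedom and a pointwise confidence
#' band on a grid.  The surface is "flat" when every non-intercept
#' coefficient interval contains zero.
#'
#' @param x predictor (typically a standardized trait).
#' @param y response (fitness, representation, ...).
#' @param degree 1 (line) or 2 (quadratic curve).
#' @param level confidence level for intervals and band.
#' @param grid_n points in the exported confidence band grid.
#' @return object of class `"surface_fit"`: `coefficients` (matrix with
#'   `estimate`, `lo`, `hi`), `flat_flag`, `degree`, `band` (data.frame
#'   `x`, `fit`, `lo`, `hi`), and the underlying `lm` fit.
#' @export
fit_surface <- function(x, y, degree = 1L, level = 0.95, grid_n = 50L) {
  degree <- as.integer(degree)
  stopifnot(degree >= 1L, length(x) == length(y))
  if (length(x) < degree + 2L)
    stop("need at least degree + 2 points", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("predictor has zero variance; surface is degenerate", call. = FALSE)
  df <- data.frame(x = x, y = y)
  fit <- stats::lm(y ~ poly(x, degree, raw = TRUE), data = df)
  ci <- stats::confint(fit, level = level)
  co <- cbind(estimate = stats::coef(fit), lo = ci[, 1], hi = ci[, 2])
  rownames(co) <- c("(Intercept)", paste0("x^", seq_len(degree)))
  flat <- all(co[-1, "lo"] <= 0 & co[-1, "hi"] >= 0)
  grid <- data.frame(x = seq(min(x), max(x), length.out = grid_n))
  band <- stats::predict(fit, newdata = grid, interval = "confidence",
                         level = level)
  structure(list(coefficients = co, flat_flag = flat, degree = degree,
                 level = level,
                 band = data.frame(x = grid$x, fit = band[, "fit"],
                                   lo = band[, "lwr"], hi = band[, "upr"]),
                 lm = fit), class = "surface_fit")
}

#' @export
print.surface_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Degree-%d selection surface (%s)\n", x$degree,
              if (x$flat_flag) "flat: all non-intercept CIs contain 0"
              else "non-flat"))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
predict.surface_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$band)
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  stats::predict(object$lm, newdata = data.frame(x = x), ...)
}

#' Fitness-surface flatness report
#'
#' Fits the quadratic surfaces of realized social fitness `w` on
#' standardized spore size and spore number, and the linear surfaces of
#' chimeric representation `C` on standardized number, size and viability.
#' The report contrasts the two: representation responds to the underlying
#' traits while realized fitness — representation discounted by viability —
#' does not, which is what makes apparent "cheating" effectively neutral.
#'
#' @param fitness a [realized_fitness()] table.
#' @param traits standardized genotypic means ([genotypic_means()]) for the
#'   same strains; must contain columns `N` and `S` (and `V` if available).
#' @param source label recorded in the report: `"genotypic"` for observed
#'   strain means, `"posterior"` for posterior-simulated strains.
#' @return object of class `"flatness_report"`: list of `surface_fit`s
#'   (`w_on_S`, `w_on_N`, `C_on_N`, `C_on_S`, `C_on_V`), logical
#'   `flat_w_on_S`, `flat_w_on_N`, and `source`.
#' @export
flatness_report <- function(fitness, traits, source = "genotypic") {
  stopifnot(inherits(fitness, "fitness_table"))
  if (nrow(fitness) == 0L) stop("empty strain set", call. = FALSE)
  if (!all(fitness$strain %in% rownames(traits)))
    stop("'traits' is missing strains present in the fitness table",
         call. = FALSE)
  tr <- traits[fitness$strain, , drop = FALSE]
  out <- list(
    w_on_S = fit_surface(tr[, "S"], fitness$w, degree = 2L),
    w_on_N = fit_surface(tr[, "N"], fitness$w, degree = 2L),
    C_on_N = fit_surface(tr[, "N"], fitness$C, degree = 1L),
    C_on_S = fit_surface(tr[, "S"], fitness$C, degree = 1L))
  if ("V" %in% colnames(tr))
    out$C_on_V <- fit_surface(tr[, "V"], fitness$C, degree = 1L)
  out$flat_w_on_S <- out$w_on_S$flat_flag
  out$flat_w_on_N <- out$w_on_N$flat_flag
  out$source <- source
  class(out) <- "flatness_report"
  out
}

#' @export
print.flatness_report <- function(x, ...) {
  cat(sprintf("Fitness-surface flatness report (%s strains)\n", x$source))
  cat(sprintf("  w ~ size    (quadratic): %s\n",
              if (x$flat_w_on_S) "flat" else "non-flat"))
  cat(sprintf("  w ~ number  (quadratic): %s\n",
              if (x$flat_w_on_N) "flat" else "non-flat"))
  for (nm in intersect(c("C_on_N", "C_on_S", "C_on_V"), names(x))) {
    co <- x[[nm]]$coefficients
    cat(sprintf("  C ~ %s (linear): slope %.3f [%.3f, %.3f]%s\n",
                sub("C_on_", "", nm), co[2, 1], co[2, 2], co[2, 3],
                if (x[[nm]]$flat_flag) "" else " *"))
  }
  invisible(x)
}
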