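#' Default pipeline configuration
#'
#' Flat key-value configuration covering every tunable of the pipeline:
#' generative parameters, model priors, chain lengths, permutation count and
#' tie tolerance.  Values mirror the defaults of [trait_params()],
#' [mtmm_priors()], [mtmm_chain()], [tournament()] and [ttri_test()].
#'
#' @return named list of class `"run_config"`.
#' @export
default_config <- function() {
  structure(list(
    n_strains = 24L, n_reps = 4L, n_plated = 100L, n_counted = 500L,
    mu_N = log(2e5), mu_S = log(6.5), mu_V = 1.1, mu_C = 0,
    h2_N = 0.25, h2_S = 0.59, h2_V = 0.62, h2_C = 0.35,
    r_NS = -0.72, r_SV = 0.86, r_NV = -0.54,
    r_NC = 0.50, r_SC = -0.55, r_VC = -0.69,
    prior_nu0 = 5, prior_psi0_scale = 0.1,
    prior_nuE = 1, prior_s2E = 0.5, prior_mu_var = 1e8,
    chain_iterations = 20000L, chain_burnin = 5000L, chain_thin = 10L,
    n_perm = 10000L, tie_tol = 0,
    n_posterior_strains = 4L), class = "run_config")
}

#' Read / write a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment.  Unknown keys are
#' rejected; missing keys take their defaults.  A written configuration
#' read back is identical (lossless round-trip).
#'
#' @param path file path.
#' @return `read_config()`: a `"run_config"` list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- default_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg))
      stop("unknown config key: ", key, call. = FALSE)
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num)) stop("non-numeric config value for ", key, call. = FALSE)
    cfg[[key]] <- if (is.integer(default_config()[[key]])) as.integer(num)
                  else num
  }
  cfg
}

#' @rdname read_config
#' @param config a `"run_config"` list.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  writeLines(sprintf("%s = %.17g", names(config),
                     vapply(config, as.numeric, numeric(1))), path)
  invisible(path)
}

.params_from_config <- function(cfg, seed) {
  trait_params(
    h2 = c(N = cfg$h2_N, S = cfg$h2_S, V = cfg$h2_V, C = cfg$h2_C),
    r = c(NS = cfg$r_NS, SV = cfg$r_SV, NV = cfg$r_NV,
          NC = cfg$r_NC, SC = cfg$r_SC, VC = cfg$r_VC),
    mu = c(N = cfg$mu_N, S = cfg$mu_S, V = cfg$mu_V, C = cfg$mu_C),
    n_strains = cfg$n_strains, n_reps = cfg$n_reps,
    n_plated = cfg$n_plated, n_counted = cfg$n_counted,
    seed = seed)
}

#' Run the full pipeline: simulate, fit, hierarchy, fitness, report
#'
#' Executes the five stages in order with per-stage seeds derived
#' deterministically from the global seed ([stage_seeds()]), writing
#' `phenotypes.csv`, `mixes.csv`, `truth.json`, `posterior.csv`,
#' `estimates.json`, `hierarchy.json`, `fitness.csv`, `surfaces.json` and a
#' consolidated `report.json` into `out_dir`.  Any stage failure aborts with
#' the stage name.  Identical configuration and seed reproduce every output
#' byte-identically.
#'
#' @param config a `"run_config"` list (see [default_config()],
#'   [read_config()]).
#' @param seed global integer seed.
#' @param out_dir output directory (created if missing).
#' @return object of class `"run_report"` (also serialized as
#'   `report.json`).
#' @export
run_pipeline <- function(config = default_config(), seed = 1L,
                         out_dir = tempfile("sporefit_run")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- stage_seeds(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ## -- simulate ------------------------------------------------------------
  sim <- stage("simulate", {
    params <- .params_from_config(config, seed)
    study <- simulate_study(params, seed = seed)
    write_study(study, out_dir)
    study
  })

  ## -- hierarchy -----------------------------------------------------------
  hier <- stage("hierarchy", {
    rep <- chimeric_representation(sim$mixes)
    trn <- tournament(rep, tie_tol = config$tie_tol)
    tt <- ttri_test(trn, n_perm = config$n_perm,
                    seed = seeds[["hierarchy"]])
    out <- list(schema_version = 1L,
                C = as.list(rep$C), P = rep$P, wins = trn$wins,
                n_ties = nrow(trn$ties),
                p_t = tt$p_t, t_tri = tt$t_tri, p_value = tt$p_value,
                n_perm = tt$n_perm, tie_tol = config$tie_tol,
                seed = unname(seeds[["hierarchy"]]))
    jsonlite::write_json(out, file.path(out_dir, "hierarchy.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    list(rep = rep, tt = tt)
  })

  ## -- fit -----------------------------------------------------------------
  fit <- stage("fit", {
    mf <- model_frame(sim$phenotypes, sim$mixes)
    priors <- mtmm_priors(nu0 = config$prior_nu0,
                          psi0_scale = config$prior_psi0_scale,
                          nuE = config$prior_nuE, s2E = config$prior_s2E,
                          mu_var = config$prior_mu_var)
    ch <- mtmm_chain(iterations = config$chain_iterations,
                     burnin = config$chain_burnin,
                     thin = config$chain_thin)
    f <- mtmm(mf, priors = priors, chain = ch, seed = seeds[["fit"]])
    .write_csv(posterior_long(f), file.path(out_dir, "posterior.csv"))
    est <- list(schema_version = 1L,
                heritability = heritability(f),
                correlations = gen_correlations(f)$pairs,
                rhat = as.list(f$rhat), converged = f$converged,
                seed = unname(seeds[["fit"]]))
    jsonlite::write_json(est, file.path(out_dir, "estimates.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    f
  })

  ## -- fitness -------------------------------------------------------------
  fitn <- stage("fitness", {
    mf <- model_frame(sim$phenotypes, sim$mixes)
    gm <- genotypic_means(mf)
    V <- pooled_viability(sim$phenotypes)
    ft <- realized_fitness(hier$rep$C, V, traits = gm)
    fr <- flatness_report(ft, gm, source = "genotypic")
    .write_csv(ft, file.path(out_dir, "fitness.csv"))
    surf <- lapply(fr[c("w_on_S", "w_on_N", "C_on_N", "C_on_S", "C_on_V")],
                   function(s) list(degree = s$degree,
                                    coefficients = s$coefficients,
                                    flat_flag = s$flat_flag,
                                    band = s$band))
    surf$schema_version <- 1L
    surf$source <- fr$source
    jsonlite::write_json(surf, file.path(out_dir, "surfaces.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    list(table = ft, report = fr)
  })

  ## -- report --------------------------------------------------------------
  report <- stage("report", {
    cfg_file <- file.path(out_dir, "config.txt")
    write_config(config, cfg_file)
    rep <- list(
      schema_version = 1L,
      package_version = as.character(utils::packageVersion("sporefit")),
      seed = as.integer(seed), stage_seeds = as.list(seeds),
      config_hash = unname(tools::md5sum(cfg_file)),
      psd_repair = sim$params$psd_repair,
      heritability = heritability(fit),
      correlations = gen_correlations(fit)$pairs,
      converged = fit$converged, rhat = as.list(fit$rhat),
      t_tri = hier$tt$t_tri, p_t = hier$tt$p_t,
      t_tri_p_value = hier$tt$p_value,
      flat_w_on_S = fitn$report$flat_w_on_S,
      flat_w_on_N = fitn$report$flat_w_on_N,
      files = list.files(out_dir))
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    rep$report_hash <- unname(tools::md5sum(file.path(out_dir, "report.json")))
    rep
  })

  structure(c(report, list(out_dir = out_dir)), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("sporefit pipeline run\n")
  cat(sprintf("  output: %s\n  seed: %d (config hash %s)\n", x$out_dir,
              x$seed, x$config_hash))
  h <- x$heritability
  cat("  H2:", paste(sprintf("%s=%.2f", h$trait, h$point), collapse = " "),
      "\n")
  r <- x$correlations
  cat("  r :", paste(sprintf("%s=%.2f", r$pair, r$point), collapse = " "),
      "\n")
  cat(sprintf("  t_tri = %.3f (p = %.4g); w-surface flat: size %s, number %s\n",
              x$t_tri, x$t_tri_p_value, x$flat_w_on_S, x$flat_w_on_N))
  invisible(x)
}
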