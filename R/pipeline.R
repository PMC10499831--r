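# End-to-end orchestration: load or simulate the four input tables, build the
# condition index and fitness, fit the selection and vital-rate models, and
# assemble a serialisable report. Each analysis section is isolated: a failed
# or unconverged section is recorded as failed without aborting the others.

#' Pipeline configuration
#'
#' Exactly one of `simulate` (a [sim_config()]) or `paths` (named list with
#' `individuals`, `fitness`, `encounters`, `popseries` CSV paths) must be
#' supplied. A YAML file with the same structure can be loaded with
#' [read_pipeline_config()].
#'
#' @param simulate A [sim_config()], or `NULL` when reading from files.
#' @param paths Named list of input CSV paths, or `NULL` when simulating.
#' @param trait Trait whose normalised value enters the selection models:
#'   `"condition"` (residual mass-on-tarsus index, default), `"mass"`, or
#'   `"tarsus"`.
#' @param boundary_year First year of the high-density period.
#' @param years Optional length-2 analysis window (inclusive).
#' @param optima_N Population sizes at which the fitness-maximising
#'   phenotype is evaluated.
#' @param mcmc An [mcmc_config()].
#' @param vital_candidates Named list of term sets for vital-rate model
#'   selection.
#' @param seed Integer seed for any stage randomness.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL,
                            trait = c("condition", "mass", "tarsus"),
                            boundary_year = 1996L, years = NULL,
                            optima_N = c(566, 800, 1071),
                            mcmc = mcmc_config(),
                            vital_candidates = list(
                              intercept = character(),
                              x = "x",
                              x_N = c("x", "N"),
                              x_N_int = c("x", "N", "x:N")),
                            seed = 1L) {
  trait <- match.arg(trait)
  if (is.null(simulate) == is.null(paths))
    stop("supply exactly one of 'simulate' or 'paths'", call. = FALSE)
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  if (!is.null(paths)) {
    need <- c("individuals", "fitness", "encounters", "popseries")
    if (!all(need %in% names(paths)))
      stop("'paths' must name: ", paste(need, collapse = ", "), call. = FALSE)
    missing <- !vapply(paths[need], file.exists, logical(1))
    if (any(missing))
      stop("input file(s) not found: ",
           paste(unlist(paths[need][missing]), collapse = ", "), call. = FALSE)
  }
  structure(list(simulate = simulate, paths = paths, trait = trait,
                 boundary_year = as.integer(boundary_year), years = years,
                 optima_N = optima_N, mcmc = mcmc,
                 vital_candidates = lapply(vital_candidates, .vital_terms),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys mirror the [pipeline_config()]
#'   arguments, with `simulate` and `mcmc` given as nested maps of
#'   [sim_config()] / [mcmc_config()] arguments (`true_params` as a map of
#'   the six selection parameters).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    if (!is.null(y$simulate$true_params))
      y$simulate$true_params <- as_dd_params(y$simulate$true_params)
    y$simulate <- do.call(sim_config, y$simulate)
  }
  if (!is.null(y$mcmc)) y$mcmc <- do.call(mcmc_config, y$mcmc)
  do.call(pipeline_config, y)
}

.section <- function(expr) {
  tryCatch(c(list(status = "ok"), expr),
           error = function(e) list(status = "failed", reason = conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Sequences the stages: condition index and trait normalisation; trait
#' trend tests; fitness construction; density-dependent selection fit with
#' posterior optima \eqn{x^*(N)}; period-specific selection fits with regime
#' classification; vital-rate model selection (CJS survival, reproductive
#' rate, brood size) with predictions at the minimum and maximum population
#' size; and trophic-chain correlations. Sections fail independently: a
#' section that errors (or a selection fit that misses the convergence
#' thresholds) is marked in the report without stopping the rest.
#'
#' @param config A [pipeline_config()].
#' @return An `analysis_report` list: `provenance`, one entry per section
#'   (each with a `status` of `"ok"`, `"failed"` or `"skipped"`), and
#'   `fits` (the heavyweight fitted objects, dropped on serialisation).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate)
    data <- list(individuals = cohort$individuals, fitness = cohort$fitness,
                 encounters = cohort$encounters, series = cohort$series)
    truth <- unclass(cohort$truth)
  } else {
    data <- list(individuals = read.csv(config$paths$individuals),
                 fitness = read.csv(config$paths$fitness),
                 encounters = read.csv(config$paths$encounters),
                 series = read.csv(config$paths$popseries))
    .validate_inputs(data)
    truth <- NULL
  }
  if (!is.null(config$years)) {
    w <- config$years
    data$individuals <- data$individuals[data$individuals$year >= w[1] &
                                         data$individuals$year <= w[2], ]
    data$fitness <- data$fitness[data$fitness$year >= w[1] &
                                 data$fitness$year <= w[2], ]
  }
  report <- list(provenance = list(
    seed = config$seed, trait = config$trait,
    boundary_year = config$boundary_year,
    simulated = !is.null(config$simulate),
    config_hash = .config_hash(config),
    package_version = as.character(utils::packageVersion("densel")),
    truth = truth))
  fits <- list()

  # --- condition index + normalised trait ---------------------------------
  cond <- .section({
    ind <- compute_condition_index(data$individuals)
    tr <- switch(config$trait, condition = ind$condition,
                 mass = ind$mass_g, tarsus = ind$tarsus_mm)
    ind$x_analysis <- normalize_trait(tr)
    data$individuals <- ind
    list(regression = as.list(attr(ind, "condition_fit")),
         n = sum(is.finite(ind$condition)))
  })
  report$condition <- cond

  # --- trait trends --------------------------------------------------------
  report$trends <- .section({
    ind <- data$individuals
    tt <- function(col) {
      t <- annual_trend_test(data.frame(year = ind$year, value = ind[[col]]))
      list(slope = t$slope, se = t$se, p_value = t$p_value, unit = t$unit)
    }
    list(condition = tt("condition"), tarsus = tt("tarsus_mm"))
  })

  # --- fitness table joined to trait and density ---------------------------
  fitness <- NULL
  report$fitness <- .section({
    f <- .ensure_twoW(data$fitness)
    ind <- data$individuals
    key <- paste(f$id, f$year)
    m <- match(key, paste(ind$id, ind$year))
    if (anyNA(m))
      stop("fitness records without matching individual-year: ",
           sum(is.na(m)), " rows")
    f$x <- ind$x_analysis[m]
    mN <- match(f$year, data$series$year)
    if (anyNA(mN))
      stop("population series missing years: ",
           paste(sort(unique(f$year[is.na(mN)])), collapse = ", "))
    f$N <- data$series$goose_n[mN]
    drop_na <- !is.finite(f$x)
    fitness <- f[!drop_na, ]
    list(n = nrow(fitness), dropped_missing_trait = sum(drop_na),
         mean_W = mean(fitness$twoW) / 2)
  })

  # --- density-dependent selection ----------------------------------------
  report$dd_selection <- if (is.null(fitness)) list(status = "skipped") else .section({
    fit <- suppressWarnings(fit_dd_selection(fitness, mcmc = config$mcmc))
    fits$dd <- fit
    optima <- if (fit$converged)
      posterior_optima(fit, N = config$optima_N) else NULL
    list(summary = fit$summary, converged = fit$converged,
         divergences = fit$divergences, optima = optima,
         status = if (fit$converged) "ok" else "failed",
         reason = if (!fit$converged) "convergence thresholds not met")
  })

  # --- period-specific selection ------------------------------------------
  report$periods <- if (is.null(fitness)) list(status = "skipped") else .section({
    parts <- split_periods(fitness, config$boundary_year)
    per <- lapply(names(parts), function(nm) {
      f <- suppressWarnings(fit_period_selection(parts[[nm]], mcmc = config$mcmc,
                                                 label = nm))
      fits[[paste0("period_", nm)]] <<- f
      list(label = nm, years = unname(range(parts[[nm]]$year)),
           summary = f$summary, regime = f$regime, converged = f$converged)
    })
    names(per) <- names(parts)
    ok <- all(vapply(per, `[[`, logical(1), "converged"))
    c(per, list(status = if (ok) "ok" else "failed",
                reason = if (!ok) "convergence thresholds not met"))
  })

  # --- vital rates ---------------------------------------------------------
  report$vital_rates <- .section({
    ind <- data$individuals
    hist <- make_histories(data$encounters, ind)
    n_eff <- sum(ncol(hist$det) - hist$first)  # individual-intervals
    cjs_cands <- lapply(config$vital_candidates, function(tm)
      fit_cjs(hist, series = data$series, phi_terms = tm))
    cjs_tab <- model_selection_aicc(cjs_cands, n = n_eff)
    best_cjs <- cjs_cands[[attr(cjs_tab, "preferred")]]
    fits$cjs <- best_cjs

    key <- paste(data$fitness$id, data$fitness$year)
    m <- match(paste(ind$id, ind$year), key)
    rep_data <- data.frame(id = ind$id, year = ind$year, x = ind$x_analysis,
                           age = if ("age" %in% names(ind)) ind$age else 2L,
                           N = data$series$goose_n[match(ind$year, data$series$year)],
                           success = as.integer(data$fitness$B[m] > 0),
                           brood = data$fitness$B[m])
    rep_data <- rep_data[!is.na(rep_data$success) & is.finite(rep_data$x), ]
    rate_cands <- lapply(config$vital_candidates, function(tm)
      fit_reproduction(rep_data, "reproductive_rate", terms = tm))
    rate_tab <- model_selection_aicc(rate_cands, n = rate_cands[[1]]$n)
    brood_cands <- lapply(config$vital_candidates, function(tm)
      fit_reproduction(rep_data, "fledged_brood_size", terms = tm))
    brood_tab <- model_selection_aicc(brood_cands, n = brood_cands[[1]]$n)
    fits$reproduction <- rate_cands[[attr(rate_tab, "preferred")]]

    Nlo <- min(data$series$goose_n); Nhi <- max(data$series$goose_n)
    grid <- seq(-2.5, 2.5, length.out = 21)
    preds <- list(
      survival_low_N = predict_rate(best_cjs, grid, Nlo),
      survival_high_N = predict_rate(best_cjs, grid, Nhi),
      reproductive_rate_low_N = predict_rate(fits$reproduction, grid, Nlo),
      reproductive_rate_high_N = predict_rate(fits$reproduction, grid, Nhi))
    list(survival = list(table = as.data.frame(cjs_tab),
                         preferred = attr(cjs_tab, "preferred")),
         reproductive_rate = list(table = as.data.frame(rate_tab),
                                  preferred = attr(rate_tab, "preferred")),
         brood_size = list(table = as.data.frame(brood_tab),
                           preferred = attr(brood_tab, "preferred")),
         predictions = preds)
  })

  # --- trophic correlations ------------------------------------------------
  report$correlations <- .section({
    cors <- trophic_correlations(data$series)
    lapply(cors, function(co)
      list(pair = co$pair, lag = co$lag, n = co$n, r = co$r,
           ci = co$ci, boundary = co$boundary))
  })
  if (identical(report$correlations$status, "failed") &&
      grepl("overlapping pairs", report$correlations$reason %||% ""))
    report$correlations$status <- "skipped"

  report$fits <- fits
  class(report) <- "analysis_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validate_inputs <- function(data) {
  need <- list(individuals = c("id", "year", "mass_g", "tarsus_mm"),
               fitness = c("id", "year"),
               encounters = c("id", "year", "detected"),
               series = c("year", "goose_n"))
  for (nm in names(need)) {
    missing <- setdiff(need[[nm]], names(data[[nm]]))
    if (length(missing))
      stop(sprintf("%s table lacks column(s): %s", nm,
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (nm in c("individuals", "fitness", "encounters")) {
    bad <- which(!is.finite(data[[nm]]$year))
    if (length(bad))
      stop(sprintf("%s: malformed year at row %d", nm, bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Write an analysis report to JSON or markdown
#'
#' JSON output round-trips losslessly through [jsonlite::fromJSON()];
#' markdown renders the posterior tables in median / 95% credible-interval
#' style. Fitted model objects (`report$fits`) are not serialised.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param path Output file.
#' @param format `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "analysis_report"))
  out <- unclass(report)
  out$fits <- NULL
  if (format == "json") {
    ok <- tryCatch({
      jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                           na = "null", force = TRUE)
      TRUE
    }, error = function(e) stop("cannot write report: ", conditionMessage(e),
                                call. = FALSE))
  } else {
    lines <- .report_markdown(out)
    con <- tryCatch(file(path, "w"),
                    error = function(e) stop("unwritable path: ", path, call. = FALSE))
    on.exit(close(con))
    writeLines(lines, con)
  }
  invisible(path)
}

.md_summary_table <- function(s) {
  c("| parameter | median | 95% CrI | Rhat | ESS |",
    "|---|---|---|---|---|",
    sprintf("| %s | %.4g | (%.4g, %.4g) | %.3f | %.0f |",
            s$parameter, s$median, s$q2.5, s$q97.5, s$rhat, s$ess))
}

.report_markdown <- function(out) {
  L <- c("# Density-dependent selection analysis report", "",
         sprintf("- seed: %d; trait: %s; boundary year: %d",
                 out$provenance$seed, out$provenance$trait,
                 out$provenance$boundary_year), "")
  for (nm in setdiff(names(out), c("provenance", "fits"))) {
    sec <- out[[nm]]
    L <- c(L, paste0("## ", nm),
           paste0("status: ", sec$status %||% "ok"), "")
    if (nm == "dd_selection" && !is.null(sec$summary))
      L <- c(L, .md_summary_table(sec$summary), "")
    if (nm == "periods") {
      for (p in intersect(c("low", "high"), names(sec))) {
        L <- c(L, paste0("### ", p, " density (", sec[[p]]$years[1], "-",
                         sec[[p]]$years[2], "), regime: ", sec[[p]]$regime),
               .md_summary_table(sec[[p]]$summary), "")
      }
    }
    if (nm == "correlations" && identical(sec$status, "ok")) {
      for (co in sec[setdiff(names(sec), c("status", "reason"))]) {
        if (is.list(co) && !is.null(co$r))
          L <- c(L, sprintf("- %s(t) ~ %s(t%+d): r = %.3f [%.3f, %.3f], n = %d",
                            co$pair[1], co$pair[2], co$lag, co$r,
                            co$ci[1], co$ci[2], co$n))
      }
      L <- c(L, "")
    }
  }
  L
}
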