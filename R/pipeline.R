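#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with defaults matching
#' the standard protocol: 15-year moving window, alpha = 0.05, median
#' (0.5-quantile) regime thresholds, composite normalization over retained
#' pixels. Round-trips through a flat `key: value` config file.
#'
#' @param input path to a stack sidecar (see [read_stack()]), or `NULL` to
#'   simulate with `sim`.
#' @param sim a [sim_config()] used when `input` is `NULL`.
#' @param window moving-window length, years.
#' @param alpha significance level for trend tests.
#' @param regime_quantile threshold quantile for regime classification.
#' @param n_surrogate surrogate replicates for window-trend significance.
#' @param response attribution response: `"darpv"` (composite), `"dar"` or
#'   `"dpv"`.
#' @param out_dir output directory (`NULL` = no files written).
#' @param seed master seed; every stochastic stage derives from it.
#' @return `pipeline_config` object.
#' @export
pipeline_config <- function(input = NULL, sim = sim_config(),
                            window = 15L, alpha = 0.05,
                            regime_quantile = 0.5, n_surrogate = 100L,
                            response = c("darpv", "dar", "dpv"),
                            out_dir = NULL, seed = 1L) {
  response <- match.arg(response)
  stopifnot(window >= 3L, alpha > 0, alpha < 1,
            regime_quantile > 0, regime_quantile < 1)
  structure(list(input = input, sim = sim, window = as.integer(window),
                 alpha = alpha, regime_quantile = regime_quantile,
                 n_surrogate = as.integer(n_surrogate), response = response,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration
#' @param config a [pipeline_config()].
#' @param path flat config file.
#' @return (write) path invisibly; (read) a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  flat <- list(input = config$input, window = config$window,
               alpha = config$alpha,
               regime_quantile = config$regime_quantile,
               n_surrogate = config$n_surrogate, response = config$response,
               out_dir = config$out_dir, seed = config$seed)
  sim <- config$sim
  for (f in c("n_years", "n_rows", "n_cols", "baseline", "phi", "sigma_rel",
              "trend"))
    flat[[paste0("sim_", f)]] <- sim[[f]]
  write_flat_config(flat, path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  flat <- read_flat_config(path)
  simf <- flat[grep("^sim_", names(flat))]
  names(simf) <- sub("^sim_", "", names(simf))
  sim <- do.call(sim_config, c(simf, list(seed = flat$seed %||% 1L)))
  pipeline_config(input = flat$input, sim = sim,
                  window = flat$window %||% 15L,
                  alpha = flat$alpha %||% 0.05,
                  regime_quantile = flat$regime_quantile %||% 0.5,
                  n_surrogate = flat$n_surrogate %||% 100L,
                  response = flat$response %||% "darpv",
                  out_dir = flat$out_dir, seed = flat$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full stability pipeline
#'
#' Stage order: acquire stack (read or simulate) -> per-pixel stability map
#' -> regime classification -> moving-window metrics -> Theil-Sen trend
#' maps of windowed PV and AR -> composite destabilization index ->
#' annual-index functioning trend + ecosystem-state typology -> driver
#' attribution (simulated covariates when the stack is simulated). A JSON
#' manifest records the configuration, seed, versions and per-stage pixel
#' counts; identical config + seed reproduces bit-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage log lines (written to stderr).
#' @return invisible list: `stack`, `stability`, `regimes`, `windows`,
#'   `trend_ar`, `trend_pv`, `composite`, `ef`, `states`, `attribution`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  stack <- if (!is.null(config$input)) read_stack(config$input)
           else simulate_stack(config$sim)
  if (config$window >= n_years(stack))
    stop("configuration error: window >= n_years")
  log_stage("[stack] %d x %d x %d", dim(stack$values)[1L],
            dim(stack$values)[2L], n_years(stack))

  sm <- stability_map(stack)
  rg <- classify_regimes(sm)
  log_stage("[stability] %d valid pixels", sum(sm$valid))

  ws <- moving_window_metrics(stack, W = config$window)
  tar <- trend_map(ws, "ar", n_surrogate = config$n_surrogate,
                   seed = config$seed + 1L)
  tpv <- trend_map(ws, "pv", n_surrogate = config$n_surrogate,
                   seed = config$seed + 2L)
  comp <- composite_index(tar, tpv)
  log_stage("[trends] %d windows; hotspot %d / coldspot %d / excluded %d",
            length(ws$anchors), sum(comp$label == 1L), sum(comp$label == 2L),
            sum(comp$excluded))

  ef <- annual_trend_map(stack)
  states <- ecosystem_state(ef, comp, alpha = config$alpha)

  attribution <- NULL
  if (is.null(config$input)) {
    drv <- simulate_drivers(config$sim)
    resp <- switch(config$response,
                   darpv = comp$value, dar = tar$slope, dpv = tpv$slope)
    cats <- stats::setNames(rep("background", length(drv$covariates)),
                            names(drv$covariates))
    tbl <- try(build_feature_table(drv$covariates, resp, categories = cats,
                                   seed = config$seed + 3L), silent = TRUE)
    if (!inherits(tbl, "try-error") && sum(tbl$split == "train") >= 100L) {
      mod <- fit_stability_model(tbl, seed = config$seed + 4L)
      attribution <- shapley_attribution(mod, tbl, seed = config$seed + 5L)
      log_stage("[attribution] validation R2 = %.3f", mod$r2_valid)
    } else {
      log_stage("[attribution] skipped: too few valid pixels")
    }
  }

  total <- prod(dim(stack$values)[1:2])
  counts <- list(total = total,
                 valid = sum(sm$valid),
                 hotspot = sum(comp$label == 1L),
                 coldspot = sum(comp$label == 2L),
                 neutral = sum(comp$label == 3L),
                 excluded = sum(comp$excluded),
                 invalid = total - sum(comp$label != 0L) - sum(comp$excluded))
  manifest <- list(
    package = "vegstab",
    version = as.character(utils::packageVersion("vegstab")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = list(window = config$window, alpha = config$alpha,
                  regime_quantile = config$regime_quantile,
                  n_surrogate = config$n_surrogate,
                  response = config$response,
                  simulated = is.null(config$input)),
    counts = counts,
    regime_thresholds = as.list(rg$thresholds),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  res <- list(stack = stack, stability = sm, regimes = rg, windows = ws,
              trend_ar = tar, trend_pv = tpv, composite = comp, ef = ef,
              states = states, attribution = attribution,
              manifest = manifest)
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config)
  invisible(res)
}

write_pipeline_outputs <- function(res, config) {
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  st <- res$stack
  wg <- function(m, name) write_ascii_grid(m, file.path(dir, name),
                                           st$xll, st$yll, st$cellsize)
  wg(res$stability$pv, "pv.asc")
  wg(res$stability$ar, "ar.asc")
  wg(res$trend_ar$slope, "dar_slope.asc")
  wg(res$trend_pv$slope, "dpv_slope.asc")
  wg(res$composite$value, "composite.asc")
  wg(res$regimes$code + 0, "regime.asc")
  wg(res$states$code + 0, "state.asc")
  jsonlite::write_json(list(regime = as.list(res$regimes$labels),
                            composite = as.list(res$composite$labels),
                            state = as.list(res$states$labels)),
                       file.path(dir, "code_tables.json"), auto_unbox = TRUE)
  if (!is.null(res$attribution)) {
    a <- res$attribution
    jsonlite::write_json(list(r2_valid = a$r2_valid,
                              importance = as.list(a$importance),
                              category_importance = as.list(a$category_importance),
                              params = a$params),
                         file.path(dir, "attribution.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
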