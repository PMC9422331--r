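#' Pipeline configuration
#'
#' Collects the stage configurations of the end-to-end analysis. The default
#' sizes are deliberately small so the whole pipeline runs in seconds; the
#' study-scale sizes live in the individual stage functions' defaults.
#'
#' @param generator A [generator_config()].
#' @param params A [cann_params()].
#' @param ratios Ratio grid for the integration sweep.
#' @param disparities Disparity grid for the sweep.
#' @param n_trials Trials per sweep cell.
#' @param noise_grid Noise grid for the stochastic-resonance stage.
#' @param sr_trials Trials per SR cell.
#' @param fc_sigma Observer disparity-noise SD for the fixed-criterion fit.
#' @param bci_sigma Measurement SD for the Bayesian fit.
#' @param decision A [decision_config()].
#' @param deltas Cue-disparity grid for decision curves.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(generator = generator_config(n_neurons = 40),
                            params = cann_params(),
                            ratios = c(1.28, 2.35),
                            disparities = seq(0, 180, by = 45),
                            n_trials = 20,
                            noise_grid = c(0.8, 6, 15),
                            sr_trials = 12,
                            fc_sigma = 30, bci_sigma = 30,
                            decision = decision_config(n_rep = 2000),
                            deltas = seq(0, 180, by = 30)) {
  structure(list(generator = generator, params = params, ratios = ratios,
                 disparities = disparities, n_trials = n_trials,
                 noise_grid = noise_grid, sr_trials = sr_trials,
                 fc_sigma = fc_sigma, bci_sigma = bci_sigma,
                 decision = decision, deltas = deltas),
            class = "pipeline_config")
}

#' Load model parameters from a YAML or JSON config file
#'
#' Reads a flat mapping of parameter overrides and merges it into the
#' defaults of [cann_params()] (section `cann`), [generator_config()]
#' (section `generator`) and [decision_config()] (section `decision`).
#' Unknown keys are an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `"pipeline_config"`.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  build <- function(fun, over) {
    over <- over %||% list()
    bad <- setdiff(names(over), names(formals(fun)))
    if (length(bad)) stop("unknown config keys: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    do.call(fun, over)
  }
  cfg <- pipeline_config(
    generator = build(generator_config, raw$generator),
    params = build(cann_params, raw$cann),
    decision = build(decision_config, raw$decision))
  for (k in intersect(names(raw), c("ratios", "disparities", "n_trials",
                                    "noise_grid", "sr_trials", "fc_sigma",
                                    "bci_sigma", "deltas")))
    cfg[[k]] <- raw[[k]]
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the stages generate -> analyze -> simulate -> sr-sweep -> fit ->
#' decide in order, writing each stage's outputs (CSV/JSON) under `out_dir`
#' together with a run manifest (resolved configuration, seed, content
#' hashes of every artifact and stage timings). Stages read their inputs
#' from the preceding stage's files, so a later stage can be re-run alone
#' against existing outputs; a missing upstream artifact is a clear error.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed controlling every stochastic stage.
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages to run (default all, in order).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 0, config = pipeline_config(),
                         stages = c("generate", "analyze", "simulate",
                                    "sr_sweep", "fit", "decide")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  need <- function(f, stage) {
    if (!file.exists(f))
      stop("stage '", stage, "' needs missing artifact ", f,
           "; run its upstream stage first", call. = FALSE)
    f
  }
  seeds <- derive_seeds(seed, 6)
  manifest <- list(seed = seed, stages = list(),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  timing <- function(stage, fun) {
    t0 <- Sys.time()
    fun()
    manifest$stages[[stage]] <<- list(
      seconds = round(as.numeric(Sys.time() - t0, "secs"), 2))
  }

  if ("generate" %in% stages) timing("generate", function() {
    cfg <- config$generator; cfg$seed <- seeds[1]
    ds <- generate_dataset(cfg)
    write_dataset(ds, p("dataset"))
  })
  if ("analyze" %in% stages) timing("analyze", function() {
    ds <- read_dataset(sub("\\.csv$", "", need(p("dataset.csv"), "analyze")))
    sm <- analyze_neurons(ds)
    readr::write_csv(sm, p("neuron_summaries.csv"))
    eif <- empirical_integration_function(sm)
    readr::write_csv(eif, p("integration_function_empirical.csv"))
    counts <- table(factor(sm$dtheta_mul[sm$group == "balanced"],
                           levels = disparity_bins))
    jsonlite::write_json(list(
      balanced_dtheta_mul = rectify_distribution(as.numeric(counts))),
      p("distributions.json"), digits = NA, auto_unbox = TRUE)
  })
  if ("simulate" %in% stages) timing("simulate", function() {
    sw <- integration_sweep(config$ratios, disparities = config$disparities,
                            n_trials = config$n_trials,
                            params = config$params, seed = seeds[2])
    readr::write_csv(sw, p("integration_sweep.csv"))
  })
  if ("sr_sweep" %in% stages) timing("sr_sweep", function() {
    eff <- sr_sweep(noise_grid = config$noise_grid,
                    disparities = config$disparities,
                    n_trials = config$sr_trials, params = config$params,
                    seed = seeds[3])
    readr::write_csv(eff, p("sr_efficiency.csv"))
  })
  if ("fit" %in% stages) timing("fit", function() {
    sw <- readr::read_csv(need(p("integration_sweep.csv"), "fit"),
                          show_col_types = FALSE, progress = FALSE)
    tgt <- sw[sw$ratio == sw$ratio[1], ]
    fc <- fit_kappa(tgt, sigma_noise = config$fc_sigma)
    cur <- bci_decision_curve(0.51, config$bci_sigma, config$deltas,
                              n = 20000, seed = seeds[4])
    bci <- fit_bci(cur[, c("dtheta_cue", "p_common")],
                   sigma = config$bci_sigma, fit = "prior")
    jsonlite::write_json(list(fc = glance(fc), bci = glance(bci)),
                         p("fits.json"), digits = NA, auto_unbox = TRUE,
                         dataframe = "rows")
  })
  if ("decide" %in% stages) timing("decide", function() {
    cur <- decision_curve(config$decision, config$deltas, seed = seeds[5])
    readr::write_csv(cur, p("decision_curve.csv"))
  })

  arts <- list.files(out_dir, full.names = TRUE)
  arts <- arts[!grepl("manifest\\.json$", arts)]
  manifest$artifacts <- lapply(stats::setNames(arts, basename(arts)),
                               function(f) unname(tools::md5sum(f)))
  manifest$config <- rapply(unclass(config), unclass, how = "replace")
  jsonlite::write_json(manifest, p("manifest.json"), digits = NA,
                       auto_unbox = TRUE, null = "null", force = TRUE)
  invisible(manifest)
}
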