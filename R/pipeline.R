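# End-to-end orchestration: one entry point dispatching the analysis stages,
# writing outputs plus a JSON manifest so every artifact is traceable to the
# exact configuration and seed that produced it.

#' Run an analysis stage end to end
#'
#' Dispatches one of the pipeline stages, writes its primary outputs under
#' `out_dir`, and records a `manifest.json` with the command, the fully
#' resolved configuration, the seed, output paths, the package version and a
#' timestamp. Stages:
#'
#' * `synth` — generate a synthetic experiment, write the localisation CSV.
#' * `simulate` — simulate an ensemble, write its diffusion histogram CSV.
#' * `fit` — fit kinetic rates to a histogram (or localisation) file.
#' * `tnti` — closed-form kinetic report for a rates configuration.
#' * `boundfrac` — target-bound fraction of an observed histogram.
#' * `search` — target-search curve, written as CSV.
#' * `gcsweep` — GC-content sweep of t_50%.
#' * `recover` — rate-recovery benchmark on synthetic ground truth.
#'
#' @param command stage name.
#' @param config a configuration list as from [read_config()], or a path to
#'   a YAML configuration file. Stages that need kinetic rates require the
#'   `rates` section.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param overrides named list merged over the configuration (e.g.
#'   `list(search = list(n_cells = 200))`).
#' @param input optional input file (histogram or localisation CSV) for
#'   `fit` and `boundfrac`.
#' @param n_particles forward-model particle count override.
#' @param quiet suppress progress messages.
#' @return List with `result` (stage-specific object) and `manifest`
#'   (invisible).
#' @export
run_stage <- function(command = c("synth", "simulate", "fit", "tnti",
                                  "boundfrac", "search", "gcsweep", "recover"),
                      config = NULL, out_dir = tempfile("mcdda-run-"),
                      seed = 1, overrides = list(), input = NULL,
                      n_particles = NULL, quiet = FALSE) {
  command <- match.arg(command)
  cfg <- if (is.character(config)) read_config(config)
         else if (is.null(config)) default_config() else config
  for (nm in names(overrides)) {
    section <- cfg[[nm]]
    cfg[[nm]] <- if (is.null(section)) overrides[[nm]] else {
      rebuilt <- modifyList(as.list(unclass(section)), overrides[[nm]])
      cls <- class(section)
      if (identical(cls, "kinetic_rates")) do.call(kinetic_rates, rebuilt)
      else structure(rebuilt, class = cls)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outputs <- character()
  need_rates <- function() {
    if (is.null(cfg$rates)) {
      stop("stage '", command, "' requires a 'rates' configuration section")
    }
    cfg$rates
  }

  result <- switch(command,
    synth = {
      say("synth: generating synthetic experiment (seed %d)", seed)
      expt <- generate_experiment(need_rates(), cfg$diffusion, cfg$imaging,
                                  cfg$geometry, seed = seed)
      p <- file.path(out_dir, "localisations.csv")
      write_localisations(expt, p)
      outputs <- c(outputs, p)
      expt
    },
    simulate = {
      n <- if (is.null(n_particles)) 50000 else n_particles
      say("simulate: %d particles (seed %d)", n, seed)
      ts <- simulate_ensemble(n, need_rates(), cfg$diffusion, cfg$imaging,
                              cfg$geometry, seed, keep_locs = FALSE)
      h <- build_histogram(track_dstars(ts), cfg$imaging)
      p <- file.path(out_dir, "histogram.csv")
      write_histogram(h, p)
      outputs <- c(outputs, p)
      h
    },
    fit = {
      if (is.null(input)) stop("missing input: 'fit' needs a histogram CSV")
      h <- read_histogram(input)
      fc <- fit_config(seed = seed)
      if (!is.null(n_particles)) fc$n_particles <- n_particles
      say("fit: %d observed tracks, %d forward particles", h$n_tracks,
          fc$n_particles)
      fit <- fit_rates(h, need_rates(), cfg$diffusion, cfg$imaging,
                       cfg$geometry, fc)
      p <- file.path(out_dir, "fit.csv")
      k <- as.numeric(fit$rates)[1:4]
      write.csv(data.frame(rate = names(fit$rates)[1:4], estimate = k),
                p, row.names = FALSE)
      outputs <- c(outputs, p)
      fit
    },
    tnti = {
      r <- need_rates()
      rep <- kinetic_report(list(configured = r))
      say("tnti: %.1f ms (PAM fraction %.1f%%)", rep$t_nti_ms, rep$f_PAM_pct)
      p <- file.path(out_dir, "tnti.csv")
      write.csv(rep, p, row.names = FALSE)
      outputs <- c(outputs, p)
      rep
    },
    boundfrac = {
      if (is.null(input)) stop("missing input: 'boundfrac' needs a histogram CSV")
      h <- read_histogram(input)
      n <- if (is.null(n_particles)) 250000 else n_particles
      say("boundfrac: grid search at %d particles per species", n)
      res <- fit_bound_fraction(h, need_rates(), cfg$diffusion, cfg$imaging,
                                cfg$geometry, n_particles = n, seed = seed)
      p <- file.path(out_dir, "bound_fraction.csv")
      write.csv(data.frame(fraction = res$fraction, sse = res$sse), p,
                row.names = FALSE)
      outputs <- c(outputs, p)
      res
    },
    search = {
      say("search: %d cells x %d repeats", cfg$search$n_cells,
          cfg$search$n_repeats)
      curve <- simulate_search(need_rates(), cfg$genome, cfg$pam, cfg$search,
                               seed = seed)
      p <- file.path(out_dir, "search_curve.csv")
      write_search_curve(curve, p)
      outputs <- c(outputs, p)
      curve
    },
    gcsweep = {
      say("gcsweep: GC 30-70%%")
      tab <- gc_sweep(need_rates(), cfg$genome, cfg$pam, cfg$search,
                      seed = seed)
      p <- file.path(out_dir, "gc_sweep.csv")
      write.csv(tab, p, row.names = FALSE)
      outputs <- c(outputs, p)
      tab
    },
    recover = {
      r <- need_rates()
      n <- if (is.null(n_particles)) 20000 else n_particles
      say("recover: benchmark at ~%d tracks", n)
      fc <- fit_config(n_particles = n, seed = seed + 99)
      recovery_suite(list(r), n_tracks = n, seed = seed, diffs = cfg$diffusion,
                     imaging = cfg$imaging, geometry = cfg$geometry,
                     config = fc)
    })

  manifest <- list(command = command,
                   seed = seed,
                   configuration = manifest_config(cfg),
                   input = if (is.null(input)) NA else input,
                   outputs = outputs,
                   package_version = as.character(packageVersion("mcdda")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(result = result, manifest = manifest,
                 manifest_path = mp, out_dir = out_dir))
}

manifest_config <- function(cfg) {
  lapply(cfg, function(x) if (is.null(x)) NULL else as.list(unclass(x)))
}
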