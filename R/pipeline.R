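#' Configure a simulated MPRA run
#'
#' Collects every knob of the end-to-end pipeline (library -> model ->
#' counts -> footprint) into a validated configuration. Exactly one model
#' mode is active per run: `"equilibrium"` (the states-and-weights engine),
#' `"multicopy"` (binding-site titration via chemical potential),
#' `"nonspecific"` (polymerase windows along the whole promoter),
#' `"induction"` (MWC inducible repressor) or `"kinetic"` (Matrix-Tree
#' steady states). All stage seeds are derived deterministically from the
#' master `seed`, so identical configurations yield byte-identical outputs.
#'
#' @param preset Architecture preset name (see [architecture_preset()]).
#' @param mode Model mode (see above).
#' @param n Library size (default 5000).
#' @param theta Per-base mutation rate (default 0.1).
#' @param spectrum Mutation spectrum: "uniform", "transitions" or "ga_ct".
#' @param params Named list of [thermo_params()] overrides (P, R, A, N_NS,
#'   alpha, ...).
#' @param energies Named list of wild-type energy overrides (`eps_p`,
#'   `eps_r`, `eps_a`).
#' @param logic Repression logic override for multi-repressor presets.
#' @param mode_options Mode-specific options: `n_sites` (multicopy),
#'   `inducer`, `mwc` (induction), `active_windows` (nonspecific), `U`,
#'   `k_on`, `conc_a`, `active` (kinetic).
#' @param noise Optional [noise_spec()] (equilibrium mode).
#' @param n_bins,coarse_base Footprint binning options.
#' @param promoter Optional wild-type [promoter()] (default
#'   [default_promoter()]).
#' @param seed Master integer seed.
#' @param out_dir Optional output directory; when set, [run_mpra()] writes
#'   the library FASTA, counts/footprint/shift-matrix TSVs and a JSON run
#'   manifest there.
#' @return A validated list of class `mpra_config`.
#' @export
mpra_config <- function(preset = "simple_repression", mode = "equilibrium",
                        n = 5000L, theta = 0.1, spectrum = "uniform",
                        params = list(), energies = list(), logic = NULL,
                        mode_options = list(), noise = NULL,
                        n_bins = 2L, coarse_base = TRUE,
                        promoter = NULL, seed = 1L, out_dir = NULL) {
  cfg <- list(preset = preset, mode = mode, n = as.integer(n), theta = theta,
              spectrum = spectrum, params = params, energies = energies,
              logic = logic, mode_options = mode_options, noise = noise,
              n_bins = as.integer(n_bins), coarse_base = coarse_base,
              promoter = promoter, seed = as.integer(seed), out_dir = out_dir)
  problems <- character()
  if (!cfg$preset %in% c("constitutive", "simple_repression", "simple_activation",
                         "repression_activation", "double_repression",
                         "double_activation")) {
    problems <- c(problems, sprintf("unknown preset '%s'", cfg$preset))
  }
  if (length(cfg$mode) != 1L ||
      !cfg$mode %in% c("equilibrium", "multicopy", "nonspecific", "induction", "kinetic")) {
    problems <- c(problems, "`mode` must be exactly one of equilibrium/multicopy/nonspecific/induction/kinetic")
  }
  if (!cfg$spectrum %in% c("uniform", "transitions", "ga_ct")) {
    problems <- c(problems, sprintf("unknown spectrum '%s'", cfg$spectrum))
  }
  if (cfg$n < 1L) problems <- c(problems, "`n` must be >= 1")
  if (!is.numeric(cfg$theta) || cfg$theta < 0 || cfg$theta > 1) {
    problems <- c(problems, "`theta` must lie in [0, 1]")
  }
  if (!is.null(cfg$promoter) && !inherits(cfg$promoter, "promoter")) {
    problems <- c(problems, "`promoter` must be a promoter object")
  }
  if (!is.null(cfg$noise) && !inherits(cfg$noise, "noise_spec")) {
    problems <- c(problems, "`noise` must be a noise_spec object")
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid MPRA configuration:\n",
                 paste0("  - ", problems, collapse = "\n")))
  }
  structure(cfg, class = "mpra_config")
}

#' @rdname mpra_config
#' @param path YAML file with `mpra_config()` fields.
#' @export
read_mpra_config <- function(path) {
  fields <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare key `n` as boolean FALSE; map it back
  names(fields)[names(fields) %in% c("FALSE", "no")] <- "n"
  do.call(mpra_config, fields)
}

resolve_spectrum <- function(name) {
  switch(name,
         uniform = spectrum_uniform(),
         transitions = spectrum_transitions(),
         ga_ct = spectrum_ga_ct())
}

build_architecture <- function(cfg, wild_type) {
  args <- c(list(preset = cfg$preset, wild_type = wild_type, logic = cfg$logic),
            cfg$energies)
  do.call(architecture_preset, args)
}

#' Run the full simulated MPRA pipeline
#'
#' Generates the mutant library, evaluates the configured occupancy model,
#' converts occupancies to expected counts, and computes the information
#' footprint and expression-shift matrix. With `out_dir` set, writes
#' `library.fasta`, `counts.tsv`, `footprint.tsv`, `shift_matrix.tsv` and a
#' machine-readable `manifest.json` recording every resolved parameter and
#' derived seed; identical configuration and seed produce byte-identical
#' files.
#'
#' @param config An [mpra_config()] (or a YAML path accepted by
#'   [read_mpra_config()]).
#' @return A list with `library`, `counts`, `footprint`, `shift_matrix`,
#'   `architecture`, `sites` (informative display positions per factor),
#'   `config` and, when written, `paths`.
#' @export
#' @examples
#' res <- run_mpra(mpra_config(n = 100, seed = 7))
#' head(res$footprint)
run_mpra <- function(config = mpra_config()) {
  if (is.character(config)) config <- read_mpra_config(config)
  stopifnot(inherits(config, "mpra_config"))
  wt <- config$promoter %||% default_promoter()
  arch <- build_architecture(config, wt)
  pars <- do.call(thermo_params, config$params)
  lib <- mutagenize(wt, n = config$n, theta = config$theta,
                    spectrum = resolve_spectrum(config$spectrum),
                    seed = derive_seed(config$seed, 1L))
  mo <- config$mode_options
  counts <- switch(
    config$mode,
    equilibrium = expected_counts(lib, arch, pars, noise = config$noise,
                                  seed = derive_seed(config$seed, 2L)),
    multicopy = expected_counts(
      lib, arch, pars,
      pbound_fun = function(l, a, p) pbound_multicopy(l, p, n_sites = mo$n_sites %||% 1L,
                                                      architecture = a)),
    nonspecific = expected_counts(
      lib, arch, pars,
      pbound_fun = function(l, a, p) pbound_nonspecific(l, p, architecture = a,
                                                        active_windows = mo$active_windows)),
    induction = expected_counts(
      lib, arch, pars,
      pbound_fun = function(l, a, p) pbound_induction(l, c = mo$inducer %||% 0,
                                                      mwc = mo$mwc %||% mwc_params(),
                                                      params = p, architecture = a)),
    kinetic = simulate_noneq_library(lib, arch, pars, U = mo$U %||% 0,
                                     k_on = mo$k_on %||% 1,
                                     conc_a = mo$conc_a,
                                     active = mo$active %||% c("A", "AP"))
  )
  fp <- information_footprint(lib, counts, n_bins = config$n_bins,
                              coarse_base = config$coarse_base)
  sm <- expression_shift_matrix(lib, counts)
  sites <- lapply(arch$sites, function(s) site_positions(s$matrix, informative_only = TRUE))
  out <- list(library = lib, counts = counts, footprint = fp, shift_matrix = sm,
              architecture = arch, sites = sites, config = config)
  if (!is.null(config$out_dir)) out$paths <- write_run_outputs(out, config$out_dir)
  out
}

write_run_outputs <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    library = file.path(dir, "library.fasta"),
    counts = file.path(dir, "counts.tsv"),
    footprint = file.path(dir, "footprint.tsv"),
    shift_matrix = file.path(dir, "shift_matrix.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_fasta(res$library, paths$library)
  write_mpra_tsv(res$counts, paths$counts)
  write_mpra_tsv(res$footprint, paths$footprint)
  write_mpra_tsv(res$shift_matrix, paths$shift_matrix)
  cfg <- res$config
  manifest <- list(
    package = "mprasim",
    version = as.character(utils::packageVersion("mprasim")),
    config = cfg[setdiff(names(cfg), c("promoter", "noise", "out_dir"))],
    promoter = (cfg$promoter %||% default_promoter())$bases,
    noise = if (!is.null(cfg$noise)) list(means = as.list(cfg$noise$means), cv = cfg$noise$cv),
    derived_seeds = list(library = derive_seed(cfg$seed, 1L),
                         noise = derive_seed(cfg$seed, 2L)),
    sites = lapply(res$sites, as.integer)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths
}

#' Sweep a pipeline parameter across replicate synthetic datasets
#'
#' Re-runs [run_mpra()] over a grid of values of one configuration field
#' (addressed by a dotted path such as `"theta"`, `"params.R"`,
#' `"energies.eps_r"` or `"mode_options.n_sites"`), with `replicates`
#' independent libraries per grid point (replicate seeds derived from the
#' master seed by counter), and records the average mutual information S at
#' each binding site.
#'
#' @param config Base [mpra_config()].
#' @param param Dotted path of the field to sweep.
#' @param values Vector (or list) of values for the field.
#' @param replicates Synthetic datasets per grid point (default 20).
#' @return Tidy tibble with columns `param`, `value`, `replicate`, `site`,
#'   `S`, and `snr`.
#' @export
sweep_mpra <- function(config, param, values, replicates = 20L) {
  stopifnot(inherits(config, "mpra_config"))
  purrr::map_dfr(seq_along(values), function(vi) {
    cfg <- set_config_field(config, param, values[[vi]])
    purrr::map_dfr(seq_len(replicates), function(r) {
      cfg$seed <- derive_seed(config$seed, vi * 1000L + r)
      res <- run_mpra(cfg)
      all_pos <- unlist(res$sites, use.names = FALSE)
      purrr::map_dfr(names(res$sites), function(f) {
        tibble::tibble(
          param = param,
          value = if (is.numeric(values[[vi]])) values[[vi]] else as.character(values[[vi]]),
          replicate = r, site = f,
          S = avg_site_information(res$footprint, res$sites[[f]]),
          snr = snr(res$footprint, all_pos)$snr)
      })
    })
  })
}

set_config_field <- function(config, param, value) {
  path <- strsplit(param, ".", fixed = TRUE)[[1]]
  if (length(path) == 1L) {
    config[[path]] <- value
  } else if (length(path) == 2L) {
    config[[path[1]]][[path[2]]] <- value
  } else {
    abort("Config paths deeper than two levels are not supported.")
  }
  config
}
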