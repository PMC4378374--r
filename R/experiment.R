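#' Preset configurations
#'
#' `"paper"` is the full-fidelity protocol: the 3275-m, 35-level column, a
#' 100-year ecological (species-sorting) phase followed by a 250-year
#' eco-evolutionary phase. `"desk"` is a reduced configuration for quick
#' exploration and routine testing: 10 levels and much shorter phases, with
#' identical model structure.
#'
#' @param preset `"paper"` or `"desk"`.
#' @param n_phyto seeding resolution (number of phytoplankton species).
#' @param phase1_years,phase2_years optional phase-length overrides.
#' @param ensemble_K optional ensemble-size override.
#' @param ... parameter overrides forwarded to [plankton_params()].
#' @return list of class `evo_protocol`: `params`, `n_phyto`, `phase1_years`,
#'   `phase2_years`, `ensemble_K`, `preset`.
#' @export
protocol_config <- function(preset = c("paper", "desk"), n_phyto = 20,
                            phase1_years = NULL, phase2_years = NULL,
                            ensemble_K = NULL, ...) {
  preset <- match.arg(preset)
  params <- plankton_params(...)
  if (preset == "desk") {
    # reduced column: shallow enough that winter convection ventilates the
    # whole column, so the annual attractor is reached within a few years
    params$grid$n_levels <- 10
    params$grid$stretch <- 1.3
    params$grid$depth <- 400
  }
  structure(list(params = params,
                 n_phyto = n_phyto,
                 phase1_years = phase1_years %||%
                   if (preset == "paper") 100 else 15,
                 phase2_years = phase2_years %||%
                   if (preset == "paper") 250 else 30,
                 ensemble_K = ensemble_K %||% if (preset == "paper") 24 else 4,
                 preset = preset),
            class = "evo_protocol")
}

# deterministic substream seeds derived from one master seed (kept < 2^31)
substream_seed <- function(seed, stream) {
  (as.integer(seed) %% 100000L) * 10000L + 7919L * stream %% 100000L
}

#' Seed a random community
#'
#' Allocates `n` phytoplankton species round-robin over the four functional
#' types (so `n` divisible by 4 gives `n/4` per type), draws each cell
#' volume log-uniformly within its type's range, and attaches the fixed
#' 9-grazer zooplankton spectrum. Initial depth profiles are uniformly low
#' (6e-9 mmol C m^-3) and the start is winter (January, day 1). Fully
#' deterministic given the seed.
#'
#' @param n number of phytoplankton species (8, 20, 40 or 80 in the
#'   reference protocol; any positive integer works).
#' @param seed integer RNG seed.
#' @param params an `evo_params` list.
#' @return list with `phyto` and `zoo` tables.
#' @export
seed_community <- function(n, seed = 1, params = plankton_params()) {
  stopifnot(n >= 1)
  ft <- functional_types(params)
  types <- rep(ft$type, length.out = n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(seed, 1L))
  lo <- ft$V_lo[match(types, ft$type)]
  hi <- ft$V_hi[match(types, ft$type)]
  vols <- 10^stats::runif(n, log10(lo), log10(hi))
  phyto <- build_species(types, vols, params)
  phyto$active <- TRUE
  list(phyto = phyto, zoo = zoo_spectrum(params))
}

#' Run the two-phase simulation protocol
#'
#' Phase 1 ("ecological"): the randomly seeded community is integrated with
#' fixed traits; species sorting selects the viable competitors and the
#' system settles on an annual limit cycle (typically within 10-20 years).
#' Phase 2 ("eco-evolutionary"): cell volumes evolve under the
#' mutation-invasion engine until the evolutionary attractor is reached.
#' Snapshots are taken at the end of both phases, the year-over-year
#' attractor distance is checked at both ends, and all surviving species are
#' classified (CSS / EBP / directional) at the end of the run.
#'
#' @param config an [protocol_config()] (or a preset name).
#' @param seed master RNG seed; all randomness (community seeding) derives
#'   from it, so `(config, seed)` reproduces the run exactly.
#' @param n_phyto optional override of the seeding resolution.
#' @return list of class `evo_run`: `seed`, `config`, `state` (final),
#'   `snapshot_phase1`, `snapshot_phase2`, `events`, `classification`,
#'   `convergence` (tibble of year-over-year distances for phase 1),
#'   `attractor_distance` (named, both phase ends).
#' @export
run_protocol <- function(config = protocol_config("desk"), seed = 1,
                         n_phyto = NULL) {
  if (is.character(config)) config <- protocol_config(config)
  p <- config$params
  n <- n_phyto %||% config$n_phyto
  com <- seed_community(n, seed, p)
  state <- init_state(com$phyto, com$zoo, p)

  # phase 1: species sorting with fixed traits
  hist <- numeric(config$phase1_years)
  for (y in seq_len(config$phase1_years)) {
    prev <- state
    state <- run_column(state, 365)
    hist[y] <- state_distance(state, prev)
  }
  snap1 <- state
  d1 <- hist[config$phase1_years]

  # phase 2: trait evolution
  evo <- run_evolution(state, config$phase2_years)
  state <- evo$state
  prev <- state
  state <- run_column(state, 365)
  d2 <- state_distance(state, prev)
  snap2 <- state
  cls <- classify_singularity(state)

  structure(list(seed = seed, config = config, state = state,
                 snapshot_phase1 = snap1, snapshot_phase2 = snap2,
                 events = evo$events, classification = cls,
                 convergence = tibble::tibble(year = seq_along(hist),
                                              distance = hist),
                 attractor_distance = c(phase1 = d1, phase2 = d2)),
            class = "evo_run")
}

#' @export
print.evo_run <- function(x, ...) {
  cat("<evo_run> seed", x$seed, "preset", x$config$preset, "\n")
  cat("  phase 1:", x$config$phase1_years, "y; phase 2:",
      x$config$phase2_years, "y\n")
  cat("  final richness:", species_richness(x$state), "\n")
  cat("  classification:", paste(sprintf("%s(%s)", x$classification$id,
                                         x$classification$class),
                                 collapse = " "), "\n")
  invisible(x)
}

#' Per-run diagnostics bundle
#'
#' Tidy one-row-per-metric summary of a protocol run at both phase ends:
#' species richness, Shannon evenness, and the Canberra distance between
#' the two phases' size distributions.
#'
#' @param run an `evo_run`.
#' @return tibble with `seed`, `phase`, `metric`, `value`.
#' @export
run_diagnostics <- function(run) {
  d1 <- size_distribution(run$snapshot_phase1)
  d2 <- size_distribution(run$snapshot_phase2)
  tibble::tibble(
    seed = run$seed,
    phase = c("t100", "t100", "t350", "t350", "both"),
    metric = c("richness", "shannon", "richness", "shannon",
               "canberra_t100_t350"),
    value = c(species_richness(run$snapshot_phase1), shannon_evenness(d1),
              species_richness(run$snapshot_phase2), shannon_evenness(d2),
              canberra(d1, d2))
  )
}

#' Run an ensemble of independent protocol simulations
#'
#' `K` runs with independent community seedings (seeds derived from the
#' master seed), summarized by the intra-group mean square distance of the
#' size distributions and per-run richness/evenness at both phase ends.
#'
#' @param config an [protocol_config()].
#' @param K ensemble size (24 in the reference protocol).
#' @param seed master seed.
#' @param n_phyto optional seeding-resolution override.
#' @return list of class `evo_ensemble`: `runs` (list of `evo_run`),
#'   `metrics` (tidy tibble), `msd` (tibble with phase-wise intra-group
#'   MSD).
#' @export
run_ensemble <- function(config = protocol_config("desk"), K = NULL,
                         seed = 1, n_phyto = NULL) {
  if (is.character(config)) config <- protocol_config(config)
  K <- K %||% config$ensemble_K
  stopifnot(K >= 1)
  seeds <- seed * 1000L + seq_len(K)
  runs <- lapply(seeds, function(s) run_protocol(config, s, n_phyto))
  d1 <- lapply(runs, function(r) size_distribution(r$snapshot_phase1))
  d2 <- lapply(runs, function(r) size_distribution(r$snapshot_phase2))
  structure(list(
    runs = runs,
    metrics = dplyr::bind_rows(lapply(runs, run_diagnostics)),
    msd = tibble::tibble(phase = c("t100", "t350"),
                         msd = c(mean_square_distance(d1),
                                 mean_square_distance(d2)))),
    class = "evo_ensemble")
}

#' Run manifest as JSON (config, seed, package version)
#' @param run an `evo_run`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_manifest <- function(run, file) {
  man <- list(seed = run$seed, preset = run$config$preset,
              n_phyto = nrow(run$snapshot_phase1$phyto),
              phase1_years = run$config$phase1_years,
              phase2_years = run$config$phase2_years,
              package_version = as.character(utils::packageVersion("evoplankton")))
  jsonlite::write_json(man, file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}
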