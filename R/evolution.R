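#' Mutation-invasion schedule
#'
#' The evolutionary engine repeats a fixed cycle: introduce two mutants per
#' resident (10% larger and 10% smaller cell volume), co-integrate them for
#' one year as passive tracers and measure invasion fitness, replace
#' residents where selection is directional, then let the system relax for
#' two years towards its new ecological attractor. The full cycle lasts
#' `eval_years + relax_years` = 3 years.
#'
#' @param params an `evo_params` list.
#' @return list with `step`, `eval_years`, `relax_years`, `cycle_years`,
#'   `amplitude`.
#' @export
evolution_schedule <- function(params = plankton_params()) {
  e <- params$evolution
  list(step = e$mutation_step, eval_years = e$eval_years,
       relax_years = e$relax_years,
       cycle_years = e$eval_years + e$relax_years,
       amplitude = e$mutant_amplitude)
}

#' Spawn the mutant pair of a resident
#'
#' Two hypothetical mutants, one slightly larger and one slightly smaller in
#' cell volume (`resident volume * (1 +/- step)`), with all physiological
#' traits rebuilt allometrically. A mutant whose volume would fall outside
#' the resident's functional-type range is not generated, so residents at a
#' range boundary get a single mutant.
#'
#' @param resident one row of a phytoplankton table.
#' @param step fractional volume step (default from `params`).
#' @param params an `evo_params` list.
#' @return tibble of 0-2 mutant species with columns of [build_species()]
#'   plus `parent` and `side` (`"-"` or `"+"`).
#' @export
spawn_mutants <- function(resident, step = NULL, params = plankton_params()) {
  if (is.null(step)) step <- params$evolution$mutation_step
  ft <- functional_types(params)
  rng <- ft[ft$type == resident$type, ]
  vols <- resident$volume * c(1 - step, 1 + step)
  sides <- c("-", "+")
  keep <- vols >= rng$V_lo & vols <= rng$V_hi
  if (!any(keep)) {
    out <- build_species(character(0), numeric(0), params)
    out$parent <- character(0); out$side <- character(0)
    return(out)
  }
  out <- build_species(rep(resident$type, sum(keep)), vols[keep], params,
                       id = paste0(resident$id, "m", sides[keep]))
  out$parent <- resident$id
  out$side <- sides[keep]
  out
}

#' Invasion fitness from annual biomass change
#'
#' `s = log(B(t + 1yr) / B(t))` with `B` the column-integrated biomass of
#' the (rare) mutant population over exactly one annual cycle of the
#' resident attractor. A mutant sharing the resident's trait has fitness
#' equal to the resident's realized annual growth rate, which is zero on a
#' perfect attractor.
#'
#' @param B_t biomass at introduction (> 0), mmol C m^-2.
#' @param B_t1 biomass one year later.
#' @return fitness per year; `-Inf` if the mutant went extinct
#'   (`B_t1 <= 0`).
#' @export
invasion_fitness <- function(B_t, B_t1) {
  stopifnot(all(B_t > 0))
  s <- ifelse(B_t1 <= 0, -Inf, log(B_t1 / B_t))
  unname(s)
}

#' Classify the selection regime at a resident
#'
#' Mutant fitnesses are compared against the resident's own realized annual
#' growth rate (not literal zero, since the system is never exactly on its
#' attractor): directional if exactly one mutant beats the resident,
#' stabilizing if neither does, disruptive if both do. Exact ties are
#' treated as not beating the resident (replacement requires strict
#' improvement). With a clamped (missing) mutant the comparison uses the
#' remaining one; with both missing the outcome is stabilizing by
#' convention.
#'
#' @param s_minus fitness of the smaller mutant (`NA` if not generated).
#' @param s_plus fitness of the larger mutant (`NA` if not generated).
#' @param s_resident the resident's realized annual growth rate.
#' @return one of `"directional-down"`, `"directional-up"`, `"stabilizing"`,
#'   `"disruptive"`.
#' @export
selection_outcome <- function(s_minus, s_plus, s_resident) {
  up <- !is.na(s_plus) && s_plus > s_resident
  down <- !is.na(s_minus) && s_minus > s_resident
  if (up && down) "disruptive"
  else if (up) "directional-up"
  else if (down) "directional-down"
  else "stabilizing"
}

#' Introduce passive mutant tracers
#'
#' Appends mutant species to the state as passive tracers: their initial
#' biomass, quota and chlorophyll depth profiles are the parent resident's
#' profiles scaled by a small amplitude (the scale cancels in the fitness
#' ratio), and they exert no feedback on nutrients, detritus, light or
#' grazer saturation -- they experience the environment without shaping it.
#'
#' @param state an `evo_state` whose phytoplankton are all active.
#' @param mutants tibble from [spawn_mutants()] (possibly row-bound over
#'   residents).
#' @param amplitude initial biomass scale relative to the parent.
#' @return the state with passive species appended.
#' @export
add_mutants <- function(state, mutants, amplitude = NULL) {
  if (is.null(amplitude)) amplitude <- state$params$evolution$mutant_amplitude
  if (nrow(mutants) == 0) return(state)
  mu <- mutants
  mu$active <- FALSE
  keep_cols <- setdiff(names(mu), c("parent", "side"))
  state$mutant_meta <- mu[, c("id", "parent", "side")]
  new_phyto <- dplyr::bind_rows(state$phyto, mu[, keep_cols])
  tr <- state$tracers
  blocks <- lapply(seq_len(nrow(mu)), function(k) {
    src <- tr[, paste0(mu$parent[k], c("_C", "_N", "_Chl")), drop = FALSE]
    out <- src * amplitude
    colnames(out) <- paste0(mu$id[k], c("_C", "_N", "_Chl"))
    out
  })
  mcols <- do.call(cbind, blocks)
  # insert mutant blocks after the phyto blocks, before the zoo blocks
  npz <- 8L + 3L * nrow(state$phyto)
  state$tracers <- cbind(tr[, seq_len(npz), drop = FALSE], mcols,
                         tr[, -seq_len(npz), drop = FALSE])
  state$phyto <- new_phyto
  state$cache$fw <- NULL
  state
}

#' Remove passive mutant tracers, keeping the resident fields untouched.
#' @param state an `evo_state` containing passive species.
#' @return the state restricted to its active phytoplankton.
#' @export
remove_mutants <- function(state) {
  passive <- !(state$phyto$active %||% rep(TRUE, nrow(state$phyto)))
  if (!any(passive)) return(state)
  drop_ids <- state$phyto$id[passive]
  drop_cols <- as.vector(t(outer(drop_ids, c("_C", "_N", "_Chl"), paste0)))
  state$tracers <- state$tracers[, setdiff(colnames(state$tracers), drop_cols),
                                 drop = FALSE]
  state$phyto <- state$phyto[!passive, , drop = FALSE]
  state$mutant_meta <- NULL
  state$cache$fw <- NULL
  state
}

#' Replace a resident's trait by the successful mutant's (attractor
#' inheritance)
#'
#' The winning trait value is attributed to the old resident population in
#' place: all allometric traits are rebuilt for the new cell volume while
#' the biomass, quota and chlorophyll depth profiles remain exactly those
#' the resident had, so the population inherits its own ecological
#' attractor.
#'
#' @param state an `evo_state`.
#' @param id resident species id.
#' @param new_volume the successful mutant's cell volume, um^3.
#' @return the state with the resident's traits swapped.
#' @export
replace_resident <- function(state, id, new_volume) {
  j <- match(id, state$phyto$id)
  if (is.na(j)) stop("unknown resident id: ", id)
  row <- build_species(state$phyto$type[j], new_volume, state$params, id = id)
  row$active <- TRUE
  cols <- intersect(names(state$phyto), names(row))
  state$phyto[j, cols] <- row[, cols]
  state$cache$fw <- NULL
  state
}

# One mutation-invasion trial: add the mutant set, co-integrate one year,
# return fitnesses for mutants and residents plus the advanced state
# (mutants still present; caller removes them).
run_trial_year <- function(state, mutants, amplitude = NULL) {
  st <- add_mutants(state, mutants, amplitude)
  B0 <- column_biomass(st)
  st <- run_column(st, 365)
  B1 <- column_biomass(st)
  ph <- B0$guild == "phyto"
  fit <- tibble::tibble(
    id = B0$id[ph],
    s = invasion_fitness(B0$biomass[ph], B1$biomass[ph][match(B0$id[ph], B1$id[ph])])
  )
  list(state = st, fitness = fit)
}

#' Run the adaptive-dynamics engine
#'
#' Starting from a state on (or near) its ecological attractor, repeats the
#' mutation-invasion-replacement-relaxation cycle for the requested horizon.
#' In every cycle all residents receive their mutant pair simultaneously and
#' all mutants are co-integrated as passive tracers over one shared year;
#' outcomes are then resolved per resident. Directional outcomes replace the
#' resident's trait; disruptive outcomes do not split the lineage (branching
#' is outside this engine's scope) -- the higher-fitness mutant wins and the
#' event is flagged.
#'
#' @param state an `evo_state`.
#' @param years horizon in years; `floor(years / 3)` full cycles are run and
#'   any remainder is integrated without evolution.
#' @param params optional parameter override for the schedule.
#' @return list with `state` and `events`, a tibble with one row per
#'   (cycle, resident): `cycle`, `year`, `id`, `type`, `old_volume`,
#'   `new_volume`, `s_minus`, `s_res`, `s_plus`, `outcome`.
#' @export
run_evolution <- function(state, years, params = NULL) {
  p <- params %||% state$params
  sch <- evolution_schedule(p)
  n_cycles <- floor(years / sch$cycle_years)
  leftover <- years - n_cycles * sch$cycle_years
  events <- list()
  for (cy in seq_len(n_cycles)) {
    residents <- state$phyto[state$phyto$active %||% rep(TRUE, nrow(state$phyto)), ]
    mutants <- dplyr::bind_rows(
      lapply(seq_len(nrow(residents)),
             function(j) spawn_mutants(residents[j, ], sch$step, p)))
    trial <- run_trial_year(state, mutants, sch$amplitude)
    fit <- trial$fitness
    state <- remove_mutants(trial$state)
    ev <- lapply(seq_len(nrow(residents)), function(j) {
      rid <- residents$id[j]
      s_res <- fit$s[fit$id == rid]
      sm <- fit$s[fit$id == paste0(rid, "m-")]
      sp <- fit$s[fit$id == paste0(rid, "m+")]
      s_minus <- if (length(sm)) sm else NA_real_
      s_plus <- if (length(sp)) sp else NA_real_
      out <- selection_outcome(s_minus, s_plus, s_res)
      newv <- residents$volume[j]
      if (out == "directional-up") newv <- residents$volume[j] * (1 + sch$step)
      if (out == "directional-down") newv <- residents$volume[j] * (1 - sch$step)
      if (out == "disruptive") {
        newv <- residents$volume[j] *
          (1 + sch$step * if (isTRUE(s_plus >= s_minus)) 1 else -1)
      }
      tibble::tibble(cycle = cy, year = floor(state$time / 365),
                     id = rid, type = residents$type[j],
                     old_volume = residents$volume[j], new_volume = newv,
                     s_minus = s_minus, s_res = s_res, s_plus = s_plus,
                     outcome = out)
    })
    ev <- dplyr::bind_rows(ev)
    for (j in seq_len(nrow(ev))) {
      if (ev$new_volume[j] != ev$old_volume[j]) {
        state <- replace_resident(state, ev$id[j], ev$new_volume[j])
      }
    }
    state <- run_column(state, 365L * sch$relax_years)
    events[[cy]] <- ev
  }
  if (leftover > 0) state <- run_column(state, round(365 * leftover))
  list(state = state,
       events = if (length(events)) dplyr::bind_rows(events) else
         tibble::tibble(cycle = integer(), year = numeric(), id = character(),
                        type = character(), old_volume = numeric(),
                        new_volume = numeric(), s_minus = numeric(),
                        s_res = numeric(), s_plus = numeric(),
                        outcome = character()))
}

#' Classify the evolutionary singularity at each resident
#'
#' One extra mutant trial per side (without modifying the input state):
#' stabilizing selection marks a continuously stable strategy (CSS, a
#' fitness maximum reached by directional convergence), disruptive selection
#' an evolutionary branching point (EBP, a convergence-stable fitness
#' minimum); anything else is still mid-slope (directional).
#'
#' @param state an `evo_state` on its eco-evolutionary attractor.
#' @param params optional parameter override.
#' @return tibble with `id`, `type`, `volume`, `s_minus`, `s_res`, `s_plus`,
#'   `outcome`, `class` (`"CSS"`, `"EBP"` or `"directional"`).
#' @export
classify_singularity <- function(state, params = NULL) {
  p <- params %||% state$params
  sch <- evolution_schedule(p)
  residents <- state$phyto[state$phyto$active %||% rep(TRUE, nrow(state$phyto)), ]
  mutants <- dplyr::bind_rows(
    lapply(seq_len(nrow(residents)),
           function(j) spawn_mutants(residents[j, ], sch$step, p)))
  trial <- run_trial_year(state, mutants, sch$amplitude)
  fit <- trial$fitness
  out <- lapply(seq_len(nrow(residents)), function(j) {
    rid <- residents$id[j]
    sm <- fit$s[fit$id == paste0(rid, "m-")]
    sp <- fit$s[fit$id == paste0(rid, "m+")]
    s_minus <- if (length(sm)) sm else NA_real_
    s_plus <- if (length(sp)) sp else NA_real_
    oc <- selection_outcome(s_minus, s_plus, fit$s[fit$id == rid])
    tibble::tibble(id = rid, type = residents$type[j],
                   volume = residents$volume[j],
                   s_minus = s_minus, s_res = fit$s[fit$id == rid],
                   s_plus = s_plus, outcome = oc,
                   class = switch(oc, stabilizing = "CSS",
                                  disruptive = "EBP", "directional"))
  })
  dplyr::bind_rows(out)
}

#' Write an evolution event log as CSV.
#' @param events the `events` tibble of [run_evolution()].
#' @param file path to a CSV file.
#' @return `file`, invisibly.
#' @export
write_events_csv <- function(events, file) {
  utils::write.csv(events, file, row.names = FALSE)
  invisible(file)
}
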