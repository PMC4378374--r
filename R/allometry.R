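#' Evaluate an allometric scaling rule
#'
#' All size-dependent traits follow a log10-linear law,
#' `trait = 10^(a + b * log10(V))`, with `V` the cell volume in cubic microns.
#' With `b = 0` the trait is size-independent; with `b != 0` it is strictly
#' monotone in volume.
#'
#' @param rule a list or named vector with elements `a` (intercept) and `b`
#'   (slope), both on the log10 scale.
#' @param volume cell volume(s) in um^3; must be strictly positive.
#' @return trait value(s), same length as `volume`.
#' @examples
#' allometric_param(list(a = 0.5, b = 0), 123)  # 10^0.5, size-independent
#' allometric_param(list(a = -0.824, b = 0.33), c(1, 1000))
#' @export
allometric_param <- function(rule, volume) {
  a <- rule[["a"]]; b <- rule[["b"]]
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(volume))
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    stop("cell volume must be strictly positive and finite")
  }
  10^(a + b * log10(volume))
}

#' Functional-type definitions
#'
#' The four phytoplankton functional types, ordered from the smallest
#' (Prochlorococcus) to the largest (diatoms). Each type has a cell-volume
#' range, a type-specific allometric intercept for the maximum growth rate,
#' and a nitrate-use flag; Prochlorococcus is the only type unable to take up
#' nitrate.
#'
#' @param params an `evo_params` list (defaults to [plankton_params()]).
#' @return A tibble with one row per functional type: `type`, `V_lo`, `V_hi`,
#'   `can_use_nitrate`, `mu_max_a`, `mu_max_b`.
#' @export
functional_types <- function(params = plankton_params()) {
  ft <- params$functional_types
  out <- tibble::tibble(
    type = names(ft),
    V_lo = unname(purrr::map_dbl(ft, ~ .x$volume_range[[1]])),
    V_hi = unname(purrr::map_dbl(ft, ~ .x$volume_range[[2]])),
    can_use_nitrate = unname(purrr::map_lgl(ft, ~ isTRUE(.x$can_use_nitrate))),
    mu_max_a = unname(purrr::map_dbl(ft, ~ .x$mu_max$a)),
    mu_max_b = unname(purrr::map_dbl(ft, ~ .x$mu_max$b))
  )
  bad <- out$V_lo >= out$V_hi
  if (any(bad)) stop("degenerate volume range for type(s): ",
                     paste(out$type[bad], collapse = ", "))
  out
}

#' Build a phytoplankton species from its functional type and cell volume
#'
#' Cell volume is the single evolving trait: every physiological trait
#' (maximum uptake rate, half-saturation, quota bounds, maximum growth rate,
#' sinking speed, carbon per cell) is its deterministic allometric image.
#' The maximum growth rate uses the type-specific intercept; all other rules
#' are shared across types.
#'
#' @param type functional type name(s) (one of the rows of
#'   [functional_types()]).
#' @param volume cell volume(s), um^3; must lie inside the type's range.
#' @param params an `evo_params` list.
#' @param id optional species id(s); autogenerated when missing.
#' @return A tibble with one row per species and columns `id`, `type`,
#'   `volume`, `can_use_nitrate`, `V_max`, `K_N`, `Q_min`, `Q_max`, `mu_max`,
#'   `sinking`, `carbon_per_cell`.
#' @examples
#' build_species("diatom", 1e4)
#' build_species(c("Prochlorococcus", "Synechococcus"), c(0.3, 2))
#' @export
build_species <- function(type, volume, params = plankton_params(), id = NULL) {
  ft <- functional_types(params)
  stopifnot(length(type) == length(volume))
  idx <- match(type, ft$type)
  if (anyNA(idx)) stop("unknown functional type(s): ",
                       paste(unique(type[is.na(idx)]), collapse = ", "))
  lo <- ft$V_lo[idx]; hi <- ft$V_hi[idx]
  # small relative tolerance so volumes computed on the log scale land inside
  out_of_range <- volume < lo * (1 - 1e-9) | volume > hi * (1 + 1e-9)
  if (any(out_of_range)) {
    k <- which(out_of_range)[1]
    stop(sprintf("volume %g um^3 outside the %s range [%g, %g]",
                 volume[k], type[k], lo[k], hi[k]))
  }
  al <- params$allometry
  if (is.null(id)) id <- paste0("P", seq_along(volume))
  tibble::tibble(
    id = id,
    type = type,
    volume = volume,
    can_use_nitrate = ft$can_use_nitrate[idx],
    V_max = allometric_param(al$V_max, volume),
    K_N = allometric_param(al$K_N, volume),
    Q_min = allometric_param(al$Q_min, volume),
    Q_max = allometric_param(al$Q_max, volume),
    mu_max = 10^(ft$mu_max_a[idx] + ft$mu_max_b[idx] * log10(volume)),
    sinking = allometric_param(al$sinking, volume),
    carbon_per_cell = allometric_param(al$carbon_per_cell, volume)
  )
}

#' Equilibrium internal quota of the Droop model
#'
#' At the grazer-free equilibrium, the internal N:C quota takes the value at
#' which Droop growth exactly balances the background mortality `m`:
#' `Q* = (Q_max - Q_min) * m / mu_max + Q_min`. It interpolates linearly
#' between `Q_min` (at `m = 0`) and `Q_max` (at `m = mu_max`).
#'
#' @param traits a list or one-row data frame with `Q_min`, `Q_max`, `mu_max`
#'   (e.g. a row of [build_species()]).
#' @param m background mortality rate, d^-1; must lie in `[0, mu_max]`.
#' @return `Q*`, mol N (mol C)^-1.
#' @export
equilibrium_quota <- function(traits, m) {
  Qmin <- traits[["Q_min"]]; Qmax <- traits[["Q_max"]]; mu <- traits[["mu_max"]]
  stopifnot(Qmin > 0, Qmax > Qmin, mu > 0, m >= 0)
  if (any(m > mu)) {
    stop("mortality exceeds mu_max: species cannot sustain itself (Q* undefined)")
  }
  unname((Qmax - Qmin) * m / mu + Qmin)
}

#' Critical nutrient concentration N* of the Droop model
#'
#' The external nutrient concentration at which a grazer-free Droop
#' population exactly balances its mortality: below `N*` it declines, above
#' it grows. `N*` is the variable-internal-stores analogue of Tilman's `R*`,
#' and under the default allometric scalings it increases with cell volume,
#' so pure nutrient competition favours the smallest cells.
#'
#' Computed as
#' `N* = K_N * mu_max * (Q* - Q_min) * Q* /
#'       (V_max * (Q_max - Q*) - mu_max * (Q* - Q_min) * Q*)`
#' with `Q*` from [equilibrium_quota()]. Light and temperature limitation
#' factors are taken at their reference value 1. When the denominator is not
#' positive the species cannot sustain itself at any nutrient concentration
#' and `Inf` is returned as a non-viability sentinel (also for `m >= mu_max`).
#'
#' @inheritParams equilibrium_quota
#' @param traits a list or one-row data frame with `V_max`, `K_N`, `Q_min`,
#'   `Q_max`, `mu_max`.
#' @return `N*` in mmol N m^-3 (`0` at `m = 0`; `Inf` if non-viable).
#' @examples
#' sp <- build_species("Synechococcus", 5)
#' critical_nutrient(sp, m = 0.05)
#' @export
critical_nutrient <- function(traits, m) {
  mu <- traits[["mu_max"]]
  if (m >= mu) return(Inf)
  Qs <- equilibrium_quota(traits, m)
  Qmin <- traits[["Q_min"]]; Qmax <- traits[["Q_max"]]
  num <- traits[["K_N"]] * mu * (Qs - Qmin) * Qs
  den <- traits[["V_max"]] * (Qmax - Qs) - mu * (Qs - Qmin) * Qs
  if (den <= 0) return(Inf)
  unname(num / den)
}

#' N* along a volume axis
#'
#' Convenience wrapper evaluating [critical_nutrient()] for one functional
#' type over a grid of cell volumes, e.g. to draw the N*-versus-size curves.
#'
#' @param type functional type name.
#' @param volumes cell volumes, um^3 (defaults to 60 log-spaced points over
#'   the type's range).
#' @param m background mortality rate, d^-1.
#' @param params an `evo_params` list.
#' @return A tibble with `type`, `volume`, `N_star`.
#' @export
nstar_curve <- function(type, volumes = NULL, m = NULL,
                        params = plankton_params()) {
  if (is.null(m)) m <- params$ecology$mortality
  ft <- functional_types(params)
  row <- ft[ft$type == type, ]
  if (nrow(row) == 0) stop("unknown functional type: ", type)
  if (is.null(volumes)) {
    volumes <- 10^seq(log10(row$V_lo), log10(row$V_hi), length.out = 60)
  }
  sp <- build_species(rep(type, length(volumes)), volumes, params)
  tibble::tibble(
    type = type, volume = volumes,
    N_star = purrr::map_dbl(seq_along(volumes),
                            ~ critical_nutrient(sp[.x, ], m))
  )
}

#' Zooplankton size spectrum
#'
#' Builds the fixed grazer community: `n` species whose body volumes are
#' log-spaced between `volume_min` and `volume_max`, so that the optimally
#' grazed prey volumes (body volume divided by the optimal predator:prey
#' ratio) tile the whole phytoplankton size range. Maximum ingestion rate is
#' allometric in body volume; kernel shape parameters are shared.
#'
#' @param params an `evo_params` list.
#' @return A tibble with one row per grazer: `id`, `volume`, `I_max`,
#'   `rho_opt`, `sigma`, `assimilation`, `quota`.
#' @export
zoo_spectrum <- function(params = plankton_params()) {
  z <- params$zooplankton
  stopifnot(z$n_species >= 0, z$rho_opt > 1, z$sigma > 0)
  V <- 10^seq(log10(z$volume_min), log10(z$volume_max), length.out = z$n_species)
  tibble::tibble(
    id = paste0("Z", seq_len(z$n_species)),
    volume = V,
    I_max = allometric_param(z$I_max, V),
    rho_opt = z$rho_opt,
    sigma = z$sigma,
    assimilation = z$assimilation,
    quota = z$quota
  )
}
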