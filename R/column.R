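#' Vertical grid of the water column
#'
#' Geometrically stretched levels (fine near the surface, where the euphotic
#' zone and all the ecology live; coarse at depth), with thicknesses summing
#' exactly to the total depth.
#'
#' @param n_levels number of levels (default 35).
#' @param depth total column depth, m (default 3275).
#' @param stretch geometric thickness ratio between consecutive levels
#'   (1 = uniform).
#' @return list of class `evo_grid`: `n`, `depth`, `h` (thicknesses),
#'   `z_int` (interface depths, length `n + 1`), `z_mid` (level mid-depths).
#' @export
column_grid <- function(n_levels = 35, depth = 3275, stretch = 1.1) {
  stopifnot(n_levels >= 1, depth > 0, stretch > 0)
  if (abs(stretch - 1) < 1e-12) {
    h <- rep(depth / n_levels, n_levels)
  } else {
    h1 <- depth * (stretch - 1) / (stretch^n_levels - 1)
    h <- h1 * stretch^(seq_len(n_levels) - 1)
  }
  h <- h * (depth / sum(h))   # exact closure against rounding
  z_int <- c(0, cumsum(h))
  structure(list(n = n_levels, depth = depth, h = h, z_int = z_int,
                 z_mid = (z_int[-1] + z_int[-(n_levels + 1)]) / 2),
            class = "evo_grid")
}

#' Seasonal forcing for a high-latitude column
#'
#' Builds the annually periodic (365-day) forcing tables emulating a
#' Norwegian Sea-like seasonal cycle: a strong surface-irradiance cycle with
#' its minimum in mid-winter, a surface-intensified seasonal temperature
#' profile, and a mixed-layer depth that deepens to several hundred metres
#' during the winter convection season (December-March) and shoals to a few
#' tens of metres in summer. The mixed layer is mapped to a vertical
#' diffusivity profile: `kappa_mixed` above the mixed-layer base, decaying to
#' the interior background `kappa_bg` across a transition of width
#' `kappa_width`.
#'
#' @param params an `evo_params` list (section `forcing`).
#' @param grid an [column_grid()] object.
#' @return list of class `evo_forcing` with daily tables: `I0` (365),
#'   `temperature` (levels x 365), `kappa` (interior interfaces x 365),
#'   `mld` (365), plus the generating parameters.
#' @export
make_forcing <- function(params = plankton_params(), grid = NULL) {
  if (is.null(grid)) grid <- column_grid(params$grid$n_levels,
                                         params$grid$depth,
                                         params$grid$stretch)
  f <- params$forcing
  day <- seq_len(365)
  phase <- 2 * pi * (day - 1) / 365
  I0 <- pmax(f$I0_mean - f$I0_amp * cos(phase), 0)
  Tsurf <- f$T_surf_mean - f$T_surf_amp * cos(phase)
  Tmat <- outer(exp(-grid$z_mid / f$z_T), Tsurf - f$T_deep) + f$T_deep
  s <- ((1 + cos(2 * pi * (day - f$mld_peak_day) / 365)) / 2)^f$mld_sharpness
  mld <- f$mld_min + (f$mld_max - f$mld_min) * s
  z_if <- grid$z_int[2:grid$n]               # interior interfaces
  kap <- vapply(seq_len(365), function(d) {
    f$kappa_bg + (f$kappa_mixed - f$kappa_bg) *
      0.5 * (1 + tanh((mld[d] - z_if) / f$kappa_width))
  }, numeric(max(grid$n - 1, 0)))
  if (grid$n == 1) kap <- matrix(0, 0, 365)
  structure(list(I0 = I0, temperature = Tmat, kappa = kap, mld = mld,
                 params = f, grid = grid),
            class = "evo_forcing")
}

#' Evaluate the forcing at an arbitrary time
#'
#' Looks up the daily forcing tables with strict annual periodicity:
#' `forcing_at(f, t)` and `forcing_at(f, t + 365)` are identical.
#'
#' @param forcing an [make_forcing()] object.
#' @param t time in days (day 1 = January 1).
#' @return list with `I0`, `temperature` (per level), `kappa` (per interior
#'   interface), `mld`, `doy`.
#' @export
forcing_at <- function(forcing, t) {
  doy <- (as.integer(floor(t)) - 1L) %% 365L + 1L
  if (doy < 1L) doy <- doy + 365L
  list(I0 = forcing$I0[doy],
       temperature = forcing$temperature[, doy],
       kappa = forcing$kappa[, doy],
       mld = forcing$mld[doy],
       doy = doy)
}

#' Write / read forcing tables as CSV
#'
#' Long format, one row per (day, depth) pair plus surface rows; reading the
#' file back reproduces the daily tables exactly.
#'
#' @param forcing an `evo_forcing` object.
#' @param file path to a CSV file.
#' @return the tibble written (invisibly) / the reconstructed tables.
#' @export
write_forcing_csv <- function(forcing, file) {
  g <- forcing$grid
  tab <- tidyr::expand_grid(day = seq_len(365), level = seq_len(g$n))
  tab$depth <- g$z_mid[tab$level]
  tab$temperature <- forcing$temperature[cbind(tab$level, tab$day)]
  tab$I0 <- forcing$I0[tab$day]
  tab$mld <- forcing$mld[tab$day]
  tab$kappa <- NA_real_
  ii <- tab$level < g$n
  tab$kappa[ii] <- forcing$kappa[cbind(tab$level[ii], tab$day[ii])]
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(tibble::as_tibble(tab))
}

#' @rdname write_forcing_csv
#' @export
read_forcing_csv <- function(file) {
  tab <- utils::read.csv(file)
  L <- max(tab$level)
  list(I0 = tab$I0[tab$level == 1],
       temperature = matrix(tab$temperature, nrow = L),
       kappa = matrix(tab$kappa, nrow = L)[-L, , drop = FALSE],
       mld = tab$mld[tab$level == 1])
}

#' Irradiance profile by Beer-Lambert attenuation
#'
#' Light decays through each layer with attenuation
#' `k = k_water + k_chl * Chl`; the returned values are level-midpoint
#' irradiances, monotone non-increasing with depth.
#'
#' @param I0 surface irradiance, W m^-2.
#' @param grid an [column_grid()] object.
#' @param chl per-level total chlorophyll, mg m^-3 (0 = no self-shading).
#' @param params an `evo_params` list.
#' @return irradiance per level, W m^-2.
#' @export
light_profile <- function(I0, grid, chl = 0, params = plankton_params()) {
  stopifnot(I0 >= 0)
  k <- params$light$k_water + params$light$k_chl * rep_len(chl, grid$n)
  att <- k * grid$h
  I0 * exp(-(cumsum(att) - att / 2))
}

# Conservative diffusion operator matrix A (dC/dt = A C) for kappa at the
# interior interfaces; flux form weighted by level thicknesses, so the
# h-weighted column integral is invariant: t(h) %*% A == 0.
diffusion_matrix <- function(kappa, grid) {
  n <- grid$n
  A <- matrix(0, n, n)
  if (n == 1) return(A)
  dz <- diff(grid$z_mid)
  for (i in seq_len(n - 1)) {
    c_ex <- kappa[i] / dz[i]
    A[i, i] <- A[i, i] - c_ex / grid$h[i]
    A[i, i + 1] <- A[i, i + 1] + c_ex / grid$h[i]
    A[i + 1, i + 1] <- A[i + 1, i + 1] - c_ex / grid$h[i + 1]
    A[i + 1, i] <- A[i + 1, i] + c_ex / grid$h[i + 1]
  }
  A
}

#' Implicit vertical diffusion
#'
#' Backward-Euler (unconditionally stable) conservative mixing: solves
#' `(I - dt A) C_new = C` with the flux-form operator `A`. The h-weighted
#' column integral of every tracer is unchanged to round-off and no new
#' extrema are created.
#'
#' @param fields numeric matrix (levels x tracers) or vector.
#' @param kappa diffusivity at the `n - 1` interior interfaces, m^2 d^-1.
#' @param dt time step, d.
#' @param grid an [column_grid()] object.
#' @return mixed fields, same shape.
#' @export
diffuse <- function(fields, kappa, dt, grid) {
  stopifnot(dt > 0, all(kappa >= 0))
  v <- is.null(dim(fields))
  if (v) fields <- matrix(fields, ncol = 1)
  M <- diag(grid$n) - dt * diffusion_matrix(kappa, grid)
  out <- solve(M, fields)
  if (v) out[, 1] else out
}

#' Conservative sinking (upwind advection)
#'
#' First-order upwind transport with downward velocity; the bottom boundary
#' is closed (zero flux), so sinking material accumulates in the deepest
#' level and the h-weighted column integral is exactly conserved. If the CFL
#' number exceeds 0.9 the step is automatically sub-stepped.
#'
#' @param fields numeric matrix (levels x tracers) or vector.
#' @param velocity sinking speed(s), m d^-1, scalar or one per tracer column.
#' @param dt time step, d.
#' @param grid an [column_grid()] object.
#' @return advected fields, same shape.
#' @export
sink_tracers <- function(fields, velocity, dt, grid) {
  stopifnot(all(velocity >= 0), dt > 0)
  v <- is.null(dim(fields))
  if (v) fields <- matrix(fields, ncol = 1)
  w <- rep_len(velocity, ncol(fields))
  nsub <- max(1L, ceiling(max(w) * dt / (0.9 * min(grid$h))))
  dts <- dt / nsub
  W <- matrix(w, grid$n, ncol(fields), byrow = TRUE)
  for (s in seq_len(nsub)) {
    flux <- fields * W
    flux[grid$n, ] <- 0                       # closed bottom
    fields <- fields + dts * (rbind(0, flux[-grid$n, , drop = FALSE]) - flux) / grid$h
  }
  if (v) fields[, 1] else fields
}

## ---- column state -----------------------------------------------------------

#' Initialize a column state
#'
#' Builds the depth-resolved tracer state for a community: nutrients from the
#' `initial` parameter section (nitrate-rich winter column), empty detritus,
#' and uniform vanishingly small plankton seed profiles, at winter (January,
#' day 1) conditions.
#'
#' @param phyto phytoplankton table ([build_species()]).
#' @param zoo grazer table ([zoo_spectrum()]).
#' @param params an `evo_params` list.
#' @param grid optional [column_grid()]; built from `params` when missing.
#' @param forcing optional [make_forcing()]; built when missing.
#' @return list of class `evo_state`: `time` (days), `grid`, `forcing`,
#'   `params`, `phyto`, `zoo`, `tracers` (levels x tracers matrix), `audit`
#'   (logged floor/clip interventions, in column-integrated mmol).
#' @export
init_state <- function(phyto, zoo, params = plankton_params(),
                       grid = NULL, forcing = NULL) {
  if (is.null(grid)) grid <- column_grid(params$grid$n_levels,
                                         params$grid$depth,
                                         params$grid$stretch)
  if (is.null(forcing)) forcing <- make_forcing(params, grid)
  if (!"active" %in% names(phyto)) phyto$active <- TRUE
  nm <- tracer_names(phyto, zoo)
  tr <- matrix(0, grid$n, length(nm), dimnames = list(NULL, nm))
  ini <- params$initial
  tr[, "NO3"] <- ini$NO3; tr[, "NO2"] <- ini$NO2; tr[, "NH4"] <- ini$NH4
  tr[, "DIC"] <- ini$DIC
  for (j in seq_len(nrow(phyto))) {
    q0 <- (phyto$Q_min[j] + phyto$Q_max[j]) / 2
    tr[, paste0(phyto$id[j], "_C")] <- ini$plankton
    tr[, paste0(phyto$id[j], "_N")] <- ini$plankton * q0
    tr[, paste0(phyto$id[j], "_Chl")] <- ini$plankton * 0.3
  }
  z0 <- if (isTRUE(params$zooplankton$static)) {
    params$zooplankton$static_biomass
  } else ini$plankton
  for (j in seq_len(nrow(zoo))) {
    tr[, paste0(zoo$id[j], "_C")] <- z0
    tr[, paste0(zoo$id[j], "_N")] <- z0 * zoo$quota[j]
  }
  structure(list(time = 0, grid = grid, forcing = forcing, params = params,
                 phyto = phyto, zoo = zoo, tracers = tr,
                 audit = list(added_N = 0, added_C = 0, clip_events = 0),
                 cache = NULL),
            class = "evo_state")
}

#' @export
print.evo_state <- function(x, ...) {
  cat("<evo_state> t =", round(x$time, 2), "d (year",
      floor(x$time / 365) + 1, ")\n")
  cat("  ", sum(x$phyto$active %||% TRUE), "active phytoplankton,",
      nrow(x$zoo), "zooplankton,", x$grid$n, "levels\n")
  bc <- column_biomass(x)
  top <- bc[order(-bc$biomass), ][seq_len(min(4, nrow(bc))), ]
  cat("  top biomass (mmol C m^-2):",
      paste(sprintf("%s=%.3g", top$id, top$biomass), collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# transport + forcing tables cached per (grid, forcing, dt)
transport_cache <- function(state) {
  g <- state$grid; p <- state$params
  dt <- p$numerics$dt_bio
  Minv <- vector("list", 365)
  Id <- diag(g$n)
  for (d in seq_len(365)) {
    A <- diffusion_matrix(state$forcing$kappa[, d], g)
    Minv[[d]] <- solve(Id - dt * A)
  }
  gT <- gamma_temperature(state$forcing$temperature, p)
  list(dt = dt, Minv = Minv, gammaT = gT, I0 = state$forcing$I0)
}

ensure_cache <- function(state) {
  if (is.null(state$cache)) state$cache <- list()
  if (is.null(state$cache$ops) ||
      !identical(state$cache$ops$dt, state$params$numerics$dt_bio)) {
    state$cache$ops <- transport_cache(state)
  }
  if (is.null(state$cache$fw)) {
    cc <- foodweb_cache(state$phyto, state$zoo, state$params, state$grid$n)
    # sinking layout: per-phyto C/N/Chl at the species' allometric speed,
    # plus the particulate detritus pools
    w3 <- rep(cc$w_phyto, each = 3)
    scols <- c(as.vector(rbind(cc$ipc, cc$ipn, cc$ipchl)), 7L, 8L)
    svel <- c(w3, state$params$ecology$w_detritus,
              state$params$ecology$w_detritus)
    keep <- svel > 0
    cc$sink_cols <- scols[keep]
    cc$sink_W <- matrix(svel[keep], state$grid$n, sum(keep), byrow = TRUE)
    dtb <- state$params$numerics$dt_bio
    cc$sink_nsub <- max(1L, ceiling(max(svel) * dtb / (0.9 * min(state$grid$h))))
    # budget weights per tracer column (passive species excluded)
    K <- 8L + 3L * (cc$np + cc$nz)
    wN <- numeric(K); wC <- numeric(K)
    wN[c(1L, 2L, 3L, 6L, 8L)] <- 1
    wC[c(4L, 5L, 7L)] <- 1
    wN[cc$ipn[cc$actp]] <- 1; wN[cc$izn] <- 1
    wC[cc$ipc[cc$actp]] <- 1; wC[cc$izc] <- 1
    cc$wN <- wN; cc$wC <- wC
    state$cache$fw <- cc
  }
  state
}

#' Advance the column state
#'
#' Operator-split integration: forward-Euler biology at the biological time
#' step, then implicit diffusion and upwind sinking, with daily re-evaluation
#' of the forcing. After every biological sub-step the state is repaired and
#' the repairs logged in the audit: negative tracers are clipped to zero,
#' every actively cycling phytoplankton species is floored at the
#' quasi-extinction level (an immigration stand-in; passive mutant tracers
#' are never floored and may go extinct), and internal quotas are clamped to
#' `[Q_min, Q_max]`.
#'
#' @param state an [init_state()] object.
#' @param days number of days to integrate (integer).
#' @return the advanced `evo_state`.
#' @export
run_column <- function(state, days) {
  stopifnot(inherits(state, "evo_state"), days >= 0)
  days <- as.integer(round(days))
  if (days == 0) return(state)
  state <- ensure_cache(state)
  ops <- state$cache$ops; cc <- state$cache$fw
  p <- state$params; g <- state$grid
  tr <- state$tracers
  dt <- ops$dt
  nsub <- max(1L, as.integer(round(1 / dt)))
  h <- g$h
  floor_C <- p$ecology$quasi_extinction_floor
  ipc_act <- cc$ipc[cc$actp]; ipn_act <- cc$ipn[cc$actp]
  Qmin_act <- cc$Qmin_m[, cc$actp, drop = FALSE]
  ipchl_act <- cc$ipchl[cc$actp]
  kw <- p$light$k_water; kchl <- p$light$k_chl
  added_N <- state$audit$added_N; added_C <- state$audit$added_C
  clip_events <- state$audit$clip_events
  ipn_all <- cc$ipn; ipc_all <- cc$ipc
  Qmin_all <- cc$Qmin_m; Qmax_all <- cc$Qmax_m
  if (cc$nz > 0 && !cc$static_zoo) {
    izc_cols <- cc$izc; izn_cols <- cc$izn; QZ_floor <- cc$QZ
  } else {
    izc_cols <- integer(0); izn_cols <- integer(0); QZ_floor <- 0
  }
  day0 <- as.integer(floor(state$time + 1e-9))
  env <- list(irradiance = NULL, gammaT = NULL)

  for (d in seq_len(days)) {
    doy <- (day0 + d - 1L) %% 365L + 1L
    Minv <- ops$Minv[[doy]]
    env$gammaT <- ops$gammaT[, doy]
    I0 <- ops$I0[doy]
    for (s in seq_len(nsub)) {
      chl <- tr[, ipchl_act, drop = FALSE]
      chl_tot <- .rowSums(chl, g$n, length(ipchl_act))
      att <- (kw + kchl * chl_tot) * h
      env$irradiance <- I0 * exp(-(cumsum(att) - att / 2))

      tr <- tr + dt * bio_tendencies(tr, cc, env, p)

      # repair: clip negatives (logged against the budgets)
      if (any(tr < 0)) {
        deficit <- pmin(tr, 0)
        colsum <- colSums(deficit * h)
        added_N <- added_N - sum(colsum * cc$wN)
        added_C <- added_C - sum(colsum * cc$wC)
        clip_events <- clip_events + sum(deficit < 0)
        tr[tr < 0] <- 0
      }
      # immigration floor for active phytoplankton
      pc <- tr[, ipc_act, drop = FALSE]
      low <- pc < floor_C
      if (any(low)) {
        add <- (floor_C - pc) * low
        added_C <- added_C + sum(colSums(add * h))
        tr[, ipc_act] <- pc + add
        # give immigrants a minimal quota
        pn <- tr[, ipn_act, drop = FALSE]
        need <- Qmin_act * tr[, ipc_act, drop = FALSE] - pn
        need[need < 0 | !low] <- 0
        if (any(need > 0)) {
          added_N <- added_N + sum(colSums(need * h))
          tr[, ipn_act] <- pn + need
        }
      }
      # immigration floor for zooplankton (same rationale; avoids decay to
      # subnormal numbers and allows grazers to re-invade with their prey)
      if (length(izc_cols)) {
        zc <- tr[, izc_cols, drop = FALSE]
        lowz <- zc < floor_C
        if (any(lowz)) {
          addz <- (floor_C - zc) * lowz
          added_C <- added_C + sum(colSums(addz * h))
          zc <- zc + addz
          tr[, izc_cols] <- zc
          zn <- tr[, izn_cols, drop = FALSE]
          needz <- QZ_floor * zc - zn
          needz[needz < 0 | !lowz] <- 0
          if (any(needz > 0)) {
            added_N <- added_N + sum(colSums(needz * h))
            tr[, izn_cols] <- zn + needz
          }
        }
      }
      # clamp quotas to [Q_min, Q_max] (all phyto; only active species
      # touch the nitrogen budget)
      pc <- tr[, ipc_all, drop = FALSE]
      pn <- tr[, ipn_all, drop = FALSE]
      qlo <- Qmin_all * pc; qhi <- Qmax_all * pc
      bel <- pn < qlo; abv <- pn > qhi
      if (any(bel) || any(abv)) {
        pn2 <- pn
        pn2[bel] <- qlo[bel]; pn2[abv] <- qhi[abv]
        dpn <- pn2 - pn
        added_N <- added_N +
          sum(colSums(dpn[, cc$actp, drop = FALSE] * h))
        tr[, ipn_all] <- pn2
      }

      # transport
      tr <- Minv %*% tr
      if (length(cc$sink_cols)) {
        f0 <- tr[, cc$sink_cols, drop = FALSE]
        dts <- dt / cc$sink_nsub
        for (ss in seq_len(cc$sink_nsub)) {
          flux <- f0 * cc$sink_W
          flux[g$n, ] <- 0
          f0 <- f0 + dts * (rbind(0, flux[-g$n, , drop = FALSE]) - flux) / h
        }
        tr[, cc$sink_cols] <- f0
      }
    }
    if (anyNA(tr)) {
      bad <- which(is.na(tr), arr.ind = TRUE)
      stop(sprintf(paste0("numerical blow-up (NaN) at t = %.2f d, level %d, ",
                          "tracer '%s'; dt_bio = %g"),
                   state$time + d, bad[1, 1], colnames(tr)[bad[1, 2]],
                   dt))
    }
  }
  state$tracers <- tr
  state$time <- state$time + days
  state$audit <- list(added_N = added_N, added_C = added_C,
                      clip_events = clip_events)
  state
}

#' One operator-split step
#'
#' Single biological sub-step (biology, repairs, diffusion, sinking) at the
#' configured `dt`; mostly useful for inspection -- [run_column()] is the
#' driver for real runs.
#'
#' @inheritParams run_column
#' @return the advanced state (time moves by `dt_bio` days).
#' @export
step_column <- function(state) {
  p <- state$params
  dt <- p$numerics$dt_bio
  st <- ensure_cache(state)
  ops <- st$cache$ops
  doy <- (as.integer(floor(st$time)) %% 365L) + 1L
  cc <- st$cache$fw
  env <- list(gammaT = ops$gammaT[, doy])
  chl_tot <- rowSums(st$tracers[, cc$ipchl[cc$actp], drop = FALSE])
  att <- (p$light$k_water + p$light$k_chl * chl_tot) * st$grid$h
  env$irradiance <- ops$I0[doy] * exp(-(cumsum(att) - att / 2))
  tr <- st$tracers + dt * bio_tendencies(st$tracers, cc, env, p)
  tr[tr < 0] <- 0
  tr <- ops$Minv[[doy]] %*% tr
  if (length(cc$sink_cols)) {
    tr[, cc$sink_cols] <- sink_tracers(tr[, cc$sink_cols, drop = FALSE],
                               cc$sink_W[1, ], dt, st$grid)
  }
  st$tracers <- tr
  st$time <- st$time + dt
  st
}

#' Column-integrated biomass per species
#'
#' @param state an `evo_state`.
#' @return tibble with `id`, `guild`, `type`, `volume`, `active`, `biomass`
#'   (mmol C m^-2, h-weighted column integral).
#' @export
column_biomass <- function(state) {
  h <- state$grid$h
  cint <- function(col) sum(state$tracers[, col] * h)
  ph <- state$phyto
  tibble::tibble(
    id = c(ph$id, state$zoo$id),
    guild = rep(c("phyto", "zoo"), c(nrow(ph), nrow(state$zoo))),
    type = c(ph$type, rep(NA_character_, nrow(state$zoo))),
    volume = c(ph$volume, state$zoo$volume),
    active = c(ph$active %||% rep(TRUE, nrow(ph)), rep(TRUE, nrow(state$zoo))),
    biomass = vapply(paste0(c(ph$id, state$zoo$id), "_C"), cint, numeric(1),
                     USE.NAMES = FALSE)
  )
}

#' Nitrogen (and carbon) budget of a column state
#'
#' Column-integrated totals over the closed budgets, together with the
#' logged repair interventions. For a closed column the audited drift
#' `total - added` is constant over arbitrary horizons up to round-off.
#'
#' @param state an `evo_state`.
#' @return list with `total_N`, `total_C` (mmol m^-2, active species only),
#'   `added_N`, `added_C` (net logged interventions), `audited_N`,
#'   `audited_C` (totals net of interventions), `clip_events`.
#' @export
nitrogen_budget <- function(state) {
  state <- ensure_cache(state)
  cc <- state$cache$fw
  h <- state$grid$h
  tN <- sum(colSums(state$tracers * h) * cc$wN)
  tC <- sum(colSums(state$tracers * h) * cc$wC)
  list(total_N = tN, total_C = tC,
       added_N = state$audit$added_N, added_C = state$audit$added_C,
       audited_N = tN - state$audit$added_N,
       audited_C = tC - state$audit$added_C,
       clip_events = state$audit$clip_events)
}

#' Year-over-year state distance
#'
#' Relative L2 distance between two tracer states (active columns only),
#' h-weighted; the year-over-year distance tends to zero as the seasonally
#' forced system settles on its annual limit cycle.
#'
#' @param a,b two `evo_state` objects on the same grid and community.
#' @return non-negative scalar.
#' @export
state_distance <- function(a, b) {
  a <- ensure_cache(a)
  cc <- a$cache$fw
  keep <- c(seq_len(8L), cc$ipc[cc$actp], cc$ipn[cc$actp], cc$izc, cc$izn)
  h <- a$grid$h
  x <- a$tracers[, keep, drop = FALSE] * sqrt(h)
  y <- b$tracers[, keep, drop = FALSE] * sqrt(h)
  sqrt(sum((x - y)^2)) / max(sqrt(sum(y^2)), 1e-300)
}

#' Integrate to the annual attractor
#'
#' Runs whole years until the year-over-year state distance falls below
#' `tol` (or `max_years` is reached), returning the state plus the
#' convergence history.
#'
#' @param state an `evo_state` (time should be at a year boundary).
#' @param max_years hard cap on the number of years.
#' @param tol year-over-year relative distance defining "on the attractor".
#' @param min_years run at least this many years.
#' @return list with `state`, `years` (tibble: `year`, `distance`),
#'   `converged`, `convergence_year` (first year reaching `tol`, `NA` if
#'   never).
#' @export
run_to_attractor <- function(state, max_years = 50, tol = 1e-7,
                             min_years = 3) {
  hist <- numeric(0)
  conv_year <- NA_integer_
  for (y in seq_len(max_years)) {
    prev <- state
    state <- run_column(state, 365)
    d <- state_distance(state, prev)
    hist <- c(hist, d)
    if (is.na(conv_year) && d < tol) conv_year <- y
    if (!is.na(conv_year) && y >= min_years && d < tol) break
  }
  list(state = state,
       years = tibble::tibble(year = seq_along(hist), distance = hist),
       converged = !is.na(conv_year),
       convergence_year = conv_year)
}

#' Write a state snapshot as CSV (long format: level x tracer).
#' @param state an `evo_state`.
#' @param file path to a CSV file.
#' @return the tibble written, invisibly.
#' @export
write_state_csv <- function(state, file) {
  tab <- tibble::as_tibble(state$tracers)
  tab <- tibble::add_column(tab,
                            level = seq_len(state$grid$n),
                            depth = state$grid$z_mid,
                            time = state$time, .before = 1)
  long <- tidyr::pivot_longer(tab, cols = -c("level", "depth", "time"),
                              names_to = "tracer", values_to = "value")
  utils::write.csv(long, file, row.names = FALSE)
  invisible(long)
}
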