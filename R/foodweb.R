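#' Size-selective grazing palatability
#'
#' Grazing efficiency is a log-normal function of the predator-to-prey
#' volume ratio, centred on the grazer's optimal ratio `rho_opt` and
#' normalized to a peak value of 1: a grazer of body volume `V_z` grazes most
#' efficiently on prey of volume `V_z / rho_opt`, symmetrically in
#' log(ratio), vanishing for much larger or much smaller prey.
#'
#' @param prey_volume prey cell volume(s), um^3.
#' @param zoo a grazer: list or one-row data frame with `volume`, `rho_opt`,
#'   `sigma` (kernel width in ln-volume units), e.g. a row of
#'   [zoo_spectrum()].
#' @return efficiencies in `[0, 1]`, same length as `prey_volume`.
#' @examples
#' z <- list(volume = 1e5, rho_opt = 1000, sigma = 0.6)
#' palatability(100, z)  # optimal prey: exactly 1
#' @export
palatability <- function(prey_volume, zoo) {
  stopifnot(all(prey_volume > 0), zoo[["volume"]] > 0)
  ratio <- zoo[["volume"]] / prey_volume
  exp(-(log(ratio / zoo[["rho_opt"]]))^2 / (2 * zoo[["sigma"]]^2))
}

#' Holling type-3 grazing fluxes of one grazer on a prey set
#'
#' Total ingestion is `I_max * Z * A^2 / (A^2 + k_A^2)` where `A` is the
#' palatability-weighted available prey biomass, apportioned across prey in
#' proportion to their palatability-weighted biomass. With no available prey
#' the flux is zero (including the all-palatabilities-zero case); the total
#' saturates at `I_max * Z`.
#'
#' @param zoo a grazer with `I_max` (and optionally kernel fields).
#' @param Z grazer biomass, mmol C m^-3.
#' @param prey_biomass prey biomasses, mmol C m^-3.
#' @param prey_palatability efficiencies in `[0, 1]` (e.g. from
#'   [palatability()]).
#' @param k_A half-saturation of the functional response on availability,
#'   mmol C m^-3.
#' @return list with `total` ingestion (mmol C m^-3 d^-1), per-prey `flux`,
#'   and the availability `A`.
#' @export
grazing_flux <- function(zoo, Z, prey_biomass, prey_palatability, k_A = 0.5) {
  stopifnot(length(prey_biomass) == length(prey_palatability),
            all(prey_biomass >= 0), Z >= 0)
  w <- prey_palatability * prey_biomass
  A <- sum(w)
  if (A <= 0) {
    return(list(total = 0, flux = numeric(length(prey_biomass)), A = 0))
  }
  total <- zoo[["I_max"]] * Z * A^2 / (A^2 + k_A^2)
  list(total = total, flux = total * w / A, A = A)
}

#' Droop uptake and growth rates of one phytoplankton species
#'
#' The variable-internal-stores model decouples population growth from the
#' external nutrient: uptake fills the internal N:C quota `Q` at rate
#' `V_max * (Q_max - Q)/(Q_max - Q_min) * N/(N + K_N)` and growth converts
#' quota into biomass at rate
#' `mu_max * gamma_T(T) * gamma_I(I) * (Q - Q_min)/(Q_max - Q_min)`.
#' Uptake therefore vanishes at a full quota or zero nutrient, growth at an
#' empty quota.
#'
#' With a named nutrient vector (`NO3`, `NO2`, `NH4`) uptake is summed over
#' the three forms, ammonium inhibits nitrate/nitrite uptake
#' (`exp(-psi * NH4)`), and nitrate uptake is zero for Prochlorococcus. A
#' single unnamed value is treated as one generic nutrient pool without
#' inhibition (the form in which the N* theory is stated).
#'
#' @param species one row of [build_species()].
#' @param N external nutrient concentration(s), mmol N m^-3.
#' @param Q internal quota, mol N (mol C)^-1, inside `[Q_min, Q_max]`.
#' @param env list with `temperature` (degC) and `irradiance` (W m^-2);
#'   `NULL` evaluates at reference conditions (`gamma_T = gamma_I = 1`).
#' @param params an `evo_params` list.
#' @return list with `uptake` (total, mol N (mol C)^-1 d^-1), `uptake_by_form`
#'   (named, when three forms are given), and `growth` (d^-1).
#' @export
droop_terms <- function(species, N, Q, env = NULL, params = plankton_params()) {
  Qmin <- species[["Q_min"]]; Qmax <- species[["Q_max"]]
  if (any(N < 0)) stop("nutrient concentration must be non-negative")
  if (Q < Qmin - 1e-12 || Q > Qmax + 1e-12) {
    stop("quota outside [Q_min, Q_max]")
  }
  Q <- min(max(Q, Qmin), Qmax)
  qf_up <- (Qmax - Q) / (Qmax - Qmin)
  qf_gr <- (Q - Qmin) / (Qmax - Qmin)
  gT <- 1; gI <- 1
  if (!is.null(env)) {
    gT <- gamma_temperature(env$temperature, params)
    gI <- gamma_light(env$irradiance, params)
  }
  if (length(N) == 1 && is.null(names(N))) {
    up <- species[["V_max"]] * qf_up * N / (N + species[["K_N"]])
    by_form <- NULL
  } else {
    stopifnot(all(c("NO3", "NO2", "NH4") %in% names(N)))
    inh <- exp(-params$ecology$psi_NH4 * N[["NH4"]])
    mm <- function(x) x / (x + species[["K_N"]])
    no3 <- if (species[["can_use_nitrate"]]) mm(N[["NO3"]]) * inh else 0
    by_form <- species[["V_max"]] * qf_up *
      c(NO3 = unname(no3), NO2 = unname(mm(N[["NO2"]]) * inh),
        NH4 = unname(mm(N[["NH4"]])))
    up <- sum(by_form)
  }
  list(uptake = unname(up), uptake_by_form = by_form,
       growth = unname(species[["mu_max"]] * gT * gI * qf_gr))
}

#' Eppley temperature factor, normalized to 1 at the reference temperature.
#' @param temperature degC.
#' @param params an `evo_params` list.
#' @return multiplicative factor (dimensionless).
#' @export
gamma_temperature <- function(temperature, params = plankton_params()) {
  exp(params$temperature$coeff * (temperature - params$temperature$T_ref))
}

#' Saturating light limitation factor, `1 - exp(-I / I_sat)`.
#' @param irradiance W m^-2.
#' @param params an `evo_params` list.
#' @return factor in `[0, 1)`.
#' @export
gamma_light <- function(irradiance, params = plankton_params()) {
  1 - exp(-pmax(irradiance, 0) / params$light$I_sat)
}

#' Number of coupled state equations per spatial location
#'
#' The tracer layout gives every plankton species -- phytoplankton and
#' zooplankton alike -- a uniform block of three state variables (carbon
#' biomass, nitrogen biomass, chlorophyll; the chlorophyll slot is inert for
#' grazers), plus eight shared compartments: four dissolved pools (NO3, NO2,
#' NH4, DIC) and four detritus pools (DOC, DON, POC, PON). The count is
#' therefore affine in the number of phytoplankton species with slope 3:
#' 59 equations at 8 phytoplankton and 9 zooplankton, 275 at 80.
#'
#' @param n_phyto number of phytoplankton species.
#' @param n_zoo number of zooplankton species (default 9).
#' @return integer equation count.
#' @examples
#' count_state_equations(8)   # 59
#' count_state_equations(80)  # 275
#' @export
count_state_equations <- function(n_phyto, n_zoo = 9) {
  stopifnot(n_phyto >= 0, n_zoo >= 0)
  as.integer(3 * (n_phyto + n_zoo) + 8)
}

## ---- internal vectorized core ----------------------------------------------

# Shared tracer column layout: 8 pools then per-species C/N/Chl blocks.
POOLS <- c("NO3", "NO2", "NH4", "DIC", "DOC", "DON", "POC", "PON")

tracer_names <- function(phyto, zoo) {
  c(POOLS,
    as.vector(t(outer(phyto$id, c("_C", "_N", "_Chl"), paste0))),
    as.vector(t(outer(zoo$id, c("_C", "_N", "_Chl"), paste0))))
}

# Precompute everything that depends only on the community composition and
# the grid size: trait broadcast matrices, palatability matrix, indices.
foodweb_cache <- function(phyto, zoo, params, n_levels) {
  np <- nrow(phyto); nz <- nrow(zoo); L <- n_levels
  active <- if ("active" %in% names(phyto)) phyto$active else rep(TRUE, np)
  bc <- function(v) matrix(v, L, length(v), byrow = TRUE)
  # palatability matrix: rows = grazers, cols = prey (phyto then smaller zoo)
  static_zoo <- isTRUE(params$zooplankton$static)
  Phi <- matrix(0, nz, np + nz)
  for (z in seq_len(nz)) {
    Phi[z, seq_len(np)] <- palatability(phyto$volume, zoo[z, ])
    if (nz > 1 && !static_zoo) {
      smaller <- which(zoo$volume < zoo$volume[z])
      if (length(smaller)) {
        Phi[z, np + smaller] <- palatability(zoo$volume[smaller], zoo[z, ])
      }
    }
  }
  # availability must only see actively cycling prey (mutants are passive)
  prey_active <- c(active, rep(TRUE, nz))
  Vmax_m <- bc(phyto$V_max)
  list(
    np = np, nz = nz, L = L, active = active, actp = which(active),
    prey_passive = which(!prey_active),
    ipc = 8L + (seq_len(np) - 1L) * 3L + 1L,
    ipn = 8L + (seq_len(np) - 1L) * 3L + 2L,
    ipchl = 8L + (seq_len(np) - 1L) * 3L + 3L,
    izc = 8L + 3L * np + (seq_len(nz) - 1L) * 3L + 1L,
    izn = 8L + 3L * np + (seq_len(nz) - 1L) * 3L + 2L,
    KN = phyto$K_N,
    KN_m = bc(phyto$K_N),
    Vmax_m = Vmax_m,
    Vmax_no3_m = Vmax_m * bc(as.numeric(phyto$can_use_nitrate)),
    Qmin_m = bc(phyto$Q_min), Qmax_m = bc(phyto$Q_max),
    dQ_m = bc(phyto$Q_max - phyto$Q_min),
    mumax_m = bc(phyto$mu_max),
    w_phyto = phyto$sinking,
    Imax_m = bc(zoo$I_max),
    lambda = if (nz) zoo$assimilation[1] else 0,
    QZ = if (nz) zoo$quota[1] else 0,
    kA = params$zooplankton$k_A,
    mZ = if (nz && !static_zoo) params$zooplankton$mortality else 0,
    static_zoo = static_zoo,
    Phi = Phi, tPhi = t(Phi)
  )
}

# fast elementwise clip helpers (avoid pmin/pmax attribute bookkeeping)
clip01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }
clip_lo <- function(x, lo) { x[x < lo] <- lo; x }

# Biological tendencies for all depth levels at once.
# tr: L x K tracer matrix; env: list(irradiance L, gammaT L); returns d(tr).
bio_tendencies <- function(tr, cc, env, p) {
  L <- cc$L; np <- cc$np; nz <- cc$nz
  ec <- p$ecology
  NO3 <- tr[, 1L]; NO2 <- tr[, 2L]; NH4 <- tr[, 3L]
  DOC <- tr[, 5L]; DON <- tr[, 6L]; POC <- tr[, 7L]; PON <- tr[, 8L]
  PC <- tr[, cc$ipc, drop = FALSE]
  PN <- tr[, cc$ipn, drop = FALSE]
  PChl <- tr[, cc$ipchl, drop = FALSE]
  ZC <- tr[, cc$izc, drop = FALSE]
  ZN <- tr[, cc$izn, drop = FALSE]

  Q <- PN / clip_lo(PC, 1e-300)
  qf_up <- clip01((cc$Qmax_m - Q) / cc$dQ_m)
  qf_gr <- clip01((Q - cc$Qmin_m) / cc$dQ_m)

  gI <- 1 - exp(-env$irradiance / p$light$I_sat)
  mu <- (env$gammaT * gI) * cc$mumax_m * qf_gr

  inh <- exp(-ec$psi_NH4 * NH4)
  u_no3 <- (NO3 * inh) / (NO3 + cc$KN_m) * cc$Vmax_no3_m * qf_up
  u_no2 <- (NO2 * inh) / (NO2 + cc$KN_m) * cc$Vmax_m * qf_up
  u_nh4 <- NH4 / (NH4 + cc$KN_m) * cc$Vmax_m * qf_up
  u_tot <- u_no3 + u_no2 + u_nh4

  # grazing: availability from actively cycling prey only
  B <- cbind(PC, ZC); BN <- cbind(PN, ZN)
  if (length(cc$prey_passive)) {
    B_act <- B; B_act[, cc$prey_passive] <- 0
    BN_act <- BN; BN_act[, cc$prey_passive] <- 0
  } else {
    B_act <- B; BN_act <- BN
  }
  A <- B_act %*% cc$tPhi                     # L x nz
  AN <- BN_act %*% cc$tPhi
  czoo <- cc$Imax_m * ZC * A / (A * A + cc$kA^2)
  G <- czoo * A                               # ingested C per grazer
  GN <- czoo * AN                             # ingested N per grazer
  loss <- czoo %*% cc$Phi                     # specific loss rate per prey

  lambda <- cc$lambda; QZ <- cc$QZ
  aC <- lambda * G; aN <- lambda * GN
  if (cc$static_zoo) {
    # prescribed grazer field: no zoo growth, everything ingested is
    # egested/remineralized so the nitrogen budget stays closed
    ZG <- 0 * aC
  } else {
    ZG <- aC                                  # zoo production (C), N-capped
    if (nz) { nlim <- aN / QZ; ii <- nlim < ZG; ZG[ii] <- nlim[ii] }
  }
  resp <- aC - ZG                             # excess C respired -> DIC
  excr <- aN - QZ * ZG                        # excess N excreted -> NH4

  m <- ec$mortality; mZ <- cc$mZ
  lossP <- loss[, seq_len(np), drop = FALSE]
  lossZ <- loss[, np + seq_len(nz), drop = FALSE]

  dPC <- (mu - m - lossP) * PC
  dPN <- u_tot * PC - (m + lossP) * PN
  lt <- p$light
  theta_t <- lt$theta_min +
    (lt$theta_max - lt$theta_min) * lt$theta_I_half /
    (lt$theta_I_half + env$irradiance)
  dPChl <- theta_t * (mu * PC) - (m + lossP) * PChl

  dZC <- ZG - (mZ + lossZ) * ZC
  dZN <- QZ * ZG - (mZ + lossZ) * ZN

  act <- cc$actp
  rs <- function(M) .rowSums(M, L, ncol(M))
  PCa <- PC[, act, drop = FALSE]; PNa <- PN[, act, drop = FALSE]
  mortC <- m * rs(PCa) + mZ * rs(ZC)
  mortN <- m * rs(PNa) + mZ * rs(ZN)
  egC <- (1 - lambda) * rs(G); egN <- (1 - lambda) * rs(GN)
  prodC <- mortC + egC; prodN <- mortN + egN

  f <- ec$f_DOM; rdom <- ec$remin_DOM; rpom <- ec$remin_POM
  dDOC <- f * prodC - rdom * DOC
  dPOC <- (1 - f) * prodC - rpom * POC
  dDON <- f * prodN - rdom * DON
  dPON <- (1 - f) * prodN - rpom * PON

  U_no3 <- rs((u_no3 * PC)[, act, drop = FALSE])
  U_no2 <- rs((u_no2 * PC)[, act, drop = FALSE])
  U_nh4 <- rs((u_nh4 * PC)[, act, drop = FALSE])
  n1 <- ec$nitrif_NH4; n2 <- ec$nitrif_NO2
  dNO3 <- n2 * NO2 - U_no3
  dNO2 <- n1 * NH4 - n2 * NO2 - U_no2
  dNH4 <- rdom * DON + rpom * PON + rs(excr) - n1 * NH4 - U_nh4
  dDIC <- rdom * DOC + rpom * POC + rs(resp) - rs((mu * PC)[, act, drop = FALSE])

  d <- matrix(0, L, ncol(tr))
  d[, 1L] <- dNO3; d[, 2L] <- dNO2; d[, 3L] <- dNH4; d[, 4L] <- dDIC
  d[, 5L] <- dDOC; d[, 6L] <- dDON; d[, 7L] <- dPOC; d[, 8L] <- dPON
  d[, cc$ipc] <- dPC; d[, cc$ipn] <- dPN; d[, cc$ipchl] <- dPChl
  d[, cc$izc] <- dZC; d[, cc$izn] <- dZN
  d
}

#' Local ecological tendencies
#'
#' Assembles the full per-depth-level biological time-derivatives: Droop
#' uptake and growth for every phytoplankton species, size-kernel Holling
#' type-3 grazing with intra-guild predation, constant background mortality
#' for both guilds, detritus production from mortality and unassimilated
#' grazing, remineralization of detritus to ammonium (and of detrital carbon
#' to DIC), and the nitrification chain NH4 -> NO2 -> NO3. The biological
#' terms conserve total nitrogen (dissolved + detrital + phytoplankton +
#' zooplankton) exactly; passive (mutant) species experience the environment
#' but contribute nothing to any shared pool.
#'
#' @param tracers numeric matrix (levels x tracers) or vector, with columns
#'   ordered as `NO3, NO2, NH4, DIC, DOC, DON, POC, PON`, then `C, N, Chl`
#'   blocks per phytoplankton species, then per zooplankton species.
#' @param phyto phytoplankton table from [build_species()] (optionally with a
#'   logical `active` column; inactive species are passive tracers).
#' @param zoo grazer table from [zoo_spectrum()].
#' @param env list with `irradiance` and `temperature`, scalars or per-level
#'   vectors.
#' @param params an `evo_params` list.
#' @return tendency matrix with the same shape and column names as `tracers`.
#' @export
local_tendencies <- function(tracers, phyto, zoo, env, params = plankton_params()) {
  if (is.null(dim(tracers))) tracers <- matrix(tracers, nrow = 1)
  if (any(tracers < 0)) stop("negative tracer state rejected")
  L <- nrow(tracers)
  cc <- foodweb_cache(phyto, zoo, params, L)
  expected <- 8L + 3L * (nrow(phyto) + nrow(zoo))
  if (ncol(tracers) != expected) {
    stop("tracer matrix has ", ncol(tracers), " columns; expected ", expected)
  }
  ev <- list(irradiance = rep_len(env$irradiance, L),
             gammaT = gamma_temperature(rep_len(env$temperature, L), params))
  d <- bio_tendencies(tracers, cc, ev, params)
  colnames(d) <- tracer_names(phyto, zoo)
  d
}

# Column-integrated totals used by the conservation audit.
# h: level thicknesses. Nitrogen pools: NO3+NO2+NH4+DON+PON + plankton N.
total_nitrogen <- function(tr, cc, h) {
  cols <- c(1L, 2L, 3L, 6L, 8L, cc$ipn[cc$actp], cc$izn)
  sum(colSums(tr[, cols, drop = FALSE] * h))
}

total_carbon <- function(tr, cc, h) {
  cols <- c(4L, 5L, 7L, cc$ipc[cc$actp], cc$izc)
  sum(colSums(tr[, cols, drop = FALSE] * h))
}
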