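# Shared fixtures: small configurations used across the suite.

# reduced column fully ventilated by winter mixing (fast annual attractor)
desk_params <- function(...) {
  protocol_config("desk", ...)$params
}

# a deterministic tiny community (one species per functional type)
tiny_community <- function(params = desk_params()) {
  phyto <- build_species(
    c("Prochlorococcus", "Synechococcus", "small-eukaryote", "diatom"),
    c(0.3, 5, 300, 5000), params)
  phyto$active <- TRUE
  list(phyto = phyto, zoo = zoo_spectrum(params))
}

# a random admissible Droop trait set for oracle checks (viable by
# construction: checks the N* denominator before accepting)
random_traits <- function() {
  repeat {
    tr <- list(
      V_max = stats::runif(1, 0.05, 1),
      K_N = stats::runif(1, 0.05, 2),
      Q_min = stats::runif(1, 0.02, 0.08),
      mu_max = stats::runif(1, 0.3, 2)
    )
    tr$Q_max <- tr$Q_min + stats::runif(1, 0.03, 0.15)
    m <- stats::runif(1, 0.01, 0.8 * tr$mu_max)
    Qs <- (tr$Q_max - tr$Q_min) * m / tr$mu_max + tr$Q_min
    den <- tr$V_max * (tr$Q_max - Qs) - tr$mu_max * (Qs - tr$Q_min) * Qs
    if (den > 1e-4) return(c(tr, list(m = m)))
  }
}

# Independent steady-state oracle for N*: integrate the grazer-free 0-D
# Droop system (nutrient N, biomass P, quota Q) with a constant nutrient
# supply until the nutrient concentration equilibrates. Deliberately not
# using any package code on the dynamics side.
nstar_ode_oracle <- function(tr, m, supply = 0.05) {
  rhs <- function(t, y, parms) {
    N <- y[1]; P <- y[2]; Q <- y[3]
    up <- tr$V_max * (tr$Q_max - Q) / (tr$Q_max - tr$Q_min) * N / (N + tr$K_N)
    gr <- tr$mu_max * (Q - tr$Q_min) / (tr$Q_max - tr$Q_min)
    list(c(supply - up * P,
           (gr - m) * P,
           up - gr * Q))
  }
  y <- c(N = tr$K_N, P = 0.1, Q = (tr$Q_min + tr$Q_max) / 2)
  # integrate in chunks until the nutrient has genuinely equilibrated
  # (both the increment over a chunk and the instantaneous dN/dt are tiny)
  for (i in 1:300) {
    out <- deSolve::lsoda(y, c(0, 5000), rhs, parms = NULL,
                          rtol = 1e-12, atol = 1e-14, maxsteps = 200000)
    ynew <- out[nrow(out), c("N", "P", "Q")]
    dN <- abs(ynew[["N"]] - y[["N"]])
    rate <- abs(rhs(0, ynew, NULL)[[1]][1])
    y <- ynew
    if (i > 2 && dN < 1e-9 * y[["N"]] && rate < 1e-12 * max(y[["N"]], 1e-9)) {
      break
    }
  }
  y[["N"]]
}
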