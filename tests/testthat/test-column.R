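p0 <- plankton_params()

test_that("the grid tiles the column depth with stretched levels", {
  g <- column_grid(35, 3275, 1.1)
  expect_equal(sum(g$h), 3275)
  expect_equal(length(g$h), 35)
  expect_true(all(g$h > 0))
  expect_false(is.unsorted(g$h, strictly = TRUE))  # finest at the surface
  expect_equal(g$z_int[36], 3275)
  gu <- column_grid(5, 100, 1)
  expect_equal(gu$h, rep(20, 5))
})

test_that("forcing is strictly annual-periodic with winter mixing and winter darkness", {
  f <- make_forcing(p0)
  for (t in c(10.3, 180, 300)) {
    expect_identical(forcing_at(f, t), forcing_at(f, t + 365))
    expect_identical(forcing_at(f, t), forcing_at(f, t + 10 * 365))
  }
  # light minimum in winter (day 1), maximum mid-year
  expect_equal(which.min(f$I0), 1)
  expect_gt(max(f$I0), 50 * min(f$I0))
  # deep winter (Dec-Mar) mixing vs stratified summer in the upper 200 m
  g <- f$grid
  upper <- which(g$z_int[2:g$n] <= 200)
  winter_days <- c(335:365, 1:90)
  summer_days <- 152:243
  expect_true(all(rowMeans(f$kappa[upper, winter_days, drop = FALSE]) >
                  rowMeans(f$kappa[upper, summer_days, drop = FALSE])))
  expect_true(all(f$kappa >= 0))
  # zero-amplitude seasonality collapses to constant forcing
  pz <- plankton_params(forcing = list(I0_amp = 0, T_surf_amp = 0,
                                       mld_min = 50, mld_max = 50))
  fz <- make_forcing(pz)
  expect_equal(diff(range(fz$I0)), 0)
  expect_equal(max(abs(apply(fz$kappa, 1, function(x) diff(range(x))))), 0)
})

test_that("forcing tables round-trip through CSV", {
  p <- desk_params()
  f <- make_forcing(p)
  file <- withr::local_tempfile(fileext = ".csv")
  write_forcing_csv(f, file)
  back <- read_forcing_csv(file)
  expect_equal(back$I0, f$I0)
  expect_equal(back$temperature, unname(f$temperature))
  expect_equal(unname(back$kappa), unname(f$kappa))
  expect_equal(back$mld, f$mld)
})

test_that("light attenuates exponentially and self-shading only dims deeper levels", {
  g <- column_grid(20, 200, 1)
  expect_equal(light_profile(0, g), rep(0, 20))
  I <- light_profile(100, g, chl = 0, p0)
  expect_equal(I, 100 * exp(-p0$light$k_water * g$z_mid))
  expect_false(is.unsorted(rev(I), strictly = TRUE))
  # biomass at level 5 reduces light strictly below it, not above
  chl <- rep(0, 20); chl[5] <- 10
  I2 <- light_profile(100, g, chl, p0)
  expect_equal(I2[1:4], I[1:4])
  expect_true(all(I2[6:20] < I[6:20]))
})

test_that("implicit diffusion conserves mass, keeps bounds, and matches the two-box solution", {
  g <- column_grid(8, 400, 1.2)
  set.seed(11)
  x <- matrix(stats::runif(8 * 3), 8, 3)
  kap <- stats::runif(7, 5, 50)
  y <- diffuse(x, kap, 0.5, g)
  expect_equal(colSums(y * g$h), colSums(x * g$h), tolerance = 1e-12)
  expect_true(all(y <= max(x) + 1e-12 & y >= min(x) - 1e-12))
  # uniform profiles are a fixed point
  u <- rep(3.3, 8)
  expect_equal(diffuse(u, kap, 1, g), u)
  # two-box analytic equilibration: dC1/dt = r (C2 - C1) etc.
  g2 <- column_grid(2, 20, 1)
  kap2 <- 7; dt <- 0.2
  x2 <- c(1, 0)
  num <- diffuse(x2, kap2, dt, g2)
  r <- kap2 / 10 / 10                 # kappa / dz / h
  # backward Euler on the 2x2 exchange system, solved in closed form
  mean_c <- 0.5
  dev <- (x2 - mean_c) / (1 + 2 * r * dt)
  expect_equal(num, mean_c + dev, tolerance = 1e-12)
})

test_that("sinking is conservative, CFL-safe and inert at zero velocity", {
  g <- column_grid(10, 100, 1)
  set.seed(12)
  x <- matrix(stats::runif(10 * 2), 10, 2)
  expect_equal(sink_tracers(x, 0, 1, g), x)
  y <- sink_tracers(x, 5, 0.5, g)
  expect_equal(colSums(y * g$h), colSums(x * g$h), tolerance = 1e-12)
  expect_true(all(y >= 0))
  # automatic sub-stepping at large CFL still conserves and stays positive
  y2 <- sink_tracers(x, 80, 1, g)
  expect_equal(colSums(y2 * g$h), colSums(x * g$h), tolerance = 1e-12)
  expect_true(all(y2 >= 0))
  # an impulse moves downward by roughly w * t on a fine grid
  gf <- column_grid(200, 100, 1)
  imp <- numeric(200); imp[20] <- 1    # z = 9.75 m
  out <- imp
  for (i in 1:20) out <- sink_tracers(out, 2, 0.5, gf)  # 10 days at 2 m/d
  com <- sum(gf$z_mid * out) / sum(out)
  expect_equal(com, gf$z_mid[20] + 20, tolerance = 0.15 * 20)
})

test_that("an abiotic column homogenizes its nutrients over winter", {
  p <- desk_params()
  phyto <- build_species("Synechococcus", 5, p)
  phyto$active <- TRUE
  st <- init_state(phyto, zoo_spectrum(p), p)
  st$tracers[, "NO3"] <- seq(2, 20, length.out = st$grid$n)  # stratified start
  st$tracers[, paste0(phyto$id, "_C")] <- 0                  # lifeless
  st$tracers[, paste0(phyto$id, "_N")] <- 0
  st$tracers[, paste0(phyto$id, "_Chl")] <- 0
  for (j in seq_len(nrow(st$zoo))) {
    st$tracers[, paste0(st$zoo$id[j], "_C")] <- 0
    st$tracers[, paste0(st$zoo$id[j], "_N")] <- 0
  }
  st$params$ecology$quasi_extinction_floor <- 0   # keep it lifeless
  before <- stats::sd(st$tracers[, "NO3"])
  st <- run_column(st, 60)                        # winter mixing season
  after <- stats::sd(st$tracers[, "NO3"])
  expect_lt(after, before / 50)
})

test_that("a closed column conserves nitrogen and carbon through a full seasonal cycle", {
  p <- desk_params()
  com <- tiny_community(p)
  st <- init_state(com$phyto, com$zoo, p)
  b0 <- nitrogen_budget(st)
  st <- run_column(st, 365)
  b1 <- nitrogen_budget(st)
  expect_lt(abs(b1$audited_N - b0$audited_N) / b0$audited_N, 1e-10)
  expect_lt(abs(b1$audited_C - b0$audited_C) / b0$audited_C, 1e-10)
  # state stayed admissible
  expect_true(all(st$tracers >= 0))
  # and the ecosystem actually did something (a bloom happened)
  expect_gt(max(column_biomass(st)$biomass), 1e-3)
})

test_that("halving the biological time step barely changes a year on the attractor", {
  p <- desk_params()
  p$zooplankton$static <- TRUE
  com <- tiny_community(p)
  st <- init_state(com$phyto, com$zoo, p)
  st <- run_column(st, 3 * 365)                 # settle on the annual cycle
  st1 <- run_column(st, 365)
  st2 <- st
  st2$params$numerics$dt_bio <- 0.025
  st2$cache <- NULL
  st2 <- run_column(st2, 365)
  b1 <- sum(column_biomass(st1)$biomass)
  b2 <- sum(column_biomass(st2)$biomass)
  expect_lt(abs(b1 - b2) / b2, 0.01)
})
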