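p0 <- plankton_params()

test_that("mutant pairs step 10% in volume and clamp at type boundaries", {
  sp <- build_species("small-eukaryote", 1000, p0)
  mu <- spawn_mutants(sp, 0.10, p0)
  expect_equal(sort(mu$volume), c(900, 1100))
  expect_equal(mu$side[order(mu$volume)], c("-", "+"))
  expect_equal(unique(mu$parent), sp$id)
  # traits are rebuilt allometrically, not copied
  expect_equal(mu$K_N, allometric_param(p0$allometry$K_N, mu$volume))
  # at the lower bound only the larger mutant exists
  lo <- build_species("small-eukaryote", 10, p0)
  mlo <- spawn_mutants(lo, 0.10, p0)
  expect_equal(mlo$side, "+")
  hi <- build_species("small-eukaryote", 1e4, p0)
  mhi <- spawn_mutants(hi, 0.10, p0)
  expect_equal(mhi$side, "-")
  # zero step duplicates the resident
  m0 <- spawn_mutants(sp, 0, p0)
  expect_equal(m0$volume, c(1000, 1000))
})

test_that("invasion fitness is the log annual biomass ratio", {
  expect_equal(invasion_fitness(2, 2), 0)
  expect_equal(invasion_fitness(1, exp(1)), 1)
  expect_equal(invasion_fitness(4, 2), -log(2))
  expect_identical(invasion_fitness(1, 0), -Inf)
  expect_error(invasion_fitness(0, 1))
})

test_that("selection outcomes compare against the resident's realized rate", {
  expect_equal(selection_outcome(-0.1, 0.1, 0), "directional-up")
  expect_equal(selection_outcome(0.1, -0.1, 0), "directional-down")
  expect_equal(selection_outcome(-0.1, -0.2, 0), "stabilizing")
  expect_equal(selection_outcome(0.1, 0.2, 0), "disruptive")
  # comparisons are against s_res, not zero
  expect_equal(selection_outcome(0.01, 0.03, 0.02), "directional-up")
  # exact ties do not replace
  expect_equal(selection_outcome(0.02, 0.02, 0.02), "stabilizing")
  # clamped mutants: compare the remaining one; none at all is stabilizing
  expect_equal(selection_outcome(NA, 0.1, 0), "directional-up")
  expect_equal(selection_outcome(NA, -0.1, 0), "stabilizing")
  expect_equal(selection_outcome(NA, NA, 0), "stabilizing")
})

test_that("replacement swaps traits in place but leaves the profiles alone", {
  p <- desk_params()
  com <- tiny_community(p)
  st <- init_state(com$phyto, com$zoo, p)
  st <- run_column(st, 30)
  tr_before <- st$tracers
  vol_new <- st$phyto$volume[3] * 1.1
  st2 <- replace_resident(st, "P3", vol_new)
  expect_identical(st2$tracers, tr_before)
  expect_equal(st2$phyto$volume[3], vol_new)
  expect_equal(st2$phyto$K_N[3], allometric_param(p$allometry$K_N, vol_new))
  expect_error(replace_resident(st, "nope", 1), "unknown resident")
})

test_that("mutants are passive tracers: the resident system is bit-identical with or without them", {
  p <- desk_params()
  com <- tiny_community(p)
  st <- init_state(com$phyto, com$zoo, p)
  st <- run_column(st, 400)          # through a bloom, biomass established
  mutants <- dplyr::bind_rows(lapply(1:4, function(j)
    spawn_mutants(st$phyto[j, ], 0.1, p)))
  with_m <- add_mutants(st, mutants)
  with_m <- run_column(with_m, 45)
  without <- run_column(st, 45)
  stripped <- remove_mutants(with_m)
  expect_identical(stripped$tracers, without$tracers)
  # and the mutants did integrate (their fields moved)
  mcol <- paste0(mutants$id[1], "_C")
  expect_false(identical(with_m$tracers[, mcol],
                         st$tracers[, paste0(mutants$parent[1], "_C")] *
                           p$evolution$mutant_amplitude))
})

test_that("a zero-step mutant has exactly the resident's fitness", {
  p <- desk_params()
  p$zooplankton$static <- TRUE
  com <- tiny_community(p)
  st <- init_state(com$phyto, com$zoo, p)
  st <- run_column(st, 3 * 365)
  clones <- spawn_mutants(st$phyto[2, ], 0, p)   # both clones of the resident
  tr <- evoplankton:::run_trial_year(st, clones)
  s_res <- tr$fitness$s[tr$fitness$id == "P2"]
  s_clone <- tr$fitness$s[grepl("^P2m", tr$fitness$id)]
  expect_lt(max(abs(s_clone - s_res)), 1e-9)
  expect_lt(abs(s_res), 1e-6)
})

test_that("the evolution engine logs coherent events and respects the schedule", {
  p <- desk_params()
  p$zooplankton$static <- TRUE
  sp <- build_species("Synechococcus", 10, p)
  sp$active <- TRUE
  st <- init_state(sp, zoo_spectrum(p), p)
  st <- run_column(st, 4 * 365)
  t0 <- st$time
  ev <- run_evolution(st, years = 6)   # exactly two 3-year cycles
  expect_equal(nrow(ev$events), 2)
  expect_equal(ev$state$time - t0, 6 * 365)
  expect_true(all(ev$events$outcome %in%
                  c("directional-up", "directional-down", "stabilizing",
                    "disruptive")))
  dir <- ev$events$outcome != "stabilizing"
  expect_true(all(ev$events$new_volume[!dir] == ev$events$old_volume[!dir]))
  expect_true(all(ev$events$new_volume[dir] != ev$events$old_volume[dir]))
  # the state's resident carries the last event's trait
  expect_equal(ev$state$phyto$volume, ev$events$new_volume[2])
})

test_that("halving the mutation step does not change which singularity is reached", {
  p <- desk_params()
  p$zooplankton$static <- TRUE
  sp <- build_species("Synechococcus", 20, p)   # uphill of the ~34 um^3 refuge
  sp$active <- TRUE
  st <- init_state(sp, zoo_spectrum(p), p)
  st <- run_column(st, 4 * 365)
  pA <- p; pA$evolution$mutation_step <- 0.10
  evA <- run_evolution(st, years = 24, params = pA)      # 8 cycles
  pB <- p; pB$evolution$mutation_step <- 0.05
  evB <- run_evolution(st, years = 45, params = pB)      # 15 cycles
  vA <- evA$state$phyto$volume
  vB <- evB$state$phyto$volume
  # same singular volume up to one coarse mutation step
  expect_lt(abs(log(vA / vB)), log(1.1))
})
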