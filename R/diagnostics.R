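#' Discrete cell-size classes
#'
#' The diagnostics currency: biomass binned into `n` log10-uniform cell
#' volume classes spanning the union of all functional-type ranges. Bins are
#' fixed by the parameter file so that distributions from different runs are
#' directly comparable.
#'
#' @param params an `evo_params` list.
#' @return list with `n`, `breaks` (length `n + 1`, log10-uniform), `mid`
#'   (geometric midpoints).
#' @export
size_bins <- function(params = plankton_params()) {
  d <- params$diagnostics
  br <- 10^seq(log10(d$size_range[[1]]), log10(d$size_range[[2]]),
               length.out = d$n_size_classes + 1)
  list(n = d$n_size_classes, breaks = br,
       mid = sqrt(br[-1] * br[-length(br)]))
}

#' Biomass distribution over the discrete size classes
#'
#' Bins the column-integrated biomass of the active phytoplankton species by
#' cell volume; several species falling in one class are summed. Shares are
#' normalized to sum to 1 when any biomass is present (`normalize = FALSE`
#' keeps raw biomass per class, for distance measures on absolute spectra).
#'
#' @param state an `evo_state`, or a data frame with columns `volume` and
#'   `biomass`.
#' @param params an `evo_params` list (bins; defaults to the state's own).
#' @param normalize return shares (default) or raw biomass.
#' @return object of class `evo_sizedist`: tibble with `class`, `volume`
#'   (bin midpoint), `p` plus attribute `breaks`.
#' @export
size_distribution <- function(state, params = NULL, normalize = TRUE) {
  if (inherits(state, "evo_state")) {
    params <- params %||% state$params
    bc <- column_biomass(state)
    bc <- bc[bc$guild == "phyto" & bc$active, ]
  } else {
    params <- params %||% plankton_params()
    bc <- state
  }
  b <- size_bins(params)
  cls <- cut(bc$volume, breaks = b$breaks, include.lowest = TRUE,
             labels = FALSE)
  if (anyNA(cls)) stop("cell volume outside the configured size range")
  p <- numeric(b$n)
  agg <- tapply(bc$biomass, cls, sum)
  p[as.integer(names(agg))] <- agg
  tot <- sum(p)
  if (normalize && tot > 0) p <- p / tot
  structure(tibble::tibble(class = seq_len(b$n), volume = b$mid, p = p),
            breaks = b$breaks, class = c("evo_sizedist", class(tibble::tibble())))
}

#' Species richness above an extinction threshold
#'
#' Number of (active) phytoplankton species whose column-integrated biomass
#' exceeds the quasi-extinction threshold; species held only by the
#' immigration floor do not count.
#'
#' @param state an `evo_state`.
#' @param threshold mmol C m^-2 (default from the parameter file, 1e-3).
#' @return integer count.
#' @export
species_richness <- function(state, threshold = NULL) {
  if (is.null(threshold)) threshold <- state$params$diagnostics$extinction_threshold
  bc <- column_biomass(state)
  bc <- bc[bc$guild == "phyto" & bc$active, ]
  sum(bc$biomass > threshold)
}

#' Shannon evenness of a size distribution
#'
#' Pielou evenness of the biomass shares over the `N` size classes:
#' `S = -sum(p_i log p_i) / log N`, with `0 log 0 = 0`, so `S` lies in
#' `[0, 1]` -- 0 when all biomass sits in a single class, 1 when it is
#' spread uniformly over all classes. (The minus sign makes the raw Shannon
#' sum positive; "high" means evenly distributed.)
#'
#' @param dist an `evo_sizedist` (or any data frame with a `p` column of
#'   shares summing to 1).
#' @return evenness in `[0, 1]`; `NA` if the distribution is empty.
#' @export
shannon_evenness <- function(dist) {
  p <- dist$p
  tot <- sum(p)
  if (tot <= 0) return(NA_real_)
  if (abs(tot - 1) > 1e-8) p <- p / tot
  nz <- p > 0
  -sum(p[nz] * log(p[nz])) / log(length(p))
}

#' Canberra distance between two size distributions
#'
#' `CD(x, y) = sum_i |x_i - y_i| / (|x_i| + |y_i|)`, with empty-in-both
#' classes contributing 0. Each occupied class contributes at most 1, so two
#' distributions with disjoint support are at distance equal to their number
#' of occupied classes. Symmetric, zero iff the binned representations are
#' identical.
#'
#' @param x,y `evo_sizedist` objects (or data frames with `p`), on the same
#'   binning.
#' @return distance `>= 0`.
#' @export
canberra <- function(x, y) {
  px <- x$p; py <- y$p
  if (length(px) != length(py)) stop("size distributions use different binnings")
  bx <- attr(x, "breaks"); by <- attr(y, "breaks")
  if (!is.null(bx) && !is.null(by) && !isTRUE(all.equal(bx, by))) {
    stop("size distributions use different binnings")
  }
  den <- abs(px) + abs(py)
  num <- abs(px - py)
  sum(ifelse(den > 0, num / den, 0))
}

#' Mean square distance of a group of size distributions
#'
#' Intra-group variability of community size structure:
#' `MSD = sum_k CD(x_k, x_mean)^2 / K`, the mean squared Canberra distance
#' of each member to the group's mean distribution. Zero iff all members
#' share the same binned distribution.
#'
#' @param dists list of `evo_sizedist` objects on a shared binning.
#' @return `MSD >= 0`.
#' @export
mean_square_distance <- function(dists) {
  K <- length(dists)
  stopifnot(K >= 1)
  P <- vapply(dists, function(d) d$p, numeric(nrow(dists[[1]])))
  mean_dist <- dists[[1]]
  mean_dist$p <- rowMeans(P)
  sum(vapply(dists, function(d) canberra(d, mean_dist)^2, numeric(1))) / K
}

#' Realized grazing background over a prey-size axis
#'
#' The summed grazing pressure a phytoplankton cell of a given volume would
#' experience: biomass-weighted palatability over all grazers (optionally
#' weighted by their maximum ingestion rates). With a discrete grazer
#' spectrum of equal abundance the curve is log-periodic: peaks at each
#' grazer's optimal prey volume, with grazing refuges (local minima) in
#' between.
#'
#' @param state an `evo_state`, or a zoo table with a `biomass` column
#'   (mmol C m^-2 or any common unit).
#' @param volumes prey volume axis, um^3 (default: 400 log-spaced points
#'   over the diagnostic size range).
#' @param weight_imax multiply each grazer's kernel by its `I_max`.
#' @return tibble with `volume` and `pressure`.
#' @export
grazing_background <- function(state, volumes = NULL, weight_imax = TRUE) {
  if (inherits(state, "evo_state")) {
    zoo <- state$zoo
    bc <- column_biomass(state)
    zoo$biomass <- bc$biomass[match(zoo$id, bc$id)]
    params <- state$params
  } else {
    zoo <- state
    params <- plankton_params()
  }
  if (is.null(volumes)) {
    rg <- params$diagnostics$size_range
    volumes <- 10^seq(log10(rg[[1]]), log10(rg[[2]]), length.out = 400)
  }
  pressure <- numeric(length(volumes))
  for (z in seq_len(nrow(zoo))) {
    wz <- zoo$biomass[z] * if (weight_imax) zoo$I_max[z] else 1
    pressure <- pressure + wz * palatability(volumes, zoo[z, ])
  }
  tibble::tibble(volume = volumes, pressure = pressure)
}

#' Invasion-fitness landscape
#'
#' For each functional type with at least one resident, a large number of
#' probe mutants spanning the type's whole volume range is introduced as
#' passive tracers (profiles cloned from the type's most abundant resident)
#' and co-integrated over one shared evaluation year; their invasion fitness
#' traces the landscape. Residents themselves sit at fitness approximately
#' zero on the attractor; at an eco-evolutionary endpoint each resident sits
#' at a local fitness maximum.
#'
#' @param state an `evo_state` on its attractor.
#' @param n_probes probes per functional type (default 200).
#' @return object of class `evo_landscape`: list with `landscape` (tibble:
#'   `type`, `volume`, `fitness`) and `residents` (tibble: `id`, `type`,
#'   `volume`, `fitness`).
#' @export
fitness_landscape <- function(state, n_probes = 200) {
  ft <- functional_types(state$params)
  bc <- column_biomass(state)
  ph <- bc[bc$guild == "phyto" & bc$active, ]
  types <- unique(state$phyto$type[state$phyto$active %||% TRUE])
  probes <- list()
  for (ty in types) {
    rows <- ph[ph$type == ty, ]
    host <- rows$id[which.max(rows$biomass)]
    rg <- ft[ft$type == ty, ]
    vols <- 10^seq(log10(rg$V_lo), log10(rg$V_hi), length.out = n_probes)
    pr <- build_species(rep(ty, n_probes), vols, state$params,
                        id = sprintf("probe_%s_%03d", ty, seq_len(n_probes)))
    pr$parent <- host
    pr$side <- "probe"
    probes[[ty]] <- pr
  }
  probes <- dplyr::bind_rows(probes)
  trial <- run_trial_year(state, probes)
  fit <- trial$fitness
  meta <- trial$state$phyto
  land <- tibble::tibble(
    type = meta$type[match(fit$id, meta$id)],
    volume = meta$volume[match(fit$id, meta$id)],
    fitness = fit$s,
    id = fit$id
  )
  res <- land[land$id %in% state$phyto$id[state$phyto$active %||% TRUE], ]
  structure(list(landscape = land[grepl("^probe_", land$id), c("type", "volume", "fitness")],
                 residents = res[, c("id", "type", "volume", "fitness")]),
            class = "evo_landscape")
}

#' Find grazing refuges (local minima of the grazing background)
#'
#' @param background tibble from [grazing_background()].
#' @return tibble with the local minima: `volume`, `pressure`.
#' @export
grazing_refuges <- function(background) {
  pr <- background$pressure
  n <- length(pr)
  is_min <- c(FALSE, pr[2:(n - 1)] < pr[1:(n - 2)] & pr[2:(n - 1)] <= pr[3:n],
              FALSE)
  background[is_min, ]
}

## ---- plotting ---------------------------------------------------------------

#' Plot a size distribution
#' @param object an `evo_sizedist`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.evo_sizedist <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$volume, y = .data$p)) +
    ggplot2::geom_col(width = 0.08, fill = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(cell ~ volume ~ (mu * m^3)),
                  y = "biomass share") +
    ggplot2::theme_minimal()
}

#' Plot a fitness landscape with resident markers
#' @param object an `evo_landscape`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.evo_landscape <- function(object, ...) {
  ggplot2::ggplot(object$landscape,
                  ggplot2::aes(x = .data$volume, y = .data$fitness,
                               colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_point(data = object$residents, colour = "red", size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(cell ~ volume ~ (mu * m^3)),
                  y = "invasion fitness (1/yr)") +
    ggplot2::theme_minimal()
}

#' Plot the seasonal forcing (surface light, mixed layer, temperature)
#' @param object an `evo_forcing`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.evo_forcing <- function(object, ...) {
  tab <- tibble::tibble(day = seq_len(365),
                        `surface irradiance (W/m2)` = object$I0,
                        `mixed layer depth (m)` = object$mld,
                        `surface temperature (degC)` = object$temperature[1, ])
  long <- tidyr::pivot_longer(tab, -"day")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "day of year", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot trait trajectories from an evolution event log
#'
#' @param events the `events` tibble of [run_evolution()].
#' @return a ggplot of cell volume against time, one line per species.
#' @export
plot_trait_trajectories <- function(events) {
  ggplot2::ggplot(events,
                  ggplot2::aes(x = .data$year, y = .data$new_volume,
                               colour = .data$type, group = .data$id)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "year", y = expression(cell ~ volume ~ (mu * m^3))) +
    ggplot2::theme_minimal()
}
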