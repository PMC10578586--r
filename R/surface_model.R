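#' Genotype parameters for the radial colony model
#'
#' Bundles the per-genotype constants of the surface growth model: vegetative
#' biomass spreads by diffusion (a phenomenological description of sliding
#' expansion), grows on nutrient with Monod kinetics, and sporulates when
#' nutrient falls below a Hill-type induction threshold.
#'
#' @param id genotype label.
#' @param D_b biomass diffusion coefficient (mm^2/h).
#' @param mu_max maximal specific growth rate (1/h).
#' @param sigma_max maximal per-capita sporulation rate (1/h); the
#'   continuous-time analog of a per-division sporulation probability.
#' @param K_g Monod half-saturation constant for growth (nutrient units).
#' @param K_s nutrient level of half-maximal sporulation induction.
#' @param m Hill steepness of sporulation induction (>= 1).
#' @param Y biomass yield per unit nutrient.
#' @return object of class `genotype_params`.
#' @export
genotype_params <- function(id = "wt", D_b = 0.01, mu_max = 0.25,
                            sigma_max = 0.02, K_g = 0.5, K_s = 0.3,
                            m = 4, Y = 1) {
  vals <- c(D_b = D_b, mu_max = mu_max, sigma_max = sigma_max,
            K_g = K_g, K_s = K_s, m = m, Y = Y)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all genotype parameters must be finite and >= 0")
  if (m < 1) stop("Hill coefficient m must be >= 1")
  if (Y <= 0) stop("yield Y must be > 0")
  structure(list(id = as.character(id), D_b = D_b, mu_max = mu_max,
                 sigma_max = sigma_max, K_g = K_g, K_s = K_s, m = m, Y = Y),
            class = "genotype_params")
}

#' Radial simulation domain
#'
#' @param R_max domain radius (mm).
#' @param n_r number of radial grid nodes (>= 50).
#' @param D_N nutrient diffusion coefficient (mm^2/h).
#' @param N0 initial (uniform) nutrient concentration.
#' @return object of class `radial_domain` with grid spacing `dr` attached.
#' @export
radial_domain <- function(R_max = 20, n_r = 201, D_N = 0.02, N0 = 1) {
  if (n_r < 50) stop("n_r must be >= 50")
  if (R_max <= 0 || N0 <= 0 || D_N < 0) stop("invalid domain parameters")
  structure(list(R_max = R_max, n_r = as.integer(n_r), D_N = D_N, N0 = N0,
                 dr = R_max / (n_r - 1),
                 r = seq(0, R_max, length.out = n_r)),
            class = "radial_domain")
}

#' Edge-transfer passaging protocol
#'
#' Describes the weekly selection regime: colonies grow for `cycle_hours`,
#' then biomass sampled from the outermost annulus of width `edge_width` is
#' used to seed a fresh plate.
#'
#' @param cycle_hours growth duration per cycle (h).
#' @param edge_width width of the edge sampling annulus (mm).
#' @param inoculum_mass total biomass transferred to the fresh plate.
#' @param inoculum_radius radius of the seeding disk on the fresh plate (mm).
#' @param n_cycles number of growth/transfer cycles.
#' @param biomass_threshold density theta defining the colony boundary.
#' @return object of class `passage_protocol`.
#' @export
passage_protocol <- function(cycle_hours = 168, edge_width = 1,
                             inoculum_mass = 0.05, inoculum_radius = 2,
                             n_cycles = 5, biomass_threshold = 0.01) {
  if (edge_width <= 0) stop("edge_width must be > 0")
  if (inoculum_mass <= 0) stop("inoculum_mass must be > 0")
  if (biomass_threshold <= 0) stop("biomass_threshold must be > 0")
  structure(list(cycle_hours = cycle_hours, edge_width = edge_width,
                 inoculum_mass = inoculum_mass,
                 inoculum_radius = inoculum_radius,
                 n_cycles = as.integer(n_cycles),
                 biomass_threshold = biomass_threshold),
            class = "passage_protocol")
}

# finite-volume cell weights: mass(f) = 2*pi*dr * sum(w * f); exactly
# conserved by the flux-form Laplacian below under zero-flux boundaries
radial_weights <- function(domain) {
  r <- domain$r; dr <- domain$dr; n <- domain$n_r
  w <- r
  w[1] <- dr / 8
  w[n] <- r[n] / 2 - dr / 8
  w
}

#' Integrate a radial field over the disk
#'
#' Computes the surface integral of `f(r)` with area element 2*pi*r*dr using
#' the finite-volume quadrature matched to the simulator's discretization,
#' so diffusion conserves this integral to round-off.
#'
#' @param f field values on the domain grid.
#' @param domain a [radial_domain()].
#' @return scalar integral.
#' @export
radial_integral <- function(f, domain) {
  2 * pi * domain$dr * sum(radial_weights(domain) * f)
}

#' Initialize a radial colony state
#'
#' @param domain a [radial_domain()].
#' @param inocula named list per genotype: `list(mass =, radius =)`. Vegetative
#'   biomass is spread uniformly over the seeding disk so that its disk
#'   integral equals the requested mass; spores start at zero and nutrient at
#'   `N0` everywhere.
#' @return object of class `radial_state` with fields `r`, `V` (n_r x
#'   genotypes), `S`, `N`, `t`.
#' @export
make_state <- function(domain, inocula) {
  ids <- names(inocula)
  if (is.null(ids) || any(!nzchar(ids))) stop("inocula must be a named list")
  n <- domain$n_r
  V <- matrix(0, n, length(ids), dimnames = list(NULL, ids))
  w <- radial_weights(domain)
  for (g in ids) {
    mass <- inocula[[g]]$mass; rad <- inocula[[g]]$radius
    if (!is.finite(mass) || mass <= 0) stop("non-positive inoculum mass for ", g)
    if (!is.finite(rad) || rad <= 0) stop("non-positive inoculum radius for ", g)
    if (rad > domain$R_max) stop("inoculum radius exceeds domain for ", g)
    inside <- domain$r <= rad
    area <- 2 * pi * domain$dr * sum(w[inside])
    V[inside, g] <- mass / area
  }
  structure(list(r = domain$r, V = V, S = V * 0, N = rep(domain$N0, n), t = 0),
            class = "radial_state")
}

# flux-form radial Laplacian (1/r) d/dr (r df/dr); zero-flux at both ends,
# symmetric limit 2 f'' at r = 0
radial_laplacian <- function(f, domain) {
  r <- domain$r; dr <- domain$dr; n <- domain$n_r
  rp <- (r[-n] + r[-1]) / 2            # half-node radii, length n-1
  dif <- f[-1] - f[-n]                 # forward differences
  L <- numeric(n)
  L[1] <- 4 * dif[1] / dr^2
  L[2:(n - 1)] <- (rp[2:(n - 1)] * dif[2:(n - 1)] -
                   rp[1:(n - 2)] * dif[1:(n - 2)]) / (r[2:(n - 1)] * dr^2)
  L[n] <- -rp[n - 1] * dif[n - 1] / ((r[n] / 2 - dr / 8) * dr^2)
  L
}

#' Explicit stability bound for the time step
#'
#' @param domain a [radial_domain()].
#' @param params list of [genotype_params()].
#' @return maximal admissible dt (h) for the explicit scheme.
#' @export
stable_dt <- function(domain, params) {
  Dmax <- max(c(domain$D_N, vapply(params, function(p) p$D_b, 0)))
  if (Dmax <= 0) return(Inf)
  0.4 * domain$dr^2 / Dmax
}

clip_small_negatives <- function(x, field, t) {
  neg <- x < 0
  if (any(neg)) {
    if (any(x[neg] < -1e-12))
      stop(sprintf("field %s went negative (min %.3e) at t = %.3f h",
                   field, min(x), t))
    x[neg] <- 0
  }
  if (any(!is.finite(x)))
    stop(sprintf("non-finite values in field %s at t = %.3f h", field, t))
  x
}

#' Advance the colony state by one explicit Euler step
#'
#' Vegetative biomass of each genotype diffuses, grows at Monod rate
#' `mu_max * N/(K_g + N)` and converts to spores at rate
#' `sigma_max * K_s^m/(K_s^m + N^m)` (sporulation induced by nutrient
#' depletion). Spores are inert. Nutrient diffuses and is consumed in
#' proportion to growth divided by yield.
#'
#' @param state a `radial_state`.
#' @param params list of [genotype_params()], one per state genotype (matched
#'   by name when named).
#' @param domain a [radial_domain()].
#' @param dt time step (h); must satisfy [stable_dt()].
#' @param freeze_nutrient if TRUE the nutrient field is held fixed (no
#'   diffusion or consumption); used for front-speed analyses.
#' @return updated `radial_state`.
#' @export
step_pde <- function(state, params, domain, dt, freeze_nutrient = FALSE) {
  ids <- colnames(state$V)
  params <- match_params(params, ids)
  if (dt > stable_dt(domain, params) * (1 + 1e-12))
    stop(sprintf("dt = %g violates stability bound %g", dt,
                 stable_dt(domain, params)))
  N <- state$N
  dN <- if (freeze_nutrient) 0 else domain$D_N * radial_laplacian(N, domain)
  Vnew <- state$V; Snew <- state$S
  for (j in seq_along(ids)) {
    p <- params[[j]]
    V <- state$V[, j]
    gN <- N / (p$K_g + N)
    hN <- p$K_s^p$m / (p$K_s^p$m + N^p$m)
    growth <- p$mu_max * gN * V
    sporulation <- p$sigma_max * hN * V
    Vnew[, j] <- V + dt * (p$D_b * radial_laplacian(V, domain) +
                             growth - sporulation)
    Snew[, j] <- state$S[, j] + dt * sporulation
    if (!freeze_nutrient) dN <- dN - growth / p$Y
  }
  tnew <- state$t + dt
  for (j in seq_along(ids)) {
    Vnew[, j] <- clip_small_negatives(Vnew[, j], paste0("V[", ids[j], "]"), tnew)
    Snew[, j] <- clip_small_negatives(Snew[, j], paste0("S[", ids[j], "]"), tnew)
  }
  Nnew <- if (freeze_nutrient) N else
    clip_small_negatives(N + dt * dN, "N", tnew)
  structure(list(r = state$r, V = Vnew, S = Snew, N = Nnew, t = tnew),
            class = "radial_state")
}

match_params <- function(params, ids) {
  if (inherits(params, "genotype_params")) params <- list(params)
  nm <- vapply(params, function(p) p$id, "")
  if (length(params) != length(ids))
    stop("need one genotype_params per genotype in the state")
  if (all(ids %in% nm)) params <- params[match(ids, nm)]
  params
}

#' Simulate colony growth, recording snapshots
#'
#' @inheritParams step_pde
#' @param t_end final time (h).
#' @param record_times times (h) at which to keep snapshots; must lie in
#'   `[0, t_end]`. Defaults to `c(0, t_end)`.
#' @return list of `radial_state` snapshots, one per recorded time.
#' @export
simulate_colony <- function(state, params, domain, t_end,
                            dt = NULL, record_times = NULL,
                            freeze_nutrient = FALSE) {
  params <- match_params(params, colnames(state$V))
  if (is.null(dt)) dt <- 0.5 * stable_dt(domain, params)
  if (is.null(record_times)) record_times <- unique(c(0, t_end))
  record_times <- sort(record_times)
  if (any(record_times < 0 | record_times > t_end + 1e-9))
    stop("record_times must lie in [0, t_end]")
  out <- vector("list", length(record_times))
  names(out) <- sprintf("t%g", record_times)
  k <- 1
  while (k <= length(record_times) && record_times[k] <= state$t + 1e-9) {
    out[[k]] <- state; k <- k + 1
  }
  while (k <= length(record_times)) {
    target <- record_times[k]
    step <- min(dt, target - state$t)
    state <- tryCatch(
      step_pde(state, params, domain, step, freeze_nutrient),
      error = function(e) stop(sprintf("at t = %.3f h: %s",
                                       state$t, conditionMessage(e))))
    if (state$t >= target - 1e-9) { out[[k]] <- state; k <- k + 1 }
  }
  out
}

#' Colony radius from a density threshold
#'
#' @param state a `radial_state`.
#' @param theta biomass density defining the boundary (> 0).
#' @return largest radius (mm) where total density (V + S over genotypes)
#'   is at least `theta`; 0 when nowhere.
#' @export
colony_radius <- function(state, theta) {
  if (theta <= 0) stop("theta must be > 0")
  total <- rowSums(state$V) + rowSums(state$S)
  idx <- which(total >= theta)
  if (length(idx) == 0) return(0)
  state$r[max(idx)]
}

#' Colony composition in the edge annulus or center disk
#'
#' @param state a `radial_state`.
#' @param region `"edge"` (annulus `[radius - edge_width, radius]`) or
#'   `"center"` (disk `[0, edge_width]`).
#' @param edge_width region width (mm).
#' @param theta boundary threshold used to locate the colony radius.
#' @param domain a [radial_domain()].
#' @return data.frame per genotype with integrated vegetative and spore mass,
#'   within-genotype vegetative/spore fractions, and the genotype's share of
#'   the region's total biomass. All-NA fractions (with attribute
#'   `undefined = TRUE`) when the region is empty.
#' @export
composition_at <- function(state, region = c("edge", "center"),
                           edge_width, theta, domain) {
  region <- match.arg(region)
  rad <- colony_radius(state, theta)
  sel <- if (region == "edge") {
    if (rad < edge_width) NULL else
      state$r >= rad - edge_width & state$r <= rad
  } else state$r <= edge_width
  ids <- colnames(state$V)
  if (is.null(sel) || !any(sel)) {
    out <- data.frame(genotype = ids, vegetative_mass = NA_real_,
                      spore_mass = NA_real_, vegetative_fraction = NA_real_,
                      spore_fraction = NA_real_, genotype_share = NA_real_)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  w <- radial_weights(domain)
  integ <- function(f) 2 * pi * domain$dr * sum(w[sel] * f[sel])
  vm <- vapply(ids, function(g) integ(state$V[, g]), 0)
  sm <- vapply(ids, function(g) integ(state$S[, g]), 0)
  tot <- vm + sm
  out <- data.frame(genotype = ids, vegetative_mass = vm, spore_mass = sm,
                    vegetative_fraction = ifelse(tot > 0, vm / tot, NA),
                    spore_fraction = ifelse(tot > 0, sm / tot, NA),
                    genotype_share = if (sum(tot) > 0) tot / sum(tot) else
                      rep(NA_real_, length(ids)))
  attr(out, "undefined") <- FALSE
  rownames(out) <- NULL
  out
}

#' Overall spore fraction of a region composition
#'
#' @param comp a [composition_at()] result.
#' @return spores / (spores + vegetative) summed over genotypes; NA for an
#'   undefined region.
#' @export
region_spore_fraction <- function(comp) {
  tot <- sum(comp$vegetative_mass) + sum(comp$spore_mass)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  sum(comp$spore_mass) / tot
}

#' Sample edge biomass for transfer to a fresh plate
#'
#' Genotype shares equal each genotype's fraction of total biomass (vegetative
#' plus spores) in the edge annulus; the total is rescaled to the protocol's
#' inoculum mass. Transferred spores germinate on the fresh substrate, i.e.
#' they seed the next cycle as vegetative biomass.
#'
#' @param state end-of-cycle `radial_state`.
#' @param protocol a [passage_protocol()].
#' @param domain a [radial_domain()].
#' @return named numeric vector of per-genotype inoculum masses.
#' @export
edge_transfer <- function(state, protocol, domain) {
  rad <- colony_radius(state, protocol$biomass_threshold)
  if (rad < protocol$edge_width)
    stop("colony radius smaller than edge annulus width")
  comp <- composition_at(state, "edge", protocol$edge_width,
                         protocol$biomass_threshold, domain)
  tot <- comp$vegetative_mass + comp$spore_mass
  if (sum(tot) <= 0) stop("extinct at edge")
  stats::setNames(protocol$inoculum_mass * tot / sum(tot), comp$genotype)
}

#' Run the serial edge-transfer passaging experiment
#'
#' Alternates a full growth cycle with edge sampling and re-seeding for
#' `n_cycles` cycles. Mirrors the selection regime that favors surface
#' spreading: only the outermost annulus propagates.
#'
#' @param genotypes list of [genotype_params()].
#' @param init_fractions initial genotype fractions (sum to 1).
#' @param domain a [radial_domain()].
#' @param protocol a [passage_protocol()].
#' @param dt time step; defaults to half the stability bound.
#' @param record_every record the radius every this many hours within a cycle
#'   (default 24).
#' @param verbose print a one-line per-cycle summary.
#' @return list of per-cycle summaries, each with `radius_series`
#'   (data.frame time, radius), `edge_spore_fraction`,
#'   `center_spore_fraction`, and `edge_genotype_fractions`.
#' @export
run_serial_passages <- function(genotypes, init_fractions, domain, protocol,
                                dt = NULL, record_every = 24, verbose = FALSE) {
  ids <- vapply(genotypes, function(p) p$id, "")
  if (anyDuplicated(ids)) stop("duplicate genotype ids")
  if (abs(sum(init_fractions) - 1) > 1e-9)
    stop("init_fractions must sum to 1")
  masses <- stats::setNames(protocol$inoculum_mass * init_fractions, ids)
  rec <- unique(c(seq(0, protocol$cycle_hours, by = record_every),
                  protocol$cycle_hours))
  out <- vector("list", protocol$n_cycles)
  for (cyc in seq_len(protocol$n_cycles)) {
    inocula <- lapply(masses, function(m)
      list(mass = m, radius = protocol$inoculum_radius))
    keep <- vapply(inocula, function(x) x$mass > 0, TRUE)
    if (!any(keep)) stop(sprintf("cycle %d: no biomass to seed", cyc))
    state <- make_state(domain, inocula[keep])
    snaps <- tryCatch(
      simulate_colony(state, genotypes[keep], domain, protocol$cycle_hours,
                      dt = dt, record_times = rec),
      error = function(e) stop(sprintf("cycle %d: %s", cyc,
                                       conditionMessage(e))))
    final <- snaps[[length(snaps)]]
    radius_series <- data.frame(
      time = rec,
      radius = vapply(snaps, colony_radius, 0,
                      theta = protocol$biomass_threshold))
    edge <- composition_at(final, "edge", protocol$edge_width,
                           protocol$biomass_threshold, domain)
    center <- composition_at(final, "center", protocol$edge_width,
                             protocol$biomass_threshold, domain)
    masses_next <- stats::setNames(rep(0, length(ids)), ids)
    transferred <- edge_transfer(final, protocol, domain)
    masses_next[names(transferred)] <- transferred
    frac <- stats::setNames(rep(0, length(ids)), ids)
    frac[edge$genotype] <- edge$genotype_share
    out[[cyc]] <- list(
      cycle = cyc,
      radius_series = radius_series,
      edge_spore_fraction = region_spore_fraction(edge),
      center_spore_fraction = region_spore_fraction(center),
      edge_genotype_fractions = frac,
      final_radius = radius_series$radius[nrow(radius_series)])
    if (verbose)
      message(sprintf(
        "cycle %d: radius %.2f mm, edge spores %.1f%%, fractions %s",
        cyc, out[[cyc]]$final_radius,
        100 * out[[cyc]]$edge_spore_fraction,
        paste(sprintf("%s=%.3f", ids, frac), collapse = " ")))
    masses <- masses_next
  }
  out
}

#' Parameter sweep of mutant-vs-wild-type competition
#'
#' Competes a wild type against mutants that differ in a single parameter
#' (biomass diffusion, maximal growth rate, or sporulation rate), starting
#' from a 50/50 mixture, and tabulates the mutant's final edge share, the
#' final colony radius, and the edge spore percentage.
#'
#' @param base wild-type [genotype_params()].
#' @param param one of `"D_b"`, `"mu_max"`, `"sigma_max"`.
#' @param values parameter values for the mutant.
#' @param domain,protocol,dt as in [run_serial_passages()].
#' @return data.frame with one row per value: `value`, `edge_mutant_pct`,
#'   `radius`, `edge_spore_pct`.
#' @export
selection_sweep <- function(base, param, values, domain, protocol, dt = NULL) {
  if (!param %in% c("D_b", "mu_max", "sigma_max"))
    stop("unknown sweep parameter: ", param)
  rows <- lapply(values, function(v) {
    mut <- base
    mut[[param]] <- v
    mut$id <- "mutant"
    wt <- base; wt$id <- "wt"
    cycles <- run_serial_passages(list(wt, mut), c(0.5, 0.5),
                                  domain, protocol, dt = dt)
    last <- cycles[[length(cycles)]]
    data.frame(value = v,
               edge_mutant_pct = 100 * last$edge_genotype_fractions[["mutant"]],
               radius = last$final_radius,
               edge_spore_pct = 100 * last$edge_spore_fraction)
  })
  do.call(rbind, rows)
}
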