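test_that("make_state places the requested inoculum mass", {
  dom <- default_domain()
  st <- make_state(dom, list(wt = list(mass = 1, radius = 2)))
  expect_equal(radial_integral(st$V[, "wt"], dom), 1, tolerance = 1e-6)
  expect_true(all(st$S == 0))
  expect_equal(st$N, rep(dom$N0, dom$n_r))
  expect_equal(st$t, 0)

  st2 <- make_state(dom, list(a = list(mass = 0.5, radius = 2),
                              b = list(mass = 0.5, radius = 2)))
  comp <- composition_at(st2, "edge", 1, 1e-6, dom)
  expect_equal(comp$genotype_share, c(0.5, 0.5))

  expect_error(make_state(dom, list(wt = list(mass = 1,
                                              radius = dom$R_max + 1))),
               "exceeds domain")
  expect_error(make_state(dom, list(wt = list(mass = -1, radius = 2))),
               "non-positive")
})

test_that("pure diffusion conserves total biomass", {
  dom <- default_domain()
  p0 <- genotype_params("wt", mu_max = 0, sigma_max = 0)
  st <- make_state(dom, list(wt = list(mass = 0.05, radius = 2)))
  m0 <- radial_integral(st$V[, 1], dom)
  for (i in 1:1000) st <- step_pde(st, list(p0), dom, 0.1)
  expect_equal(radial_integral(st$V[, 1], dom), m0, tolerance = 1e-6)
})

test_that("the stability bound and field sanity are enforced", {
  dom <- default_domain()
  st <- make_state(dom, list(wt = list(mass = 0.05, radius = 2)))
  expect_error(step_pde(st, list(default_wt()), dom,
                        2 * stable_dt(dom, list(default_wt()))),
               "stability")
})

test_that("with diffusion off, nodes follow the scalar ODE", {
  dom <- default_domain()
  p <- genotype_params("wt", D_b = 0, mu_max = 0.3, sigma_max = 0.05)
  dom$D_N <- 0
  st <- make_state(dom, list(wt = list(mass = 0.05, radius = 5)))
  # independent integration of the same right-hand side per node
  rhs <- function(t, y, parms) {
    gN <- y[3] / (p$K_g + y[3])
    hN <- p$K_s^p$m / (p$K_s^p$m + y[3]^p$m)
    dV <- p$mu_max * gN * y[1] - p$sigma_max * hN * y[1]
    dS <- p$sigma_max * hN * y[1]
    dN <- -p$mu_max / p$Y * gN * y[1]
    list(c(dV, dS, dN))
  }
  nodes <- c(1, 10, 25)
  sim <- st
  for (i in 1:5000) sim <- step_pde(sim, list(p), dom, 0.001)
  for (i in nodes) {
    sol <- deSolve::lsoda(c(V = unname(st$V[i, 1]), S = 0, N = dom$N0), c(0, 5),
                          rhs, NULL, rtol = 1e-10, atol = 1e-12)
    if (st$V[i, 1] > 0) {
      expect_equal(unname(sim$V[i, 1]), unname(sol[2, "V"]), tolerance = 1e-4)
      expect_equal(unname(sim$S[i, 1]), unname(sol[2, "S"]), tolerance = 1e-4)
      expect_equal(sim$N[i], unname(sol[2, "N"]), tolerance = 1e-4)
    }
  }
})

test_that("spore mass strictly increases when nutrient is depleted", {
  dom <- default_domain()
  p <- genotype_params("wt", sigma_max = 0.05)
  st <- make_state(dom, list(wt = list(mass = 0.05, radius = 2)))
  st$N <- rep(1e-4, dom$n_r)           # far below K_s: h(N) near 1
  st2 <- step_pde(st, list(p), dom, 0.1)
  expect_gt(radial_integral(st2$S[, 1], dom), radial_integral(st$S[, 1], dom))
})

test_that("per-step mass accounting matches the growth ledger", {
  dom <- default_domain()
  p <- default_wt()
  st <- day7_run()[[2]]                # t = 24 h, active growth
  gN <- st$N / (p$K_g + st$N)
  expected_gain <- 0.1 * radial_integral(p$mu_max * gN * st$V[, 1], dom)
  st2 <- step_pde(st, list(p), dom, 0.1)
  gain <- radial_integral(st2$V[, 1] + st2$S[, 1], dom) -
    radial_integral(st$V[, 1] + st$S[, 1], dom)
  expect_equal(gain, expected_gain, tolerance = 1e-6)
})

test_that("simulate_colony honors record times and depletes nutrient", {
  snaps <- day7_run()
  dom <- default_domain()
  expect_equal(vapply(snaps, function(s) s$t, 0),
               c(t0 = 0, t24 = 24, t72 = 72, t168 = 168))
  ntot <- vapply(snaps, function(s) radial_integral(s$N, dom), 0)
  expect_true(all(diff(ntot) <= 1e-9))
  # t_end = 0 returns the initial state unchanged
  st <- make_state(dom, list(wt = list(mass = 0.05, radius = 2)))
  out <- simulate_colony(st, list(default_wt()), dom, 0, dt = 0.1)
  expect_equal(out[[1]]$V, st$V)
})

test_that("day-7 colony shows the spatial colony-development pattern", {
  dom <- default_domain()
  f7 <- day7_run()[[4]]
  rad <- colony_radius(f7, 0.01)
  expect_gt(rad, 5)
  # nutrient depleted toward the center, minimum at r = 0
  expect_lt(f7$N[1], f7$N[which.min(abs(dom$r - rad))])
  expect_equal(which.min(f7$N), 1)
  # nutrient monotone non-decreasing from center to the front
  front <- which.min(abs(dom$r - rad))
  expect_true(all(diff(f7$N[1:front]) >= -1e-9))
  # spores enriched at the center relative to the edge
  ce <- composition_at(f7, "center", 1, 0.01, dom)
  ee <- composition_at(f7, "edge", 1, 0.01, dom)
  expect_gt(region_spore_fraction(ce), region_spore_fraction(ee))
})

test_that("the expansion front approaches the Fisher wave speed", {
  dom <- radial_domain(R_max = 15, n_r = 301, D_N = 0.01, N0 = 1)
  p <- genotype_params("wt", D_b = 0.01, mu_max = 0.25, sigma_max = 0)
  st <- make_state(dom, list(wt = list(mass = 0.05, radius = 1.5)))
  snaps <- simulate_colony(st, list(p), dom, 120, dt = 0.05,
                           record_times = c(60, 120),
                           freeze_nutrient = TRUE)
  r1 <- colony_radius(snaps[[1]], 0.01)
  r2 <- colony_radius(snaps[[2]], 0.01)
  v_obs <- (r2 - r1) / 60
  v_kpp <- 2 * sqrt(p$D_b * p$mu_max * dom$N0 / (p$K_g + dom$N0))
  expect_lt(abs(v_obs - v_kpp) / v_kpp, 0.2)
})

test_that("colony_radius reads a step profile and degenerate cases", {
  dom <- default_domain()
  st <- make_state(dom, list(wt = list(mass = 1, radius = 2)))
  st$V[, 1] <- as.numeric(dom$r <= 5)
  expect_equal(colony_radius(st, 0.5), 5, tolerance = dom$dr + 1e-12)
  st$V[, 1] <- 0
  expect_equal(colony_radius(st, 0.5), 0)
  st$V[, 1] <- as.numeric(dom$r <= 5)
  expect_equal(colony_radius(st, 2), 0)
})

test_that("composition_at reports region fractions and undefined regions", {
  dom <- default_domain()
  st <- make_state(dom, list(wt = list(mass = 1, radius = 2)))
  # spores only in the center disk, vegetative cells only at the edge
  st$V[, 1] <- 0; st$S[, 1] <- 0
  st$S[dom$r <= 1, 1] <- 1
  st$V[dom$r >= 9 & dom$r <= 10, 1] <- 1
  expect_equal(region_spore_fraction(
    composition_at(st, "center", 1, 0.5, dom)), 1)
  expect_equal(region_spore_fraction(
    composition_at(st, "edge", 1, 0.5, dom)), 0)
  # S = V everywhere: spore fraction one half in both regions
  st$V[, 1] <- 1; st$S[, 1] <- 1
  expect_equal(region_spore_fraction(
    composition_at(st, "edge", 1, 0.5, dom)), 0.5)
  expect_equal(region_spore_fraction(
    composition_at(st, "center", 1, 0.5, dom)), 0.5)
  # genotype shares follow the 3:1 edge ratio
  st2 <- make_state(dom, list(a = list(mass = 1, radius = 2),
                              b = list(mass = 1, radius = 2)))
  st2$V[, "a"] <- 1; st2$V[, "b"] <- 3
  comp <- composition_at(st2, "edge", 1, 0.5, dom)
  expect_equal(comp$genotype_share[comp$genotype == "b"], 0.75)
  # empty region is undefined, not zero
  st3 <- make_state(dom, list(wt = list(mass = 1, radius = 2)))
  st3$V[, 1] <- 0
  st3$V[dom$r <= 0.3, 1] <- 1
  out <- composition_at(st3, "edge", 1, 0.5, dom)
  expect_true(attr(out, "undefined"))
  expect_true(all(is.na(out$spore_fraction)))
})
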