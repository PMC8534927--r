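test_that("density profiles are bounded and vanish for a closed entrance", {
  run <- simulate_run(run_config(lattice_config(50, 2), kinetics_params(),
                                 boundary_rates(0, 1), warmup = 100,
                                 sample = 400, seed = 1))
  prof <- measure_density(run)
  expect_true(all(prof$rho == 0))
  expect_identical(prof$bulk, 0)
})

test_that("the high-density bulk sits at 1 - beta", {
  run <- run_hd_lowload()            # quasi-2D, low load, alpha=0.9, beta=0.2
  prof <- measure_density(run)
  expect_lt(abs(prof$bulk - 0.8), 0.02 + 3 * prof$bulk_se)
  run2 <- run_hd_highload()          # high load, beta=0.3
  prof2 <- measure_density(run2)
  expect_lt(abs(prof2$bulk - 0.7), 0.02 + 3 * prof2$bulk_se)
})

test_that("jump counts, bond crossings and the mean current are one ledger", {
  run <- run_ld_lowload()
  # a realized displacement of length d crosses exactly d bonds
  expect_identical(sum(run$bond_raw), sum((1:4) * run$jump_long))
  # spatially averaged current re-derived from the raw crossing counts
  lat <- run$config$lattice
  expect_equal(mean(run$block_J),
               sum(run$bond_raw) / (run$config$sample * lat$Lx * lat$Ly),
               tolerance = 1e-12)
})

test_that("the stationary longitudinal current is uniform across bonds", {
  run <- run_hd_highload()
  J <- run$bond_current
  interior <- J[10:(length(J) - 10)]
  expect_lt(sd(interior) / mean(interior), 0.06)
})

test_that("the net transverse current vanishes by up/down symmetry", {
  for (run in list(run_ld_lowload(), run_hd_highload())) {
    cur <- measure_current(run)
    expect_lt(abs(cur$transverse), 3 * cur$transverse_se + 1e-4)
  }
})

test_that("lane relabeling leaves the density profile unchanged", {
  run <- run_hd_highload()
  lane_bulk <- rowMeans(run$density[, 75:225])
  expect_lt(max(lane_bulk) - min(lane_bulk), 0.02)
})

test_that("an unobstructed unloaded motor only takes 4-step jumps", {
  kin <- kinetics_params(Satt = 0, Sdet = 1, Px = 1, Py = 0)
  init <- matrix(0L, 1, 64); init[1, 1] <- 1L
  run <- simulate_run(run_config(lattice_config(64, 1), kin,
                                 boundary_rates(0, 0), warmup = 0,
                                 sample = 5000, seed = 5, periodic = TRUE,
                                 init = init))
  expect_identical(sum(run$jump_long[1:3]), 0)
  expect_gt(run$jump_long[[4]], 0)
})

test_that("short steps dominate congested high-load traffic", {
  h <- jump_histogram(run_hd_highload())
  expect_gt(h$counts["longitudinal", "1"], h$counts["longitudinal", "4"])
})

test_that("long jumps are relatively more frequent in LD than in HD", {
  pLD <- jump_histogram(run_ld_lowload())$prop["longitudinal", "4"]
  pHD <- jump_histogram(run_hd_lowload())$prop["longitudinal", "4"]
  expect_gt(pLD, pHD)
})

test_that("entrance-side density oscillations have a 4-column period under long jumps", {
  run <- run_ld_lowload()
  expect_identical(oscillation_period(measure_density(run)), 4L)
})

test_that("tagged particles A, B, C are ordered by entry epoch", {
  run <- simulate_run(run_config(lattice_config(40, 2), low_load(),
                                 boundary_rates(0.5, 0.5), warmup = 0,
                                 sample = 2000, seed = 31,
                                 record_events = TRUE))
  tags <- tag_particles(run)
  expect_setequal(tags$class, c("A", "B", "C"))
  expect_identical(sum(tags$class == "A"), 1L)
  tA <- tags$t_en[tags$class == "A"]
  tB <- tags$t_en[tags$class == "B"]
  tC <- tags$t_en[tags$class == "C"]
  expect_true(tA <= tB && tB <= tC)
  expect_gte(tB, 40)          # c_B * Lx
  expect_gte(tC, 1600)        # c_C * Lx^2
  # a closed entrance leaves nothing to tag
  empty <- simulate_run(run_config(lattice_config(40, 2), low_load(),
                                   boundary_rates(0, 1), warmup = 0,
                                   sample = 50, seed = 32,
                                   record_events = TRUE))
  expect_warning(t0 <- tag_particles(empty), "no particles")
  expect_identical(nrow(t0), 0L)
})

test_that("trajectories advance monotonically along the drive direction", {
  run <- simulate_run(run_config(lattice_config(60, 4), kinetics_params(),
                                 boundary_rates(0.4, 0.6), warmup = 0,
                                 sample = 1500, seed = 33,
                                 record_events = TRUE))
  ids <- unique(run$events$id)[1:10]
  for (id in ids) {
    tr <- trajectory(run, id)
    expect_true(all(diff(tr$x) >= 0))      # only forward longitudinal moves
    expect_true(all(diff(tr$t) > 0))
  }
  expect_error(trajectory(run, 10^6), "unknown particle")
})

test_that("the MSD pipeline recovers known biased-walk growth laws", {
  # oracle: hand-built Bernoulli walker, variance q(1-q)t, second moment
  # (qt)^2 + q(1-q)t
  set.seed(8)
  q <- 0.6
  trajs <- lapply(1:400, function(i) {
    steps <- rbinom(1000, 1, q)
    data.frame(t = 0:1000, x = cumsum(c(0, steps)), y = 0)
  })
  msd_var <- msd_ensemble(trajs, axis = "x", detrend = TRUE)
  fit_var <- fit_msd(msd_var, window = c(10, 1000), model = "power")
  expect_equal(fit_var$xi, 1, tolerance = 0.05)
  expect_equal(msd_var$msd[500] / (q * (1 - q) * 500), 1, tolerance = 0.15)
  msd_raw <- msd_ensemble(trajs, axis = "x", detrend = FALSE)
  fit_raw <- fit_msd(msd_raw, window = c(30, 1000), model = "power")
  expect_equal(fit_raw$xi, 2, tolerance = 0.05)
})

test_that("transverse motion of a lone motor on the cylinder is diffusive", {
  trajs <- msd_ensemble_fixture()
  m <- msd_ensemble(trajs, axis = "y", detrend = TRUE)
  fit <- fit_msd(m, model = "power")
  expect_equal(fit$xi, 1, tolerance = 0.15)
})

test_that("MSD fits refuse thin ensembles and narrow windows", {
  trajs <- msd_ensemble_fixture()
  m <- msd_ensemble(trajs[1:20], axis = "x")
  expect_error(fit_msd(m), "realizations")
  m_full <- msd_ensemble(trajs, axis = "x")
  expect_error(fit_msd(m_full, window = c(50, 100)), "1.5 decades")
})

test_that("dwell fits recover the rate of a known geometric generator", {
  set.seed(9)
  for (p in c(0.1, 0.3, 0.7)) {
    f <- fit_dwell(synth_geometric_dwell(20000, p))
    expect_identical(f$model, "single")
    expect_equal(f$lambda[1], -log(1 - p), tolerance = 0.05)
  }
  # two-stage generator: model selection flips to double and both stage
  # rates are recovered
  set.seed(10)
  w2 <- rgeom(20000, 0.6) + rgeom(20000, 0.08) + 1L
  f2 <- fit_dwell(w2)
  expect_identical(f2$model, "double")
  expect_equal(f2$lambda[1], -log(1 - 0.6), tolerance = 0.15)
  expect_equal(f2$lambda[2], -log(1 - 0.08), tolerance = 0.15)
  # thin samples yield the histogram only
  expect_warning(f3 <- fit_dwell(synth_geometric_dwell(50, 0.3)), "histogram")
  expect_true(is.na(f3$model))
})

test_that("dwell times come from realized jumps and are at least 1 MCS", {
  run <- make_fixtures("dwell")
  w <- dwell_times(run)
  expect_true(all(w >= 1))
  expect_gt(length(w), 500)
})

test_that("profile fits recover a synthetic tangent shape within 5%", {
  set.seed(11)
  truth <- list(rmax = 0.45, q = 0.01, x0 = 150)
  fits <- replicate(5, {
    prof <- synth_tangent_profile(300, truth$rmax, truth$q, truth$x0,
                                  noise = 0.01)
    coef <- fit_profile(prof, form = "tangent")$par
    c(coef[["rmax"]], coef[["q"]])
  })
  expect_equal(mean(fits[1, ]), truth$rmax, tolerance = 0.05)
  expect_equal(mean(fits[2, ]), truth$q, tolerance = 0.05)
  # a flat profile fits with a degenerate tangent: the implied modulation
  # depth rmax * q * tan(q * half-span) stays below the noise floor
  flat <- structure(list(x = 1:300, rho = rep(0.4, 300) + rnorm(300, 0, 0.002),
                         bulk = 0.4, bulk_se = 1e-4),
                    class = "density_profile")
  pf <- fit_profile(flat, "tangent")$par
  depth <- pf[["rmax"]] * pf[["q"]] * abs(tan(pf[["q"]] * 120))
  expect_lt(depth, 0.003)
})

test_that("a domain-wall profile is better described by tanh than a line", {
  set.seed(12)
  x <- 1:300
  rho <- 0.25 + 0.35 * (tanh((x - 160) / 35) + 1) / 2 + rnorm(300, 0, 0.01)
  prof <- structure(list(x = x, rho = rho, bulk = mean(rho), bulk_se = 1e-3),
                    class = "density_profile")
  fit <- fit_profile(prof, form = "tanh")
  lin_sd <- sd(resid(lm(rho ~ x, data.frame(x = x, rho = rho)[30:270, ])))
  expect_lt(fit$residual_sd, lin_sd)
  expect_equal(unname(fit$par["x0"]), 160, tolerance = 0.05)
})
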