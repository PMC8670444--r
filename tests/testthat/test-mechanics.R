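test_that("model construction follows the quasihemispherical contract", {
  p <- finger_params(n_nodes = 41, finger_radius = 8)
  st <- build_model(p)
  expect_length(st$x, 41)
  expect_gt(min(st$z), 0)                       # no node touches the plate
  expect_equal(st$x + rev(st$x), rep(0, 41), tolerance = 1e-12)  # symmetry
  expect_equal(st$z, rev(st$z), tolerance = 1e-12)
  apex <- which.min(st$z)
  expect_equal(st$x[apex], 0, tolerance = 1e-12)

  expect_error(finger_params(n_nodes = 2), "n_nodes")
  expect_error(finger_params(finger_radius = -8), "positive")
  expect_error(finger_params(mu = -0.1), "mu")
  expect_error(finger_params(node_mass = Inf), "positive")
})

test_that("an unloaded resting model is a fixed point of the stepper", {
  p <- finger_params(n_nodes = 21)
  st <- build_model(p)
  st2 <- step_model(st, p, bone_force = 0)
  expect_equal(st2$x, st$x, tolerance = 1e-12)
  expect_equal(st2$z, st$z, tolerance = 1e-12)
  expect_equal(max(abs(st2$vx), abs(st2$vz)), 0, tolerance = 1e-12)
})

test_that("frictionless contact carries zero tangential force", {
  p <- finger_params(n_nodes = 21, mu = 0, target_force = 2,
                     skin_stiffness_normal = 0.3)
  sim <- simulate_press(p, max_time = 4)
  expect_true(any(sim$state$contact))
  expect_equal(max(abs(sim$state$ft)), 0, tolerance = 1e-15)
  expect_equal(max(abs(sim$profile$p_tangential)), 0, tolerance = 1e-15)
})

test_that("single contacted node obeys the stick-slip return mapping", {
  p <- finger_params(n_nodes = 3, membrane_stiffness = 1e-9,
                     bulk_stiffness = 1e-9, kv_damping = 0,
                     mass_damping = 0, contact_damping = 0,
                     mu = 0.5, skin_stiffness_normal = 2,
                     skin_stiffness_tangential = 0.6)
  st <- build_model(p)
  # place the middle node in contact with a stretched stick spring well
  # beyond the Coulomb bound
  i <- 2
  pen <- 0.1
  st$z[i] <- -pen
  st$contact[i] <- TRUE
  st$onset_x[i] <- st$x[i]; st$onset_z[i] <- 0
  st$anchor[i] <- st$x[i] + 1            # far beyond mu*fn/kt
  st2 <- step_model(st, p, 0)
  fn_expect <- p$skin_stiffness_normal * pen
  expect_equal(st2$fn[i], fn_expect, tolerance = 1e-9)
  expect_equal(abs(st2$ft[i]), p$mu * fn_expect, tolerance = 1e-9)
  # anchor was projected back onto the cone
  expect_equal(st2$anchor[i] - st$x[i],
               p$mu * fn_expect / p$skin_stiffness_tangential,
               tolerance = 1e-9)
})

test_that("stepper matches an independent single-node stick-slip oracle", {
  kt <- 0.6; kn <- 2; mu <- 0.5
  p <- finger_params(n_nodes = 3, membrane_stiffness = 1e-12,
                     bulk_stiffness = 1e-12, kv_damping = 0,
                     mass_damping = 0, contact_damping = 0,
                     mu = mu, skin_stiffness_normal = kn,
                     skin_stiffness_tangential = kt,
                     node_mass = 1e-3, dt = 1e-5)
  st <- build_model(p)
  i <- 2
  st$z[i] <- -0.05
  st$contact[i] <- TRUE
  st$onset_x[i] <- st$x[i]; st$onset_z[i] <- 0
  st$anchor[i] <- st$x[i] + 0.3
  st$vx[i] <- 5  # mm/s, moving away from the anchor pull

  # independent scalar re-implementation of the same discrete dynamics
  m_eff <- p$node_mass * 1e-3
  ox <- st$x[i]; oz <- st$z[i]; ovx <- st$vx[i]; ovz <- 0; oa <- st$anchor[i]
  nsteps <- 2000
  for (k in seq_len(nsteps)) {
    pen <- max(-oz, 0)
    fn <- kn * pen
    ft <- kt * (oa - ox)
    if (abs(ft) > mu * fn) {
      oa <- ox + sign(ft) * mu * fn / kt
      ft <- sign(ft) * mu * fn
    }
    ovx <- ovx + p$dt * ft / m_eff
    ovz <- ovz + p$dt * fn / m_eff
    ox <- ox + p$dt * ovx
    oz <- oz + p$dt * ovz
  }
  for (k in seq_len(nsteps)) st <- step_model(st, p, 0)
  expect_equal(st$x[i], ox, tolerance = 1e-6)
  expect_equal(st$z[i], oz, tolerance = 1e-6)
  expect_equal(st$anchor[i], oa, tolerance = 1e-6)
})

test_that("energy is non-increasing without external work", {
  p <- finger_params(n_nodes = 21)
  st <- build_model(p)
  set.seed(5)
  st$vx <- rnorm(21, 0, 5)
  st$vz <- rnorm(21, 0, 5)
  e <- numeric(200)
  for (k in 1:200) {
    st <- step_model(st, p, 0)
    e[k] <- frictouch:::model_energy(st, p)
  }
  expect_true(all(diff(e) <= 1e-10))
})

test_that("press reaches force balance and respects the Coulomb cone", {
  sim <- cached_press(0.3)
  expect_true(sim$converged)
  # force balance within 1%
  expect_equal(sum(sim$state$fn), sim$params$target_force,
               tolerance = 0.01)
  # Coulomb cone with solver slack
  st <- sim$state
  ic <- st$contact
  expect_true(all(abs(st$ft[ic]) <=
                    sim$params$mu * st$fn[ic] + 1e-8))
  # no adhesion
  expect_true(all(st$fn >= 0))
  # non-contacted nodes carry no interfacial force
  expect_true(all(st$fn[!ic] == 0) && all(st$ft[!ic] == 0))
  # displacements bounded by the finger size
  ur <- sqrt((st$x[ic] - st$onset_x[ic])^2 + (st$z[ic] - st$onset_z[ic])^2)
  expect_true(all(ur <= sim$params$finger_radius))
})

test_that("identical parameters reproduce the simulation bit for bit", {
  p <- finger_params(n_nodes = 15, target_force = 1.5, mu = 0.25,
                     skin_stiffness_normal = 0.5)
  s1 <- simulate_press(p, max_time = 3)
  s2 <- simulate_press(p, max_time = 3)
  expect_identical(s1$divergence, s2$divergence)
  expect_identical(s1$profile, s2$profile)
  expect_identical(s1$state$x, s2$state$x)
})

test_that("divergence sweep tables are ordered, labelled and reproducible", {
  p <- finger_params(n_nodes = 15, target_force = 1.5)
  sw <- divergence_vs_force_sweep(p, mu_list = c(0.3, 0.3),
                                  force_grid = c(0.75, 1.5))
  expect_true(all(c("mu", "force_N", "divergence", "phase") %in% names(sw)))
  # identical mu entries give identical divergences (determinism)
  eq <- sw[sw$phase == "equilibrium", ]
  expect_equal(nrow(eq), 2)
  expect_identical(eq$divergence[1], eq$divergence[2])

  one <- divergence_vs_force_sweep(p, mu_list = 0.3, force_grid = numeric())
  expect_equal(nrow(one), 1)
  expect_identical(one$divergence[1], eq$divergence[1])
  expect_error(divergence_vs_force_sweep(p, mu_list = numeric()), "length")
})

test_that("non-finite forces raise an informative integration error", {
  p <- finger_params(n_nodes = 5)
  st <- build_model(p)
  st$x[3] <- NaN
  expect_error(step_model(st, p, 0), "node")
})

test_that("glance and autoplot summarise a press", {
  sim <- cached_press(0.3)
  gl <- glance(sim)
  expect_equal(gl$mu, 0.3)
  expect_true(gl$converged)
  sp <- stress_profile(sim)
  expect_named(sp, c("r_mm", "p_normal", "p_tangential"))
  expect_true(all(sp$p_normal >= 0))
  expect_s3_class(ggplot2::autoplot(sim), "ggplot")
  expect_s3_class(tidy(sim), "tbl_df")
})
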