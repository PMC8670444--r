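#' Parameters of the axisymmetric fingertip contact model
#'
#' The fingertip is modelled as a cross-section of a quasihemispherical
#' membrane of surface nodes connected to their neighbours by Kelvin–Voigt
#' (spring + parallel damper) elements and to a single rigid bone element
#' by distributed pulp springs. Pressing the bone down brings nodes into
#' unilateral (no-adhesion) penalty contact with a rigid plate; each
#' contacted node interacts tangentially through an elastoplastic stick
#' spring obeying the Coulomb cone \eqn{|f_t| \le \mu f_n}: the spring
#' anchor is dragged back onto the cone whenever the bound is violated
#' (radial return), reproducing stick–slip.
#'
#' Default stiffness, damping and mass values are calibrated so that a 3 N
#' press reproduces the expected friction dependence of the contacted-skin
#' divergence (about 0.04 at \eqn{\mu} = 0.1 down to about 0.02 at
#' \eqn{\mu} = 0.6); all are overridable.
#'
#' @param n_nodes Number of surface nodes along the profile (>= 3; odd
#'   values place one node at the apex).
#' @param finger_radius Radius of the quasihemispherical profile (mm).
#' @param arc_angle_deg Half-opening angle of the modelled profile (deg).
#' @param skin_stiffness_normal Plate contact penalty stiffness (N/mm).
#' @param skin_stiffness_tangential Interfacial stick-spring stiffness
#'   (N/mm).
#' @param membrane_stiffness Neighbour-to-neighbour skin stiffness (N/mm).
#' @param kv_damping Kelvin–Voigt damper in parallel with each membrane
#'   spring (N·s/mm).
#' @param bulk_stiffness Total pulp stiffness toward the bone (N/mm),
#'   distributed over the nodes.
#' @param node_mass Mass per surface node (kg).
#' @param mass_damping Per-node viscous drag (N·s/mm), applied implicitly.
#' @param contact_damping Normal contact damper (N·s/mm); the total normal
#'   force is clipped at zero so the plate never pulls (no adhesion).
#' @param mu Coulomb friction coefficient (>= 0).
#' @param target_force Normal load ramped onto the bone element (N).
#' @param ramp_rate Load rate (N/s); the default matches the experimental
#'   force rate of 3.6 N/s.
#' @param dt Integration step (s); `NULL` picks a stable step from the
#'   stiffest element (0.1 of the shortest vibration period).
#' @param equilibrium_tol Residual node speed (mm/s) below which, together
#'   with a bone-force balance within 1%, the press counts as static
#'   equilibrium.
#' @param clearance Initial apex height above the plate (mm).
#' @return A validated list of class `finger_params`.
#' @export
finger_params <- function(n_nodes = 41, finger_radius = 8,
                          arc_angle_deg = 60,
                          skin_stiffness_normal = 0.3,
                          skin_stiffness_tangential = 0.6,
                          membrane_stiffness = 5,
                          kv_damping = 0.002,
                          bulk_stiffness = 10,
                          node_mass = 1e-3,
                          mass_damping = 1e-3,
                          contact_damping = 5e-4,
                          mu = 0.3, target_force = 3,
                          ramp_rate = 3.6, dt = NULL,
                          equilibrium_tol = 0.05,
                          clearance = 0.05) {
  p <- as.list(environment())
  chk <- function(ok, msg) if (!ok) stop("invalid parameter: ", msg,
                                         call. = FALSE)
  num_ok <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)
  chk(num_ok(n_nodes) && n_nodes >= 3, "n_nodes must be >= 3")
  for (nm in c("finger_radius", "skin_stiffness_normal",
               "skin_stiffness_tangential", "membrane_stiffness",
               "bulk_stiffness", "node_mass", "target_force",
               "ramp_rate", "equilibrium_tol", "clearance")) {
    chk(num_ok(p[[nm]]) && p[[nm]] > 0, paste(nm, "must be positive"))
  }
  for (nm in c("kv_damping", "mass_damping", "contact_damping")) {
    chk(num_ok(p[[nm]]) && p[[nm]] >= 0, paste(nm, "must be >= 0"))
  }
  chk(num_ok(mu) && mu >= 0, "mu must be >= 0")
  chk(num_ok(arc_angle_deg) && arc_angle_deg > 10 && arc_angle_deg < 90,
      "arc_angle_deg must be in (10, 90)")
  if (is.null(dt)) {
    m_eff <- node_mass * 1e-3  # N s^2 / mm
    k_max <- skin_stiffness_normal + skin_stiffness_tangential +
      2 * membrane_stiffness + bulk_stiffness
    p$dt <- 0.1 / sqrt(k_max / m_eff)
  } else {
    chk(num_ok(dt) && dt > 0, "dt must be positive")
  }
  p$n_nodes <- as.integer(n_nodes)
  class(p) <- "finger_params"
  p
}

#' Build the initial node state of the fingertip model
#'
#' Lays the surface nodes on the quasihemispherical profile above the
#' plate (no node initially in contact) and initialises velocities,
#' stick-spring anchors and interfacial forces to zero.
#'
#' @param params A [finger_params()] object.
#' @return A list of class `finger_state` holding node positions `x`, `z`
#'   (mm), velocities, stick anchors, contact flags, contact-onset
#'   reference positions and the bone element state.
#' @export
build_model <- function(params) {
  stopifnot(inherits(params, "finger_params"))
  n <- params$n_nodes
  th <- seq(-params$arc_angle_deg, params$arc_angle_deg,
            length.out = n) * pi / 180
  R <- params$finger_radius
  bone_z <- R + params$clearance
  x <- R * sin(th)
  z <- bone_z - R * cos(th)
  if (min(z) <= 0) stop("invalid parameter: profile touches the plate at rest",
                        call. = FALSE)
  state <- list(
    x = x, z = z, vx = numeric(n), vz = numeric(n),
    anchor = x, contact = rep(FALSE, n),
    onset_x = rep(NA_real_, n), onset_z = rep(NA_real_, n),
    fn = numeric(n), ft = numeric(n),
    x0 = x, z0 = z,
    u0x = sin(th), u0z = -cos(th),     # material pulp directions
    rest_len = sqrt(diff(x)^2 + diff(z)^2),
    bone_z = bone_z, bone_vz = 0, t = 0)
  class(state) <- "finger_state"
  state
}

# one semi-implicit Euler step under external bone load f_ext (N, downward)
mech_step <- function(st, p, f_ext) {
  n <- p$n_nodes
  m_eff <- p$node_mass * 1e-3           # N s^2/mm
  kb <- p$bulk_stiffness / n            # per-node pulp stiffness
  fx <- numeric(n); fz <- numeric(n)

  # membrane Kelvin-Voigt elements between neighbours
  dx <- diff(st$x); dz <- diff(st$z)
  len <- sqrt(dx^2 + dz^2)
  len <- pmax(len, 1e-9)
  ex <- dx / len; ez <- dz / len
  dvx <- diff(st$vx); dvz <- diff(st$vz)
  s_el <- p$membrane_stiffness * (len - st$rest_len) +
    p$kv_damping * (dvx * ex + dvz * ez)
  fseg_x <- s_el * ex; fseg_z <- s_el * ez
  fx[1:(n - 1)] <- fx[1:(n - 1)] + fseg_x
  fz[1:(n - 1)] <- fz[1:(n - 1)] + fseg_z
  fx[2:n] <- fx[2:n] - fseg_x
  fz[2:n] <- fz[2:n] - fseg_z

  # pulp springs along each node's material (initial radial) direction:
  # the pulp compresses toward the bone without acting like a rigid
  # expanding sphere
  ux <- st$u0x; uz <- st$u0z
  proj <- (st$x - 0) * ux + (st$z - st$bone_z) * uz
  rel_v <- st$vx * ux + (st$vz - st$bone_vz) * uz
  s_b <- -kb * (proj - p$finger_radius) - p$kv_damping * rel_v
  fx <- fx + s_b * ux
  fz <- fz + s_b * uz
  bone_f <- -sum(s_b * uz) - f_ext      # reaction + external load

  # plate contact: unilateral penalty, clipped to forbid adhesion
  pen <- -st$z
  fn <- pmax(p$skin_stiffness_normal * pen - p$contact_damping * st$vz, 0)
  fn[pen <= 0] <- 0
  contact <- pen > 0
  # contact onset bookkeeping: reference = position at first touch
  new_c <- contact & !st$contact
  st$onset_x[new_c] <- st$x[new_c]
  st$onset_z[new_c] <- st$z[new_c]
  st$anchor[new_c] <- st$x[new_c]

  # elastoplastic tangential stick spring with Coulomb radial return
  ft <- numeric(n)
  ic <- which(contact)
  if (length(ic)) {
    ft_trial <- p$skin_stiffness_tangential * (st$anchor[ic] - st$x[ic])
    fmax <- p$mu * fn[ic]
    slip <- abs(ft_trial) > fmax
    if (any(slip)) {
      js <- ic[slip]
      st$anchor[js] <- st$x[js] +
        sign(ft_trial[slip]) * fmax[slip] / p$skin_stiffness_tangential
      ft_trial[slip] <- sign(ft_trial[slip]) * fmax[slip]
    }
    ft[ic] <- ft_trial
  }
  st$anchor[!contact] <- st$x[!contact]

  fx <- fx + ft
  fz <- fz + fn
  if (any(!is.finite(fx)) || any(!is.finite(fz))) {
    bad <- which(!is.finite(fx) | !is.finite(fz))[1]
    stop("non-finite force at node ", bad, " (t = ", st$t, " s)",
         call. = FALSE)
  }

  # semi-implicit Euler with implicit viscous drag
  drag <- 1 / (1 + p$mass_damping * p$dt / m_eff)
  st$vx <- (st$vx + p$dt * fx / m_eff) * drag
  st$vz <- (st$vz + p$dt * fz / m_eff) * drag
  st$x <- st$x + p$dt * st$vx
  st$z <- st$z + p$dt * st$vz

  bone_m <- 100 * m_eff
  st$bone_vz <- (st$bone_vz + p$dt * bone_f / bone_m) * drag
  st$bone_z <- st$bone_z + p$dt * st$bone_vz

  st$fn <- fn; st$ft <- ft
  st$contact <- contact
  st$t <- st$t + p$dt
  st
}

#' Advance the fingertip model by one time step
#'
#' One semi-implicit (symplectic) Euler step: membrane and pulp
#' Kelvin–Voigt forces, unilateral penalty contact with the plate, and the
#' elastoplastic Coulomb stick–slip update of the tangential anchors. In
#' the absence of external work input the total mechanical energy is
#' non-increasing (all dampers dissipate; the plastic slip dissipates).
#'
#' @param state A `finger_state`.
#' @param params The matching [finger_params()].
#' @param bone_force External downward load on the bone element (N).
#' @return The updated `finger_state`.
#' @export
step_model <- function(state, params, bone_force = 0) {
  stopifnot(inherits(state, "finger_state"),
            inherits(params, "finger_params"))
  mech_step(state, params, bone_force)
}

# total mechanical energy (mJ = N mm): kinetic + membrane + pulp + contact
# penalty + stick springs
model_energy <- function(st, p) {
  m_eff <- p$node_mass * 1e-3
  kin <- 0.5 * m_eff * sum(st$vx^2 + st$vz^2) +
    0.5 * 100 * m_eff * st$bone_vz^2
  len <- sqrt(diff(st$x)^2 + diff(st$z)^2)
  e_mem <- 0.5 * p$membrane_stiffness * sum((len - st$rest_len)^2)
  proj <- st$x * st$u0x + (st$z - st$bone_z) * st$u0z
  e_bulk <- 0.5 * (p$bulk_stiffness / p$n_nodes) *
    sum((proj - p$finger_radius)^2)
  pen <- pmax(-st$z, 0)
  e_con <- 0.5 * p$skin_stiffness_normal * sum(pen^2)
  e_t <- 0.5 * p$skin_stiffness_tangential *
    sum((st$anchor - st$x)[st$contact]^2)
  kin + e_mem + e_bulk + e_con + e_t
}

#' Simulate a full press to static equilibrium
#'
#' Ramps the bone load linearly at `ramp_rate` up to `target_force`, then
#' steps until static equilibrium: maximum node speed below
#' `equilibrium_tol` and bone-force balance within 1% of the target for
#' 100 consecutive checks. Displacements are referenced to each node's
#' position at its own contact onset. If the iteration cap is reached the
#' result is returned with `converged = FALSE`.
#'
#' @param params A [finger_params()].
#' @param force_grid Optional force levels (N) at which the contacted-skin
#'   divergence is recorded as the ramp crosses them.
#' @param max_time Simulated-time cap (s).
#' @param record_every Sampling stride (steps) of the force time series.
#' @return An object of class `press_sim`: `params`, `state`, `force_series`
#'   (tibble `t_s`, `bone_force_N`, `contact_force_N`), `profile` (tibble
#'   `r_mm`, `u_r_mm`, `u_z_mm`, `p_normal`, `p_tangential` per contacted
#'   node), `divergence` (contacted-skin mean divergence), `divergence_at`
#'   (tibble of crossings of `force_grid`), `tangential_energy_mJ`,
#'   `converged`, `iterations`.
#' @export
simulate_press <- function(params, force_grid = NULL, max_time = 6,
                           record_every = 200L) {
  stopifnot(inherits(params, "finger_params"))
  st <- build_model(params)
  p <- params
  n_steps_max <- ceiling(max_time / p$dt)
  t_ramp <- p$target_force / p$ramp_rate
  rec_t <- c(); rec_f <- c(); rec_cf <- c()
  grid_pending <- sort(force_grid)
  grid_div <- numeric(0); grid_f <- numeric(0)
  ok_streak <- 0L
  converged <- FALSE
  i <- 0L
  while (i < n_steps_max) {
    i <- i + 1L
    f_ext <- min(p$ramp_rate * st$t, p$target_force)
    st <- mech_step(st, p, f_ext)
    if (length(grid_pending) && sum(st$fn) >= grid_pending[1]) {
      grid_f <- c(grid_f, grid_pending[1])
      grid_div <- c(grid_div, contacted_divergence(st)$mean)
      grid_pending <- grid_pending[-1]
    }
    if (i %% record_every == 0L) {
      rec_t <- c(rec_t, st$t); rec_f <- c(rec_f, f_ext)
      rec_cf <- c(rec_cf, sum(st$fn))
    }
    if (st$t >= t_ramp) {
      speed <- max(abs(st$vx), abs(st$vz), abs(st$bone_vz))
      bal <- abs(sum(st$fn) - p$target_force) <= 0.01 * p$target_force
      if (speed < p$equilibrium_tol && bal) {
        ok_streak <- ok_streak + 1L
        if (ok_streak >= 100L) { converged <- TRUE; break }
      } else ok_streak <- 0L
    }
  }
  div <- contacted_divergence(st)
  prof <- interfacial_profile(st)
  e_t <- sum(st$ft[st$contact]^2) / (2 * p$skin_stiffness_tangential)
  # elastic energy held in the skin (membrane) elements of the contact zone
  ic <- range(which(st$contact))
  segs <- if (any(st$contact)) seq(ic[1], max(ic[1], ic[2] - 1)) else integer()
  len <- sqrt(diff(st$x)^2 + diff(st$z)^2)
  e_m <- 0.5 * p$membrane_stiffness *
    sum((len[segs] - st$rest_len[segs])^2)
  structure(list(params = p, state = st,
                 force_series = tibble::tibble(t_s = rec_t,
                                               bone_force_N = rec_f,
                                               contact_force_N = rec_cf),
                 profile = prof,
                 divergence = div$mean,
                 divergence_table = div$table,
                 divergence_at = tibble::tibble(force_N = grid_f,
                                                divergence = grid_div),
                 tangential_energy_mJ = e_t,
                 membrane_energy_mJ = e_m,
                 skin_energy_mJ = e_t + e_m,
                 converged = converged, iterations = i),
            class = "press_sim")
}

# area-weighted axisymmetric divergence of the contacted skin,
# div u = du_r/dr + u_r/r, displacements referenced to contact onset.
# The incipient rim (nodes carrying less than rim_fraction of the peak
# interfacial pressure) is not yet mechanically engaged and is excluded:
# freshly landed nodes have zero onset-referenced displacement by
# definition, which would cancel the boundary flux of the engaged contact.
contacted_divergence <- function(st, rim_fraction = 0.1) {
  ic <- which(st$contact & !is.na(st$onset_x) &
                st$fn >= rim_fraction * max(st$fn))
  if (length(ic) < 3) {
    return(list(mean = NA_real_,
                table = tibble::tibble(r_mm = numeric(),
                                       u_r_mm = numeric(),
                                       divergence = numeric())))
  }
  r <- abs(st$onset_x[ic])
  u_r <- sign(st$onset_x[ic]) * (st$x[ic] - st$onset_x[ic])
  # apex node: sign(0) = 0 would zero its displacement; by symmetry its
  # radial displacement is 0 anyway
  ord <- order(r)
  r <- r[ord]; u_r <- u_r[ord]
  # merge the two symmetric half-profiles: average duplicates in r
  ur_s <- tapply(u_r, round(r, 9), mean)
  r_s <- as.numeric(names(ur_s))
  u <- as.numeric(ur_s)
  nn <- length(r_s)
  if (nn < 3) {
    return(list(mean = NA_real_,
                table = tibble::tibble(r_mm = r_s, u_r_mm = u,
                                       divergence = NA_real_)))
  }
  dudr <- numeric(nn)
  dudr[1] <- (u[2] - u[1]) / (r_s[2] - r_s[1])
  dudr[nn] <- (u[nn] - u[nn - 1]) / (r_s[nn] - r_s[nn - 1])
  if (nn > 2) {
    dudr[2:(nn - 1)] <- (u[3:nn] - u[1:(nn - 2)]) /
      (r_s[3:nn] - r_s[1:(nn - 2)])
  }
  div <- ifelse(r_s < 1e-9, 2 * dudr, dudr + u / pmax(r_s, 1e-9))
  # annulus area weights r * dr (apex gets its half-cell)
  dr <- numeric(nn)
  dr[1] <- (r_s[2] - r_s[1]) / 2 + r_s[1]
  dr[nn] <- (r_s[nn] - r_s[nn - 1]) / 2
  if (nn > 2) dr[2:(nn - 1)] <- (r_s[3:nn] - r_s[1:(nn - 2)]) / 2
  w <- pmax(r_s, dr[1] / 2) * dr
  list(mean = sum(w * div) / sum(w),
       table = tibble::tibble(r_mm = r_s, u_r_mm = u, divergence = div))
}

# interfacial line-stress profile over contacted nodes (N/mm)
interfacial_profile <- function(st) {
  ic <- which(st$contact)
  if (!length(ic)) {
    return(tibble::tibble(r_mm = numeric(), u_r_mm = numeric(),
                          u_z_mm = numeric(), p_normal = numeric(),
                          p_tangential = numeric()))
  }
  x <- st$x[ic]
  ord <- order(x)
  ic <- ic[ord]; x <- x[ord]
  nn <- length(ic)
  dx <- numeric(nn)
  if (nn == 1) {
    dx <- 1
  } else {
    dx[1] <- x[2] - x[1]
    dx[nn] <- x[nn] - x[nn - 1]
    if (nn > 2) dx[2:(nn - 1)] <- (x[3:nn] - x[1:(nn - 2)]) / 2
  }
  tibble::tibble(
    r_mm = x,
    u_r_mm = st$x[ic] - st$onset_x[ic],
    u_z_mm = st$z[ic] - st$onset_z[ic],
    p_normal = st$fn[ic] / dx,
    p_tangential = st$ft[ic] / dx)
}

#' Interfacial stress profiles of a converged press
#'
#' Normal and tangential line-stress (N/mm) against the radial position of
#' each contacted node. At equal load the normal profile is essentially
#' friction-independent while the tangential profile grows with \eqn{\mu};
#' the integral of the normal profile recovers the applied bone force.
#'
#' @param sim A `press_sim` from [simulate_press()].
#' @return A tibble `r_mm`, `p_normal`, `p_tangential`, plus the per-node
#'   forces implied by trapezoidal spacing.
#' @export
stress_profile <- function(sim) {
  stopifnot(inherits(sim, "press_sim"))
  sim$profile[, c("r_mm", "p_normal", "p_tangential")]
}

#' Contacted-skin divergence across friction coefficients and load levels
#'
#' Runs one press per friction coefficient and records the contacted-skin
#' divergence as the ramp crosses each requested force level, plus the
#' final static-equilibrium value. At fixed load the divergence is
#' monotone non-increasing in \eqn{\mu} (within solver tolerance):
#' high-friction skin is pinned where it lands, low-friction skin keeps
#' expanding radially.
#'
#' @param params A [finger_params()] (its `mu` is overridden).
#' @param mu_list Friction coefficients (nonempty).
#' @param force_grid Force levels (N) at which divergence is recorded
#'   during the ramp.
#' @return A tibble with columns `mu`, `force_N`, `divergence`, and
#'   `phase` (`"ramp"` crossings and the `"equilibrium"` endpoint), rows
#'   ordered by `mu`.
#' @export
divergence_vs_force_sweep <- function(params, mu_list,
                                      force_grid = c(1, 2, 3)) {
  stopifnot(length(mu_list) >= 1)
  out <- purrr::map_dfr(mu_list, function(m) {
    p <- params
    p$mu <- m
    sim <- simulate_press(p, force_grid = force_grid)
    dplyr::bind_rows(
      dplyr::mutate(sim$divergence_at, mu = m, phase = "ramp"),
      tibble::tibble(force_N = p$target_force,
                     divergence = sim$divergence,
                     mu = m, phase = "equilibrium"))
  })
  dplyr::arrange(out[, c("mu", "force_N", "divergence", "phase")],
                 .data$mu, .data$force_N)
}

#' @export
print.press_sim <- function(x, ...) {
  cat("Fingertip press simulation (mu =", x$params$mu,
      ", target", x$params$target_force, "N)\n")
  cat(sprintf("  %s after %d steps (t = %.3f s)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$state$t))
  cat(sprintf("  contact force %.3f N over %d nodes\n",
              sum(x$state$fn), sum(x$state$contact)))
  cat(sprintf("  contacted-skin divergence: %.4f\n", x$divergence))
  invisible(x)
}
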