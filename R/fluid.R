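## D3Q27 lattice-Boltzmann BGK solver with WALE LES closure.

#' D3Q27 velocity set
#'
#' The 27 discrete directions (all combinations of -1/0/1), their quadrature
#' weights (8/27, 2/27, 1/54, 1/216 by squared speed) and the squared lattice
#' sound speed 1/3.
#'
#' @return List with `K` (27 x 3 integer matrix), `w` (27 weights), `c_s2`.
#' @export
d3q27 <- function() d3q27_set()

#' Physical-to-lattice unit scaling
#'
#' Maps the physical air properties and grid choice onto lattice units. The
#' molecular relaxation time is `tau0 = 1/2 + 3 nu_lat`; stability requires
#' `tau0 > 1/2` and the inlet speed to stay below about 0.1 lattice units
#' (low-Mach constraint), which is checked at startup.
#'
#' @param dx lattice spacing (m per lattice unit).
#' @param dt time step (s).
#' @param nu_phys kinematic viscosity (m^2 s^-1); the default is air at
#'   1.7894e-5 Pa s dynamic viscosity and 1.225 kg m^-3.
#' @param rho_phys physical density (kg m^-3).
#' @param u_max_phys largest expected physical speed (m s^-1), used for the
#'   Mach check.
#' @return A `unit_scaling` list with conversion factors and `tau0`.
#' @export
unit_scaling <- function(dx, dt, nu_phys = 1.7894e-5 / 1.225,
                         rho_phys = 1.225, u_max_phys = NULL) {
  nu_lat <- nu_phys * dt / dx^2
  tau0 <- 0.5 + 3 * nu_lat
  u_factor <- dt / dx            # u_lat = u_phys * u_factor
  if (!is.null(u_max_phys)) {
    u_lat <- u_max_phys * u_factor
    if (u_lat > 0.1)
      stop(sprintf(paste0("maximum lattice velocity %.3f exceeds the 0.1 ",
                          "low-Mach limit; decrease dt or refine the grid"),
                   u_lat))
  }
  structure(list(dx = dx, dt = dt, nu_phys = nu_phys, rho_phys = rho_phys,
                 nu_lat = nu_lat, tau0 = tau0, u_factor = u_factor,
                 accel_factor = dt^2 / dx),
            class = "unit_scaling")
}

#' Pick a time step for a target lattice inlet velocity
#' @param dx lattice spacing (m).
#' @param u0 physical inlet speed (m s^-1).
#' @param u_lat target lattice speed (default 0.05).
#' @return dt in seconds.
#' @export
choose_dt <- function(dx, u0, u_lat = 0.05) u_lat * dx / u0

#' Node flags for a box domain
#'
#' Builds the flag field: 0 fluid, 1 inlet, 2 outflow, 3 wall, 4 solid.
#' Faces not listed stay periodic (streaming wraps around).
#'
#' @param n integer vector (nx, ny, nz).
#' @param top,bottom,sides one of `"periodic"`, `"inlet"`, `"outflow"`,
#'   `"wall"`, `"fluid"`; top is the z = max face.
#' @return Integer vector of length prod(n).
#' @export
make_flags <- function(n, top = "periodic", bottom = "periodic",
                       sides = "periodic") {
  code <- c(periodic = 0L, fluid = 0L, inlet = 1L, outflow = 2L, wall = 3L)
  stopifnot(top %in% names(code), bottom %in% names(code),
            sides %in% names(code))
  fl <- array(0L, dim = n)
  if (sides != "periodic") {
    fl[c(1, n[1]), , ] <- code[[sides]]
    fl[, c(1, n[2]), ] <- code[[sides]]
  }
  if (bottom != "periodic") fl[, , 1] <- code[[bottom]]
  if (top != "periodic") fl[, , n[3]] <- code[[top]]
  as.integer(fl)
}

#' Create a fluid state
#'
#' Initializes the D3Q27 distribution field at equilibrium for the given
#' density and velocity. The state is an environment so solver kernels can
#' update it in place.
#'
#' @param n integer vector (nx, ny, nz).
#' @param scaling a `unit_scaling`.
#' @param flags flag field from [make_flags()] (default all periodic fluid).
#' @param rho0 initial lattice density (1 corresponds to the physical air
#'   density).
#' @param u0 initial lattice velocity (length 3) or an n x 3 matrix.
#' @param les enable the WALE eddy-viscosity closure.
#' @param Bw WALE constant (0.325).
#' @param u_inlet_phys inlet velocity vector in m/s (used for inlet flags).
#' @param body_accel_phys constant body acceleration on the fluid in m/s^2
#'   (e.g. `c(0, 0, -9.81)` for gravity); NULL for none.
#' @return A `fluid_state` environment.
#' @export
fluid_state <- function(n, scaling, flags = NULL, rho0 = 1,
                        u0 = c(0, 0, 0), les = TRUE, Bw = 0.325,
                        u_inlet_phys = c(0, 0, 0), body_accel_phys = NULL) {
  n <- as.integer(n)
  nn <- prod(n)
  if (is.null(flags)) flags <- integer(nn)
  rho <- rep(rho0, nn)
  u <- if (is.matrix(u0)) u0 else matrix(u0, nn, 3, byrow = TRUE)
  st <- new.env(parent = emptyenv())
  st$dims <- n
  st$scaling <- scaling
  st$flags <- as.integer(flags)
  st$f <- lbm_equilibrium(rho, u)
  st$fbuf <- matrix(0, nn, 27)
  st$les <- les
  st$Bw <- Bw
  st$u_inlet_lat <- u_inlet_phys * scaling$u_factor
  st$force <- NULL                     # n x 3 lattice force density, or NULL
  st$body_force_lat <- if (is.null(body_accel_phys)) NULL else
    body_accel_phys * scaling$accel_factor
  st$step_count <- 0L
  class(st) <- c("fluid_state", "environment")
  st
}

#' Equilibrium distributions
#'
#' Standard second-order D3Q27 equilibrium. Moments satisfy
#' `rowSums(f) = rho` and `t(f) %*% K = rho u` exactly.
#'
#' @param rho lattice density vector (or scalar).
#' @param u lattice velocity, n x 3 matrix (or length-3 vector).
#' @return n x 27 matrix of equilibrium values.
#' @export
equilibrium <- function(rho, u) {
  if (!is.matrix(u)) u <- matrix(u, nrow = length(rho), ncol = 3, byrow = TRUE)
  if (any(rho <= 0)) stop("rho must be positive")
  if (any(sqrt(rowSums(u^2)) > 0.3))
    stop("lattice velocity above 0.3 is outside the low-Mach regime")
  lbm_equilibrium(rho, u)
}

#' Macroscopic density and velocity
#'
#' `rho = sum_a f_a`, `u = (sum_a f_a K_a + F/2) / rho`; the half-force term
#' is the standard correction when a body force is active.
#'
#' @param f n x 27 distribution matrix or a `fluid_state`.
#' @param force optional n x 3 lattice force density.
#' @return List with `rho` and `u` (n x 3).
#' @export
macroscopics <- function(f, force = NULL) {
  if (inherits(f, "fluid_state")) {
    force <- total_force(f)
    f <- f$f
  }
  lbm_macroscopics(f, force)
}

total_force <- function(state) {
  F <- state$force
  bf <- state$body_force_lat
  if (is.null(bf)) return(F)
  base <- matrix(bf, prod(state$dims), 3, byrow = TRUE)
  if (is.null(F)) base else F + base
}

#' Velocity-gradient tensor field
#'
#' Second-order central differences in the interior, one-sided at
#' non-periodic boundaries. Column `a + 3 * (b - 1)` holds du_a/dx_b.
#'
#' @param u n x 3 velocity field.
#' @param dims grid dimensions.
#' @param dx grid spacing.
#' @param periodic wrap differences around the domain.
#' @return n x 9 gradient matrix.
#' @export
velocity_gradient <- function(u, dims, dx = 1, periodic = TRUE)
  lbm_velocity_gradient(u, as.integer(dims), dx, periodic)

#' WALE eddy viscosity
#'
#' Wall-adapting local eddy-viscosity closure
#' `nu_t = (Bw Delta)^2 (Sd:Sd)^{3/2} / ((S:S)^{5/2} + (Sd:Sd)^{5/4})`
#' where S is the resolved strain rate and Sd the traceless symmetric part
#' of the squared velocity gradient. Vanishes identically in pure shear and
#' rigid rotation; the 0/0 limit is guarded to 0.
#'
#' @param g n x 9 velocity-gradient field (see [velocity_gradient()]).
#' @param Bw model constant, 0.325.
#' @param Delta filter scale (the grid spacing).
#' @return Non-negative eddy-viscosity vector.
#' @export
wale_viscosity <- function(g, Bw = 0.325, Delta = 1)
  wale_viscosity_cpp(g, Bw, Delta)

#' Strain rate from the non-equilibrium second moment
#'
#' Diagnostic alternative to the finite-difference gradient:
#' `S = -1/(2 rho c_s^2 tau) sum_a (f_a - f_a^eq) K_a K_a^T` (lattice units).
#'
#' @param f n x 27 distributions.
#' @param tau relaxation-time vector (recycled if scalar).
#' @param force optional lattice force for the velocity moment.
#' @return n x 9 symmetric strain-rate field.
#' @export
strain_from_nonequilibrium <- function(f, tau, force = NULL) {
  mac <- lbm_macroscopics(f, force)
  if (length(tau) == 1) tau <- rep(tau, nrow(f))
  lbm_strain_noneq(f, mac$rho, mac$u, tau)
}

#' Vorticity magnitude field
#' @inheritParams velocity_gradient
#' @return Vector of |curl u|.
#' @export
vorticity <- function(u, dims, dx = 1, periodic = TRUE)
  vorticity_cpp(u, as.integer(dims), dx, periodic)

#' Apply inlet and outflow boundary conditions
#'
#' Inlet nodes are refilled with the equilibrium at the prescribed inlet
#' velocity; outflow nodes copy the distributions of their nearest interior
#' neighbour (zero-gradient extrapolation). Wall and solid nodes are handled
#' during streaming by half-way bounce-back.
#'
#' @param state a `fluid_state`.
#' @return The state, invisibly.
#' @export
apply_boundaries <- function(state) {
  lbm_apply_bc(state$f, state$flags, state$dims, state$u_inlet_lat, 1.0)
  invisible(state)
}

#' Effective relaxation-time field
#'
#' `tau_eff = 1/2 + 3 (nu_mol + nu_t)` per node, with `nu_t` from the WALE
#' closure on the finite-difference velocity gradient (the full gradient
#' tensor is needed for the g^2 term, which the non-equilibrium moment cannot
#' supply).
#'
#' @param state a `fluid_state`.
#' @param u current lattice velocity field.
#' @return Vector of relaxation times.
#' @export
effective_tau <- function(state, u) {
  if (!state$les) return(rep(state$scaling$tau0, nrow(u)))
  periodic <- all(state$flags == 0L)
  g <- lbm_velocity_gradient(u, state$dims, 1.0, periodic)
  nut <- wale_viscosity_cpp(g, state$Bw, 1.0)
  state$nu_t <- nut
  state$scaling$tau0 + 3 * nut
}

#' One collide-and-stream update
#'
#' Exactly the BGK evolution
#' `f_a(r + K_a dt, t + dt) - f_a(r, t) = -(f_a - f_a^eq)/tau + dt F_a`
#' with a per-node effective relaxation time (molecular + WALE) and Guo
#' forcing, followed by pull streaming with half-way bounce-back at walls and
#' the inlet/outflow refill.
#'
#' @param state a `fluid_state`.
#' @return The state, invisibly (updated in place).
#' @export
collide_and_stream <- function(state) {
  Ftot <- total_force(state)
  mac <- lbm_macroscopics(state$f, Ftot)
  tau <- effective_tau(state, mac$u)
  lbm_collide(state$f, mac$rho, mac$u, tau, Ftot)
  lbm_stream(state$f, state$fbuf, state$flags, state$dims)
  tmp <- state$f; state$f <- state$fbuf; state$fbuf <- tmp
  if (any(state$flags == 1L | state$flags == 2L)) apply_boundaries(state)
  state$step_count <- state$step_count + 1L
  invisible(state)
}

#' Total lattice mass of the state
#' @param state a `fluid_state` (or an n x 27 matrix).
#' @return Sum of all distribution values.
#' @export
total_mass <- function(state) {
  f <- if (inherits(state, "fluid_state")) state$f else state
  lbm_total_mass(f)
}

#' Run several fluid steps
#' @param state a `fluid_state`.
#' @param n_steps number of steps.
#' @return The state, invisibly.
#' @export
run_fluid <- function(state, n_steps) {
  for (i in seq_len(n_steps)) collide_and_stream(state)
  invisible(state)
}
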