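## Explicit thin-shell elastodynamics for leaves, petioles and branches.

#' Elastic material of the plant tissue
#'
#' Defaults follow measured cotton leaf properties: Young's modulus
#' 46.5 MPa, Poisson ratio 0.32, density 700 kg m^-3. Leaf thickness is not a
#' published constant; it is the dominant stiffness sensitivity and defaults
#' to 0.5 mm. Damping is mass-proportional, used to tame explicit ringing.
#'
#' @param E Young's modulus (Pa).
#' @param nu Poisson ratio.
#' @param rho density (kg m^-3).
#' @param thickness shell thickness (m).
#' @param damping mass-proportional damping coefficient (s^-1).
#' @return A `cf_material` list.
#' @export
cf_material <- function(E = 46.5e6, nu = 0.32, rho = 700,
                        thickness = 5e-4, damping = 5) {
  stopifnot(E > 0, nu >= 0, nu < 0.5, rho > 0, thickness > 0, damping >= 0)
  structure(list(E = E, nu = nu, rho = rho, thickness = thickness,
                 damping = damping), class = "cf_material")
}

new_shell_state <- function(nodes, tris, material, fixed,
                            thickness_per_tri = NULL) {
  st <- new.env(parent = emptyenv())
  nodes <- matrix(as.numeric(nodes), nrow(nodes), 3)
  st$nodes <- nodes + 0                  # n x 3, metres; explicit copies so
  st$rest_nodes <- nodes + 0             # in-place kernel updates cannot alias
  st$vel <- matrix(0, nrow(nodes), 3)
  st$accel <- matrix(0, nrow(nodes), 3)
  st$tris <- tris                        # m x 3, 1-based
  st$material <- material
  st$fixed <- fixed
  st$ext_force <- matrix(0, nrow(nodes), 3)
  tris0 <- tris - 1L
  pre <- shell_precompute(nodes, tris0)
  kb <- material$E * material$thickness^3 / (12 * (1 - material$nu^2))
  shell_rest_hinges(nodes, pre$hinges, pre$theta0, pre$hcoef, kb)
  st$pre <- pre
  st$mass <- shell_lumped_mass(nodes, tris0, material$rho, material$thickness)
  st$min_edge <- shell_min_edge(nodes, tris0)
  st$gravity <- c(0, 0, -9.81)
  class(st) <- c("shell_state", "environment")
  st
}

#' Build a structural shell from a plant model
#'
#' Triangle thin shells (constant-strain membrane + discrete-hinge bending)
#' for the leaves and petioles; the stem and branches are included as fixed
#' geometry. Constraints idealize the attachments as rigid clamps: all stem
#' and branch nodes are fixed, each petiole is clamped at its base ring, and
#' each leaf is clamped over a small basal patch around its petiole junction.
#' Node positions are converted from mm (plant frame) to metres.
#'
#' @param plant a `plant_model` (or a single `cf_mesh`, taken as one free
#'   leaf).
#' @param material a `cf_material`.
#' @param origin translation applied after mm-to-m conversion (metres),
#'   e.g. to centre the plant in a fluid domain.
#' @param clamp_radius basal clamp radius for leaves, as a fraction of the
#'   leaf bounding-radius.
#' @param include which plant components enter the shell.
#' @return A `shell_state` with a `components` attribute table mapping
#'   triangle ranges to plant components (type, kind, layer).
#' @export
build_shell <- function(plant, material = cf_material(),
                        origin = c(0, 0, 0), clamp_radius = 0.18,
                        include = c("stem", "branches", "petioles", "leaves")) {
  if (inherits(plant, "cf_mesh")) {
    nodes <- plant$vertices / 1000
    nodes <- sweep(nodes, 2, origin, "+")
    st <- new_shell_state(nodes, plant$faces, material,
                          logical(nrow(nodes)))
    st$components <- data.frame(type = "leaf", kind = NA, layer = NA,
                                tri_from = 1L, tri_to = nrow(plant$faces),
                                node_from = 1L, node_to = nrow(nodes))
    return(st)
  }
  stopifnot(inherits(plant, "plant_model"))
  comp <- list()
  add <- function(mesh, type, kind = NA, layer = NA, fixed) {
    comp[[length(comp) + 1L]] <<- list(mesh = mesh, type = type, kind = kind,
                                       layer = layer, fixed = fixed)
  }
  if ("stem" %in% include)
    add(plant$stem, "stem", fixed = rep(TRUE, nrow(plant$stem$vertices)))
  if ("branches" %in% include)
    for (b in plant$branches)
      add(b, "branch", fixed = rep(TRUE, nrow(b$vertices)))
  if ("petioles" %in% include)
    for (p in plant$petioles) {
      # clamp the base ring: first half of the tube vertices sit at the
      # branch end by construction
      n2 <- nrow(p$vertices) / 2
      add(p, "petiole",
          fixed = c(rep(TRUE, n2), rep(FALSE, nrow(p$vertices) - n2)))
    }
  if ("leaves" %in% include)
    for (lf in plant$leaves) {
      v <- lf$mesh$vertices
      # clamp a basal patch around the petiole junction so the leaf is
      # cantilevered from its attachment
      d_att <- sqrt(rowSums(sweep(v, 2, attach_pos(lf))^2))
      r_leaf <- max(sqrt(rowSums(sweep(v, 2, colMeans(v))^2)))
      add(lf$mesh, "leaf", kind = lf$kind, layer = lf$layer_id,
          fixed = d_att <= clamp_radius * r_leaf)
    }
  # assemble
  V <- list(); Fc <- list(); fixed <- list(); rows <- list()
  nv <- 0L; nt <- 0L
  for (i in seq_along(comp)) {
    m <- comp[[i]]$mesh
    V[[i]] <- m$vertices
    Fc[[i]] <- m$faces + nv
    fixed[[i]] <- comp[[i]]$fixed
    rows[[i]] <- data.frame(type = comp[[i]]$type,
                            kind = comp[[i]]$kind,
                            layer = comp[[i]]$layer,
                            tri_from = nt + 1L, tri_to = nt + nrow(m$faces),
                            node_from = nv + 1L,
                            node_to = nv + nrow(m$vertices),
                            stringsAsFactors = FALSE)
    nv <- nv + nrow(m$vertices)
    nt <- nt + nrow(m$faces)
  }
  nodes <- do.call(rbind, V) / 1000
  nodes <- sweep(nodes, 2, origin, "+")
  st <- new_shell_state(nodes, do.call(rbind, Fc), material,
                        unlist(fixed))
  st$components <- do.call(rbind, rows)
  st
}

attach_pos <- function(leaf_rec) {
  # the leaf mesh vertex that coincides with the petiole end: the one
  # closest to all others along the basal direction is simply the vertex
  # placed at the template attach point, which is the mesh vertex nearest
  # the petiole end; the petiole end equals that vertex by construction
  leaf_rec$mesh$vertices[which.min(
    sqrt(rowSums(sweep(leaf_rec$mesh$vertices, 2, leaf_rec$attach)^2))), ]
}

#' Internal elastic forces of the shell
#'
#' Saint Venant-Kirchhoff constant-strain-triangle membrane (plane stress)
#' plus discrete-hinge bending with plate rigidity E t^3 / (12 (1 - nu^2)).
#' Zero at the rest state; invariant under rigid motions; internal forces
#' over any free patch sum to zero (Newton's third law within the mesh).
#'
#' @param shell a `shell_state`.
#' @return n x 3 force matrix (N).
#' @export
internal_forces <- function(shell) {
  m <- shell$material
  shell_internal_forces(shell$nodes, shell$tris - 1L, shell$pre$dminv,
                        shell$pre$area0, shell$pre$hinges, shell$pre$theta0,
                        shell$pre$hcoef, m$E, m$nu, m$thickness)
}

#' Stable explicit time step estimate
#'
#' Courant-type bound from the smallest element edge and the membrane wave
#' speed sqrt(E / (rho (1 - nu^2))).
#'
#' @param shell a `shell_state`.
#' @param safety safety factor.
#' @return dt in seconds.
#' @export
stable_dt <- function(shell, safety = 0.4) {
  m <- shell$material
  c_w <- sqrt(m$E / (m$rho * (1 - m$nu^2)))
  safety * shell$min_edge / c_w
}

#' One explicit dynamics step
#'
#' Velocity-Verlet (kick-drift-kick) update with gravity, the externally
#' applied nodal force (`shell$ext_force`, e.g. from the fluid), and
#' mass-proportional damping. Fixed nodes never move.
#'
#' @param shell a `shell_state`.
#' @param dt time step (s); must not exceed the stability estimate.
#' @param gravity gravitational acceleration vector (m s^-2).
#' @return The shell, invisibly (updated in place).
#' @export
explicit_step <- function(shell, dt, gravity = shell$gravity) {
  if (dt > stable_dt(shell, safety = 1))
    stop(sprintf("dt = %.3g s exceeds the explicit stability estimate %.3g s",
                 dt, stable_dt(shell, safety = 1)))
  fint <- internal_forces(shell)
  shell_step(shell$nodes, shell$vel, shell$accel, fint, shell$ext_force,
             shell$mass, shell$fixed, dt, shell$material$damping, gravity)
  invisible(shell)
}

#' Run the shell to (damped) static equilibrium
#' @param shell a `shell_state`.
#' @param dt step size (default the stability estimate).
#' @param max_steps bail-out limit.
#' @param tol velocity norm (m/s) below which the state counts as static.
#' @param check_every steps between convergence checks.
#' @param gravity gravity vector; zero by default (pure load equilibrium).
#' @return The shell, invisibly.
#' @export
settle_shell <- function(shell, dt = stable_dt(shell), max_steps = 2e5,
                         tol = 1e-5, check_every = 500,
                         gravity = c(0, 0, 0)) {
  for (i in seq_len(max_steps)) {
    explicit_step(shell, dt, gravity = gravity)
    if (i %% check_every == 0) {
      vmax <- max(abs(shell$vel))
      if (vmax < tol) return(invisible(shell))
    }
  }
  stop("shell did not reach static equilibrium within ", max_steps, " steps")
}

#' Clamped-strip cantilever benchmark
#'
#' A rectangular strip clamped at one end under a uniform surface pressure,
#' run to static equilibrium with the explicit solver. In the
#' small-deflection regime the tip deflection approaches the Euler-Bernoulli
#' closed form q L^4 / (8 E I) with q = p w and I = w t^3 / 12. The
#' comparison assumes uniaxial (beam) stress, so the default material has
#' nu = 0.
#'
#' @param length strip length (m).
#' @param width strip width (m).
#' @param load uniform pressure (N m^-2), applied along -z.
#' @param material a `cf_material`; nu = 0 by default for the beam
#'   comparison.
#' @param n_len,n_wid elements along the strip and across it.
#' @param max_steps equilibrium iteration bail-out.
#' @return List with `deflection` (tip, m, positive down), `analytic`
#'   (q L^4/(8 E I)) and the shell state.
#' @export
cantilever_benchmark <- function(length = 0.1, width = 0.02, load = 0.2,
                                 material = cf_material(nu = 0, damping = 25),
                                 n_len = 40, n_wid = 4, max_steps = 5e5) {
  # one extra element column behind the clamp: fixing two node columns
  # enforces both zero displacement and zero slope at the root
  h <- length / n_len
  xs <- seq(-h, length, length.out = n_len + 2)
  ys <- seq(0, width, length.out = n_wid + 1)
  g <- expand.grid(x = xs, y = ys)
  nodes <- cbind(g$x, g$y, 0)
  id <- function(i, j) (j - 1L) * (n_len + 2L) + i
  # herringbone split (diagonal direction alternates row by row): an aligned
  # diagonal pattern lets the skew hinges exert a net twisting couple that
  # softens the strip artificially
  tris <- NULL
  for (j in seq_len(n_wid))
    for (i in seq_len(n_len + 1L)) {
      a <- id(i, j); b <- id(i + 1, j); c <- id(i + 1, j + 1); d <- id(i, j + 1)
      if (j %% 2 == 1) tris <- rbind(tris, c(a, b, c), c(a, c, d))
      else             tris <- rbind(tris, c(a, b, d), c(b, c, d))
    }
  fixed <- nodes[, 1] <= 0
  shell <- new_shell_state(nodes, tris, material, fixed)
  # consistent nodal load: pressure times the nodal tributary area, on the
  # free span only
  area_w <- shell_lumped_mass(nodes, tris - 1L, 1, 1)  # tributary areas
  area_w[fixed] <- 0
  shell$ext_force <- cbind(0, 0, -load * area_w)
  dt <- stable_dt(shell)
  settle_shell(shell, dt, max_steps = max_steps, tol = 1e-6 * length,
               gravity = c(0, 0, 0))
  tip <- which(shell$rest_nodes[, 1] == max(nodes[, 1]))
  deflection <- -mean(shell$nodes[tip, 3] - shell$rest_nodes[tip, 3])
  EI <- material$E * width * material$thickness^3 / 12
  q <- load * width
  list(deflection = deflection, analytic = q * length^4 / (8 * EI),
       shell = shell)
}

#' Total mass of the shell (sum of lumped nodal masses)
#' @param shell a `shell_state`.
#' @return kg.
#' @export
shell_mass <- function(shell) sum(shell$mass)
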