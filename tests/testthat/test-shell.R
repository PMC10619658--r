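test_that("internal forces vanish at rest and under rigid motions", {
  m <- strip_mesh(0.02, 0.01, 4, 2)
  sh <- canopyflow:::new_shell_state(m$nodes, m$tris, cf_material(),
                                     logical(nrow(m$nodes)))
  expect_lt(max(abs(internal_forces(sh))), 1e-12)
  rot <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0,
                              0, 0, 1), 3, 3, byrow = TRUE)
  sh$nodes <- sweep(m$nodes %*% t(rot(0.8)), 2, c(0.4, -0.1, 0.2), "+")
  expect_lt(max(abs(internal_forces(sh))), 1e-10)
})

test_that("internal forces are the exact gradient of the elastic energy", {
  m <- strip_mesh(0.02, 0.01, 2, 1)
  sh <- canopyflow:::new_shell_state(m$nodes, m$tris, cf_material(),
                                     logical(nrow(m$nodes)))
  set.seed(20)
  x <- m$nodes + matrix(rnorm(length(m$nodes), 0, 5e-4), nrow(m$nodes), 3)
  sh$nodes <- x
  fa <- internal_forces(sh)
  eps <- 1e-8
  fd <- fa * 0
  for (i in seq_len(nrow(x))) for (d in 1:3) {
    xp <- x; xp[i, d] <- xp[i, d] + eps
    xm <- x; xm[i, d] <- xm[i, d] - eps
    fd[i, d] <- -(oracle_shell_energy(sh, xp) -
                  oracle_shell_energy(sh, xm)) / (2 * eps)
  }
  expect_lt(max(abs(fa - fd)) / max(abs(fa)), 1e-5)
})

test_that("internal forces carry no net force or torque", {
  m <- strip_mesh(0.03, 0.015, 5, 2)
  sh <- canopyflow:::new_shell_state(m$nodes, m$tris, cf_material(),
                                     logical(nrow(m$nodes)))
  set.seed(21)
  sh$nodes <- m$nodes + matrix(rnorm(length(m$nodes), 0, 1e-3),
                               nrow(m$nodes), 3)
  f <- internal_forces(sh)
  expect_lt(max(abs(colSums(f))), 1e-12 * max(abs(f)) * nrow(f))
  tq <- colSums(cbind(sh$nodes[, 2] * f[, 3] - sh$nodes[, 3] * f[, 2],
                      sh$nodes[, 3] * f[, 1] - sh$nodes[, 1] * f[, 3],
                      sh$nodes[, 1] * f[, 2] - sh$nodes[, 2] * f[, 1]))
  expect_lt(max(abs(tq)), 1e-12 * max(abs(f)))
})

test_that("a built leaf shell carries the right mass and flat rest hinges", {
  mat <- cf_material()
  lm <- leaf_template_mesh(make_leaf_template("ovate", 4206.25))
  sh <- build_shell(cf_mesh(lm$vertices, lm$faces), mat)
  expect_lt(abs(shell_mass(sh) - mat$rho * mat$thickness * 4.20625e-3) /
            (mat$rho * mat$thickness * 4.20625e-3), 1e-9)
  expect_lt(max(abs(sh$pre$theta0)), 1e-12)        # flat leaf: zero hinges
})

test_that("stem and branch nodes of a plant shell are fully fixed", {
  p <- generate_plant(plant_spec(rng_seed = 5L, leaf_outline_n = 24L))
  sh <- build_shell(p)
  comp <- sh$components
  for (i in which(comp$type %in% c("stem", "branch"))) {
    idx <- seq(comp$node_from[i], comp$node_to[i])
    expect_true(all(sh$fixed[idx]))
  }
  # each leaf has at least one free and one clamped node
  for (i in which(comp$type == "leaf")) {
    idx <- seq(comp$node_from[i], comp$node_to[i])
    expect_true(any(sh$fixed[idx]) && any(!sh$fixed[idx]))
  }
})

test_that("fixed nodes never move and free fall is exact kinematics", {
  m <- strip_mesh(0.02, 0.01, 3, 2)
  mat <- cf_material(damping = 0)
  sh <- canopyflow:::new_shell_state(m$nodes, m$tris, mat,
                                     m$nodes[, 1] == 0)
  dt <- stable_dt(sh)
  # zero force, zero velocity: state unchanged (to force round-off)
  explicit_step(sh, dt, gravity = c(0, 0, 0))
  expect_lt(max(abs(sh$nodes - sh$rest_nodes)), 1e-15)
  # rigid free fall: internal forces vanish on the unconstrained mesh, so
  # displacement is exactly 1/2 g t^2 under velocity-Verlet
  sh2 <- canopyflow:::new_shell_state(m$nodes, m$tris, mat,
                                      logical(nrow(m$nodes)))
  nstep <- 2000L
  for (i in seq_len(nstep)) explicit_step(sh2, dt)
  t_tot <- nstep * dt
  drop <- sh2$rest_nodes[, 3] - sh2$nodes[, 3]
  expect_lt(max(abs(drop - 0.5 * 9.81 * t_tot^2)) / (0.5 * 9.81 * t_tot^2),
            1e-3)
  # clamped nodes stayed put in the constrained shell
  expect_identical(sh$nodes[sh$fixed, ], sh$rest_nodes[sh$fixed, ])
  expect_error(explicit_step(sh, 100 * dt), "stability")
})

test_that("damping makes the mechanical energy decay monotonically", {
  m <- strip_mesh(0.02, 0.01, 4, 2)
  mat <- cf_material(damping = 40)
  sh <- canopyflow:::new_shell_state(m$nodes, m$tris, mat,
                                     logical(nrow(m$nodes)))
  set.seed(22)
  sh$vel <- matrix(rnorm(length(m$nodes), 0, 0.1), nrow(m$nodes), 3)
  dt <- stable_dt(sh)
  energy <- function()
    0.5 * sum(sh$mass * rowSums(sh$vel^2)) +
      oracle_shell_energy(sh, sh$nodes)
  # sample every 1500 steps so the damping trend dominates the bounded
  # shadow-energy oscillation of the symplectic integrator
  es <- numeric(6)
  es[1] <- energy()
  for (b in 2:6) {
    for (i in 1:1500) explicit_step(sh, dt, gravity = c(0, 0, 0))
    es[b] <- energy()
  }
  expect_true(all(diff(es) < 0))
  expect_lt(es[6], 0.2 * es[1])
})

test_that("the clamped strip converges to the Euler-Bernoulli deflection", {
  r_coarse <- cantilever_benchmark(n_len = 20, n_wid = 2, max_steps = 2e6)
  r_fine <- cantilever_benchmark(n_len = 60, n_wid = 6, max_steps = 2e6)
  err_c <- abs(r_coarse$deflection - r_coarse$analytic) / r_coarse$analytic
  err_f <- abs(r_fine$deflection - r_fine$analytic) / r_fine$analytic
  expect_lt(err_f, 0.05)
  expect_lt(err_f, err_c)                          # refinement improves it
  # doubling E halves the deflection in the linear regime
  r2 <- cantilever_benchmark(n_len = 20, n_wid = 2, max_steps = 2e6,
                             material = cf_material(E = 2 * 46.5e6, nu = 0,
                                                    damping = 25))
  expect_lt(abs(r_coarse$deflection / r2$deflection - 2), 0.1)
})
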