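test_that("the D3Q27 velocity set satisfies its quadrature identities", {
  set <- d3q27()
  expect_equal(sum(set$w), 1, tolerance = 1e-15)
  expect_equal(colSums(set$w * set$K), c(0, 0, 0), tolerance = 1e-15)
  second <- t(set$K) %*% (set$w * set$K)
  expect_equal(second, diag(3) / 3, tolerance = 1e-15,
               ignore_attr = TRUE)
})

test_that("equilibrium reproduces its defining moments", {
  set <- d3q27()
  expect_equal(as.numeric(equilibrium(1, c(0, 0, 0))), set$w,
               tolerance = 1e-15)
  set.seed(5)
  rho <- runif(20, 0.5, 2)
  u <- matrix(runif(60, -0.08, 0.08), 20, 3)
  feq <- equilibrium(rho, u)
  mom <- oracle_moments(feq)              # brute-force 27-term sums
  expect_equal(mom$rho, rho, tolerance = 1e-12)
  expect_equal(mom$u, u, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(equilibrium(-1, c(0, 0, 0)), "positive")
  expect_error(equilibrium(1, c(0.4, 0, 0)), "0.3")
})

test_that("macroscopics invert equilibrium and match explicit sums", {
  feq <- equilibrium(2, c(0.03, -0.02, 0.01))
  mac <- macroscopics(feq)
  expect_equal(mac$rho, 2, tolerance = 1e-13)
  expect_equal(as.numeric(mac$u), c(0.03, -0.02, 0.01), tolerance = 1e-13)
  set.seed(6)
  f <- matrix(runif(27 * 10, 0.01, 0.1), 10, 27)
  mac <- macroscopics(f)
  mom <- oracle_moments(f)
  expect_equal(mac$rho, mom$rho, tolerance = 1e-13)
  expect_equal(mac$u, mom$u, tolerance = 1e-13, ignore_attr = TRUE)
})

test_that("equilibrium moments shift correctly under a velocity offset", {
  u0 <- c(0.02, -0.01, 0.03); du <- c(0.03, 0.02, -0.01)
  m1 <- oracle_moments(equilibrium(1.3, u0 + du))
  expect_equal(as.numeric(m1$u) - du, u0, tolerance = 1e-12)
  expect_equal(m1$rho, 1.3, tolerance = 1e-12)
})

test_that("one collide-and-stream step equals the hand-rolled update", {
  dims <- c(3L, 3L, 3L)
  sc <- unit_scaling(1, 1, nu_phys = 0.1)       # tau = 0.8
  st <- fluid_state(dims, sc, les = FALSE)
  set.seed(8)
  st$f <- st$f * (1 + 0.05 * runif(length(st$f)))
  expected <- oracle_lbm_step(st$f + 0, dims, sc$tau0)
  collide_and_stream(st)
  expect_equal(st$f, expected, tolerance = 1e-13)
})

test_that("uniform equilibrium is a fixed point and mass is conserved", {
  sc <- unit_scaling(1, 1, nu_phys = 1 / 6)
  st <- fluid_state(c(6, 6, 6), sc, les = FALSE, u0 = c(0.02, 0, -0.01))
  f0 <- st$f + 0
  run_fluid(st, 10)
  expect_equal(st$f, f0, tolerance = 1e-13)
  # perturbed periodic box: total mass invariant over 1000 steps
  st2 <- fluid_state(c(8, 8, 8), sc, les = TRUE)
  set.seed(9)
  st2$f <- st2$f * (1 + 0.02 * runif(length(st2$f)))
  m0 <- total_mass(st2)
  run_fluid(st2, 1000)
  expect_lt(abs(total_mass(st2) - m0) / m0, 1e-10)
})

test_that("velocity gradients are exact for linear fields, O(dx^2) for smooth", {
  dims <- c(8L, 8L, 8L)
  g <- expand.grid(x = 0:7, y = 0:7, z = 0:7)
  u <- cbind(0.3 * g$y, 0, 0)                      # u_x = a y
  gr <- velocity_gradient(u, dims, dx = 1, periodic = FALSE)
  expect_equal(gr[, 1 + 3 * 1], rep(0.3, nrow(u)), tolerance = 1e-13)
  expect_equal(max(abs(gr[, -(1 + 3 * 1)])), 0, tolerance = 1e-13)
  # uniform field: zero gradient
  gr0 <- velocity_gradient(matrix(1, prod(dims), 3), dims, 1, periodic = TRUE)
  expect_equal(max(abs(gr0)), 0, tolerance = 1e-14)
  # sin field converges at second order under grid refinement
  err <- vapply(c(16, 32), function(N) {
    gg <- expand.grid(x = 0:(N - 1), y = 0:(N - 1), z = 0:2)
    k <- 2 * pi / N
    uu <- cbind(sin(k * gg$x), 0, 0)
    gr <- velocity_gradient(uu, c(N, N, 3), dx = 1, periodic = TRUE)
    max(abs(gr[, 1] - k * cos(k * gg$x)))
  }, numeric(1))
  expect_gt(err[1] / err[2], 3.4)                  # ~4 for O(dx^2)
  expect_error(velocity_gradient(matrix(1, 4, 3), c(2, 2, 1), 1), "3 nodes")
})

test_that("WALE vanishes in pure shear and matches closed forms", {
  gshear <- matrix(0, 1, 9); gshear[1, 1 + 3 * 1] <- 0.7
  expect_identical(wale_viscosity(gshear)[1], 0)
  # rigid rotation: S = 0 but sym(g^2) is not traceless, and the closed
  # form is nu_t = (Bw Delta)^2 (2/3)^(1/4) |omega|
  W <- matrix(c(0, -1, 0.5, 1, 0, -0.2, -0.5, 0.2, 0), 3, 3, byrow = TRUE)
  omega <- sqrt(0.2^2 + 0.5^2 + 1^2)
  grot <- matrix(as.numeric(W), 1, 9)
  expect_equal(wale_viscosity(grot)[1], 0.325^2 * (2 / 3)^0.25 * omega,
               tolerance = 1e-12)
  expect_identical(wale_viscosity(matrix(0, 1, 9))[1], 0)
  set.seed(10)
  for (i in 1:20) {
    G <- matrix(rnorm(9), 3, 3)
    gv <- matrix(as.numeric(G), 1, 9)
    expect_equal(wale_viscosity(gv, Bw = 0.325, Delta = 1.7)[1],
                 oracle_wale(G, 0.325, 1.7), tolerance = 1e-12)
    expect_gte(wale_viscosity(gv)[1], 0)
  }
})

test_that("non-equilibrium strain is zero at equilibrium and symmetric", {
  feq <- equilibrium(rep(1, 8), matrix(0.02, 8, 3))
  S <- strain_from_nonequilibrium(feq, tau = 0.8)
  expect_lt(max(abs(S)), 1e-14)
  set.seed(11)
  f <- matrix(runif(27 * 5, 0.01, 0.1), 5, 27)
  S <- strain_from_nonequilibrium(f, tau = 0.9)
  Sm <- matrix(S[3, ], 3, 3)
  expect_identical(Sm, t(Sm))
})

test_that("Poiseuille channel flow matches the parabolic profile within 1%", {
  n <- c(3L, 3L, 34L)
  fl <- array(0L, dim = n); fl[, , 1] <- 3L; fl[, , n[3]] <- 3L
  sc <- unit_scaling(1, 1, nu_phys = 0.1)
  st <- fluid_state(n, sc, flags = as.integer(fl), les = FALSE)
  a <- 1e-6
  st$force <- matrix(rep(c(a, 0, 0), each = prod(n)), ncol = 3)
  run_fluid(st, 20000)
  u <- array(macroscopics(st)$u[, 1], dim = n)
  H <- n[3] - 2; zc <- (n[3] + 1) / 2; z <- seq_len(n[3])
  ana <- a / (2 * 0.1) * ((H / 2)^2 - (z - zc)^2)
  interior <- 2:(n[3] - 1)
  expect_lt(max(abs(u[2, 2, interior] - ana[interior])) / max(ana), 0.01)
})

test_that("shear-wave decay matches the molecular viscosity within 2%", {
  N <- 24L; nu <- 0.02; k <- 2 * pi / N
  g <- expand.grid(x = 0:(N - 1), y = 0:(N - 1), z = 0:(N - 1))
  u0 <- 0.02
  st <- fluid_state(c(N, N, N), unit_scaling(1, 1, nu), les = FALSE,
                    u0 = cbind(u0 * sin(k * g$x) * cos(k * g$y),
                               -u0 * cos(k * g$x) * sin(k * g$y), 0))
  E0 <- sum(rowSums(macroscopics(st)$u^2))
  steps <- 200L
  run_fluid(st, steps)
  E1 <- sum(rowSums(macroscopics(st)$u^2))
  rate <- -log(E1 / E0) / steps
  expect_lt(abs(rate / (4 * nu * k^2) - 1), 0.04)  # 24^3 preview; 48^3 in the
})                                                 # acceptance suite

test_that("an established uniform inlet flow passes through unchanged", {
  n <- c(12L, 12L, 12L)
  sc <- unit_scaling(1.5 / 12, choose_dt(1.5 / 12, 5, 0.05), u_max_phys = 5)
  fl <- make_flags(n, top = "inlet", bottom = "outflow", sides = "outflow")
  st <- fluid_state(n, sc, flags = fl, les = TRUE,
                    u_inlet_phys = c(0, 0, -5),
                    u0 = c(0, 0, -5 * sc$u_factor))
  run_fluid(st, 400)
  sp <- sqrt(rowSums(macroscopics(st)$u^2)) / sc$u_factor
  expect_lt(max(abs(sp[st$flags == 0L] - 5)) / 5, 0.01)
  # zero inlet: fluid stays at rest
  st0 <- fluid_state(n, sc, flags = fl, les = TRUE,
                     u_inlet_phys = c(0, 0, 0))
  run_fluid(st0, 100)
  expect_lt(max(abs(macroscopics(st0)$u)), 1e-12)
})

test_that("vorticity recovers closed forms", {
  N <- 9L
  g <- expand.grid(x = 0:(N - 1), y = 0:(N - 1), z = 0:(N - 1))
  om <- 0.3
  u <- cbind(-om * (g$y - 4), om * (g$x - 4), 0)   # rigid rotation
  w <- vorticity(u, c(N, N, N), dx = 1, periodic = FALSE)
  inner <- g$x %in% 1:7 & g$y %in% 1:7 & g$z %in% 1:7
  expect_equal(w[inner], rep(2 * om, sum(inner)), tolerance = 1e-12)
  expect_lt(max(vorticity(matrix(1, N^3, 3), c(N, N, N), 1)), 1e-14)
})

test_that("instability is reported with a location, not silently produced", {
  sc <- unit_scaling(1, 1, nu_phys = 1e-9)
  st <- fluid_state(c(4, 4, 4), sc, les = FALSE)
  mac <- macroscopics(st$f)
  expect_error(
    canopyflow:::lbm_collide(st$f, mac$rho, mac$u,
                             rep(0.4, 64), NULL),
    "tau <= 0.5")
})
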