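# Shared fixtures and independent oracles, built in code at test time.

# herringbone rectangular strip (row-alternating diagonals)
strip_mesh <- function(L, W, nl, nw, x0 = 0) {
  xs <- seq(x0, L, length.out = nl + 1L)
  ys <- seq(0, W, length.out = nw + 1L)
  ncx <- length(xs)
  g <- expand.grid(x = xs, y = ys)
  nodes <- cbind(g$x, g$y, 0)
  id <- function(i, j) (j - 1L) * ncx + i
  tris <- NULL
  for (j in seq_len(nw))
    for (i in seq_len(ncx - 1L)) {
      a <- id(i, j); b <- id(i + 1, j); c <- id(i + 1, j + 1); d <- id(i, j + 1)
      if (j %% 2 == 1) tris <- rbind(tris, c(a, b, c), c(a, c, d))
      else             tris <- rbind(tris, c(a, b, d), c(b, c, d))
    }
  list(nodes = nodes, tris = tris)
}

# brute-force D3Q27 moment sums (independent of the solver's C++ loops)
oracle_moments <- function(f) {
  set <- d3q27()
  rho <- as.numeric(f %*% rep(1, 27))
  u <- (f %*% set$K) / rho
  list(rho = rho, u = u)
}

# term-by-term WALE evaluation from a 3x3 gradient matrix
oracle_wale <- function(G, Bw = 0.325, Delta = 1) {
  S <- (G + t(G)) / 2
  G2 <- G %*% G
  Sd <- (G2 + t(G2)) / 2 - diag(3) * sum(diag(G2)) / 3
  SS <- sum(S * S); SdSd <- sum(Sd * Sd)
  den <- SS^(5 / 2) + SdSd^(5 / 4)
  if (den == 0) return(0)
  (Bw * Delta)^2 * SdSd^(3 / 2) / den
}

# hand-rolled single BGK collide-and-stream step on a periodic lattice
oracle_lbm_step <- function(f, dims, tau) {
  set <- d3q27()
  n <- prod(dims)
  mom <- oracle_moments(f)
  feq <- matrix(0, n, 27)
  for (a in 1:27) {
    cu <- mom$u %*% set$K[a, ]
    usq <- rowSums(mom$u^2)
    feq[, a] <- set$w[a] * mom$rho * (1 + 3 * cu + 4.5 * cu^2 - 1.5 * usq)
  }
  fpost <- f - (f - feq) / tau
  fnew <- matrix(0, n, 27)
  idx <- function(x, y, z) 1 + x + dims[1] * (y + dims[2] * z)
  for (z in 0:(dims[3] - 1)) for (y in 0:(dims[2] - 1)) for (x in 0:(dims[1] - 1))
    for (a in 1:27) {
      s <- c(x, y, z) - set$K[a, ]
      s <- (s + dims) %% dims
      fnew[idx(x, y, z), a] <- fpost[idx(s[1], s[2], s[3]), a]
    }
  fnew
}

# total energy of a shell state (membrane StVK + hinge bending), used as the
# independent oracle for internal_forces via finite differences
oracle_shell_energy <- function(shell, x) {
  mat <- shell$material
  mu <- mat$E / (2 * (1 + mat$nu)); lam <- mat$E * mat$nu / (1 - mat$nu^2)
  rest <- shell$rest_nodes; tris <- shell$tris
  Etot <- 0
  for (t in seq_len(nrow(tris))) {
    i <- tris[t, ]
    X <- rest[i, ]; xx <- x[i, ]
    u1 <- X[2, ] - X[1, ]; u2 <- X[3, ] - X[1, ]
    nrm <- pracma_cross(u1, u2)
    A0 <- 0.5 * sqrt(sum(nrm^2))
    e1 <- u1 / sqrt(sum(u1^2))
    nz <- nrm / sqrt(sum(nrm^2))
    e2 <- pracma_cross(nz, e1)
    Dm <- matrix(c(sum(u1 * e1), 0, sum(u2 * e1), sum(u2 * e2)), 2, 2)
    Fg <- cbind(xx[2, ] - xx[1, ], xx[3, ] - xx[1, ]) %*% solve(Dm)
    Eg <- 0.5 * (t(Fg) %*% Fg - diag(2))
    Etot <- Etot + A0 * mat$thickness *
      (0.5 * lam * sum(diag(Eg))^2 + mu * sum(Eg^2))
  }
  hinges <- shell$pre$hinges
  for (h in seq_len(nrow(hinges))) {
    iv <- hinges[h, ] + 1
    th <- dihedral_angle(x[iv[1], ], x[iv[2], ], x[iv[3], ], x[iv[4], ])
    Etot <- Etot + 0.5 * shell$pre$hcoef[h] * (th - shell$pre$theta0[h])^2
  }
  Etot
}

pracma_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

dihedral_angle <- function(x0, x1, x2, x3) {
  e <- x1 - x0
  nA <- pracma_cross(e, x2 - x0)
  nB <- pracma_cross(x3 - x0, e)
  atan2(sum(pracma_cross(nA, nB) * e) / sqrt(sum(e^2)), sum(nA * nB))
}

# small single-leaf shell clamped near its base, centred in a fluid domain
single_leaf_shell <- function(material, origin = c(0.75, 0.72, 0.8),
                              area = 4206.25, n_outline = 48,
                              clamp = 0.025) {
  tpl <- make_leaf_template("ovate", area, n = n_outline)
  lm <- leaf_template_mesh(tpl)
  shell <- build_shell(cf_mesh(lm$vertices, lm$faces), material,
                       origin = origin)
  att <- which.min(shell$nodes[, 2])
  d <- sqrt(rowSums(sweep(shell$nodes, 2, shell$nodes[att, ])^2))
  shell$fixed <- d < clamp
  shell
}
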