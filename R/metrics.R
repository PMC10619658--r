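## Validation and reporting: velocity probes, NMAE, linear fit, canopy
## relative-height profiles.

#' Lattice coordinates of physical points
#'
#' Lattice nodes are cell-centred: node i (0-based) sits at (i + 1/2) dx.
#'
#' @param x points in metres (n x 3 or length-3).
#' @param dx lattice spacing (m).
#' @return Same shape, in lattice units.
#' @export
lattice_coords <- function(x, dx) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 3)
  x / dx - 0.5
}

#' A set of velocity sampling points
#'
#' @param points n x 3 matrix of coordinates (m).
#' @param layer character vector of layer labels (recycled).
#' @return A `probe_set` data.frame.
#' @export
probe_set <- function(points, layer = "all") {
  points <- matrix(as.numeric(points), ncol = 3)
  data.frame(x = points[, 1], y = points[, 2], z = points[, 3],
             layer = rep_len(layer, nrow(points)))
}

#' Default 3 x 3 probe grid (three layers, three points each)
#'
#' Field measurements give no printed probe coordinates, so a smoke-test
#' grid is provided: three points per canopy layer at the layer mid-heights.
#'
#' @param domain_size cube edge (m).
#' @param layer_mid_z mid-heights of the lower/middle/upper layers (m).
#' @return A `probe_set`.
#' @export
default_probe_grid <- function(domain_size = 1.5,
                               layer_mid_z = c(0.25, 0.70, 1.10)) {
  cx <- domain_size / 2
  off <- domain_size * c(-0.1, 0, 0.1)
  pts <- do.call(rbind, lapply(seq_along(layer_mid_z), function(i)
    cbind(cx + off, cx, layer_mid_z[i])))
  probe_set(pts, layer = rep(c("lower", "middle", "upper"), each = 3))
}

trilinear <- function(u, dims, p) {
  # p in lattice coordinates; clamp to the cell grid
  p <- pmin(pmax(p, 0), dims - 1 - 1e-9)
  i0 <- floor(p); fr <- p - i0
  val <- numeric(ncol(u))
  for (dx_ in 0:1) for (dy_ in 0:1) for (dz_ in 0:1) {
    w <- prod(ifelse(c(dx_, dy_, dz_) == 1, fr, 1 - fr))
    if (w == 0) next
    i <- pmin(i0 + c(dx_, dy_, dz_), dims - 1)
    idx <- 1 + i[1] + dims[1] * (i[2] + dims[2] * i[3])
    val <- val + w * u[idx, ]
  }
  val
}

#' Sample airflow speed at probe points
#'
#' Trilinear interpolation of the velocity magnitude at each probe, either
#' from a `fluid_state` (current field) or from every frame of a
#' `simulation_record` that stored the fluid field.
#'
#' @param x a `fluid_state` or `simulation_record`.
#' @param probes a `probe_set`.
#' @return data.frame point_id, layer, time_s, speed_mps.
#' @export
sample_velocity <- function(x, probes) {
  pts <- as.matrix(probes[, c("x", "y", "z")])
  sample_field <- function(u_phys, dims, dx, time) {
    pl <- lattice_coords(pts, dx)
    if (any(pl < -0.5 - 1e-9) || any(sweep(pl, 2, dims - 0.5) > 1e-9))
      stop("probe point outside the fluid domain")
    sp <- vapply(seq_len(nrow(pl)), function(i)
      sqrt(sum(trilinear(u_phys, dims, pl[i, ])^2)), numeric(1))
    data.frame(point_id = seq_len(nrow(pl)), layer = probes$layer,
               time_s = time, speed_mps = sp)
  }
  if (inherits(x, "fluid_state")) {
    mac <- lbm_macroscopics(x$f, NULL)
    u_phys <- mac$u / x$scaling$u_factor
    return(sample_field(u_phys, x$dims, x$scaling$dx, NA_real_))
  }
  stopifnot(inherits(x, "simulation_record"))
  frames <- Filter(function(fr) !is.null(fr$u), x$frames)
  if (length(frames) == 0) stop("record stored no fluid fields")
  do.call(rbind, lapply(frames, function(fr)
    sample_field(fr$u, x$dims, x$scaling$dx, fr$time)))
}

#' Normalized mean absolute error (percent)
#'
#' `NMAE = mean(|s - m|) / mean(m) * 100` with normalization by the mean of
#' the measured series (the commonest convention); `"pointwise"` divides
#' each absolute error by its own measured value before averaging.
#'
#' @param simulated,measured equal-length numeric series.
#' @param normalization `"mean"` or `"pointwise"`.
#' @return NMAE in percent.
#' @export
nmae <- function(simulated, measured, normalization = c("mean", "pointwise")) {
  normalization <- match.arg(normalization)
  if (length(simulated) != length(measured) || length(measured) < 1)
    stop("series must have equal, positive length")
  if (normalization == "mean") {
    mm <- mean(measured)
    if (mm == 0) stop("mean of measured series is zero")
    100 * mean(abs(simulated - measured)) / mm
  } else {
    if (any(measured == 0)) stop("pointwise normalization needs nonzero values")
    100 * mean(abs(simulated - measured) / abs(measured))
  }
}

#' Linear fit of measured on simulated values
#'
#' Ordinary least squares M = a S + b with the coefficient of
#' determination R^2 = 1 - SS_res / SS_tot.
#'
#' @param simulated,measured equal-length numeric series (n >= 2,
#'   non-constant `simulated`).
#' @return A `fit_result`: slope, intercept, r_squared, n.
#' @export
linear_fit <- function(simulated, measured) {
  if (length(simulated) != length(measured) || length(simulated) < 2)
    stop("need at least two paired values")
  if (stats::sd(simulated) == 0) stop("simulated values are constant")
  fit <- stats::lm(measured ~ simulated)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n = length(simulated)),
            class = "fit_result")
}

#' Canopy relative-height profiles
#'
#' Ten (by default) equal height bands across the canopy, each reporting the
#' windward area and porosity of its leaves plus the band-mean airflow speed
#' and vorticity from the stored fluid field.
#'
#' @param record a `simulation_record` with at least one stored fluid frame.
#' @param n_bands number of canopy-relative-height bands.
#' @param mode porosity convention passed to [stratified_porosity()].
#' @param resolution render resolution.
#' @return data.frame crh, A_mm2, S_mm2, porosity, mean_speed_mps,
#'   mean_vorticity_s (NA porosity for empty bands).
#' @export
crh_profiles <- function(record, n_bands = 10L, mode = "optical",
                         resolution = 192L) {
  lv <- leaf_rows(record$components)
  has_leaves <- nrow(lv) > 0
  # canopy height range from the rest leaf geometry (or the full domain for
  # an empty canopy)
  if (has_leaves) {
    idx <- unlist(lapply(seq_len(nrow(lv)), function(i)
      seq(lv$node_from[i], lv$node_to[i])))
    zr <- range(record$rest_nodes[idx, 3])
  } else {
    zr <- c(0, record$scaling$dx * record$dims[3])
  }
  edges <- seq(zr[1], zr[2], length.out = n_bands + 1L)
  crh <- seq_len(n_bands) * round(100 / n_bands)

  por <- rep(NA_real_, n_bands); A <- rep(NA_real_, n_bands)
  S <- rep(NA_real_, n_bands)
  if (has_leaves) {
    ts <- stratified_porosity(record, bands = "crh", n_crh = n_bands,
                              mode = mode, resolution = resolution)
    last <- ts[ts$time_s == max(ts$time_s), ]
    ord <- match(paste0(crh, "%"), last$band)
    por <- last$P[ord]; A <- last$A_mm2[ord]; S <- last$S_mm2[ord]
  }
  frames <- Filter(function(fr) !is.null(fr$u), record$frames)
  if (length(frames) == 0) stop("record stored no fluid fields")
  fr <- frames[[length(frames)]]
  dx <- record$scaling$dx; dims <- record$dims
  zc <- (rep(seq_len(dims[3]), each = 1) - 0.5) * dx   # node heights
  node_z <- rep(zc, each = dims[1] * dims[2])
  speed <- sqrt(rowSums(fr$u^2))
  vort <- vorticity(fr$u, dims, dx, periodic = FALSE)
  ms <- numeric(n_bands); mv <- numeric(n_bands)
  for (b in seq_len(n_bands)) {
    inb <- node_z >= edges[b] & node_z < edges[b + 1L] + 1e-12
    ms[b] <- mean(speed[inb]); mv[b] <- mean(vort[inb])
  }
  data.frame(crh = crh, A_mm2 = A, S_mm2 = S, porosity = por,
             mean_speed_mps = ms, mean_vorticity_s = mv)
}
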