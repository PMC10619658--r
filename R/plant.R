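#' @useDynLib canopyflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif
#' @importFrom grDevices chull
NULL

## ---- RNG hygiene -----------------------------------------------------------

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## ---- Polygons and triangle meshes ------------------------------------------

#' Signed polygon area (shoelace formula)
#'
#' @param xy two-column matrix of vertices of a closed polygon (last vertex
#'   implicitly joined to the first).
#' @return Signed area; positive for counter-clockwise winding.
#' @export
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Construct a triangle mesh
#'
#' @param vertices numeric n x 3 matrix (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @return An object of class `cf_mesh`.
#' @export
cf_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  stopifnot(nrow(vertices) >= 3, max(faces) <= nrow(vertices), min(faces) >= 1)
  structure(list(vertices = vertices, faces = faces), class = "cf_mesh")
}

#' Total surface area of a triangle mesh
#'
#' Sum of the areas of all triangles, each half the norm of the edge cross
#' product.
#'
#' @param mesh a `cf_mesh`.
#' @return Area in the square of the mesh's length unit (mm^2 for plant
#'   meshes). A fully degenerate (zero-area) mesh returns 0 with a warning.
#' @export
mesh_area <- function(mesh) {
  a <- mesh_area_cpp(mesh$vertices, mesh$faces)
  if (a == 0) warning("mesh has zero area (degenerate triangles)")
  a
}

# Fan-triangulate a star-shaped polygon about its centroid.
triangulate_polygon <- function(xy) {
  n <- nrow(xy)
  cen <- colMeans(xy)
  vertices <- cbind(rbind(cen, xy), 0)
  faces <- cbind(1L, 1L + seq_len(n), 1L + c(seq_len(n)[-1L], 1L))
  cf_mesh(vertices, faces)
}

## ---- Leaf templates --------------------------------------------------------

leaf_kinds <- c("ovate", "three_lobed", "five_lobed")

# Unit outlines, centred so the petiole attaches at the base (minimum y).
# The ovate is an egg curve (ellipse with a linear y-modulation of width);
# lobed leaves are radial cosine-lobed polar curves. Shapes are fixed,
# documented constants; only overall scale varies with the target area.
leaf_unit_outline <- function(kind, n = 256L) {
  s <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  xy <- switch(kind,
    ovate = {
      y <- cos(s)                       # base at s = pi
      x <- 0.72 * sin(s) * (1 - 0.25 * cos(s))
      cbind(x, y)
    },
    three_lobed = {
      r <- 1 + 0.42 * cos(3 * (s - pi / 2))
      cbind(r * sin(s), r * cos(s))     # lobe pointing away from the base
    },
    five_lobed = {
      r <- 1 + 0.38 * cos(5 * (s - pi / 2))
      cbind(r * sin(s), r * cos(s))
    },
    stop("unknown leaf kind: ", kind)
  )
  colnames(xy) <- c("x", "y")
  xy
}

#' Parametric leaf outline template scaled to a target planform area
#'
#' Generates a closed 2D outline of one of the three cotton leaf classes
#' (ovate, three-lobed, five-lobed) and scales it so its planform (windward)
#' area matches `target_area`. The default areas used throughout the package
#' are 4206.25, 7859.10 and 9823.00 mm^2 for the three classes.
#'
#' @param kind one of `"ovate"`, `"three_lobed"`, `"five_lobed"`.
#' @param target_area planform area in mm^2.
#' @param n number of outline vertices.
#' @return A `leaf_template`: list with `kind`, `outline` (n x 2, mm),
#'   `target_area`, and `attach_point` (2-vector on the outline, at the leaf
#'   base where the petiole joins).
#' @export
make_leaf_template <- function(kind, target_area, n = 256L) {
  kind <- match.arg(kind, leaf_kinds)
  if (!is.numeric(target_area) || length(target_area) != 1L || target_area <= 0)
    stop("target_area must be a positive number")
  unit <- leaf_unit_outline(kind, n)
  a0 <- abs(polygon_area(unit))
  outline <- unit * sqrt(target_area / a0)
  attach_idx <- which.min(outline[, 2])
  structure(
    list(kind = kind, outline = outline, target_area = target_area,
         attach_point = outline[attach_idx, ], attach_index = attach_idx),
    class = "leaf_template")
}

#' Triangle mesh of a leaf template (z = 0 plane)
#' @param template a `leaf_template`.
#' @return A `cf_mesh` in mm with the leaf in the z = 0 plane.
#' @export
leaf_template_mesh <- function(template) triangulate_polygon(template$outline)

## ---- Plant specification ---------------------------------------------------

#' Cotton plant specification
#'
#' Phenotypic parameters of the virtual plant. Defaults follow field-measured
#' cotton morphometry: 130 cm tall main stem divided into 20 segments,
#' fruiting branches on nodes 5-20, leaf class fractions 20/55/25% for
#' ovate/three-lobed/five-lobed with windward areas 4206.25/7859.10/9823.00
#' mm^2, and the canopy stratified at 0-50 (lower), 50-90 (middle) and
#' 90-130 cm (upper).
#'
#' @param height plant height in cm.
#' @param n_stem_segments number of main-stem segments.
#' @param fruiting_node_range inclusive node index range bearing fruiting
#'   branches.
#' @param leaf_type_fractions named fractions for the three leaf classes
#'   (must sum to 1).
#' @param leaf_areas named planform areas (mm^2) for the three classes.
#' @param layer_bounds strictly increasing layer boundary heights (cm).
#' @param petiole_length_mean,petiole_length_sd petiole length distribution
#'   (mm); measured distributions are not published, so these are
#'   configurable placeholders.
#' @param petiole_diameter_mean,petiole_diameter_sd petiole diameter (mm).
#' @param leaves_per_branch leaves on each fruiting branch.
#' @param branch_internode_length spacing between leaves on a branch (mm).
#' @param stem_diameter main stem diameter (mm).
#' @param branch_diameter fruiting branch diameter (mm).
#' @param leaf_tilt_sd s.d. of the random leaf plane tilt (degrees).
#' @param azimuth_jitter_sd s.d. of branch azimuth jitter around the 137.5
#'   degree spiral (degrees).
#' @param leaf_outline_n outline vertices per leaf mesh (also the fan
#'   triangle count); coarser meshes keep the structural solver's stable
#'   time step workable in coupled runs.
#' @param rng_seed integer seed making the generated plant reproducible.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(height = 130,
                       n_stem_segments = 20L,
                       fruiting_node_range = c(5L, 20L),
                       leaf_type_fractions = c(ovate = 0.20,
                                               three_lobed = 0.55,
                                               five_lobed = 0.25),
                       leaf_areas = c(ovate = 4206.25,
                                      three_lobed = 7859.10,
                                      five_lobed = 9823.00),
                       layer_bounds = c(0, 50, 90, 130),
                       petiole_length_mean = 60, petiole_length_sd = 10,
                       petiole_diameter_mean = 3, petiole_diameter_sd = 0.3,
                       leaves_per_branch = 3L,
                       branch_internode_length = 80,
                       stem_diameter = 12,
                       branch_diameter = 5,
                       leaf_tilt_sd = 5,
                       azimuth_jitter_sd = 10,
                       leaf_outline_n = 48L,
                       rng_seed = 1L) {
  spec <- list(height = height, n_stem_segments = as.integer(n_stem_segments),
               fruiting_node_range = as.integer(fruiting_node_range),
               leaf_type_fractions = leaf_type_fractions,
               leaf_areas = leaf_areas, layer_bounds = layer_bounds,
               petiole_length_mean = petiole_length_mean,
               petiole_length_sd = petiole_length_sd,
               petiole_diameter_mean = petiole_diameter_mean,
               petiole_diameter_sd = petiole_diameter_sd,
               leaves_per_branch = as.integer(leaves_per_branch),
               branch_internode_length = branch_internode_length,
               stem_diameter = stem_diameter,
               branch_diameter = branch_diameter,
               leaf_tilt_sd = leaf_tilt_sd,
               azimuth_jitter_sd = azimuth_jitter_sd,
               leaf_outline_n = as.integer(leaf_outline_n),
               rng_seed = as.integer(rng_seed))
  validate_plant_spec(spec)
  structure(spec, class = "plant_spec")
}

validate_plant_spec <- function(spec) {
  stopifnot(spec$height > 0, spec$n_stem_segments >= 1)
  if (abs(sum(spec$leaf_type_fractions) - 1) > 1e-9)
    stop("leaf_type_fractions must sum to 1")
  if (any(diff(spec$layer_bounds) <= 0))
    stop("layer_bounds must be strictly increasing")
  rng <- spec$fruiting_node_range
  if (rng[1] < 1 || rng[2] > spec$n_stem_segments || rng[1] > rng[2])
    stop("fruiting_node_range must lie within [1, n_stem_segments]")
  if (spec$branch_internode_length <= 0 || spec$leaves_per_branch < 1)
    stop("infeasible branch geometry")
  invisible(spec)
}

#' Write / read a plant specification as YAML
#' @param spec a `plant_spec`.
#' @param path file path.
#' @return `read_plant_spec` returns the reconstructed `plant_spec`.
#' @export
write_plant_spec <- function(spec, path) {
  x <- unclass(spec)
  # named vectors become YAML maps (write_yaml drops vector names)
  x$leaf_type_fractions <- as.list(x$leaf_type_fractions)
  x$leaf_areas <- as.list(x$leaf_areas)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_plant_spec
#' @export
read_plant_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$leaf_type_fractions <- unlist(raw$leaf_type_fractions)
  raw$leaf_areas <- unlist(raw$leaf_areas)
  raw$layer_bounds <- unlist(raw$layer_bounds)
  raw$fruiting_node_range <- as.integer(unlist(raw$fruiting_node_range))
  do.call(plant_spec, raw)
}

## ---- Leaf kind schedule (largest remainder) --------------------------------

#' Integer leaf-class counts by largest-remainder apportionment
#'
#' For a total of `n` leaves, returns per-class counts whose deviation from
#' `n * fraction` is below 1 for every class.
#'
#' @param n total leaf count.
#' @param fractions named fractions summing to 1.
#' @return Named integer vector of counts summing to `n`.
#' @export
apportion_leaf_kinds <- function(n, fractions) {
  quota <- n * fractions
  counts <- floor(quota)
  rem <- quota - counts
  short <- n - sum(counts)
  if (short > 0) {
    take <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[take] <- counts[take] + 1
  }
  storage.mode(counts) <- "integer"
  counts
}

## ---- Mesh primitives -------------------------------------------------------

# Open cylinder tube between two 3D points.
tube_mesh <- function(p0, p1, diameter, n_around = 8L) {
  axis <- p1 - p0
  len <- sqrt(sum(axis^2))
  if (len <= 0) stop("zero-length tube")
  az <- axis / len
  ref <- if (abs(az[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * az) * az; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(az[2] * e1[3] - az[3] * e1[2],
          az[3] * e1[1] - az[1] * e1[3],
          az[1] * e1[2] - az[2] * e1[1])
  th <- seq(0, 2 * pi, length.out = n_around + 1L)[-(n_around + 1L)]
  r <- diameter / 2
  ring <- t(vapply(th, function(t) r * (cos(t) * e1 + sin(t) * e2),
                   numeric(3)))
  v <- rbind(sweep(ring, 2, p0, "+"), sweep(ring, 2, p1, "+"))
  f <- NULL
  for (i in seq_len(n_around)) {
    j <- if (i == n_around) 1L else i + 1L
    f <- rbind(f,
               c(i, j, n_around + i),
               c(j, n_around + j, n_around + i))
  }
  cf_mesh(v, f)
}

rotation_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

rotation_axis <- function(axis, deg) {
  a <- deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  c <- cos(a); s <- sin(a); C <- 1 - c
  matrix(c(u[1]^2 * C + c, u[1] * u[2] * C - u[3] * s, u[1] * u[3] * C + u[2] * s,
           u[2] * u[1] * C + u[3] * s, u[2]^2 * C + c, u[2] * u[3] * C - u[1] * s,
           u[3] * u[1] * C - u[2] * s, u[3] * u[2] * C + u[1] * s, u[3]^2 * C + c),
         3, 3, byrow = TRUE)
}

transform_mesh <- function(mesh, rot = diag(3), shift = c(0, 0, 0)) {
  cf_mesh(sweep(mesh$vertices %*% t(rot), 2, shift, "+"), mesh$faces)
}

## ---- Plant generation ------------------------------------------------------

#' Generate a 3D virtual cotton plant
#'
#' Builds the main stem, straight fruiting branches on the specified nodes,
#' petioles and leaves as triangle meshes (mm, z up, root at the origin).
#' Branch azimuths follow an alternate 137.5-degree spiral with seedable
#' jitter; leaf classes are apportioned over the total leaf count by largest
#' remainder and assigned in a seeded random order; each leaf is labelled
#' with its canopy layer from its attachment height.
#'
#' @param spec a `plant_spec`.
#' @return A `plant_model`: list with `stem` (mesh), `branches`, `petioles`
#'   (lists of meshes), `leaves` (list of records: `mesh`, `kind`, `layer_id`,
#'   `attach` point mm, `attach_height_cm`), `root_position` and the `spec`.
#' @export
generate_plant <- function(spec = plant_spec()) {
  validate_plant_spec(spec)
  with_seed(spec$rng_seed, {
    h_mm <- spec$height * 10
    seg <- h_mm / spec$n_stem_segments
    stem <- tube_mesh(c(0, 0, 0), c(0, 0, h_mm), spec$stem_diameter)
    nodes <- seq(spec$fruiting_node_range[1], spec$fruiting_node_range[2])
    n_branches <- length(nodes)
    n_leaves <- n_branches * spec$leaves_per_branch
    counts <- apportion_leaf_kinds(n_leaves, spec$leaf_type_fractions)
    kinds <- sample(rep(names(counts), counts))
    templates <- lapply(stats::setNames(leaf_kinds, leaf_kinds), function(k)
      make_leaf_template(k, spec$leaf_areas[[k]], n = spec$leaf_outline_n))

    branches <- list(); petioles <- list(); leaves <- list()
    li <- 0L
    for (bi in seq_along(nodes)) {
      z <- nodes[bi] * seg
      azim <- (bi - 1) * 137.5 + rnorm(1, 0, spec$azimuth_jitter_sd)
      dirv <- rotation_z(azim) %*% c(1, 0, 0)
      blen <- spec$leaves_per_branch * spec$branch_internode_length
      p1 <- c(0, 0, z) + blen * as.numeric(dirv)
      branches[[bi]] <- tube_mesh(c(0, 0, z), p1, spec$branch_diameter)
      for (k in seq_len(spec$leaves_per_branch)) {
        li <- li + 1L
        attach <- c(0, 0, z) +
          k * spec$branch_internode_length * as.numeric(dirv)
        plen <- max(5, rnorm(1, spec$petiole_length_mean,
                             spec$petiole_length_sd))
        pdia <- max(0.5, rnorm(1, spec$petiole_diameter_mean,
                               spec$petiole_diameter_sd))
        pet_azim <- azim + rnorm(1, 0, 30)
        pdir <- as.numeric(rotation_z(pet_azim) %*% c(1, 0, 0))
        pend <- attach + plen * pdir
        petioles[[li]] <- tube_mesh(attach, pend, pdia)
        kind <- kinds[li]
        tpl <- templates[[kind]]
        lm0 <- leaf_template_mesh(tpl)
        # put the attach point at the origin; the template is already flat
        # in the horizontal plane extending along +y, so spin it into the
        # petiole azimuth and add a small random tilt out of the plane
        v <- sweep(lm0$vertices, 2, c(tpl$attach_point, 0))
        lm <- cf_mesh(v, lm0$faces)
        rot_az <- rotation_z(pet_azim - 90)              # leaf along petiole
        tilt_ax <- as.numeric(rotation_z(runif(1, 0, 360)) %*% c(1, 0, 0))
        rot_tilt <- rotation_axis(tilt_ax, rnorm(1, 0, spec$leaf_tilt_sd))
        lm <- transform_mesh(lm, rot_tilt %*% rot_az, pend)
        leaves[[li]] <- list(mesh = lm, kind = kind, layer_id = NA_character_,
                             attach = attach, attach_height_cm = z / 10)
      }
    }
    plant <- structure(list(stem = stem, branches = branches,
                            petioles = petioles, leaves = leaves,
                            root_position = c(0, 0, 0), spec = spec),
                       class = "plant_model")
    assign_layers(plant, spec$layer_bounds)
  })
}

#' Label each leaf with its canopy layer
#'
#' Layers are half-open height intervals `[lo, hi)` on the leaf attachment
#' height, with the top interval closed, so the labels always partition the
#' leaf set. With the default bounds (0, 50, 90, 130 cm) the labels are
#' `lower`, `middle`, `upper`.
#'
#' @param plant a `plant_model`.
#' @param layer_bounds strictly increasing boundary heights (cm).
#' @return The plant with `layer_id` set on every leaf.
#' @export
assign_layers <- function(plant, layer_bounds = plant$spec$layer_bounds) {
  if (any(diff(layer_bounds) <= 0)) stop("layer_bounds must be increasing")
  n_layers <- length(layer_bounds) - 1L
  labels <- if (n_layers == 3L) c("lower", "middle", "upper")
            else paste0("layer", seq_len(n_layers))
  for (i in seq_along(plant$leaves)) {
    h <- plant$leaves[[i]]$attach_height_cm
    if (h < layer_bounds[1] || h > layer_bounds[n_layers + 1L])
      stop("leaf attachment height ", h, " cm outside layer bounds")
    id <- findInterval(h, layer_bounds, rightmost.closed = TRUE)
    plant$leaves[[i]]$layer_id <- labels[id]
  }
  plant
}

#' All meshes of a plant as one flat list
#' @param plant a `plant_model`.
#' @param what subset of components to include.
#' @return List of `cf_mesh`.
#' @export
plant_meshes <- function(plant, what = c("stem", "branches", "petioles",
                                         "leaves")) {
  out <- list()
  if ("stem" %in% what) out <- c(out, list(plant$stem))
  if ("branches" %in% what) out <- c(out, plant$branches)
  if ("petioles" %in% what) out <- c(out, plant$petioles)
  if ("leaves" %in% what) out <- c(out, lapply(plant$leaves, `[[`, "mesh"))
  out
}

# Concatenate triangle meshes into one.
merge_meshes <- function(meshes) {
  nv <- 0L; V <- list(); F <- list()
  for (m in meshes) {
    V[[length(V) + 1L]] <- m$vertices
    F[[length(F) + 1L]] <- m$faces + nv
    nv <- nv + nrow(m$vertices)
  }
  cf_mesh(do.call(rbind, V), do.call(rbind, F))
}

## ---- Mesh export / import --------------------------------------------------

#' Export a plant or mesh to STL or OBJ
#'
#' Writes all plant meshes merged into a single surface. STL may be ascii or
#' binary; OBJ is text. Units are mm.
#'
#' @param x a `plant_model` or a `cf_mesh`.
#' @param path output file; the format is inferred from the extension unless
#'   given explicitly.
#' @param format `"stl"` or `"obj"`.
#' @param binary for STL, write the binary flavour (default TRUE).
#' @return The path, invisibly.
#' @export
export_mesh <- function(x, path, format = c("auto", "stl", "obj"),
                        binary = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- tolower(tools::file_ext(path))
  mesh <- if (inherits(x, "plant_model")) merge_meshes(plant_meshes(x)) else x
  stopifnot(inherits(mesh, "cf_mesh"))
  switch(format,
         stl = write_stl(mesh, path, binary = binary),
         obj = write_obj(mesh, path),
         stop("unsupported mesh format: ", format))
  invisible(path)
}

#' Read / write triangle meshes in STL or OBJ format
#' @param mesh a `cf_mesh`.
#' @param path file path.
#' @param binary write binary STL (TRUE) or ascii (FALSE).
#' @return `read_mesh` returns a `cf_mesh`.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    tri <- t(cbind(stl_normals(v, f),
                   v[f[, 1], ], v[f[, 2], ], v[f[, 3], ]))
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(tri[, i]), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    nrm <- stl_normals(v, f)
    writeLines("solid canopyflow", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(sprintf("facet normal %.9g %.9g %.9g",
                           nrm[i, 1], nrm[i, 2], nrm[i, 3]),
                   "  outer loop",
                   sprintf("    vertex %.9g %.9g %.9g",
                           v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid canopyflow", con)
  }
  invisible(path)
}

stl_normals <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n / len
}

#' @rdname write_stl
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), con)
  invisible(path)
}

#' @rdname write_stl
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         obj = read_obj(path),
         stop("unsupported mesh format: ", ext))
}

read_stl <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  head <- readBin(con, "raw", 80)
  if (grepl("^solid", rawToChar(head[1:5]))) {
    close(con); on.exit()
    txt <- readLines(path)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
    nf <- nrow(nums) / 3
    return(cf_mesh(nums, matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE)))
  }
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  v <- matrix(0, 3 * nf, 3)
  for (i in seq_len(nf)) {
    vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "raw", 2)
    v[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  cf_mesh(v, matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE))
}

read_obj <- function(path) {
  txt <- readLines(path)
  vl <- strsplit(trimws(grep("^v ", txt, value = TRUE)), "\\s+")
  fl <- strsplit(trimws(grep("^f ", txt, value = TRUE)), "\\s+")
  v <- do.call(rbind, lapply(vl, function(p) as.numeric(p[2:4])))
  f <- do.call(rbind, lapply(fl, function(p)
    as.integer(sub("/.*", "", p[2:4]))))
  cf_mesh(v, f)
}

#' Plant bounding box
#' @param plant a `plant_model`.
#' @return 2 x 3 matrix (min and max corners, mm).
#' @export
plant_bbox <- function(plant) {
  v <- merge_meshes(plant_meshes(plant))$vertices
  rbind(apply(v, 2, min), apply(v, 2, max))
}
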