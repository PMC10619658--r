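test_that("leaf templates hit their target planform areas and scale linearly", {
  areas <- c(ovate = 4206.25, three_lobed = 7859.10, five_lobed = 9823.00)
  for (k in names(areas)) {
    tpl <- make_leaf_template(k, areas[[k]])
    a_poly <- abs(polygon_area(tpl$outline))         # shoelace oracle
    a_mesh <- mesh_area(leaf_template_mesh(tpl))     # triangle-sum route
    expect_lt(abs(a_poly - areas[[k]]) / areas[[k]], 1e-3)
    expect_lt(abs(a_mesh - a_poly) / a_poly, 1e-9)
    # attach point lies on the outline
    expect_true(any(apply(tpl$outline, 1, function(p)
      all(p == tpl$attach_point))))
  }
  # pure scaling: area(c * A) = c * area(A)
  a1 <- abs(polygon_area(make_leaf_template("three_lobed", 1.0)$outline))
  a7 <- abs(polygon_area(make_leaf_template("three_lobed", 7.0)$outline))
  expect_equal(a7 / a1, 7.0, tolerance = 1e-12)
  expect_error(make_leaf_template("round", 10), "one of")
  expect_error(make_leaf_template("ovate", -1), "positive")
})

test_that("leaf outlines are simple polygons", {
  for (k in c("ovate", "three_lobed", "five_lobed")) {
    o <- make_leaf_template(k, 5000)$outline
    # a star-shaped polygon about the centroid cannot self-intersect:
    # polar angles about the centroid must be strictly monotone (mod 2pi)
    cen <- colMeans(o)
    ang <- atan2(o[, 2] - cen[2], o[, 1] - cen[1])
    dd <- diff(ang)
    dd <- ifelse(dd < -pi, dd + 2 * pi, ifelse(dd > pi, dd - 2 * pi, dd))
    expect_true(all(dd > 0) || all(dd < 0))
  }
})

test_that("largest-remainder apportionment is within one of every quota", {
  fr <- c(ovate = 0.20, three_lobed = 0.55, five_lobed = 0.25)
  expect_identical(unname(apportion_leaf_kinds(20, fr)), c(4L, 11L, 5L))
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(1:200, 1)
    p <- runif(3); p <- p / sum(p)
    cnt <- apportion_leaf_kinds(n, p)
    expect_identical(sum(cnt), as.integer(n))
    expect_true(all(abs(cnt - n * p) < 1))
  }
})

test_that("generated plants respect the phenotype schedule", {
  p <- generate_plant(plant_spec(rng_seed = 7L))
  expect_length(p$branches, 16L)                     # nodes 5-20 inclusive
  expect_length(p$leaves, 16L * 3L)
  kinds <- table(vapply(p$leaves, `[[`, "", "kind"))
  expect_identical(as.integer(kinds[c("ovate", "three_lobed", "five_lobed")]),
                   unname(apportion_leaf_kinds(48, p$spec$leaf_type_fractions)))
  bb <- plant_bbox(p)
  expect_lt(abs((bb[2, 3] - bb[1, 3]) / 10 - 130) / 130, 0.01)
})

test_that("plant generation is deterministic for a fixed seed", {
  p1 <- generate_plant(plant_spec(rng_seed = 3L))
  p2 <- generate_plant(plant_spec(rng_seed = 3L))
  expect_identical(p1, p2)
  p3 <- generate_plant(plant_spec(rng_seed = 4L))
  expect_false(identical(p1$leaves[[1]]$mesh$vertices,
                         p3$leaves[[1]]$mesh$vertices))
})

test_that("layer labels partition the leaves with half-open bounds", {
  p <- generate_plant(plant_spec(rng_seed = 11L))
  lays <- vapply(p$leaves, `[[`, "", "layer_id")
  expect_false(anyNA(lays))
  expect_identical(length(lays), sum(table(lays)))
  # attachment heights map to the right layer, boundary goes up
  h <- vapply(p$leaves, `[[`, 0, "attach_height_cm")
  expect_true(all(lays[h >= 50 & h < 90] == "middle"))
  expect_true(all(lays[h < 50] == "lower"))
  expect_true(all(lays[h >= 90] == "upper"))
  # a leaf exactly on a bound belongs to the upper of the two layers
  p2 <- p
  p2$leaves[[1]]$attach_height_cm <- 50
  p2 <- assign_layers(p2, c(0, 50, 90, 130))
  expect_identical(p2$leaves[[1]]$layer_id, "middle")
  p2$leaves[[1]]$attach_height_cm <- 200
  expect_error(assign_layers(p2, c(0, 50, 90, 130)), "outside")
})

test_that("mesh area matches closed forms and is subdivision invariant", {
  tri <- cf_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), cbind(1, 2, 3))
  expect_equal(mesh_area(tri), 0.5, tolerance = 1e-15)
  lm <- leaf_template_mesh(make_leaf_template("five_lobed", 9823.00))
  a0 <- mesh_area(lm)
  sub <- canopyflow:::subdivide_to_edge(lm$vertices, lm$faces, 10)
  expect_lt(abs(mesh_area(cf_mesh(sub$vertices, sub$faces)) - a0) / a0, 1e-9)
  dg <- cf_mesh(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), cbind(1, 2, 3))
  expect_warning(a <- mesh_area(dg), "zero area")
  expect_identical(a, 0)
})

test_that("STL and OBJ exports round-trip losslessly", {
  lm <- leaf_template_mesh(make_leaf_template("ovate", 4206.25))
  for (ext in c("stl", "obj")) {
    f <- tempfile(fileext = paste0(".", ext))
    export_mesh(lm, f)
    back <- read_mesh(f)
    expect_identical(nrow(back$faces), nrow(lm$faces))
    expect_lt(abs(mesh_area(back) - mesh_area(lm)) / mesh_area(lm), 1e-6)
    unlink(f)
  }
  # ascii STL flavour
  f <- tempfile(fileext = ".stl")
  write_stl(lm, f, binary = FALSE)
  expect_lt(abs(mesh_area(read_mesh(f)) - mesh_area(lm)) / mesh_area(lm), 1e-6)
  unlink(f)
  # independent loader oracle: trimesh reads the binary STL and reports the
  # same surface area
  f <- tempfile(fileext = ".stl")
  write_stl(lm, f, binary = TRUE)
  out <- suppressWarnings(system2(
    "python", c("-c", shQuote(sprintf(
      "import trimesh; print(trimesh.load('%s').area)", f))),
    stdout = TRUE, stderr = FALSE))
  a_ext <- suppressWarnings(as.numeric(tail(out, 1)))
  expect_false(is.na(a_ext))
  expect_lt(abs(a_ext - mesh_area(lm)) / mesh_area(lm), 1e-6)
  unlink(f)
  # whole plant: OBJ and STL agree on total surface area
  p <- generate_plant(plant_spec(rng_seed = 2L, leaf_outline_n = 24L))
  f1 <- tempfile(fileext = ".stl"); f2 <- tempfile(fileext = ".obj")
  export_mesh(p, f1); export_mesh(p, f2)
  expect_lt(abs(mesh_area(read_mesh(f1)) - mesh_area(read_mesh(f2))) /
            mesh_area(read_mesh(f2)), 1e-6)
  unlink(c(f1, f2))
})

test_that("plant specification round-trips through its YAML description", {
  sp <- plant_spec(rng_seed = 99L, leaves_per_branch = 2L)
  f <- tempfile(fileext = ".yml")
  write_plant_spec(sp, f)
  sp2 <- read_plant_spec(f)
  expect_equal(sp2, sp)
  expect_identical(generate_plant(sp2), generate_plant(sp))
  unlink(f)
})
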