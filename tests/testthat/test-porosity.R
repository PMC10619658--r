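square_mesh <- function(side = 100, z = 0)
  cf_mesh(rbind(c(0, 0, z), c(side, 0, z), c(side, side, z), c(0, side, z)),
          rbind(c(1, 2, 3), c(1, 3, 4)))

test_that("axis-aligned squares rasterize to exact pixel blocks", {
  img <- render_projection(square_mesh(100), "top",
                           bounds = c(-10, 110, -10, 110), resolution = 120)
  expect_identical(sum(img$mask_truth), 10000L)
  expect_equal(img$mm_per_pixel, 1, tolerance = 1e-12)
  # two disjoint leaves: foreground adds up
  m2 <- cf_mesh(square_mesh(40)$vertices + rep(c(200, 0, 0), each = 4),
                square_mesh(40)$faces)
  both <- render_projection(list(square_mesh(40), m2), "top",
                            bounds = c(-10, 250, -10, 60), resolution = 260)
  one <- render_projection(square_mesh(40), "top",
                           bounds = c(-10, 250, -10, 60), resolution = 260)
  two <- render_projection(m2, "top",
                           bounds = c(-10, 250, -10, 60), resolution = 260)
  expect_identical(sum(both$mask_truth),
                   sum(one$mask_truth) + sum(two$mask_truth))
  expect_error(render_projection(list(), "top"), "no meshes")
  expect_error(render_projection(square_mesh(10), "top", resolution = 32),
               "64")
})

test_that("windward area is resolution-stable and follows the projection cosine", {
  lm <- leaf_template_mesh(make_leaf_template("ovate", 4206.25))
  a <- vapply(c(256, 512), function(res) {
    img <- render_projection(lm, "top", resolution = res)
    windward_area(preprocess(img), img$mm_per_pixel)
  }, numeric(1))
  expect_lt(abs(a[1] - 4206.25) / 4206.25, 0.01)
  expect_lt(abs(a[2] - a[1]) / a[1], 0.005)
  # tilting by 60 degrees halves the projected area
  R <- matrix(c(1, 0, 0, 0, cos(pi / 3), -sin(pi / 3),
                0, sin(pi / 3), cos(pi / 3)), 3, 3, byrow = TRUE)
  tl <- cf_mesh(lm$vertices %*% t(R), lm$faces)
  img <- render_projection(tl, "top", resolution = 400)
  a_tilt <- windward_area(preprocess(img), img$mm_per_pixel)
  expect_lt(abs(a_tilt / a[2] - 0.5), 0.02)
  expect_identical(windward_area(matrix(0L, 8, 8), 1), 0)
})

test_that("preprocessing reproduces the rasterizer mask and survives noise", {
  lm <- leaf_template_mesh(make_leaf_template("three_lobed", 7859.10))
  img <- render_projection(lm, "top", resolution = 256)
  mask <- preprocess(img)
  expect_lt(mean(mask != img$mask_truth), 0.002)   # median filter edge nibble
  # salt-and-pepper noise at 1%: under 0.5% of pixels may flip
  set.seed(40)
  noisy <- img$pixels
  flip <- sample(length(noisy), round(0.01 * length(noisy)))
  noisy[flip] <- ifelse(runif(length(flip)) < 0.5, 0, 1)
  mask_n <- preprocess(noisy)
  expect_lt(mean(mask_n != img$mask_truth), 0.005)
  # inverted contrast with the polarity flag gives the same mask
  mask_inv <- preprocess(1 - img$pixels, foreground = "light")
  expect_identical(mask_inv, preprocess(img$pixels, foreground = "dark"))
  expect_error(preprocess(matrix(0.5, 32, 32)), "no threshold")
})

test_that("outer contour area measures hulls with pixel-extent correction", {
  mask <- matrix(0L, 30, 30)
  mask[1:10, 1:10] <- 1L
  expect_equal(outer_contour_area(mask, 1), 100, tolerance = 1e-12)
  expect_equal(outer_contour_area(mask, 1, pixel_extent_correction = FALSE),
               81, tolerance = 1e-12)
  # two opposite corner blocks: hull spans both
  mask2 <- matrix(0L, 30, 30)
  mask2[1:5, 1:5] <- 1L; mask2[26:30, 26:30] <- 1L
  expect_gt(outer_contour_area(mask2, 1), 2 * 25)
  # hull contains the foreground for arbitrary masks
  set.seed(41)
  for (i in 1:5) {
    m <- matrix(as.integer(runif(400) < 0.2), 20, 20)
    if (sum(m) < 3) next
    expect_gte(outer_contour_area(m, 1) + 1e-9, windward_area(m, 1))
  }
  expect_error(outer_contour_area(matrix(0L, 5, 5), 1), "foreground")
  expect_s3_class(tryCatch(outer_contour_area(matrix(0L, 5, 5), 1),
                           error = identity), "cf_empty_layer")
})

test_that("the two porosity conventions are exact complements", {
  # constructed mask: 50 foreground pixels inside a 100-pixel hull
  mask <- matrix(0L, 20, 20)
  mask[1:10, 1:10] <- matrix(as.integer(seq_len(100) %% 2 == 0), 10, 10)
  mask[1, 1] <- mask[10, 10] <- mask[1, 10] <- mask[10, 1] <- 1L
  A <- windward_area(mask, 1)
  S <- outer_contour_area(mask, 1)
  expect_equal(S, 100, tolerance = 1e-12)
  expect_equal(layer_porosity(A, S, "literal"), A / 100, tolerance = 1e-12)
  expect_equal(layer_porosity(A, S, "literal") +
               layer_porosity(A, S, "optical"), 1, tolerance = 1e-12)
  set.seed(42)
  for (i in 1:10) {
    A <- runif(1); S <- A + runif(1)
    expect_equal(layer_porosity(A, S, "literal") +
                 layer_porosity(A, S, "optical"), 1, tolerance = 1e-14)
    expect_true(layer_porosity(A, S, "optical") >= 0 &&
                layer_porosity(A, S, "optical") <= 1)
  }
  expect_error(layer_porosity(2, 1), "A_i <= S_i")
})

test_that("an exactly half-covered hull yields porosity one half", {
  # 50 foreground pixels whose hull is the full 10 x 10 block: rows 1-4
  # and row 10 fully on (the extreme rows pin the hull corners)
  mask <- matrix(0L, 20, 20)
  mask[1:10, c(1:4, 10)] <- 1L
  expect_identical(sum(mask), 50L)
  A <- windward_area(mask, 1)
  S <- outer_contour_area(mask, 1)
  expect_equal(S, 100, tolerance = 1e-12)
  expect_equal(layer_porosity(A, S, "literal"), 0.5, tolerance = 1e-12)
  expect_equal(layer_porosity(A, S, "optical"), 0.5, tolerance = 1e-12)
})

test_that("stratified porosity runs per frame, per band, with a baseline", {
  p <- generate_plant(plant_spec(rng_seed = 6L, leaf_outline_n = 24L,
                                 leaves_per_branch = 2L))
  mat <- cf_material(thickness = 2e-3, damping = 30)
  cfg <- coupling_config(inlet_speed = 0, duration = 0.01,
                         output_interval = 0.005, n = 32,
                         store_fluid = "none", shell_gravity = FALSE,
                         fluid_gravity = FALSE)
  rec <- run_simulation(p, mat, cfg)
  ts <- stratified_porosity(rec, bands = "layers", resolution = 128)
  expect_s3_class(ts, "porosity_time_series")
  expect_setequal(unique(ts$band), c("lower", "middle", "upper"))
  ok <- !is.na(ts$P)
  expect_true(all(ts$P[ok] >= 0 & ts$P[ok] <= 1))
  expect_true(all(ts$A_mm2[ok] <= ts$S_mm2[ok] + 1e-9))
  expect_equal(ts$P_literal[ok] + ts$P_optical[ok], rep(1, sum(ok)),
               tolerance = 1e-12)
  # no wind, no gravity: porosity equals the baseline, variation is zero
  expect_lt(max(abs(ts$dP[ok])), 1e-12)
  # canopy relative height mode: exactly ten bands
  crh <- stratified_porosity(rec, bands = "crh", n_crh = 10, resolution = 96)
  expect_identical(sort(unique(crh$band)),
                   sort(paste0(seq(10, 100, by = 10), "%")))
})

test_that("PNG image round trips preserve the raster", {
  lm <- leaf_template_mesh(make_leaf_template("ovate", 4206.25))
  img <- render_projection(lm, "top", resolution = 128)
  f <- tempfile(fileext = ".png")
  write_image_png(img, f)
  back <- read_image_png(f)
  expect_equal(dim(back), dim(img$pixels))
  expect_lt(max(abs(back - img$pixels)), 1 / 255)
  unlink(f)
})
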