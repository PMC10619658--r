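## Stratified canopy porosity from projection images: render, binarize,
## outer-contour and windward areas, porosity per layer / canopy relative
## height over time.

#' Orthographic projection image of leaf meshes
#'
#' Rasterizes triangle meshes onto a white background along a view axis
#' (`"top"` projects onto the x-y plane, `"front"` onto x-z). Foreground
#' (plant) pixels are dark. Pixels are square; a pixel is foreground when
#' its centre falls inside a projected triangle.
#'
#' @param meshes a `cf_mesh` or list of them (mm), or an n x 3 vertex matrix
#'   with `faces`.
#' @param view_axis `"top"` or `"front"`.
#' @param bounds projection-plane bounds `c(umin, umax, vmin, vmax)` in mm;
#'   default the mesh bounding box plus a 2% margin.
#' @param resolution pixels along the horizontal (u) axis; at least 64.
#' @return A `projection_image`: list with `pixels` (grayscale in [0, 1],
#'   white background), `mask_truth` (exact rasterizer foreground),
#'   `mm_per_pixel`, `view_axis`, `bounds`, `frame_time`.
#' @export
render_projection <- function(meshes, view_axis = c("top", "front"),
                              bounds = NULL, resolution = 256L) {
  view_axis <- match.arg(view_axis)
  if (inherits(meshes, "cf_mesh")) meshes <- list(meshes)
  if (length(meshes) == 0) stop("no meshes to render")
  resolution <- as.integer(resolution)
  if (resolution < 64) stop("resolution must be at least 64 px")
  mesh <- merge_meshes(meshes)
  proj_cols <- if (view_axis == "top") c(1L, 2L) else c(1L, 3L)
  pts <- mesh$vertices[, proj_cols, drop = FALSE]
  if (is.null(bounds)) {
    rx <- range(pts[, 1]); ry <- range(pts[, 2])
    mx <- 0.02 * max(diff(rx), diff(ry), 1e-9)
    bounds <- c(rx[1] - mx, rx[2] + mx, ry[1] - mx, ry[2] + mx)
  }
  mm_per_pixel <- (bounds[2] - bounds[1]) / resolution
  height <- max(1L, as.integer(round((bounds[4] - bounds[3]) / mm_per_pixel)))
  # snap the v-extent so pixels stay square
  bounds[4] <- bounds[3] + height * mm_per_pixel
  mask <- raster_triangles(pts, mesh$faces, bounds, resolution, height)
  structure(list(pixels = 1 - 0.9 * mask, mask_truth = mask,
                 mm_per_pixel = mm_per_pixel, view_axis = view_axis,
                 bounds = bounds, frame_time = NA_real_),
            class = "projection_image")
}

#' Binarize a projection image
#'
#' The image-processing leg of the porosity pipeline: 3 x 3 median-filter
#' denoising, grayscale conversion, Otsu thresholding, binarization. The
#' foreground polarity is `"dark"` for package-rendered images (plant dark on
#' white); `"auto"` picks the minority side.
#'
#' @param image a `projection_image` or a numeric matrix in [0, 1].
#' @param foreground `"dark"`, `"light"` or `"auto"`.
#' @param denoise apply the median filter.
#' @return Integer foreground mask (same shape), with `mm_per_pixel`
#'   attribute when available.
#' @export
preprocess <- function(image, foreground = c("dark", "light", "auto"),
                       denoise = TRUE) {
  foreground <- match.arg(foreground)
  mm <- NULL
  if (inherits(image, "projection_image")) {
    mm <- image$mm_per_pixel
    image <- image$pixels
  }
  g <- as.matrix(image)
  if (max(g) > 1 || min(g) < 0) g <- (g - min(g)) / max(1e-12, diff(range(g)))
  if (diff(range(g)) < 1e-12)
    stop("no threshold: image has no contrast")
  if (denoise && min(dim(g)) >= 3)
    g <- as.matrix(EBImage::medianFilter(EBImage::Image(g), size = 1))
  thr <- EBImage::otsu(EBImage::Image(g), range = c(0, 1))
  mask <- if (foreground == "dark") (g < thr)
          else if (foreground == "light") (g > thr)
          else {
    dark <- g < thr
    if (sum(dark) <= sum(!dark)) dark else !dark
  }
  mask <- matrix(as.integer(mask), nrow(g), ncol(g))
  if (!is.null(mm)) attr(mask, "mm_per_pixel") <- mm
  mask
}

empty_layer_error <- function(msg) {
  stop(structure(class = c("cf_empty_layer", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Outer-contour (projection) area S_i
#'
#' Area enclosed by the outermost leaf edge of the projection, realized as
#' the convex hull of the foreground pixels. By default the hull is taken
#' over the four corners of each foreground pixel rather than the centres,
#' which removes the half-pixel rim underestimate (a 10 x 10 px block then
#' measures exactly 100 px^2).
#'
#' @param mask integer foreground mask.
#' @param mm_per_pixel scale (mm per pixel side).
#' @param pixel_extent_correction use pixel corners (TRUE) or centres.
#' @return S_i in mm^2.
#' @export
outer_contour_area <- function(mask, mm_per_pixel = attr(mask, "mm_per_pixel"),
                               pixel_extent_correction = TRUE) {
  if (is.null(mm_per_pixel)) stop("mm_per_pixel required")
  fg <- which(mask != 0, arr.ind = TRUE)
  if (nrow(fg) < 3) empty_layer_error("fewer than 3 foreground pixels")
  pts <- fg - 0.5                      # pixel centres
  if (pixel_extent_correction) {
    pts <- rbind(fg - 1, cbind(fg[, 1], fg[, 2] - 1),
                 cbind(fg[, 1] - 1, fg[, 2]), fg)
  }
  h <- grDevices::chull(pts)
  if (length(h) < 3) empty_layer_error("foreground pixels are collinear")
  area_px <- abs(polygon_area(pts[h, , drop = FALSE]))
  if (area_px == 0) empty_layer_error("degenerate foreground hull")
  area_px * mm_per_pixel^2
}

#' Windward (projected leaf) area A_i
#'
#' Foreground pixel count times the pixel area.
#'
#' @inheritParams outer_contour_area
#' @return A_i in mm^2.
#' @export
windward_area <- function(mask, mm_per_pixel = attr(mask, "mm_per_pixel")) {
  if (is.null(mm_per_pixel)) stop("mm_per_pixel required")
  sum(mask != 0) * mm_per_pixel^2
}

#' Layer porosity from the two areas
#'
#' The stratified porosity of a layer relates the windward leaf area A_i to
#' the outer-contour area S_i. Two conventions are provided: `"literal"`
#' is the ratio P = A_i / S_i; `"optical"` is the void fraction
#' P = 1 - A_i / S_i (the fraction of the contour plane not occupied by
#' leaf), which matches the optical-porosity definition and is the default.
#'
#' @param A_i windward area (mm^2).
#' @param S_i contour area (mm^2); must satisfy `0 <= A_i <= S_i`.
#' @param mode `"optical"` or `"literal"`.
#' @return Porosity in [0, 1].
#' @export
layer_porosity <- function(A_i, S_i, mode = c("optical", "literal")) {
  mode <- match.arg(mode)
  if (any(A_i < 0) || any(S_i <= 0) || any(A_i > S_i * (1 + 1e-9)))
    stop("areas must satisfy 0 <= A_i <= S_i")
  r <- pmin(1, A_i / S_i)
  if (mode == "literal") r else 1 - r
}

mask_porosity <- function(mask, mm_per_pixel = attr(mask, "mm_per_pixel"),
                          pixel_extent_correction = TRUE) {
  A <- windward_area(mask, mm_per_pixel)
  S <- outer_contour_area(mask, mm_per_pixel, pixel_extent_correction)
  list(A = A, S = S, P_literal = layer_porosity(A, S, "literal"),
       P_optical = layer_porosity(A, S, "optical"))
}

leaf_rows <- function(components) {
  components[components$type == "leaf", , drop = FALSE]
}

frame_band_mesh <- function(record, frame, rows, z_range_mm = NULL) {
  nodes_mm <- frame$nodes * 1000
  tris <- record$tris
  keep <- unlist(lapply(seq_len(nrow(rows)), function(i)
    seq(rows$tri_from[i], rows$tri_to[i])))
  tr <- tris[keep, , drop = FALSE]
  if (!is.null(z_range_mm)) {
    zc <- (nodes_mm[tr[, 1], 3] + nodes_mm[tr[, 2], 3] +
           nodes_mm[tr[, 3], 3]) / 3
    tr <- tr[zc >= z_range_mm[1] & zc < z_range_mm[2], , drop = FALSE]
  }
  if (nrow(tr) == 0) return(NULL)
  cf_mesh(nodes_mm, tr)
}

#' Stratified porosity over a simulation record
#'
#' Applies the five-step porosity procedure to every output frame: render
#' the band's leaves as a top-view projection, binarize, measure the
#' outer-contour area S_i and windward area A_i, and form the porosity
#' P_i. Bands are either the named canopy layers (leaves grouped by their
#' attachment layer) or `n_crh` equal canopy-relative-height slices
#' (triangles binned by their current centroid height). The t = 0 no-wind
#' frame provides the baseline; the dynamic variation `dP` is the change in
#' porosity relative to that initial porosity.
#'
#' @param record a `simulation_record`.
#' @param bands `"layers"` or `"crh"`.
#' @param n_crh number of canopy-relative-height bands (10 gives
#'   10%, 20%, ..., 100%).
#' @param mode porosity convention, `"optical"` (void fraction, default) or
#'   `"literal"` (A/S).
#' @param resolution render resolution (px).
#' @param view_axis projection direction (top view matches downward
#'   airflow).
#' @return A `porosity_time_series` data.frame with columns time_s, band,
#'   A_mm2, S_mm2, P_literal, P_optical, P, dP; empty bands give NA rows
#'   with a warning. Attributes: `mode`, `baseline`.
#' @export
stratified_porosity <- function(record, bands = c("layers", "crh"),
                                n_crh = 10L, mode = c("optical", "literal"),
                                resolution = 256L,
                                view_axis = "top") {
  bands <- match.arg(bands)
  mode <- match.arg(mode)
  lv <- leaf_rows(record$components)
  if (nrow(lv) == 0) stop("record contains no leaves")
  # common projection bounds: rest leaf extent plus a deformation margin
  rest_mm <- record$rest_nodes * 1000
  idx <- unlist(lapply(seq_len(nrow(lv)), function(i)
    seq(lv$node_from[i], lv$node_to[i])))
  proj_cols <- if (view_axis == "top") c(1L, 2L) else c(1L, 3L)
  rx <- range(rest_mm[idx, proj_cols[1]]); ry <- range(rest_mm[idx, proj_cols[2]])
  mx <- 0.15 * max(diff(rx), diff(ry))
  bounds <- c(rx[1] - mx, rx[2] + mx, ry[1] - mx, ry[2] + mx)
  zr <- range(rest_mm[idx, 3])

  band_defs <- if (bands == "layers") {
    lapply(split(seq_len(nrow(lv)), lv$layer), function(i)
      list(rows = lv[i, , drop = FALSE], z = NULL))
  } else {
    edges <- seq(zr[1], zr[2] + 1e-9, length.out = n_crh + 1L)
    stats::setNames(lapply(seq_len(n_crh), function(b)
      list(rows = lv, z = c(edges[b], edges[b + 1L]))),
      paste0(seq_len(n_crh) * round(100 / n_crh), "%"))
  }

  measure_frame <- function(frame) {
    do.call(rbind, lapply(names(band_defs), function(bn) {
      bd <- band_defs[[bn]]
      mesh <- frame_band_mesh(record, frame, bd$rows, bd$z)
      row <- data.frame(time_s = frame$time, band = bn, A_mm2 = NA_real_,
                        S_mm2 = NA_real_, P_literal = NA_real_,
                        P_optical = NA_real_, stringsAsFactors = FALSE)
      if (is.null(mesh)) return(row)
      img <- render_projection(mesh, view_axis, bounds, resolution)
      if (sum(img$mask_truth) < 3) return(row)   # band renders to nothing
      res <- tryCatch({
        mask <- preprocess(img)
        mask_porosity(mask, img$mm_per_pixel)
      }, cf_empty_layer = function(e) NULL)
      if (is.null(res)) return(row)
      row$A_mm2 <- res$A; row$S_mm2 <- res$S
      row$P_literal <- res$P_literal; row$P_optical <- res$P_optical
      row
    }))
  }
  base <- measure_frame(record$baseline)
  out <- do.call(rbind, lapply(record$frames, measure_frame))
  pcol <- if (mode == "optical") "P_optical" else "P_literal"
  out$P <- out[[pcol]]
  base$P <- base[[pcol]]
  out$dP <- out$P - base$P[match(out$band, base$band)]
  if (anyNA(out$P))
    warning("some bands were empty; porosity reported as NA there")
  structure(out, mode = mode, baseline = base,
            class = c("porosity_time_series", class(out)))
}

#' Write a porosity time series (or any table) to CSV
#' @param x data.frame.
#' @param path output path.
#' @export
write_porosity_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a mask or grayscale image as PNG
#' @param image matrix in [0, 1] (or 0/1 mask), or `projection_image`.
#' @param path file path.
#' @return `read_image_png` returns a numeric matrix in [0, 1].
#' @export
write_image_png <- function(image, path) {
  if (inherits(image, "projection_image")) image <- image$pixels
  png::writePNG(t(image[, rev(seq_len(ncol(image))), drop = FALSE]), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  m <- t(a)
  m[, rev(seq_len(ncol(m))), drop = FALSE]
}
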