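#' Regions of interest for point counting
#'
#' ROIs come in three flavours: axis-aligned rectangles, simple polygons
#' (vertices in um), and binary pixel masks with a physical pixel size.
#' A probe point exactly on an ROI boundary counts on the top/right boundary
#' only, mirroring the counting frame's inclusion-line convention so that
#' tiling probes never double count.
#'
#' @param x0,y0 lower-left corner, um.
#' @param width,height rectangle extent, um.
#' @return An object of class `roi`.
#' @export
roi_rect <- function(x0, y0, width, height) {
  assert_scalar_num(width, "width", positive = TRUE)
  assert_scalar_num(height, "height", positive = TRUE)
  structure(list(type = "rect", x0 = x0, y0 = y0,
                 width = width, height = height),
            class = "roi")
}

#' @rdname roi_rect
#' @param x,y polygon vertex coordinates, um (not closed).
#' @export
roi_polygon <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  structure(list(type = "polygon", x = as.numeric(x), y = as.numeric(y)),
            class = "roi")
}

#' @rdname roi_rect
#' @param mask logical or 0/1 matrix (rows = y, columns = x).
#' @param pixel_size_um physical edge length of one pixel, um.
#' @param origin xy position of the mask's lower-left corner, um.
#' @export
roi_mask <- function(mask, pixel_size_um = 1, origin = c(0, 0)) {
  stopifnot(is.matrix(mask))
  structure(list(type = "mask", mask = mask != 0,
                 pixel_size_um = pixel_size_um, origin = origin),
            class = "roi")
}

roi_bbox <- function(roi) {
  switch(roi$type,
    rect = c(roi$x0, roi$y0, roi$x0 + roi$width, roi$y0 + roi$height),
    polygon = c(min(roi$x), min(roi$y), max(roi$x), max(roi$y)),
    mask = c(roi$origin[1], roi$origin[2],
             roi$origin[1] + ncol(roi$mask) * roi$pixel_size_um,
             roi$origin[2] + nrow(roi$mask) * roi$pixel_size_um)
  )
}

# Even-odd ray crossing; half-open edge handling makes shared edges of a
# polygon tiling count a point exactly once.
point_in_polygon <- function(px, py, vx, vy) {
  inside <- logical(length(px))
  n <- length(vx)
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Test which points fall inside an ROI
#'
#' @param roi an ROI from [roi_rect()], [roi_polygon()] or [roi_mask()].
#' @param x,y point coordinates, um.
#' @return Logical vector. Rectangles apply the half-open rule
#'   `(x0, x0+w] x (y0, y0+h]`; polygon boundaries follow the even-odd
#'   crossing convention; mask points look up the containing pixel.
#' @export
roi_contains <- function(roi, x, y) {
  stopifnot(inherits(roi, "roi"))
  switch(roi$type,
    rect = x > roi$x0 & x <= roi$x0 + roi$width &
           y > roi$y0 & y <= roi$y0 + roi$height,
    polygon = point_in_polygon(x, y, roi$x, roi$y),
    mask = {
      px <- ceiling((x - roi$origin[1]) / roi$pixel_size_um)
      py <- ceiling((y - roi$origin[2]) / roi$pixel_size_um)
      ok <- px >= 1 & px <= ncol(roi$mask) & py >= 1 & py <= nrow(roi$mask)
      res <- logical(length(x))
      res[ok] <- roi$mask[cbind(py[ok], px[ok])]
      res
    }
  )
}

roi_area <- function(roi) {
  switch(roi$type,
    rect = roi$width * roi$height,
    polygon = {
      n <- length(roi$x)
      j <- c(n, seq_len(n - 1))
      abs(sum(roi$x[j] * roi$y - roi$x * roi$y[j])) / 2
    },
    mask = sum(roi$mask) * roi$pixel_size_um^2
  )
}

#' Square point grid for Cavalieri counting
#'
#' A systematic square grid with one point per `a_p` um^2 and a uniformly
#' random offset within one grid period, as required for unbiased area (and
#' hence volume) estimation.
#'
#' @param a_p area per point, um^2 (> 0); grid spacing is `sqrt(a_p)`.
#' @param offset optional fixed 2-vector offset in um within one period.
#' @param seed integer seed for the random offset.
#' @return A `point_grid` with `a_p`, `spacing` and `offset`.
#' @export
point_grid <- function(a_p, offset = NULL, seed = NULL) {
  assert_scalar_num(a_p, "a_p", positive = TRUE)
  spacing <- sqrt(a_p)
  if (is.null(offset)) {
    offset <- with_seed(seed, stats::runif(2, 0, spacing))
  }
  offset <- offset %% spacing
  structure(list(a_p = a_p, spacing = spacing, offset = offset),
            class = "point_grid")
}

#' Count grid points hitting an ROI on one section
#'
#' Lays the offset grid over the ROI bounding box (the ROI is 100% covered)
#' and counts points inside the ROI under the boundary rule of
#' [roi_contains()]. Over random offsets, `E[P] * a_p` equals the ROI area.
#'
#' @param roi the region of interest.
#' @param grid a [point_grid()].
#' @return Integer point count P.
#' @export
count_points <- function(roi, grid) {
  stopifnot(inherits(grid, "point_grid"))
  bb <- roi_bbox(roi)
  d <- grid$spacing
  ix <- seq(floor((bb[1] - grid$offset[1]) / d),
            ceiling((bb[3] - grid$offset[1]) / d))
  iy <- seq(floor((bb[2] - grid$offset[2]) / d),
            ceiling((bb[4] - grid$offset[2]) / d))
  gx <- grid$offset[1] + ix * d
  gy <- grid$offset[2] + iy * d
  pts <- expand.grid(x = gx, y = gy)
  sum(roi_contains(roi, pts$x, pts$y))
}

#' Cavalieri volume estimate from section point counts
#'
#' `Volume = T * a(p) * sum(P)` where `T` is the spacing between sampled
#' sections, `a(p)` the grid area per point, and `P` the per-section counts
#' of points hitting the ROI. Fewer than 200 total points triggers a
#' precision warning (the conventional minimum for accurate estimates).
#'
#' @param P_per_section integer vector of per-section point counts (>= 0).
#' @param a_p area per point, um^2.
#' @param T spacing between sampled sections, um.
#' @return A `cavalieri_estimate` with `volume` (um^3), `volume_per_section`,
#'   `P_sum`, and the inputs.
#' @examples
#' cavalieri_volume(c(50, 50, 50, 50), a_p = 100, T = 240)$volume # 4.8e6
#' @export
cavalieri_volume <- function(P_per_section, a_p, T) {
  if (length(P_per_section) == 0) stop("`P_per_section` must be non-empty")
  if (any(P_per_section < 0)) stop("point counts must be >= 0")
  assert_scalar_num(a_p, "a_p", positive = TRUE)
  assert_scalar_num(T, "T", positive = TRUE)
  P_sum <- sum(P_per_section)
  if (P_sum < 200) {
    log_exclusion("low_point_count",
                  sprintf("Cavalieri P_sum = %d < 200", P_sum))
    warning(sprintf("only %d points counted (< 200): volume estimate may be imprecise",
                    P_sum), call. = FALSE)
  }
  structure(
    list(T = T, a_p = a_p, P_per_section = P_per_section, P_sum = P_sum,
         volume = T * a_p * P_sum,
         volume_per_section = T * a_p * P_per_section),
    class = "cavalieri_estimate"
  )
}

#' @export
print.cavalieri_estimate <- function(x, ...) {
  cat(sprintf(
    "<cavalieri_estimate> V = %.4g um^3 (T = %g um, a(p) = %g um^2, sum P = %d over %d sections)\n",
    x$volume, x$T, x$a_p, x$P_sum, length(x$P_per_section)))
  invisible(x)
}

#' Unbiased counting frame for the optical disector
#'
#' A rectangular frame of area `a = width * height` with one associated
#' corner point (the upper-right corner, p = 1) and a disector height `h`
#' along z. The right and upper borders are inclusion lines; the left and
#' lower borders are exclusion lines.
#'
#' @param x0,y0 frame origin (lower-left corner), um.
#' @param width,height frame extent, um.
#' @param disector_height disector height h, um.
#' @return A `counting_frame`.
#' @export
counting_frame <- function(x0, y0, width, height, disector_height) {
  assert_scalar_num(width, "width", positive = TRUE)
  assert_scalar_num(height, "height", positive = TRUE)
  assert_scalar_num(disector_height, "disector_height", positive = TRUE)
  structure(list(x0 = x0, y0 = y0, width = width, height = height,
                 disector_height = disector_height,
                 area = width * height, p = 1L),
            class = "counting_frame")
}

#' Optical-disector count within one frame
#'
#' A cell is counted iff its unique counting point (1) lies strictly inside
#' the frame laterally, or on the right/upper inclusion border -- never on
#' the left/lower exclusion border -- and (2) has z within
#' `(guard_top, guard_top + h]` measured down from the section top (the zero
#' position set where the first cell comes into focus; no top guard zone by
#' default).
#'
#' @param frame a [counting_frame()].
#' @param cells data.frame with columns `x`, `y` and `z_rel` (counting-point
#'   depth within the section, measured um).
#' @param t_measured optional measured section thickness, um; an error is
#'   raised if the disector does not fit inside it.
#' @param guard_top top guard-zone height, um (default 0).
#' @return Integer count Q-.
#' @export
disector_count <- function(frame, cells, t_measured = NULL, guard_top = 0) {
  stopifnot(inherits(frame, "counting_frame"))
  if (!is.null(t_measured) &&
      guard_top + frame$disector_height > t_measured) {
    stop("disector height (plus guard zone) exceeds measured section thickness")
  }
  if (nrow(cells) == 0) return(0L)
  inc <- cells$x > frame$x0 & cells$x <= frame$x0 + frame$width &
    cells$y > frame$y0 & cells$y <= frame$y0 + frame$height &
    cells$z_rel > guard_top &
    cells$z_rel <= guard_top + frame$disector_height
  sum(inc)
}

#' Place counting frames systematically over an ROI
#'
#' Frames are laid on an `n_x` by `n_y` systematic grid with a uniformly
#' random phase, constrained to fit inside the ROI bounding box (so lateral
#' frame placement is uniform over admissible origins). A frame's corner
#' point is its upper-right corner; frames whose corner misses the ROI keep
#' their counts but contribute no corner point.
#'
#' @param roi the region of interest.
#' @param frame_width,frame_height frame extent, um.
#' @param disector_height disector height h, um.
#' @param n_x,n_y frames per axis (default 4 x 6 = 24, within the 21-24
#'   frames-per-ROI design range).
#' @param target_range frame-count range that triggers no warning.
#' @param seed integer seed for the random phase.
#' @return List of [counting_frame()]s, each with a `corner_in_roi` flag.
#' @export
place_frames <- function(roi, frame_width, frame_height, disector_height,
                         n_x = 4, n_y = 6, target_range = c(21, 24),
                         seed = NULL) {
  bb <- roi_bbox(roi)
  span_x <- bb[3] - bb[1] - frame_width
  span_y <- bb[4] - bb[2] - frame_height
  if (span_x < 0 || span_y < 0) stop("frame does not fit inside the ROI bounding box")
  n_frames <- n_x * n_y
  if (n_frames < target_range[1] || n_frames > target_range[2]) {
    warning(sprintf("%d frames per ROI is outside the configured %d-%d range",
                    n_frames, target_range[1], target_range[2]), call. = FALSE)
  }
  with_seed(seed, {
    px <- span_x / n_x
    py <- span_y / n_y
    ox <- stats::runif(1, 0, max(px, .Machine$double.eps))
    oy <- stats::runif(1, 0, max(py, .Machine$double.eps))
    frames <- vector("list", n_frames)
    k <- 1L
    for (i in seq_len(n_x)) {
      for (j in seq_len(n_y)) {
        f <- counting_frame(bb[1] + ox + (i - 1) * px,
                            bb[2] + oy + (j - 1) * py,
                            frame_width, frame_height, disector_height)
        f$corner_in_roi <- roi_contains(roi, f$x0 + f$width, f$y0 + f$height)
        frames[[k]] <- f
        k <- k + 1L
      }
    }
    frames
  })
}

#' Number-weighted mean section thickness
#'
#' `tQ_bar = sum(t_i * Q_i) / sum(Q_i)`: sections contribute in proportion
#' to the cells counted in them. With no counted cells the unweighted mean
#' is returned with a warning.
#'
#' @param t per-section measured thicknesses, um.
#' @param Q per-section disector counts.
#' @return Scalar tQ_bar, um.
#' @export
number_weighted_mean_thickness <- function(t, Q) {
  stopifnot(length(t) == length(Q), length(t) >= 1)
  if (sum(Q) == 0) {
    warning("all disector counts are zero; returning unweighted mean thickness",
            call. = FALSE)
    return(mean(t))
  }
  sum(t * Q) / sum(Q)
}

#' Numerical density from optical-disector counts
#'
#' The thickness-corrected optical-disector estimator
#' `Nv = (tQ_bar / BA) * sum(Q-) / (h * (a/p) * sum(P))`,
#' where `tQ_bar` is the number-weighted mean measured section thickness,
#' `BA` the block advance, `h` the disector height, `a/p` the frame area per
#' corner point, and `sum(P)` the number of corner points hitting reference
#' tissue. The `tQ_bar / BA` factor corrects for z shrinkage of the cut
#' sections (it is 1 when measured thickness equals the block advance).
#'
#' @param Q_sum total disector count over all frames.
#' @param P_corner_sum number of frame corner points hitting the ROI (> 0).
#' @param tQ_bar number-weighted mean section thickness, um.
#' @param BA block advance, um.
#' @param h disector height, um.
#' @param a_p_frame frame area per corner point, um^2.
#' @return An `nv_estimate` with `Nv` in cells/um^3.
#' @examples
#' nv_estimate(100, 20, tQ_bar = 40, BA = 40, h = 10, a_p_frame = 400)$Nv
#' @export
nv_estimate <- function(Q_sum, P_corner_sum, tQ_bar, BA, h, a_p_frame) {
  assert_scalar_num(BA, "BA", positive = TRUE)
  assert_scalar_num(h, "h", positive = TRUE)
  assert_scalar_num(a_p_frame, "a_p_frame", positive = TRUE)
  assert_scalar_num(Q_sum, "Q_sum", nonneg = TRUE)
  if (tQ_bar > BA) stop("`tQ_bar` cannot exceed the block advance `BA`")
  if (P_corner_sum <= 0) {
    stop("no corner points hit reference tissue (sum P = 0): density undefined")
  }
  structure(
    list(tQ_bar = tQ_bar, BA = BA, h = h, a_p_frame = a_p_frame,
         Q_sum = Q_sum, P_corner_sum = P_corner_sum,
         Nv = (tQ_bar / BA) * Q_sum / (h * a_p_frame * P_corner_sum)),
    class = "nv_estimate"
  )
}

#' @export
print.nv_estimate <- function(x, ...) {
  cat(sprintf(
    "<nv_estimate> Nv = %.4g cells/um^3 (sum Q- = %g over sum P = %g corner points, tQ-/BA = %.3f)\n",
    x$Nv, x$Q_sum, x$P_corner_sum, x$tQ_bar / x$BA))
  invisible(x)
}

#' Total cell number from density and reference volume
#'
#' `N = V_ref * Nv`.
#'
#' @param Nv numerical density (cells/um^3) or an [nv_estimate()].
#' @param Vref reference volume (um^3) or a [cavalieri_volume()] estimate.
#' @return Estimated total number of cells.
#' @export
total_number <- function(Nv, Vref) {
  if (inherits(Nv, "nv_estimate")) Nv <- Nv$Nv
  if (inherits(Vref, "cavalieri_estimate")) Vref <- Vref$volume
  assert_scalar_num(Nv, "Nv", nonneg = TRUE)
  assert_scalar_num(Vref, "Vref", nonneg = TRUE)
  Vref * Nv
}

#' Soma volume from serial-plane areas
#'
#' Cavalieri estimate of a soma's volume from its delineated area on
#' consecutive optical planes spaced `T` um apart. The default (standard
#' Cavalieri) mode is `sum(A) * T`; the `paper_literal` mode multiplies by
#' the number of planes as well (`sum(A) * n * T`), retained for
#' compatibility with reports using that convention.
#'
#' @param plane_areas per-plane areas A_i, um^2 (>= 0, non-empty).
#' @param T plane spacing, um.
#' @param mode `"standard"` (default) or `"paper_literal"`.
#' @return A `soma_volume_estimate` with `volume` (um^3).
#' @export
soma_volume <- function(plane_areas, T = 1,
                        mode = c("standard", "paper_literal")) {
  mode <- match.arg(mode)
  if (length(plane_areas) == 0) stop("`plane_areas` must be non-empty")
  if (any(plane_areas < 0)) stop("plane areas must be >= 0")
  assert_scalar_num(T, "T", positive = TRUE)
  n <- length(plane_areas)
  vol <- sum(plane_areas) * T
  if (mode == "paper_literal") vol <- vol * n
  structure(
    list(plane_areas = plane_areas, plane_spacing = T, n_planes = n,
         volume = vol, mode = mode),
    class = "soma_volume_estimate"
  )
}

#' @export
print.soma_volume_estimate <- function(x, ...) {
  cat(sprintf("<soma_volume_estimate> V = %.4g um^3 (%d planes, T = %g um, mode = %s)\n",
              x$volume, x$n_planes, x$plane_spacing, x$mode))
  invisible(x)
}

#' Background-corrected mean soma intensity
#'
#' Mean marker intensity over the delineated soma pixels with the per-image
#' background subtracted; negative corrected values are clamped at 0 with a
#' warning.
#'
#' @param pixels_in_soma intensity values of the soma pixels (non-empty).
#' @param background background level, a.u.
#' @return A `soma_intensity` with `mean_intensity`, `background`,
#'   `corrected`.
#' @export
soma_intensity <- function(pixels_in_soma, background = 0) {
  if (length(pixels_in_soma) == 0) stop("`pixels_in_soma` must be non-empty")
  m <- mean(pixels_in_soma)
  corr <- m - background
  if (corr < 0) {
    warning("background exceeds mean soma intensity; clamping corrected value at 0",
            call. = FALSE)
    corr <- 0
  }
  structure(list(mean_intensity = m, background = background,
                 corrected = corr),
            class = "soma_intensity")
}

#' End-to-end stereological estimate on a sectioned tissue
#'
#' Runs the full design on a [section_field()] result: Cavalieri reference
#' volume from point counts on the sampled sections, optical-disector counts
#' in systematically placed frames, the number-weighted thickness
#' correction, and the resulting density and total number. Used for
#' parameter-recovery validation against the generator's ground truth.
#'
#' @param tissue a `sectioned_tissue`.
#' @param roi lateral ROI (default: the full block cross-section).
#' @param a_p_grid Cavalieri grid area per point, um^2.
#' @param frame_width,frame_height,disector_height counting-frame geometry, um.
#' @param n_x,n_y frames per axis per section.
#' @param seed integer seed for grid and frame phases.
#' @return A `stereology_estimate` with the `cavalieri` and `nv` component
#'   estimates, `N_total`, and the per-section tallies.
#' @export
estimate_region <- function(tissue, roi = NULL, a_p_grid = 2704,
                            frame_width = 20, frame_height = 20,
                            disector_height = 10, n_x = 4, n_y = 6,
                            seed = NULL) {
  stopifnot(inherits(tissue, "sectioned_tissue"))
  if (is.null(roi)) roi <- roi_rect(0, 0, tissue$bounds[1], tissue$bounds[2])
  sec <- tissue$sections[tissue$sections$sampled, , drop = FALSE]
  if (nrow(sec) == 0) stop("no sampled sections in tissue")
  seeds <- derive_seeds(seed %||% sample.int(.Machine$integer.max, 1),
                        2L * nrow(sec))
  P <- integer(nrow(sec))
  Q_sec <- integer(nrow(sec))
  Q_sum <- 0L
  P_corner <- 0L
  for (i in seq_len(nrow(sec))) {
    grid <- point_grid(a_p_grid, seed = seeds[2 * i - 1])
    P[i] <- count_points(roi, grid)
    frames <- place_frames(roi, frame_width, frame_height, disector_height,
                           n_x = n_x, n_y = n_y, seed = seeds[2 * i])
    cells_i <- tissue$cells[tissue$cells$section_id == sec$section_id[i], ]
    # only cells inside the ROI are eligible; frames keep their in-ROI
    # counts even when their corner point misses the reference tissue
    cells_i <- cells_i[roi_contains(roi, cells_i$x, cells_i$y), ]
    q <- vapply(frames, disector_count, integer(1), cells = cells_i,
                t_measured = sec$t[i])
    Q_sec[i] <- sum(q)
    Q_sum <- Q_sum + sum(q)
    P_corner <- P_corner + sum(vapply(frames, `[[`, logical(1), "corner_in_roi"))
  }
  cav <- cavalieri_volume(P, a_p = a_p_grid, T = tissue$T)
  tQ_bar <- number_weighted_mean_thickness(sec$t, Q_sec)
  nv <- nv_estimate(Q_sum, P_corner, tQ_bar, BA = sec$BA[1],
                    h = disector_height, a_p_frame = frame_width * frame_height)
  structure(
    list(cavalieri = cav, nv = nv, N_total = total_number(nv, cav),
         P_per_section = P, Q_per_section = Q_sec, tQ_bar = tQ_bar),
    class = "stereology_estimate"
  )
}

#' @export
print.stereology_estimate <- function(x, ...) {
  cat(sprintf(
    "<stereology_estimate> Vref = %.4g um^3, Nv = %.4g /um^3, N = %.1f cells\n",
    x$cavalieri$volume, x$nv$Nv, x$N_total))
  invisible(x)
}
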