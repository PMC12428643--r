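test_that("Cavalieri volume follows V = T * a(p) * sum(P)", {
  est <- cavalieri_volume(c(50, 50, 50, 50), a_p = 100, T = 240)
  expect_equal(est$volume, 4.8e6)
  expect_equal(est$P_sum, 200)
  expect_equal(est$volume_per_section, rep(1.2e6, 4))

  expect_warning(z <- cavalieri_volume(c(0, 0, 0), a_p = 100, T = 240),
                 "200")
  expect_equal(z$volume, 0)
  expect_warning(cavalieri_volume(rep(10, 5), 100, 240), "imprecise")
  expect_error(cavalieri_volume(numeric(0), 100, 240), "non-empty")
  expect_error(cavalieri_volume(c(-1, 5), 100, 240), ">= 0")
})

test_that("point counting covers the ROI and is unbiased over offsets", {
  # 100 x 100 um ROI densely covered by a 10 um grid anchored at (0, 0):
  # half-open boundary rule counts exactly area / a_p points
  g <- point_grid(100, offset = c(0, 0))
  expect_equal(count_points(roi_rect(0, 0, 100, 100), g), 100)

  # an ROI smaller than one grid period that the offset grid misses
  expect_equal(count_points(roi_rect(3, 3, 2, 2), g), 0)

  # systematic-sampling unbiasedness: E[P] * a_p = area, circle ROI
  r <- 40
  theta <- seq(0, 2 * pi, length.out = 73)[-73]
  circ <- roi_polygon(50 + r * cos(theta), 50 + r * sin(theta))
  P <- vapply(1:200, function(s)
    count_points(circ, point_grid(100, seed = s)), numeric(1))
  xs <- 50 + r * cos(theta); ys <- 50 + r * sin(theta)
  nx <- c(xs[-1], xs[1]); ny <- c(ys[-1], ys[1])
  area_poly <- 0.5 * abs(sum(xs * ny - nx * ys))
  se <- stats::sd(P * 100) / sqrt(length(P))
  expect_lt(abs(mean(P * 100) - area_poly), 3 * se)
})

test_that("polygon containment agrees with an independent implementation", {
  theta <- seq(0, 2 * pi, length.out = 13)[-13]
  vx <- 50 + 40 * cos(theta) * (1 + 0.3 * sin(3 * theta))
  vy <- 50 + 40 * sin(theta) * (1 + 0.3 * sin(3 * theta))
  poly <- roi_polygon(vx, vy)
  withr::with_seed(31, {
    px <- stats::runif(500, 0, 100)
    py <- stats::runif(500, 0, 100)
  })
  expect_equal(roi_contains(poly, px, py),
               as.logical(mgcv::in.out(cbind(c(vx, vx[1]), c(vy, vy[1])),
                                       cbind(px, py))))
})

test_that("counting-frame rules: inclusion borders in, exclusion borders out", {
  fr <- counting_frame(0, 0, 20, 20, disector_height = 10)
  cell <- function(x, y, z) data.frame(x = x, y = y, z_rel = z)
  expect_equal(disector_count(fr, cell(20, 10, 5)), 1)  # right border: in
  expect_equal(disector_count(fr, cell(10, 20, 5)), 1)  # upper border: in
  expect_equal(disector_count(fr, cell(0, 10, 5)), 0)   # left border: out
  expect_equal(disector_count(fr, cell(10, 0, 5)), 0)   # lower border: out
  expect_equal(disector_count(fr, cell(0, 0, 5)), 0)    # lower-left corner
  expect_equal(disector_count(fr, cell(20, 20, 5)), 1)  # upper-right corner
  expect_equal(disector_count(fr, cell(10, 10, 0)), 0)  # z at the top plane
  expect_equal(disector_count(fr, cell(10, 10, 10)), 1) # z = h inclusive
  expect_equal(disector_count(fr, cell(10, 10, 10.01)), 0)
  expect_error(disector_count(fr, cell(1, 1, 1), t_measured = 8), "exceeds")
})

test_that("disector count matches a brute-force oracle on random cells", {
  withr::with_seed(17, {
    cells <- data.frame(x = stats::runif(1000, -5, 105),
                        y = stats::runif(1000, -5, 105),
                        z_rel = stats::runif(1000, 0, 30))
    for (rep in 1:5) {
      fr <- counting_frame(stats::runif(1, 0, 80), stats::runif(1, 0, 80),
                           20, 20, disector_height = stats::runif(1, 5, 25))
      expect_identical(disector_count(fr, cells),
                       brute_force_disector(fr, cells))
    }
  })
})

test_that("tiling a section with frames counts every cell exactly once", {
  f <- simulate_cell_field(2e-4, c(500, 500, 240), seed = 23)
  tt <- section_field(f, BA = 40, shrinkage = 0.75, sampling_interval = 6,
                      seed = 24)
  sec_id <- tt$sections$section_id[tt$sections$sampled][1]
  cells <- tt$cells[tt$cells$section_id == sec_id, ]
  t_meas <- tt$sections$t[sec_id]
  total <- 0L
  for (ix in 0:24) for (iy in 0:24) {
    fr <- counting_frame(ix * 20, iy * 20, 20, 20, disector_height = t_meas)
    total <- total + disector_count(fr, cells)
  }
  # counting points at z_rel = 0 are excluded by the half-open z band but
  # occur with probability zero for continuous positions
  expect_identical(total, nrow(cells))
})

test_that("Nv estimator reproduces the worked value and guards its domain", {
  nv <- nv_estimate(100, 20, tQ_bar = 40, BA = 40, h = 10, a_p_frame = 400)
  expect_equal(nv$Nv, 1.25e-3)
  expect_equal(nv_estimate(0, 20, 40, 40, 10, 400)$Nv, 0)
  expect_error(nv_estimate(100, 0, 40, 40, 10, 400), "undefined")
  expect_error(nv_estimate(100, 20, 50, 40, 10, 400), "exceed")
})

test_that("number-weighted mean thickness weights by counted cells", {
  expect_equal(number_weighted_mean_thickness(rep(30, 6), c(3, 1, 4, 1, 5, 9)),
               30)
  expect_equal(number_weighted_mean_thickness(c(20, 40), c(1, 3)), 35)
  expect_equal(number_weighted_mean_thickness(c(40, 20), c(3, 1)), 35)
  expect_warning(m <- number_weighted_mean_thickness(c(20, 40), c(0, 0)),
                 "unweighted")
  expect_equal(m, 30)
})

test_that("total number is the exact product of density and volume", {
  expect_equal(total_number(1.25e-3, 4.8e6), 6000)
  expect_equal(total_number(1.25e-3, 0), 0)
  nv <- nv_estimate(100, 20, 40, 40, 10, 400)
  cav <- cavalieri_volume(rep(50, 4), 100, 240)
  expect_equal(total_number(nv, cav), nv$Nv * cav$volume)
})

test_that("soma volume estimator handles both modes and a sphere", {
  expect_equal(soma_volume(100, T = 1)$volume, 100)

  # sphere of radius 5 um sampled at 1 um plane spacing
  z <- seq(-4.5, 4.5, by = 1)
  areas <- pi * (25 - z^2)
  est <- soma_volume(areas, T = 1)
  expect_lt(abs(est$volume - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.05)

  lit <- soma_volume(areas, T = 1, mode = "paper_literal")
  expect_equal(lit$volume, est$volume * length(areas))

  expect_error(soma_volume(numeric(0), 1), "non-empty")
  expect_equal(soma_volume(c(0, 0), 1)$volume, 0)
})

test_that("soma intensity subtracts background and clamps at zero", {
  si <- soma_intensity(rep(1000, 50), background = 200)
  expect_equal(si$corrected, 800)
  expect_warning(s2 <- soma_intensity(rep(100, 10), background = 150),
                 "clamping")
  expect_equal(s2$corrected, 0)
  checker <- rep(c(0, 100), 50)
  expect_equal(soma_intensity(checker, background = 10)$corrected, 40)
  expect_error(soma_intensity(numeric(0)), "non-empty")
})

test_that("estimates scale correctly with units: V ~ s^3, Nv ~ s^-3, N fixed", {
  withr::with_seed(41, {
    for (i in 1:10) {
      P <- stats::rpois(5, 80)
      a_p <- stats::runif(1, 50, 500)
      T_sp <- stats::runif(1, 100, 300)
      Q <- stats::rpois(1, 60)
      Pc <- stats::rpois(1, 20) + 1
      h <- stats::runif(1, 5, 15)
      BA <- stats::runif(1, 30, 50)
      tq <- BA * stats::runif(1, 0.5, 1)
      s <- 2
      v1 <- suppressWarnings(cavalieri_volume(P, a_p, T_sp))$volume
      v2 <- suppressWarnings(cavalieri_volume(P, a_p * s^2, T_sp * s))$volume
      expect_equal(v2, v1 * s^3)
      n1 <- nv_estimate(Q, Pc, tq, BA, h, a_p)$Nv
      n2 <- nv_estimate(Q, Pc, tq * s, BA * s, h * s, a_p * s^2)$Nv
      expect_equal(n2, n1 / s^3)
      expect_equal(total_number(n2, v2), total_number(n1, v1))
    }
  })
})

test_that("end-to-end regional estimate recovers a known density", {
  f <- simulate_cell_field(1e-4, c(500, 500, 1200), seed = 55)
  Ns <- vapply(1:40, function(i) {
    tt <- section_field(f, BA = 40, shrinkage = 0.75, sampling_interval = 6,
                        seed = 100 + i)
    estimate_region(tt, seed = 900 + i)$N_total
  }, numeric(1))
  se <- stats::sd(Ns) / sqrt(length(Ns))
  expect_lt(abs(mean(Ns) - nrow(f$cells)), 3 * se)
})
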