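# Config used to test the geometric core of the estimator on analytic
# (noise-free) curves: no dead-band, no end-weighting.
analytic_config <- function(...) {
  tortuosity_config(angle_floor_rad = 0, end_trim = 0, ...)
}

test_that("resample_chain spaces points evenly and keeps endpoints", {
  chain <- cbind(10, 1:100)
  poly <- resample_chain(chain, spacing_px = 5, smoothing_window = 9)
  expect_equal(nrow(poly$points), 21)            # 99 px of arc at 5 px
  expect_equal(poly$points[1, ], c(10, 1))
  expect_equal(poly$points[21, ], c(10, 100))
  # collinear in, collinear out
  expect_true(all(abs(turning_angles(poly)) < 1e-9))
  # spacing contract
  d <- sqrt(rowSums(diff(poly$points)^2))
  expect_true(all(d >= 0.5 * 5 & d <= 1.5 * 5))
})

test_that("a 2-point chain is returned unchanged", {
  chain <- cbind(c(1, 7), c(2, 9))
  poly <- resample_chain(chain)
  expect_equal(poly$points, chain)
  expect_error(resample_chain(cbind(1, 2)), "at least 2")
})

test_that("smoothing reduces deviation of a jittered straight chain", {
  set.seed(21)
  x <- 1:120
  jitter <- sample(c(-1, 0, 1), 120, replace = TRUE)
  jitter[c(1, 120)] <- 0   # endpoints are preserved exactly by design
  chain <- cbind(40 + jitter, x)
  dev_before <- max(abs(chain[, 1] - 40))
  poly <- resample_chain(chain, spacing_px = 5, smoothing_window = 9)
  dev_after <- max(abs(poly$points[, 1] - 40))
  expect_lt(dev_after, dev_before)
})

test_that("turning angles match hand geometry", {
  expect_equal(turning_angles(cbind(c(0, 1, 1), c(0, 0, 1))), pi / 2)
  expect_equal(turning_angles(cbind(c(0, 1, 2), c(0, 1, 2))), 0)
  expect_length(turning_angles(cbind(c(0, 1), c(0, 1))), 0)
  # k points equally spaced on a circle: every interior angle = 2 pi / (k-1)
  k <- 13
  th <- seq(0, 2 * pi, length.out = k)
  pts <- cbind(50 * sin(th), 50 * cos(th))
  ang <- turning_angles(pts)
  expect_length(ang, k - 2)
  expect_equal(ang, rep(2 * pi / (k - 1), k - 2), tolerance = 1e-9)
})

test_that("straight segments give cti 1, ic 0, oc 0", {
  for (ang in c(0.2, 0.9, 1.4)) {
    t0 <- seq(0, 200, by = 1)
    chain <- cbind(300 - t0 * sin(ang), 10 + t0 * cos(ang))
    st <- segment_tortuosity(chain, tortuosity_config())
    expect_equal(st$cti, 1, tolerance = 1e-6)
    expect_equal(st$ic, 0)
    expect_equal(st$oc, 0)
    expect_false(st$flagged)
  }
})

test_that("analytic semicircle matches arc/chord = pi/2 and total curvature pi", {
  th <- seq(0, pi, length.out = 4001)
  chain <- cbind(300 - 100 * sin(th), 300 - 100 * cos(th))
  st <- segment_tortuosity(chain, analytic_config())
  expect_equal(st$cti, pi / 2, tolerance = 0.01 * pi / 2)
  expect_equal(st$ic, pi, tolerance = 0.05 * pi)
})

test_that("analytic sinusoids match the quadrature oracle", {
  # arc/chord at the wavelength used for raster validation
  x <- seq(0, 100, length.out = 4001)
  chain <- cbind(300 - 10 * sin(2 * pi * x / 100), 100 + x)
  st <- segment_tortuosity(chain, analytic_config())
  expect_equal(st$cti, sinusoid_ratio_oracle(10, 100), tolerance = 0.01)
  # total absolute curvature within the tangent-filter passband
  lam <- 250
  x2 <- seq(0, 2 * lam, length.out = 8001)
  chain2 <- cbind(300 - 25 * sin(2 * pi * x2 / lam), 50 + x2)
  kap <- stats::integrate(function(u) {
    yp <- 25 * 2 * pi / lam * cos(2 * pi * u / lam)
    ypp <- -25 * (2 * pi / lam)^2 * sin(2 * pi * u / lam)
    abs(ypp) / (1 + yp^2)
  }, 0, 2 * lam, subdivisions = 500L)$value
  st2 <- segment_tortuosity(chain2, analytic_config())
  expect_equal(st2$ic, kap, tolerance = 0.05 * kap)
})

test_that("cti is at least 1, and 1 only for straight polylines", {
  set.seed(33)
  cfg <- tortuosity_config()
  for (rep in 1:10) {
    t0 <- seq(0, 300, by = 1)
    a <- stats::runif(1, 0, 30)
    ph <- stats::runif(1, 0, 2 * pi)
    chain <- cbind(200 + a * sin(2 * pi * t0 / 150 + ph), 10 + t0)
    st <- segment_tortuosity(chain, cfg)
    expect_gte(st$cti, 1 - 1e-9)
    if (a > 2) expect_gt(st$cti, 1 + 1e-6)
  }
})

test_that("metrics are invariant under rigid motion of analytic chains", {
  x <- seq(0, 300, length.out = 3001)
  chain <- cbind(200 - 15 * sin(2 * pi * x / 150), 20 + x)
  rot <- function(p, th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sweep(p %*% t(R), 2, c(40, -13), "+")
  }
  cfg <- tortuosity_config()
  s0 <- segment_tortuosity(chain, cfg)
  s1 <- segment_tortuosity(rot(chain, 0.6), cfg)
  expect_equal(s1$cti, s0$cti, tolerance = 1e-6)
  expect_equal(s1$ic, s0$ic, tolerance = 1e-4)
  expect_equal(s1$oc, s0$oc, tolerance = 1e-4)
})

test_that("cti is scale invariant; ic is stable when spacing scales along", {
  x <- seq(0, 300, length.out = 3001)
  chain <- cbind(200 - 20 * sin(2 * pi * x / 150), 20 + x)
  big <- chain * 2
  cfg1 <- analytic_config(spacing_px = 5, smoothing_window = 9,
                          tangent_window_px = 35)
  cfg2 <- analytic_config(spacing_px = 10, smoothing_window = 18,
                          tangent_window_px = 70)
  s1 <- segment_tortuosity(chain, cfg1)
  s2 <- segment_tortuosity(big, cfg2)
  expect_equal(s2$cti, s1$cti, tolerance = 0.002)
  expect_equal(s2$ic, s1$ic, tolerance = 0.02 * s1$ic)
})

test_that("closed-loop segments are flagged and excluded from image means", {
  th <- seq(0, 2 * pi, length.out = 400)
  loop <- cbind(100 + 40 * sin(th), 100 + 40 * cos(th))
  st <- segment_tortuosity(loop, tortuosity_config())
  expect_true(st$flagged)
  ok <- segment_tortuosity(cbind(10, seq(1, 100)), tortuosity_config())
  res <- image_tortuosity(list(st, ok), "img")
  expect_equal(res$n_segments, 1)
  expect_equal(res$n_flagged, 1)
  expect_error(image_tortuosity(list(st), "only_flagged"), "only_flagged")
})

test_that("image-level aggregation is the unweighted mean of segments", {
  mk <- function(cti, ic, oc, arc) {
    structure(list(segment_id = "s", theta = numeric(0),
                   theta_weight = numeric(0), cti = cti, ic = ic, oc = oc,
                   arc_length_px = arc, chord_length_px = arc,
                   flagged = FALSE), class = "segment_tortuosity")
  }
  one <- image_tortuosity(list(mk(1.2, 2, 0.05, 100)), "one")
  expect_equal(one$cti, 1.2)
  two <- image_tortuosity(list(mk(1.0, 1, 0.02, 100), mk(1.2, 3, 0.04, 300)), "two")
  expect_equal(two$cti, 1.1)
  expect_equal(two$ic, 2)
  lw <- image_tortuosity(list(mk(1.0, 1, 0.02, 100), mk(1.2, 3, 0.04, 300)), "lw",
                         config = tortuosity_config(aggregate = "length_weighted"))
  expect_equal(lw$cti, (1.0 * 100 + 1.2 * 300) / 400)
  expect_error(image_tortuosity(list(), "none"), "none")
})

test_that("the angle-sum CTI variant is exposed and >= 1", {
  x <- seq(0, 300, length.out = 3001)
  chain <- cbind(200 - 20 * sin(2 * pi * x / 150), 20 + x)
  st <- segment_tortuosity(chain, tortuosity_config(cti_formula = "angle_sum"))
  expect_gt(st$cti, 1)
  straight <- segment_tortuosity(cbind(10, seq(1, 200)),
                                 tortuosity_config(cti_formula = "angle_sum"))
  expect_equal(straight$cti, 1)
})

test_that("config hashes are stable and sensitive to every field", {
  c1 <- tortuosity_config()
  c2 <- tortuosity_config()
  expect_identical(config_hash(c1), config_hash(c2))
  c3 <- tortuosity_config(spacing_px = 6)
  expect_false(config_hash(c1) == config_hash(c3))
  c4 <- tortuosity_config(cti_formula = "angle_sum")
  expect_false(config_hash(c1) == config_hash(c4))
})
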