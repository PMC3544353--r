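test_that("grayscale conversion applies luma weights and passes gray through", {
  # channel-equal image collapses to the shared value (weights sum to 1)
  g <- array(rep(c(10, 200), each = 4), dim = c(2, 2, 3))
  g[, , 2] <- g[, , 1]
  g[, , 3] <- g[, , 1]
  expect_equal(to_grayscale(g), g[, , 1])

  red <- array(c(255, 0, 0), dim = c(1, 1, 3))
  blue <- array(c(0, 0, 255), dim = c(1, 1, 3))
  expect_equal(to_grayscale(red)[1, 1], 76.245)
  expect_equal(to_grayscale(blue)[1, 1], 0.114 * 255)

  m <- matrix(runif(12), 3, 4)
  expect_identical(to_grayscale(m), m)
})

test_that("grayscale conversion rejects bad input and drops alpha with a warning", {
  bad <- matrix(c(1, NA, 3, 4), 2, 2)
  expect_error(to_grayscale(bad), class = "dfa2d_error_image")
  rgba <- array(runif(16), dim = c(2, 2, 4))
  expect_warning(g <- to_grayscale(rgba), "alpha")
  expect_equal(dim(g), c(2, 2))
  expect_error(to_grayscale(array(1, dim = c(2, 2, 5))), class = "dfa2d_error_format")
})

test_that("integration matches the hand-derived 2x2 example and the loop oracle", {
  expect_equal(integrate_image(matrix(c(1, 5, 3, 7), 2, 2)),
               matrix(c(-3, -1, -2, 0), 2, 2))
  for (seed in 1:5) {
    px <- rand_image(13, 17, seed)
    expect_equal(integrate_image(px), naive_integrate(px), tolerance = 1e-12)
  }
})

test_that("integration is zero for constant images and linear in intensity", {
  expect_equal(integrate_image(matrix(7.3, 9, 12)), matrix(0, 9, 12))
  px <- rand_image(16, 16, 3)
  expect_equal(integrate_image(2.5 * px + 40), 2.5 * integrate_image(px),
               tolerance = 1e-12)
  expect_error(integrate_image(matrix(numeric(0), 0, 5)), class = "dfa2d_error_image")
})

test_that("segment grid bookkeeping follows floor arithmetic", {
  g <- segment_grid(100, 80, 8)
  expect_equal(g$M_s, 12)
  expect_equal(g$N_s, 10)
  expect_equal(g$discarded_rows, 4)
  expect_equal(g$discarded_cols, 0)

  g2 <- segment_grid(16, 16, 4)
  expect_equal(c(g2$M_s, g2$N_s, g2$discarded_rows, g2$discarded_cols), c(4, 4, 0, 0))

  # sweep: counts and discards always consistent
  for (M in c(16, 23, 40)) {
    for (N in c(17, 32)) {
      for (s in 4:floor(min(M, N) / 4)) {
        g <- segment_grid(M, N, s)
        expect_equal(g$M_s, M %/% s)
        expect_equal(g$N_s, N %/% s)
        expect_equal(g$M_s * s + g$discarded_rows, M)
        expect_equal(g$N_s * s + g$discarded_cols, N)
      }
    }
  }
})

test_that("segment grid enforces scale bounds with informative errors", {
  expect_error(segment_grid(16, 16, 5), class = "dfa2d_error_scale")
  expect_error(segment_grid(16, 16, 3), class = "dfa2d_error_scale")
  expect_error(segment_grid(100, 100, 4.5), class = "dfa2d_error_scale")
  expect_error(segment_grid(8, 8, 4), class = "dfa2d_error_dimension")
  # relaxed testing bound admits s = 2 and 3
  expect_equal(segment_grid(16, 16, 2, relax_min = TRUE)$M_s, 8)
  expect_equal(segment_grid(16, 16, 3, relax_min = TRUE)$M_s, 5)
  expect_error(segment_grid(16, 16, 2), class = "dfa2d_error_scale")
})

test_that("plane fit recovers exact planes and matches a normal-equations oracle", {
  s <- 5
  plane <- 2 + outer(3 * seq_len(s), 4 * seq_len(s), "+")
  f <- fit_plane(plane)
  expect_equal(c(f$intercept, f$row_slope, f$col_slope, f$mse), c(2, 3, 4, 0),
               tolerance = 1e-10)

  fc <- fit_plane(matrix(6.5, 4, 4))
  expect_equal(c(fc$intercept, fc$row_slope, fc$col_slope, fc$mse), c(6.5, 0, 0, 0),
               tolerance = 1e-12)

  saddle <- fit_plane(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(saddle$row_slope, 0)
  expect_equal(saddle$col_slope, 0)
  expect_equal(saddle$mse, 0.25)

  # generic segment against lm()
  set.seed(11)
  seg <- matrix(rnorm(49), 7, 7)
  d <- data.frame(z = as.vector(seg), o = rep(1:7, times = 7), p = rep(1:7, each = 7))
  ref <- lm(z ~ o + p, data = d)
  f2 <- fit_plane(seg)
  expect_equal(unname(c(f2$intercept, f2$row_slope, f2$col_slope)),
               unname(coef(ref)), tolerance = 1e-10)
  expect_equal(f2$mse, mean(resid(ref)^2), tolerance = 1e-10)

  expect_error(fit_plane(matrix(1, 2, 3)), class = "dfa2d_error_segment")
  expect_error(fit_plane(matrix(c(1, Inf, 2, 3), 2, 2)), class = "dfa2d_error_segment")
})

test_that("fluctuation is zero for constant images and planar surfaces", {
  const <- matrix(42, 32, 32)
  surf <- integrate_image(const)
  for (s in c(4, 6, 8)) expect_equal(fluctuation(surf, s), 0)
  # a globally planar surface is captured exactly by every segment's fit
  planar <- outer(0.7 * 1:40, -1.3 * 1:40, "+") + 5
  for (s in c(4, 7, 10)) expect_lt(fluctuation(planar, s), 1e-9)
})

test_that("vectorized fluctuation equals the naive loop implementation", {
  px <- rand_image(24, 24, 99)
  f_vec <- fluctuation(integrate_image(px), 4)
  expect_equal(f_vec, naive_fluctuation(px, 4), tolerance = 1e-10)
  # a few sizes and every valid scale
  for (seed in 1:5) {
    for (dims in list(c(16, 16), c(24, 24), c(32, 24))) {
      px <- rand_image(dims[1], dims[2], seed)
      surf <- integrate_image(px)
      for (s in 4:floor(min(dims) / 4)) {
        expect_equal(fluctuation(surf, s), naive_fluctuation(px, s),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("fluctuation curve points are per-scale independent and sorted", {
  px <- rand_image(48, 48, 7)
  single <- fluctuation_curve(px, 4)
  pair <- fluctuation_curve(px, c(8, 4))
  expect_identical(single$fluctuation[1], pair$fluctuation[pair$scale == 4])
  expect_equal(pair$scale, c(4, 8))
  expect_true(all(pair$fluctuation >= 0))
  expect_error(fluctuation_curve(px, integer(0)), class = "dfa2d_error_config")

  const_curve <- fluctuation_curve(matrix(1, 64, 64), 4:11)
  expect_equal(nrow(const_curve), 8)
  expect_equal(const_curve$fluctuation, rep(0, 8))
})

test_that("scaling-exponent fit recovers exact power laws and matches lm", {
  curve <- tibble::tibble(scale = 4:11, fluctuation = (4:11)^0.7)
  expect_equal(fit_scaling_exponent(curve, 4, 11)$estimate, 0.7, tolerance = 1e-12)

  curve2 <- tibble::tibble(scale = 4:11, fluctuation = 3 * (4:11)^1.0)
  f2 <- fit_scaling_exponent(curve2, 4, 11)
  expect_equal(f2$estimate, 1.0, tolerance = 1e-12)
  expect_equal(f2$intercept, log(3), tolerance = 1e-12)

  set.seed(5)
  noisy <- tibble::tibble(scale = 4:20,
                          fluctuation = exp(0.6 * log(4:20) + rnorm(17, sd = 0.05)))
  mine <- fit_scaling_exponent(noisy, 4, 20)
  ref <- lm(log(fluctuation) ~ log(scale), data = noisy)
  expect_equal(mine$estimate, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(mine$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(mine$r.squared, summary(ref)$r.squared, tolerance = 1e-10)

  zero <- tibble::tibble(scale = 4:6, fluctuation = c(1, 0, 2))
  expect_error(fit_scaling_exponent(zero, 4, 6), class = "dfa2d_error_degenerate")
  one <- tibble::tibble(scale = 4:8, fluctuation = (4:8)^0.5)
  expect_error(fit_scaling_exponent(one, 5, 5), class = "dfa2d_error_scales")
})

test_that("dfa2d uses the 4..11 short-range scales and is affine invariant", {
  img <- generate_surface(surface_spec("fbm", H = 0.5, dims = c(64, 64), seed = 2))
  fit <- dfa2d(img)
  a1 <- tidy(fit)[tidy(fit)$term == "alpha1", ]
  expect_equal(a1$n_scales, 8)
  expect_equal(c(a1$s_min, a1$s_max), c(4, 11))
  expect_true(all(4:11 %in% fit$provenance$scales))

  for (ac in list(c(2.5, 17), c(-1, 255), c(0.25, -3))) {
    fit2 <- dfa2d(ac[1] * img + ac[2])
    expect_equal(tidy(fit2)$estimate, tidy(fit)$estimate, tolerance = 1e-9)
  }
})

test_that("dfa2d rejects degenerate and undersized images", {
  expect_error(dfa2d(matrix(5, 64, 64)), class = "dfa2d_error_degenerate")
  expect_error(dfa2d(matrix(runif(1600), 40, 40)), class = "dfa2d_error_dimension")
})

test_that("dfa2d omits alpha2 and the global alpha for images with no long-range scales", {
  img <- generate_surface(surface_spec("fbm", H = 0.5, dims = c(44, 44), seed = 4))
  expect_warning(fit <- dfa2d(img), "alpha2")
  expect_identical(tidy(fit)$term, "alpha1")
  expect_true(is.na(glance(fit)$alpha2))
})

test_that("dfa2d is deterministic", {
  img <- generate_surface(surface_spec("fbm", H = 0.3, dims = c(64, 64), seed = 8))
  f1 <- dfa2d(img, id = "x")
  f2 <- dfa2d(img, id = "x")
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$curve, f2$curve)
})
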