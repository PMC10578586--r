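test_that("dish detection recovers a synthetic dish", {
  g <- gen_colony_image(80, dish_radius = 200, size = 512,
                        blur_sigma = 0, shading = 0, noise_sd = 0)
  dish <- detect_dish(g$img)
  expect_lt(abs(dish$cx - 256), 2)
  expect_lt(abs(dish$cy - 256), 2)
  expect_lt(abs(dish$radius - 200), 2)
  expect_false(dish$truncated)
  expect_error(detect_dish(matrix(0.5, 128, 128)), "dish not found")
})

test_that("a frame-truncated dish is fitted with the residual flag raised", {
  g <- gen_colony_image(60, center = c(256, 190), dish_radius = 200,
                        size = 512, blur_sigma = 0)
  dish <- detect_dish(g$img)
  expect_true(dish$truncated)
  expect_lt(abs(dish$radius - 200), 8)
})

test_that("colony segmentation recovers a clean disk", {
  g <- gen_colony_image(80, blur_sigma = 0, shading = 0, noise_sd = 0)
  dish <- detect_dish(g$img)
  ol <- segment_colony(g$img, dish)
  expect_lt(abs(outline_radius(ol)$radius_px - 80), 1)
  expect_gte(nrow(ol$points), 16)
  # colony absent
  flat <- g$img
  flat[] <- 0.08
  yy <- matrix(seq_len(512), 512, 512)
  xx <- t(yy)
  flat[sqrt((xx - 256)^2 + (yy - 256)^2) <= g$truth$dish_radius] <- 0.35
  expect_error(segment_colony(flat, detect_dish(flat)), "colony not found")
})

test_that("with two blobs the larger component is kept", {
  g <- gen_colony_image(70, blur_sigma = 0)
  img <- g$img
  yy <- matrix(seq_len(512), 512, 512); xx <- t(yy)
  img[sqrt((xx - 256)^2 + (yy - 100)^2) <= 15] <- 0.85   # small second blob
  dish <- detect_dish(img)
  expect_message(ol <- segment_colony(img, dish), "keeping the largest")
  expect_lt(abs(outline_radius(ol)$radius_px - 70), 1.5)
})

test_that("sigmoid fitting recovers exact parameters and degrades safely", {
  x <- 0:20
  prof <- 0 + 1 / (1 + exp(-(x - 10) / 2))
  fit <- fit_sigmoid(prof, x = x)
  expect_true(fit$converged)
  expect_equal(fit$x0, 10, tolerance = 1e-6)
  expect_equal(fit$s, 2, tolerance = 1e-5)
  # constant profile is unidentifiable
  expect_false(fit_sigmoid(rep(1, 15))$converged)
  # decreasing profile: negative amplitude, same inflection
  fit2 <- fit_sigmoid(rev(prof), x = x)
  expect_true(fit2$converged)
  expect_lt(fit2$b, 0)
  expect_equal(fit2$x0, 10, tolerance = 1e-5)
  expect_error(fit_sigmoid(c(1, 2, 3)), ">= 7")
})

test_that("refinement corrects shading bias and respects bounds", {
  g <- gen_colony_image(80, blur_sigma = 2, shading = 0.2, noise_sd = 0.01,
                        seed = 5)
  dish <- detect_dish(g$img)
  ol <- segment_colony(g$img, dish)
  err_pre <- abs(outline_radius(ol)$radius_px - 80)
  ref <- refine_outline(g$img, ol)
  err_post <- abs(outline_radius(ref)$radius_px - 80)
  expect_lt(err_post, 0.5)
  expect_lte(err_post, err_pre)
  expect_true(all(abs(ref$shift) <= 8 + 1e-9))
  # zero shift bound is a no-op
  ref0 <- refine_outline(g$img, ol, max_shift = 0)
  expect_equal(ref0$points, ol$points)
  # flat image: all fits fail, outline unchanged
  flat <- matrix(0.5, 512, 512)
  reff <- refine_outline(flat, ol)
  expect_equal(reff$points, ol$points)
  expect_false(any(reff$converged))
})

test_that("refinement reduces error across a shading grid", {
  for (sh in c(0, 0.1, 0.2, 0.4)) {
    g <- gen_colony_image(80, blur_sigma = 2, shading = sh, noise_sd = 0.01,
                          seed = 3)
    dish <- detect_dish(g$img)
    ol <- segment_colony(g$img, dish)
    ref <- refine_outline(g$img, ol)
    expect_lte(abs(outline_radius(ref)$radius_px - 80),
               abs(outline_radius(ol)$radius_px - 80) + 1e-9)
  }
})

test_that("outline radius matches closed forms", {
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  gon <- data.frame(x = 50 * cos(th) + 100, y = 50 * sin(th) + 100)
  expect_equal(outline_radius(gon)$radius_px, 50, tolerance = 0.01)
  sq <- data.frame(x = c(0, 2, 2, 0), y = c(0, 0, 2, 2))
  expect_equal(outline_radius(sq)$radius_px, 2 / sqrt(pi))
  expect_equal(outline_radius(sq[4:1, ])$radius_px, 2 / sqrt(pi))
  r <- outline_radius(gon, pixel_size_mm = 0.1)
  expect_equal(r$radius_mm, 5, tolerance = 0.01)
  expect_error(outline_radius(data.frame(x = c(0, 1, 2), y = c(0, 1, 2))),
               "degenerate")
})

test_that("the measured radius is invariant to image rotation", {
  g <- gen_colony_image(60, center = c(230, 270), blur_sigma = 2,
                        shading = 0.2, noise_sd = 0.01, seed = 2)
  run <- function(img) {
    d <- detect_dish(img)
    outline_radius(refine_outline(img, segment_colony(img, d)))$radius_px
  }
  rot90 <- function(m) t(m)[, nrow(m):1]
  expect_lt(abs(run(g$img) - run(rot90(g$img))), 0.2)
})

test_that("process_series measures a trajectory and isolates failures", {
  radii <- seq(30, 80, by = 10)
  ser <- gen_image_series(radii, blur_sigma = 2, shading = 0.1,
                          noise_sd = 0.01)
  res <- process_series(ser$manifest, images = ser$images)
  expect_true(all(res$ok))
  expect_true(all(abs(res$radius_px - radii) < 1))
  expect_true(all(diff(res$radius_px) > 0))
  # one corrupt image mid-series is flagged, others unaffected
  imgs <- ser$images
  imgs[[3]] <- matrix(0.5, 512, 512)
  res2 <- process_series(ser$manifest, images = imgs)
  expect_false(res2$ok[3])
  expect_true(all(res2$ok[-3]))
  expect_equal(res2$radius_px[-3], res$radius_px[-3], tolerance = 1e-9)
  # empty series gives an empty table
  empty <- process_series(data.frame(path = character(0),
                                     time_h = numeric(0)))
  expect_equal(nrow(empty), 0)
})
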