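test_that("GA and GGA count hue-band pixels against all pixels", {
  # half pure green (hue 120), half pure red (hue 0)
  px <- array(0, c(2, 2, 3))
  px[1, , 1] <- 255  # top row red
  px[2, , 2] <- 255  # bottom row green
  pl <- rgb_to_hsi(rgb_image(px))
  expect_equal(green_area(pl), 0.5)
  expect_equal(greener_green_area(pl), 0.5)
  expect_equal(green_area(rgb_to_hsi(uniform_image(255, 0, 0))), 0)
  # hue 70 (yellow-green): inside GA's [60,180), outside GGA's [80,180)
  pl_yg <- rgb_to_hsi(rgb_image(array(col2rgb(hsv(70 / 360, 1, 1)),
                                      c(1, 1, 3))))
  expect_equal(pl_yg$hue[1, 1], 70, tolerance = 0.5)
  expect_equal(green_area(pl_yg), 1)
  expect_equal(greener_green_area(pl_yg), 0)
  # all pixels hue 120
  pl_g <- rgb_to_hsi(uniform_image(0, 255, 0))
  expect_equal(green_area(pl_g), 1)
  expect_equal(greener_green_area(pl_g), 1)
  # achromatic pixels count in the denominator, never as green
  px2 <- array(128, c(1, 2, 3))
  px2[1, 1, ] <- c(0, 255, 0)
  expect_equal(green_area(rgb_to_hsi(rgb_image(px2))), 0.5)
})

test_that("GA recovers the programmed vegetation fraction on generator scenes", {
  sc <- render_scene(scene_spec(veg_fraction = 0.37, chlorotic_share = 0,
                                seed = 101))
  pl <- rgb_to_hsi(sc$image)
  expect_equal(green_area(pl), 0.37, tolerance = 0.01)
  expect_equal(green_area(pl), mean(sc$veg_mask), tolerance = 0.005)
  # half the vegetation chlorotic: GGA is half of GA
  sc2 <- render_scene(scene_spec(veg_fraction = 0.37, chlorotic_share = 0.5,
                                 seed = 102))
  expect_equal(greener_green_area(rgb_to_hsi(sc2$image)), 0.185,
               tolerance = 0.01)
})

test_that("CSI follows its definition and its guards", {
  expect_equal(crop_senescence_index(0.4, 0.4), 0)
  expect_equal(crop_senescence_index(1, 0), 100)
  expect_true(is.na(crop_senescence_index(0, 0)))
  expect_error(crop_senescence_index(0.2, 0.5), "GGA")
  expect_equal(crop_senescence_index(0.4, 0.2), 50)
})

test_that("TGI expands the triangle-area coefficients and evaluates Eq-style cases", {
  k <- tgi_coefficients(c(670, 550, 480))
  expect_identical(unname(k), c(190, 120))
  # equal bands -> zero
  expect_equal(tgi(uniform_image(80, 80, 80)), 0)
  # direct substitution: R670 = 0.1, R550 = 0.5, R480 = 0.1 -> 38
  img <- uniform_image(0.1 * 255, 0.5 * 255, 0.1 * 255)
  expect_equal(tgi(img), 38, tolerance = 0.5)
  # linear index: per-pixel average equals channel-mean form on any image
  set.seed(5)
  rnd <- rgb_image(array(sample(0:255, 300, TRUE), c(10, 10, 3)))
  expect_equal(tgi(rnd, per_pixel = TRUE), tgi(rnd), tolerance = 1e-9)
})

test_that("NGRDI follows its definition with a black-image guard", {
  expect_equal(ngrdi(uniform_image(120, 120, 7)), 0)
  expect_equal(ngrdi(uniform_image(0.25 * 255, 0.5 * 255, 0)), 1 / 3,
               tolerance = 1e-9)
  expect_true(is.na(ngrdi(uniform_image(0, 0, 0))))
  expect_true(ngrdi(uniform_image(130, 90, 60)) < 0)  # soil is redder
  # per-pixel equals channel-mean form on a uniform image
  u <- uniform_image(90, 180, 40, h = 3, w = 3)
  expect_equal(ngrdi(u, per_pixel = TRUE), ngrdi(u), tolerance = 1e-9)
})

test_that("NDLab and NDLuv evaluate the literal normalized-difference formula", {
  # uniform a* = -20, b* = 30 -> ((21 - 30)/(21 + 30)) + 1
  fake <- structure(list(a_star = matrix(-20, 2, 2),
                         b_star = matrix(30, 2, 2),
                         u_star = matrix(-10, 2, 2),
                         v_star = matrix(20, 2, 2),
                         dim = c(2, 2)), class = "color_planes")
  expect_equal(ndlab(fake), (21 - 30) / (21 + 30) + 1, tolerance = 1e-12)
  expect_equal(ndluv(fake), (11 - 20) / (11 + 20) + 1, tolerance = 1e-12)
  # the printed formula yields 2 at the chroma origin (documented quirk)
  zero <- structure(list(a_star = matrix(0, 1, 1), b_star = matrix(0, 1, 1),
                         u_star = matrix(0, 1, 1), v_star = matrix(0, 1, 1),
                         dim = c(1, 1)), class = "color_planes")
  expect_equal(ndlab(zero), 2)
  expect_equal(ndluv(zero), 2)
  # near-zero denominators are excluded; all-excluded -> NA
  degen <- structure(list(a_star = matrix(1, 1, 1), b_star = matrix(0, 1, 1),
                          dim = c(1, 1)), class = "color_planes")
  expect_true(is.na(ndlab(degen)))
  # plane-mean variant agrees with per-pixel on uniform planes
  expect_equal(ndlab(fake, per_pixel = FALSE), ndlab(fake))
})

test_that("NDLab and NDLuv order greener above chlorotic and soil scenes", {
  green <- render_scene(scene_spec(veg_fraction = 0.6, chlorotic_share = 0,
                                   seed = 21))
  chlor <- render_scene(scene_spec(veg_fraction = 0.6, chlorotic_share = 0.8,
                                   seed = 21))
  soil <- render_scene(scene_spec(veg_fraction = 0, seed = 21))
  nd_g <- ndlab(rgb_to_cielab(green$image))
  nd_c <- ndlab(rgb_to_cielab(chlor$image))
  expect_gt(nd_g, nd_c)
  # NDLuv's denominator (1 - u*) + v* changes sign for strongly coloured
  # soil (a documented instability of the literal formula), so the
  # soil-below-vegetation ordering is checked on a low-chroma soil
  grey_soil <- render_scene(scene_spec(veg_fraction = 0, seed = 21,
                                       soil_color = c(100, 90, 80),
                                       soil_jitter = 3))
  grey_veg <- render_scene(scene_spec(veg_fraction = 0.6,
                                      chlorotic_share = 0, seed = 21,
                                      soil_color = c(100, 90, 80),
                                      soil_jitter = 3))
  expect_gt(ndluv(color_planes(grey_veg$image)),
            ndluv(color_planes(grey_soil$image)))
  expect_gt(ndlab(rgb_to_cielab(green$image)),
            ndlab(rgb_to_cielab(soil$image)))
})

test_that("summarize_plot fills the full record and is deterministic", {
  soil <- render_scene(scene_spec(veg_fraction = 0, seed = 31))
  rec <- summarize_plot(soil$image, plot_id = "p1")
  expect_equal(rec$GA, 0)
  expect_true(is.na(rec$CSI))
  expect_lt(rec$NGRDI, 0)
  expect_identical(rec, summarize_plot(soil$image, plot_id = "p1"))
  sc <- render_scene(scene_spec(seed = 32))
  rec2 <- summarize_plot(sc$image)
  expect_true(all(!is.na(rec2[setdiff(names(rec2), "plot_id")])))
  expect_true(rec2$GGA <= rec2$GA)
})

test_that("hue mean is circular, not arithmetic", {
  expect_equal(circular_mean_deg(c(350, 10)), 0)
  expect_equal(circular_mean_deg(c(90, 110)), 100)
  expect_true(is.na(circular_mean_deg(NA_real_)))
})

test_that("record invariants hold across random scenes and brightness scaling", {
  set.seed(99)
  for (s in sample.int(10000, 25)) {
    sp <- scene_spec(width = 60, height = 45, veg_fraction = runif(1),
                     chlorotic_share = runif(1), seed = s)
    sc <- render_scene(sp)
    pl <- rgb_to_hsi(sc$image)
    ga <- green_area(pl); gga <- greener_green_area(pl)
    expect_true(gga <= ga && ga <= 1 && gga >= 0)
    csi <- crop_senescence_index(ga, gga)
    expect_true(is.na(csi) || (csi >= 0 && csi <= 100))
  }
  # hue-threshold indices are insensitive to uniform brightness scaling
  sc <- render_scene(scene_spec(seed = 77, veg_fraction = 0.4,
                                chlorotic_share = 0.3))
  ga0 <- green_area(rgb_to_hsi(sc$image))
  gga0 <- greener_green_area(rgb_to_hsi(sc$image))
  for (k in c(0.5, 0.7, 0.9)) {
    dim_img <- rgb_image(round(unclass(sc$image) * k))
    expect_equal(green_area(rgb_to_hsi(dim_img)), ga0, tolerance = 0.02)
    expect_equal(greener_green_area(rgb_to_hsi(dim_img)), gga0,
                 tolerance = 0.02)
  }
})
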