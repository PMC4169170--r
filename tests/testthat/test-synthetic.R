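test_that("tube rendering produces the specified bands", {
  # degenerate fraction: no cleared band at all
  all_dense <- render_settling_image(tube_spec(width_px = 10, height_px = 50,
                                               cleared_fraction = 0))
  expect_true(all(all_dense == 200))
  # fully cleared: only the very bottom row of the line is dense pellet
  all_clear <- render_settling_image(tube_spec(width_px = 10, height_px = 50,
                                               cleared_fraction = 1))
  expect_true(all(all_clear[1:49, ] == 30))
  expect_true(all(all_clear[50, ] == 200))

  # exact step construction at half height
  img <- render_settling_image(tube_spec(width_px = 4, height_px = 100,
                                         cleared_fraction = 0.5,
                                         clear_level = 30, dense_level = 200))
  expect_true(all(img[1:50, ] == 30))
  expect_true(all(img[51:100, ] == 200))

  expect_error(tube_spec(cleared_fraction = 1.2),
               class = "biofilmq_validation_error")
  expect_error(tube_spec(cleared_fraction = 0.5, clear_level = 100,
                         dense_level = 100),
               class = "biofilmq_validation_error")
})

test_that("noise-free settling recovery is exact up to pixel discretization", {
  for (f in seq(0, 1, by = 0.1)) {
    img <- render_settling_image(tube_spec(width_px = 20, height_px = 400,
                                           cleared_fraction = f))
    meas <- settling_score(img, list(profile_line(10, 0, 10, 399)))
    expect_equal(meas$ratio, f, tolerance = 2 / 399)
  }
})

test_that("noisy settling recovery stays within the assay tolerance", {
  lines <- lapply(c(10, 30, 50), function(x) profile_line(x, 0, x, 399))
  img <- render_settling_image(tube_spec(width_px = 60, height_px = 400,
                                         cleared_fraction = 0.8,
                                         noise_sd = 2, seed = 99))
  expect_equal(settling_score(img, lines)$ratio, 0.8, tolerance = 0.02)
})

test_that("rendering is deterministic for a fixed seed", {
  spec <- tube_spec(cleared_fraction = 0.4, noise_sd = 3, seed = 5)
  expect_identical(render_settling_image(spec), render_settling_image(spec))
  spec2 <- tube_spec(cleared_fraction = 0.4, noise_sd = 3, seed = 6)
  expect_false(identical(render_settling_image(spec),
                         render_settling_image(spec2)))
})

test_that("spot rendering reports the clamped ground truth", {
  expect_equal(render_invasion_image(spot_spec(background_level = 20,
                                               spot_level = 120))$truth, 100)
  expect_equal(render_invasion_image(spot_spec(background_level = 50,
                                               spot_level = 50))$truth, 0)
  expect_equal(render_invasion_image(spot_spec(background_level = 50,
                                               spot_level = 10))$truth, 0)
  expect_error(spot_spec(spot_cx = 5, spot_radius_px = 25),
               class = "biofilmq_validation_error")
})

test_that("noise-free spot images reproduce truth within one gray unit", {
  ri <- render_invasion_image(spot_spec(background_level = 20,
                                        spot_level = 120, noise_sd = 0))
  meas <- measure_spot(ri$image, circle_roi(60, 60, 25))
  expect_equal(meas$corrected, ri$truth, tolerance = 1)
})

test_that("simulated panels have the declared long-format structure", {
  spec <- panel_spec(n_strains = 8, n_technical = 3, seed = 21)
  pan <- simulate_panel(spec)
  expect_equal(nrow(pan), 8 * length(BIOFILM_PHENOTYPES) * 2 * 3)
  expect_silent(validate_panel(pan))
  expect_setequal(unique(pan$ploidy), c("haploid", "diploid"))
  expect_true(all(pan$value >= 0))
  expect_true(all(pan$ordinal_score %in% 0:5))
})

test_that("panel simulation is byte-identical for a fixed seed", {
  spec <- panel_spec(n_strains = 6, seed = 77)
  expect_identical(simulate_panel(spec), simulate_panel(spec))
})

test_that("ordinal scores are monotone in the latent value", {
  pan <- simulate_panel(panel_spec(n_strains = 40, seed = 13))
  lat <- attr(pan, "latent_haploid")
  hap <- pan[pan$ploidy == "haploid" & pan$replicate_id == 1, ]
  for (ph in BIOFILM_PHENOTYPES) {
    sub <- hap[hap$phenotype == ph, ]
    o <- order(lat[sub$strain, ph])
    expect_true(all(diff(sub$ordinal_score[o]) >= 0))
  }
})

test_that("an identity latent correlation yields uncorrelated ordinal scores", {
  p <- length(BIOFILM_PHENOTYPES)
  spec <- panel_spec(n_strains = 500, latent_correlation = diag(p), seed = 31)
  pan <- simulate_panel(spec)
  hap <- pan[pan$ploidy == "haploid" & pan$replicate_id == 1, ]
  wide <- do.call(cbind, lapply(BIOFILM_PHENOTYPES, function(ph) {
    sub <- hap[hap$phenotype == ph, ]
    sub$ordinal_score[order(sub$strain)]
  }))
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    tau <- kendall_tau(wide[, i], wide[, j])$statistic
    expect_lt(abs(tau), 0.1)
  }
})

test_that("invalid correlation matrices are rejected", {
  bad <- matrix(0.9, 3, 3); diag(bad) <- 1; bad[1, 2] <- -0.9
  expect_error(panel_spec(phenotypes = c("a", "b", "c"),
                          latent_correlation = bad,
                          diploid_effect = c(a = 1, b = 1, c = 1)),
               class = "biofilmq_validation_error")
  nd <- diag(3); nd[1, 2] <- nd[2, 1] <- 2
  expect_error(panel_spec(phenotypes = c("a", "b", "c"),
                          latent_correlation = nd,
                          diploid_effect = c(a = 1, b = 1, c = 1)),
               class = "biofilmq_validation_error")
})

test_that("exception strains override the diploid effect", {
  exc <- list(S002 = c(flocculation = 2.0))
  pan <- simulate_panel(panel_spec(n_strains = 4, replicate_sd = 0,
                                   exception_strains = exc, seed = 9))
  lat_h <- attr(pan, "latent_haploid")
  lat_d <- attr(pan, "latent_diploid")
  expect_equal(lat_d["S002", "flocculation"],
               2.0 * lat_h["S002", "flocculation"])
  expect_equal(lat_d["S001", "flocculation"],
               default_diploid_effect()[["flocculation"]] *
                 lat_h["S001", "flocculation"])
})
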