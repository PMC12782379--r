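test_that("generated limbs meet their analytic section profiles", {
  # pure cylinder, no noise or individual variation
  p <- limb_params(length = 80, a0 = 30, b0 = 30, taper = 1,
                   shape = "cylindrical", noise_sd = 0, shape_var = 0)
  m <- generate_limb(p, seed = 1)$mesh
  expect_equal(diff(range(m$vertices[, 3])), 80, tolerance = 0.5)
  for (z in c(-20, -40, -60)) {
    expect_equal(slice_area(m, z)$area, pi * 900, tolerance = 0.01)
  }
  # conical taper 0.5: distal area ~ 0.25 x proximal area
  p2 <- limb_params(length = 80, a0 = 30, b0 = 30, taper = 0.5,
                    shape = "conical", noise_sd = 0, shape_var = 0)
  m2 <- generate_limb(p2, seed = 1)$mesh
  expect_equal(slice_area(m2, -79.2)$area / slice_area(m2, -0.8)$area, 0.25,
               tolerance = 0.02)
  # determinism: same params + seed -> bitwise-identical mesh
  pn <- limb_params(length = 70, a0 = 25, b0 = 20, taper = 0.6,
                    shape = "conical", noise_sd = 0.2)
  g1 <- generate_limb(pn, seed = 42)
  g2 <- generate_limb(pn, seed = 42)
  expect_identical(g1$mesh$vertices, g2$mesh$vertices)
  expect_identical(g1$mesh$faces, g2$mesh$faces)
  # parameter validation
  expect_error(limb_params(length = 80, taper = 1, shape = "conical"),
               "taper")
  expect_error(limb_params(length = 80, taper = 0.6, shape = "cylindrical"),
               "taper")
})

test_that("derived sockets offset the limb by the radial clearance", {
  p <- limb_params(length = 80, a0 = 25, b0 = 20, taper = 0.7,
                   shape = "conical", noise_sd = 0, shape_var = 0)
  gl <- generate_limb(p, seed = 1)
  sock <- derive_socket(gl$mesh, socket_design(clearance = 2, cutout = FALSE))
  # oracle: shoelace area of the analytically offset ellipse at mid-limb
  z <- -40
  rho <- pactr:::limb_profile(p, 0.5)
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  base <- cbind(25 * rho * cos(th), 20 * rho * sin(th))
  u <- base / sqrt(rowSums(base^2))
  offset_poly <- base + 2 * u
  oracle <- abs(pactr:::shoelace_area(offset_poly))
  expect_equal(slice_area(sock$mesh, z)$area, oracle, tolerance = 0.01)
  # cutout: slice loops may open but areas remain finite
  sock2 <- derive_socket(gl$mesh, socket_design(cutout = TRUE))
  s <- slice_area(sock2$mesh, -0.08 * 80)
  expect_true(is.finite(s$area))
  expect_gt(s$area, 0)
  # a limb that did not come from the generator is rejected
  expect_error(derive_socket(fixture_cube(), socket_design()),
               "generate_limb")
})

test_that("sockets strictly contain their limbs wherever clearance is positive", {
  gl <- fixture_limb(seed = 17, noise_sd = 0.2)
  sock <- derive_socket(gl$mesh, socket_design(clearance = 2,
                                               cutout = FALSE))$mesh
  f <- signed_distances(gl$mesh, sock, n = 6000, seed = 1)
  # limb sampled against the socket: everywhere inside (negative signed)
  expect_lt(max(f$signed), 0)
})

test_that("the anterior-distal trimline clears 45% of the limb length", {
  gl <- fixture_limb(seed = 18, noise_sd = 0)
  sock <- derive_socket(gl$mesh, socket_design())$mesh
  L <- diff(range(gl$mesh$vertices[, 3]))
  v <- sock$vertices
  # anterior rim: highest z among anterior (y > 0) vertices
  rim_z <- max(v[v[, 2] > 0, 3])
  distal_z <- min(v[, 3])
  expect_gt(rim_z - distal_z, 0.45 * L)
})

test_that("cohorts are deterministic and match the target population", {
  coh <- generate_cohort(19, seed = 9)
  s <- summarize_library(coh$library)
  expect_equal(nrow(s$participants), 19)
  # mean length within 2 standard errors of the population mean
  se <- 23.4 / sqrt(19)
  expect_lt(abs(s$summary$mean[s$summary$variable == "limb_length"] - 76.3),
            2 * se)
  # length-class labels consistent with the stated rule
  expect_identical(s$participants$length_class,
                   pactr:::length_class_rule(s$participants$limb_length,
                                             s$participants$age))
  # regeneration with the same seed gives an identical library
  coh2 <- generate_cohort(19, seed = 9)
  expect_identical(serialize(coh$library, NULL), serialize(coh2$library, NULL))
})

test_that("large cohorts converge on the population spec", {
  big <- summarize_library(generate_cohort(200, seed = 77)$library)
  len <- big$participants$limb_length
  expect_lt(abs(mean(len) - 76.3), 3 * 23.4 / sqrt(200) + 1)  # + truncation shift
  expect_true(all(len >= 35 & len <= 125))
  shape_frac <- mean(big$participants$shape_class == "conical")
  expect_lt(abs(shape_frac - 0.7), 3 * sqrt(0.7 * 0.3 / 200))
  ped <- mean(big$participants$age < 18)
  expect_lt(abs(ped - 9 / 19), 3 * sqrt(0.5 * 0.5 / 200) + 0.02)
})
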