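test_that("landmark frames reject degenerate configurations", {
  expect_error(landmark_set(c(0, 0, 0), c(3, 0, 0), c(10, 0, 0)), "closer than 5")
  expect_error(landmark_set(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)), "collinear")
  lm <- landmark_set(c(-28, 0, 0), c(28, 0, 0), c(0, -23, 0))
  expect_s3_class(lm, "landmark_set")
})

test_that("alignment is the identity on canonical input and idempotent", {
  gl <- fixture_limb(seed = 2)
  al <- align_limb(gl$mesh, gl$landmarks)
  expect_equal(max(abs(al$mesh$vertices - gl$mesh$vertices)), 0,
               tolerance = 1e-9)
  expect_equal(al$transform$rotation, diag(3), tolerance = 1e-9)
  al2 <- align_limb(al$mesh, al$landmarks)
  expect_equal(al2$mesh$vertices, al$mesh$vertices, tolerance = 1e-9)
  # frame axes orthonormal
  rot <- al$transform$rotation
  expect_equal(crossprod(rot), diag(3), tolerance = 1e-9)
  expect_equal(det(rot), 1, tolerance = 1e-9)
})

test_that("alignment recovers a known rigid displacement", {
  gl <- fixture_limb(seed = 3)
  tf <- rigid_transform(rot_z(0.4) %*% rot_x(0.3), c(10, -5, 30))
  moved <- apply_transform(gl$mesh, tf)
  lm <- landmark_set(
    apply_transform(rbind(gl$landmarks$medial_epicondyle), tf),
    apply_transform(rbind(gl$landmarks$lateral_epicondyle), tf),
    apply_transform(rbind(gl$landmarks$olecranon), tf), "right")
  al <- align_limb(moved, lm)
  expect_equal(max(abs(al$mesh$vertices - gl$mesh$vertices)), 0,
               tolerance = 1e-6)
})

test_that("left limbs are mirrored into the canonical right-side frame", {
  right <- fixture_limb(seed = 5, side = "right")
  left <- fixture_limb(seed = 5, side = "left")
  al <- align_limb(left$mesh, left$landmarks)
  expect_true(al$mirrored)
  expect_equal(max(abs(al$mesh$vertices - right$mesh$vertices)), 0,
               tolerance = 1e-6)
  expect_identical(al$landmarks$side, "right")
})

test_that("socket registration is a fixed point and recovers z-rotations", {
  # symmetric fixture: the principal axis of the socket is exactly z
  limb <- fixture_limb(noise_sd = 0, shape_var = 0)$mesh
  sk <- derive_socket(limb, socket_design(cutout = FALSE))
  reg <- register_socket_to_limb(sk$mesh, sk$indent_point, sk$obturator_point)
  expect_equal(max(abs(reg$vertices - sk$mesh$vertices)), 0, tolerance = 1e-6)
  # pre-rotated 30 degrees about z (plus a shift): recovered within 0.1 deg
  tf <- rigid_transform(rot_z(pi / 6), c(3, 4, -2))
  regr <- register_socket_to_limb(
    apply_transform(sk$mesh, tf),
    apply_transform(rbind(sk$indent_point), tf),
    apply_transform(rbind(sk$obturator_point), tf))
  dev <- max(abs(regr$vertices - reg$vertices))
  r_max <- max(sqrt(rowSums(reg$vertices[, 1:2]^2)))
  expect_lt(dev / r_max, 0.1 * pi / 180)
  # olecranon tip as an alternative posterior reference gives the same frame
  tip <- sk$mesh$vertices[which.min(sk$mesh$vertices[, 2]), ]
  reg2 <- register_socket_to_limb(sk$mesh, sk$indent_point, tip)
  # both references lie in the sagittal plane: frames agree within 0.5 deg
  expect_lt(max(abs(reg2$vertices - reg$vertices)) / r_max, 0.5 * pi / 180)
  # far-away reference point is rejected
  expect_error(register_socket_to_limb(sk$mesh, sk$indent_point + c(30, 0, 0),
                                       sk$obturator_point), "reference point")
})

test_that("ICP recovers rigid maps with a monotone residual", {
  pc <- sample_surface(fixture_limb(seed = 9)$mesh, 2000, seed = 1)$points
  self <- icp_register(pc, pc)
  expect_lt(self$residual, 1e-9)
  tf <- rigid_transform(rot_z(0.3) %*% rot_x(-0.15), c(6, -2, 4))
  moved <- apply_transform(pc, tf)
  fit <- icp_register(moved, pc)
  expect_lt(fit$residual, 1e-6)
  expect_true(all(diff(fit$trace) <= 1e-9))
  # noisy self-registration settles at the nearest-neighbour noise floor
  set.seed(11)
  noisy <- pc + matrix(rnorm(length(pc), sd = 0.1), ncol = 3)
  floor_rmse <- sqrt(mean(pactr:::cpp_nearest(noisy, pc)$dist^2))
  fitn <- icp_register(noisy, pc)
  expect_equal(fitn$residual, floor_rmse, tolerance = 0.2)
  # degenerate collinear cloud
  line <- cbind(1:10, 1:10, 1:10)
  expect_error(icp_register(line, pc), "collinear")
})
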