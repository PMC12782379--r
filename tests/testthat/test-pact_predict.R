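test_that("shape distance matches trivial cases and the brute-force oracle", {
  p <- matrix(c(0, 0, 0), 1)
  expect_equal(shape_distance(p, p), 0)
  expect_equal(shape_distance(p, matrix(c(3, 4, 0), 1)), 5)
  set.seed(4)
  a <- matrix(rnorm(1500), ncol = 3)
  b <- matrix(rnorm(1500), ncol = 3)
  expect_equal(shape_distance(a, b), brute_nn_mean(a, b), tolerance = 1e-9)
  expect_equal(shape_distance(a, b, symmetric = TRUE),
               (brute_nn_mean(a, b) + brute_nn_mean(b, a)) / 2,
               tolerance = 1e-9)
})

test_that("length normalization reproduces the published length ratios", {
  entry <- local({
    gl <- fixture_limb(seed = 1, length = 100)
    library_entry(participant_meta("A", "M", 30, 100, "short", "conical"),
                  gl$mesh, gl$landmarks,
                  derive_socket(gl$mesh, socket_design())$mesh)
  })
  same <- length_normalize(100, entry)
  expect_equal(same$sf_k, 1)
  expect_identical(same$limb$vertices, entry$limb$vertices)
  expect_equal(length_normalize(50, entry)$sf_k, 0.5)
  # ratio of the two printed extreme cohort lengths
  demo <- reference_demographics()
  sf <- demo$limb_length[demo$id == "P19"] / demo$limb_length[demo$id == "P03"]
  expect_equal(round(sf, 3), 3.477)
  norm <- length_normalize(50, entry)
  expect_equal(diff(range(norm$limb$vertices[, 3])), 50, tolerance = 0.1)
  expect_error(length_normalize(-1, entry), "positive")
})

test_that("retrieval returns the query's own entry and is scale equivariant", {
  coh <- generate_cohort(5, seed = 21)
  lib <- coh$library
  query <- lib$entries[["S03"]]$limb
  r <- retrieve_best_match(query, lib, n = 10000, seed = 2)
  expect_identical(r$matched_id, "S03")
  expect_lt(r$d_l2, 0.05)
  expect_equal(r$sf_k, 1)
  # isotropic x1.3 leaves the winner unchanged, sf_k tracks the scale
  big <- trimesh(query$vertices * 1.3, query$faces)
  r2 <- retrieve_best_match(big, lib, n = 10000, seed = 2)
  expect_identical(r2$matched_id, "S03")
  expect_equal(r2$sf_k, 1.3, tolerance = 1e-6)
  expect_lt(r2$d_l2, 0.05 * 1.3)
  # winner agrees with an exhaustive per-entry comparison
  oracle <- r$distances$id[which.min(r$distances$d_l2)]
  expect_identical(r$matched_id, oracle)
})

test_that("anisotropic factors recover constructed axis scalings", {
  limb <- fixture_limb(seed = 6, noise_sd = 0)$mesh
  expect_equal(anisotropic_factors(limb, limb), list(sf_ml = 1, sf_ap = 1))
  v <- limb$vertices
  v[, 2] <- v[, 2] * 1.2
  stretched <- trimesh(v, limb$faces)
  f <- anisotropic_factors(stretched, limb)
  expect_equal(f$sf_ap, 1.2, tolerance = 0.01)
  expect_equal(f$sf_ml, 1, tolerance = 0.01)
})

test_that("socket scaling preserves topology and obeys volume/area laws", {
  sock <- derive_socket(fixture_limb(seed = 2, noise_sd = 0)$mesh,
                        socket_design(cutout = FALSE))$mesh
  ident <- apply_scaling(sock, scaling_factors(1, 1, 1))
  expect_identical(ident$vertices, sock$vertices)
  dbl <- apply_scaling(sock, scaling_factors(2, 1, 1))
  expect_equal(mesh_volume(dbl, 0.5) / mesh_volume(sock, 0.5), 8,
               tolerance = 0.02)
  # pure anisotropic (1.1, 0.9): every slice area scales by 0.99
  an <- apply_scaling(sock, scaling_factors(1, 1.1, 0.9))
  zr <- range(sock$vertices[, 3])
  for (fr in c(0.25, 0.5, 0.75)) {
    z <- zr[1] + fr * diff(zr)
    expect_equal(slice_area(an, z)$area / slice_area(sock, z)$area, 0.99,
                 tolerance = 0.01)
  }
  expect_error(scaling_factors(0, 1, 1), "positive")
})

test_that("the full pipeline is the identity on a library member", {
  coh <- generate_cohort(4, seed = 31)
  lib <- coh$library
  entry <- lib$entries[["S02"]]
  pr <- predict_socket(entry$limb, lib = lib, aligned = TRUE)
  expect_identical(pr$matched_id, "S02")
  expect_equal(pr$factors$sf_k, 1)
  expect_equal(pr$factors$sf_ml, 1)
  expect_equal(pr$factors$sf_ap, 1)
  expect_identical(pr$socket$vertices, entry$socket$vertices)
  # predicted socket z-extent equals the matched socket extent times sf_k
  expect_equal(diff(range(pr$socket$vertices[, 3])),
               diff(range(entry$socket$vertices[, 3])) * pr$factors$sf_k,
               tolerance = 0.1)
})

test_that("planted scaling factors are recovered through the pipeline", {
  r0 <- recovery_trial(seed = 14, noise_sd = 0)
  expect_true(r0$matched)
  rel <- abs(r0$recovered - r0$planted) / r0$planted
  expect_lt(rel[["sf_k"]], 0.01)
  expect_lt(rel[["sf_ml"]], 0.02)
  expect_lt(rel[["sf_ap"]], 0.02)
  r1 <- recovery_trial(seed = 14, noise_sd = 0.2)
  expect_true(r1$matched)
  rel1 <- abs(r1$recovered - r1$planted) / r1$planted
  expect_lt(rel1[["sf_k"]], 0.02)
  expect_lt(rel1[["sf_ml"]], 0.05)
  expect_lt(rel1[["sf_ap"]], 0.05)
})
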