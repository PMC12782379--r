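test_that("signed distances carry the inside/outside convention", {
  sock <- derive_socket(fixture_limb(seed = 8, noise_sd = 0)$mesh,
                        socket_design())$mesh
  f <- signed_distances(sock, sock, n = 4000, seed = 1)
  expect_true(all(abs(f$signed) < 1e-6))
  s50 <- fixture_sphere(r = 50, n = 48)
  s51 <- fixture_sphere(r = 51, n = 48)
  fo <- signed_distances(s51, s50, n = 6000, seed = 2)
  expect_equal(mean(fo$signed), 1, tolerance = 0.05)
  expect_gt(min(fo$signed), 0)
  fi <- signed_distances(s50, s51, n = 6000, seed = 2)
  expect_equal(mean(fi$signed), -1, tolerance = 0.05)
  expect_lt(max(fi$signed), 0)
  # |d| preserved under swap within sampling tolerance
  expect_equal(mean(abs(fi$signed)), mean(abs(fo$signed)), tolerance = 0.05)
})

test_that("mean-split thresholds flag exactly the pronounced deviations", {
  field <- structure(list(points = matrix(0, 5, 3),
                          signed = c(1, 2, 3, -1, -5)),
                     class = "signed_distance_field")
  m <- pronounced_mask(field)
  expect_equal(m$threshold_pos, 2)
  expect_equal(m$threshold_neg, -3)
  expect_identical(which(m$flagged), c(3L, 5L))
  zero <- structure(list(points = matrix(0, 4, 3), signed = rep(0, 4)),
                    class = "signed_distance_field")
  expect_false(any(pronounced_mask(zero)$flagged))
  # independent recomputation agrees exactly on a large random field
  set.seed(9)
  s <- rnorm(5000)
  big <- structure(list(points = matrix(rnorm(15000), ncol = 3), signed = s),
                   class = "signed_distance_field")
  m2 <- pronounced_mask(big)
  expect_identical(m2$flagged,
                   (s > mean(s[s > 0])) | (s < mean(s[s < 0])))
})

test_that("DBSCAN recovers planted patches and rejects sparse noise", {
  set.seed(5)
  patch1 <- matrix(rnorm(900, sd = 2), ncol = 3)
  patch2 <- sweep(matrix(rnorm(900, sd = 2), ncol = 3), 2, c(40, 0, 0), "+")
  regions <- cluster_deviations(rbind(patch1, patch2), rep(1, 600), eps = 5,
                                min_samples = 10)
  expect_length(regions, 2)
  cents <- t(vapply(regions, function(r) r$centroid, numeric(3)))
  d <- sqrt(rowSums((cents - rbind(c(0, 0, 0), c(40, 0, 0)))^2))
  d_swap <- sqrt(rowSums((cents - rbind(c(40, 0, 0), c(0, 0, 0)))^2))
  expect_lt(min(max(d), max(d_swap)), 2)
  # uniform sparse noise below the density threshold yields no regions
  noise <- matrix(runif(300, 0, 200), ncol = 3)
  expect_length(cluster_deviations(noise, rep(1, 100), eps = 5,
                                   min_samples = 10), 0)
  # duplicated patch at one location merges into a single region
  dup <- rbind(patch1, patch1)
  expect_length(cluster_deviations(dup, rep(1, 600), eps = 5,
                                   min_samples = 10), 1)
  # opposite signs are clustered separately
  mixed <- cluster_deviations(rbind(patch1, patch1),
                              c(rep(1, 300), rep(-1, 300)), eps = 5,
                              min_samples = 10)
  expect_length(mixed, 2)
  expect_setequal(vapply(mixed, function(r) r$sign, ""),
                  c("inflation", "deflation"))
})

test_that("pooled aggregation recovers a shared anatomical direction", {
  dir <- pactr:::normalize3(c(0, 0.8, -0.6))
  regions <- lapply(1:3, function(i) {
    set.seed(i)
    jitter <- pactr:::normalize3(dir + rnorm(3, sd = 0.03))
    structure(list(points = matrix(0, 1, 3), centroid = jitter * (20 + 5 * i),
                   sign = "inflation", size = 50,
                   participant = sprintf("P%02d", i)),
              class = "deviation_region")
  })
  common <- aggregate_regions(regions, eps_norm = 0.25, min_samples = 2)
  expect_length(common, 1)
  expect_equal(common[[1]]$incidence, 3)
  expect_equal(sqrt(sum(common[[1]]$direction^2)), 1, tolerance = 1e-6)
  ang <- 180 / pi * acos(sum(common[[1]]$direction * dir))
  expect_lt(ang, 10)
  # single participant, single region: its own unit vector, zero SDs
  one <- aggregate_regions(regions[1], eps_norm = 0.25, min_samples = 1)
  expect_length(one, 1)
  expect_equal(one[[1]]$direction,
               pactr:::normalize3(regions[[1]]$centroid), tolerance = 1e-9)
  expect_equal(unname(one[[1]]$direction_sd), c(0, 0, 0))
  # serialization in the unit-vector table format
  expect_match(format_unit_vector(common[[1]]),
               "^[+-]\\d\\.\\d\\d \\(\\d\\.\\d\\d\\) x [+-]\\d\\.\\d\\d")
})

test_that("an end-to-end planted patch produces an inflation region at its direction", {
  limb <- fixture_limb(seed = 12, noise_sd = 0)$mesh
  dir <- pactr:::normalize3(c(0, 0.8, -0.6))
  ref <- derive_socket(limb, socket_design())$mesh
  pred <- derive_socket(limb, socket_design(patches = list(
    list(direction = dir, amplitude = 3, extent_deg = 30))))$mesh
  loc <- evaluate_local(pred, ref, config = pact_config(sample_n = 8000),
                        seed = 3, participant = "X")
  infl <- Filter(function(r) r$sign == "inflation", loc$regions)
  expect_gte(length(infl), 1)
  main <- infl[[which.max(vapply(infl, function(r) r$size, 0))]]
  u <- pactr:::normalize3(main$centroid)
  expect_lt(180 / pi * acos(sum(u * dir)), 15)
})
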