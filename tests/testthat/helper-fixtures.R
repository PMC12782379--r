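# Programmatic geometric fixtures shared across tests.

fixture_cube <- function(s = 1) {
  v <- as.matrix(expand.grid(c(0, s), c(0, s), c(0, s)))
  dimnames(v) <- NULL
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  trimesh(v, f)
}

# closed cylinder along z in [0, h]; sector_deg < 360 leaves an open shell
# (three-quarter designs) and drops the end caps
fixture_cylinder <- function(r = 10, h = 40, n = 96, sector_deg = 360,
                             caps = TRUE) {
  full <- sector_deg >= 360
  th <- if (full) {
    2 * pi * (seq_len(n) - 1) / n
  } else {
    seq(0, sector_deg * pi / 180, length.out = n)
  }
  ring0 <- cbind(r * cos(th), r * sin(th), 0)
  ring1 <- cbind(r * cos(th), r * sin(th), h)
  v <- rbind(ring0, ring1)
  j <- seq_len(if (full) n else n - 1)
  jn <- if (full) c(2:n, 1) else j + 1
  f <- rbind(cbind(j, jn, n + j), cbind(jn, n + jn, n + j))
  if (caps && full) {
    v <- rbind(v, c(0, 0, 0), c(0, 0, h))
    b <- 2 * n + 1
    t_ <- 2 * n + 2
    f <- rbind(f, cbind(jn, j, b), cbind(n + j, n + jn, t_))
  }
  trimesh(v, f)
}

# closed cone: apex at z = 0, base radius r at z = h, capped base
fixture_cone <- function(r = 15, h = 60, n = 96) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  ring <- cbind(r * cos(th), r * sin(th), h)
  v <- rbind(c(0, 0, 0), ring, c(0, 0, h))
  j <- seq_len(n)
  jn <- c(2:n, 1)
  f <- rbind(cbind(1, 1 + j, 1 + jn),          # side
             cbind(1 + jn, 1 + j, n + 2))      # base cap
  trimesh(v, f)
}

# lat-long unit-ish sphere
fixture_sphere <- function(r = 1, n = 32) {
  th <- seq(0, pi, length.out = n)
  ph <- 2 * pi * (seq_len(2 * n) - 1) / (2 * n)
  rings <- th[-c(1, n)]
  v <- do.call(rbind, lapply(rings, function(t) {
    cbind(r * sin(t) * cos(ph), r * sin(t) * sin(ph), r * cos(t))
  }))
  v <- rbind(c(0, 0, r), v, c(0, 0, -r))
  nr <- length(rings)
  nt <- 2 * n
  j <- seq_len(nt)
  jn <- c(2:nt, 1)
  f <- cbind(1, 1 + j, 1 + jn)
  for (i in seq_len(nr - 1)) {
    a <- 1 + (i - 1) * nt
    b <- 1 + i * nt
    f <- rbind(f, cbind(a + j - 1, b + j - 1, a + jn - 1),
               cbind(a + jn - 1, b + j - 1, b + jn - 1))
  }
  last <- 2 + nr * nt
  a <- 1 + (nr - 1) * nt
  f <- rbind(f, cbind(last, a + jn - 1, a + j - 1))
  trimesh(v, f)
}

# brute-force mean nearest-neighbour distance (oracle for shape_distance)
brute_nn_mean <- function(p, q) {
  mean(apply(p, 1, function(x) {
    sqrt(min(colSums((t(q) - x)^2)))
  }))
}

rot_z <- function(th) {
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

rot_x <- function(th) {
  matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
}

# a small synthetic aligned limb + landmarks for alignment tests
fixture_limb <- function(seed = 1, length = 80, noise_sd = 0.2,
                         shape_var = 0.05, side = "right") {
  p <- limb_params(length = length, a0 = 28, b0 = 23, taper = 0.6,
                   shape = "conical", noise_sd = noise_sd,
                   shape_var = shape_var, side = side)
  generate_limb(p, seed = seed)
}
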