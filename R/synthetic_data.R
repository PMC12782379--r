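#' Parameters of a synthetic residual limb
#'
#' Synthetic limbs are surfaces of revolution with elliptical cross-sections:
#' the proximal section has semi-axes `a0` (medio-lateral) and `b0`
#' (anterior-posterior), and the radius profile tapers smoothly
#' (cosine-blended) toward the distal end by the `taper` ratio. Bulbous limbs
#' add a raised-cosine bulge near the distal third. Optional zero-mean radial
#' Gaussian noise emulates scan roughness.
#'
#' @param length proximal-distal limb length, mm.
#' @param a0,b0 proximal ellipse semi-axes, mm.
#' @param taper distal/proximal radius ratio, in (0, 1.2]. Cylindrical limbs
#'   must have taper within 0.05 of 1; conical limbs taper <= 0.8.
#' @param shape `"conical"`, `"cylindrical"` or `"bulbous"`.
#' @param bulge_amp,bulge_width bulge amplitude (relative to the local
#'   radius) and width (fraction of length), bulbous only.
#' @param noise_sd radial surface noise SD, mm.
#' @param shape_var relative amplitude SD of the smooth per-limb harmonic
#'   shape variation that emulates individual bony and soft-tissue contours
#'   (0 disables it).
#' @param side `"right"` or `"left"`.
#' @param n_theta,n_z mesh resolution (angular and longitudinal).
#' @return List of class `limb_params`.
#' @export
limb_params <- function(length, a0 = 25, b0 = 22, taper = 0.6,
                        shape = c("conical", "cylindrical", "bulbous"),
                        bulge_amp = 0.15, bulge_width = 0.15, noise_sd = 0,
                        shape_var = 0.05, side = c("right", "left"),
                        n_theta = 64L, n_z = 48L) {
  shape <- match.arg(shape)
  side <- match.arg(side)
  if (!is.finite(length) || length <= 0) stop("length must be positive", call. = FALSE)
  if (taper <= 0 || taper > 1.2) stop("taper must be in (0, 1.2]", call. = FALSE)
  if (shape == "cylindrical" && abs(taper - 1) > 0.05) {
    stop("cylindrical limbs need taper within 0.05 of 1", call. = FALSE)
  }
  if (shape == "conical" && taper > 0.8) {
    stop("conical limbs need taper <= 0.8", call. = FALSE)
  }
  if (a0 <= 0 || b0 <= 0 || noise_sd < 0 || shape_var < 0) {
    stop("bad limb parameters", call. = FALSE)
  }
  structure(list(length = length, a0 = a0, b0 = b0, taper = taper,
                 shape = shape, bulge_amp = bulge_amp,
                 bulge_width = bulge_width, noise_sd = noise_sd,
                 shape_var = shape_var, side = side,
                 n_theta = as.integer(n_theta), n_z = as.integer(n_z)),
            class = "limb_params")
}

# Relative radius profile rho(t), t = 0 proximal .. 1 distal.
limb_profile <- function(p, t) {
  rho <- 1 + (p$taper - 1) * (1 - cos(pi * t)) / 2
  if (p$shape == "bulbous") {
    d <- (t - 0.7) / p$bulge_width
    rho <- rho * (1 + p$bulge_amp * exp(-d^2))
  }
  rho
}

# Smooth individual shape variation: low-order angular/longitudinal
# harmonics with random amplitude and phase, vanishing at the proximal rim
# (t = 0, so landmarks stay on the nominal ellipse) and at the distal tip.
harmonic_modes <- cbind(k_theta = c(1, 2, 1, 3, 2), k_z = c(1, 1, 2, 1, 2))

draw_harmonics <- function(p, seed) {
  if (p$shape_var <= 0) return(NULL)
  k <- nrow(harmonic_modes)
  with_seed(seed, list(amp = rnorm(k, 0, p$shape_var),
                       phase = runif(k, 0, 2 * pi)))
}

# Elementwise radial multiplier at (theta, t); theta and t recycled together.
harmonic_mult <- function(harm, theta, t) {
  m <- 1
  if (is.null(harm)) return(m)
  for (i in seq_along(harm$amp)) {
    m <- m + harm$amp[i] * sin(pi * harmonic_modes[i, "k_z"] * t) *
      cos(harmonic_modes[i, "k_theta"] * theta + harm$phase[i])
  }
  m
}

revolve_grid <- function(p) {
  theta <- 2 * pi * (seq_len(p$n_theta) - 1) / p$n_theta
  t <- seq(0, 1, length.out = p$n_z + 1)
  list(theta = theta, t = t, z = -p$length * t)
}

# Faces for a closed-bottom tube grid: rings (nr x n_theta, row-major ring
# blocks) plus a tip vertex fan. Winding gives outward normals for rings laid
# out proximal (z high) to distal.
tube_faces <- function(nr, nt, tip_index) {
  fl <- vector("list", nr - 1)
  j <- seq_len(nt)
  jn <- c(2:nt, 1)
  for (i in seq_len(nr - 1)) {
    o1 <- (i - 1) * nt
    o2 <- i * nt
    fl[[i]] <- rbind(cbind(o1 + j, o2 + j, o1 + jn),
                     cbind(o1 + jn, o2 + j, o2 + jn))
  }
  f <- do.call(rbind, fl)
  o <- (nr - 1) * nt
  rbind(f, cbind(o + j, tip_index, o + jn))
}

#' Generate a synthetic limb mesh with landmarks
#'
#' Builds the surface of revolution described by [limb_params()]: open at the
#' proximal trim (as a scan trimmed at the epicondyles is), closed distally
#' by a fan cap, z running from 0 (proximal, epicondyle level) to `-length`
#' (distal tip), epicondyle landmarks on the x axis and the olecranon
#' posterior. Left-side limbs are mirrored about the sagittal plane. Output
#' is deterministic per seed.
#'
#' @param p a [limb_params()].
#' @param seed RNG seed for the surface noise.
#' @return List with `mesh` ([trimesh], generation parameters attached as
#'   attribute `limb_params`) and `landmarks` ([landmark_set]).
#' @export
generate_limb <- function(p, seed = 1) {
  stopifnot(inherits(p, "limb_params"))
  g <- revolve_grid(p)
  nt <- p$n_theta
  nr <- p$n_z + 1
  rho <- limb_profile(p, g$t)
  ct <- cos(g$theta)
  st <- sin(g$theta)
  harm <- draw_harmonics(p, seed)
  hm <- if (is.null(harm)) {
    1
  } else {
    outer(g$t, g$theta, function(t, th) harmonic_mult(harm, th, t))
  }
  x <- outer(rho * p$a0, ct) * hm  # nr x nt
  y <- outer(rho * p$b0, st) * hm
  if (p$noise_sd > 0) {
    noise <- with_seed(seed + 1, matrix(rnorm(nr * nt, sd = p$noise_sd), nr, nt))
    rr <- sqrt(x^2 + y^2)
    x <- x * (1 + noise / rr)
    y <- y * (1 + noise / rr)
  }
  v <- cbind(as.vector(t(x)), as.vector(t(y)), rep(g$z, each = nt))
  v <- rbind(v, c(0, 0, -p$length))
  f <- tube_faces(nr, nt, nrow(v))
  mesh <- trimesh(v, f)
  lm <- landmark_set(medial_epicondyle = c(-p$a0, 0, 0),
                     lateral_epicondyle = c(p$a0, 0, 0),
                     olecranon = c(0, -p$b0, 0),
                     side = "right")
  if (p$side == "left") {
    mv <- mesh$vertices
    mv[, 1] <- -mv[, 1]
    mesh <- trimesh(mv, mesh$faces[, c(1, 3, 2)])
    lm <- landmark_set(medial_epicondyle = c(p$a0, 0, 0),
                       lateral_epicondyle = c(-p$a0, 0, 0),
                       olecranon = lm$olecranon, side = "left")
  }
  attr(mesh, "limb_params") <- p
  attr(mesh, "harmonics") <- harm
  list(mesh = mesh, landmarks = lm)
}

#' Socket design parameters for the synthetic generator
#'
#' Synthetic sockets emulate the qualitative features of three-quarter
#' transradial designs: a radial clearance over the limb surface, a rounded
#' distal-end relief, a proximal trimline whose deepest indent seats the
#' epicondyles (at z = 0), an optional posterior olecranon cutout, and
#' optional planted deviation patches (raised-cosine bumps defined by a unit
#' direction from the anatomical origin, an amplitude in mm and an angular
#' extent) used as ground truth in deviation-recovery tests.
#'
#' @param clearance radial clearance delta over the limb surface, mm.
#' @param relief distal end relief depth, mm.
#' @param trim_indent how far the trimline rises above the epicondyle-level
#'   indent elsewhere around the rim, mm.
#' @param cutout add the posterior olecranon cutout?
#' @param cutout_width_deg angular width of the cutout.
#' @param cutout_frac cutout vertical half-extent as a fraction of limb length.
#' @param patches list of `list(direction, amplitude, extent_deg)` planted
#'   deviation patches (positive amplitude = inflation).
#' @param n_cap rows used for the rounded distal cap.
#' @return List of class `socket_design`.
#' @export
socket_design <- function(clearance = 2, relief = 4, trim_indent = 10,
                          cutout = TRUE, cutout_width_deg = 60,
                          cutout_frac = 0.12, patches = list(), n_cap = 8L) {
  if (clearance < 0 || relief <= 0 || trim_indent < 0) {
    stop("bad socket design parameters", call. = FALSE)
  }
  structure(list(clearance = clearance, relief = relief,
                 trim_indent = trim_indent, cutout = cutout,
                 cutout_width_deg = cutout_width_deg,
                 cutout_frac = cutout_frac, patches = patches,
                 n_cap = as.integer(n_cap)),
            class = "socket_design")
}

apply_patches <- function(v, patches) {
  for (pa in patches) {
    d <- normalize3(pa$direction)
    a0 <- pa$extent_deg * pi / 180
    u <- v / pmax(sqrt(rowSums(v^2)), 1e-12)
    ang <- acos(pmax(pmin(u %*% d, 1), -1))
    w <- ifelse(ang < a0, 0.5 * (1 + cos(pi * ang / a0)), 0)
    v <- v + as.vector(pa$amplitude * w) * u
  }
  v
}

#' Derive a synthetic socket from a generated limb
#'
#' Offsets the limb's analytic surface radially outward by the clearance,
#' adds a rounded distal relief cap, cuts the proximal trimline with its
#' deepest indent at the epicondyle level (z = 0), optionally removes a
#' posterior olecranon cutout, and applies any planted deviation patches.
#' Only meshes produced by [generate_limb()] (which carry their generation
#' parameters) are supported; the socket surface is built from the noise-free
#' analytic profile, as prosthetist sockets are smooth CAD surfaces.
#'
#' The socket is returned already registered in the limb's anatomical frame,
#' together with the two registration reference points: the deepest trimline
#' indent (lateral, z = 0) and the posterior obturator/olecranon reference.
#'
#' @param limb a [trimesh] from [generate_limb()] (right side / aligned).
#' @param d a [socket_design()].
#' @param seed reserved for randomized design features; unused by the
#'   current deterministic design.
#' @return List with `mesh` ([trimesh]), `indent_point`, `obturator_point`.
#' @export
derive_socket <- function(limb, d, seed = 1) {
  p <- attr(limb, "limb_params")
  if (is.null(p)) {
    stop("derive_socket needs a limb produced by generate_limb()", call. = FALSE)
  }
  stopifnot(inherits(d, "socket_design"))
  L <- p$length
  nt <- p$n_theta
  theta <- 2 * pi * (seq_len(nt) - 1) / nt
  # trimline: deepest indent (z = 0) at the epicondyles (theta = 0, pi),
  # rising by trim_indent at the anterior/posterior quadrants
  z_trim <- d$trim_indent * (1 - cos(2 * theta)) / 2
  nz <- p$n_z
  ncap <- d$n_cap
  nr <- nz + ncap + 1
  harm <- attr(limb, "harmonics")
  ellipse_radius <- function(th, t) {
    rho <- limb_profile(p, t) * harmonic_mult(harm, th, t)
    cbind(p$a0 * rho * cos(th), p$b0 * rho * sin(th))
  }
  rows <- vector("list", nr)
  for (i in seq_len(nr)) {
    if (i <= nz + 1) {
      # wall rows: from the per-column trim top down to the distal end
      s <- (i - 1) / nz
      z <- z_trim + s * (-L - z_trim)
      t <- pmax(0, pmin(1, -z / L))
      xy <- ellipse_radius(theta, t)
      rr <- sqrt(rowSums(xy^2))
      u <- xy / rr
      xy <- xy + d$clearance * u
      rows[[i]] <- cbind(xy, z)
    } else {
      # rounded relief cap below the distal end
      s <- (i - nz - 1) / ncap
      zc <- -L - d$relief * sin(s * pi / 2)
      shrink <- cos(s * pi / 2)
      xy <- ellipse_radius(theta, 1)
      rr <- sqrt(rowSums(xy^2))
      u <- xy / rr
      xy <- (xy + d$clearance * u) * shrink
      rows[[i]] <- cbind(xy, zc)
    }
  }
  v <- do.call(rbind, rows)
  v <- rbind(v, c(0, 0, -L - d$relief))
  v <- apply_patches(v, d$patches)
  f <- tube_faces(nr, nt, nrow(v))
  if (d$cutout) {
    # posterior hole centred below the trimline
    th0 <- -pi / 2
    zc0 <- -0.08 * L
    wth <- d$cutout_width_deg * pi / 360  # half-width in radians
    wz <- d$cutout_frac * L
    vth <- atan2(v[, 2], v[, 1])
    dth <- atan2(sin(vth - th0), cos(vth - th0))
    inside <- (dth / wth)^2 + ((v[, 3] - zc0) / wz)^2 < 1
    inside[nrow(v)] <- FALSE
    drop_face <- inside[f[, 1]] & inside[f[, 2]] & inside[f[, 3]]
    f <- f[!drop_face, , drop = FALSE]
    used <- sort(unique(as.vector(f)))
    remap <- match(seq_len(nrow(v)), used)
    v <- v[used, , drop = FALSE]
    f <- matrix(remap[f], ncol = 3)
    obturator <- c(0, -(p$b0 * limb_profile(p, -zc0 / L) + d$clearance),
                   zc0 - wz)
  } else {
    obturator <- c(0, -(p$b0 + d$clearance), -0.02 * L)
  }
  indent <- c(p$a0 + d$clearance, 0, 0)
  mesh <- trimesh(v, f)
  attr(mesh, "socket_design") <- d
  list(mesh = mesh, indent_point = indent, obturator_point = obturator)
}

#' Population defaults for synthetic cohorts
#'
#' Moment-matched to the published reference cohort: limb lengths are drawn
#' from a normal distribution with mean 76.3 mm and SD 23.4 mm truncated to
#' 35-125 mm; ages from a pediatric/adult mixture (9/19 pediatric, uniform
#' 9-17 y; adults uniform 18-67 y); sexes balanced; shapes mostly conical
#' with the remainder cylindrical.
#'
#' @param ... overrides of the named defaults.
#' @return List of population parameters.
#' @export
cohort_population <- function(...) {
  pop <- list(
    length_mean = 76.3, length_sd = 23.4, length_range = c(35, 125),
    p_pediatric = 9 / 19, age_pediatric = c(9, 17), age_adult = c(18, 67),
    p_female = 0.5,
    shape_probs = c(conical = 0.7, cylindrical = 0.3, bulbous = 0),
    a0_range = c(18, 30), aspect_range = c(0.75, 1.0),
    taper_conical = c(0.45, 0.75), taper_cylindrical = c(0.96, 1.04),
    taper_bulbous = c(0.8, 1.0),
    noise_sd = 0.2,
    clearance_range = c(1.5, 3), relief_range = c(2, 8),
    trim_indent_range = c(8, 15), p_cutout = 0.7,
    cutout_width_range = c(50, 80)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(pop))
  if (length(bad)) stop("unknown population field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  pop[names(dots)] <- dots
  pop
}

# Documented stand-in for the clinician length classes: limb length relative
# to a nominal age-scaled forearm length (130 mm at birth to 260 mm adult).
length_class_rule <- function(length, age) {
  nominal <- 130 + 130 * pmin(age, 18) / 18
  ratio <- length / nominal
  ifelse(ratio > 0.55, "long", ifelse(ratio >= 0.33, "short", "very_short"))
}

#' Generate a synthetic limb-socket cohort with known ground truth
#'
#' Draws `n` participants from the population spec, generates each limb and
#' derives its socket, and assembles a [socket_library]. The ground-truth
#' record stores every generator parameter for recovery tests. Deterministic
#' per seed.
#'
#' @param n cohort size (>= 2).
#' @param seed RNG seed.
#' @param population a [cohort_population()] spec.
#' @return List with `library` ([socket_library]) and `ground_truth` (list
#'   per participant: `limb_params`, `socket_design`, reference points,
#'   `limb_seed`).
#' @export
generate_cohort <- function(n, seed = 1, population = cohort_population()) {
  if (n < 2) stop("a cohort needs at least 2 participants", call. = FALSE)
  pop <- population
  draws <- with_seed(seed, {
    len <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        l <- rnorm(1, pop$length_mean, pop$length_sd)
        if (l >= pop$length_range[1] && l <= pop$length_range[2]) break
      }
      len[i] <- l
    }
    ped <- runif(n) < pop$p_pediatric
    age <- ifelse(ped,
                  runif(n, pop$age_pediatric[1], pop$age_pediatric[2]),
                  runif(n, pop$age_adult[1], pop$age_adult[2]))
    sex <- ifelse(runif(n) < pop$p_female, "F", "M")
    shape <- sample(names(pop$shape_probs), n, replace = TRUE,
                    prob = pop$shape_probs)
    taper <- vapply(shape, function(s) {
      r <- pop[[paste0("taper_", s)]]
      runif(1, r[1], r[2])
    }, 0)
    a0 <- runif(n, pop$a0_range[1], pop$a0_range[2])
    b0 <- a0 * runif(n, pop$aspect_range[1], pop$aspect_range[2])
    clearance <- runif(n, pop$clearance_range[1], pop$clearance_range[2])
    relief <- runif(n, pop$relief_range[1], pop$relief_range[2])
    indent <- runif(n, pop$trim_indent_range[1], pop$trim_indent_range[2])
    cutout <- runif(n) < pop$p_cutout
    cwidth <- runif(n, pop$cutout_width_range[1], pop$cutout_width_range[2])
    list(len = len, age = round(age), sex = sex, shape = shape, taper = taper,
         a0 = a0, b0 = b0, clearance = clearance, relief = relief,
         indent = indent, cutout = cutout, cwidth = cwidth)
  })
  entries <- vector("list", n)
  truth <- vector("list", n)
  ids <- sprintf("S%02d", seq_len(n))
  for (i in seq_len(n)) {
    lp <- limb_params(length = draws$len[i], a0 = draws$a0[i], b0 = draws$b0[i],
                      taper = draws$taper[i], shape = draws$shape[i],
                      noise_sd = pop$noise_sd)
    limb_seed <- (seed + 7919 * i) %% .Machine$integer.max
    gl <- generate_limb(lp, seed = limb_seed)
    sd_ <- socket_design(clearance = draws$clearance[i],
                         relief = draws$relief[i],
                         trim_indent = draws$indent[i],
                         cutout = draws$cutout[i],
                         cutout_width_deg = draws$cwidth[i])
    sock <- derive_socket(gl$mesh, sd_)
    meta <- participant_meta(ids[i], draws$sex[i], draws$age[i],
                             limb_length = draws$len[i],
                             length_class = length_class_rule(draws$len[i],
                                                              draws$age[i]),
                             shape_class = draws$shape[i])
    entries[[i]] <- library_entry(meta, gl$mesh, gl$landmarks, sock$mesh)
    truth[[i]] <- list(limb_params = lp, socket_design = sd_,
                       indent_point = sock$indent_point,
                       obturator_point = sock$obturator_point,
                       limb_seed = limb_seed)
  }
  names(truth) <- ids
  list(library = build_library(entries), ground_truth = truth)
}
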