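#' Scaling factors applied to a retrieved socket
#'
#' `sf_k` is the isotropic length-normalization factor (input limb length
#' over matched library limb length), `sf_ml` and `sf_ap` the anisotropic
#' medio-lateral and anterior-posterior refinement factors. All
#' dimensionless and strictly positive.
#'
#' @param sf_k,sf_ml,sf_ap positive scalars.
#' @return An object of class `scaling_factors`.
#' @export
scaling_factors <- function(sf_k, sf_ml = 1, sf_ap = 1) {
  vals <- c(sf_k, sf_ml, sf_ap)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("scaling factors must be finite and positive", call. = FALSE)
  }
  structure(list(sf_k = sf_k, sf_ml = sf_ml, sf_ap = sf_ap),
            class = "scaling_factors")
}

#' Mean nearest-neighbour surface distance between two point clouds
#'
#' The shape-retrieval similarity metric: `d = (1/n) sum ||p_i - q_i||` where
#' `q_i` is the nearest point in `Q` to `p_i`. One-directional `P -> Q` by
#' default; `symmetric = TRUE` averages both directions.
#'
#' @param p,q [pointcloud]s or point matrices.
#' @param symmetric average the two one-directional distances.
#' @return Distance in mm.
#' @export
shape_distance <- function(p, q, symmetric = FALSE) {
  pm <- as_points(p)
  qm <- as_points(q)
  d <- mean(cpp_nearest(pm, qm)$dist)
  if (symmetric) d <- (d + mean(cpp_nearest(qm, pm)$dist)) / 2
  d
}

#' Isotropic length normalization of a library limb
#'
#' Computes `sf_k = input_length / entry_length` and scales the entry's limb
#' mesh uniformly by `sf_k` about the anatomical frame origin, so its
#' proximal-distal length equals the input's.
#'
#' @param input_length input limb length, mm.
#' @param entry a [library_entry].
#' @return List with `sf_k` and `limb` (the scaled [trimesh]).
#' @export
length_normalize <- function(input_length, entry) {
  stopifnot(inherits(entry, "library_entry"))
  lk <- entry$meta$limb_length
  if (!is.finite(input_length) || input_length <= 0 || lk <= 0) {
    stop("limb lengths must be positive", call. = FALSE)
  }
  sf_k <- input_length / lk
  list(sf_k = sf_k, limb = trimesh(entry$limb$vertices * sf_k, entry$limb$faces))
}

#' Retrieve the best-matching library limb for an aligned input limb
#'
#' Every library limb is length-normalized to the input limb and compared by
#' [shape_distance()] on seeded surface samples; the entry with the smallest
#' distance wins. Ties are broken by the smaller `|sf_k - 1|` (least
#' geometric distortion), then by id order.
#'
#' @param input aligned limb [trimesh].
#' @param lib a [socket_library].
#' @param n surface sample size per mesh.
#' @param seed RNG seed for sampling.
#' @param symmetric symmetrize the distance (see [shape_distance()]).
#' @return List with `matched_id`, `sf_k`, `d_l2` (mm) and `distances`
#'   (per-entry data.frame).
#' @export
retrieve_best_match <- function(input, lib, n = 10000, seed = 1,
                                symmetric = FALSE) {
  stopifnot(inherits(input, "trimesh"), inherits(lib, "socket_library"))
  if (length(lib$entries) == 0) stop("empty library", call. = FALSE)
  input_length <- diff(range(input$vertices[, 3]))
  query <- sample_surface(input, n, seed)$points
  ids <- names(lib$entries)
  res <- lapply(lib$entries, function(entry) {
    sf_k <- input_length / entry$meta$limb_length
    # sampling commutes with uniform scaling: sample once, scale the points
    cloud <- sample_surface(entry$limb, n, seed)$points * sf_k
    d <- mean(cpp_nearest(query, cloud)$dist)
    if (symmetric) d <- (d + mean(cpp_nearest(cloud, query)$dist)) / 2
    c(d = d, sf_k = sf_k)
  })
  tab <- data.frame(id = ids,
                    d_l2 = vapply(res, `[[`, 0, "d"),
                    sf_k = vapply(res, `[[`, 0, "sf_k"),
                    row.names = NULL)
  ord <- order(tab$d_l2, abs(tab$sf_k - 1), tab$id)
  best <- tab[ord[1], ]
  list(matched_id = best$id, sf_k = best$sf_k, d_l2 = best$d_l2,
       distances = tab)
}

#' Anisotropic refinement factors from whole-mesh caliper extents
#'
#' `sf_ap` is the ratio of the input limb's anterior-posterior (y) extent to
#' that of the isotropically scaled matched limb; `sf_ml` the analogous
#' medio-lateral (x) ratio.
#'
#' @param input aligned input limb [trimesh].
#' @param scaled_match the matched limb [trimesh] after isotropic scaling.
#' @return List with `sf_ap` and `sf_ml`.
#' @export
anisotropic_factors <- function(input, scaled_match) {
  ext <- vapply(c("x", "y"), function(ax) {
    c(measure_extent(input, ax), measure_extent(scaled_match, ax))
  }, numeric(2))
  if (any(ext <= 0)) stop("zero caliper extent", call. = FALSE)
  list(sf_ml = unname(ext[1, "x"] / ext[2, "x"]),
       sf_ap = unname(ext[1, "y"] / ext[2, "y"]))
}

#' Apply the socket scaling step
#'
#' Maps socket coordinates `(x, y, z)` to
#' `(sf_k * sf_ml * x, sf_k * sf_ap * y, sf_k * z)` about the anatomical
#' frame origin. The anisotropic factors act only on the cross-sectional
#' plane so the proximal-distal length set by `sf_k` is preserved.
#'
#' @param socket registered socket [trimesh].
#' @param f a [scaling_factors].
#' @return The scaled [trimesh].
#' @export
apply_scaling <- function(socket, f) {
  stopifnot(inherits(socket, "trimesh"), inherits(f, "scaling_factors"))
  v <- socket$vertices
  v[, 1] <- v[, 1] * f$sf_k * f$sf_ml
  v[, 2] <- v[, 2] * f$sf_k * f$sf_ap
  v[, 3] <- v[, 3] * f$sf_k
  trimesh(v, socket$faces)
}

#' Predict a customized socket for a new limb scan
#'
#' The full retrieve-and-refine pipeline: align the input limb to the
#' anatomical frame, retrieve the closest length-normalized library limb by
#' mean nearest-neighbour surface distance, apply the isotropic factor
#' `sf_k` to the retrieved socket, measure the anisotropic
#' anterior-posterior and medio-lateral factors between the input limb and
#' the scaled matched limb, and apply them to the socket.
#'
#' @param limb input limb [trimesh] (raw scan frame).
#' @param landmarks the limb's [landmark_set].
#' @param lib a [socket_library].
#' @param config a [pact_config()].
#' @param aligned set to `TRUE` when `limb` is already in the anatomical
#'   frame (landmarks may then be omitted).
#' @return An object of class `prediction_result`: `matched_id`, `factors`
#'   ([scaling_factors]), `d_l2` (mm), `socket` (predicted [trimesh] in the
#'   input limb's frame), `input_length` (mm) and `distances` (retrieval
#'   table).
#' @export
predict_socket <- function(limb, landmarks = NULL, lib, config = pact_config(),
                           aligned = FALSE) {
  stopifnot(inherits(lib, "socket_library"))
  if (!aligned) {
    if (is.null(landmarks)) stop("landmarks required to align the input limb",
                                 call. = FALSE)
    limb <- align_limb(limb, landmarks)$mesh
  }
  ret <- retrieve_best_match(limb, lib, n = config$sample_n, seed = config$seed,
                             symmetric = config$symmetric_distance)
  entry <- lib$entries[[ret$matched_id]]
  input_length <- diff(range(limb$vertices[, 3]))
  norm <- length_normalize(input_length, entry)
  aniso <- anisotropic_factors(limb, norm$limb)
  factors <- scaling_factors(ret$sf_k, aniso$sf_ml, aniso$sf_ap)
  socket <- apply_scaling(entry$socket, factors)
  structure(list(matched_id = ret$matched_id, factors = factors,
                 d_l2 = ret$d_l2, socket = socket,
                 input_length = input_length, distances = ret$distances),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("socket prediction: matched %s (d_L2 = %.3f mm)\n",
              x$matched_id, x$d_l2))
  cat(sprintf("  SF_k = %.3f, SF_M-L = %.3f, SF_A-P = %.3f\n",
              x$factors$sf_k, x$factors$sf_ml, x$factors$sf_ap))
  invisible(x)
}
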