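#' Participant metadata
#'
#' Demographics and clinician-assigned qualitative limb descriptors for one
#' library participant: length class ("long", "short", "very_short") and
#' shape class ("conical", "cylindrical", "bulbous").
#'
#' @param id participant label.
#' @param sex `"M"` or `"F"`.
#' @param age years (> 0).
#' @param limb_length aligned limb z-extent in mm (> 0).
#' @param length_class,shape_class qualitative descriptors.
#' @return An object of class `participant_meta`.
#' @export
participant_meta <- function(id, sex, age, limb_length,
                             length_class = c("short", "very_short", "long"),
                             shape_class = c("conical", "cylindrical", "bulbous")) {
  length_class <- match.arg(length_class)
  shape_class <- match.arg(shape_class)
  sex <- match.arg(sex, c("M", "F"))
  if (!is.finite(age) || age <= 0) stop("age must be positive", call. = FALSE)
  if (!is.finite(limb_length) || limb_length <= 0) {
    stop("limb_length must be positive", call. = FALSE)
  }
  structure(list(id = as.character(id), sex = sex, age = as.numeric(age),
                 limb_length = as.numeric(limb_length),
                 length_class = length_class, shape_class = shape_class),
            class = "participant_meta")
}

#' One registered limb-socket pair
#'
#' Bundles the aligned limb mesh with its landmarks and the socket registered
#' into the same anatomical frame. The recorded `limb_length` must agree with
#' the limb mesh z-extent within 1 mm.
#'
#' @param meta a [participant_meta].
#' @param limb aligned [trimesh].
#' @param landmarks the limb's [landmark_set] in the aligned frame.
#' @param socket registered [trimesh].
#' @return An object of class `library_entry`.
#' @export
library_entry <- function(meta, limb, landmarks, socket) {
  stopifnot(inherits(meta, "participant_meta"), inherits(limb, "trimesh"),
            inherits(landmarks, "landmark_set"), inherits(socket, "trimesh"))
  zext <- diff(range(limb$vertices[, 3]))
  if (abs(zext - meta$limb_length) > 1) {
    stop(sprintf("entry %s: limb_length %.1f mm disagrees with mesh z-extent %.1f mm",
                 meta$id, meta$limb_length, zext), call. = FALSE)
  }
  structure(list(meta = meta, limb = limb, landmarks = landmarks,
                 socket = socket), class = "library_entry")
}

#' Build a reference library of limb-socket pairs
#'
#' @param entries list of [library_entry] objects with unique ids.
#' @return An object of class `socket_library` (entries keyed by id).
#' @export
build_library <- function(entries) {
  if (length(entries) == 0) stop("cannot build an empty library", call. = FALSE)
  stopifnot(all(vapply(entries, inherits, TRUE, "library_entry")))
  ids <- vapply(entries, function(e) e$meta$id, "")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate participant id: %s", ids[duplicated(ids)][1]),
         call. = FALSE)
  }
  structure(list(entries = setNames(entries, ids)), class = "socket_library")
}

#' @export
print.socket_library <- function(x, ...) {
  cat(sprintf("socket_library: %d limb-socket pairs (%s)\n",
              length(x$entries), paste(head(names(x$entries), 6), collapse = ", ")))
  invisible(x)
}

#' Leave one participant out of the library
#'
#' Returns a new library without the given id; the input is not modified.
#'
#' @param lib a [socket_library] with at least 2 entries.
#' @param id participant id to exclude.
#' @return A [socket_library].
#' @export
leave_one_out <- function(lib, id) {
  stopifnot(inherits(lib, "socket_library"))
  if (!id %in% names(lib$entries)) {
    stop(sprintf("unknown participant id: %s", id), call. = FALSE)
  }
  if (length(lib$entries) < 2) {
    stop("cannot leave one out of a single-entry library", call. = FALSE)
  }
  build_library(lib$entries[setdiff(names(lib$entries), id)])
}

#' Summarize a library or a demographics table
#'
#' Per-entry metadata plus the sample mean and (n-1) standard deviation of
#' age and limb length, mirroring the usual cohort demographics table.
#'
#' @param lib a [socket_library] or a data.frame with columns `id`, `sex`,
#'   `age`, `limb_length`, `length_class`, `shape_class`.
#' @return List with `participants` (data.frame) and `summary` (data.frame
#'   with columns variable/mean/sd; sd is `NA` for a single entry).
#' @export
summarize_library <- function(lib) {
  df <- if (inherits(lib, "socket_library")) {
    do.call(rbind, lapply(lib$entries, function(e) {
      as.data.frame(unclass(e$meta), stringsAsFactors = FALSE)
    }))
  } else {
    as.data.frame(lib)
  }
  rownames(df) <- NULL
  sd_or_na <- function(x) if (length(x) > 1) sd(x) else NA_real_
  summ <- data.frame(
    variable = c("age", "limb_length"),
    mean = c(mean(df$age), mean(df$limb_length)),
    sd = c(sd_or_na(df$age), sd_or_na(df$limb_length))
  )
  list(participants = df, summary = summ)
}

#' Demographics of the published 19-participant reference cohort
#'
#' The printed participant table (id, sex, age, limb length in mm and the
#' clinician-assigned length/shape classes) bundled with the package. These
#' values parameterize the synthetic cohort generator's population defaults.
#'
#' @return A data.frame with 19 rows.
#' @export
reference_demographics <- function() {
  path <- system.file("extdata", "reference_cohort_demographics.csv",
                      package = "pactr", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Save / load a library as a JSON manifest plus mesh and landmark files
#'
#' Meshes are written as full-precision ASCII PLY so a save/load round trip
#' reproduces vertex coordinates bitwise; landmarks as JSON sidecars.
#'
#' @param lib a [socket_library].
#' @param dir output directory (created if missing).
#' @return The manifest path (save) or a [socket_library] (load).
#' @export
save_library <- function(lib, dir) {
  stopifnot(inherits(lib, "socket_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(lib$entries, function(e) {
    id <- e$meta$id
    limb_path <- file.path(dir, paste0(id, "_limb.ply"))
    socket_path <- file.path(dir, paste0(id, "_socket.ply"))
    lm_path <- file.path(dir, paste0(id, "_limb.landmarks.json"))
    write_mesh(e$limb, limb_path)
    write_mesh(e$socket, socket_path)
    write_landmarks(e$landmarks, lm_path)
    c(e$meta[c("id", "sex", "age", "limb_length", "length_class", "shape_class")],
      list(limb = basename(limb_path), socket = basename(socket_path),
           landmarks = basename(lm_path)))
  })
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(unname(manifest), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_library
#' @param path manifest JSON path, or the directory containing `manifest.json`.
#' @export
load_library <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  manifest <- jsonlite::read_json(path, simplifyVector = FALSE)
  dir <- dirname(path)
  entries <- lapply(manifest, function(m) {
    meta <- participant_meta(m$id, m$sex, m$age, m$limb_length,
                             m$length_class, m$shape_class)
    library_entry(meta,
                  limb = load_mesh(file.path(dir, m$limb)),
                  landmarks = read_landmarks(file.path(dir, m$landmarks)),
                  socket = load_mesh(file.path(dir, m$socket)))
  })
  build_library(entries)
}
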