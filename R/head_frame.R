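#' Required facial landmarks
#'
#' The three anatomical points the head coordinate frame is built from:
#' the orbital margins lateral to the right and left lateral canthi, and a
#' point 1 cm below the bottom of the lower lip.
#' @export
HEAD_LANDMARKS <- c("right_canthus", "left_canthus", "sublip")

#' A single timestamped landmark frame
#'
#' One sample from one device: named 3D points (millimetres, device world
#' frame) at a timestamp. Additional named points are permitted and
#' ignored by the kinematics. A frame flagged `dropout = TRUE` represents a
#' sample where face tracking was lost; its points may be missing.
#'
#' @param timestamp seconds from recording start (`>= 0`).
#' @param points named list of numeric length-3 vectors (x, y, z in mm).
#' @param dropout logical dropout flag.
#' @return An object of class `landmark_frame`.
#' @export
landmark_frame <- function(timestamp, points, dropout = FALSE) {
  stopifnot(is.numeric(timestamp), length(timestamp) == 1L, timestamp >= 0)
  if (!dropout) {
    missing <- setdiff(HEAD_LANDMARKS, names(points))
    if (length(missing) > 0L) {
      stop("missing landmark(s): ", paste(missing, collapse = ", "),
           " (dropout frame passed unfiltered?)", call. = FALSE)
    }
    for (nm in HEAD_LANDMARKS) {
      p <- points[[nm]]
      if (!is.numeric(p) || length(p) != 3L || !all(is.finite(p))) {
        stop("landmark '", nm, "' must be a finite numeric xyz triple",
             call. = FALSE)
      }
    }
  }
  structure(list(timestamp = timestamp, points = points, dropout = dropout),
            class = "landmark_frame")
}

# Row-wise cross product of two n x 3 matrices.
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norm <- function(a) sqrt(rowSums(a * a))

# Vectorised head-frame construction. pr, pl, ps: n x 3 matrices of
# right-canthus, left-canthus and sublip world coordinates (mm). Returns
# list(X, Y, Z): n x 3 matrices of the head basis vectors in world
# coordinates (columns of the per-frame orientation matrices).
#
# Geometry: origin at the canthal midpoint; x toward the right canthus;
# y = unit(x cross (sublip - origin)), the facial-plane normal with the
# sign that makes z = x cross y point away from the sublip side of the
# canthal line (i.e. toward world up when the face is upright at the
# neutral calibration pose); z completes the right-handed frame.
head_frames <- function(pr, pl, ps, area_tol_mm2 = 1) {
  origin <- (pr + pl) / 2
  xv <- pr - origin
  sv <- ps - origin
  xn <- row_norm(xv)
  if (any(xn < 1e-9)) {
    stop("degenerate geometry: coincident canthus landmarks in frame(s) ",
         paste(utils::head(which(xn < 1e-9), 5), collapse = ", "),
         call. = FALSE)
  }
  X <- xv / xn
  yv <- row_cross(X, sv)
  # |x-hat cross s| = twice the area of triangle (origin, right_canthus,
  # sublip) divided by |xv| ... area = |xv cross sv| / 2 = |yv| * |xv| / 2
  area <- row_norm(yv) * xn / 2
  if (any(area <= area_tol_mm2)) {
    stop("degenerate geometry: collinear landmarks (triangle area <= ",
         area_tol_mm2, " mm^2) in frame(s) ",
         paste(utils::head(which(area <= area_tol_mm2), 5), collapse = ", "),
         call. = FALSE)
  }
  Y <- yv / row_norm(yv)
  Z <- row_cross(X, Y)
  list(X = X, Y = Y, Z = Z)
}

#' Build the head coordinate frame from one landmark frame
#'
#' Constructs the anatomical head frame: origin at the midpoint of the two
#' canthal landmarks; x axis the unit vector from the origin toward the
#' right canthus (mediolateral, pointing to the subject's right); y axis
#' the unit normal of the plane through the origin, the right canthus and
#' the sublip point (anteroposterior), with its sign fixed so that the
#' completed z axis `z = x × y` points toward world up at an upright
#' neutral pose (the sublip lies below the canthal line, so
#' `y = unit(x × (sublip − origin))` achieves this for every frame);
#' z mutually orthogonal (superior, through the forehead).
#'
#' @param f a [landmark_frame()] (not a dropout frame).
#' @param area_tol_mm2 collinearity guard: the landmark triangle must have
#'   area greater than this (mm^2).
#' @return A 3x3 orientation matrix whose columns are the head x, y, z axes
#'   expressed in the device world frame (orthonormal, det +1).
#' @export
#' @examples
#' f <- landmark_frame(0, list(
#'   right_canthus = c(45, 0, 0), left_canthus = c(-45, 0, 0),
#'   sublip = c(0, -70, 0)))
#' build_head_frame(f)
build_head_frame <- function(f, area_tol_mm2 = 1) {
  if (inherits(f, "landmark_frame") && isTRUE(f$dropout)) {
    stop("dropout frame passed unfiltered to build_head_frame", call. = FALSE)
  }
  pts <- if (inherits(f, "landmark_frame")) f$points else f
  missing <- setdiff(HEAD_LANDMARKS, names(pts))
  if (length(missing) > 0L) {
    stop("missing landmark(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  h <- head_frames(matrix(pts$right_canthus, 1),
                   matrix(pts$left_canthus, 1),
                   matrix(pts$sublip, 1),
                   area_tol_mm2 = area_tol_mm2)
  cbind(drop(h$X), drop(h$Y), drop(h$Z))
}

#' Neutral face landmark template
#'
#' Neutral head-frame coordinates (mm) of the three required landmarks,
#' used by the simulator as the rigid face model. The defaults place the
#' canthi 90 mm apart on the mediolateral axis and the sublip point 70 mm
#' below their midpoint; they are plumbing constants for the forward
#' model, not measured anthropometry.
#'
#' @param right_canthus,left_canthus,sublip numeric xyz triples (mm).
#' @return An object of class `face_template`: a named list of points.
#' @export
face_template <- function(right_canthus = c(45, 0, 0),
                          left_canthus = c(-45, 0, 0),
                          sublip = c(0, -70, 0)) {
  tpl <- list(right_canthus = right_canthus,
              left_canthus = left_canthus,
              sublip = sublip)
  # must form a non-degenerate triangle
  build_head_frame(tpl)
  structure(tpl, class = "face_template")
}
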