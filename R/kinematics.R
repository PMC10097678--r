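## Pantograph (planar five-bar) kinematics, manipulandum trajectories,
## stereo joint triangulation and workspace angle maps.
##
## Coordinate conventions:
##  * manipulandum frame: origin at the center of the left motor, X toward
##    the right motor, Y "up" in the linkage plane (elbow-up working branch).
##  * 3D joint frame: X lateral-right, Y anterior, Z up (cm).

LANDMARKS <- c("scapulothoracic", "glenohumeral", "elbow", "wrist", "endpoint")

#' Pantograph geometry
#'
#' Describes the planar five-bar linkage used as a robotic manipulandum: two
#' motors separated by `motor_separation_d`, each driving a proximal link of
#' length `proximal_link_lp` whose distal link (length `distal_link_ld`)
#' joins the other chain at the endpoint.
#'
#' @param motor_separation_d distance between the two motor hubs (cm).
#' @param proximal_link_lp proximal link length (cm).
#' @param distal_link_ld distal link length (cm).
#' @return an object of class `pantograph_geometry`.
#' @export
pantograph_geometry <- function(motor_separation_d = 2,
                                proximal_link_lp = 2,
                                distal_link_ld = 3) {
  stopifnot(motor_separation_d > 0, proximal_link_lp > 0, distal_link_ld > 0)
  if (distal_link_ld + proximal_link_lp <= motor_separation_d / 2)
    stop("geometry cannot reach the midline: ld + lp must exceed d/2")
  structure(list(d = motor_separation_d, lp = proximal_link_lp,
                 ld = distal_link_ld),
            class = "pantograph_geometry")
}

#' @export
print.pantograph_geometry <- function(x, ...) {
  cat(sprintf("pantograph: motor separation %.3g cm, links lp=%.3g, ld=%.3g cm\n",
              x$d, x$lp, x$ld))
  invisible(x)
}

elbow_points <- function(geom, theta_left, theta_right) {
  list(left = c(geom$lp * cos(theta_left), geom$lp * sin(theta_left)),
       right = c(geom$d + geom$lp * cos(theta_right),
                 geom$lp * sin(theta_right)))
}

## intersection of two circles (centers c1, c2, common radius r);
## returns the two intersection points or NULL when disjoint
circle_intersections <- function(c1, c2, r1, r2) {
  dvec <- c2 - c1
  d <- sqrt(sum(dvec^2))
  if (d > r1 + r2 + 1e-12 || d < abs(r1 - r2) - 1e-12 || d < 1e-15) return(NULL)
  a <- (d^2 + r1^2 - r2^2) / (2 * d)
  h2 <- r1^2 - a^2
  h <- sqrt(max(h2, 0))
  mid <- c1 + a * dvec / d
  perp <- c(-dvec[2], dvec[1]) / d
  list(mid + h * perp, mid - h * perp)
}

#' Forward kinematics of the pantograph
#'
#' Maps the two motor angles (radians, counterclockwise from the +X axis at
#' each hub) to the endpoint position, taking the elbow-up branch (the
#' intersection with the larger Y).
#'
#' @param geom a [pantograph_geometry()].
#' @param theta_left,theta_right motor angles in radians.
#' @return numeric `c(x, y)` endpoint in cm (manipulandum frame).
#' @export
forward_kinematics <- function(geom, theta_left, theta_right) {
  stopifnot(inherits(geom, "pantograph_geometry"),
            is.finite(theta_left), is.finite(theta_right))
  el <- elbow_points(geom, theta_left, theta_right)
  pts <- circle_intersections(el$left, el$right, geom$ld, geom$ld)
  if (is.null(pts))
    stop("unreachable configuration: distal-link circles do not intersect")
  if (pts[[1]][2] >= pts[[2]][2]) pts[[1]] else pts[[2]]
}

## candidate motor angles placing one chain's elbow so that the distal link
## reaches `target`; hub at `hub`
chain_angles <- function(hub, lp, ld, target) {
  pts <- circle_intersections(hub, target, lp, ld)
  if (is.null(pts)) return(NULL)
  vapply(pts, function(e) atan2(e[2] - hub[2], e[1] - hub[1]), numeric(1))
}

#' Inverse kinematics of the pantograph
#'
#' Finds motor angles whose forward kinematics (elbow-up branch) reproduce
#' the target endpoint. Each chain admits two elbow placements; the outward
#' working mode (left elbow clockwise of the motor-to-target ray, right elbow
#' counterclockwise) is preferred, falling back to any combination whose
#' forward kinematics reproduce the target.
#'
#' @param geom a [pantograph_geometry()].
#' @param target numeric `c(x, y)` endpoint in cm.
#' @param tol round-trip acceptance tolerance (cm).
#' @return list with `theta_left`, `theta_right` (radians).
#' @export
inverse_kinematics <- function(geom, target, tol = 1e-6) {
  stopifnot(inherits(geom, "pantograph_geometry"),
            length(target) == 2, all(is.finite(target)))
  thl <- chain_angles(c(0, 0), geom$lp, geom$ld, target)
  if (is.null(thl))
    stop("target unreachable by the left chain")
  thr <- chain_angles(c(geom$d, 0), geom$lp, geom$ld, target)
  if (is.null(thr))
    stop("target unreachable by the right chain")
  ## cross product of (elbow - hub) with (target - hub): sign picks the
  ## working mode
  cross_sign <- function(hub, theta) {
    e <- geom$lp * c(cos(theta), sin(theta))
    tt <- target - hub
    e[1] * tt[2] - e[2] * tt[1]
  }
  ord_l <- order(vapply(thl, function(a) cross_sign(c(0, 0), a), numeric(1)))
  ord_r <- order(-vapply(thr, function(b) cross_sign(c(geom$d, 0), b),
                         numeric(1)))
  combos <- expand.grid(il = ord_l, ir = ord_r)   # preferred combo first
  best <- NULL; best_err <- Inf
  for (k in seq_len(nrow(combos))) {
    a <- thl[combos$il[k]]; b <- thr[combos$ir[k]]
    p <- tryCatch(forward_kinematics(geom, a, b), error = function(e) NULL)
    if (is.null(p)) next
    err <- sqrt(sum((p - target)^2))
    if (err <= tol) { best <- c(a, b); best_err <- err; break }
    if (err < best_err) { best_err <- err; best <- c(a, b) }
  }
  if (is.null(best) || best_err > tol)
    stop("no elbow-up branch solution reproduces the target endpoint")
  list(theta_left = best[1], theta_right = best[2])
}

#' Trapezoidal-velocity point-to-point trajectory
#'
#' Straight-line displacement from `start` to `end` with a trapezoidal speed
#' profile (constant acceleration, cruise at `peak_velocity`, symmetric
#' deceleration), sampled on a 1 kHz grid. When the distance is too short for
#' a cruise phase the profile degenerates to a triangle.
#'
#' @param start,end numeric `c(x, y)` in cm.
#' @param peak_velocity cruise speed, cm/s.
#' @param accel acceleration magnitude, cm/s^2.
#' @param sample_rate_hz sampling rate of the returned trajectory (default 1000).
#' @return list of class `trajectory`: `times_s`, `positions` (n x 2),
#'   `speed_cms`, `duration_s`, `amplitude_mm`, `peak_velocity`, `accel`.
#' @export
trapezoid_trajectory <- function(start, end, peak_velocity, accel,
                                 sample_rate_hz = 1000) {
  stopifnot(length(start) == 2, length(end) == 2,
            peak_velocity > 0, accel > 0, sample_rate_hz > 0)
  dist <- sqrt(sum((end - start)^2))
  if (dist <= 0) stop("zero-distance trajectory")
  if (dist >= peak_velocity^2 / accel) {           # cruise phase exists
    v <- peak_velocity
    t_acc <- v / accel
    duration <- dist / v + v / accel
  } else {                                          # triangular profile
    v <- sqrt(dist * accel)
    t_acc <- v / accel
    duration <- 2 * t_acc
  }
  t <- seq(0, duration, by = 1 / sample_rate_hz)
  if (t[length(t)] < duration) t <- c(t, duration)
  t_dec <- duration - t_acc
  s <- ifelse(t < t_acc, 0.5 * accel * t^2,
        ifelse(t <= t_dec, 0.5 * accel * t_acc^2 + v * (t - t_acc),
               dist - 0.5 * accel * (duration - t)^2))
  speed <- ifelse(t < t_acc, accel * t,
           ifelse(t <= t_dec, v, accel * (duration - t)))
  u <- (end - start) / dist
  pos <- cbind(start[1] + s * u[1], start[2] + s * u[2])
  colnames(pos) <- c("x", "y")
  structure(list(times_s = t, positions = pos, speed_cms = speed,
                 duration_s = duration, amplitude_mm = dist * 10,
                 peak_velocity = v, accel = accel),
            class = "trajectory")
}

#' Linear two-view triangulation of tracked joints
#'
#' Recovers 3D positions of the five forelimb landmarks (scapulothoracic,
#' glenohumeral, elbow, wrist, endpoint) from matched stereo pixel
#' coordinates by the direct linear transform: each point is the
#' least-squares null vector of the homogeneous two-view system, expressed in
#' the frame whose origin is camera 1's optical center.
#'
#' @param pixel_pairs numeric matrix (n x 4), columns
#'   `cam1_u, cam1_v, cam2_u, cam2_v`; one row per landmark. Row names, when
#'   present, are kept.
#' @param calibration list of two 3 x 4 projection matrices `P1`, `P2`.
#' @return matrix (n x 3) of 3D points (class `joint_set_3d` when the five
#'   standard landmarks are supplied, with a `conditioning` attribute
#'   carrying a warning flag for near-parallel rays).
#' @export
triangulate_joints <- function(pixel_pairs, calibration) {
  pixel_pairs <- as.matrix(pixel_pairs)
  stopifnot(ncol(pixel_pairs) == 4, all(is.finite(pixel_pairs)),
            length(calibration) == 2)
  P1 <- calibration[[1]]; P2 <- calibration[[2]]
  stopifnot(all(dim(P1) == c(3, 4)), all(dim(P2) == c(3, 4)))
  if (qr(P1)$rank < 3 || qr(P2)$rank < 3) stop("rank-deficient projection matrix")
  cam_center <- function(P) { v <- svd(P, nv = 4)$v[, 4]; v[1:3] / v[4] }
  C1 <- cam_center(P1); C2 <- cam_center(P2)
  n <- nrow(pixel_pairs)
  out <- matrix(NA_real_, n, 3, dimnames = list(rownames(pixel_pairs),
                                                c("x", "y", "z")))
  cond <- numeric(n)
  for (i in seq_len(n)) {
    u1 <- pixel_pairs[i, 1]; v1 <- pixel_pairs[i, 2]
    u2 <- pixel_pairs[i, 3]; v2 <- pixel_pairs[i, 4]
    A <- rbind(u1 * P1[3, ] - P1[1, ],
               v1 * P1[3, ] - P1[2, ],
               u2 * P2[3, ] - P2[1, ],
               v2 * P2[3, ] - P2[2, ])
    sv <- svd(A)
    X <- sv$v[, 4]
    if (abs(X[4]) < 1e-12) stop("point at infinity: near-parallel rays")
    out[i, ] <- X[1:3] / X[4]
    r1 <- out[i, ] - C1; r2 <- out[i, ] - C2
    cs <- sum(r1 * r2) / sqrt(sum(r1^2) * sum(r2^2))
    cond[i] <- rad2deg(acos(pmin(pmax(abs(cs), -1), 1)))  # ray angle, deg
  }
  ill <- cond < 0.5   # triangulation depth ill-conditioned for shallow ray angles
  if (any(ill)) warning("near-parallel rays for ", sum(ill), " landmark(s)")
  if (n == 5 && (is.null(rownames(out)) || identical(rownames(out), LANDMARKS))) {
    rownames(out) <- LANDMARKS
    class(out) <- c("joint_set_3d", class(out))
  }
  attr(out, "conditioning") <- cond
  out
}

#' Least-squares similarity transform (rotation, isotropic scale, translation)
#'
#' Fits `target ~ scale * R %*% source + t` over matched 3D point sets with
#' the reflection-free (det(R) = +1) closed-form solution based on the SVD of
#' the cross-covariance (Umeyama's method).
#'
#' @param source_points,target_points numeric matrices (n x 3), n >= 3
#'   non-collinear correspondences.
#' @return object of class `similarity_transform`: `rotation` (3 x 3,
#'   det = +1), `scale`, `translation`, `rms_residual`.
#' @export
fit_similarity_transform <- function(source_points, target_points) {
  X <- as.matrix(source_points); Y <- as.matrix(target_points)
  stopifnot(ncol(X) == 3, ncol(Y) == 3, nrow(X) == nrow(Y), nrow(X) >= 3)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  S <- crossprod(Yc, Xc) / nrow(X)           # cross-covariance target x source
  sv <- svd(S)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("degenerate (collinear) source points")
  D <- diag(3)
  if (det(sv$u %*% t(sv$v)) < 0) D[3, 3] <- -1
  R <- sv$u %*% D %*% t(sv$v)
  var_x <- mean(rowSums(Xc^2))
  s <- sum(sv$d * diag(D)) / var_x
  t0 <- my - s * as.vector(R %*% mx)
  fitted <- sweep(s * Xc %*% t(R), 2, my, FUN = "+")
  rms <- sqrt(mean(rowSums((Y - fitted)^2)))
  structure(list(rotation = R, scale = s, translation = t0,
                 rms_residual = rms),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("similarity transform: scale %.6g, RMS residual %.3g\n",
              x$scale, x$rms_residual))
  cat("rotation:\n"); print(round(x$rotation, 6))
  cat("translation:", format(x$translation, digits = 6), "\n")
  invisible(x)
}

#' Apply or invert a similarity transform
#'
#' @param transform a [fit_similarity_transform()] result.
#' @param points numeric matrix (n x 3).
#' @return transformed matrix (n x 3).
#' @export
apply_similarity_transform <- function(transform, points) {
  P <- as.matrix(points)
  stopifnot(inherits(transform, "similarity_transform"), ncol(P) == 3)
  sweep(transform$scale * P %*% t(transform$rotation), 2,
        transform$translation, FUN = "+")
}

#' @rdname apply_similarity_transform
#' @export
invert_similarity_transform <- function(transform) {
  stopifnot(inherits(transform, "similarity_transform"))
  Rinv <- t(transform$rotation)
  sinv <- 1 / transform$scale
  structure(list(rotation = Rinv, scale = sinv,
                 translation = -sinv * as.vector(Rinv %*% transform$translation),
                 rms_residual = transform$rms_residual),
            class = "similarity_transform")
}

#' Humerus abduction/adduction azimuth angle
#'
#' Signed azimuth angle, in the XZ plane, between the -Z axis and the humerus
#' vector (glenohumeral to elbow). Positive angles point laterally (+X,
#' abduction), negative medially (adduction); 0 when the projected humerus
#' points straight down.
#'
#' @param joints a `joint_set_3d` matrix (rows named as in
#'   [triangulate_joints()]) or a list with `glenohumeral` and `elbow`
#'   3-vectors.
#' @return angle in degrees, in (-180, 180].
#' @export
humerus_azimuth_angle <- function(joints) {
  if (is.matrix(joints)) {
    g <- joints["glenohumeral", ]; e <- joints["elbow", ]
  } else {
    g <- joints$glenohumeral; e <- joints$elbow
  }
  v <- e - g
  if (sqrt(v[1]^2 + v[3]^2) < 1e-12)
    stop("humerus parallel to the Y axis: azimuth angle undefined")
  ang <- rad2deg(atan2(v[1], -v[3]))
  if (ang <= -180) ang <- ang + 360
  unname(ang)
}

#' Humerus-angle map over the planar workspace
#'
#' Builds a bilinear interpolator of the humerus azimuth angle over a regular
#' workspace lattice, from per-grid-point joint sets (or precomputed angles).
#'
#' @param grid_xy matrix (n x 2) of workspace positions (cm) forming a full
#'   regular lattice.
#' @param joint_sets list of n `joint_set_3d` objects, or `NULL` when
#'   `angles` is given.
#' @param angles optional numeric vector of n angles (degrees), bypassing
#'   [humerus_azimuth_angle()].
#' @return object of class `angle_map` with `x`, `y` (lattice axes) and `z`
#'   (angle matrix, rows = x, cols = y).
#' @export
build_angle_map <- function(grid_xy, joint_sets = NULL, angles = NULL) {
  grid_xy <- as.matrix(grid_xy)
  stopifnot(ncol(grid_xy) == 2)
  if (is.null(angles)) {
    stopifnot(length(joint_sets) == nrow(grid_xy))
    angles <- vapply(joint_sets, humerus_azimuth_angle, numeric(1))
  }
  stopifnot(length(angles) == nrow(grid_xy))
  xs <- sort(unique(grid_xy[, 1])); ys <- sort(unique(grid_xy[, 2]))
  if (length(xs) * length(ys) != nrow(grid_xy))
    stop("grid points do not form a complete regular lattice")
  z <- matrix(NA_real_, length(xs), length(ys))
  ix <- match(grid_xy[, 1], xs); iy <- match(grid_xy[, 2], ys)
  z[cbind(ix, iy)] <- angles
  if (anyNA(z)) stop("grid points do not form a complete regular lattice")
  structure(list(x = xs, y = ys, z = z), class = "angle_map")
}

#' Interpolate an angle map
#'
#' @param map an [build_angle_map()] result.
#' @param xy matrix (n x 2) or length-2 vector of query positions (cm).
#' @return interpolated angles (degrees).
#' @export
interpolate_angle_map <- function(map, xy) {
  stopifnot(inherits(map, "angle_map"))
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  if (any(xy[, 1] < min(map$x) - 1e-12 | xy[, 1] > max(map$x) + 1e-12 |
          xy[, 2] < min(map$y) - 1e-12 | xy[, 2] > max(map$y) + 1e-12))
    stop("query outside the workspace grid hull")
  ## interp2 expects z indexed [y, x]
  pracma::interp2(map$x, map$y, t(map$z),
                  pmin(pmax(xy[, 1], min(map$x)), max(map$x)),
                  pmin(pmax(xy[, 2], min(map$y)), max(map$y)),
                  method = "linear")
}

#' Humerus-angle change along a movement
#'
#' Difference between the interpolated workspace angle at the displaced
#' endpoint and at the start: positive values mean increased abduction.
#'
#' @param map an [build_angle_map()] result.
#' @param start numeric `c(x, y)` start position (cm).
#' @param direction_deg movement azimuth in degrees.
#' @param distance_mm movement amplitude in mm.
#' @return change in angle (degrees).
#' @export
angle_change_for_displacement <- function(map, start, direction_deg,
                                          distance_mm) {
  stopifnot(length(start) == 2, is.finite(direction_deg), distance_mm >= 0)
  d_cm <- distance_mm / 10
  end <- start + d_cm * c(cos(deg2rad(direction_deg)),
                          sin(deg2rad(direction_deg)))
  as.numeric(interpolate_angle_map(map, rbind(end)) -
             interpolate_angle_map(map, rbind(start)))
}
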