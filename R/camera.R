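#' Pinhole camera intrinsics
#'
#' The sensor is modelled as an ideal pinhole: a 3D point `(X, Y, Z)` in the
#' camera frame projects to image coordinates `x = f X / Z`, `y = f Y / Z`,
#' then through the intrinsic matrix `K` (focal length `f`, pixel scales
#' `sx`, `sy`, skew, principal point) to pixel coordinates. By default the
#' focal length is derived from the vertical field of view so that the image
#' height spans `fov_v` degrees — the geometry of a consumer depth camera
#' (640 x 480, 43 degrees vertical FOV) is the default stand-in.
#'
#' @param width,height image size in pixels.
#' @param fov_v full vertical field of view in degrees (used to derive `f`
#'   when `f` is `NULL`).
#' @param f focal length in pixel units (overrides `fov_v` if given).
#' @param sx,sy relative pixel scales.
#' @param skew pixel skew coefficient.
#' @param ox,oy principal point in pixels; defaults to the image centre.
#' @return An object of class `"camera_intrinsics"`.
#' @export
camera_intrinsics <- function(width = 640L, height = 480L, fov_v = 43,
                              f = NULL, sx = 1, sy = 1, skew = 0,
                              ox = NULL, oy = NULL) {
  stopifnot(width >= 1, height >= 1, sx > 0, sy > 0)
  if (is.null(f)) {
    if (fov_v <= 0 || fov_v >= 180) stop("fov_v must be in (0, 180)")
    f <- (height / 2) / tan(fov_v / 2 * pi / 180) / sy
  }
  if (f <= 0) stop("focal length must be > 0")
  if (is.null(ox)) ox <- (width - 1) / 2
  if (is.null(oy)) oy <- (height - 1) / 2
  if (ox < 0 || ox >= width || oy < 0 || oy >= height) {
    stop("principal point must lie inside the image")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 f = f, sx = sx, sy = sy, skew = skew, ox = ox, oy = oy),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera_intrinsics: %dx%d px, f = %.2f (fx = %.2f, fy = %.2f),",
              x$width, x$height, x$f, x$f * x$sx, x$f * x$sy),
      sprintf("principal point (%.1f, %.1f), skew %.3g\n", x$ox, x$oy,
              x$skew))
  invisible(x)
}

#' Polar camera placement
#'
#' The camera sits on a sphere around the subject: azimuth `theta` (0 =
#' frontal view, 90 = subject's left side, 180 = back), elevation `phi`
#' (positive above the subject), at `distance` dm from the look-at point.
#' The optical axis points at `look_at` (by default the body centre at half
#' stature, resolved at ray-cast time).
#'
#' @param theta azimuth in degrees.
#' @param phi elevation in degrees, in `[-90, 90]`.
#' @param distance camera-to-subject distance in dm (default 43 dm = 4.3 m,
#'   the framing distance that accommodates the tallest subjects with the
#'   default optics).
#' @param look_at 3-vector (dm) or `NULL` for the subject's body centre.
#' @return An object of class `"camera_placement"`.
#' @export
camera_placement <- function(theta = 0, phi = 0, distance = 43,
                             look_at = NULL) {
  if (phi < -90 || phi > 90) stop("phi must be in [-90, 90]")
  if (distance <= 0) stop("distance must be > 0")
  structure(list(theta = theta, phi = phi, distance = distance,
                 look_at = look_at),
            class = "camera_placement")
}

#' Camera extrinsics from a polar placement
#'
#' World frame: `+y` up, subject facing `+z`, subject's left toward `+x`.
#' The camera centre is
#' `C = look_at + D * (sin(theta) cos(phi), sin(phi), cos(theta) cos(phi))`,
#' the optical axis points at `look_at`, and the roll is fixed by keeping
#' the world up vector upright in the image (at `|phi| = 90` the view is
#' degenerate and world `-z` is used as the up reference, so an overhead
#' image has the subject's front toward the image top).
#'
#' @param placement a [camera_placement()].
#' @param look_at explicit look-at point (overrides the placement's).
#' @return List with `R` (3 x 3 rotation; rows are the camera right, down
#'   and forward axes in world coordinates), `C` (camera centre) and
#'   `T = -R C`, so a world point maps to the camera frame as `R x + T`.
#' @export
place_camera <- function(placement, look_at = NULL) {
  stopifnot(inherits(placement, "camera_placement"))
  la <- if (!is.null(look_at)) look_at else placement$look_at
  if (is.null(la)) stop("look_at must be resolved before placing the camera")
  th <- placement$theta * pi / 180
  ph <- placement$phi * pi / 180
  C <- la + placement$distance *
    c(sin(th) * cos(ph), sin(ph), cos(th) * cos(ph))
  fwd <- la - C
  fwd <- fwd / sqrt(sum(fwd^2))
  up <- if (abs(placement$phi) > 89.99) c(0, 0, -sign(placement$phi)) else
    c(0, 1, 0)
  right <- c(fwd[2] * up[3] - fwd[3] * up[2],
             fwd[3] * up[1] - fwd[1] * up[3],
             fwd[1] * up[2] - fwd[2] * up[1])
  right <- right / sqrt(sum(right^2))
  down <- c(fwd[2] * right[3] - fwd[3] * right[2],
            fwd[3] * right[1] - fwd[1] * right[3],
            fwd[1] * right[2] - fwd[2] * right[1])
  R <- rbind(right, down, fwd)
  dimnames(R) <- NULL
  list(R = R, C = C, T = as.numeric(-R %*% C))
}

#' Project camera-frame points to pixel coordinates
#'
#' Applies the perspective division `x = f X / Z`, `y = f Y / Z` and the
#' intrinsic matrix. Integer pixel coordinates address pixel centres.
#'
#' @param points numeric n x 3 matrix (or 3-vector) of camera-frame points
#'   with `Z > 0`.
#' @param intrinsics a [camera_intrinsics()].
#' @return n x 2 matrix of `(u, v)` pixel coordinates.
#' @export
project <- function(points, intrinsics) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  p <- if (is.null(dim(points))) matrix(points, 1) else as.matrix(points)
  if (any(p[, 3] <= 0)) stop("point behind camera: Z must be > 0")
  xn <- p[, 1] / p[, 3]
  yn <- p[, 2] / p[, 3]
  cbind(u = intrinsics$f * intrinsics$sx * xn +
          intrinsics$f * intrinsics$skew * yn + intrinsics$ox,
        v = intrinsics$f * intrinsics$sy * yn + intrinsics$oy)
}

#' Framing distance for a target stature
#'
#' For a camera with full vertical field of view `fov_v`, a subject of
#' height `maxStature` exactly fills the frame at distance `D` given by
#' `maxStature = 2 tan(psi) D` with `psi = fov_v / 2` (the half field of
#' view). [framing_distance()] inverts this for `D`; [max_stature()]
#' applies it. Units are whatever the input uses (dm in, dm out).
#'
#' @param stature the tallest stature to accommodate.
#' @param fov_v full vertical field of view in degrees.
#' @return The required distance.
#' @export
framing_distance <- function(stature, fov_v = 43) {
  stopifnot(stature > 0, fov_v > 0, fov_v < 180)
  stature / (2 * tan(fov_v / 2 * pi / 180))
}

#' @rdname framing_distance
#' @param distance camera distance.
#' @export
max_stature <- function(distance, fov_v = 43) {
  stopifnot(distance > 0, fov_v > 0, fov_v < 180)
  2 * tan(fov_v / 2 * pi / 180) * distance
}

#' Ray-cast a mesh through a virtual depth camera
#'
#' Traces one ray per pixel centre from the camera through the scene and
#' keeps the nearest intersection only (the surface a depth sensor would
#' see). The result is an organized acquisition: a depth map, the
#' camera-frame point cloud on the pixel grid, the per-pixel identifier of
#' the triangle hit, and the deduplicated sorted list of visible triangle
#' ids — the visibility ground truth from which the view body surface area
#' is computed.
#'
#' @param mesh a [mesh3t()] object (dm units).
#' @param intrinsics a [camera_intrinsics()].
#' @param placement a [camera_placement()]; a `NULL` look-at resolves to the
#'   body centre (bounding-box centre in x/z at half bounding-box height).
#' @param check_inside error when the camera centre falls inside the mesh
#'   bounding box (on by default; disable for deliberately open scenes such
#'   as large calibration planes).
#' @return An object of class `"raycast"`: list with `depth` (H x W, dm, NA
#'   = miss), `points` (H x W x 3, camera frame), `hit_ids` (H x W face
#'   ids), `visible_ids`, `visible_areas` (named per-face areas of the
#'   visible triangles), `incidence` (H x W, radians between ray and surface
#'   normal), plus the camera geometry used.
#' @export
raycast <- function(mesh, intrinsics = camera_intrinsics(),
                    placement = camera_placement(), check_inside = TRUE) {
  stopifnot(inherits(mesh, "mesh3t"))
  bb <- apply(mesh$vertices, 2, range)
  la <- placement$look_at
  if (is.null(la)) {
    la <- c(mean(bb[, 1]), bb[1, 2] + (bb[2, 2] - bb[1, 2]) / 2,
            mean(bb[, 3]))
  }
  ext <- place_camera(placement, look_at = la)
  if (check_inside && all(ext$C >= bb[1, ] - 1e-9) &&
        all(ext$C <= bb[2, ] + 1e-9)) {
    stop("camera lies inside the mesh bounding box")
  }
  res <- .raycast_cpp(mesh$vertices, mesh$faces - 1L, ext$C, ext$R,
                      intrinsics$f * intrinsics$sx,
                      intrinsics$f * intrinsics$sy,
                      intrinsics$f * intrinsics$skew,
                      intrinsics$ox, intrinsics$oy,
                      intrinsics$width, intrinsics$height)
  hit_rows <- res$hit
  hit_ids <- matrix(NA_integer_, nrow(hit_rows), ncol(hit_rows))
  ok <- !is.na(hit_rows)
  hit_ids[ok] <- mesh$face_ids[hit_rows[ok]]
  vis_rows <- sort(unique(hit_rows[ok]))
  areas <- face_areas(mesh)[vis_rows]
  visible_ids <- mesh$face_ids[vis_rows]
  o <- order(visible_ids)
  visible_ids <- visible_ids[o]
  areas <- areas[o]
  names(areas) <- as.character(visible_ids)
  pts <- array(NA_real_, c(nrow(hit_rows), ncol(hit_rows), 3L))
  pts[, , 1] <- res$px
  pts[, , 2] <- res$py
  pts[, , 3] <- res$pz
  structure(list(depth = res$depth, points = pts, hit_ids = hit_ids,
                 visible_ids = visible_ids, visible_areas = areas,
                 incidence = res$incidence, intrinsics = intrinsics,
                 placement = placement, look_at = la, camera = ext),
            class = "raycast")
}

#' @export
print.raycast <- function(x, ...) {
  n_hit <- sum(!is.na(x$depth))
  cat(sprintf(
    "raycast: %dx%d px, theta %.0f deg, phi %.0f deg, distance %.1f dm\n",
    x$intrinsics$width, x$intrinsics$height, x$placement$theta,
    x$placement$phi, x$placement$distance))
  cat(sprintf("  %d/%d pixels hit, %d visible triangles, VBSA %.3f dm^2\n",
              n_hit, length(x$depth), length(x$visible_ids),
              sum(x$visible_areas)))
  invisible(x)
}

#' Depth-sensor noise model
#'
#' Axial noise perturbs each measured depth with a zero-mean Gaussian whose
#' standard deviation may depend on depth and on the incidence angle between
#' the ray and the surface; lateral noise jitters which pixel a sample is
#' drawn from. The default coefficients follow the published empirical
#' model for a structured-light consumer depth camera: axial
#' `sigma_z(z) = 0.0012 + 0.0019 (z - 0.4)^2` meters (depth `z` in meters)
#' and lateral sigma 0.815 px. Noise is off by default throughout the
#' package.
#'
#' @param axial_sigma function `(depth_dm, incidence_rad) -> sigma in dm`.
#' @param lateral_sigma function `(depth_dm) -> sigma in pixels`.
#' @param enabled if `FALSE` the model is the identity.
#' @param seed RNG seed used by [apply_noise()].
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(axial_sigma = NULL, lateral_sigma = NULL,
                        enabled = TRUE, seed = 1L) {
  if (is.null(axial_sigma)) {
    axial_sigma <- function(depth, incidence) {
      10 * (0.0012 + 0.0019 * (depth / 10 - 0.4)^2)
    }
  }
  if (is.null(lateral_sigma)) {
    lateral_sigma <- function(depth) rep(0.815, length(depth))
  }
  structure(list(axial_sigma = axial_sigma, lateral_sigma = lateral_sigma,
                 enabled = enabled, seed = seed),
            class = "noise_model")
}

#' Apply sensor noise to an acquisition
#'
#' Axial: each finite depth is perturbed by `N(0, sigma(depth, incidence)^2)`
#' and the corresponding point is rescaled along its own ray. Lateral: each
#' pixel resamples its depth from a pixel offset by a Gaussian jitter (in
#' pixels), emulating edge blur. The visibility ground truth (`hit_ids`,
#' `visible_ids`) is left untouched: sensor noise corrupts the measured
#' geometry, not which surface was seen.
#'
#' @param result a [raycast()] result.
#' @param noise a [noise_model()].
#' @param seed overrides the model's seed.
#' @return The perturbed `"raycast"` object.
#' @export
apply_noise <- function(result, noise, seed = NULL) {
  stopifnot(inherits(result, "raycast"), inherits(noise, "noise_model"))
  if (!noise$enabled) return(result)
  if (is.null(seed)) seed <- noise$seed
  H <- nrow(result$depth)
  W <- ncol(result$depth)
  local_seed(seed, {
    depth <- result$depth
    ok <- which(!is.na(depth))
    # lateral jitter: resample depth from a Gaussian-offset source pixel
    if (length(ok)) {
      sl <- noise$lateral_sigma(depth[ok])
      rr <- ((ok - 1L) %% H) + 1L
      cc <- ((ok - 1L) %/% H) + 1L
      sr <- pmin(pmax(rr + as.integer(round(stats::rnorm(length(ok), 0, sl))),
                      1L), H)
      sc <- pmin(pmax(cc + as.integer(round(stats::rnorm(length(ok), 0, sl))),
                      1L), W)
      src <- (sc - 1L) * H + sr
      newd <- depth[src]
      keep <- !is.na(newd)
      depth[ok[keep]] <- newd[keep]
    }
    # axial perturbation along each pixel's own ray
    ok <- which(!is.na(depth))
    if (length(ok)) {
      sa <- noise$axial_sigma(depth[ok], result$incidence[ok])
      newd <- depth[ok] + stats::rnorm(length(ok), 0, sa)
      ratio <- newd / result$depth[ok]
      depth[ok] <- newd
      for (k in 1:3) {
        pl <- result$points[, , k]
        pl[ok] <- pl[ok] * ratio
        result$points[, , k] <- pl
      }
    }
    result$depth <- depth
  })
  result
}
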