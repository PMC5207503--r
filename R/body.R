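#' Parameters of a synthetic body
#'
#' The generator drives a parametric-primitive humanoid (lathed torso with
#' elliptical cross-sections, capsule limbs, sphere head) from five macro
#' parameters. The humanoid is a geometric stand-in for a morphable-model
#' body: what matters for view-area analysis is controllable size and shape
#' — a frontal width larger than the body depth, and arms slightly bent
#' forward so that oblique views produce occlusions — not anatomical detail.
#'
#' @param stature body height in cm (> 0).
#' @param girth dimensionless scale of torso/limb cross-sections; acts as the
#'   weight proxy (> 0; 1 = reference build).
#' @param muscle_fat fat/muscle balance in `[0, 1]`; 0 = lean, 1 = fat
#'   (widens waist/belly and thickens limbs).
#' @param gender_shape proportion blend in `[0, 1]`; 0 = feminine proportions
#'   (wider hips, deeper bust), 1 = masculine (wider shoulders).
#' @param age age in years (grouping only; does not deform the mesh).
#' @return An object of class `"body_params"`.
#' @export
body_params <- function(stature = 175, girth = 1, muscle_fat = 0.5,
                        gender_shape = 0.5, age = 30) {
  if (!is.numeric(stature) || stature <= 0) stop("stature must be > 0")
  if (!is.numeric(girth) || girth <= 0) stop("girth must be > 0")
  if (muscle_fat < 0 || muscle_fat > 1) stop("muscle_fat must be in [0, 1]")
  if (gender_shape < 0 || gender_shape > 1) {
    stop("gender_shape must be in [0, 1]")
  }
  if (age <= 0) stop("age must be > 0")
  structure(list(stature = stature, girth = girth, muscle_fat = muscle_fat,
                 gender_shape = gender_shape, age = age),
            class = "body_params")
}

# ---- geometric primitives (all lengths in dm) -------------------------------

# ring mesh along +y: heights[i] paired with half-width a[i] (x) and
# half-depth b[i] (z); the cross-section is an egg of two half-ellipses
# (front depth b * (1 + asym), back depth b * (1 - asym)), and ring centres
# may shift forward via cz; capped with triangle fans at both ends
lathe_mesh <- function(heights, a, b, n_seg = 24L, center_x = 0, cz = 0,
                       asym = 0) {
  ang <- 2 * pi * (seq_len(n_seg) - 1L) / n_seg
  sa <- sin(ang)
  nv <- length(heights)
  cz <- rep_len(cz, nv)
  asym <- rep_len(asym, nv)
  verts <- do.call(rbind, lapply(seq_len(nv), function(i) {
    bi <- b[i] * (1 + asym[i] * sign(sa))
    cbind(center_x + a[i] * cos(ang), heights[i], cz[i] + bi * sa)
  }))
  idx <- function(ring, k) (ring - 1L) * n_seg + ((k - 1L) %% n_seg) + 1L
  f <- list()
  for (r in seq_len(nv - 1L)) {
    k <- seq_len(n_seg)
    # outward-facing quads split into two triangles
    f[[length(f) + 1L]] <- cbind(idx(r, k), idx(r, k + 1L), idx(r + 1L, k))
    f[[length(f) + 1L]] <- cbind(idx(r + 1L, k), idx(r, k + 1L),
                                 idx(r + 1L, k + 1L))
  }
  v <- rbind(verts, c(center_x, heights[1], cz[1]),
             c(center_x, heights[nv], cz[nv]))
  bot <- nrow(v) - 1L
  top <- nrow(v)
  k <- seq_len(n_seg)
  f[[length(f) + 1L]] <- cbind(bot, idx(1L, k + 1L), idx(1L, k))
  f[[length(f) + 1L]] <- cbind(top, idx(nv, k), idx(nv, k + 1L))
  list(vertices = v, faces = do.call(rbind, f))
}

# capsule from p0 to p1 with radius r (cylinder + hemispherical caps),
# built along a canonical axis and rotated into place
capsule_mesh <- function(p0, p1, r, n_seg = 16L, n_cap = 4L) {
  axis <- p1 - p0
  len <- sqrt(sum(axis^2))
  # canonical: along +y from 0 to len; spherical cap profiles below 0 and
  # above len, cylinder in between
  ca <- seq(0, pi / 2, length.out = n_cap + 1L)
  hs <- c(-r * cos(ca), len + r * sin(ca))
  rs <- c(r * sin(ca), r * cos(ca))
  m <- lathe_mesh(hs, pmax(rs, 1e-9), pmax(rs, 1e-9), n_seg = n_seg)
  v <- m$vertices
  # rotate canonical +y onto the capsule axis, then translate to p0
  if (len < 1e-12) {
    rot <- diag(3)
  } else {
    y <- c(0, 1, 0)
    d <- axis / len
    vx <- c(y[2] * d[3] - y[3] * d[2], y[3] * d[1] - y[1] * d[3],
            y[1] * d[2] - y[2] * d[1])
    s <- sqrt(sum(vx^2))
    cth <- sum(y * d)
    if (s < 1e-12) {
      rot <- if (cth > 0) diag(3) else diag(c(-1, -1, 1))
    } else {
      K <- matrix(c(0, vx[3], -vx[2], -vx[3], 0, vx[1], vx[2], -vx[1], 0),
                  3, 3)
      rot <- diag(3) + K + K %*% K * ((1 - cth) / s^2)
    }
  }
  v <- v %*% t(rot)
  v <- sweep(v, 2, p0, "+")
  list(vertices = v, faces = m$faces)
}

sphere_mesh <- function(center, r, n_seg = 16L, n_rings = 8L) {
  ph <- seq(-pi / 2, pi / 2, length.out = n_rings + 1L)[-c(1L, n_rings + 1L)]
  m <- lathe_mesh(r * sin(ph), r * cos(ph), r * cos(ph), n_seg = n_seg)
  # replace flat caps at the first/last ring with true poles
  v <- m$vertices
  np <- nrow(v)
  v[np - 1L, 2] <- -r
  v[np, 2] <- r
  v <- sweep(v, 2, center, "+")
  list(vertices = v, faces = m$faces)
}

merge_parts <- function(parts) {
  off <- 0L
  vs <- list()
  fs <- list()
  for (p in parts) {
    vs[[length(vs) + 1L]] <- p$vertices
    fs[[length(fs) + 1L]] <- p$faces + off
    off <- off + nrow(p$vertices)
  }
  mesh3t(do.call(rbind, vs), do.call(rbind, fs))
}

# ---- body profile -----------------------------------------------------------

# torso cross-section profile and joint layout, all as functions of the
# macro parameters; one source of truth shared by make_body() and
# measure_subject() so tape measurements are analytic, not mesh-sampled
body_profile <- function(params) {
  stopifnot(inherits(params, "body_params"))
  S <- params$stature / 10  # dm
  g <- params$girth
  m <- params$muscle_fat
  gs <- params$gender_shape
  # torso knots: height fraction, half-width a (x), depth-to-width ratio
  hk <- c(0.47, 0.52, 0.575, 0.62, 0.70, 0.73, 0.78, 0.82)
  aw <- c(0.080,
          0.092 * (1 + 0.06 * (1 - gs)),        # hip
          0.082 * (1 + 0.25 * m),               # belly
          0.070 * (1 + 0.35 * m),               # waist
          0.078,                                # underbust
          0.084,                                # bust
          0.090 * (1 + 0.08 * gs),
          0.082 * (1 + 0.12 * gs))              # shoulder
  br <- c(0.62, 0.62, 0.62 + 0.30 * m, 0.62 + 0.30 * m, 0.62,
          0.62 + 0.18 * (1 - gs), 0.60, 0.58)
  # the human trunk carries more surface in front (belly, chest/bust) than
  # in the flatter back: ring centres shift forward (cz) and the front half
  # of the cross-section is deeper than the back half (asym)
  cz <- c(0, 0.004, 0.010 + 0.008 * m, 0.008 + 0.006 * m, 0.006,
          0.008, 0.003, 0) * S * g
  asym <- c(0.05, 0.10, 0.28 + 0.1 * m, 0.28 + 0.1 * m, 0.22,
            0.25, 0.15, 0.08)
  a <- aw * S * g
  b <- aw * br * S * g
  limb_g <- sqrt(g) * (1 + 0.12 * m)
  list(
    S = S,
    torso = list(hk = hk, a = a, b = b, cz = cz, asym = asym),
    sections = list(hip = 2L, belly = 3L, waist = 4L, underbust = 5L,
                    bust = 6L, shoulder = 8L),
    neck_r = 0.026 * S * limb_g,
    head_r = 0.065 * S,
    arm_r = 0.028 * S * limb_g,
    forearm_r = 0.024 * S * limb_g,
    hand_r = 0.032 * S * sqrt(limb_g),
    leg_r = 0.042 * S * sqrt(g) * (1 + 0.15 * m),
    foot_r = 0.030 * S,
    shoulder_x = a[8],
    hip_x = 0.052 * S,
    limb_g = limb_g
  )
}

torso_rings <- function(prof, n_rings = 14L) {
  hk <- prof$torso$hk
  h <- seq(hk[1], hk[length(hk)], length.out = n_rings)
  a <- stats::spline(hk, prof$torso$a, xout = h)$y
  b <- stats::spline(hk, prof$torso$b, xout = h)$y
  cz <- stats::spline(hk, prof$torso$cz, xout = h)$y
  asym <- stats::spline(hk, prof$torso$asym, xout = h)$y
  list(h = h * prof$S, a = pmax(a, 1e-6), b = pmax(b, 1e-6), cz = cz,
       asym = pmin(pmax(asym, 0), 0.6))
}

#' Generate a synthetic humanoid mesh
#'
#' Builds a deterministic triangle mesh from [body_params()]: a lathed torso
#' with elliptical cross-sections (frontal width greater than depth), capsule
#' arms bent slightly forward and inward (so forearms sit in front of the
#' belly, as in a relaxed standing pose), capsule legs, forward-pointing
#' feet and a sphere head. The mesh bounding box spans exactly the requested
#' stature: head apex at the stature, foot soles on the floor plane `y = 0`.
#' The world frame is `+y` up, subject facing `+z`, subject's left toward
#' `+x`. The analytic solid volume (for the density-based weight proxy) is
#' attached as `attr(, "volume_dm3")`.
#'
#' @param params a [body_params()] object.
#' @param n_seg segments per ring for the torso lathe (limbs use `2/3` of
#'   this); controls mesh resolution.
#' @return A [mesh3t()] body mesh (units dm) with attributes `params` and
#'   `volume_dm3`.
#' @export
make_body <- function(params, n_seg = 24L) {
  stopifnot(inherits(params, "body_params"))
  prof <- body_profile(params)
  S <- prof$S
  tr <- torso_rings(prof)
  limb_seg <- max(12L, as.integer(round(n_seg * 2 / 3)))
  parts <- list(lathe_mesh(tr$h, tr$a, tr$b, n_seg = n_seg, cz = tr$cz,
                           asym = tr$asym))
  # neck and head
  parts[[length(parts) + 1L]] <-
    capsule_mesh(c(0, 0.80 * S, 0), c(0, 0.885 * S, 0), prof$neck_r,
                 n_seg = limb_seg)
  parts[[length(parts) + 1L]] <-
    sphere_mesh(c(0, S - prof$head_r, 0), prof$head_r, n_seg = limb_seg + 4L,
                n_rings = 10L)
  # arms hang at the sides, bent slightly forward at shoulder and elbow
  # (relaxed standing pose): beside the torso in the frontal view, they
  # increasingly overlap it as the camera swings toward the side, and from
  # behind the forward-held forearms are partly occluded by the trunk
  for (s in c(-1, 1)) {
    sh <- c(s * prof$shoulder_x, 0.80 * S, 0.005 * S)
    du <- c(s * 0.06, -0.99, 0.04)
    du <- du / sqrt(sum(du^2))
    el <- sh + 0.175 * S * du
    df <- c(s * 0.02, -0.99, 0.10)
    df <- df / sqrt(sum(df^2))
    wr <- el + 0.155 * S * df
    parts[[length(parts) + 1L]] <-
      capsule_mesh(sh, el, prof$arm_r, n_seg = limb_seg)
    parts[[length(parts) + 1L]] <-
      capsule_mesh(el, wr, prof$forearm_r, n_seg = limb_seg)
    parts[[length(parts) + 1L]] <-
      sphere_mesh(wr + 0.015 * S * df, prof$hand_r, n_seg = limb_seg,
                  n_rings = 6L)
    # legs and feet
    hip <- c(s * prof$hip_x, 0.50 * S, 0)
    ank <- c(s * prof$hip_x, 0.06 * S, 0)
    parts[[length(parts) + 1L]] <-
      capsule_mesh(hip, ank, prof$leg_r, n_seg = limb_seg)
    # feet splayed outward ~12 degrees as in a natural stance
    fd <- c(s * sin(12 * pi / 180), 0, cos(12 * pi / 180))
    parts[[length(parts) + 1L]] <-
      capsule_mesh(c(s * prof$hip_x, prof$foot_r, 0.01 * S),
                   c(s * prof$hip_x, prof$foot_r, 0.01 * S) + 0.08 * S * fd,
                   prof$foot_r, n_seg = limb_seg)
  }
  mesh <- merge_parts(parts)
  attr(mesh, "params") <- params
  attr(mesh, "volume_dm3") <- body_volume(prof)
  mesh
}

# analytic solid volume of the primitive assembly (dm^3); overlaps at the
# joints are counted once per primitive, which is acceptable for a proxy
body_volume <- function(prof) {
  S <- prof$S
  tr <- torso_rings(prof, n_rings = 40L)
  area <- pi * tr$a * tr$b
  torso <- sum(diff(tr$h) * (area[-1] + area[-length(area)]) / 2)
  caps <- function(r, l) pi * r^2 * l + 4 / 3 * pi * r^3
  torso +
    caps(prof$neck_r, 0.085 * S) +
    4 / 3 * pi * prof$head_r^3 +
    2 * (caps(prof$arm_r, 0.175 * S) + caps(prof$forearm_r, 0.155 * S)) +
    2 * 4 / 3 * pi * prof$hand_r^3 +
    2 * caps(prof$leg_r, 0.44 * S) +
    2 * caps(prof$foot_r, 0.08 * S)
}

# Ramanujan's second approximation; exact for circles, relative error
# < 1e-9 at the aspect ratios used here
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Tape-measure a synthetic body
#'
#' Circumferences are computed analytically as the perimeters of the
#' elliptical cross-sections of the parametric solids at the named heights
#' (hip, belly, waist, underbust, bust, neck, upper arm, thigh), not sampled
#' from the mesh, so they are exact for the generated geometry. Stature is
#' the mesh bounding-box height; weight is a density-based proxy
#' (`1.0 kg/dm^3` times the analytic solid volume scaled by a packing factor
#' of `0.985`, the approximate density of the human body).
#'
#' @param mesh a mesh produced by [make_body()].
#' @param params the [body_params()] used (defaults to the ones attached to
#'   the mesh).
#' @return Named list of measurements in cm (weight in kg, `wbsa_dm2` in
#'   dm^2).
#' @export
measure_subject <- function(mesh, params = attr(mesh, "params")) {
  stopifnot(inherits(mesh, "mesh3t"))
  if (is.null(params)) stop("params missing: mesh was not made by make_body")
  prof <- body_profile(params)
  bb <- range(mesh$vertices[, 2])
  sec <- prof$sections
  circ <- function(i) {
    h <- prof$torso$hk[i] * prof$S
    if (h < bb[1] || h > bb[2]) stop("section height outside body")
    # egg cross-section: mean of the front and back half-ellipse perimeters
    a <- prof$torso$a[i]
    b <- prof$torso$b[i]
    as <- prof$torso$asym[i]
    10 * (ellipse_perimeter(a, b * (1 + as)) +
            ellipse_perimeter(a, b * (1 - as))) / 2  # dm -> cm
  }
  list(
    stature_cm = 10 * (bb[2] - bb[1]),
    weight_kg = 0.985 * attr(mesh, "volume_dm3"),
    hip_circ_cm = circ(sec$hip),
    waist_circ_cm = circ(sec$waist),
    underbust_circ_cm = circ(sec$underbust),
    bust_circ_cm = circ(sec$bust),
    neck_circ_cm = 10 * 2 * pi * prof$neck_r,
    frontchest_cm = 10 * 2 * prof$torso$a[sec$bust],
    upper_arm_circ_cm = 10 * 2 * pi * prof$arm_r,
    thigh_circ_cm = 10 * 2 * pi * prof$leg_r,
    wbsa_dm2 = mesh_area(mesh)$wbsa
  )
}

#' Du Bois height-weight body surface area formula
#'
#' The classical estimator `WBSA = 0.007184 * W^0.425 * H^0.725` with weight
#' `W` in kg and stature `H` in cm, returning square meters. Used as the
#' formula baseline against which view-based estimates are compared.
#'
#' @param weight weight in kg (> 0); vectorised.
#' @param stature stature in cm (> 0); vectorised.
#' @return Body surface area in m^2.
#' @examples
#' du_bois(70, 170) # about 1.81 m^2
#' @export
du_bois <- function(weight, stature) {
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("weight must be positive")
  }
  if (any(!is.finite(stature)) || any(stature <= 0)) {
    stop("stature must be positive")
  }
  0.007184 * weight^0.425 * stature^0.725
}

# run expr with a fixed RNG seed, restoring the caller's RNG state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(expr)
}

subject_record <- function(subject_id, params, small_max, big_min,
                           with_mesh = FALSE, n_seg = 24L) {
  mesh <- make_body(params, n_seg = n_seg)
  meas <- measure_subject(mesh, params)
  rec <- data.frame(
    subject_id = subject_id,
    age = params$age,
    gender = if (params$gender_shape >= 0.5) "male" else "female",
    age_group = if (params$age <= 15) "kid" else "adult",
    stature_group = if (meas$stature_cm <= small_max) "small"
      else if (meas$stature_cm > big_min) "big" else "normal",
    stature_param_cm = params$stature,
    girth = params$girth,
    muscle_fat = params$muscle_fat,
    gender_shape = params$gender_shape,
    wbsa_dm2 = meas$wbsa_dm2,
    stringsAsFactors = FALSE
  )
  rec <- cbind(rec, as.data.frame(meas[names(meas) != "wbsa_dm2"]))
  if (with_mesh) list(record = rec, mesh = mesh) else list(record = rec)
}

#' Sample a fully random virtual population
#'
#' Each macro parameter is drawn i.i.d. from a uniform distribution over its
#' configured interval — deliberately uniform rather than normal so the
#' population over-represents extreme builds (very small, very tall, very
#' obese subjects), which are exactly the ones that stress a surface-area
#' predictor. Ranges default to stature 120-220 cm and girth spanning
#' emaciated to obese.
#'
#' @param n number of subjects (>= 1).
#' @param seed RNG seed; the population is fully reproducible from
#'   `(seed, ranges)`.
#' @param ranges named list of `c(min, max)` intervals for `stature`,
#'   `girth`, `muscle_fat`, `gender_shape`, `age`.
#' @param small_max,big_min stature group cut points in cm (small <=
#'   `small_max`; big > `big_min`).
#' @param keep_meshes if `TRUE`, also return the generated meshes.
#' @param compute build each mesh and record WBSA and measurements; set to
#'   `FALSE` for a parameters-only table (fast for large populations).
#' @param n_seg mesh resolution passed to [make_body()].
#' @return A data frame of subject records (one row per subject: parameters,
#'   measurements, WBSA in dm^2, group labels), or a list
#'   `list(records, meshes)` when `keep_meshes = TRUE`.
#' @export
sample_random_population <- function(n, seed = 1L,
                                     ranges = list(
                                       stature = c(120, 220),
                                       girth = c(0.7, 1.4),
                                       muscle_fat = c(0, 1),
                                       gender_shape = c(0, 1),
                                       age = c(6, 80)),
                                     small_max = 140, big_min = 200,
                                     keep_meshes = FALSE, compute = TRUE,
                                     n_seg = 24L) {
  if (n < 1) stop("n must be >= 1")
  for (nm in c("stature", "girth", "muscle_fat", "gender_shape", "age")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2L || r[2] < r[1]) {
      stop("invalid or empty range for ", nm)
    }
  }
  draw <- local_seed(seed, {
    lapply(c("stature", "girth", "muscle_fat", "gender_shape", "age"),
           function(nm) stats::runif(n, ranges[[nm]][1], ranges[[nm]][2]))
  })
  names(draw) <- c("stature", "girth", "muscle_fat", "gender_shape", "age")
  recs <- vector("list", n)
  meshes <- if (keep_meshes) vector("list", n) else NULL
  for (i in seq_len(n)) {
    p <- body_params(draw$stature[i], draw$girth[i], draw$muscle_fat[i],
                     draw$gender_shape[i], draw$age[i])
    if (compute) {
      sr <- subject_record(sprintf("R%04d", i), p, small_max, big_min,
                           with_mesh = keep_meshes, n_seg = n_seg)
      recs[[i]] <- sr$record
      if (keep_meshes) meshes[[i]] <- sr$mesh
    } else {
      recs[[i]] <- data.frame(
        subject_id = sprintf("R%04d", i), age = p$age,
        gender = if (p$gender_shape >= 0.5) "male" else "female",
        age_group = if (p$age <= 15) "kid" else "adult",
        stature_group = if (p$stature <= small_max) "small"
          else if (p$stature > big_min) "big" else "normal",
        stature_param_cm = p$stature, girth = p$girth,
        muscle_fat = p$muscle_fat, gender_shape = p$gender_shape,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  attr(records, "seed") <- seed
  if (keep_meshes) list(records = records, meshes = meshes) else records
}

#' Sample a survey-style virtual population (base subjects plus variations)
#'
#' Emulates building a population from a body-measurement survey: a table of
#' base subjects with fixed identity parameters (stature, age, gender blend)
#' is expanded by `k_variations` systematic variations per subject that
#' change only girth and the muscle/fat balance — producing a fat version
#' and a skinny version of the same individual — on a near-square grid over
#' the configured ranges. With 500 base subjects and 25 variations this
#' yields the reference population size of 12500.
#'
#' @param base either a data frame with columns `stature_cm`, `age`,
#'   `gender_shape` (one row per base subject), or an integer number of base
#'   subjects to draw uniformly (stature 145-195 cm, age 15-75).
#' @param k_variations variations per base subject (>= 1).
#' @param seed RNG seed (used only when `base` is a count).
#' @param girth_range,muscle_fat_range intervals covered by the variation
#'   grid.
#' @param include_base also emit each unvaried base subject.
#' @param compute_wbsa build each mesh and record WBSA/measurements; set to
#'   `FALSE` to generate only the parameter table (fast for large
#'   populations).
#' @param small_max,big_min stature group cut points in cm.
#' @param n_seg mesh resolution passed to [make_body()].
#' @return A data frame with `nrow(base) * k_variations` rows (plus base rows
#'   if requested).
#' @export
sample_nhanes_style_population <- function(base = 500L, k_variations = 25L,
                                           seed = 1L,
                                           girth_range = c(0.75, 1.3),
                                           muscle_fat_range = c(0.1, 0.9),
                                           include_base = FALSE,
                                           compute_wbsa = TRUE,
                                           small_max = 140, big_min = 200,
                                           n_seg = 24L) {
  if (k_variations < 1) stop("k_variations must be >= 1")
  if (is.numeric(base) && length(base) == 1L) {
    nb <- as.integer(base)
    b <- local_seed(seed, data.frame(
      stature_cm = stats::runif(nb, 145, 195),
      age = stats::runif(nb, 15, 75),
      gender_shape = stats::runif(nb, 0, 1)))
  } else {
    b <- as.data.frame(base)
    if (!all(c("stature_cm", "age", "gender_shape") %in% names(b))) {
      stop("base must have columns stature_cm, age, gender_shape")
    }
  }
  # near-square grid over (girth, muscle_fat); k = k1 * k2 with k1 <= k2
  k <- as.integer(k_variations)
  k1 <- as.integer(floor(sqrt(k)))
  while (k %% k1 != 0L) k1 <- k1 - 1L
  k2 <- k %/% k1
  gseq <- if (k1 == 1L) mean(girth_range)
    else seq(girth_range[1], girth_range[2], length.out = k1)
  mseq <- if (k2 == 1L) mean(muscle_fat_range)
    else seq(muscle_fat_range[1], muscle_fat_range[2], length.out = k2)
  grid <- expand.grid(girth = gseq, muscle_fat = mseq)
  rows <- list()
  for (i in seq_len(nrow(b))) {
    variants <- if (include_base) {
      rbind(data.frame(girth = 1, muscle_fat = 0.5), grid)
    } else {
      grid
    }
    for (j in seq_len(nrow(variants))) {
      p <- body_params(b$stature_cm[i], variants$girth[j],
                       variants$muscle_fat[j], b$gender_shape[i], b$age[i])
      id <- sprintf("B%03dV%02d", i, j - (if (include_base) 1L else 0L))
      if (compute_wbsa) {
        rows[[length(rows) + 1L]] <-
          subject_record(id, p, small_max, big_min, n_seg = n_seg)$record
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = id, age = p$age,
          gender = if (p$gender_shape >= 0.5) "male" else "female",
          age_group = if (p$age <= 15) "kid" else "adult",
          stature_group = if (p$stature <= small_max) "small"
            else if (p$stature > big_min) "big" else "normal",
          stature_param_cm = p$stature, girth = p$girth,
          muscle_fat = p$muscle_fat, gender_shape = p$gender_shape,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  out
}

#' Rebuild the mesh for one population record
#'
#' Population tables are parameter tables: meshes are regenerated
#' deterministically from the recorded parameters rather than stored.
#'
#' @param record one row of a population data frame.
#' @param n_seg mesh resolution passed to [make_body()].
#' @return The subject's [mesh3t()] mesh.
#' @export
mesh_from_record <- function(record, n_seg = 24L) {
  make_body(body_params(record$stature_param_cm, record$girth,
                        record$muscle_fat, record$gender_shape, record$age),
            n_seg = n_seg)
}
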