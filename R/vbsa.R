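#' Ground-truth view body surface area
#'
#' The view body surface area (VBSA) ground truth is the sum of the areas of
#' the triangles hit by at least one camera ray, looked up on the *original*
#' mesh — no surface reconstruction is involved, so the value carries no
#' reconstruction noise. Full triangle areas are counted, which can
#' overestimate on partially visible silhouette triangles; [subdivide()]
#' the mesh to shrink that bias.
#'
#' @param mesh the [mesh3t()] that was ray cast.
#' @param result the [raycast()] result.
#' @return VBSA in dm^2.
#' @export
vbsa_ground_truth <- function(mesh, result) {
  stopifnot(inherits(mesh, "mesh3t"), inherits(result, "raycast"))
  if (length(result$visible_ids) == 0L) return(0)
  idx <- match(result$visible_ids, mesh$face_ids)
  if (anyNA(idx)) {
    stop("visible ids not found in mesh: ",
         paste(utils::head(result$visible_ids[is.na(idx)], 5), collapse = ", "))
  }
  sum(face_areas(mesh)[idx])
}

#' Simulate depth-sensor holes
#'
#' Emulates the dropouts of real depth sensors (IR interference, reflective
#' surfaces): every visible triangle is removed independently with
#' probability `p`, and the pixels that sampled a removed triangle are
#' blanked from the depth map and point cloud. The expected surviving area
#' is `(1 - p)` times the ground-truth VBSA.
#'
#' @param result a [raycast()] result.
#' @param p per-triangle removal probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return List with `result` (the degraded `"raycast"` object) and `vbsa`
#'   (surviving visible area, dm^2).
#' @export
simulate_holes <- function(result, p, seed = 1L) {
  stopifnot(inherits(result, "raycast"))
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  ids <- result$visible_ids
  drop <- local_seed(seed, stats::runif(length(ids)) < p)
  dropped <- ids[drop]
  out <- result
  if (length(dropped)) {
    blank <- out$hit_ids %in% dropped
    out$depth[blank] <- NA_real_
    out$incidence[blank] <- NA_real_
    out$hit_ids[blank] <- NA_integer_
    for (k in 1:3) {
      pl <- out$points[, , k]
      pl[blank] <- NA_real_
      out$points[, , k] <- pl
    }
    out$visible_ids <- ids[!drop]
    out$visible_areas <- out$visible_areas[!drop]
  }
  list(result = out, vbsa = sum(out$visible_areas))
}

#' Mesh a single view from its organized point cloud
#'
#' Because the acquisition is organized (points live on the pixel grid),
#' the view surface can be meshed directly and cheaply: every 2 x 2 pixel
#' quad whose four depths are finite and whose depth spread is below
#' `depth_jump_threshold` emits two triangles. The threshold prevents
#' bridging across depth discontinuities (silhouette edges, limbs in front
#' of the torso); holes simply emit no triangles and leave jagged
#' boundaries — the error pathway a reconstruction-based area estimate
#' actually suffers from.
#'
#' @param result a [raycast()] result (possibly noisy / with holes).
#' @param depth_jump_threshold maximum allowed depth spread within a quad,
#'   in dm (> 0).
#' @return A [mesh3t()] of the visible surface, in camera-frame
#'   coordinates; its [mesh_area()] is the reconstruction-based VBSA.
#' @export
reconstruct_organized <- function(result, depth_jump_threshold = 0.2) {
  stopifnot(inherits(result, "raycast"))
  if (depth_jump_threshold <= 0) stop("depth_jump_threshold must be > 0")
  d <- result$depth
  H <- nrow(d)
  W <- ncol(d)
  if (H < 2L || W < 2L) stop("organized grid too small to mesh")
  d00 <- d[-H, -W]
  d10 <- d[-1, -W]
  d01 <- d[-H, -1]
  d11 <- d[-1, -1]
  dmin <- pmin(d00, d10, d01, d11)
  dmax <- pmax(d00, d10, d01, d11)
  good <- which(!is.na(dmin) & (dmax - dmin) < depth_jump_threshold)
  if (!length(good)) stop("no quads survive the depth-jump threshold")
  # linear vertex index of the quad's top-left pixel in the full grid
  r <- ((good - 1L) %% (H - 1L)) + 1L
  c0 <- ((good - 1L) %/% (H - 1L)) + 1L
  i00 <- (c0 - 1L) * H + r
  i10 <- i00 + 1L
  i01 <- i00 + H
  i11 <- i01 + 1L
  verts <- cbind(as.vector(result$points[, , 1]),
                 as.vector(result$points[, , 2]),
                 as.vector(result$points[, , 3]))
  faces <- rbind(cbind(i00, i10, i11), cbind(i00, i11, i01))
  used <- sort(unique(as.vector(faces)))
  remap <- integer(H * W)
  remap[used] <- seq_along(used)
  mesh3t(verts[used, , drop = FALSE],
         matrix(remap[faces], ncol = 3L))
}

#' Smooth and voxel-decimate an organized acquisition
#'
#' Optional cleanup before [reconstruct_organized()]: depths are smoothed by
#' a local least-squares plane fit over each 3 x 3 pixel window (on the
#' symmetric window this equals the masked window mean), then the point set
#' is downsampled on a voxel grid — within each voxel only the point nearest
#' the voxel centroid is kept and all other pixels in the voxel are mapped
#' to it, preserving the organized structure while collapsing redundant
#' detail.
#'
#' @param result a [raycast()] result.
#' @param voxel_size voxel edge length in dm (> 0); as it approaches 0 the
#'   operation approaches the identity.
#' @param smooth apply the plane smoothing step.
#' @return The cleaned `"raycast"` object.
#' @export
smooth_and_decimate <- function(result, voxel_size = 0.1, smooth = TRUE) {
  stopifnot(inherits(result, "raycast"))
  if (voxel_size <= 0) stop("voxel_size must be > 0")
  d <- result$depth
  H <- nrow(d)
  W <- ncol(d)
  if (smooth) {
    ok <- !is.na(d)
    z <- ifelse(ok, d, 0)
    acc <- matrix(0, H, W)
    cnt <- matrix(0, H, W)
    for (dr in -1:1) {
      for (dc in -1:1) {
        rs <- max(1, 1 + dr):min(H, H + dr)
        rd <- rs - dr
        cs <- max(1, 1 + dc):min(W, W + dc)
        cd <- cs - dc
        acc[rd, cd] <- acc[rd, cd] + z[rs, cs]
        cnt[rd, cd] <- cnt[rd, cd] + ok[rs, cs]
      }
    }
    sm <- d
    sm[ok] <- acc[ok] / cnt[ok]
    ratio <- sm / result$depth
    result$depth <- sm
    for (k in 1:3) {
      pl <- result$points[, , k]
      pl[ok] <- pl[ok] * ratio[ok]
      result$points[, , k] <- pl
    }
  }
  # voxel decimation with nearest-kept-point mapping
  ok <- which(!is.na(result$depth))
  if (length(ok)) {
    px <- result$points[, , 1][ok]
    py <- result$points[, , 2][ok]
    pz <- result$points[, , 3][ok]
    vx <- floor(px / voxel_size)
    vy <- floor(py / voxel_size)
    vz <- floor(pz / voxel_size)
    key <- paste(vx, vy, vz)
    grp <- match(key, unique(key))
    cx <- tapply(px, grp, mean)[grp]
    cy <- tapply(py, grp, mean)[grp]
    cz <- tapply(pz, grp, mean)[grp]
    d2 <- (px - cx)^2 + (py - cy)^2 + (pz - cz)^2
    ordv <- order(grp, d2)
    keep_first <- ordv[!duplicated(grp[ordv])]
    rep_idx <- keep_first[grp]
    coords <- list(px, py, pz)
    for (k in 1:3) {
      pl <- result$points[, , k]
      pl[ok] <- coords[[k]][rep_idx]
      result$points[, , k] <- pl
    }
    dep <- result$depth
    dep[ok] <- pz[rep_idx]
    result$depth <- dep
  }
  result
}

#' One subject-view VBSA record
#'
#' Bundles the quantities the sweep stores per subject and camera cell:
#' the ground-truth VBSA, optionally the hole-degraded VBSA and the
#' reconstruction-based VBSA, together with the full camera settings, so
#' every output row is self-describing.
#'
#' @param mesh subject mesh.
#' @param result [raycast()] result for this view.
#' @param subject_id subject identifier.
#' @param hole_fraction per-triangle dropout probability (0 = off).
#' @param reconstruct also compute the reconstruction-based VBSA.
#' @param depth_jump_threshold passed to [reconstruct_organized()].
#' @param seed seed for the hole simulation.
#' @return One-row data frame.
#' @export
vbsa_record <- function(mesh, result, subject_id = "subject",
                        hole_fraction = 0, reconstruct = FALSE,
                        depth_jump_threshold = 0.2, seed = 1L) {
  gt <- vbsa_ground_truth(mesh, result)
  holes <- if (hole_fraction > 0) {
    simulate_holes(result, hole_fraction, seed = seed)$vbsa
  } else {
    gt
  }
  recon <- if (reconstruct) {
    mesh_area(reconstruct_organized(result, depth_jump_threshold))$wbsa
  } else {
    NA_real_
  }
  data.frame(subject_id = subject_id,
             theta = result$placement$theta,
             phi = result$placement$phi,
             distance_dm = result$placement$distance,
             width = result$intrinsics$width,
             height = result$intrinsics$height,
             vbsa_gt = gt,
             vbsa_holes = holes,
             vbsa_recon = recon,
             hole_fraction = hole_fraction,
             wbsa = mesh_area(mesh)$wbsa,
             stringsAsFactors = FALSE)
}
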