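test_that("ground-truth VBSA sums visible-triangle areas", {
  tri <- mesh3t(rbind(c(-50, -50, 0), c(50, -50, 0), c(0, 80, 0)),
                rbind(c(1, 2, 3)))
  K <- camera_intrinsics(64, 48)
  rc <- raycast(tri, K, camera_placement(0, 0, 30, look_at = c(0, 0, 0)))
  expect_equal(vbsa_ground_truth(tri, rc), mesh_area(tri)$wbsa)

  # camera behind the open side of a one-sided scene still works: a miss
  # everywhere yields zero view area
  off <- raycast(tri, K, camera_placement(0, 0, 500, look_at = c(0, 400, 0)))
  expect_equal(vbsa_ground_truth(tri, off), 0)

  bogus <- rc
  bogus$visible_ids <- 999L
  expect_error(vbsa_ground_truth(tri, bogus), "not found")
})

test_that("hole simulation removes the expected area fraction", {
  m <- icosphere(5, 3)
  rc <- raycast(m, camera_intrinsics(), camera_placement(0, 0, 43,
                                                         look_at = c(0, 0, 0)))
  gt <- vbsa_ground_truth(m, rc)

  h0 <- simulate_holes(rc, 0, seed = 1)
  expect_equal(h0$vbsa, gt)
  expect_identical(h0$result$hit_ids, rc$hit_ids)

  h1 <- simulate_holes(rc, 1, seed = 1)
  expect_equal(h1$vbsa, 0)
  expect_true(all(is.na(h1$result$depth)))
  expect_length(h1$result$visible_ids, 0)

  ratios <- vapply(1:500, function(s) {
    simulate_holes(rc, 0.3, seed = s)$vbsa / gt
  }, 0)
  expect_equal(mean(ratios), 0.7, tolerance = 0.02)
  # degraded area decreases stochastically in p
  mean_at <- function(p) mean(vapply(1:60, function(s) {
    simulate_holes(rc, p, seed = s)$vbsa
  }, 0))
  expect_gt(mean_at(0.1), mean_at(0.3))
  expect_gt(mean_at(0.3), mean_at(0.6))
  expect_error(simulate_holes(rc, 1.5), "p must")
})

test_that("hole pixels are blanked consistently with the dropped ids", {
  m <- icosphere(5, 3)
  rc <- raycast(m, camera_intrinsics(160, 120),
                camera_placement(0, 0, 43, look_at = c(0, 0, 0)))
  h <- simulate_holes(rc, 0.4, seed = 11)
  kept <- h$result$hit_ids[!is.na(h$result$hit_ids)]
  expect_true(all(kept %in% h$result$visible_ids))
  expect_equal(sum(h$result$visible_areas), h$vbsa)
  blanked <- is.na(h$result$hit_ids) & !is.na(rc$hit_ids)
  expect_true(all(is.na(h$result$depth[blanked])))
})

test_that("organized reconstruction recovers planar patch areas", {
  wall <- plane_mesh(half = 40, z = 0)
  K <- camera_intrinsics(160, 120)
  D <- 30
  rc <- raycast(wall, K, camera_placement(0, 0, D, look_at = c(0, 0, 0)))
  rec <- reconstruct_organized(rc, depth_jump_threshold = 0.5)
  # each pixel quad spans (D/fx) x (D/fy) on a fronto-parallel plane
  expected <- (K$width - 1) * (K$height - 1) * D^2 / (K$f^2 * K$sx * K$sy)
  expect_equal(mesh_area(rec)$wbsa, expected, tolerance = 0.01)

  # 45-degree tilted plane (z_w = x_w): the exact visible region is the
  # projective image of the pixel-centre rectangle, a planar quadrilateral
  tilt <- mesh3t(rbind(c(-40, -40, -40), c(40, -40, 40),
                       c(40, 40, 40), c(-40, 40, -40)),
                 rbind(c(1, 2, 3), c(1, 3, 4)))
  rct <- raycast(tilt, K, camera_placement(0, 0, D, look_at = c(0, 0, 0)),
                 check_inside = FALSE)
  rect <- reconstruct_organized(rct, depth_jump_threshold = 5)
  ext <- place_camera(camera_placement(0, 0, D), look_at = c(0, 0, 0))
  n_pl <- c(1, 0, -1)
  corner <- function(u, v) {
    d <- as.numeric(t(ext$R) %*% c((u - K$ox) / (K$f * K$sx),
                                   (v - K$oy) / (K$f * K$sy), 1))
    tt <- -sum(n_pl * ext$C) / sum(n_pl * d)
    ext$C + tt * d
  }
  q <- rbind(corner(0, 0), corner(K$width - 1, 0),
             corner(K$width - 1, K$height - 1), corner(0, K$height - 1))
  oracle <- heron_area(q[1, ], q[2, ], q[3, ]) +
    heron_area(q[1, ], q[3, ], q[4, ])
  expect_equal(mesh_area(rect)$wbsa, oracle, tolerance = 0.02)
  # foreshortening: the tilted sheet carries more area than a fronto-
  # parallel plane seen through the same pixels at the same central depth
  expect_gt(mesh_area(rect)$wbsa, expected)
})

test_that("depth jumps are not bridged", {
  # two fronto-parallel half-planes at different depths
  near <- mesh3t(rbind(c(-40, -40, 5), c(0, -40, 5), c(0, 40, 5),
                       c(-40, 40, 5)), rbind(c(1, 2, 3), c(1, 3, 4)))
  far <- mesh3t(rbind(c(0, -40, -5), c(40, -40, -5), c(40, 40, -5),
                      c(0, 40, -5)), rbind(c(1, 2, 3), c(1, 3, 4)))
  both <- mesh3t(rbind(near$vertices, far$vertices),
                 rbind(near$faces, far$faces + 4L))
  rc <- raycast(both, camera_intrinsics(80, 60),
                camera_placement(0, 0, 30, look_at = c(0, 0, 0)))
  rec <- reconstruct_organized(rc, depth_jump_threshold = 2)
  # no reconstructed triangle spans the 10 dm depth step
  z <- rec$vertices[, 3]
  span <- apply(rec$faces, 1, function(f) max(z[f]) - min(z[f]))
  expect_lt(max(span), 2)
  expect_error(reconstruct_organized(rc, 0), "threshold")
})

test_that("smoothing leaves noiseless planes alone and shrinks noise", {
  wall <- plane_mesh(half = 40, z = 0)
  K <- camera_intrinsics(120, 90)
  rc <- raycast(wall, K, camera_placement(0, 0, 30, look_at = c(0, 0, 0)))
  sm <- smooth_and_decimate(rc, voxel_size = 1e-6)
  ok <- !is.na(rc$depth)
  expect_lt(max(abs(sm$depth[ok] - rc$depth[ok])), 1e-6)

  nm <- noise_model(axial_sigma = function(d, i) rep(0.05, length(d)),
                    lateral_sigma = function(d) rep(0, length(d)), seed = 2)
  noisy <- apply_noise(rc, nm)
  smn <- smooth_and_decimate(noisy, voxel_size = 1e-6)
  expect_lt(stats::sd((smn$depth - rc$depth)[ok]),
            stats::sd((noisy$depth - rc$depth)[ok]))
  expect_lt(stats::sd((smn$depth - rc$depth)[ok]), 0.05)
  expect_error(smooth_and_decimate(rc, voxel_size = 0), "voxel_size")
})

test_that("voxel decimation collapses points onto representatives", {
  m <- icosphere(5, 2)
  rc <- raycast(m, camera_intrinsics(80, 60),
                camera_placement(0, 0, 43, look_at = c(0, 0, 0)))
  dec <- smooth_and_decimate(rc, voxel_size = 1, smooth = FALSE)
  ok <- !is.na(dec$depth)
  pts <- cbind(dec$points[, , 1][ok], dec$points[, , 2][ok],
               dec$points[, , 3][ok])
  expect_lt(nrow(unique(round(pts, 9))), sum(ok))
})

test_that("subdividing shrinks the partial-visibility overestimate", {
  body <- make_body(body_params(170, 1, 0.5, 0.5, 30))
  K <- camera_intrinsics()
  pl <- camera_placement(45, 0, 43)
  v0 <- vbsa_ground_truth(body, raycast(body, K, pl))
  b1 <- subdivide(body, 1)
  v1 <- vbsa_ground_truth(b1, raycast(b1, K, pl))
  expect_lte(v1, v0)
})

test_that("VBSA records carry the full camera settings", {
  m <- icosphere(5, 2)
  rc <- raycast(m, camera_intrinsics(80, 60),
                camera_placement(30, -45, 43, look_at = c(0, 0, 0)))
  rec <- vbsa_record(m, rc, subject_id = "s1", hole_fraction = 0.2,
                     reconstruct = TRUE, seed = 3)
  expect_equal(rec$theta, 30)
  expect_equal(rec$phi, -45)
  expect_equal(rec$distance_dm, 43)
  expect_equal(rec$width, 80)
  expect_lte(rec$vbsa_holes, rec$vbsa_gt)
  expect_gt(rec$vbsa_gt, 0)
  expect_lte(rec$vbsa_gt, rec$wbsa)
  expect_false(is.na(rec$vbsa_recon))
})
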