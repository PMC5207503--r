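test_that("the default angle grid has 65 cells with polar views collapsed", {
  g <- angle_grid()
  expect_equal(nrow(g), 65L)
  expect_equal(sum(abs(g$phi) == 90), 2L)
  expect_true(all(g$theta[abs(g$phi) == 90] == 0))
  expect_equal(length(unique(g$theta)), 9L)
  full <- angle_grid(full_azimuth = TRUE)
  expect_gt(nrow(full), nrow(g))
  expect_error(angle_grid(theta = numeric()), "non-empty")
})

make_test_config <- function(angles, n_subj, seed = 1) {
  sweep_config(angles = angles, width = 96L, height = 72L,
               models = c(vbsa = "wbsa ~ vbsa",
                          vbsa_stature = "wbsa ~ vbsa + stature_cm"),
               k = 3L, seed = seed)
}

test_that("a sweep produces one record per subject and cell, deterministically", {
  pop <- sample_random_population(8, seed = 42, n_seg = 16L)
  angles <- data.frame(theta = c(0, 90), phi = c(0, 0))
  cfg <- make_test_config(angles)

  res1 <- run_sweep(pop, cfg, n_seg = 16L)
  expect_equal(nrow(res1$vbsa), 8L * 2L)
  expect_true(all(res1$vbsa$vbsa_gt > 0))
  expect_true(all(res1$vbsa$vbsa_gt <= res1$vbsa$wbsa))
  expect_true(all(c("theta", "phi", "distance_dm", "width", "height",
                    "fov_v", "noise", "hole_fraction") %in%
                    names(res1$vbsa)))

  res2 <- run_sweep(pop, cfg, n_seg = 16L)
  expect_identical(res1$vbsa, res2$vbsa)
  expect_identical(res1$fits, res2$fits)

  # both model variants fitted at both cells
  expect_equal(nrow(res1$fits), 2L * 2L)
  expect_true("c_stature_cm" %in% names(res1$fits))

  # single subject, single angle: one record
  one <- run_sweep(pop[3, ], sweep_config(
    angles = data.frame(theta = 45, phi = 0), width = 96L, height = 72L,
    models = character(), k = 3L), n_seg = 16L)
  expect_equal(nrow(one$vbsa), 1L)
})

test_that("sweeps resume from cached per-cell files", {
  pop <- sample_random_population(6, seed = 4, n_seg = 16L)
  angles <- data.frame(theta = c(0, 90), phi = c(0, 0))
  cfg <- sweep_config(angles = angles, width = 96L, height = 72L,
                      models = c(vbsa = "wbsa ~ vbsa"), k = 3L)
  dir <- withr::local_tempdir()
  res1 <- run_sweep(pop, cfg, out_dir = dir, n_seg = 16L)
  expect_true(file.exists(file.path(dir, "manifest.txt")))
  expect_true(file.exists(file.path(dir, "angle_fits.csv")))
  cells <- list.files(dir, pattern = "^vbsa_t")
  expect_length(cells, 2L)

  # poison one cached cell: the rerun must trust the cache, not recompute
  poisoned <- file.path(dir, cells[1])
  tab <- read.csv(poisoned)
  tab$vbsa_gt <- tab$vbsa_gt + 100
  write.csv(tab, poisoned, row.names = FALSE)
  res2 <- run_sweep(pop, cfg, out_dir = dir, n_seg = 16L)
  expect_equal(res2$vbsa$vbsa_gt[res2$vbsa$theta == tab$theta[1]],
               tab$vbsa_gt, tolerance = 1e-9)

  # removing the poisoned cell and rerunning regenerates the original
  file.remove(poisoned)
  res3 <- run_sweep(pop, cfg, out_dir = dir, n_seg = 16L)
  expect_equal(res3$vbsa$vbsa_gt, res1$vbsa$vbsa_gt, tolerance = 1e-9)
})

test_that("reports collapse fits into per-angle curves", {
  set.seed(8)
  fits <- list()
  for (th in c(0, 45, 90)) {
    d <- data.frame(vbsa = stats::runif(60, 40, 140))
    d$wbsa <- 2 * d$vbsa + 5 + stats::rnorm(60)
    fits[[length(fits) + 1L]] <-
      wbsa_model(wbsa ~ vbsa, d, k = 5, seed = 1, theta = th, phi = 0)
  }
  tab <- angle_fit_table(fits, model = "vbsa")
  rep <- report_sweep(tab)
  expect_s3_class(rep, "sweep_report")
  expect_equal(nrow(rep$curves), 3L)
  # constant generating slope shows up as a flat coefficient curve
  expect_lt(diff(range(rep$curves$c1)), 0.05)
  expect_output(print(rep), "c1 range")
  expect_error(report_sweep(tab[0, ]), "empty")

  one <- report_sweep(tab[1, , drop = FALSE])
  expect_equal(nrow(one$curves), 1L)

  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(rep))
})

test_that("reports append the height-weight formula baseline", {
  pop <- sample_random_population(5, seed = 13, n_seg = 16L)
  d <- data.frame(vbsa = stats::runif(30, 40, 140))
  d$wbsa <- 2 * d$vbsa + 5
  tab <- suppressWarnings(
    angle_fit_table(wbsa_model(wbsa ~ vbsa, d, cv = FALSE, theta = 0,
                               phi = 0)))
  dir <- withr::local_tempdir()
  rep <- report_sweep(tab, population = pop, out_dir = dir)
  expect_equal(nrow(rep$du_bois), 5L)
  expect_equal(rep$du_bois$du_bois_dm2,
               100 * du_bois(pop$weight_kg, pop$stature_cm), tolerance = 1e-9)
  expect_true(file.exists(file.path(dir, "report_curves.csv")))
  expect_true(file.exists(file.path(dir, "du_bois_comparison.csv")))
})

test_that("acquisition writers emit readable text formats", {
  m <- icosphere(5, 2)
  rc <- raycast(m, camera_intrinsics(48, 36),
                camera_placement(0, 0, 43, look_at = c(0, 0, 0)))
  ply <- withr::local_tempfile(fileext = ".ply")
  write_ply(rc, ply)
  lines <- readLines(ply)
  expect_equal(lines[1], "ply")
  expect_true(any(grepl("comment organized rows 36 cols 48", lines)))
  n_declared <- as.integer(sub("element vertex ", "",
                               grep("element vertex", lines, value = TRUE)))
  expect_equal(n_declared, sum(!is.na(rc$depth)))

  dcsv <- withr::local_tempfile(fileext = ".csv")
  write_depth_csv(rc, dcsv)
  d <- as.matrix(read.csv(dcsv, header = FALSE))
  expect_equal(dim(d), dim(rc$depth))
  expect_equal(unname(d), unname(rc$depth), tolerance = 1e-9)

  cfgf <- withr::local_tempfile(fileext = ".cfg")
  write_config(list(theta = 30, phi = -45, label = "frontal"), cfgf)
  cfg <- read_config(cfgf)
  expect_equal(cfg$theta, 30)
  expect_equal(cfg$label, "frontal")
})

test_that("the command-line driver generates a population table", {
  cli <- system.file("cli", "vbsa", package = "vbsar")
  expect_true(nzchar(cli))
  out <- withr::local_tempfile(fileext = ".csv")
  res <- system2("Rscript", c(cli, "generate-population", "--n", "4",
                              "--seed", "2", "--out", out, "--fast"),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  tab <- read.csv(out)
  expect_equal(nrow(tab), 4L)
  expect_true("girth" %in% names(tab))
})
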