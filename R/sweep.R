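#' Camera angle grid
#'
#' The default sweep covers azimuths 0-180 degrees on the subject's left
#' side (the bodies are symmetric, so the right side is redundant) and
#' elevations 0, +/-30, +/-45, +/-60, +/-90 degrees. At `phi = +/-90`
#' (straight overhead / below) the azimuth does not change the view, so
#' only `theta = 0` is kept: the default grid has 9 x 7 + 2 = 65 cells.
#'
#' @param theta azimuth values in degrees.
#' @param phi elevation values in degrees.
#' @param full_azimuth if `TRUE`, mirror the azimuths to the right side as
#'   negative angles.
#' @return Data frame with columns `theta`, `phi`, one row per camera cell.
#' @export
angle_grid <- function(theta = c(0, 30, 45, 60, 90, 120, 135, 150, 180),
                       phi = c(0, -30, 30, -45, 45, -60, 60, -90, 90),
                       full_azimuth = FALSE) {
  if (!length(theta) || !length(phi)) stop("angle grids must be non-empty")
  if (full_azimuth) theta <- sort(unique(c(theta, -theta)))
  g <- expand.grid(theta = theta, phi = phi, KEEP.OUT.ATTRS = FALSE)
  g <- g[abs(g$phi) < 90 | g$theta == 0, , drop = FALSE]
  g <- g[order(g$phi, g$theta), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Sweep configuration
#'
#' Bundles every setting of an end-to-end experiment: the angle grid, the
#' camera optics and distance, noise and hole settings, the model variants
#' to fit and the fold seed. The default distance of 43 dm (4.3 m) is the
#' framing distance that accommodates the tallest subjects with the default
#' 43-degree vertical field of view.
#'
#' @param angles data frame from [angle_grid()].
#' @param distance camera distance in dm.
#' @param width,height,fov_v camera optics (see [camera_intrinsics()]).
#' @param noise `NULL` or a [noise_model()].
#' @param hole_fraction per-triangle dropout probability.
#' @param models named character vector or list mapping a model label to a
#'   formula (as text), e.g. `c(vbsa = "wbsa ~ vbsa")`.
#' @param groups character vector of grouping column names (in addition to
#'   the ungrouped fit), e.g. `c("gender", "age_group")`.
#' @param k,seed cross-validation folds and seed.
#' @return An object of class `"sweep_config"`.
#' @export
sweep_config <- function(angles = angle_grid(), distance = 43,
                         width = 640L, height = 480L, fov_v = 43,
                         noise = NULL, hole_fraction = 0,
                         models = c(vbsa = "wbsa ~ vbsa"),
                         groups = character(), k = 10L, seed = 1L) {
  stopifnot(nrow(angles) >= 1, distance > 0,
            hole_fraction >= 0, hole_fraction <= 1)
  structure(list(angles = angles, distance = distance, width = width,
                 height = height, fov_v = fov_v, noise = noise,
                 hole_fraction = hole_fraction, models = as.list(models),
                 groups = groups, k = k, seed = seed),
            class = "sweep_config")
}

cell_filename <- function(theta, phi) {
  sprintf("vbsa_t%+04d_p%+04d.csv", as.integer(round(theta)),
          as.integer(round(phi)))
}

#' Run a full per-angle experiment
#'
#' For every subject and camera cell: rebuild the subject's mesh, ray-cast
#' it, extract the VBSA record (optionally with sensor noise and hole
#' simulation); then, per camera cell, group and model variant, fit and
#' cross-validate the WBSA prediction model. When `out_dir` is given, each
#' camera cell is written to its own CSV as soon as it is computed and
#' already-present cell files are loaded instead of recomputed, so an
#' interrupted sweep resumes where it stopped; a `manifest.txt` records the
#' seed, configuration and package version.
#'
#' @param population population data frame from
#'   [sample_random_population()] or [sample_nhanes_style_population()].
#' @param config a [sweep_config()].
#' @param out_dir output directory for per-cell CSVs, fit table and
#'   manifest, or `NULL` to keep everything in memory.
#' @param n_seg mesh resolution passed to [make_body()].
#' @param subdivide_levels rounds of midpoint subdivision applied to each
#'   body before ray casting; finer triangles shrink the full-triangle
#'   counting overestimate on partially visible silhouettes.
#' @param verbose print progress.
#' @return List with `vbsa` (one row per subject x cell) and `fits` (one
#'   row per cell x group x model, see [angle_fit_table()]).
#' @export
run_sweep <- function(population, config = sweep_config(), out_dir = NULL,
                      n_seg = 24L, subdivide_levels = 1L, verbose = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  pop <- as.data.frame(population)
  if (!nrow(pop)) stop("empty population")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  intr <- camera_intrinsics(config$width, config$height, config$fov_v)
  meshes <- lapply(seq_len(nrow(pop)), function(i) {
    m <- mesh_from_record(pop[i, ], n_seg = n_seg)
    if (subdivide_levels > 0) m <- subdivide(m, subdivide_levels)
    m
  })
  cells <- vector("list", nrow(config$angles))
  for (ci in seq_len(nrow(config$angles))) {
    th <- config$angles$theta[ci]
    ph <- config$angles$phi[ci]
    cache <- if (!is.null(out_dir)) {
      file.path(out_dir, cell_filename(th, ph))
    }
    if (!is.null(cache) && file.exists(cache)) {
      cells[[ci]] <- utils::read.csv(cache, stringsAsFactors = FALSE)
      next
    }
    if (verbose) {
      message(sprintf("cell theta=%g phi=%g", th, ph))
    }
    rows <- lapply(seq_len(nrow(pop)), function(i) {
      rc <- raycast(meshes[[i]], intr,
                    camera_placement(th, ph, config$distance))
      if (!is.null(config$noise) && config$noise$enabled) {
        rc <- apply_noise(rc, config$noise,
                          seed = config$seed + 7919L * i)
      }
      vbsa_record(meshes[[i]], rc, subject_id = pop$subject_id[i],
                  hole_fraction = config$hole_fraction,
                  seed = config$seed + 104729L * i)
    })
    cell <- do.call(rbind, rows)
    cell$noise <- !is.null(config$noise) && config$noise$enabled
    cell$fov_v <- config$fov_v
    cells[[ci]] <- cell
    if (!is.null(cache)) utils::write.csv(cell, cache, row.names = FALSE)
  }
  vbsa_tab <- do.call(rbind, cells)
  # predictor used downstream: degraded VBSA when holes are simulated
  vbsa_tab$vbsa <- if (config$hole_fraction > 0) vbsa_tab$vbsa_holes else
    vbsa_tab$vbsa_gt
  merged <- merge(vbsa_tab,
                  pop[, setdiff(names(pop), c("wbsa_dm2")), drop = FALSE],
                  by = "subject_id", sort = FALSE)
  fit_rows <- list()
  for (ci in seq_len(nrow(config$angles))) {
    th <- config$angles$theta[ci]
    ph <- config$angles$phi[ci]
    d <- merged[merged$theta == th & merged$phi == ph, , drop = FALSE]
    for (mn in names(config$models)) {
      fml <- stats::as.formula(config$models[[mn]])
      f <- wbsa_model(fml, d, k = config$k, seed = config$seed,
                      theta = th, phi = ph, group = "all")
      fit_rows[[length(fit_rows) + 1L]] <- angle_fit_table(f, model = mn)
      for (gc in config$groups) {
        gf <- tryCatch(
          fit_by_group(d, fml, gc, k = config$k, seed = config$seed,
                       theta = th, phi = ph),
          error = function(e) NULL)
        if (!is.null(gf)) {
          fit_rows[[length(fit_rows) + 1L]] <-
            angle_fit_table(gf, model = mn)
        }
      }
    }
  }
  if (length(fit_rows)) {
    all_cols <- unique(unlist(lapply(fit_rows, names)))
    fit_rows <- lapply(fit_rows, function(r) {
      for (cc in setdiff(all_cols, names(r))) r[[cc]] <- NA_real_
      r[all_cols]
    })
    fits <- do.call(rbind, fit_rows)
  } else {
    fits <- data.frame()
  }
  if (!is.null(out_dir)) {
    if (nrow(fits)) {
      utils::write.csv(fits, file.path(out_dir, "angle_fits.csv"),
                       row.names = FALSE)
    }
    writeLines(c(
      sprintf("package: vbsar %s",
              as.character(utils::packageVersion("vbsar"))),
      sprintf("seed: %d", config$seed),
      sprintf("distance_dm: %g", config$distance),
      sprintf("resolution: %dx%d", config$width, config$height),
      sprintf("fov_v_deg: %g", config$fov_v),
      sprintf("hole_fraction: %g", config$hole_fraction),
      sprintf("noise: %s",
              !is.null(config$noise) && config$noise$enabled),
      sprintf("k_folds: %d", config$k),
      sprintf("n_subjects: %d", nrow(pop)),
      sprintf("n_cells: %d", nrow(config$angles))),
      file.path(out_dir, "manifest.txt"))
  }
  list(vbsa = vbsa_tab, fits = fits)
}

#' Summarise a sweep into per-angle curves
#'
#' Collapses the fit table into the curves the analysis reads off: the VBSA
#' coefficient `c1` and the cross-validation RMSE as functions of azimuth,
#' one curve per elevation, group and model variant. When a population with
#' `weight_kg` and a stature column is supplied, a height-weight formula
#' baseline is appended: the Du Bois estimate per subject and its error
#' against the mesh ground truth.
#'
#' @param fits fit table from [run_sweep()] (`$fits`) or
#'   [angle_fit_table()].
#' @param population optional population data frame for the formula
#'   baseline.
#' @param out_dir optional directory to write `report_curves.csv` (and
#'   `du_bois_comparison.csv` if computed).
#' @return An object of class `"sweep_report"`: list with `curves`,
#'   `du_bois` (or `NULL`) and the input table.
#' @export
report_sweep <- function(fits, population = NULL, out_dir = NULL) {
  if (is.list(fits) && !is.data.frame(fits) && !is.null(fits$fits)) {
    fits <- fits$fits
  }
  if (!is.data.frame(fits) || !nrow(fits)) stop("empty fit table")
  keep <- c("phi", "group", "model", "theta", "c1", "c0", "cv_rmse",
            "cv_mape", "n")
  curves <- fits[, intersect(keep, names(fits)), drop = FALSE]
  curves <- curves[order(curves$model, curves$group, curves$phi,
                         curves$theta), , drop = FALSE]
  rownames(curves) <- NULL
  db <- NULL
  if (!is.null(population) && all(c("weight_kg", "wbsa_dm2") %in%
                                    names(population))) {
    st <- if ("stature_cm" %in% names(population)) {
      population$stature_cm
    } else {
      population$stature_param_cm
    }
    db_dm2 <- 100 * du_bois(population$weight_kg, st)  # m^2 -> dm^2
    db <- data.frame(subject_id = population$subject_id,
                     wbsa_dm2 = population$wbsa_dm2,
                     du_bois_dm2 = db_dm2,
                     error_dm2 = db_dm2 - population$wbsa_dm2)
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(curves, file.path(out_dir, "report_curves.csv"),
                     row.names = FALSE)
    if (!is.null(db)) {
      utils::write.csv(db, file.path(out_dir, "du_bois_comparison.csv"),
                       row.names = FALSE)
    }
  }
  structure(list(curves = curves, du_bois = db, fits = fits),
            class = "sweep_report")
}

#' @export
print.sweep_report <- function(x, ...) {
  cat("Sweep report:", nrow(x$fits), "fits,",
      length(unique(x$curves$phi)), "elevations,",
      length(unique(x$curves$theta)), "azimuths\n")
  rng <- range(x$curves$c1, na.rm = TRUE)
  cat(sprintf("  c1 range: [%.3f, %.3f]\n", rng[1], rng[2]))
  if (any(is.finite(x$curves$cv_rmse))) {
    rng <- range(x$curves$cv_rmse, na.rm = TRUE)
    cat(sprintf("  CV RMSE range: [%.3f, %.3f] dm^2\n", rng[1], rng[2]))
  }
  if (!is.null(x$du_bois)) {
    cat(sprintf("  Du Bois baseline: mean |error| %.2f dm^2\n",
                mean(abs(x$du_bois$error_dm2))))
  }
  invisible(x)
}

#' @export
plot.sweep_report <- function(x, group = "all",
                              model = x$curves$model[1], ...) {
  cv <- x$curves[x$curves$group == group & x$curves$model == model, ]
  if (!nrow(cv)) stop("no curves for that group/model")
  phis <- sort(unique(cv$phi))
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (what in c("c1", "cv_rmse")) {
    ok <- is.finite(cv[[what]])
    if (!any(ok)) next
    graphics::plot(NA, xlim = range(cv$theta), ylim = range(cv[[what]][ok]),
                   xlab = "azimuth theta (deg)",
                   ylab = if (what == "c1") "VBSA coefficient c1" else
                     expression(paste("CV RMSE (", dm^2, ")")), ...)
    for (i in seq_along(phis)) {
      d <- cv[cv$phi == phis[i], ]
      d <- d[order(d$theta), ]
      graphics::lines(d$theta, d[[what]], col = i, type = "b", pch = 16)
    }
    graphics::legend("topleft", legend = sprintf("phi %g", phis),
                     col = seq_along(phis), lty = 1, cex = 0.7, bty = "n")
  }
  invisible(x)
}
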