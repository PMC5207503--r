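#' Write an organized point cloud as ASCII PLY
#'
#' Writes the finite points of an acquisition with their pixel row/column as
#' extra properties, and records the organized grid size in a header
#' comment (`comment organized rows <H> cols <W>`); points are emitted in
#' column-major pixel order, so the organized structure can be rebuilt.
#'
#' @param result a [raycast()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(result, path) {
  stopifnot(inherits(result, "raycast"))
  ok <- which(!is.na(result$depth))
  H <- nrow(result$depth)
  x <- result$points[, , 1][ok]
  y <- result$points[, , 2][ok]
  z <- result$points[, , 3][ok]
  rr <- ((ok - 1L) %% H)
  cc <- ((ok - 1L) %/% H)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment organized rows %d cols %d", H,
                       ncol(result$depth)),
               sprintf("element vertex %d", length(ok)),
               "property float x", "property float y", "property float z",
               "property int row", "property int col", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g %d %d", x, y, z, rr, cc), con)
  invisible(path)
}

#' Write a depth map as a CSV matrix
#'
#' One row per pixel row; misses are written as the literal `NA` sentinel.
#'
#' @param result a [raycast()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth_csv <- function(result, path) {
  stopifnot(inherits(result, "raycast"))
  utils::write.table(result$depth, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "NA")
  invisible(path)
}

#' Read/write plain-text key-value configuration
#'
#' Configuration files are `key = value` lines; blank lines and `#`
#' comments are ignored, and values that parse as numbers are returned
#' numeric.
#'
#' @param path file path.
#' @return [read_config()]: a named list. [write_config()]: `path`,
#'   invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_config
#' @param config named list of scalar values.
#' @export
write_config <- function(config, path) {
  writeLines(vapply(names(config), function(k) {
    sprintf("%s = %s", k, format(config[[k]]))
  }, ""), path)
  invisible(path)
}
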