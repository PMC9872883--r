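# Readers/writers for Mueller-map stacks, anisotropy map sets, moment tables
# and run manifests.
#
# Two stack formats:
#  * multi-page float32 TIFF (16 pages, page order f11, f21, f31, f41, f12,
#    ... f44, i.e. column-major through the 4x4), values affinely rescaled
#    into [0, 1] with scale/offset recorded in a JSON sidecar ("<file>.json")
#    because baseline TIFF float storage is [0, 1]; round trip is exact to
#    float32 quantization;
#  * a plain "array archive" (.mma): gzipped stream with a one-line JSON
#    header (version, names, dimensions, pixel convention) followed by the
#    arrays as doubles — bit-lossless.
#
# Pixel coordinate convention in every header: row-major, origin top-left,
# 0-based.

.IO_VERSION <- "muellertomo-1"
.PIXEL_CONVENTION <- "row-major, origin top-left, 0-based"

.page_names <- function() {
  as.vector(outer(1:4, 1:4, function(i, j) sprintf("f%d%d", i, j)))
}

#' Write a Mueller map
#'
#' Format by extension: `.tif`/`.tiff` (16-page float32 TIFF plus JSON
#' sidecar) or `.mma` (lossless array archive).
#'
#' @param map A [mueller_map()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mueller_map <- function(map, path) {
  stopifnot(inherits(map, "mueller_map"))
  ext <- tolower(tools::file_ext(path))
  d <- dim(map$f)
  pages <- lapply(seq_len(16L), function(k) {
    j <- (k - 1L) %/% 4L + 1L; i <- (k - 1L) %% 4L + 1L
    map$f[, , i, j]
  })
  names(pages) <- .page_names()
  meta <- list(version = .IO_VERSION, kind = "mueller_map",
               pages = .page_names(), dim = d[1:2],
               pixel_convention = .PIXEL_CONVENTION,
               normalized = isTRUE(map$normalized),
               phase_plane = map$phase_plane,
               wavelength = map$geometry$wavelength,
               thickness = map$geometry$thickness)
  if (ext %in% c("tif", "tiff")) .write_tiff_stack(pages, path, meta)
  else if (ext == "mma") .write_archive(pages, path, meta)
  else stop("unknown Mueller map format: .", ext,
            " (expected .tif/.tiff or .mma)")
  invisible(path)
}

#' Read a Mueller map
#' @param path File written by [write_mueller_map()].
#' @return A [mueller_map()].
#' @export
read_mueller_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  r <- if (ext %in% c("tif", "tiff")) .read_tiff_stack(path, expected = 16L)
  else if (ext == "mma") .read_archive(path, expected = 16L)
  else stop("unknown Mueller map format: .", ext)
  meta <- r$meta
  d <- meta$dim
  f <- array(0, c(d[1], d[2], 4L, 4L))
  for (k in seq_len(16L)) {
    j <- (k - 1L) %/% 4L + 1L; i <- (k - 1L) %% 4L + 1L
    f[, , i, j] <- r$pages[[k]]
  }
  geom <- measurement_geometry(meta$wavelength %||% 0.6328,
                               meta$thickness %||% 40)
  mueller_map(f, geometry = geom,
              phase_plane = meta$phase_plane %||% NULL,
              normalize = FALSE)
}

#' Write an anisotropy map set
#'
#' Four observable pages plus the validity mask page, same formats as
#' [write_mueller_map()].
#' @param maps An `anisotropy_maps` object.
#' @param path Output file (`.tif`/`.tiff` or `.mma`).
#' @return `path`, invisibly.
#' @export
write_map_set <- function(maps, path) {
  stopifnot(inherits(maps, "anisotropy_maps"))
  obs <- c("phi_L", "phi_circ", "delta_L", "delta_circ")
  pages <- lapply(maps[obs], function(m) { m[!is.finite(m)] <- 0; m })
  pages$valid <- maps$valid * 1
  meta <- list(version = .IO_VERSION, kind = "map_set",
               pages = c(obs, "valid"), dim = dim(maps$phi_L),
               pixel_convention = .PIXEL_CONVENTION,
               phase_plane = maps$phase_plane, mode = maps$mode)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) .write_tiff_stack(pages, path, meta)
  else if (ext == "mma") .write_archive(pages, path, meta)
  else stop("unknown map set format: .", ext)
  invisible(path)
}

#' Read an anisotropy map set
#' @param path File written by [write_map_set()].
#' @return An `anisotropy_maps` object.
#' @export
read_map_set <- function(path) {
  ext <- tolower(tools::file_ext(path))
  r <- if (ext %in% c("tif", "tiff")) .read_tiff_stack(path, expected = 5L)
  else if (ext == "mma") .read_archive(path, expected = 5L)
  else stop("unknown map set format: .", ext)
  p <- r$pages
  valid <- p[[5]] > 0.5
  obs <- lapply(p[1:4], function(m) { m[!valid] <- NaN; m })
  names(obs) <- c("phi_L", "phi_circ", "delta_L", "delta_circ")
  structure(c(obs, list(components = NULL, valid = valid,
                        phase_plane = r$meta$phase_plane %||% NULL,
                        geometry = measurement_geometry(),
                        mode = r$meta$mode %||% "matrix_log")),
            class = "anisotropy_maps")
}

.write_tiff_stack <- function(pages, path, meta) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF output")
  lo <- min(vapply(pages, min, numeric(1)))
  hi <- max(vapply(pages, max, numeric(1)))
  scale <- if (hi > lo) hi - lo else 1
  scaled <- lapply(pages, function(m) (m - lo) / scale)
  suppressWarnings(tiff::writeTIFF(scaled, path, bits.per.sample = 32L,
                                   compression = "none", reduce = FALSE))
  meta$offset <- lo; meta$scale <- scale
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.read_tiff_stack <- function(path, expected) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF input")
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing TIFF sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != expected)
    stop(sprintf("%s: found %d page(s), expected %d (order %s)", path,
                 length(pages), expected,
                 paste(meta$pages, collapse = ", ")))
  pages <- lapply(pages, function(m) m * meta$scale + meta$offset)
  list(pages = pages, meta = meta)
}

.write_archive <- function(pages, path, meta) {
  meta$pages <- names(pages)
  meta$dim <- dim(pages[[1]])
  con <- gzfile(path, "wb")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)
  writeLines(as.character(hdr), con)
  for (m in pages) writeBin(as.numeric(m), con, size = 8, endian = "little")
  invisible(path)
}

.read_archive <- function(path, expected = NULL) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  meta <- jsonlite::fromJSON(readLines(con, n = 1L))
  if (is.null(meta$version) || !identical(meta$version, .IO_VERSION))
    stop("unrecognized archive version in ", path)
  d <- meta$dim
  n <- length(meta$pages)
  if (!is.null(expected) && n != expected)
    stop(sprintf("%s: found %d array(s), expected %d (order %s)", path, n,
                 expected, paste(meta$pages, collapse = ", ")))
  pages <- lapply(seq_len(n), function(k)
    matrix(readBin(con, "numeric", n = d[1] * d[2], size = 8,
                   endian = "little"), d[1], d[2]))
  names(pages) <- meta$pages
  list(pages = pages, meta = meta)
}

#' Write a cohort moment table as CSV
#'
#' Columns: `sample_id`, `class`, `observable`, `phase_plane`, `Z1..Z4`.
#' @param df data.frame in that layout (see [cohort_moment_table()]).
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_moments_csv <- function(df, path) {
  need <- c("sample_id", "class", "observable", "phase_plane",
            paste0("Z", 1:4))
  stopifnot(all(need %in% names(df)))
  write.csv(df[need], path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort moment table
#' @param path CSV written by [write_moments_csv()].
#' @return data.frame.
#' @export
read_moments_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write a JSON run manifest
#'
#' Every stochastic artifact records its seed here, making outputs
#' regenerable from the manifest alone.
#' @param manifest Named list (must contain a `seed` entry).
#' @param path Output JSON.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(!is.null(manifest$seed))
  manifest$version <- .IO_VERSION
  manifest$pixel_convention <- .PIXEL_CONVENTION
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a JSON run manifest
#' @param path Manifest file.
#' @return Named list.
#' @export
read_manifest <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Render an anisotropy map to PNG
#'
#' Fixed-viridis pseudo-color rendering of one observable map.
#' @param maps An `anisotropy_maps` object (or bare numeric matrix).
#' @param path Output PNG.
#' @param observable Map to render when `maps` is an `anisotropy_maps`.
#' @param palette Colormap name for [grDevices::hcl.colors()].
#' @return `path`, invisibly.
#' @export
render_map <- function(maps, path, observable = "phi_L",
                       palette = "viridis") {
  m <- if (inherits(maps, "anisotropy_maps")) maps[[observable]] else as.matrix(maps)
  m[!is.finite(m)] <- min(m[is.finite(m)])
  png(path, width = ncol(m) * 4, height = nrow(m) * 4)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); dev.off() })
  image(t(m[nrow(m):1, , drop = FALSE]), col = hcl.colors(64, palette),
        axes = FALSE, useRaster = TRUE)
  invisible(path)
}
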