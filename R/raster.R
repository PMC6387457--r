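#' Height raster (canopy-top grid)
#'
#' A regular, axis-aligned grid of canopy-top heights (metres) with `NA`
#' as nodata. Cells are half-open `[x0 + i*s, x0 + (i+1)*s)`; points on the
#' outer max edge are assigned to the last cell. `data` is a matrix with
#' rows indexing y (row 1 = smallest y) and columns indexing x.
#'
#' @param data numeric matrix of heights (rows = y, cols = x), `NA` nodata.
#' @param origin numeric length-2 (x0, y0) of the grid's minimum corner, m.
#' @param cell_size cell edge length, m.
#' @return an object of class `height_raster`.
#' @export
height_raster <- function(data, origin, cell_size) {
  stopifnot(is.matrix(data), length(origin) == 2, cell_size > 0)
  structure(list(data = data, origin = as.numeric(origin),
                 cell_size = as.numeric(cell_size)),
            class = "height_raster")
}

#' @export
print.height_raster <- function(x, ...) {
  cat(sprintf("height_raster: %d x %d cells of %.3f m, origin (%.3f, %.3f)\n",
              nrow(x$data), ncol(x$data), x$cell_size,
              x$origin[1], x$origin[2]))
  v <- x$data[is.finite(x$data)]
  cat(sprintf("  valid cells: %d (%.0f%%), height range [%.3f, %.3f] m\n",
              length(v), 100 * length(v) / length(x$data),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

# cell index (0-based) with max-edge points pulled into the last cell
.cell_index <- function(coord, origin, cell, n) {
  i <- floor((coord - origin) / cell)
  i[coord == origin + n * cell] <- n - 1
  i
}

#' Rasterize a point cloud to a canopy-top (DSM-style) height raster
#'
#' Each cell receives the maximum point height falling in it; cells with no
#' points hold `NA` (nodata). The grid is axis-aligned with its origin at
#' the cloud's minimum corner unless an explicit extent is given.
#'
#' @param cloud a [point_cloud()].
#' @param cell_size cell edge length, m.
#' @param extent optional list with `origin` (x0, y0) and `size` (sx, sy)
#'   in metres forcing the grid placement (used to put several clouds on a
#'   common grid).
#' @return a [height_raster()].
#' @export
rasterize_dsm <- function(cloud, cell_size, extent = NULL) {
  if (cell_size <= 0) stop("cell_size must be > 0")
  m <- unclass(point_cloud(cloud))
  if (nrow(m) == 0) {
    warning("empty cloud: returning an all-nodata raster")
    if (is.null(extent)) extent <- list(origin = c(0, 0), size = c(cell_size, cell_size))
  }
  if (is.null(extent)) {
    origin <- c(min(m[, 1]), min(m[, 2]))
    size <- c(max(m[, 1]), max(m[, 2])) - origin
    size <- pmax(size, cell_size * 1e-9)
  } else {
    origin <- extent$origin
    size <- extent$size
  }
  nx <- max(1L, as.integer(ceiling(size[1] / cell_size - 1e-9)))
  ny <- max(1L, as.integer(ceiling(size[2] / cell_size - 1e-9)))
  grid <- matrix(NA_real_, ny, nx)
  if (nrow(m) > 0) {
    ix <- .cell_index(m[, 1], origin[1], cell_size, nx)
    iy <- .cell_index(m[, 2], origin[2], cell_size, ny)
    ok <- ix >= 0 & ix < nx & iy >= 0 & iy < ny
    ix <- ix[ok]; iy <- iy[ok]; z <- m[ok, 3]
    # ascending-height assignment leaves the per-cell maximum in place
    o <- order(z)
    grid[cbind(iy[o] + 1L, ix[o] + 1L)] <- z[o]
  }
  height_raster(grid, origin, cell_size)
}

#' Read an ESRI ASCII grid as a height raster
#'
#' @param path file path.
#' @return a [height_raster()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  body_start <- 1L
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) == 2 && grepl("^[A-Za-z_]+$", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      body_start <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ESRI ASCII grid header incomplete: missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nodata <- hdr$nodata_value
  if (is.null(nodata)) {
    warning("missing NODATA_value line; assuming -9999")
    nodata <- -9999
  }
  toks <- unlist(strsplit(trimws(lines[body_start:length(lines)]), "\\s+"))
  vals <- as.numeric(toks[nzchar(toks)])
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr)
    stop("ESRI ASCII grid body size mismatch: expected ", nc * nr,
         " values, got ", length(vals))
  # file rows run north to south; internal rows run south to north
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m <- m[nr:1, , drop = FALSE]
  m[m == nodata] <- NA_real_
  height_raster(m, c(hdr$xllcorner, hdr$yllcorner), hdr$cellsize)
}

#' Write a height raster as an ESRI ASCII grid
#'
#' @param raster a [height_raster()].
#' @param path output path.
#' @param nodata nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "height_raster"))
  m <- raster$data
  nr <- nrow(m); nc <- ncol(m)
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.17g", raster$origin[1]),
           sprintf("yllcorner %.17g", raster$origin[2]),
           sprintf("cellsize %.17g", raster$cell_size),
           sprintf("NODATA_value %.10g", nodata))
  out <- m[nr:1, , drop = FALSE]  # write north to south
  out[!is.finite(out)] <- nodata
  rows <- apply(out, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
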