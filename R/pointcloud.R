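#' Construct a point cloud
#'
#' A point cloud is an N x 3 numeric matrix of metric x, y, z coordinates
#' (metres) with class `point_cloud`. All reconstruction and trait
#' extraction functions consume and produce this representation.
#'
#' @param coords numeric matrix or data frame with three columns (x, y, z).
#' @return an N x 3 matrix of class `point_cloud`, columns named x, y, z.
#' @export
point_cloud <- function(coords) {
  if (is.null(coords)) coords <- matrix(numeric(0), 0, 3)
  m <- as.matrix(coords)
  if (length(m) == 0) m <- matrix(numeric(0), 0, 3)
  if (ncol(m) != 3) stop("a point cloud needs exactly 3 columns (x, y, z)")
  if (nrow(m) > 0 && any(!is.finite(m)))
    stop("point cloud contains non-finite coordinates")
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  class(m) <- c("point_cloud", class(m))
  m
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points\n", nrow(x)))
  if (nrow(x) > 0) {
    rng <- apply(x, 2, range)
    cat(sprintf("  x: [%.3f, %.3f] m  y: [%.3f, %.3f] m  z: [%.3f, %.3f] m\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

#' Read a PLY point cloud
#'
#' Supports ASCII and binary-little-endian PLY with float or double vertex
#' x, y, z properties. Non-coordinate vertex properties are read past and
#' dropped with a warning; non-vertex elements are ignored.
#'
#' @param path file path.
#' @return a [point_cloud()].
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0)
      stop("malformed PLY header: end_header not found (line ",
           length(header) + 1, ")")
    header <- c(header, ln)
    if (identical(trimws(ln), "end_header")) break
    if (length(header) > 1000) stop("malformed PLY header: too long")
  }
  if (!identical(trimws(header[1]), "ply"))
    stop("malformed PLY header: missing 'ply' magic (line 1)")
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1)
    stop("malformed PLY header: missing format line (line 2)")
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)

  # parse elements and their properties in order
  elems <- list()
  cur <- NULL
  for (i in seq_along(header)) {
    tok <- strsplit(trimws(header[i]), "\\s+")[[1]]
    if (length(tok) == 0) next
    if (tok[1] == "element") {
      if (!is.null(cur)) elems[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  types = character(), names = character())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list")
        stop("unsupported PLY list property in element '", cur$name,
             "' (line ", i, ")")
      cur$types <- c(cur$types, tok[2])
      cur$names <- c(cur$names, tok[3])
    }
  }
  if (!is.null(cur)) elems[[cur$name]] <- cur
  if (is.null(elems$vertex)) stop("PLY file has no vertex element")
  ve <- elems$vertex
  if (!all(c("x", "y", "z") %in% ve$names))
    stop("PLY vertex element lacks x/y/z properties")
  extra <- setdiff(ve$names, c("x", "y", "z"))
  if (length(extra) > 0)
    warning("dropping unsupported vertex properties: ",
            paste(extra, collapse = ", "))

  sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
             short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
             int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
             float = 4L, float32 = 4L, double = 8L, float64 = 8L)

  if (fmt == "ascii") {
    rows <- readLines(con, n = ve$count)
    if (length(rows) < ve$count)
      stop("truncated PLY file: expected ", ve$count, " vertex rows, got ",
           length(rows))
    vals <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
    m <- do.call(rbind, vals)
    colnames(m) <- ve$names
  } else {
    nprop <- length(ve$names)
    m <- matrix(NA_real_, ve$count, nprop, dimnames = list(NULL, ve$names))
    if (length(unique(ve$types)) == 1 && ve$types[1] %in%
        c("float", "float32", "double", "float64")) {
      sz <- sizes[[ve$types[1]]]
      raw <- readBin(con, "double", n = ve$count * nprop, size = sz,
                     endian = "little")
      if (length(raw) < ve$count * nprop)
        stop("truncated PLY file: expected ", ve$count * nprop,
             " values, got ", length(raw))
      m[] <- matrix(raw, ve$count, nprop, byrow = TRUE)
    } else {
      for (r in seq_len(ve$count)) {
        for (p in seq_len(nprop)) {
          tp <- ve$types[p]
          sz <- sizes[[tp]]
          if (is.null(sz)) stop("unsupported PLY property type: ", tp)
          what <- if (tp %in% c("float", "float32", "double", "float64"))
            "double" else "integer"
          v <- readBin(con, what, n = 1L, size = sz, endian = "little")
          if (length(v) < 1) stop("truncated PLY file at vertex ", r)
          m[r, p] <- v
        }
      }
    }
  }
  out <- m[, c("x", "y", "z"), drop = FALSE]
  # float-typed coordinates are float32-representable by construction:
  # snap parsed ASCII decimals to float32 so both encodings read equal
  f32 <- ve$types[match(c("x", "y", "z"), ve$names)] %in% c("float", "float32")
  if (all(f32) && nrow(out) > 0)
    out[] <- readBin(writeBin(as.vector(out), raw(), size = 4L,
                              endian = "little"),
                     "double", n = length(out), size = 4L, endian = "little")
  point_cloud(out)
}

#' Write a point cloud to PLY
#'
#' @param cloud a [point_cloud()] (or N x 3 matrix).
#' @param path output path.
#' @param format `"binary_little_endian"` (default; x, y, z as 4-byte
#'   floats) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path, format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  m <- unclass(point_cloud(cloud))
  # coordinates are declared float32 in the header: quantize up front so
  # ASCII and binary encodings of the same cloud read back identically
  m[] <- readBin(writeBin(as.vector(m), raw(), size = 4L, endian = "little"),
                 "double", n = length(m), size = 4L, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply",
           paste("format", format, "1.0"),
           sprintf("element vertex %d", nrow(m)),
           "property float x", "property float y", "property float z",
           "end_header")
  writeLines(hdr, con)
  if (nrow(m) > 0) {
    if (format == "ascii") {
      writeLines(sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3]), con)
    } else {
      writeBin(as.vector(t(m)), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}

#' Apply a rigid pose to a point cloud
#'
#' Maps every point through `p -> R p + t`, e.g. to move a reconstruction
#' from its camera-0 frame into the plot frame using the first camera pose.
#'
#' @param cloud a [point_cloud()].
#' @param pose a [rigid_pose()].
#' @return the transformed [point_cloud()].
#' @export
transform_cloud <- function(cloud, pose) {
  m <- unclass(point_cloud(cloud))
  out <- m %*% t(pose$R)
  out <- sweep(out, 2, pose$t, "+")
  point_cloud(out)
}

#' Crop a point cloud to a rectangular footprint
#'
#' Keeps points with x in `[xlim[1], xlim[2]]` and y in `[ylim[1], ylim[2]]`
#' (z unrestricted), e.g. to restrict a reconstruction to the 1 m2 sampling
#' plot before trait extraction.
#'
#' @param cloud a [point_cloud()].
#' @param xlim,ylim numeric length-2 bounds, m.
#' @return the cropped [point_cloud()].
#' @export
crop_cloud <- function(cloud, xlim = c(0, 1), ylim = c(0, 1)) {
  m <- unclass(point_cloud(cloud))
  keep <- m[, 1] >= xlim[1] & m[, 1] <= xlim[2] &
          m[, 2] >= ylim[1] & m[, 2] <= ylim[2]
  point_cloud(m[keep, , drop = FALSE])
}
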