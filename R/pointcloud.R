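#' Construct a plant point cloud
#'
#' A point cloud stores `n` 3D positions in meters, optionally with a per-point
#' semantic label (`"stem"` or `"leaf"`) and a per-point organ instance id
#' (positive integer; `-1` marks unassigned points).
#'
#' @param points numeric matrix with `n` rows and 3 columns (x, y, z in m).
#' @param labels optional character vector of per-point classes in
#'   `c("stem", "leaf")`, one entry per point.
#' @param instances optional integer vector of per-point organ ids, one entry
#'   per point; `-1` means unassigned.
#' @return an object of class `point_cloud`.
#' @export
point_cloud <- function(points, labels = NULL, instances = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("`points` must have exactly 3 columns")
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) stop("all point coordinates must be finite")
  colnames(points) <- c("x", "y", "z")
  rownames(points) <- NULL
  n <- nrow(points)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) stop("`labels` must have one entry per point")
    bad <- !labels %in% c("stem", "leaf")
    if (any(bad)) stop("labels must be 'stem' or 'leaf'")
  }
  if (!is.null(instances)) {
    instances <- as.integer(instances)
    if (length(instances) != n) stop("`instances` must have one entry per point")
    if (anyNA(instances)) stop("instance ids must not be NA (use -1 for unassigned)")
  }
  structure(list(points = points, labels = labels, instances = instances),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points", nrow(x$points)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat(sprintf(" [%s]", paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  }
  if (!is.null(x$instances))
    cat(sprintf(", %d organ instance(s)", length(unique(x$instances[x$instances > 0]))))
  cat("\n")
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

# label <-> integer code used in files (0 = stem, 1 = leaf)
.label_to_int <- function(labels) ifelse(labels == "stem", 0L, 1L)
.int_to_label <- function(codes) ifelse(codes == 0L, "stem", "leaf")

.guess_format <- function(path) {
  if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
}

#' Read a point cloud from disk
#'
#' Supports PLY (ASCII and binary little-endian) and whitespace-separated XYZ.
#' The XYZ dialect accepts optional 4th and 5th integer columns holding the
#' semantic class code (0 = stem, 1 = leaf) and the organ instance id. PLY
#' vertex properties named `semantic`/`label`/`class` and
#' `instance`/`organ` are mapped to labels and instance ids.
#'
#' @param path file to read.
#' @param format `"ply"`, `"xyz"`, or `"auto"` (from the file extension).
#' @return a [point_cloud()].
#' @export
read_point_cloud <- function(path, format = c("auto", "ply", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .guess_format(path)
  cloud <- if (format == "ply") .read_ply(path) else .read_xyz(path)
  if (n_points(cloud) == 0) stop("empty point cloud in ", path)
  cloud
}

#' Write a point cloud to disk
#'
#' @param cloud a [point_cloud()]; must be non-empty.
#' @param path output file.
#' @param format `"ply"`, `"xyz"`, or `"auto"`; PLY is written in ASCII unless
#'   `binary = TRUE`.
#' @param binary write binary little-endian PLY instead of ASCII.
#' @return invisibly, `path`.
#' @export
write_point_cloud <- function(cloud, path, format = c("auto", "ply", "xyz"),
                              binary = FALSE) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (n_points(cloud) == 0) stop("refusing to write an empty point cloud")
  if (format == "ply") .write_ply(cloud, path, binary) else .write_xyz(cloud, path)
  invisible(path)
}

.read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty point cloud in ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("parse error in ", path, " at line ", which(nf < 3)[1],
         ": expected at least 3 columns")
  }
  ncol_use <- min(nf)
  vals <- vapply(fields, function(f) suppressWarnings(as.numeric(f[seq_len(ncol_use)])),
                 numeric(ncol_use))
  vals <- if (ncol_use == 1) matrix(vals, ncol = 1) else t(vals)
  if (anyNA(vals)) {
    stop("parse error in ", path, " at line ", which(apply(is.na(vals), 1, any))[1],
         ": non-numeric field")
  }
  labels <- if (ncol_use >= 4) .int_to_label(as.integer(vals[, 4])) else NULL
  instances <- if (ncol_use >= 5) as.integer(vals[, 5]) else NULL
  point_cloud(vals[, 1:3, drop = FALSE], labels, instances)
}

.write_xyz <- function(cloud, path) {
  m <- cloud$points
  out <- cbind(m,
               if (!is.null(cloud$labels)) .label_to_int(cloud$labels),
               if (!is.null(cloud$instances)) cloud$instances)
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
}

# --- PLY ---------------------------------------------------------------------

.ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                    short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                    int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply")) stop("parse error in ", path, " at line 1: not a PLY file")
  fmt <- NULL; nvert <- NULL
  props <- character(); ptypes <- character()
  lineno <- 1L; in_vertex <- FALSE
  repeat {
    ln <- readLines(con, n = 1)
    lineno <- lineno + 1L
    if (length(ln) == 0) stop("parse error in ", path, ": header not terminated")
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0) next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      in_vertex <- identical(tok[2], "vertex")
      if (in_vertex) nvert <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex) {
      if (identical(tok[2], "list"))
        stop("parse error in ", path, " at line ", lineno, ": list property on vertex")
      ptypes <- c(ptypes, tok[2]); props <- c(props, tok[3])
    } else if (tok[1] == "end_header") break
  }
  if (is.null(fmt) || is.null(nvert))
    stop("parse error in ", path, ": missing format or vertex element")
  if (!all(ptypes %in% names(.ply_type_size)))
    stop("parse error in ", path, ": unknown property type ",
         ptypes[!ptypes %in% names(.ply_type_size)][1])
  np <- length(props)
  if (fmt == "ascii") {
    vals <- matrix(NA_real_, nvert, np)
    for (i in seq_len(nvert)) {
      ln <- readLines(con, n = 1)
      lineno <- lineno + 1L
      if (length(ln) == 0) stop("parse error in ", path, ": truncated at vertex ", i)
      f <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (length(f) < np || anyNA(f[seq_len(np)]))
        stop("parse error in ", path, " at line ", lineno, ": bad vertex record")
      vals[i, ] <- f[seq_len(np)]
    }
  } else if (fmt == "binary_little_endian") {
    sizes <- .ply_type_size[ptypes]
    raw <- readBin(con, "raw", n = nvert * sum(sizes))
    if (length(raw) < nvert * sum(sizes)) stop("parse error in ", path, ": truncated binary data")
    vals <- matrix(NA_real_, nvert, np)
    offs <- cumsum(c(0L, sizes))
    rec <- sum(sizes)
    for (j in seq_len(np)) {
      sel <- as.vector(outer(seq_len(sizes[j]), (seq_len(nvert) - 1L) * rec + offs[j], "+"))
      bytes <- raw[sel]
      what <- if (ptypes[j] %in% c("float", "float32", "double", "float64")) "double" else "integer"
      vals[, j] <- readBin(bytes, what, n = nvert, size = sizes[j],
                           endian = "little",
                           signed = !(ptypes[j] %in% c("uchar", "uint8", "ushort", "uint16")))
    }
  } else stop("parse error in ", path, ": unsupported PLY format '", fmt, "'")
  need <- c("x", "y", "z")
  if (!all(need %in% props)) stop("parse error in ", path, ": missing x/y/z properties")
  pts <- vals[, match(need, props), drop = FALSE]
  labcol <- intersect(c("semantic", "label", "class"), props)
  inscol <- intersect(c("instance", "organ", "instance_id"), props)
  labels <- if (length(labcol)) .int_to_label(as.integer(vals[, match(labcol[1], props)])) else NULL
  instances <- if (length(inscol)) as.integer(vals[, match(inscol[1], props)]) else NULL
  point_cloud(pts, labels, instances)
}

.write_ply <- function(cloud, path, binary = FALSE) {
  n <- n_points(cloud)
  has_lab <- !is.null(cloud$labels)
  has_ins <- !is.null(cloud$instances)
  hdr <- c("ply",
           sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
           "comment plantreg4d point cloud",
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z",
           if (has_lab) "property int semantic",
           if (has_ins) "property int instance",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (binary) {
    lab <- if (has_lab) .label_to_int(cloud$labels) else NULL
    for (i in seq_len(n)) {
      writeBin(as.double(cloud$points[i, ]), con, size = 8, endian = "little")
      if (has_lab) writeBin(as.integer(lab[i]), con, size = 4, endian = "little")
      if (has_ins) writeBin(as.integer(cloud$instances[i]), con, size = 4, endian = "little")
    }
  } else {
    body <- apply(format(cloud$points, digits = 17, trim = TRUE, scientific = FALSE),
                  1, paste, collapse = " ")
    if (has_lab) body <- paste(body, .label_to_int(cloud$labels))
    if (has_ins) body <- paste(body, cloud$instances)
    writeLines(body, con)
  }
}
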