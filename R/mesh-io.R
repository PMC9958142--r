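## Mesh input/output: PLY (ASCII + binary little-endian), STL (ASCII +
## binary), OBJ (v/f records). Coordinates are mm; vertex order is preserved
## for PLY/OBJ because downstream correspondence is index-based. STL has no
## vertex identity, so reading STL merges coincident vertices at 1e-8 mm.
## Per-vertex scalar properties: "region" (integer-coded anatomical tag) and
## "distance" (floating-point, mm). Face indices are 0-based internally.

.plyTypeSize <- c(char = 1L, uchar = 1L, uint8 = 1L, int8 = 1L,
                  short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                  int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                  float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.plyIsFloat <- function(type) type %in% c("float", "float32", "double",
                                          "float64")

.regionToInt <- function(labels) {
  i <- match(labels, REGION_LEVELS)
  i[is.na(i)] <- match("other", REGION_LEVELS)
  i - 1L
}

.intToRegion <- function(codes) {
  codes <- as.integer(codes)
  codes[codes < 0L | codes >= length(REGION_LEVELS)] <-
    match("other", REGION_LEVELS) - 1L
  REGION_LEVELS[codes + 1L]
}

#' Read a shape from a mesh file
#'
#' Supported formats: PLY (ASCII and binary little-endian), STL (ASCII and
#' binary) and OBJ (\code{v}/\code{f} records). PLY and OBJ preserve vertex
#' order exactly; STL carries no vertex identity, so coincident vertices are
#' merged at a 1e-8 mm tolerance. A per-vertex integer property named
#' \code{region} is decoded into anatomical region labels; a floating
#' property named \code{distance} is attached as the \code{overlay}
#' attribute.
#'
#' @param path file to read.
#' @param format one of \code{"ply"}, \code{"stl"}, \code{"obj"},
#'   \code{"auto"} (by extension).
#' @return a \linkS4class{TriMesh} when faces are present, else a
#'   \linkS4class{PointSet}. Any \code{distance} overlay is attached as
#'   \code{attr(x, "overlay")}.
#' @seealso \code{\link{writeShape}}, \code{\link{writeScalarOverlay}}
#' @export
readShape <- function(path, format = c("auto", "ply", "stl", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "stl", "obj"))
      stop("cannot infer format from extension '", ext, "'")
    format <- ext
  }
  res <- switch(format,
                ply = .readPLY(path),
                stl = .readSTL(path),
                obj = .readOBJ(path))
  if (nrow(res$points) == 0L)
    stop("empty geometry in ", path)
  id <- tools::file_path_sans_ext(basename(path))
  shape <- if (nrow(res$faces)) {
    triMesh(res$points, res$faces, labels = res$labels, id = id)
  } else {
    pointSet(res$points, labels = res$labels, id = id)
  }
  if (!is.null(res$overlay)) attr(shape, "overlay") <- res$overlay
  shape
}

#' Write a shape to a mesh file
#'
#' PLY output carries faces (if any), the \code{region} integer property when
#' the shape is labelled, and round-trips coordinates through
#' \code{\link{readShape}} to better than 1e-6 mm. OBJ writes \code{v}/
#' \code{f} records; STL requires faces and stores no vertex identity.
#'
#' @param shape a \linkS4class{PointSet} or \linkS4class{TriMesh}.
#' @param path output file.
#' @param format \code{"ply"}, \code{"stl"} or \code{"obj"} (default from
#'   extension).
#' @param binary write the binary dialect (PLY little-endian / binary STL).
#' @return \code{path}, invisibly.
#' @export
writeShape <- function(shape, path, format = c("auto", "ply", "stl", "obj"),
                       binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "stl", "obj"))
      stop("cannot infer format from extension '", ext, "'")
    format <- ext
  }
  validObject(shape)
  pts <- shapePoints(shape)
  faces <- if (is(shape, "TriMesh")) meshFaces(shape) else
    matrix(integer(0), 0L, 3L)
  labels <- regionLabels(shape)
  switch(format,
         ply = .writePLY(path, pts, faces, labels = labels, binary = binary),
         stl = .writeSTL(path, pts, faces, binary = binary),
         obj = .writeOBJ(path, pts, faces))
  invisible(path)
}

#' Write a per-vertex scalar overlay (distance map) as PLY
#'
#' Writes the mesh with a per-vertex floating-point property named
#' \code{distance} (mm). Values round-trip through \code{\link{readShape}}
#' to better than 1e-6.
#'
#' @param mesh a \linkS4class{TriMesh} or \linkS4class{PointSet}.
#' @param values one finite scalar per point (mm).
#' @param path output PLY file.
#' @param binary write binary little-endian PLY.
#' @return \code{path}, invisibly.
#' @export
writeScalarOverlay <- function(mesh, values, path, binary = FALSE) {
  pts <- shapePoints(mesh)
  if (length(values) != nrow(pts))
    stop("values must have exactly one entry per point")
  if (!all(is.finite(values)))
    stop("overlay values must be finite")
  faces <- if (is(mesh, "TriMesh")) meshFaces(mesh) else
    matrix(integer(0), 0L, 3L)
  .writePLY(path, pts, faces, labels = regionLabels(mesh),
            overlay = as.numeric(values), binary = binary)
  invisible(path)
}

## ---------------------------------------------------------------- PLY ----

.writePLY <- function(path, pts, faces, labels = NULL, overlay = NULL,
                      binary = FALSE) {
  n <- nrow(pts); f <- nrow(faces)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0"
           else "format ascii 1.0",
           "comment pedicleSSM",
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z",
           if (!is.null(labels)) "property int region",
           if (!is.null(overlay)) "property double distance",
           sprintf("element face %d", f),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  vcols <- cbind(pts,
                 if (!is.null(labels)) .regionToInt(labels),
                 if (!is.null(overlay)) overlay)
  if (binary) {
    ncolv <- ncol(vcols)
    hasRegion <- !is.null(labels)
    for (i in seq_len(n)) {
      writeBin(as.numeric(pts[i, ]), con, size = 8L, endian = "little")
      if (hasRegion)
        writeBin(as.integer(.regionToInt(labels[i])), con, size = 4L,
                 endian = "little")
      if (!is.null(overlay))
        writeBin(as.numeric(overlay[i]), con, size = 8L, endian = "little")
    }
    if (f) for (i in seq_len(f)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(faces[i, ]), con, size = 4L, endian = "little")
    }
  } else {
    fmt <- paste(rep("%.17g", 3L), collapse = " ")
    lines <- sprintf(fmt, vcols[, 1L], vcols[, 2L], vcols[, 3L])
    k <- 4L
    if (!is.null(labels)) {
      lines <- paste(lines, sprintf("%d", as.integer(vcols[, k])))
      k <- k + 1L
    }
    if (!is.null(overlay))
      lines <- paste(lines, sprintf("%.17g", vcols[, k]))
    writeLines(lines, con, sep = "\n")
    if (f)
      writeLines(sprintf("3 %d %d %d", faces[, 1L], faces[, 2L],
                         faces[, 3L]), con, sep = "\n")
  }
  path
}

.readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  line <- readLines(con, n = 1L)
  if (!length(line) || trimws(line) != "ply")
    stop("not a PLY file (missing 'ply' magic): ", path)
  fmt <- NULL
  elements <- list()   # list of list(name, count, props=list(name,type,list))
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("PLY header truncated before end_header: ", path)
    tk <- strsplit(trimws(line), "\\s+")[[1L]]
    if (!length(tk) || tk[1L] == "comment") next
    if (tk[1L] == "format") {
      fmt <- tk[2L]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop("unsupported PLY format dialect '", fmt, "' in ", path)
    } else if (tk[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tk[2L], count = as.integer(tk[3L]), props = list())
    } else if (tk[1L] == "property") {
      if (is.null(cur)) stop("PLY property before element in ", path)
      if (tk[2L] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tk[5L], type = tk[4L], countType = tk[3L],
               list = TRUE)
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tk[3L], type = tk[2L], list = FALSE)
      }
    } else if (tk[1L] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    } else {
      stop("unrecognised PLY header line: '", line, "' in ", path)
    }
  }
  if (is.null(elements$vertex)) stop("PLY has no vertex element: ", path)
  readers <- if (fmt == "ascii") .readPLYAscii(con, elements, path)
             else .readPLYBinary(con, elements, path)
  vdat <- readers$vertex
  need <- c("x", "y", "z")
  if (!all(need %in% names(vdat)))
    stop("PLY vertex element lacks x/y/z properties: ", path)
  pts <- cbind(vdat$x, vdat$y, vdat$z)
  labels <- if (!is.null(vdat$region)) .intToRegion(vdat$region) else
    character(0)
  overlay <- vdat$distance
  faces <- readers$faces
  list(points = pts, faces = faces, labels = labels, overlay = overlay)
}

.readPLYAscii <- function(con, elements, path) {
  out <- list(faces = matrix(integer(0), 0L, 3L))
  for (el in elements) {
    if (el$count == 0L) next
    lines <- readLines(con, n = el$count)
    if (length(lines) < el$count)
      stop("PLY element '", el$name, "' truncated in ", path)
    if (any(vapply(el$props, `[[`, TRUE, "list"))) {
      ## list element (faces): parse row-wise
      fl <- lapply(strsplit(trimws(lines), "\\s+"), function(tk) {
        cnt <- as.integer(tk[1L])
        if (is.na(cnt) || length(tk) < 1L + cnt)
          stop("malformed PLY list line '", paste(tk, collapse = " "),
               "' in ", path)
        as.integer(tk[2L:(1L + cnt)])
      })
      tri <- do.call(rbind, lapply(fl, .fanTriangulate))
      if (el$name == "face") out$faces <- tri
    } else {
      toks <- strsplit(trimws(lines), "\\s+")
      np <- length(el$props)
      bad <- which(lengths(toks) < np)
      if (length(bad))
        stop("malformed PLY vertex line ", bad[1L], " in ", path)
      M <- suppressWarnings(
        matrix(as.numeric(unlist(toks)), ncol = length(toks[[1L]]),
               byrow = TRUE))
      if (any(is.na(M)))
        stop("non-numeric PLY vertex data in ", path)
      dat <- lapply(seq_len(np), function(j) M[, j])
      names(dat) <- vapply(el$props, `[[`, "", "name")
      out[[el$name]] <- dat
    }
  }
  out
}

.readPLYBinary <- function(con, elements, path) {
  out <- list(faces = matrix(integer(0), 0L, 3L))
  for (el in elements) {
    if (el$count == 0L) next
    if (any(vapply(el$props, `[[`, TRUE, "list"))) {
      tris <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        p <- el$props[[1L]]
        cnt <- .readScalar(con, p$countType, path)
        idx <- .readN(con, p$type, cnt, path)
        tris[[i]] <- .fanTriangulate(as.integer(idx))
      }
      if (el$name == "face") out$faces <- do.call(rbind, tris)
    } else {
      sizes <- .plyTypeSize[vapply(el$props, `[[`, "", "type")]
      if (any(is.na(sizes)))
        stop("unknown PLY property type in ", path)
      rec <- sum(sizes)
      raw <- readBin(con, "raw", n = rec * el$count)
      if (length(raw) < rec * el$count)
        stop("PLY element '", el$name, "' truncated in ", path)
      dat <- vector("list", length(el$props))
      off <- 0L
      for (j in seq_along(el$props)) {
        p <- el$props[[j]]
        sz <- .plyTypeSize[[p$type]]
        pos <- as.vector(outer(seq_len(sz), (seq_len(el$count) - 1L) * rec,
                               "+")) + off
        dat[[j]] <- .decodeRaw(raw[pos], p$type, el$count)
        off <- off + sz
      }
      names(dat) <- vapply(el$props, `[[`, "", "name")
      out[[el$name]] <- dat
    }
  }
  out
}

.fanTriangulate <- function(idx) {
  if (length(idx) < 3L) stop("PLY face with fewer than 3 vertices")
  if (length(idx) == 3L) return(matrix(idx, 1L, 3L))
  cbind(idx[1L], idx[2L:(length(idx) - 1L)], idx[3L:length(idx)])
}

.decodeRaw <- function(raw, type, n) {
  switch(type,
         float = , float32 = readBin(raw, "double", n = n, size = 4L,
                                     endian = "little"),
         double = , float64 = readBin(raw, "double", n = n, size = 8L,
                                      endian = "little"),
         char = , int8 = readBin(raw, "integer", n = n, size = 1L,
                                 signed = TRUE, endian = "little"),
         uchar = , uint8 = readBin(raw, "integer", n = n, size = 1L,
                                   signed = FALSE, endian = "little"),
         short = , int16 = readBin(raw, "integer", n = n, size = 2L,
                                   signed = TRUE, endian = "little"),
         ushort = , uint16 = readBin(raw, "integer", n = n, size = 2L,
                                     signed = FALSE, endian = "little"),
         int = , int32 = , uint = , uint32 =
           readBin(raw, "integer", n = n, size = 4L, endian = "little"),
         stop("unknown PLY type ", type))
}

.readScalar <- function(con, type, path) {
  sz <- .plyTypeSize[[type]]
  raw <- readBin(con, "raw", n = sz)
  if (length(raw) < sz) stop("PLY binary data truncated in ", path)
  .decodeRaw(raw, type, 1L)
}

.readN <- function(con, type, n, path) {
  sz <- .plyTypeSize[[type]]
  raw <- readBin(con, "raw", n = sz * n)
  if (length(raw) < sz * n) stop("PLY binary data truncated in ", path)
  .decodeRaw(raw, type, n)
}

## ---------------------------------------------------------------- STL ----

.writeSTL <- function(path, pts, faces, binary = FALSE) {
  if (!nrow(faces))
    stop("STL requires faces; write a PLY/OBJ point cloud instead")
  f <- faces + 1L
  v1 <- pts[f[, 1L], , drop = FALSE]
  v2 <- pts[f[, 2L], , drop = FALSE]
  v3 <- pts[f[, 3L], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(faces)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(faces))) {
      writeBin(as.numeric(c(nrm[i, ], v1[i, ], v2[i, ], v3[i, ])), con,
               size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid shape", con)
    for (i in seq_len(nrow(faces))) {
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g",
                           nrm[i, 1], nrm[i, 2], nrm[i, 3]),
                   "    outer loop",
                   sprintf("      vertex %.17g %.17g %.17g",
                           c(v1[i, 1], v2[i, 1], v3[i, 1]),
                           c(v1[i, 2], v2[i, 2], v3[i, 2]),
                           c(v1[i, 3], v2[i, 3], v3[i, 3])),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid shape", con)
  }
  path
}

.readSTL <- function(path) {
  head <- readBin(path, "raw", n = 512L)
  printable <- head[head >= as.raw(9L) & head <= as.raw(126L)]
  txt <- rawToChar(printable)
  isAscii <- grepl("^\\s*solid", txt) && grepl("facet", txt)
  tri <- if (isAscii) .readSTLAscii(path) else .readSTLBinary(path)
  if (!nrow(tri)) stop("empty geometry in ", path)
  ## merge coincident vertices at 1e-8 mm (STL stores no vertex identity)
  key <- apply(round(tri / 1e-8), 1L, paste, collapse = ",")
  uniq <- !duplicated(key)
  pts <- tri[uniq, , drop = FALSE]
  map <- match(key, key[uniq])
  faces <- matrix(map - 1L, ncol = 3L, byrow = TRUE)
  keep <- faces[, 1L] != faces[, 2L] & faces[, 1L] != faces[, 3L] &
    faces[, 2L] != faces[, 3L]
  list(points = pts, faces = faces[keep, , drop = FALSE],
       labels = character(0), overlay = NULL)
}

.readSTLAscii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vidx <- grep("^\\s*vertex\\s", lines)
  if (length(vidx) %% 3L != 0L)
    stop("ASCII STL with vertex count not a multiple of 3 (line ",
         if (length(vidx)) vidx[length(vidx)] else 0L, "): ", path)
  toks <- strsplit(trimws(lines[vidx]), "\\s+")
  M <- matrix(NA_real_, length(vidx), 3L)
  for (i in seq_along(toks)) {
    v <- suppressWarnings(as.numeric(toks[[i]][2:4]))
    if (any(is.na(v)))
      stop("malformed STL vertex at line ", vidx[i], ": ", path)
    M[i, ] <- v
  }
  M
}

.readSTLBinary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (!length(nf) || is.na(nf) || nf < 0L)
    stop("malformed binary STL header: ", path)
  raw <- readBin(con, "raw", n = 50L * nf)
  if (length(raw) < 50L * nf)
    stop("binary STL truncated (expected ", nf, " facets): ", path)
  M <- matrix(NA_real_, 3L * nf, 3L)
  for (i in seq_len(nf)) {
    rec <- raw[((i - 1L) * 50L + 1L):(i * 50L)]
    vals <- readBin(rec[13:48], "double", n = 9L, size = 4L,
                    endian = "little")
    M[(3L * i - 2L):(3L * i), ] <- matrix(vals, 3L, 3L, byrow = TRUE)
  }
  M
}

## ---------------------------------------------------------------- OBJ ----

.writeOBJ <- function(path, pts, faces) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g", pts[, 1L], pts[, 2L],
                     pts[, 3L]), con)
  if (nrow(faces))
    writeLines(sprintf("f %d %d %d", faces[, 1L] + 1L, faces[, 2L] + 1L,
                       faces[, 3L] + 1L), con)
  path
}

.readOBJ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vsel <- grep("^v\\s", lines)
  fsel <- grep("^f\\s", lines)
  pts <- matrix(numeric(0), 0L, 3L)
  if (length(vsel)) {
    toks <- strsplit(trimws(lines[vsel]), "\\s+")
    pts <- matrix(NA_real_, length(vsel), 3L)
    for (i in seq_along(toks)) {
      v <- suppressWarnings(as.numeric(toks[[i]][2:4]))
      if (any(is.na(v)))
        stop("malformed OBJ vertex at line ", vsel[i], ": ", path)
      pts[i, ] <- v
    }
  }
  faces <- matrix(integer(0), 0L, 3L)
  if (length(fsel)) {
    fl <- lapply(seq_along(fsel), function(k) {
      tk <- strsplit(trimws(lines[fsel[k]]), "\\s+")[[1L]][-1L]
      idx <- suppressWarnings(as.integer(sub("/.*$", "", tk)))
      if (any(is.na(idx)) || length(idx) < 3L)
        stop("malformed OBJ face at line ", fsel[k], ": ", path)
      .fanTriangulate(idx - 1L)
    })
    faces <- do.call(rbind, fl)
  }
  list(points = pts, faces = faces, labels = character(0), overlay = NULL)
}
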