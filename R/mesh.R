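#' Triangle surface mesh in mm
#'
#' @param vertices `n x 3` numeric matrix of vertex positions, mm.
#' @param faces `m x 3` integer matrix of 1-based vertex indices.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) stop("vertices must be n x 3")
  if (nrow(faces) > 0 && ncol(faces) != 3) stop("faces must be m x 3")
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, area %.2f mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Total surface area of a triangle mesh
#'
#' Sum over faces of half the cross-product magnitude of two edge vectors.
#'
#' @param mesh a [triangle_mesh()].
#' @return area in mm^2 (0 for an empty face list).
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  sum(.face_areas(mesh))
}

.face_areas <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(numeric(0))
  v0 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  e1 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE] - v0
  e2 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE] - v0
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# outward unit face normals (direction as stored: right-hand rule)
.face_normals <- function(mesh) {
  v0 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  e1 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE] - v0
  e2 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE] - v0
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

#' Weld duplicate vertices and drop degenerate faces
#'
#' @param mesh a [triangle_mesh()].
#' @param area_tol faces with area below this are removed (mm^2).
#' @return a cleaned [triangle_mesh()].
#' @export
clean_mesh <- function(mesh, area_tol = 1e-12) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$vertices) == 0) return(mesh)
  key <- paste(mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3],
               sep = "\r")
  first <- !duplicated(key)
  remap <- match(key, key[first])
  new_v <- mesh$vertices[first, , drop = FALSE]
  new_f <- matrix(remap[mesh$faces], ncol = 3)
  # drop faces with repeated vertices or ~zero area
  ok <- new_f[, 1] != new_f[, 2] & new_f[, 2] != new_f[, 3] &
    new_f[, 1] != new_f[, 3]
  m <- triangle_mesh(new_v, new_f[ok, , drop = FALSE])
  m$faces <- m$faces[.face_areas(m) > area_tol, , drop = FALSE]
  m
}

#' Extract the bone surface from a binary mask
#'
#' Isosurface of the binary field at level 0.5, computed on a grid padded by
#' one empty voxel layer so bone touching the volume border still closes.
#' Cells are decomposed into six tetrahedra around a fixed diagonal and each
#' level-crossing tetrahedron contributes its midpoint triangles; the
#' decomposition is identical on both sides of every shared cell face, so
#' the extracted surface of a solid blob is watertight. Vertex coordinates
#' are scaled to mm by the voxel spacing, consistent with voxel centres at
#' `(index - 1) * spacing`.
#'
#' @param mask a [bone_mask()] with at least one true voxel.
#' @return a cleaned [triangle_mesh()] with outward-oriented faces.
#' @export
extract_surface <- function(mask) {
  stopifnot(inherits(mask, "bone_mask"))
  if (!any(mask$values)) stop("empty mask: nothing to extract")
  d <- dim(mask$values)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask$values
  raw <- .cpp_isosurface(as.vector(padded), as.integer(dim(padded)))
  verts <- sweep(raw$vertices - 1, 2, mask$spacing, "*")
  clean_mesh(triangle_mesh(verts, raw$faces))
}

#' Write a triangle mesh as STL
#'
#' Binary STL: 80-byte header, uint32 triangle count, then one 50-byte
#' record per face (float32 normal, three float32 vertices, uint16
#' attribute). ASCII STL uses the `solid`/`facet` grammar. STL itself is
#' unit-less; this package fixes mm throughout.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file.
#' @param format `"binary"` or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, format = c("binary", "ascii")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- match.arg(format)
  nf <- nrow(mesh$faces)
  normals <- if (nf > 0) .face_normals(mesh) else matrix(0, 0, 3)
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "orbfloor mesh (mm)"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    if (nf > 0) {
      # 50-byte records: 12 float32 (normal, v1, v2, v3) + uint16 attribute
      rec <- rbind(t(normals), t(v1), t(v2), t(v3))   # 12 x nf
      fbytes <- writeBin(as.numeric(rec), raw(), size = 4, endian = "little")
      out <- matrix(as.raw(0), nrow = 50, ncol = nf)
      out[1:48, ] <- matrix(fbytes, nrow = 48)
      writeBin(as.vector(out), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid orbfloor", con)
    if (nf > 0) {
      txt <- sprintf(
        paste0("facet normal %.9g %.9g %.9g\n outer loop\n",
               "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
               "  vertex %.9g %.9g %.9g\n endloop\nendfacet"),
        normals[, 1], normals[, 2], normals[, 3],
        v1[, 1], v1[, 2], v1[, 3],
        v2[, 1], v2[, 2], v2[, 3],
        v3[, 1], v3[, 2], v3[, 3])
      writeLines(txt, con)
    }
    writeLines("endsolid orbfloor", con)
  }
  invisible(path)
}

#' Read an STL file (binary or ASCII)
#'
#' Format is detected from the file: a file is binary when its size matches
#' the `84 + 50 * n` record layout for the triangle count in its header;
#' otherwise it must parse as ASCII. Per-facet vertices are welded into a
#' shared vertex list.
#'
#' @param path STL file.
#' @return a [triangle_mesh()].
#' @export
read_stl <- function(path) {
  size <- file.info(path)$size
  if (is.na(size) || size < 15) stop("malformed STL: file too small")
  is_binary <- FALSE
  if (size >= 84) {
    con <- file(path, "rb")
    seek(con, 80)
    nf <- readBin(con, "integer", size = 4, endian = "little")
    close(con)
    if (!is.na(nf) && nf >= 0 && size == 84 + 50 * as.numeric(nf))
      is_binary <- TRUE
  }
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, 80)
    nf <- readBin(con, "integer", size = 4, endian = "little")
    if (nf == 0) return(triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
    body <- readBin(con, "raw", n = 50 * nf)
    if (length(body) < 50 * nf)
      stop("malformed binary STL: truncated record at byte ",
           84 + length(body))
    rec <- matrix(body, nrow = 50)
    vals <- readBin(as.vector(rec[1:48, ]), "numeric", n = 12 * nf,
                    size = 4, endian = "little")
    tri <- matrix(vals, nrow = 12)[4:12, , drop = FALSE]
    verts <- t(matrix(tri, 3))
  } else {
    lines <- readLines(path, warn = FALSE)
    if (!any(grepl("^\\s*solid", lines[1])))
      stop("malformed STL: neither binary layout nor ASCII 'solid' header ",
           "(byte 0)")
    vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vlines) %% 3 != 0)
      stop("malformed ASCII STL: vertex count ", length(vlines),
           " not a multiple of 3")
    nums <- lapply(strsplit(trimws(vlines), "\\s+"), function(tok) {
      x <- suppressWarnings(as.numeric(tok[2:4]))
      if (any(is.na(x))) stop("malformed ASCII STL vertex line: ",
                              paste(tok, collapse = " "))
      x
    })
    verts <- do.call(rbind, nums)
  }
  if (nrow(verts) == 0) return(triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  clean_mesh(triangle_mesh(verts, faces), area_tol = 0)
}
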