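#' Triangle surface mesh
#'
#' Container for a triangulated surface. Vertex correspondence between two
#' meshes (template and injected target) is carried purely by vertex order;
#' there is no per-vertex identifier.
#'
#' @param vertices n x 3 numeric matrix of coordinates in mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class \code{surface_mesh}.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = ncol(as.matrix(faces)))
  if (nrow(vertices) < 4L) stop("mesh needs at least 4 vertices")
  if (ncol(vertices) != 3L) stop("'vertices' must be n x 3")
  if (ncol(faces) != 3L) stop("only triangle faces are supported")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
          faces[, 2] == faces[, 3]))
    stop("degenerate (repeated-index) triangle in faces")
  structure(list(vertices = unname(vertices), faces = unname(faces)),
            class = "surface_mesh")
}

#' @method print surface_mesh
#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Read a triangle mesh (ASCII PLY or OBJ)
#'
#' The format is chosen by file extension. Only triangle faces are accepted;
#' a quad or polygon face is an error. Vertex order is preserved exactly,
#' since downstream correspondence relies on it.
#'
#' @param path path to a .ply (ASCII) or .obj file.
#' @return A \code{\link{surface_mesh}}.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         obj = read_obj(path),
         stop("unsupported mesh format '.", ext, "' (use .ply or .obj)"))
}

#' Write a triangle mesh (ASCII PLY or OBJ)
#'
#' Round-trips with \code{\link{read_mesh}}: vertex order and coordinates are
#' preserved (coordinates printed with 9 significant digits, well below the
#' 1e-6 mm contract).
#'
#' @param mesh a \code{\link{surface_mesh}}.
#' @param path output path ending in .ply or .obj.
#' @return \code{path}, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$faces
  if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(v)),
             "property float x", "property float y", "property float z",
             paste("element face", nrow(f)),
             "property list uchar int vertex_indices",
             "end_header")
    vl <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
    fl <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
    writeLines(c(hdr, vl, fl), path)
  } else if (ext == "obj") {
    vl <- sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
    fl <- sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
    writeLines(c(vl, fl), path)
  } else stop("unsupported mesh format '.", ext, "'")
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  if (!grepl("ascii", lines[2]))
    stop("only ASCII PLY is supported: ", path)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("PLY header not terminated")
  hdr <- trimws(lines[seq_len(endh)])
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr,
                                                   value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face ", hdr,
                                                 value = TRUE)[1]))
  if (is.na(nv) || nv == 0L) stop("PLY has no vertices")
  body <- lines[(endh + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vtx <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                               function(x) as.numeric(x[1:3])))
  fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  cnt <- vapply(fl, function(x) as.integer(x[1]), integer(1))
  if (any(cnt != 3L)) stop("non-triangle face in PLY (", cnt[cnt != 3L][1],
                           " vertices)")
  fc <- do.call(rbind, lapply(fl, function(x) as.integer(x[2:4]) + 1L))
  surface_mesh(vtx, fc)
}

read_obj <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0L) stop("OBJ has no vertices")
  vtx <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                               function(x) as.numeric(x[2:4])))
  fparts <- strsplit(fl, "\\s+")
  if (any(lengths(fparts) != 4L)) stop("non-triangle face in OBJ")
  fc <- do.call(rbind, lapply(fparts, function(x)
    as.integer(sub("/.*", "", x[2:4]))))
  surface_mesh(vtx, fc)
}

#' Icosphere template mesh
#'
#' Generates a geodesic sphere by repeated midpoint subdivision of an
#' icosahedron, then scales to an ellipsoid. Used as the template shape of
#' the synthetic cohort and as an analytic test surface.
#'
#' @param subdiv number of subdivision rounds (0 gives 12 vertices; each
#'   round roughly quadruples the face count; 3 gives 642 vertices).
#' @param radius numeric length 1 or 3; (semi-)axes in mm.
#' @return A \code{\link{surface_mesh}} with unit-direction vertices scaled
#'   by \code{radius}.
#' @export
icosphere <- function(subdiv = 3L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mid <- new.env(hash = TRUE)
    newv <- list()
    get_mid <- function(a, b) {
      k <- edge_key(a, b)
      if (!is.null(mid[[k]])) return(mid[[k]])
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1L]] <<- p
      idx <- nrow(v) + length(newv)
      mid[[k]] <- idx
      idx
    }
    newf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, c3); ca <- get_mid(c3, a)
      newf[4 * i - 3, ] <- c(a, ab, ca)
      newf[4 * i - 2, ] <- c(b, bc, ab)
      newf[4 * i - 1, ] <- c(c3, ca, bc)
      newf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  radius <- rep_len(radius, 3L)
  surface_mesh(sweep(v, 2L, radius, "*"), f)
}

#' Per-vertex outward normals
#'
#' Area-weighted average of incident face normals, normalised to unit
#' length. Face winding is assumed counter-clockwise seen from outside
#' (true for \code{\link{icosphere}} and meshes derived from it).
#'
#' @param mesh a \code{\link{surface_mesh}}.
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  vn <- matrix(0, nrow(v), 3L)
  for (k in 1:3) {
    agg <- rowsum(fn, group = f[, k])
    idx <- as.integer(rownames(agg))
    vn[idx, ] <- vn[idx, ] + agg
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}
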