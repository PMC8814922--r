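# Triangulated scalp meshes: construction from a head volume, plain-text
# OBJ/PLY I/O, nearest-vertex queries, and area-weighted vertex normals.

#' Construct a head model
#'
#' A triangulated scalp surface plus the three fiducial landmarks used to
#' build the NLR frame.
#'
#' @param vertices n x 3 numeric matrix of mm coordinates.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param landmarks optional `landmark_set`.
#' @return An object of class `head_model`.
#' @export
head_model <- function(vertices, faces, landmarks = NULL) {
  vertices <- as.matrix(vertices); faces <- as.matrix(faces)
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = unname(vertices), faces = unname(faces),
                 landmarks = landmarks),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$landmarks)) ", with fiducials" else ""))
  invisible(x)
}

#' Nearest mesh vertex to a point
#'
#' @param mesh a `head_model`.
#' @param point numeric mm triple.
#' @return 1-based vertex index (ties broken by lowest index).
#' @export
nearest_vertex <- function(mesh, point) {
  if (nrow(mesh$vertices) == 0L) stop("mesh has no vertices")
  d2 <- rowSums(sweep(mesh$vertices, 2, as.numeric(point))^2)
  which.min(d2)
}

#' Outward vertex normal
#'
#' Area-weighted mean of the normals of the faces incident to the vertex,
#' normalized, and flipped if necessary so that it points away from the mesh
#' centroid.
#'
#' @param mesh a `head_model`.
#' @param vertex 1-based vertex index (must belong to at least one face).
#' @return Unit length-3 vector.
#' @export
vertex_normal <- function(mesh, vertex) {
  f <- mesh$faces
  inc <- which(f[, 1] == vertex | f[, 2] == vertex | f[, 3] == vertex)
  if (length(inc) == 0L) stop("isolated vertex: no incident faces")
  n <- c(0, 0, 0)
  for (i in inc) {
    v1 <- mesh$vertices[f[i, 1], ]; v2 <- mesh$vertices[f[i, 2], ]
    v3 <- mesh$vertices[f[i, 3], ]
    n <- n + .cross(v2 - v1, v3 - v1) / 2  # cross/2 = area-weighted normal
  }
  n <- .unit(n)
  outward <- mesh$vertices[vertex, ] - colMeans(mesh$vertices)
  if (sum(n * outward) < 0) n <- -n
  n
}

#' Total surface area of a mesh
#' @param mesh a `head_model`.
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) {
  f <- mesh$faces
  a <- 0
  for (i in seq_len(nrow(f))) {
    v1 <- mesh$vertices[f[i, 1], ]; v2 <- mesh$vertices[f[i, 2], ]
    v3 <- mesh$vertices[f[i, 3], ]
    a <- a + .norm3(.cross(v2 - v1, v3 - v1)) / 2
  }
  a
}

#' Uniform Laplacian mesh smoothing
#'
#' Each step moves every vertex a fraction `lambda` of the way toward the
#' mean of its edge-connected neighbours. A small `lambda` limits the
#' shrinkage uniform Laplacian smoothing induces on closed surfaces.
#'
#' @param mesh a `head_model`.
#' @param steps number of smoothing iterations.
#' @param lambda step size in (0, 1] (default 0.1).
#' @return The smoothed `head_model`.
#' @export
laplacian_smooth <- function(mesh, steps = 100, lambda = 0.1) {
  if (steps <= 0) return(mesh)
  nv <- nrow(mesh$vertices)
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  edges <- rbind(edges, edges[, 2:1])
  edges <- unique(edges)
  deg <- tabulate(edges[, 1], nbins = nv)
  V <- mesh$vertices
  for (s in seq_len(steps)) {
    acc <- matrix(0, nv, 3)
    acc[, 1] <- rowsum(V[edges[, 2], 1], edges[, 1], reorder = TRUE)
    acc[, 2] <- rowsum(V[edges[, 2], 2], edges[, 1], reorder = TRUE)
    acc[, 3] <- rowsum(V[edges[, 2], 3], edges[, 1], reorder = TRUE)
    mean_nb <- acc / deg
    V <- V + lambda * (mean_nb - V)
  }
  head_model(V, mesh$faces, mesh$landmarks)
}

#' Extract a head surface mesh from a volume
#'
#' Thresholds the volume into head/background, extracts the boundary
#' isosurface between foreground and background voxels (each exposed voxel
#' face contributes two triangles with outward orientation), and applies
#' uniform Laplacian smoothing. Vertex coordinates are in mm
#' (`(index - 1) * voxel_size`, face corners offset by half a voxel).
#'
#' @param volume `spatial_map` or 3D array (e.g. a masked T1 head image).
#' @param intensity_threshold voxels with values above this are head
#'   (default: midpoint between the volume's min and max).
#' @param smoothing_steps Laplacian smoothing iterations (default 100).
#' @param lambda smoothing step size (default 0.1).
#' @return A `head_model` (no landmarks attached).
#' @export
head_mesh_from_volume <- function(volume, intensity_threshold = NULL,
                                  smoothing_steps = 100, lambda = 0.1) {
  v <- .map_values(volume)
  vs <- if (inherits(volume, "spatial_map")) volume$voxel_size else c(1, 1, 1)
  if (is.null(intensity_threshold))
    intensity_threshold <- (min(v) + max(v)) / 2
  fg <- v > intensity_threshold
  if (!any(fg)) stop("no foreground voxels above the intensity threshold")
  mesh <- .boundary_mesh(fg, vs)
  laplacian_smooth(mesh, steps = smoothing_steps, lambda = lambda)
}

# Boundary-face ("cuberille") isosurface of a binary volume: for each
# foreground voxel face adjacent to background, emit the unit quad at the
# voxel boundary, split into two outward-oriented triangles. Vertices sit on
# the half-voxel lattice and are merged by exact key.
.boundary_mesh <- function(fg, voxel_size) {
  d <- dim(fg)
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  # corner offsets (in half-voxel units) for the exposed face in direction s,
  # ordered counter-clockwise seen from outside
  face_corners <- function(s) {
    if (all(s == c(1, 0, 0)))  return(rbind(c(1,-1,-1), c(1,1,-1), c(1,1,1), c(1,-1,1)))
    if (all(s == c(-1, 0, 0))) return(rbind(c(-1,-1,-1), c(-1,-1,1), c(-1,1,1), c(-1,1,-1)))
    if (all(s == c(0, 1, 0)))  return(rbind(c(-1,1,-1), c(-1,1,1), c(1,1,1), c(1,1,-1)))
    if (all(s == c(0, -1, 0))) return(rbind(c(-1,-1,-1), c(1,-1,-1), c(1,-1,1), c(-1,-1,1)))
    if (all(s == c(0, 0, 1)))  return(rbind(c(-1,-1,1), c(1,-1,1), c(1,1,1), c(-1,1,1)))
    rbind(c(-1,-1,-1), c(-1,1,-1), c(1,1,-1), c(1,-1,-1))
  }
  vert_key <- character(0)
  vert_env <- new.env(hash = TRUE, parent = emptyenv())
  verts <- list(); nverts <- 0L
  faces <- list(); nfaces <- 0L
  get_vid <- function(p) {  # p in half-voxel units (integer-valued * 1)
    key <- paste(p, collapse = ",")
    vid <- vert_env[[key]]
    if (is.null(vid)) {
      nverts <<- nverts + 1L
      vid <- nverts
      vert_env[[key]] <- vid
      verts[[vid]] <<- p
    }
    vid
  }
  idx <- which(fg)
  ai <- arrayInd(idx, d)
  for (k in seq_len(nrow(ai))) {
    p <- ai[k, ]
    for (s in dirs) {
      q <- p + s
      exposed <- any(q < 1) || any(q > d) || !fg[q[1], q[2], q[3]]
      if (!exposed) next
      fc <- face_corners(s)
      vids <- integer(4)
      for (j in 1:4) vids[j] <- get_vid(2 * (p - 1) + fc[j, ])
      faces[[nfaces + 1L]] <- vids[c(1, 2, 3)]
      faces[[nfaces + 2L]] <- vids[c(1, 3, 4)]
      nfaces <- nfaces + 2L
    }
  }
  V <- do.call(rbind, verts) / 2            # back to voxel units
  V <- sweep(V, 2, voxel_size, "*")         # mm, 0-based voxel convention
  Fm <- do.call(rbind, faces)
  head_model(V, Fm)
}

#' Read a triangulated mesh from OBJ or ASCII PLY
#'
#' @param path file path; format inferred from the extension.
#' @return A `head_model` (no landmarks).
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") .read_obj(path)
  else if (ext == "ply") .read_ply(path)
  else stop("unsupported mesh format: ", ext)
}

#' Write a mesh to OBJ or ASCII PLY
#'
#' @param mesh a `head_model`.
#' @param path output path; format inferred from the extension.
#' @return The path, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") .write_obj(mesh, path)
  else if (ext == "ply") .write_ply(mesh, path)
  else stop("unsupported mesh format: ", ext)
  invisible(path)
}

.read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  V <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
    as.numeric(x[2:4])))
  Fm <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
    as.integer(sub("/.*", "", x[2:4]))))
  head_model(V, Fm)
}

.write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

.read_ply <- function(path) {
  lines <- readLines(path)
  if (!grepl("^ply", lines[1])) stop("not a PLY file")
  hdr_end <- which(lines == "end_header")[1]
  nv <- as.integer(sub(".*vertex\\s+", "", grep("element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+", "", grep("element face", lines, value = TRUE)[1]))
  body <- lines[(hdr_end + 1):length(lines)]
  V <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  Fm <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                              function(x) as.integer(x[2:4]) + 1L))
  head_model(V, Fm)
}

.write_ply <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
}

#' Read fiducial landmarks from JSON
#'
#' Expects `{"nasion": [x,y,z], "lpa": [x,y,z], "rpa": [x,y,z]}` in mm.
#'
#' @param path JSON file path.
#' @return A `landmark_set`.
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::fromJSON(path)
  need <- c("nasion", "lpa", "rpa")
  if (!all(need %in% names(j)))
    stop("landmark file must contain fields: ", paste(need, collapse = ", "))
  landmark_set(j$nasion, j$lpa, j$rpa)
}

#' Write fiducial landmarks to JSON
#' @param landmarks a `landmark_set`.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(list(nasion = landmarks$nasion,
                            lpa = landmarks$left_preauricular,
                            rpa = landmarks$right_preauricular),
                       path, digits = NA)
  invisible(path)
}
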