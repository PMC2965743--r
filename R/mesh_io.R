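# boundary label <-> integer tag mapping used in both exchange formats
.label_tags <- c(external_membrane = 1L, ttubule_membrane = 2L,
                 reflective = 3L)

#' Write a labeled mesh to Gmsh MSH 2.2 ASCII
#'
#' Boundary triangles are written as element type 2 with their label as
#' the physical tag (1 = external_membrane, 2 = ttubule_membrane,
#' 3 = reflective); tetrahedra as element type 4 with physical tag 0.
#' @param mesh a `labeled_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_msh <- function(mesh, path) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$vertices))), con)
  writeLines(paste(seq_len(nrow(mesh$vertices)),
                   formatC(mesh$vertices[, 1], format = "g", digits = 17),
                   formatC(mesh$vertices[, 2], format = "g", digits = 17),
                   formatC(mesh$vertices[, 3], format = "g", digits = 17)),
             con)
  nf <- nrow(mesh$facets); ntet <- nrow(mesh$tets)
  writeLines(c("$EndNodes", "$Elements", as.character(nf + ntet)), con)
  tags <- .label_tags[mesh$facet_label]
  writeLines(paste(seq_len(nf), 2L, 2L, tags, tags,
                   mesh$facets[, 1], mesh$facets[, 2], mesh$facets[, 3]),
             con)
  writeLines(paste(nf + seq_len(ntet), 4L, 2L, 0L, 0L,
                   mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                   mesh$tets[, 4]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a labeled mesh from Gmsh MSH 2.2 ASCII
#'
#' Inverse of [write_mesh_msh()]. Triangles with physical tags 1/2/3 are
#' interpreted as external_membrane / ttubule_membrane / reflective
#' boundary facets. Geometry statistics are recomputed; generator
#' metadata (spec, skeleton, membrane distances) is not stored in the
#' format and is absent from the result.
#' @param path input file path.
#' @return a `labeled_mesh`.
#' @export
read_mesh_msh <- function(path) {
  lines <- readLines(path)
  sec <- function(tag) which(lines == tag)
  i0 <- sec("$Nodes"); i1 <- sec("$EndNodes")
  nn <- as.integer(lines[i0 + 1L])
  nodes <- utils::read.table(text = lines[(i0 + 2L):(i1 - 1L)])
  stopifnot(nrow(nodes) == nn)
  verts <- as.matrix(nodes[order(nodes[[1]]), 2:4])
  dimnames(verts) <- NULL
  e0 <- sec("$Elements"); e1 <- sec("$EndElements")
  elems <- strsplit(lines[(e0 + 2L):(e1 - 1L)], "[ \t]+")
  etype <- vapply(elems, function(x) as.integer(x[2]), integer(1))
  tris <- t(vapply(elems[etype == 2L], function(x) {
    ntags <- as.integer(x[3])
    as.integer(x[c(4L, (4L + ntags):(6L + ntags))])
  }, integer(4)))
  tets <- t(vapply(elems[etype == 4L], function(x) {
    ntags <- as.integer(x[3])
    as.integer(x[(4L + ntags):(7L + ntags)])
  }, integer(4)))
  facets <- tris[, 2:4, drop = FALSE]
  label <- names(.label_tags)[match(tris[, 1], .label_tags)]
  rebuild_labeled_mesh(verts, tets, facets, label)
}

#' Write a labeled mesh as a legacy VTK unstructured grid (ASCII)
#'
#' Writes tetrahedra plus the labeled boundary triangles; the facet
#' label is stored as integer `CELL_DATA` (`boundary_label`; 0 for
#' volume cells, 1/2/3 as in [write_mesh_msh()]). Optional per-vertex
#' scalar fields are written as `POINT_DATA`.
#' @param mesh a `labeled_mesh`.
#' @param path output file path.
#' @param point_data optional named list of per-vertex numeric vectors.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = NULL) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); ntet <- nrow(mesh$tets)
  nf <- nrow(mesh$facets)
  writeLines(c("# vtk DataFile Version 3.0",
               "t-tubule compartment mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nv, "double")), con)
  writeLines(paste(mesh$vertices[, 1], mesh$vertices[, 2],
                   mesh$vertices[, 3]), con)
  writeLines(paste("CELLS", ntet + nf, 5L * ntet + 4L * nf), con)
  writeLines(paste(4L, mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                   mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  writeLines(paste(3L, mesh$facets[, 1] - 1L, mesh$facets[, 2] - 1L,
                   mesh$facets[, 3] - 1L), con)
  writeLines(paste("CELL_TYPES", ntet + nf), con)
  writeLines(as.character(c(rep(10L, ntet), rep(5L, nf))), con)
  writeLines(c(paste("CELL_DATA", ntet + nf),
               "SCALARS boundary_label int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(c(rep(0L, ntet),
                            .label_tags[mesh$facet_label])), con)
  if (!is.null(point_data)) {
    writeLines(paste("POINT_DATA", nv), con)
    for (nm in names(point_data)) {
      writeLines(c(paste("SCALARS", nm, "double 1"),
                   "LOOKUP_TABLE default"), con)
      writeLines(as.character(point_data[[nm]]), con)
    }
  }
  invisible(path)
}

#' Read a labeled mesh from a legacy VTK unstructured grid
#' @param path input file path (as written by [write_mesh_vtk()]).
#' @return a `labeled_mesh`.
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  nv <- as.integer(strsplit(lines[ip], " +")[[1]][2])
  pts <- scan(text = lines[(ip + 1L):(ip + nv)], quiet = TRUE)
  verts <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  ncell <- as.integer(strsplit(lines[ic], " +")[[1]][2])
  cells <- strsplit(trimws(lines[(ic + 1L):(ic + ncell)]), " +")
  sizes <- vapply(cells, function(x) as.integer(x[1]), integer(1))
  tets <- t(vapply(cells[sizes == 4L],
                   function(x) as.integer(x[2:5]) + 1L, integer(4)))
  facets <- t(vapply(cells[sizes == 3L],
                     function(x) as.integer(x[2:4]) + 1L, integer(3)))
  id <- grep("^SCALARS boundary_label", lines)[1]
  vals <- as.integer(lines[(id + 2L):(id + 1L + ncell)])
  label <- names(.label_tags)[match(vals[sizes == 3L], .label_tags)]
  rebuild_labeled_mesh(verts, tets, facets, label)
}

# assemble a labeled_mesh from raw arrays read from an exchange file
rebuild_labeled_mesh <- function(verts, tets, facets, label) {
  stopifnot(all(label %in% names(.label_tags)))
  vol <- signed_tet_volume(verts, tets)
  flip <- vol < 0
  tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  mesh <- structure(list(
    vertices = verts, tets = tets, facets = facets,
    facet_label = label, facet_area = triangle_areas(verts, facets),
    facet_centroid = (verts[facets[, 1], , drop = FALSE] +
                        verts[facets[, 2], , drop = FALSE] +
                        verts[facets[, 3], , drop = FALSE]) / 3,
    membrane_distance = NULL, spec = NULL, h = NA_real_,
    box = apply(verts, 2, max), skeleton = NULL),
    class = "labeled_mesh")
  mesh$stats <- compute_geometry_stats(mesh)
  mesh
}

#' Export a solution as a VTK time series
#'
#' Writes one legacy VTK file per output time with all species as point
#' data, suitable for ParaView-style animation.
#' @param solution a [run_3d()] result with recorded fields.
#' @param dir output directory (created if needed).
#' @param stride keep every `stride`-th output time.
#' @return character vector of written paths, invisibly.
#' @export
export_solution_vtk <- function(solution, dir, stride = 1L) {
  stopifnot(inherits(solution, "solution"), !is.null(solution$fields))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- seq(1L, length(solution$time), by = stride)
  paths <- character(0)
  for (i in idx) {
    pd <- lapply(solution$fields, function(f) f[, i])
    p <- file.path(dir, sprintf("frame_%04d.vtk", i - 1L))
    write_mesh_vtk(solution$mesh, p, point_data = pd)
    paths <- c(paths, p)
  }
  invisible(paths)
}
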