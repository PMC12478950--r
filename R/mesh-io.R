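# Bone-geometry mesh I/O: ASCII STL and VTK PolyData (`.vtp`), triangles only.

#' Read a triangle mesh (`.stl` ASCII or `.vtp`)
#'
#' Dispatch is by file extension. Faces must be triangles; anything else is a
#' format error. STL facets are re-indexed by exact vertex coincidence.
#'
#' @param path file path.
#' @return a [tri_mesh()].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl_ascii(path),
         vtp = read_vtp(path),
         stop("unsupported mesh format '.", ext, "'", call. = FALSE))
}

#' Write a triangle mesh (`.stl` ASCII or `.vtp`)
#'
#' @param mesh a [tri_mesh()].
#' @param path output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl_ascii(mesh, path),
         vtp = write_vtp(mesh, path),
         stop("unsupported mesh format '.", ext, "'", call. = FALSE))
  invisible(path)
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vlines <- grep("^vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0) stop("'", path, "': empty or non-ASCII STL", call. = FALSE)
  # loop sizes: count vertices between each outer loop / endloop pair
  loop_open <- grep("^outer loop", lines)
  loop_close <- grep("^endloop", lines)
  if (length(loop_open) != length(loop_close))
    stop("'", path, "': unbalanced facet loops", call. = FALSE)
  sizes <- vapply(seq_along(loop_open), function(i)
    sum(grepl("^vertex\\s", lines[loop_open[i]:loop_close[i]])), 0L)
  if (any(sizes != 3))
    stop("'", path, "': non-triangular facet (", max(sizes),
         " vertices)", call. = FALSE)
  verts <- t(vapply(vlines, function(l)
    parse_nums(sub("^vertex\\s+", "", l), 3, "vertex"), numeric(3)))
  rownames(verts) <- NULL
  key <- apply(verts, 1, function(v) paste(sprintf("%.9g", v), collapse = "_"))
  uidx <- !duplicated(key)
  vmap <- match(key, key[uidx])
  faces <- matrix(vmap, ncol = 3, byrow = TRUE)
  tri_mesh(vertices = verts[uidx, , drop = FALSE], faces = faces)
}

write_stl_ascii <- function(mesh, path) {
  if (nrow(mesh$faces) == 0) stop("refusing to write empty mesh", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- mesh$vertices[mesh$faces[i, ], , drop = FALSE]
    n <- pracma_cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeLines(c(sprintf("facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "  outer loop",
                 sprintf("    vertex %.17g %.17g %.17g",
                         tri[, 1], tri[, 2], tri[, 3]),
                 "  endloop",
                 "endfacet"), con)
  }
  writeLines("endsolid mesh", con)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

read_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, "//Piece")
  if (inherits(piece, "xml_missing"))
    stop("'", path, "': no PolyData Piece", call. = FALSE)
  pts <- parse_nums(xml2::xml_text(
    xml2::xml_find_first(piece, "./Points/DataArray")), what = "points")
  if (length(pts) == 0) stop("'", path, "': empty mesh", call. = FALSE)
  verts <- matrix(pts, ncol = 3, byrow = TRUE)
  conn <- parse_nums(xml2::xml_text(xml2::xml_find_first(
    piece, "./Polys/DataArray[@Name='connectivity']")), what = "connectivity")
  offs <- parse_nums(xml2::xml_text(xml2::xml_find_first(
    piece, "./Polys/DataArray[@Name='offsets']")), what = "offsets")
  sizes <- diff(c(0, offs))
  if (any(sizes != 3))
    stop("'", path, "': non-triangular polygon (size ", max(sizes), ")",
         call. = FALSE)
  faces <- matrix(as.integer(conn) + 1L, ncol = 3, byrow = TRUE)
  tri_mesh(vertices = verts, faces = faces)
}

write_vtp <- function(mesh, path) {
  if (nrow(mesh$faces) == 0) stop("refusing to write empty mesh", call. = FALSE)
  doc <- xml2::xml_new_root("VTKFile", type = "PolyData", version = "0.1",
                            byte_order = "LittleEndian")
  pd <- xml2::xml_add_child(doc, "PolyData")
  piece <- xml2::xml_add_child(pd, "Piece",
                               NumberOfPoints = as.character(nrow(mesh$vertices)),
                               NumberOfVerts = "0", NumberOfLines = "0",
                               NumberOfStrips = "0",
                               NumberOfPolys = as.character(nrow(mesh$faces)))
  pts <- xml2::xml_add_child(piece, "Points")
  xml2::xml_add_child(pts, "DataArray", type = "Float64",
                      NumberOfComponents = "3", format = "ascii",
                      paste(sprintf("%.17g", t(mesh$vertices)), collapse = " "))
  polys <- xml2::xml_add_child(piece, "Polys")
  xml2::xml_add_child(polys, "DataArray", type = "Int32",
                      Name = "connectivity", format = "ascii",
                      paste(t(mesh$faces) - 1L, collapse = " "))
  xml2::xml_add_child(polys, "DataArray", type = "Int32", Name = "offsets",
                      format = "ascii",
                      paste(seq_len(nrow(mesh$faces)) * 3L, collapse = " "))
  xml2::write_xml(doc, path)
}

#' Signed volume of a closed triangle mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for
#' consistently outward-wound closed surfaces. Used to verify that mirroring
#' preserves volume and outward orientation.
#'
#' @param mesh a [tri_mesh()].
#' @return signed volume (m^3).
#' @export
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  s <- 0
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c3 <- v[f[i, 3], ]
    s <- s + sum(a * pracma_cross(b, c3))
  }
  s / 6
}
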