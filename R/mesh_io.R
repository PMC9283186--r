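## Mesh interchange. VTU (ASCII XML) is the primary format: tetrahedra
## and tagged boundary triangles are written as cells with an integer
## cell-data field "boundary_tag" ({0: volume, 1: inlet, 2: outlet,
## 3: solid}). Gmsh MSH 2.2 ASCII is supported as a secondary format with
## the tag as the physical group. Connectivity on disk follows each
## format's convention (VTU 0-based, MSH 1-based) and is normalized to
## the package's 1-based indexing on read.

#' Write a mesh to disk
#'
#' @param mesh a `tet_mesh` (tagged or not).
#' @param path output file path.
#' @param format `"vtu"` or `"msh"`; default guessed from the extension.
#' @param point_data optional named list of nodal vectors (e.g. a
#'   concentration field) written as VTU point data (VTU only).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, point_data = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
         vtu = write_vtu(mesh, path, point_data),
         msh = write_msh(mesh, path),
         stop("unsupported mesh format: ", format,
              " (supported: vtu, msh)"))
  invisible(path)
}

#' Read a mesh from disk
#'
#' @param path input file (.vtu or .msh).
#' @param format `"vtu"` or `"msh"`; default guessed from the extension.
#' @return a `tet_mesh` with boundary tags restored from the file's
#'   tagged triangles.
#' @export
read_mesh <- function(path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
         vtu = read_vtu(path),
         msh = read_msh(path),
         stop("unsupported mesh format: ", format,
              " (supported: vtu, msh)"))
}

fmt_num <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)

write_vtu <- function(mesh, path, point_data = NULL) {
  n <- nrow(mesh$nodes)
  ntet <- nrow(mesh$tets)
  ntri <- nrow(mesh$facets)
  tag <- mesh$facet_tag
  tag[is.na(tag)] <- 0L

  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w(' <UnstructuredGrid>')
  w(sprintf('  <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, ntet + ntri))
  w('   <Points>')
  w('    <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(mesh$nodes, 1, function(r) paste(fmt_num(r), collapse = " ")),
             con)
  w('    </DataArray>')
  w('   </Points>')
  w('   <Cells>')
  w('    <DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(c(apply(mesh$tets - 1L, 1, paste, collapse = " "),
               if (ntri) apply(mesh$facets - 1L, 1, paste, collapse = " ")),
             con)
  w('    </DataArray>')
  w('    <DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(as.character(c(seq_len(ntet) * 4L,
                            ntet * 4L + seq_len(ntri) * 3L)), con)
  w('    </DataArray>')
  w('    <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(as.character(c(rep(10L, ntet), rep(5L, ntri))), con)
  w('    </DataArray>')
  w('   </Cells>')
  w('   <CellData Scalars="boundary_tag">')
  w('    <DataArray type="Int32" Name="boundary_tag" format="ascii">')
  writeLines(as.character(c(rep(0L, ntet), tag)), con)
  w('    </DataArray>')
  w('   </CellData>')
  if (!is.null(point_data)) {
    w('   <PointData>')
    for (nm in names(point_data)) {
      w(sprintf('    <DataArray type="Float64" Name="%s" format="ascii">', nm))
      writeLines(fmt_num(point_data[[nm]]), con)
      w('    </DataArray>')
    }
    w('   </PointData>')
  }
  w('  </Piece>')
  w(' </UnstructuredGrid>')
  w('</VTKFile>')
}

scan_text <- function(x) scan(text = x, quiet = TRUE)

read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  get_arr <- function(xpath) {
    nd <- xml2::xml_find_first(piece, xpath)
    if (inherits(nd, "xml_missing")) return(NULL)
    scan_text(xml2::xml_text(nd))
  }
  pts <- get_arr(".//Points/DataArray")
  conn <- get_arr(".//Cells/DataArray[@Name='connectivity']")
  offs <- get_arr(".//Cells/DataArray[@Name='offsets']")
  types <- get_arr(".//Cells/DataArray[@Name='types']")
  tags <- get_arr(".//CellData/DataArray[@Name='boundary_tag']")
  if (is.null(pts) || is.null(conn) || is.null(offs) || is.null(types))
    stop("malformed VTU: missing Points/Cells arrays")
  conn <- as.integer(conn); offs <- as.integer(offs)
  nodes <- matrix(pts, ncol = 3L, byrow = TRUE)

  starts <- c(1, head(offs, -1) + 1)
  is_tet <- types == 10
  is_tri <- types == 5
  if (!any(is_tet)) stop("no tetrahedra in mesh file")
  tets <- t(vapply(which(is_tet),
                   function(i) conn[starts[i]:offs[i]], integer(4))) + 1L
  mesh <- tet_mesh(nodes, tets)
  if (any(is_tri)) {
    if (is.null(tags))
      stop("missing tag table: VTU must carry an integer cell-data field ",
           "'boundary_tag'")
    tris <- t(vapply(which(is_tri),
                     function(i) conn[starts[i]:offs[i]], integer(3))) + 1L
    mesh <- apply_facet_tags(mesh, tris, as.integer(tags[is_tri]))
  }
  mesh
}

## transfer triangle tags from file onto the mesh's extracted boundary
apply_facet_tags <- function(mesh, tris, tags) {
  key_mesh <- face_key(mesh$facets)
  key_file <- face_key(tris)
  hit <- match(key_mesh, key_file)
  if (anyNA(hit))
    stop("missing tag table: ", sum(is.na(hit)),
         " boundary facets have no tagged triangle in the file ",
         "(required tags: boundary_tag in {1 inlet, 2 outlet, 3 solid})")
  mesh$facet_tag <- tags[hit]
  mesh
}

write_msh <- function(mesh, path) {
  tag <- mesh$facet_tag
  tag[is.na(tag)] <- 0L
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("$MeshFormat"); w("2.2 0 8"); w("$EndMeshFormat")
  w("$Nodes"); w(as.character(nrow(mesh$nodes)))
  writeLines(paste(seq_len(nrow(mesh$nodes)),
                   fmt_num(mesh$nodes[, 1]), fmt_num(mesh$nodes[, 2]),
                   fmt_num(mesh$nodes[, 3])), con)
  w("$EndNodes")
  ntet <- nrow(mesh$tets); ntri <- nrow(mesh$facets)
  w("$Elements"); w(as.character(ntet + ntri))
  writeLines(paste(seq_len(ntri), 2L, 2L, tag, tag,
                   mesh$facets[, 1], mesh$facets[, 2], mesh$facets[, 3]), con)
  writeLines(paste(ntri + seq_len(ntet), 4L, 2L, 0L, 0L,
                   mesh$tets[, 1], mesh$tets[, 2],
                   mesh$tets[, 3], mesh$tets[, 4]), con)
  w("$EndElements")
}

read_msh <- function(path) {
  ln <- readLines(path)
  sec <- function(name) {
    i0 <- match(paste0("$", name), ln)
    i1 <- match(paste0("$End", name), ln)
    if (is.na(i0) || is.na(i1)) stop("malformed MSH: missing $", name)
    ln[(i0 + 1):(i1 - 1)]
  }
  nd <- sec("Nodes")
  n <- as.integer(nd[1])
  ntab <- matrix(scan_text(nd[-1]), ncol = 4L, byrow = TRUE)
  ## node ids may be arbitrary; build a dense renumbering
  ids <- as.integer(ntab[, 1])
  remap <- integer(max(ids)); remap[ids] <- seq_len(n)
  nodes <- ntab[, 2:4, drop = FALSE]

  el <- sec("Elements")
  tets <- list(); tris <- list(); tri_tag <- integer(0)
  for (line in el[-1]) {
    v <- scan_text(line)
    type <- v[2]; ntags <- v[3]
    nodes_v <- remap[v[(4 + ntags):length(v)]]
    if (type == 4) tets[[length(tets) + 1L]] <- nodes_v
    else if (type == 2) {
      tris[[length(tris) + 1L]] <- nodes_v
      tri_tag <- c(tri_tag, if (ntags >= 1) v[4] else 0)
    }
  }
  if (!length(tets)) stop("no tetrahedra in mesh file")
  mesh <- tet_mesh(nodes, do.call(rbind, tets))
  if (length(tris)) {
    if (all(tri_tag == 0))
      stop("missing tag table: MSH triangles carry no physical tags ",
           "(required: {1 inlet, 2 outlet, 3 solid})")
    mesh <- apply_facet_tags(mesh, do.call(rbind, tris), as.integer(tri_tag))
  }
  mesh
}
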