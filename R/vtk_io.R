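# Minimal ASCII VTK XML reader/writer (UnstructuredGrid .vtu, PolyData .vtp).
# Only the subset of the format the package produces and consumes:
# ASCII DataArrays, tetrahedral cells (type 10), triangles (type 5),
# polylines/polygons in PolyData, point/cell data arrays.

vtk_num <- function(x, int = FALSE) {
  if (int) paste(format(as.integer(x), scientific = FALSE), collapse = " ")
  else paste(format(x, digits = 17, scientific = TRUE), collapse = " ")
}

vtk_data_array <- function(values, name, ncomp = 1L, int = FALSE) {
  type <- if (int) "Int64" else "Float64"
  sprintf(
    '<DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
    type, name, ncomp, vtk_num(values, int = int))
}

parse_data_array <- function(node) {
  txt <- xml2::xml_text(node)
  vals <- scan(text = txt, quiet = TRUE)
  nc <- xml2::xml_attr(node, "NumberOfComponents")
  nc <- if (is.na(nc)) 1L else as.integer(nc)
  if (nc > 1L) matrix(vals, ncol = nc, byrow = TRUE) else vals
}

find_array <- function(parent, name) {
  arrs <- xml2::xml_find_all(parent, ".//DataArray")
  nm <- vapply(arrs, function(a) xml2::xml_attr(a, "Name"), character(1))
  hit <- which(nm == name)
  if (!length(hit)) stop("DataArray '", name, "' not found")
  parse_data_array(arrs[[hit[1]]])
}

#' Write a tetrahedral mesh frame as VTK XML UnstructuredGrid (.vtu)
#'
#' @param points `n x 3` node coordinates. Written as-is; callers decide
#'   the length unit (the package's phantom writers use mm on disk).
#' @param tets `m x 4` 1-based tetrahedron connectivity.
#' @param path output file.
#' @param point_data,cell_data optional named lists of vectors/matrices.
#' @return invisibly, `path`.
#' @export
write_vtu <- function(points, tets, path, point_data = NULL,
                      cell_data = NULL) {
  n <- nrow(points); m <- nrow(tets)
  pd <- cd <- ""
  fmt_fields <- function(lst) {
    paste(vapply(names(lst), function(nm) {
      v <- lst[[nm]]
      nc <- if (is.matrix(v)) ncol(v) else 1L
      vtk_data_array(if (is.matrix(v)) t(v) else v, nm, nc,
                     int = is.integer(v))
    }, character(1)), collapse = "\n")
  }
  if (!is.null(point_data) && length(point_data))
    pd <- sprintf("<PointData>\n%s\n</PointData>", fmt_fields(point_data))
  if (!is.null(cell_data) && length(cell_data))
    cd <- sprintf("<CellData>\n%s\n</CellData>", fmt_fields(cell_data))
  body <- sprintf(
'<?xml version="1.0"?>
<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">
<UnstructuredGrid>
<Piece NumberOfPoints="%d" NumberOfCells="%d">
<Points>
%s
</Points>
<Cells>
%s
%s
%s
</Cells>
%s
%s
</Piece>
</UnstructuredGrid>
</VTKFile>',
    n, m,
    vtk_data_array(t(points), "Points", 3L),
    vtk_data_array(t(tets) - 1L, "connectivity", 1L, int = TRUE),
    vtk_data_array(seq_len(m) * 4L, "offsets", 1L, int = TRUE),
    vtk_data_array(rep(10L, m), "types", 1L, int = TRUE),
    pd, cd)
  writeLines(body, path)
  invisible(path)
}

#' Read a tetrahedral VTK XML UnstructuredGrid (.vtu)
#'
#' @param path input file.
#' @return list with `points` (`n x 3`), `tets` (`m x 4`, 1-based),
#'   `point_data` and `cell_data` (named lists).
#' @export
read_vtu <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  pts <- find_array(xml2::xml_find_first(piece, "./Points"), "Points")
  cells <- xml2::xml_find_first(piece, "./Cells")
  conn <- as.integer(find_array(cells, "connectivity"))
  types <- as.integer(find_array(cells, "types"))
  if (any(types != 10L))
    stop("only tetrahedral (VTK type 10) cells are supported")
  tets <- matrix(conn + 1L, ncol = 4L, byrow = TRUE)
  read_fields <- function(tag) {
    nd <- xml2::xml_find_first(piece, paste0("./", tag))
    out <- list()
    if (!inherits(nd, "xml_missing")) {
      for (a in xml2::xml_find_all(nd, "./DataArray"))
        out[[xml2::xml_attr(a, "Name")]] <- parse_data_array(a)
    }
    out
  }
  list(points = pts, tets = tets,
       point_data = read_fields("PointData"),
       cell_data = read_fields("CellData"))
}

#' Write VTK XML PolyData (.vtp) with polylines and/or polygons
#'
#' @param points `n x 3` coordinates.
#' @param lines list of integer vectors (1-based point indices per
#'   polyline), or `NULL`.
#' @param polys list of integer vectors per polygon, or `NULL`.
#' @param path output file.
#' @param point_data optional named list of per-point arrays.
#' @param line_names optional character vector naming each polyline;
#'   written as a `BranchName` field.
#' @return invisibly, `path`.
#' @export
write_vtp <- function(points, path, lines = NULL, polys = NULL,
                      point_data = NULL, line_names = NULL) {
  cell_block <- function(tag, idx_list) {
    if (is.null(idx_list) || !length(idx_list)) return(sprintf("<%s>\n</%s>", tag, tag))
    conn <- unlist(idx_list) - 1L
    offs <- cumsum(vapply(idx_list, length, integer(1)))
    sprintf("<%s>\n%s\n%s\n</%s>", tag,
            vtk_data_array(conn, "connectivity", 1L, int = TRUE),
            vtk_data_array(offs, "offsets", 1L, int = TRUE), tag)
  }
  pd <- ""
  if (!is.null(point_data) && length(point_data)) {
    pd <- sprintf("<PointData>\n%s\n</PointData>", paste(
      vapply(names(point_data), function(nm) {
        v <- point_data[[nm]]
        vtk_data_array(if (is.matrix(v)) t(v) else v, nm,
                       if (is.matrix(v)) ncol(v) else 1L,
                       int = is.integer(v))
      }, character(1)), collapse = "\n"))
  }
  extra <- ""
  if (!is.null(line_names))
    extra <- sprintf(
      '<FieldData>\n<DataArray type="String" Name="BranchName" format="ascii">\n%s\n</DataArray>\n</FieldData>',
      paste(line_names, collapse = " "))
  body <- sprintf(
'<?xml version="1.0"?>
<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">
<PolyData>
<Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="%d" NumberOfStrips="0" NumberOfPolys="%d">
%s
<Points>
%s
</Points>
%s
%s
%s
</Piece>
</PolyData>
</VTKFile>',
    nrow(points), length(lines %||% list()), length(polys %||% list()),
    extra, vtk_data_array(t(points), "Points", 3L),
    cell_block("Lines", lines), cell_block("Polys", polys), pd)
  writeLines(body, path)
  invisible(path)
}

#' Read VTK XML PolyData (.vtp)
#'
#' @param path input file.
#' @return list with `points`, `lines` (list of 1-based index vectors),
#'   `polys`, `point_data`, and `line_names` (from the `BranchName` field
#'   array if present).
#' @export
read_vtp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  pts <- find_array(xml2::xml_find_first(piece, "./Points"), "Points")
  read_cells <- function(tag) {
    nd <- xml2::xml_find_first(piece, paste0("./", tag))
    if (inherits(nd, "xml_missing")) return(list())
    arrs <- xml2::xml_find_all(nd, "./DataArray")
    if (!length(arrs)) return(list())
    conn <- as.integer(find_array(nd, "connectivity")) + 1L
    offs <- as.integer(find_array(nd, "offsets"))
    starts <- c(1L, head(offs, -1L) + 1L)
    Map(function(s, e) conn[s:e], starts, offs)
  }
  pd <- list()
  pdn <- xml2::xml_find_first(piece, "./PointData")
  if (!inherits(pdn, "xml_missing"))
    for (a in xml2::xml_find_all(pdn, "./DataArray"))
      pd[[xml2::xml_attr(a, "Name")]] <- parse_data_array(a)
  nm_node <- xml2::xml_find_first(
    piece, "./FieldData/DataArray[@Name='BranchName']")
  line_names <- if (inherits(nm_node, "xml_missing")) NULL
                else strsplit(trimws(xml2::xml_text(nm_node)), "\\s+")[[1]]
  list(points = pts, lines = read_cells("Lines"),
       polys = read_cells("Polys"), point_data = pd,
       line_names = line_names)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
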