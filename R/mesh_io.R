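# Triangle-mesh file I/O: Wavefront OBJ (ASCII v/f records) and VRML97
# IndexedFaceSet (the export format of common cell-tracking software).
# Polygon faces are fan-triangulated on read.

.fan_triangulate <- function(idx_list) {
  do.call(rbind, lapply(idx_list, function(ii) {
    if (length(ii) < 3) stop("face with fewer than 3 vertices")
    if (length(ii) == 3) return(matrix(ii, 1, 3))
    cbind(ii[1], ii[2:(length(ii) - 1)], ii[3:length(ii)])
  }))
}

#' Read and write Wavefront OBJ meshes
#'
#' Supports the ASCII `v x y z` / `f i j k ...` records; `f` indices may
#' carry `/texture/normal` suffixes, which are ignored. Faces with more
#' than three vertices are fan-triangulated.
#'
#' @param path File path.
#' @param mesh A `surface_mesh`.
#' @return `read_obj()` returns a `surface_mesh`.
#' @export
read_obj <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines)
  flines <- grep("^f\\s", lines)
  if (length(vlines) == 0 || length(flines) == 0)
    stop("parse error in ", path, ": no vertex or face records found")
  verts <- t(vapply(lines[vlines], function(l) {
    parts <- strsplit(trimws(l), "\\s+")[[1]][-1]
    x <- suppressWarnings(as.numeric(parts[1:3]))
    if (anyNA(x)) stop("parse error: malformed vertex line: ", l)
    x
  }, numeric(3), USE.NAMES = FALSE))
  faces <- lapply(lines[flines], function(l) {
    parts <- strsplit(trimws(l), "\\s+")[[1]][-1]
    idx <- suppressWarnings(as.integer(sub("/.*$", "", parts)))
    if (anyNA(idx) || length(idx) < 3)
      stop("parse error: malformed face line: ", l)
    idx
  })
  surface_mesh(verts, .fan_triangulate(faces))
}

#' @rdname read_obj
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# triangle mesh", con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

.vrml_block <- function(txt, keyword, path) {
  at <- regexpr(keyword, txt)
  if (at < 0) stop("parse error in ", path, ": no '", keyword, "' block")
  rest <- substring(txt, at)
  open <- regexpr("\\[", rest)
  if (open < 0) stop("parse error in ", path, ": '", keyword,
                     "' without '['")
  rest <- substring(rest, open + 1)
  close_at <- regexpr("\\]", rest)
  if (close_at < 0) stop("parse error in ", path, ": unterminated '",
                         keyword, "' block")
  substring(rest, 1, close_at - 1)
}

#' Read and write VRML97 IndexedFaceSet meshes
#'
#' Reads the first `Coordinate point [...]` and `coordIndex [...]` blocks
#' of a VRML97 (`#VRML V2.0`) file; `coordIndex` polygons are terminated by
#' `-1` and fan-triangulated. `write_vrml()` emits a minimal single-shape
#' VRML97 file that `read_vrml()` round-trips.
#'
#' @param path File path.
#' @param mesh A `surface_mesh`.
#' @return `read_vrml()` returns a `surface_mesh`.
#' @export
read_vrml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  pts <- .vrml_block(txt, "point", path)
  nums <- suppressWarnings(as.numeric(
    strsplit(trimws(gsub(",", " ", pts)), "\\s+")[[1]]))
  if (length(nums) == 0 || anyNA(nums) || length(nums) %% 3 != 0)
    stop("parse error in ", path, ": point block is not a multiple of 3 numbers")
  verts <- matrix(nums, ncol = 3, byrow = TRUE)
  ids <- .vrml_block(txt, "coordIndex", path)
  idx <- suppressWarnings(as.integer(
    strsplit(trimws(gsub(",", " ", ids)), "\\s+")[[1]]))
  if (length(idx) == 0 || anyNA(idx))
    stop("parse error in ", path, ": malformed coordIndex block")
  polys <- split(idx, cumsum(c(0, head(idx, -1) == -1)))
  polys <- lapply(polys, function(p) p[p >= 0] + 1L)
  polys <- polys[lengths(polys) >= 3]
  if (length(polys) == 0)
    stop("parse error in ", path, ": no complete faces in coordIndex")
  surface_mesh(verts, .fan_triangulate(polys))
}

#' @rdname read_vrml
#' @export
write_vrml <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#VRML V2.0 utf8", "Shape {", "  geometry IndexedFaceSet {",
               "    coord Coordinate {", "      point ["), con)
  writeLines(sprintf("        %.9g %.9g %.9g,", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(c("      ]", "    }", "    coordIndex ["), con)
  writeLines(sprintf("      %d, %d, %d, -1,", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  writeLines(c("    ]", "  }", "}"), con)
  invisible(path)
}

#' Read a mesh file, guessing the format from its extension
#'
#' @param path File path (`.obj`, `.wrl` or `.vrml`).
#' @param format `"auto"`, `"obj"` or `"vrml"`.
#' @return A `surface_mesh`.
#' @export
read_mesh <- function(path, format = c("auto", "obj", "vrml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", basename(path)))
    format <- switch(ext, obj = "obj", wrl = "vrml", vrml = "vrml",
                     stop("cannot guess mesh format from extension '.",
                          ext, "'"))
  }
  if (format == "obj") read_obj(path) else read_vrml(path)
}

#' Read tracked cell meshes laid out as class/series/cell/t&lt;k&gt;
#'
#' Expects the directory convention
#' `<root>/<class>/<series_id>/<cell_id>/t<index>.obj` (or `.wrl`): one
#' mesh file per cell per time point, series id doubling as the
#' cross-validation group key.
#'
#' @param root Root directory.
#' @return A list with one element per cell: `meshes` (time-ordered),
#'   `class`, `group_id` (the series id), `cell_id`.
#' @export
read_mesh_tracks <- function(root) {
  if (!dir.exists(root)) stop("directory not found: ", root)
  out <- list()
  for (cls in list.dirs(root, recursive = FALSE)) {
    for (ser in list.dirs(cls, recursive = FALSE)) {
      for (cell in list.dirs(ser, recursive = FALSE)) {
        files <- list.files(cell, pattern = "^t\\d+\\.(obj|wrl|vrml)$",
                            full.names = TRUE)
        if (length(files) == 0) next
        ord <- order(as.integer(sub("^t(\\d+)\\..*$", "\\1",
                                    basename(files))))
        out[[length(out) + 1]] <- list(
          meshes = lapply(files[ord], read_mesh),
          class = basename(cls), group_id = basename(ser),
          cell_id = basename(cell))
      }
    }
  }
  if (length(out) == 0) stop("no mesh tracks found under ", root)
  out
}
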