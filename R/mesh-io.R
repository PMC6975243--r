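# Readers and writers for the three mesh formats laser-scan toolchains
# commonly export: PLY (ASCII / binary little-endian), STL (ASCII / binary)
# and OBJ (v/f records). Coordinates are treated as millimetres.

#' Read a facet mesh from PLY, STL or OBJ
#'
#' The format is detected from the file extension. Meshes are cleaned on
#' read: duplicate vertices are welded at 1e-9 mm (so STL triangle soup
#' becomes a connected surface), degenerate faces and unreferenced
#' vertices are dropped. STL and OBJ carry no units, so an explicit
#' `units` override is provided; PLY files from scanners are mm already.
#'
#' @param path Path to a `.ply`, `.stl` or `.obj` file.
#' @param units Either `"mm"` (default) or `"m"`; metre coordinates are
#'   scaled by 1000 into mm.
#' @param name Facet label; defaults to the file name without extension.
#' @return A [facet_mesh()].
#' @export
read_mesh <- function(path, units = c("mm", "m"), name = NULL) {
  units <- match.arg(units)
  if (!file.exists(path)) fm_abort(sprintf("mesh file not found: %s", path), "fm_io_error")
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    ply = read_ply(path),
    stl = read_stl(path),
    obj = read_obj(path),
    fm_abort(sprintf("unsupported mesh format '.%s' (expected .ply, .stl or .obj)", ext), "fm_format_error")
  )
  v <- raw$vertices
  if (units == "m") v <- v * 1000
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  facet_mesh(v, raw$faces, name = name, clean = TRUE)
}

#' Write a facet mesh to PLY, STL or OBJ
#'
#' PLY is written binary little-endian with double-precision coordinates
#' (the round-trip contract: re-reading reproduces vertices within
#' 1e-6 mm); `format = "ascii"` selects ASCII PLY. STL is ASCII; OBJ
#' writes `v`/`f` records.
#'
#' @param mesh A [facet_mesh()].
#' @param path Output path; extension selects the format.
#' @param format For PLY only: `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  validate_mesh(mesh)
  dir <- dirname(path)
  if (!dir.exists(dir)) fm_abort(sprintf("directory does not exist: %s", dir), "fm_io_error")
  if (file.access(dir, 2) != 0) fm_abort(sprintf("directory is not writable: %s", dir), "fm_io_error")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = write_ply(mesh, path, binary = identical(format, "binary")),
    stl = write_stl_ascii(mesh, path),
    obj = write_obj(mesh, path),
    fm_abort(sprintf("unsupported mesh format '.%s'", ext), "fm_format_error")
  )
  invisible(path)
}

## ---- PLY ----------------------------------------------------------------

ply_type_size <- c(
  char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
  short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
  int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
  float = 4L, float32 = 4L, double = 8L, float64 = 8L
)

ply_read_values <- function(bytes, type, n) {
  size <- ply_type_size[[type]]
  what <- if (type %in% c("float", "float32", "double", "float64")) "numeric" else "integer"
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16"))
  # uint/uint32 read signed; index values in practice stay below 2^31
  readBin(bytes, what = what, n = n, size = size, signed = if (size < 4) signed else TRUE,
          endian = "little")
}

read_ply <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  # locate end_header
  hit <- grepRaw("end_header", bytes, fixed = TRUE)
  if (length(hit) == 0) fm_abort("not a PLY file (no end_header found)", "fm_format_error")
  hdr_end <- hit[1] + nchar("end_header") - 1L
  # header runs to the newline after end_header
  j <- hdr_end + 1L
  while (j <= length(bytes) && bytes[j] != as.raw(10L)) j <- j + 1L
  header <- strsplit(rawToChar(bytes[1:(j - 1L)]), "\r?\n")[[1]]
  body_start <- j + 1L

  if (!grepl("^ply", header[1])) fm_abort("not a PLY file", "fm_format_error")
  fmt_line <- grep("^format", header, value = TRUE)
  if (length(fmt_line) != 1) fm_abort("PLY header missing format line", "fm_format_error")
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    fm_abort(sprintf("unsupported PLY format '%s'", fmt), "fm_format_error")
  }

  # parse elements/properties in order
  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0) next
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face)) {
    fm_abort("PLY file lacks vertex/face elements", "fm_format_error")
  }

  if (fmt == "ascii") {
    tokens <- scan(text = rawToChar(bytes[body_start:length(bytes)]), what = character(),
                   quiet = TRUE)
    pos <- 1L
    out <- list()
    for (el in elements) {
      nprop <- length(el$props)
      islist <- vapply(el$props, function(p) isTRUE(p$list), logical(1))
      if (!any(islist)) {
        ntok <- el$count * nprop
        vals <- as.numeric(tokens[pos:(pos + ntok - 1L)])
        pos <- pos + ntok
        m <- matrix(vals, ncol = nprop, byrow = TRUE)
        colnames(m) <- names(el$props)
        out[[el$name]] <- m
      } else {
        rows <- vector("list", el$count)
        for (r in seq_len(el$count)) {
          vals <- setNames(vector("list", nprop), names(el$props))
          for (pn in names(el$props)) {
            p <- el$props[[pn]]
            if (isTRUE(p$list)) {
              cnt <- as.integer(tokens[pos]); pos <- pos + 1L
              vals[[pn]] <- as.numeric(tokens[pos:(pos + cnt - 1L)]); pos <- pos + cnt
            } else {
              vals[[pn]] <- as.numeric(tokens[pos]); pos <- pos + 1L
            }
          }
          rows[[r]] <- vals
        }
        out[[el$name]] <- rows
      }
    }
    verts <- out$vertex
    vm <- cbind(verts[, "x"], verts[, "y"], verts[, "z"])
    face_rows <- out$face
    list_prop <- names(which(vapply(elements$face$props, function(p) isTRUE(p$list), logical(1))))[1]
    idx <- lapply(face_rows, function(r) r[[list_prop]])
    if (any(lengths(idx) != 3)) fm_abort("only triangular PLY faces are supported", "fm_format_error")
    fm <- matrix(as.integer(unlist(idx)), ncol = 3, byrow = TRUE) + 1L
    return(list(vertices = vm, faces = fm))
  }

  ## binary little-endian
  cursor <- body_start
  vertices <- NULL
  faces <- NULL
  for (el in elements) {
    islist <- vapply(el$props, function(p) isTRUE(p$list), logical(1))
    if (!any(islist)) {
      types <- vapply(el$props, function(p) p$type, character(1))
      sizes <- ply_type_size[types]
      row_bytes <- sum(sizes)
      total <- el$count * row_bytes
      block <- bytes[cursor:(cursor + total - 1L)]
      cursor <- cursor + total
      if (length(unique(types)) == 1) {
        vals <- ply_read_values(block, types[1], el$count * length(types))
        m <- matrix(vals, ncol = length(types), byrow = TRUE)
      } else {
        # mixed scalar types: slice columns out of the raw record matrix
        rec <- matrix(block, nrow = row_bytes)
        offs <- cumsum(c(0L, sizes))
        m <- matrix(0, el$count, length(types))
        for (k in seq_along(types)) {
          colbytes <- as.vector(rec[(offs[k] + 1L):offs[k + 1L], , drop = FALSE])
          m[, k] <- ply_read_values(as.raw(colbytes), types[k], el$count)
        }
      }
      colnames(m) <- names(el$props)
      if (el$name == "vertex") vertices <- m
    } else {
      if (length(el$props) != 1) {
        fm_abort("binary PLY face element with extra properties is not supported", "fm_format_error")
      }
      p <- el$props[[1]]
      csize <- ply_type_size[[p$count_type]]
      isize <- ply_type_size[[p$type]]
      # common case: all faces are triangles -> fixed-length records
      rec_bytes <- csize + 3L * isize
      total <- el$count * rec_bytes
      block <- bytes[cursor:(cursor + total - 1L)]
      rec <- matrix(block, nrow = rec_bytes)
      counts <- ply_read_values(as.raw(as.vector(rec[1:csize, , drop = FALSE])), p$count_type, el$count)
      if (any(counts != 3)) fm_abort("only triangular PLY faces are supported", "fm_format_error")
      cursor <- cursor + total
      idxbytes <- as.raw(as.vector(rec[(csize + 1L):rec_bytes, , drop = FALSE]))
      idx <- ply_read_values(idxbytes, p$type, 3L * el$count)
      m <- matrix(as.integer(idx), ncol = 3, byrow = TRUE) + 1L
      if (el$name == "face") faces <- m
    }
  }
  if (is.null(vertices) || is.null(faces)) fm_abort("PLY file lacks vertex/face data", "fm_format_error")
  list(vertices = cbind(vertices[, "x"], vertices[, "y"], vertices[, "z"]), faces = faces)
}

write_ply <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    "comment facetmorph mesh",
    sprintf("element vertex %d", nrow(v)),
    "property double x",
    "property double y",
    "property double z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
    writeBin(as.vector(t(v)), con, size = 8, endian = "little")
    idx <- writeBin(as.integer(t(f) - 1L), raw(), size = 4, endian = "little")
    rec <- matrix(as.raw(0), nrow = 13L, ncol = nrow(f))
    rec[1, ] <- as.raw(3L)
    rec[2:13, ] <- matrix(idx, nrow = 12L)
    writeBin(as.vector(rec), con)
  } else {
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(sprintf("%.9f %.9f %.9f", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
}

## ---- STL ----------------------------------------------------------------

read_stl <- function(path) {
  n_bytes <- file.size(path)
  probe <- readBin(path, "raw", min(n_bytes, 512L))
  txt <- suppressWarnings(rawToChar(probe))
  is_ascii <- grepl("^\\s*solid", txt) && grepl("facet", txt)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0) {
      fm_abort("malformed ASCII STL (vertex count not a multiple of 3)", "fm_format_error")
    }
    coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(t) as.numeric(t[2:4])))
    faces <- matrix(seq_len(nrow(coords)), ncol = 3, byrow = TRUE)
    list(vertices = coords, faces = faces)
  } else {
    bytes <- readBin(path, "raw", n_bytes)
    ntri <- readBin(bytes[81:84], "integer", 1, size = 4, endian = "little")
    need <- 84L + 50L * ntri
    if (length(bytes) < need) fm_abort("truncated binary STL", "fm_format_error")
    rec <- matrix(bytes[85:need], nrow = 50L)
    vb <- as.raw(as.vector(rec[13:48, , drop = FALSE]))
    vals <- readBin(vb, "numeric", 9L * ntri, size = 4, endian = "little")
    coords <- matrix(vals, ncol = 3, byrow = TRUE)
    faces <- matrix(seq_len(nrow(coords)), ncol = 3, byrow = TRUE)
    list(vertices = coords, faces = faces)
  }
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- face_normals(mesh)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("solid %s", mesh$name), con)
  fmt <- paste(
    "facet normal %.9e %.9e %.9e",
    " outer loop",
    "  vertex %.9e %.9e %.9e",
    "  vertex %.9e %.9e %.9e",
    "  vertex %.9e %.9e %.9e",
    " endloop",
    "endfacet",
    sep = "\n"
  )
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  writeLines(sprintf(
    fmt, n[, 1], n[, 2], n[, 3],
    a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3], cc[, 1], cc[, 2], cc[, 3]
  ), con)
  writeLines(sprintf("endsolid %s", mesh$name), con)
}

## ---- OBJ ----------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(fl) == 0) fm_abort("OBJ file lacks v/f records", "fm_format_error")
  coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(t) as.numeric(t[2:4])))
  idx <- lapply(strsplit(trimws(fl), "\\s+"), function(t) {
    as.integer(sub("/.*$", "", t[-1]))
  })
  if (any(lengths(idx) != 3)) fm_abort("only triangular OBJ faces are supported", "fm_format_error")
  faces <- matrix(unlist(idx), ncol = 3, byrow = TRUE)
  list(vertices = coords, faces = faces)
}

write_obj <- function(mesh, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(sprintf("# facetmorph mesh '%s'", mesh$name), con)
  writeLines(sprintf("v %.9f %.9f %.9f", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}
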