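# Mesh, network and embryo-directory I/O. Triangle-only internally; polygon
# faces in input files are fan-triangulated on read.

fan_triangulate <- function(idx_list) {
  do.call(rbind, lapply(idx_list, function(ix) {
    if (length(ix) < 3L) {
      abort("face with fewer than 3 vertices", "invalid_mesh")
    }
    if (length(ix) == 3L) return(matrix(ix, 1, 3))
    cbind(ix[1], ix[2:(length(ix) - 1)], ix[3:length(ix)])
  }))
}

#' Read a Wavefront OBJ mesh
#'
#' Supports `v` and `f` records; face fields of the `v/vt/vn` form keep the
#' vertex index; polygon faces are fan-triangulated. Negative (relative)
#' indices are not supported.
#'
#' @param path File path.
#' @param cell_id Label for the mesh (default: file name without extension).
#' @return A `blastomere_mesh`.
#' @export
read_obj <- function(path, cell_id = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path), "io_error")
  if (is.null(cell_id)) cell_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (!length(vlines) || !length(flines)) {
    abort(sprintf("OBJ file has no vertices or no faces: %s", path), "io_error")
  }
  V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vlines)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  faces <- lapply(strsplit(trimws(sub("^f", "", flines)), "\\s+"), function(x) {
    ix <- as.integer(vapply(strsplit(x, "/"), `[`, character(1), 1))
    if (anyNA(ix) || any(ix < 1L)) {
      abort(sprintf("unsupported face record in %s", path), "io_error")
    }
    ix
  })
  blastomere_mesh(V, fan_triangulate(faces), cell_id = cell_id)
}

#' Write a Wavefront OBJ mesh
#'
#' @param mesh A `blastomere_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# %s", mesh$cell_id),
    sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
            mesh$vertices[, 3]),
    sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  ), con)
  invisible(path)
}

ply_type_info <- function(type) {
  switch(type,
    char = , int8 = list(what = "integer", size = 1, signed = TRUE),
    uchar = , uint8 = list(what = "integer", size = 1, signed = FALSE),
    short = , int16 = list(what = "integer", size = 2, signed = TRUE),
    ushort = , uint16 = list(what = "integer", size = 2, signed = FALSE),
    int = , int32 = list(what = "integer", size = 4, signed = TRUE),
    uint = , uint32 = list(what = "integer", size = 4, signed = TRUE),
    float = , float32 = list(what = "numeric", size = 4, signed = TRUE),
    double = , float64 = list(what = "numeric", size = 8, signed = TRUE),
    abort(sprintf("unsupported PLY type '%s'", type), "io_error")
  )
}

#' Read a PLY mesh (ascii or binary)
#'
#' Supports `ascii`, `binary_little_endian` and `binary_big_endian` PLY files
#' with a vertex element carrying `x`, `y`, `z` properties (extra scalar
#' properties are skipped) and a face element with one index list property.
#' Polygon faces are fan-triangulated.
#'
#' @param path File path.
#' @param cell_id Label for the mesh (default: file name without extension).
#' @return A `blastomere_mesh`.
#' @export
read_ply <- function(path, cell_id = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path), "io_error")
  if (is.null(cell_id)) cell_id <- sub("\\.[^.]*$", "", basename(path))
  con <- file(path, "rb")
  on.exit(close(con))
  # read the header byte-by-byte so the connection position is exact when
  # binary data follows (readLines would read ahead)
  read_hdr_line <- function() {
    bytes <- raw()
    repeat {
      b <- readBin(con, "raw", n = 1)
      if (!length(b)) abort("PLY header not terminated", "io_error")
      if (b == as.raw(10L)) break
      bytes <- c(bytes, b)
    }
    sub("\r$", "", rawToChar(bytes))
  }
  header <- character()
  repeat {
    ln <- read_hdr_line()
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
  }
  if (trimws(header[1]) != "ply") abort("not a PLY file", "io_error")
  fmt_line <- grep("^format", header, value = TRUE)
  fmt <- strsplit(trimws(fmt_line[1]), "\\s+")[[1]][2]
  endian <- switch(fmt, binary_little_endian = "little",
                   binary_big_endian = "big", ascii = NA_character_,
                   abort(sprintf("unsupported PLY format '%s'", fmt), "io_error"))

  # parse element/property structure
  elements <- list()
  cur <- NULL
  for (ln in header) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face)) {
    abort("PLY file lacks vertex or face element", "io_error")
  }

  if (is.na(endian)) {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    pos <- 0L
    take <- function(n) {
      out <- body[pos + seq_len(n)]
      pos <<- pos + n
      out
    }
    read_element <- function(el) {
      lapply(strsplit(trimws(take(el$count)), "\\s+"), as.numeric)
    }
  } else {
    read_scalar <- function(type) {
      ti <- ply_type_info(type)
      readBin(con, ti$what, n = 1, size = ti$size, signed = ti$signed,
              endian = endian)
    }
    read_element <- function(el) {
      lapply(seq_len(el$count), function(i) {
        unlist(lapply(el$props, function(p) {
          if (p$list) {
            cnt <- read_scalar(p$count_type)
            # keep the count prefix so rows match the ascii layout
            c(cnt, vapply(seq_len(cnt), function(j) read_scalar(p$type),
                          numeric(1)))
          } else {
            read_scalar(p$type)
          }
        }))
      })
    }
  }

  out <- list()
  for (el in elements) {
    out[[el$name]] <- read_element(el)
  }
  vnames <- vapply(elements$vertex$props, `[[`, character(1), "name")
  xyz <- match(c("x", "y", "z"), vnames)
  if (anyNA(xyz)) abort("PLY vertex element lacks x/y/z", "io_error")
  V <- do.call(rbind, lapply(out$vertex, function(row) row[xyz]))
  faces <- lapply(out$face, function(row) {
    cnt <- as.integer(row[1])
    as.integer(row[1 + seq_len(cnt)]) + 1L # PLY indices are 0-based
  })
  blastomere_mesh(V, fan_triangulate(faces), cell_id = cell_id)
}

#' Write a PLY mesh
#'
#' Emits ascii PLY (plain text) or binary little-endian when
#' `format = "binary"`.
#'
#' @param mesh A `blastomere_mesh`.
#' @param path Output path.
#' @param format `"ascii"` (default) or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, format = c("ascii", "binary")) {
  format <- match.arg(format)
  V <- mesh$vertices
  F0 <- mesh$faces - 1L
  hdr <- c("ply",
           if (format == "ascii") "format ascii 1.0"
           else "format binary_little_endian 1.0",
           sprintf("comment %s", mesh$cell_id),
           sprintf("element vertex %d", nrow(V)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(F0)),
           "property list uchar int vertex_indices",
           "end_header")
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(hdr,
                 sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
                 sprintf("3 %d %d %d", F0[, 1], F0[, 2], F0[, 3])), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.vector(t(V)), con, size = 8, endian = "little")
    for (i in seq_len(nrow(F0))) {
      writeBin(as.integer(3), con, size = 1, endian = "little")
      writeBin(as.integer(F0[i, ]), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' Read any supported mesh file
#'
#' Dispatches on the file extension (`.obj`, `.ply`).
#'
#' @param path File path.
#' @param cell_id Optional label.
#' @return A `blastomere_mesh`.
#' @export
read_mesh <- function(path, cell_id = NULL) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         obj = read_obj(path, cell_id),
         ply = read_ply(path, cell_id),
         abort(sprintf("unsupported mesh format '.%s'", ext), "io_error"))
}

# embryo directories --------------------------------------------------------

#' Write an embryo as a directory of per-cell meshes
#'
#' One mesh file per blastomere (named by `cell_id`) plus a one-row
#' `metadata.csv` carrying the embryo id, stage and any outcome labels.
#'
#' @param emb An `embryo`.
#' @param dir Output directory (created if missing).
#' @param format Mesh format, `"ply"` (ascii) or `"obj"`.
#' @return `dir`, invisibly.
#' @export
write_embryo_dir <- function(emb, dir, format = c("ply", "obj")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in emb$blastomeres) {
    p <- file.path(dir, paste0(m$cell_id, ".", format))
    if (format == "ply") write_ply(m, p) else write_obj(m, p)
  }
  md <- emb$metadata
  row <- data.frame(embryo_id = emb$embryo_id, stage = emb$stage)
  if (inherits(md, "outcome_record")) {
    row <- cbind(row, as.data.frame(unclass(md)[setdiff(names(md), "embryo_id")],
                                    stringsAsFactors = FALSE))
  }
  utils::write.csv(row, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an embryo from a directory of per-cell meshes
#'
#' @param dir Directory containing `.obj`/`.ply` files (one per cell) and an
#'   optional `metadata.csv`.
#' @return An `embryo`; metadata columns, when present, are attached as an
#'   `outcome_record`.
#' @export
read_embryo_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(obj|ply)$", full.names = TRUE,
                           ignore.case = TRUE))
  if (!length(files)) {
    abort(sprintf("no mesh files in %s", dir), "io_error")
  }
  meshes <- lapply(files, read_mesh)
  md_path <- file.path(dir, "metadata.csv")
  metadata <- NULL
  embryo_id <- basename(dir)
  if (file.exists(md_path)) {
    md <- utils::read.csv(md_path, stringsAsFactors = FALSE)
    if (nrow(md)) {
      if (!is.null(md$embryo_id)) embryo_id <- md$embryo_id[1]
      args <- as.list(md[1, intersect(names(md), names(formals(outcome_record))),
                        drop = FALSE])
      args$embryo_id <- embryo_id
      metadata <- do.call(outcome_record, args)
    }
  }
  embryo(meshes, embryo_id = embryo_id, metadata = metadata)
}

# network export -------------------------------------------------------------

#' Export a contact network as GraphML
#'
#' @param net A `contact_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Export a contact network as a two-column CSV edge list
#'
#' Columns `from`, `to` with 1-based node indices; isolated nodes are implied
#' by `n_nodes`, recorded in a comment-free companion convention (the
#' descriptor CSV carries the stage).
#'
#' @param net A `contact_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edgelist_csv <- function(net, path) {
  df <- data.frame(from = net$edges[, 1], to = net$edges[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
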