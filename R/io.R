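## Mesh input/output: STL (ASCII and binary) and PLY (ASCII). Neither format
## has an attribute channel, so per-triangle region and material labels
## travel in a sidecar JSON (triangle index -> label) next to the mesh file.

## STL stores loose triangles; rebuild shared vertices by exact key matching
## after rounding to 1e-6 mm.
weld_vertices <- function(tri_xyz) {
  key <- apply(round(tri_xyz, 6), 1, paste, collapse = ",")
  uid <- !duplicated(key)
  vertices <- tri_xyz[uid, , drop = FALSE]
  index <- match(key, key[uid])
  list(vertices = vertices,
       triangles = matrix(index, ncol = 3, byrow = TRUE))
}

sidecar_path <- function(path) paste0(path, ".labels.json")

write_sidecar <- function(mesh, path) {
  jsonlite::write_json(list(region = mesh$region, material = mesh$material),
                       sidecar_path(path), auto_unbox = FALSE)
}

read_sidecar <- function(path, n_tri) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    warning("no label sidecar found for ", path,
            "; all labels set to UNRESOLVED")
    return(list(region = rep("UNRESOLVED", n_tri),
                material = rep("WALL", n_tri)))
  }
  lab <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (length(lab$region) != n_tri)
    stop("label sidecar length does not match triangle count in ", path)
  lab
}

#' Write a surface mesh to STL or PLY
#'
#' STL can be ASCII or binary; PLY is ASCII. Region/material labels are
#' written to a `<path>.labels.json` sidecar.
#'
#' @param mesh a `surface_mesh`.
#' @param path output file path.
#' @param format `"stl"` or `"ply"`.
#' @param binary for STL: write the 50-byte-record binary layout.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("stl", "ply"), binary = FALSE) {
  format <- match.arg(format)
  v <- mesh$vertices; tr <- mesh$triangles
  if (format == "stl") {
    a <- v[tr[, 1], , drop = FALSE]
    b <- v[tr[, 2], , drop = FALSE]
    c3 <- v[tr[, 3], , drop = FALSE]
    e1 <- b - a; e2 <- c3 - a
    nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    len <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-30)
    nrm <- cbind(nx, ny, nz) / len
    if (binary) {
      con <- file(path, "wb")
      on.exit(close(con))
      writeBin(raw(80), con)
      writeBin(as.integer(nrow(tr)), con, size = 4, endian = "little")
      block <- t(cbind(nrm, a, b, c3))          # 12 floats per facet
      for (i in seq_len(nrow(tr))) {
        writeBin(as.numeric(block[, i]), con, size = 4, endian = "little")
        writeBin(raw(2), con)
      }
    } else {
      fmt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3])
      lines <- c("solid mesh",
                 as.vector(rbind(paste("facet normal", fmt(nrm)),
                                 "outer loop",
                                 paste("vertex", fmt(a)),
                                 paste("vertex", fmt(b)),
                                 paste("vertex", fmt(c3)),
                                 "endloop", "endfacet")),
                 "endsolid mesh")
      writeLines(lines, path)
    }
  } else {
    header <- c("ply", "format ascii 1.0",
                paste("element vertex", nrow(v)),
                "property double x", "property double y", "property double z",
                paste("element face", nrow(tr)),
                "property list uchar int vertex_indices", "end_header")
    writeLines(c(header,
                 sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
                 sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L,
                         tr[, 3] - 1L)),
               path)
  }
  write_sidecar(mesh, path)
  invisible(path)
}

#' Read a surface mesh from STL or PLY
#'
#' STL flavour (ASCII vs binary) is auto-detected. Labels are restored from
#' the sidecar JSON when present; otherwise all triangles are `UNRESOLVED`
#' with a warning.
#'
#' @param path input file path.
#' @param format `"stl"` or `"ply"`.
#' @return a `surface_mesh`.
#' @export
read_mesh <- function(path, format = c("stl", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "stl") {
    ## ASCII STL starts with "solid" AND contains "facet" early on;
    ## binary files are sized exactly 84 + 50 * n_facets.
    head_raw <- readBin(path, "raw", n = 512)
    head_txt <- rawToChar(head_raw[head_raw != as.raw(0)])
    Encoding(head_txt) <- "bytes"
    is_ascii <- grepl("^\\s*solid", head_txt, useBytes = TRUE) &&
      grepl("facet", head_txt, useBytes = TRUE)
    if (is_ascii) {
      lines <- readLines(path, warn = FALSE)
      vlines <- grep("^\\s*vertex", lines, value = TRUE)
      if (length(vlines) == 0 || length(vlines) %% 3 != 0)
        stop("malformed ASCII STL: vertex count not a multiple of 3 in ",
             path)
      xyz <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                   function(f) as.numeric(f[2:4])))
      if (anyNA(xyz)) stop("malformed ASCII STL: non-numeric vertex in ",
                           path)
    } else {
      con <- file(path, "rb")
      on.exit(close(con))
      readBin(con, "raw", n = 80)
      n_fac <- readBin(con, "integer", size = 4, endian = "little")
      if (!isTRUE(n_fac > 0)) stop("malformed binary STL header in ", path)
      xyz <- matrix(NA_real_, 3 * n_fac, 3)
      for (i in seq_len(n_fac)) {
        vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
        if (length(vals) < 12)
          stop("malformed binary STL: truncated facet ", i, " in ", path)
        xyz[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, byrow = TRUE)
        readBin(con, "raw", n = 2)
      }
    }
    w <- weld_vertices(xyz)
    lab <- suppressWarnings(read_sidecar(path, nrow(w$triangles)))
    if (!file.exists(sidecar_path(path)))
      warning("no label sidecar found for ", path,
              "; all labels set to UNRESOLVED")
    return(surface_mesh(w$vertices, w$triangles, lab$region, lab$material))
  }
  ## PLY (ASCII)
  lines <- readLines(path, warn = FALSE)
  he <- match("end_header", lines)
  if (is.na(he)) stop("malformed PLY: missing end_header in ", path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  vtx <- do.call(rbind, lapply(strsplit(lines[(he + 1):(he + nv)], "\\s+"),
                               function(f) as.numeric(f[1:3])))
  fc <- do.call(rbind,
                lapply(strsplit(lines[(he + nv + 1):(he + nv + nf)], "\\s+"),
                       function(f) as.integer(f[2:4]) + 1L))
  lab <- suppressWarnings(read_sidecar(path, nf))
  if (!file.exists(sidecar_path(path)))
    warning("no label sidecar found for ", path,
            "; all labels set to UNRESOLVED")
  surface_mesh(vtx, fc, lab$region, lab$material)
}
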