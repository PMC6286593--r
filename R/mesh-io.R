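#' Read a triangle mesh (PLY, STL or OBJ)
#'
#' PLY is read in ascii and binary-little-endian form; an integer face
#' property named `tag` (0 = scan, 1 = wall, 2 = lid) is restored into the
#' mesh tags. STL is read in ascii and binary form, OBJ in its basic
#' `v`/`f` form.
#'
#' @param path file path; format chosen from the extension.
#' @return a `triangle_mesh`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         stl = read_stl(path),
         obj = read_obj(path),
         stop(sprintf("unsupported mesh format '%s'", ext)))
}

#' Write a triangle mesh (ascii PLY, STL or OBJ)
#'
#' @param mesh a `triangle_mesh`.
#' @param path output path; format chosen from the extension. Face tags are
#'   preserved only by PLY (as an integer face property `tag`).
#' @return invisibly, `path`.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(mesh, path),
         stl = write_stl(mesh, path),
         obj = write_obj(mesh, path),
         stop(sprintf("unsupported mesh format '%s'", ext)))
  invisible(path)
}

#' Read a point cloud (PLY or XYZ text)
#'
#' XYZ files carry one `x y z [nx ny nz]` record per line.
#' @param path file path.
#' @return a `point_cloud` (with normals when present).
#' @export
read_cloud <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    ply <- parse_ply(path)
    v <- ply$vertex
    nrm <- NULL
    if (all(c("nx", "ny", "nz") %in% colnames(v))) {
      nrm <- as.matrix(v[, c("nx", "ny", "nz")])
      len <- sqrt(rowSums(nrm^2))
      if (any(len < 1e-12)) nrm <- NULL else nrm <- nrm / len
    }
    return(point_cloud(as.matrix(v[, c("x", "y", "z")]), nrm))
  }
  if (ext %in% c("xyz", "txt")) {
    tab <- as.matrix(read.table(path))
    if (ncol(tab) >= 6) {
      nrm <- tab[, 4:6]
      nrm <- nrm / sqrt(rowSums(nrm^2))
      return(point_cloud(tab[, 1:3], nrm))
    }
    return(point_cloud(tab[, 1:3]))
  }
  stop(sprintf("unsupported point-cloud format '%s'", ext))
}

#' Write a point cloud (ascii PLY or XYZ text)
#' @param cloud a `point_cloud`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cloud <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  ext <- tolower(tools::file_ext(path))
  P <- cloud$points; N <- cloud$normals
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    props <- c("property float x", "property float y", "property float z")
    if (!is.null(N))
      props <- c(props, "property float nx", "property float ny",
                 "property float nz")
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(P)), props, "end_header"),
               con)
    dat <- if (is.null(N)) P else cbind(P, N)
    writeLines(apply(format(dat, trim = TRUE, digits = 9), 1, paste,
                     collapse = " "), con)
    return(invisible(path))
  }
  if (ext %in% c("xyz", "txt")) {
    dat <- if (is.null(N)) P else cbind(P, N)
    write.table(dat, path, row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  stop(sprintf("unsupported point-cloud format '%s'", ext))
}

# ---- PLY -------------------------------------------------------------------

.ply_tag_levels <- c("scan", "wall", "lid")

parse_ply <- function(path) {
  # read whole file; locate the end of the (text) header byte-wise so the
  # same path handles ascii and binary bodies
  raw <- readBin(path, "raw", file.info(path)$size)
  hdr_end <- grepRaw("end_header", raw) + nchar("end_header")
  # consume trailing newline (and possible \r)
  while (hdr_end <= length(raw) && raw[hdr_end] %in% as.raw(c(10L, 13L)))
    hdr_end <- hdr_end + 1L
  header <- strsplit(rawToChar(raw[seq_len(hdr_end - 1L)]), "\r?\n")[[1]]
  fmt <- sub("^format\\s+", "", grep("^format", header, value = TRUE)[1])
  fmt <- strsplit(fmt, "\\s+")[[1]][1]
  elements <- list()
  cur <- NULL
  for (l in header) {
    w <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(w) == 0) next
    if (w[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = w[2], count = as.integer(w[3]), props = list())
    } else if (w[1] == "property" && !is.null(cur)) {
      if (w[2] == "list") {
        cur$props[[w[5]]] <- list(list = TRUE, ctype = w[3], vtype = w[4])
      } else {
        cur$props[[w[3]]] <- list(list = FALSE, vtype = w[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur

  type_size <- function(t) switch(t, char = 1L, uchar = 1L, int8 = 1L,
    uint8 = 1L, short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L, int = 4L,
    uint = 4L, int32 = 4L, uint32 = 4L, float = 4L, float32 = 4L, double = 8L,
    float64 = 8L, stop("unknown ply type ", t))
  read_scalar <- function(con, t) {
    sz <- type_size(t)
    if (t %in% c("float", "float32", "double", "float64"))
      readBin(con, "double", 1, size = sz, endian = "little")
    else
      readBin(con, "integer", 1, size = sz, endian = "little",
              signed = !(t %in% c("uchar", "uint8", "ushort", "uint16")))
  }

  out <- list()
  if (fmt == "ascii") {
    body <- strsplit(rawToChar(raw[hdr_end:length(raw)]), "\r?\n")[[1]]
    body <- body[nzchar(trimws(body))]
    pos <- 1L
    for (el in elements) {
      rows <- body[pos:(pos + el$count - 1L)]
      pos <- pos + el$count
      toks <- strsplit(trimws(rows), "\\s+")
      has_list <- any(vapply(el$props, function(p) p$list, logical(1)))
      if (!has_list) {
        m <- do.call(rbind, lapply(toks, as.numeric))
        colnames(m) <- names(el$props)
        out[[el$name]] <- as.data.frame(m)
      } else {
        # assume one leading list property (vertex_indices) + scalar props
        pn <- names(el$props)
        lists <- lapply(toks, function(tk) {
          n <- as.integer(tk[1])
          list(idx = as.integer(tk[2:(1 + n)]),
               rest = as.numeric(tk[-seq_len(1 + n)]))
        })
        idx <- do.call(rbind, lapply(lists, function(x) x$idx))
        rest <- do.call(rbind, lapply(lists, function(x) x$rest))
        res <- list(indices = idx)
        scal <- pn[!vapply(el$props, function(p) p$list, logical(1))]
        if (length(scal) && !is.null(rest) && ncol(rest) == length(scal))
          for (j in seq_along(scal)) res[[scal[j]]] <- rest[, j]
        out[[el$name]] <- res
      }
    }
  } else if (fmt == "binary_little_endian") {
    con <- rawConnection(raw[hdr_end:length(raw)], "rb")
    on.exit(close(con))
    for (el in elements) {
      pn <- names(el$props)
      has_list <- any(vapply(el$props, function(p) p$list, logical(1)))
      if (!has_list) {
        m <- matrix(0, el$count, length(pn))
        for (i in seq_len(el$count))
          for (j in seq_along(pn))
            m[i, j] <- read_scalar(con, el$props[[j]]$vtype)
        colnames(m) <- pn
        out[[el$name]] <- as.data.frame(m)
      } else {
        idx <- vector("list", el$count)
        scal <- pn[!vapply(el$props, function(p) p$list, logical(1))]
        rest <- matrix(0, el$count, length(scal))
        for (i in seq_len(el$count)) {
          for (j in seq_along(pn)) {
            p <- el$props[[j]]
            if (p$list) {
              n <- read_scalar(con, p$ctype)
              idx[[i]] <- vapply(seq_len(n), function(q)
                as.numeric(read_scalar(con, p$vtype)), numeric(1))
            } else {
              rest[i, match(pn[j], scal)] <- read_scalar(con, p$vtype)
            }
          }
        }
        res <- list(indices = do.call(rbind, idx))
        for (j in seq_along(scal)) res[[scal[j]]] <- rest[, j]
        out[[el$name]] <- res
      }
    }
  } else stop("unsupported PLY format: ", fmt)
  out
}

read_ply <- function(path) {
  ply <- parse_ply(path)
  if (is.null(ply$vertex) || is.null(ply$face))
    stop("PLY file lacks vertex or face elements")
  v <- as.matrix(ply$vertex[, c("x", "y", "z")])
  f <- ply$face$indices + 1L
  tags <- NULL
  if (!is.null(ply$face$tag))
    tags <- .ply_tag_levels[as.integer(ply$face$tag) + 1L]
  triangle_mesh(v, f, tags = tags)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nf <- nrow(mesh$faces)
  hdr <- c("ply", "format ascii 1.0",
           "comment face property tag: 0=scan 1=wall 2=lid",
           sprintf("element vertex %d", nrow(mesh$vertices)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices")
  if (!is.null(mesh$tags)) hdr <- c(hdr, "property int tag")
  writeLines(c(hdr, "end_header"), con)
  writeLines(apply(format(mesh$vertices, trim = TRUE, digits = 9), 1, paste,
                   collapse = " "), con)
  f0 <- mesh$faces - 1L
  if (is.null(mesh$tags)) {
    writeLines(sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3]), con)
  } else {
    tg <- match(mesh$tags, .ply_tag_levels) - 1L
    tg[is.na(tg)] <- 0L
    writeLines(sprintf("3 %d %d %d %d", f0[, 1], f0[, 2], f0[, 3], tg), con)
  }
}

# ---- STL -------------------------------------------------------------------

read_stl <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  is_ascii <- identical(rawToChar(raw[1:5]), "solid") &&
    length(grepRaw("facet", raw[1:min(1000, length(raw))])) > 0
  if (is_ascii) {
    lines <- strsplit(rawToChar(raw), "\r?\n")[[1]]
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(w)
      as.numeric(w[2:4])))
  } else {
    con <- rawConnection(raw, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80)
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    xyz <- matrix(0, nf * 3L, 3L)
    for (i in seq_len(nf)) {
      vals <- readBin(con, "double", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      xyz[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
  }
  # weld duplicate vertices
  key <- apply(round(xyz, 9), 1, paste, collapse = "_")
  uid <- !duplicated(key)
  verts <- xyz[uid, , drop = FALSE]
  map <- match(key, key[uid])
  faces <- matrix(map, ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces)
}

write_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  n <- cross3(v[f[, 2], , drop = FALSE] - a, v[f[, 3], , drop = FALSE] - a)
  n <- n / pmax(sqrt(rowSums(n^2)), 1e-30)
  writeLines("solid surfdose", con)
  for (i in seq_len(nrow(f))) {
    writeLines(c(sprintf("facet normal %g %g %g", n[i, 1], n[i, 2], n[i, 3]),
                 "  outer loop",
                 sprintf("    vertex %g %g %g", v[f[i, ], 1], v[f[i, ], 2],
                         v[f[i, ], 3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid surfdose", con)
}

# ---- OBJ -------------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(w)
    as.numeric(w[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(w) {
    idx <- as.integer(vapply(strsplit(w[-1], "/"), `[`, character(1), 1))
    if (length(idx) != 3L) stop("only triangular OBJ faces are supported")
    idx
  }))
  triangle_mesh(verts, faces)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}
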