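#' Read a 3D volume (NIfTI-1 or MetaImage)
#'
#' NIfTI (`.nii`, `.nii.gz`) is handled through RNifti; MetaImage
#' (`.mhd` + raw, or local `.mha`) through a built-in reader. The returned
#' grid uses the voxel-center origin convention of [volume_image()].
#'
#' @param path file path.
#' @return a `volume_image`.
#' @export
read_volume <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L) stop("only 3D NIfTI volumes are supported")
    arr <- array(as.numeric(arr), dim = dim(arr))  # strip NIfTI attributes
    xf <- RNifti::xform(img)
    spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
    origin <- xf[1:3, 4]
    return(volume_image(arr, origin = origin, spacing = spacing))
  }
  if (grepl("\\.mhd$", lp) || grepl("\\.mha$", lp)) return(read_metaimage(path))
  stop(sprintf("unsupported volume format: %s", path))
}

#' Write a 3D volume (NIfTI-1 or MetaImage)
#'
#' @param vol a `volume_image`.
#' @param path output path (`.nii`, `.nii.gz`, `.mhd` or `.mha`).
#' @param datatype `"float"` (32-bit, for dose) or `"short"` (16-bit signed,
#'   for HU volumes).
#' @return invisibly, `path`.
#' @export
write_volume <- function(vol, path, datatype = c("float", "short")) {
  stopifnot(inherits(vol, "volume_image"))
  datatype <- match.arg(datatype)
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    vals <- if (datatype == "short") round(vol$values) else vol$values
    img <- RNifti::asNifti(vals)
    img <- RNifti::`pixdim<-`(img, vol$spacing)
    xf <- diag(4)
    diag(xf)[1:3] <- vol$spacing
    xf[1:3, 4] <- vol$origin
    img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
    img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
    RNifti::writeNifti(img, path,
                       datatype = if (datatype == "short") "int16" else "float")
    return(invisible(path))
  }
  if (grepl("\\.mhd$", lp) || grepl("\\.mha$", lp))
    return(write_metaimage(vol, path, datatype))
  stop(sprintf("unsupported volume format: %s", path))
}

read_metaimage <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  kv <- list()
  local_data <- FALSE
  hdr_len <- 0L
  for (l in lines) {
    hdr_len <- hdr_len + nchar(l, type = "bytes") + 1L
    parts <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    key <- trimws(parts[1]); val <- trimws(paste(parts[-1], collapse = "="))
    kv[[key]] <- val
    if (key == "ElementDataFile") {
      local_data <- identical(val, "LOCAL")
      break
    }
  }
  dims <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(kv$ElementSpacing))
    as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(kv$Offset))
    as.numeric(strsplit(kv$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  et <- kv$ElementType
  n <- prod(dims)
  if (local_data) {
    raw <- readBin(path, "raw", file.info(path)$size)
    con <- rawConnection(raw[(hdr_len + 1L):length(raw)], "rb")
  } else {
    con <- file(file.path(dirname(path), kv$ElementDataFile), "rb")
  }
  on.exit(close(con))
  vals <- switch(et,
    MET_SHORT = readBin(con, "integer", n, size = 2, endian = "little"),
    MET_FLOAT = readBin(con, "double", n, size = 4, endian = "little"),
    MET_DOUBLE = readBin(con, "double", n, size = 8, endian = "little"),
    MET_UCHAR = readBin(con, "integer", n, size = 1, signed = FALSE),
    stop("unsupported MetaImage ElementType: ", et))
  volume_image(array(as.numeric(vals), dim = dims), origin = origin,
               spacing = spacing)
}

write_metaimage <- function(vol, path, datatype) {
  local_data <- grepl("\\.mha$", tolower(path))
  et <- if (datatype == "short") "MET_SHORT" else "MET_FLOAT"
  dims <- dim(vol$values)
  datafile <- if (local_data) "LOCAL" else
    paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %d %d %d", dims[1], dims[2], dims[3]),
           sprintf("ElementSpacing = %.9g %.9g %.9g", vol$spacing[1],
                   vol$spacing[2], vol$spacing[3]),
           sprintf("Offset = %.9g %.9g %.9g", vol$origin[1], vol$origin[2],
                   vol$origin[3]),
           sprintf("ElementType = %s", et),
           sprintf("ElementDataFile = %s", datafile))
  write_payload <- function(con) {
    if (datatype == "short")
      writeBin(as.integer(round(vol$values)), con, size = 2,
               endian = "little")
    else
      writeBin(as.numeric(vol$values), con, size = 4, endian = "little")
  }
  if (local_data) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    write_payload(con)
  } else {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(con))
    write_payload(con)
  }
  invisible(path)
}
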