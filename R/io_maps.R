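#' Write a 3-D scalar field as an Analyze 7.5 volume
#'
#' Writes a `.img`/`.hdr` pair (little-endian). The voxel pitch is
#' recorded in the header `pixdim` and the world origin of the grid
#' corner is carried in the header `descrip` field (Analyze 7.5 has no
#' native world origin). A plain raw + text-sidecar format is available
#' as a fallback.
#'
#' @param field 3-D numeric array (finite values).
#' @param path Output path without extension.
#' @param pitch Voxel edge length, mm.
#' @param origin World coordinate of the grid corner, mm.
#' @param datatype `"float32"` or `"float64"`.
#' @param format `"analyze"` (default) or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_map <- function(field, path, pitch = 1, origin = c(0, 0, 0),
                      datatype = c("float32", "float64"),
                      format = c("analyze", "raw")) {
  datatype <- match.arg(datatype)
  format <- match.arg(format)
  stopifnot(is.array(field), length(dim(field)) == 3L)
  if (!all(is.finite(field))) stop("field contains non-finite values")
  if (format == "analyze") {
    dt <- if (datatype == "float32") 16L else 64L
    vol <- oro.nifti::anlz(field, datatype = dt)
    vol@"pixdim"[2:4] <- rep(pitch, 3)
    vol@"descrip" <- sprintf("origin=%.9g,%.9g,%.9g", origin[1], origin[2], origin[3])
    oro.nifti::writeANALYZE(vol, path, gzipped = FALSE)
  } else {
    con <- file(paste0(path, ".raw"), "wb")
    on.exit(close(con))
    writeBin(as.numeric(field), con,
             size = if (datatype == "float32") 4L else 8L, endian = "little")
    writeLines(c(paste0("dims\t", paste(dim(field), collapse = " ")),
                 paste0("pitch_mm\t", format(pitch, digits = 15)),
                 paste0("origin_mm\t", paste(format(origin, digits = 15), collapse = " ")),
                 paste0("datatype\t", datatype),
                 "endian\tlittle"),
               paste0(path, ".rawhdr"))
  }
  invisible(path)
}

#' Read a 3-D scalar field written by [write_map()]
#'
#' @param path Path without extension.
#' @param format `"analyze"` or `"raw"`.
#' @return Numeric array with attributes `pitch` and `origin`.
#' @export
read_map <- function(path, format = c("analyze", "raw")) {
  format <- match.arg(format)
  if (format == "analyze") {
    hdr <- paste0(path, ".hdr")
    img <- paste0(path, ".img")
    if (!file.exists(hdr) || !file.exists(img))
      stop("format error: missing .hdr/.img pair at ", path)
    # sanity-check payload size against the header before decoding
    con <- file(hdr, "rb")
    sz <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    endian <- if (sz == 348L) "little" else "big"
    seek(con, 40)
    dims <- readBin(con, "integer", n = 8, size = 2, endian = endian)
    seek(con, 70)
    dtcode <- readBin(con, "integer", n = 1, size = 2, endian = endian)
    bitpix <- readBin(con, "integer", n = 1, size = 2, endian = endian)
    close(con)
    if (!dtcode %in% c(16L, 64L))
      stop("format error: unsupported data type code ", dtcode)
    expected <- prod(dims[2:4]) * (bitpix / 8)
    if (file.info(img)$size < expected)
      stop("format error: payload shorter than header dimensions imply")
    vol <- oro.nifti::readANALYZE(path)
    x <- array(as.numeric(oro.nifti::img_data(vol)), dim = vol@"dim_"[2:4])
    origin <- c(0, 0, 0)
    m <- regmatches(vol@"descrip",
                    regexec("origin=([-0-9.eE+]+),([-0-9.eE+]+),([-0-9.eE+]+)",
                            vol@"descrip"))[[1]]
    if (length(m) == 4L) origin <- as.numeric(m[2:4])
    attr(x, "pitch") <- vol@"pixdim"[2]
    attr(x, "origin") <- origin
    x
  } else {
    hdr <- paste0(path, ".rawhdr")
    if (!file.exists(hdr)) stop("format error: missing sidecar ", hdr)
    kv <- strsplit(readLines(hdr), "\t")
    meta <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
    dims <- as.integer(strsplit(meta$dims, " ")[[1]])
    datatype <- meta$datatype
    if (!datatype %in% c("float32", "float64"))
      stop("format error: unsupported data type ", datatype)
    size <- if (datatype == "float32") 4L else 8L
    raw_path <- paste0(path, ".raw")
    n <- prod(dims)
    if (file.info(raw_path)$size < n * size)
      stop("format error: payload shorter than header dimensions imply")
    con <- file(raw_path, "rb")
    on.exit(close(con))
    x <- array(readBin(con, "numeric", n = n, size = size, endian = "little"),
               dim = dims)
    attr(x, "pitch") <- as.numeric(meta$pitch_mm)
    attr(x, "origin") <- as.numeric(strsplit(meta$origin_mm, " ")[[1]])
    x
  }
}
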