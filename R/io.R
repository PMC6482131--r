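#' Read a CT volume
#'
#' Supported inputs: MetaImage (`.mhd`/`.mha`), NIfTI-1 (`.nii`/`.nii.gz`),
#' or a directory containing exactly one uncompressed little-endian DICOM
#' series.  Geometry is returned in the LPS (DICOM) world frame; NIfTI RAS
#' orientation is converted on read.  DICOM stored values are converted to HU
#' with the rescale slope/intercept, and slices are sorted by position along
#' the slice normal.
#'
#' @param path file or DICOM directory.
#' @return `image_volume`.
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path)) stop("read_volume: no such file: ", path)
  lp <- tolower(path)
  if (grepl("\\.(mhd|mha)$", lp)) return(read_metaimage(path))
  if (grepl("\\.nii(\\.gz)?$", lp)) return(read_nifti_lps(path))
  stop("read_volume: unsupported format: ", path)
}

#' Write a volume to MetaImage or NIfTI
#'
#' Lossless round-trip: `read_volume(write_volume(v, p))` reproduces all
#' fields (voxels stored as binary doubles for MetaImage; float64 NIfTI).
#'
#' @param volume `image_volume`.
#' @param path output path ending in `.mhd`, `.mha`, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  lp <- tolower(path)
  if (grepl("\\.(mhd|mha)$", lp)) write_metaimage(volume, path)
  else if (grepl("\\.nii(\\.gz)?$", lp)) write_nifti_lps(volume, path)
  else stop("write_volume: unsupported extension: ", path)
  invisible(path)
}

## ---- MetaImage ------------------------------------------------------------

met_types <- list(MET_CHAR = list(what = "integer", size = 1, signed = TRUE),
                  MET_UCHAR = list(what = "integer", size = 1, signed = FALSE),
                  MET_SHORT = list(what = "integer", size = 2, signed = TRUE),
                  MET_USHORT = list(what = "integer", size = 2, signed = FALSE),
                  MET_INT = list(what = "integer", size = 4, signed = TRUE),
                  MET_UINT = list(what = "integer", size = 4, signed = FALSE),
                  MET_FLOAT = list(what = "numeric", size = 4, signed = TRUE),
                  MET_DOUBLE = list(what = "numeric", size = 8, signed = TRUE))

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list(); nheader_bytes <- 0
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) stop("read_volume: truncated MetaImage header: ", path)
    nheader_bytes <- nheader_bytes + nchar(line, type = "bytes") + 1
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("read_volume: malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3) stop("read_volume: only 3-D MetaImage supported")
  ty <- met_types[[hdr$ElementType]]
  if (is.null(ty)) stop("read_volume: unsupported ElementType ", hdr$ElementType)
  if (identical(hdr$CompressedData, "True"))
    stop("read_volume: compressed MetaImage not supported")
  msb <- identical(hdr$BinaryDataByteOrderMSB, "True") ||
    identical(hdr$ElementByteOrderMSB, "True")
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- readBin(con, "raw", n = n * ty$size)
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    raw <- readBin(rawpath, "raw", n = n * ty$size)
  }
  if (length(raw) < n * ty$size) stop("read_volume: truncated MetaImage data: ", path)
  endian <- if (msb) "big" else "little"
  vals <- readBin(raw, ty$what, n = n, size = ty$size, signed = ty$signed,
                  endian = endian)
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  direction <- if (!is.null(hdr$TransformMatrix))
    matrix(as.numeric(strsplit(hdr$TransformMatrix, "\\s+")[[1]]), 3, 3,
           byrow = TRUE) else diag(3)
  image_volume(array(as.numeric(vals), dim = dims), spacing, origin, direction)
}

write_metaimage <- function(volume, path) {
  local_data <- grepl("\\.mha$", tolower(path))
  datafile <- if (local_data) "LOCAL" else paste0(
    sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           paste("TransformMatrix =",
                 paste(format(as.numeric(t(volume$direction)), digits = 17),
                       collapse = " ")),
           paste("Offset =", paste(format(volume$origin, digits = 17),
                                   collapse = " ")),
           paste("ElementSpacing =", paste(format(volume$spacing, digits = 17),
                                           collapse = " ")),
           paste("DimSize =", paste(dim(volume$voxels), collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", datafile))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("write_volume: cannot open ", path,
                                           ": ", conditionMessage(e)))
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (local_data) {
    writeBin(as.numeric(volume$voxels), con, size = 8, endian = "little")
  } else {
    rawpath <- file.path(dirname(path), datafile)
    rcon <- file(rawpath, "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(as.numeric(volume$voxels), rcon, size = 8, endian = "little")
  }
}

## ---- NIfTI (RAS on disk <-> LPS in memory) --------------------------------

ras_to_lps <- diag(c(-1, -1, 1))

read_nifti_lps <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3) stop("read_volume: only 3-D NIfTI supported")
  m <- RNifti::xform(img)                  # 4x4 voxel -> RAS world
  L <- ras_to_lps %*% m[1:3, 1:3]
  spacing <- sqrt(colSums(L^2))
  direction <- sweep(L, 2, spacing, "/")
  origin <- as.numeric(ras_to_lps %*% m[1:3, 4])
  image_volume(array(as.numeric(arr), dim = dim(arr)), spacing, origin,
               direction)
}

write_nifti_lps <- function(volume, path) {
  m <- diag(4)
  m[1:3, 1:3] <- ras_to_lps %*% volume$direction %*% diag(volume$spacing)
  m[1:3, 4] <- as.numeric(ras_to_lps %*% volume$origin)
  img <- RNifti::asNifti(volume$voxels, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
}

## ---- DICOM series (minimal reader) ----------------------------------------

# Parses uncompressed little-endian single-frame CT slices (explicit or
# implicit VR).  Enough of the standard for reading a series exported by a
# scanner or by the test fixture writer; no sequences, no compressed syntaxes.

dcm_tag <- function(g, e) sprintf("%04X,%04X", g, e)

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  pos <- 1
  explicit <- TRUE
  if (length(raw) > 132 && rawToChar(raw[129:132]) == "DICM") {
    pos <- 133
    # file meta group is always explicit LE
    meta <- list()
    repeat {
      if (pos + 7 > length(raw)) break
      g <- readBin(raw[pos:(pos + 1)], "integer", size = 2, signed = FALSE,
                   endian = "little")
      if (g != 2L) break
      el <- parse_element(raw, pos, explicit = TRUE)
      meta[[dcm_tag(el$group, el$elem)]] <- el
      pos <- el$next_pos
    }
    ts <- meta[["0002,0010"]]
    if (!is.null(ts)) {
      uid <- trimws(rawToChar(ts$value))
      uid <- gsub("\\x00", "", uid, useBytes = TRUE)
      if (uid == "1.2.840.10008.1.2") explicit <- FALSE
      else if (uid != "1.2.840.10008.1.2.1")
        stop("read_volume: unsupported DICOM transfer syntax ", uid)
    }
  }
  els <- list()
  while (pos + 7 <= length(raw)) {
    el <- parse_element(raw, pos, explicit)
    els[[dcm_tag(el$group, el$elem)]] <- el
    pos <- el$next_pos
    if (el$group == 0x7FE0 && el$elem == 0x0010) break
  }
  els
}

parse_element <- function(raw, pos, explicit) {
  u16 <- function(p) readBin(raw[p:(p + 1)], "integer", size = 2,
                             signed = FALSE, endian = "little")
  u32 <- function(p) readBin(raw[p:(p + 3)], "numeric", size = 4,
                             endian = "little") # avoid int overflow
  u32i <- function(p) {
    b <- as.integer(raw[p:(p + 3)])
    b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
  }
  g <- u16(pos); e <- u16(pos + 2)
  if (explicit) {
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32i(pos + 8); vstart <- pos + 12
    } else {
      len <- u16(pos + 6); vstart <- pos + 8
    }
  } else {
    vr <- NA_character_
    len <- u32i(pos + 4); vstart <- pos + 8
  }
  if (len == 4294967295)
    stop("read_volume: DICOM undefined-length element not supported")
  value <- if (len > 0) raw[vstart:(vstart + len - 1)] else raw(0)
  list(group = g, elem = e, vr = vr, value = value, next_pos = vstart + len)
}

dcm_str <- function(els, tag, default = NULL) {
  el <- els[[tag]]
  if (is.null(el)) return(default)
  s <- rawToChar(el$value)
  trimws(gsub("\\x00", "", s, useBytes = TRUE))
}

dcm_ds <- function(els, tag, default = NULL) {
  s <- dcm_str(els, tag)
  if (is.null(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_us <- function(els, tag) {
  el <- els[[tag]]
  if (is.null(el)) return(NULL)
  readBin(el$value, "integer", n = length(el$value) / 2, size = 2,
          signed = FALSE, endian = "little")[1]
}

read_dicom_series <- function(path) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("read_volume: no files in DICOM directory ", path)
  slices <- lapply(files, function(f) {
    els <- tryCatch(parse_dicom_file(f),
                    error = function(e) stop("read_volume: cannot parse DICOM file ",
                                             f, ": ", conditionMessage(e)))
    els
  })
  uids <- vapply(slices, function(els) dcm_str(els, "0020,000E", ""), "")
  useries <- unique(uids)
  if (length(useries) > 1)
    stop("read_volume: directory contains ", length(useries),
         " DICOM series: ", paste(useries, collapse = ", "))
  first <- slices[[1]]
  rows <- dcm_us(first, "0028,0010"); cols <- dcm_us(first, "0028,0011")
  bits <- dcm_us(first, "0028,0100")
  if (is.null(bits) || bits != 16)
    stop("read_volume: only 16-bit DICOM pixel data supported")
  pixrep <- dcm_us(first, "0028,0103"); if (is.null(pixrep)) pixrep <- 0L
  ps <- dcm_ds(first, "0028,0030", c(1, 1))     # row spacing, column spacing
  iop <- dcm_ds(first, "0020,0037", c(1, 0, 0, 0, 1, 0))
  rowdir <- iop[1:3]; coldir <- iop[4:6]
  normal <- c(rowdir[2] * coldir[3] - rowdir[3] * coldir[2],
              rowdir[3] * coldir[1] - rowdir[1] * coldir[3],
              rowdir[1] * coldir[2] - rowdir[2] * coldir[1])
  ipp <- t(vapply(slices, function(els) dcm_ds(els, "0020,0032", c(0, 0, 0)),
                  numeric(3)))
  ord <- order(ipp %*% normal)
  slices <- slices[ord]; ipp <- ipp[ord, , drop = FALSE]
  nz <- length(slices)
  zsp <- if (nz > 1) mean(diff(as.numeric(ipp %*% normal))) else {
    st <- dcm_ds(first, "0018,0050", 1); st[1]
  }
  vox <- array(0, dim = c(cols, rows, nz))
  for (k in seq_len(nz)) {
    els <- slices[[k]]
    pd <- els[["7FE0,0010"]]
    if (is.null(pd)) stop("read_volume: DICOM slice without PixelData")
    stored <- readBin(pd$value, "integer", n = rows * cols, size = 2,
                      signed = pixrep == 1, endian = "little")
    slope <- dcm_ds(els, "0028,1053", 1)[1]
    inter <- dcm_ds(els, "0028,1052", 0)[1]
    # row-major on disk: column (x) fastest
    vox[, , k] <- matrix(stored * slope + inter, nrow = cols, ncol = rows)
  }
  direction <- cbind(rowdir, coldir, normal)
  # DICOM: IOP row direction = direction of increasing column index (x)
  image_volume(vox, spacing = c(ps[2], ps[1], abs(zsp)),
               origin = ipp[1, ], direction = direction)
}
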