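## Minimal DICOM support: an explicit-VR little-endian reader for axial CT
## series plus a matching writer used to build synthetic fixtures at run
## time. No installed R package reads DICOM, and the method only needs
## plain single-frame axial CT slices, so the subset is deliberately small:
## uncompressed explicit-VR little endian, MONOCHROME2, 16-bit pixels,
## identity row/column orientation. Anything else is rejected loudly.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

uint16le <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])

uint32le <- function(raw4) {
  as.numeric(raw4[1]) + 256 * as.numeric(raw4[2]) +
    65536 * as.numeric(raw4[3]) + 16777216 * as.numeric(raw4[4])
}

rawUint16 <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %% 256L, x %/% 256L))
}

rawUint32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

## One explicit-VR element as raw bytes; value already raw and even-padded.
dcmElement <- function(group, element, vr, value) {
  if (length(value) %% 2L == 1L)
    value <- c(value, if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" "))
  hdr <- c(rawUint16(group), rawUint16(element), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(hdr, as.raw(c(0, 0)), rawUint32(length(value)), value)
  } else {
    c(hdr, rawUint16(length(value)), value)
  }
}

dcmString <- function(group, element, vr, s) {
  dcmElement(group, element, vr, charToRaw(s))
}

#' Write a VoxelVolume as a synthetic DICOM CT series
#'
#' Fixture plumbing: emits one explicit-VR little-endian single-frame CT
#' file per transverse slice (signed 16-bit pixels, rescale slope 1 /
#' intercept -1024, identity axial orientation), enough for
#' [loadVolume()] to reconstruct the volume. Intended for building test
#' inputs programmatically, not for clinical interchange.
#'
#' @param volume a [VoxelVolume-class]; values are rounded to integer HU.
#' @param dir output directory (created if absent).
#' @param dropSlices optional integer vector of 1-based slice indices to
#'   omit, to fabricate non-uniform slice gaps.
#' @return invisibly, the vector of file paths written.
#' @export
writeDicomSeries <- function(volume, dir, dropSlices = integer(0)) {
  stopifnot(is(volume, "VoxelVolume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(volume@data)
  sp <- volume@spacing
  paths <- character(0)
  for (k in seq_len(d[3])) {
    if (k %in% dropSlices) next
    raw16 <- as.integer(round(volume@data[, , k])) + 1024L
    if (any(raw16 < -32768L | raw16 > 32767L))
      stop("HU values out of int16 range after rescale")
    pix <- writeBin(raw16, raw(), size = 2, endian = "little")
    zpos <- volume@origin[3] + (k - 0.5) * sp[3]
    ds <- c(
      dcmString(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      dcmString(0x0008, 0x0018, "UI",
                sprintf("1.2.826.0.1.3680043.9999.%d", k)),
      dcmString(0x0020, 0x0013, "IS", as.character(k)),
      dcmString(0x0020, 0x0032, "DS",
                sprintf("%.6f\\%.6f\\%.6f", volume@origin[1] + 0.5 * sp[1],
                        volume@origin[2] + 0.5 * sp[2], zpos)),
      dcmString(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      dcmElement(0x0028, 0x0002, "US", rawUint16(1)),
      dcmString(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcmElement(0x0028, 0x0010, "US", rawUint16(d[2])),  # Rows (AP)
      dcmElement(0x0028, 0x0011, "US", rawUint16(d[1])),  # Columns (RL)
      dcmString(0x0028, 0x0030, "DS", sprintf("%.6f\\%.6f", sp[2], sp[1])),
      dcmElement(0x0028, 0x0100, "US", rawUint16(16)),
      dcmElement(0x0028, 0x0101, "US", rawUint16(16)),
      dcmElement(0x0028, 0x0102, "US", rawUint16(15)),
      dcmElement(0x0028, 0x0103, "US", rawUint16(1)),
      dcmString(0x0028, 0x1052, "DS", "-1024"),
      dcmString(0x0028, 0x1053, "DS", "1"),
      dcmString(0x0018, 0x0050, "DS", sprintf("%.6f", sp[3])),
      dcmElement(0x7FE0, 0x0010, "OW", pix)
    )
    meta <- c(
      dcmElement(0x0002, 0x0010, "UI", charToRaw(TS_EXPLICIT_LE))
    )
    meta <- c(dcmElement(0x0002, 0x0000, "UL", rawUint32(length(meta))), meta)
    path <- file.path(dir, sprintf("slice_%04d.dcm", k))
    con <- file(path, "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

## Parse one DICOM file into the handful of attributes the loader needs.
parseDicomFile <- function(path) {
  bytes <- readBin(path, raw(), file.info(path)$size)
  if (length(bytes) < 134L || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  out <- list()
  n <- length(bytes)
  while (pos + 7L <= n) {
    group <- uint16le(bytes[pos:(pos + 1L)])
    element <- uint16le(bytes[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit-VR or corrupt element in ", path,
           " (only explicit-VR little endian is supported)")
    if (vr %in% LONG_VRS) {
      len <- uint32le(bytes[(pos + 8L):(pos + 11L)])
      vstart <- pos + 12L
    } else {
      len <- uint16le(bytes[(pos + 6L):(pos + 7L)])
      vstart <- pos + 8L
    }
    if (vstart + len - 1L > n) stop("truncated element in ", path)
    val <- if (len > 0) bytes[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, element)
    out[[key]] <- list(vr = vr, value = val)
    pos <- vstart + len
  }
  ts <- out[["0002,0010"]]
  if (!is.null(ts)) {
    ts$value <- ts$value[ts$value != as.raw(0)]  # strip UI null padding
    uid <- sub("\\s+$", "", rawToChar(ts$value))
    if (uid != TS_EXPLICIT_LE)
      stop("unsupported transfer syntax ", uid, " in ", path)
  }
  out
}

dcmNumeric <- function(el) {
  if (is.null(el)) return(NULL)
  if (el$vr == "US") {
    n <- length(el$value) %/% 2L
    return(vapply(seq_len(n), function(i)
      uint16le(el$value[(2L * i - 1L):(2L * i)]), 0))
  }
  if (el$vr == "UL") {
    n <- length(el$value) %/% 4L
    return(vapply(seq_len(n), function(i)
      uint32le(el$value[(4L * i - 3L):(4L * i)]), 0))
  }
  txt <- sub("\\s+$", "", rawToChar(el$value[el$value != as.raw(0)]))
  as.numeric(strsplit(txt, "\\\\")[[1]])
}

loadDicomSeries <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory ", dir)
  slices <- lapply(files, parseDicomFile)

  getReq <- function(sl, key, what) {
    v <- dcmNumeric(sl[[key]])
    if (is.null(v)) stop("missing ", what, " in DICOM slice")
    v
  }
  rows <- vapply(slices, function(s) getReq(s, "0028,0010", "Rows"), 0)
  cols <- vapply(slices, function(s) getReq(s, "0028,0011", "Columns"), 0)
  if (length(unique(rows)) != 1L || length(unique(cols)) != 1L)
    stop("contradictory in-plane grid across DICOM slices")
  ps <- t(vapply(slices, function(s)
    getReq(s, "0028,0030", "PixelSpacing"), numeric(2)))
  if (any(apply(ps, 2, function(x) diff(range(x))) > 1e-9))
    stop("contradictory spacing metadata across DICOM slices")
  orient <- t(vapply(slices, function(s)
    getReq(s, "0020,0037", "ImageOrientationPatient"), numeric(6)))
  if (any(abs(sweep(orient, 2, c(1, 0, 0, 0, 1, 0))) > 1e-6))
    stop("unsupported DICOM orientation (only identity axial is supported)")
  ipp <- t(vapply(slices, function(s)
    getReq(s, "0020,0032", "ImagePositionPatient"), numeric(3)))
  if (any(apply(ipp[, 1:2, drop = FALSE], 2,
                function(x) diff(range(x))) > 1e-6))
    stop("contradictory spacing metadata: slice in-plane positions differ")

  ord <- order(ipp[, 3])
  slices <- slices[ord]
  z <- ipp[ord, 3]
  nz <- length(z)
  if (nz >= 2L) {
    gaps <- diff(z)
    nominal <- stats::median(gaps)
    bad <- which(abs(gaps - nominal) > 0.01 * nominal)
    if (length(bad))
      stop(sprintf(
        "non-uniform slice spacing: gap between slices %d and %d is %.4f mm (nominal %.4f mm)",
        bad[1], bad[1] + 1L, gaps[bad[1]], nominal))
    dz <- nominal
  } else {
    dz <- dcmNumeric(slices[[1]][["0018,0050"]])
    if (is.null(dz)) stop("missing spacing metadata: single slice without SliceThickness")
  }
  if (!is.finite(dz) || dz <= 0) stop("missing or contradictory spacing metadata")

  nx <- as.integer(cols[1]); ny <- as.integer(rows[1])
  dat <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    sl <- slices[[k]]
    bits <- getReq(sl, "0028,0100", "BitsAllocated")
    if (bits != 16) stop("only 16-bit DICOM pixel data is supported")
    signed <- getReq(sl, "0028,0103", "PixelRepresentation") == 1
    pd <- sl[["7FE0,0010"]]
    if (is.null(pd)) stop("missing PixelData in DICOM slice")
    raw16 <- readBin(pd$value, "integer", n = nx * ny, size = 2,
                     signed = signed, endian = "little")
    slope <- dcmNumeric(sl[["0028,1053"]]); if (is.null(slope)) slope <- 1
    icpt <- dcmNumeric(sl[["0028,1052"]]); if (is.null(icpt)) icpt <- 0
    dat[, , k] <- matrix(slope * raw16 + icpt, nx, ny)
  }
  VoxelVolume(dat, spacing = c(ps[1, 2], ps[1, 1], dz),
              origin = c(ipp[1, 1] - 0.5 * ps[1, 2],
                         ipp[1, 2] - 0.5 * ps[1, 1],
                         z[1] - 0.5 * dz),
              sourceId = basename(dir))
}
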