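# Minimal DICOM reader/writer: explicit-VR little-endian transfer syntax only,
# covering the tags needed for CT/CBCT series, RT Dose and RT Structure Set
# objects.  Datasets are represented as named lists keyed "GGGGEEEE" (upper-case
# hex); sequences (SQ) are lists of item datasets.

dcm_tag <- function(group, element) sprintf("%04X%04X", group, element)

.vr_long <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.vr_text <- c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN", "SH", "ST", "TM",
              "UI", "UC", "UR")

dcm_parse_value <- function(vr, bytes) {
  if (vr %in% .vr_text) {
    s <- rawToChar(bytes[bytes != as.raw(0)])
    s <- sub("[ ]+$", "", s)
    return(strsplit(s, "\\\\")[[1]])
  }
  switch(vr,
         DS = , IS = {
           s <- rawToChar(bytes[bytes != as.raw(0)])
           as.numeric(strsplit(trimws(s), "\\\\")[[1]])
         },
         US = readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
                      endian = "little", signed = FALSE),
         SS = readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
                      endian = "little", signed = TRUE),
         UL = , SL = readBin(bytes, "integer", n = length(bytes) / 4, size = 4,
                             endian = "little"),
         FL = readBin(bytes, "double", n = length(bytes) / 4, size = 4,
                      endian = "little"),
         FD = readBin(bytes, "double", n = length(bytes) / 8, size = 8,
                      endian = "little"),
         bytes)  # OB/OW/UN and anything else stays raw
}

# parse one dataset from `raw` starting at cursor position `pos` (1-based),
# stopping at `end` (inclusive) or at an item-delimitation tag
dcm_parse_dataset <- function(raw, pos, end) {
  out <- list()
  while (pos + 7 <= end + 1) {
    grp <- readBin(raw[pos:(pos + 1)], "integer", size = 2, endian = "little",
                   signed = FALSE)
    ele <- readBin(raw[(pos + 2):(pos + 3)], "integer", size = 2,
                   endian = "little", signed = FALSE)
    if (grp == 0xFFFE && ele %in% c(0xE00D, 0xE0DD))  # delimiters
      return(list(ds = out, pos = pos + 8))
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% .vr_long) {
      len <- readBin(raw[(pos + 8):(pos + 11)], "integer", size = 4,
                     endian = "little")
      pos <- pos + 12
    } else {
      len <- readBin(raw[(pos + 6):(pos + 7)], "integer", size = 2,
                     endian = "little", signed = FALSE)
      pos <- pos + 8
    }
    key <- dcm_tag(grp, ele)
    if (vr == "SQ") {
      items <- list()
      if (len == -1L) {  # undefined length
        repeat {
          ig <- readBin(raw[pos:(pos + 1)], "integer", size = 2,
                        endian = "little", signed = FALSE)
          ie <- readBin(raw[(pos + 2):(pos + 3)], "integer", size = 2,
                        endian = "little", signed = FALSE)
          il <- readBin(raw[(pos + 4):(pos + 7)], "integer", size = 4,
                        endian = "little")
          pos <- pos + 8
          if (ig == 0xFFFE && ie == 0xE0DD) break
          if (!(ig == 0xFFFE && ie == 0xE000)) stop("malformed sequence item")
          item_end <- if (il == -1L) end else pos + il - 1
          r <- dcm_parse_dataset(raw, pos, item_end)
          items[[length(items) + 1]] <- r$ds
          pos <- r$pos
        }
      } else {
        sq_end <- pos + len - 1
        while (pos < sq_end) {
          il <- readBin(raw[(pos + 4):(pos + 7)], "integer", size = 4,
                        endian = "little")
          pos <- pos + 8
          item_end <- if (il == -1L) sq_end else pos + il - 1
          r <- dcm_parse_dataset(raw, pos, item_end)
          items[[length(items) + 1]] <- r$ds
          pos <- r$pos
        }
      }
      out[[key]] <- items
    } else {
      bytes <- if (len > 0) raw[pos:(pos + len - 1)] else raw(0)
      out[[key]] <- dcm_parse_value(vr, bytes)
      pos <- pos + len
    }
  }
  list(ds = out, pos = pos)
}

#' Read a DICOM file (explicit VR little endian)
#'
#' @param path file path.
#' @return named list of data elements keyed `"GGGGEEEE"`; sequence elements
#'   are lists of item datasets, pixel data stays raw.
#' @export
read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 136 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  ds <- dcm_parse_dataset(raw, 133, length(raw))$ds
  ts <- ds[[dcm_tag(0x0002, 0x0010)]]
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1")
    stop("unsupported transfer syntax ", ts,
         " (only explicit VR little endian)", call. = FALSE)
  ds
}

dcm_need <- function(ds, group, element, what) {
  v <- ds[[dcm_tag(group, element)]]
  if (is.null(v))
    stop("missing required DICOM tag (", sprintf("%04X,%04X", group, element),
         ") ", what, call. = FALSE)
  v
}

# ---- writer ---------------------------------------------------------------

dcm_encode_value <- function(vr, value) {
  if (vr %in% .vr_text) {
    s <- paste(value, collapse = "\\")
    b <- charToRaw(s)
    if (length(b) %% 2) b <- c(b, if (vr == "UI") as.raw(0) else charToRaw(" "))
    return(b)
  }
  b <- switch(vr,
              DS = charToRaw(paste(vapply(value, function(v) sprintf("%.10g", v), ""),
                                   collapse = "\\")),
              IS = charToRaw(paste(format(as.integer(value)), collapse = "\\")),
              US = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
              SS = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
              UL = , SL = writeBin(as.integer(value), raw(), size = 4, endian = "little"),
              FL = writeBin(as.numeric(value), raw(), size = 4, endian = "little"),
              FD = writeBin(as.numeric(value), raw(), size = 8, endian = "little"),
              as.raw(value))
  if (length(b) %% 2) b <- c(b, charToRaw(" "))
  b
}

dcm_encode_element <- function(group, element, vr, value) {
  body <- if (vr == "SQ") {
    items <- lapply(value, function(item) {
      enc <- dcm_encode_dataset(item)
      c(writeBin(c(0xFFFEL, 0xE000L), raw(), size = 2, endian = "little"),
        writeBin(length(enc), raw(), size = 4, endian = "little"), enc)
    })
    do.call(c, c(items, list(raw(0))))
  } else dcm_encode_value(vr, value)
  head <- c(writeBin(as.integer(c(group, element)), raw(), size = 2, endian = "little"),
            charToRaw(vr))
  if (vr %in% .vr_long) {
    c(head, as.raw(c(0, 0)), writeBin(length(body), raw(), size = 4,
                                      endian = "little"), body)
  } else {
    c(head, writeBin(length(body), raw(), size = 2, endian = "little"), body)
  }
}

# elements: list of list(group, element, vr, value); sorted before writing
dcm_encode_dataset <- function(elements) {
  if (!length(elements)) return(raw(0))
  ord <- order(vapply(elements, function(e) e$group * 2^16 + e$element, 0))
  do.call(c, lapply(elements[ord], function(e)
    dcm_encode_element(e$group, e$element, e$vr, e$value)))
}

el <- function(group, element, vr, value) list(group = group, element = element,
                                               vr = vr, value = value)

#' Write a DICOM file (explicit VR little endian)
#'
#' @param elements list of data elements, each `list(group, element, vr,
#'   value)`; sequences use `vr = "SQ"` with a list of item element lists.
#' @param path output path.
#' @param sop_class,sop_instance UIDs for the file-meta group.
#' @export
write_dicom_file <- function(elements, path,
                             sop_class = "1.2.840.10008.5.1.4.1.1.2",
                             sop_instance = dicom_uid()) {
  meta <- list(el(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
               el(0x0002, 0x0002, "UI", sop_class),
               el(0x0002, 0x0003, "UI", sop_instance),
               el(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
  meta_raw <- dcm_encode_dataset(meta)
  body <- c(dcm_encode_element(0x0002, 0x0000, "UL", length(meta_raw)),
            meta_raw, dcm_encode_dataset(elements))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  invisible(path)
}

.uid_counter <- local({ i <- 0L; function() { i <<- i + 1L; i } })

#' Generate a unique-enough DICOM UID under a test root
#' @export
dicom_uid <- function() {
  sprintf("1.2.826.0.1.3680043.9999.%d.%d.%d",
          as.integer(Sys.time()) %% 100000L, Sys.getpid() %% 10000L, .uid_counter())
}

# ---- CT / CBCT series -----------------------------------------------------

dcm_check_orientation <- function(iop) {
  if (max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-4)
    stop("only axis-aligned (identity orientation) DICOM volumes are supported",
         call. = FALSE)
}

#' Read a DICOM CT/CBCT series into an image volume
#'
#' @param paths a directory containing the series, or a vector of file paths.
#' @param spacing_tol tolerated relative deviation of inter-slice spacing from
#'   uniformity before a hard error.
#' @return an [image_volume()] in Hounsfield-like rescaled units.
#' @export
read_dicom_series <- function(paths, spacing_tol = 0.01) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, full.names = TRUE, pattern = "\\.dcm$")
  if (length(paths) < 2) stop("a DICOM series needs >= 2 slices", call. = FALSE)
  slices <- lapply(paths, read_dicom_file)
  z <- vapply(slices, function(ds) dcm_need(ds, 0x0020, 0x0032,
                                            "ImagePositionPatient")[3], 0)
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  dz <- diff(z)
  if (any(abs(dz - mean(dz)) > spacing_tol * abs(mean(dz))))
    stop("non-uniform DICOM slice spacing beyond tolerance", call. = FALSE)
  ds1 <- slices[[1]]
  dcm_check_orientation(dcm_need(ds1, 0x0020, 0x0037, "ImageOrientationPatient"))
  rows <- dcm_need(ds1, 0x0028, 0x0010, "Rows")
  cols <- dcm_need(ds1, 0x0028, 0x0011, "Columns")
  ps <- dcm_need(ds1, 0x0028, 0x0030, "PixelSpacing")  # (row, col) = (y, x)
  slope <- ds1[[dcm_tag(0x0028, 0x1053)]] %||% 1
  inter <- ds1[[dcm_tag(0x0028, 0x1052)]] %||% 0
  bits <- dcm_need(ds1, 0x0028, 0x0100, "BitsAllocated")
  signed <- (ds1[[dcm_tag(0x0028, 0x0103)]] %||% 0) == 1
  arr <- array(0, c(cols, rows, length(slices)))
  for (s in seq_along(slices)) {
    px <- dcm_need(slices[[s]], 0x7FE0, 0x0010, "PixelData")
    v <- readBin(px, "integer", n = rows * cols, size = bits / 8,
                 endian = "little", signed = signed)
    arr[, , s] <- v  # column index fastest in DICOM row-major order
  }
  origin <- dcm_need(ds1, 0x0020, 0x0032, "ImagePositionPatient")
  image_volume(arr * slope + inter, spacing = c(ps[2], ps[1], mean(dz)),
               origin = origin)
}

#' Read a DICOM RT Dose object
#'
#' Honors `DoseGridScaling`: returned values are `scaling * stored_pixel` Gy.
#'
#' @param path RT Dose file.
#' @return a [dose_grid()] on the dose object's native grid.
#' @export
read_dicom_rtdose <- function(path) {
  ds <- read_dicom_file(path)
  dcm_check_orientation(dcm_need(ds, 0x0020, 0x0037, "ImageOrientationPatient"))
  rows <- dcm_need(ds, 0x0028, 0x0010, "Rows")
  cols <- dcm_need(ds, 0x0028, 0x0011, "Columns")
  nfr <- as.integer(dcm_need(ds, 0x0028, 0x0008, "NumberOfFrames"))
  ps <- dcm_need(ds, 0x0028, 0x0030, "PixelSpacing")
  off <- dcm_need(ds, 0x3004, 0x000C, "GridFrameOffsetVector")
  scaling <- dcm_need(ds, 0x3004, 0x000E, "DoseGridScaling")
  bits <- dcm_need(ds, 0x0028, 0x0100, "BitsAllocated")
  px <- dcm_need(ds, 0x7FE0, 0x0010, "PixelData")
  v <- readBin(px, "integer", n = rows * cols * nfr, size = bits / 8,
               endian = "little", signed = FALSE)
  dz <- if (nfr > 1) mean(diff(off)) else 1
  origin <- dcm_need(ds, 0x0020, 0x0032, "ImagePositionPatient")
  dose_grid(array(v * scaling, c(cols, rows, nfr)),
            spacing = c(ps[2], ps[1], dz), origin = origin + c(0, 0, off[1]))
}

#' Read contours from a DICOM RT Structure Set
#'
#' @param path RT Structure Set file.
#' @return named list: per structure, a list of closed planar contours, each an
#'   n x 3 matrix of world mm coordinates.
#' @export
read_dicom_rtstruct <- function(path) {
  ds <- read_dicom_file(path)
  rois <- dcm_need(ds, 0x3006, 0x0020, "StructureSetROISequence")
  names_by_number <- stats::setNames(
    vapply(rois, function(r) dcm_need(r, 0x3006, 0x0026, "ROIName"), ""),
    vapply(rois, function(r) as.character(dcm_need(r, 0x3006, 0x0022, "ROINumber")), ""))
  contours <- dcm_need(ds, 0x3006, 0x0039, "ROIContourSequence")
  out <- list()
  for (rc in contours) {
    num <- as.character(dcm_need(rc, 0x3006, 0x0084, "ReferencedROINumber"))
    cs <- rc[[dcm_tag(0x3006, 0x0040)]]
    polys <- lapply(cs %||% list(), function(cnt) {
      dat <- dcm_need(cnt, 0x3006, 0x0050, "ContourData")
      matrix(dat, ncol = 3, byrow = TRUE)
    })
    out[[names_by_number[[num]]]] <- polys
  }
  out
}

read_dicom_bundle <- function(paths, plan_meta, required_structures = NULL) {
  if (is.null(plan_meta) || is.null(plan_meta$total_fractions))
    stop("DICOM dialect needs `plan_meta` with at least `total_fractions`",
         call. = FALSE)
  image <- read_dicom_series(paths$ct)
  dose_native <- read_dicom_rtdose(paths$rtdose)
  dose <- if (same_geometry(dose_native, image)) dose_native else {
    r <- resample_to_grid(dose_native, image, background = 0)
    dose_grid(r$voxels, image$spacing, image$origin)
  }
  contours <- read_dicom_rtstruct(paths$rtstruct)
  roles <- plan_meta$roles %||% list()
  rx <- plan_meta$prescriptions %||% list()
  structures <- lapply(names(contours), function(nm) {
    mask <- rasterize_contours(contours[[nm]], image)
    role <- roles[[nm]] %||% "oar"
    rt_structure(nm, role, mask,
                 prescription = if (role == "target") rx[[nm]] else NULL)
  })
  plan <- plan_context(plan_meta$total_fractions, structures)
  if (length(required_structures)) {
    miss <- setdiff(required_structures, names(plan$structures))
    if (length(miss))
      stop("structure(s) referenced in endpoint config but absent from bundle: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  list(image = image, plan = plan, dose = dose)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
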