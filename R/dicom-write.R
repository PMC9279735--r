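# DICOM writers. Primarily used to materialise volumes as portable DICOM-RT
# objects and to build test fixtures at run time.

ct_common_elements <- function(vol, rows, cols) {
  list(el(0x0008, 0x0060, "CS", "CT"),
       el(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0)),
       el(0x0028, 0x0002, "US", 1),
       el(0x0028, 0x0004, "CS", "MONOCHROME2"),
       el(0x0028, 0x0010, "US", rows),
       el(0x0028, 0x0011, "US", cols),
       el(0x0028, 0x0030, "DS", c(vol$spacing[2], vol$spacing[1])),
       el(0x0028, 0x0100, "US", 16),
       el(0x0028, 0x0101, "US", 16),
       el(0x0028, 0x0102, "US", 15),
       el(0x0028, 0x0103, "US", 0))
}

#' Write an image volume as a DICOM CT series
#'
#' One file per axial slice, explicit VR little endian, identity orientation,
#' 16-bit pixels with rescale intercept -1024 (values are clamped to the
#' representable range).
#'
#' @param vol an [image_volume()] in HU-like units.
#' @param dir output directory.
#' @return vector of file paths, invisibly.
#' @export
write_dicom_ct_series <- function(vol, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- vol_dim(vol)
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    px <- round(vol$voxels[, , k]) + 1024
    px <- pmin(pmax(px, 0), 65535)
    elems <- c(ct_common_elements(vol, rows = d[2], cols = d[1]),
               list(el(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
                    el(0x0008, 0x0018, "UI", dicom_uid()),
                    el(0x0018, 0x0050, "DS", vol$spacing[3]),
                    el(0x0020, 0x0013, "IS", k),
                    el(0x0020, 0x0032, "DS",
                       c(vol$origin[1], vol$origin[2],
                         vol$origin[3] + (k - 1) * vol$spacing[3])),
                    el(0x0028, 0x1052, "DS", -1024),
                    el(0x0028, 0x1053, "DS", 1),
                    el(0x7FE0, 0x0010, "OW",
                       writeBin(as.integer(px), raw(), size = 2,
                                endian = "little"))))
    paths[k] <- file.path(dir, sprintf("ct_%04d.dcm", k))
    write_dicom_file(elems, paths[k])
  }
  invisible(paths)
}

#' Write a dose grid as a DICOM RT Dose object
#'
#' Multi-frame 16-bit storage with `DoseGridScaling` chosen from the maximum
#' dose (or given explicitly); stored pixel times scaling reproduces Gy.
#'
#' @param dose a [dose_grid()].
#' @param path output file.
#' @param scaling Gy per stored pixel unit; default spans the dose range over
#'   the 16-bit scale.
#' @export
write_dicom_rtdose <- function(dose, path, scaling = NULL) {
  d <- vol_dim(dose)
  if (is.null(scaling)) scaling <- max(dose$voxels, 1e-6) / 60000
  px <- pmin(pmax(round(dose$voxels / scaling), 0), 65535)
  elems <- c(ct_common_elements(dose, rows = d[2], cols = d[1]),
             list(el(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.481.2"),
                  el(0x0008, 0x0018, "UI", dicom_uid()),
                  el(0x0008, 0x0060, "CS", "RTDOSE"),
                  el(0x0020, 0x0032, "DS", dose$origin),
                  el(0x0028, 0x0008, "IS", d[3]),
                  el(0x3004, 0x0002, "CS", "GY"),
                  el(0x3004, 0x000C, "DS", (seq_len(d[3]) - 1) * dose$spacing[3]),
                  el(0x3004, 0x000E, "DS", scaling),
                  el(0x7FE0, 0x0010, "OW",
                     writeBin(as.integer(px), raw(), size = 2,
                              endian = "little"))))
  elems <- elems[!vapply(elems, function(e)
    e$group == 0x0008 && e$element == 0x0060 && identical(e$value, "CT"), TRUE)]
  write_dicom_file(elems, path, sop_class = "1.2.840.10008.5.1.4.1.1.481.2")
  invisible(path)
}

#' Write contours as a DICOM RT Structure Set
#'
#' @param contours named list; per structure, a list of closed planar contours
#'   (n x 3 world mm matrices).
#' @param path output file.
#' @export
write_dicom_rtstruct <- function(contours, path) {
  roi_items <- lapply(seq_along(contours), function(i)
    list(el(0x3006, 0x0022, "IS", i),
         el(0x3006, 0x0026, "LO", names(contours)[i])))
  contour_items <- lapply(seq_along(contours), function(i) {
    cseq <- lapply(contours[[i]], function(poly)
      list(el(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
           el(0x3006, 0x0046, "IS", nrow(poly)),
           el(0x3006, 0x0050, "DS", as.numeric(t(poly)))))
    list(el(0x3006, 0x0040, "SQ", cseq),
         el(0x3006, 0x0084, "IS", i))
  })
  elems <- list(el(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.481.3"),
                el(0x0008, 0x0018, "UI", dicom_uid()),
                el(0x0008, 0x0060, "CS", "RTSTRUCT"),
                el(0x3006, 0x0020, "SQ", roi_items),
                el(0x3006, 0x0039, "SQ", contour_items))
  write_dicom_file(elems, path, sop_class = "1.2.840.10008.5.1.4.1.1.481.3")
  invisible(path)
}
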