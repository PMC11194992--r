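# Minimal DICOM Part-10 I/O, Explicit VR Little Endian only.
#
# Scope: single-frame monochrome images with the handful of attributes the
# preprocessing pipeline needs (geometry, bit depth, windowing, patient and
# modality tags). This is deliberately not a general DICOM implementation —
# no installed package provides one here — and it refuses files outside the
# transfer syntax it writes.

EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
SECONDARY_CAPTURE_UID <- "1.2.840.10008.5.1.4.1.1.7"

# little-endian unsigned integer -> raw
uintN_raw <- function(x, n_bytes) {
  x <- as.numeric(x)
  out <- raw(n_bytes * length(x))
  for (b in seq_len(n_bytes)) {
    out[seq(b, length(out), by = n_bytes)] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

raw_uintN <- function(r, n_bytes) {
  m <- matrix(as.integer(r), nrow = n_bytes)
  as.numeric(256^(seq_len(n_bytes) - 1) %*% m)
}

# one explicit-VR data element
dicom_element <- function(group, element, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L) {  # even-length padding
    value_raw <- c(value_raw, if (vr %in% c("UI", "OB")) as.raw(0)
                   else charToRaw(" "))
  }
  head <- c(uintN_raw(group, 2L), uintN_raw(element, 2L), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), uintN_raw(length(value_raw), 4L), value_raw)
  } else {
    c(head, uintN_raw(length(value_raw), 2L), value_raw)
  }
}

el_str <- function(group, element, vr, s) {
  dicom_element(group, element, vr, charToRaw(as.character(s)))
}
el_us <- function(group, element, v) {
  dicom_element(group, element, "US", uintN_raw(v, 2L))
}

new_uid <- function(suffix) paste0("1.2.826.0.1.3680043.9.7432.", suffix)

#' Write a single-frame monochrome DICOM file
#'
#' Emits a Part-10 file in the Explicit VR Little Endian transfer syntax:
#' 16-bit unsigned MONOCHROME2 pixel data with rows/columns, bit-depth,
#' window and patient attributes. This is the on-disk format the synthetic
#' phantom generator produces and the preprocessing pipeline consumes.
#'
#' @param pixels Integer matrix of pixel values in `[0, 65535]` (rows =
#'   image rows).
#' @param path Output file path (conventionally `.dcm` or `.dic`).
#' @param patient_id Subject identifier stored in the PatientID attribute.
#' @param modality Two-letter DICOM modality code (default `"MR"`).
#' @param window_center,window_width Display window; defaults cover the
#'   full 16-bit range so 8-bit conversion is a pure linear rescale.
#' @param instance Integer used to build a distinct SOP instance UID.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(pixels, path, patient_id = "anon", modality = "MR",
                        window_center = 32767.5, window_width = 65536,
                        instance = 1L) {
  pixels <- round(as.matrix(pixels))
  if (any(pixels < 0) || any(pixels > 65535)) {
    stop("pixel values must lie in [0, 65535]", call. = FALSE)
  }
  rows <- nrow(pixels); cols <- ncol(pixels)
  pix_raw <- uintN_raw(as.vector(t(pixels)), 2L)  # row-major on disk

  meta <- c(
    dicom_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    el_str(0x0002, 0x0002, "UI", SECONDARY_CAPTURE_UID),
    el_str(0x0002, 0x0003, "UI", new_uid(instance)),
    el_str(0x0002, 0x0010, "UI", EXPLICIT_VR_LE),
    el_str(0x0002, 0x0012, "UI", new_uid("0.1"))
  )
  meta <- c(dicom_element(0x0002, 0x0000, "UL", uintN_raw(length(meta), 4L)),
            meta)

  body <- c(
    el_str(0x0008, 0x0016, "UI", SECONDARY_CAPTURE_UID),
    el_str(0x0008, 0x0018, "UI", new_uid(instance)),
    el_str(0x0008, 0x0060, "CS", modality),
    el_str(0x0010, 0x0010, "PN", patient_id),
    el_str(0x0010, 0x0020, "LO", patient_id),
    el_us(0x0028, 0x0002, 1L),
    el_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    el_us(0x0028, 0x0010, rows),
    el_us(0x0028, 0x0011, cols),
    el_us(0x0028, 0x0100, 16L),
    el_us(0x0028, 0x0101, 16L),
    el_us(0x0028, 0x0102, 15L),
    el_us(0x0028, 0x0103, 0L),
    el_str(0x0028, 0x1050, "DS", format(window_center)),
    el_str(0x0028, 0x1051, "DS", format(window_width)),
    dicom_element(0x7FE0, 0x0010, "OW", pix_raw)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

#' Read a DICOM file written in Explicit VR Little Endian
#'
#' Parses the attributes the pipeline needs (geometry, bit depth, window,
#' patient, modality) and the pixel data. Files in other transfer syntaxes
#' or without pixel data raise a format error naming the path.
#'
#' @param path Path to a `.dcm`/`.dic` file.
#' @return List with `pixels` (numeric matrix), `rows`, `cols`,
#'   `bits_allocated`, `window_center`, `window_width`, `patient_id`,
#'   `modality`, `path`.
#' @export
read_dicom <- function(path) {
  if (!file.exists(path)) stop("no such DICOM file: ", path, call. = FALSE)
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 160 || rawToChar(r[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  }
  pos <- 133L
  out <- list(path = path, bits_allocated = 16L)
  pixel_raw <- NULL
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8L <= length(r) + 1L) {
    group <- raw_uintN(r[pos:(pos + 1L)], 2L)
    element <- raw_uintN(r[(pos + 2L):(pos + 3L)], 2L)
    vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop("unsupported (non-explicit-VR?) DICOM encoding in: ", path,
           call. = FALSE)
    }
    if (vr %in% long_vrs) {
      len <- raw_uintN(r[(pos + 8L):(pos + 11L)], 4L)
      val_start <- pos + 12L
    } else {
      len <- raw_uintN(r[(pos + 6L):(pos + 7L)], 2L)
      val_start <- pos + 8L
    }
    val <- if (len > 0) r[val_start:(val_start + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, element)
    str_val <- function() trimws(rawToChar(val))
    switch(key,
      "0008,0060" = out$modality <- str_val(),
      "0010,0020" = out$patient_id <- str_val(),
      "0028,0010" = out$rows <- as.integer(raw_uintN(val, 2L)),
      "0028,0011" = out$cols <- as.integer(raw_uintN(val, 2L)),
      "0028,0100" = out$bits_allocated <- as.integer(raw_uintN(val, 2L)),
      "0028,1050" = out$window_center <- as.numeric(str_val()),
      "0028,1051" = out$window_width <- as.numeric(str_val()),
      "7FE0,0010" = pixel_raw <- val,
      NULL
    )
    pos <- val_start + len
  }
  if (is.null(pixel_raw) || is.null(out$rows) || is.null(out$cols)) {
    stop("missing pixel data or geometry in DICOM file: ", path,
         call. = FALSE)
  }
  n_bytes <- out$bits_allocated %/% 8L
  v <- raw_uintN(pixel_raw[seq_len(out$rows * out$cols * n_bytes)], n_bytes)
  out$pixels <- matrix(v, nrow = out$rows, ncol = out$cols, byrow = TRUE)
  out
}
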