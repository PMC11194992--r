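#' @title Synthetic brain-phantom generator
#' @description
#' Deterministic generator of two-class axial brain-like slices so the
#' whole pipeline is testable without access-restricted clinical data.
#' Each phantom has an elliptical bright skull ring, textured interior
#' tissue, and two small striatal foci whose intensity and shape differ by
#' class: healthy-control foci are bright and elongated (the comma-shaped
#' tracer uptake of an intact striatum) while disease-class foci are
#' dimmer and rounder (the dot appearance of reduced uptake). A
#' controllable fraction of slices is emitted near-blank to exercise the
#' empty-slice filter. The generator emulates the image *structure* the
#' pipeline depends on — blanks, a strippable skull, a separable class
#' signal — not MRI physics.
#' @name synthetic_data
NULL

#' Phantom generation parameters
#'
#' @param size Square image side in pixels (default 256, the native
#'   acquisition matrix the pipeline expects to resize from).
#' @param skull_radius Outer skull radius as a fraction of `size/2`.
#' @param skull_thickness Ring thickness in pixels.
#' @param tissue_mean,tissue_noise Interior tissue base intensity and
#'   Gaussian texture standard deviation (8-bit units).
#' @param focus_radius Striatal focus radius in pixels.
#' @param separation Mean intensity gap between HC and PD foci (8-bit
#'   units); 0 makes the classes indistinguishable.
#' @param blank_fraction Fraction of generated slices that are near-blank.
#' @param modality `"t1t2"` or `"datscan"` (metadata only).
#' @param seed Integer seed.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(size = 256L, skull_radius = 0.85,
                         skull_thickness = 8, tissue_mean = 120,
                         tissue_noise = 10, focus_radius = 10,
                         separation = 40, blank_fraction = 0,
                         modality = c("t1t2", "datscan"), seed = 1L) {
  modality <- match.arg(modality)
  if (blank_fraction < 0 || blank_fraction >= 1) {
    stop("`blank_fraction` must lie in [0, 1)", call. = FALSE)
  }
  structure(list(size = as.integer(size), skull_radius = skull_radius,
                 skull_thickness = skull_thickness,
                 tissue_mean = tissue_mean, tissue_noise = tissue_noise,
                 focus_radius = focus_radius, separation = separation,
                 blank_fraction = blank_fraction, modality = modality,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one phantom slice
#'
#' Draws a single 8-bit slice plus its true head mask. HC foci have mean
#' intensity `tissue_mean + 60 + separation` and eccentricity 2 (comma);
#' PD foci have mean `tissue_mean + 60` and eccentricity 1 (dot). Blank
#' slices are low-amplitude noise with an all-false mask.
#'
#' @param spec A [phantom_spec()].
#' @param label `"PD"` or `"HC"`.
#' @param blank Emit a near-blank slice instead of anatomy.
#' @return List with `pixels` (8-bit matrix), `mask` (logical head mask),
#'   `label`, `is_blank`, and `focus_intensity` (the realized focus mean).
#' @export
generate_image <- function(spec, label = c("PD", "HC"), blank = FALSE) {
  label <- match.arg(label)
  n <- spec$size
  if (blank) {
    return(list(pixels = matrix(sample(0:8, n * n, replace = TRUE), n, n),
                mask = matrix(FALSE, n, n), label = label, is_blank = TRUE,
                focus_intensity = NA_real_))
  }
  ctr <- (n + 1) / 2
  xs <- matrix(seq_len(n) - ctr, n, n)        # rows
  ys <- t(xs)                                  # cols
  r_outer <- spec$skull_radius * n / 2
  # mildly elliptical skull, as in an axial head slice
  rr <- sqrt((xs / 1.0)^2 + (ys / 0.85)^2)
  head_mask <- rr <= r_outer
  ring <- rr <= r_outer & rr >= (r_outer - spec$skull_thickness)

  img <- matrix(stats::rnorm(n * n, 4, 2), n, n)          # background
  interior <- head_mask & !ring
  img[interior] <- spec$tissue_mean +
    stats::rnorm(sum(interior), 0, spec$tissue_noise)
  img[ring] <- 230 + stats::rnorm(sum(ring), 0, 4)

  # two striatal foci, left and right of midline, slightly anterior
  base <- spec$tissue_mean + 60
  focus_mean <- if (label == "HC") base + spec$separation else base
  ecc <- if (label == "HC") 2.0 else 1.0       # comma vs dot
  jitter <- stats::rnorm(2, 0, 2)
  for (side in c(-1, 1)) {
    cx <- -0.08 * n + jitter[1]                # anterior offset (rows)
    cy <- side * 0.18 * n + jitter[2]
    d <- sqrt((xs - cx)^2 + ((ys - cy) / ecc)^2)
    focus <- d <= spec$focus_radius & interior
    img[focus] <- focus_mean + stats::rnorm(sum(focus), 0, 5)
  }
  list(pixels = pmin(pmax(round(img), 0), 255), mask = head_mask,
       label = label, is_blank = FALSE, focus_intensity = focus_mean)
}

#' Generate a labelled phantom dataset on disk
#'
#' Writes `n_pd + n_hc` single-frame 16-bit DICOM files (8-bit phantom
#' values scaled by 257 with a matching linear display window, so the
#' pipeline's windowing is exercised), true head masks as PNG, and a CSV
#' truth manifest with per-file class, subject, blankness and focus
#' parameters. `round(blank_fraction * n)` slices are emitted blank,
#' spread over the shuffled file order. Fixed seed gives byte-identical
#' pixel data and manifests.
#'
#' @param spec A [phantom_spec()].
#' @param n_pd,n_hc Number of disease / control slices (>= 1).
#' @param dir Output directory (created if needed).
#' @param subjects_per_class Slices are grouped into this many subjects
#'   per class (default 5) for subject-aware splitting.
#' @return Invisibly, the truth manifest data frame (also written as
#'   `truth_manifest.csv` in `dir`).
#' @export
generate_dataset <- function(spec, n_pd, n_hc, dir,
                             subjects_per_class = 5L) {
  stopifnot(inherits(spec, "phantom_spec"), n_pd >= 1L, n_hc >= 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mask_dir <- file.path(dir, "truth_masks")
  dir.create(mask_dir, showWarnings = FALSE)

  n <- n_pd + n_hc
  labels <- c(rep("PD", n_pd), rep("HC", n_hc))
  n_blank <- round(spec$blank_fraction * n)

  with_preserved_seed(spec$seed, {
    blank_idx <- if (n_blank > 0) sample.int(n, n_blank) else integer()
    rows <- vector("list", n)
    counter <- c(PD = 0L, HC = 0L)
    for (i in seq_len(n)) {
      lab <- labels[i]
      counter[lab] <- counter[lab] + 1L
      subj <- sprintf("%s%03d", lab,
                      (counter[lab] - 1L) %% subjects_per_class + 1L)
      im <- generate_image(spec, lab, blank = i %in% blank_idx)
      fname <- sprintf("img_%04d_%s.dcm", i, lab)
      write_dicom(im$pixels * 257L, file.path(dir, fname),
                  patient_id = subj,
                  modality = if (spec$modality == "datscan") "NM" else "MR",
                  instance = i)
      mask_file <- sprintf("img_%04d_%s_mask.png", i, lab)
      png::writePNG(im$mask * 1, file.path(mask_dir, mask_file))
      rows[[i]] <- data.frame(
        path = fname, subject_id = subj, label = lab,
        is_blank = im$is_blank, mask_path = file.path("truth_masks",
                                                      mask_file),
        focus_intensity = im$focus_intensity, stringsAsFactors = FALSE)
    }
    manifest <- do.call(rbind, rows)
    utils::write.csv(manifest, file.path(dir, "truth_manifest.csv"),
                     row.names = FALSE)
    invisible(manifest)
  })
}

#' Per-image features for the tiny trainer
#'
#' Block-mean downsampling of each (grayscale) image to an `cells x cells`
#' grid, scaled to `[0, 1]` — 64 cheap features by default that carry the
#' phantom class signal (focus intensity lives in a few central cells).
#'
#' @param images List of 8-bit matrices (or HxWx3 arrays; first channel
#'   used).
#' @param cells Grid side (default 8).
#' @return Numeric feature matrix, one row per image.
#' @export
image_features <- function(images, cells = 8L) {
  t(vapply(images, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    n <- nrow(m)
    edges <- floor(seq(0, n, length.out = cells + 1L))
    g <- matrix(0, cells, cells)
    for (i in seq_len(cells)) {
      for (j in seq_len(cells)) {
        g[i, j] <- mean(m[(edges[i] + 1L):edges[i + 1L],
                          (edges[j] + 1L):edges[j + 1L]])
      }
    }
    as.numeric(g) / 255
  }, numeric(cells * cells)))
}
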