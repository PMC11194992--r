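#' @title Image preprocessing pipeline
#' @description
#' Converts raw DICOM series to 8-bit images, removes near-blank ("empty
#' tuple") slices below a mean-intensity threshold of 30, skull-strips with
#' an Otsu mask, crops to the head bounding box, resizes to 224x224x3 and
#' splits the survivors 80:20 into train/test and the train part 80:20
#' again into train/validation.
#' @name preprocessing
NULL

#' Pipeline configuration
#'
#' @param input_dir Directory of `.dcm`/`.dic` files.
#' @param output_dir Directory for converted images and the manifest.
#' @param empty_threshold Mean-intensity cutoff (8-bit units) below which a
#'   slice is discarded as empty; default 30.
#' @param target_size Output size, default `c(224, 224, 3)`.
#' @param test_fraction,val_fraction Carve fractions for the two 80:20
#'   splits; each in (0, 1).
#' @param seed Integer seed for the split shuffle.
#' @param format `"png"` (lossless, default) or `"jpeg"`.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input_dir, output_dir, empty_threshold = 30,
                            target_size = c(224L, 224L, 3L),
                            test_fraction = 0.2, val_fraction = 0.2,
                            seed = 1L, format = c("png", "jpeg")) {
  format <- match.arg(format)
  if (empty_threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  for (f in c(test_fraction, val_fraction)) {
    if (f <= 0 || f >= 1) stop("split fractions must lie in (0, 1)",
                               call. = FALSE)
  }
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 empty_threshold = empty_threshold,
                 target_size = as.integer(target_size),
                 test_fraction = test_fraction,
                 val_fraction = val_fraction, seed = as.integer(seed),
                 format = format),
            class = "pipeline_config")
}

new_image_record <- function(pixels, path, subject_id = NA_character_,
                             label = NA_character_,
                             modality = NA_character_) {
  structure(list(pixels = pixels, path = path, subject_id = subject_id,
                 label = label, modality = modality, mask = NULL,
                 flags = list(empty = FALSE, stripped = FALSE)),
            class = "image_record")
}

#' Convert a DICOM file to an 8-bit image record
#'
#' Applies the file's display window (or a min-max window when absent) as a
#' linear map to `[0, 255]`, preserving the original geometry; the resize
#' to network input size happens later in the pipeline.
#'
#' @param path DICOM file path.
#' @param out_dir Optional directory: when given, the 8-bit image is also
#'   written there (same basename, format per `format`).
#' @param format `"png"` or `"jpeg"`.
#' @return An `"image_record"` with `pixels` in `[0, 255]`.
#' @export
convert_dicom <- function(path, out_dir = NULL, format = "png") {
  d <- read_dicom(path)
  p <- d$pixels
  if (!is.null(d$window_center) && !is.null(d$window_width) &&
      d$window_width > 0) {
    lo <- d$window_center - d$window_width / 2
    p8 <- (p - lo) / d$window_width * 255
  } else {
    rng <- range(p)
    p8 <- if (rng[2] > rng[1]) (p - rng[1]) / (rng[2] - rng[1]) * 255
          else p * 0
  }
  p8 <- round(pmin(pmax(p8, 0), 255))
  rec <- new_image_record(p8, path, subject_id = d$patient_id %||% NA,
                          modality = d$modality %||% NA)
  if (!is.null(out_dir)) {
    out <- file.path(out_dir, paste0(
      tools::file_path_sans_ext(basename(path)), ".", format))
    write_image(rec$pixels, out, format)
    rec$converted_path <- out
  }
  rec
}

write_image <- function(pixels, path, format = "png") {
  arr <- if (length(dim(pixels)) == 3L) pixels / 255
         else array(rep(pixels / 255, 3L), dim = c(dim(pixels), 3L))
  if (format == "png") {
    png::writePNG(arr, path)
  } else {
    if (!requireNamespace("jpeg", quietly = TRUE)) {
      stop("the 'jpeg' package is needed for JPEG output", call. = FALSE)
    }
    jpeg::writeJPEG(arr, path, quality = 0.95)
  }
  invisible(path)
}

#' Is a slice empty (near-blank)?
#'
#' A slice is an "empty tuple" — an array carrying no anatomy, which only
#' degrades training — when its mean 8-bit intensity falls below the
#' threshold (default 30).
#'
#' @param record An `"image_record"`.
#' @param threshold Mean-intensity cutoff.
#' @return Logical.
#' @export
is_empty <- function(record, threshold = 30) {
  mean(record$pixels) < threshold
}

# ---- binary morphology (hand-rolled: no image package in this stack) ------

otsu_threshold <- function(pixels) {
  counts <- tabulate(as.integer(pixels) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) - 1L  # threshold on the 0..255 scale
}

shift_mask <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

binary_dilate <- function(m, iterations = 1L) {
  for (i in seq_len(iterations)) {
    out <- m
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                   c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
      out <- out | shift_mask(m, d[1], d[2])
    }
    m <- out
  }
  m
}

binary_erode <- function(m, iterations = 1L) {
  !binary_dilate(!m, iterations)
}

binary_close <- function(m, iterations = 2L) {
  binary_erode(binary_dilate(m, iterations), iterations)
}

# Connected components under 4-connectivity via vectorized frontier BFS;
# returns an integer label matrix (0 = background).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  fg <- which(mask)
  lab <- 0L
  for (seed in fg) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    frontier <- seed
    labels[seed] <- lab
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      cands <- c(frontier[r > 1L] - 1L, frontier[r < nr] + 1L,
                 frontier[frontier > nr] - nr,
                 frontier[frontier <= (nc - 1L) * nr] + nr)
      cands <- unique(cands[mask[cands] & labels[cands] == 0L])
      labels[cands] <- lab
      frontier <- cands
    }
  }
  labels
}

largest_component <- function(mask) {
  labels <- label_components(mask)
  if (max(labels) == 0L) return(mask & FALSE)
  sizes <- tabulate(labels[labels > 0L])
  labels == which.max(sizes)
}

# Fill interior holes: anything not reachable from the border through the
# background belongs to the object.
fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- !mask
  border <- c(which(bg[1, ]) * nr - nr + 1L, which(bg[nr, ]) * nr,
              which(bg[, 1]), (nc - 1L) * nr + which(bg[, nc]))
  outside <- matrix(FALSE, nr, nc)
  frontier <- unique(border)
  outside[frontier] <- TRUE
  while (length(frontier)) {
    r <- (frontier - 1L) %% nr + 1L
    cands <- c(frontier[r > 1L] - 1L, frontier[r < nr] + 1L,
               frontier[frontier > nr] - nr,
               frontier[frontier <= (nc - 1L) * nr] + nr)
    cands <- unique(cands[bg[cands] & !outside[cands]])
    outside[cands] <- TRUE
    frontier <- cands
  }
  !outside
}

#' Strip skull and background from a head image
#'
#' Transparent, testable stand-in for a full brain-extraction tool: global
#' Otsu threshold, largest 4-connected component, morphological closing,
#' interior hole filling. Pixels outside the resulting head mask are
#' zeroed and the mask is kept on the record (its area is logged in the
#' pipeline's filter log).
#'
#' @param record A non-empty `"image_record"`.
#' @return The record with masked pixels, `mask`, and
#'   `flags$stripped = TRUE`.
#' @export
skull_strip <- function(record) {
  thr <- otsu_threshold(record$pixels)
  mask <- record$pixels > thr
  if (!any(mask)) {
    stop("skull stripping failed: no foreground found in ",
         record$path %||% "<in-memory image>", call. = FALSE)
  }
  mask <- fill_holes(binary_close(largest_component(mask)))
  record$pixels <- record$pixels * mask
  record$mask <- mask
  record$flags$stripped <- TRUE
  record
}

bilinear_resize <- function(m, out_h, out_w) {
  nr <- nrow(m); nc <- ncol(m)
  # align pixel centers between grids
  rc <- pmin(pmax((seq_len(out_h) - 0.5) * nr / out_h + 0.5, 1), nr)
  cc <- pmin(pmax((seq_len(out_w) - 0.5) * nc / out_w + 0.5, 1), nc)
  r0 <- pmin(floor(rc), nr - 1L); c0 <- pmin(floor(cc), nc - 1L)
  ar <- rc - r0; ac <- cc - c0
  m00 <- m[r0, c0]; m10 <- m[r0 + 1, c0]
  m01 <- m[r0, c0 + 1]; m11 <- m[r0 + 1, c0 + 1]
  w_r <- matrix(ar, out_h, out_w); w_c <- matrix(ac, out_h, out_w,
                                                byrow = TRUE)
  m00 * (1 - w_r) * (1 - w_c) + m10 * w_r * (1 - w_c) +
    m01 * (1 - w_r) * w_c + m11 * w_r * w_c
}

#' Crop to the head and resize to network input size
#'
#' Crops to the head-mask bounding box (the full frame when no mask is
#' set), zero-pads the crop to a square so aspect ratio is preserved,
#' resamples bilinearly to the target spatial size and replicates the
#' grayscale plane to three channels.
#'
#' @param record An `"image_record"`.
#' @param target Output size, default `c(224, 224, 3)`.
#' @return The record with `pixels` as a `target`-shaped array in
#'   `[0, 255]`.
#' @export
crop_and_resize <- function(record, target = c(224L, 224L, 3L)) {
  m <- record$pixels
  mask <- record$mask
  if (!is.null(mask) && any(mask)) {
    rr <- range(which(rowSums(mask) > 0))
    cr <- range(which(colSums(mask) > 0))
    if (diff(rr) < 1 || diff(cr) < 1) {
      stop("degenerate crop box for ", record$path %||% "<image>",
           call. = FALSE)
    }
    m <- m[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  }
  side <- max(dim(m))  # zero-pad to square, crop centered
  sq <- matrix(0, side, side)
  ro <- (side - nrow(m)) %/% 2L
  co <- (side - ncol(m)) %/% 2L
  sq[ro + seq_len(nrow(m)), co + seq_len(ncol(m))] <- m
  rs <- bilinear_resize(sq, target[1L], target[2L])
  rs <- pmin(pmax(rs, 0), 255)
  record$pixels <- array(rep(rs, target[3L]),
                         dim = c(target[1L], target[2L], target[3L]))
  record
}

# Largest-remainder apportionment of `total` across strata of sizes `n`.
apportion <- function(n, total) {
  ideal <- n * total / sum(n)
  base <- floor(ideal)
  short <- total - sum(base)
  if (short > 0) {
    extra <- order(ideal - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Split records into train / validation / test sets
#'
#' Two nested 80:20 holdout carves with the floor convention: the test set
#' takes `floor(test_fraction * n)` records, then the validation set takes
#' `floor(val_fraction * n_train)` of the remainder. Class proportions are
#' preserved as closely as integer rounding allows (stratified shuffle;
#' the floor rule fixes the totals, largest-remainder apportionment fixes
#' the per-class counts). With `by_subject = TRUE` whole subjects are
#' assigned to one split only, guarding against subject leakage at the
#' cost of exact totals.
#'
#' @param manifest Data frame with a `label` column (and `subject_id` when
#'   `by_subject`).
#' @param seed Integer seed for the shuffle.
#' @param test_fraction,val_fraction Carve fractions (defaults 0.2).
#' @param by_subject Assign whole subjects rather than slices.
#' @return The manifest with a `split` factor column
#'   (`train`/`validation`/`test`).
#' @export
split_dataset <- function(manifest, seed = 1L, test_fraction = 0.2,
                          val_fraction = 0.2, by_subject = FALSE) {
  stopifnot(is.data.frame(manifest), "label" %in% names(manifest))
  n <- nrow(manifest)
  classes <- unique(manifest$label)
  if (length(classes) < 2L) {
    stop("a class is absent: need both PD and HC labels to split",
         call. = FALSE)
  }
  units <- if (by_subject) {
    stopifnot("subject_id" %in% names(manifest))
    manifest$subject_id
  } else {
    seq_len(n)
  }

  with_preserved_seed(seed, {
    if (by_subject) {
      # greedy subject-level carve per class, approximating the fractions
      split <- rep("train", n)
      for (cl in classes) {
        subj <- unique(units[manifest$label == cl])
        subj <- sample(subj)
        sizes <- vapply(subj, function(s)
          sum(units == s & manifest$label == cl), integer(1))
        cum <- cumsum(sizes)
        n_cl <- sum(sizes)
        k_test <- which.min(abs(cum - test_fraction * n_cl))
        test_subj <- subj[seq_len(k_test)]
        rest <- subj[-seq_len(k_test)]
        cum2 <- cumsum(sizes[-seq_len(k_test)])
        k_val <- which.min(abs(cum2 - val_fraction * (n_cl - cum[k_test])))
        val_subj <- rest[seq_len(k_val)]
        split[units %in% test_subj & manifest$label == cl] <- "test"
        split[units %in% val_subj & manifest$label == cl] <- "validation"
      }
    } else {
      n_test <- floor(test_fraction * n)
      n_val <- floor(val_fraction * (n - n_test))
      class_n <- vapply(classes, function(cl) sum(manifest$label == cl),
                        integer(1))
      test_per_class <- apportion(class_n, n_test)
      val_per_class <- apportion(class_n - test_per_class, n_val)
      split <- rep("train", n)
      for (k in seq_along(classes)) {
        idx <- sample(which(manifest$label == classes[k]))
        take_test <- idx[seq_len(test_per_class[k])]
        take_val <- idx[test_per_class[k] + seq_len(val_per_class[k])]
        split[take_test] <- "test"
        split[take_val] <- "validation"
      }
    }
    manifest$split <- factor(split, levels = c("train", "validation",
                                               "test"))
    manifest
  })
}

#' Run the full preprocessing pipeline
#'
#' Convert every DICOM file in the input directory, drop empty slices,
#' skull-strip, crop and resize, write the retained images and a dataset
#' manifest (CSV) plus a JSON summary. Labels and subject identifiers are
#' taken from a `truth_manifest.csv` in the input directory when present
#' (the synthetic generator writes one) and from the DICOM PatientID
#' otherwise. Per-file failures are logged and skipped; the pipeline is
#' deterministic given the same inputs and seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `manifest` (data frame including split
#'   assignments), `filtered` (data frame of removed files and reasons)
#'   and `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  files <- sort(list.files(config$input_dir, pattern = "\\.(dcm|dic)$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    stop("no DICOM files found in ", config$input_dir, call. = FALSE)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  truth_path <- file.path(config$input_dir, "truth_manifest.csv")
  truth <- if (file.exists(truth_path)) {
    utils::read.csv(truth_path, stringsAsFactors = FALSE)
  } else NULL

  rows <- list()
  filtered <- list()
  for (f in files) {
    base <- basename(f)
    res <- tryCatch({
      rec <- convert_dicom(f)
      if (!is.null(truth)) {
        tr <- truth[basename(truth$path) == base, , drop = FALSE]
        if (nrow(tr) == 1L) {
          rec$label <- tr$label
          rec$subject_id <- tr$subject_id
        }
      }
      if (is_empty(rec, config$empty_threshold)) {
        filtered[[base]] <- data.frame(
          path = base, reason = "empty",
          mean_intensity = mean(rec$pixels), mask_area = NA_integer_)
        NULL
      } else {
        rec <- skull_strip(rec)
        rec <- crop_and_resize(rec, config$target_size)
        out <- file.path(config$output_dir, paste0(
          tools::file_path_sans_ext(base), ".", config$format))
        write_image(rec$pixels, out, config$format)
        data.frame(path = basename(out), source = base,
                   subject_id = rec$subject_id %||% NA_character_,
                   label = rec$label %||% NA_character_,
                   mean_intensity = mean(rec$pixels),
                   mask_area = sum(rec$mask),
                   stringsAsFactors = FALSE)
      }
    }, error = function(e) {
      filtered[[base]] <<- data.frame(
        path = base, reason = paste("error:", conditionMessage(e)),
        mean_intensity = NA_real_, mask_area = NA_integer_)
      NULL
    })
    if (!is.null(res)) rows[[base]] <- res
  }

  manifest <- do.call(rbind, unname(rows))
  filtered_df <- if (length(filtered)) do.call(rbind, unname(filtered))
                 else data.frame(path = character(), reason = character(),
                                 mean_intensity = numeric(),
                                 mask_area = integer())
  if (!is.null(manifest) && length(unique(manifest$label)) >= 2L) {
    manifest <- split_dataset(manifest, seed = config$seed,
                              test_fraction = config$test_fraction,
                              val_fraction = config$val_fraction)
  } else if (!is.null(manifest)) {
    manifest$split <- factor("train", levels = c("train", "validation",
                                                 "test"))
  }

  utils::write.csv(manifest, file.path(config$output_dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(filtered_df,
                   file.path(config$output_dir, "filter_log.csv"),
                   row.names = FALSE)
  summary <- list(
    n_input = length(files),
    n_retained = nrow(manifest) %||% 0L,
    n_filtered = nrow(filtered_df),
    per_split = as.list(table(manifest$split)),
    per_class = as.list(table(manifest$label)),
    empty_threshold = config$empty_threshold,
    seed = config$seed
  )
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE),
             file.path(config$output_dir, "summary.json"))
  invisible(list(manifest = manifest, filtered = filtered_df,
                 summary = summary))
}
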