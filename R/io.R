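## File I/O: volumes as NIfTI (.nii.gz), projection images as 32-bit float
## TIFF with a JSON scale sidecar, tables as CSV with explicit units in the
## headers, motion models as JSON.

#' Write a 3D grid to a NIfTI file
#'
#' @param grid a \linkS4class{DoseGrid} or \linkS4class{StructureMask}.
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeVolume <- function(grid, path) {
  vox <- voxelData(grid)
  if (is.logical(vox)) vox <- array(as.numeric(vox), dim(vox))
  img <- RNifti::asNifti(vox)
  RNifti::pixdim(img) <- voxelSpacing(grid)
  RNifti::writeNifti(img, path, datatype = "double")
  orig <- gridOrigin(grid)
  jsonlite::write_json(list(origin_mm = orig),
                       paste0(path, ".origin.json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' Read a 3D grid from a NIfTI file
#'
#' @param path input path.
#' @param mask read as a \linkS4class{StructureMask} (voxels > 0.5).
#' @param label structure label when \code{mask} is TRUE.
#' @return a \linkS4class{DoseGrid} or \linkS4class{StructureMask}.
#' @export
readVolume <- function(path, mask = FALSE, label = "structure") {
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim(img))
  sp <- RNifti::pixdim(img)
  sidecar <- paste0(path, ".origin.json")
  orig <- if (file.exists(sidecar))
    as.numeric(unlist(jsonlite::read_json(sidecar)$origin_mm))
  else c(0, 0, 0)
  if (mask)
    StructureMask(array(vox > 0.5, dim(vox)), spacing = sp, origin = orig,
                  label = label)
  else DoseGrid(vox, spacing = sp, origin = orig)
}

#' Write a projection image as 32-bit float TIFF
#'
#' Intensities are affinely mapped to [0, 1] for storage; the mapping
#' (\code{lo}, \code{hi}) and pixel spacing are stored in a JSON sidecar so
#' the round trip recovers the original values to 32-bit float precision.
#'
#' @param image an \linkS4class{Image2D}.
#' @param path output path (.tiff).
#' @return the path, invisibly.
#' @export
writeImage2D <- function(image, path) {
  stopifnot(is(image, "Image2D"))
  m <- pixelData(image)
  lo <- min(m); hi <- max(m)
  scaled <- if (hi > lo) (m - lo) / (hi - lo) else m * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  jsonlite::write_json(list(lo = lo, hi = hi,
                            pixel_spacing_mm = pixelSpacing(image)),
                       paste0(path, ".scale.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a projection image written by [writeImage2D()]
#'
#' @param path input path.
#' @return an \linkS4class{Image2D}.
#' @export
readImage2D <- function(path) {
  sidecar <- paste0(path, ".scale.json")
  if (!file.exists(sidecar))
    stop("missing scale sidecar for image: ", path)
  sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  m <- tiff::readTIFF(path)
  if (is.array(m) && length(dim(m)) == 3L) m <- m[, , 1]
  Image2D(m * (sc$hi - sc$lo) + sc$lo, pixelSpacing = sc$pixel_spacing_mm)
}

#' Read a ground-truth or tracking table
#'
#' CSV columns are validated; a non-numeric coordinate raises a parse error
#' naming the offending row.
#'
#' @param path CSV path.
#' @param numericCols columns required to be numeric.
#' @return a data.frame.
#' @export
readTrackingTable <- function(path,
                              numericCols = c("x_mm", "y_mm", "z_mm")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(numericCols, names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("non-numeric value in column '", col, "' at row ", bad,
           " of ", path)
    }
  }
  df
}

#' Write a motion model to JSON
#'
#' Serializes the 105 x 3 coefficient matrix, cutoff ratio, retained count
#' and kind with full numeric precision, so the round trip preserves the
#' coefficients exactly.
#'
#' @param model a \linkS4class{MotionModel}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMotionModel <- function(model, path) {
  stopifnot(is(model, "MotionModel"))
  jsonlite::write_json(
    list(kind = model@kind, cutoff_ratio = model@cutoffRatio,
         retained = model@retained, n_obs = model@nObs,
         coefficients = coefMatrix(model)),
    path, auto_unbox = TRUE, digits = I(17), matrix = "rowmajor")
  invisible(path)
}

#' Read a motion model written by [writeMotionModel()]
#'
#' @param path input path.
#' @return a \linkS4class{MotionModel}.
#' @export
readMotionModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  coef <- matrix(as.numeric(t(j$coefficients)), 105L, 3L, byrow = TRUE)
  new("MotionModel", coefficients = coef, kind = j$kind,
      cutoffRatio = j$cutoff_ratio, retained = as.integer(j$retained),
      nObs = as.integer(j$n_obs))
}

#' Write a cohort to the on-disk layout
#'
#' Layout: \code{patientXX/drr_A.tiff}, \code{drr_B.tiff},
#' \code{fractions/fYY/img_NNNN_A.tiff} (+ B), \code{masks/*.nii.gz} and a
#' cohort-level \code{truth.csv} with columns
#' patient, fraction, image, x_mm, y_mm, z_mm.
#'
#' @param cohort an \code{"orthoCohort"}.
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "orthoCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pat in cohort$patients) {
    pd <- file.path(dir, sprintf("patient%02d", pat$index))
    dir.create(pd, recursive = TRUE, showWarnings = FALSE)
    writeImage2D(pat$drr$A, file.path(pd, "drr_A.tiff"))
    writeImage2D(pat$drr$B, file.path(pd, "drr_B.tiff"))
    md <- file.path(pd, "masks")
    dir.create(md, showWarnings = FALSE)
    for (nm in names(pat$masks))
      writeVolume(pat$masks[[nm]], file.path(md, paste0(nm, ".nii.gz")))
    for (f in seq_along(pat$fractions)) {
      fd <- file.path(pd, "fractions", sprintf("f%02d", f))
      dir.create(fd, recursive = TRUE, showWarnings = FALSE)
      imgs <- pat$fractions[[f]]$images
      for (n in seq_along(imgs)) {
        writeImage2D(imgs[[n]]$A, file.path(fd, sprintf("img_%04d_A.tiff", n)))
        writeImage2D(imgs[[n]]$B, file.path(fd, sprintf("img_%04d_B.tiff", n)))
      }
    }
  }
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Default run configuration
#'
#' All processing constants default to the tracking chain's standard
#' values: bandpass gradient g = 0.02, fiducial selection fraction 0.5\%,
#' neighbour offset 10 px, 128 NMI bins, coupled passes (+/-20 step 4,
#' +/-2 step 1), subregion passes (+/-10 step 2, +/-1 step 1), singular
#' value cutoffs R = 1.2 (inter) and 7.0 (intra), 5 fractions and 10
#' stochastic repeats. The cohort block sets the synthetic study size and
#' the imaging geometry used for it.
#'
#' @param seed master seed.
#' @return a nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    geometry = list(image_size = 128L, pixel_spacing_mm = 1.25),
    cohort = list(n_patients = 4L, n_fractions = 3L, n_images = 6L,
                  noise = 0.02, intensity_perturbation = 0.05,
                  baseline_sigma_mm = 5, ptv_margin_mm = 5,
                  n_fiducials = 3L),
    preprocess = list(g = 0.02, top_fraction = 0.005,
                      neighbour_offset = 10L, equalization_grid = 5L),
    registration = list(bins = 128L),
    model = list(R_inter = 1.2, R_intra = 7.0),
    dose = list(fractions = 5L, repeats = 10L, n_beams = 16L,
                prescription_Gy = 35, grid_pad_mm = 30),
    seed = as.integer(seed))
}

#' Read a run configuration from a YAML file
#'
#' Missing blocks and keys fall back to [defaultRunConfig()].
#'
#' @param path YAML file path.
#' @return a nested configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  for (blk in names(user)) {
    if (is.list(user[[blk]]) && blk %in% names(cfg))
      cfg[[blk]][names(user[[blk]])] <- user[[blk]]
    else cfg[[blk]] <- user[[blk]]
  }
  cfg
}
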