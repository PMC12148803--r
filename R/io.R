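# Configuration (YAML) and volume I/O (NIfTI).

default_run_config <- function() {
  list(
    seed = 1L,
    output = ".",
    phantom = list(image_size = 64L, pixel_spacing = 0.977,
                   slice_thickness = 1.0, n_healthy = 200L,
                   n_unhealthy = 200L, n_volumes = 2L, volume_depth = 16L,
                   hu_air = -1000, hu_lung = -800, hu_body = 40,
                   hu_tumor = 20, tumor_radius_range = c(2, 5),
                   noise_sigma = 20, texture_amp = 30,
                   asymmetry_jitter = 0.3, seed = 1L),
    generator = list(input_size = 512L, base_channels = 32L, depth = 4L,
                     kernel = 3L, slope = 0.2),
    discriminator = list(first_channels = 64L, n_downsamples = 3L,
                         kernel = 3L, slope = 0.2),
    loss = list(lambda_c = 10, lambda_i = 5, lambda_s = 1),
    train = list(total_epochs = 200L, decay_epochs = 50L,
                 initial_lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                 batch_size = 16L, similarity = TRUE),
    segment = list(per_slice_otsu = FALSE, median = "3d", hu_offset = 0,
                   hu_divisor = 1500, bn_mode = "batch")
  )
}

#' Load a run configuration
#'
#' Reads a YAML file and merges it over the defaults, which are the
#' published hyperparameters (`lambda_c` 10, `lambda_i` 5, learning rate
#' 2e-4, 200 epochs with 50 decay epochs, Adam betas 0.5/0.999, generator
#' base 32 channels, discriminator first layer 64 channels). Unknown keys
#' and invalid values are rejected with the offending key named. An empty
#' file yields the defaults.
#'
#' @param path YAML file path.
#' @return An object of class `run_config` (a nested list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- default_run_config()
  check_keys <- function(u, d, prefix = "") {
    for (nm in names(u)) {
      if (!nm %in% names(d))
        stop("unknown config key: ", prefix, nm)
      if (is.list(d[[nm]]) && !is.null(names(d[[nm]])))
        check_keys(u[[nm]] %||% list(), d[[nm]], paste0(prefix, nm, "."))
    }
  }
  check_keys(user, cfg)
  cfg <- modifyList(cfg, user)
  # validate through the typed constructors
  do.call(phantom_spec, cfg$phantom)
  do.call(generator_spec, cfg$generator)
  do.call(discriminator_spec,
          c(list(input_height = cfg$generator$input_size,
                 input_width = cfg$generator$input_size),
            cfg$discriminator))
  do.call(train_config, c(cfg$train,
                          list(weights = do.call(loss_weights, cfg$loss),
                               seed = cfg$seed)))
  if (!cfg$segment$median %in% c("2d", "3d"))
    stop("invalid value for config key segment.median")
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a CT volume or slice from NIfTI
#'
#' Returns the image with voxel spacing taken from the NIfTI header
#' (`pixdim`); missing or non-positive spacing is an error, never a silent
#' default.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [ct_slice()] (2D) or [ct_volume()] (3D), intensities as stored
#'   (HU for CT).
#' @export
read_volume <- function(path) {
  if (dir.exists(path))
    stop("directory input not supported; supported formats: ",
         "NIfTI (.nii, .nii.gz)")
  ext <- tolower(sub("^.*?((\\.nii)?\\.[^.]+)$", "\\1", path))
  if (!ext %in% c(".nii", ".nii.gz"))
    stop("unsupported file extension '", ext,
         "'; supported formats: NIfTI (.nii, .nii.gz)")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  spacing <- RNifti::pixdim(img)[seq_along(d)]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("missing or invalid voxel spacing in NIfTI header of ", path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = d)
  id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  if (length(d) == 2L) ct_slice(arr, spacing, id = id)
  else if (length(d) == 3L) ct_volume(arr, spacing, id = id)
  else stop("unsupported image dimensionality: ", length(d))
}

#' Write a binary mask as uint8 NIfTI
#'
#' @param mask 0/1 array; spacing taken from its `"spacing"` attribute
#'   unless given.
#' @param path Output `.nii` or `.nii.gz` path.
#' @param spacing Voxel spacing per axis, mm.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, spacing = NULL) {
  spacing <- spacing %||% attr(mask, "spacing", exact = TRUE)
  if (is.null(spacing)) stop("mask has no spacing; pass `spacing`")
  m <- mask_data(mask)
  arr <- array(as.integer(m != 0), dim(m) %||% length(m))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, spacing)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Apply a DICOM-style linear rescale to stored values
#'
#' `HU = stored * slope + intercept`, the rescale convention of CT storage
#' formats (e.g. stored 1024 with slope 1 and intercept -1024 is 0 HU).
#'
#' @param stored Numeric stored values.
#' @param slope,intercept Rescale slope and intercept.
#' @return Values in HU.
#' @export
apply_hu_rescale <- function(stored, slope = 1, intercept = 0) {
  stored * slope + intercept
}
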