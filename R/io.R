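#' Write / read a multi-coil k-space container
#'
#' Serializes an [multicoil_kspace()] (and optionally the simulation ground
#' truth) to a directory: real and imaginary parts as 3-D NIfTI volumes
#' (`kspace_real.nii.gz`, `kspace_imag.nii.gz`, PE x FE x coil), the PE
#' acquisition mask and geometry metadata as a YAML sidecar (`meta.yaml`),
#' and ground truth, when given, under `truth_*` volumes.
#'
#' @param ks an `mc_kspace`.
#' @param path directory to create/write into.
#' @param truth optional list with complex `image` and complex array `sens`
#'   (as returned by [simulate_phantom_kspace()]).
#' @param seed optional integer recorded in the metadata.
#' @return `path`, invisibly.
#' @export
write_kspace <- function(ks, path, truth = NULL, seed = NULL) {
  stopifnot(inherits(ks, "mc_kspace"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(Re(ks$data), file.path(path, "kspace_real.nii.gz"))
  RNifti::writeNifti(Im(ks$data), file.path(path, "kspace_imag.nii.gz"))
  meta <- list(grid = as.integer(dim(ks$data)[1:2]),
               n_coils = as.integer(dim(ks$data)[3]),
               delta_k = ks$delta_k,
               mask_pe = as.logical(ks$mask))
  if (!is.null(seed)) meta$seed <- as.integer(seed)
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  if (!is.null(truth)) {
    RNifti::writeNifti(Re(truth$image), file.path(path, "truth_image_real.nii.gz"))
    RNifti::writeNifti(Im(truth$image), file.path(path, "truth_image_imag.nii.gz"))
    RNifti::writeNifti(Re(truth$sens), file.path(path, "truth_sens_real.nii.gz"))
    RNifti::writeNifti(Im(truth$sens), file.path(path, "truth_sens_imag.nii.gz"))
  }
  invisible(path)
}

#' @rdname write_kspace
#' @return for `read_kspace`: the `mc_kspace` (with a `truth` attribute when
#'   ground truth was stored).
#' @export
read_kspace <- function(path) {
  meta <- yaml::read_yaml(file.path(path, "meta.yaml"))
  re <- as.array(RNifti::readNifti(file.path(path, "kspace_real.nii.gz")))
  im <- as.array(RNifti::readNifti(file.path(path, "kspace_imag.nii.gz")))
  data <- array(complex(real = re, imaginary = im), dim = dim(re))
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  ks <- multicoil_kspace(data, acquired_mask = unlist(meta$mask_pe),
                         delta_k = unlist(meta$delta_k))
  tf <- file.path(path, "truth_image_real.nii.gz")
  if (file.exists(tf)) {
    ire <- as.array(RNifti::readNifti(tf))
    iim <- as.array(RNifti::readNifti(file.path(path, "truth_image_imag.nii.gz")))
    sre <- as.array(RNifti::readNifti(file.path(path, "truth_sens_real.nii.gz")))
    sim <- as.array(RNifti::readNifti(file.path(path, "truth_sens_imag.nii.gz")))
    attr(ks, "truth") <- list(
      image = matrix(complex(real = ire, imaginary = iim), nrow(ire)),
      sens = array(complex(real = sre, imaginary = sim), dim = dim(sre)))
  }
  ks
}

#' Write reconstruction outputs
#'
#' Saves the reconstructed magnitude image as NIfTI and as a PNG preview,
#' and the quality report (method, sampling, window, NMSE, PSNR) as JSON.
#'
#' @param report a [reconstruct_report()] result.
#' @param prefix output path prefix; files `<prefix>.nii.gz`,
#'   `<prefix>.png`, `<prefix>.json` are written.
#' @param extra named list merged into the JSON report (e.g. kernel, seed).
#' @return invisibly, the JSON report as a list.
#' @export
write_recon_report <- function(report, prefix, extra = list()) {
  stopifnot(inherits(report, "recon_report"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(report$recon_image, paste0(prefix, ".nii.gz"))
  img <- report$recon_image
  grDevices::png(paste0(prefix, ".png"), width = ncol(img), height = nrow(img))
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::image(t(img[nrow(img):1, ]), col = grDevices::gray.colors(256),
                  axes = FALSE, useRaster = TRUE)
  grDevices::dev.off()
  out <- c(list(method = report$method,
                R = report$scheme$R, acs = report$scheme$n_acs,
                window = c(report$window$n_pe_blocks, report$window$n_fe_cols),
                nmse = report$nmse, psnr = report$psnr),
           extra)
  jsonlite::write_json(out, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
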