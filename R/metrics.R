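#' Normalized root error between a reconstruction and its reference
#'
#' `sqrt(sum |recon - ref|^2 / sum |ref|^2)`.  Note the square root: this is
#' a normalized *root* metric (so a reconstruction of twice the reference
#' scores exactly 1), kept under the field's customary name NMSE.
#'
#' @param recon,ref real images of identical shape; `ref` must not be all
#'   zero.
#' @return non-negative real scalar; 0 iff the images are identical.
#' @export
nmse <- function(recon, ref) {
  if (!all(dim(recon) == dim(ref))) stop("image shapes differ")
  den <- sum(abs(ref)^2)
  if (den == 0) stop("reference image is all zero")
  sqrt(sum(abs(recon - ref)^2) / den)
}

#' Peak signal-to-noise ratio from the NMSE
#'
#' `10 * log10(255^2 / nmse_value)`, in dB — derived from the normalized
#' root error of [nmse()] rather than a mean-squared error, so the absolute
#' level is offset from the conventional PSNR definition; differences
#' between methods on the same reference are unaffected.  Strictly
#' decreasing in the error; an exact reconstruction (`nmse_value = 0`)
#' reports `+Inf`.
#'
#' @param nmse_value non-negative real scalar.
#' @return real scalar in dB (or `Inf`).
#' @export
psnr <- function(nmse_value) {
  stopifnot(nmse_value >= 0)
  if (nmse_value == 0) return(Inf)
  10 * log10(255^2 / nmse_value)
}

#' End-to-end reconstruction with quality report
#'
#' Undersamples fully sampled k-space under `scheme`, reconstructs with the
#' requested method, inverse-transforms with sum-of-squares combination,
#' and scores against the non-accelerated reference (the SOS image of the
#' fully sampled input).
#'
#' @param full a fully sampled [multicoil_kspace()].
#' @param scheme a [sampling_scheme()].
#' @param win an [interp_window()].
#' @param method `"grappa"` or `"psvr"`.
#' @param ... further arguments to [grappa_reconstruct()] or
#'   [psvr_grappa_reconstruct()] (kernel, `C`, `l_max`, ...).
#' @return an object of class `recon_report`: fields `recon_image`,
#'   `reference_image`, `recon_kspace`, `nmse`, `psnr`, `method`, `window`,
#'   `scheme`.
#' @export
reconstruct_report <- function(full, scheme, win,
                               method = c("grappa", "psvr"), ...) {
  method <- match.arg(method)
  stopifnot(all(full$mask))
  ref <- ifft_and_sos(full)
  und <- undersample(full, scheme)
  rec_ks <- switch(method,
    grappa = grappa_reconstruct(und, scheme, win, ...),
    psvr = psvr_grappa_reconstruct(und, scheme, win, ...))
  img <- ifft_and_sos(rec_ks)
  err <- nmse(img, ref)
  structure(list(recon_image = img, reference_image = ref,
                 recon_kspace = rec_ks, nmse = err, psnr = psnr(err),
                 method = method, window = win, scheme = scheme),
            class = "recon_report")
}

#' @export
print.recon_report <- function(x, ...) {
  cat(sprintf(
    "<recon_report> %s | R = %d, ACS = %d, window %dx%d | NMSE = %.4g (%.2f%%), PSNR = %.2f dB\n",
    x$method, x$scheme$R, x$scheme$n_acs,
    x$window$n_pe_blocks, x$window$n_fe_cols,
    x$nmse, 100 * x$nmse, x$psnr))
  invisible(x)
}
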