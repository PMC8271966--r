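#' Image + ROI container for SNR computation
#'
#' @param image 2D numeric matrix of nonnegative pixel values
#' @param signal_region logical matrix (same dim): signal ROI mask
#' @param background_region logical matrix (same dim): background mask;
#'   must be disjoint from the signal mask
#' @param n_subsamples number of random sub-ROIs used to estimate the SNR
#'   spread (default 10)
#' @return an object of class `image_roi`
#' @export
image_roi <- function(image, signal_region, background_region,
                      n_subsamples = 10L) {
  image <- as.matrix(image)
  if (any(!is.finite(image)) || any(image < 0))
    stop("image must be finite and nonnegative")
  if (!identical(dim(image), dim(signal_region)) ||
      !identical(dim(image), dim(background_region)))
    stop("masks must have the same dimensions as the image")
  signal_region <- array(as.logical(signal_region), dim(image))
  background_region <- array(as.logical(background_region), dim(image))
  if (!any(signal_region) || !any(background_region))
    stop("signal and background masks must be non-empty")
  if (any(signal_region & background_region))
    stop("signal and background masks must be disjoint")
  if (n_subsamples < 1) stop("n_subsamples must be >= 1")
  structure(
    list(image = image, signal_region = signal_region,
         background_region = background_region,
         n_subsamples = as.integer(n_subsamples)),
    class = "image_roi")
}

# run `expr` under a temporary R RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' ROI-based signal-to-noise ratio in dB
#'
#' \eqn{SNR = 20 \log_{10}(S_R / S_n)} where \eqn{S_R} is the mean
#' normalized pixel value over the signal ROI and \eqn{S_n} the mean over
#' the background. To attach an uncertainty, \eqn{S_R} is recomputed over
#' `n_subsamples` random sub-ROIs of half the signal-region area (pixels
#' drawn uniformly without replacement from the signal mask, seeded), and
#' the mean and standard deviation of the resulting SNRs are reported.
#'
#' Normalization (`"max"`, the default) divides the image by its maximum;
#' since the statistic is a ratio, this leaves the SNR unchanged and exists
#' so that reported \eqn{S_R}, \eqn{S_n} refer to normalized pixel values.
#' `"minmax"` maps the image to [0, 1]; `"none"` uses raw values.
#'
#' @param roi an [image_roi()]
#' @param seed RNG seed for sub-ROI placement
#' @param normalize `"max"` (default), `"minmax"` or `"none"`
#' @param subsample_fraction fraction of the signal region per sub-ROI
#' @return list with `mean_db`, `sd_db`, `snr_full_db` (full-ROI value),
#'   `sr`, `sn`, `n_subsamples`, `seed`
#' @examples
#' img <- matrix(0.05, 20, 20); img[8:12, 8:12] <- 0.5
#' sig <- matrix(FALSE, 20, 20); sig[8:12, 8:12] <- TRUE
#' snr_db(image_roi(img, sig, !sig), seed = 1)$mean_db # exactly 20 dB
#' @export
snr_db <- function(roi, seed = 1L, normalize = c("max", "minmax", "none"),
                   subsample_fraction = 0.5) {
  stopifnot(inherits(roi, "image_roi"))
  normalize <- match.arg(normalize)
  img <- roi$image
  if (normalize == "max") {
    m <- max(img)
    if (m > 0) img <- img / m
  } else if (normalize == "minmax") {
    rng <- range(img)
    if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng)
  }
  sig <- img[roi$signal_region]
  sn <- mean(img[roi$background_region])
  if (sn <= 0) stop("background mean is zero: SNR undefined")
  nsub <- max(1L, floor(length(sig) * subsample_fraction))
  if (nsub > length(sig))
    stop("sub-ROI larger than the signal region")
  snrs <- .with_seed(seed, {
    vapply(seq_len(roi$n_subsamples), function(i) {
      20 * log10(mean(sig[sample.int(length(sig), nsub)]) / sn)
    }, numeric(1))
  })
  list(mean_db = mean(snrs),
       sd_db = if (length(snrs) > 1L) sd(snrs) else 0,
       snr_full_db = 20 * log10(mean(sig) / sn),
       sr = mean(sig), sn = sn,
       n_subsamples = roi$n_subsamples, seed = as.integer(seed))
}

#' Pixelwise average of image frames
#'
#' Averaging N frames with i.i.d. zero-mean noise improves the SNR by
#' \eqn{20 \log_{10}(\sqrt{N})} (about 13 dB for the 20-frame averaging
#' used in acquisition).
#'
#' @param frames list of 2D numeric matrices with identical dimensions
#' @return the pixelwise mean frame
#' @export
frame_average <- function(frames) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("frames must be a non-empty list of matrices")
  d <- dim(frames[[1]])
  for (f in frames)
    if (!identical(dim(f), d)) stop("all frames must have the same dimensions")
  Reduce(`+`, frames) / length(frames)
}
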