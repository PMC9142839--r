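# Shared image-core operations: TIFF/CSV I/O, decay integration,
# circular-average smoothing and linear contrast rescaling.

.readTiffPlane <- function(path, plane = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
  if (plane > length(pages))
    stop("requested plane ", plane, " of a ", length(pages), "-page TIFF")
  m <- pages[[plane]]
  if (length(dim(m)) != 2L)
    stop("requested plane is not a single 2-D grayscale plane")
  m
}

#' Read a single-channel intensity image from TIFF
#'
#' Reads one grayscale plane of a single- or multi-page TIFF with
#' values as stored (no rescaling to [0, 1]).
#'
#' @param path TIFF file path.
#' @param channel channel tag to attach (see [IntensityImage-class]).
#' @param plane page index for multi-page files (default 1).
#' @return An [IntensityImage-class].
#' @seealso [writeIntensityImage()]
#' @export
readIntensityImage <- function(path, channel, plane = 1L) {
  m <- .readTiffPlane(path, plane)
  storage.mode(m) <- "double"
  intensityImage(m, channel)
}

#' Write an intensity image to TIFF
#'
#' Stores pixel values as unsigned integers of the given bit depth.
#' Values are rounded; integer-valued images round-trip exactly through
#' [readIntensityImage()].
#'
#' @param img an [IntensityImage-class].
#' @param path output path.
#' @param bitsPerSample 8 or 16.
#' @return \code{path}, invisibly.
#' @export
writeIntensityImage <- function(img, path, bitsPerSample = 16L) {
  .writeTiffInt(pixels(img), path, bitsPerSample)
}

.writeTiffInt <- function(m, path, bitsPerSample = 16L) {
  stopifnot(bitsPerSample %in% c(8L, 16L))
  maxv <- 2^bitsPerSample - 1
  m <- round(m)
  if (any(m < 0 | m > maxv, na.rm = TRUE))
    stop("values outside the ", bitsPerSample, "-bit range [0, ", maxv, "]")
  m[is.na(m)] <- 0
  tiff::writeTIFF(m / maxv, path, bits.per.sample = bitsPerSample,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Read / write integer label masks as TIFF
#'
#' Label images are stored as 16-bit integer TIFF; ids round-trip
#' exactly.
#'
#' @param path TIFF file path.
#' @param plane page index for multi-page files.
#' @return [readLabelImage()] returns a [LabelImage-class];
#'   [writeLabelImage()] returns \code{path} invisibly.
#' @export
readLabelImage <- function(path, plane = 1L) {
  m <- .readTiffPlane(path, plane)
  labelImage(m)
}

#' @rdname readLabelImage
#' @param img a [LabelImage-class].
#' @export
writeLabelImage <- function(img, path) {
  .writeTiffInt(labels2d(img), path, 16L)
}

#' Read / write a photon-count decay stack as multi-page TIFF
#'
#' One page per time bin, in temporal order.
#'
#' @param path TIFF file path.
#' @param channel channel tag.
#' @return [readDecayStack()] returns a [DecayStack-class].
#' @export
readDecayStack <- function(path, channel) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
  a <- array(0, dim = c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (i in seq_along(pages)) a[i, , ] <- pages[[i]]
  decayStack(a, channel)
}

#' @rdname readDecayStack
#' @param stack a [DecayStack-class].
#' @export
writeDecayStack <- function(stack, path) {
  a <- counts(stack)
  maxv <- 2^16 - 1
  if (max(a) > maxv) stop("counts exceed the 16-bit range")
  pages <- lapply(seq_len(dim(a)[1L]), function(i) a[i, , ] / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

# Sliding-window box sum with edge truncation, via a summed-area table.
.boxSum <- function(m, r) {
  if (r == 0L) return(m)
  h <- nrow(m); w <- ncol(m)
  sat <- apply(apply(m, 2L, cumsum), 1L, cumsum)   # sat[c, r] after t()
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))                   # (h+1) x (w+1), 1-padded
  r1 <- pmax(seq_len(h) - r, 1L); r2 <- pmin(seq_len(h) + r, h)
  c1 <- pmax(seq_len(w) - r, 1L); c2 <- pmin(seq_len(w) + r, w)
  out <- matrix(0, h, w)
  for (j in seq_len(w)) {
    a <- c1[j]; b <- c2[j] + 1L
    out[, j] <- sat[cbind(r2 + 1L, b)] - sat[cbind(r1, b)] -
      sat[cbind(r2 + 1L, a)] + sat[cbind(r1, a)]
  }
  out
}

#' Integrate a photon-count decay stack into an intensity image
#'
#' At every pixel the decay curve is summed over all time bins and over
#' the surrounding (2r+1) x (2r+1) spatial window (a sliding bin, so
#' every pixel receives a binned value; r = 1 gives the usual 3x3 bin).
#' Windows are truncated at the image edge; no padding is invented.
#'
#' @param stack a [DecayStack-class].
#' @param binRadius window radius r >= 0; 0 sums over time only.
#' @return An [IntensityImage-class] of the stack's spatial shape.
#' @examples
#' st <- decayStack(array(1, c(10, 5, 5)), "NADPH")
#' pixels(integrateDecay(st, 1))[3, 3]  # interior: 9 px * 10 bins = 90
#' @export
integrateDecay <- function(stack, binRadius = 1L) {
  if (length(binRadius) != 1L || binRadius < 0 ||
      binRadius != round(binRadius))
    stop("binRadius must be a nonnegative integer")
  temporal <- colSums(counts(stack))               # h x w
  intensityImage(.boxSum(temporal, as.integer(binRadius)),
                 channel(stack))
}

#' Smooth an image with a circular average filter
#'
#' Each pixel is replaced by the mean over pixels whose centers lie
#' within Euclidean distance \code{radius}. Near edges the kernel is
#' renormalized over in-bounds pixels, so constants are preserved
#' everywhere.
#'
#' @param img an [IntensityImage-class].
#' @param radius kernel radius in pixels (> 0).
#' @return The smoothed [IntensityImage-class].
#' @export
smoothCircularAverage <- function(img, radius = 1) {
  if (length(radius) != 1L || !is.finite(radius) || radius <= 0)
    stop("radius must be a positive number")
  m <- pixels(img)
  h <- nrow(m); w <- ncol(m)
  r <- floor(radius)
  acc <- matrix(0, h, w); cnt <- matrix(0, h, w)
  for (dr in -r:r) for (dc in -r:r) {
    if (dr * dr + dc * dc > radius * radius) next
    rs <- max(1L, 1L - dr):min(h, h - dr)   # dest rows
    cs <- max(1L, 1L - dc):min(w, w - dc)   # dest cols
    acc[rs, cs] <- acc[rs, cs] + m[rs + dr, cs + dc]
    cnt[rs, cs] <- cnt[rs, cs] + 1
  }
  intensityImage(acc / cnt, channel(img))
}

#' Linearly rescale image contrast to a custom maximum
#'
#' Maps [0, max(img)] linearly onto [0, newMax].
#'
#' @param img an [IntensityImage-class] with a positive maximum.
#' @param newMax new maximal intensity (> 0).
#' @return The rescaled [IntensityImage-class].
#' @export
rescaleContrast <- function(img, newMax) {
  if (length(newMax) != 1L || !is.finite(newMax) || newMax <= 0)
    stop("newMax must be a positive number")
  m <- pixels(img)
  old <- max(m, na.rm = TRUE)
  if (old <= 0) stop("cannot rescale an all-zero image")
  intensityImage(m * (newMax / old), channel(img))
}
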