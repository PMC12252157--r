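#' Print image container
#'
#' A 2-D intensity grid in \[0, 1\] with an isotropic physical scale.
#' Multichannel (RGB) arrays are converted to grayscale by channel
#' averaging at construction.
#'
#' @param pixels numeric matrix (rows x cols) with values in \[0, 1\], or a
#'   3-D array whose third dimension is color channels.
#' @param mm_per_pixel physical size of one pixel, mm (> 0).
#' @param source_id free-text identifier.
#' @return An object of class `print_image`.
#' @export
print_image <- function(pixels, mm_per_pixel, source_id = "") {
  if (length(dim(pixels)) == 3) {
    pixels <- apply(pixels, c(1, 2), mean)
  }
  if (!is.matrix(pixels) || length(pixels) == 0) {
    stop_domain("`pixels` must be a non-empty matrix")
  }
  check_positive(mm_per_pixel, "mm_per_pixel")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop_domain("pixel intensities must lie in [0, 1]")
  }
  structure(
    list(pixels = pixels, mm_per_pixel = mm_per_pixel, source_id = source_id),
    class = "print_image"
  )
}

#' @export
print.print_image <- function(x, ...) {
  cat(sprintf("<print_image> %dx%d px at %.4g mm/px (%.3g x %.3g mm)%s\n",
              nrow(x$pixels), ncol(x$pixels), x$mm_per_pixel,
              nrow(x$pixels) * x$mm_per_pixel, ncol(x$pixels) * x$mm_per_pixel,
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' Read a PNG or TIFF image as a print_image
#'
#' @param path image file (8- or 16-bit grayscale or RGB PNG/TIFF).
#' @param mm_per_pixel physical pixel size, mm.
#' @return A [print_image()].
#' @export
read_print_image <- function(path, mm_per_pixel) {
  img <- EBImage::readImage(path)
  px <- as.array(img)
  print_image(px, mm_per_pixel, source_id = basename(path))
}

#' Write a print_image to PNG
#'
#' @param image a [print_image()].
#' @param path output PNG path.
#' @export
write_print_image <- function(image, path) {
  stopifnot(inherits(image, "print_image"))
  EBImage::writeImage(EBImage::Image(image$pixels), path, type = "png")
  invisible(path)
}

#' Preprocess a mesh image for scoring and classification
#'
#' The standard chain applied to every top-down mesh photograph before
#' fidelity scoring or classification: grayscale (done at construction),
#' Gaussian smoothing, global Otsu binarization, and resize to a fixed
#' matrix size (default 128 x 128, the classifier's input). The physical
#' scale is updated by the resize factors so measurements in mm survive
#' preprocessing.
#'
#' @param image a [print_image()].
#' @param target_size integer pair `c(rows, cols)`, default `c(128, 128)`.
#' @param gaussian_sigma Gaussian filter standard deviation in pixels
#'   (applied before thresholding), default 1.
#' @return A binary [print_image()] (values exactly 0/1) of the target
#'   size, with updated `mm_per_pixel` (geometric mean of the two axis
#'   scale factors; axes are resized by the same factor for square
#'   targets from square inputs).
#' @export
preprocess_image <- function(image, target_size = c(128, 128),
                             gaussian_sigma = 1) {
  stopifnot(inherits(image, "print_image"))
  if (any(target_size <= 0) || length(target_size) != 2) {
    stop_domain("`target_size` must be two positive integers")
  }
  px <- image$pixels
  if (gaussian_sigma > 0) {
    px <- as.matrix(EBImage::gblur(EBImage::Image(px), sigma = gaussian_sigma))
    px <- pmin(pmax(px, 0), 1)
  }
  # Otsu needs both classes present; an (all-)constant image binarizes to 0
  thr <- if (diff(range(px)) < 1e-12) Inf else EBImage::otsu(EBImage::Image(px))
  bin <- (px > thr) * 1
  rs <- as.matrix(EBImage::resize(EBImage::Image(bin),
                                  w = target_size[1], h = target_size[2]))
  bin_rs <- (rs >= 0.5) * 1
  scale_r <- nrow(image$pixels) / target_size[1]
  scale_c <- ncol(image$pixels) / target_size[2]
  print_image(bin_rs, image$mm_per_pixel * sqrt(scale_r * scale_c),
              source_id = image$source_id)
}

# Zhang-Suen binary thinning: reduces a binary foreground to its one-pixel
# skeleton; used to sample strand half-widths from the distance transform.
zhang_suen_skeleton <- function(bin) {
  img <- bin != 0
  h <- nrow(img); w <- ncol(img)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- img
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad
      ri <- 2:(h + 1); ci <- 2:(w + 1)
      p2 <- p[ri - 1, ci]; p3 <- p[ri - 1, ci + 1]; p4 <- p[ri, ci + 1]
      p5 <- p[ri + 1, ci + 1]; p6 <- p[ri + 1, ci]; p7 <- p[ri + 1, ci - 1]
      p8 <- p[ri, ci - 1]; p9 <- p[ri - 1, ci - 1]
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      core <- p[ri, ci] & bsum >= 2 & bsum <= 6 & a == 1
      if (step == 1) {
        del <- core & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        del <- core & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(del)) {
        changed <- TRUE
        sub <- pad[ri, ci]
        sub[del] <- FALSE
        pad[ri, ci] <- sub
      }
    }
    if (!changed) break
  }
  pad[2:(h + 1), 2:(w + 1)]
}

#' Measure a printed mesh from its binary image
#'
#' Image-based analogue of caliper measurement: overall length and width
#' come from the tight bounding box of the foreground; the strand
#' (filament) diameter is estimated as `2 * median(d) - 1` pixels, where
#' `d` are Euclidean distance-transform values sampled on the foreground
#' skeleton (the -1 accounts for the pixel-center offset of the distance
#' map). All values are converted to mm via the image scale.
#'
#' @param binary a binarized [print_image()] (as from [preprocess_image()]
#'   or [render_mesh()]).
#' @return A [mesh_measurement()] with `length`, `width`,
#'   `filament_diameter` in mm.
#' @export
measure_mesh <- function(binary) {
  stopifnot(inherits(binary, "print_image"))
  px <- binary$pixels
  if (!all(px %in% c(0, 1))) {
    stop_domain("measure_mesh needs a binarized image; run preprocess_image() first")
  }
  fg <- which(px == 1, arr.ind = TRUE)
  if (nrow(fg) == 0) {
    stop_domain("empty foreground: nothing to measure")
  }
  len_px <- diff(range(fg[, 1])) + 1
  wid_px <- diff(range(fg[, 2])) + 1
  dmap <- as.matrix(EBImage::distmap(EBImage::Image(px)))
  skel <- zhang_suen_skeleton(px)
  dvals <- dmap[skel]
  if (length(dvals) == 0) dvals <- max(dmap)
  fd_px <- max(2 * median(dvals) - 1, 1)
  mesh_measurement(
    length = len_px * binary$mm_per_pixel,
    width = wid_px * binary$mm_per_pixel,
    filament_diameter = fd_px * binary$mm_per_pixel
  )
}
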