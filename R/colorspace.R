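#' Reference white points for CIE Lab* conversion
#'
#' Tristimulus values (Xn, Yn, Zn), with Yn normalised to 100, of the D65
#' illuminant under the CIE 1964 10-degree supplementary observer (the
#' default: large natural surfaces such as fruit slices are viewed at wide
#' angle) or the CIE 1931 2-degree observer.
#'
#' @param observer `"10"` (default) or `"2"`.
#' @return Numeric vector `c(Xn, Yn, Zn)`.
#' @examples
#' white_point()       # D65 / 10 degrees
#' white_point("2")    # D65 / 2 degrees
#' @export
white_point <- function(observer = c("10", "2")) {
  observer <- match.arg(as.character(observer), c("10", "2"))
  if (observer == "10") {
    c(Xn = 94.811, Yn = 100.000, Zn = 107.304)
  } else {
    c(Xn = 95.047, Yn = 100.000, Zn = 108.883)
  }
}

# sRGB (IEC 61966-2-1, D65) linear-RGB -> XYZ matrix; Y row sums to 1.
.srgb_to_xyz_mat <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

# white the matrix actually encodes (the 2-degree D65 white, by construction)
.srgb_native_white <- rowSums(.srgb_to_xyz_mat) * 100

# Bradford cone-response matrix for chromatic adaptation
.bradford <- matrix(c(
   0.8951,  0.2664, -0.1614,
  -0.7502,  1.7135,  0.0367,
   0.0389, -0.0685,  1.0296
), nrow = 3, byrow = TRUE)

# Bradford adaptation from source to destination white (tristimulus, Y = 100)
.adapt_matrix <- function(src, dst) {
  s <- as.vector(.bradford %*% src)
  d <- as.vector(.bradford %*% dst)
  solve(.bradford) %*% diag(d / s) %*% .bradford
}

# effective linear-RGB -> XYZ matrix for a reference white: the raster is
# chromatically adapted from the sRGB native white to the requested white,
# so the encoding white maps exactly to L* = 100, a* = b* = 0 under any
# supported observer
.rgb_xyz_for_white <- function(white) {
  .adapt_matrix(.srgb_native_white, white * 100 / white[2]) %*%
    .srgb_to_xyz_mat
}

# piecewise sRGB companding (electro-optical transfer), vectorised
.srgb_decode <- function(s) {
  ifelse(s <= 0.04045, s / 12.92, ((s + 0.055) / 1.055)^2.4)
}

.srgb_encode <- function(lin) {
  lin <- pmax(lin, 0)
  ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
}

# CIE f(t) with the (6/29)^3 linear-segment threshold, and its inverse
.lab_f <- function(t) {
  delta <- 6 / 29
  ifelse(t > delta^3, t^(1 / 3), t / (3 * delta^2) + 4 / 29)
}

.lab_f_inv <- function(ft) {
  delta <- 6 / 29
  ifelse(ft > delta, ft^3, 3 * delta^2 * (ft - 4 / 29))
}

.check_rgb <- function(img) {
  if (!(is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L))
    stop("expected an H x W x 3 raster; got dimensions ",
         paste(dim(img), collapse = " x "),
         if (length(dim(img)) == 3L && dim(img)[3] == 4L)
           " (alpha channels are not supported; flatten the image first)")
  if (any(img < 0 | img > 255) || any(img != round(img)))
    stop("RGB channel values must be integers in [0, 255]")
  invisible(img)
}

#' Convert an 8-bit sRGB raster to CIE Lab*
#'
#' Element-wise, deterministic sRGB -> linear RGB -> XYZ -> Lab* conversion.
#' The chain is the standard one: piecewise sRGB decoding, the sRGB/D65
#' RGB-to-XYZ matrix, then the CIE cube-root `f(t)` with the (6/29)^3
#' linear-segment threshold relative to the chosen reference white. Because
#' the sRGB matrix is defined against the 2-degree D65 white, the XYZ
#' values are chromatically adapted (Bradford) from that native white to
#' the requested reference white, so the encoding white (255, 255, 255)
#' maps to exactly (100, 0, 0) under either observer while chromatic
#' colours shift slightly with the observer choice.
#'
#' @param img H x W x 3 array of integers in \[0, 255\] (sRGB).
#' @param white Reference white `c(Xn, Yn, Zn)`; see [white_point()].
#' @return H x W x 3 numeric array with channels L* (0-100), a*, b*.
#' @examples
#' px <- array(c(255L, 0L, 255L), dim = c(1, 1, 3))
#' srgb_to_lab(px)  # the magenta chroma-key background, ~ (61, 98, -61)
#' @export
srgb_to_lab <- function(img, white = white_point()) {
  .check_rgb(img)
  stopifnot(length(white) == 3L, all(white > 0))
  d <- dim(img)
  lin <- .srgb_decode(as.vector(img) / 255)
  m <- matrix(lin, ncol = 3L)                       # pixels x (R,G,B)
  xyz <- m %*% t(.rgb_xyz_for_white(white)) * 100   # pixels x (X,Y,Z)
  fx <- .lab_f(xyz[, 1] / white[1])
  fy <- .lab_f(xyz[, 2] / white[2])
  fz <- .lab_f(xyz[, 3] / white[3])
  lab <- cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
  array(lab, dim = d)
}

#' Convert a CIE Lab* raster back to 8-bit sRGB
#'
#' Inverse of [srgb_to_lab()] up to 8-bit quantisation. Out-of-gamut values
#' are clipped to \[0, 255\] and the number of affected pixels is attached as
#' the `"clipped"` attribute (and reported via a message when
#' `quiet = FALSE`).
#'
#' @param lab H x W x 3 numeric array (L* in \[0, 100\], a*, b*).
#' @param white Reference white `c(Xn, Yn, Zn)`.
#' @param quiet Suppress the clipped-pixel message.
#' @return H x W x 3 integer array in \[0, 255\] with attribute `clipped`,
#'   the count of pixels whose RGB fell outside the gamut before clipping.
#' @export
lab_to_srgb <- function(lab, white = white_point(), quiet = TRUE) {
  if (!(is.array(lab) && length(dim(lab)) == 3L && dim(lab)[3] == 3L))
    stop("expected an H x W x 3 Lab* raster")
  d <- dim(lab)
  m <- matrix(as.vector(lab), ncol = 3L)
  if (any(m[, 1] < -1e-6 | m[, 1] > 100 + 1e-6))
    stop("L* must lie in [0, 100]")
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- cbind(.lab_f_inv(fx) * white[1],
               .lab_f_inv(fy) * white[2],
               .lab_f_inv(fz) * white[3]) / 100
  rgb_lin <- xyz %*% t(solve(.rgb_xyz_for_white(white)))
  out_of_gamut <- rowSums(rgb_lin < -1e-9 | rgb_lin > 1 + 1e-9) > 0
  rgb_lin[rgb_lin < 0] <- 0
  rgb_lin[rgb_lin > 1] <- 1
  rgb8 <- round(.srgb_encode(rgb_lin) * 255)
  rgb8[rgb8 < 0] <- 0
  rgb8[rgb8 > 255] <- 255
  n_clip <- sum(out_of_gamut)
  if (!quiet && n_clip > 0)
    message(n_clip, " pixel(s) fell outside the sRGB gamut and were clipped")
  out <- array(as.integer(rgb8), dim = d)
  attr(out, "clipped") <- n_clip
  attr(out, "clipped_mask") <- matrix(out_of_gamut, d[1], d[2])
  out
}

# TRUE for Lab* triples whose exact sRGB image lies inside the gamut
.in_srgb_gamut <- function(L, a, b, white = white_point()) {
  fy <- (L + 16) / 116
  fx <- fy + a / 500
  fz <- fy - b / 200
  xyz <- cbind(.lab_f_inv(fx) * white[1],
               .lab_f_inv(fy) * white[2],
               .lab_f_inv(fz) * white[3]) / 100
  rgb <- xyz %*% t(solve(.rgb_xyz_for_white(white)))
  rowSums(rgb < -1e-9 | rgb > 1 + 1e-9) == 0
}

#' Read an 8-bit RGB image (PNG or TIFF)
#'
#' @param path File path; format inferred from the extension.
#' @return H x W x 3 integer array in \[0, 255\]. Images with an alpha
#'   channel are rejected.
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: '", ext, "' (use PNG or TIFF)")
  )
  if (length(dim(raw)) == 2L)
    stop("greyscale images are not supported; expected 3 channels")
  if (dim(raw)[3] == 4L)
    stop("image has an alpha channel; flatten it before analysis")
  if (dim(raw)[3] != 3L)
    stop("expected 3 channels, got ", dim(raw)[3])
  array(as.integer(round(raw * 255)), dim = dim(raw))
}

#' Write an 8-bit RGB image (PNG or TIFF)
#'
#' @param img H x W x 3 integer array in \[0, 255\].
#' @param path Output path; format inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(img, path) {
  .check_rgb(img)
  ext <- tolower(tools::file_ext(path))
  arr <- array(img / 255, dim = dim(img))
  switch(ext,
    png  = png::writePNG(arr, path),
    tif  = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    stop("unsupported image format: '", ext, "'")
  )
  invisible(path)
}
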