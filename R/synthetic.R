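#' Configuration for the synthetic browning dataset generator
#'
#' Defines the study design the generator emulates: two treatment groups
#' (control, antioxidant-treated) photographed at 30-min intervals over 9 h,
#' each slice's per-pixel Browning/Yellowing Index values following a
#' three-parameter Weibull distribution whose shape factor drifts linearly
#' in exposure time, slices rendered as discs on a magenta chroma-key
#' background.
#'
#' Defaults encode the study conditions: YI shape lines
#' 1.280 / 0.885 + 0.00125 t for control / treated with slice-to-slice
#' noise sd 0.18; BI shape lines 2.380 / 1.721 + 0.00076 t with noise sd
#' 0.54; background Lab* (61, 98, -61); 108 slices per group spread over the
#' 19-point 0-540 min grid (round-robin, so per-timepoint counts differ by
#' at most one). The pixel-level Weibull scale (10) and location (0.5) are
#' modelling choices that keep index values in realistic ranges; they are
#' not study quantities. Per-pixel BI and YI draws are coupled through a
#' Gaussian copula (`copula_rho`, default 0.3) because browning and
#' yellowing co-occur on real slices. Per-pixel lightness is set from the
#' slice's expected BI through a linear darkening map
#' `L* = l_base - l_per_bi * E[BI]` (browner slices are darker).
#'
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of (config, seed).
#' @param timepoints Exposure times in minutes.
#' @param slices_per_group Total slices per treatment group.
#' @param discs_per_image Slices rendered per image (grid layout when > 1).
#' @param image_size Cell edge in pixels for one disc.
#' @param disc_radius Disc radius in pixels.
#' @param background_lab Nominal background colour in Lab* (the rounded
#'   values conventionally quoted for the chroma-key).
#' @param background_rgb Exact 8-bit sRGB pixel painted as background. The
#'   default, pure magenta (255, 0, 255), decodes to Lab*
#'   (60.3, 98.6, -61.8) under the default white point — the quoted
#'   `background_lab` to within rounding, and inside the default
#'   [threshold_ranges()] windows. (Encoding the rounded Lab* values
#'   instead would land at (255, 16, 255), whose a* of 97.6 escapes the
#'   a* threshold window, so the background is substituted digitally in
#'   RGB, as a chroma-key is.)
#' @param yi_intercepts,yi_slope,bi_intercepts,bi_slope Shape-factor lines
#'   per group (named `control`, `treated`); slopes per minute.
#' @param noise_sd_yi,noise_sd_bi Slice-level Gaussian noise sd around the
#'   lines.
#' @param pixel_alpha,pixel_gamma Weibull scale/location of per-pixel index
#'   draws.
#' @param copula_rho Gaussian-copula correlation between per-pixel BI and
#'   YI draws.
#' @param l_base,l_per_bi Linear darkening map from expected BI to L*.
#' @param beta_floor Lower truncation for generated shape factors.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             timepoints = seq(0, 540, by = 30),
                             slices_per_group = 108L,
                             discs_per_image = 1L,
                             image_size = 96L,
                             disc_radius = 40L,
                             background_lab = c(61, 98, -61),
                             background_rgb = c(255L, 0L, 255L),
                             yi_intercepts = c(control = 1.280, treated = 0.885),
                             yi_slope = 0.00125,
                             bi_intercepts = c(control = 2.380, treated = 1.721),
                             bi_slope = 0.00076,
                             noise_sd_yi = 0.18,
                             noise_sd_bi = 0.54,
                             pixel_alpha = 10,
                             pixel_gamma = 0.5,
                             copula_rho = 0.3,
                             l_base = 80,
                             l_per_bi = 1.0,
                             beta_floor = 0.05) {
  stopifnot(pixel_alpha > 0, noise_sd_yi >= 0, noise_sd_bi >= 0,
            all(diff(timepoints) > 0), disc_radius >= 1,
            image_size >= 2 * disc_radius + 2,
            copula_rho > -1, copula_rho < 1)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "generator_config")
}

#' Generate the ground-truth shape-factor table
#'
#' For each slice the true shape factor of each index is
#' `group intercept + slope * time + N(0, sd)`, truncated below at
#' `beta_floor`. Slices are assigned to timepoints round-robin within each
#' group. Deterministic given `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return data.frame with `slice_id`, `group`, `time_min`, `beta_bi_true`,
#'   `beta_yi_true`.
#' @export
generate_shape_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  groups <- c("control", "treated")
  tab <- do.call(rbind, lapply(groups, function(g) {
    tmins <- rep(cfg$timepoints, length.out = cfg$slices_per_group)
    data.frame(group = g, time_min = sort(tmins))
  }))
  n <- nrow(tab)
  tab$slice_id <- sprintf("s%03d", seq_len(n))
  mu_bi <- cfg$bi_intercepts[tab$group] + cfg$bi_slope * tab$time_min
  mu_yi <- cfg$yi_intercepts[tab$group] + cfg$yi_slope * tab$time_min
  tab$beta_bi_true <- pmax(mu_bi + stats::rnorm(n, 0, cfg$noise_sd_bi),
                           cfg$beta_floor)
  tab$beta_yi_true <- pmax(mu_yi + stats::rnorm(n, 0, cfg$noise_sd_yi),
                           cfg$beta_floor)
  rownames(tab) <- NULL
  tab[, c("slice_id", "group", "time_min", "beta_bi_true", "beta_yi_true")]
}

# paint one disc of Weibull-distributed index values into a Lab canvas,
# using the current RNG stream; returns canvas plus the disc's pixel mask
.paint_disc <- function(lab, cx, cy, r, beta_bi, beta_yi, cfg) {
  h <- dim(lab)[1]; w <- dim(lab)[2]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  inside <- (rows - cy)^2 + (cols - cx)^2 <= r^2
  idx <- which(inside)
  n <- length(idx)
  z1 <- stats::rnorm(n)
  z2 <- cfg$copula_rho * z1 + sqrt(1 - cfg$copula_rho^2) * stats::rnorm(n)
  bi <- qweibull3(stats::pnorm(z1), cfg$pixel_alpha, beta_bi, cfg$pixel_gamma)
  yi <- qweibull3(stats::pnorm(z2), cfg$pixel_alpha, beta_yi, cfg$pixel_gamma)
  mean_bi <- cfg$pixel_gamma + cfg$pixel_alpha * gamma(1 + 1 / beta_bi)
  L <- min(max(cfg$l_base - cfg$l_per_bi * mean_bi, 20), 95)
  ab <- lab_from_indices(bi, yi, L)
  # enforce the render contract that every painted pixel is representable
  # in sRGB: extreme tail draws (heavy-tailed at low shape factors) are
  # shrunk toward the Weibull location until their Lab* image lies in
  # gamut, and the number of affected pixels is reported. Without this a
  # clipped pixel would decode to a wild index value and corrupt the
  # slice's fitted location parameter.
  bad <- !.in_srgb_gamut(L, ab$a, ab$b)
  n_trunc <- sum(bad)
  iter <- 0L
  while (any(bad) && iter < 200L) {
    bi[bad] <- cfg$pixel_gamma + 0.9 * (bi[bad] - cfg$pixel_gamma)
    yi[bad] <- cfg$pixel_gamma + 0.9 * (yi[bad] - cfg$pixel_gamma)
    ab_bad <- lab_from_indices(bi[bad], yi[bad], L)
    ab$a[bad] <- ab_bad$a
    ab$b[bad] <- ab_bad$b
    bad[bad] <- !.in_srgb_gamut(L, ab_bad$a, ab_bad$b)
    iter <- iter + 1L
  }
  Lc <- lab[, , 1]; ac <- lab[, , 2]; bc <- lab[, , 3]
  Lc[idx] <- L; ac[idx] <- ab$a; bc[idx] <- ab$b
  list(lab = array(c(Lc, ac, bc), dim = dim(lab)), mask = inside,
       n_truncated = n_trunc)
}

# encode a Lab canvas to sRGB, then substitute the chroma-key background
# pixel-for-pixel (digital background substitution); clipping is counted
# over foreground (disc) pixels only
.encode_canvas <- function(lab, fg_mask, background_rgb) {
  rgb <- lab_to_srgb(lab)
  clip_fg <- sum(attr(rgb, "clipped_mask") & fg_mask)
  for (ch in 1:3) {
    plane <- rgb[, , ch]
    plane[!fg_mask] <- background_rgb[ch]
    rgb[, , ch] <- plane
  }
  out <- array(as.integer(rgb), dim = dim(rgb))
  attr(out, "clipped") <- clip_fg
  out
}

.blank_canvas <- function(h, w, background_lab) {
  array(rep(background_lab, each = h * w), dim = c(h, w, 3))
}

#' Render one synthetic slice image
#'
#' Inverts the analysis chain: per-pixel (BI, YI) pairs are drawn from the
#' three-parameter Weibull with the slice's shape factors (coupled by a
#' Gaussian copula), converted to Lab* via the index inversion at the
#' slice's lightness, and encoded to 8-bit sRGB on a magenta canvas.
#'
#' @param beta_bi,beta_yi True shape factors of the slice.
#' @param cfg A [generator_config()] (geometry and pixel-model settings).
#' @param seed Seed for the per-pixel draws.
#' @return H x W x 3 integer sRGB array with attribute `clipped` (pixels
#'   that still fell outside the gamut at encoding, normally 0) and
#'   `truncated` (tail draws shrunk toward the Weibull location so their
#'   colour is representable in sRGB; see [generator_config()]).
#' @export
render_slice_image <- function(beta_bi, beta_yi, cfg = generator_config(),
                               seed = cfg$seed) {
  stopifnot(beta_bi > 0, beta_yi > 0)
  set.seed(seed)
  s <- cfg$image_size
  lab <- .blank_canvas(s, s, cfg$background_lab)
  p <- .paint_disc(lab, cx = (s + 1) / 2, cy = (s + 1) / 2,
                   r = cfg$disc_radius, beta_bi, beta_yi, cfg)
  out <- .encode_canvas(p$lab, p$mask, cfg$background_rgb)
  attr(out, "truncated") <- p$n_truncated
  out
}

#' Generate a full synthetic dataset on disk
#'
#' Writes one PNG per image (one or more discs each), a ground-truth CSV
#' and a manifest JSON. Regenerating with the same configuration and seed
#' is byte-identical.
#'
#' @param cfg A [generator_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `truth` (the truth table, including the
#'   image file and component index of each slice), `manifest` and `dir`.
#' @export
generate_dataset <- function(cfg = generator_config(), dir) {
  stopifnot(inherits(cfg, "generator_config"))
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- generate_shape_trajectories(cfg)        # seeds the stream
  n <- nrow(truth)
  slice_seeds <- sample.int(.Machine$integer.max - 1L, n)
  k <- cfg$discs_per_image
  n_img <- ceiling(n / k)
  grid_cols <- ceiling(sqrt(k))
  grid_rows <- ceiling(k / grid_cols)
  s <- cfg$image_size
  truth$image <- NA_character_
  truth$component <- NA_integer_
  truth$clipped_px <- NA_integer_
  truth$truncated_px <- NA_integer_
  for (i in seq_len(n_img)) {
    sl <- ((i - 1L) * k + 1L):min(i * k, n)
    fname <- sprintf("img_%04d.png", i)
    lab <- .blank_canvas(grid_rows * s, grid_cols * s, cfg$background_lab)
    fg <- matrix(FALSE, grid_rows * s, grid_cols * s)
    for (j in seq_along(sl)) {
      cell <- j - 1L
      row <- cell %/% grid_cols
      col <- cell %% grid_cols
      set.seed(slice_seeds[sl[j]])
      p <- .paint_disc(lab,
                       cx = col * s + (s + 1) / 2,
                       cy = row * s + (s + 1) / 2,
                       r = cfg$disc_radius,
                       truth$beta_bi_true[sl[j]],
                       truth$beta_yi_true[sl[j]], cfg)
      lab <- p$lab
      fg <- fg | p$mask
      truth$image[sl[j]] <- fname
      truth$component[sl[j]] <- j
      truth$truncated_px[sl[j]] <- p$n_truncated
    }
    rgb <- .encode_canvas(lab, fg, cfg$background_rgb)
    truth$clipped_px[sl] <- attr(rgb, "clipped")
    write_rgb_image(rgb, file.path(img_dir, fname))
  }
  truth_path <- file.path(dir, "truth.csv")
  utils::write.csv(truth, truth_path, row.names = FALSE)
  cfg_plain <- unclass(cfg)
  manifest <- list(
    seed = cfg$seed,
    config = cfg_plain,
    config_hash = hash_object(cfg_plain),
    n_slices = n,
    n_images = n_img,
    images = file.path("images", sprintf("img_%04d.png", seq_len(n_img)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(truth = truth, manifest = manifest, dir = dir))
}

#' Stable MD5 hash of an R object via its canonical JSON form
#'
#' @param x A list-like object serialisable by jsonlite.
#' @return MD5 hex string.
#' @export
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}
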