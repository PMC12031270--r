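# shared fixtures and brute-force oracles, all built in code

# uniform Lab image
uniform_lab <- function(L, a, b, h = 8, w = 8) {
  array(rep(c(L, a, b), each = h * w), dim = c(h, w, 3))
}

# logical disc mask from the disc equation (independent of the package's
# rendering code)
disc_mask <- function(h, w, cx, cy, r) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rows - cy)^2 + (cols - cx)^2 <= r^2
}

# brute-force 8-connectivity flood fill; returns number of components
flood_count <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- !mask
  count <- 0L
  for (start in which(mask)) {
    if (seen[start]) next
    count <- count + 1L
    stack <- start
    seen[start] <- TRUE
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (p - 1L) %% h + 1L; c <- (p - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) {
          q <- (cc - 1L) * h + rr
          if (!seen[q]) { seen[q] <- TRUE; stack <- c(stack, q) }
        }
      }
    }
  }
  count
}

# paper-structured slice-record table drawn straight from the trajectory
# generator (shape factors without the imaging stage)
traj_records <- function(seed, ...) {
  cfg <- generator_config(seed = seed, ...)
  tr <- generate_shape_trajectories(cfg)
  data.frame(slice_id = tr$slice_id, group = tr$group,
             time_min = tr$time_min,
             beta_bi = tr$beta_bi_true, beta_yi = tr$beta_yi_true)
}

# tiny generator config for image-based tests (small discs, quick fits)
small_cfg <- function(seed = 1, ...) {
  generator_config(seed = seed, slices_per_group = 8L, image_size = 40L,
                   disc_radius = 16L, ...)
}
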