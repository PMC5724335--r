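# shared helpers: run the full mechanics chain on a phantom, and a small
# cache so several tests can reuse the same deterministic phantom results

run_dense_chain <- function(spec, sigma_px = 1, poly_order = 5) {
  ph <- generate_dense_phantom(spec)
  fld <- suppressWarnings(phase_to_displacement(
    ph$phase_x, ph$phase_y, ph$magnitude,
    encoding_frequency = ph$encoding_frequency,
    frame_times = ph$frame_times, pixel_spacing = ph$pixel_spacing))
  tr <- build_trajectories(fld, ph$mask_ref, sigma_px = sigma_px,
                           poly_order = poly_order)
  sc <- compute_strains(tr, ph$lv_center)
  list(ph = ph, fld = fld, tr = tr, sc = sc)
}

.chain_cache <- new.env(parent = emptyenv())

cached_chain <- function(key, spec) {
  if (is.null(.chain_cache[[key]]))
    .chain_cache[[key]] <- run_dense_chain(spec)
  .chain_cache[[key]]
}

# rigid trajectories built directly from a closed-form motion (no imaging),
# for tensor-level checks
analytic_trajectories <- function(motion, grid_size = 48, spacing = 1,
                                  r_in = 12, r_out = 20, n_frames = 5) {
  g <- pixel_grid(grid_size, spacing)
  r <- sqrt(g$x^2 + g$y^2)
  mask <- r >= r_in & r <= r_out
  idx <- which(mask)
  X0 <- cbind(g$x[idx], g$y[idx])
  nf <- n_frames
  pos <- array(NA_real_, c(nrow(X0), 2, nf))
  for (f in seq_len(nf)) pos[, , f] <- motion(X0, (f - 1) / (nf - 1))
  structure(list(X0 = X0, pos = pos,
                 valid = matrix(TRUE, nrow(X0), nf),
                 frame_times = (seq_len(nf) - 1) * 30,
                 pixel_spacing = spacing, ref_index = idx,
                 grid_dim = c(grid_size, grid_size)),
            class = "trajectories")
}

# synthetic strain_curves object from element curves on a sector layout
make_strain_curves <- function(ecc, angles, frame_times, n_sectors = 6,
                               insertion = 0) {
  sector <- pmin(floor(((angles - insertion) %% 360) /
                         (360 / n_sectors)) + 1L, n_sectors)
  seg <- t(sapply(seq_len(n_sectors), function(s) {
    rows <- which(sector == s)
    colMeans(ecc[rows, , drop = FALSE], na.rm = TRUE)
  }))
  structure(list(ecc = ecc, err = ecc, angle = angles,
                 radius = rep(15, nrow(ecc)), sector = sector,
                 ecc_segment = seg, err_segment = seg,
                 ecc_slice = colMeans(ecc, na.rm = TRUE),
                 err_slice = colMeans(ecc, na.rm = TRUE),
                 frame_times = frame_times, n_sectors = n_sectors,
                 rv_insertion_angle = insertion),
            class = "strain_curves")
}
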