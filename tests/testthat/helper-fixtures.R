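# Shared fixtures: small, deterministic, built in code.

default_acq0 <- function() acquisition_spec(noise_sigma = 0)

# binary mask of straight tube(s) from polylines (um), default pitch
tube_mask <- function(polylines, radii, dims, pitch = c(2, 2, 3)) {
  pamvasc:::rasterize_phantom(polylines, radii, dims, pitch) > 0
}

# Sierpinski carpet raster, n iterations (3^n x 3^n logical matrix)
sierpinski_carpet <- function(n) {
  m <- matrix(TRUE, 1, 1)
  for (i in seq_len(n)) {
    k <- nrow(m)
    out <- matrix(FALSE, 3 * k, 3 * k)
    for (bi in 0:2) for (bj in 0:2) {
      if (bi == 1 && bj == 1) next
      out[bi * k + seq_len(k), bj * k + seq_len(k)] <- m
    }
    m <- out
  }
  m
}

# small phantom spec for fast generator tests
small_spec <- function(...) {
  args <- utils::modifyList(list(volume_size_um = c(300, 300, 300),
                                 n_sprouts = 4L), list(...))
  do.call(phantom_spec, args)
}
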