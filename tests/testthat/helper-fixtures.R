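# shared small fixtures, built in code at test time

# small geometry matched to a 32^2 x 8 grid: keeps reconstructions instant
tiny_geometry <- function(tof_sigma_mm = 0) {
  scanner_geometry(n_angles = 30L, n_radial_bins = 32L, n_slices = 8L,
                   radial_spacing_mm = 3, slice_spacing_mm = 3,
                   tof_sigma_mm = tof_sigma_mm)
}

# smooth, deliberately asymmetric blob phantom on the tiny grid (for
# projector / transform / registration tests); compact support in all axes
tiny_blob_volume <- function(dims = c(32, 32, 8), vs = 3) {
  xs <- (seq_len(dims[1]) - (dims[1] + 1) / 2) * vs
  ys <- (seq_len(dims[2]) - (dims[2] + 1) / 2) * vs
  zs <- (seq_len(dims[3]) - (dims[3] + 1) / 2) * vs
  a <- array(0, dims)
  for (k in seq_len(dims[3])) {
    zterm <- zs[k]^2 / (2 * 4^2)
    main <- exp(-outer(xs^2 / (2 * 10^2), ys^2 / (2 * 16^2), `+`) - zterm)
    lump <- 0.8 * exp(-outer((xs + 15)^2, (ys - 18)^2, `+`) / (2 * 6^2) - zterm)
    a[, , k] <- main + lump
  }
  image_volume(a, vs, role = "activity")
}

# single-slice uniform disk phantom
disk_volume <- function(n = 32, vs = 3, radius_mm = 30) {
  xs <- (seq_len(n) - (n + 1) / 2) * vs
  a <- array(0, c(n, n, 1))
  a[, , 1] <- (outer(xs^2, xs^2, `+`) <= radius_mm^2) * 1
  image_volume(a, vs, role = "activity")
}

# independent Poisson log-likelihood oracle (plain formula on arrays)
oracle_loglik <- function(y, ybar) {
  y <- as.numeric(y); ybar <- as.numeric(ybar)
  if (any(y > 0 & ybar <= 0)) return(-Inf)
  pos <- ybar > 0
  sum(y[pos] * log(ybar[pos])) - sum(ybar)
}

# default 64x64x32 phantom, built once per test run
std_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_phantom()
    cache
  }
})
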