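# Shared fixtures built in code.

# sparse, well-separated point emitters: the regime the nearest-neighbour
# precision estimator is defined for
sparse_emitter_model <- function(sigma = 12, frames = 5000) {
  emitter_model(
    n_clusters = 40, cluster_diameter_nm = 0, emitters_per_cluster = 1,
    frames = frames, activation_prob = 0.05, sigma_true_nm = sigma,
    background_per_um2 = 1e-4, fov_nm = 6000, min_separation = 600
  )
}

# a custom unit whose bypass resistance is tuned to equal the Path-1
# resistance (identical parallel paths up to quadrature error)
balanced_unit <- function() {
  eps <- 1e-3
  W13 <- 25; L13 <- 100; W2 <- 50
  r_main <- segment_hydraulics(channel_segment(W13, W13, 1, 15))$R_Pa_s_m3
  r_byp <- segment_hydraulics(channel_segment(W2, W2, 1, 15))$R_Pa_s_m3
  # R1 ~ L13 * r_main (taper and gap regions are made negligible)
  L2 <- L13 * r_main / r_byp
  trap_unit_from_dims(L11 = eps, L12 = eps, W12 = W13 - eps, W13 = W13,
                      L13 = L13, W2 = W2, L2 = L2, height = 15)
}

# twin-channel raster domain: two identical parallel slots between inlet
# and outlet, for field symmetry checks
twin_channel_domain <- function(length = 120, slot = 10, wall = 10,
                                height = 15, dx = 0.5) {
  ny <- round((2 * slot + wall) / dx)
  nx <- round(length / dx)
  yc <- (seq_len(ny) - 0.5) * dx
  mask <- matrix(TRUE, nx, ny)
  solid <- yc > slot & yc < slot + wall
  lead <- round(0.15 * nx)
  mask[(lead + 1):(nx - lead), solid] <- FALSE
  labels <- matrix(1L, nx, ny)
  labels[1, ] <- 2L; labels[nx, ] <- 3L
  structure(list(
    dx = dx, x0 = 0, y0 = 0, nx = nx, ny = ny,
    xc = (seq_len(nx) - 0.5) * dx, yc = yc,
    mask_fluid = mask, mask = mask, labels = labels, particle_radius = 0,
    gates = list(), layout = NULL, unit = NULL, height = height
  ), class = "raster_domain")
}
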