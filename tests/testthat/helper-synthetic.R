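# Shared fixtures, built in code.

# small noisy uniform-translation pair
make_uniform_pair <- function(side = 256, u = c(2, 0.6), snr_db = 50,
                              density = 8e-3, seed = 1, pixel_size = 1) {
  set.seed(seed)
  shape <- c(side, side)
  beads <- generate_bead_field(shape, density)
  ref <- render_beads(beads, shape)
  moved <- apply_displacement(beads, displacement_uniform(u), shape)
  session <- render_beads(moved, shape)
  image_pair(add_pixel_noise(ref, snr_db), add_pixel_noise(session, snr_db),
             pixel_size)
}

# tiny dense elastostatic problem with a smooth traction field
make_toy_inversion <- function(n = 9, spacing = 11, noise_um = 0.02,
                               sigma2 = NULL, seed = 42) {
  set.seed(seed)
  sub <- substrate_model(5000, 0.45, 50)
  kern <- build_spectral_kernel(sub, n, spacing)
  op <- assemble_dense_operator(kern)
  xs <- (seq_len(n) - 0.5) * spacing
  gx <- matrix(xs, n, n, byrow = TRUE)
  gy <- matrix(xs, n, n)
  tr <- four_island_field(n * spacing, s = 15)(gx, gy)
  t_true <- c(as.vector(tr$tx), as.vector(tr$ty))
  u_clean <- op$M %*% t_true
  uh <- as.numeric(u_clean) + rnorm(2 * n * n, sd = noise_um)
  if (is.null(sigma2)) sigma2 <- rep(noise_um^2, 2 * n * n)
  list(obs = observation_model(uh, sigma2, op),
       obs0 = observation_model(uh, rep(0, 2 * n * n), op),
       reg = build_regularizer(n, n, "laplacian"),
       t_true = t_true, kern = kern, op = op, n = n, substrate = sub)
}
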