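# Shared fixtures: small dielectric bodies, toy networks, and trace builders.

eps0 <- 8.8541878128e-12

body_cell <- function(radius = 7.5e-6) dielectric_body(60, 0.01, radius)
body_buffer <- function() dielectric_body(78, 0.005)

# random physically admissible dielectric parameters
random_body <- function(with_radius = FALSE) {
  dielectric_body(
    eps_rel = runif(1, 2, 100),
    sigma = 10^runif(1, -6, 2),
    radius = if (with_radius) 10^runif(1, -6, -5) else NULL
  )
}

# noise-free saturating trace at 50 fps
make_trace <- function(L0 = 16, strain = 0.0864, tau = 2, duration = 10,
                       fps = 50, noise_sd = 0, cell_id = "c1") {
  t <- seq(0, duration, by = 1 / fps)
  len <- L0 * (1 + strain * (1 - exp(-t / max(tau, 1e-12))))
  if (noise_sd > 0) len <- len + rnorm(length(t), 0, noise_sd)
  data.frame(cell_id = cell_id, time_s = t, length_um = len,
             stringsAsFactors = FALSE)
}

withr_local_tempfile <- function(ext) {
  withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
}

withr_local_tempdir <- function() {
  withr::local_tempdir(.local_envir = parent.frame())
}

# two-resistor bridge used against hand mesh-current algebra
toy_bridge <- function(R1 = 1e12, R2 = 2e12, R3 = 3e12, R4 = 4e12,
                       R5 = 5e12) {
  net <- depmech::add_edge(depmech:::new_hydraulic_network(),
                           "A", "B", R1, "e1")
  net <- depmech::add_edge(net, "B", "C", R2, "e2")
  net <- depmech::add_edge(net, "A", "D", R3, "e3")
  net <- depmech::add_edge(net, "D", "C", R4, "e4")
  net <- depmech::add_edge(net, "B", "D", R5, "e5")
  net
}
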