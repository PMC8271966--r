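# Independent plain-R reference implementation of the photon transport,
# used as a statistical oracle for the optimized kernel on tiny grids.
# Deliberately straightforward: one photon at a time, R's own RNG,
# hop-drop-spin with the optical properties at the current position,
# no voxel traversal tricks, no early-termination shortcuts.
#
# Returns per-voxel absorbed weight plus the weight ledger. Valid for
# homogeneous (or piecewise-homogeneous with voxel-scale steps) media.
reference_transport <- function(grid, launch_pos, launch_dir, n_photons,
                                weight_min = 1e-4, roulette_p = 0.1) {
  h <- grid$voxel_size
  ext <- grid$extent
  props <- grid$regions
  mu_a <- vapply(props, `[[`, numeric(1), "mu_a") / 10    # per mm
  mu_s <- scattering_from_reduced(
    vapply(props, `[[`, numeric(1), "mu_s_prime"),
    vapply(props, `[[`, numeric(1), "g")) / 10
  gg <- vapply(props, `[[`, numeric(1), "g")
  mu_t <- mu_a + mu_s
  absorbed <- array(0, dim = grid$dim)
  launched <- deposited <- escaped <- 0

  vox_of <- function(p) {
    i <- floor(p / h) + 1L
    pmin(pmax(i, 1L), grid$dim)
  }
  inside <- function(p) all(p >= 0) && all(p < ext)

  for (ph in seq_len(n_photons)) {
    p <- launch_pos[if (nrow(launch_pos) > 1L) ph else 1L, ]
    d <- launch_dir[if (nrow(launch_dir) > 1L) ph else 1L, ]
    w <- 1
    launched <- launched + 1
    repeat {
      if (!inside(p)) { escaped <- escaped + w; break }
      v <- vox_of(p)
      r <- grid$region_map[v[1], v[2], v[3]]
      if (mu_t[r] <= 0) { escaped <- escaped + w; break }
      s <- -log(runif(1)) / mu_t[r]
      p <- p + d * s
      if (!inside(p)) { escaped <- escaped + w; break }
      v <- vox_of(p)
      r <- grid$region_map[v[1], v[2], v[3]]
      dw <- w * mu_a[r] / mu_t[r]
      absorbed[v[1], v[2], v[3]] <- absorbed[v[1], v[2], v[3]] + dw
      deposited <- deposited + dw
      w <- w - dw
      # Henyey-Greenstein deflection
      g1 <- gg[r]
      ct <- if (abs(g1) < 1e-6) 2 * runif(1) - 1 else {
        tmp <- (1 - g1^2) / (1 - g1 + 2 * g1 * runif(1))
        max(-1, min(1, (1 + g1^2 - tmp^2) / (2 * g1)))
      }
      st <- sqrt(1 - ct^2)
      phi <- 2 * pi * runif(1)
      if (abs(d[3]) > 0.99999) {
        d <- c(st * cos(phi), st * sin(phi), sign(d[3]) * ct)
      } else {
        den <- sqrt(1 - d[3]^2)
        d <- c(st * (d[1] * d[3] * cos(phi) - d[2] * sin(phi)) / den + d[1] * ct,
               st * (d[2] * d[3] * cos(phi) + d[1] * sin(phi)) / den + d[2] * ct,
               -st * cos(phi) * den + d[3] * ct)
      }
      d <- d / sqrt(sum(d^2))
      if (w < weight_min) {
        if (runif(1) <= roulette_p) w <- w / roulette_p
        else { escaped <- escaped + w; break }
      }
    }
  }
  list(absorbed = absorbed, launched = launched, deposited = deposited,
       escaped = escaped)
}
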