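# Rasterization oracles and small utilities shared across tests.

# Digital disc: pixel centres within radius r of the canvas centre.
oracle_disc <- function(r, pad = 2) {
  n <- 2 * ceiling(r) + 2 * pad + 1
  cx <- ceiling(r) + pad + 1
  d <- outer(seq_len(n), seq_len(n),
             function(i, j) sqrt((i - cx)^2 + (j - cx)^2))
  d <= r
}

# Border-pixel count of a logical mask: foreground pixels with >= 1
# 4-neighbour outside the mask (off-image counts as background).
oracle_border_count <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  up <- rbind(FALSE, mask[-n, , drop = FALSE])
  down <- rbind(mask[-1, , drop = FALSE], FALSE)
  left <- cbind(FALSE, mask[, -m, drop = FALSE])
  right <- cbind(mask[, -1, drop = FALSE], FALSE)
  sum(mask & !(up & down & left & right))
}

# Measure a single logical mask through the package's measurement path.
measure_mask <- function(mask) {
  measure_organoids(matrix(as.integer(mask), nrow(mask), ncol(mask)))
}

moment_skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3

# Single-well layout row.
one_well <- function(well_id = "A01", compound_id = "DMSO",
                     concentration_uM = 0, role = "vehicle_control",
                     cell_line = "PC-3") {
  data.frame(well_id = well_id, compound_id = compound_id,
             concentration_uM = concentration_uM, cell_line = cell_line,
             replicate = 1, role = role)
}

# A and P for a population of rendered shapes (fixed session RNG assumed).
render_population <- function(n, mu = 8, sigma = 0.4, branch_rate = 6,
                              round_frac = 0, jitter = 0.1) {
  A <- P <- numeric(n)
  nb_out <- integer(n)
  for (i in seq_len(n)) {
    a <- stats::rlnorm(1, mu, sigma)
    nb <- if (stats::runif(1) < round_frac) 0L else stats::rpois(1, branch_rate)
    r0 <- max(2, organoscreen:::core_radius_for_area(a, nb, 1, 0.25))
    m <- render_organoid(r0, nb, r0, max(3, 0.25 * r0), jitter = jitter)
    mm <- measure_mask(m)
    A[i] <- mm$A; P[i] <- mm$P; nb_out[i] <- nb
  }
  data.frame(A = A, P = P, n_branches = nb_out)
}
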