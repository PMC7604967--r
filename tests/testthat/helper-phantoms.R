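# Shared fixture builders. All phantoms are generated in code at test time;
# grids are kept small (48-80 voxels at 1 mm) so the geometry tests stay fast.

straight_artery <- function(name = "M1", x = 30, y = 30, z = c(10, 50),
                            radius = 3, nf = 0, wrap = NULL) {
  artery_spec(name, rbind(c(x, y, z[1]), c(x, y, z[2])), radius_mm = radius,
              narrowing_fraction = nf, wrap_angle_deg = wrap)
}

wrap_phantom <- function(wrap_angle, nf = 0, seed = 1, arteries = NULL,
                         grid = 60, ...) {
  if (is.null(arteries))
    arteries <- list(straight_artery(nf = nf))
  make_phantom(phantom_spec(grid_shape = rep(grid, 3),
                            tumor_kind = "annular_wrap",
                            wrap_angle_deg = wrap_angle,
                            arteries = arteries, seed = seed, ...))
}

sphere_phantom <- function(r_mm = 10, spacing = 1, seed = 1, margin = 4) {
  n <- ceiling((2 * r_mm + 2 * margin) / spacing)
  ctr <- rep((n - 1) * spacing / 2, 3)
  make_phantom(phantom_spec(grid_shape = rep(n, 3),
                            spacing_mm = rep(spacing, 3),
                            tumor_center_mm = ctr,
                            tumor_semiaxes_mm = rep(r_mm, 3), seed = seed))
}

# Solid z-axis cylinder mask (flat ends), used for centerline checks.
cylinder_mask <- function(shape = c(20, 20, 40), center = c(10, 10),
                          radius = 3, z_range = 3:(shape[3] - 2)) {
  m <- array(FALSE, shape)
  for (k in z_range)
    for (i in seq_len(shape[1]))
      for (j in seq_len(shape[2]))
        if ((i - center[1])^2 + (j - center[2])^2 <= radius^2) m[i, j, k] <- TRUE
  m
}

# Hard-cut quarter torus mask: tube radius r around a quarter circle of
# radius R in the z = cz plane. Analytic centerline arc length: pi * R / 2.
quarter_torus_mask <- function(shape = c(48, 48, 48), R = 20, r = 3,
                               cx = c(10, 10, 25)) {
  g <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                   k = seq_len(shape[3]))
  x <- g$i - 1; y <- g$j - 1; z <- g$k - 1
  rho <- sqrt((x - cx[1])^2 + (y - cx[2])^2)
  ang <- atan2(y - cx[2], x - cx[1])
  array(((rho - R)^2 + (z - cx[3])^2 <= r^2) & ang >= 0 & ang <= pi / 2, shape)
}

# Independent Spearman oracle: Pearson product-moment formula applied to
# hand-computed mid-ranks (no call into the package's spearman_rho).
midranks <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1]] == x[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

spearman_oracle <- function(x, y) {
  rx <- midranks(x); ry <- midranks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
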