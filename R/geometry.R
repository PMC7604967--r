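# Internal voxel/curve geometry shared by the phantom generator and the
# feature extractor. Convention throughout: voxel indices are 1-based in R,
# physical coordinates are (index - 1) * spacing (axis-aligned, no affine).

.ARTERY_NAMES <- c("C4", "C5", "M1", "M2", "A1", "A2")

.vox_coord <- function(idx, spacing) {
  # idx: n x 3 matrix of 1-based voxel indices -> n x 3 physical mm
  sweep(idx - 1, 2, spacing, `*`)
}

.phys_to_vox <- function(x, spacing) {
  # nearest-voxel lookup; returns n x 3 1-based indices (may be out of range)
  round(sweep(x, 2, spacing, `/`)) + 1L
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalise a zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Orthonormal frame (u, v) perpendicular to a unit tangent t.
.perp_frame <- function(t) {
  ref <- diag(3)[, which.min(abs(t))]
  u <- .unit(ref - sum(ref * t) * t)
  v <- .cross3(t, u)
  list(u = u, v = v)
}

# Resample a control polyline to roughly even segments of length <= step.
.resample_polyline <- function(ctrl, step) {
  ctrl <- as.matrix(ctrl)
  if (nrow(ctrl) < 2) stop("polyline needs at least 2 control points")
  seg <- diff(ctrl)
  len <- sqrt(rowSums(seg^2))
  if (any(len == 0)) stop("polyline has coincident control points")
  s <- c(0, cumsum(len))
  total <- s[length(s)]
  n_out <- max(2L, ceiling(total / step) + 1L)
  s_out <- seq(0, total, length.out = n_out)
  out <- matrix(NA_real_, n_out, 3)
  for (ax in 1:3) out[, ax] <- approx(s, ctrl[, ax], xout = s_out)$y
  list(points = out, s = s_out, length = total)
}

# For query points X (n x 3), distance to a polyline P plus arc-length
# parameter and per-point angular position around the local tangent.
# Returns dist (mm), s (mm), angle_deg in [0, 360).
.polyline_project <- function(X, P) {
  X <- as.matrix(X)
  n <- nrow(X)
  nseg <- nrow(P) - 1L
  seg_vec <- diff(P)
  seg_len <- sqrt(rowSums(seg_vec^2))
  s0 <- c(0, cumsum(seg_len))
  best_d2 <- rep(Inf, n)
  best_s <- numeric(n)
  best_seg <- integer(n)
  best_foot <- matrix(0, n, 3)
  for (j in seq_len(nseg)) {
    d <- seg_vec[j, ]
    rel <- sweep(X, 2, P[j, ])
    tt <- pmin(pmax((rel %*% d) / seg_len[j]^2, 0), 1)[, 1]
    foot <- cbind(P[j, 1] + tt * d[1], P[j, 2] + tt * d[2], P[j, 3] + tt * d[3])
    d2 <- rowSums((X - foot)^2)
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_s[upd] <- s0[j] + tt[upd] * seg_len[j]
      best_seg[upd] <- j
      best_foot[upd, ] <- foot[upd, , drop = FALSE]
    }
  }
  # angles in the plane perpendicular to the segment tangent
  angle <- rep(NA_real_, n)
  for (j in unique(best_seg)) {
    t_j <- .unit(seg_vec[j, ])
    fr <- .perp_frame(t_j)
    sel <- best_seg == j
    rv <- X[sel, , drop = FALSE] - best_foot[sel, , drop = FALSE]
    angle[sel] <- (atan2(rv %*% fr$v, rv %*% fr$u) * 180 / pi) %% 360
  }
  list(dist = sqrt(best_d2), s = best_s, angle_deg = angle)
}

# Indices (n x 3) and physical coords of all voxels in a physical bounding box.
.bbox_voxels <- function(shape, spacing, lo, hi) {
  i0 <- pmax(floor(lo / spacing) + 1L, 1L)
  i1 <- pmin(ceiling(hi / spacing) + 1L, shape)
  if (any(i0 > i1)) return(NULL)
  idx <- as.matrix(expand.grid(i = i0[1]:i1[1], j = i0[2]:i1[2], k = i0[3]:i1[3]))
  dimnames(idx) <- NULL
  idx
}

.grid_extent <- function(shape, spacing) (shape - 1) * spacing

# Smooth cosine bump, 0 outside [s0, s1], peaking at 1 mid-span.
.bump <- function(s, s0, s1) {
  w <- numeric(length(s))
  inside <- s >= s0 & s <= s1
  w[inside] <- sin(pi * (s[inside] - s0) / (s1 - s0))^2
  w
}
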