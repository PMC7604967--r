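#' Tumor volume from a binary mask
#'
#' Counts foreground voxels and multiplies by the voxel volume.
#'
#' @param tumor_mask logical 3D array.
#' @param spacing_mm voxel edge lengths in mm.
#' @return Volume in cm3. An empty mask returns 0 with a warning.
#' @export
compute_tumor_volume <- function(tumor_mask, spacing_mm) {
  if (length(dim(tumor_mask)) != 3) stop("tumor_mask must be a 3D array")
  if (any(spacing_mm <= 0)) stop("spacing_mm must be positive")
  n <- sum(tumor_mask != 0)
  if (n == 0) warning("tumor mask is empty; volume is 0")
  n * prod(spacing_mm) / 1000
}

#' Grade tumor volume
#'
#' Three-level volume grade: grade 1 below 20 cm3, grade 2 for the closed
#' interval 20-50 cm3, grade 3 above 50 cm3.
#'
#' @param volume_cm3 non-negative volume in cm3.
#' @return Integer grade 1, 2 or 3.
#' @export
grade_volume <- function(volume_cm3) {
  if (!is.finite(volume_cm3) || volume_cm3 < 0)
    stop("volume_cm3 must be a non-negative number")
  if (volume_cm3 < 20) 1L else if (volume_cm3 <= 50) 2L else 3L
}

#' Extract a vessel centerline from a tubular mask
#'
#' Two-pass estimate. First the mask's voxels are ordered along the vessel
#' by geodesic distance on the 26-connected voxel graph (endpoints found by
#' a double sweep), binned into slabs of roughly 1.5 voxels of arc length,
#' and per-slab centroids form an initial centerline. Geodesic slabs are
#' tilted near curvature and end caps, so in a second pass every voxel is
#' re-projected onto the smoothed initial polyline; the corrected axial
#' positions re-bin the voxels and the projection distances give the local
#' radius (largest perpendicular distance to a mask voxel centre in the
#' slab, so it tracks lumen narrowing). Tangents are central differences.
#'
#' @param artery_mask logical 3D array containing a single tubular component.
#' @param spacing_mm voxel edge lengths in mm.
#' @param name vessel name used in error messages.
#' @return Object of class `vessel_geometry` with `centerline_points`
#'   (n x 3 mm), `tangents` (n x 3 unit vectors), `local_radius_mm` (n),
#'   `arc_length_mm` (polyline length of the centerline).
#' @export
extract_centerline <- function(artery_mask, spacing_mm, name = "artery") {
  idx <- which(artery_mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop("not a tube: '", name, "' mask is empty")
  shape <- dim(artery_mask)
  lin <- (idx[, 1] - 1L) + shape[1] * ((idx[, 2] - 1L) + shape[2] * (idx[, 3] - 1L))
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  off <- off[seq_len(nrow(off) / 2), , drop = FALSE]  # half: undirected edges
  edges <- NULL
  wts <- NULL
  for (r in seq_len(nrow(off))) {
    d <- off[r, ]
    nb <- sweep(idx, 2, d, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] & nb[, 2] >= 1 & nb[, 2] <= shape[2] &
      nb[, 3] >= 1 & nb[, 3] <= shape[3]
    lin_nb <- (nb[, 1] - 1L) + shape[1] * ((nb[, 2] - 1L) + shape[2] * (nb[, 3] - 1L))
    m <- match(lin_nb, lin)
    hit <- ok & !is.na(m)
    if (any(hit)) {
      edges <- rbind(edges, cbind(which(hit), m[hit]))
      wts <- c(wts, rep(sqrt(sum((d * spacing_mm)^2)), sum(hit)))
    }
  }
  g <- igraph::make_graph(t(edges), n = nrow(idx), directed = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1)
    stop("not a tube: '", name, "' mask has ", comp$no, " connected components")
  d1 <- igraph::distances(g, v = 1, weights = wts)[1, ]
  e1 <- which.max(d1)
  s <- igraph::distances(g, v = e1, weights = wts)[1, ]
  coords <- .vox_coord(idx, spacing_mm)
  L <- max(s)
  h <- 1.5 * max(spacing_mm)
  if (L <= 0) stop("not a tube: '", name, "' mask is degenerate")
  bin_centroids <- function(s_par, L_par) {
    nb <- max(2L, ceiling(L_par / h))
    b <- pmin(pmax(1L, ceiling(s_par / L_par * nb)), nb)
    pts <- t(vapply(seq_len(nb), function(k)
      colMeans(coords[b == k, , drop = FALSE]), numeric(3)))
    keep <- stats::complete.cases(pts)
    list(pts = pts[keep, , drop = FALSE], bin = b,
         bins_kept = seq_len(nb)[keep], nb = nb)
  }
  smooth_pts <- function(pts, passes = 2) {
    np <- nrow(pts)
    if (np < 3) return(pts)
    for (p in seq_len(passes)) {
      sm <- pts
      sm[2:(np - 1), ] <- (pts[1:(np - 2), ] + pts[2:(np - 1), ] + pts[3:np, ]) / 3
      pts <- sm
    }
    pts
  }
  # pass 1: geodesic parameterization
  b1 <- bin_centroids(s, L)
  if (nrow(b1$pts) < 2) stop("not a tube: '", name, "' mask is too short")
  poly <- smooth_pts(b1$pts)
  # pass 2: re-project voxels onto the initial polyline
  pr <- .polyline_project(coords, poly)
  L2 <- max(pr$s)
  if (L2 <= 0) stop("not a tube: '", name, "' mask is degenerate")
  b2 <- bin_centroids(pr$s, L2)
  pts <- smooth_pts(b2$pts)
  np <- nrow(pts)
  if (np < 2) stop("not a tube: '", name, "' mask is too short")
  tg <- matrix(0, np, 3)
  tg[1, ] <- pts[2, ] - pts[1, ]
  tg[np, ] <- pts[np, ] - pts[np - 1, ]
  if (np > 2) tg[2:(np - 1), ] <- pts[3:np, ] - pts[1:(np - 2), ]
  tg <- t(apply(tg, 1, .unit))
  # voxels whose projection clamped at the polyline ends measure an oblique
  # distance, not a lumen radius; leave them out of the radius profile
  valid <- pr$s > 0 & pr$s < L2
  rad <- vapply(b2$bins_kept, function(k) {
    d <- pr$dist[b2$bin == k & valid]
    if (length(d)) max(d) else NA_real_
  }, 0)
  rad[is.na(rad)] <- stats::median(rad, na.rm = TRUE)
  rad <- pmax(rad, min(spacing_mm) / 2)
  # bin centroids sit half a bin inside the tube ends; extend the end
  # points along the local tangents so the polyline spans the full vessel
  half_bin <- L2 / b2$nb / 2
  pts[1, ] <- pts[1, ] - tg[1, ] * half_bin
  pts[np, ] <- pts[np, ] + tg[np, ] * half_bin
  # End-cap slabs bias the radius low; mark interior points for
  # radius-based decisions such as narrowing.
  s_mid <- (b2$bins_kept - 0.5) / b2$nb * L2
  r_med <- stats::median(rad)
  interior <- s_mid > r_med & s_mid < L2 - r_med
  if (sum(interior) < 3) interior <- rep(TRUE, np)
  structure(list(artery_name = name, centerline_points = pts, tangents = tg,
                 local_radius_mm = rad, interior = interior,
                 arc_length_mm = sum(sqrt(rowSums(diff(pts)^2)))),
            class = "vessel_geometry")
}

#' Build an encasement record
#'
#' @param artery_name vessel name.
#' @param involved logical; any circumferential tumor contact.
#' @param max_coverage_deg largest per-point angular coverage, 0-360.
#' @param fully_encircled logical; coverage reached the full-encirclement
#'   threshold at some centerline point.
#' @param narrowed logical; lumen caliber reduced within the vessel.
#' @return Object of class `encasement_result`.
#' @export
encasement_result <- function(artery_name, involved, max_coverage_deg = 0,
                              fully_encircled = FALSE, narrowed = FALSE) {
  if (max_coverage_deg < 0 || max_coverage_deg > 360)
    stop("max_coverage_deg must lie in [0, 360]")
  if (fully_encircled && !involved) stop("fully_encircled requires involved")
  if (narrowed && !involved) stop("narrowed requires involved")
  if ((max_coverage_deg == 0) != (!involved))
    stop("max_coverage_deg must be 0 exactly when not involved")
  structure(list(artery_name = artery_name, involved = involved,
                 max_coverage_deg = max_coverage_deg,
                 fully_encircled = fully_encircled, narrowed = narrowed),
            class = "encasement_result")
}

#' Angular tumor coverage around a vessel
#'
#' At every centerline point, 360 one-degree angular bins are cast in the
#' plane perpendicular to the local tangent, each probed over a radial band
#' from the vessel surface to `probe_band_mm` beyond it; a bin counts as
#' covered when any probe sample lands in the tumor mask. The per-point
#' coverage is the covered angle in degrees; the vessel's coverage is the
#' maximum over points. Full encirclement uses a threshold slightly below
#' the literal 360 degrees to tolerate voxelization.
#'
#' @param tumor_mask logical 3D array on the same grid as the vessel.
#' @param vessel a [extract_centerline()] result.
#' @param spacing_mm voxel edge lengths in mm.
#' @param probe_band_mm radial probe depth beyond the vessel surface.
#' @param full_encirclement_deg coverage (deg) counted as complete encirclement.
#' @return An `encasement_result` (with `narrowed = FALSE`; see
#'   [detect_narrowing()]).
#' @export
angular_coverage <- function(tumor_mask, vessel, spacing_mm,
                             probe_band_mm = 2, full_encirclement_deg = 355) {
  stopifnot(inherits(vessel, "vessel_geometry"))
  shape <- dim(tumor_mask)
  extent <- .grid_extent(shape, spacing_mm)
  pts <- vessel$centerline_points
  if (any(pts < -max(spacing_mm)) ||
      any(sweep(pts, 2, extent) > max(spacing_mm)))
    stop("vessel '", vessel$artery_name, "' lies outside the grid")
  angles <- (seq_len(360) - 0.5) * pi / 180
  ca <- cos(angles); sa <- sin(angles)
  best <- 0
  for (i in seq_len(nrow(pts))) {
    fr <- .perp_frame(vessel$tangents[i, ])
    radii <- seq(vessel$local_radius_mm[i],
                 vessel$local_radius_mm[i] + probe_band_mm, by = 0.4)
    dirs <- cbind(ca, sa) %*% rbind(fr$u, fr$v)      # 360 x 3
    P <- dirs[rep(seq_len(360), length(radii)), ] *
      rep(radii, each = 360)
    P <- sweep(P, 2, pts[i, ], `+`)
    vx <- .phys_to_vox(P, spacing_mm)
    ok <- vx[, 1] >= 1 & vx[, 1] <= shape[1] & vx[, 2] >= 1 & vx[, 2] <= shape[2] &
      vx[, 3] >= 1 & vx[, 3] <= shape[3]
    hit <- logical(nrow(vx))
    hit[ok] <- tumor_mask[vx[ok, , drop = FALSE]]
    covered <- rowSums(matrix(hit, nrow = 360)) > 0
    best <- max(best, sum(covered))
    if (best == 360) break
  }
  encasement_result(vessel$artery_name, involved = best > 0,
                    max_coverage_deg = best,
                    fully_encircled = best >= full_encirclement_deg)
}

#' Detect lumen narrowing along a vessel
#'
#' The vessel counts as narrowed when its minimum local radius falls below
#' `(1 - delta)` times the reference radius, the median local radius over
#' the vessel (self-referenced: no contralateral vessel is available).
#' Only interior centerline points enter the decision — radius estimates
#' at the tube ends are biased low by the end caps.
#'
#' @param vessel a [extract_centerline()] result with >= 5 centerline points.
#' @param delta relative caliber reduction threshold (default 0.20).
#' @return Logical.
#' @export
detect_narrowing <- function(vessel, delta = 0.20) {
  stopifnot(inherits(vessel, "vessel_geometry"))
  r <- vessel$local_radius_mm
  if (length(r) < 5)
    stop("insufficient geometry: '", vessel$artery_name,
         "' has fewer than 5 centerline points")
  r <- r[vessel$interior]
  min(r) < (1 - delta) * stats::median(r)
}

#' Arterial involvement score (0-4)
#'
#' One point for involvement of any artery, plus one point each for:
#' complete encirclement of an artery, involvement of more than one artery,
#' and narrowing of an arterial lumen. Each feature contributes at most one
#' point no matter how many arteries exhibit it.
#'
#' @param encasements list of `encasement_result` objects, one per assessed
#'   artery.
#' @return Integer 0-4.
#' @export
arterial_involvement_score <- function(encasements) {
  if (!all(vapply(encasements, inherits, TRUE, "encasement_result")))
    stop("encasements must be a list of encasement_result objects")
  inv <- vapply(encasements, `[[`, TRUE, "involved")
  if (!any(inv)) return(0L)
  full <- vapply(encasements, `[[`, TRUE, "fully_encircled")
  narrow <- vapply(encasements, `[[`, TRUE, "narrowed")
  1L + as.integer(any(full)) + as.integer(sum(inv) > 1) +
    as.integer(any(narrow & inv))
}

.overlap_flag <- function(mask_a, mask_b, spacing_mm, tau_cm3) {
  ov <- sum(mask_a & mask_b) * prod(spacing_mm) / 1000
  structure(ov > tau_cm3, overlap_cm3 = ov)
}

#' Cavernous sinus involvement
#'
#' True when the tumor/CS overlap volume strictly exceeds `tau_cs_cm3`
#' (infiltration, not mere abutment).
#'
#' @param tumor_mask,cs_mask logical 3D arrays on the same grid.
#' @param spacing_mm voxel edge lengths in mm.
#' @param tau_cs_cm3 overlap threshold in cm3.
#' @return Logical, with the measured overlap attached as attribute
#'   `overlap_cm3`.
#' @export
assess_cs_involvement <- function(tumor_mask, cs_mask, spacing_mm,
                                  tau_cs_cm3 = 0.1) {
  if (!identical(dim(tumor_mask), dim(cs_mask)))
    stop("tumor and CS masks must share the same grid")
  .overlap_flag(tumor_mask != 0, cs_mask != 0, spacing_mm, tau_cs_cm3)
}

#' Bone invasion
#'
#' True when the tumor/bone overlap volume strictly exceeds `tau_bone_cm3`;
#' adjacency without overlap does not count.
#'
#' @param tumor_mask,bone_mask logical 3D arrays on the same grid.
#' @param spacing_mm voxel edge lengths in mm.
#' @param tau_bone_cm3 overlap threshold in cm3.
#' @return Logical, with the measured overlap attached as attribute
#'   `overlap_cm3`.
#' @export
assess_bone_invasion <- function(tumor_mask, bone_mask, spacing_mm,
                                 tau_bone_cm3 = 0.1) {
  if (!identical(dim(tumor_mask), dim(bone_mask)))
    stop("tumor and bone masks must share the same grid")
  .overlap_flag(tumor_mask != 0, bone_mask != 0, spacing_mm, tau_bone_cm3)
}

#' Extract all radiologic features from a segmentation set
#'
#' Runs the full measurement stage: tumor volume and grade, per-artery
#' encasement (centerline extraction, angular coverage, narrowing), CS
#' involvement and bone invasion, and the derived 0-4 arterial score.
#' Assessed arteries are exactly `C4, C5, M1, M2, A1, A2`; a segment with
#' no mask is treated as not involved (logged via `message`). Narrowing
#' only counts for involved arteries.
#'
#' @param seg a [segmentation_set()].
#' @param config a [pipeline_config()]; thresholds are taken from it.
#' @return Object of class `radiologic_features`: `tumor_volume_cm3`,
#'   `volume_grade`, `encasements` (list of `encasement_result`),
#'   `arterial_score`, `cs_involved`, `bone_invaded`, plus a `raw` list with
#'   per-artery coverage and overlap volumes for audit.
#' @export
extract_features <- function(seg, config = pipeline_config()) {
  stopifnot(inherits(seg, "segmentation_set"))
  sp <- seg$spacing_mm
  vol <- compute_tumor_volume(seg$tumor_mask, sp)
  encasements <- list()
  coverage <- stats::setNames(numeric(0), character(0))
  for (nm in .ARTERY_NAMES) {
    if (is.null(seg$artery_masks[[nm]])) {
      if (isTRUE(config$verbose))
        message("artery ", nm, ": no mask; treated as not involved")
      next
    }
    vessel <- extract_centerline(seg$artery_masks[[nm]], sp, name = nm)
    enc <- angular_coverage(seg$tumor_mask, vessel, sp,
                            probe_band_mm = config$probe_band_mm,
                            full_encirclement_deg = config$full_encirclement_deg)
    narrowed <- FALSE
    if (enc$involved) {
      narrowed <- tryCatch(detect_narrowing(vessel, delta = config$narrowing_delta),
                           error = function(e) {
                             warning("artery ", nm, ": ", conditionMessage(e),
                                     "; narrowing set to FALSE")
                             FALSE
                           })
    }
    enc$narrowed <- narrowed
    encasements[[nm]] <- enc
    coverage[nm] <- enc$max_coverage_deg
  }
  cs <- assess_cs_involvement(seg$tumor_mask, seg$cs_mask, sp, config$tau_cs_cm3)
  bone <- assess_bone_invasion(seg$tumor_mask, seg$bone_mask, sp, config$tau_bone_cm3)
  structure(list(
    tumor_volume_cm3 = vol,
    volume_grade = grade_volume(vol),
    encasements = encasements,
    arterial_score = arterial_involvement_score(encasements),
    cs_involved = as.logical(cs),
    bone_invaded = as.logical(bone),
    raw = list(coverage_deg = coverage,
               cs_overlap_cm3 = attr(cs, "overlap_cm3"),
               bone_overlap_cm3 = attr(bone, "overlap_cm3"))
  ), class = "radiologic_features")
}

#' Assemble a feature record from already-graded components
#'
#' Convenience constructor for tabular workflows where the four graded
#' features are known but no imaging is available.
#'
#' @param volume_grade 1-3.
#' @param arterial_score 0-4.
#' @param cs_involved,bone_invaded logicals.
#' @param tumor_volume_cm3 optional raw volume; must agree with the grade.
#' @return Object of class `radiologic_features`.
#' @export
radiologic_features <- function(volume_grade, arterial_score, cs_involved,
                                bone_invaded, tumor_volume_cm3 = NA_real_) {
  if (!volume_grade %in% 1:3) stop("volume_grade must be 1, 2 or 3")
  if (!arterial_score %in% 0:4) stop("arterial_score must be 0-4")
  if (!is.na(tumor_volume_cm3) && grade_volume(tumor_volume_cm3) != volume_grade)
    stop("tumor_volume_cm3 inconsistent with volume_grade")
  structure(list(tumor_volume_cm3 = tumor_volume_cm3,
                 volume_grade = as.integer(volume_grade),
                 encasements = list(),
                 arterial_score = as.integer(arterial_score),
                 cs_involved = isTRUE(cs_involved),
                 bone_invaded = isTRUE(bone_invaded),
                 raw = list()),
            class = "radiologic_features")
}

#' @export
print.radiologic_features <- function(x, ...) {
  cat(sprintf("<radiologic_features> volume %.2f cm3 (grade %d) | arterial %d | CS %s | bone %s\n",
              x$tumor_volume_cm3, x$volume_grade, x$arterial_score,
              x$cs_involved, x$bone_invaded))
  for (e in x$encasements)
    cat(sprintf("  %s: coverage %.0f deg%s%s\n", e$artery_name, e$max_coverage_deg,
                if (e$fully_encircled) ", encircled" else "",
                if (e$narrowed) ", narrowed" else ""))
  invisible(x)
}
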