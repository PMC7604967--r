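#' Describe an artery for the phantom generator
#'
#' @param name one of `C4, C5, M1, M2, A1, A2`.
#' @param control_points_mm numeric matrix (>= 2 x 3) of centerline control
#'   points in mm, in grid coordinates.
#' @param radius_mm nominal lumen radius in mm.
#' @param narrowing_fraction relative caliber reduction in `[0, 1)`; the lumen
#'   radius dips smoothly to `radius_mm * (1 - narrowing_fraction)` over the
#'   narrowing span.
#' @param narrowing_span_mm length-2 arc-length interval (mm from the first
#'   control point) over which the narrowing is applied; default is the
#'   central 30% of the vessel.
#' @param wrap_angle_deg per-artery circumferential tumor coverage for
#'   `annular_wrap` phantoms; `NULL` falls back to the spec-level angle, 0
#'   means this artery is not wrapped.
#' @return A list of class `artery_spec`.
#' @export
artery_spec <- function(name, control_points_mm, radius_mm = 3,
                        narrowing_fraction = 0, narrowing_span_mm = NULL,
                        wrap_angle_deg = NULL) {
  if (!name %in% .ARTERY_NAMES)
    stop("unknown artery name: ", name)
  control_points_mm <- as.matrix(control_points_mm)
  if (ncol(control_points_mm) != 3 || nrow(control_points_mm) < 2)
    stop("control_points_mm must be an n x 3 matrix with n >= 2")
  if (radius_mm <= 0) stop("radius_mm must be positive")
  if (narrowing_fraction < 0 || narrowing_fraction >= 1)
    stop("narrowing_fraction must lie in [0, 1)")
  if (!is.null(wrap_angle_deg) &&
      (wrap_angle_deg < 0 || wrap_angle_deg > 360))
    stop("wrap_angle_deg must lie in [0, 360]")
  structure(list(name = name, control_points_mm = control_points_mm,
                 radius_mm = radius_mm,
                 narrowing_fraction = narrowing_fraction,
                 narrowing_span_mm = narrowing_span_mm,
                 wrap_angle_deg = wrap_angle_deg),
            class = "artery_spec")
}

#' Specify a synthetic 3D phantom
#'
#' A phantom is a small co-registered scene — tumor, arteries, cavernous
#' sinus block, bone slab — whose radiologic features (volume, encasement
#' angle, narrowing, CS overlap, bone contact) are known by construction,
#' so the measurement pipeline can be validated against ground truth.
#'
#' Two tumor kinds are supported. `ellipsoid` places an axis-aligned
#' ellipsoid of given semiaxes (analytic volume `4/3 * pi * a * b * c`).
#' `annular_wrap` builds, around each wrapped artery, an annular collar in
#' the plane perpendicular to the local centerline tangent spanning exactly
#' `wrap_angle_deg` of circumference — the ground-truth encasement angle.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing_mm voxel edge lengths in mm.
#' @param tumor_kind `"ellipsoid"` or `"annular_wrap"`.
#' @param tumor_center_mm ellipsoid centre (mm); default grid centre.
#' @param tumor_semiaxes_mm ellipsoid semiaxes (mm).
#' @param wrap_angle_deg default circumferential coverage, 0-360 degrees,
#'   for arteries that do not set their own.
#' @param wrap_thickness_mm radial thickness of the annular collar.
#' @param arteries list of [artery_spec()] objects (unique names).
#' @param cs_overlap_voxels intended exact tumor/CS overlap in voxels.
#' @param bone_contact logical; if `TRUE` the bone slab is routed through the
#'   lower part of the tumor, otherwise it sits at the grid floor clear of it.
#' @param seed integer; drives the sub-voxel jitter applied to the whole
#'   scene (all structures shift together, so ground truth is unchanged).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(160, 160, 160), spacing_mm = c(1, 1, 1),
                         tumor_kind = c("ellipsoid", "annular_wrap"),
                         tumor_center_mm = NULL, tumor_semiaxes_mm = c(15, 12, 10),
                         wrap_angle_deg = 360, wrap_thickness_mm = 4,
                         arteries = list(), cs_overlap_voxels = 0,
                         bone_contact = FALSE, seed = 1L) {
  tumor_kind <- match.arg(tumor_kind)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 8))
    stop("grid_shape must be 3 integers >= 8")
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive numbers")
  if (wrap_angle_deg < 0 || wrap_angle_deg > 360)
    stop("wrap_angle_deg must lie in [0, 360]")
  if (wrap_thickness_mm <= 0) stop("wrap_thickness_mm must be positive")
  if (cs_overlap_voxels < 0) stop("cs_overlap_voxels must be >= 0")
  if (length(arteries)) {
    if (!all(vapply(arteries, inherits, TRUE, "artery_spec")))
      stop("arteries must be a list of artery_spec objects")
    nm <- vapply(arteries, `[[`, "", "name")
    if (anyDuplicated(nm)) stop("artery names must be unique within a spec")
    names(arteries) <- nm
  }
  if (is.null(tumor_center_mm))
    tumor_center_mm <- .grid_extent(grid_shape, spacing_mm) / 2
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 tumor_kind = tumor_kind,
                 tumor_center_mm = as.numeric(tumor_center_mm),
                 tumor_semiaxes_mm = as.numeric(tumor_semiaxes_mm),
                 wrap_angle_deg = wrap_angle_deg,
                 wrap_thickness_mm = wrap_thickness_mm,
                 arteries = arteries, cs_overlap_voxels = cs_overlap_voxels,
                 bone_contact = bone_contact, seed = as.integer(seed)),
            class = "phantom_spec")
}

.wrap_angle_of <- function(spec, art) {
  if (!is.null(art$wrap_angle_deg)) art$wrap_angle_deg else spec$wrap_angle_deg
}

.narrowing_span <- function(art, total_len) {
  if (!is.null(art$narrowing_span_mm)) art$narrowing_span_mm
  else c(0.35, 0.65) * total_len
}

# Rasterize one artery as a tube of (possibly narrowed) radius.
.rasterize_tube <- function(shape, spacing, ctrl, radius, nf, span) {
  rs <- .resample_polyline(ctrl, step = 2)
  lo <- apply(ctrl, 2, min) - radius - max(spacing)
  hi <- apply(ctrl, 2, max) + radius + max(spacing)
  idx <- .bbox_voxels(shape, spacing, lo, hi)
  mask <- array(FALSE, shape)
  if (is.null(idx)) return(mask)
  pr <- .polyline_project(.vox_coord(idx, spacing), rs$points)
  r_s <- radius
  if (nf > 0) r_s <- radius * (1 - nf * .bump(pr$s, span[1], span[2]))
  inside <- pr$dist <= r_s
  mask[idx[inside, , drop = FALSE]] <- TRUE
  mask
}

# Annular collar around an artery: radial band [radius, radius + thickness],
# angular span wrap_deg starting at 0 deg in the perpendicular-plane frame,
# axial span the central 60% of the vessel.
.rasterize_wrap <- function(shape, spacing, ctrl, radius, thickness, wrap_deg) {
  rs <- .resample_polyline(ctrl, step = 2)
  outer_r <- radius + thickness
  lo <- apply(ctrl, 2, min) - outer_r - max(spacing)
  hi <- apply(ctrl, 2, max) + outer_r + max(spacing)
  idx <- .bbox_voxels(shape, spacing, lo, hi)
  mask <- array(FALSE, shape)
  if (is.null(idx) || wrap_deg <= 0) return(mask)
  pr <- .polyline_project(.vox_coord(idx, spacing), rs$points)
  span <- c(0.2, 0.8) * rs$length
  inside <- pr$dist > radius & pr$dist <= outer_r &
    pr$s >= span[1] & pr$s <= span[2] &
    (wrap_deg >= 360 | pr$angle_deg <= wrap_deg)
  mask[idx[inside, , drop = FALSE]] <- TRUE
  mask
}

.rasterize_ellipsoid <- function(shape, spacing, center, semi) {
  ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - 1) * spacing[a] - center[a])^2 / semi[a]^2)
  q <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  q <= 1
}

.check_overflow <- function(lo, hi, extent, what) {
  if (any(lo < 0) || any(hi > extent))
    stop("phantom overflow: ", what, " exceeds the grid")
}

#' Generate a phantom and its ground truth
#'
#' Builds the label masks described by a [phantom_spec()] and returns them
#' together with analytically known truth values for every feature the
#' measurement pipeline reports. The seed jitters the whole scene by a
#' sub-voxel offset (exercising voxelization robustness) without changing
#' the ground truth.
#'
#' Truth conventions (kept consistent with the feature extractor's
#' documented defaults): an artery counts as `narrowed` when its
#' `narrowing_fraction` is at least the 20% detection threshold; CS
#' infiltration and bone invasion are true when the constructed overlap
#' exceeds 0.1 cm3. For `annular_wrap` phantoms the truth coverage is the
#' requested wrap angle; for `ellipsoid` phantoms involvement is determined
#' by a direct voxel distance check against the artery centerline (coverage
#' truth is reported as `NA` in that case).
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `seg` (a [segmentation_set()]) and `truth`
#'   (class `phantom_truth`: `analytic_tumor_volume_cm3`, per-artery
#'   `arteries` table with `involved`, `max_coverage_deg`, `narrowed`,
#'   `cs_involved`, `bone_invaded`).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$grid_shape
  spacing <- spec$spacing_mm
  extent <- .grid_extent(shape, spacing)
  vox_cm3 <- prod(spacing) / 1000
  set.seed(spec$seed)
  jitter <- runif(3, -0.5, 0.5) * spacing

  # arteries
  artery_masks <- list()
  for (art in spec$arteries) {
    ctrl <- sweep(art$control_points_mm, 2, jitter, `+`)
    .check_overflow(apply(ctrl, 2, min) - art$radius_mm,
                    apply(ctrl, 2, max) + art$radius_mm, extent,
                    paste0("artery ", art$name))
    total_len <- .resample_polyline(ctrl, 2)$length
    artery_masks[[art$name]] <- .rasterize_tube(
      shape, spacing, ctrl, art$radius_mm, art$narrowing_fraction,
      .narrowing_span(art, total_len))
  }
  if (length(artery_masks) > 1) {
    nm <- names(artery_masks)
    for (i in seq_along(nm)[-1]) for (j in seq_len(i - 1)) {
      if (any(artery_masks[[i]] & artery_masks[[j]]))
        stop("label collision: arteries ", nm[j], " and ", nm[i], " overlap")
    }
  }
  any_artery <- Reduce(`|`, artery_masks, array(FALSE, shape))

  # tumor
  wrapped <- character(0)
  if (spec$tumor_kind == "ellipsoid") {
    ctr <- spec$tumor_center_mm + jitter
    semi <- spec$tumor_semiaxes_mm
    .check_overflow(ctr - semi, ctr + semi, extent, "ellipsoid tumor")
    tumor <- .rasterize_ellipsoid(shape, spacing, ctr, semi)
    truth_vol <- 4 / 3 * pi * prod(semi) / 1000
  } else {
    tumor <- array(FALSE, shape)
    truth_vol <- 0
    for (art in spec$arteries) {
      w <- .wrap_angle_of(spec, art)
      if (w <= 0) next
      wrapped <- c(wrapped, art$name)
      ctrl <- sweep(art$control_points_mm, 2, jitter, `+`)
      outer_r <- art$radius_mm + spec$wrap_thickness_mm
      .check_overflow(apply(ctrl, 2, min) - outer_r,
                      apply(ctrl, 2, max) + outer_r, extent,
                      paste0("annular wrap around ", art$name))
      tumor <- tumor | .rasterize_wrap(shape, spacing, ctrl, art$radius_mm,
                                       spec$wrap_thickness_mm, w)
      len <- .resample_polyline(ctrl, 2)$length
      truth_vol <- truth_vol + 0.6 * len * (min(w, 360) / 360) *
        pi * (outer_r^2 - art$radius_mm^2) / 1000
    }
    if (!length(wrapped))
      warning("annular_wrap phantom with wrap angle 0 everywhere: tumor mask is empty")
  }
  tumor <- tumor & !any_artery

  # cavernous sinus: exactly cs_overlap_voxels of overlap with the tumor,
  # extended by an adjacent non-tumor block so CS is a plausible region.
  cs <- array(FALSE, shape)
  if (spec$cs_overlap_voxels > 0) {
    tidx <- which(tumor, arr.ind = TRUE)
    if (nrow(tidx) < spec$cs_overlap_voxels)
      stop("phantom overflow: cs_overlap_voxels exceeds tumor size")
    ord <- order(tidx[, 1], tidx[, 2], tidx[, 3])
    core <- tidx[ord[seq_len(spec$cs_overlap_voxels)], , drop = FALSE]
    cs[core] <- TRUE
    lo <- pmax(apply(core, 2, min) - c(4L, 2L, 2L), 1L)
    hi <- pmin(apply(core, 2, max) + c(0L, 2L, 2L), shape)
    block <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    cs[block] <- TRUE
    cs <- cs & (!tumor | array(FALSE, shape))
    cs[core] <- TRUE           # keep exactly the intended overlap
    cs <- cs & !any_artery
    cs_overlap <- sum(cs & tumor)
  } else {
    cs[2:5, 2:5, 2:5] <- TRUE
    cs <- cs & !tumor & !any_artery
    cs_overlap <- 0L
  }

  # bone slab
  bone <- array(FALSE, shape)
  if (spec$bone_contact) {
    tz <- which(apply(tumor, 3, any))
    if (!length(tz)) stop("bone_contact requested but tumor mask is empty")
    zc <- tz[max(1L, ceiling(0.12 * length(tz)))]
    zr <- max(1L, zc - 1L):min(shape[3], zc + 1L)
    bone[, , zr] <- TRUE
    bone <- bone & !any_artery & !cs
  } else {
    bone[, , 1:min(3L, shape[3])] <- TRUE
    bone <- bone & !tumor & !any_artery & !cs
  }
  bone_overlap <- sum(bone & tumor)

  seg <- segmentation_set(tumor, artery_masks, cs, bone, spacing)

  art_truth <- data.frame(name = character(0), involved = logical(0),
                          max_coverage_deg = numeric(0), narrowed = logical(0),
                          stringsAsFactors = FALSE)
  for (art in spec$arteries) {
    if (spec$tumor_kind == "annular_wrap") {
      w <- .wrap_angle_of(spec, art)
      involved <- w > 0
      cov <- if (involved) min(w, 360) else 0
    } else {
      # direct voxel distance check, independent of the angular-casting detector
      ctrl <- sweep(art$control_points_mm, 2, jitter, `+`)
      rs <- .resample_polyline(ctrl, 2)
      tidx <- which(tumor, arr.ind = TRUE)
      involved <- FALSE
      if (nrow(tidx)) {
        pr <- .polyline_project(.vox_coord(tidx, spacing), rs$points)
        involved <- any(pr$dist <= art$radius_mm + 2)
      }
      cov <- if (involved) NA_real_ else 0
    }
    art_truth <- rbind(art_truth, data.frame(
      name = art$name, involved = involved, max_coverage_deg = cov,
      narrowed = involved & art$narrowing_fraction >= 0.20,
      stringsAsFactors = FALSE))
  }

  truth <- structure(list(
    analytic_tumor_volume_cm3 = truth_vol,
    arteries = art_truth,
    cs_involved = cs_overlap * vox_cm3 > 0.1,
    bone_invaded = bone_overlap * vox_cm3 > 0.1,
    cs_overlap_voxels = cs_overlap,
    bone_overlap_voxels = bone_overlap
  ), class = "phantom_truth")

  list(seg = seg, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> volume %.3f cm3 | CS %s | bone %s\n",
              x$analytic_tumor_volume_cm3, x$cs_involved, x$bone_invaded))
  if (nrow(x$arteries)) print(x$arteries)
  invisible(x)
}
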