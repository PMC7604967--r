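#' Co-registered segmentation masks for one patient
#'
#' Bundles the binary label masks the scoring pipeline consumes: tumor,
#' named arterial segments, cavernous-sinus region and skull, all on one
#' axis-aligned voxel grid. Physical coordinates are `(index - 1) * spacing`
#' in millimetres; no affine orientation handling is attempted.
#'
#' @param tumor_mask logical 3D array.
#' @param artery_masks named list of logical 3D arrays; names must be drawn
#'   from the assessed segments `C4, C5, M1, M2, A1, A2` (cavernous and
#'   clinoid internal carotid, sphenoidal and insular middle cerebral,
#'   pre- and post-communicating anterior cerebral). Segments without a mask
#'   are treated as not involved downstream.
#' @param cs_mask logical 3D array for the cavernous sinus (may overlap the
#'   tumor: that overlap is what CS infiltration means).
#' @param bone_mask logical 3D array for the skull.
#' @param spacing_mm numeric length-3, voxel edge lengths in mm (all > 0).
#'
#' @return An object of class `segmentation_set`.
#' @export
segmentation_set <- function(tumor_mask, artery_masks = list(), cs_mask = NULL,
                             bone_mask = NULL, spacing_mm = c(1, 1, 1)) {
  shape <- dim(tumor_mask)
  if (length(shape) != 3) stop("tumor_mask must be a 3D array")
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive finite numbers")
  if (is.null(cs_mask)) cs_mask <- array(FALSE, shape)
  if (is.null(bone_mask)) bone_mask <- array(FALSE, shape)
  if (length(artery_masks)) {
    nm <- names(artery_masks)
    if (is.null(nm) || any(!nzchar(nm))) stop("artery_masks must be named")
    bad <- setdiff(nm, .ARTERY_NAMES)
    if (length(bad))
      stop("unknown artery name(s): ", paste(bad, collapse = ", "))
    if (anyDuplicated(nm)) stop("duplicate artery names")
  }
  for (m in c(list(tumor = tumor_mask, cs = cs_mask, bone = bone_mask), artery_masks)) {
    if (!identical(dim(m), shape))
      stop("all masks must share the same grid shape")
  }
  structure(
    list(
      tumor_mask = tumor_mask != 0,
      artery_masks = lapply(artery_masks, function(m) m != 0),
      cs_mask = cs_mask != 0,
      bone_mask = bone_mask != 0,
      spacing_mm = as.numeric(spacing_mm)
    ),
    class = "segmentation_set"
  )
}

#' @export
print.segmentation_set <- function(x, ...) {
  vv <- prod(x$spacing_mm) / 1000
  cat("<segmentation_set> grid ", paste(dim(x$tumor_mask), collapse = "x"),
      " @ ", paste(signif(x$spacing_mm, 3), collapse = "x"), " mm\n", sep = "")
  cat(sprintf("  tumor: %.2f cm3 | arteries: %s | CS: %s | bone: %s\n",
              sum(x$tumor_mask) * vv,
              if (length(x$artery_masks)) paste(names(x$artery_masks), collapse = ",") else "none",
              if (any(x$cs_mask)) "present" else "empty",
              if (any(x$bone_mask)) "present" else "empty"))
  invisible(x)
}
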