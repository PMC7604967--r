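# Bit flags for the multi-label NIfTI encoding. Structures may overlap
# (tumor infiltrating CS or bone), so each voxel's label is a bitmask:
# tumor = 1, CS = 2, bone = 4, arteries C4..A2 = 8, 16, 32, 64, 128, 256.
.LABEL_BITS <- c(tumor = 1L, cs = 2L, bone = 4L,
                 C4 = 8L, C5 = 16L, M1 = 32L, M2 = 64L, A1 = 128L, A2 = 256L)

.write_mask_nifti <- function(mask, spacing_mm, path) {
  im <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
  RNifti::pixdim(im) <- spacing_mm
  RNifti::writeNifti(im, path)
  path
}

.read_mask_nifti <- function(path) {
  im <- RNifti::readNifti(path)
  list(mask = as.array(im) != 0, spacing = RNifti::pixdim(im),
       raw = as.array(im))
}

#' Write a segmentation set as NIfTI
#'
#' Either one file per structure (`tumor.nii.gz`, `cs.nii.gz`,
#' `bone.nii.gz`, `<artery>.nii.gz`) or a single multi-label volume
#' (`labels.nii.gz`) whose voxel values are bitmasks (tumor = 1, CS = 2,
#' bone = 4, arteries 8...256) so that overlapping structures round-trip
#' exactly; the bit table is written alongside as `labels.json`.
#'
#' @param seg a [segmentation_set()].
#' @param dir output directory (created if needed).
#' @param multi_label write one bitmask volume instead of per-structure files.
#' @return Invisibly, the paths written.
#' @export
write_segmentation_set <- function(seg, dir, multi_label = FALSE) {
  stopifnot(inherits(seg, "segmentation_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- seg$spacing_mm
  if (multi_label) {
    lab <- array(0L, dim(seg$tumor_mask))
    lab <- lab + .LABEL_BITS[["tumor"]] * seg$tumor_mask +
      .LABEL_BITS[["cs"]] * seg$cs_mask + .LABEL_BITS[["bone"]] * seg$bone_mask
    for (nm in names(seg$artery_masks))
      lab <- lab + .LABEL_BITS[[nm]] * seg$artery_masks[[nm]]
    im <- RNifti::asNifti(array(as.integer(lab), dim(lab)))
    RNifti::pixdim(im) <- sp
    p <- file.path(dir, "labels.nii.gz")
    RNifti::writeNifti(im, p)
    jsonlite::write_json(as.list(.LABEL_BITS), file.path(dir, "labels.json"),
                         auto_unbox = TRUE)
    return(invisible(c(p, file.path(dir, "labels.json"))))
  }
  paths <- c(
    .write_mask_nifti(seg$tumor_mask, sp, file.path(dir, "tumor.nii.gz")),
    .write_mask_nifti(seg$cs_mask, sp, file.path(dir, "cs.nii.gz")),
    .write_mask_nifti(seg$bone_mask, sp, file.path(dir, "bone.nii.gz")))
  for (nm in names(seg$artery_masks))
    paths <- c(paths, .write_mask_nifti(seg$artery_masks[[nm]], sp,
                                        file.path(dir, paste0(nm, ".nii.gz"))))
  invisible(paths)
}

#' Read a segmentation set from NIfTI
#'
#' Accepts either a directory written by [write_segmentation_set()]
#' (per-structure files, or a `labels.nii.gz` + `labels.json` bitmask
#' pair), or an explicit list of paths. Shapes and voxel spacings must
#' agree across files; a mismatch is a hard error naming the offending
#' file. Missing artery files produce a warning and are treated as absent.
#'
#' @param dir directory containing the files (used when `paths` is NULL).
#' @param paths optional named list: `tumor`, `cs`, `bone`, and `arteries`
#'   (named list of paths).
#' @return A [segmentation_set()].
#' @export
read_segmentation_set <- function(dir = NULL, paths = NULL) {
  if (is.null(paths)) {
    if (is.null(dir)) stop("provide dir or paths")
    ml <- file.path(dir, "labels.nii.gz")
    if (file.exists(ml)) {
      bits <- unlist(jsonlite::read_json(file.path(dir, "labels.json")))
      r <- .read_mask_nifti(ml)
      raw <- as.integer(r$raw)
      dims <- dim(r$raw)
      get <- function(bit) array(bitwAnd(raw, bit) > 0, dims)
      arts <- list()
      for (nm in .ARTERY_NAMES) {
        m <- get(bits[[nm]])
        if (any(m)) arts[[nm]] <- m
      }
      return(segmentation_set(get(bits[["tumor"]]), arts, get(bits[["cs"]]),
                              get(bits[["bone"]]), r$spacing))
    }
    paths <- list(tumor = file.path(dir, "tumor.nii.gz"),
                  cs = file.path(dir, "cs.nii.gz"),
                  bone = file.path(dir, "bone.nii.gz"),
                  arteries = stats::setNames(
                    as.list(file.path(dir, paste0(.ARTERY_NAMES, ".nii.gz"))),
                    .ARTERY_NAMES))
  }
  if (!file.exists(paths$tumor)) stop("tumor mask file not found: ", paths$tumor)
  tum <- .read_mask_nifti(paths$tumor)
  check <- function(r, f) {
    if (!identical(dim(r$mask), dim(tum$mask)))
      stop("grid shape mismatch in ", f)
    if (max(abs(r$spacing - tum$spacing)) > 1e-4)
      stop("voxel spacing mismatch in ", f)
    r$mask
  }
  cs <- bone <- NULL
  if (!is.null(paths$cs) && file.exists(paths$cs))
    cs <- check(.read_mask_nifti(paths$cs), paths$cs)
  if (!is.null(paths$bone) && file.exists(paths$bone))
    bone <- check(.read_mask_nifti(paths$bone), paths$bone)
  arts <- list()
  for (nm in names(paths$arteries)) {
    f <- paths$arteries[[nm]]
    if (!file.exists(f)) {
      warning("artery mask missing for ", nm, "; treated as absent")
      next
    }
    m <- check(.read_mask_nifti(f), f)
    if (any(m)) arts[[nm]] <- m
  }
  segmentation_set(tum$mask, arts, cs, bone, tum$spacing)
}

#' Write / read cohort CSV
#'
#' Schema: one row per patient with columns `volume_grade` (1-3),
#' `arterial_score` (0-4), `cs_involved` (0/1), `bone_invaded` (0/1), and
#' optionally `total_score` (recomputed and cross-checked on read; a
#' mismatch is an error), `simpson_grade` (I-IV as 1-4) and `outcome_grade`
#' (0-3).
#'
#' @param cohort a `cohort_table`.
#' @param path CSV file path.
#' @return `write_cohort_csv` returns the path invisibly;
#'   `read_cohort_csv` returns a `cohort_table`.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  out <- as.data.frame(cohort)
  out$cs_involved <- as.integer(out$cs_involved)
  out$bone_invaded <- as.integer(out$bone_invaded)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path)
  cohort_table(df, provenance = "user")
}

#' Pipeline configuration
#'
#' Every threshold that affects a score component, plus statistics options.
#' All values are echoed into run reports for auditability.
#'
#' @param full_encirclement_deg angular coverage counted as complete
#'   encirclement (default 355, tolerating voxelization of a literal 360).
#' @param narrowing_delta relative caliber reduction counted as narrowing.
#' @param tau_cs_cm3,tau_bone_cm3 overlap volumes (cm3) above which CS
#'   involvement / bone invasion are called (strict inequality).
#' @param probe_band_mm radial probe depth beyond the vessel surface for
#'   angular coverage.
#' @param band_cutoffs length-2 score cutoffs for the resection band.
#' @param regression_family `"proportional_odds"` or `"binary"`.
#' @param discriminant_mode `"resubstitution"` or `"loo"`.
#' @param seed integer seed echoed to stochastic components.
#' @param verbose logical.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(full_encirclement_deg = 355, narrowing_delta = 0.20,
                            tau_cs_cm3 = 0.1, tau_bone_cm3 = 0.1,
                            probe_band_mm = 2, band_cutoffs = c(4, 7),
                            regression_family = c("proportional_odds", "binary"),
                            discriminant_mode = c("resubstitution", "loo"),
                            seed = 1L, verbose = FALSE) {
  regression_family <- match.arg(regression_family)
  discriminant_mode <- match.arg(discriminant_mode)
  if (full_encirclement_deg <= 0 || full_encirclement_deg > 360)
    stop("full_encirclement_deg must lie in (0, 360]")
  if (narrowing_delta <= 0 || narrowing_delta >= 1)
    stop("narrowing_delta must lie in (0, 1)")
  if (tau_cs_cm3 < 0 || tau_bone_cm3 < 0) stop("overlap thresholds must be >= 0")
  if (probe_band_mm <= 0) stop("probe_band_mm must be positive")
  if (length(band_cutoffs) != 2 || band_cutoffs[1] > band_cutoffs[2])
    stop("band_cutoffs must be two non-decreasing numbers")
  structure(list(full_encirclement_deg = as.numeric(full_encirclement_deg),
                 narrowing_delta = as.numeric(narrowing_delta),
                 tau_cs_cm3 = as.numeric(tau_cs_cm3),
                 tau_bone_cm3 = as.numeric(tau_bone_cm3),
                 probe_band_mm = as.numeric(probe_band_mm),
                 band_cutoffs = as.numeric(band_cutoffs),
                 regression_family = regression_family,
                 discriminant_mode = discriminant_mode,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#' @param path JSON file path.
#' @param config a [pipeline_config()].
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

#' Run the full scoring pipeline
#'
#' Per segmentation set: feature extraction, total score, predicted band.
#' Failures are isolated per patient (captured and reported; the batch
#' continues). When a cohort with at least 3 graded patients is supplied,
#' the statistics battery is run as well. Deterministic given config and
#' inputs.
#'
#' @param config a [pipeline_config()].
#' @param segmentations list of [segmentation_set()] objects (may be empty).
#' @param cohort optional `cohort_table`.
#' @return A list of class `run_report`: `scores` (per-patient
#'   `score_result` or error message), `features`, `stats` (or NULL),
#'   `config`, `version`, `timestamp`.
#' @export
run_pipeline <- function(config = pipeline_config(), segmentations = list(),
                         cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!length(segmentations) && is.null(cohort))
    stop("no inputs: supply segmentations and/or a cohort")
  scores <- list()
  features <- list()
  for (i in seq_along(segmentations)) {
    id <- names(segmentations)[i]
    if (is.null(id) || !nzchar(id)) id <- paste0("patient", i)
    res <- tryCatch({
      f <- extract_features(segmentations[[i]], config)
      list(features = f, score = total_score(f, cutoffs = config$band_cutoffs))
    }, error = function(e) list(error = conditionMessage(e)))
    if (!is.null(res$error)) {
      warning("patient ", id, " failed: ", res$error)
      scores[[id]] <- list(error = res$error)
    } else {
      features[[id]] <- res$features
      scores[[id]] <- res$score
    }
  }
  stats <- NULL
  if (!is.null(cohort) && "simpson_grade" %in% names(cohort) &&
      sum(!is.na(cohort$simpson_grade)) >= 3) {
    stats <- cohort_stats(cohort, config)
  } else if (!is.null(cohort)) {
    stats <- list(descriptives = descriptive_summary(cohort))
  }
  structure(list(scores = scores, features = features, stats = stats,
                 config = config,
                 version = as.character(utils::packageVersion("mswmscore")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            class = "run_report")
}

#' Write a run report as JSON
#'
#' Fixed key order and 6-significant-digit floats, so reports from
#' identical inputs diff cleanly apart from the timestamp.
#'
#' @param report a `run_report`.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  strip <- function(x) {
    if (inherits(x, "radiologic_features")) x$encasements <- lapply(x$encasements, unclass)
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  jsonlite::write_json(strip(report), path, auto_unbox = TRUE, digits = 6,
                       force = TRUE)
  invisible(path)
}
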