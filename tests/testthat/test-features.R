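test_that("tumor volume is voxel count times voxel volume", {
  expect_warning(v0 <- compute_tumor_volume(array(FALSE, c(5, 5, 5)), c(1, 1, 1)),
                 "empty")
  expect_equal(v0, 0)
  block <- array(FALSE, c(12, 12, 12))
  block[2:11, 2:11, 2:11] <- TRUE
  expect_equal(compute_tumor_volume(block, c(1, 1, 1)), 1.0)
  # anisotropic spacing
  expect_equal(compute_tumor_volume(block, c(0.5, 1, 2)), 1.0)
  # voxelized 10 mm sphere at 0.5 mm within 2% of analytic volume
  ph <- sphere_phantom(r_mm = 10, spacing = 0.5)
  v <- compute_tumor_volume(ph$seg$tumor_mask, ph$seg$spacing_mm)
  expect_equal(v, 4 / 3 * pi, tolerance = 0.02)
})

test_that("volume grading uses the documented closed-interval boundaries", {
  expect_equal(grade_volume(9.3), 1L)
  expect_equal(grade_volume(171.9), 3L)
  expect_equal(grade_volume(19.999), 1L)
  expect_equal(grade_volume(20), 2L)
  expect_equal(grade_volume(50), 2L)
  expect_equal(grade_volume(50.001), 3L)
  expect_equal(grade_volume(0), 1L)
  expect_error(grade_volume(-1), "non-negative")
})

test_that("centerline of a straight cylinder recovers axis, radius and length", {
  cyl <- cylinder_mask()
  vg <- extract_centerline(cyl, c(1, 1, 1))
  # interior radius estimates within half a voxel of the true 3 mm
  r_int <- vg$local_radius_mm[vg$interior]
  expect_true(all(abs(r_int - 3) <= 0.5))
  # interior centerline points on the axis (physical (9, 9))
  pts <- vg$centerline_points[vg$interior, ]
  expect_true(all(abs(pts[, 1] - 9) < 0.5))
  expect_true(all(abs(pts[, 2] - 9) < 0.5))
  expect_equal(vg$arc_length_mm, 35, tolerance = 0.05)
  # tangents along z
  expect_true(all(abs(abs(vg$tangents[vg$interior, 3]) - 1) < 0.05))
})

test_that("centerline arc length of a curved tube matches analytic geometry", {
  tor <- quarter_torus_mask()
  vg <- extract_centerline(tor, c(1, 1, 1), "C4")
  expect_equal(vg$arc_length_mm, 20 * pi / 2, tolerance = 0.05)
  r_int <- vg$local_radius_mm[vg$interior]
  expect_true(all(abs(r_int - 3) <= 0.5))
})

test_that("non-tubular masks are rejected with informative errors", {
  d <- array(FALSE, c(20, 20, 20))
  d[3:5, 3:5, 3:15] <- TRUE
  d[15:17, 15:17, 3:15] <- TRUE
  expect_error(extract_centerline(d, c(1, 1, 1), "A1"),
               "not a tube: 'A1'.*components")
  expect_error(extract_centerline(array(FALSE, c(10, 10, 10)), c(1, 1, 1), "M2"),
               "not a tube: 'M2'")
})

test_that("angular coverage tracks the constructed wrap angle", {
  ph <- wrap_phantom(180, seed = 2)
  vg <- extract_centerline(ph$seg$artery_masks$M1, c(1, 1, 1), "M1")
  enc <- angular_coverage(ph$seg$tumor_mask, vg, c(1, 1, 1))
  expect_true(enc$involved)
  expect_equal(enc$max_coverage_deg, 180, tolerance = 10 / 180)
  expect_false(enc$fully_encircled)

  ph360 <- wrap_phantom(360, seed = 4)
  vg360 <- extract_centerline(ph360$seg$artery_masks$M1, c(1, 1, 1), "M1")
  enc360 <- angular_coverage(ph360$seg$tumor_mask, vg360, c(1, 1, 1))
  expect_true(enc360$fully_encircled)

  # tumor far from every probe band: not involved, coverage 0
  far <- array(FALSE, dim(ph$seg$tumor_mask))
  far[55:58, 55:58, 55:58] <- TRUE
  enc0 <- angular_coverage(far, vg, c(1, 1, 1))
  expect_false(enc0$involved)
  expect_equal(enc0$max_coverage_deg, 0)
})

test_that("angular coverage is invariant under 90-degree grid rotation", {
  ph <- wrap_phantom(180, seed = 6)
  rot <- function(m) aperm(m[, , dim(m)[3]:1], c(1, 3, 2)) # 90 deg about x
  vg1 <- extract_centerline(ph$seg$artery_masks$M1, c(1, 1, 1), "M1")
  c1 <- angular_coverage(ph$seg$tumor_mask, vg1, c(1, 1, 1))$max_coverage_deg
  vg2 <- extract_centerline(rot(ph$seg$artery_masks$M1), c(1, 1, 1), "M1")
  c2 <- angular_coverage(rot(ph$seg$tumor_mask), vg2, c(1, 1, 1))$max_coverage_deg
  expect_lte(abs(c1 - c2), 5)
})

test_that("narrowing detection thresholds at the relative caliber reduction", {
  vg_uniform <- extract_centerline(cylinder_mask(), c(1, 1, 1))
  expect_false(detect_narrowing(vg_uniform))

  ph30 <- wrap_phantom(360, nf = 0.30, seed = 3)
  vg30 <- extract_centerline(ph30$seg$artery_masks$M1, c(1, 1, 1), "M1")
  expect_true(detect_narrowing(vg30))

  ph05 <- wrap_phantom(360, nf = 0.05, seed = 3)
  vg05 <- extract_centerline(ph05$seg$artery_masks$M1, c(1, 1, 1), "M1")
  expect_false(detect_narrowing(vg05))

  short <- vg_uniform
  short$local_radius_mm <- short$local_radius_mm[1:4]
  expect_error(detect_narrowing(short), "insufficient geometry")
})

test_that("arterial involvement scoring matches the published worked scenarios", {
  partial_m1 <- encasement_result("M1", TRUE, 180)
  full_ica <- encasement_result("C4", TRUE, 360, fully_encircled = TRUE)
  full_narrow_m1 <- encasement_result("M1", TRUE, 360, TRUE, TRUE)
  full_narrow_ica <- encasement_result("C4", TRUE, 360, TRUE, TRUE)
  absent <- encasement_result("A1", FALSE)

  expect_equal(arterial_involvement_score(list(partial_m1, absent)), 1L)
  expect_equal(arterial_involvement_score(list(full_ica, absent)), 2L)
  expect_equal(arterial_involvement_score(list(full_narrow_m1, absent)), 3L)
  expect_equal(arterial_involvement_score(list(full_narrow_ica, full_narrow_m1)), 4L)
  expect_equal(arterial_involvement_score(list(absent)), 0L)
  expect_equal(arterial_involvement_score(list()), 0L)
})

test_that("arterial score is monotone and bounded under feature additions", {
  set.seed(1)
  segs <- c("C4", "C5", "M1", "M2", "A1", "A2")
  for (rep in 1:30) {
    n <- sample(1:6, 1)
    base <- lapply(seq_len(n), function(i) {
      inv <- runif(1) < 0.6
      encasement_result(segs[i], inv, if (inv) runif(1, 1, 354) else 0,
                        fully_encircled = FALSE,
                        narrowed = inv && runif(1) < 0.4)
    })
    s0 <- arterial_involvement_score(base)
    expect_true(s0 %in% 0:4)
    # adding a newly involved artery never decreases the score
    more <- c(base, list(encasement_result("A2", TRUE, 90)))
    expect_gte(arterial_involvement_score(more), s0)
    # upgrading one to full encirclement never decreases the score
    up <- base
    up[[1]] <- encasement_result(up[[1]]$artery_name, TRUE, 360,
                                 fully_encircled = TRUE,
                                 narrowed = up[[1]]$narrowed)
    expect_gte(arterial_involvement_score(up), s0)
    # marking one narrowed never decreases the score
    nr <- base
    nr[[1]] <- encasement_result(nr[[1]]$artery_name, TRUE,
                                 max(nr[[1]]$max_coverage_deg, 10),
                                 fully_encircled = nr[[1]]$fully_encircled,
                                 narrowed = TRUE)
    expect_gte(arterial_involvement_score(nr), s0)
  }
})

test_that("encasement result invariants are enforced", {
  expect_error(encasement_result("M1", FALSE, 90), "0 exactly")
  expect_error(encasement_result("M1", FALSE, 0, fully_encircled = TRUE),
               "requires involved")
  expect_error(encasement_result("M1", FALSE, 0, narrowed = TRUE),
               "requires involved")
  expect_error(encasement_result("M1", TRUE, 400), "360")
})

test_that("CS and bone overlap calls use a strict volume threshold", {
  a <- array(FALSE, c(20, 20, 20)); a[2:10, 2:10, 2:10] <- TRUE
  b_far <- array(FALSE, c(20, 20, 20)); b_far[15:18, 15:18, 15:18] <- TRUE
  expect_false(assess_cs_involvement(a, b_far, c(1, 1, 1)))
  expect_false(assess_bone_invasion(a, b_far, c(1, 1, 1)))

  b_big <- array(FALSE, c(20, 20, 20)); b_big[2:11, 2:11, 2:11] <- TRUE
  expect_true(assess_cs_involvement(a, b_big, c(1, 1, 1)))   # 729 mm3 overlap

  # overlap exactly at the threshold does not count (strict inequality)
  b_tau <- array(FALSE, c(20, 20, 20)); b_tau[2:6, 2:5, 2:6] <- TRUE  # 100 voxels
  expect_equal(sum(a & b_tau), 100)
  expect_false(assess_cs_involvement(a, b_tau, c(1, 1, 1)))
  expect_true(assess_cs_involvement(a, b_tau, c(1, 1, 1), tau_cs_cm3 = 0.099))

  # adjacency without overlap never counts
  b_touch <- array(FALSE, c(20, 20, 20)); b_touch[11:14, 2:10, 2:10] <- TRUE
  expect_equal(sum(a & b_touch), 0)
  expect_false(assess_bone_invasion(a, b_touch, c(1, 1, 1)))
  expect_equal(attr(assess_bone_invasion(a, b_big, c(1, 1, 1)), "overlap_cm3"),
               0.729)
})

test_that("full feature extraction recovers composite phantom ground truth", {
  a <- straight_artery("M1", x = 40, y = 12, z = c(10, 70))
  ph <- make_phantom(phantom_spec(grid_shape = c(80, 80, 80),
                                  tumor_center_mm = c(40, 38, 40),
                                  tumor_semiaxes_mm = c(20, 18, 15),
                                  arteries = list(a),
                                  cs_overlap_voxels = 150, seed = 9))
  f <- extract_features(ph$seg)
  expect_equal(f$volume_grade, 2L)    # 22.6 cm3
  expect_equal(f$tumor_volume_cm3, ph$truth$analytic_tumor_volume_cm3,
               tolerance = 0.02)
  expect_equal(f$arterial_score, 0L)  # artery clear of the tumor
  expect_true(f$cs_involved)
  expect_false(f$bone_invaded)
  sc <- total_score(f)
  expect_equal(sc$total, 4L)
})

test_that("empty tumor yields the floor feature set", {
  seg <- segmentation_set(array(FALSE, c(10, 10, 10)))
  expect_warning(f <- extract_features(seg), "empty")
  expect_equal(f$tumor_volume_cm3, 0)
  expect_equal(f$volume_grade, 1L)
  expect_equal(f$arterial_score, 0L)
  expect_false(f$cs_involved)
  expect_false(f$bone_invaded)
})
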