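make_test_study <- function(nx = 32, ny = 32, nz = 6, radii = c(10, 10),
                            lesion_fun = NULL) {
  atl <- make_region_atlas(c(nx, ny), radii)
  cord <- array(atl$cord_mask, dim = c(nx, ny, nz))
  lesion <- array(FALSE, dim = c(nx, ny, nz))
  if (!is.null(lesion_fun)) lesion <- lesion_fun(cord)
  list(study = lesion_study(cord, lesion), atlas = atl)
}

test_that("axial projection is a logical union along the S-I axis", {
  ts <- make_test_study()
  # single voxel
  l <- ts$study$lesion_mask; l[16, 16, 3] <- TRUE
  st <- lesion_study(ts$study$cord_mask, l)
  proj <- project_lesion_axial(st)
  expect_equal(sum(proj), 1)
  expect_true(proj[16, 16])
  # same pixel on every slice: union is idempotent
  l2 <- array(FALSE, dim = dim(l)); l2[16, 16, ] <- TRUE
  expect_equal(project_lesion_axial(lesion_study(ts$study$cord_mask, l2)),
               proj)
  # disjoint lesions on two slices match the brute-force union
  l3 <- array(FALSE, dim = dim(l))
  l3[14:15, 16:18, 2] <- TRUE
  l3[17:19, 12:13, 5] <- TRUE
  st3 <- lesion_study(ts$study$cord_mask, l3)
  expect_equal(project_lesion_axial(st3), project_bruteforce(l3))
  expect_equal(sum(project_lesion_axial(st3)), 2 * 3 + 3 * 2)
})

test_that("projection ignores slice order and duplication", {
  ph <- make_cord_phantom(random_phantom_spec(3))
  st <- ph$study
  proj <- project_lesion_axial(st)
  perm <- sample(dim(st$lesion_mask)[3])
  st_perm <- lesion_study(st$cord_mask[, , perm], st$lesion_mask[, , perm])
  expect_identical(project_lesion_axial(st_perm), proj)
  dup <- c(seq_len(dim(st$lesion_mask)[3]), 1, 1)
  st_dup <- lesion_study(st$cord_mask[, , dup], st$lesion_mask[, , dup])
  expect_identical(project_lesion_axial(st_dup), proj)
})

test_that("spared fraction arithmetic is exact", {
  proj <- matrix(FALSE, 4, 4)
  w <- matrix(0, 4, 4)
  w[1, 1:4] <- c(1, 2, 3, 4)  # total weight 10
  expect_equal(compute_spared_fraction(proj, w), 100)
  proj[1, 2] <- TRUE; proj[1, 1] <- TRUE  # covers weight 3
  expect_equal(compute_spared_fraction(proj, w), 70)
  proj[1, ] <- TRUE
  expect_equal(compute_spared_fraction(proj, w), 0)
  expect_error(compute_spared_fraction(proj, matrix(0, 4, 4)), "zero total")
  expect_error(compute_spared_fraction(matrix(FALSE, 3, 3), w), "share a grid")
})

test_that("no lesion and whole-cord lesion give the two extreme profiles", {
  ts <- make_test_study()
  expect_equal(unname(profile_vec(spared_profile(ts$study, ts$atlas))),
               rep(100, 5))
  full <- lesion_study(ts$study$cord_mask, ts$study$cord_mask)
  expect_equal(unname(profile_vec(spared_profile(full, ts$atlas))),
               rep(0, 5))
})

test_that("a half-cord lesion zeroes its sector and spares the mirror sector", {
  # circular cord on an even grid; the lesion is the anterior (+y) half.
  # The anterior sector is wholly lesioned and the posterior wholly spared.
  # The lateral sectors are split close to half: the half-open sector
  # boundaries put each 45-degree diagonal wholly into one sector, so the
  # lateral splits deviate from 50% by the handful of diagonal pixels
  # (their spared parts still sum to exactly one sector's worth).
  ts <- make_test_study(lesion_fun = function(cord) {
    ys <- array(rep(seq_len(32), each = 32), dim = c(32, 32, 6))
    cord & ys > 16.5
  })
  prof <- spared_profile(ts$study, ts$atlas)
  expect_equal(prof[["spared_anterior"]], 0)
  expect_equal(prof[["spared_posterior"]], 100)
  expect_equal(prof[["spared_left"]] + prof[["spared_right"]], 100)
  expect_lt(abs(prof[["spared_left"]] - 50), 6)
  expect_lt(abs(prof[["spared_right"]] - 50), 6)
  expect_equal(prof[["spared_total"]], 50)
})

test_that("a left-half-cord lesion spares the right sector fully", {
  ts <- make_test_study(lesion_fun = function(cord) {
    xs <- array(rep(seq_len(32), 32 * 6), dim = c(32, 32, 6))
    cord & xs > 16.5
  })
  prof <- spared_profile(ts$study, ts$atlas)
  expect_equal(prof[["spared_left"]], 0)
  expect_equal(prof[["spared_right"]], 100)
  expect_equal(prof[["spared_total"]], 50)
})

test_that("spared percentages match the enumeration oracle on random phantoms", {
  for (s in 1:10) {
    ph <- make_cord_phantom(random_phantom_spec(s))
    expect_identical(profile_vec(spared_profile(ph$study, ph$atlas)),
                     profile_vec(ph$truth))
  }
  # weighted (radial) atlas: agreement within 1e-9 relative
  atlw <- make_region_atlas(c(48, 48), c(14, 10), weighting = "radial")
  for (s in 1:5) {
    spec <- random_phantom_spec(s)
    ph <- make_cord_phantom(spec, atlw)
    a <- profile_vec(spared_profile(ph$study, atlw))
    b <- profile_vec(enumerate_spared_profile(spec$lesion_shapes, atlw))
    expect_lt(max(abs(a - b) / pmax(abs(b), 1e-12)), 1e-9)
  }
})

test_that("lesion containment and shape mismatches are rejected", {
  ts <- make_test_study()
  bad <- ts$study$lesion_mask; bad[1, 1, 1] <- TRUE  # outside the cord
  expect_error(lesion_study(ts$study$cord_mask, bad), "contained")
  expect_error(lesion_study(ts$study$cord_mask,
                            array(FALSE, dim = c(32, 32, 5))),
               "identical shape")
})

test_that("slicewise alignment recovers translation and scale", {
  atl <- make_region_atlas(c(48, 48), c(10, 10))
  tmpl <- atl$cord_mask
  # identity
  st <- lesion_study(array(tmpl, dim = c(48, 48, 3)),
                     array(FALSE, dim = c(48, 48, 3)))
  al <- slicewise_align(st, tmpl)
  expect_equal(al$transforms$dx, rep(0, 3))
  expect_equal(al$transforms$scale, rep(1, 3))
  expect_identical(al$study$cord_mask, st$cord_mask)
  # translation by (3, -2): recovered transform is (-3, 2)
  sub2d <- shift_mask(tmpl, 3, -2)
  st2 <- lesion_study(array(sub2d, dim = c(48, 48, 2)),
                      array(FALSE, dim = c(48, 48, 2)))
  al2 <- slicewise_align(st2, tmpl)
  expect_equal(al2$transforms$dx, rep(-3, 2))
  expect_equal(al2$transforms$dy, rep(2, 2))
  expect_identical(al2$study$cord_mask[, , 1], tmpl)
  # area dilated x2: isotropic scale ~ 1/sqrt(2), aligned area matches
  big <- make_region_atlas(c(48, 48), c(10 * sqrt(2), 10 * sqrt(2)))$cord_mask
  st3 <- lesion_study(array(big, dim = c(48, 48, 1)),
                      array(FALSE, dim = c(48, 48, 1)))
  al3 <- slicewise_align(st3, tmpl)
  expect_equal(al3$transforms$scale[1], 1 / sqrt(2), tolerance = 0.02)
  expect_equal(sum(al3$study$cord_mask[, , 1]), sum(tmpl))
})

test_that("empty cord slices get the identity transform and are flagged", {
  atl <- make_region_atlas(c(48, 48), c(10, 10))
  cord <- array(atl$cord_mask, dim = c(48, 48, 3))
  cord[, , 2] <- FALSE
  st <- lesion_study(cord, array(FALSE, dim = c(48, 48, 3)))
  expect_message(al <- slicewise_align(st, atl$cord_mask), "empty")
  expect_true(al$transforms$empty[2])
  expect_equal(al$transforms$scale[2], 1)
})

test_that("masks and atlases survive a NIfTI round trip", {
  ph <- make_cord_phantom(random_phantom_spec(12))
  dir <- withr::local_tempdir()
  paths <- write_lesion_study(ph$study, dir, prefix = "t")
  st <- read_lesion_study(paths["cord"], paths["lesion"])
  expect_identical(st$cord_mask, ph$study$cord_mask)
  expect_identical(st$lesion_mask, ph$study$lesion_mask)
  expect_equal(st$voxel_size, ph$study$voxel_size)
  write_region_atlas(ph$atlas, file.path(dir, "atlas"))
  atl2 <- read_region_atlas(file.path(dir, "atlas"))
  expect_equal(atl2$region_weights, ph$atlas$region_weights)
  expect_identical(profile_vec(spared_profile(st, atl2)),
                   profile_vec(ph$truth))
})
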