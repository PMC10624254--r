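test_that("single-layer sphere volume matches the analytic value", {
  v <- make_layered_head(layer_radii = 50, layer_tissues = "Muscle",
                         spacing = 1)
  vol <- sum(v$data == 1L) * voxel_volume_mm3(v)
  expect_lt(abs(vol - 4 / 3 * pi * 50^3) / (4 / 3 * pi * 50^3), 0.05)
})

test_that("shell voxel volumes converge to analytic volumes as spacing shrinks", {
  radii <- c(50, 44, 38)
  shells <- c(4 / 3 * pi * (50^3 - 44^3), 4 / 3 * pi * (44^3 - 38^3),
              4 / 3 * pi * 38^3)
  errs <- sapply(c(2, 1, 0.5), function(sp) {
    v <- make_layered_head(radii, c("Skin", "Skull cortical", "Muscle"),
                           spacing = sp)
    max(abs(sapply(1:3, function(l) sum(v$data == l) * voxel_volume_mm3(v)) -
              shells) / shells)
  })
  expect_true(all(diff(errs) < 0))       # monotone improvement
  expect_lt(errs[3], 0.02)
})

test_that("default head carries a 1.0 mm skin shell and nested layers", {
  v <- make_layered_head(spacing = 1)
  expect_equal(attr(v, "skin_thickness_achieved"), 1.0)
  expect_identical(v$labels$tissue[1], "Skin")

  v2 <- make_layered_head(spacing = 2)   # skin thinner than spacing: snapped
  expect_equal(attr(v2, "skin_thickness_achieved"), 2)
  # nesting: bounding box of each shell contains the next inner one
  bb <- lapply(1:5, function(l) apply(which(v2$data == l, arr.ind = TRUE),
                                      2, range))
  for (l in 1:4) {
    expect_true(all(bb[[l]][1, ] <= bb[[l + 1]][1, ]))
    expect_true(all(bb[[l]][2, ] >= bb[[l + 1]][2, ]))
    expect_gt(sum(v2$data == l), 0)
  }
})

test_that("layered-head preconditions reject bad geometry", {
  expect_error(make_layered_head(c(50, 50, 40), rep("Muscle", 3), spacing = 1),
               "decreasing")
  expect_error(make_layered_head(c(50, 49, 48), rep("Muscle", 3), spacing = 2),
               "spacing")
  expect_error(make_layered_head(c(50, 40), "Muscle", spacing = 1), "length")
})

test_that("internal air cavity is labeled and excluded from tissue layers", {
  v <- make_layered_head(c(30, 29, 22), c("Skin", "Skull cortical", "Muscle"),
                         spacing = 1,
                         air_cavity = list(center = c(0, 0, 0), radius = 8))
  expect_true("Air (internal)" %in% v$labels$tissue)
  cav <- sum(v$data == 4L)
  expect_gt(cav, 0)
  expect_lt(abs(cav - 4 / 3 * pi * 8^3) / (4 / 3 * pi * 8^3), 0.1)
})

test_that("merge_with_priority takes the highest covering label", {
  d <- c(6, 6, 6)
  m3 <- box_mask(d, c(1, 1, 1), c(4, 4, 4))
  m7 <- box_mask(d, c(3, 3, 3), c(6, 6, 6))
  v <- merge_with_priority(list(list(label = 3, mask = m3),
                                list(label = 7, mask = m7)))
  expect_true(all(v$data[m3 & m7] == 7L))
  expect_true(all(v$data[m3 & !m7] == 3L))
  expect_true(all(v$data[!m3 & !m7] == 0L))

  # disjoint masks: plain union
  a <- box_mask(d, c(1, 1, 1), c(2, 2, 2)); b <- box_mask(d, c(5, 5, 5), c(6, 6, 6))
  v2 <- merge_with_priority(list(list(label = 2, mask = a),
                                 list(label = 9, mask = b)))
  expect_equal(sum(v2$data == 2L), sum(a))
  expect_equal(sum(v2$data == 9L), sum(b))

  # three nested masks vs brute-force per-voxel max
  n1 <- box_mask(d, c(3, 3, 3), c(4, 4, 4))
  n2 <- box_mask(d, c(2, 2, 2), c(5, 5, 5))
  n3 <- box_mask(d, c(1, 1, 1), c(6, 6, 6))
  v3 <- merge_with_priority(list(list(label = 1, mask = n1),
                                 list(label = 2, mask = n2),
                                 list(label = 3, mask = n3)))
  brute <- pmax(1 * n1, 2 * n2, 3 * n3)
  expect_equal(as.vector(v3$data), as.vector(brute))

  expect_error(merge_with_priority(list(
    list(label = 1, mask = array(TRUE, c(2, 2, 2))),
    list(label = 2, mask = array(TRUE, c(3, 2, 2))))), "shapes")
})

test_that("merge_with_priority is idempotent and order-independent", {
  d <- c(5, 5, 5)
  set.seed(7)
  masks <- lapply(1:4, function(l)
    list(label = l, mask = array(runif(prod(d)) > 0.5, d)))
  v1 <- merge_with_priority(masks)
  v2 <- merge_with_priority(rev(masks))
  expect_identical(v1$data, v2$data)
  # re-merging the result with itself changes nothing
  again <- merge_with_priority(c(masks, masks))
  expect_identical(again$data, v1$data)
})

test_that("supplant fills every in-body hole from the nearest label", {
  # no holes: identity
  v <- cube_phantom(4, spacing = 1)
  body <- array(TRUE, dim(v$data))
  expect_identical(supplant_unassigned(v, body)$data, v$data)

  # single hole with a unique nearest neighbor carrying label 5
  lab <- array(0L, c(7, 7, 7))
  lab[2, 4, 4] <- 5L; lab[7, 4, 4] <- 3L
  vol <- label_volume(lab, labels = c(A = 5, B = 3))
  body <- array(TRUE, c(7, 7, 7))
  out <- supplant_unassigned(vol, body)
  expect_identical(out$data[3, 4, 4], 5L)   # closer to the 5
  expect_identical(out$data[6, 4, 4], 3L)
  expect_true(all(out$data[body] > 0L))
  # labeled voxels never change
  expect_identical(out$data[2, 4, 4], 5L)
  expect_identical(out$data[7, 4, 4], 3L)

  # equidistant tie resolves to the smallest label
  lab2 <- array(0L, c(5, 1, 1)); lab2[2] <- 9L; lab2[4] <- 2L
  v2 <- label_volume(lab2, labels = c(hi = 9, lo = 2))
  out2 <- supplant_unassigned(v2, array(TRUE, c(5, 1, 1)))
  expect_identical(out2$data[3, 1, 1], 2L)

  expect_error(supplant_unassigned(
    label_volume(array(0L, c(3, 3, 3)), labels = c(X = 1)),
    array(TRUE, c(3, 3, 3))), "no labeled voxel")
})

test_that("supplant matches an exhaustive nearest-donor scan", {
  set.seed(11)
  d <- c(6, 5, 4); sp <- c(1, 1.5, 2)
  lab <- array(0L, d)
  lab[sample(prod(d), 10)] <- sample(2:6, 10, replace = TRUE)
  vol <- label_volume(lab, spacing = sp,
                      labels = setNames(2:6, paste0("t", 2:6)))
  out <- supplant_unassigned(vol, array(TRUE, d))
  src <- which(lab > 0L); src_ijk <- arrayInd(src, d)
  for (h in which(lab == 0L)) {
    hijk <- arrayInd(h, d)
    d2 <- colSums((t(src_ijk) - as.vector(hijk))^2 * sp^2)
    best <- min(lab[src[abs(d2 - min(d2)) < 1e-9]])
    expect_identical(out$data[h], best)
  }
})

test_that("Lanczos resampling agrees with a direct kernel-sum oracle", {
  n <- 40
  arr <- array(as.numeric(seq_len(n)), c(n, 1, 1))   # 1-D ramp
  out <- resample_volume(arr, target_spacing = c(2, 1, 1), spacing = 1)
  oracle <- sapply(seq_len(dim(out)[1]), function(j) {
    p <- (j - 1) * 2
    idx <- (floor(p) - 2):(floor(p) + 3)
    w <- lanczos_kernel(p - idx, 3)
    idx <- pmin(pmax(idx, 0), n - 1)
    sum(w * arr[idx + 1, 1, 1]) / sum(w)
  })
  expect_equal(as.vector(out[, 1, 1]), oracle, tolerance = 1e-12)

  # identical target spacing: values unchanged (interpolating kernel)
  expect_equal(resample_volume(arr, 1, spacing = 1)[, 1, 1], arr[, 1, 1])

  # constant field preserved to kernel tolerance at any spacing
  cst <- array(3.7, c(10, 9, 8))
  expect_lt(max(abs(resample_volume(cst, 0.65, spacing = 1) - 3.7)), 1e-6)

  expect_error(resample_volume(cst, 0, spacing = 1), "positive")
})

test_that("label grids resample nearest-neighbor and stay integral", {
  v <- make_layered_head(c(20, 19, 14), c("Skin", "Skull cortical", "Muscle"),
                         spacing = 1)
  half <- resample_volume(v, 2)
  expect_true(is.integer(half$data))
  expect_true(all(half$data %in% c(0L, 1L, 2L, 3L)))
  # physical extent preserved within one voxel
  expect_lt(abs(dim(half$data)[1] * 2 - dim(v$data)[1] * 1), 2 + 1e-9)
  expect_error(resample_volume(v, 2, method = "lanczos"), "nearest")
})

test_that("perturb_mask modes behave and are seed-reproducible", {
  m <- box_mask(c(12, 12, 12), c(4, 4, 4), c(9, 9, 9))
  expect_identical(perturb_mask(m, "dilate", 0), m)
  expect_equal(dice(perturb_mask(m, "boundary-noise", 0, seed = 1), m), 1.0)

  # erode-then-dilate preserves the interior of a large cube (opening)
  er <- perturb_mask(m, "erode", 2)
  op <- perturb_mask(er, "dilate", 2)
  interior <- box_mask(c(12, 12, 12), c(6, 6, 6), c(7, 7, 7))
  expect_true(all(op[interior]))
  expect_true(all(op <= m + 0))          # opening never grows past the cube

  a <- perturb_mask(m, "boundary-noise", 2, seed = 42, prob = 0.4)
  b <- perturb_mask(m, "boundary-noise", 2, seed = 42, prob = 0.4)
  c2 <- perturb_mask(m, "boundary-noise", 2, seed = 43, prob = 0.4)
  expect_identical(a, b)
  expect_false(identical(a, c2))

  expect_error(perturb_mask(m, "erode", 99), "magnitude")
  expect_error(perturb_mask(m, "dilate", -1), "non-negative")
})

test_that("rater mask sets are reproducible under a fixed seed", {
  gold <- ball_mask(16, 5)
  s1 <- make_rater_set(gold, n_raters = 3, magnitudes = 1, seed = 5,
                       tissue = "Liver", spacing = 1)
  s2 <- make_rater_set(gold, n_raters = 3, magnitudes = 1, seed = 5,
                       tissue = "Liver", spacing = 1)
  expect_identical(s1$raters, s2$raters)
  expect_s3_class(s1, "rater_mask_set")
  expect_length(s1$raters, 3)
})
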