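test_that("HU calibration is the linear rescale", {
  raw <- matrix(c(0, 500, 1000, 2000), 2, 2)
  expect_identical(to_hu(raw, 1, 0)$values, raw)
  expect_equal(to_hu(matrix(1000, 1, 1), 1, -1024)$values[1, 1], -24)
  expect_true(all(to_hu(matrix(7, 3, 3), 2, -10)$values == 4))
  expect_error(to_hu(raw, 0, 0), "slope")
})

test_that("binarization marks exactly the air-like compartments", {
  tissue <- hu_image(matrix(40, 8, 8), 1)
  expect_false(any(binarize_lungs(tissue, -400)))

  spec <- small_phantom()
  sl <- make_phantom_slice(spec)
  b <- binarize_lungs(sl$image, -400)
  expect_identical(b, sl$image$values < -400)
  # air-like set = exterior air plus the lung compartments
  expect_identical(b, sl$image$values %in% c(-1000, -850) &
                     matrix(TRUE, 96, 96))

  below_min <- min(sl$image$values) - 1
  expect_false(any(binarize_lungs(sl$image, below_min)))
})

test_that("uint8 windowing maps endpoints, midpoints and clips", {
  img <- hu_image(matrix(c(-1200, 600, -300, -2000, 1000, 0), 2, 3), 1)
  u <- hu_to_uint8(img, c(-1200, 600))
  expect_equal(u$values[1, 1], 0)     # window min
  expect_equal(u$values[2, 1], 255)   # window max
  expect_equal(u$values[1, 2], 128)   # 127.5 rounds half-up
  expect_equal(u$values[2, 2], 0)     # clipped low
  expect_equal(u$values[1, 3], 255)   # clipped high
  expect_error(hu_to_uint8(img, c(10, 10)), "window")
})

test_that("masking is exact, idempotent and shape-checked", {
  img <- uint8_image(matrix(7L, 4, 4))
  all_true <- lung_mask(matrix(TRUE, 4, 4))
  all_false <- lung_mask(matrix(FALSE, 4, 4))
  expect_identical(apply_mask(img, all_true)$values, img$values)
  expect_true(all(apply_mask(img, all_false)$values == 0))
  m <- lung_mask(matrix(c(TRUE, FALSE), 4, 4))
  once <- apply_mask(img, m)
  expect_identical(apply_mask(once, m)$values, once$values)
  expect_error(apply_mask(img, lung_mask(matrix(TRUE, 3, 3))), "mismatch")
})

test_that("lung-mask extraction covers the lungs with a bounded margin", {
  spec <- small_phantom()
  sl <- make_phantom_slice(spec)
  mask <- extract_lung_mask(binarize_lungs(sl$image, -400))
  true_area <- with(spec$left_lung_ellipse, pi * ax * ay) +
    with(spec$right_lung_ellipse, pi * ax * ay)
  ratio <- sum(mask$values) / true_area
  expect_gte(ratio, 1.0)
  expect_lte(ratio, 1.3)
  expect_equal(mask$n_components, 2)
  expect_type(mask$values[1, 1], "logical")
})

test_that("border-connected air alone yields an empty mask with a warning", {
  b <- matrix(FALSE, 20, 20)
  b[1:20, 1:3] <- TRUE  # touches the border
  expect_warning(m <- extract_lung_mask(b), "empty")
  expect_false(any(m$values))
})

test_that("mask extraction is equivariant under horizontal mirroring", {
  spec <- small_phantom(
    left_lung_ellipse = list(cx = 30, cy = 48, ax = 13, ay = 20),
    right_lung_ellipse = list(cx = 65, cy = 46, ax = 16, ay = 22))
  sl <- make_phantom_slice(spec)
  flip <- function(m) m[, ncol(m):1]
  direct <- extract_lung_mask(binarize_lungs(sl$image, -400))$values
  mirrored <- extract_lung_mask(flip(binarize_lungs(sl$image, -400)))$values
  expect_identical(mirrored, flip(direct))
})

test_that("bone removal touches only bone and its edge neighbourhood", {
  spec_nb <- small_phantom(bone_arcs = list())
  sl <- make_phantom_slice(spec_nb)
  u8 <- hu_to_uint8(sl$image)
  expect_identical(remove_bone(u8, sl$image)$values, u8$values)

  all_bone <- hu_image(matrix(700, 10, 10), 1)
  ub <- hu_to_uint8(all_bone)
  expect_true(all(remove_bone(ub, all_bone)$values == 0))

  # an arc on the lower body rim, well clear of the lung mask and its margin
  spec <- small_phantom(bone_arcs = list(
    list(r_inner = 0.93, r_outer = 0.99, theta = c(60, 120))))
  slb <- make_phantom_slice(spec)
  mask <- extract_lung_mask(binarize_lungs(slb$image, -400))
  masked <- apply_mask(hu_to_uint8(slb$image), mask)
  cleaned <- remove_bone(masked, slb$image)
  expect_identical(cleaned$values[mask$values], masked$values[mask$values])
})

test_that("the composed pipeline keeps nodules inside the mask and is deterministic", {
  spec <- small_phantom()
  nod <- centered_nodule(spec, 8)
  sl <- make_phantom_slice(spec, nod)
  a <- preprocess_slice(sl$image)
  b <- preprocess_slice(sl$image)
  expect_identical(a$image$values, b$image$values)
  gt <- sl$gt_boxes
  sub <- a$mask$values[(gt$y_min + 1):gt$y_max, (gt$x_min + 1):gt$x_max]
  expect_true(all(sub))
  expect_true(all(a$image$values[!a$mask$values] == 0))
})

test_that("the composed pipeline is flip-equivariant on phantoms", {
  spec <- small_phantom()
  sl <- make_phantom_slice(spec, centered_nodule(spec, 6))
  flip <- function(m) m[, ncol(m):1]
  direct <- preprocess_slice(sl$image)
  flipped <- preprocess_slice(hu_image(flip(sl$image$values), sl$image$spacing))
  expect_identical(flipped$image$values, flip(direct$image$values))
  expect_identical(flipped$mask$values, flip(direct$mask$values))
})

test_that("masking properties hold on random binary masks", {
  withr::with_seed(9, {
    for (i in 1:20) {
      img <- uint8_image(matrix(sample(0:255, 64, TRUE), 8, 8))
      m <- lung_mask(matrix(sample(c(TRUE, FALSE), 64, TRUE), 8, 8))
      once <- apply_mask(img, m)
      expect_identical(apply_mask(once, m)$values, once$values)
      expect_true(all(once$values[!m$values] == 0))
    }
  })
})
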