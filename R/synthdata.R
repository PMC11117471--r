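#' Specify a CT phantom slice
#'
#' Describes a simple thorax-like phantom: an elliptical body of soft tissue
#' on an air background, two elliptical air-filled lungs, and optional rib-like
#' bone arcs along the body boundary. Compartments carry fixed Hounsfield
#' values chosen to respect the real ordering air < lung < soft tissue < bone,
#' which is all the downstream HU-threshold preprocessing relies on. The
#' default geometry mimics a 512 x 512 thorax slice at 0.7 mm/px.
#'
#' @param image_size Pixels per side of the square slice.
#' @param spacing Pixel spacing, mm per pixel.
#' @param body_ellipse,left_lung_ellipse,right_lung_ellipse Named lists with
#'   `cx`, `cy`, `ax`, `ay` (centre and semi-axes, pixels). Defaults scale
#'   with `image_size`.
#' @param hu_levels Named list of compartment HU values: `background_air`,
#'   `lung_air`, `soft_tissue`, `bone`.
#' @param bone_arcs List of arc descriptors, each a named list with
#'   `r_inner`, `r_outer` (fractions of the body semi-axes) and
#'   `theta` (length-2 angle range in degrees, measured from the body centre).
#' @param noise_sd Additive Gaussian noise, HU standard deviation. Off (0) by
#'   default so threshold-based tests are exact.
#' @param seed Integer seed used for the noise draw.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = 512,
                         spacing = 0.7,
                         body_ellipse = NULL,
                         left_lung_ellipse = NULL,
                         right_lung_ellipse = NULL,
                         hu_levels = list(background_air = -1000,
                                          lung_air = -850,
                                          soft_tissue = 40,
                                          bone = 700),
                         bone_arcs = NULL,
                         noise_sd = 0,
                         seed = 1L) {
  n <- image_size
  if (is.null(body_ellipse)) {
    body_ellipse <- list(cx = 0.50 * n, cy = 0.52 * n, ax = 0.42 * n, ay = 0.36 * n)
  }
  if (is.null(left_lung_ellipse)) {
    left_lung_ellipse <- list(cx = 0.335 * n, cy = 0.50 * n, ax = 0.15 * n, ay = 0.225 * n)
  }
  if (is.null(right_lung_ellipse)) {
    right_lung_ellipse <- list(cx = 0.665 * n, cy = 0.50 * n, ax = 0.15 * n, ay = 0.225 * n)
  }
  if (is.null(bone_arcs)) {
    bone_arcs <- list(
      list(r_inner = 0.93, r_outer = 0.99, theta = c(200, 340)),
      list(r_inner = 0.93, r_outer = 0.99, theta = c(20, 160))
    )
  }
  spec <- structure(
    list(image_size = as.integer(image_size), spacing = spacing,
         body_ellipse = body_ellipse,
         left_lung_ellipse = left_lung_ellipse,
         right_lung_ellipse = right_lung_ellipse,
         hu_levels = hu_levels, bone_arcs = bone_arcs,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  hu <- spec$hu_levels
  if (!(hu$background_air <= hu$lung_air && hu$lung_air < hu$soft_tissue &&
        hu$soft_tissue < hu$bone)) {
    rlang::abort("hu_levels must satisfy background_air <= lung_air < soft_tissue < bone")
  }
  if (spec$spacing <= 0) rlang::abort("spacing must be > 0")
  # lungs strictly inside the body: test boundary samples of each lung ellipse
  th <- seq(0, 2 * pi, length.out = 64)
  inside_body <- function(e) {
    px <- e$cx + e$ax * cos(th); py <- e$cy + e$ay * sin(th)
    b <- spec$body_ellipse
    all(((px - b$cx) / b$ax)^2 + ((py - b$cy) / b$ay)^2 < 1)
  }
  if (!inside_body(spec$left_lung_ellipse) || !inside_body(spec$right_lung_ellipse)) {
    rlang::abort("lung ellipses must lie strictly inside the body ellipse")
  }
  spec
}

# TRUE where pixel centres fall inside the ellipse
ellipse_mask <- function(n, e) {
  x <- matrix(rep(seq_len(n) - 0.5, each = n), nrow = n)   # column index - 0.5
  y <- matrix(rep(seq_len(n) - 0.5, times = n), nrow = n)  # row index - 0.5
  ((x - e$cx) / e$ax)^2 + ((y - e$cy) / e$ay)^2 <= 1
}

#' Tibble of nodules to insert into a phantom
#'
#' Positions are world millimetres (origin at the volume corner, axes aligned
#' with pixel indices); diameters are millimetres and must be >= 3 mm, the
#' conventional lower bound for annotated pulmonary nodules.
#'
#' @param x_mm,y_mm Nodule centre coordinates, mm.
#' @param diameter_mm Nodule diameters, mm (>= 3).
#' @param intensity Nodule HU value(s); recycled. Default -50 HU, a
#'   soft-tissue-like density well above lung air.
#' @return A tibble with one row per nodule.
#' @export
nodule_spec <- function(x_mm = numeric(), y_mm = numeric(),
                        diameter_mm = numeric(), intensity = -50) {
  out <- tibble::tibble(x_mm = as.numeric(x_mm), y_mm = as.numeric(y_mm),
                        diameter_mm = as.numeric(diameter_mm),
                        intensity = rep_len(as.numeric(intensity),
                                            length(x_mm)))
  if (nrow(out) > 0 && any(out$diameter_mm < 3)) {
    rlang::abort("nodule diameters must be >= 3 mm")
  }
  out
}

# analytic tight pixel box of a disk given continuous centre (px) and radius
nodule_box_px <- function(cx_px, cy_px, r_px) {
  boxes(floor(cx_px - r_px), floor(cy_px - r_px),
        ceiling(cx_px + r_px), ceiling(cy_px + r_px))
}

#' Rasterize a phantom slice with inserted nodules
#'
#' Paints the compartments in HU, rasterizes each nodule as a disk (a pixel
#' belongs to the disk when its centre lies within the nodule radius), and
#' returns the slice plus the ground-truth pixel bounding box of every nodule.
#' Each nodule disk must lie entirely within a lung ellipse; a nodule that
#' does not is rejected with an error naming its row.
#'
#' @param spec A [phantom_spec()].
#' @param nodules A [nodule_spec()] tibble (possibly empty).
#' @return A list: `image` ([hu_image()]), `gt_boxes` (box tibble, one row per
#'   nodule), `nodules` (input tibble augmented with pixel-centre columns).
#' @export
make_phantom_slice <- function(spec, nodules = nodule_spec()) {
  spec <- validate_phantom_spec(spec)
  n <- spec$image_size
  hu <- spec$hu_levels
  img <- matrix(hu$background_air, n, n)
  body <- ellipse_mask(n, spec$body_ellipse)
  img[body] <- hu$soft_tissue
  lungL <- ellipse_mask(n, spec$left_lung_ellipse)
  lungR <- ellipse_mask(n, spec$right_lung_ellipse)
  img[lungL | lungR] <- hu$lung_air

  b <- spec$body_ellipse
  if (length(spec$bone_arcs) > 0) {
    x <- matrix(rep(seq_len(n) - 0.5, each = n), nrow = n)
    y <- matrix(rep(seq_len(n) - 0.5, times = n), nrow = n)
    rr <- sqrt(((x - b$cx) / b$ax)^2 + ((y - b$cy) / b$ay)^2)
    ang <- (atan2(y - b$cy, x - b$cx) * 180 / pi) %% 360
    for (arc in spec$bone_arcs) {
      th <- arc$theta %% 360
      in_theta <- if (th[1] <= th[2]) ang >= th[1] & ang <= th[2] else
        ang >= th[1] | ang <= th[2]
      sel <- rr >= arc$r_inner & rr <= arc$r_outer & in_theta & body & !(lungL | lungR)
      img[sel] <- hu$bone
    }
  }

  gt <- boxes()
  if (nrow(nodules) > 0) {
    x <- matrix(rep(seq_len(n) - 0.5, each = n), nrow = n)
    y <- matrix(rep(seq_len(n) - 0.5, times = n), nrow = n)
    for (i in seq_len(nrow(nodules))) {
      cx <- nodules$x_mm[i] / spec$spacing
      cy <- nodules$y_mm[i] / spec$spacing
      r <- nodules$diameter_mm[i] / (2 * spec$spacing)
      disk <- (x - cx)^2 + (y - cy)^2 <= r^2
      if (!any(disk)) {
        rlang::abort(sprintf("nodule %d is smaller than one pixel at this spacing", i))
      }
      if (!(all(lungL[disk]) || all(lungR[disk]))) {
        rlang::abort(sprintf(
          "nodule %d (%.1f mm at %.1f, %.1f mm) does not lie fully inside a lung",
          i, nodules$diameter_mm[i], nodules$x_mm[i], nodules$y_mm[i]))
      }
      img[disk] <- nodules$intensity[i]
      gt <- dplyr::bind_rows(gt, nodule_box_px(cx, cy, r))
    }
  }

  if (spec$noise_sd > 0) {
    img <- img + withr::with_seed(spec$seed,
      matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n))
  }
  nodules$cx_px <- nodules$x_mm / spec$spacing
  nodules$cy_px <- nodules$y_mm / spec$spacing
  list(image = hu_image(img, spec$spacing), gt_boxes = gt, nodules = nodules)
}

#' Sample random nodules that fit inside the phantom's lungs
#'
#' Draws centres uniformly inside a lung ellipse shrunk by the nodule radius,
#' so every drawn nodule satisfies the containment invariant by construction.
#'
#' @param spec A [phantom_spec()].
#' @param n Number of nodules.
#' @param diameter_range Length-2 mm range to draw diameters from (uniform).
#' @param intensity Nodule HU value.
#' @param seed Integer seed.
#' @return A [nodule_spec()] tibble.
#' @export
sample_nodules <- function(spec, n, diameter_range = c(4, 16),
                           intensity = -50, seed = 1L) {
  stopifnot(diameter_range[1] >= 3)
  withr::with_seed(seed, {
    d <- stats::runif(n, diameter_range[1], diameter_range[2])
    side <- sample(c("L", "R"), n, replace = TRUE)
    xs <- ys <- numeric(n)
    for (i in seq_len(n)) {
      e <- if (side[i] == "L") spec$left_lung_ellipse else spec$right_lung_ellipse
      r_px <- d[i] / (2 * spec$spacing)
      # shrink semi-axes by the radius plus a 1-px raster guard
      ax <- e$ax - r_px - 1; ay <- e$ay - r_px - 1
      if (ax <= 0 || ay <= 0) rlang::abort("nodule too large for the lung ellipse")
      repeat {
        u <- stats::runif(1, -1, 1); v <- stats::runif(1, -1, 1)
        if (u^2 + v^2 <= 1) break
      }
      xs[i] <- (e$cx + ax * u) * spec$spacing
      ys[i] <- (e$cy + ay * v) * spec$spacing
    }
    nodule_spec(xs, ys, d, intensity)
  })
}

#' Sample a synthetic bounding-box population from a log-normal mixture
#'
#' Produces width/height pairs for anchor-clustering experiments. Each mixture
#' component is an independent log-normal in width and height with a shared
#' log-scale standard deviation.
#'
#' @param n Number of boxes (>= 1).
#' @param components A data frame with columns `mean_log_w`, `mean_log_h`,
#'   `log_sd`, `weight` (weights must sum to 1).
#' @param seed Integer seed.
#' @return A tibble with columns `width`, `height`, `component`.
#' @export
sample_nodule_boxes <- function(n, components, seed = 1L) {
  if (length(n) != 1 || n < 1) rlang::abort("n must be a positive count")
  components <- tibble::as_tibble(components)
  need <- c("mean_log_w", "mean_log_h", "log_sd", "weight")
  if (!all(need %in% names(components))) {
    rlang::abort(paste0("components needs columns: ", paste(need, collapse = ", ")))
  }
  if (abs(sum(components$weight) - 1) > 1e-8) {
    rlang::abort("component weights must sum to 1")
  }
  withr::with_seed(seed, {
    comp <- sample.int(nrow(components), n, replace = TRUE,
                       prob = components$weight)
    w <- stats::rlnorm(n, components$mean_log_w[comp], components$log_sd[comp])
    h <- stats::rlnorm(n, components$mean_log_h[comp], components$log_sd[comp])
    out <- box_wh(w, h)
    out$component <- comp
    out
  })
}

#' Write a phantom dataset to disk
#'
#' Writes one MetaImage volume (`<name>.mhd` + `<name>.raw`) holding the
#' slices, an annotation CSV in the standard nodule-archive dialect
#' (`seriesuid, coordX, coordY, coordZ, diameter_mm`, world millimetres), and
#' a JSON manifest recording the seed and geometry.
#'
#' @param slices List of [hu_image()] slices.
#' @param nodules Tibble with columns `slice` (0-based slice index), `x_mm`,
#'   `y_mm`, `diameter_mm` (one row per nodule; may be empty).
#' @param dir Output directory (created if needed).
#' @param name Series name, used for file names and `seriesuid`.
#' @param slice_thickness Out-of-plane spacing in mm; defaults to in-plane.
#' @param manifest Optional named list merged into the manifest JSON.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(slices, nodules, dir, name = "phantom",
                          slice_thickness = NULL, manifest = list()) {
  if (nrow(nodules) > 0 &&
      !all(c("slice", "x_mm", "y_mm", "diameter_mm") %in% names(nodules))) {
    rlang::abort("nodules needs columns slice, x_mm, y_mm, diameter_mm")
  }
  if (nrow(nodules) > 0 && length(slices) == 0) {
    rlang::abort("annotations refer to slices but no slices were given")
  }
  if (nrow(nodules) > 0 && max(nodules$slice) >= length(slices)) {
    rlang::abort("annotation slice index exceeds the number of slices")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- tibble::tibble(seriesuid = character(), coordX = numeric(),
                        coordY = numeric(), coordZ = numeric(),
                        diameter_mm = numeric())
  if (length(slices) > 0) {
    sp <- slices[[1]]$spacing
    if (is.null(slice_thickness)) slice_thickness <- sp
    write_mhd(slices, file.path(dir, paste0(name, ".mhd")), slice_thickness)
    if (nrow(nodules) > 0) {
      ann <- tibble::tibble(
        seriesuid = name,
        coordX = nodules$x_mm, coordY = nodules$y_mm,
        coordZ = (nodules$slice + 0.5) * slice_thickness,
        diameter_mm = nodules$diameter_mm)
    }
  }
  utils::write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE)
  manifest <- c(list(name = name, n_slices = length(slices),
                     n_nodules = nrow(ann)), manifest)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @param name Series name.
#' @return A list: `slices` (list of [hu_image()]), `annotations` (the CSV as
#'   a tibble with an added 0-based `slice` column), `gt_boxes` (list, per
#'   slice, of ground-truth box tibbles reconstructed from the annotations),
#'   `spacing`, `slice_thickness`.
#' @export
read_dataset <- function(dir, name = "phantom") {
  ann <- tibble::as_tibble(utils::read.csv(file.path(dir, "annotations.csv")))
  mhd <- file.path(dir, paste0(name, ".mhd"))
  if (!file.exists(mhd)) {
    return(list(slices = list(), annotations = ann, gt_boxes = list(),
                spacing = NA_real_, slice_thickness = NA_real_))
  }
  vol <- read_mhd(mhd)
  ann$slice <- if (nrow(ann) > 0)
    as.integer(floor(ann$coordZ / vol$slice_thickness)) else integer()
  gt <- lapply(seq_along(vol$slices) - 1L, function(z) {
    rows <- ann[ann$slice == z, , drop = FALSE]
    if (nrow(rows) == 0) return(boxes())
    nodule_box_px(rows$coordX / vol$spacing, rows$coordY / vol$spacing,
                  rows$diameter_mm / (2 * vol$spacing))
  })
  list(slices = vol$slices, annotations = ann, gt_boxes = gt,
       spacing = vol$spacing, slice_thickness = vol$slice_thickness)
}
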