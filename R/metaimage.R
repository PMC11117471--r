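#' Write a stack of slices as a MetaImage volume
#'
#' Writes the uncompressed MetaImage dialect used by public lung-CT archives:
#' a plain-text `.mhd` header (DimSize, ElementSpacing, Offset, ElementType,
#' ElementDataFile) next to a little-endian `.raw` voxel file, x fastest,
#' then y, then z. The world origin sits at the volume corner and world axes
#' are aligned with the array indices, so pixel `(x, y)` on slice `z` has
#' world position `((x + 0.5) * spacing, (y + 0.5) * spacing,
#' (z + 0.5) * slice_thickness)` mm at the voxel centre.
#'
#' @param slices A list of [hu_image()] slices with equal shape and spacing.
#' @param path Output `.mhd` path; the `.raw` file is written next to it.
#' @param slice_thickness Out-of-plane spacing in mm; defaults to the
#'   in-plane spacing.
#' @return `path`, invisibly.
#' @export
write_mhd <- function(slices, path, slice_thickness = NULL) {
  stopifnot(length(slices) >= 1)
  shp <- dim(slices[[1]]$values)
  sp <- slices[[1]]$spacing
  ok <- vapply(slices, function(s) {
    inherits(s, "hu_image") && identical(dim(s$values), shp) &&
      isTRUE(all.equal(s$spacing, sp))
  }, logical(1))
  if (!all(ok)) rlang::abort("all slices must be hu_image of equal shape and spacing")
  if (is.null(slice_thickness)) slice_thickness <- sp

  vals <- unlist(lapply(slices, function(s) as.vector(t(s$values))),
                 use.names = FALSE)
  integral <- all(vals == round(vals)) && all(abs(vals) < 32768)
  etype <- if (integral) "MET_SHORT" else "MET_DOUBLE"

  raw_path <- sub("\\.mhd$", ".raw", path)
  if (identical(raw_path, path)) raw_path <- paste0(path, ".raw")
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    "Offset = 0 0 0",
    sprintf("ElementSpacing = %.17g %.17g %.17g", sp, sp, slice_thickness),
    sprintf("DimSize = %d %d %d", shp[2], shp[1], length(slices)),
    sprintf("ElementType = %s", etype),
    sprintf("ElementDataFile = %s", basename(raw_path))
  )
  writeLines(header, path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  if (integral) {
    writeBin(as.integer(round(vals)), con, size = 2, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read a MetaImage volume into a list of HU slices
#'
#' Supports the subset written by [write_mhd()]: uncompressed local raw data,
#' MET_SHORT / MET_UCHAR / MET_FLOAT / MET_DOUBLE element types, little-endian.
#'
#' @param path Path to a `.mhd` header.
#' @return A list with elements `slices` (list of [hu_image()]),
#'   `spacing` (in-plane, mm) and `slice_thickness` (mm).
#' @export
read_mhd <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " = "), character(1))
  get <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  if (!identical(get("CompressedData", "False"), "False")) {
    rlang::abort("compressed MetaImage data is not supported")
  }
  if (!identical(get("BinaryDataByteOrderMSB", "False"), "False")) {
    rlang::abort("big-endian MetaImage data is not supported")
  }
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spac <- as.numeric(strsplit(get("ElementSpacing", "1 1 1"), "\\s+")[[1]])
  etype <- get("ElementType")
  nvox <- prod(dims)
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- switch(etype,
    MET_SHORT  = readBin(con, "integer", nvox, size = 2, signed = TRUE,
                         endian = "little"),
    MET_UCHAR  = readBin(con, "integer", nvox, size = 1, signed = FALSE,
                         endian = "little"),
    MET_FLOAT  = readBin(con, "double", nvox, size = 4, endian = "little"),
    MET_DOUBLE = readBin(con, "double", nvox, size = 8, endian = "little"),
    rlang::abort(paste0("unsupported ElementType: ", etype))
  )
  if (length(v) != nvox) rlang::abort("raw file shorter than DimSize promises")
  nx <- dims[1]; ny <- dims[2]; nz <- if (length(dims) >= 3) dims[3] else 1L
  slices <- lapply(seq_len(nz), function(z) {
    off <- (z - 1) * nx * ny
    m <- matrix(as.numeric(v[off + seq_len(nx * ny)]), nrow = ny, ncol = nx,
                byrow = TRUE)
    hu_image(m, spac[1])
  })
  list(slices = slices, spacing = spac[1],
       slice_thickness = if (length(spac) >= 3) spac[3] else spac[1])
}
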