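#' 3-D voxel grid
#'
#' The basic data carrier of the package: a 3-D array of scalars together
#' with its geometry (isotropic or anisotropic voxel spacing in mm and the
#' physical position of the centre of voxel `[1,1,1]`) and a role tag that
#' records what the values mean. Voxel index `(i,j,k)` (1-based in R) maps
#' to the physical point `origin + (i-1, j-1, k-1) * spacing` (mm).
#'
#' @param values numeric 3-D array.
#' @param spacing per-axis voxel size in mm (length 1 or 3, all > 0).
#' @param origin physical position (mm) of the centre of the first voxel.
#' @param role one of `"HU"`, `"density"`, `"activity"`, `"tia"`, `"dose"`,
#'   `"dose_per_primary"`, `"uncertainty"`, `"counts"`, `"label"`,
#'   `"mask"`, `"other"`. Non-negativity is enforced for the physical
#'   quantities that cannot be negative (density, activity, TIA, dose,
#'   uncertainty).
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       role = "other") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  if (any(dim(values) < 1L)) stop("all three dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have length 3")
  role <- match.arg(role, c("HU", "density", "activity", "tia", "dose",
                            "dose_per_primary", "uncertainty", "counts",
                            "label", "mask", "other"))
  nonneg <- c("density", "activity", "tia", "dose", "dose_per_primary",
              "uncertainty", "counts")
  if (role %in% nonneg && any(values < 0, na.rm = TRUE))
    stop(sprintf("a grid with role '%s' must be non-negative everywhere", role))
  structure(list(values = values, spacing = spacing, origin = origin,
                 role = role),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid [%s]> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              x$role, d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  values in [%g, %g], sum %g\n",
              min(x$values), max(x$values), sum(x$values)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

#' Test whether two grids live on the same lattice
#'
#' Two grids are aligned iff dimensions, spacing and origin agree exactly
#' (spacing and origin to a 1e-9 mm tolerance). Every cross-grid operation
#' in the package requires alignment.
#'
#' @param a,b `voxel_grid` objects.
#' @export
grids_aligned <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < 1e-9) &&
    all(abs(a$origin - b$origin) < 1e-9)
}

stop_unless_aligned <- function(a, b, what = "grids") {
  if (!grids_aligned(a, b))
    stop(sprintf("%s must be aligned (same dims, spacing and origin)", what))
  invisible(TRUE)
}

#' Derive a grid on the same lattice with new values
#' @param grid a `voxel_grid` providing the geometry.
#' @param values replacement array (same dims).
#' @param role role tag of the result.
#' @export
grid_like <- function(grid, values, role = grid$role) {
  if (!identical(dim(values), dim(grid$values)))
    stop("replacement values must have the parent grid's dimensions")
  voxel_grid(values, grid$spacing, grid$origin, role)
}

## ---- material table and HU conversions -------------------------------------

#' Piecewise-linear HU-to-density table with material bins
#'
#' Anchors of a piecewise-linear Hounsfield-unit to mass-density curve plus
#' HU intervals for a coarse 4-material segmentation (air / lung /
#' soft tissue / bone). The bundled default reproduces the densities a
#' stylised Schneider-type conversion relies on (air 0.00121, lung ~0.26,
#' soft tissue 1.00, liver-like 1.06, bone up to 1.90 g/cm3).
#'
#' @param hu numeric vector of HU breakpoints, strictly increasing.
#' @param density matching densities in g/cm3, non-decreasing.
#' @return a `material_table` object.
#' @export
material_table <- function(hu = c(-1000, -740, -98, 0, 60, 400, 1500),
                           density = c(0.00121, 0.26, 0.93, 1.000, 1.06,
                                       1.25, 1.90)) {
  hu <- as.numeric(hu); density <- as.numeric(density)
  if (length(hu) == 0L) stop("empty material table")
  if (length(hu) != length(density)) stop("hu and density lengths differ")
  if (any(diff(hu) <= 0)) stop("HU breakpoints must be strictly increasing")
  if (any(diff(density) < 0)) stop("densities must be non-decreasing with HU")
  structure(list(hu = hu, density = density,
                 # material bins: [lower, upper) in HU
                 bins = data.frame(
                   material = c("air", "lung", "soft_tissue", "bone"),
                   lower = c(-Inf, -950, -200, 200),
                   upper = c(-950, -200, 200, Inf))),
            class = "material_table")
}

#' Convert a CT in Hounsfield units to a mass-density grid
#'
#' Piecewise-linear interpolation between the table anchors, clamped at the
#' extreme anchors. Monotone non-decreasing in HU by construction.
#'
#' @param ct `voxel_grid` with role `"HU"`.
#' @param table a [material_table()].
#' @return `voxel_grid` with role `"density"` (g/cm3), aligned with `ct`.
#' @export
hu_to_density <- function(ct, table = material_table()) {
  if (!is_voxel_grid(ct) || ct$role != "HU") stop("`ct` must have role 'HU'")
  if (!inherits(table, "material_table")) stop("`table` must be a material_table")
  rho <- stats::approx(table$hu, table$density, xout = as.vector(ct$values),
                       rule = 2)$y
  grid_like(ct, array(rho, dim(ct$values)), role = "density")
}

#' Assign a coarse material id to each CT voxel
#'
#' Bins HU into air / lung / soft tissue / bone using the table's bin
#' boundaries (air below -950 HU, lung -950..-200, soft tissue -200..200,
#' bone above 200).
#'
#' @inheritParams hu_to_density
#' @return `voxel_grid` with role `"label"`; integer codes with a
#'   `materials` attribute naming them.
#' @export
hu_to_material <- function(ct, table = material_table()) {
  if (!is_voxel_grid(ct) || ct$role != "HU") stop("`ct` must have role 'HU'")
  b <- table$bins
  id <- array(0L, dim(ct$values))
  for (m in seq_len(nrow(b)))
    id[ct$values >= b$lower[m] & ct$values < b$upper[m]] <- m
  out <- grid_like(ct, id, role = "label")
  attr(out, "materials") <- b$material
  out
}

## ---- padding ---------------------------------------------------------------

#' Zero-pad a grid so an integer number of patches fits
#'
#' Pads each axis up to the next multiple of `stride` (padding goes on the
#' high-index side) and then adds `extra_per_face` symmetric zero voxels on
#' every face. The returned record inverts the operation exactly via
#' [crop_back()]. The grid origin is shifted so voxel centres of the
#' original volume keep their physical positions.
#'
#' @param grid a `voxel_grid`.
#' @param stride patch edge in voxels (>= 1); may be per-axis (length 3).
#' @param extra_per_face symmetric halo width in voxels (>= 0).
#' @return list with elements `grid` (padded) and `record` (a
#'   `padding_record`: `low`, `high`, `original_dim`).
#' @export
zero_pad <- function(grid, stride, extra_per_face = 0L) {
  stride <- as.integer(stride)
  if (length(stride) == 1L) stride <- rep(stride, 3L)
  if (any(stride < 1L)) stop("`stride` must be >= 1")
  extra <- as.integer(extra_per_face)
  if (length(extra) == 1L) extra <- rep(extra, 3L)
  if (any(extra < 0L)) stop("`extra_per_face` must be >= 0")
  d <- dim(grid$values)
  core <- stride * as.integer(ceiling(d / stride))
  low <- extra
  high <- (core - d) + extra
  out <- array(0, core + 2L * extra)
  out[low[1] + seq_len(d[1]), low[2] + seq_len(d[2]), low[3] + seq_len(d[3])] <-
    grid$values
  record <- structure(list(low = low, high = high, original_dim = d),
                      class = "padding_record")
  padded <- voxel_grid(out, grid$spacing, grid$origin - low * grid$spacing,
                       grid$role)
  list(grid = padded, record = record)
}

#' Invert [zero_pad()]
#' @param grid the padded `voxel_grid`.
#' @param record the `padding_record` returned by [zero_pad()].
#' @export
crop_back <- function(grid, record) {
  if (!inherits(record, "padding_record")) stop("`record` is not a padding_record")
  d <- record$original_dim
  if (!identical(dim(grid$values), d + record$low + record$high))
    stop("grid dimensions do not match the padding record")
  vals <- grid$values[record$low[1] + seq_len(d[1]),
                      record$low[2] + seq_len(d[2]),
                      record$low[3] + seq_len(d[3]), drop = FALSE]
  voxel_grid(vals, grid$spacing, grid$origin + record$low * grid$spacing,
             grid$role)
}

## ---- resampling ------------------------------------------------------------

#' Resample a grid onto a target geometry
#'
#' Maps each target voxel centre into the source grid and interpolates:
#' trilinear for continuous volumes, nearest-neighbour for labels/masks.
#' Target centres outside the source support are filled with `fill`
#' (default -1000 for HU, i.e. air outside the scanned field of view, and 0
#' otherwise).
#'
#' @param grid source `voxel_grid`.
#' @param dims integer target dimensions (length 3).
#' @param spacing target voxel size mm (length 1 or 3).
#' @param origin target origin mm (length 3).
#' @param mode `"linear"` or `"nearest"`.
#' @param fill out-of-support fill value.
#' @export
resample_to <- function(grid, dims, spacing, origin = grid$origin,
                        mode = c("linear", "nearest"),
                        fill = if (grid$role == "HU") -1000 else 0) {
  mode <- match.arg(mode)
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) stop("degenerate target dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("target spacing must be > 0")
  d <- dim(grid$values)
  # continuous source index (0-based) of each target centre, per axis
  ax_idx <- lapply(1:3, function(a) {
    centers <- origin[a] + (seq_len(dims[a]) - 1) * spacing[a]
    (centers - grid$origin[a]) / grid$spacing[a]
  })
  if (mode == "nearest") {
    near <- lapply(1:3, function(a) as.integer(round(ax_idx[[a]])) + 1L)
    ok <- lapply(1:3, function(a) near[[a]] >= 1L & near[[a]] <= d[a])
    ia <- pmin(pmax(near[[1]], 1L), d[1]); ja <- pmin(pmax(near[[2]], 1L), d[2])
    ka <- pmin(pmax(near[[3]], 1L), d[3])
    out <- grid$values[ia, ja, ka, drop = FALSE]
    dim(out) <- dims
    bad <- outer(outer(!ok[[1]], !ok[[2]], "|"), !ok[[3]], "|")
    out[bad] <- fill
  } else {
    lo <- lapply(ax_idx, floor)
    fr <- lapply(1:3, function(a) ax_idx[[a]] - lo[[a]])
    lo <- lapply(lo, as.integer)
    inb <- lapply(1:3, function(a) ax_idx[[a]] >= 0 & ax_idx[[a]] <= d[a] - 1)
    i0 <- lapply(1:3, function(a) pmin(pmax(lo[[a]], 0L), d[a] - 1L))
    i1 <- lapply(1:3, function(a) pmin(i0[[a]] + 1L, d[a] - 1L))
    out <- array(0, dims)
    for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
      wi <- if (cx) fr[[1]] else 1 - fr[[1]]
      wj <- if (cy) fr[[2]] else 1 - fr[[2]]
      wk <- if (cz) fr[[3]] else 1 - fr[[3]]
      ii <- (if (cx) i1[[1]] else i0[[1]]) + 1L
      jj <- (if (cy) i1[[2]] else i0[[2]]) + 1L
      kk <- (if (cz) i1[[3]] else i0[[3]]) + 1L
      w <- outer(outer(wi, wj), wk)
      out <- out + w * grid$values[ii, jj, kk, drop = FALSE]
    }
    bad <- outer(outer(!inb[[1]], !inb[[2]], "|"), !inb[[3]], "|")
    out[bad] <- fill
  }
  voxel_grid(out, spacing, origin, grid$role)
}

## ---- NIfTI I/O -------------------------------------------------------------

#' Read a volume from NIfTI
#'
#' Spacing and origin are taken from the header; the role tag is read from
#' a `<file>.json` sidecar when present, else from `role`.
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @param role fallback role tag.
#' @export
read_volume <- function(path, role = "other") {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img)[1:3])
  spacing <- RNifti::pixdim(img)[1:3]
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  origin <- c(0, 0, 0)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$role)) role <- meta$role
    if (!is.null(meta$origin)) origin <- as.numeric(meta$origin)
  }
  voxel_grid(vals, spacing, origin, role)
}

#' Write a volume to NIfTI (+ JSON sidecar with role and origin)
#' @param grid a `voxel_grid`.
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_volume <- function(grid, path) {
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  jsonlite::write_json(list(role = grid$role, origin = grid$origin,
                            spacing = grid$spacing),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
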