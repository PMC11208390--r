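#' Specification of the SIRT-like digital patient
#'
#' All geometry in physical mm; the defaults emulate a post-therapy Y-90
#' bremsstrahlung SPECT/CT study: a 64 x 64 x 42 grid at 9.59 mm, a body
#' and liver of soft-tissue HU, low-density lungs, activity confined to
#' the treated (right) liver lobe with a 3x hot lesion, a small lung
#' shunt, multiplicative log-normal activity texture, and a 10 mm FWHM
#' Gaussian blur standing in for SPECT resolution.
#'
#' @param dims grid dimensions.
#' @param voxel_mm isotropic voxel size.
#' @param administered_gbq administered activity in GBq.
#' @param shunt_fraction fraction of activity shunted to the lungs
#'   (0..0.2).
#' @param lesion_multiplier activity multiplier inside the lesion.
#' @param lesion_radius_mm lesion sphere radius.
#' @param treated_lobe `"right"` or `"left"`.
#' @param texture_sigma log-sd of the multiplicative activity texture
#'   (0 disables it).
#' @param blur_fwhm_mm Gaussian blur FWHM applied to the activity map.
#' @param include_spine add a bone-HU spine rod.
#' @param seed integer seed for the texture.
#' @export
phantom_spec <- function(dims = c(64, 64, 42), voxel_mm = 9.59,
                         administered_gbq = 1.5, shunt_fraction = 0.05,
                         lesion_multiplier = 3, lesion_radius_mm = 25,
                         treated_lobe = c("right", "left"),
                         texture_sigma = 0.4, blur_fwhm_mm = 10,
                         include_spine = TRUE, seed = 1) {
  treated_lobe <- match.arg(treated_lobe)
  if (shunt_fraction < 0 || shunt_fraction > 0.2)
    stop("shunt_fraction must be in [0, 0.2]")
  if (administered_gbq < 0) stop("administered activity must be >= 0")
  structure(list(dims = as.integer(dims), voxel_mm = voxel_mm,
                 administered_gbq = administered_gbq,
                 shunt_fraction = shunt_fraction,
                 lesion_multiplier = lesion_multiplier,
                 lesion_radius_mm = lesion_radius_mm,
                 treated_lobe = treated_lobe,
                 texture_sigma = texture_sigma,
                 blur_fwhm_mm = blur_fwhm_mm,
                 include_spine = isTRUE(include_spine), seed = seed),
            class = "phantom_spec")
}

## voxel-centre coordinate arrays (mm) for a dims/voxel grid
.coords <- function(dims, voxel_mm) {
  lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * voxel_mm)
}

.ellipsoid <- function(dims, voxel_mm, center, semi) {
  cc <- .coords(dims, voxel_mm)
  dx <- (cc[[1]] - center[1]) / semi[1]
  dy <- (cc[[2]] - center[2]) / semi[2]
  dz <- (cc[[3]] - center[3]) / semi[3]
  outer(outer(dx^2, dy^2, "+"), dz^2, "+") <= 1
}

## separable Gaussian blur with zero boundary; kernel renormalised to sum 1
.gauss_blur <- function(values, voxel_mm, fwhm_mm) {
  if (fwhm_mm <= 0) return(values)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  half <- max(1L, ceiling(3 * sigma_vox))
  k1 <- exp(-((-half):half)^2 / (2 * sigma_vox^2))
  k1 <- k1 / sum(k1)
  k3 <- outer(outer(k1, k1), k1)
  out <- conv3_cpp(as.vector(values), as.integer(dim(values)),
                   as.vector(k3), as.integer(dim(k3)))
  array(out, dim(values))
}

#' Generate the synthetic SIRT patient
#'
#' Builds a CT (HU), an activity map (Bq, summing to the administered
#' activity before blurring; the blur clips a negligible amount of mass at
#' the grid edge, reported in the `clipped_fraction` attribute of the
#' activity grid) and a VOI label map (1 = liver, 2 = lungs, 3 = remainder
#' of body). Deterministic: the same spec and seed give bit-identical
#' output.
#'
#' @param spec a [phantom_spec()].
#' @return list with `ct`, `activity`, `vois` (`voxel_grid`s) plus organ
#'   masks (`body`, `liver`, `lungs`, `lesion`, `treated`).
#' @export
make_synthetic_patient <- function(spec = phantom_spec()) {
  d <- spec$dims; v <- spec$voxel_mm
  ext <- d * v
  ctr <- ext / 2
  body <- .ellipsoid(d, v, c(ctr[1], ctr[2], ctr[3]),
                     c(0.42, 0.33, 0.48) * ext)
  liver_c <- c(ctr[1] + 0.10 * ext[1], ctr[2] - 0.05 * ext[2],
               ctr[3] + 0.12 * ext[3])
  liver <- .ellipsoid(d, v, liver_c, c(95, 75, 70)) & body
  lung_z <- ctr[3] + 0.33 * ext[3]
  lungs <- (.ellipsoid(d, v, c(ctr[1] - 0.14 * ext[1], ctr[2], lung_z),
                       c(55, 45, 60)) |
            .ellipsoid(d, v, c(ctr[1] + 0.14 * ext[1], ctr[2], lung_z),
                       c(55, 45, 60))) & body & !liver
  if (!any(liver) || !any(lungs)) stop("organs fall outside the grid")
  ct <- array(-1000, d)
  ct[body] <- 0
  ct[lungs] <- -740
  ct[liver] <- 60
  if (spec$include_spine) {
    spine <- .ellipsoid(d, v, c(ctr[1], ctr[2] + 0.22 * ext[2], ctr[3]),
                        c(20, 20, 0.45 * ext[3])) & body
    ct[spine & !liver & !lungs] <- 400
  }
  # treated lobe: half of the liver on one side of the lobe plane
  xcoord <- .coords(d, v)[[1]]
  side_x <- if (spec$treated_lobe == "right") xcoord >= liver_c[1] - 15 else
    xcoord <= liver_c[1] + 15
  side <- array(rep(side_x, times = d[2] * d[3]), d)
  treated <- liver & side
  lesion_c <- liver_c + c(if (spec$treated_lobe == "right") 45 else -45,
                          -10, 10)
  lesion <- .ellipsoid(d, v, lesion_c, rep(spec$lesion_radius_mm, 3)) &
    treated
  act <- array(0, d)
  act[treated] <- 1
  act[lesion] <- spec$lesion_multiplier
  if (spec$texture_sigma > 0) {
    set.seed(spec$seed)
    tex <- array(exp(rnorm(prod(d), 0, spec$texture_sigma)), d)
    act <- act * tex
  }
  liver_act <- sum(act)
  total_bq <- spec$administered_gbq * 1e9
  act <- act / liver_act * (1 - spec$shunt_fraction) * total_bq
  if (spec$shunt_fraction > 0)
    act[lungs] <- spec$shunt_fraction * total_bq / sum(lungs)
  pre_blur_total <- sum(act)
  act_b <- .gauss_blur(act, v, spec$blur_fwhm_mm)
  clipped <- (pre_blur_total - sum(act_b)) / pre_blur_total
  vois <- array(0L, d)
  vois[body] <- 3L
  vois[lungs] <- 2L
  vois[liver] <- 1L
  activity <- voxel_grid(act_b, v, role = "activity")
  attr(activity, "clipped_fraction") <- clipped
  attr(activity, "pre_blur") <- act
  out <- list(ct = voxel_grid(ct, v, role = "HU"),
              activity = activity,
              vois = voxel_grid(vois, v, role = "label"),
              body = body, liver = liver, lungs = lungs,
              lesion = lesion, treated = treated, spec = spec)
  attr(out$vois, "names_map") <- c(liver = 1L, lungs = 2L, rob = 3L)
  out
}

#' Water-sphere benchmark phantom
#'
#' A voxelised water sphere of the requested mass (radius
#' `(3 m / (4 pi rho))^(1/3)`, 24.29 mm for 60 g) centred in an air box
#' with at least a 3-voxel margin, with a uniform unit TIA over the sphere
#' voxels.
#'
#' @param mass_g sphere mass in grams (> 0).
#' @param voxel_mm voxel pitch; the sphere must span at least 5 voxels.
#' @return list of `voxel_grid`s: `density` (water 1.0 / air 0.00121),
#'   `tia` (uniform over the sphere), `mask`, plus `radius_mm`.
#' @export
make_benchmark_sphere <- function(mass_g = 60, voxel_mm = 2) {
  if (mass_g <= 0) stop("mass must be > 0")
  rho_water <- 1.0
  r_mm <- (3 * mass_g / (4 * pi * rho_water))^(1 / 3) * 10
  if (2 * r_mm / voxel_mm < 5)
    stop("sphere under-resolved: fewer than 5 voxels across the diameter")
  half <- ceiling(r_mm / voxel_mm) + 3L
  n <- as.integer(2 * half + 1)
  cc <- (seq_len(n) - (half + 1)) * voxel_mm
  inside <- outer(outer(cc^2, cc^2, "+"), cc^2, "+") <= r_mm^2
  dens <- array(0.00121, c(n, n, n))
  dens[inside] <- rho_water
  tia <- array(0, c(n, n, n))
  tia[inside] <- 1
  list(density = voxel_grid(dens, voxel_mm, role = "density"),
       tia = voxel_grid(tia, voxel_mm, role = "tia"),
       mask = voxel_grid(inside + 0, voxel_mm, role = "mask"),
       radius_mm = r_mm)
}

#' Analytic toy kernel for exact mosaicking tests
#'
#' A compactly supported, centrally peaked, exactly symmetric kernel:
#' `"uniform"` is constant over the cube of the given Chebyshev
#' half-width, `"tent"` decreases linearly with Chebyshev distance from
#' the centre. Used as a deterministic linear dose engine when verifying
#' the layout-equivalence properties.
#'
#' @param half_width support half-width in voxels (>= 0; 0 gives a delta).
#' @param voxel_mm voxel size tag of the kernel.
#' @param shape `"uniform"` or `"tent"`.
#' @return a [voxel_kernel()], normalised to sum 1.
#' @export
make_toy_kernel <- function(half_width, voxel_mm = 9.59,
                            shape = c("uniform", "tent")) {
  shape <- match.arg(shape)
  half_width <- as.integer(half_width)
  if (half_width < 0L) stop("half_width must be >= 0")
  n <- 2L * half_width + 1L
  idx <- abs(seq_len(n) - (half_width + 1L))
  # Chebyshev distance from the centre, per voxel
  ax <- array(idx, c(n, n, n))
  ay <- aperm(array(idx, c(n, n, n)), c(2, 1, 3))
  az <- aperm(array(idx, c(n, n, n)), c(2, 3, 1))
  cheb <- pmax(ax, ay, az)
  k <- if (shape == "uniform") array(1, c(n, n, n)) else
    (half_width + 1) - cheb
  k <- k / sum(k)
  voxel_kernel(k, voxel_mm, medium = "toy",
               meta = list(shape = shape, half_width = half_width))
}
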