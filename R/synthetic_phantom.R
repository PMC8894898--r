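# Voxel-level hippocampus-like phantoms: a bent ellipsoid implicit surface,
# radially modulated by a band-limited seeded harmonic field ("fraying"),
# optionally carved by spherical cavities on the lateral body, voxelized on
# a regular grid. Atrophy scales the cross-section towards the centerline
# so the volume scales (approximately) with the atrophy factor.

#' Configuration for the hippocampus phantom generator
#'
#' @param semi_axes ellipsoid semi-axes (a, b, c) in mm; `a` is the long
#'   (antero-posterior) axis. Defaults give a volume of about 3600 mm^3.
#' @param bend dimensionless banana-bend: the centerline is displaced by
#'   `bend * b * (x/a)^2` along the second axis.
#' @param atrophy volume-atrophy factor in (0, 1]: cross-section semi-axes
#'   b and c are scaled by `sqrt(atrophy)`, so the volume scales by about
#'   `atrophy`.
#' @param fray_amplitude amplitude of the surface indentation field, in
#'   units of the implicit function (0 = smooth surface; 0.2 is marked
#'   fraying).
#' @param fray_frequency spatial frequency of the indentation field,
#'   cycles across the long axis.
#' @param n_harmonics number of random harmonics in the band-limited field.
#' @param n_cavities,cavity_radius number and radius (mm) of spherical
#'   cavities carved into the lateral body surface.
#' @param spacing voxel spacing (mm).
#' @param jitter rigid translation magnitude (mm) applied to the sampling
#'   grid, emulating re-scan repositioning.
#' @param margin empty border around the shape, mm.
#' @param seed integer seed (mandatory).
#' @return A list of class `phantomConfig`.
#' @export
phantomConfig <- function(semi_axes = c(19, 7.5, 6), bend = 0.35,
                          atrophy = 1, fray_amplitude = 0,
                          fray_frequency = 3, n_harmonics = 12L,
                          n_cavities = 0L, cavity_radius = 2.5,
                          spacing = c(1, 1, 1), jitter = 0, margin = 3,
                          seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(seed) || is.na(seed)) stop("seed is mandatory")
  if (cfg$atrophy <= 0 || cfg$atrophy > 1)
    stop("atrophy factor must be in (0, 1]")
  if (cfg$fray_amplitude < 0) stop("fray amplitude must be >= 0")
  if (any(cfg$spacing <= 0)) stop("spacing must be positive")
  class(cfg) <- "phantomConfig"
  cfg
}

# band-limited random field: sum of cosine harmonics with wave vectors of
# magnitude ~ fray_frequency cycles per long-axis length, unit variance
.fray_field <- function(X, Y, Z, cfg) {
  H <- cfg$n_harmonics
  L <- 2 * cfg$semi_axes[1]
  dir <- matrix(rnorm(3 * H), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  freq <- cfg$fray_frequency * (0.75 + 0.5 * runif(H))
  amp <- rnorm(H)
  phase <- runif(H, 0, 2 * pi)
  field <- 0
  for (h in seq_len(H)) {
    k <- 2 * pi * freq[h] / L
    field <- field + amp[h] *
      cos(k * (dir[h, 1] * X + dir[h, 2] * Y + dir[h, 3] * Z) + phase[h])
  }
  field / sqrt(sum(amp^2) / 2)
}

#' Generate a hippocampus-like binary phantom mask
#'
#' Voxelizes the implicit shape described by a [phantomConfig()]:
#' `g(p) = (x/a)^2 + ((y - bend b (x/a)^2) / (b sqrt(v)))^2 +
#' (z / (c sqrt(v)))^2 - 1 + amplitude * noise(p) <= 0`, optionally carved
#' by cavity spheres placed on the lateral body surface. Pure function of
#' the config (including its seed).
#'
#' @param config a [phantomConfig()].
#' @return A [BinaryMask-class].
#' @export
generateHippocampusMask <- function(config = phantomConfig()) {
  stopifnot(inherits(config, "phantomConfig"))
  cfg <- config
  withr::with_seed(as.integer(cfg$seed), {
    a <- cfg$semi_axes[1]
    b <- cfg$semi_axes[2] * sqrt(cfg$atrophy)
    c_ <- cfg$semi_axes[3] * sqrt(cfg$atrophy)
    m <- cfg$margin + cfg$jitter
    ext <- c(a + m,
             cfg$semi_axes[2] * (1 + abs(cfg$bend)) + m,
             cfg$semi_axes[3] + m)
    nvox <- ceiling(2 * ext / cfg$spacing) + 1
    grid <- lapply(1:3, function(ax)
      (seq_len(nvox[ax]) - 1) * cfg$spacing[ax] - ext[ax])
    off <- if (cfg$jitter > 0) {
      u <- rnorm(3); cfg$jitter * runif(1) * u / sqrt(sum(u^2))
    } else c(0, 0, 0)
    dims <- as.integer(nvox)
    X <- array(grid[[1]] - off[1], dim = dims)
    Y <- array(rep(grid[[2]] - off[2], each = dims[1]), dim = dims)
    Z <- array(rep(grid[[3]] - off[3], each = dims[1] * dims[2]), dim = dims)
    Yc <- Y - cfg$bend * cfg$semi_axes[2] * (X / a)^2
    g <- (X / a)^2 + (Yc / b)^2 + (Z / c_)^2 - 1
    if (cfg$fray_amplitude > 0)
      g <- g + cfg$fray_amplitude * .fray_field(X, Y, Z, cfg)
    inside <- g <= 0
    if (cfg$n_cavities > 0) {
      # cavities on the lateral (+y) body surface, spread along the long axis
      cx <- seq(-0.5, 0.5, length.out = cfg$n_cavities) * a
      for (ci in seq_len(cfg$n_cavities)) {
        cen <- c(cx[ci],
                 cfg$bend * cfg$semi_axes[2] * (cx[ci] / a)^2 +
                   b * sqrt(max(1 - (cx[ci] / a)^2, 0)),
                 0)
        d2 <- (X - cen[1])^2 + (Y - cen[2])^2 + (Z - cen[3])^2
        inside <- inside & (d2 > cfg$cavity_radius^2)
      }
    }
    if (!any(inside)) stop("phantom left the grid: empty mask")
    BinaryMask(inside, spacing = cfg$spacing)
  })
}

#' Generate a two-hippocampus labelled subject volume
#'
#' Places a left and a (mirrored) right phantom in one label volume under
#' the FreeSurfer aseg dialect (17 = left, 53 = right). In RAS axis order
#' the left structure sits at lower x; phantom long axes run along y
#' (antero-posterior).
#'
#' @param left,right [phantomConfig()]s for the two sides.
#' @param gap_mm centre-to-centre gap between the structures along x.
#' @return List with `volume` (a [LabelVolume-class]) and `truth` (the two
#'   configs plus per-side planted atrophy/fraying).
#' @export
generateLabelledSubject <- function(left = phantomConfig(seed = 1L),
                                    right = phantomConfig(seed = 2L),
                                    gap_mm = 14) {
  ml <- generateHippocampusMask(left)
  mr <- generateHippocampusMask(right)
  if (!isTRUE(all.equal(left$spacing, right$spacing)))
    stop("left/right phantoms must share voxel spacing")
  # phantom axes (long, lateral, vertical) -> volume axes (x = left/right,
  # y = antero-posterior, z = inferior/superior): long axis becomes y
  al <- aperm(ml@mask, c(2, 1, 3))
  ar <- aperm(mr@mask, c(2, 1, 3))
  ar <- ar[rev(seq_len(dim(ar)[1])), , , drop = FALSE]  # mirror in x
  gap_vox <- max(ceiling(gap_mm / left$spacing[2]), 1)
  nx <- dim(al)[1] + dim(ar)[1] + gap_vox
  ny <- max(dim(al)[2], dim(ar)[2])
  nz <- max(dim(al)[3], dim(ar)[3])
  lab <- array(0L, dim = c(nx, ny, nz))
  ins <- function(lab, m, x0, id) {
    d <- dim(m)
    sub <- lab[x0 + seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
    if (any(sub[m] != 0L)) stop("structures overlap")
    sub[m] <- id
    lab[x0 + seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- sub
    lab
  }
  lab <- ins(lab, al, 0L, 17L)
  lab <- ins(lab, ar, dim(al)[1] + gap_vox, 53L)
  spacing <- c(left$spacing[2], left$spacing[1], left$spacing[3])
  list(volume = LabelVolume(lab, spacing = spacing, orientation = "RAS"),
       truth = list(left = left, right = right,
                    planted = data.frame(
                      side = c("left", "right"),
                      atrophy = c(left$atrophy, right$atrophy),
                      fray_amplitude = c(left$fray_amplitude,
                                         right$fray_amplitude))))
}
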