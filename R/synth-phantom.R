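# Seeded generators for imaging phantoms with voxel-exact ground truth.
# Ground truth always refers to the pre-blur, pre-noise masks.

# evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of an engulfment phantom
#'
#' Describes a synthetic 3-channel volume emulating microglia with internal
#' lysosome compartments and fiber fragments, a controlled fraction of which
#' is placed inside lysosomes (the known ground-truth engulfed material).
#' Microglia are spheres, lysosomes are concentric spheres whose volume is a
#' stated fraction of the cell volume, and fiber fragments are short
#' axis-aligned cylinders, clipped to the lysosome for engulfed fragments
#' and placed clear of all microglia otherwise.
#'
#' @param grid_shape voxels per axis `(z, y, x)`.
#' @param voxel_size um per voxel `(dz, dy, dx)`.
#' @param n_microglia number of microglial cells.
#' @param lysosome_fraction fraction of each cell volume occupied by its
#'   lysosome compartment, in `[0, 1]`.
#' @param n_fiber_fragments number of fiber fragments.
#' @param engulfed_fraction fraction of fragments placed inside lysosomes,
#'   in `[0, 1]`.
#' @param blur_sigma isotropic Gaussian blur, um (0 = none).
#' @param noise_sd additive Gaussian noise SD in intensity units (foreground
#'   amplitude is 200); clipped at 0.
#' @param seed integer RNG seed.
#' @return An `engulfment_phantom_spec` list.
#' @export
engulfment_phantom_spec <- function(grid_shape = c(40L, 128L, 128L),
                                    voxel_size = c(0.5, 0.2, 0.2),
                                    n_microglia = 3L,
                                    lysosome_fraction = 0.2,
                                    n_fiber_fragments = 12L,
                                    engulfed_fraction = 0.5,
                                    blur_sigma = 0.2,
                                    noise_sd = 10,
                                    seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            length(voxel_size) == 3L, all(voxel_size > 0),
            n_microglia >= 0, n_fiber_fragments >= 0,
            lysosome_fraction >= 0, lysosome_fraction <= 1,
            engulfed_fraction >= 0, engulfed_fraction <= 1,
            blur_sigma >= 0, noise_sd >= 0)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 n_microglia = as.integer(n_microglia),
                 lysosome_fraction = lysosome_fraction,
                 n_fiber_fragments = as.integer(n_fiber_fragments),
                 engulfed_fraction = engulfed_fraction,
                 blur_sigma = blur_sigma, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "engulfment_phantom_spec")
}

# voxel linear indices of an ellipsoid: center in um, radius in um
sphere_voxels <- function(center_um, radius_um, grid, vox) {
  zi <- seq_len(grid[1]); yi <- seq_len(grid[2]); xi <- seq_len(grid[3])
  # voxel centers in um
  zc <- (zi - 0.5) * vox[1]; yc <- (yi - 0.5) * vox[2]; xc <- (xi - 0.5) * vox[3]
  # restrict to bounding box first
  zi <- zi[abs(zc - center_um[1]) <= radius_um + vox[1]]
  yi <- yi[abs(yc - center_um[2]) <= radius_um + vox[2]]
  xi <- xi[abs(xc - center_um[3]) <= radius_um + vox[3]]
  if (!length(zi) || !length(yi) || !length(xi)) return(integer(0))
  g <- expand.grid(z = zi, y = yi, x = xi)
  d2 <- ((g$z - 0.5) * vox[1] - center_um[1])^2 +
        ((g$y - 0.5) * vox[2] - center_um[2])^2 +
        ((g$x - 0.5) * vox[3] - center_um[3])^2
  keep <- d2 <= radius_um^2
  (g$x[keep] - 1L) * grid[1] * grid[2] + (g$y[keep] - 1L) * grid[1] + g$z[keep]
}

# voxel linear indices of a cylinder along `axis` (1=z,2=y,3=x)
cylinder_voxels <- function(center_um, radius_um, length_um, axis, grid, vox) {
  ctr <- lapply(1:3, function(a) (seq_len(grid[a]) - 0.5) * vox[a])
  half <- ifelse(1:3 == axis, length_um / 2, radius_um)
  idx <- lapply(1:3, function(a)
    which(abs(ctr[[a]] - center_um[a]) <= half[a] + vox[a]))
  if (any(lengths(idx) == 0L)) return(integer(0))
  g <- expand.grid(z = idx[[1]], y = idx[[2]], x = idx[[3]])
  dd <- cbind((g$z - 0.5) * vox[1] - center_um[1],
              (g$y - 0.5) * vox[2] - center_um[2],
              (g$x - 0.5) * vox[3] - center_um[3])
  ax <- abs(dd[, axis]) <= length_um / 2
  rad <- rowSums(dd[, -axis, drop = FALSE]^2) <= radius_um^2
  keep <- ax & rad
  (g$x[keep] - 1L) * grid[1] * grid[2] + (g$y[keep] - 1L) * grid[1] + g$z[keep]
}

# separable Gaussian blur; sigma in um, per-axis sigma in voxels
gaussian_blur3d <- function(arr, sigma_um, vox) {
  if (sigma_um <= 0) return(arr)
  d <- dim(arr)
  for (axis in 1:3) {
    s <- sigma_um / vox[axis]
    if (s < 1e-3) next
    n <- d[axis]
    K <- stats::dnorm(outer(seq_len(n), seq_len(n), "-"), sd = s)
    K <- K / rowSums(K)                      # renormalised (replicate edges)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    dm <- dim(a)
    a <- K %*% matrix(a, nrow = n)
    dim(a) <- dm
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Generate an engulfment phantom
#'
#' Produces a 3-channel [volume_image] (channels `microglia`, `lysosome`,
#' `fiber`, foreground amplitude 200) and voxel-exact ground truth volumes
#' computed on the pre-blur masks. Lysosome voxels are a subset of microglia
#' voxels and exactly the engulfed fragments lie inside lysosome voxels.
#' Identical spec and seed give bit-identical output.
#'
#' @param spec an [engulfment_phantom_spec].
#' @return A list with `volume` (a [volume_image]) and `truth` (list with
#'   `true_microglia_um3`, `true_lysosome_um3`, `true_engulfed_um3`).
#' @export
gen_engulfment_phantom <- function(spec) {
  stopifnot(inherits(spec, "engulfment_phantom_spec"))
  with_seed(spec$seed, {
    grid <- spec$grid_shape; vox <- spec$voxel_size
    ext <- grid * vox                        # physical extent per axis, um
    vv <- prod(vox)
    mg <- lg <- fb <- logical(prod(grid))
    r_cell <- 0.16 * min(ext)                # cell radius scales with FOV
    r_lyso <- r_cell * spec$lysosome_fraction^(1 / 3)
    centers <- vector("list", spec$n_microglia)
    if (spec$n_microglia > 0 && any(ext < 2 * r_cell))
      stop("placement error: grid too small for microglia of radius ",
           signif(r_cell, 3), " um")
    for (i in seq_len(spec$n_microglia)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        ctr <- vapply(1:3, function(a) stats::runif(1, r_cell, ext[a] - r_cell),
                      0)
        vx <- sphere_voxels(ctr, r_cell, grid, vox)
        if (length(vx) && !any(mg[vx])) {    # cells must not merge
          mg[vx] <- TRUE
          lg[sphere_voxels(ctr, r_lyso, grid, vox)] <- TRUE
          centers[[i]] <- ctr
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("placement error: could not place microglia #", i)
    }
    lg <- lg & mg                            # enforce nesting exactly
    n_eng <- round(spec$engulfed_fraction * spec$n_fiber_fragments)
    # engulfed pieces are compact cylinders kept wholly inside the lysosome
    # with a margin; at the default geometry (r_lyso ~ 2 um) they are
    # ~1.1 um in radius, well above the supported blur scale (sigma <=
    # 0.3 um), matching real engulfed fiber pieces (~1-2 um) which are
    # resolvable at confocal resolution
    eng_r <- 0.64 * r_lyso; eng_len <- r_lyso
    eng_reach <- sqrt((eng_len / 2)^2 + eng_r^2)   # farthest corner from center
    frag_r <- 0.5; frag_len <- 2.5           # free (non-engulfed) fragments
    engulfed_idx <- integer(0)
    for (i in seq_len(n_eng)) {
      if (spec$n_microglia == 0L)
        stop("placement error: engulfed fragments need >= 1 microglia")
      slack <- r_lyso - eng_reach - 0.1
      if (slack < 0)
        stop("placement error: lysosome radius ", signif(r_lyso, 3),
             " um too small to contain an engulfed fragment")
      ctr <- centers[[sample.int(spec$n_microglia, 1L)]] +
        stats::runif(3, -slack, slack) / sqrt(3)
      vx <- cylinder_voxels(ctr, eng_r, eng_len, sample.int(3, 1L),
                            grid, vox)
      vx <- vx[lg[vx]]                       # guaranteed subset; keep exact
      if (length(vx) < 8L)
        stop("placement error: could not place engulfed fragment #", i)
      fb[vx] <- TRUE
      engulfed_idx <- c(engulfed_idx, vx)
    }
    for (i in seq_len(spec$n_fiber_fragments - n_eng)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        ctr <- vapply(1:3, function(a)
          stats::runif(1, frag_len / 2, ext[a] - frag_len / 2), 0)
        vx <- cylinder_voxels(ctr, frag_r, frag_len, sample.int(3, 1L),
                              grid, vox)
        if (length(vx) && !any(mg[vx]) && !any(fb[vx])) {
          fb[vx] <- TRUE
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("placement error: could not place free fragment #", i)
    }
    truth <- list(true_microglia_um3 = sum(mg) * vv,
                  true_lysosome_um3 = sum(lg) * vv,
                  true_engulfed_um3 = length(unique(engulfed_idx)) * vv)
    mk <- function(v) {
      a <- array(200 * v, grid)
      a <- gaussian_blur3d(a, spec$blur_sigma, vox)
      if (spec$noise_sd > 0)
        a <- pmax(a + stats::rnorm(length(a), 0, spec$noise_sd), 0)
      a
    }
    dat <- array(0, c(3L, grid))
    dat[1, , , ] <- mk(mg); dat[2, , , ] <- mk(lg); dat[3, , , ] <- mk(fb)
    list(volume = volume_image(dat, vox, c("microglia", "lysosome", "fiber")),
         truth = truth)
  })
}

#' Generate a non-touching puncta phantom
#'
#' Places `n_puncta` spheres with at least one background voxel between any
#' two objects, so 26-connected labeling must recover the exact count.
#'
#' @param grid_shape voxels `(z, y, x)`.
#' @param voxel_size um per voxel.
#' @param n_puncta number of puncta.
#' @param radius_range um, min and max sphere radius.
#' @param blur_sigma,noise_sd optional degradation as in
#'   [gen_engulfment_phantom()].
#' @param seed RNG seed.
#' @return List with `volume` (single-channel [volume_image], channel
#'   `puncta`) and `truth` (`true_count`, `true_total_um3`,
#'   `per_object_voxels`).
#' @export
gen_puncta_phantom <- function(grid_shape = c(24L, 96L, 96L),
                               voxel_size = c(0.3, 0.1, 0.1),
                               n_puncta = 25L,
                               radius_range = c(0.3, 0.6),
                               blur_sigma = 0, noise_sd = 0, seed = 1L) {
  stopifnot(all(grid_shape >= 1), all(voxel_size > 0), n_puncta >= 0,
            length(radius_range) == 2L, all(radius_range > 0))
  with_seed(seed, {
    grid <- as.integer(grid_shape); vox <- as.numeric(voxel_size)
    ext <- grid * vox
    occ <- logical(prod(grid))
    per_obj <- integer(0)
    for (i in seq_len(n_puncta)) {
      placed <- FALSE
      for (try in seq_len(1000L)) {
        r <- stats::runif(1, radius_range[1], radius_range[2])
        ctr <- vapply(1:3, function(a) stats::runif(1, r, ext[a] - r), 0)
        # candidate dilated by the gap requirement (one voxel per axis)
        vx <- sphere_voxels(ctr, r, grid, vox)
        dil <- sphere_voxels(ctr, r + max(vox) * 1.8, grid, vox)
        if (length(vx) && !any(occ[dil])) {
          occ[vx] <- TRUE
          per_obj <- c(per_obj, length(vx))
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("placement error: could not place punctum #", i,
                        " with a 1-voxel gap")
    }
    a <- array(200 * occ, grid)
    a <- gaussian_blur3d(a, blur_sigma, vox)
    if (noise_sd > 0) a <- pmax(a + stats::rnorm(length(a), 0, noise_sd), 0)
    dat <- array(a, c(1L, grid))
    list(volume = volume_image(dat, vox, "puncta"),
         truth = list(true_count = length(per_obj),
                      true_total_um3 = sum(per_obj) * prod(vox),
                      per_object_voxels = per_obj))
  })
}
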