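#' Construct a confocal stack object
#'
#' @param data 3D numeric array indexed `[x, y, z]` (voxel counts).
#' @param voxel voxel sizes `c(x, y, z)`, nm.
#' @param channel channel label.
#' @return object of class `confocal_stack`.
#' @export
confocal_stack <- function(data, voxel, channel = 1L) {
  stop_if_not(length(dim(data)) == 3L, "data must be a 3D array")
  stop_if_not(length(voxel) == 3L && all(voxel > 0),
              "voxel must be 3 positive sizes (nm)")
  structure(list(data = data, voxel = voxel, channel = channel),
            class = "confocal_stack")
}

#' @export
print.confocal_stack <- function(x, ...) {
  cat("<confocal_stack> ", paste(dim(x$data), collapse = " x "),
      " voxels (", paste(x$voxel, collapse = " x "), " nm), channel ",
      x$channel, "\n", sep = "")
  invisible(x)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Simulate a diffraction-limited confocal stack of a scene
#'
#' Renders every stretch of the requested channel as a 3D Gaussian of the
#' configured PSF FWHM (lateral/axial), sampled at voxel centers on the
#' confocal grid, each stretch contributing total intensity
#' `intensity_per_stretch`. Optional Poisson shot noise is applied voxelwise
#' on top of a constant background. At the 250/750-nm diffraction limit,
#' stretches of one domain merge into a single subdiffraction blob.
#'
#' @param scene an `rd_scene`; 2D scenes are placed at mid-depth of `z_extent`.
#' @param img an [imaging_config()] (uses `confocal_voxel`, `psf_fwhm`).
#' @param channel scene channel to render.
#' @param intensity_per_stretch expected total counts contributed by one
#'   stretch.
#' @param background constant background counts per voxel.
#' @param noise `"none"` or `"poisson"`.
#' @param z_extent axial extent of the stack in nm (for 2D scenes).
#' @param seed optional integer seed.
#' @return a [confocal_stack()].
#' @export
simulate_confocal_stack <- function(scene, img, channel = 1L,
                                    intensity_per_stretch = 1000,
                                    background = 0,
                                    noise = c("none", "poisson"),
                                    z_extent = 2000, seed = NULL) {
  stopifnot(inherits(scene, "rd_scene"), inherits(img, "imaging_config"))
  noise <- match.arg(noise)
  with_seed(seed, {
    vox <- img$confocal_voxel
    sig <- c(rep(fwhm_to_sigma(img$psf_fwhm[1]), 2L),
             fwhm_to_sigma(img$psf_fwhm[2]))
    field <- scene$field_size
    if (length(field) == 2L) field <- c(field, z_extent)
    stop_if_not(all(field >= 3 * c(img$psf_fwhm[1], img$psf_fwhm[1],
                                   img$psf_fwhm[2])),
                "field smaller than 3 x PSF")
    dims <- pmax(1L, ceiling(field / vox))
    st <- scene$stretches[scene$stretches$channel == channel, , drop = FALSE]
    stop_if_not(nrow(st) > 0, "no stretches in channel ", channel)
    z <- st$z_nm %||% rep(field[3] / 2, nrow(st))
    pos <- cbind(st$x_nm, st$y_nm, z)
    arr <- array(0, dims)
    ## voxel-center coordinate axes
    ax <- lapply(1:3, function(k) (seq_len(dims[k]) - 0.5) * vox[k])
    ## normalized Gaussian weight per axis, truncated at +-4 sigma
    for (i in seq_len(nrow(pos))) {
      w <- vector("list", 3L)
      idx <- vector("list", 3L)
      for (k in 1:3) {
        keep <- which(abs(ax[[k]] - pos[i, k]) <= 4 * sig[k])
        if (length(keep) == 0L) keep <- which.min(abs(ax[[k]] - pos[i, k]))
        g <- exp(-(ax[[k]][keep] - pos[i, k])^2 / (2 * sig[k]^2))
        idx[[k]] <- keep
        w[[k]] <- g / sum(g)
      }
      block <- outer(outer(w[[1]], w[[2]]), w[[3]]) * intensity_per_stretch
      arr[idx[[1]], idx[[2]], idx[[3]]] <-
        arr[idx[[1]], idx[[2]], idx[[3]]] + block
    }
    arr <- arr + background
    if (noise == "poisson")
      arr <- array(stats::rpois(length(arr), arr), dims)
    confocal_stack(arr, vox, channel)
  })
}
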