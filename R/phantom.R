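#' Specification for a synthetic soma phantom
#'
#' Describes a synthetic 3D fluorescence volume containing sphere-like somata
#' with known ground truth, emulating the regimes seen in whole-brain
#' fluorescence imaging: dense and sparse somata of varying radius and
#' brightness, touching soma pairs, soma-mimicking background speckles,
#' uneven illumination, and sensor noise.
#'
#' All stochastic choices are drawn from a single RNG stream seeded with
#' `seed`, in a documented order (per-soma radius, intensity, placement;
#' then noise blobs; then the Gaussian noise field), so the same spec is
#' bit-reproducible.
#'
#' @param shape integer length-3, volume dimensions in voxels (x, y, z).
#' @param n_somata number of somata to place.
#' @param radius_range `(min, max)` soma radius in voxels; `min >= 2` and
#'   `max < min(shape)/4`.
#' @param intensity_range `(min, max)` peak soma intensity in `[0, 1]`.
#' @param overlap_fraction fraction of somata placed as touching pairs
#'   (centers at distance `1.2 * (r1 + r2) / 2`, so their masks touch or
#'   merge).
#' @param n_noise_blobs number of soma-mimicking background speckles
#'   (strictly smaller than `radius_range[1]`); these appear in the rendered
#'   volume but never in the ground-truth mask.
#' @param illumination_gradient amplitude `g` in `[0, 1]` of a multiplicative
#'   linear ramp along x from `1 - g` to `1`.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param seed integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(shape = c(48, 48, 48), n_somata = 4, seed = 1)
#' sample <- generate_phantom(spec)
#' sample$centroids
phantom_spec <- function(shape = c(64, 64, 64),
                         n_somata = 12,
                         radius_range = c(3, 6),
                         intensity_range = c(0.4, 1),
                         overlap_fraction = 0,
                         n_noise_blobs = 6,
                         illumination_gradient = 0.2,
                         noise_sigma = 0.02,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) abort("`shape` must be 3 positive integers")
  if (radius_range[1] < 2) abort("minimum soma radius must be >= 2 voxels")
  if (radius_range[2] < radius_range[1]) abort("radius_range must be (min, max)")
  if (radius_range[2] >= min(shape) / 4)
    abort("maximum soma radius must be < min(shape)/4")
  if (any(intensity_range < 0) || any(intensity_range > 1) ||
      intensity_range[2] < intensity_range[1])
    abort("intensity_range must be an increasing pair in [0, 1]")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    abort("overlap_fraction must be in [0, 1]")
  if (illumination_gradient < 0 || illumination_gradient > 1)
    abort("illumination_gradient must be in [0, 1]")
  if (noise_sigma < 0) abort("noise_sigma must be >= 0")
  structure(
    list(shape = shape, n_somata = as.integer(n_somata),
         radius_range = as.numeric(radius_range),
         intensity_range = as.numeric(intensity_range),
         overlap_fraction = overlap_fraction,
         n_noise_blobs = as.integer(n_noise_blobs),
         illumination_gradient = illumination_gradient,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Add one soft-edged ball to `vol` (max-composited) and optionally to `mask`.
# Hard ball support d <= r with a 1-voxel raised-cosine intensity rolloff.
render_ball <- function(vol, mask, center, r, intensity, in_mask) {
  d <- dim(vol)
  lo <- pmax(floor(center - r), 0)
  hi <- pmin(ceiling(center + r), d - 1)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- (xs - center[1])^2
  dy2 <- (ys - center[2])^2
  dz2 <- (zs - center[3])^2
  dist <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  fall <- ifelse(dist <= r - 1, 1,
                 ifelse(dist <= r, 0.5 * (1 + cos(pi * (dist - (r - 1)))), 0))
  sub <- vol[xs + 1, ys + 1, zs + 1, drop = FALSE]
  vol[xs + 1, ys + 1, zs + 1] <- pmax(sub, intensity * fall)
  if (in_mask) {
    msub <- mask[xs + 1, ys + 1, zs + 1, drop = FALSE]
    mask[xs + 1, ys + 1, zs + 1] <- pmax(msub, as.integer(dist <= r))
  }
  list(vol = vol, mask = mask)
}

place_center <- function(shape, r, centers, radii, max_tries = 200L) {
  lo <- ceiling(r) + 1
  hi <- shape - 2 - ceiling(r)
  if (any(hi < lo)) abort("soma radius too large for volume",
                          class = "somamapper_overcrowded")
  for (i in seq_len(max_tries)) {
    c0 <- floor(runif(3, lo, hi + 1))
    ok <- TRUE
    if (length(radii) > 0) {
      dd <- sqrt(colSums((t(centers) - c0)^2))
      ok <- all(dd >= radii + r + 2)
    }
    if (ok) return(c0)
  }
  abort(sprintf("could not place a soma of radius %.1f after %d tries; spec is overcrowded",
                r, max_tries),
        class = "somamapper_overcrowded")
}

#' Generate a synthetic phantom volume with ground truth
#'
#' Renders the somata described by a [phantom_spec()] as soft-edged balls
#' (binary hard-ball ground-truth mask, 1-voxel cosine intensity rolloff),
#' adds sub-soma-scale noise blobs, a multiplicative illumination ramp and
#' additive Gaussian noise, and clips intensities to `[0, 1]`.  Soma centers
#' sit on voxel centers (integer 0-based coordinates); touching pairs place
#' the partner at distance `1.2 * (r1 + r2) / 2` in a random direction.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_sample`: a list with `volume` (a
#'   [volume3d()]), `mask` (a [seg_mask()] marking exactly the soma voxels),
#'   and `centroids` (a tibble `id, x, y, z, radius, intensity, paired`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  local_seed(spec$seed, {
    shape <- spec$shape
    vol <- array(0, shape)
    mask <- array(0L, shape)
    n <- spec$n_somata
    n_pairs <- floor(spec$overlap_fraction * n / 2)
    centers <- matrix(numeric(0), ncol = 3)
    radii <- numeric(0)
    intens <- numeric(0)
    paired <- logical(0)

    add_soma <- function(center, r, it, is_pair) {
      res <- render_ball(vol, mask, center, r, it, in_mask = TRUE)
      vol <<- res$vol; mask <<- res$mask
      centers <<- rbind(centers, center)
      radii <<- c(radii, r)
      intens <<- c(intens, it)
      paired <<- c(paired, is_pair)
    }

    k <- 0L
    # touching pairs first, then singles; each soma draws radius, intensity,
    # then placement, in that order
    while (k < 2L * n_pairs) {
      r1 <- runif(1, spec$radius_range[1], spec$radius_range[2])
      i1 <- runif(1, spec$intensity_range[1], spec$intensity_range[2])
      c1 <- place_center(shape, r1, centers, radii)
      r2 <- runif(1, spec$radius_range[1], spec$radius_range[2])
      i2 <- runif(1, spec$intensity_range[1], spec$intensity_range[2])
      sep <- 1.2 * (r1 + r2) / 2
      c2 <- NULL
      for (try in 1:200) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        cand <- round(c1 + sep * u)
        inside <- all(cand >= ceiling(r2) + 1) &&
          all(cand <= shape - 2 - ceiling(r2))
        clear <- TRUE
        if (inside && length(radii) > 0) {
          dd <- sqrt(colSums((t(centers) - cand)^2))
          clear <- all(dd >= radii + r2 + 2)
        }
        if (inside && clear) { c2 <- cand; break }
      }
      if (is.null(c2))
        abort("could not place overlap-pair partner; spec is overcrowded",
              class = "somamapper_overcrowded")
      add_soma(c1, r1, i1, TRUE)
      add_soma(c2, r2, i2, TRUE)
      k <- k + 2L
    }
    while (k < n) {
      r <- runif(1, spec$radius_range[1], spec$radius_range[2])
      it <- runif(1, spec$intensity_range[1], spec$intensity_range[2])
      c0 <- place_center(shape, r, centers, radii)
      add_soma(c0, r, it, FALSE)
      k <- k + 1L
    }

    # soma-mimicking background speckles: rendered, never in the mask
    if (spec$n_noise_blobs > 0) {
      rmax <- max(1, spec$radius_range[1] - 1)
      for (i in seq_len(spec$n_noise_blobs)) {
        r <- runif(1, 1, rmax)
        it <- runif(1, spec$intensity_range[1], spec$intensity_range[2])
        c0 <- floor(runif(3, 1, shape - 1))
        res <- render_ball(vol, mask, c0, r, it, in_mask = FALSE)
        vol <- res$vol
      }
    }

    # multiplicative illumination ramp along x: 1 - g ... 1
    g <- spec$illumination_gradient
    if (g > 0 && shape[1] > 1) {
      ramp <- 1 - g + g * (seq_len(shape[1]) - 1) / (shape[1] - 1)
      vol <- vol * ramp  # recycles along the first dimension
    }
    if (spec$noise_sigma > 0)
      vol <- vol + array(rnorm(prod(shape), 0, spec$noise_sigma), shape)
    vol <- pmin(pmax(vol, 0), 1)
    dim(vol) <- shape

    rownames(centers) <- NULL
    centroids <- tibble(
      id = seq_along(radii),
      x = if (length(radii)) centers[, 1] else numeric(0),
      y = if (length(radii)) centers[, 2] else numeric(0),
      z = if (length(radii)) centers[, 3] else numeric(0),
      radius = radii, intensity = intens, paired = paired
    )
    structure(
      list(spec = spec, volume = volume3d(vol),
           mask = seg_mask(mask), centroids = centroids),
      class = "phantom_sample"
    )
  })
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %s voxels, %d somata, %d mask voxels\n",
              paste(dim(x$volume), collapse = " x "),
              nrow(x$centroids), sum(x$mask$data)))
  invisible(x)
}

#' Generate a labeled 2D MIP classification set
#'
#' Positive examples are maximum-intensity projections of phantoms containing
#' at least one soma, with soma counts cycling through `1..n_somata` so the
#' set covers diverse densities; negatives are projections of soma-free
#' phantoms that still carry noise blobs, illumination ramp, and sensor
#' noise (the background regime the classifier must reject).  Per-image
#' seeds are derived deterministically from `spec$seed`, so the set is
#' reproducible.
#'
#' @param spec a [phantom_spec()]; positives carry between 1 and
#'   `spec$n_somata` somata, negatives none.
#' @param n_pos,n_neg number of positive / negative examples.
#' @return A tibble with list-column `image` (2D matrices), `label`
#'   (1 = soma present), and `seed`.
#' @export
generate_classification_set <- function(spec, n_pos, n_neg) {
  stopifnot(inherits(spec, "phantom_spec"), n_pos >= 0, n_neg >= 0)
  n_pos <- as.integer(n_pos)
  n_neg <- as.integer(n_neg)
  one <- function(i, positive) {
    s <- spec
    s$seed <- (spec$seed + 104729L * i) %% .Machine$integer.max
    nmax <- max(1L, spec$n_somata)
    s$n_somata <- if (positive) ((i - 1L) %% nmax) + 1L else 0L
    ph <- generate_phantom(s)
    list(image = mip(ph$volume)$data, seed = s$seed)
  }
  pos <- lapply(seq_len(n_pos), one, positive = TRUE)
  neg <- lapply(n_pos + seq_len(n_neg), one, positive = FALSE)
  tibble(
    image = c(lapply(pos, `[[`, "image"), lapply(neg, `[[`, "image")),
    label = c(rep(1L, n_pos), rep(0L, n_neg)),
    seed = c(vapply(pos, `[[`, integer(1), "seed"),
             vapply(neg, `[[`, integer(1), "seed"))
  )
}
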