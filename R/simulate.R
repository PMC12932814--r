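#' Growth parameters for the synthetic dendritic fingerprint
#'
#' The simulator emulates the thin-layer dendritic crystal pattern of a
#' crystallised plate: needles nucleate near the plate centre with a
#' radially outward orientation and grow as random walks with small angular
#' diffusion; side branches nucleate with a per-step probability at a fixed
#' relative angle plus jitter.
#'
#' @param n_seeds Number of primary needles nucleating near the centre.
#' @param length_scale Mean needle length in pixels (lognormal mean).
#' @param length_shape Lognormal sigma of needle length (dispersion).
#' @param branch_prob Per-step probability of spawning a side branch.
#' @param needle_width Rendered needle width in pixels.
#' @param texture_grain Length-2 numeric: amplitude and correlation length
#'   (px) of the multiplicative speckle applied before quantisation.
#' @param background_level Base grey value of the plate, 0..255.
#' @param plate_radius Plate radius in pixels (>= 64).
#' @return A validated list of class `ccc_growth_params`.
#' @export
growth_params <- function(n_seeds = 25, length_scale = 30, length_shape = 0.35,
                          branch_prob = 0.12, needle_width = 2,
                          texture_grain = c(0.08, 3),
                          background_level = 60, plate_radius = 96) {
  p <- list(n_seeds = as.integer(n_seeds), length_scale = length_scale,
            length_shape = length_shape, branch_prob = branch_prob,
            needle_width = needle_width, texture_grain = texture_grain,
            background_level = background_level,
            plate_radius = as.integer(plate_radius))
  nums <- unlist(p[c("n_seeds", "length_scale", "length_shape", "branch_prob",
                     "needle_width", "background_level", "plate_radius")])
  if (any(!is.finite(nums)) || any(nums < 0)) {
    stop("growth parameters must be finite and non-negative")
  }
  if (p$branch_prob > 1) stop("branch_prob must lie in [0, 1]")
  if (p$plate_radius < 64L) stop("plate_radius must be >= 64")
  if (length(p$texture_grain) != 2L || any(p$texture_grain < 0)) {
    stop("texture_grain must be c(amplitude, correlation length), both >= 0")
  }
  class(p) <- "ccc_growth_params"
  p
}

#' Construct a fingerprint image object
#'
#' @param pixels Integer matrix of 8-bit grey values (0..255).
#' @param centre Plate centre as `c(row, col)`.
#' @param plate_radius Plate radius in pixels.
#' @return An object of class `ccc_image`.
#' @export
ccc_image <- function(pixels, centre = (dim(pixels) + 1) / 2,
                      plate_radius = floor(min(dim(pixels)) / 2)) {
  stopifnot(is.matrix(pixels), length(centre) == 2L, plate_radius > 0)
  storage.mode(pixels) <- "integer"
  if (any(pixels < 0L | pixels > 255L)) stop("pixels must lie in 0..255")
  structure(list(pixels = pixels, centre = as.numeric(centre),
                 plate_radius = as.numeric(plate_radius)),
            class = "ccc_image")
}

#' @export
print.ccc_image <- function(x, ...) {
  cat(sprintf("CCC fingerprint image %dx%d, centre (%.1f, %.1f), radius %g\n",
              nrow(x$pixels), ncol(x$pixels), x$centre[1], x$centre[2],
              x$plate_radius))
  invisible(x)
}

# distance of every pixel from the plate centre
.radius_map <- function(nr, nc, centre) {
  dr <- (seq_len(nr) - centre[1])^2
  dc <- (seq_len(nc) - centre[2])^2
  sqrt(outer(dr, dc, `+`))
}

# stamp one sub-pixel point onto the coverage accumulator with an
# anti-aliased disc of diameter `width`
.stamp <- function(acc, y, x, width) {
  r <- width / 2 + 0.5
  i0 <- max(1L, floor(y - r)); i1 <- min(nrow(acc), ceiling(y + r))
  j0 <- max(1L, floor(x - r)); j1 <- min(ncol(acc), ceiling(x + r))
  if (i0 > i1 || j0 > j1) return(acc)
  ii <- i0:i1; jj <- j0:j1
  d <- sqrt(outer((ii - y)^2, (jj - x)^2, `+`))
  cov <- pmin(1, pmax(0, width / 2 + 0.5 - d))
  acc[ii, jj] <- pmax(acc[ii, jj], cov)
  acc
}

#' Simulate one synthetic crystallisation fingerprint
#'
#' Deterministic for a fixed `(params, seed)` pair: identical calls
#' reproduce bit-identical images.
#'
#' @param params A [growth_params()] object.
#' @param seed Integer seed.
#' @return A [ccc_image()].
#' @examples
#' img <- simulate_fingerprint(growth_params(n_seeds = 5), seed = 1)
#' @export
simulate_fingerprint <- function(params, seed) {
  stopifnot(inherits(params, "ccc_growth_params"))
  R <- params$plate_radius
  n <- 2L * R + 1L
  centre <- c(R + 1, R + 1)
  seed_disc <- max(2, 0.12 * R)
  if (params$n_seeds > 0 && seed_disc >= R) {
    stop("plate too small to place seeds")
  }
  with_seed(seed, {
    acc <- matrix(0, n, n)
    # needle queue: each entry (y, x, angle, length, depth)
    queue <- vector("list", 0)
    for (s in seq_len(params$n_seeds)) {
      rr <- seed_disc * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      y <- centre[1] + rr * sin(th); x <- centre[2] + rr * cos(th)
      ang <- atan2(y - centre[1], x - centre[2]) + stats::rnorm(1, 0, 0.3)
      len <- stats::rlnorm(1, log(params$length_scale) -
                             params$length_shape^2 / 2, params$length_shape)
      queue[[length(queue) + 1L]] <- list(y = y, x = x, angle = ang,
                                          len = len, depth = 0L)
    }
    n_drawn <- 0L
    while (length(queue) > 0L && n_drawn < 2000L) {
      nd <- queue[[1L]]; queue[[1L]] <- NULL
      n_drawn <- n_drawn + 1L
      y <- nd$y; x <- nd$x; ang <- nd$angle
      steps <- max(1L, round(nd$len))
      acc <- .stamp(acc, y, x, params$needle_width)
      for (k in seq_len(steps)) {
        ang <- ang + stats::rnorm(1, 0, 0.06)
        y <- y + sin(ang); x <- x + cos(ang)
        if (sqrt((y - centre[1])^2 + (x - centre[2])^2) > 0.96 * R) break
        acc <- .stamp(acc, y, x, params$needle_width)
        if (nd$depth < 4L && params$branch_prob > 0 &&
            stats::runif(1) < params$branch_prob) {
          side <- sample(c(-1, 1), 1L)
          child_ang <- ang + side * (0.6 + stats::rnorm(1, 0, 0.1))
          child_len <- stats::rlnorm(1, log(0.6 * params$length_scale) -
                                       params$length_shape^2 / 2,
                                     params$length_shape)
          queue[[length(queue) + 1L]] <- list(y = y, x = x, angle = child_ang,
                                              len = child_len,
                                              depth = nd$depth + 1L)
        }
      }
    }
    needle_level <- min(255, params$background_level + 160)
    img <- params$background_level + acc * (needle_level - params$background_level)
    grain <- params$texture_grain
    if (grain[1] > 0) {
      noise <- matrix(stats::rnorm(n * n), n, n)
      if (grain[2] > 0) {
        noise <- EBImage::gblur(EBImage::Image(noise), sigma = grain[2])
        noise <- EBImage::imageData(noise)
        sdn <- stats::sd(noise)
        if (sdn > 0) noise <- noise / sdn
      }
      img <- img * exp(grain[1] * noise)
    }
    rmap <- .radius_map(n, n, centre)
    img[rmap > R] <- params$background_level
    img <- round(pmax(pmin(img, 255), 0))
    ccc_image(img, centre = centre, plate_radius = R)
  })
}

.effect_factors <- c("batch", "host_tree", "blending", "subspecies")

#' Effect specification for the synthetic generators
#'
#' Shared configuration grammar for direct (feature-table) and image-latent
#' synthesis. Each `effects` entry maps a target (an analysis variable in
#' direct mode, a [growth_params()] field in image mode) to a named vector
#' of standardised effect sizes per factor contrast. The contrast is the
#' first canonical level minus the second (VAA - VAAu, apple - oak with
#' pine at 0, machine - hand, batch 2109 - 2204), so a target with effect
#' `d` differs between the two groups by `d * residual_sigma`.
#'
#' @param effects Named list: target -> named numeric of per-factor d.
#' @param residual_sigma Within-group SD (direct mode, response scale) or
#'   SD of the per-plate log-latent noise (image mode). Must be > 0.
#' @param day_effects,batch_effects Optional additive offsets, named or
#'   positional by level (day 1..6; batch 2109, 2204).
#' @param baseline Named numeric of per-target means; defaults provided for
#'   the seven analysis variables.
#' @param seed Integer seed used by the generators.
#' @return An object of class `ccc_effect_spec`.
#' @examples
#' spec <- effect_spec(effects = list(l250 = c(subspecies = 1.76)), seed = 1)
#' @export
effect_spec <- function(effects = list(), residual_sigma = 1,
                        day_effects = NULL, batch_effects = NULL,
                        baseline = NULL, seed = 1L) {
  if (!is.list(effects)) stop("effects must be a named list")
  if (length(effects) && is.null(names(effects))) stop("effects must be named")
  for (v in names(effects)) {
    e <- effects[[v]]
    if (!is.numeric(e) || is.null(names(e))) {
      stop("effects[['", v, "']] must be a named numeric vector")
    }
    bad <- setdiff(names(e), .effect_factors)
    if (length(bad)) {
      stop("unknown contrast factor(s) for '", v, "': ",
           paste(bad, collapse = ", "))
    }
    if (any(!is.finite(e))) stop("effect sizes must be finite")
  }
  if (!is.numeric(residual_sigma) || residual_sigma <= 0) {
    stop("residual_sigma must be > 0")
  }
  structure(list(effects = effects, residual_sigma = residual_sigma,
                 day_effects = day_effects, batch_effects = batch_effects,
                 baseline = baseline, seed = as.integer(seed)),
            class = "ccc_effect_spec")
}

.default_baseline <- c(kappa = 0.25, diagonal_moment = 5, entropy = 6.5,
                       cluster_shade = -40, lend = 120, l220 = 35, l250 = 20)

# signed half-contrast per record for one factor: first canonical level
# gets +1/2, second -1/2 (pine contributes 0 to the apple-oak contrast)
.contrast_sign <- function(design, fac) {
  lev <- switch(fac,
    batch = .batch_levels,
    host_tree = c("apple", "oak"),
    blending = .blending_levels,
    subspecies = .subspecies_levels,
    stop("no contrast defined for factor '", fac, "'")
  )
  x <- as.character(design[[fac]])
  out <- numeric(nrow(design))
  out[x == lev[1]] <- 0.5
  out[x == lev[2]] <- -0.5
  out
}

.level_offsets <- function(eff, levels) {
  out <- stats::setNames(numeric(length(levels)), levels)
  if (is.null(eff)) return(out)
  if (is.null(names(eff))) {
    if (length(eff) > length(levels)) stop("too many level offsets supplied")
    out[seq_along(eff)] <- eff
  } else {
    bad <- setdiff(names(eff), levels)
    if (length(bad)) stop("unknown level(s): ", paste(bad, collapse = ", "))
    out[names(eff)] <- eff
  }
  out
}

#' Generate a direct-mode feature table with a known statistical truth
#'
#' Draws the seven analysis variables for every plate of the design from
#' the linear model
#' `value = baseline + sum(contrast * d * residual_sigma) + day + batch +
#' Normal(0, residual_sigma)`, so recovered group differences have a known
#' standardised effect size.
#'
#' @param design A `ccc_design`.
#' @param spec An [effect_spec()] whose targets are analysis variables.
#' @return A data frame with `plate_id` and the seven variable columns.
#' @export
generate_feature_table <- function(design, spec) {
  stopifnot(inherits(spec, "ccc_effect_spec"), is.data.frame(design))
  vars <- analysis_variables()
  bad <- setdiff(names(spec$effects), vars)
  if (length(bad)) {
    stop("unknown variable(s) in effect spec: ", paste(bad, collapse = ", "))
  }
  base <- .default_baseline
  if (!is.null(spec$baseline)) base[names(spec$baseline)] <- spec$baseline
  n <- nrow(design)
  day_off <- .level_offsets(spec$day_effects, as.character(1:6))
  batch_off <- .level_offsets(spec$batch_effects, .batch_levels)
  out <- data.frame(plate_id = design$plate_id, stringsAsFactors = FALSE)
  with_seed(spec$seed, {
    for (v in vars) {
      mu <- rep(base[[v]], n)
      eff <- spec$effects[[v]]
      for (fac in names(eff)) {
        mu <- mu + .contrast_sign(design, fac) * eff[[fac]] * spec$residual_sigma
      }
      mu <- mu + day_off[as.character(design$day)]
      mu <- mu + batch_off[as.character(design$batch)]
      out[[v]] <- as.numeric(mu) + stats::rnorm(n, 0, spec$residual_sigma)
    }
  })
  out
}

#' Generate a set of synthetic fingerprint images for a design
#'
#' The effect spec targets [growth_params()] fields; contrasts and day /
#' batch offsets act additively on the log of the targeted parameter (with
#' per-plate lognormal latent noise of SD `residual_sigma`), so larger `d`
#' separates the latent parameter distributions of the contrasted groups.
#' `branch_prob` is clamped to `[0, 1]` after the log-scale shift.
#'
#' @param design A `ccc_design`.
#' @param latent_spec An [effect_spec()] whose targets are growth-parameter
#'   fields; use a small `residual_sigma` (log scale), e.g. 0.05.
#' @param seed Master seed; each plate draws from its own child stream so
#'   adding plates never perturbs existing ones.
#' @param base_params Baseline [growth_params()].
#' @param dir Optional directory: when given, images are written as 8-bit
#'   greyscale PNGs named `<plate_id>.png` plus a `metadata.csv`.
#' @return List with `images` (named list of [ccc_image()]) and `metadata`
#'   (data frame of realised latent parameters per plate).
#' @export
generate_image_set <- function(design, latent_spec, seed,
                               base_params = growth_params(), dir = NULL) {
  stopifnot(inherits(latent_spec, "ccc_effect_spec"), is.data.frame(design))
  latent_fields <- c("n_seeds", "length_scale", "length_shape", "branch_prob",
                     "needle_width", "background_level")
  bad <- setdiff(names(latent_spec$effects), latent_fields)
  if (length(bad)) {
    stop("effect spec targets unknown growth parameter(s): ",
         paste(bad, collapse = ", "))
  }
  n <- nrow(design)
  day_off <- .level_offsets(latent_spec$day_effects, as.character(1:6))
  batch_off <- .level_offsets(latent_spec$batch_effects, .batch_levels)
  sig <- latent_spec$residual_sigma
  images <- vector("list", n)
  meta_rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- base_params
    pseed <- child_seed(seed, i)
    shift_common <- day_off[as.character(design$day[i])] +
      batch_off[as.character(design$batch[i])]
    noise <- with_seed(child_seed(pseed, 7L), stats::rnorm(1, 0, sig))
    for (f in names(latent_spec$effects)) {
      eff <- latent_spec$effects[[f]]
      shift <- shift_common + noise
      for (fac in names(eff)) {
        shift <- shift + .contrast_sign(design[i, , drop = FALSE], fac) *
          eff[[fac]] * sig
      }
      val <- p[[f]] * exp(shift)
      if (f == "branch_prob") val <- min(1, max(0, val))
      if (f == "n_seeds") val <- max(1L, as.integer(round(val)))
      if (f == "background_level") val <- min(250, max(0, val))
      p[[f]] <- val
    }
    images[[i]] <- simulate_fingerprint(p, seed = pseed)
    meta_rows[[i]] <- data.frame(
      plate_id = design$plate_id[i], seed = pseed,
      n_seeds = p$n_seeds, length_scale = p$length_scale,
      length_shape = p$length_shape, branch_prob = p$branch_prob,
      needle_width = p$needle_width, background_level = p$background_level,
      plate_radius = p$plate_radius, stringsAsFactors = FALSE
    )
  }
  names(images) <- design$plate_id
  metadata <- do.call(rbind, meta_rows)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(n)) {
      png::writePNG(images[[i]]$pixels / 255,
                    file.path(dir, paste0(design$plate_id[i], ".png")))
    }
    utils::write.csv(cbind(metadata,
                           file = paste0(design$plate_id, ".png")),
                     file.path(dir, "metadata.csv"), row.names = FALSE)
  }
  list(images = images, metadata = metadata)
}
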