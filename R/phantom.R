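## Phantom geometry: random disk targets inside a circular diffusive domain,
## and rasterization of the fluorescence-yield map eta*mu_af.

#' Disk fluorophore target
#'
#' @param center numeric length-2, target center in domain-centered mm.
#' @param radius disk radius (mm).
#' @param contrast ratio of target \code{mu_af} to background \code{mu_af}.
#' @return a \code{target_spec} list.
#' @export
target_spec <- function(center, radius, contrast = 4) {
  stopifnot(length(center) == 2, is.finite(center), radius > 0, contrast > 0)
  structure(list(center = as.numeric(center), radius = radius,
                 contrast = contrast), class = "target_spec")
}

#' Phantom specification
#'
#' A circular diffusive domain of radius \code{domain_radius} holding 1--3
#' non-overlapping disk targets.  The fluorescence yield field
#' \eqn{\eta\mu_{af}(r)} equals the background yield outside all targets and
#' \code{contrast} times the background inside a target.
#'
#' @param targets list of \code{\link{target_spec}} objects (may be empty for
#'   a homogeneous phantom).
#' @param background an \code{\link{optical_properties}} object.
#' @param domain_radius domain radius (mm); default 50.
#' @param rng_seed integer seed recorded for provenance (may be NA).
#' @return a \code{phantom_spec} list.
#' @export
phantom_spec <- function(targets = list(), background = optical_properties(),
                         domain_radius = 50, rng_seed = NA_integer_) {
  stopifnot(domain_radius > 0, length(targets) <= 3)
  for (tg in targets) {
    stopifnot(inherits(tg, "target_spec"))
    if (sqrt(sum(tg$center^2)) + tg$radius > domain_radius)
      stop("target disk extends outside the domain")
  }
  if (length(targets) >= 2) {
    for (a in seq_len(length(targets) - 1)) for (b in (a + 1):length(targets)) {
      d <- sqrt(sum((targets[[a]]$center - targets[[b]]$center)^2))
      if (d < targets[[a]]$radius + targets[[b]]$radius)
        stop("target disks overlap")
    }
  }
  structure(list(domain_radius = domain_radius, background = background,
                 targets = targets, rng_seed = rng_seed),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Phantom: radius %g mm, %d target(s), seed %s\n",
              x$domain_radius, length(x$targets), format(x$rng_seed)))
  for (tg in x$targets)
    cat(sprintf("  disk at (%.2f, %.2f) mm, r=%.2f mm, contrast %g:1\n",
                tg$center[1], tg$center[2], tg$radius, tg$contrast))
  invisible(x)
}

#' Default phantom-generation settings
#'
#' Targets have radii drawn uniformly from \code{radius_range}, a fixed
#' fluorophore contrast against background, and centers uniform over the set
#' of admissible positions (disk fully inside the domain minus a boundary
#' margin), with rejection sampling enforcing non-overlap.
#'
#' @param radius_range numeric length-2 (mm); default \code{c(4, 8)}.
#' @param contrast target:background \code{mu_af} ratio; default 4.
#' @param margin minimum gap between a target edge and the domain boundary
#'   (mm); default 2.
#' @param min_gap minimum edge-to-edge distance between targets (mm);
#'   default 0 (touching allowed, overlap not).
#' @param max_attempts rejection-sampling budget per target.
#' @return a list of settings.
#' @export
phantom_config <- function(radius_range = c(4, 8), contrast = 4, margin = 2,
                           min_gap = 0, max_attempts = 1000L) {
  stopifnot(length(radius_range) == 2, radius_range[1] > 0,
            radius_range[2] >= radius_range[1], margin >= 0, min_gap >= 0)
  list(radius_range = radius_range, contrast = contrast, margin = margin,
       min_gap = min_gap, max_attempts = as.integer(max_attempts))
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Sample a random phantom specification
#'
#' Draws \code{n_targets} disk targets with radii uniform in the configured
#' range and centers uniform over the admissible region (rejection sampling
#' for non-overlap).  Fully determined by \code{rng_seed}.
#'
#' @param rng_seed integer seed.
#' @param n_targets 1, 2 or 3.
#' @param config settings from \code{\link{phantom_config}}.
#' @param background an \code{\link{optical_properties}} object.
#' @param domain_radius domain radius (mm).
#' @return a \code{\link{phantom_spec}}.
#' @export
sample_phantom_spec <- function(rng_seed, n_targets = 1L,
                                config = phantom_config(),
                                background = optical_properties(),
                                domain_radius = 50) {
  stopifnot(n_targets %in% 1:3)
  with_seed(rng_seed, {
    targets <- list()
    for (k in seq_len(n_targets)) {
      ok <- FALSE
      for (att in seq_len(config$max_attempts)) {
        radius <- stats::runif(1, config$radius_range[1], config$radius_range[2])
        rmax <- domain_radius - config$margin - radius
        if (rmax <= 0) next
        # uniform over the admissible disk of radius rmax
        rr <- rmax * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        center <- c(rr * cos(th), rr * sin(th))
        clear <- TRUE
        for (tg in targets) {
          d <- sqrt(sum((center - tg$center)^2))
          if (d < radius + tg$radius + config$min_gap) { clear <- FALSE; break }
        }
        if (clear) {
          targets[[k]] <- target_spec(center, radius, config$contrast)
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("rejection sampling failed: domain too crowded for target ", k)
    }
    phantom_spec(targets, background, domain_radius, as.integer(rng_seed))
  })
}

#' Sample a two-target phantom with a prescribed edge-to-edge separation
#'
#' Used by the resolution experiment: two disks whose closest edges are
#' exactly \code{separation} mm apart, the pair placed at a random position
#' and orientation inside the domain.
#'
#' @param rng_seed integer seed.
#' @param separation edge-to-edge distance (mm).
#' @param config settings from \code{\link{phantom_config}}; both radii are
#'   drawn from its \code{radius_range}.
#' @param equal_radii draw one radius and use it for both disks (default
#'   TRUE, matching a resolution-bar layout).
#' @inheritParams sample_phantom_spec
#' @return a \code{\link{phantom_spec}} with two targets.
#' @export
sample_resolution_spec <- function(rng_seed, separation,
                                   config = phantom_config(),
                                   equal_radii = TRUE,
                                   background = optical_properties(),
                                   domain_radius = 50) {
  stopifnot(separation >= 0)
  with_seed(rng_seed, {
    for (att in seq_len(config$max_attempts)) {
      r1 <- stats::runif(1, config$radius_range[1], config$radius_range[2])
      r2 <- if (equal_radii) r1 else
        stats::runif(1, config$radius_range[1], config$radius_range[2])
      gap <- r1 + r2 + separation     # center-to-center distance
      th <- stats::runif(1, 0, 2 * pi)
      u <- c(cos(th), sin(th))
      rmax <- domain_radius - config$margin - max(r1, r2)
      mid <- rmax * sqrt(stats::runif(1)) * {
        a <- stats::runif(1, 0, 2 * pi); c(cos(a), sin(a))
      }
      c1 <- mid - u * gap / 2
      c2 <- mid + u * gap / 2
      inside <- function(cc, r)
        sqrt(sum(cc^2)) + r <= domain_radius - config$margin
      if (inside(c1, r1) && inside(c2, r2))
        return(phantom_spec(list(target_spec(c1, r1, config$contrast),
                                 target_spec(c2, r2, config$contrast)),
                            background, domain_radius, as.integer(rng_seed)))
    }
    stop("rejection sampling failed for separation ", separation, " mm")
  })
}

#' Evaluate the fluorescence yield field at points
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param points n x 2 matrix of (x, y) positions in mm.
#' @return numeric vector of \eqn{\eta\mu_{af}} values; points outside the
#'   domain get 0.
#' @export
yield_at <- function(spec, points) {
  points <- matrix(points, ncol = 2)
  y0 <- spec$background$yield
  vals <- rep(y0, nrow(points))
  for (tg in spec$targets) {
    d2 <- (points[, 1] - tg$center[1])^2 + (points[, 2] - tg$center[2])^2
    vals[d2 <= tg$radius^2] <- y0 * tg$contrast
  }
  vals[points[, 1]^2 + points[, 2]^2 > spec$domain_radius^2] <- 0
  vals
}

#' Rasterize the ground-truth yield image
#'
#' Samples \eqn{\eta\mu_{af}} on an N x N grid over the bounding square of
#' the domain.  Row 1 is the top of the image (y = +domain_radius), pixels
#' are sampled at cell centers, and pixels outside the circular domain are 0.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param grid_size image side N (>= 8).
#' @return an N x N numeric matrix (class \code{yield_image}).
#' @export
rasterize_yield <- function(spec, grid_size = 128L) {
  N <- as.integer(grid_size)
  stopifnot(N >= 8)
  R <- spec$domain_radius
  px <- 2 * R / N
  xs <- -R + (seq_len(N) - 0.5) * px
  ys <- R - (seq_len(N) - 0.5) * px
  pts <- cbind(x = rep(xs, each = N), y = rep(ys, times = N))
  # pts ordered column-major for a [row, col] matrix: row (y) fastest
  img <- matrix(yield_at(spec, pts), nrow = N, ncol = N)
  structure(img, class = c("yield_image", "matrix"), pixel_mm = px)
}

#' Serialize / restore a phantom specification as JSON
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return \code{phantom_to_json}: a JSON string; \code{phantom_from_json}:
#'   the restored \code{phantom_spec}.
#' @export
phantom_to_json <- function(spec) {
  jsonlite::toJSON(list(
    domain_radius = spec$domain_radius,
    rng_seed = spec$rng_seed,
    background = unclass(spec$background)[c("mu_ax", "mu_am", "mu_sx",
                                            "mu_sm", "mu_af", "eta")],
    targets = lapply(spec$targets, function(tg)
      list(center = tg$center, radius = tg$radius, contrast = tg$contrast))
  ), auto_unbox = TRUE, digits = NA)
}

#' @rdname phantom_to_json
#' @param json a JSON string produced by \code{phantom_to_json}.
#' @export
phantom_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  bg <- do.call(optical_properties, as.list(x$background))
  targets <- lapply(x$targets, function(tg)
    target_spec(unlist(tg$center), tg$radius, tg$contrast))
  phantom_spec(targets, bg, x$domain_radius,
               if (is.null(x$rng_seed)) NA_integer_ else as.integer(x$rng_seed))
}
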