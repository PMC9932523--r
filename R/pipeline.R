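## Experiment orchestration: dataset generation, model training and the
## three simulation studies (single-target accuracy, two-target resolution,
## multi-target robustness) plus the locality-module ablation.

#' Experiment profile
#'
#' Bundles the problem sizes for a full study.  \code{"desk"} is the
#' CPU-sized profile used throughout the package's own tests and scripts:
#' 300 phantoms (240/30/30 split), 32 x 32 images, a small network, short
#' Adam training.  \code{"paper"} is the full-scale protocol (10,000
#' phantoms, 128 x 128 images): identical code path, hours of compute.
#'
#' @param profile \code{"desk"} or \code{"paper"}.
#' @return a list with \code{n}, \code{split}, \code{N}, \code{mesh_edge},
#'   \code{geometry}, \code{net} and \code{train} settings.
#' @export
xclt_profile <- function(profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  if (profile == "desk")
    list(name = "desk", n = 300L, split = c(240L, 30L, 30L), N = 32L,
         mesh_edge = 2.5, geometry = scan_geometry(),
         net = network_config(N = 32L, n = 4L, C = 24L,
                              depths = c(1L, 1L, 1L, 1L),
                              heads = c(2L, 2L, 4L, 4L), window = 4L,
                              mlp_ratio = 2, locality_hidden_max = 512L),
         train = list(epochs = 7L, batch = 8L, lr = 5e-3, lr_decay = 0.85,
                      warmup = 1L, peak_weight = 6, augment = TRUE))
  else
    list(name = "paper", n = 10000L, split = c(8000L, 1000L, 1000L),
         N = 128L, mesh_edge = 50 / 36, geometry = scan_geometry(),
         net = network_config(),
         train = list(epochs = 60L, batch = 8L, lr = 1e-3, lr_decay = 0.95,
                      warmup = 3L, peak_weight = 6, augment = TRUE))
}

#' Generate a simulated XCLT dataset
#'
#' For each record: sample a phantom, simulate its sheet-scan sinogram with
#' the FEM forward model, add the configured relative Gaussian noise,
#' upscale to N x N, and rasterize the max-normalized ground-truth yield
#' image.  The coupled diffusion systems are precomputed once as a linear
#' operator (\code{\link{sinogram_operator}}), so generation is fast and
#' fully deterministic given \code{base_seed}.
#'
#' @param n number of phantoms.
#' @param base_seed integer; record i uses seed \code{base_seed + i}.
#' @param mesh a \code{\link{build_mesh}} result.
#' @param geometry a \code{\link{scan_geometry}}.
#' @param N image (and upscaled sinogram) side.
#' @param n_targets integer 1--3, a vector recycled over records, or
#'   \code{"mixed12"} for an alternating 1/2-target pool.
#' @param separations if non-NULL, generate two-target resolution phantoms
#'   with these edge-to-edge distances (mm), recycled over records.
#' @param background an \code{\link{optical_properties}} object.
#' @param config a \code{\link{phantom_config}}.
#' @return an \code{xclt_dataset}: list with arrays \code{sinos_raw}
#'   (n x angles x sheets, noisy), \code{sinos} (n x N x N, normalized
#'   upscaled), \code{images} (n x N x N ground truth, max = 1), JSON
#'   \code{specs}, and the generation metadata.
#' @export
generate_dataset <- function(n, base_seed = 0L, mesh, geometry = scan_geometry(),
                             N = 32L, n_targets = 1L, separations = NULL,
                             background = optical_properties(),
                             config = phantom_config()) {
  op <- sinogram_operator(mesh, geometry, background)
  nt <- if (identical(n_targets, "mixed12")) rep(c(1L, 2L), length.out = n)
        else rep(as.integer(n_targets), length.out = n)
  sinos_raw <- array(0, c(n, geometry$n_angles, geometry$n_sheets))
  sinos <- array(0, c(n, N, N))
  images <- array(0, c(n, N, N))
  specs <- character(n)
  for (i in seq_len(n)) {
    seed_i <- base_seed + i
    spec <- if (!is.null(separations))
      sample_resolution_spec(seed_i, separations[(i - 1) %% length(separations) + 1],
                             config, background = background,
                             domain_radius = mesh$radius)
    else
      sample_phantom_spec(seed_i, nt[i], config, background, mesh$radius)
    sino <- apply_sinogram_operator(op, spec)
    sino <- add_noise(sino, geometry$noise_level, seed = seed_i + 1000000L)
    sino <- upscale_sinogram(sino, N)
    sinos_raw[i, , ] <- sino$raw
    sinos[i, , ] <- sino$upscaled
    images[i, , ] <- normalize_max(rasterize_yield(spec, N))
    specs[i] <- phantom_to_json(spec)
  }
  structure(list(sinos_raw = sinos_raw, sinos = sinos, images = images,
                 specs = specs, geometry = geometry, N = N,
                 base_seed = as.integer(base_seed),
                 domain_radius = mesh$radius),
            class = "xclt_dataset")
}

#' @export
print.xclt_dataset <- function(x, ...) {
  cat(sprintf("XCLT dataset: %d records, sinograms %dx%d -> %dx%d, seed %d\n",
              dim(x$sinos_raw)[1], dim(x$sinos_raw)[2], dim(x$sinos_raw)[3],
              x$N, x$N, x$base_seed))
  invisible(x)
}

#' Save / load a dataset (RDS container)
#'
#' @param ds an \code{xclt_dataset}.
#' @param file path.
#' @export
save_dataset <- function(ds, file) saveRDS(ds, file)

#' @rdname save_dataset
#' @export
load_dataset <- function(file) readRDS(file)

#' Train/validation/test split indices
#'
#' @param ds an \code{xclt_dataset}.
#' @param split integer length-3; must sum to at most the dataset size.
#' @return list of index vectors \code{train}, \code{val}, \code{test}
#'   (disjoint, exhaustive over the first \code{sum(split)} records).
#' @export
split_dataset <- function(ds, split = c(240L, 30L, 30L)) {
  n <- dim(ds$sinos)[1]
  stopifnot(sum(split) <= n)
  list(train = seq_len(split[1]),
       val = split[1] + seq_len(split[2]),
       test = split[1] + split[2] + seq_len(split[3]))
}

#' Train a reconstruction network on a dataset
#'
#' @param ds an \code{xclt_dataset}.
#' @param kind model kind for \code{\link{build_model}}.
#' @param net a \code{\link{network_config}} (must match \code{ds$N}).
#' @param split a \code{\link{split_dataset}} result.
#' @param train list with \code{epochs}, \code{batch}, \code{lr}.
#' @param seed weight-initialization / shuffling seed.
#' @param verbose print per-epoch losses.
#' @return the trained \code{recon_model} (with \code{history}).
#' @export
run_training <- function(ds, kind = "swin_cnn", net = network_config_small(),
                         split = split_dataset(ds),
                         train = list(epochs = 15L, batch = 8L, lr = 1e-3),
                         seed = 1L, verbose = FALSE) {
  stopifnot(net$N == ds$N)
  model <- build_model(kind, net, seed = seed)
  if (isTRUE(train$augment)) {
    aug <- augment_dataset(ds, split$train)
    tr_x <- aug$sinos
    tr_y <- aug$images
  } else {
    tr_x <- ds$sinos[split$train, , , drop = FALSE]
    tr_y <- ds$images[split$train, , , drop = FALSE]
  }
  pp <- sinogram_preproc(tr_x)
  model <- train_model(model,
              apply_preproc(pp, tr_x),
              tr_y,
              apply_preproc(pp, ds$sinos[split$val, , , drop = FALSE]),
              ds$images[split$val, , , drop = FALSE],
              epochs = train$epochs, batch = train$batch, lr = train$lr,
              lr_decay = if (is.null(train$lr_decay)) 1 else train$lr_decay,
              warmup = if (is.null(train$warmup)) 0L else train$warmup,
              peak_weight = if (is.null(train$peak_weight)) 1 else
                train$peak_weight,
              seed = seed, verbose = verbose)
  model$preproc <- pp
  model
}

## ---- exact geometric augmentation ------------------------------------------
## The scan geometry (angles 0..170 deg in 10 deg steps, symmetric offsets)
## and the square raster share the symmetry group of the square: rotating a
## phantom by 90/180/270 deg or mirroring it maps the raw sinogram to a row
## permutation (with column flips for wrapped angles) and the image to an
## exact raster transform.  p(theta + 180, s) = p(theta, -s).

## rotate phantom by rot90 * 90 deg CCW, then optionally mirror about the
## horizontal axis
augment_raw <- function(raw, rot90 = 0L, mirror = FALSE) {
  na <- nrow(raw)
  stopifnot(na %% 2 == 0)   # 180 deg covered in `na` rows
  if (rot90 %% 2 == 1) {
    k <- na %/% 2
    # theta' = theta + 90: first k rows wrap (column flip), rest shift down
    raw <- rbind(raw[(k + 1):na, ncol(raw):1, drop = FALSE],
                 raw[1:k, , drop = FALSE])
  }
  if (rot90 %/% 2 %% 2 == 1)   # 180 deg: offsets flip, angles unchanged
    raw <- raw[, ncol(raw):1, drop = FALSE]
  if (mirror) {
    # reflection about the x-axis: p'(theta, s) = p(180 - theta, -s);
    # the theta = 0 row maps to itself with no offset flip
    raw <- raw[c(1, na:2), , drop = FALSE]
    raw[2:na, ] <- raw[2:na, ncol(raw):1, drop = FALSE]
  }
  raw
}

#' @keywords internal
augment_image <- function(img, rot90 = 0L, mirror = FALSE) {
  for (i in seq_len(rot90 %% 4))
    img <- t(img)[nrow(img):1, , drop = FALSE]   # 90 deg CCW
  if (mirror) img <- img[nrow(img):1, , drop = FALSE]
  img
}

#' Augment a dataset with its exact dihedral symmetries
#'
#' Expands each record into its 8 square-symmetry images (4 rotations x
#' optional mirror), transforming the raw sinogram by the corresponding
#' row/column permutation and re-upscaling.  Used on the training split
#' only; the transforms are exact for the continuous physics, so this
#' enlarges the training distribution without new simulations.
#'
#' @param ds an \code{xclt_dataset}.
#' @param indices records to augment (default: all).
#' @return an \code{xclt_dataset} with \code{8 * length(indices)} records.
#' @export
augment_dataset <- function(ds, indices = seq_len(dim(ds$sinos)[1])) {
  n <- length(indices)
  N <- ds$N
  geo <- ds$geometry
  sinos_raw <- array(0, c(8 * n, geo$n_angles, geo$n_sheets))
  sinos <- array(0, c(8 * n, N, N))
  images <- array(0, c(8 * n, N, N))
  k <- 0
  for (i in indices) {
    for (mirror in c(FALSE, TRUE)) for (rot in 0:3) {
      k <- k + 1
      raw <- augment_raw(ds$sinos_raw[i, , ], rot, mirror)
      sinos_raw[k, , ] <- raw
      mx <- max(raw)
      sinos[k, , ] <- bilinear_resize(if (mx > 0) raw / mx else raw, N, N)
      images[k, , ] <- augment_image(ds$images[i, , ], rot, mirror)
    }
  }
  structure(list(sinos_raw = sinos_raw, sinos = sinos, images = images,
                 specs = rep(ds$specs[indices], each = 8), geometry = geo,
                 N = N, base_seed = ds$base_seed,
                 domain_radius = ds$domain_radius),
            class = "xclt_dataset")
}

#' Input standardization for network training
#'
#' The max-normalized sinograms of different phantoms share a dominant
#' background-yield response and differ from each other by only a few
#' percent, which conditions gradient-based training very poorly.  The
#' networks therefore consume standardized inputs: the training-set mean
#' sinogram is subtracted and the residual divided by its global standard
#' deviation.  The statistics are stored with the model and re-applied by
#' \code{\link{reconstruct}}, so the public data contract (sinograms in
#' [0, 1]) is unchanged.
#'
#' @param sinos (n, N, N) array of training sinograms.
#' @return list with the mean image \code{center} and scalar \code{scale}.
#' @export
sinogram_preproc <- function(sinos) {
  ctr <- apply(sinos, c(2, 3), mean)
  resid <- sweep(sinos, c(2, 3), ctr)
  list(center = ctr, scale = max(stats::sd(resid), 1e-12))
}

#' @rdname sinogram_preproc
#' @param pp a \code{sinogram_preproc} result.
#' @param x an N x N sinogram or an (n, N, N) array of them.
#' @return the standardized array, same shape.
#' @export
apply_preproc <- function(pp, x) {
  if (length(dim(x)) == 2) (x - pp$center) / pp$scale
  else sweep(x, c(2, 3), pp$center) / pp$scale
}

#' Filtered-backprojection reconstructions for dataset records
#'
#' Reconstructs from the raw (noisy) sinograms onto the dataset's N x N
#' grid.
#'
#' @param ds an \code{xclt_dataset}.
#' @param indices records to reconstruct.
#' @param filter an \code{\link{fbp_filter}}.
#' @return list of N x N images in [0, 1].
#' @export
fbp_dataset <- function(ds, indices, filter = fbp_filter("ramp")) {
  op <- radon_operator(ds$N, ds$geometry$angles, ds$geometry$offsets,
                       ds$domain_radius)
  lapply(indices, function(i) fbp_reconstruct(ds$sinos_raw[i, , ], op, filter))
}

#' Network reconstructions for dataset records
#'
#' @param ds an \code{xclt_dataset}.
#' @param model a trained \code{recon_model}.
#' @param indices records to reconstruct.
#' @return list of N x N images in [0, 1].
#' @export
model_dataset <- function(ds, model, indices) {
  rec <- reconstruct(model, ds$sinos[indices, , , drop = FALSE])
  lapply(seq_along(indices), function(i) rec[i, , ])
}

dataset_gt <- function(ds, indices) lapply(indices, function(i) ds$images[i, , ])

#' Run one of the simulation experiments
#'
#' \describe{
#'   \item{single_target}{train Swin-CNN and AUTOMAP on a single-target
#'     pool; compare both with FBP on the held-out test set.}
#'   \item{resolution}{train Swin-CNN on a mixed 1--2-target pool; test on
#'     two-target phantoms with edge-to-edge separations 2/4/6/8 mm.}
#'   \item{robustness}{train Swin-CNN on the mixed pool; test on
#'     three-target phantoms scanned with 30 and with 50 parallel sheets.}
#'   \item{ablation}{train the three Swin variants (full, without-CNN,
#'     without-locality) over several seeds on the single-target pool and
#'     compare mean metrics.}
#' }
#'
#' @param kind experiment name (see details).
#' @param profile an \code{\link{xclt_profile}} list.
#' @param seed master seed; all dataset and model seeds derive from it.
#' @param seeds (ablation only) vector of training seeds.
#' @param methods subset of \code{c("fbp", "automap", "swin_cnn")} for the
#'   non-ablation experiments.
#' @param out_dir if non-NULL, write per-method CSV metric tables, a JSON
#'   summary and a profile-plot PNG there.
#' @param verbose print progress.
#' @return a list with per-method \code{\link{metric_report}}s, the mean
#'   metric table, and pairwise improvement percentages.
#' @export
run_experiment <- function(kind = c("single_target", "resolution",
                                    "robustness", "ablation"),
                           profile = xclt_profile("desk"), seed = 1L,
                           seeds = 1:3,
                           methods = c("fbp", "automap", "swin_cnn"),
                           out_dir = NULL, verbose = FALSE) {
  kind <- match.arg(kind)
  mesh <- build_mesh(50, profile$mesh_edge)
  say <- function(...) if (verbose) message(sprintf(...))
  reports <- list()

  if (kind == "single_target") {
    ds <- generate_dataset(profile$n, seed * 1000L, mesh, profile$geometry,
                           profile$N, n_targets = 1L)
    sp <- split_dataset(ds, profile$split)
    gt <- dataset_gt(ds, sp$test)
    if ("fbp" %in% methods)
      reports$fbp <- metric_report(gt, fbp_dataset(ds, sp$test))
    for (mk in intersect(methods, c("automap", "swin_cnn"))) {
      say("training %s ...", mk)
      mdl <- run_training(ds, mk, profile$net, sp, profile$train,
                          seed = seed, verbose = verbose)
      reports[[mk]] <- metric_report(gt, model_dataset(ds, mdl, sp$test))
    }
  } else if (kind == "resolution") {
    ds <- generate_dataset(profile$n, seed * 1000L, mesh, profile$geometry,
                           profile$N, n_targets = "mixed12")
    sp <- split_dataset(ds, profile$split)
    n_test <- profile$split[3]
    test_ds <- generate_dataset(n_test, seed * 1000L + 600000L, mesh,
                                profile$geometry, profile$N,
                                separations = c(2, 4, 6, 8))
    gt <- dataset_gt(test_ds, seq_len(n_test))
    if ("fbp" %in% methods)
      reports$fbp <- metric_report(gt, fbp_dataset(test_ds, seq_len(n_test)))
    for (mk in intersect(methods, c("automap", "swin_cnn"))) {
      say("training %s ...", mk)
      mdl <- run_training(ds, mk, profile$net, sp, profile$train,
                          seed = seed, verbose = verbose)
      reports[[mk]] <- metric_report(gt, model_dataset(test_ds, mdl,
                                                       seq_len(n_test)))
    }
  } else if (kind == "robustness") {
    ds <- generate_dataset(profile$n, seed * 1000L, mesh, profile$geometry,
                           profile$N, n_targets = "mixed12")
    sp <- split_dataset(ds, profile$split)
    say("training swin_cnn ...")
    mdl <- run_training(ds, "swin_cnn", profile$net, sp, profile$train,
                        seed = seed, verbose = verbose)
    n_test <- profile$split[3]
    for (ns in c(30L, 50L)) {
      geo <- scan_geometry(n_sheets = ns, sheet_step = 100 / ns,
                           noise_level = profile$geometry$noise_level)
      test_ds <- generate_dataset(n_test, seed * 1000L + 700000L + ns, mesh,
                                  geo, profile$N, n_targets = 3L)
      gt <- dataset_gt(test_ds, seq_len(n_test))
      tag <- sprintf("sheets%d", ns)
      reports[[paste0("fbp_", tag)]] <-
        metric_report(gt, fbp_dataset(test_ds, seq_len(n_test)))
      reports[[paste0("swin_cnn_", tag)]] <-
        metric_report(gt, model_dataset(test_ds, mdl, seq_len(n_test)))
    }
  } else {  # ablation
    ds <- generate_dataset(profile$n, seed * 1000L, mesh, profile$geometry,
                           profile$N, n_targets = 1L)
    sp <- split_dataset(ds, profile$split)
    gt <- dataset_gt(ds, sp$test)
    kinds <- c("swin_cnn", "swin_without_cnn", "swin_without_locality")
    for (mk in kinds) {
      per_seed <- lapply(seeds, function(s) {
        say("training %s (seed %d) ...", mk, s)
        mdl <- run_training(ds, mk, profile$net, sp, profile$train,
                            seed = s, verbose = FALSE)
        metric_report(gt, model_dataset(ds, mdl, sp$test))
      })
      means <- sapply(per_seed, function(r) r$aggregate$mean)
      reports[[mk]] <- list(per_seed = per_seed,
                            mean = rowMeans(means),
                            sd = apply(means, 1, stats::sd))
    }
  }

  summary_tab <- if (kind == "ablation")
    do.call(rbind, lapply(reports, function(r) r$mean))
  else
    do.call(rbind, lapply(reports, function(r) r$aggregate$mean))
  improvements <- experiment_improvements(summary_tab)
  res <- list(kind = kind, reports = reports, summary = summary_tab,
              improvements = improvements, seed = seed)
  if (!is.null(out_dir)) write_experiment(res, out_dir,
                                          ds_for_profiles = NULL)
  res
}

## pairwise improvement table: every non-baseline method vs every other
experiment_improvements <- function(tab) {
  mn <- rownames(tab)
  out <- list()
  for (a in mn) for (b in mn) {
    if (a == b) next
    out[[paste(a, "vs", b)]] <- c(
      mse_reduction_pct = improvement_pct(tab[a, "mse"], tab[b, "mse"],
                                          lower_is_better = TRUE),
      psnr_gain_pct = improvement_pct(tab[a, "psnr"], tab[b, "psnr"]),
      pc_gain_pct = improvement_pct(tab[a, "pc"], tab[b, "pc"]))
  }
  out
}

write_experiment <- function(res, out_dir, ds_for_profiles = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(res$reports)) {
    r <- res$reports[[nm]]
    if (inherits(r, "metric_report"))
      utils::write.csv(r$per_image,
                       file.path(out_dir, paste0("metrics_", nm, ".csv")),
                       row.names = FALSE)
  }
  utils::write.csv(data.frame(method = rownames(res$summary), res$summary),
                   file.path(out_dir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(res$improvements,
                       file.path(out_dir, "improvements.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Profile plot through reconstructed images
#'
#' Plots ground truth and reconstructions along one image row (the row
#' through the image center by default), the standard way to visualize
#' whether two nearby targets are resolved.
#'
#' @param gt ground-truth image.
#' @param recs named list of reconstructed images.
#' @param row image row to section (default: center).
#' @param file optional PNG path.
#' @export
plot_profiles <- function(gt, recs, row = nrow(gt) %/% 2, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 500)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(gt[row, ], type = "l", lwd = 2, xlab = "pixel",
                 ylab = "normalized yield", ylim = c(0, 1.05),
                 main = sprintf("profile along row %d", row))
  cols <- seq_along(recs) + 1
  for (i in seq_along(recs))
    graphics::lines(recs[[i]][row, ], col = cols[i], lty = 2, lwd = 2)
  graphics::legend("topright", c("ground truth", names(recs)),
                   col = c(1, cols), lty = c(1, rep(2, length(recs))),
                   lwd = 2, bty = "n")
  invisible(NULL)
}
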