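## Image-quality metrics: MSE, PSNR and Pearson correlation between a
## ground-truth yield image GT and a reconstruction R, plus per-set
## aggregation.  Both images are conventionally max-normalized before
## metric computation (see normalize_max).

#' Normalize an image to maximum 1
#'
#' @param img numeric matrix.
#' @return the image divided by its maximum (unchanged if the maximum is 0).
#' @export
normalize_max <- function(img) {
  mx <- max(img)
  if (mx > 0) img / mx else img
}

#' Mean square error between two images
#'
#' \eqn{MSE = \frac{1}{N^2}\sum_{ij} (GT_{ij} - R_{ij})^2}.
#'
#' @param gt,rec equally sized numeric matrices.
#' @return non-negative scalar.
#' @export
img_mse <- function(gt, rec) {
  if (!all(dim(gt) == dim(rec))) stop("image shapes differ")
  mean((gt - rec)^2)
}

#' Peak signal-to-noise ratio (dB)
#'
#' \eqn{PSNR = 10\log_{10}(\max(GT)^2 / MSE)}.
#'
#' @inheritParams img_mse
#' @return PSNR in dB; errors on identical images (infinite PSNR).
#' @export
img_psnr <- function(gt, rec) {
  m <- img_mse(gt, rec)
  if (m == 0) stop("identical images: PSNR is infinite")
  10 * log10(max(gt)^2 / m)
}

#' Pearson correlation between two images
#'
#' Computed over all pixels (background included).
#'
#' @inheritParams img_mse
#' @return correlation in [-1, 1]; errors if either image is constant.
#' @export
img_pearson <- function(gt, rec) {
  if (!all(dim(gt) == dim(rec))) stop("image shapes differ")
  if (stats::sd(gt) == 0 || stats::sd(rec) == 0)
    stop("constant image: Pearson correlation undefined")
  stats::cor(as.vector(gt), as.vector(rec))
}

#' Metric report for a set of reconstructions
#'
#' Computes MSE, PSNR and Pearson correlation per image (after
#' max-normalizing both ground truth and reconstruction) and aggregates
#' mean and standard deviation.
#'
#' @param gt_list,rec_list lists of equally sized matrices.
#' @param ids optional image identifiers.
#' @param normalize max-normalize both images first (default TRUE).
#' @return a \code{metric_report}: list with \code{per_image} data frame
#'   (id, mse, psnr, pc) and \code{aggregate} (mean and sd per metric).
#' @export
metric_report <- function(gt_list, rec_list, ids = NULL, normalize = TRUE) {
  stopifnot(length(gt_list) == length(rec_list))
  n <- length(gt_list)
  if (is.null(ids)) ids <- seq_len(n)
  rows <- vapply(seq_len(n), function(i) {
    gt <- gt_list[[i]]; rec <- rec_list[[i]]
    if (normalize) { gt <- normalize_max(gt); rec <- normalize_max(rec) }
    c(img_mse(gt, rec), img_psnr(gt, rec), img_pearson(gt, rec))
  }, numeric(3))
  per_image <- data.frame(id = ids, mse = rows[1, ], psnr = rows[2, ],
                          pc = rows[3, ])
  agg <- list(
    mean = c(mse = mean(per_image$mse), psnr = mean(per_image$psnr),
             pc = mean(per_image$pc)),
    sd = c(mse = stats::sd(per_image$mse), psnr = stats::sd(per_image$psnr),
           pc = stats::sd(per_image$pc)))
  structure(list(per_image = per_image, aggregate = agg),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  m <- x$aggregate$mean; s <- x$aggregate$sd
  cat(sprintf("Metrics over %d images:\n", nrow(x$per_image)))
  cat(sprintf("  MSE  %.4f +- %.4f\n  PSNR %.2f +- %.2f dB\n  PC   %.4f +- %.4f\n",
              m["mse"], s["mse"], m["psnr"], s["psnr"], m["pc"], s["pc"]))
  invisible(x)
}

#' Write a metric report as CSV + JSON aggregate
#'
#' @param report a \code{\link{metric_report}}.
#' @param csv_file per-image CSV path.
#' @param json_file aggregate JSON path (optional).
#' @export
write_metric_report <- function(report, csv_file, json_file = NULL) {
  utils::write.csv(report$per_image, csv_file, row.names = FALSE)
  if (!is.null(json_file))
    jsonlite::write_json(lapply(report$aggregate, as.list), json_file,
                         auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Relative improvement of one method over another (percent)
#'
#' For PSNR/PC (higher is better): \code{100 * (m_new - m_base) / m_base};
#' for MSE (lower is better): \code{100 * (m_base - m_new) / m_base}.
#'
#' @param new_value,base_value metric values for the new method and the
#'   baseline.
#' @param lower_is_better TRUE for error-type metrics such as MSE.
#' @return percentage improvement.
#' @export
improvement_pct <- function(new_value, base_value, lower_is_better = FALSE) {
  if (lower_is_better) 100 * (base_value - new_value) / base_value
  else 100 * (new_value - base_value) / base_value
}
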