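check_image <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(arg, " must be a numeric matrix of intensities", call. = FALSE)
  }
  if (nrow(img) < 2 || ncol(img) < 2) {
    stop(arg, " must be at least 2x2 pixels", call. = FALSE)
  }
  if (any(!is.finite(img)) || any(img < 0)) {
    stop(arg, " intensities must be finite and non-negative", call. = FALSE)
  }
  invisible(img)
}

check_mask <- function(mask, img) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("mask must be a logical matrix", call. = FALSE)
  }
  if (!identical(dim(mask), dim(img))) {
    stop("mask and image dimensions differ", call. = FALSE)
  }
  invisible(mask)
}

otsu_level <- function(values) {
  rng <- range(values)
  if (rng[1] == rng[2]) {
    stop("cannot threshold an image with constant intensity", call. = FALSE)
  }
  # EBImage's Otsu works on a 2-D image; feed the values as a 1 x n strip
  EBImage::otsu(matrix(values, nrow = 1), range = rng,
                levels = max(256L, length(unique(values))))
}

#' Segment the cell region of a fluorescence image
#'
#' Stands in for the manual cell outline drawn during quantification: the
#' image is thresholded (Otsu's method by default, or a fixed level), the
#' largest connected above-threshold component is kept, and its holes are
#' filled.
#'
#' @param img Numeric intensity matrix (grayscale, non-negative).
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param level Threshold level, required when `method = "fixed"`.
#' @return A logical mask matrix the same shape as `img`.
#' @export
segment_mask <- function(img, method = c("otsu", "fixed"), level = NULL) {
  check_image(img)
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(level) || !is.numeric(level) || length(level) != 1) {
      stop("a single numeric level is required when method = \"fixed\"",
           call. = FALSE)
    }
  } else {
    level <- otsu_level(as.vector(img))
  }
  fg <- img > level
  if (!any(fg)) stop("no cell found: nothing above the threshold", call. = FALSE)
  labels <- EBImage::bwlabel(fg)
  sizes <- tabulate(labels[labels > 0])
  keep <- which.max(sizes)
  mask <- labels == keep
  filled <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0
  matrix(as.logical(filled), nrow = nrow(img), ncol = ncol(img))
}

#' Coalescence index of a fluorescence signal within a cell outline
#'
#' Summarizes how organized (ring-like or punctate) versus diffuse a signal
#' is inside the cell region. The in-mask intensities are min-max normalized
#' to \eqn{[0, 1]} and the index is their mean divided by their sample
#' (\eqn{n - 1}) standard deviation. With
#' `preprocess = "binary"` the in-mask values are first binarized at an
#' Otsu level computed within the mask, in which case the index has the
#' closed form \eqn{p / \sqrt{p (1 - p)\, n / (n - 1)}} for an above-
#' threshold pixel fraction \eqn{p}.
#'
#' The index is undefined (an error) when the in-mask values have no spread.
#' Min-max normalization makes it invariant to affine intensity maps
#' \eqn{v \mapsto a v + b}, \eqn{a > 0}.
#'
#' @param img Numeric intensity matrix.
#' @param mask Logical matrix congruent with `img`, at least 2 pixels `TRUE`.
#' @param preprocess `"raw"` (default) or `"binary"`.
#' @return A one-row tibble of class `coalescence_result` with columns
#'   `ci`, `n_pixels`, `preprocess`.
#' @export
#' @examples
#' img <- matrix(c(0, 1, 0, 1), 2, 2)
#' coalescence_index(img, matrix(TRUE, 2, 2))$ci  # 0.5 / sqrt(1/3)
coalescence_index <- function(img, mask, preprocess = c("raw", "binary")) {
  check_image(img)
  check_mask(mask, img)
  preprocess <- match.arg(preprocess)
  v <- img[mask]
  n <- length(v)
  if (n < 2) stop("mask must contain at least 2 pixels", call. = FALSE)
  if (max(v) == min(v)) {
    stop("coalescence index undefined: no intensity spread within the mask",
         call. = FALSE)
  }
  if (preprocess == "binary") {
    v <- as.numeric(v > otsu_level(v))
    if (max(v) == min(v)) {
      stop("coalescence index undefined: binarization left no spread",
           call. = FALSE)
    }
  }
  z <- (v - min(v)) / (max(v) - min(v))
  out <- tibble::tibble(
    ci = mean(z) / stats::sd(z),
    n_pixels = n,
    preprocess = preprocess
  )
  class(out) <- c("coalescence_result", class(out))
  out
}

#' Ratio of integrated intensities between two channels
#'
#' For the published screen this is the phosphomyosin:actin ratio — the
#' integrated (summed) in-mask intensity of the phosphomyosin channel
#' divided by the integrated in-mask phalloidin intensity of the same cell.
#'
#' @param channel_a,channel_b Numeric intensity matrices of equal shape.
#' @param mask Logical matrix congruent with the channels.
#' @return A single numeric ratio.
#' @export
intensity_ratio <- function(channel_a, channel_b, mask) {
  check_image(channel_a, "channel_a")
  check_image(channel_b, "channel_b")
  if (!identical(dim(channel_a), dim(channel_b))) {
    stop("channel dimensions differ", call. = FALSE)
  }
  check_mask(mask, channel_a)
  denom <- sum(channel_b[mask])
  if (denom <= 0) {
    stop("integrated intensity of channel_b within the mask is zero",
         call. = FALSE)
  }
  sum(channel_a[mask]) / denom
}

#' Normalize per-cell intensities by the brightest cell
#'
#' Divides each cell's fluorescence intensity by the highest intensity in
#' the set, so the brightest cell maps to 1.
#'
#' @param cell_values Nonempty numeric vector of positive intensities.
#' @return Numeric vector of the same length on \eqn{(0, 1]}.
#' @export
normalized_mean_intensity <- function(cell_values) {
  if (length(cell_values) == 0 || !is.numeric(cell_values)) {
    stop("cell_values must be a nonempty numeric vector", call. = FALSE)
  }
  m <- max(cell_values)
  if (!is.finite(m) || m <= 0) {
    stop("maximum intensity must be positive", call. = FALSE)
  }
  cell_values / m
}

#' Fraction of contracted cells per frame and pooled
#'
#' Tallies a contractility assay: per image frame, the number of contracted
#' cells over contracted plus relaxed, with ambiguous cell states excluded
#' from the denominator. Frames with no unambiguous cell are reported as
#' undefined (`NA`), not zero.
#'
#' @param counts A data frame with non-negative integer columns
#'   `contracted`, `relaxed`, `ambiguous` (one row per frame); a missing
#'   `ambiguous` column is treated as zeros.
#' @return A `contraction_tally`: the per-frame tibble gains `fraction` and
#'   `undefined` columns; [glance()] gives the pooled fraction.
#' @export
#' @examples
#' contraction_fraction(data.frame(contracted = c(3, 0),
#'                                 relaxed = c(7, 10), ambiguous = c(1, 0)))
contraction_fraction <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("contracted", "relaxed") %in% names(counts)))
  if (is.null(counts$ambiguous)) counts$ambiguous <- 0
  vals <- c(counts$contracted, counts$relaxed, counts$ambiguous)
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  per_frame <- tibble::as_tibble(counts) |>
    dplyr::mutate(
      denominator = .data$contracted + .data$relaxed,
      fraction = ifelse(.data$denominator > 0,
                        .data$contracted / .data$denominator, NA_real_),
      undefined = .data$denominator == 0
    )
  pooled_denom <- sum(per_frame$denominator)
  structure(
    list(
      per_frame = per_frame,
      pooled = if (pooled_denom > 0) sum(per_frame$contracted) / pooled_denom
               else NA_real_
    ),
    class = "contraction_tally"
  )
}

#' @export
print.contraction_tally <- function(x, ...) {
  cat("<contraction_tally> ", nrow(x$per_frame), " frame(s), pooled fraction ",
      format(x$pooled, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @rdname contraction_fraction
#' @param x A `contraction_tally`.
#' @param ... Unused.
#' @export
tidy.contraction_tally <- function(x, ...) {
  x$per_frame
}

#' @rdname contraction_fraction
#' @export
glance.contraction_tally <- function(x, ...) {
  tibble::tibble(
    n_frames = nrow(x$per_frame),
    n_undefined_frames = sum(x$per_frame$undefined),
    pooled_fraction = x$pooled
  )
}

#' Plot per-frame contracted-cell fractions
#'
#' @param object A `contraction_tally`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contraction_tally <- function(object, ...) {
  df <- object$per_frame |>
    dplyr::mutate(frame = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$fraction)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = object$pooled, linetype = 2) +
    ggplot2::labs(x = "frame", y = "fraction contracted",
                  title = "Contracted-cell fraction per frame") +
    ggplot2::theme_minimal()
}

#' Read a single-channel image into an intensity matrix
#'
#' Accepts TIFF or PNG; multi-channel images are averaged to one channel.
#'
#' @param path Image path.
#' @return Numeric matrix of non-negative intensities.
#' @export
read_cell_image <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) > 2) dat <- apply(dat, c(1, 2), mean)
  check_image(matrix(as.numeric(dat), nrow = nrow(dat)))
}
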