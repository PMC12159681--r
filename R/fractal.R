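#' Box-counting fractal dimension of a binary image
#'
#' Counts, for each box size, the boxes of a fixed-origin grid containing at
#' least one foreground pixel, and returns the negative slope of the
#' least-squares fit of log(count) against log(box size). Default box sizes
#' are dyadic, from 2 px up to a quarter of the smaller image side.
#'
#' @param image logical or 0/1 matrix; `TRUE`/non-zero is foreground.
#' @param box_sizes integer box edge lengths in px; at least 3, spanning at
#'   least one octave.
#' @param region optional logical matrix restricting the analysis.
#' @return list with `fd`, `box_sizes`, `counts` and the fitted `intercept`.
#' @export
#' @examples
#' img <- matrix(FALSE, 64, 64); img[32, ] <- TRUE
#' box_counting_fd(img)$fd  # about 1
box_counting_fd <- function(image, box_sizes = NULL, region = NULL) {
  if (is.numeric(image)) image <- image != 0
  stopifnot(is.matrix(image), is.logical(image))
  if (!is.null(region)) {
    stopifnot(is.logical(region), all(dim(region) == dim(image)))
    image <- image & region
  }
  if (!any(image)) stop_domain("image contains no foreground pixels")
  if (is.null(box_sizes)) {
    smax <- floor(min(dim(image)) / 4)
    box_sizes <- 2^(1:floor(log2(smax)))
  }
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (length(box_sizes) < 3L)
    stop_domain("at least 3 box sizes are required")
  if (max(box_sizes) < 2 * min(box_sizes))
    stop_domain("box sizes must span at least one octave")
  idx <- which(image, arr.ind = TRUE)
  counts <- vapply(box_sizes, function(s) {
    nrow(unique(cbind((idx[, 1] - 1L) %/% s, (idx[, 2] - 1L) %/% s)))
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, log(box_sizes)), log(counts))
  list(fd = -as.numeric(fit$coefficients[2]),
       box_sizes = box_sizes, counts = counts,
       intercept = as.numeric(fit$coefficients[1]))
}

#' Summarize per-slice fractal dimensions over a short-axis stack
#'
#' The global value is the mean over all slices; the maximal apical value is
#' the maximum over the apical half of the stack.
#'
#' @param fds numeric vector of per-slice FDs, ordered base to apex.
#' @return list with `global` and `max_apical`.
#' @export
fd_summarize <- function(fds) {
  stopifnot(is.numeric(fds), length(fds) >= 1L)
  apical <- fds[seq.int(ceiling(length(fds) / 2) + as.integer(length(fds) > 1),
                        length(fds))]
  if (length(fds) == 1L) apical <- fds
  list(global = mean(fds), max_apical = max(apical))
}

#' Read a binary mask from a PNG file
#'
#' Convenience reader for externally produced trabeculation masks; any pixel
#' with mean channel intensity above 0.5 is foreground.
#'
#' @param path PNG file path.
#' @return logical matrix.
#' @export
read_mask_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop_domain("reading PNG masks requires the 'png' package")
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3, dim(a)[3])), drop = FALSE],
                                       c(1, 2), mean)
  a > 0.5
}
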