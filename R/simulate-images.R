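#' Simulate granular and diffuse fluorescence images
#'
#' Builds matched pairs of cell images for granularity benchmarking. Each
#' image is a square intensity grid with a circular "cytoplasm" mask.
#' Granular cells concentrate the signal in at most `max_foci` Gaussian foci
#' inside the mask (cytoplasmic granules); diffuse cells spread it uniformly
#' plus optional white noise. All images are rescaled so the summed
#' intensity inside the mask is exactly `total_intensity`, making the
#' classes comparable in total signal and separable only by its spatial
#' distribution.
#'
#' @param n_granular,n_diffuse number of cells per class.
#' @param total_intensity summed masked intensity per cell.
#' @param seed integer seed.
#' @param side image side length in pixels.
#' @param noise_sd white-noise SD for diffuse cells, as a fraction of the
#'   uniform level (0 gives perfectly flat diffuse cells, CV = 0).
#' @param max_foci maximum number of granules per granular cell.
#' @param focus_sd granule Gaussian SD in pixels.
#' @return list of `masked_image` objects, each a list with `image` (numeric
#'   matrix), `mask` (logical matrix) and `label` (`"granular"` or
#'   `"diffuse"`).
#' @examples
#' cells <- simulate_images(3, 3, total_intensity = 1e5, seed = 1)
#' cells[[1]]$label
#' @export
simulate_images <- function(n_granular, n_diffuse, total_intensity = 1e6,
                            seed = 1L, side = 64L, noise_sd = 0.05,
                            max_foci = 10L, focus_sd = 2) {
  set.seed(derive_seed(seed, "images"))
  ctr <- (side + 1) / 2
  xy <- expand.grid(row = seq_len(side), col = seq_len(side))
  mask <- matrix(sqrt((xy$row - ctr)^2 + (xy$col - ctr)^2) <= side * 0.38,
                 side, side)
  one_cell <- function(label) {
    img <- matrix(0, side, side)
    if (label == "granular") {
      n_foci <- sample(3:max_foci, 1L)
      inside <- which(mask, arr.ind = TRUE)
      centers <- inside[sample(nrow(inside), n_foci), , drop = FALSE]
      for (f in seq_len(n_foci)) {
        img <- img + exp(-((xy$row - centers[f, 1])^2 +
                           (xy$col - centers[f, 2])^2) / (2 * focus_sd^2))
      }
    } else {
      img[] <- 1
      if (noise_sd > 0) {
        img <- img + matrix(rnorm(side^2, 0, noise_sd), side, side)
        img[img < 0] <- 0
      }
    }
    img[!mask] <- 0
    s <- sum(img[mask])
    if (s <= 0) stop("degenerate image: no signal inside mask")
    img <- img * (total_intensity / s)
    structure(list(image = img, mask = mask, label = label),
              class = "masked_image")
  }
  c(lapply(seq_len(n_granular), function(i) one_cell("granular")),
    lapply(seq_len(n_diffuse), function(i) one_cell("diffuse")))
}

#' Write / read an intensity grid as whitespace-delimited text
#'
#' Plain-text interchange for images and masks (one matrix row per line).
#' TIFF input is supported through [read_image_tiff()] when the `tiff`
#' package is installed.
#'
#' @param m numeric (or logical) matrix.
#' @param path file path.
#' @export
write_image_grid <- function(m, path) {
  write.table(m * 1, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_image_grid
#' @export
read_image_grid <- function(path) {
  as.matrix(read.table(path, header = FALSE))
}

#' Read a grayscale TIFF image as an intensity matrix
#'
#' @param path TIFF file path.
#' @return numeric matrix of pixel intensities.
#' @export
read_image_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("reading TIFF requires the 'tiff' package; ",
         "use read_image_grid() for plain-text grids")
  }
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}
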