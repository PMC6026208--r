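#' Specify a synthetic ommatidial lattice
#'
#' Describes a hexagonally packed field of ommatidia with controllable
#' positional disorder.  Wild-type compound eyes pack ommatidia on a
#' near-perfect hexagonal lattice; rough-eye phenotypes perturb it.  The
#' generator emulates this with offset-row packing (odd rows shifted by half
#' the spacing, row pitch \code{spacing * sqrt(3)/2}), isotropic Gaussian
#' positional jitter, independent site dropout, and pairwise fusion of
#' neighbouring facets.
#'
#' @param n_rows,n_cols Lattice dimensions (facet counts).
#' @param spacing Centre-to-centre distance of adjacent ommatidia, in pixels.
#' @param ommatidium_radius Facet radius in pixels; rendered blobs are
#'   isotropic Gaussians with SD \code{ommatidium_radius/2}, truncated at 3 SD.
#' @param jitter_sigma SD (pixels) of the isotropic positional noise added
#'   independently to each axis of each surviving centre.
#' @param dropout_rate Probability that a lattice site is removed.
#' @param fusion_rate Probability that a surviving site fuses with its nearest
#'   surviving neighbour; the pair is replaced by a single blob at the
#'   midpoint.
#' @param background_noise_sd SD of additive Gaussian pixel noise (intensity
#'   units; images are scaled to \code{[0, 1]}).
#' @param seed Integer seed; identical specs give byte-identical images.
#'
#' @return An object of class \code{lattice_spec}.
#' @seealso [generate_eye_image()]
#' @export
lattice_spec <- function(n_rows = 20L, n_cols = 20L, spacing = 10,
                         ommatidium_radius = 3, jitter_sigma = 0,
                         dropout_rate = 0, fusion_rate = 0,
                         background_noise_sd = 0, seed = 1L) {
  n_rows <- assert_count(n_rows, "n_rows")
  n_cols <- assert_count(n_cols, "n_cols")
  if (!is.numeric(spacing) || spacing <= 0) {
    stop("'spacing' must be positive", call. = FALSE)
  }
  if (!is.numeric(ommatidium_radius) || ommatidium_radius <= 0) {
    stop("'ommatidium_radius' must be positive", call. = FALSE)
  }
  if (spacing <= ommatidium_radius) {
    stop("'spacing' must exceed 'ommatidium_radius' (facets must not overlap)",
         call. = FALSE)
  }
  if (!is.numeric(jitter_sigma) || jitter_sigma < 0) {
    stop("'jitter_sigma' must be >= 0", call. = FALSE)
  }
  assert_fraction(dropout_rate, "dropout_rate")
  assert_fraction(fusion_rate, "fusion_rate")
  if (!is.numeric(background_noise_sd) || background_noise_sd < 0) {
    stop("'background_noise_sd' must be >= 0", call. = FALSE)
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, spacing = spacing,
                 ommatidium_radius = ommatidium_radius,
                 jitter_sigma = jitter_sigma, dropout_rate = dropout_rate,
                 fusion_rate = fusion_rate,
                 background_noise_sd = background_noise_sd,
                 seed = as.integer(seed)),
            class = "lattice_spec")
}

# Ideal offset-row hexagonal lattice positions, origin at the top-left pixel
# centre (x = column, y = row).
#' @keywords internal
#' @noRd
hex_lattice_centers <- function(n_rows, n_cols, spacing, pad) {
  rows <- rep(seq_len(n_rows), each = n_cols)
  cols <- rep(seq_len(n_cols), times = n_rows)
  x <- pad + (cols - 1) * spacing + ifelse(rows %% 2 == 0, spacing / 2, 0)
  y <- pad + (rows - 1) * spacing * sqrt(3) / 2
  data.frame(x = x, y = y)
}

#' Render a synthetic eye-surface image with known centres
#'
#' Draws one radially symmetric Gaussian blob per surviving lattice site onto
#' a grayscale canvas, applying (in order) positional jitter, independent
#' dropout, and pairwise fusion, then additive background noise.  The returned
#' ground-truth table lists the post-dropout/fusion centres, which is what a
#' perfect detector should recover.
#'
#' @param spec A [lattice_spec()].
#' @return A list with components \code{image} (an \code{eye_image}: pixel
#'   matrix in \code{[0, 1]} plus provenance) and \code{centers} (data frame
#'   \code{id}, \code{x}, \code{y} of true blob centres, sub-pixel, origin at
#'   the top-left pixel centre).
#' @examples
#' out <- generate_eye_image(lattice_spec(n_rows = 8, n_cols = 8, seed = 7))
#' nrow(out$centers)
#' @export
generate_eye_image <- function(spec) {
  if (!inherits(spec, "lattice_spec")) {
    stop("'spec' must be a lattice_spec", call. = FALSE)
  }
  blob_sd <- spec$ommatidium_radius / 2
  pad <- ceiling(spec$spacing + 3 * blob_sd)
  with_seed(spec$seed, {
    centers <- hex_lattice_centers(spec$n_rows, spec$n_cols, spec$spacing, pad)
    n0 <- nrow(centers)
    # jitter, then dropout, then fusion -- each drawn from the same stream
    centers$x <- centers$x + rnorm(n0, 0, spec$jitter_sigma)
    centers$y <- centers$y + rnorm(n0, 0, spec$jitter_sigma)
    keep <- runif(n0) >= spec$dropout_rate
    centers <- centers[keep, , drop = FALSE]
    centers <- apply_fusion(centers, spec$fusion_rate)
    img <- render_blobs(centers,
                        width  = ceiling((spec$n_cols - 1) * spec$spacing +
                                           spec$spacing / 2 + 2 * pad) + 1L,
                        height = ceiling((spec$n_rows - 1) * spec$spacing *
                                           sqrt(3) / 2 + 2 * pad) + 1L,
                        blob_sd = blob_sd)
    if (spec$background_noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, spec$background_noise_sd),
                          nrow = nrow(img))
    }
    img <- pmin(pmax(img, 0), 1)
    centers <- data.frame(id = seq_len(nrow(centers)),
                          x = centers$x, y = centers$y)
    list(image = eye_image(img, provenance = "synthetic hexagonal lattice"),
         centers = centers)
  })
}

# Fuse a fraction of sites with their nearest surviving neighbour.  Fusion
# candidates are drawn independently at `rate`; each is merged with its
# nearest not-yet-consumed neighbour (both removed, midpoint added).  A
# candidate whose partner was already consumed is skipped.
#' @keywords internal
#' @noRd
apply_fusion <- function(centers, rate) {
  n <- nrow(centers)
  if (rate <= 0 || n < 2) {
    # consume no RNG when fusion is off so dropout-only runs are unaffected
    return(centers)
  }
  cand <- which(runif(n) < rate)
  if (!length(cand)) return(centers)
  alive <- rep(TRUE, n)
  merged_x <- numeric(0)
  merged_y <- numeric(0)
  for (i in cand) {
    if (!alive[i]) next
    others <- which(alive)
    others <- others[others != i]
    if (!length(others)) break
    d2 <- (centers$x[others] - centers$x[i])^2 +
      (centers$y[others] - centers$y[i])^2
    j <- others[which.min(d2)]
    alive[i] <- FALSE
    alive[j] <- FALSE
    merged_x <- c(merged_x, (centers$x[i] + centers$x[j]) / 2)
    merged_y <- c(merged_y, (centers$y[i] + centers$y[j]) / 2)
  }
  data.frame(x = c(centers$x[alive], merged_x),
             y = c(centers$y[alive], merged_y))
}

# Accumulate truncated Gaussian blobs onto a height x width canvas.
#' @keywords internal
#' @noRd
render_blobs <- function(centers, width, height, blob_sd) {
  img <- matrix(0, nrow = height, ncol = width)
  r <- ceiling(3 * blob_sd)
  for (i in seq_len(nrow(centers))) {
    cx <- centers$x[i]
    cy <- centers$y[i]
    c0 <- max(1L, floor(cx) - r + 1L)
    c1 <- min(width, ceiling(cx) + r + 1L)
    r0 <- max(1L, floor(cy) - r + 1L)
    r1 <- min(height, ceiling(cy) + r + 1L)
    if (c0 > c1 || r0 > r1) next
    xs <- (c0:c1) - 1  # pixel centres in image coordinates
    ys <- (r0:r1) - 1
    gx <- exp(-((xs - cx)^2) / (2 * blob_sd^2))
    gy <- exp(-((ys - cy)^2) / (2 * blob_sd^2))
    patch <- outer(gy, gx)
    patch[patch < exp(-4.5)] <- 0  # truncate at 3 SD
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + patch
  }
  img
}

#' Construct an eye-surface image object
#'
#' @param pixels Numeric matrix of intensities (rows = image rows).
#' @param pixel_size Optional physical pixel size (arbitrary units).
#' @param provenance Free-text origin of the image.
#' @return An object of class \code{eye_image}.
#' @export
eye_image <- function(pixels, pixel_size = NULL, provenance = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("'pixels' must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(pixels))) {
    stop("'pixels' must contain only finite intensities", call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 provenance = provenance),
            class = "eye_image")
}

#' @export
print.eye_image <- function(x, ...) {
  cat(sprintf("<eye_image> %d x %d px, intensity range [%.3g, %.3g]\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Write an eye image to PNG or TIFF
#'
#' PNG output is 8-bit grayscale; TIFF output is stored as 16-bit grayscale.
#'
#' @param image An \code{eye_image}.
#' @param path Output file; format chosen from the extension (.png/.tif/.tiff).
#' @return \code{path}, invisibly.
#' @export
write_eye_image <- function(image, path) {
  stopifnot(inherits(image, "eye_image"))
  px <- pmin(pmax(image$pixels, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(px, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, where = path, bits.per.sample = 16L)
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read an eye image from PNG or TIFF
#'
#' @param path Image file (.png/.tif/.tiff); multi-channel images are
#'   averaged to grayscale.
#' @return An \code{eye_image}.
#' @export
read_eye_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), mean)
  eye_image(px, provenance = path)
}
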