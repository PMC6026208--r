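#' Detect ommatidial centres in an eye-surface image
#'
#' Band-pass filters the image with a difference of Gaussians (smoothing
#' scales 0.2 and 0.6 times the expected facet spacing, which suppresses both
#' pixel noise and slow illumination gradients), finds local intensity maxima
#' above an intensity quantile, enforces a minimum separation of 0.6 times
#' the expected spacing (stronger peaks win), and refines each surviving peak
#' to sub-pixel precision by three-point Gaussian interpolation of the
#' narrow-scale smoothed profile along each axis.  Fully deterministic.
#'
#' Coordinates follow the image convention: x = column, y = row, origin at
#' the centre of the top-left pixel.
#'
#' @param image An \code{eye_image} (or bare numeric matrix).
#' @param expected_spacing Approximate centre-to-centre facet distance in
#'   pixels; must be at least 3.
#' @param threshold_quantile Quantile of the band-passed intensities below
#'   which candidate peaks are discarded.
#' @return An object of class \code{ommatidial_centers}: list with
#'   \code{points} (data frame \code{x}, \code{y}) and \code{N}.
#'   A blank (constant) image yields zero centres, not an error.
#' @examples
#' out <- generate_eye_image(lattice_spec(n_rows = 8, n_cols = 8, seed = 2))
#' detect_ommatidia(out$image, expected_spacing = 10)$N
#' @export
detect_ommatidia <- function(image, expected_spacing,
                             threshold_quantile = 0.95) {
  if (inherits(image, "eye_image")) image <- image$pixels
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("'image' must be an eye_image or numeric matrix", call. = FALSE)
  }
  if (!is.numeric(expected_spacing) || expected_spacing < 3) {
    stop("'expected_spacing' must be >= 3 pixels", call. = FALSE)
  }
  assert_fraction(threshold_quantile, "threshold_quantile")
  empty <- structure(list(points = data.frame(x = numeric(0), y = numeric(0)),
                          N = 0L,
                          params = list(expected_spacing = expected_spacing,
                                        threshold_quantile = threshold_quantile)),
                     class = "ommatidial_centers")
  if (diff(range(image)) < .Machine$double.eps * 100) return(empty)
  narrow <- EBImage::gblur(image, sigma = 0.2 * expected_spacing)
  dog <- narrow - EBImage::gblur(image, sigma = 0.6 * expected_spacing)
  peaks <- local_maxima(dog)
  thr <- stats::quantile(dog, threshold_quantile, names = FALSE)
  peaks <- peaks[dog[peaks] > thr & dog[peaks] > 0]
  if (!length(peaks)) return(empty)
  nr <- nrow(dog)
  pr <- ((peaks - 1L) %% nr) + 1L     # row index
  pc <- ((peaks - 1L) %/% nr) + 1L    # column index
  ord <- order(dog[peaks], decreasing = TRUE)
  pr <- pr[ord]; pc <- pc[ord]
  keep <- suppress_close(pc, pr, min_sep = 0.6 * expected_spacing)
  pr <- pr[keep]; pc <- pc[keep]
  pts <- t(vapply(seq_along(pr), function(i) {
    peak_refine(narrow, pr[i], pc[i])
  }, numeric(2)))
  points <- data.frame(x = pts[, 1], y = pts[, 2])
  points <- points[order(points$y, points$x), , drop = FALSE]
  rownames(points) <- NULL
  structure(list(points = points, N = nrow(points),
                 params = list(expected_spacing = expected_spacing,
                               threshold_quantile = threshold_quantile)),
            class = "ommatidial_centers")
}

#' @export
print.ommatidial_centers <- function(x, ...) {
  cat(sprintf("<ommatidial_centers> N = %d detected\n", x$N))
  invisible(x)
}

# Interior = strictly inside the convex hull of the centre set, by more than
# 0.6 of the median nearest-neighbour spacing.  Hull vertices sit at distance
# zero; collinear boundary points (straight lattice rows) also sit on the
# hull polygon and are equally boundary-truncated, so the test is distance
# to the hull boundary, not hull-vertex membership.
#' @keywords internal
#' @noRd
interior_flags <- function(x, y) {
  n <- length(x)
  hull <- grDevices::chull(x, y)
  if (length(hull) < 3L) return(rep(FALSE, n))
  d2 <- as.matrix(stats::dist(cbind(x, y)))
  diag(d2) <- Inf
  nn <- apply(d2, 1, min)
  tol <- 0.6 * stats::median(nn)
  hx <- x[hull]; hy <- y[hull]
  m <- length(hull)
  dmin <- rep(Inf, n)
  for (e in seq_len(m)) {
    ax <- hx[e]; ay <- hy[e]
    bx <- hx[if (e == m) 1L else e + 1L]; by <- hy[if (e == m) 1L else e + 1L]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    t_ <- if (len2 > 0) pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) /
                                       len2)) else 0
    dmin <- pmin(dmin, sqrt((x - (ax + t_ * vx))^2 + (y - (ay + t_ * vy))^2))
  }
  dmin > tol
}

# Linear indices of pixels >= all 8 neighbours (plateau members included;
# the min-separation pass keeps one per plateau).  Border pixels excluded.
#' @keywords internal
#' @noRd
local_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) return(integer(0))
  core <- m[2:(nr - 1), 2:(nc - 1)]
  ok <- core >= m[1:(nr - 2), 2:(nc - 1)] & core >= m[3:nr, 2:(nc - 1)] &
    core >= m[2:(nr - 1), 1:(nc - 2)] & core >= m[2:(nr - 1), 3:nc] &
    core >= m[1:(nr - 2), 1:(nc - 2)] & core >= m[1:(nr - 2), 3:nc] &
    core >= m[3:nr, 1:(nc - 2)] & core >= m[3:nr, 3:nc]
  idx <- which(ok)
  r <- ((idx - 1L) %% (nr - 2L)) + 2L
  c <- ((idx - 1L) %/% (nr - 2L)) + 2L
  (c - 1L) * nr + r
}

# Greedy non-maximum suppression: points come ordered by decreasing strength;
# keep a point only if no stronger kept point lies within min_sep.
#' @keywords internal
#' @noRd
suppress_close <- function(x, y, min_sep) {
  n <- length(x)
  keep <- logical(n)
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_len(n)) {
    if (!length(kx) || min((kx - x[i])^2 + (ky - y[i])^2) >= min_sep^2) {
      keep[i] <- TRUE
      kx <- c(kx, x[i]); ky <- c(ky, y[i])
    }
  }
  keep
}

# Sub-pixel refinement on the narrow-scale smoothed image, where each facet
# is a clean Gaussian peak: re-centre to the local maximum in a small window,
# then interpolate per axis with the three-point Gaussian formula (exact for
# a Gaussian profile; parabolic fallback when a log is unusable).  Returns
# (x, y) in top-left-origin coordinates.
#' @keywords internal
#' @noRd
peak_refine <- function(m, row, col, wiggle = 2L) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- max(2L, row - wiggle); r1 <- min(nr - 1L, row + wiggle)
  c0 <- max(2L, col - wiggle); c1 <- min(nc - 1L, col + wiggle)
  patch <- m[r0:r1, c0:c1, drop = FALSE]
  k <- which.max(patch)
  row <- r0 + ((k - 1L) %% nrow(patch))
  col <- c0 + ((k - 1L) %/% nrow(patch))
  interp1 <- function(fm, f0, fp) {
    if (fm > 0 && f0 > 0 && fp > 0) {
      lm <- log(fm); l0 <- log(f0); lp <- log(fp)
      den <- lm - 2 * l0 + lp
      if (den < 0) return(0.5 * (lm - lp) / den)
    }
    den <- fm - 2 * f0 + fp
    if (den < 0) 0.5 * (fm - fp) / den else 0
  }
  dy <- interp1(m[row - 1L, col], m[row, col], m[row + 1L, col])
  dx <- interp1(m[row, col - 1L], m[row, col], m[row, col + 1L])
  c(col - 1 + max(-1, min(1, dx)), row - 1 + max(-1, min(1, dy)))
}

#' Local neighbour-vector geometry of detected ommatidia
#'
#' For each ommatidium, takes its k = min(6, N-1) nearest neighbours by
#' Euclidean distance (distance ties broken by smaller azimuth, then by point
#' index) and records the neighbour vector lengths, azimuths, and the sorted
#' angular gaps between consecutive vectors.  In a perfect hexagonal lattice
#' every interior facet has six equidistant neighbours at 60-degree gaps, so
#' deviations of these quantities measure local lattice disorder.  Points on
#' the convex hull of the centre set — or within 0.6 of the median
#' nearest-neighbour spacing of it, which catches collinear boundary rows —
#' are flagged non-interior: their neighbourhoods are truncated by the eye
#' boundary and would inflate any disorder measure.
#'
#' @param centers An \code{ommatidial_centers} object, or a data frame /
#'   matrix with columns \code{x}, \code{y}.
#' @return An object of class \code{local_vector_set}: list with
#'   \code{vectors} (per-point list of \code{neighbors}, \code{lengths},
#'   \code{azimuths}, \code{gaps} in degrees, \code{k}), \code{interior}
#'   (logical), and \code{points}.
#' @export
compute_local_vectors <- function(centers) {
  pts <- if (inherits(centers, "ommatidial_centers")) centers$points
         else as.data.frame(centers)
  assert_columns(pts, c("x", "y"), "centers")
  n <- nrow(pts)
  if (n < 2L) stop("need at least 2 centers to form neighbour vectors",
                   call. = FALSE)
  x <- pts$x; y <- pts$y
  interior <- interior_flags(x, y)
  vectors <- vector("list", n)
  for (i in seq_len(n)) {
    dx <- x - x[i]; dy <- y - y[i]
    d <- sqrt(dx^2 + dy^2)
    az <- (atan2(dy, dx) * 180 / pi) %% 360
    others <- setdiff(seq_len(n), i)
    # round distances so exact geometric ties (square lattice diagonals)
    # survive floating point and fall through to the azimuth/index rule
    ord <- others[order(round(d[others], 9), az[others], others)]
    k <- min(6L, n - 1L)
    nb <- ord[seq_len(k)]
    o <- order(az[nb])
    nb <- nb[o]
    gaps <- if (k >= 2L) {
      a <- az[nb]
      diff(c(a, a[1] + 360))
    } else {
      numeric(0)
    }
    vectors[[i]] <- list(neighbors = nb, lengths = d[nb], azimuths = az[nb],
                         gaps = gaps, k = k)
  }
  structure(list(vectors = vectors, interior = interior, points = pts),
            class = "local_vector_set")
}

#' Phenotypic score of ommatidial disorder
#'
#' Aggregates the local neighbour geometry into a single severity score.
#' Each interior ommatidium i contributes a disorder term
#' \deqn{d_i = w_L \, \mathrm{CV}(l_j) + w_A \frac{1}{k_i} \sum_j
#'   \frac{|\Delta\theta_j - 60|}{60},}
#' the coefficient of variation of its neighbour vector lengths plus the mean
#' relative deviation of its angular gaps from the hexagonal 60 degrees.  The
#' score is \eqn{S = 100 \cdot \mathrm{mean}_i(d_i)} over interior ommatidia.
#' S is zero exactly on a perfect hexagonal lattice, invariant under rigid
#' motions and uniform scaling of the centre set, and increases with
#' positional disorder; higher S = more severe rough-eye phenotype.
#'
#' @param vectors A \code{local_vector_set} (from [compute_local_vectors()]).
#' @param length_weight,angle_weight Weights \eqn{w_L}, \eqn{w_A} of the two
#'   disorder components (defaults 1 and 1).
#' @return An object of class \code{phenotypic_score}: list with \code{S},
#'   per-ommatidium \code{d} (NA for boundary/degenerate points),
#'   \code{N_interior}, and parameter echo.
#' @examples
#' out <- generate_eye_image(lattice_spec(n_rows = 8, n_cols = 8, seed = 2))
#' v <- compute_local_vectors(detect_ommatidia(out$image, 10))
#' phenotypic_score(v)$S
#' @export
phenotypic_score <- function(vectors, length_weight = 1, angle_weight = 1) {
  if (!inherits(vectors, "local_vector_set")) {
    stop("'vectors' must be a local_vector_set", call. = FALSE)
  }
  n <- length(vectors$vectors)
  d <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!vectors$interior[i]) next
    v <- vectors$vectors[[i]]
    if (v$k < 2L) next
    cv <- stats::sd(v$lengths) / mean(v$lengths)
    ang <- mean(abs(v$gaps - 60) / 60)
    d[i] <- length_weight * cv + angle_weight * ang
  }
  scored <- which(!is.na(d))
  if (!length(scored)) {
    stop("no interior ommatidia with at least 2 neighbours; cannot score",
         call. = FALSE)
  }
  structure(list(S = 100 * mean(d[scored]), d = d,
                 N_interior = length(scored),
                 params = list(length_weight = length_weight,
                               angle_weight = angle_weight)),
            class = "phenotypic_score")
}

#' @export
print.phenotypic_score <- function(x, ...) {
  cat(sprintf("<phenotypic_score> S = %.3f over %d interior ommatidia\n",
              x$S, x$N_interior))
  invisible(x)
}

#' Score a batch of labelled eye images
#'
#' Runs detection and scoring over a list of images, one row per image.
#' Per-image failures (blank images, unreadable files, too few interior
#' facets) are recorded with their reason rather than dropped.
#'
#' @param images List of \code{eye_image} objects or image file paths.
#' @param genotypes Character vector of genotype labels, recycled to the
#'   image count if length one.
#' @param expected_spacing,threshold_quantile Passed to [detect_ommatidia()].
#' @param length_weight,angle_weight Passed to [phenotypic_score()].
#' @return Data frame with columns \code{genotype}, \code{image},
#'   \code{n_detected}, \code{n_interior}, \code{score}, \code{status},
#'   \code{reason}.  Deterministic: identical inputs give identical tables.
#' @export
score_batch <- function(images, genotypes, expected_spacing = 10,
                        threshold_quantile = 0.95,
                        length_weight = 1, angle_weight = 1) {
  if (!length(images)) stop("'images' must be non-empty", call. = FALSE)
  if (length(genotypes) == 1L) genotypes <- rep(genotypes, length(images))
  if (length(genotypes) != length(images)) {
    stop("'genotypes' must match 'images' in length", call. = FALSE)
  }
  rows <- lapply(seq_along(images), function(i) {
    img_id <- if (is.character(images[[i]])) images[[i]] else
      sprintf("image%03d", i)
    res <- tryCatch({
      img <- if (is.character(images[[i]])) read_eye_image(images[[i]])
             else images[[i]]
      cen <- detect_ommatidia(img, expected_spacing, threshold_quantile)
      sc <- phenotypic_score(compute_local_vectors(cen),
                             length_weight, angle_weight)
      data.frame(genotype = genotypes[i], image = img_id, n_detected = cen$N,
                 n_interior = sc$N_interior, score = sc$S, status = "ok",
                 reason = "")
    }, error = function(e) {
      data.frame(genotype = genotypes[i], image = img_id,
                 n_detected = NA_integer_, n_interior = NA_integer_,
                 score = NA_real_, status = "error",
                 reason = conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentile-rank concordance between two scoring conditions
#'
#' Converts two genotype-to-score maps (for example, screens run with and
#' without Dicer2 enhancement of RNAi) to percentile ranks over their shared
#' genotypes and reports the Pearson correlation between the two rankings.
#' The percentile rank of a score is \code{100 * (n_below + 0.5 * n_tied) /
#' n}, the tie-splitting convention (a value tied only with itself sits at
#' the midpoint of its own mass).
#'
#' @param scores_a,scores_b Named numeric vectors (genotype -> score); at
#'   least 3 genotypes must be shared.
#' @return A list with \code{ranks} (data frame \code{genotype},
#'   \code{rank_a}, \code{rank_b}) and \code{r} (Pearson correlation).
#' @examples
#' percentile_ranks(c(a = 5, b = 10, c = 20), c(a = 6, b = 11, c = 19))$r
#' @export
percentile_ranks <- function(scores_a, scores_b) {
  shared <- intersect(names(scores_a), names(scores_b))
  if (length(shared) < 3L) {
    stop("need at least 3 shared genotypes", call. = FALSE)
  }
  prank <- function(v) {
    vapply(v, function(s) {
      100 * (sum(v < s) + 0.5 * sum(v == s)) / length(v)
    }, numeric(1))
  }
  ra <- prank(scores_a[shared])
  rb <- prank(scores_b[shared])
  list(ranks = data.frame(genotype = shared, rank_a = unname(ra),
                          rank_b = unname(rb)),
       r = stats::cor(ra, rb))
}
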