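# Gradient-vector-flow quantification of FISH signals.
#
# The chain is: Gaussian edge map -> GVF diffusion of the edge gradient ->
# one active contour (snake) per homolog seed -> background-corrected
# integrated intensity inside each contour -> normalized homolog
# intensity ratio |I1 - I2| / (I1 + I2).

.check_image <- function(image, min_dim = 32L) {
  if (inherits(image, "fish_image")) image <- image$pixels
  image <- as.matrix(image)
  if (!is.numeric(image) || any(!is.finite(image)))
    stop_named("image must be a finite numeric matrix")
  if (any(image < 0)) stop_named("image intensities must be non-negative")
  if (nrow(image) < min_dim || ncol(image) < min_dim)
    stop_named("image must be at least %dx%d pixels", min_dim, min_dim)
  image
}

# 4-neighbor Laplacian with replicated (Neumann) borders.
.lap <- function(m) {
  n <- nrow(m); p <- ncol(m)
  m[c(1L, seq_len(n - 1L)), ] + m[c(seq_len(n - 1L) + 1L, n), ] +
    m[, c(1L, seq_len(p - 1L))] + m[, c(seq_len(p - 1L) + 1L, p)] - 4 * m
}

# Central-difference gradient with replicated borders.
# Rows are y, columns are x; gx differentiates across columns.
.gradient2d <- function(m) {
  n <- nrow(m); p <- ncol(m)
  gx <- (m[, c(seq_len(p - 1L) + 1L, p)] - m[, c(1L, seq_len(p - 1L))]) / 2
  gy <- (m[c(seq_len(n - 1L) + 1L, n), ] - m[c(1L, seq_len(n - 1L)), ]) / 2
  list(gx = gx, gy = gy)
}

.gaussian_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- nrow(m); p <- ncol(m)
  # replicate-pad then separable convolution
  rows <- c(rep(1L, r), seq_len(n), rep(n, r))
  cols <- c(rep(1L, r), seq_len(p), rep(p, r))
  mp <- m[rows, cols]
  mp <- apply(mp, 2L, function(col) stats::filter(col, k, sides = 2L))
  mp <- t(apply(mp, 1L, function(row) stats::filter(row, k, sides = 2L)))
  mp[r + seq_len(n), r + seq_len(p)]
}

#' Edge map of a FISH image
#'
#' Squared gradient magnitude of the Gaussian-smoothed image, rescaled to
#' [0, 1]. This is the standard edge functional the gradient vector flow
#' field diffuses; rescaling makes it invariant to overall exposure.
#'
#' @param image numeric intensity matrix (or a `fish_image`).
#' @param sigma Gaussian smoothing scale in px (> 0, default 2).
#' @return matrix in [0, 1] of the same shape as `image`.
#' @export
edge_map <- function(image, sigma = 2) {
  image <- .check_image(image, min_dim = 8L)
  stopifnot(sigma > 0)
  g <- .gaussian_smooth(image, sigma)
  gr <- .gradient2d(g)
  e <- gr$gx^2 + gr$gy^2
  mx <- max(e)
  if (mx > 0) e <- e / mx
  e
}

#' Gradient vector flow field
#'
#' Diffuses the gradient of an edge map into a smooth vector field that
#' extends the capture range of an active contour: near edges the field
#' approximates the edge gradient; far from edges it is interpolated
#' smoothly. Iterates the explicit update
#' `u <- u + dt * (mu * Laplacian(u) - (u - fx) * (fx^2 + fy^2))`
#' (likewise `v`) from `(u, v) = (fx, fy)` until the maximum per-pixel
#' update falls below `tol` or the iteration cap is reached.
#'
#' @param edge edge map matrix (as from [edge_map()]).
#' @param mu regularization weight (> 0, default 0.2).
#' @param iterations iteration cap (default 80).
#' @param tol stopping threshold on the max per-pixel update
#'   (default 1e-3).
#' @param dt explicit time step (default 1; stable for `mu * dt <= 1/4`).
#' @return an object of class `gvf_field`: list with `u`, `v` and
#'   `residual_history`.
#' @export
gvf_field <- function(edge, mu = 0.2, iterations = 80, tol = 1e-3, dt = 1) {
  edge <- as.matrix(edge)
  stopifnot(mu > 0, iterations >= 1)
  gr <- .gradient2d(edge)
  fx <- gr$gx; fy <- gr$gy
  b <- fx^2 + fy^2
  u <- fx; v <- fy
  hist <- numeric(0L)
  for (it in seq_len(iterations)) {
    du <- dt * (mu * .lap(u) - (u - fx) * b)
    dv <- dt * (mu * .lap(v) - (v - fy) * b)
    u <- u + du
    v <- v + dv
    if (any(!is.finite(u)) || any(!is.finite(v)))
      stop_named("GVF diverged to non-finite values at iteration %d", it)
    res <- max(abs(du), abs(dv))
    hist <- c(hist, res)
    if (res < tol) break
  }
  structure(list(u = u, v = v, residual_history = hist),
            class = "gvf_field")
}

#' Locate homolog signal seeds
#'
#' Finds the `n_expected` brightest local maxima of the smoothed image,
#' constrained to be pairwise separated by at least `min_separation`
#' pixels, standing in for the expected probe target location on each
#' homolog. A cell in which the expected number of signals cannot be
#' located is unscorable (mirroring the exclusion rules for qualitative
#' scoring) and raises an error of class `dachroma_unscorable`.
#'
#' @param image intensity matrix (or `fish_image`).
#' @param n_expected number of signals (default 2: one per homolog).
#' @param min_separation minimum seed separation in px (default 6).
#' @param sigma smoothing scale used before peak picking (default 2).
#' @param coords optional user-supplied seed coordinates (matrix with
#'   columns `row`, `col`), overriding detection.
#' @return `data.frame` with columns `row`, `col`, `value`.
#' @export
detect_signal_seeds <- function(image, n_expected = 2, min_separation = 6,
                                sigma = 2, coords = NULL) {
  image <- .check_image(image)
  stopifnot(n_expected >= 1)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n_expected)
      .unscorable("expected %d seed(s), got %d", n_expected, nrow(coords))
    return(data.frame(row = coords[, 1L], col = coords[, 2L],
                      value = image[coords]))
  }
  s <- .gaussian_smooth(image, sigma)
  n <- nrow(s); p <- ncol(s)
  shift <- function(dr, dc) s[pmin(pmax(seq_len(n) + dr, 1L), n),
                              pmin(pmax(seq_len(p) + dc, 1L), p)]
  # strict comparison: constant plateaus (e.g. flat background) are
  # not signals
  is_max <- TRUE
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    is_max <- is_max & (s > shift(dr, dc))
  }
  # exclude flat plateaus at the border
  is_max[c(1L, n), ] <- FALSE
  is_max[, c(1L, p)] <- FALSE
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    .unscorable("no local maxima found; expected %d", n_expected)
  ord <- order(s[idx], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  picked <- matrix(numeric(0L), ncol = 2L)
  for (i in seq_len(nrow(idx))) {
    if (nrow(picked) == n_expected) break
    cand <- idx[i, ]
    if (nrow(picked) == 0L ||
        all(sqrt(rowSums((t(t(picked) - cand))^2)) >= min_separation))
      picked <- rbind(picked, cand)
  }
  if (nrow(picked) < n_expected)
    .unscorable("found %d separated signal(s), expected %d",
                nrow(picked), n_expected)
  data.frame(row = picked[, 1L], col = picked[, 2L],
             value = image[picked])
}

.unscorable <- function(fmt, ...) {
  stop(structure(class = c("dachroma_unscorable", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

.bilinear <- function(m, y, x) {
  n <- nrow(m); p <- ncol(m)
  y <- pmin(pmax(y, 1), n); x <- pmin(pmax(x, 1), p)
  y0 <- pmin(floor(y), n - 1L); x0 <- pmin(floor(x), p - 1L)
  dy <- y - y0; dx <- x - x0
  m[cbind(y0, x0)] * (1 - dy) * (1 - dx) +
    m[cbind(y0 + 1L, x0)] * dy * (1 - dx) +
    m[cbind(y0, x0 + 1L)] * (1 - dy) * dx +
    m[cbind(y0 + 1L, x0 + 1L)] * dy * dx
}

# Resample a closed polygon to n equally spaced vertices by arc
# length: prevents vertices from bunching at the strongest edge point.
.resample_contour <- function(ry, rx, n) {
  yy <- c(ry, ry[1L]); xx <- c(rx, rx[1L])
  seg <- sqrt(diff(yy)^2 + diff(xx)^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total < 1e-9) return(list(ry = ry, rx = rx))
  at <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  list(ry = approx(s, yy, xout = at, ties = "ordered")$y,
       rx = approx(s, xx, xout = at, ties = "ordered")$y)
}

# Cyclic pentadiagonal internal-energy (stiffness) matrix of a closed
# snake with tension alpha and rigidity beta.
.snake_matrix <- function(n, alpha, beta) {
  A <- matrix(0, n, n)
  coef <- c(beta, -alpha - 4 * beta, 2 * alpha + 6 * beta,
            -alpha - 4 * beta, beta)
  for (k in -2:2) {
    idx <- ((seq_len(n) - 1L + k) %% n) + 1L
    A[cbind(seq_len(n), idx)] <- A[cbind(seq_len(n), idx)] + coef[k + 3L]
  }
  A
}

#' Evolve an active contour under a GVF field
#'
#' A closed snake is initialized as a small circle around the seed and
#' relaxed under internal tension/rigidity forces and the external GVF
#' force with the standard semi-implicit update
#' `x <- solve(gamma I + A, gamma x + kappa f(x))`. Evolution stops when
#' the maximum vertex displacement drops below `tol` or after `steps`
#' updates. The filled interior of the final contour is returned as a
#' binary mask; a contour that collapses below 4 px of area, or that
#' finds no boundary support (zero external force along the final
#' contour, as in a flat background), is unscorable.
#'
#' @param seed numeric `c(row, col)` seed position inside the image.
#' @param field a [gvf_field()].
#' @param alpha tension weight (>= 0, default 0.1).
#' @param beta rigidity weight (>= 0, default 0.5).
#' @param gamma viscosity (step damping, default 1).
#' @param kappa external force weight (default 0.6).
#' @param steps step cap (default 400).
#' @param tol convergence threshold in px (default 0.01).
#' @param radius initial circle radius in px (default 3).
#' @param npoints number of snake vertices (default 40).
#' @param normalize use unit GVF force vectors (default TRUE), making
#'   the boundary attraction independent of signal amplitude so dim and
#'   bright homolog signals converge alike.
#' @return logical mask matrix with attribute `contour` (the final
#'   vertex polygon, columns `row`, `col`).
#' @export
evolve_contour <- function(seed, field, alpha = 0.1, beta = 0.5,
                           gamma = 1, kappa = 0.6, steps = 400,
                           tol = 0.01, radius = 3, npoints = 40,
                           normalize = TRUE) {
  stopifnot(inherits(field, "gvf_field"), alpha >= 0, beta >= 0)
  u <- field$u; v <- field$v
  n <- nrow(u); p <- ncol(u)
  seed <- as.numeric(seed)
  if (seed[1L] < 1 || seed[1L] > n || seed[2L] < 1 || seed[2L] > p)
    stop_named("seed lies outside the image")
  th <- seq(0, 2 * pi, length.out = npoints + 1L)[-(npoints + 1L)]
  ry <- seed[1L] + radius * sin(th)
  rx <- seed[2L] + radius * cos(th)
  M <- solve(gamma * diag(npoints) + .snake_matrix(npoints, alpha, beta))
  for (s in seq_len(steps)) {
    fx <- .bilinear(u, ry, rx)
    fy <- .bilinear(v, ry, rx)
    if (normalize) {
      fn <- sqrt(fx^2 + fy^2)
      scale <- ifelse(fn > 1e-10, 1 / fn, 0)
      fx <- fx * scale
      fy <- fy * scale
    }
    new_y <- M %*% (gamma * ry + kappa * fy)
    new_x <- M %*% (gamma * rx + kappa * fx)
    new_y <- pmin(pmax(new_y, 1), n)
    new_x <- pmin(pmax(new_x, 1), p)
    disp <- max(abs(new_y - ry), abs(new_x - rx))
    ry <- as.numeric(new_y); rx <- as.numeric(new_x)
    if (s %% 10L == 0L) {
      rs <- .resample_contour(ry, rx, npoints)
      ry <- rs$ry; rx <- rs$rx
    }
    if (disp < tol) break
  }
  support <- mean(sqrt(.bilinear(u, ry, rx)^2 + .bilinear(v, ry, rx)^2))
  if (support < 1e-8)
    .unscorable("contour found no boundary support (flat background?)")
  # rasterize the polygon interior
  rr <- range(ry); cr <- range(rx)
  rows <- max(1L, floor(rr[1L])):min(n, ceiling(rr[2L]))
  cols <- max(1L, floor(cr[1L])):min(p, ceiling(cr[2L]))
  gy <- rep(rows, times = length(cols))
  gx <- rep(cols, each = length(rows))
  inside <- pracma::inpolygon(gx, gy, rx, ry, boundary = TRUE)
  mask <- matrix(FALSE, n, p)
  mask[cbind(gy[inside], gx[inside])] <- TRUE
  mask[round(seed[1L]), round(seed[2L])] <- TRUE  # containment by construction
  if (sum(mask) < 4L)
    .unscorable("contour collapsed to %d px (< 4)", sum(mask))
  attr(mask, "contour") <- cbind(row = ry, col = rx)
  mask
}

.dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
  EBImage::dilate(mask * 1, brush) > 0
}

#' Background-corrected integrated intensity over a mask
#'
#' Sums `pixel - background` over the mask, floored at 0. The default
#' background model is the median intensity of a 2-px-wide annulus
#' dilated around the mask (local background); if the annulus is empty
#' the global `percentile` of the image is used instead.
#'
#' @param image intensity matrix (or `fish_image`).
#' @param mask logical matrix of the same shape, non-empty.
#' @param background `"annulus"` (default), `"percentile"` (global
#'   percentile) or `"none"`.
#' @param annulus_width annulus width in px (default 2).
#' @param percentile global fallback percentile (default 0.5).
#' @return integrated intensity in arbitrary units (>= 0).
#' @export
integrated_intensity <- function(image, mask,
                                 background = c("annulus", "percentile",
                                                "none"),
                                 annulus_width = 2, percentile = 0.5) {
  image <- .check_image(image)
  background <- match.arg(background)
  mask <- mask > 0
  if (!any(mask)) stop_named("mask is empty")
  bg <- 0
  if (background == "annulus") {
    ring <- .dilate_mask(mask, annulus_width) & !mask
    bg <- if (any(ring)) median(image[ring])
          else quantile(image, percentile, names = FALSE)
  } else if (background == "percentile") {
    bg <- quantile(image, percentile, names = FALSE)
  }
  max(0, sum(image[mask] - bg))
}

#' Normalized homolog intensity ratio
#'
#' `|I1 - I2| / (I1 + I2)`: 0 when the homolog signals are equal
#' (equivalent accessibility), approaching 1 as one homolog's signal
#' vanishes (differential accessibility). Symmetric in its arguments and
#' invariant under common rescaling.
#'
#' @param i1,i2 integrated homolog intensities (a.u., >= 0).
#' @return ratio in [0, 1].
#' @examples
#' intensity_ratio(100, 50)  # 1/3
#' @export
intensity_ratio <- function(i1, i2) {
  stopifnot(length(i1) == length(i2))
  if (any(i1 < 0 | i2 < 0)) stop_named("intensities must be >= 0")
  if (any(i1 + i2 == 0))
    .unscorable("undefined intensity ratio: both homolog signals are zero")
  abs(i1 - i2) / (i1 + i2)
}

#' Configuration for the GVF quantification chain
#'
#' All numerical knobs of [quantify_cell()] in one place, with stable
#' defaults. `mask_grow` dilates each converged contour mask before
#' integration so the point-spread tail beyond the gradient ridge is
#' included in the signal sum.
#'
#' @param sigma edge-map smoothing scale (px).
#' @param mu,gvf_iterations,gvf_tol GVF diffusion parameters.
#' @param alpha,beta,gamma,kappa,steps,tol,radius,npoints,normalize
#'   snake parameters (see [evolve_contour()]).
#' @param window per-signal analysis window half-width in px
#'   (default 10): the edge map and GVF field are computed locally
#'   around each seed so segmentation is homolog-brightness invariant.
#' @param mask_grow px of mask dilation before integration (default 2).
#' @param annulus_width background annulus width (px).
#' @param min_separation seed separation floor (px).
#' @return named list.
#' @export
gvf_config <- function(sigma = 2, mu = 0.2, gvf_iterations = 80,
                       gvf_tol = 1e-3, alpha = 0.1, beta = 0.5,
                       gamma = 1, kappa = 0.6, steps = 400, tol = 0.01,
                       radius = 3, npoints = 40, normalize = TRUE,
                       window = 10, mask_grow = 2, annulus_width = 2,
                       min_separation = 6) {
  as.list(environment())
}

#' Quantify both homolog signals in one metaphase image
#'
#' Runs the full chain: per-signal edge map, GVF field and contour
#' (computed inside a window of `window` px half-width around each
#' seed, so the locally rescaled edge map makes the segmentation
#' invariant to each homolog's brightness), mask disambiguation (pixels
#' claimed by both contours go to the nearer seed),
#' background-corrected integration on the full image, and the
#' normalized intensity ratio. Homologs are ordered by descending
#' intensity so `i1 >= i2`; the ratio is invariant to that ordering.
#'
#' @param image intensity matrix or `fish_image`.
#' @param seeds optional seed coordinates (2-row matrix / data.frame with
#'   `row`, `col`); detected with [detect_signal_seeds()] when `NULL`.
#' @param config list from [gvf_config()].
#' @return object of class `signal_quant`: list with `i1`, `i2`,
#'   `ratio`, `masks` (list of 2), `seeds`.
#' @export
quantify_cell <- function(image, seeds = NULL, config = gvf_config()) {
  image <- .check_image(image)
  if (is.null(seeds)) {
    seeds <- detect_signal_seeds(image, n_expected = 2,
                                 min_separation = config$min_separation,
                                 sigma = config$sigma)
  } else {
    seeds <- as.data.frame(seeds)
    names(seeds)[1:2] <- c("row", "col")
    if (nrow(seeds) != 2L)
      .unscorable("exactly two homolog seeds required, got %d", nrow(seeds))
  }
  n <- nrow(image); p <- ncol(image)
  w <- config$window
  masks <- lapply(seq_len(2L), function(i) {
    r0 <- max(1L, round(seeds$row[i]) - w)
    r1 <- min(n, round(seeds$row[i]) + w)
    c0 <- max(1L, round(seeds$col[i]) - w)
    c1 <- min(p, round(seeds$col[i]) + w)
    e <- edge_map(image[r0:r1, c0:c1], sigma = config$sigma)
    f <- gvf_field(e, mu = config$mu,
                   iterations = config$gvf_iterations,
                   tol = config$gvf_tol)
    m_loc <- evolve_contour(c(seeds$row[i] - r0 + 1,
                              seeds$col[i] - c0 + 1), f,
                            alpha = config$alpha, beta = config$beta,
                            gamma = config$gamma, kappa = config$kappa,
                            steps = config$steps, tol = config$tol,
                            radius = config$radius,
                            npoints = config$npoints,
                            normalize = config$normalize)
    m <- matrix(FALSE, n, p)
    m[r0:r1, c0:c1] <- m_loc
    m
  })
  masks <- lapply(masks, .dilate_mask, r = config$mask_grow)
  both <- masks[[1L]] & masks[[2L]]
  if (any(both)) {
    idx <- which(both, arr.ind = TRUE)
    d1 <- (idx[, 1L] - seeds$row[1L])^2 + (idx[, 2L] - seeds$col[1L])^2
    d2 <- (idx[, 1L] - seeds$row[2L])^2 + (idx[, 2L] - seeds$col[2L])^2
    masks[[1L]][idx[d1 > d2, , drop = FALSE]] <- FALSE
    masks[[2L]][idx[d1 <= d2, , drop = FALSE]] <- FALSE
  }
  ii <- vapply(masks, function(m)
    integrated_intensity(image, m, annulus_width = config$annulus_width),
    numeric(1L))
  ord <- order(ii, decreasing = TRUE)
  structure(list(i1 = ii[ord[1L]], i2 = ii[ord[2L]],
                 ratio = intensity_ratio(ii[1L], ii[2L]),
                 masks = masks[ord], seeds = seeds),
            class = "signal_quant")
}

#' Quantify a batch of cells, tallying unscorable ones
#'
#' Applies [quantify_cell()] to a list of images; cells raising
#' `dachroma_unscorable` conditions are excluded with their reason
#' recorded, mirroring the exclusion rules of qualitative scoring.
#'
#' @param images list of intensity matrices (or `fish_image` objects).
#' @param seeds optional list of per-cell seed tables.
#' @param config list from [gvf_config()].
#' @return `data.frame` with columns `cell_id`, `i1`, `i2`, `ratio`,
#'   `excluded_reason` (`NA` for scored cells).
#' @export
quantify_cells <- function(images, seeds = NULL, config = gvf_config()) {
  out <- lapply(seq_along(images), function(i) {
    q <- tryCatch(
      quantify_cell(images[[i]],
                    seeds = if (is.null(seeds)) NULL else seeds[[i]],
                    config = config),
      dachroma_unscorable = function(e) e)
    if (inherits(q, "condition")) {
      data.frame(cell_id = i, i1 = NA_real_, i2 = NA_real_,
                 ratio = NA_real_, excluded_reason = conditionMessage(q))
    } else {
      data.frame(cell_id = i, i1 = q$i1, i2 = q$i2, ratio = q$ratio,
                 excluded_reason = NA_character_)
    }
  })
  do.call(rbind, out)
}
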