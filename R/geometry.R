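N_AVOGADRO <- 6.02214076e23
NM2_PER_CM2 <- 1e14

#' Film surface area
#'
#' Area of a solid substrate film in cm^2. By convention both faces of
#' the film count toward the surface and edges are neglected; this
#' convention reproduces the usual substrate surface concentrations for
#' standard film sizes (a 2 x 5 mm film gives 0.2 cm^2, i.e. 200 cm^2/L
#' in a 1 ml reaction).
#'
#' @param shape `"disc"` or `"rect"`.
#' @param diameter_cm disc diameter, cm (for `shape = "disc"`).
#' @param width_cm,height_cm rectangle sides, cm (for `shape = "rect"`).
#' @param both_faces count both faces (default `TRUE`).
#' @return Area in cm^2.
#' @examples
#' film_area("rect", width_cm = 0.2, height_cm = 0.5)  # 0.2 cm^2
#' film_area("disc", diameter_cm = 2.54 / 4)           # 0.25-inch disc
#' @export
film_area <- function(shape = c("disc", "rect"), diameter_cm = NULL,
                      width_cm = NULL, height_cm = NULL, both_faces = TRUE) {
  shape <- match.arg(shape)
  face <- switch(shape,
    disc = {
      if (is.null(diameter_cm) || diameter_cm <= 0) {
        stop("disc needs a positive diameter_cm", call. = FALSE)
      }
      pi * (diameter_cm / 2)^2
    },
    rect = {
      if (is.null(width_cm) || is.null(height_cm) ||
          width_cm <= 0 || height_cm <= 0) {
        stop("rect needs positive width_cm and height_cm", call. = FALSE)
      }
      width_cm * height_cm
    }
  )
  if (both_faces) 2 * face else face
}

#' Areal number density from an adsorbed amount
#'
#' Converts an adsorbed molar amount spread over a film surface into a
#' molecular areal density.
#'
#' @param amount_pmol adsorbed amount, pmol (>= 0).
#' @param area_cm2 total surface area, cm^2 (see [film_area()]).
#' @return A `density_spec`: list with `lambda` (molecules per nm^2) and
#'   a provenance tag.
#' @examples
#' a <- film_area("disc", diameter_cm = 2.54 / 4)
#' areal_density(4, a)  # ~0.038 molecules / nm^2
#' @export
areal_density <- function(amount_pmol, area_cm2) {
  if (amount_pmol < 0) stop("amount_pmol must be >= 0", call. = FALSE)
  if (area_cm2 <= 0) stop("area_cm2 must be positive", call. = FALSE)
  density_spec(amount_pmol * 1e-12 * N_AVOGADRO / (area_cm2 * NM2_PER_CM2),
               provenance = "amount+area")
}

#' @rdname areal_density
#' @param lambda areal density, molecules per nm^2.
#' @param provenance free-text origin tag.
#' @export
density_spec <- function(lambda, provenance = "direct") {
  if (lambda < 0 || !is.finite(lambda)) {
    stop("lambda must be finite and >= 0", call. = FALSE)
  }
  structure(list(lambda = lambda, provenance = provenance),
            class = "density_spec")
}

as_lambda <- function(d) {
  if (inherits(d, "density_spec")) d$lambda else as.numeric(d)
}

#' Center-to-center spacing on an even square grid
#'
#' Separation distance if the same number of molecules were placed on a
#' regular square lattice: `1/sqrt(lambda)`.
#'
#' @param d a `density_spec` or a plain density in nm^-2 (> 0).
#' @return Spacing in nm.
#' @export
grid_spacing <- function(d) {
  lambda <- as_lambda(d)
  if (lambda <= 0) stop("density must be positive", call. = FALSE)
  1 / sqrt(lambda)
}

#' Mean nearest-neighbor distance of a planar Poisson process
#'
#' Closed form for homogeneous complete spatial randomness:
#' `1/(2*sqrt(lambda))`. Serves as the analytic reference for the Monte
#' Carlo simulations of randomly placed molecules.
#'
#' @inheritParams grid_spacing
#' @return Mean nearest-neighbor distance in nm.
#' @export
poisson_nn_mean <- function(d) {
  lambda <- as_lambda(d)
  if (lambda <= 0) stop("density must be positive", call. = FALSE)
  1 / (2 * sqrt(lambda))
}

#' Planar point pattern
#'
#' Container for molecule coordinates inside a rectangular or circular
#' window, with the boundary convention used for nearest-neighbor
#' distances: `"toroidal"` (periodic wrap, edge-bias free; rectangular
#' windows only) or `"bounded"` (plain Euclidean distances, as in
#' localization-microscopy quadrant analysis, which applies no edge
#' correction).
#'
#' @param x,y coordinates, nm.
#' @param window list: `list(shape = "rect", width =, height =)` or
#'   `list(shape = "disc", radius =, centre = c(x, y))`, nm.
#' @param boundary `"bounded"` or `"toroidal"`.
#' @return Object of class `point_pattern`.
#' @export
point_pattern <- function(x, y, window, boundary = c("bounded", "toroidal")) {
  boundary <- match.arg(boundary)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (is.null(window$shape)) stop("window needs a shape", call. = FALSE)
  if (window$shape == "rect") {
    if (any(x < 0 | x > window$width | y < 0 | y > window$height)) {
      stop("points outside rectangular window", call. = FALSE)
    }
  } else if (window$shape == "disc") {
    ctr <- if (is.null(window$centre)) c(0, 0) else window$centre
    if (any((x - ctr[1])^2 + (y - ctr[2])^2 > window$radius^2 * (1 + 1e-9))) {
      stop("points outside circular window", call. = FALSE)
    }
    window$centre <- ctr
  } else {
    stop("window shape must be 'rect' or 'disc'", call. = FALSE)
  }
  if (boundary == "toroidal" && window$shape != "rect") {
    stop("toroidal boundary requires a rectangular window", call. = FALSE)
  }
  structure(list(x = x, y = y, window = window, boundary = boundary),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points, %s window, %s boundary\n",
              length(x$x), x$window$shape, x$boundary))
  invisible(x)
}

window_area <- function(window) {
  switch(window$shape,
         rect = window$width * window$height,
         disc = pi * window$radius^2)
}

#' Simulate a homogeneous Poisson point pattern
#'
#' Draws a Poisson-distributed number of points with expectation
#' `lambda * area` and places them uniformly in the window.
#' Deterministic for a given seed.
#'
#' @param d density (`density_spec` or nm^-2).
#' @param window window geometry (see [point_pattern()]).
#' @param boundary boundary convention of the resulting pattern.
#' @param seed integer seed.
#' @return A [point_pattern].
#' @export
simulate_point_pattern <- function(d, window,
                                   boundary = c("toroidal", "bounded"),
                                   seed = 1) {
  boundary <- match.arg(boundary)
  lambda <- as_lambda(d)
  area <- window_area(window)
  if (lambda * area < 2) {
    stop("expected point count below 2; enlarge the window or density",
         call. = FALSE)
  }
  with_seed(seed, {
    n <- stats::rpois(1, lambda * area)
    if (window$shape == "rect") {
      x <- stats::runif(n, 0, window$width)
      y <- stats::runif(n, 0, window$height)
    } else {
      r <- window$radius * sqrt(stats::runif(n))
      a <- stats::runif(n, 0, 2 * pi)
      ctr <- if (is.null(window$centre)) c(0, 0) else window$centre
      x <- ctr[1] + r * cos(a)
      y <- ctr[2] + r * sin(a)
    }
    point_pattern(x, y, window, boundary)
  })
}

#' Nearest-neighbor distances of a point pattern
#'
#' Distance from each point to its nearest other point, with the
#' toroidal metric when the pattern carries a toroidal boundary.
#' Pairwise distances are evaluated in blocks so patterns of tens of
#' thousands of points stay within modest memory; `method = "brute"`
#' forces a single full double loop (the O(n^2) reference path, identical
#' results).
#'
#' @param p a [point_pattern] with at least 2 points.
#' @param method `"blocked"` (default) or `"brute"`.
#' @param block_size points per block for the blocked path.
#' @return Numeric vector of per-point nearest-neighbor distances, nm.
#' @export
nn_distances <- function(p, method = c("blocked", "brute"),
                         block_size = 2048L) {
  method <- match.arg(method)
  stopifnot(inherits(p, "point_pattern"))
  n <- length(p$x)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  toroidal <- p$boundary == "toroidal"
  W <- if (toroidal) p$window$width else NA_real_
  H <- if (toroidal) p$window$height else NA_real_
  if (method == "brute") block_size <- n
  out <- numeric(n)
  for (start in seq(1, n, by = block_size)) {
    idx <- start:min(start + block_size - 1, n)
    dx <- abs(outer(p$x[idx], p$x, `-`))
    dy <- abs(outer(p$y[idx], p$y, `-`))
    if (toroidal) {
      dx <- pmin(dx, W - dx)
      dy <- pmin(dy, H - dy)
    }
    d2 <- dx * dx + dy * dy
    d2[cbind(seq_along(idx), idx)] <- Inf  # exclude self
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Mean minimum separation distance
#'
#' Mean over points of the distance to each point's nearest neighbor —
#' the summary used throughout for surface-density arguments.
#'
#' @inheritParams nn_distances
#' @return Mean nearest-neighbor distance, nm.
#' @export
mean_min_distance <- function(p, method = c("blocked", "brute")) {
  mean(nn_distances(p, method = match.arg(method)))
}

#' Linearly scale a measured surface density to another concentration
#'
#' Inverts the Poisson mean nearest-neighbor formula at a reference
#' solution concentration (`lambda_ref = (1 / (2 d_ref))^2`), then scales
#' the density linearly with concentration — the assumption that surface
#' coverage in the sub-saturating regime is proportional to solution
#' concentration.
#'
#' @param conc_ref reference solution concentration (any unit, consistent
#'   with `conc_target`).
#' @param mean_nn_ref measured mean minimum separation distance at the
#'   reference concentration, nm (> 0).
#' @param conc_target target concentration (same unit as `conc_ref`).
#' @return A `density_spec` at the target concentration.
#' @examples
#' d <- scale_density_linear(0.2, 400, 75)   # 200 pM -> 75 nM
#' poisson_nn_mean(d)                        # ~20.7 nm
#' @export
scale_density_linear <- function(conc_ref, mean_nn_ref, conc_target) {
  if (mean_nn_ref <= 0) stop("reference distance must be positive",
                             call. = FALSE)
  if (conc_ref <= 0 || conc_target <= 0) {
    stop("concentrations must be positive", call. = FALSE)
  }
  lambda_ref <- (1 / (2 * mean_nn_ref))^2
  density_spec(lambda_ref * conc_target / conc_ref,
               provenance = "concentration-scaled")
}

#' Cubic-lattice spacing for a bulk molar concentration
#'
#' Center-to-center spacing if molecules at bulk concentration `c` were
#' placed on a cubic lattice: `(N_A * c)^(-1/3)`.
#'
#' @param conc_molar concentration in mol/L (> 0).
#' @return Spacing in nm.
#' @examples
#' molar_to_spacing_3d(2e-3)  # ~9.4 nm at 2 mM
#' @export
molar_to_spacing_3d <- function(conc_molar) {
  if (conc_molar <= 0) stop("concentration must be positive", call. = FALSE)
  # molecules per nm^3: mol/L * N_A / (1e24 nm^3 per L)
  n_per_nm3 <- conc_molar * N_AVOGADRO / 1e24
  n_per_nm3^(-1 / 3)
}

#' @rdname molar_to_spacing_3d
#' @param spacing_nm cubic-lattice spacing in nm (> 0).
#' @return `spacing_to_molar_3d`: concentration in mol/L.
#' @examples
#' spacing_to_molar_3d(18.8 / 2)  # 8 molecules in a 188 A cube -> 2 mM
#' @export
spacing_to_molar_3d <- function(spacing_nm) {
  if (spacing_nm <= 0) stop("spacing must be positive", call. = FALSE)
  (1 / spacing_nm^3) * 1e24 / N_AVOGADRO
}

#' Quadrant analysis of localization-microscopy fields of view
#'
#' Emulates the standard single-molecule surface-density workflow: each
#' circular field of view is split into four equal quadrants by the two
#' axes through its center, a blank-control count of coordinates is
#' removed uniformly at random from each field (background subtraction),
#' and per-quadrant molecule counts and mean minimum separation distances
#' are summarized across all quadrants. No edge correction is applied,
#' matching the bounded estimator used on real data.
#'
#' @param patterns list of [point_pattern]s with disc windows, one per
#'   field of view (two fields x four quadrants gives the usual eight
#'   summaries).
#' @param blank_counts integer vector (recycled) of blank-control counts
#'   to remove per field; clamped with a warning if it exceeds the
#'   detected count.
#' @param seed integer seed for the random removals.
#' @return List with `per_quadrant` (data frame: field, quadrant, count,
#'   mean_min_distance) and `summary` (means and SDs over quadrants).
#' @export
tirf_quadrant_analysis <- function(patterns, blank_counts = 0, seed = 1) {
  if (inherits(patterns, "point_pattern")) patterns <- list(patterns)
  blank_counts <- rep_len(as.integer(blank_counts), length(patterns))
  rows <- with_seed(seed, {
    do.call(rbind, lapply(seq_along(patterns), function(i) {
      p <- patterns[[i]]
      stopifnot(inherits(p, "point_pattern"))
      if (p$window$shape != "disc") {
        stop("quadrant analysis expects circular fields of view",
             call. = FALSE)
      }
      x <- p$x; y <- p$y
      nb <- blank_counts[i]
      if (nb > length(x)) {
        warning(sprintf("field %d: blank count %d exceeds detections %d; removing all",
                        i, nb, length(x)), call. = FALSE)
        nb <- length(x)
      }
      if (nb > 0) {
        drop <- sample(length(x), nb)
        x <- x[-drop]; y <- y[-drop]
      }
      ctr <- p$window$centre
      # quadrants by the two axes through the center; points on an axis
      # fall to the lower-index quadrant
      qx <- x > ctr[1]
      qy <- y > ctr[2]
      quad <- 1L + as.integer(qx) + 2L * as.integer(qy)
      do.call(rbind, lapply(1:4, function(q) {
        inq <- quad == q
        mmd <- if (sum(inq) >= 2) {
          sub <- point_pattern(x[inq], y[inq], p$window, boundary = "bounded")
          mean_min_distance(sub)
        } else NA_real_
        data.frame(field = i, quadrant = q, count = sum(inq),
                   mean_min_distance = mmd)
      }))
    }))
  })
  list(
    per_quadrant = rows,
    summary = data.frame(
      count_mean = mean(rows$count),
      count_sd = stats::sd(rows$count),
      mmd_mean = mean(rows$mean_min_distance, na.rm = TRUE),
      mmd_sd = stats::sd(rows$mean_min_distance, na.rm = TRUE)
    )
  )
}
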