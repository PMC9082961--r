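#' Parametric wheat-leaf shape
#'
#' A leaf is modelled as a flat lamina with a symmetric width profile
#' \deqn{w(x) = W (4 (x/L)(1 - x/L))^a, \quad 0 \le x \le L,} which peaks at
#' mid-leaf with maximum width `W`; `a = 0` gives a rectangle and the default
#' `a = 0.5` a lanceolate outline. Lamina thickness is interpolated linearly
#' through readings at the base, middle and tip — the same three stations at
#' which thickness is measured in the field. The midrib is carried as a
#' diameter profile through the same three stations; its volume is an add-on
#' to the lamina volume (see [true_volume()]).
#'
#' @param length leaf length `L` in mm.
#' @param max_width maximum lamina width `W` in mm.
#' @param width_exponent shape exponent `a` (dimensionless, `>= 0`).
#' @param thickness numeric length-3: lamina thickness (mm) at base, middle
#'   and tip. The base must be at least as thick as the tip.
#' @param midrib numeric length-3: midrib diameter (mm) at base, middle and
#'   tip. The basal midrib diameter must be at least the basal lamina
#'   thickness.
#' @param width_fun optional function `w(x)` overriding the parametric
#'   profile (used for analytic test shapes); must be vectorised and
#'   non-negative on `[0, L]`.
#' @return an object of class `leaf_shape`.
#' @seealso [leaf_specimen()], [true_area()], [true_volume()]
#' @examples
#' sh <- leaf_shape(length = 150, max_width = 12,
#'                  thickness = c(0.30, 0.25, 0.20),
#'                  midrib = c(0.6, 0.45, 0.30))
#' true_area(leaf_specimen(sh))
#' @export
leaf_shape <- function(length, max_width, width_exponent = 0.5,
                       thickness = c(0.30, 0.25, 0.20),
                       midrib = c(0.60, 0.45, 0.30),
                       width_fun = NULL) {
  stopifnot(length > 0, max_width > 0, width_exponent >= 0,
            length(thickness) == 3, all(thickness > 0),
            length(midrib) == 3, all(midrib > 0))
  if (thickness[1] < thickness[3]) {
    stop("lamina must taper toward the tip: thickness[base] >= thickness[tip]")
  }
  if (midrib[1] < thickness[1]) {
    stop("basal midrib diameter must be >= basal lamina thickness")
  }
  structure(
    list(length = unname(length), max_width = unname(max_width),
         width_exponent = unname(width_exponent),
         thickness = as.numeric(thickness),
         midrib = as.numeric(midrib),
         width_fun = width_fun),
    class = "leaf_shape")
}

#' @export
print.leaf_shape <- function(x, ...) {
  cat(sprintf("Leaf shape: L = %.1f mm, W = %.2f mm, a = %.2f\n",
              x$length, x$max_width, x$width_exponent))
  cat(sprintf("  lamina thickness (base/middle/tip): %.3f/%.3f/%.3f mm\n",
              x$thickness[1], x$thickness[2], x$thickness[3]))
  cat(sprintf("  midrib diameter  (base/middle/tip): %.3f/%.3f/%.3f mm\n",
              x$midrib[1], x$midrib[2], x$midrib[3]))
  invisible(x)
}

# Width profile of a shape, vectorised over x (mm). Zero outside [0, L].
leaf_width_profile <- function(shape, x) {
  if (!is.null(shape$width_fun)) {
    w <- shape$width_fun(x)
    w[x < 0 | x > shape$length] <- 0
    return(pmax(w, 0))
  }
  u <- x / shape$length
  g <- 4 * u * (1 - u)
  w <- ifelse(g > 0, shape$max_width * g^shape$width_exponent, 0)
  if (shape$width_exponent == 0) w <- ifelse(u >= 0 & u <= 1, shape$max_width, 0)
  w
}

# Lamina thickness profile: linear through (0, base), (L/2, middle), (L, tip).
leaf_thickness_profile <- function(shape, x) {
  stats::approx(c(0, shape$length / 2, shape$length), shape$thickness,
                xout = pmin(pmax(x, 0), shape$length), rule = 2)$y
}

# Midrib diameter profile, same stations.
midrib_diameter_profile <- function(shape, x) {
  stats::approx(c(0, shape$length / 2, shape$length), shape$midrib,
                xout = pmin(pmax(x, 0), shape$length), rule = 2)$y
}

#' A leaf specimen: a whole leaf or a piece cut from one
#'
#' A specimen is a shape plus an interval `[x0, x1]` along the leaf axis.
#' Whole leaves span `[0, L]`. Specimens carry the ground truth used to
#' validate the measurement chain: the true silhouette area, lamina volume,
#' and midrib volume. The *true* midrib volume is the geometric
#' cylinder/cone model volume multiplied by `midrib_mismatch`, so that the
#' discrepancy between a real midrib and its idealised model can be emulated
#' (a mismatch of 1 makes midrib exclusion exact).
#'
#' @param shape a [leaf_shape()].
#' @param interval numeric length-2, the piece interval `[x0, x1]` in mm
#'   (default the whole leaf).
#' @param id specimen identifier (character).
#' @param midrib_mismatch multiplicative factor linking the modelled midrib
#'   volume to the specimen's true midrib volume (default 1 = exact model).
#' @return an object of class `leaf_specimen`.
#' @export
leaf_specimen <- function(shape, interval = c(0, shape$length),
                          id = "leaf-1", midrib_mismatch = 1) {
  stopifnot(inherits(shape, "leaf_shape"), length(interval) == 2)
  interval <- as.numeric(interval)
  if (!(interval[1] >= 0 && interval[1] < interval[2] &&
        interval[2] <= shape$length + 1e-9)) {
    stop("piece interval must satisfy 0 <= x0 < x1 <= L")
  }
  stopifnot(midrib_mismatch > 0)
  structure(
    list(shape = shape, interval = interval, id = as.character(id),
         midrib_mismatch = midrib_mismatch),
    class = "leaf_specimen")
}

#' @export
print.leaf_specimen <- function(x, ...) {
  cat(sprintf("Leaf specimen '%s'%s: interval [%.1f, %.1f] mm of L = %.1f mm\n",
              x$id, if (is_complete_leaf(x)) " (complete leaf)" else " (piece)",
              x$interval[1], x$interval[2], x$shape$length))
  cat(sprintf("  true area %.1f mm^2, lamina volume %.2f mm^3, midrib %.2f mm^3\n",
              true_area(x), lamina_volume(x), true_midrib_volume(x)))
  invisible(x)
}

#' Is a specimen a complete leaf?
#'
#' @param s a [leaf_specimen()].
#' @param tol interval tolerance in mm.
#' @return logical. A complete leaf spans the whole `[0, L]` axis; the
#'   distinction selects the conical (complete leaf) versus cylindrical
#'   (piece) midrib model.
#' @export
is_complete_leaf <- function(s, tol = 1e-6) {
  s$interval[1] <= tol && s$interval[2] >= s$shape$length - tol
}

# Adaptive quadrature of f over [x0, x1], relative tolerance 1e-8.
leaf_quadrature <- function(f, x0, x1) {
  stats::integrate(f, lower = x0, upper = x1, rel.tol = 1e-8,
                   subdivisions = 500L)$value
}

#' True silhouette area of a specimen
#'
#' Ground-truth area \eqn{\int_{x_0}^{x_1} w(x)\,dx} by adaptive quadrature
#' (relative tolerance 1e-8). This is the oracle against which both the
#' optical and the volumetric estimators are validated.
#'
#' @param s a [leaf_specimen()].
#' @return area in mm^2.
#' @export
true_area <- function(s) {
  stopifnot(inherits(s, "leaf_specimen"))
  leaf_quadrature(function(x) leaf_width_profile(s$shape, x),
                  s$interval[1], s$interval[2])
}

# Lamina-only volume: integral of w(x) t(x) over the piece interval.
lamina_volume <- function(s) {
  leaf_quadrature(function(x) {
    leaf_width_profile(s$shape, x) * leaf_thickness_profile(s$shape, x)
  }, s$interval[1], s$interval[2])
}

# Geometric midrib model volume of the specimen (cylinder for pieces, cone
# for complete leaves), using the midrib diameter at the piece base.
midrib_model_volume <- function(s) {
  len <- diff(s$interval)
  t_bm <- midrib_diameter_profile(s$shape, s$interval[1])
  midrib_volume(len, t_bm, model = if (is_complete_leaf(s)) "cone" else "cylinder")
}

# True (simulated) midrib volume = model volume x mismatch factor.
true_midrib_volume <- function(s) {
  midrib_model_volume(s) * s$midrib_mismatch
}

#' True volume of a specimen
#'
#' Lamina volume \eqn{\int w(x) t(x) dx} by adaptive quadrature, plus the
#' specimen's true midrib volume when `include_midrib = TRUE`.
#'
#' @param s a [leaf_specimen()].
#' @param include_midrib include the midrib add-on volume?
#' @return volume in mm^3.
#' @export
true_volume <- function(s, include_midrib = TRUE) {
  stopifnot(inherits(s, "leaf_specimen"))
  v <- lamina_volume(s)
  if (include_midrib) v <- v + true_midrib_volume(s)
  v
}

#' Sampled mean lamina thickness of a specimen
#'
#' Emulates micrometer sampling of the thickness profile under one of the
#' field schemes: `three_point` (base, middle and tip of the piece, averaged),
#' `every_2cm` (readings every 20 mm along the piece, starting at its base;
#' pieces shorter than 20 mm get a single mid-piece reading), or
#' `middle_only` (one mid-piece reading). Optional Gaussian reading noise
#' emulates the micrometer (0.01 mm resolution instrument).
#'
#' @param s a [leaf_specimen()].
#' @param scheme sampling scheme, see Details.
#' @param noise_sd micrometer reading noise SD in mm (default 0 = exact).
#' @param seed optional integer seed for the reading noise.
#' @return mean thickness in mm.
#' @export
mean_thickness <- function(s, scheme = c("three_point", "every_2cm", "middle_only"),
                           noise_sd = 0, seed = NULL) {
  stopifnot(inherits(s, "leaf_specimen"))
  scheme <- match.arg(scheme)
  x0 <- s$interval[1]; x1 <- s$interval[2]
  pts <- switch(scheme,
    three_point = c(x0, (x0 + x1) / 2, x1),
    every_2cm = if (x1 - x0 < 20) (x0 + x1) / 2 else seq(x0, x1, by = 20),
    middle_only = (x0 + x1) / 2)
  readings <- leaf_thickness_profile(s$shape, pts)
  if (noise_sd > 0) {
    readings <- with_seed(seed, readings + rnorm(length(readings), 0, noise_sd))
    readings <- pmax(readings, 0.01)  # a micrometer never reads <= 0
  }
  mean(readings)
}

#' Cut a specimen into pieces along the leaf axis
#'
#' Partitions the specimen interval at the given cut points, preserving the
#' parent shape. Lamina area and volume are additive over the pieces; the
#' cylinder midrib model of each piece uses the midrib diameter at that
#' piece's base, so modelled midrib volumes of pieces are not in general
#' additive to the parent cone model (mirroring the field protocol, where
#' each sample's midrib is modelled independently).
#'
#' @param s a [leaf_specimen()].
#' @param cuts numeric vector of cut positions strictly inside the interval.
#' @return list of `leaf_specimen` pieces.
#' @export
cut_specimen <- function(s, cuts) {
  stopifnot(inherits(s, "leaf_specimen"))
  cuts <- sort(unique(as.numeric(cuts)))
  if (any(cuts <= s$interval[1]) || any(cuts >= s$interval[2])) {
    stop("cut positions must lie strictly inside the specimen interval")
  }
  edges <- c(s$interval[1], cuts, s$interval[2])
  lapply(seq_len(length(edges) - 1), function(i) {
    leaf_specimen(s$shape, interval = edges[i:(i + 1)],
                  id = sprintf("%s-p%d", s$id, i),
                  midrib_mismatch = s$midrib_mismatch)
  })
}
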