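# Reference density of air-free water (g/cm^3) on a 15-30 degC grid at
# 0.5 degC steps, standard handbook values. Stored once; water_density()
# interpolates linearly and converts to g/mm^3.
.water_density_grid <- list(
  temp = seq(15, 30, by = 0.5),
  rho_g_cm3 = c(
    0.9990996, 0.9990228, 0.9989430, 0.9988604, 0.9987749, 0.9986866,
    0.9985956, 0.9985018, 0.9984052, 0.9983060, 0.9982041, 0.9980996,
    0.9979925, 0.9978828, 0.9977705, 0.9976558, 0.9975385, 0.9974187,
    0.9972965, 0.9971719, 0.9970449, 0.9969155, 0.9967837, 0.9966496,
    0.9965132, 0.9963745, 0.9962335, 0.9960903, 0.9959448, 0.9957971,
    0.9956473))

#' Density of water at a given temperature
#'
#' Linear interpolation on an embedded reference grid (15-30 degC in 0.5
#' degC steps, handbook values for air-free water). No extrapolation:
#' temperatures outside the grid raise an error.
#'
#' @param temp water temperature in degC (vectorised).
#' @return density in g/mm^3.
#' @examples
#' water_density(22)  # ~0.0009978 g/mm^3
#' @export
water_density <- function(temp) {
  g <- .water_density_grid
  if (any(temp < min(g$temp) | temp > max(g$temp))) {
    stop(sprintf("temperature outside the embedded density table (%g-%g degC)",
                 min(g$temp), max(g$temp)))
  }
  stats::approx(g$temp, g$rho_g_cm3, xout = temp)$y / 1000
}

#' Retainer volume from its immersion weight
#'
#' On immersion of the suspended retainer the balance reading increases by
#' the weight of displaced water, so \eqn{V_r = \Delta W_r / \rho_T}.
#'
#' @param dW_r balance reading change on immersing the retainer, g (`> 0`).
#' @param temp water temperature in degC.
#' @return retainer volume in mm^3.
#' @export
retainer_volume <- function(dW_r, temp) {
  if (any(dW_r <= 0)) stop("retainer immersion reading dW_r must be positive")
  dW_r / water_density(temp)
}

#' Leaf volume by the suspension technique
#'
#' For each replicate, \eqn{V_l = \Delta W_t / \rho_T - V_r}; replicates are
#' combined by [aggregate_replicates()] (outlying replicates, e.g. from
#' trapped air bubbles, are discarded before averaging). Small negative
#' results within the balance rounding bound are clamped to zero with a
#' warning; larger negatives indicate a protocol failure (typically bubbles
#' on the retainer-only run) and raise an error.
#'
#' @param rec a [suspension_record()] (or a data.frame with columns `dW_t`
#'   and `temp`).
#' @param V_r retainer volume in mm^3 (`>= 0`); defaults to the volume
#'   implied by the record's own mean `dW_r`.
#' @param resolution balance resolution in g, used for the rounding bound.
#' @return list with `V_l` (mm^3, replicate-aggregated), `replicates`
#'   (per-replicate volumes) and `n_used`.
#' @export
leaf_volume_suspension <- function(rec, V_r = NULL, resolution = 0.001) {
  stopifnot(all(c("dW_t", "temp") %in% names(rec)))
  rho <- water_density(rec$temp)
  if (is.null(V_r)) {
    if (!"dW_r" %in% names(rec)) stop("V_r not given and record has no dW_r")
    V_r <- mean(rec$dW_r / rho)
  }
  stopifnot(V_r >= 0)
  v <- rec$dW_t / rho - V_r
  bound <- resolution / min(rho)  # one balance step, in mm^3
  if (any(v < -bound)) {
    stop("negative leaf volume beyond the rounding bound: suspect bubbles or a measurement error")
  }
  if (any(v < 0)) {
    warning("replicate volume slightly negative (within rounding); clamped to 0")
    v <- pmax(v, 0)
  }
  agg <- aggregate_replicates(v)
  list(V_l = agg$estimate, replicates = v, n_used = agg$n_used)
}

#' Leaf volume on the Specific Gravity Bench
#'
#' On the SGB the cage (retainer) hangs from a load cell and is immersed by
#' raising the water container. With the dry weights of the cage
#' (`W_r1`) and of the leaf pile (`W_l1`), and the underwater weight of the
#' immersed set (`W_T2`), the displaced-water balance gives
#' \deqn{V_l = (W_{l1} - W_{T2} + W_{r2}) / \rho_T} when the underwater
#' cage weight `W_r2` was recorded, and the `W_r2`-free form
#' \deqn{V_l = (W_{l1} + W_{r1} - W_{T2} - V_r \rho_T) / \rho_T}
#' otherwise (substituting \eqn{W_{r2} = W_{r1} - V_r \rho_T}). Both paths
#' agree exactly on consistent records.
#'
#' @param rec a [sgb_record()] (or list/data.frame with fields `W_l1`,
#'   `W_T2`, `temp`, and `W_r1` and/or `W_r2`).
#' @param V_r retainer (cage) volume in mm^3; defaults to
#'   `(W_r1 - W_r2)/rho` when both weights are present.
#' @param w_r2_tol consistency tolerance (g) between a recorded `W_r2` and
#'   the value implied by `W_r1` and `V_r`.
#' @return list with `V_l` (mm^3), `replicates` and `n_used`, as for
#'   [leaf_volume_suspension()].
#' @export
leaf_volume_sgb <- function(rec, V_r = NULL, w_r2_tol = 0.01) {
  stopifnot(all(c("W_l1", "W_T2", "temp") %in% names(rec)))
  rho <- water_density(rec$temp)
  has_r2 <- !is.null(rec$W_r2) && !all(is.na(rec$W_r2))
  if (is.null(V_r)) {
    if (!has_r2 || is.null(rec$W_r1)) {
      stop("V_r not given and the record lacks W_r1/W_r2 to derive it")
    }
    V_r <- mean((rec$W_r1 - rec$W_r2) / rho)
  }
  stopifnot(V_r >= 0)
  if (has_r2 && !is.null(rec$W_r1)) {
    implied <- rec$W_r1 - V_r * rho
    if (any(abs(rec$W_r2 - implied) > w_r2_tol)) {
      stop("inconsistent record: W_r2 does not match W_r1 - V_r * rho within tolerance")
    }
  }
  v <- if (has_r2) {
    (rec$W_l1 - rec$W_T2 + rec$W_r2) / rho
  } else {
    (rec$W_l1 + rec$W_r1 - rec$W_T2 - V_r * rho) / rho
  }
  agg <- aggregate_replicates(v)
  list(V_l = agg$estimate, replicates = v, n_used = agg$n_used)
}

#' Midrib volume from sample length and basal midrib diameter
#'
#' Short pieces, along which the midrib diameter varies little, use a
#' cylinder \eqn{V_m = L \pi (T_{b.m}/2)^2}; complete leaves use a cone of
#' the same base and height (one third of the cylinder).
#'
#' @param L sample length in mm (`> 0`).
#' @param T_bm basal midrib diameter in mm (`> 0`).
#' @param model `"cylinder"` (pieces) or `"cone"` (complete leaves).
#' @return midrib volume in mm^3.
#' @examples
#' midrib_volume(100, 1, "cylinder")  # 25 * pi
#' midrib_volume(100, 1, "cone")      # 25 * pi / 3
#' @export
midrib_volume <- function(L, T_bm, model = c("cylinder", "cone")) {
  model <- match.arg(model)
  if (any(L <= 0)) stop("sample length must be positive")
  if (any(T_bm <= 0)) stop("basal midrib diameter must be positive")
  v <- L * pi * (T_bm / 2)^2
  if (model == "cone") v <- v / 3
  v
}

#' Volumetric leaf area
#'
#' The central estimator: leaf area as volume divided by mean lamina
#' thickness, \eqn{VLA = (V_l - V_m) / T_l}, with `V_m = 0` when the midrib
#' is not excluded.
#'
#' @param V_l leaf (or pile) volume in mm^3 (`> 0`).
#' @param T_l mean lamina thickness in mm (`> 0`).
#' @param V_m midrib volume to exclude, mm^3 (`0 <= V_m < V_l`).
#' @return leaf area in mm^2.
#' @examples
#' volumetric_leaf_area(250, 0.25)          # 1000 mm^2
#' volumetric_leaf_area(250, 0.25, 0.045 * 250)  # midrib share excluded
#' @export
volumetric_leaf_area <- function(V_l, T_l, V_m = 0) {
  if (any(V_l <= 0)) stop("leaf volume must be positive")
  if (any(T_l <= 0)) stop("mean thickness must be positive")
  if (any(V_m < 0) || any(V_m >= V_l)) stop("midrib volume must satisfy 0 <= V_m < V_l")
  (V_l - V_m) / T_l
}

#' Combine replicate volume readings
#'
#' Replicate underwater weighings are repeated until a stable value is
#' reached; a replicate disturbed by trapped bubbles deviates far from the
#' others. Replicates whose absolute deviation from the median exceeds
#' three times the inter-replicate spread (the median absolute deviation)
#' are discarded, and the rest averaged.
#'
#' @param values numeric vector of replicate measurements (length >= 1).
#' @return list with `estimate` (mean of retained replicates), `n_used`,
#'   and logical vector `used`.
#' @export
aggregate_replicates <- function(values) {
  if (length(values) == 0) stop("at least one replicate is required")
  if (length(values) == 1) {
    return(list(estimate = values, n_used = 1L, used = TRUE))
  }
  dev <- abs(values - median(values))
  spread <- median(dev)
  used <- dev <= 3 * spread
  list(estimate = mean(values[used]), n_used = sum(used), used = used)
}
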