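#' Parameters of a synthetic wheat-leaf population
#'
#' Defaults emulate a mid-season wheat canopy: mean leaf length 150 mm,
#' maximum width 12 mm, lamina thickness tapering 0.30/0.25/0.20 mm
#' (base/middle/tip, mean about 0.25 mm) and a midrib diameter profile of
#' 0.60/0.45/0.30 mm. The coefficients of variation default to the seasonal
#' values observed for field-grown wheat (length about 21%, width 19%,
#' lamina thickness 13-15%, midrib 12-24%). Dimension marginals are
#' log-normal; a Gaussian copula with a single exchangeable correlation
#' `rho` induces the moderate positive inter-dimension correlations seen in
#' real canopies.
#'
#' @param n number of leaves.
#' @param mean named numeric vector of dimension means (mm); names
#'   `length`, `width`, `t_base`, `t_middle`, `t_tip`, `m_base`, `m_middle`,
#'   `m_tip`.
#' @param cv named numeric vector of coefficients of variation (fractions),
#'   same names.
#' @param rho exchangeable copula correlation in `[0, 1)`.
#' @param width_exponent silhouette shape exponent, see [leaf_shape()].
#' @param seed integer seed; the draw is a pure function of the parameters
#'   and this seed.
#' @return an object of class `population_params`.
#' @export
population_params <- function(n = 14,
                              mean = c(length = 150, width = 12,
                                       t_base = 0.30, t_middle = 0.25, t_tip = 0.20,
                                       m_base = 0.60, m_middle = 0.45, m_tip = 0.30),
                              cv = c(length = 0.210, width = 0.193,
                                     t_base = 0.153, t_middle = 0.129, t_tip = 0.145,
                                     m_base = 0.236, m_middle = 0.143, m_tip = 0.125),
                              rho = 0.5, width_exponent = 0.5, seed = 1L) {
  dims <- c("length", "width", "t_base", "t_middle", "t_tip",
            "m_base", "m_middle", "m_tip")
  defaults <- eval(formals(population_params)$mean)
  default_cv <- eval(formals(population_params)$cv)
  mean <- utils::modifyList(as.list(defaults), as.list(mean))
  cv <- utils::modifyList(as.list(default_cv), as.list(cv))
  mean <- unlist(mean)[dims]; cv <- unlist(cv)[dims]
  if (any(is.na(mean)) || any(mean <= 0)) stop("all dimension means must be positive")
  if (any(is.na(cv)) || any(cv < 0)) stop("all CVs must be non-negative")
  if (!(n >= 1)) stop("n must be >= 1")
  stopifnot(rho >= 0, rho < 1, width_exponent >= 0)
  structure(list(n = as.integer(n), mean = mean, cv = cv, rho = rho,
                 width_exponent = width_exponent, seed = as.integer(seed)),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf("Population parameters: n = %d, rho = %.2f, seed = %d\n",
              x$n, x$rho, x$seed))
  print(data.frame(mean = x$mean, cv_pct = 100 * x$cv))
  invisible(x)
}

#' Draw a population of complete synthetic leaves
#'
#' Draws `params$n` leaves with log-normal dimension marginals coupled by a
#' Gaussian copula (exchangeable correlation `rho`). Two shape invariants
#' are enforced after the marginal draw: base thickness readings thicker
#' than tip readings are swapped into order, and the basal midrib diameter
#' is floored at the basal lamina thickness.
#'
#' @param params a [population_params()].
#' @return list of [leaf_specimen()] objects (complete leaves).
#' @examples
#' pop <- sample_population(population_params(n = 5, seed = 42))
#' sapply(pop, true_area)
#' @export
sample_population <- function(params) {
  stopifnot(inherits(params, "population_params"))
  n <- params$n
  dims <- names(params$mean)
  k <- length(dims)
  draws <- with_seed(params$seed, {
    z <- matrix(rnorm(n * k), n, k)
    if (params$rho > 0) {
      # exchangeable correlation: z_i = sqrt(rho) * shared + sqrt(1-rho) * own
      shared <- rnorm(n)
      z <- sqrt(params$rho) * shared + sqrt(1 - params$rho) * z
    }
    z
  })
  x <- sapply(seq_len(k), function(j) {
    qlnorm_mean_cv(draws[, j], params$mean[j], params$cv[j])
  })
  x <- matrix(x, n, k, dimnames = list(NULL, dims))
  # enforce taper: base >= tip for lamina thickness
  swap <- x[, "t_base"] < x[, "t_tip"]
  if (any(swap)) {
    tmp <- x[swap, "t_base"]
    x[swap, "t_base"] <- x[swap, "t_tip"]
    x[swap, "t_tip"] <- tmp
  }
  x[, "m_base"] <- pmax(x[, "m_base"], x[, "t_base"])
  lapply(seq_len(n), function(i) {
    leaf_specimen(
      leaf_shape(length = x[i, "length"], max_width = x[i, "width"],
                 width_exponent = params$width_exponent,
                 thickness = x[i, c("t_base", "t_middle", "t_tip")],
                 midrib = x[i, c("m_base", "m_middle", "m_tip")]),
      id = sprintf("leaf-%03d", i))
  })
}

#' Generate a study-style specimen set of leaf pieces and whole leaves
#'
#' Emulates the bench experiment in which several leaves were cut into
#' pieces ranging from under 1 cm^2 to full leaves. Target silhouette areas
#' are drawn log-uniformly over `area_range`; for each target a leaf is
#' drawn from the population, rescaled isotropically in plan (length and
#' width) when the target exceeds its full area, or cut to a piece whose
#' quadrature area matches the target (relative tolerance 1e-6). Each
#' specimen's midrib add-on is calibrated so that the modelled midrib volume
#' is a `midrib_fraction` share of its total volume (drawn uniformly, the
#' 2-8% range observed in wheat), then perturbed by the multiplicative
#' `midrib_mismatch` factor (uniform on `1 +/- mismatch`) that emulates how
#' far a real midrib departs from its cylinder/cone idealisation.
#'
#' @param n number of specimens (default 14, the bench sample count).
#' @param area_range target silhouette area range in mm^2.
#' @param params population the source leaves are drawn from
#'   ([population_params()]; its `n` and `seed` are ignored).
#' @param midrib_fraction length-2 range of the modelled midrib volume as a
#'   fraction of total specimen volume.
#' @param midrib_mismatch half-width of the uniform multiplicative model
#'   mismatch on the midrib add-on (0 = exact model).
#' @param seed integer seed.
#' @return list of [leaf_specimen()] objects.
#' @export
sample_leaf_pieces <- function(n = 14, area_range = c(60, 3500),
                               params = population_params(),
                               midrib_fraction = c(0.02, 0.08),
                               midrib_mismatch = 0.20, seed = 1L) {
  stopifnot(n >= 1, length(area_range) == 2, all(area_range > 0),
            area_range[1] < area_range[2],
            midrib_fraction[1] > 0, midrib_fraction[2] < 0.5,
            midrib_mismatch >= 0, midrib_mismatch < 1)
  with_seed(seed, {
    targets <- exp(runif(n, log(area_range[1]), log(area_range[2])))
    frac <- runif(n, midrib_fraction[1], midrib_fraction[2])
    mism <- if (midrib_mismatch > 0) runif(n, 1 - midrib_mismatch, 1 + midrib_mismatch)
            else rep(1, n)
    base_pop <- sample_population(
      population_params(n = n, mean = params$mean, cv = params$cv,
                        rho = params$rho, width_exponent = params$width_exponent,
                        seed = sample.int(.Machine$integer.max, 1)))
    lapply(seq_len(n), function(i) {
      sp <- base_pop[[i]]
      full_area <- true_area(sp)
      if (targets[i] >= full_area) {
        # scale the plan dimensions so the full leaf hits the target area
        sc <- sqrt(targets[i] / full_area)
        sh <- sp$shape
        sp <- leaf_specimen(
          leaf_shape(sh$length * sc, sh$max_width * sc, sh$width_exponent,
                     sh$thickness, sh$midrib),
          id = sprintf("sample-%02d", i))
      } else {
        # cut a piece: random basal position, apical end solved for area
        sh <- sp$shape
        area_to <- function(x1, x0) {
          leaf_quadrature(function(x) leaf_width_profile(sh, x), x0, x1)
        }
        x0 <- runif(1, 0, 0.5 * sh$length)
        while (area_to(sh$length, x0) < targets[i]) x0 <- x0 / 2
        x1 <- stats::uniroot(function(x1) area_to(x1, x0) - targets[i],
                             lower = x0 + 1e-6, upper = sh$length,
                             tol = 1e-9)$root
        sp <- leaf_specimen(sh, interval = c(x0, x1),
                            id = sprintf("sample-%02d", i))
      }
      calibrate_midrib(sp, frac[i], mism[i], id = sprintf("sample-%02d", i))
    })
  })
}

# Rescale a specimen's midrib diameter profile so that its modelled midrib
# volume is `fraction` of the total specimen volume, then attach the model
# mismatch factor. The basal diameter is floored at the basal lamina
# thickness (shape invariant), which can leave small thick pieces slightly
# above the requested fraction.
calibrate_midrib <- function(sp, fraction, mismatch, id = sp$id) {
  v_lam <- lamina_volume(sp)
  v_m_target <- fraction / (1 - fraction) * v_lam
  v_m_now <- midrib_model_volume(sp)
  sc <- sqrt(v_m_target / v_m_now)  # volume scales with diameter squared
  sh <- sp$shape
  new_midrib <- pmax(sh$midrib * sc, sh$thickness)
  shape <- leaf_shape(sh$length, sh$max_width, sh$width_exponent,
                      sh$thickness, new_midrib, width_fun = sh$width_fun)
  leaf_specimen(shape, interval = sp$interval, id = id,
                midrib_mismatch = mismatch)
}

#' Ground-truth table for a specimen set
#'
#' @param specimens list of [leaf_specimen()].
#' @return data.frame with one row per specimen: id, interval, completeness,
#'   true area (mm^2), lamina / midrib / total volumes (mm^3), modelled
#'   midrib volume, and the exact profile-mean thickness.
#' @export
specimen_truth <- function(specimens) {
  stopifnot(length(specimens) >= 1)
  rows <- lapply(specimens, function(s) {
    data.frame(
      specimen_id = s$id,
      x0 = s$interval[1], x1 = s$interval[2],
      complete_leaf = is_complete_leaf(s),
      true_area = true_area(s),
      lamina_volume = lamina_volume(s),
      midrib_volume_true = true_midrib_volume(s),
      midrib_volume_model = midrib_model_volume(s),
      total_volume = true_volume(s, include_midrib = TRUE),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
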