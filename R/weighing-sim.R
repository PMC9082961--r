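#' Suspension weighing record
#'
#' Container for the balance readings of one suspension-technique
#' measurement: per replicate, the reading change on immersing the empty
#' retainer (`dW_r`) and on immersing retainer plus leaf (`dW_t`), with the
#' water temperature.
#'
#' @param dW_r retainer immersion readings, g (one per replicate).
#' @param dW_t retainer-plus-leaf immersion readings, g.
#' @param temp water temperature in degC.
#' @return object of class `suspension_record` (a data.frame with one row
#'   per replicate plus a `temp` column).
#' @export
suspension_record <- function(dW_r, dW_t, temp) {
  n <- max(length(dW_r), length(dW_t))
  dW_r <- rep_len(dW_r, n); dW_t <- rep_len(dW_t, n)
  if (any(dW_t < dW_r)) {
    stop("dW_t must be >= dW_r for any leaf of non-negative volume")
  }
  water_density(temp)  # validates the temperature range
  structure(data.frame(replicate = seq_len(n), dW_r = dW_r, dW_t = dW_t,
                       temp = temp),
            class = c("suspension_record", "data.frame"))
}

#' SGB weighing record
#'
#' @param W_r1 dry cage weight in air, g.
#' @param W_l1 dry leaf-pile weights in air, g (one per replicate).
#' @param W_T2 underwater weights of the immersed set, g.
#' @param temp water temperature, degC.
#' @param W_r2 optional underwater cage weight, g (must be `< W_r1`).
#' @return object of class `sgb_record` (a data.frame with one row per
#'   replicate).
#' @export
sgb_record <- function(W_r1, W_l1, W_T2, temp, W_r2 = NA_real_) {
  n <- max(length(W_l1), length(W_T2))
  if (!all(is.na(W_r2)) && any(W_r2 >= W_r1, na.rm = TRUE)) {
    stop("W_r2 must be below W_r1 (the immersed cage is buoyed)")
  }
  water_density(temp)
  structure(data.frame(replicate = seq_len(n), W_r1 = W_r1,
                       W_r2 = rep_len(W_r2, n), W_l1 = rep_len(W_l1, n),
                       W_T2 = rep_len(W_T2, n), temp = temp),
            class = c("sgb_record", "data.frame"))
}

# Quantise a reading to the instrument resolution (g).
round_to_resolution <- function(x, resolution) {
  if (resolution <= 0) return(x)
  round(x / resolution) * resolution
}

#' Simulate a suspension weighing of a known volume
#'
#' Inverts the suspension relation: the balance reading change equals the
#' displaced-water weight, so before rounding
#' \eqn{\Delta W_t = (V + V_r)\rho_T} and \eqn{\Delta W_r = V_r \rho_T}.
#' Gaussian reading noise (optional) is added before quantising to the
#' balance resolution (0.001 g by default).
#'
#' @param V_true true specimen volume in mm^3 (`> 0`).
#' @param temp water temperature in degC (within the density table).
#' @param retainer_volume true retainer volume in mm^3.
#' @param n_replicates number of replicates (the bench protocol repeats two
#'   or three times to catch bubble errors).
#' @param noise_sd Gaussian reading noise SD in g (default 0: rounding is
#'   the only error).
#' @param resolution balance resolution in g.
#' @param seed integer seed.
#' @return a [suspension_record()].
#' @export
simulate_suspension_weighing <- function(V_true, temp = 22,
                                         retainer_volume = 2000,
                                         n_replicates = 3, noise_sd = 0,
                                         resolution = 0.001, seed = NULL) {
  stopifnot(V_true > 0, retainer_volume >= 0, n_replicates >= 1)
  rho <- water_density(temp)
  with_seed(seed, {
    dW_r <- round_to_resolution(
      retainer_volume * rho + rnorm(n_replicates, 0, noise_sd), resolution)
    dW_t <- round_to_resolution(
      (V_true + retainer_volume) * rho + rnorm(n_replicates, 0, noise_sd),
      resolution)
    suspension_record(dW_r = dW_r, dW_t = pmax(dW_t, dW_r), temp = temp)
  })
}

#' Simulate an SGB weighing of a known volume
#'
#' The immersed set (cage plus leaf pile) hangs from the load cell, which
#' therefore reads the dry weight minus the displaced-water weight:
#' \eqn{W_{T2} = W_{dry} + W_{r1} - (V + V_r)\rho_T} before noise and
#' quantisation; \eqn{W_{l1} = W_{dry}} and
#' \eqn{W_{r2} = W_{r1} - V_r \rho_T}.
#'
#' @param V_true true leaf-pile volume in mm^3.
#' @param W_dry dry weight of the leaf pile in g (`> 0`).
#' @param temp water temperature in degC.
#' @param retainer list with `W_r1` (dry cage weight, g) and `V_r` (cage
#'   volume, mm^3).
#' @param n_replicates number of underwater weighings.
#' @param noise_sd Gaussian load-cell noise SD in g.
#' @param resolution load-cell resolution in g.
#' @param seed integer seed.
#' @param record_w_r2 include the underwater cage weight in the record?
#' @return an [sgb_record()].
#' @export
simulate_sgb_weighing <- function(V_true, W_dry, temp = 22,
                                  retainer = list(W_r1 = 20, V_r = 2000),
                                  n_replicates = 3, noise_sd = 0,
                                  resolution = 0.001, seed = NULL,
                                  record_w_r2 = TRUE) {
  stopifnot(V_true > 0, W_dry > 0, retainer$V_r >= 0)
  rho <- water_density(temp)
  with_seed(seed, {
    W_l1 <- round_to_resolution(W_dry + rnorm(n_replicates, 0, noise_sd),
                                resolution)
    W_T2 <- round_to_resolution(
      W_dry + retainer$W_r1 - (V_true + retainer$V_r) * rho +
        rnorm(n_replicates, 0, noise_sd), resolution)
    W_r2 <- if (record_w_r2) {
      round_to_resolution(retainer$W_r1 - retainer$V_r * rho +
                            rnorm(n_replicates, 0, noise_sd), resolution)
    } else {
      NA_real_
    }
    sgb_record(W_r1 = retainer$W_r1, W_l1 = W_l1, W_T2 = W_T2, temp = temp,
               W_r2 = W_r2)
  })
}
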