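#' Assign specimens to random virtual piles
#'
#' Each pile is an independent simple random sample of `group_size`
#' distinct specimens ("without replacement" within a pile); the same
#' specimen may appear in many piles. With `group_size` equal to the
#' population size every pile is the full set. The assignment is a pure
#' function of the inputs and the seed.
#'
#' @param ids specimen identifiers (or any vector to sample from).
#' @param group_size pile size (`<=` number of specimens).
#' @param n_groups number of piles.
#' @param seed integer seed.
#' @return list of length `n_groups`; each element a vector of
#'   `group_size` distinct ids.
#' @export
assign_piles <- function(ids, group_size, n_groups, seed = 1L) {
  n <- length(ids)
  if (group_size > n) stop("group_size exceeds the number of specimens")
  stopifnot(group_size >= 1, n_groups >= 1)
  with_seed(seed, {
    lapply(seq_len(n_groups), function(g) ids[sample.int(n, group_size)])
  })
}

#' Volumetric leaf area of a pile
#'
#' The pile VLA divides the summed member volumes by the unweighted mean of
#' the members' mean thicknesses:
#' \deqn{VLA_{pile} = \sum_i V_i / \overline{T}.}
#' With `exclude_midrib = TRUE` the summed volumes are `V_i - Vm_i`. The
#' alternative literal reading "sum of the individual VLAs divided by the
#' mean thickness" is dimensionally inconsistent but available as
#' `mode = "sum_vlas"` for comparison.
#'
#' @param volumes member leaf volumes in mm^3.
#' @param thicknesses member mean thicknesses in mm (`> 0`).
#' @param midrib_volumes member midrib volumes (mm^3), used when excluding.
#' @param exclude_midrib subtract the midrib volumes?
#' @param mode `"sum_volumes"` (default) or `"sum_vlas"` (the literal,
#'   dimensionally inconsistent variant).
#' @return pile leaf area in mm^2.
#' @export
pile_vla <- function(volumes, thicknesses, midrib_volumes = 0,
                     exclude_midrib = FALSE,
                     mode = c("sum_volumes", "sum_vlas")) {
  mode <- match.arg(mode)
  stopifnot(length(volumes) >= 1)
  if (any(thicknesses <= 0)) stop("thicknesses must be positive")
  v <- if (exclude_midrib) volumes - rep_len(midrib_volumes, length(volumes))
       else volumes
  switch(mode,
    sum_volumes = sum(v) / mean(thicknesses),
    sum_vlas = sum(v / rep_len(thicknesses, length(v))) / mean(thicknesses))
}

#' Pile analysis: pile-level agreement of volumetric and optical leaf area
#'
#' Groups measured specimens into random virtual piles, computes each
#' pile's volumetric area (summed volumes over mean thickness, with and
#' without midrib exclusion) and optical area (sum of member optical
#' areas), and fits the full method-agreement analysis at the pile level.
#'
#' @param volumes per-specimen leaf volumes in mm^3 (midrib included).
#' @param thicknesses per-specimen mean thicknesses in mm.
#' @param olas per-specimen optical leaf areas in mm^2.
#' @param midrib_volumes per-specimen modelled midrib volumes in mm^3.
#' @param group_size specimens per pile (default 7).
#' @param n_groups number of piles (default 100).
#' @param seed integer seed for the grouping.
#' @return object of class `pile_analysis`: list with `piles` (data.frame
#'   of per-pile VLA incl/excl, OLA and mean thickness) and the
#'   [method_agreement()] fits `agreement_incl` and `agreement_excl`.
#' @export
pile_analysis <- function(volumes, thicknesses, olas, midrib_volumes = 0,
                          group_size = 7, n_groups = 100, seed = 1L) {
  n <- length(volumes)
  stopifnot(length(thicknesses) == n, length(olas) == n)
  midrib_volumes <- rep_len(midrib_volumes, n)
  piles <- assign_piles(seq_len(n), group_size, n_groups, seed = seed)
  rows <- lapply(seq_along(piles), function(g) {
    idx <- piles[[g]]
    data.frame(
      pile_id = g,
      pile_vla_incl = pile_vla(volumes[idx], thicknesses[idx]),
      pile_vla_excl = pile_vla(volumes[idx], thicknesses[idx],
                               midrib_volumes[idx], exclude_midrib = TRUE),
      pile_ola = sum(olas[idx]),
      mean_thickness = mean(thicknesses[idx]))
  })
  piles_df <- do.call(rbind, rows)
  structure(list(
    piles = piles_df,
    agreement_incl = method_agreement(piles_df$pile_ola, piles_df$pile_vla_incl,
                                      labels = c("pile OLA", "pile VLA (midrib incl.)")),
    agreement_excl = method_agreement(piles_df$pile_ola, piles_df$pile_vla_excl,
                                      labels = c("pile OLA", "pile VLA (midrib excl.)")),
    group_size = group_size, n_groups = n_groups, seed = seed),
    class = "pile_analysis")
}

#' @export
print.pile_analysis <- function(x, ...) {
  cat(sprintf("Pile analysis: %d piles of %d specimens\n",
              x$n_groups, x$group_size))
  cat("Midrib included:\n"); print(x$agreement_incl)
  cat("Midrib excluded:\n"); print(x$agreement_excl)
  invisible(x)
}

#' @export
plot.pile_analysis <- function(x, ...) {
  plot(x$agreement_excl, ...)
  invisible(x)
}

#' Thickness-sampling error experiment
#'
#' Emulates estimating the mean leaf thickness of a pile by measuring a
#' random subset: `n_groups` groups of `k` leaves are drawn from the
#' thickness population (without replacement within a group), and the grand
#' mean of the group means is compared with the true population mean.
#'
#' @param population numeric vector of leaf thicknesses (mm).
#' @param k leaves sampled per group (default 5).
#' @param n_groups number of virtual groups (default 100).
#' @param seed integer seed.
#' @return object of class `thickness_sampling`: list with `group_means`,
#'   `mu` (population mean), `sd_group_means`, `grand_mean` and
#'   `pct_difference` (`100 |grand mean - mu| / mu`).
#' @export
thickness_sampling_experiment <- function(population, k = 5, n_groups = 100,
                                          seed = 1L) {
  if (length(population) == 0) stop("empty thickness population")
  if (k > length(population)) stop("k exceeds the population size")
  groups <- assign_piles(population, k, n_groups, seed = seed)
  gm <- vapply(groups, mean, numeric(1))
  mu <- mean(population)
  structure(list(group_means = gm, mu = mu,
                 sd_group_means = if (n_groups > 1) sd(gm) else 0,
                 grand_mean = mean(gm),
                 pct_difference = 100 * abs(mean(gm) - mu) / mu,
                 k = k, n_groups = n_groups,
                 n_population = length(population)),
            class = "thickness_sampling")
}

#' @export
print.thickness_sampling <- function(x, ...) {
  cat(sprintf("Thickness sampling: %d groups of %d from n = %d\n",
              x$n_groups, x$k, x$n_population))
  cat(sprintf("  mu = %.4f mm, grand mean = %.4f mm, SD of group means = %.4f\n",
              x$mu, x$grand_mean, x$sd_group_means))
  cat(sprintf("  difference = %.3f%%\n", x$pct_difference))
  invisible(x)
}

#' Histogram summary of the thickness-sampling group means
#'
#' Bin edges and counts of the distribution of group means, for export
#' alongside the experiment summary.
#'
#' @param x a [thickness_sampling_experiment()] result.
#' @param breaks passed to [graphics::hist()].
#' @return data.frame with `bin_low`, `bin_high`, `count`.
#' @export
thickness_sampling_histogram <- function(x, breaks = "Sturges") {
  stopifnot(inherits(x, "thickness_sampling"))
  h <- graphics::hist(x$group_means, breaks = breaks, plot = FALSE)
  data.frame(bin_low = h$breaks[-length(h$breaks)], bin_high = h$breaks[-1],
             count = h$counts)
}
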