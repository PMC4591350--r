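#' Simulate one Phenotype Microarray kinetic curve
#'
#' Evaluates a sigmoid model on a time grid and adds Gaussian noise,
#' clipping the signal at zero (OmniLog color units cannot be negative).
#' The default grid is one read every 15 minutes for 72 hours
#' (289 points), the OmniLog acquisition schedule.
#'
#' @inheritParams sigmoid_value
#' @param params Named vector/list with `A`, `mu`, `lambda`, `y0` and,
#'   for the Richards model, `nu`.
#' @param t_grid Strictly increasing time grid in hours.
#' @param noise_sd Gaussian noise standard deviation (signal units, `>= 0`).
#' @param seed Integer seed.
#' @param strain_id,plate_id,well_id,substrate,replicate Curve metadata.
#' @return A `KineticCurve`: list with metadata plus `times` and `signals`.
#' @examples
#' kc <- simulate_pm_curve("gompertz", c(A = 100, mu = 10, lambda = 5, y0 = 0),
#'                         noise_sd = 0, seed = 1)
#' kc$signals[kc$times == 5] # ~6.598
#' @export
simulate_pm_curve <- function(model, params, t_grid = seq(0, 72, by = 0.25),
                              noise_sd = 0, seed = 1,
                              strain_id = "strain", plate_id = "plate",
                              well_id = "w01", substrate = "substrate",
                              replicate = 1L) {
  if (any(diff(t_grid) <= 0)) stop_("t_grid must be strictly increasing")
  if (noise_sd < 0) stop_("noise_sd must be >= 0")
  p <- as.list(params)
  if (is.null(p$A) || p$A < 0) stop_("params must include A >= 0")
  y <- sigmoid_value(model, t_grid, A = p$A, mu = p$mu %||% 0,
                     lambda = p$lambda %||% 0, y0 = p$y0 %||% 0,
                     nu = p$nu %||% 1)
  if (noise_sd > 0)
    y <- with_seed(seed, y + rnorm(length(y), 0, noise_sd))
  y <- pmax(y, 0)
  kinetic_curve(strain_id = strain_id, plate_id = plate_id, well_id = well_id,
                substrate = substrate, replicate = replicate,
                times = t_grid, signals = y)
}

# Trapezoidal AUC of the noiseless model above baseline, used for truth
# labels (baseline-subtracted, consistent with curve_parameters()).
noiseless_auc <- function(model, p, t_grid = seq(0, 72, by = 0.25)) {
  y <- sigmoid_value(model, t_grid, A = p$A, mu = p$mu %||% 0,
                     lambda = p$lambda %||% 0, y0 = p$y0 %||% 0,
                     nu = p$nu %||% 1)
  pracma::trapz(t_grid, pmax(y - (p$y0 %||% 0), 0))
}

#' Simulate a two-strain Phenotype Microarray plate with known truth
#'
#' Generates one kinetic curve per strain x substrate x replicate from
#' per-strain sigmoid parameters and labels each substrate's true
#' specificity: the strain with the strictly larger noiseless
#' baseline-subtracted AUC when the relative difference
#' `|a1 - a2| / mean(a1, a2)` exceeds 50%, otherwise `"none"`. The 50%
#' margin keeps planted effects well clear of the noise-induced sigma
#' band, so recovery tests are unambiguous.
#'
#' @param strain_ids Character vector of exactly two strain ids.
#' @param effect_spec Named list (one entry per substrate); each entry is
#'   a list with `model` (default `"gompertz"`) and one named parameter
#'   vector per strain id (`A`, `mu`, `lambda`, `y0`, optional `nu`).
#' @param n_replicates Replicates per strain x substrate (default 2, the
#'   assay's duplicate design).
#' @param noise_sd Gaussian noise SD added to every curve.
#' @param t_grid Time grid in hours.
#' @param plate_id Plate id recorded on every curve.
#' @param seed Integer seed; curves are reproducible per well.
#' @return A list with `curves` (list of `KineticCurve`) and `truth`
#'   (`PlateTruth`: `substrate_ids`, `params`, `noise_sd`, `specific_for`).
#' @export
simulate_pm_plate <- function(strain_ids, effect_spec, n_replicates = 2L,
                              noise_sd = 5, t_grid = seq(0, 72, by = 0.25),
                              plate_id = "PM01", seed = 1) {
  if (length(strain_ids) != 2L) stop_("strain_ids must name exactly two strains")
  if (n_replicates < 1L) stop_("n_replicates must be >= 1")
  substrates <- names(effect_spec)
  if (is.null(substrates) || any(!nzchar(substrates)))
    stop_("effect_spec must be a named list keyed by substrate")
  curves <- list()
  specific <- setNames(character(length(substrates)), substrates)
  well <- 0L
  for (s in substrates) {
    spec <- effect_spec[[s]]
    model <- spec$model %||% "gompertz"
    for (st in strain_ids)
      if (is.null(spec[[st]]))
        stop_("effect_spec for substrate %s lacks parameters for strain %s", s, st)
    a <- vapply(strain_ids, function(st)
      noiseless_auc(model, as.list(spec[[st]]), t_grid), numeric(1))
    m <- mean(a)
    specific[s] <- if (m > 0 && abs(a[1] - a[2]) / m > 0.5)
      strain_ids[which.max(a)] else "none"
    for (st in strain_ids) for (rep_i in seq_len(n_replicates)) {
      well <- well + 1L
      curves[[length(curves) + 1L]] <- simulate_pm_curve(
        model, spec[[st]], t_grid = t_grid, noise_sd = noise_sd,
        seed = (as.numeric(seed) * 100003 + well) %% 2147483647,
        strain_id = st, plate_id = plate_id,
        well_id = sprintf("w%03d", well), substrate = s, replicate = rep_i)
    }
  }
  truth <- list(substrate_ids = substrates,
                params = effect_spec,
                noise_sd = noise_sd,
                specific_for = specific)
  list(curves = curves, truth = truth)
}
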