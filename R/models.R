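#' Sigmoid growth-curve models
#'
#' Evaluate one of the three reparameterized sigmoid models used for
#' Phenotype Microarray kinetic curves. All three share the biologically
#' interpretable parameters: plateau signal `A` (maximum rise above the
#' baseline), maximum slope `mu` (signal units per hour), lag time
#' `lambda` (hours) and baseline `y0`. The Richards model carries one
#' extra shape parameter `nu`; at `nu = 1` it coincides exactly with the
#' logistic form.
#'
#' The parameterizations are:
#' \describe{
#'   \item{logistic}{`y(t) = y0 + A / (1 + exp(4 mu / A (lambda - t) + 2))`}
#'   \item{gompertz}{`y(t) = y0 + A exp(-exp(mu e / A (lambda - t) + 1))`}
#'   \item{richards}{`y(t) = y0 + A (1 + nu exp(1 + nu)
#'     exp(mu / A (1 + nu)^(1 + 1/nu) (lambda - t)))^(-1/nu)`}
#' }
#' `A = 0` degenerates to the constant baseline `y0` for every model.
#'
#' @param model One of `"logistic"`, `"gompertz"`, `"richards"`.
#' @param t Time points (hours).
#' @param A Plateau rise above baseline (signal units, `>= 0`).
#' @param mu Maximum slope (signal units per hour, `>= 0`).
#' @param lambda Lag time (hours, `>= 0`).
#' @param y0 Baseline signal.
#' @param nu Richards shape parameter (`> 0`); ignored by the other models.
#' @return Numeric vector of model values at `t`.
#' @examples
#' sigmoid_value("gompertz", t = 5, A = 100, mu = 10, lambda = 5, y0 = 0)
#' # 100 * exp(-e) ~= 6.598
#' @export
sigmoid_value <- function(model = c("logistic", "gompertz", "richards"),
                          t, A, mu, lambda, y0, nu = 1) {
  model <- match.arg(model)
  if (A < 0) stop_("plateau parameter A must be >= 0, got %g", A)
  if (A == 0) return(rep(y0, length(t)))
  switch(model,
    logistic = y0 + A / (1 + exp(pmin(4 * mu / A * (lambda - t) + 2, 700))),
    gompertz = y0 + A * exp(-exp(pmin(mu * exp(1) / A * (lambda - t) + 1, 700))),
    richards = {
      if (nu <= 0) stop_("richards shape nu must be > 0, got %g", nu)
      e <- pmin(mu / A * (1 + nu)^(1 + 1 / nu) * (lambda - t), 700)
      y0 + A * (1 + nu * exp(1 + nu) * exp(e))^(-1 / nu)
    })
}

sigmoid_models <- c("logistic", "gompertz", "richards")

# Number of free parameters per model (used by best_fit tie-breaking).
sigmoid_n_params <- c(logistic = 4L, gompertz = 4L, richards = 5L)
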