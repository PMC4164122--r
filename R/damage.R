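# Lung-injury model: fluid infiltration (lung weight gain) maps to a paired
# reduction in oxygen diffusing capacity and a pulmonary shunt. Damage is
# static during a simulation (injury assumed at steady state and simulation
# time shorter than recovery time).

#' Shunt implied by a diffusing-capacity reduction
#'
#' The coupling between the two damage parameters derived from uniform
#' oleic-acid injury: `shunt = 0.15 * D_L_reduction`, clipped to \[0, 1\].
#'
#' @param dl_reduction Fractional reduction of O2 diffusing capacity in
#'   \[0, 1\]. Vectorized.
#' @return Shunt fraction of cardiac output.
#' @export
shunt_from_dl_reduction <- function(dl_reduction) {
  if (any(!is.finite(dl_reduction)) || any(dl_reduction < 0 | dl_reduction > 1))
    stop_invalid("dl_reduction must lie in [0, 1]")
  pmin(pmax(0.15 * dl_reduction, 0), 1)
}

#' Construct a damage state from per-segment lung weight gain
#'
#' Fluid infiltration is quantified as fractional lung weight gain per
#' segment. The whole-lung shunt is `k_w` times the volume-weighted mean
#' weight gain; per-segment diffusing-capacity reductions invert the
#' shunt/D_L coupling regionally: `dl_reduction_k = k_w * dW_k / 0.15`,
#' clipped to \[0, 1\]. Undamaged segments are untouched.
#'
#' @param model A `lung_model`.
#' @param weight_gain Either a single fraction applied uniformly, or a named
#'   numeric vector over segment ids, or a list `list(region = "right",
#'   dW = ...)` applying `dW` to one lung only.
#' @param k_w Calibration slope, shunt per unit fractional weight gain. Not
#'   printed in the source calibration data; the default is the package's
#'   synthetic-reconstruction value and quantitative work should set it
#'   explicitly.
#' @return An object of class `damage_state`: per-segment `weight_gain` and
#'   `dl_reduction`, plus the global `shunt` (baseline + damage shunt).
#' @export
damage_from_weight_change <- function(model, weight_gain, k_w = 0.25) {
  stopifnot(inherits(model, "lung_model"))
  if (!is.numeric(k_w) || k_w <= 0) stop_invalid("k_w must be positive")
  ids <- model$segments$id
  dW <- rep(0, length(ids)); names(dW) <- ids
  if (is.list(weight_gain) && !is.null(weight_gain$region)) {
    sel <- model$segments$side == weight_gain$region
    dW[sel] <- weight_gain$dW
  } else if (length(weight_gain) == 1L && is.null(names(weight_gain))) {
    dW[] <- weight_gain
  } else {
    if (is.null(names(weight_gain)))
      stop_invalid("per-segment weight gain must be named by segment id")
    dW[names(weight_gain)] <- weight_gain
  }
  if (any(dW < 0)) stop_invalid("weight gain must be non-negative")
  mean_dW <- sum(model$segments$f * dW)
  shunt_damage <- k_w * mean_dW
  if (shunt_damage > 1) {
    warning("damage shunt exceeds 1; saturating")
    shunt_damage <- 1
  }
  dl_red <- pmin(k_w * dW / 0.15, 1)
  new_damage_state(model, dl_red, shunt_damage, dW, k_w)
}

new_damage_state <- function(model, dl_reduction, shunt_damage,
                             weight_gain = NULL, k_w = NA_real_) {
  if (is.null(weight_gain)) weight_gain <- rep(0, nrow(model$segments))
  shunt <- min(model$shunt_baseline + shunt_damage, 1)
  structure(list(weight_gain = weight_gain,
                 dl_reduction = dl_reduction,
                 shunt = shunt,
                 shunt_damage = shunt_damage,
                 k_w = k_w),
            class = "damage_state")
}

#' Healthy (undamaged) state for a lung model
#'
#' @param model A `lung_model`.
#' @return A `damage_state` with zero D_L reduction and baseline shunt.
#' @export
healthy_damage <- function(model) {
  new_damage_state(model, rep(0, nrow(model$segments)), 0)
}

#' Uniform damage state from a (shunt, D_L reduction) pair
#'
#' Applies the same diffusing-capacity reduction to every segment and the
#' given damage shunt globally; used by the calibration fitter.
#'
#' @param model A `lung_model`.
#' @param shunt Damage shunt fraction (added to the baseline shunt).
#' @param dl_reduction Uniform fractional D_L reduction in \[0, 1\].
#' @return A `damage_state`.
#' @export
uniform_damage <- function(model, shunt, dl_reduction) {
  if (shunt < 0 || shunt > 1 || dl_reduction < 0 || dl_reduction > 1)
    stop_invalid("shunt and dl_reduction must lie in [0, 1]")
  new_damage_state(model, rep(dl_reduction, nrow(model$segments)), shunt)
}

#' @export
print.damage_state <- function(x, ...) {
  cat(sprintf(
    "Lung damage state: shunt %.3f (damage %.3f), mean D_L reduction %.3f\n",
    x$shunt, x$shunt_damage, mean(x$dl_reduction)))
  if (any(x$weight_gain > 0))
    cat(sprintf("  weight gain: mean %.3f, %d segment(s) affected\n",
                mean(x$weight_gain), sum(x$weight_gain > 0)))
  invisible(x)
}

#' Fit shunt and D_L reduction to arterial-oxygen observations
#'
#' Reproduces the damage-calibration procedure: for each experimental
#' condition, find the (damage shunt, D_L reduction) pair whose steady-state
#' model prediction of arterial oxygen across workloads minimizes the
#' least-squares error against the observations. Optimization is bounded
#' L-BFGS-B on the unit square.
#'
#' @param observations Data frame with columns `condition`, `work` (W) and
#'   `value`: observed steady-state arterial O2 (`P_a_O2` in mmHg or `SaO2`
#'   as a fraction, per `response`).
#' @param model A `lung_model` (typically goat or sheep).
#' @param response Which arterial quantity the observations are:
#'   `"P_a_O2"` or `"SaO2"`.
#' @param control,blood,solver Optional parameter lists passed to
#'   [steady_state()].
#' @param start Starting values `c(shunt, dl_reduction)`.
#' @return An object of class `damage_fit`: a data frame of per-condition
#'   optima (`shunt`, `dl_reduction`, `rss`, `convergence`) plus the call.
#' @export
fit_shunt_dl <- function(observations, model, response = c("P_a_O2", "SaO2"),
                         control = list(), blood = list(), solver = list(),
                         start = c(0.05, 0.3)) {
  response <- match.arg(response)
  stopifnot(all(c("condition", "work", "value") %in% names(observations)))
  # extreme corners of the unit square settle slowly; give the solver room
  solver <- utils::modifyList(list(max_breaths = 600), solver)
  conds <- unique(observations$condition)
  res <- lapply(conds, function(cond) {
    obs <- observations[observations$condition == cond, ]
    if (nrow(obs) < 2) stop_invalid("need >= 2 observations per condition")
    objective <- function(par) {
      dmg <- uniform_damage(model, par[1], par[2])
      pred <- vapply(obs$work, function(w) {
        ss <- steady_state(model, work = w, damage = dmg, control = control,
                           blood = blood, solver = solver)
        ss[[response]]
      }, numeric(1))
      sum((pred - obs$value)^2)
    }
    opt <- stats::optim(start, objective, method = "L-BFGS-B",
                        lower = c(0, 0), upper = c(1, 1),
                        control = list(factr = 1e10, parscale = c(0.1, 0.3)))
    if (!opt$convergence %in% c(0, 52))  # 52: line-search warnings are benign
      stop("shunt/D_L fit did not converge for condition '", cond,
           "': ", opt$message, call. = FALSE)
    data.frame(condition = cond, shunt = opt$par[1], dl_reduction = opt$par[2],
               rss = opt$value, convergence = opt$convergence)
  })
  out <- do.call(rbind, res)
  structure(list(fits = out, response = response, call = match.call()),
            class = "damage_fit")
}

#' @export
print.damage_fit <- function(x, ...) {
  cat("Damage calibration fit (least-squares on", x$response, "):\n")
  print(x$fits, row.names = FALSE)
  invisible(x)
}

#' @export
coef.damage_fit <- function(object, ...) {
  as.matrix(object$fits[, c("shunt", "dl_reduction")])
}

#' Fit the pooled shunt-vs-damage line
#'
#' Ordinary least squares through calibration points (x = D_L reduction or
#' fractional lung weight gain, y = shunt). The intercept can be pinned to
#' zero, the default, since an undamaged lung has no damage shunt.
#'
#' @param points Data frame with columns `x` and `shunt` (a `x_value` /
#'   `shunt` pair from [generate_calibration_data()] also works).
#' @param intercept If `FALSE` (default) the line is forced through the
#'   origin.
#' @return List with `slope`, `intercept`, `r_squared` and the underlying
#'   `lm` fit.
#' @export
fit_damage_line <- function(points, intercept = FALSE) {
  if (!is.null(points$x_value) && is.null(points$x)) points$x <- points$x_value
  stopifnot(all(c("x", "shunt") %in% names(points)))
  if (nrow(points) < 2) stop_invalid("need at least 2 calibration points")
  if (diff(range(points$x)) == 0)
    stop("degenerate calibration set: all x values equal", call. = FALSE)
  fit <- if (intercept) stats::lm(shunt ~ x, data = points)
         else stats::lm(shunt ~ x - 1, data = points)
  cf <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((points$shunt - mean(points$shunt))^2)
  list(slope = unname(if (intercept) cf["x"] else cf["x"]),
       intercept = if (intercept) unname(cf["(Intercept)"]) else 0,
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       fit = fit)
}
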