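# Sensitivity of the per-cycle cost difference to the caseload parameters.
#
# DCost is viewed as a function g(R, P, D, H): the per-cycle robotic dose and
# the annual cycles per setting. The setting shares, the assistant weight and
# the supervised group size are differentiated through their dependence on
# (P, D, H); the annual robotic volume in the depreciation term is R x n.
# Elasticities E_i = dg/dx_i * x_i / g are normalized into the Differential
# Importance Measure DIM_i = E_i / sum(E_j), which ranks parameters under
# proportional (percentage) perturbations rather than unit ones.

# DCost as a function of the four free caseload parameters, all organizational
# and unit-cost parameters held fixed.
dcost_of <- function(params, R, P, D, H) {
  n <- P + D + H
  p_t <- P / n
  h_t <- H / n
  ph_n <- supervision_mean(params$supervised_outpatient,
                           params$supervised_inpatient_daycase, p_t)
  w <- assistant_weight(p_t, h_t)
  physio_share <- params$treatment_duration * params$physio_hourly / ph_n
  energy <- params$energy_price * params$power_absorption *
    params$treatment_duration
  uplift <- 1 + params$overhead_rate
  c_t <- params$physio_hourly * params$treatment_duration * uplift
  volume_free <- uplift * (physio_share +
                             params$assistant_cost_per_assisted_treatment * w +
                             energy + params$consumables_per_treatment)
  # R x C_depr has R in numerator and denominator: depreciation contributes
  # uplift * K / (lifetime * n) per cycle, independent of R
  R * (volume_free - c_t) +
    uplift * equipment_capital(params) / (params$robot_lifetime * n)
}

#' Partial derivatives of the per-cycle cost difference
#'
#' Differentiates `DCost(R, P, D, H)` at a reference volume profile, with the
#' setting shares, assistant weight and supervised group size treated as
#' functions of `(P, D, H)`. Both closed-form derivatives and central finite
#' differences are returned; the constructor errors if the two disagree beyond
#' `tol` in relative terms, which guards the hand-derived formulas.
#'
#' @param params a calibrated [cost_parameters()] object.
#' @param profile a [volume_profile()] with `R`, `P`, `D`, `H` all positive.
#' @param step relative step of the central difference (default `1e-6`).
#' @param tol maximum tolerated relative disagreement between analytic and
#'   numeric derivatives (default `1e-6`).
#' @return A list of class `sensitivity_report` with `partials` (analytic,
#'   named `R`, `P`, `D`, `H`), `partials_numeric`, `reference_point` and
#'   `reference_dcost`.
#' @export
partial_derivatives <- function(params, profile, step = 1e-6, tol = 1e-6) {
  stopifnot(inherits(params, "cost_parameters"),
            inherits(profile, "volume_profile"))
  x0 <- c(R = profile$R, P = profile$P, D = profile$D, H = profile$H)
  if (any(x0 <= 0)) {
    stop("partial derivatives require an interior point: R, P, D, H all > 0",
         call. = FALSE)
  }
  R <- x0["R"]; P <- x0["P"]; D <- x0["D"]; H <- x0["H"]
  n <- P + D + H
  p_t <- P / n; h_t <- H / n
  uplift <- 1 + params$overhead_rate
  c_t <- params$physio_hourly * params$treatment_duration * uplift
  ph_n <- supervision_mean(params$supervised_outpatient,
                           params$supervised_inpatient_daycase, p_t)
  w <- assistant_weight(p_t, h_t)
  physio_share <- params$treatment_duration * params$physio_hourly / ph_n
  energy <- params$energy_price * params$power_absorption *
    params$treatment_duration
  c_pns <- params$assistant_cost_per_assisted_treatment
  kap <- uplift * equipment_capital(params) / params$robot_lifetime

  d_R <- uplift * (physio_share + c_pns * w + energy +
                     params$consumables_per_treatment) - c_t

  # share derivatives: d(P/n)/dP = (n - P)/n^2, d(P/n)/dD = -P/n^2, etc.
  share_grad <- function(dpt, dht) {
    dphn <- (params$supervised_outpatient -
               params$supervised_inpatient_daycase) * dpt
    dphys <- -physio_share / ph_n * dphn
    dw <- -dpt - dht / 2
    R * uplift * (dphys + c_pns * dw) - kap / n^2
  }
  d_P <- share_grad((n - P) / n^2, -H / n^2)
  d_D <- share_grad(-P / n^2, -H / n^2)
  d_H <- share_grad(-P / n^2, (n - H) / n^2)

  analytic <- c(R = unname(d_R), P = unname(d_P), D = unname(d_D),
                H = unname(d_H))

  numeric_grad <- vapply(names(x0), function(nm) {
    h <- step * x0[[nm]]
    up <- x0; up[[nm]] <- up[[nm]] + h
    dn <- x0; dn[[nm]] <- dn[[nm]] - h
    (dcost_of(params, up["R"], up["P"], up["D"], up["H"]) -
       dcost_of(params, dn["R"], dn["P"], dn["D"], dn["H"])) / (2 * h)
  }, numeric(1))

  rel <- abs(analytic - numeric_grad) /
    pmax(abs(analytic), .Machine$double.eps)
  if (any(rel > tol)) {
    stop("analytic and central-difference derivatives disagree beyond tol: ",
         paste(names(rel)[rel > tol], collapse = ", "), call. = FALSE)
  }

  structure(
    list(partials = analytic,
         partials_numeric = numeric_grad,
         reference_point = x0,
         reference_dcost = dcost_of(params, R, P, D, H)),
    class = "sensitivity_report"
  )
}

#' Differential Importance Measure
#'
#' Normalized elasticities of an output with respect to its parameters:
#' `E_i = partial_i * x_i / g(x0)` and `DIM_i = E_i / sum(E_j)`. DIM ranks
#' parameters by their influence under proportional perturbations and always
#' sums to one.
#'
#' @param partials named numeric vector of partial derivatives at the
#'   reference point.
#' @param reference_point parameter values `x_i0`, same order as `partials`.
#' @param reference_dcost output value `g(x0)` at the reference (nonzero).
#' @return A list of class `sensitivity_report` with `partials`,
#'   `elasticities`, `dims`, `reference_point` and `reference_dcost`.
#' @examples
#' differential_importance(
#'   partials = c(R = -10.53, P = -0.65, D = -0.43, H = -0.48),
#'   reference_point = c(R = 17.88, P = 27.67, D = 167.33, H = 102.00),
#'   reference_dcost = -49.60
#' )$dims
#' @export
differential_importance <- function(partials, reference_point,
                                    reference_dcost) {
  stopifnot(length(partials) == length(reference_point))
  if (reference_dcost == 0) {
    stop("`reference_dcost` must be nonzero (elasticities are undefined)",
         call. = FALSE)
  }
  e <- partials * reference_point / reference_dcost
  if (sum(e) == 0) {
    stop("elasticities sum to zero; DIM is degenerate", call. = FALSE)
  }
  structure(
    list(partials = partials,
         elasticities = e,
         dims = e / sum(e),
         reference_point = reference_point,
         reference_dcost = reference_dcost),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity of DCost at the reference point\n")
  cat(sprintf("  reference DCost = %.2f euro/cycle at (%s)\n",
              x$reference_dcost,
              paste(sprintf("%s = %.2f", names(x$reference_point),
                            x$reference_point), collapse = ", ")))
  tab <- data.frame(partial = round(x$partials, 4))
  if (!is.null(x$elasticities)) tab$elasticity <- round(x$elasticities, 4)
  if (!is.null(x$dims)) tab$DIM <- round(x$dims, 3)
  print(tab)
  invisible(x)
}

#' Capacity and clinical constraints
#'
#' The two constraints bounding the robotic activity: the robotic gym can
#' deliver at most `max_annual_robotic` treatments per year (`R x n`), and at
#' most a fraction `max_robotic_fraction` of a cycle's treatments can be
#' delivered robotically (`R / S`), since lower-limb and other treatments fall
#' outside the device set.
#'
#' @param max_annual_robotic annual robotic treatment capacity
#'   (default 8,250 = 50 weeks x 55 slots x 3 treatments per slot).
#' @param max_robotic_fraction maximum robotic share of a cycle (default 0.35).
#' @return An object of class `constraint_set`.
#' @export
constraint_set <- function(max_annual_robotic = 8250,
                           max_robotic_fraction = 0.35) {
  stopifnot(max_annual_robotic > 0,
            max_robotic_fraction > 0, max_robotic_fraction <= 1)
  structure(list(max_annual_robotic = max_annual_robotic,
                 max_robotic_fraction = max_robotic_fraction),
            class = "constraint_set")
}

#' Annual robotic gym capacity
#'
#' @param weeks_per_year weeks the gym is open (default 50).
#' @param slots_per_week treatment slots per week (default 55: 10 on each
#'   weekday plus 5 on Saturday).
#' @param treatments_per_slot concurrent treatments per slot (default 3).
#' @return Maximum robotic treatments per year.
#' @examples
#' gym_capacity()  # 8250
#' @export
gym_capacity <- function(weeks_per_year = 50, slots_per_week = 55,
                         treatments_per_slot = 3) {
  weeks_per_year * slots_per_week * treatments_per_slot
}

#' Cost-difference surface over robotic dose and annual caseload
#'
#' Evaluates `DCost` on a grid of per-cycle robotic dose `R` and annual
#' caseload `n`, holding the proportions between the three settings fixed at
#' the profile's values, with annual robotic volume `R x n` in the
#' depreciation term. Cells violating the capacity or clinical constraint are
#' flagged infeasible, and the `DCost = 0` break-even boundary is extracted by
#' linear interpolation along `R` within each `n` column.
#'
#' @param params a calibrated [cost_parameters()] object.
#' @param profile a [volume_profile()] fixing the setting proportions and `S`.
#' @param r_grid,n_grid ascending positive grids for the robotic dose and the
#'   annual caseload.
#' @param constraints a [constraint_set()].
#' @return A long-format `data.frame` with columns `R`, `n`, `dcost`,
#'   `feasible`, carrying the break-even boundary (`n`, `R_break_even`) as
#'   attribute `"break_even"`.
#' @export
dcost_surface <- function(params, profile, r_grid, n_grid,
                          constraints = constraint_set()) {
  stopifnot(all(r_grid > 0), all(n_grid > 0),
            !is.unsorted(r_grid, strictly = TRUE),
            !is.unsorted(n_grid, strictly = TRUE))
  frac <- c(P = profile$P, D = profile$D, H = profile$H) / profile$n
  grid <- expand.grid(R = r_grid, n = n_grid, KEEP.OUT.ATTRS = FALSE)
  grid$dcost <- mapply(function(r, n) {
    dcost_of(params, r, frac["P"] * n, frac["D"] * n, frac["H"] * n)
  }, grid$R, grid$n)
  grid$feasible <- grid$R * grid$n <= constraints$max_annual_robotic &
    grid$R / profile$S <= constraints$max_robotic_fraction

  be <- do.call(rbind, lapply(n_grid, function(n) {
    col <- grid[grid$n == n, ]
    sgn <- sign(col$dcost)
    cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (!length(cross)) return(NULL)
    i <- cross[1]
    r0 <- col$R[i] + (0 - col$dcost[i]) *
      (col$R[i + 1] - col$R[i]) / (col$dcost[i + 1] - col$dcost[i])
    data.frame(n = n, R_break_even = r0)
  }))
  attr(grid, "break_even") <- be
  grid
}

#' Maximize savings under the capacity and clinical constraints
#'
#' `DCost` decreases monotonically in both the robotic dose `R` and the annual
#' caseload `n` (for a calibrated model in the savings regime), so the
#' constrained maximum saving is attained on the constraint boundary:
#'
#' * `"increase_R_only"` holds `n` at the profile value and raises `R` to the
#'   largest feasible dose `min(max_fraction x S, capacity / n)`;
#' * `"increase_R_and_n"` raises the dose to the clinical cap
#'   `R* = max_fraction x S` and fills the gym, `n* = capacity / R*`.
#'
#' @param params a calibrated [cost_parameters()] object.
#' @param profile the reference [volume_profile()].
#' @param constraints a [constraint_set()].
#' @param scenario `"increase_R_only"` or `"increase_R_and_n"`.
#' @return An object of class `optimization_result`: list with `r_star`,
#'   `n_star`, `dcost_at_optimum` (euro/cycle, annual robotic volume
#'   `r_star x n_star`), `binding_constraints` and `scenario`.
#' @examples
#' params <- default_smp_costs()
#' optimize_savings(params, default_smp_profile(), constraint_set(),
#'                  scenario = "increase_R_and_n")
#' @export
optimize_savings <- function(params, profile, constraints = constraint_set(),
                             scenario = c("increase_R_only",
                                          "increase_R_and_n")) {
  scenario <- match.arg(scenario)
  cap <- constraints$max_annual_robotic
  r_clinical <- constraints$max_robotic_fraction * profile$S
  if (scenario == "increase_R_only") {
    n_star <- profile$n
    if (cap / n_star <= 0) stop("infeasible constraint set", call. = FALSE)
    r_star <- min(r_clinical, cap / n_star)
    binding <- if (r_clinical <= cap / n_star) "clinical" else "capacity"
  } else {
    r_star <- r_clinical
    n_star <- cap / r_star
    binding <- c("clinical", "capacity")
  }
  frac <- c(P = profile$P, D = profile$D, H = profile$H) / profile$n
  dc <- dcost_of(params, r_star, frac["P"] * n_star, frac["D"] * n_star,
                 frac["H"] * n_star)
  structure(
    list(r_star = r_star, n_star = n_star,
         dcost_at_optimum = unname(dc),
         binding_constraints = binding, scenario = scenario),
    class = "optimization_result"
  )
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("Constrained savings optimum (%s)\n", x$scenario))
  cat(sprintf("  R* = %.2f treatments/cycle, n* = %.2f cycles/year (robotic volume %.0f)\n",
              x$r_star, x$n_star, x$r_star * x$n_star))
  cat(sprintf("  DCost at optimum = %.2f euro/cycle; binding: %s\n",
              x$dcost_at_optimum, paste(x$binding_constraints, collapse = ", ")))
  invisible(x)
}
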