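# Deterministic per-cycle cost algebra for mixed vs. conventional rehabilitation.
#
# A conventional treatment costs the physiotherapist's time with an indirect-
# cost uplift. A technology-assisted (robotic) treatment shares one therapist
# across a supervised group, adds an assistant cost weighted by the share of
# patients who need transport to the gym, linear depreciation of the robotic
# equipment (purchase + maintenance + training spread over lifetime x annual
# volume), energy and consumables. DCost is the per-cycle cost difference,
# mixed minus conventional; negative values mean the mixed pathway saves money.

#' Cost parameters of the rehabilitation service
#'
#' All unit costs and organizational parameters of the cost model. Monetary
#' values are in euro; the overhead rate is the indirect-cost fraction added
#' uniformly to every direct cost component.
#'
#' @param physio_hourly physiotherapist cost (euro/h).
#' @param assistant_hourly assistant cost (euro/h); kept for reporting the
#'   implied assistant minutes per treatment, not used directly (see
#'   [calibrate_assistant_cost()]).
#' @param treatment_duration duration of one treatment (hours).
#' @param energy_price electricity price (euro/kWh).
#' @param power_absorption mean power draw of the robotic solution (kW).
#' @param robot_price purchase price of the full device set (euro).
#' @param maintenance_annual annual maintenance fee (euro/year).
#' @param maintenance_years number of years the maintenance fee is paid over
#'   the lifetime (default 7: an 8-year lifetime with the first year under
#'   warranty).
#' @param training_cost_direct direct (pre-overhead) cost of personnel
#'   training over the robot lifetime (euro).
#' @param robot_lifetime expected equipment lifetime (years).
#' @param overhead_rate indirect-cost fraction added to direct costs
#'   (default 0.25).
#' @param consumables_per_treatment direct consumables cost (euro/treatment).
#' @param assistant_cost_per_assisted_treatment direct assistant cost per
#'   treatment that needs assistance (euro/treatment); usually back-solved by
#'   [calibrate_assistant_cost()].
#' @param supervised_outpatient patients supervised per therapist in the
#'   outpatient setting.
#' @param supervised_inpatient_daycase patients supervised per therapist in
#'   the inpatient and day-case settings.
#'
#' @return An object of class `cost_parameters`.
#' @seealso [default_smp_costs()] for the reference values.
#' @export
cost_parameters <- function(physio_hourly,
                            treatment_duration,
                            energy_price,
                            power_absorption,
                            robot_price,
                            maintenance_annual,
                            maintenance_years = 7,
                            training_cost_direct,
                            robot_lifetime,
                            overhead_rate = 0.25,
                            consumables_per_treatment = 0,
                            assistant_cost_per_assisted_treatment = 0,
                            supervised_outpatient,
                            supervised_inpatient_daycase,
                            assistant_hourly = NA_real_) {
  p <- list(
    physio_hourly = physio_hourly,
    treatment_duration = treatment_duration,
    energy_price = energy_price,
    power_absorption = power_absorption,
    robot_price = robot_price,
    maintenance_annual = maintenance_annual,
    maintenance_years = maintenance_years,
    training_cost_direct = training_cost_direct,
    robot_lifetime = robot_lifetime,
    overhead_rate = overhead_rate,
    consumables_per_treatment = consumables_per_treatment,
    assistant_cost_per_assisted_treatment = assistant_cost_per_assisted_treatment,
    supervised_outpatient = supervised_outpatient,
    supervised_inpatient_daycase = supervised_inpatient_daycase,
    assistant_hourly = assistant_hourly
  )
  nonneg <- c("physio_hourly", "energy_price", "power_absorption",
              "robot_price", "maintenance_annual", "maintenance_years",
              "training_cost_direct", "overhead_rate",
              "consumables_per_treatment",
              "assistant_cost_per_assisted_treatment")
  for (nm in nonneg) {
    if (p[[nm]] < 0) stop("`", nm, "` must be >= 0", call. = FALSE)
  }
  if (p$robot_lifetime <= 0) stop("`robot_lifetime` must be > 0", call. = FALSE)
  if (p$treatment_duration <= 0) {
    if (p$treatment_duration < 0) stop("`treatment_duration` must be >= 0",
                                       call. = FALSE)
  }
  if (p$supervised_outpatient < 1 || p$supervised_inpatient_daycase < 1) {
    stop("supervision ratios must be >= 1 patient per therapist",
         call. = FALSE)
  }
  structure(p, class = "cost_parameters")
}

#' Reference cost parameters of the source hospital
#'
#' Physiotherapist 19.50 euro/h, assistant 16.48 euro/h, 45-minute treatments,
#' energy 0.36 euro/kWh at 0.28 kW, robot set 152,256 euro with 15,767
#' euro/year maintenance over 7 of the 8 lifetime years, training valued as 75
#' lost 45-minute physiotherapist slots (1,096.88 euro direct), 25% overhead,
#' supervision of 4 outpatients or 3 inpatients/day-cases per therapist. The
#' assistant cost per assisted treatment is not a published unit cost; it is
#' back-solved by [calibrate_assistant_cost()], which [default_smp_costs()]
#' applies when `calibrated = TRUE` (the default).
#'
#' @param calibrated apply the assistant-cost calibration against the
#'   reference marginal saving of -10.53 euro per additional robotic treatment.
#' @param profile the [volume_profile()] at which to calibrate.
#' @return A `cost_parameters` object.
#' @export
default_smp_costs <- function(calibrated = TRUE,
                              profile = default_smp_profile()) {
  params <- cost_parameters(
    physio_hourly = 19.50,
    assistant_hourly = 16.48,
    treatment_duration = 0.75,
    energy_price = 0.36,
    power_absorption = 0.28,
    robot_price = 152256,
    maintenance_annual = 15767,
    maintenance_years = 7,
    training_cost_direct = training_cost_direct(75, 0.75, 19.50),
    robot_lifetime = 8,
    overhead_rate = 0.25,
    consumables_per_treatment = 0,
    assistant_cost_per_assisted_treatment = 0,
    supervised_outpatient = 4,
    supervised_inpatient_daycase = 3
  )
  if (calibrated) {
    params <- calibrate_assistant_cost(params, profile,
                                       anchor_dDCost_dR = -10.53)
  }
  params
}

#' Direct cost of personnel training
#'
#' Training is valued as physiotherapist productivity loss: the number of
#' therapist slots devoted to training over the robot lifetime, times the slot
#' duration, times the hourly rate. The result is a direct cost; the overhead
#' uplift is applied downstream like any other direct component.
#'
#' @param slots therapist slots devoted to training.
#' @param slot_hours duration of one slot (hours).
#' @param hourly_rate therapist cost (euro/h).
#' @return Direct training cost (euro).
#' @examples
#' training_cost_direct(75, 0.75, 19.50)          # 1096.875
#' training_cost_direct(75, 0.75, 19.50) * 1.25   # overhead-inclusive
#' @export
training_cost_direct <- function(slots, slot_hours, hourly_rate) {
  stopifnot(slots >= 0, slot_hours >= 0, hourly_rate >= 0)
  slots * slot_hours * hourly_rate
}

#' Overhead-inclusive cost of a conventional treatment
#'
#' One-to-one therapist time: hourly rate x treatment duration, uplifted by
#' the overhead rate.
#'
#' @param params a [cost_parameters()] object.
#' @return Cost of one conventional treatment (euro), overhead-inclusive.
#' @export
conventional_treatment_cost <- function(params) {
  stopifnot(inherits(params, "cost_parameters"))
  params$physio_hourly * params$treatment_duration * (1 + params$overhead_rate)
}

#' Mean supervised group size
#'
#' Weighted average of the per-setting supervision ratios, weighted by the
#' outpatient cycle share: outpatients are supervised in larger groups than
#' the more severe inpatients and day cases.
#'
#' @param supervised_outpatient patients per therapist, outpatient setting.
#' @param supervised_inpatient_daycase patients per therapist, other settings.
#' @param p_treat_pct outpatient share of cycles, in `[0, 1]`.
#' @return Mean patients supervised per therapist.
#' @examples
#' supervision_mean(4, 3, 0.0932)  # 3.0932
#' @export
supervision_mean <- function(supervised_outpatient,
                             supervised_inpatient_daycase,
                             p_treat_pct) {
  stopifnot(supervised_outpatient >= 1, supervised_inpatient_daycase >= 1,
            p_treat_pct >= 0, p_treat_pct <= 1)
  supervised_outpatient * p_treat_pct +
    supervised_inpatient_daycase * (1 - p_treat_pct)
}

# total capitalized equipment cost: purchase + maintenance + direct training
equipment_capital <- function(params) {
  params$robot_price +
    params$maintenance_annual * params$maintenance_years +
    params$training_cost_direct
}

#' Linear depreciation per robotic treatment
#'
#' Purchase price, lifetime maintenance and training cost, spread evenly over
#' the lifetime and the annual robotic treatment volume. A direct cost
#' (pre-overhead).
#'
#' @param params a [cost_parameters()] object.
#' @param annual_robotic_treatments robotic treatments delivered per year.
#' @return Depreciation cost per robotic treatment (euro, direct).
#' @export
depreciation_per_treatment <- function(params, annual_robotic_treatments) {
  stopifnot(inherits(params, "cost_parameters"))
  if (annual_robotic_treatments <= 0) {
    stop("`annual_robotic_treatments` must be > 0", call. = FALSE)
  }
  equipment_capital(params) /
    (params$robot_lifetime * annual_robotic_treatments)
}

# assistant weight: share of robotic treatments needing an assistant
# (all inpatients, half of day cases, no outpatients)
assistant_weight <- function(p_treat_pct, h_treat_pct) {
  1 - p_treat_pct - h_treat_pct / 2
}

#' Overhead-inclusive cost of a robotic treatment
#'
#' Sums the per-treatment direct components and applies the overhead uplift:
#' therapist time shared across the supervised group, assistant cost weighted
#' by the share of treatments needing assistance (all inpatients, half of the
#' day cases), linear equipment depreciation, energy, and consumables.
#'
#' @param params a [cost_parameters()] object.
#' @param profile a [volume_profile()].
#' @param annual_robotic_treatments robotic treatments delivered per year
#'   (depreciation denominator).
#' @return A list with the overhead-inclusive `robotic_treatment_cost` and the
#'   direct components `physio_share`, `assistant_component`, `depreciation`,
#'   `energy`, `consumables`, plus `assistant_weight` and `supervision_mean`.
#' @export
robotic_treatment_cost <- function(params, profile, annual_robotic_treatments) {
  stopifnot(inherits(params, "cost_parameters"),
            inherits(profile, "volume_profile"))
  robotic_cost_components(params, profile$p_treat_pct, profile$h_treat_pct,
                          annual_robotic_treatments)
}

# shares-based workhorse, also used by the per-year simulation
robotic_cost_components <- function(params, p_treat_pct, h_treat_pct,
                                    annual_robotic_treatments) {
  ph_n <- supervision_mean(params$supervised_outpatient,
                           params$supervised_inpatient_daycase,
                           p_treat_pct)
  w <- assistant_weight(p_treat_pct, h_treat_pct)
  physio_share <- params$treatment_duration * params$physio_hourly / ph_n
  energy <- params$energy_price * params$power_absorption *
    params$treatment_duration
  depreciation <- depreciation_per_treatment(params, annual_robotic_treatments)
  assistant <- params$assistant_cost_per_assisted_treatment * w
  direct <- physio_share + assistant + depreciation + energy +
    params$consumables_per_treatment
  list(
    robotic_treatment_cost = (1 + params$overhead_rate) * direct,
    physio_share = physio_share,
    assistant_component = assistant,
    depreciation = depreciation,
    energy = energy,
    consumables = params$consumables_per_treatment,
    assistant_weight = w,
    supervision_mean = ph_n
  )
}

#' Per-cycle costs of mixed and conventional rehabilitation
#'
#' Evaluates the full cost breakdown at a volume profile: the cost of one
#' conventional cycle (`S` treatments at the conventional rate), of one mixed
#' cycle (`T` conventional plus `R` robotic treatments), and their difference
#' `DCost = C_mix - C_conv = R x (C_r - C_T)`. Negative `DCost` means the
#' mixed pathway is cheaper.
#'
#' @inheritParams robotic_treatment_cost
#' @param annual_robotic_treatments robotic treatments per year used in the
#'   depreciation term; defaults to `profile$R * profile$n`.
#' @return An object of class `cost_breakdown`: a list with
#'   `conventional_treatment_cost`, `robotic_treatment_cost`, the direct
#'   components, `cycle_conventional`, `cycle_mixed` and `cost_difference`
#'   (euro/cycle).
#' @examples
#' params <- default_smp_costs()
#' cycle_costs(params, default_smp_profile(), annual_robotic_treatments = 5311)
#' @export
cycle_costs <- function(params, profile,
                        annual_robotic_treatments = profile$R * profile$n) {
  c_t <- conventional_treatment_cost(params)
  rob <- robotic_treatment_cost(params, profile, annual_robotic_treatments)
  c_r <- rob$robotic_treatment_cost
  structure(
    c(
      list(
        conventional_treatment_cost = c_t,
        cycle_conventional = profile$S * c_t,
        cycle_mixed = profile$T * c_t + profile$R * c_r,
        cost_difference = profile$R * (c_r - c_t),
        annual_robotic_treatments = annual_robotic_treatments
      ),
      rob
    ),
    class = "cost_breakdown"
  )
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("Per-cycle cost breakdown (euro)\n")
  cat(sprintf("  conventional treatment C_T = %.4f, robotic treatment C_r = %.4f (diff %.4f)\n",
              x$conventional_treatment_cost, x$robotic_treatment_cost,
              x$robotic_treatment_cost - x$conventional_treatment_cost))
  cat(sprintf("  direct components of C_r: physio %.4f, assistant %.4f, depreciation %.4f, energy %.4f, consumables %.4f\n",
              x$physio_share, x$assistant_component, x$depreciation,
              x$energy, x$consumables))
  cat(sprintf("  conventional cycle %.2f, mixed cycle %.2f\n",
              x$cycle_conventional, x$cycle_mixed))
  cat(sprintf("  DCost = %.2f per cycle (negative favours the mixed pathway)\n",
              x$cost_difference))
  invisible(x)
}

#' Back-solve the assistant cost from a marginal-saving anchor
#'
#' The assistant cost per assisted treatment is not an observable unit cost.
#' It is identified from the marginal effect of one additional robotic
#' treatment on the per-cycle cost difference: because the depreciation term
#' contributes a volume-independent amount to the cycle cost, that marginal
#' effect equals the volume-independent part of `C_r - C_T`, so the anchor
#' pins down the assistant component uniquely.
#'
#' @param params a [cost_parameters()] object (its assistant cost is ignored).
#' @param profile the [volume_profile()] defining the setting shares.
#' @param anchor_dDCost_dR target marginal saving per additional robotic
#'   treatment (euro/treatment, negative when robotics saves money).
#' @return `params` with `assistant_cost_per_assisted_treatment` replaced by
#'   the back-solved value, and `implied_assistant_minutes` attached (the
#'   minutes of assistant time per assisted treatment the value corresponds to
#'   at `assistant_hourly`).
#' @export
calibrate_assistant_cost <- function(params, profile, anchor_dDCost_dR) {
  stopifnot(inherits(params, "cost_parameters"),
            inherits(profile, "volume_profile"))
  if (anchor_dDCost_dR >= 0) {
    stop("`anchor_dDCost_dR` must be negative (a marginal saving)",
         call. = FALSE)
  }
  c_t <- conventional_treatment_cost(params)
  ph_n <- supervision_mean(params$supervised_outpatient,
                           params$supervised_inpatient_daycase,
                           profile$p_treat_pct)
  w <- assistant_weight(profile$p_treat_pct, profile$h_treat_pct)
  physio_share <- params$treatment_duration * params$physio_hourly / ph_n
  energy <- params$energy_price * params$power_absorption *
    params$treatment_duration
  c_pns <- ((anchor_dDCost_dR + c_t) / (1 + params$overhead_rate) -
              physio_share - energy - params$consumables_per_treatment) / w
  if (c_pns < 0) {
    stop("calibration failed: back-solved assistant cost is negative (",
         round(c_pns, 4), "); the anchor is inconsistent with the other ",
         "cost components", call. = FALSE)
  }
  params$assistant_cost_per_assisted_treatment <- c_pns
  if (is.finite(params$assistant_hourly) && params$assistant_hourly > 0) {
    params$implied_assistant_minutes <- 60 * c_pns / params$assistant_hourly
  }
  params
}
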