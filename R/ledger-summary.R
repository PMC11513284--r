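# Descriptive summaries of a rehabilitation ledger: the annual volume profile
# consumed by the cost model, and the Barthel-severity comparison across care
# settings that motivates the per-setting supervision ratios.

#' Annual volume profile of a rehabilitation service
#'
#' Container for the caseload and dose structure of a period: annual cycle
#' counts per setting (`P` outpatient, `H` day case, `D` inpatient), their
#' total `n`, the outpatient and day-case cycle shares, and the mean numbers of
#' total (`S`), robotic (`R`) and conventional (`T`) treatments per cycle.
#'
#' @param P,H,D annual rehabilitation cycles in the outpatient, day-case and
#'   inpatient settings (cycles/year).
#' @param S mean treatments per cycle; must equal `R + T`.
#' @param R mean robotic treatments per cycle.
#' @param T mean conventional treatments per cycle.
#' @param p_treat_pct,h_treat_pct optional overrides for the outpatient and
#'   day-case cycle shares; default `P/n` and `H/n`.
#'
#' @return An object of class `volume_profile` with fields `P`, `H`, `D`, `n`,
#'   `p_treat_pct`, `h_treat_pct`, `S`, `R`, `T`.
#' @export
volume_profile <- function(P, H, D, S, R, T = S - R,
                           p_treat_pct = NULL, h_treat_pct = NULL) {
  stopifnot(P >= 0, H >= 0, D >= 0, S > 0, R >= 0, T >= 0)
  n <- P + H + D
  if (n <= 0) stop("total annual caseload must be positive", call. = FALSE)
  if (abs(S - (R + T)) > 1e-9) {
    stop("`S` must equal `R + T` (got S = ", S, ", R + T = ", R + T, ")",
         call. = FALSE)
  }
  if (is.null(p_treat_pct)) p_treat_pct <- P / n
  if (is.null(h_treat_pct)) h_treat_pct <- H / n
  stopifnot(p_treat_pct >= 0, p_treat_pct <= 1,
            h_treat_pct >= 0, h_treat_pct <= 1,
            p_treat_pct + h_treat_pct <= 1 + 1e-12)
  structure(
    list(P = P, H = H, D = D, n = n,
         p_treat_pct = p_treat_pct, h_treat_pct = h_treat_pct,
         S = S, R = R, T = T),
    class = "volume_profile"
  )
}

#' @export
print.volume_profile <- function(x, ...) {
  cat("Annual volume profile\n")
  cat(sprintf("  cycles/year: P = %.2f (outpatient), H = %.2f (day case), D = %.2f (inpatient), n = %.2f\n",
              x$P, x$H, x$D, x$n))
  cat(sprintf("  cycle shares: outpatient %.2f%%, day case %.2f%%\n",
              100 * x$p_treat_pct, 100 * x$h_treat_pct))
  cat(sprintf("  treatments/cycle: S = %.2f = R %.2f (robotic) + T %.2f (conventional)\n",
              x$S, x$R, x$T))
  invisible(x)
}

#' Reference volume profile of the source hospital
#'
#' The published three-year averages: 83 outpatient, 306 day-case and 502
#' inpatient cycles over 3 years (27.67 / 102.00 / 167.33 cycles/year,
#' n = 297), mean cycle length 67.94 treatments of which 17.88 robotic. The
#' annual caseloads are kept as exact thirds so the cycle shares equal
#' 83/891 (9.32%) and 306/891 (34.34%) exactly, which keeps the profile
#' consistent with the share algebra of the sensitivity analysis.
#'
#' @return A `volume_profile`.
#' @export
default_smp_profile <- function() {
  volume_profile(P = 83 / 3, H = 102, D = 502 / 3,
                 S = 67.94, R = 17.88, T = 50.06)
}

#' Summarize a ledger into an annual volume profile
#'
#' Counts cycles per setting, divides by the number of years to obtain annual
#' caseloads, and averages the per-cycle treatment counts.
#'
#' @param records a ledger `data.frame` (see [generate_ledger()]).
#' @param n_years length of the period covered by the ledger, in years.
#' @return A [volume_profile()].
#' @examples
#' led <- generate_ledger(default_smp_spec(), n_cycles = 500)
#' summarize_ledger(led, n_years = 3)
#' @export
summarize_ledger <- function(records, n_years) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("cannot summarize an empty ledger", call. = FALSE)
  }
  stopifnot(n_years > 0)
  counts <- c(
    outpatient = sum(records$setting == "outpatient"),
    day_case = sum(records$setting == "day_case"),
    inpatient = sum(records$setting == "inpatient")
  )
  total_per_cycle <- records$robotic_treatments + records$conventional_treatments
  volume_profile(
    P = counts[["outpatient"]] / n_years,
    H = counts[["day_case"]] / n_years,
    D = counts[["inpatient"]] / n_years,
    S = mean(total_per_cycle),
    R = mean(records$robotic_treatments),
    T = mean(records$conventional_treatments)
  )
}

#' Compare admission severity across care settings
#'
#' Tests whether the Barthel Index at admission differs across the outpatient,
#' day-case and inpatient groups: a Kruskal-Wallis test over the three groups
#' followed by pairwise two-sample Wilcoxon rank-sum tests with Bonferroni
#' correction (factor 3). Quartiles use linear interpolation between order
#' statistics (`stats::quantile` type 7); rank tests use mid-ranks with the
#' normal approximation, appropriate for the tie-heavy integer Barthel scale.
#'
#' @param records a ledger `data.frame` with `setting` and `barthel_admission`.
#' @return An object of class `severity_comparison`: a list with
#'   `kw_statistic`, `kw_p`, `pairwise_p` (Bonferroni-adjusted, named
#'   "a vs b"), and `medians_and_quartiles` (per-group median, q1, q3, n).
#' @export
severity_comparison <- function(records) {
  stopifnot(all(c("setting", "barthel_admission") %in% names(records)))
  groups <- split(records$barthel_admission, records$setting)
  for (s in SETTINGS) {
    if (length(groups[[s]]) < 2L) {
      stop("setting '", s, "' has fewer than 2 Barthel observations",
           call. = FALSE)
    }
  }
  groups <- groups[SETTINGS]

  kw <- stats::kruskal.test(groups)

  pairs <- utils::combn(SETTINGS, 2)
  raw <- apply(pairs, 2, function(pr) {
    suppressWarnings(
      stats::wilcox.test(groups[[pr[1]]], groups[[pr[2]]], exact = FALSE)
    )$p.value
  })
  adj <- stats::p.adjust(raw, method = "bonferroni")
  names(adj) <- apply(pairs, 2, paste, collapse = " vs ")

  mq <- t(vapply(groups, function(g) {
    q <- stats::quantile(g, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    c(median = q[2], q1 = q[1], q3 = q[3], n = length(g))
  }, numeric(4)))

  structure(
    list(
      kw_statistic = unname(kw$statistic),
      kw_p = kw$p.value,
      pairwise_p = adj,
      medians_and_quartiles = mq,
      quartile_type = "linear interpolation (type 7)"
    ),
    class = "severity_comparison"
  )
}

#' @export
print.severity_comparison <- function(x, ...) {
  cat("Barthel admission severity by care setting\n")
  cat(sprintf("  Kruskal-Wallis chi-squared = %.3f, p = %.3g\n",
              x$kw_statistic, x$kw_p))
  cat("  Bonferroni-adjusted pairwise Wilcoxon p-values:\n")
  for (nm in names(x$pairwise_p)) {
    cat(sprintf("    %-25s %.3g\n", nm, x$pairwise_p[[nm]]))
  }
  cat("  Median (q1, q3):\n")
  mq <- x$medians_and_quartiles
  for (s in rownames(mq)) {
    cat(sprintf("    %-10s %.2f (%.2f, %.2f), n = %d\n",
                s, mq[s, "median"], mq[s, "q1"], mq[s, "q3"],
                as.integer(mq[s, "n"])))
  }
  invisible(x)
}
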