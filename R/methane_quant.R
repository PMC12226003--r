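#' Fit a GC calibration curve
#'
#' Ordinary least-squares line `area = slope * ppm + intercept` over the
#' standard mixing ratios, with the inverse map
#' `ppm(area) = (area - intercept) / slope` used to convert sample peak
#' areas to headspace mixing ratios.
#'
#' @param standards_ppm Standard mixing ratios in ppm (default the
#'   five-point curve 2.02, 4.99, 10.1, 100, 1000 ppm).
#' @param areas Measured peak areas, same length as `standards_ppm`.
#' @param force_zero Force the intercept through zero (default `FALSE`).
#' @return An object of class `phn_calibration`: list with
#'   `standards_ppm`, `areas`, `slope`, `intercept`, `r_squared`, and the
#'   inverse function `ppm(area)`.
#' @export
fit_calibration <- function(standards_ppm = c(2.02, 4.99, 10.1, 100, 1000),
                            areas, force_zero = FALSE) {
  if (length(standards_ppm) != length(areas)) {
    stop("standards and areas must have equal length")
  }
  if (length(unique(standards_ppm)) < 2L) {
    stop("calibration needs at least 2 distinct standards")
  }
  fit <- if (force_zero) lm(areas ~ 0 + standards_ppm)
         else lm(areas ~ standards_ppm)
  slope <- unname(coef(fit)[["standards_ppm"]])
  intercept <- if (force_zero) 0 else unname(coef(fit)[["(Intercept)"]])
  if (!is.finite(slope) || slope <= 0) {
    stop("non-physical calibration: slope <= 0")
  }
  # exact standard curves trip summary.lm's perfect-fit warning; expected
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(
    standards_ppm = standards_ppm, areas = areas,
    slope = slope, intercept = intercept, r_squared = r2,
    ppm = function(area) (area - intercept) / slope
  ), class = "phn_calibration")
}

#' @export
print.phn_calibration <- function(x, ...) {
  cat(sprintf("GC calibration: area = %.6g * ppm + %.6g (r^2 = %.6f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' CH4 Bunsen solubility constants
#'
#' Coefficients of the natural-seawater CH4 Bunsen solubility fit of
#' Wiesenburg & Guinasso (1979, J. Chem. Eng. Data 24:356-360),
#' `ln beta = A1 + A2*(100/T) + A3*ln(T/100) +
#'  S*(B1 + B2*(T/100) + B3*(T/100)^2)`,
#' read from the packaged configuration file so their provenance stays
#' auditable.
#'
#' @return Named list with vectors `A` (length 3) and `B` (length 3) and a
#'   `source` string.
#' @export
ch4_bunsen_coefficients <- function() {
  yaml::read_yaml(system.file("extdata", "ch4_bunsen_coefficients.yaml",
                              package = "phnomp", mustWork = TRUE))
}

#' Bunsen solubility coefficient of methane
#'
#' Volume of CH4 at STP dissolving per volume of liquid per atmosphere of
#' CH4 partial pressure, from the Wiesenburg & Guinasso (1979) polynomial.
#' Valid over the fitted range 273-313 K and 0-40 permil salinity;
#' decreases with both temperature and salinity.
#'
#' @param temperature Temperature in kelvin.
#' @param salinity Salinity in permil (default 0, fresh medium).
#' @param coefficients Coefficient list as from [ch4_bunsen_coefficients()].
#' @return Dimensionless Bunsen coefficient (L gas STP per L liquid per atm).
#' @export
bunsen_coefficient <- function(temperature, salinity = 0,
                               coefficients = ch4_bunsen_coefficients()) {
  if (any(temperature < 273 | temperature > 313)) {
    stop("temperature outside fitted range 273-313 K")
  }
  if (any(salinity < 0 | salinity > 40)) {
    stop("salinity outside fitted range 0-40 permil")
  }
  A <- as.numeric(coefficients$A)
  B <- as.numeric(coefficients$B)
  t100 <- temperature / 100
  lnb <- A[1] + A[2] / t100 + A[3] * log(t100) +
    salinity * (B[1] + B[2] * t100 + B[3] * t100^2)
  exp(lnb)
}

#' Serum-bottle geometry and incubation conditions
#'
#' Defaults describe a 125 mL serum bottle with 20 mL medium and 105 mL
#' headspace, crimped at ambient pressure and incubated at 30 degrees C
#' with shaking, in fresh (zero-salinity) medium.
#'
#' @param V_liq Liquid volume in liters.
#' @param V_head Headspace volume in liters.
#' @param temperature Temperature in kelvin.
#' @param pressure Headspace pressure in atm.
#' @param salinity Salinity in permil.
#' @param V_bottle Total bottle volume in liters (consistency check only).
#' @return A list of class `phn_geometry`.
#' @export
bottle_geometry <- function(V_liq = 0.020, V_head = 0.105,
                            temperature = 303.15, pressure = 1.0,
                            salinity = 0, V_bottle = 0.125) {
  if (V_liq <= 0 || V_head <= 0) stop("volumes must be positive")
  if (V_liq + V_head > V_bottle + 1e-12) {
    stop("V_liq + V_head exceeds bottle volume")
  }
  structure(list(V_liq = V_liq, V_head = V_head, temperature = temperature,
                 pressure = pressure, salinity = salinity,
                 V_bottle = V_bottle), class = "phn_geometry")
}

# ideal gas constant, L atm / (mol K); molar volume of ideal gas at STP, L/mol
.R_GAS <- 0.082057
.V_MOLAR <- 22.414

#' Partition a headspace mixing ratio into the bottle CH4 inventory
#'
#' Assuming full liquid-headspace equilibrium, converts a measured
#' headspace mixing ratio into headspace amount (ideal gas), dissolved
#' concentration (Bunsen coefficient at the bottle's temperature and
#' salinity) and the total bottle inventory normalized to liquid volume --
#' the scale on which production rates and mass balances are reported.
#'
#' @param mixing_ratio Headspace CH4 mixing ratio(s) in ppm (mole fraction
#'   x 1e6).
#' @param geometry A [bottle_geometry()].
#' @return A data.frame with columns `mixing_ratio` (ppm),
#'   `headspace_nmol`, `dissolved_umol_L` (per liter of liquid),
#'   `total_nmol`, `conc_umol_L` (total per liter of liquid).
#' @export
headspace_partition <- function(mixing_ratio, geometry = bottle_geometry()) {
  if (any(mixing_ratio < 0)) stop("negative mixing ratio")
  p_ch4 <- mixing_ratio * 1e-6 * geometry$pressure          # atm
  head_mol <- p_ch4 * geometry$V_head /
    (.R_GAS * geometry$temperature)
  beta <- bunsen_coefficient(geometry$temperature, geometry$salinity)
  diss_mol_L <- beta * p_ch4 / .V_MOLAR                     # mol per L liquid
  total_mol <- head_mol + diss_mol_L * geometry$V_liq
  data.frame(
    mixing_ratio = mixing_ratio,
    headspace_nmol = head_mol * 1e9,
    dissolved_umol_L = diss_mol_L * 1e6,
    total_nmol = total_mol * 1e9,
    conc_umol_L = total_mol / geometry$V_liq * 1e6
  )
}

#' Invert the headspace partition
#'
#' Recovers the headspace mixing ratio that yields a given total bottle
#' inventory; the partition is linear in the mixing ratio so the inverse is
#' exact. Used by the simulator and by round-trip checks.
#'
#' @param total_nmol Total CH4 in the bottle, nmol.
#' @param geometry A [bottle_geometry()].
#' @return Mixing ratio(s) in ppm.
#' @export
mixing_ratio_from_total <- function(total_nmol, geometry = bottle_geometry()) {
  beta <- bunsen_coefficient(geometry$temperature, geometry$salinity)
  per_ppm <- 1e-6 * geometry$pressure *
    (geometry$V_head / (.R_GAS * geometry$temperature) +
       beta * geometry$V_liq / .V_MOLAR)                    # mol per ppm
  (total_nmol * 1e-9) / per_ppm
}

#' Estimate a volumetric CH4 production rate
#'
#' Default method fits an ordinary least-squares slope of concentration
#' against time inside the window, pooling replicates when a `replicate`
#' vector is given; the endpoint method uses `(C_end - C_start)/(t_end -
#' t_start)` on window boundaries (means across replicates at the boundary
#' timepoints).
#'
#' @param time Time in hours.
#' @param conc CH4 concentration in nmol per liter (per liquid volume).
#' @param window Numeric `c(t_start, t_end)` in hours; default spans the
#'   data.
#' @param method `"regression"` (default) or `"endpoint"`.
#' @param replicate Optional replicate labels, for pooled fits.
#' @return A list of class `phn_rate`: `rate` and `stderr` in nmol L^-1
#'   h^-1, `window`, `method`, `n`.
#' @export
production_rate <- function(time, conc, window = range(time),
                            method = c("regression", "endpoint"),
                            replicate = NULL) {
  method <- match.arg(method)
  if (length(unique(time)) < 2L) {
    stop("need at least 2 distinct timepoints")
  }
  if (window[2] <= window[1]) stop("window end must exceed window start")
  keep <- time >= window[1] & time <= window[2]
  t <- time[keep]; y <- conc[keep]
  rep_ <- if (is.null(replicate)) rep(1L, length(t)) else replicate[keep]
  if (length(unique(t)) < 2L) {
    stop("need at least 2 distinct timepoints inside the window")
  }
  for (g in split(t, rep_)) {
    if (is.unsorted(g, strictly = FALSE)) stop("non-monotone time in series")
  }
  if (method == "regression") {
    fit <- lm(y ~ t)
    rate <- unname(coef(fit)[["t"]])
    # noise-free series fit exactly; the perfect-fit warning is expected
    se <- suppressWarnings(summary(fit)$coefficients["t", "Std. Error"])
  } else {
    t0 <- min(t); t1 <- max(t)
    c0 <- mean(y[t == t0]); c1 <- mean(y[t == t1])
    rate <- (c1 - c0) / (t1 - t0)
    se <- NA_real_
  }
  structure(list(rate = rate, stderr = se, window = window, method = method,
                 n = length(t)), class = "phn_rate")
}

#' @export
print.phn_rate <- function(x, ...) {
  cat(sprintf("CH4 production rate: %.4g nmol L^-1 h^-1 (%s, %g-%g h, n=%d)\n",
              x$rate, x$method, x$window[1], x$window[2], x$n))
  invisible(x)
}

#' Methane / organic-phosphorus consumption stoichiometry
#'
#' Computes dissolved organic phosphorus pointwise as `DOP = TDP - DIP`,
#' then the net changes `dCH4(t) = CH4(t) - CH4(0)` and `dDOP(t) = DOP(0) -
#' DOP(t)` and their ratio trajectory. A ratio near 1 indicates complete
#' methylphosphonate dealkylation (one CH4 released per P harvested).
#' Negative DOP values are flagged, never clamped; ratios where `|dDOP|`
#' falls below `floor` are reported as `NA`.
#'
#' @param time Time in hours (aligned across inputs).
#' @param ch4 Total CH4 per liquid volume, umol/L.
#' @param tdp Total dissolved phosphorus, umol/L.
#' @param dip Dissolved inorganic phosphorus, umol/L.
#' @param floor Smallest `|dDOP|` for which a ratio is defined (umol/L,
#'   default 0.05, about the precision of colorimetric P determination).
#' @return A list of class `phn_stoich`: `trajectory` data.frame (`time`,
#'   `ch4`, `dop`, `delta_ch4`, `delta_dop`, `ratio`), endpoint
#'   `delta_ch4`, `delta_dop`, `ratio`, and `negative_dop_flag`.
#' @export
stoichiometric_series <- function(time, ch4, tdp, dip, floor = 0.05) {
  n <- length(time)
  if (length(ch4) != n || length(tdp) != n || length(dip) != n) {
    stop("time, ch4, tdp, dip must be aligned (equal length)")
  }
  dop <- tdp - dip
  neg <- any(dop < 0)
  if (neg) warning("negative DOP values (TDP < DIP) flagged, not clamped")
  d_ch4 <- ch4 - ch4[1]
  d_dop <- dop[1] - dop
  ratio <- ifelse(abs(d_dop) > floor, d_ch4 / d_dop, NA_real_)
  structure(list(
    trajectory = data.frame(time = time, ch4 = ch4, dop = dop,
                            delta_ch4 = d_ch4, delta_dop = d_dop,
                            ratio = ratio),
    delta_ch4 = d_ch4[n], delta_dop = d_dop[n], ratio = ratio[n],
    negative_dop_flag = neg
  ), class = "phn_stoich")
}

#' Phosphate dose-response trend of final CH4
#'
#' Spearman rank correlation of mean final CH4 against the initial Pi
#' concentration, with a monotone-decrease verdict: correlation negative
#' and every consecutive mean difference non-positive within a noise
#' tolerance.
#'
#' @param final_ch4 Named list (or data.frame with columns `Pi_initial`,
#'   `value`) of replicate final CH4 values per Pi level; names are Pi
#'   concentrations in umol/L.
#' @param tol Allowed upward wobble between consecutive means, as a
#'   fraction of the mean range (default 0.05).
#' @return List with `pi_levels`, `means`, `spearman_rho`,
#'   `monotone_decreasing`.
#' @export
dose_response_trend <- function(final_ch4, tol = 0.05) {
  if (is.data.frame(final_ch4)) {
    final_ch4 <- split(final_ch4$value, final_ch4$Pi_initial)
  }
  pi_levels <- as.numeric(names(final_ch4))
  if (length(pi_levels) < 3L) stop("need at least 3 Pi levels")
  if (anyNA(pi_levels)) stop("Pi levels must be numeric names")
  o <- order(pi_levels)
  pi_levels <- pi_levels[o]
  means <- vapply(final_ch4[o], mean, numeric(1))
  rho <- if (sd(means) == 0) 0 else {
    suppressWarnings(cor(pi_levels, means, method = "spearman"))
  }
  slack <- tol * diff(range(means))
  mono <- rho < 0 && all(diff(means) <= slack)
  list(pi_levels = pi_levels, means = unname(means), spearman_rho = rho,
       monotone_decreasing = mono)
}

#' Test phosphate repression of CH4 production
#'
#' Two-sample t-test comparing production rates before and after phosphate
#' addition, with a one-sided option for the directional hypothesis that
#' Pi represses production. The pooled (equal-variance) form is the
#' default: with triplicate bottles per group the Welch approximation is
#' markedly conservative (empirical size well below its nominal level),
#' while the pooled test is exact under the homoscedastic null that
#' replicate bottles represent; set `var_equal = FALSE` for Welch.
#'
#' @param before Production rates before Pi addition (n >= 2).
#' @param after Production rates after Pi addition (n >= 2).
#' @param alternative `"two.sided"` (default) or `"greater"` (before >
#'   after).
#' @param var_equal Use the pooled-variance t-test (default `TRUE`).
#' @param alpha Significance level (default 0.05).
#' @return List with `statistic`, `p_value`, `significant`, `alpha`,
#'   `mean_before`, `mean_after`.
#' @export
repression_test <- function(before, after,
                            alternative = c("two.sided", "greater"),
                            var_equal = TRUE, alpha = 0.05) {
  alternative <- match.arg(alternative)
  if (length(before) < 2L || length(after) < 2L) {
    stop("each group needs at least 2 observations")
  }
  if (var(before) == 0 && var(after) == 0) {
    # degenerate: no within-group variability
    if (mean(before) == mean(after)) {
      return(list(statistic = 0, p_value = 1, significant = FALSE,
                  alpha = alpha, mean_before = mean(before),
                  mean_after = mean(after)))
    }
    delta <- mean(before) - mean(after)
    return(list(statistic = sign(delta) * Inf, p_value = 0,
                significant = TRUE, alpha = alpha,
                mean_before = mean(before), mean_after = mean(after)))
  }
  ht <- t.test(before, after, alternative = alternative,
               var.equal = var_equal)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       significant = ht$p.value < alpha, alpha = alpha,
       mean_before = mean(before), mean_after = mean(after))
}
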