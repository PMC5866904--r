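#' Peak concentration and its time
#'
#' Maximum observed quantifiable concentration and the time at which it
#' occurs; ties are broken toward the earliest time.
#'
#' @param profile A [conc_time_profile()].
#' @return A list with `cmax` (µmol/L) and `tmax` (min).
#' @export
find_cmax_tmax <- function(profile) {
  q <- quantifiable(profile)
  if (q$n < 1L) not_evaluable("all samples below LLOQ", profile$subject_id)
  i <- which.max(q$conc)   # first maximum = earliest on ties
  list(cmax = q$conc[i], tmax = q$times[i])
}

#' Back-extrapolate the time-zero concentration of an IV bolus
#'
#' The integration starts at time zero but the first blood sample is drawn
#' later (1 min in the emulated design), so `C0` is obtained by log-linear
#' extrapolation through the first two quantifiable samples. If those two
#' samples are non-decreasing (no initial decline), the first observed
#' concentration is used and the fallback is flagged.
#'
#' @param profile A [conc_time_profile()].
#' @return A list with `c0` (µmol/L) and logical `fallback`.
#' @export
back_extrapolate_c0 <- function(profile) {
  q <- quantifiable(profile)
  if (q$n < 2L) not_evaluable("fewer than 2 quantifiable samples",
                              profile$subject_id)
  t1 <- q$times[1]; t2 <- q$times[2]
  c1 <- q$conc[1]; c2 <- q$conc[2]
  if (c2 < c1 && c1 > 0 && c2 > 0) {
    slope <- log(c2 / c1) / (t2 - t1)
    list(c0 = exp(log(c1) - slope * t1), fallback = FALSE)
  } else {
    list(c0 = c1, fallback = TRUE)
  }
}

#' Linear trapezoid for one segment
#'
#' Area `dt * (c1 + c2) / 2`, used in ascending (and degenerate) periods.
#'
#' @param c1,c2 Segment endpoint values (`>= 0`).
#' @param dt Segment width, min (`> 0`).
#' @return Area over the segment.
#' @export
trapezoid_linear <- function(c1, c2, dt) {
  if (any(dt <= 0)) stop("dt must be positive", call. = FALSE)
  if (any(c(c1, c2) < 0)) stop("values must be non-negative", call. = FALSE)
  dt * (c1 + c2) / 2
}

#' Logarithmic trapezoid for one segment
#'
#' Area `dt * (c1 - c2) / log(c1 / c2)`, exact when the two endpoints lie on
#' one exponential; used in descending periods. Rejects degenerate input
#' (`c1 == c2` or non-positive values) — the integrator falls back to the
#' linear rule and flags the segment.
#'
#' @param c1,c2 Segment endpoint values (both `> 0`, `c1 != c2`).
#' @param dt Segment width, min (`> 0`).
#' @return Area over the segment.
#' @export
trapezoid_log <- function(c1, c2, dt) {
  if (any(dt <= 0)) stop("dt must be positive", call. = FALSE)
  if (any(c(c1, c2) <= 0) || any(c1 == c2)) {
    stop("log trapezoid requires positive, unequal endpoint values",
         call. = FALSE)
  }
  dt * (c1 - c2) / log(c1 / c2)
}

# Vectorised segment areas with the linear-up/log-down rule. `rule_log` says
# which segments the caller assigned to the log rule; degenerate segments
# (equal or non-positive values) fall back to linear, reported in `fallback`.
segment_areas <- function(y1, y2, dt, rule_log) {
  area <- dt * (y1 + y2) / 2
  ok <- rule_log & y1 > 0 & y2 > 0 & y1 != y2
  area[ok] <- dt[ok] * (y1[ok] - y2[ok]) / log(y1[ok] / y2[ok])
  list(area = area, fallback = rule_log & !ok)
}

#' Integrate AUC and AUMC up to the last quantifiable sample
#'
#' Prepends the back-extrapolated time-zero point, then integrates the
#' concentration curve and the first-moment curve (`C * t`) segment by
#' segment: the linear trapezoid where the concentration is non-decreasing
#' across the segment, the log trapezoid where it is strictly decreasing.
#' The rule assignment is decided per segment from the concentration; for
#' the moment curve the chosen rule is applied to the `C * t` values
#' (falling back to linear where `C * t` is zero or constant — always the
#' case for the segment starting at time zero).
#'
#' @param profile A [conc_time_profile()].
#' @param c0 Concentration at time zero, µmol/L (see
#'   [back_extrapolate_c0()]).
#' @return A list with `auc_last` (µmol·min/L), `aumc_last` (µmol·min²/L)
#'   and a character vector `flags`.
#' @export
integrate_auc_aumc <- function(profile, c0) {
  q <- quantifiable(profile)
  if (q$n < 3L) not_evaluable("fewer than 3 quantifiable samples",
                              profile$subject_id)
  if (!is.finite(c0) || c0 < 0) stop("c0 must be non-negative", call. = FALSE)
  tt <- c(0, q$times)
  cc <- c(c0, q$conc)
  n <- length(tt)
  t1 <- tt[-n]; t2 <- tt[-1]
  c1 <- cc[-n]; c2 <- cc[-1]
  dt <- t2 - t1
  descending <- c2 < c1                 # strict decrease -> log rule

  auc <- segment_areas(c1, c2, dt, descending)
  y1 <- c1 * t1; y2 <- c2 * t2
  aumc <- segment_areas(y1, y2, dt, descending)

  flags <- character(0)
  if (any(auc$fallback)) flags <- c(flags, "auc_linear_fallback")
  # the first moment segment starts at y = 0 by construction; only flag
  # fallbacks beyond it
  if (any(aumc$fallback[-1]) || (aumc$fallback[1] && t1[1] != 0)) {
    flags <- c(flags, "aumc_linear_fallback")
  }
  list(auc_last = sum(auc$area), aumc_last = sum(aumc$area), flags = flags)
}

#' Fit the terminal-phase rate constant
#'
#' Ordinary least-squares regression of `log(y)` on time over a terminal
#' window, where `y` is the concentration (`transform = "conc"`, giving
#' `lambda_z`) or the concentration-time product (`transform =
#' "conc_times_time"`, giving the starred rate constant used for the AUMC
#' tail). The window is chosen automatically: among all contiguous windows
#' that end at the last quantifiable sample, contain at least three points,
#' start strictly after the peak of `y`, and have a positive fitted rate
#' constant, the one with the largest adjusted R² wins; near-ties (within
#' 1e-9) go to the window with more points. A fixed window can be supplied
#' instead.
#'
#' @param profile A [conc_time_profile()].
#' @param transform `"conc"` or `"conc_times_time"`.
#' @param window Optional numeric `c(t_lo, t_hi)`: use exactly the
#'   quantifiable samples with `t_lo <= t <= t_hi`.
#' @return An object of class `lambda_z_fit`: `lambda_z` (1/min),
#'   `intercept_log`, `r_squared`, `adjusted_r_squared`, `n_points`,
#'   `time_range`, and `c_last_pred` — the regression-predicted value of `y`
#'   at the last quantifiable time.
#' @export
fit_lambda_z <- function(profile, transform = c("conc", "conc_times_time"),
                         window = NULL) {
  transform <- match.arg(transform)
  q <- quantifiable(profile)
  if (q$n < 3L) not_evaluable("fewer than 3 quantifiable samples",
                              profile$subject_id)
  y <- if (transform == "conc") q$conc else q$conc * q$times
  if (any(y <= 0)) {
    keep <- y > 0
    y <- y[keep]; tq <- q$times[keep]
  } else tq <- q$times
  n <- length(y)
  if (n < 3L) not_evaluable("fewer than 3 positive samples for regression",
                            profile$subject_id)
  t_last <- tq[n]
  z <- log(y)

  if (!is.null(window)) {
    sel <- tq >= window[1] & tq <= window[2]
    if (sum(sel) < 3L) {
      not_evaluable("lambda_z window contains fewer than 3 points",
                    profile$subject_id)
    }
    fit <- ols_loglinear(tq[sel], z[sel])
    if (fit$slope >= 0) not_evaluable("no terminal decline in fixed window",
                                      profile$subject_id)
    return(new_lambda_z_fit(fit, tq[sel], t_last, transform))
  }

  ipeak <- which.max(y)
  starts <- which(seq_len(n) > ipeak & (n - seq_len(n) + 1L) >= 3L)
  if (!length(starts)) {
    not_evaluable("fewer than 3 candidate terminal points after the peak",
                  profile$subject_id)
  }
  # all-suffix OLS via reverse cumulative sums
  rc <- function(v) rev(cumsum(rev(v)))
  Sn <- n - starts + 1
  Sx <- rc(tq)[starts];  Sz <- rc(z)[starts]
  Sxx <- rc(tq^2)[starts]; Szz <- rc(z^2)[starts]; Sxz <- rc(tq * z)[starts]
  sxx <- Sxx - Sx^2 / Sn
  szz <- Szz - Sz^2 / Sn
  sxz <- Sxz - Sx * Sz / Sn
  slope <- sxz / sxx
  r2 <- ifelse(szz > 0, pmin(1, sxz^2 / (sxx * szz)), 1)
  adj <- 1 - (1 - r2) * (Sn - 1) / (Sn - 2)
  ok <- slope < 0
  if (!any(ok)) not_evaluable("no terminal decline", profile$subject_id)
  adj_ok <- adj[ok]
  best_adj <- max(adj_ok)
  cand <- which(ok)[adj_ok >= best_adj - 1e-9]
  pick <- cand[which.max(Sn[cand])]    # tie -> more points (earliest start)
  sel_t <- tq[seq.int(starts[pick], n)]
  fit <- ols_loglinear(sel_t, z[seq.int(starts[pick], n)])
  new_lambda_z_fit(fit, sel_t, t_last, transform)
}

ols_loglinear <- function(x, z) {
  n <- length(x)
  mx <- mean(x); mz <- mean(z)
  sxx <- sum((x - mx)^2)
  sxz <- sum((x - mx) * (z - mz))
  szz <- sum((z - mz)^2)
  slope <- sxz / sxx
  r2 <- if (szz > 0) min(1, sxz^2 / (sxx * szz)) else 1
  list(slope = slope, intercept = mz - slope * mx, r_squared = r2,
       adjusted_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2), n = n)
}

new_lambda_z_fit <- function(fit, sel_t, t_last, transform) {
  structure(list(lambda_z = -fit$slope,
                 intercept_log = fit$intercept,
                 r_squared = fit$r_squared,
                 adjusted_r_squared = fit$adjusted_r_squared,
                 n_points = fit$n,
                 time_range = range(sel_t),
                 c_last_pred = exp(fit$intercept + fit$slope * t_last),
                 t_last = t_last,
                 transform = transform),
            class = "lambda_z_fit")
}

#' @export
print.lambda_z_fit <- function(x, ...) {
  cat(sprintf(
    "<lambda_z_fit> (%s) lambda = %.5g /min, %d points over [%g, %g] min, adj R2 = %.4f\n",
    x$transform, x$lambda_z, x$n_points, x$time_range[1], x$time_range[2],
    x$adjusted_r_squared))
  invisible(x)
}

#' Extrapolate AUC and AUMC to infinite time
#'
#' `auc_inf = auc_last + C_last_pred / lambda_z`, where `C_last_pred` is the
#' terminal regression's predicted concentration at the last quantifiable
#' time. The first-moment tail divides the predicted moment-curve value at
#' the last time by the starred rate constant: with `aumc_tail = "star"`
#' (default) the predicted `C*t` comes from the starred fit itself; with
#' `aumc_tail = "lambda_z"` it is the lambda-z fit's predicted `C_last`
#' multiplied by the last time. `aumc_tail = "standard"` instead uses the
#' canonical moment tail `C_last_pred * t_last / lambda_z +
#' C_last_pred / lambda_z^2`, which needs no starred fit and remains defined
#' when elimination is so slow that `C*t` is still rising at the last sample
#' (no positive starred rate constant exists there).
#'
#' @param auc_last,aumc_last Areas to the last quantifiable sample.
#' @param fit `lambda_z_fit` on the concentration.
#' @param fit_star `lambda_z_fit` on the concentration-time product; may be
#'   `NULL` for `aumc_tail = "standard"`.
#' @param t_last Last quantifiable time, min.
#' @param aumc_tail `"star"`, `"lambda_z"` or `"standard"`.
#' @return A list with `auc_inf`, `aumc_inf`, `auc_extrapolated_pct` and
#'   `flags` (contains `"extrapolation_gt_20pct"` when more than 20% of
#'   `auc_inf` lies beyond the data — reported, not rejected, since severely
#'   impaired livers genuinely show such tails).
#' @export
extrapolate_to_infinity <- function(auc_last, aumc_last, fit, fit_star,
                                    t_last,
                                    aumc_tail = c("star", "lambda_z",
                                                  "standard")) {
  aumc_tail <- match.arg(aumc_tail)
  if (fit$lambda_z <= 0) not_evaluable("non-positive terminal rate constant")
  if (aumc_tail != "standard" &&
      (is.null(fit_star) || fit_star$lambda_z <= 0)) {
    not_evaluable("non-positive starred terminal rate constant")
  }
  auc_inf <- auc_last + fit$c_last_pred / fit$lambda_z
  moment_tail <- switch(aumc_tail,
                        star = fit_star$c_last_pred / fit_star$lambda_z,
                        lambda_z = fit$c_last_pred * t_last / fit_star$lambda_z,
                        standard = fit$c_last_pred * t_last / fit$lambda_z +
                          fit$c_last_pred / fit$lambda_z^2)
  aumc_inf <- aumc_last + moment_tail
  pct <- 100 * (auc_inf - auc_last) / auc_inf
  flags <- if (pct > 20) "extrapolation_gt_20pct" else character(0)
  list(auc_inf = auc_inf, aumc_inf = aumc_inf, auc_extrapolated_pct = pct,
       flags = flags)
}

#' Derive clearance, volumes, residence time and half-lives
#'
#' Standard noncompartmental identities for an IV bolus:
#' `CL = dose / AUC_inf` (converted to mL/min), `Vz = CL / lambda_z`,
#' `MRT = AUMC_inf / AUC_inf`, `Vss = dose * AUMC_inf / AUC_inf^2`
#' (equivalently `CL * MRT`), `t_half_beta = ln(2) / lambda_z` and
#' `t_half_eff = 0.693 * MRT`.
#'
#' @param auc_inf µmol·min/L.
#' @param aumc_inf µmol·min²/L.
#' @param fit `lambda_z_fit` on the concentration.
#' @param dose µmol.
#' @return A list with `cl` (mL/min), `v_z` (mL), `v_ss` (mL), `mrt` (min),
#'   `t_half_beta` (min), `t_half_eff` (min).
#' @export
derive_parameters <- function(auc_inf, aumc_inf, fit, dose) {
  if (!is.finite(dose) || dose <= 0) stop("dose must be positive", call. = FALSE)
  if (any(c(auc_inf, aumc_inf) <= 0)) {
    stop("areas must be positive", call. = FALSE)
  }
  cl <- 1000 * dose / auc_inf          # (µmol) / (µmol·min/L) -> L/min -> mL/min
  mrt <- aumc_inf / auc_inf
  list(cl = cl,
       v_z = cl / fit$lambda_z,
       v_ss = cl * mrt,
       mrt = mrt,
       t_half_beta = log(2) / fit$lambda_z,
       t_half_eff = 0.693 * mrt)
}

#' Run the full noncompartmental analysis for one subject
#'
#' Orchestrates peak detection, time-zero back-extrapolation, linear-up/
#' log-down integration, terminal regressions on the concentration and on
#' the concentration-time product, extrapolation to infinity, and parameter
#' derivation. BLQ samples are excluded throughout. All computations use the
#' recorded (actual) sampling times. Profiles that cannot be analysed raise
#' a structured `gadnca_not_evaluable` condition rather than returning a
#' partial result.
#'
#' @param profile A [conc_time_profile()].
#' @param dose Dose in µmol; defaults to the profile's own.
#' @param lambda_z_window,lambda_z_star_window Optional fixed regression
#'   windows `c(t_lo, t_hi)` overriding the automatic selection.
#' @param clast `"pred"` (regression-predicted last concentration, the
#'   default) or `"obs"` (last observed) for the AUC tail.
#' @param aumc_tail Passed to [extrapolate_to_infinity()]. The default
#'   `"standard"` moment tail is defined for every profile with a terminal
#'   decline and is unbiased on exponential tails; the starred variants
#'   divide by a rate constant that does not exist when elimination is slow
#'   enough that `C*t` is still rising at the last sample (common after 90%
#'   hepatectomy) and can inflate the moment tail when it is barely positive.
#'   When a starred mode is requested but no declining `C*t` window exists,
#'   the subject falls back to the `"standard"` tail with the flag
#'   `"aumc_tail_standard_fallback"` rather than being declared not
#'   evaluable.
#' @return An object of class `nca_result`; see [as.data.frame.nca_result()].
#' @examples
#' cfg <- cohort_config(seed = 7)
#' prof <- simulate_subject(cfg, "control", 1)
#' res <- run_nca(prof)
#' res$cl
#' @export
run_nca <- function(profile, dose = profile$dose,
                    lambda_z_window = NULL, lambda_z_star_window = NULL,
                    clast = c("pred", "obs"),
                    aumc_tail = c("standard", "star", "lambda_z")) {
  clast <- match.arg(clast)
  aumc_tail <- match.arg(aumc_tail)
  q <- quantifiable(profile)
  if (q$n < 3L) not_evaluable("fewer than 3 quantifiable samples",
                              profile$subject_id)

  peak <- find_cmax_tmax(profile)
  c0 <- back_extrapolate_c0(profile)
  areas <- integrate_auc_aumc(profile, c0$c0)
  fit <- fit_lambda_z(profile, "conc", window = lambda_z_window)
  # the starred fit is reported whenever it exists, but only the "star" and
  # "lambda_z" tail modes depend on it
  fit_star <- tryCatch(
    fit_lambda_z(profile, "conc_times_time", window = lambda_z_star_window),
    gadnca_not_evaluable = function(e) NULL)
  star_fallback <- FALSE
  if (aumc_tail != "standard" && is.null(fit_star)) {
    aumc_tail <- "standard"
    star_fallback <- TRUE
  }
  if (clast == "obs") fit$c_last_pred <- q$conc[q$n]
  t_last <- q$times[q$n]
  ext <- extrapolate_to_infinity(areas$auc_last, areas$aumc_last,
                                 fit, fit_star, t_last, aumc_tail)
  par <- derive_parameters(ext$auc_inf, ext$aumc_inf, fit, dose)

  flags <- c(areas$flags, ext$flags)
  if (star_fallback) flags <- c(flags, "aumc_tail_standard_fallback")
  if (c0$fallback) flags <- c(flags, "c0_fallback")
  if (fit$r_squared < 0.8) flags <- c(flags, "lambda_z_r2_lt_0.8")
  if (par$v_z < par$v_ss) flags <- c(flags, "vz_lt_vss")

  structure(list(subject_id = profile$subject_id,
                 group = profile$group,
                 dose = dose,
                 c0 = c0$c0,
                 cmax = peak$cmax,
                 tmax = peak$tmax,
                 cmax_per_dose = peak$cmax / dose,
                 auc_last = areas$auc_last,
                 aumc_last = areas$aumc_last,
                 auc_inf = ext$auc_inf,
                 aumc_inf = ext$aumc_inf,
                 auc_inf_per_dose = ext$auc_inf / dose,
                 auc_extrapolated_pct = ext$auc_extrapolated_pct,
                 lambda_z = fit$lambda_z,
                 lambda_z_star = if (is.null(fit_star)) NA_real_ else
                   fit_star$lambda_z,
                 cl = par$cl,
                 v_z = par$v_z,
                 v_ss = par$v_ss,
                 mrt = par$mrt,
                 t_half_beta = par$t_half_beta,
                 t_half_eff = par$t_half_eff,
                 t_last = t_last,
                 lambda_z_fit = fit,
                 lambda_z_star_fit = fit_star,
                 quality_flags = flags),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> subject %s (%s)\n", x$subject_id, x$group))
  cat(sprintf("  Cmax %.1f umol/L at %g min; AUClast %.1f, AUCinf %.1f umol*min/L (%.1f%% extrapolated)\n",
              x$cmax, x$tmax, x$auc_last, x$auc_inf, x$auc_extrapolated_pct))
  cat(sprintf("  CL %.2f mL/min, Vss %.1f mL, Vz %.1f mL, MRT %.1f min, t1/2b %.1f min\n",
              x$cl, x$v_ss, x$v_z, x$mrt, x$t_half_beta))
  if (length(x$quality_flags)) {
    cat("  flags:", paste(x$quality_flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' One-row data frame of an NCA result
#'
#' @param x An `nca_result`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return A one-row data.frame with the full parameter set plus fit
#'   diagnostics and semicolon-joined quality flags.
#' @export
as.data.frame.nca_result <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(subject_id = x$subject_id, group = x$group, dose = x$dose,
             cmax = x$cmax, tmax = x$tmax, cmax_per_dose = x$cmax_per_dose,
             auc_last = x$auc_last, aumc_last = x$aumc_last,
             auc_inf = x$auc_inf, aumc_inf = x$aumc_inf,
             auc_inf_per_dose = x$auc_inf_per_dose,
             auc_extrapolated_pct = x$auc_extrapolated_pct,
             lambda_z = x$lambda_z, lambda_z_star = x$lambda_z_star,
             lambda_z_r2 = x$lambda_z_fit$r_squared,
             lambda_z_n_points = x$lambda_z_fit$n_points,
             cl = x$cl, v_z = x$v_z, v_ss = x$v_ss, mrt = x$mrt,
             t_half_beta = x$t_half_beta, t_half_eff = x$t_half_eff,
             quality_flags = paste(x$quality_flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Run NCA on every profile in a cohort
#'
#' @param cohort A `pk_cohort` or list of [conc_time_profile()] objects.
#' @param ... Passed to [run_nca()].
#' @return A list with `parameters` (data.frame, one row per evaluable
#'   subject) and `failures` (data.frame `subject_id`, `group`, `reason`).
#' @export
nca_cohort <- function(cohort, ...) {
  rows <- list(); fails <- list()
  for (p in cohort) {
    res <- tryCatch(run_nca(p, ...), gadnca_not_evaluable = function(e) e)
    if (inherits(res, "gadnca_not_evaluable")) {
      fails[[length(fails) + 1L]] <-
        data.frame(subject_id = p$subject_id, group = p$group,
                   reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- as.data.frame(res)
    }
  }
  empty_fail <- data.frame(subject_id = character(0), group = character(0),
                           reason = character(0), stringsAsFactors = FALSE)
  list(parameters = if (length(rows)) do.call(rbind, rows) else NULL,
       failures = if (length(fails)) do.call(rbind, fails) else empty_fail)
}
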