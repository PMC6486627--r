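# Quantitative biochemistry: rate extraction from NADH-coupled absorbance
# traces, Michaelis-Menten fitting, the exact quadratic single-site
# (Rossi-Taylor) fluorescence-polarization isotherm, and circular-dichroism
# mean-residue-ellipticity conversion. Nonlinear fits use
# Levenberg-Marquardt least squares (minpack.lm) from a small deterministic
# multi-start grid so a poor initial guess cannot trap the fit in a local
# minimum.

#' Default molar extinction coefficient of NADH at 340 nm
#'
#' Standard literature value, 6220 per molar per cm.
#' @export
EPSILON_NADH_340 <- 6220

#' Initial velocity from an NADH-coupled absorbance trace
#'
#' In the coupled assay each ATP hydrolysed oxidises one NADH, so the
#' initial rate of A340 decrease converts directly to an ATPase velocity
#' via Beer-Lambert. The slope is taken by linear fit over the initial
#' window of the trace, by default the points before 10\% of the total
#' observed NADH consumption, where the trace is still linear.
#'
#' @param trace Data frame with columns `time` (s) and `a340` (absorbance).
#' @param pathlength Cuvette/well pathlength, cm.
#' @param epsilon_nadh Extinction coefficient, per molar per cm.
#' @param window_frac Fraction of the total observed absorbance drop
#'   defining the initial-rate window (default 0.10).
#' @return Velocity in micromolar per second (>= 0). A non-decreasing trace
#'   returns 0 with a warning.
#' @export
nadh_rate <- function(trace, pathlength = 1, epsilon_nadh = EPSILON_NADH_340,
                      window_frac = 0.10) {
  stopifnot(all(c("time", "a340") %in% names(trace)), nrow(trace) >= 5,
            pathlength > 0, epsilon_nadh > 0)
  trace <- trace[order(trace$time), , drop = FALSE]
  drop_total <- trace$a340[1] - min(trace$a340)
  if (drop_total <= 0) {
    warning("absorbance trace is non-decreasing; returning zero rate")
    return(0)
  }
  cutoff <- trace$a340[1] - window_frac * drop_total
  in_window <- trace$a340 >= cutoff
  # always keep enough points for a slope
  idx <- seq_len(max(3, sum(in_window[seq_len(which.min(trace$a340))])))
  fit <- stats::lm(a340 ~ time, data = trace[idx, , drop = FALSE])
  slope <- stats::coef(fit)[["time"]]
  max(0, -slope / (epsilon_nadh * pathlength) * 1e6)
}

#' The Michaelis-Menten rate law
#'
#' `v = kcat * E * S / (Km + S)`.
#'
#' @param s Substrate concentration (mM).
#' @param kcat Turnover number (per s).
#' @param km Michaelis constant (mM).
#' @param e_uM Enzyme concentration (uM); with `v` in uM/s this makes
#'   `kcat` come out in per-second units.
#' @return Velocity, uM/s.
#' @export
mm_velocity <- function(s, kcat, km, e_uM) kcat * e_uM * s / (km + s)

new_fit_result <- function(class2, estimates, data, fitted, converged, extra = list()) {
  resid <- data$.response - fitted
  structure(
    c(list(estimates = estimates, data = data, fitted = fitted,
           residuals = resid, rss = sum(resid^2), converged = converged),
      extra),
    class = c(class2, "helicore_fit")
  )
}

# Run nlsLM from each start in a deterministic grid; keep the converged fit
# with the lowest deviance. Jitter factors are fixed, not random.
multistart_nls <- function(formula, data, starts, lower) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st, lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || stats::deviance(fit) < stats::deviance(best))) {
      best <- fit
    }
  }
  best
}

#' Fit the Michaelis-Menten equation to pooled rate data
#'
#' Nonlinear least squares of `v = kcat * E * S / (Km + S)` on the pooled
#' data points (replicates enter individually, not as means). Starting
#' values come from the data (`Vmax = max(v)`, `Km` = substrate
#' concentration nearest half-max) and a deterministic grid of scaled
#' starts guards against local minima. Asymptotic standard errors are
#' reported for every free parameter.
#'
#' @param data Data frame with columns `s_mM` (substrate, mM) and `v0`
#'   (initial velocity, uM/s); at least 4 distinct substrate levels.
#' @param e_uM Enzyme concentration (uM); defaults to a `e_uM` column of
#'   `data` if present.
#' @return Object of class `mm_fit`: estimates (`kcat` per s, `km` mM) with
#'   standard errors, residuals, residual sum of squares and a convergence
#'   flag. Non-convergence is flagged, never silently replaced.
#' @export
fit_michaelis_menten <- function(data, e_uM = NULL) {
  stopifnot(all(c("s_mM", "v0") %in% names(data)))
  if (is.null(e_uM)) {
    if (!"e_uM" %in% names(data)) stop("enzyme concentration e_uM required")
    e_uM <- data$e_uM[1]
  }
  if (length(unique(data$s_mM)) < 4) {
    stop("need >= 4 distinct substrate concentrations for identifiability")
  }
  stopifnot(all(data$s_mM >= 0), e_uM > 0)
  d <- data.frame(s = data$s_mM, v = data$v0)
  vmax0 <- max(d$v)
  km0 <- d$s[which.min(abs(d$v - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(d$s[d$s > 0])
  kcat0 <- vmax0 / e_uM
  starts <- list(
    list(kcat = kcat0, km = km0),
    list(kcat = kcat0 * 1.5, km = km0 * 0.5),
    list(kcat = kcat0 * 0.75, km = km0 * 2)
  )
  fit <- multistart_nls(v ~ kcat * e_uM * s / (km + s), d, starts,
                        lower = c(kcat = 1e-12, km = 1e-12))
  if (is.null(fit)) {
    return(new_fit_result("mm_fit",
      estimates = tibble::tibble(term = c("kcat", "km"),
                                 estimate = NA_real_, std.error = NA_real_),
      data = cbind(d, .response = d$v), fitted = rep(NA_real_, nrow(d)),
      converged = FALSE, extra = list(e_uM = e_uM)))
  }
  sm <- summary(fit)
  est <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = unname(sm$coefficients[, "Estimate"]),
    std.error = unname(sm$coefficients[, "Std. Error"])
  )
  new_fit_result("mm_fit", est, cbind(d, .response = d$v),
                 fitted = stats::fitted(fit), converged = TRUE,
                 extra = list(e_uM = e_uM))
}

#' Exact single-site binding isotherm with ligand depletion
#'
#' Fraction of labeled ligand bound at total receptor `rt` and total
#' labeled-ligand concentration `lt`, from the quadratic solution of the
#' single-site equilibrium (no free-ligand approximation):
#' `FB = ((Kd + Lt + Rt) - sqrt((Kd + Lt + Rt)^2 - 4 Lt Rt)) / (2 Lt)`.
#'
#' @param rt Total receptor (titrated protein) concentration, uM.
#' @param kd Dissociation constant, uM.
#' @param lt Total labeled ligand concentration, uM.
#' @return Fraction bound in `[0, 1]`.
#' @export
fp_fraction_bound <- function(rt, kd, lt) {
  s <- kd + lt + rt
  (s - sqrt(s^2 - 4 * lt * rt)) / (2 * lt)
}

#' Fit a fluorescence-polarization titration
#'
#' Fits the exact quadratic single-site isotherm to an FP titration of a
#' fixed, low concentration of labeled RNA with increasing protein. The raw
#' polarization is related to fraction bound by
#' `P = P_free + (P_bound - P_free) * FB`; the plateaus can be co-fit
#' (`normalize = "fit"`), fixed from supplied values
#' (`normalize = "fixed"`), or the input may already be fraction bound
#' (`normalize = "none"`).
#'
#' @param data Data frame with `rt_uM` and either `polarization` (for
#'   `"fit"`/`"fixed"`) or `fb` (for `"none"`).
#' @param lt_nM Total labeled ligand concentration, nM (default 6).
#' @param normalize `"fit"`, `"fixed"` or `"none"`.
#' @param p_free,p_bound Plateau polarizations for `normalize = "fixed"`.
#' @return Object of class `fp_fit`; estimates include `kd` (uM) and, in
#'   `"fit"` mode, `p_free` and `p_bound`. `$data$fb` holds the normalized
#'   fraction bound (fitted plateaus map to exactly 0 and 1). A titration
#'   that does not span the binding transition yields a wide-confidence
#'   warning.
#' @export
fit_fp_binding <- function(data, lt_nM = 6,
                           normalize = c("fit", "fixed", "none"),
                           p_free = NULL, p_bound = NULL) {
  normalize <- match.arg(normalize)
  stopifnot("rt_uM" %in% names(data), lt_nM > 0)
  lt <- lt_nM / 1000  # uM
  d <- data.frame(rt = data$rt_uM)
  d <- d[order(d$rt), , drop = FALSE]
  if (normalize == "none") {
    stopifnot("fb" %in% names(data))
    d$y <- data$fb[order(data$rt_uM)]
  } else {
    stopifnot("polarization" %in% names(data))
    d$y <- data$polarization[order(data$rt_uM)]
  }
  kd0 <- max(stats::median(d$rt[d$rt > 0]), 1e-6)
  mk_starts <- function(base) list(base,
                                   utils::modifyList(base, list(kd = base$kd * 0.3)),
                                   utils::modifyList(base, list(kd = base$kd * 3)))
  if (normalize == "fit") {
    starts <- mk_starts(list(kd = kd0, pf = min(d$y), pb = max(d$y)))
    fit <- multistart_nls(
      y ~ pf + (pb - pf) * fp_fraction_bound(rt, kd, lt),
      d, starts, lower = c(kd = 1e-9, pf = -Inf, pb = -Inf))
  } else if (normalize == "fixed") {
    stopifnot(!is.null(p_free), !is.null(p_bound))
    d$y <- (d$y - p_free) / (p_bound - p_free)
    starts <- mk_starts(list(kd = kd0))
    fit <- multistart_nls(y ~ fp_fraction_bound(rt, kd, lt), d, starts,
                          lower = c(kd = 1e-9))
  } else {
    starts <- mk_starts(list(kd = kd0))
    fit <- multistart_nls(y ~ fp_fraction_bound(rt, kd, lt), d, starts,
                          lower = c(kd = 1e-9))
  }
  if (is.null(fit)) {
    return(new_fit_result("fp_fit",
      estimates = tibble::tibble(term = "kd", estimate = NA_real_,
                                 std.error = NA_real_),
      data = cbind(d, .response = d$y), fitted = rep(NA_real_, nrow(d)),
      converged = FALSE, extra = list(lt_uM = lt, normalize = normalize)))
  }
  sm <- summary(fit)
  term_map <- c(kd = "kd", pf = "p_free", pb = "p_bound")
  est <- tibble::tibble(
    term = unname(term_map[rownames(sm$coefficients)]),
    estimate = unname(sm$coefficients[, "Estimate"]),
    std.error = unname(sm$coefficients[, "Std. Error"])
  )
  kd_hat <- est$estimate[est$term == "kd"]
  if (max(d$rt) < 2 * kd_hat) {
    warning("titration does not span the binding transition; Kd confidence is wide")
  }
  d2 <- cbind(d, .response = d$y)
  if (normalize == "fit") {
    pf <- est$estimate[est$term == "p_free"]
    pb <- est$estimate[est$term == "p_bound"]
    d2$fb <- (d$y - pf) / (pb - pf)
  } else {
    d2$fb <- d$y
  }
  new_fit_result("fp_fit", est, d2, fitted = stats::fitted(fit),
                 converged = TRUE, extra = list(lt_uM = lt, normalize = normalize))
}

#' Convert an observed CD signal to mean residue ellipticity
#'
#' `MRE = theta_mdeg * MRW / (10 * pathlength_cm * conc_mg_ml)`, in
#' deg cm^2 per dmol.
#'
#' @param theta_obs Observed ellipticity, millidegrees.
#' @param mean_residue_weight Mean residue weight, g/mol (protein molecular
#'   weight divided by the number of peptide bonds).
#' @param concentration Protein concentration, mg/ml.
#' @param pathlength Cell pathlength, cm.
#' @return Mean residue ellipticity (vectorised over `theta_obs`).
#' @export
mean_residue_ellipticity <- function(theta_obs, mean_residue_weight,
                                     concentration, pathlength) {
  stopifnot(mean_residue_weight > 0, concentration > 0, pathlength > 0)
  theta_obs * mean_residue_weight / (10 * pathlength * concentration)
}

# ---- broom-style methods -----------------------------------------------

#' Tidiers for helicore fit and transform objects
#'
#' `tidy()` returns one row per parameter or quantity; `glance()` returns a
#' one-row model summary.
#'
#' @param x A fitted object (`mm_fit`, `fp_fit`, `kabsch_fit`,
#'   `transform_decomposition`).
#' @param ... Unused.
#' @name tidy_helicore
NULL

#' @rdname tidy_helicore
#' @export
tidy.helicore_fit <- function(x, ...) x$estimates

#' @rdname tidy_helicore
#' @export
glance.helicore_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = nrow(x$data), converged = x$converged)
}

#' @export
print.helicore_fit <- function(x, ...) {
  cat(sprintf("%s (%s): rss %.4g, n = %d\n", class(x)[1],
              if (x$converged) "converged" else "NOT converged",
              x$rss, nrow(x$data)))
  print(x$estimates)
  invisible(x)
}

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  e <- tidy(object)
  s <- if (is.null(newdata)) object$data$s else newdata$s_mM
  mm_velocity(s, e$estimate[e$term == "kcat"], e$estimate[e$term == "km"],
              object$e_uM)
}

#' @export
predict.fp_fit <- function(object, newdata = NULL, ...) {
  e <- tidy(object)
  rt <- if (is.null(newdata)) object$data$rt else newdata$rt_uM
  fp_fraction_bound(rt, e$estimate[e$term == "kd"], object$lt_uM)
}
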