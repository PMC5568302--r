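#' Spectrum curve container
#'
#' @param wavelength Strictly increasing numeric grid (nm).
#' @param absorbance Numeric vector of the same length.
#' @param label Optional curve label.
#' @return Data frame of class `spectrum_curve` with columns `wavelength`
#'   and `absorbance`.
#' @export
spectrum_curve <- function(wavelength, absorbance, label = "") {
  if (length(wavelength) != length(absorbance)) stop("lengths differ")
  if (any(diff(wavelength) <= 0)) stop("wavelength grid must be strictly increasing")
  if (anyNA(absorbance)) stop("absorbance contains missing values")
  structure(data.frame(wavelength = wavelength, absorbance = absorbance),
            label = label, class = c("spectrum_curve", "data.frame"))
}

#' Visual pigment alpha-band absorbance template
#'
#' Evaluates the standard unimodal rhodopsin/porphyropsin alpha-band
#' template of the vision literature (Govardovskii-type), parameterised by
#' the peak wavelength and the chromophore class. A1 pigments use
#' 11-cis-retinal, A2 pigments 11-cis-3-dehydroretinal; for the same opsin
#' the A2 template peaks at a longer wavelength and is broader. The shape
#' is a function of `x = wavelength / lambda_max` only, so it is invariant
#' under rescaling of the wavelength axis relative to the peak.
#'
#' @param wavelength Numeric vector of wavelengths (nm).
#' @param lambda_max Peak absorbance wavelength (nm).
#' @param chromophore `"A1"` or `"A2"`.
#' @return Numeric vector of relative absorbance (peak approximately 1).
#' @export
pigment_template <- function(wavelength, lambda_max, chromophore = c("A1", "A2")) {
  chromophore <- match.arg(chromophore)
  x <- wavelength / lambda_max
  if (chromophore == "A1") {
    a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
    A <- 69.7; B <- 28; b <- 0.922; C <- -14.9; cc <- 1.104; D <- 0.674
  } else {
    a <- 0.875 + 0.0268 * exp((lambda_max - 665) / 40.7)
    A <- 62.7 + 1.834 * exp((lambda_max - 625) / 54.2)
    B <- 20.85; b <- 0.9101; C <- -10.37; cc <- 1.1123; D <- 0.5343
  }
  1 / (exp(A * (a - x)) + exp(B * (b - x)) + exp(C * (cc - x)) + D)
}

#' Parameters for the absorbance spectrum simulator
#'
#' @param lambda_max_a1,lambda_max_a2 Peak wavelengths (nm) of the pure A1
#'   and A2 pigments of one opsin allele; the A2 peak must be at the longer
#'   wavelength (the A2 chromophore red-shifts absorption).
#' @param a2_fraction Mixing fraction phi in [0, 1] of the A2 pigment.
#' @param noise_sd Gaussian noise standard deviation (absorbance units,
#'   relative to a peak of 1).
#' @param wavelength_grid Evaluation grid (nm); the default 350-750 nm at
#'   1 nm spans all opsin peaks considered with margin for the curve
#'   shoulders.
#' @param seed Integer seed.
#' @return Object of class `sim_spectrum_params`.
#' @export
sim_spectrum_params <- function(lambda_max_a1 = 503, lambda_max_a2 = 523,
                                a2_fraction = 0.5, noise_sd = 0,
                                wavelength_grid = 350:750, seed = 1L) {
  if (lambda_max_a2 <= lambda_max_a1) {
    stop("lambda_max_a2 must exceed lambda_max_a1 (A2 pigments are red-shifted)")
  }
  if (a2_fraction < 0 || a2_fraction > 1) stop("a2_fraction must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (min(wavelength_grid) > lambda_max_a1 || max(wavelength_grid) < lambda_max_a2) {
    stop("wavelength grid does not bracket both peak wavelengths")
  }
  structure(list(lambda_max_a1 = lambda_max_a1, lambda_max_a2 = lambda_max_a2,
                 a2_fraction = a2_fraction, noise_sd = noise_sd,
                 wavelength_grid = wavelength_grid, seed = as.integer(seed)),
            class = "sim_spectrum_params")
}

#' Simulate a (possibly mixed-chromophore) absorbance spectrum
#'
#' Returns `(1 - phi) * template_A1 + phi * template_A2` evaluated on the
#' grid, normalised so the noiseless peak is 1, plus Gaussian noise.
#'
#' @param params A [sim_spectrum_params()] object.
#' @return A [spectrum_curve()].
#' @export
simulate_spectrum <- function(params) {
  stopifnot(inherits(params, "sim_spectrum_params"))
  set.seed(params$seed)
  wl <- params$wavelength_grid
  phi <- params$a2_fraction
  mix <- (1 - phi) * pigment_template(wl, params$lambda_max_a1, "A1") +
    phi * pigment_template(wl, params$lambda_max_a2, "A2")
  mix <- mix / max(mix)
  if (params$noise_sd > 0) mix <- mix + stats::rnorm(length(wl), 0, params$noise_sd)
  spectrum_curve(wl, mix, label = sprintf("phi=%.2f", phi))
}

#' Dark-minus-bleached difference spectrum
#'
#' Isolates the photolabile pigment as the pointwise difference between the
#' dark (unbleached) and photobleached absorbance curves. Curves on
#' different grids are linearly interpolated onto the overlap of the two
#' grids.
#'
#' @param dark,bleached [spectrum_curve()] objects.
#' @return A [spectrum_curve()] of the difference.
#' @export
difference_spectrum <- function(dark, bleached) {
  lo <- max(min(dark$wavelength), min(bleached$wavelength))
  hi <- min(max(dark$wavelength), max(bleached$wavelength))
  if (lo >= hi) stop("wavelength grids do not overlap")
  wl <- sort(unique(c(dark$wavelength[dark$wavelength >= lo & dark$wavelength <= hi],
                      bleached$wavelength[bleached$wavelength >= lo & bleached$wavelength <= hi])))
  d <- stats::approx(dark$wavelength, dark$absorbance, xout = wl)$y
  b <- stats::approx(bleached$wavelength, bleached$absorbance, xout = wl)$y
  spectrum_curve(wl, d - b, label = "difference")
}

# Quadratic-vertex peak location for one curve; window_nm is the full width
# of the fit window around the grid argmax.
.peak_vertex <- function(wavelength, absorbance, window_nm = 20) {
  i0 <- which.max(absorbance)
  if (i0 == 1L || i0 == length(absorbance)) {
    stop("peak lies on the grid boundary; not bracketed")
  }
  sel <- abs(wavelength - wavelength[i0]) <= window_nm / 2
  if (sum(sel) < 3L) sel <- seq.int(max(1L, i0 - 1L), min(length(absorbance), i0 + 1L))
  x <- wavelength[sel] - wavelength[i0]
  y <- absorbance[sel]
  fit <- stats::lm.fit(cbind(1, x, x^2), y)
  co <- fit$coefficients
  if (!is.finite(co[3L]) || co[3L] >= 0) return(wavelength[i0])
  vertex <- -co[2L] / (2 * co[3L])
  wavelength[i0] + max(min(vertex, window_nm / 2), -window_nm / 2)
}

#' Estimate the peak absorbance wavelength with a standard error
#'
#' For each replicate curve the peak is located as the vertex of a
#' quadratic fitted to the points within half the window width of the grid
#' argmax (robust to 1 nm grid quantisation); the mean and standard error
#' of the mean across replicate curves are reported, as done for repeated
#' spectrophotometric measurements of one pigment preparation.
#'
#' @param curves A [spectrum_curve()] or list of them.
#' @param window_nm Full width (nm) of the quadratic fit window.
#' @return List of class `lambda_max_estimate`: `lambda_max` (mean, nm),
#'   `se` (nm; 0 for a single curve), `per_curve`.
#' @export
estimate_lambda_max <- function(curves, window_nm = 20) {
  if (inherits(curves, "spectrum_curve")) curves <- list(curves)
  if (!length(curves)) stop("need at least one curve")
  per <- vapply(curves, function(cv) {
    .peak_vertex(cv$wavelength, cv$absorbance, window_nm)
  }, numeric(1L))
  se <- if (length(per) > 1L) stats::sd(per) / sqrt(length(per)) else 0
  structure(list(lambda_max = mean(per), se = se, per_curve = per),
            class = "lambda_max_estimate")
}

#' @export
print.lambda_max_estimate <- function(x, ...) {
  cat(sprintf("lambda_max = %.2f nm (SE %.3f nm, %d curve(s))\n",
              x$lambda_max, x$se, length(x$per_curve)))
  invisible(x)
}

#' Build a standard absorbance template from replicate curves
#'
#' Reproduces the construction of standard curves for A1 and A2 pigments:
#' each input curve is rescaled to unit peak absorbance and shifted so its
#' peak wavelength coincides with zero on a peak-relative grid, the curves
#' are averaged pointwise over the common grid, smoothed with a centred
#' moving average, re-centred, and re-normalised to unit peak.
#'
#' @param curves List of at least two [spectrum_curve()] objects.
#' @param smooth_window_nm Moving-average window (nm).
#' @param reference_lambda_max Peak wavelength recorded as the template's
#'   reference; defaults to the mean of the input peak estimates.
#' @return Object of class `standard_template` with `rel_wavelength`
#'   (nm relative to peak), `absorbance`, `lambda_max` (reference).
#' @export
build_standard_template <- function(curves, smooth_window_nm = 5,
                                    reference_lambda_max = NULL) {
  if (inherits(curves, "spectrum_curve")) curves <- list(curves)
  if (length(curves) < 2L) stop("need at least two curves to build a template")
  peaks <- vapply(curves, function(cv) {
    estimate_lambda_max(cv)$lambda_max
  }, numeric(1L))
  rel <- lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    list(x = cv$wavelength - peaks[i], y = cv$absorbance / max(cv$absorbance))
  })
  lo <- max(vapply(rel, function(r) min(r$x), numeric(1L)))
  hi <- min(vapply(rel, function(r) max(r$x), numeric(1L)))
  step <- min(vapply(curves, function(cv) min(diff(cv$wavelength)), numeric(1L)))
  grid <- seq(ceiling(lo), floor(hi), by = step)
  avg <- rowMeans(vapply(rel, function(r) {
    stats::approx(r$x, r$y, xout = grid)$y
  }, numeric(length(grid))))
  k <- max(1L, round(smooth_window_nm / step))
  if (k %% 2L == 0L) k <- k + 1L
  if (k > 1L) {
    sm <- stats::filter(avg, rep(1 / k, k), sides = 2L)
    avg[!is.na(sm)] <- sm[!is.na(sm)]
  }
  # re-centre so the smoothed peak sits exactly at 0
  v <- .peak_vertex(grid, avg, window_nm = 20)
  grid <- grid - v
  avg <- avg / max(avg)
  structure(list(rel_wavelength = grid, absorbance = avg,
                 lambda_max = if (is.null(reference_lambda_max)) mean(peaks) else reference_lambda_max),
            class = "standard_template")
}

#' Place a standard template at a target peak wavelength
#'
#' Translates the template along the wavelength axis so its peak sits at
#' the target (the identical curve with a different peak wavelength).
#'
#' @param template A `standard_template`.
#' @param target_lambda_max Target peak (nm).
#' @param wavelength_grid Output grid (nm); defaults to the template's
#'   support translated to the target.
#' @return A [spectrum_curve()].
#' @export
shift_template <- function(template, target_lambda_max, wavelength_grid = NULL) {
  stopifnot(inherits(template, "standard_template"))
  src <- template$rel_wavelength + target_lambda_max
  if (is.null(wavelength_grid)) {
    wl <- src
    y <- template$absorbance
  } else {
    wl <- wavelength_grid
    if (min(wl) < min(src) - 1e-9 || max(wl) > max(src) + 1e-9) {
      stop("target grid extends beyond the template's coverage")
    }
    y <- stats::approx(src, template$absorbance, xout = wl)$y
  }
  spectrum_curve(wl, y, label = sprintf("template@%.1fnm", target_lambda_max))
}

#' Estimate the A2 chromophore fraction by template mixture fitting
#'
#' A photoreceptor contains both A1 and A2 pigments of the same opsin, so a
#' microspectrophotometric absorbance curve is a mixture
#' `(1 - phi) * A1 + phi * A2` of the two pure templates. The fraction
#' `phi` is estimated by grid search (step `phi_step`): in `"peak-match"`
#' mode the mixture's peak wavelength is matched to the observed peak
#' wavelength; in `"curve-match"` mode the full unit-peak curves are
#' matched by least squares.
#'
#' @param observed A [spectrum_curve()] (either mode) or a single observed
#'   peak wavelength in nm (`"peak-match"` only).
#' @param template_a1,template_a2 Pure-chromophore template curves
#'   ([spectrum_curve()]) on a common grid, e.g. from [shift_template()].
#' @param mode `"peak-match"` (default, as when matching a reported peak
#'   value) or `"curve-match"`.
#' @param phi_step Grid step for the searched A2 fraction.
#' @return Object of class `mixture_fit`: `a2_fraction`, `lambda_max`
#'   (fitted mixture peak, nm), `residual`, `mode`, and the searched
#'   profile.
#' @export
fit_a1_a2_mixture <- function(observed, template_a1, template_a2,
                              mode = c("peak-match", "curve-match"),
                              phi_step = 0.01) {
  mode <- match.arg(mode)
  if (!identical(template_a1$wavelength, template_a2$wavelength)) {
    wl <- sort(unique(c(template_a1$wavelength, template_a2$wavelength)))
    wl <- wl[wl >= max(min(template_a1$wavelength), min(template_a2$wavelength)) &
               wl <= min(max(template_a1$wavelength), max(template_a2$wavelength))]
    template_a1 <- spectrum_curve(wl, stats::approx(template_a1$wavelength,
                                                    template_a1$absorbance, wl)$y)
    template_a2 <- spectrum_curve(wl, stats::approx(template_a2$wavelength,
                                                    template_a2$absorbance, wl)$y)
  }
  wl <- template_a1$wavelength
  t1 <- template_a1$absorbance / max(template_a1$absorbance)
  t2 <- template_a2$absorbance / max(template_a2$absorbance)
  lm1 <- .peak_vertex(wl, t1)
  lm2 <- .peak_vertex(wl, t2)
  if (lm2 <= lm1) stop("template peak wavelengths must be distinct (A2 > A1)")
  phis <- seq(0, 1, by = phi_step)
  mix_peak <- function(phi) {
    m <- (1 - phi) * t1 + phi * t2
    .peak_vertex(wl, m)
  }
  if (mode == "peak-match") {
    obs_lm <- if (inherits(observed, "spectrum_curve") || is.data.frame(observed)) {
      estimate_lambda_max(spectrum_curve(observed$wavelength, observed$absorbance))$lambda_max
    } else {
      as.numeric(observed)
    }
    clamped <- FALSE
    if (obs_lm < lm1 || obs_lm > lm2) {
      warning("observed peak wavelength outside the template interval; clamping")
      obs_lm <- min(max(obs_lm, lm1), lm2)
      clamped <- TRUE
    }
    peaks <- vapply(phis, mix_peak, numeric(1L))
    crit <- abs(peaks - obs_lm)
    best <- which.min(crit)
    fit_lm <- peaks[best]
  } else {
    if (!(inherits(observed, "spectrum_curve") || is.data.frame(observed))) {
      stop("curve-match mode needs an observed spectrum curve")
    }
    obs_y <- stats::approx(observed$wavelength, observed$absorbance, xout = wl)$y
    if (anyNA(obs_y)) {
      keep <- !is.na(obs_y)
      if (sum(keep) < 10L) stop("observed curve barely overlaps the templates")
      wl_fit <- wl[keep]; obs_y <- obs_y[keep]
      t1f <- t1[keep]; t2f <- t2[keep]
    } else {
      wl_fit <- wl; t1f <- t1; t2f <- t2
    }
    obs_y <- obs_y / max(obs_y)
    crit <- vapply(phis, function(phi) {
      m <- (1 - phi) * t1f + phi * t2f
      m <- m / max(m)
      sum((m - obs_y)^2)
    }, numeric(1L))
    best <- which.min(crit)
    fit_lm <- mix_peak(phis[best])
    clamped <- FALSE
  }
  structure(list(a2_fraction = phis[best], lambda_max = fit_lm,
                 residual = crit[best], mode = mode, clamped = clamped,
                 profile = data.frame(phi = phis, criterion = crit)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("A1/A2 mixture fit (%s): A2 fraction = %.2f (%.0f%%), mixture peak = %.1f nm\n",
              x$mode, x$a2_fraction, 100 * x$a2_fraction, x$lambda_max))
  if (isTRUE(x$clamped)) cat("  note: observed peak was outside the template interval\n")
  invisible(x)
}

#' Read / write two-column spectrum CSV files
#'
#' @param path CSV file with columns `wavelength_nm` (or `wavelength`) and
#'   `absorbance`.
#' @return A [spectrum_curve()].
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  wl_col <- intersect(c("wavelength_nm", "wavelength"), names(d))[1L]
  if (is.na(wl_col)) stop("no wavelength column found in ", path)
  spectrum_curve(d[[wl_col]], d$absorbance, label = basename(path))
}

#' @rdname read_spectrum_csv
#' @param curve A [spectrum_curve()] to write.
#' @export
write_spectrum_csv <- function(curve, path) {
  utils::write.csv(data.frame(wavelength_nm = curve$wavelength,
                              absorbance = curve$absorbance),
                   path, row.names = FALSE)
  invisible(path)
}
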