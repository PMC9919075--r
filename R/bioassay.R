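#' Two-fold broth-microdilution series (mg/mL)
#'
#' The nine-well dilution series used for MIC determination, from 3.12 down
#' to 0.0125 mg/mL. Shipped as a constant because it is a rounded two-fold
#' series whose printed rounding cannot be recomputed from a rule.
#' @export
mic_dilution_series <- c(3.12, 1.56, 0.78, 0.39, 0.20,
                         0.10, 0.05, 0.025, 0.0125)

#' Enzyme inhibition rate from an absorbance quadruple
#'
#' Computes `[1 - (Asa - Asc) / (Aea - Aec)] * 100`, where `Asa` is the
#' sample group (enzyme + sample + substrate), `Asc` the sample control
#' (sample + buffer), `Aea` the enzyme activity group (buffer + enzyme +
#' substrate) and `Aec` the enzyme blank (substrate + buffer). Negative
#' rates are legal (samples can interfere with the readout) and are not
#' clamped. Vectorized over replicates.
#'
#' @param asa,asc,aea,aec absorbances (finite; `aea - aec > 0`).
#' @return inhibition rate(s) in percent.
#' @export
inhibition_rate <- function(asa, asc, aea, aec) {
  vals <- c(asa, asc, aea, aec)
  if (!all(is.finite(vals))) stop("absorbances must be finite", call. = FALSE)
  if (any(aea - aec <= 0)) {
    stop("Aea - Aec <= 0: enzyme activity control shows no signal",
         call. = FALSE)
  }
  (1 - (asa - asc) / (aea - aec)) * 100
}

four_pl_curve <- function(conc, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + (ic50 / conc)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `rate = bottom + (top - bottom)/(1 + (ic50/c)^hill)`
#' with multi-start initialization: a grid over Hill slopes {0.5, 1, 2, 4}
#' and IC50 candidates at the observed concentration quantiles is screened
#' by residual sum of squares, and the best starts are refined by
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]). The reported IC50 is the
#' curve-midpoint parameter.
#'
#' A fit is declared degenerate (not converged) when the response carries no
#' dose information: all rates equal, or fewer than 3 rates above 10%
#' inhibition.
#'
#' @param concentrations positive concentrations (>= 4 distinct).
#' @param rates observed inhibition rates, percent.
#' @return object of class `four_pl_fit`: list with `bottom`, `top`,
#'   `ic50`, `hill`, `rss`, `converged`, and `reason` when degenerate.
#' @export
fit_four_pl <- function(concentrations, rates) {
  stopifnot(length(concentrations) == length(rates))
  if (!all(is.finite(concentrations)) || any(concentrations <= 0)) {
    stop("concentrations must be positive and finite", call. = FALSE)
  }
  if (!all(is.finite(rates))) stop("rates must be finite", call. = FALSE)
  if (length(unique(concentrations)) < 4) {
    stop("need >= 4 distinct concentrations to fit a 4PL curve",
         call. = FALSE)
  }
  degenerate <- function(reason) {
    structure(list(bottom = NA_real_, top = NA_real_, ic50 = NA_real_,
                   hill = NA_real_, rss = NA_real_, converged = FALSE,
                   reason = reason),
              class = "four_pl_fit")
  }
  if (stats::sd(rates) == 0) return(degenerate("flat response"))
  if (sum(rates > 10) < 3) return(degenerate("fewer than 3 rates above 10%"))

  lo <- min(rates); hi <- max(rates)
  ic50_grid <- unique(stats::quantile(concentrations,
                                      c(0.1, 0.25, 0.5, 0.75, 0.9),
                                      names = FALSE))
  starts <- expand.grid(hill = c(0.5, 1, 2, 4), ic50 = ic50_grid)
  starts$rss <- vapply(seq_len(nrow(starts)), function(i) {
    sum((rates - four_pl_curve(concentrations, lo, hi,
                               starts$ic50[i], starts$hill[i]))^2)
  }, numeric(1))
  starts <- starts[order(starts$rss), , drop = FALSE]

  best <- NULL
  for (i in seq_len(min(3L, nrow(starts)))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        rates ~ bottom + (top - bottom) / (1 + (ic50 / concentrations)^hill),
        start = list(bottom = lo, top = hi,
                     ic50 = starts$ic50[i], hill = starts$hill[i]),
        lower = c(bottom = -Inf, top = -Inf, ic50 = 1e-9, hill = 0.05),
        upper = c(bottom = Inf, top = Inf, ic50 = Inf, hill = 50),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
                   ic50 = unname(cf["ic50"]), hill = unname(cf["hill"]),
                   rss = rss)
    }
  }
  if (is.null(best)) return(degenerate("no optimizer start converged"))
  structure(c(best, list(converged = TRUE, reason = NA_character_)),
            class = "four_pl_fit")
}

#' Summarize replicate IC50 fits as mean +/- sd
#'
#' @param fits list of `four_pl_fit` objects (one per replicate).
#' @return list with `mean`, `sd` (n-1; NA for a single replicate),
#'   `n` (converged replicates) and `reason` when the endpoint is missing
#'   (no converged fit).
#' @export
summarize_ic50 <- function(fits) {
  stopifnot(length(fits) >= 1)
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) {
    return(list(mean = NA_real_, sd = NA_real_, n = 0L,
                reason = "no converged replicate fit"))
  }
  ic <- vapply(fits[ok], `[[`, numeric(1), "ic50")
  s <- mean_sd(ic)
  list(mean = s$mean, sd = s$sd, n = s$n,
       reason = if (s$n < 2) "single replicate: sd undefined" else NA_character_)
}

#' Read the MIC from a microdilution plate
#'
#' The MIC is the lowest concentration at which all wells at that
#' concentration and above show no growth (TTC indicator). Controls are
#' checked first (blank and negative must be clear, positive must grow), and
#' the growth pattern must be monotone along the dilution series; growth at
#' a concentration above a clear well is a plate error.
#'
#' Off-scale plates are censored: an all-growth plate gives `> max(series)`
#' (value NA), an all-clear plate gives the series minimum flagged as
#' censored below (the true MIC may be lower).
#'
#' @param plate a `mic_plate` (see [gen_mic_plate()]).
#' @return list with `mic` (mg/mL; NA when censored above), `censored`
#'   (`"none"`, `"above"`, `"below"`) and `label` (e.g. `">3.12"`,
#'   `"<=0.0125"`).
#' @export
read_mic <- function(plate) {
  stopifnot(inherits(plate, "mic_plate"),
            length(plate$growth) == length(plate$series),
            all(diff(plate$series) < 0))
  ctl <- plate$controls
  if (!isTRUE(ctl$positive) || isTRUE(ctl$negative) || isTRUE(ctl$blank)) {
    stop("control failure: positive control must grow, negative and blank must not",
         call. = FALSE)
  }
  g <- plate$growth
  # monotone check: no-growth block at high concentrations, growth below
  if (any(g)) {
    first_growth <- which(g)[1]
    offending <- which(!g & seq_along(g) > first_growth)
    if (length(offending)) {
      stop(sprintf(
        "non-monotone growth pattern: growth at %s mg/mL above clear well(s) at %s mg/mL",
        plate$series[first_growth],
        paste(plate$series[offending], collapse = ", ")), call. = FALSE)
    }
  }
  if (all(g)) {
    return(list(mic = NA_real_, censored = "above",
                label = sprintf(">%g", max(plate$series))))
  }
  if (!any(g)) {
    return(list(mic = min(plate$series), censored = "below",
                label = sprintf("<=%g", min(plate$series))))
  }
  mic <- plate$series[max(which(!g))]
  list(mic = mic, censored = "none", label = sprintf("%g", mic))
}

#' Summarize replicate inhibition-zone diameters
#'
#' @param diameters replicate zone diameters in mm (>= 2 values).
#' @return list with `mean`, `sd` (n-1) and `label` formatted as
#'   `"9.60 +/- 0.53"` style (two decimals, Unicode plus-minus).
#' @export
zone_summary <- function(diameters) {
  stopifnot(length(diameters) >= 2, all(is.finite(diameters)))
  s <- mean_sd(diameters)
  list(mean = s$mean, sd = s$sd,
       label = sprintf("%.2f ± %.2f", s$mean, s$sd))
}

#' Assemble endpoint summaries into an activity table
#'
#' Builds the per-sample bioactivity table consumed by the gray relational
#' and PLS stages. Each endpoint carries a direction: zone diameters are
#' `higher_is_active`, IC50 endpoints `lower_is_active`. Samples missing an
#' endpoint (e.g. an IC50 that never converged) are NA and masked
#' downstream.
#'
#' @param endpoints named list; each element a list with `values` (named
#'   numeric, names = sample ids) and `direction`
#'   (`"higher_is_active"` or `"lower_is_active"`).
#' @return object of class `activity_table`: list with `sample_ids`,
#'   `values` (samples x endpoints matrix, NA = missing) and `direction`
#'   (named character).
#' @export
build_activity_table <- function(endpoints) {
  stopifnot(is.list(endpoints))
  if (length(endpoints) == 0) {
    return(structure(list(sample_ids = character(),
                          values = matrix(numeric(), 0, 0),
                          direction = character()),
                     class = "activity_table"))
  }
  if (is.null(names(endpoints)) || any(names(endpoints) == "")) {
    stop("endpoints must be a named list", call. = FALSE)
  }
  ids <- sort(unique(unlist(lapply(endpoints, function(e) names(e$values)))))
  if (length(ids) == 0) stop("endpoint values must be named by sample id",
                             call. = FALSE)
  vals <- matrix(NA_real_, length(ids), length(endpoints),
                 dimnames = list(ids, names(endpoints)))
  dir <- character(length(endpoints))
  names(dir) <- names(endpoints)
  for (e in names(endpoints)) {
    ep <- endpoints[[e]]
    if (!ep$direction %in% c("higher_is_active", "lower_is_active")) {
      stop(sprintf("endpoint '%s': unknown direction '%s'", e, ep$direction),
           call. = FALSE)
    }
    if (anyDuplicated(names(ep$values))) {
      dup <- names(ep$values)[duplicated(names(ep$values))]
      v <- split(unname(ep$values), names(ep$values))
      if (any(vapply(v, function(x) length(unique(x)) > 1, logical(1)))) {
        stop(sprintf("endpoint '%s': conflicting duplicate entries for %s",
                     e, paste(unique(dup), collapse = ", ")), call. = FALSE)
      }
      ep$values <- ep$values[!duplicated(names(ep$values))]
    }
    vals[names(ep$values), e] <- ep$values
    dir[e] <- ep$direction
  }
  structure(list(sample_ids = ids, values = vals, direction = dir),
            class = "activity_table")
}

#' @export
print.activity_table <- function(x, ...) {
  cat(sprintf("activity_table: %d samples x %d endpoints (%d missing values)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
print.four_pl_fit <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf("4PL fit: IC50 = %.4g, hill = %.3g, range [%.3g, %.3g], rss = %.3g\n",
                x$ic50, x$hill, x$bottom, x$top, x$rss))
  } else {
    cat(sprintf("4PL fit: not converged (%s)\n", x$reason))
  }
  invisible(x)
}
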