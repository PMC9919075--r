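#' Match a sample peak list against reference retention times
#'
#' Assigns each characteristic (reference) peak the nearest sample peak
#' within a retention-time window. Candidate (reference, sample) pairs with
#' |delta rt| <= window are taken greedily by ascending |delta rt| (ties
#' broken toward the earlier-eluting reference peak); each sample peak is
#' used at most once. Reference peaks with no candidate left are marked
#' missing (NA area).
#'
#' If two reference peaks lie closer than twice the window, an ambiguity
#' warning is recorded in the report (a single sample peak could plausibly
#' match either).
#'
#' @param reference strictly increasing reference retention times (minutes),
#'   or a peak-list data frame with column `rt_min`.
#' @param sample data frame with columns `rt_min` and `area` (one sample's
#'   peak list; `sample_id` column optional).
#' @param window maximal |delta rt| for a match, minutes (> 0).
#' @return list with `areas` (one value per reference peak, NA = missing),
#'   `rt_dev` (signed rt deviation of each match), and `report`, a one-row
#'   data frame with counts `matched`, `missing` and flag `ambiguous`.
#' @export
match_peaks <- function(reference, sample, window = 0.2) {
  if (is.data.frame(reference)) reference <- reference$rt_min
  stopifnot(window > 0, all(diff(reference) > 0),
            is.data.frame(sample), all(c("rt_min", "area") %in% names(sample)))
  nr <- length(reference)
  ambiguous <- any(diff(reference) < 2 * window)
  if (ambiguous) {
    warning("reference peaks closer than 2*window: ambiguous assignments possible",
            call. = FALSE)
  }
  cand <- expand.grid(ref = seq_len(nr), smp = seq_len(nrow(sample)))
  cand$d <- abs(reference[cand$ref] - sample$rt_min[cand$smp])
  cand <- cand[cand$d <= window, , drop = FALSE]
  cand <- cand[order(cand$d, reference[cand$ref]), , drop = FALSE]
  areas <- rep(NA_real_, nr)
  rt_dev <- rep(NA_real_, nr)
  used_ref <- logical(nr)
  used_smp <- logical(nrow(sample))
  for (i in seq_len(nrow(cand))) {
    r <- cand$ref[i]; s <- cand$smp[i]
    if (!used_ref[r] && !used_smp[s]) {
      used_ref[r] <- TRUE
      used_smp[s] <- TRUE
      areas[r] <- sample$area[s]
      rt_dev[r] <- sample$rt_min[s] - reference[r]
    }
  }
  sid <- if ("sample_id" %in% names(sample) && nrow(sample) > 0) {
    as.character(sample$sample_id[1])
  } else NA_character_
  list(
    areas = areas, rt_dev = rt_dev,
    report = data.frame(sample_id = sid, matched = sum(used_ref),
                        missing = sum(!used_ref), ambiguous = ambiguous)
  )
}

#' Assemble matched peak lists into a characteristic-peak matrix
#'
#' Runs [match_peaks()] for every sample and stacks the matched area vectors
#' into a samples x peaks matrix (class `peak_matrix`). Missing matches are
#' NA until [apply_area_floor()] replaces them.
#'
#' @param samples list of per-sample peak-list data frames
#'   (`sample_id`, `rt_min`, `area`).
#' @param reference_rts strictly increasing reference retention times.
#' @param window matching window, minutes.
#' @return object of class `peak_matrix`: list with `areas` (matrix),
#'   `reference_rts`, `normalized` flag, `floor_value`, and `match_report`
#'   (one row per sample, columns `matched + missing = n peaks`).
#' @export
build_peak_matrix <- function(samples, reference_rts, window = 0.2) {
  stopifnot(is.list(samples), length(samples) >= 1)
  res <- lapply(samples, function(s) {
    suppressWarnings(match_peaks(reference_rts, s, window))
  })
  ambiguous <- any(diff(reference_rts) < 2 * window)
  if (ambiguous) {
    warning("reference peaks closer than 2*window: ambiguous assignments possible",
            call. = FALSE)
  }
  areas <- do.call(rbind, lapply(res, `[[`, "areas"))
  ids <- vapply(seq_along(samples), function(i) {
    sid <- res[[i]]$report$sample_id
    if (is.na(sid)) sprintf("S%d", i) else sid
  }, character(1))
  dimnames(areas) <- list(ids, sprintf("P%d", seq_along(reference_rts)))
  report <- do.call(rbind, lapply(res, `[[`, "report"))
  report$sample_id <- ids
  structure(
    list(areas = areas, reference_rts = reference_rts, normalized = FALSE,
         floor_value = NA_real_, n_floored = 0L, match_report = report),
    class = "peak_matrix"
  )
}

#' Refine reference retention times by the median of matched times
#'
#' One anchor pass matches every sample against the initial reference; the
#' reference is then replaced by the per-peak median of the matched
#' retention times, and a final matching pass is run against the refined
#' reference. This gives a robust consensus reference when no single sample
#' is authoritative.
#'
#' @inheritParams build_peak_matrix
#' @param initial_rts initial (anchor) reference retention times.
#' @return list with `reference_rts` (refined) and `matrix` (the
#'   `peak_matrix` from the final pass).
#' @export
refine_reference <- function(samples, initial_rts, window = 0.2) {
  pass1 <- suppressWarnings(
    lapply(samples, function(s) match_peaks(initial_rts, s, window))
  )
  dev <- do.call(rbind, lapply(pass1, `[[`, "rt_dev"))
  med_dev <- apply(dev, 2, stats::median, na.rm = TRUE)
  med_dev[!is.finite(med_dev)] <- 0
  refined <- initial_rts + med_dev
  if (any(diff(refined) <= 0)) {
    warning("refined reference rts no longer increasing; keeping anchor rts",
            call. = FALSE)
    refined <- initial_rts
  }
  list(reference_rts = refined,
       matrix = build_peak_matrix(samples, refined, window))
}

#' Replace missing or zero peak areas with a detection floor
#'
#' Undetected characteristic peaks (NA after matching, or zero) are set to a
#' small positive floor before normalization, so every sample has a complete
#' positive area vector.
#'
#' @param matrix a `peak_matrix`.
#' @param floor positive replacement value (default 0.01).
#' @return the `peak_matrix` with floored areas and `n_floored` updated.
#' @export
apply_area_floor <- function(matrix, floor = 0.01) {
  stopifnot(inherits(matrix, "peak_matrix"), floor > 0)
  if (isTRUE(matrix$normalized)) {
    stop("apply the area floor before normalization", call. = FALSE)
  }
  miss <- is.na(matrix$areas) | matrix$areas == 0
  matrix$areas[miss] <- floor
  matrix$floor_value <- floor
  matrix$n_floored <- matrix$n_floored + sum(miss)
  matrix
}

#' Normalize each sample's areas to its total
#'
#' Divides each row by its total area so that samples become comparable
#' compositions. The default denominator is the total over the matched
#' characteristic peaks; alternatively a supplied per-sample total (e.g. the
#' full-chromatogram area) can be used.
#'
#' @param matrix a `peak_matrix` with no missing entries (apply the floor
#'   first).
#' @param denominator `"characteristic_total"` (row sum over the
#'   characteristic peaks) or `"supplied_total"`.
#' @param supplied_totals per-sample totals when
#'   `denominator = "supplied_total"`.
#' @return the normalized `peak_matrix` (rows sum to 1 under the
#'   characteristic-total denominator).
#' @export
normalize_rows <- function(matrix,
                           denominator = c("characteristic_total",
                                           "supplied_total"),
                           supplied_totals = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(matrix, "peak_matrix"))
  if (anyNA(matrix$areas)) {
    stop("matrix has missing entries; apply_area_floor() first", call. = FALSE)
  }
  den <- if (denominator == "characteristic_total") {
    rowSums(matrix$areas)
  } else {
    stopifnot(!is.null(supplied_totals),
              length(supplied_totals) == nrow(matrix$areas))
    supplied_totals
  }
  bad <- which(den == 0)
  if (length(bad)) {
    stop(sprintf("zero normalization denominator for sample(s): %s",
                 paste(rownames(matrix$areas)[bad], collapse = ", ")),
         call. = FALSE)
  }
  matrix$areas <- matrix$areas / den
  matrix$normalized <- TRUE
  matrix
}

#' Relative standard deviation of replicate peak matrices
#'
#' Method-validation summary: for each (sample, peak) cell, the RSD (%) of
#' the replicate values, `100 * sd / mean` with the n-1 standard deviation;
#' per peak, the worst (maximum) cell RSD and a pass flag at the threshold.
#'
#' @param replicate_matrices list of >= 2 `peak_matrix` objects (or bare
#'   matrices) of identical shape.
#' @param threshold pass threshold in percent (default 5).
#' @return list with `rsd_matrix` (samples x peaks, NA where the replicate
#'   mean is zero), `per_peak` (max RSD per peak), `pass` (logical per
#'   peak: RSD strictly below threshold), `undefined` (peaks with any
#'   zero-mean cell), `threshold`.
#' @export
compute_rsd <- function(replicate_matrices, threshold = 5) {
  stopifnot(length(replicate_matrices) >= 2)
  mats <- lapply(replicate_matrices, function(m) {
    if (inherits(m, "peak_matrix")) m$areas else as.matrix(m)
  })
  dims <- unique(lapply(mats, dim))
  if (length(dims) != 1) stop("replicates have differing shapes", call. = FALSE)
  arr <- simplify2array(mats)
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  rsd <- ifelse(mu == 0, NA_real_, 100 * sdv / abs(mu))
  per_peak <- apply(rsd, 2, function(x) {
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  })
  list(rsd_matrix = rsd, per_peak = per_peak,
       pass = !is.na(per_peak) & per_peak < threshold,
       undefined = colnames(mu)[apply(is.na(rsd), 2, any)],
       threshold = threshold)
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("peak_matrix: %d samples x %d peaks (%s%s)\n",
              nrow(x$areas), ncol(x$areas),
              if (x$normalized) "row-normalized" else "raw areas",
              if (!is.na(x$floor_value))
                sprintf(", floor %g on %d entries", x$floor_value, x$n_floored)
              else ""))
  invisible(x)
}
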