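#' Ground truth for a synthetic fingerprint study
#'
#' Defines the latent structure a synthetic spectrum-effect study is built
#' from: reference retention times for the characteristic peaks, a strictly
#' positive true peak-area matrix (extracts x peaks), the subset of peaks
#' that actually drive bioactivity, and their effect weights on the
#' row-normalized areas.
#'
#' Areas are drawn log-normally: characteristic peaks are, by construction,
#' all major constituents, so peak-specific medians span about one order of
#' magnitude and share a common between-extract log-sd (default 0.25, giving
#' area dispersion commensurate with the relative spread typical of
#' endpoint panels such as inhibition-zone tables). The active peaks
#' co-vary through a shared latent factor (`congener_cor`, the pairwise
#' log-area correlation): putative active constituents nominated by
#' spectrum-effect screens are typically chemical congeners from one
#' biosynthetic family, whose abundances rise and fall together across
#' extracts of different polarity. Effect weights are the reciprocal
#' dispersion of each active peak's normalized area, rescaled to unit mean
#' contribution, so every planted constituent carries equal signal.
#'
#' @param n_samples number of extracts (default 10).
#' @param n_peaks number of characteristic peaks (default 20).
#' @param n_active number of peaks carrying a planted activity effect.
#' @param seed integer seed; the truth object and everything generated from
#'   it are pure functions of the parameters and this seed.
#' @param rt_range retention-time span in minutes for the reference peaks.
#' @param sdlog between-extract log-sd of true areas.
#' @param abundance_range range of median peak areas (arbitrary units).
#' @param congener_cor pairwise correlation of the active peaks' log areas.
#' @return An object of class `fingerprint_truth`: a list with
#'   `n_samples`, `n_peaks`, `reference_rts` (strictly increasing, minutes),
#'   `true_area_matrix`, `active_index_set`, `effect_weights` (named by
#'   active peak), and `seed`.
#' @export
gen_fingerprint_truth <- function(n_samples = 10, n_peaks = 20, n_active = 3,
                                  seed = 1, rt_range = c(1, 52), sdlog = 0.25,
                                  abundance_range = c(20, 200),
                                  congener_cor = 0.9) {
  stopifnot(n_samples >= 2, n_peaks >= 2, n_active >= 1, n_active <= n_peaks,
            congener_cor >= 0, congener_cor < 1)
  with_seed(substream_seed(seed, 11), {
    gaps <- stats::runif(n_peaks, 1.2, 4)
    rts <- rt_range[1] + cumsum(gaps)
    rts <- rt_range[1] + (rts - min(rts)) / (max(rts) - min(rts)) *
      diff(rt_range)
    stopifnot(all(diff(rts) > 0))
    meanlog <- stats::runif(n_peaks, log(abundance_range[1]),
                            log(abundance_range[2]))
    active <- sort(sample.int(n_peaks, n_active))
    # shared latent factor makes the active congeners co-vary
    lam <- sqrt(congener_cor)
    f <- stats::rnorm(n_samples)
    z <- matrix(stats::rnorm(n_samples * n_peaks), n_samples, n_peaks)
    z[, active] <- lam * f + sqrt(1 - lam^2) * z[, active, drop = FALSE]
    areas <- exp(sweep(z * sdlog, 2, meanlog, "+"))
    dimnames(areas) <- list(sprintf("S%d", seq_len(n_samples)),
                            sprintf("P%d", seq_len(n_peaks)))
    norm <- areas / rowSums(areas)
    w <- 1 / apply(norm, 2, stats::sd)[active]
    w <- w * n_active / sum(w * colMeans(norm)[active])
    structure(
      list(n_samples = n_samples, n_peaks = n_peaks,
           reference_rts = round(rts, 3), true_area_matrix = areas,
           active_index_set = active, effect_weights = w, seed = seed),
      class = "fingerprint_truth"
    )
  })
}

#' Latent potency of each sample under a fingerprint truth
#'
#' The noiseless latent potency is the weighted sum of the active peaks'
#' row-normalized areas.
#'
#' @param truth a `fingerprint_truth`.
#' @return numeric vector, one value per sample.
#' @export
latent_potency <- function(truth) {
  stopifnot(inherits(truth, "fingerprint_truth"))
  norm <- truth$true_area_matrix / rowSums(truth$true_area_matrix)
  drop(norm[, truth$active_index_set, drop = FALSE] %*% truth$effect_weights)
}

#' Generate per-sample peak tables from a fingerprint truth
#'
#' Each sample's peak list carries the true areas at retention times jittered
#' by Gaussian noise; peaks are independently dropped (undetected) with a
#' given probability. Deterministic for a fixed truth.
#'
#' @param truth a `fingerprint_truth`.
#' @param rt_jitter_sd Gaussian sd of retention-time jitter, minutes (>= 0).
#' @param dropout_prob probability a peak is missing from a sample's table.
#' @return list of data frames (one per sample) with columns `sample_id`,
#'   `rt_min`, `area`, ordered by retention time.
#' @export
gen_peak_tables <- function(truth, rt_jitter_sd = 0.02, dropout_prob = 0) {
  stopifnot(inherits(truth, "fingerprint_truth"),
            rt_jitter_sd >= 0, dropout_prob >= 0, dropout_prob < 1)
  with_seed(substream_seed(truth$seed, 23), {
    lapply(seq_len(truth$n_samples), function(s) {
      rt <- truth$reference_rts +
        stats::rnorm(truth$n_peaks, 0, rt_jitter_sd)
      keep <- stats::runif(truth$n_peaks) >= dropout_prob
      d <- data.frame(
        sample_id = rownames(truth$true_area_matrix)[s],
        rt_min = rt[keep],
        area = truth$true_area_matrix[s, keep],
        row.names = NULL
      )
      d[order(d$rt_min), , drop = FALSE]
    })
  })
}

#' Generate a bioactivity endpoint from a fingerprint truth
#'
#' Realizes one activity endpoint from the latent potency
#' \eqn{u_s = \sum_{j \in active} w_j x^{norm}_{sj} + N(0, noise\_sd)}.
#' A `zone` endpoint (inhibition-zone diameter, mm) is an increasing affine
#' function of potency, `base + scale * u`; an `ic50` endpoint is the
#' decreasing link `scale / (u + offset)` so that more potent samples have
#' smaller IC50.
#'
#' @param truth a `fingerprint_truth`.
#' @param noise_sd Gaussian sd of the potency noise (>= 0).
#' @param endpoint_kind `"zone"` or `"ic50"`.
#' @param base,scale,offset link parameters. `scale` defaults to 2 mm per
#'   potency unit for zones and 300 ug/mL for the ic50 link, giving zone
#'   diameters in the 7--18 mm range and IC50 values of order 100 ug/mL for
#'   the default truth.
#' @param stream_offset integer distinguishing independent endpoint draws
#'   from the same truth.
#' @return list with `values` (named per sample), `potency` (noiseless
#'   latent potency), `potency_realized` (with noise), `endpoint_kind`.
#' @export
gen_activity <- function(truth, noise_sd = 0,
                         endpoint_kind = c("zone", "ic50"),
                         base = 6, scale = NULL, offset = 0.5,
                         stream_offset = 0) {
  endpoint_kind <- match.arg(endpoint_kind)
  stopifnot(inherits(truth, "fingerprint_truth"), noise_sd >= 0)
  if (is.null(scale)) scale <- if (endpoint_kind == "zone") 2 else 300
  u0 <- latent_potency(truth)
  u <- with_seed(substream_seed(truth$seed, 37 + stream_offset),
                 u0 + stats::rnorm(length(u0), 0, noise_sd))
  if (endpoint_kind == "zone") {
    v <- base + scale * u
  } else {
    if (any(u + offset <= 0)) {
      stop("nonpositive potency under the ic50 link: u + offset <= 0",
           call. = FALSE)
    }
    v <- scale / (u + offset)
  }
  names(v) <- rownames(truth$true_area_matrix)
  list(values = v, potency = u0, potency_realized = u,
       endpoint_kind = endpoint_kind)
}

#' Generate four-parameter logistic dose-response records
#'
#' Inhibition at concentration c follows
#' `bottom + (top - bottom) / (1 + (ic50 / c)^hill)` plus Gaussian noise,
#' with replicate structure.
#'
#' @param ic50 true half-maximal concentration (> 0).
#' @param hill Hill slope (> 0).
#' @param bottom,top lower/upper asymptotes, percent (`top > bottom`).
#' @param concentrations positive concentration series.
#' @param noise_sd Gaussian noise sd in percent inhibition.
#' @param replicates replicates per concentration.
#' @param seed integer seed.
#' @return data frame with columns `concentration`, `replicate`,
#'   `inhibition`.
#' @export
gen_dose_response <- function(ic50, hill = 1, bottom = 0, top = 100,
                              concentrations, noise_sd = 0, replicates = 3,
                              seed = 1) {
  stopifnot(ic50 > 0, hill > 0, top > bottom, all(concentrations > 0),
            replicates >= 1)
  conc <- rep(concentrations, each = replicates)
  mu <- bottom + (top - bottom) / (1 + (ic50 / conc)^hill)
  y <- with_seed(substream_seed(seed, 53),
                 mu + stats::rnorm(length(mu), 0, noise_sd))
  data.frame(concentration = conc,
             replicate = rep(seq_len(replicates), times = length(concentrations)),
             inhibition = y)
}

#' Generate a broth-microdilution plate with a known MIC
#'
#' Wells at concentrations at or above the true MIC show no growth; wells
#' below it show growth. A true MIC above the series maximum yields an
#' all-growth plate; at or below the series minimum, an all-clear plate.
#'
#' @param true_mic true minimum inhibitory concentration (mg/mL).
#' @param series strictly decreasing concentration series; defaults to the
#'   two-fold dilution series [mic_dilution_series].
#' @return object of class `mic_plate`: list with `series`, `growth`
#'   (logical per well) and `controls` (blank/negative no growth, positive
#'   growth).
#' @export
gen_mic_plate <- function(true_mic, series = mic_dilution_series) {
  stopifnot(true_mic > 0, all(diff(series) < 0))
  structure(
    list(series = series, growth = series < true_mic,
         controls = list(blank = FALSE, negative = FALSE, positive = TRUE)),
    class = "mic_plate"
  )
}

#' Generate a synthetic annotation universe with one planted enriched term
#'
#' Builds an identifier universe, a term-to-member map with one term whose
#' overlap with the study set is planted exactly, and the study set itself.
#' All remaining terms are uniform random subsets of the universe.
#'
#' @param seed integer seed.
#' @param universe_size number of identifiers in the universe.
#' @param n_terms number of annotation terms (the planted term is `T01`).
#' @param planted_term_size size of the planted term.
#' @param study_size size of the study set.
#' @param planted_overlap exact overlap between the planted term and the
#'   study set (`<= min(planted_term_size, study_size)`).
#' @param term_size_range size range for the non-planted terms.
#' @return list with `universe` (character), `terms` (named list of
#'   character vectors), `study` (character), `planted_term` (`"T01"`).
#' @export
gen_target_data <- function(seed = 1, universe_size = 500, n_terms = 20,
                            planted_term_size = 40, study_size = 50,
                            planted_overlap = 25,
                            term_size_range = c(10, 60)) {
  if (planted_overlap > min(planted_term_size, study_size)) {
    stop("planted_overlap exceeds min(planted_term_size, study_size)",
         call. = FALSE)
  }
  if (max(planted_term_size, study_size, term_size_range) > universe_size) {
    stop("set sizes exceed universe_size", call. = FALSE)
  }
  with_seed(substream_seed(seed, 71), {
    universe <- sprintf("g%04d", seq_len(universe_size))
    planted <- sample(universe, planted_term_size)
    in_both <- sample(planted, planted_overlap)
    outside <- setdiff(universe, planted)
    study <- c(in_both, sample(outside, study_size - planted_overlap))
    terms <- vector("list", n_terms)
    names(terms) <- sprintf("T%02d", seq_len(n_terms))
    terms[[1L]] <- sort(planted)
    for (i in seq_len(n_terms)[-1L]) {
      sz <- sample(seq(term_size_range[1], term_size_range[2]), 1L)
      terms[[i]] <- sort(sample(universe, sz))
    }
    list(universe = universe, terms = terms, study = sort(study),
         planted_term = "T01")
  })
}

#' Write a complete synthetic demo dataset to a directory
#'
#' Emits the delimited-text inputs the pipeline reads: per-sample peak
#' tables, a zone-diameter activity table and an IC50 activity table, all
#' generated from one `fingerprint_truth`.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed driving every generator.
#' @param noise_frac activity noise as a fraction of the potency sd.
#' @return (invisibly) a list with the truth object and file paths.
#' @export
gen_demo_dataset <- function(dir, seed = 1, noise_frac = 0.1) {
  truth <- gen_fingerprint_truth(seed = seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- gen_peak_tables(truth, rt_jitter_sd = 0.02, dropout_prob = 0.05)
  peaks_path <- file.path(dir, "peak_tables.tsv")
  write_peak_tables(tabs, peaks_path)
  ns <- noise_frac * stats::sd(latent_potency(truth))
  zone <- gen_activity(truth, ns, "zone", stream_offset = 1)
  ic50 <- gen_activity(truth, ns, "ic50", stream_offset = 2)
  act <- build_activity_table(list(
    zone_demo = list(values = zone$values, direction = "higher_is_active"),
    ic50_demo = list(values = ic50$values, direction = "lower_is_active")
  ))
  act_path <- file.path(dir, "activity_table.tsv")
  write_activity_table(act, act_path)
  invisible(list(truth = truth, peak_tables = peaks_path,
                 activity_table = act_path))
}
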