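#' Build characteristic sequences from an activity table
#'
#' Converts each endpoint into a gray-relational characteristic sequence in
#' which larger values mean more active: zone-diameter endpoints pass
#' through unchanged, IC50 endpoints are transformed to their reciprocal.
#' Samples missing an endpoint are dropped from that sequence (recorded in
#' `dropped`).
#'
#' @param activity an `activity_table`.
#' @return named list of `char_sequence` objects, each a list with
#'   `endpoint`, `values` (named by sample), `transform`
#'   (`"identity"` or `"reciprocal"`) and `dropped` (sample ids removed for
#'   missingness).
#' @export
build_characteristic_sequences <- function(activity) {
  stopifnot(inherits(activity, "activity_table"))
  out <- lapply(colnames(activity$values), function(e) {
    v <- activity$values[, e]
    dropped <- names(v)[is.na(v)]
    v <- v[!is.na(v)]
    if (activity$direction[[e]] == "lower_is_active") {
      if (any(v == 0)) {
        stop(sprintf("endpoint '%s': IC50 of 0 has no reciprocal", e),
             call. = FALSE)
      }
      v <- 1 / v
      tr <- "reciprocal"
    } else {
      tr <- "identity"
    }
    structure(list(endpoint = e, values = v, transform = tr,
                   dropped = dropped),
              class = "char_sequence")
  })
  names(out) <- colnames(activity$values)
  out
}

#' Deng's gray relational degree of each peak against one endpoint
#'
#' Implements Deng's relational analysis between a characteristic sequence
#' `y0` (the bioactivity) and each peak's area subsequence: (1) each
#' sequence is normalized (default: divided by its own mean, making degrees
#' invariant to positive rescaling); (2) absolute deviations
#' `delta_i(k) = |y0(k) - x_i(k)|` are formed; (3) the global minimum and
#' maximum deviation over all peaks and samples are taken; (4) relational
#' coefficients `xi_i(k) = (dmin + rho * dmax) / (delta_i(k) + rho * dmax)`;
#' (5) the relational degree `r_i` is the mean coefficient over samples.
#' Peaks are ranked by descending degree, ties broken by ascending peak
#' index.
#'
#' @param y0 a `char_sequence` (or named numeric vector) for one endpoint.
#' @param X a `peak_matrix` (normalized) or samples x peaks matrix; rows are
#'   restricted to the samples present in `y0`.
#' @param rho resolution coefficient in (0, 1]; conventional default 0.5.
#' @param normalization `"mean"` (divide by sequence mean, default),
#'   `"initial"` (divide by first element) or `"none"`.
#' @return object of class `gra_result`: list with `endpoint`, `degree`
#'   (named per peak, in (0, 1]), `rank` (1 = highest degree), `rho`,
#'   `normalization` and `samples` used.
#' @export
gra_degree <- function(y0, X, rho = 0.5,
                       normalization = c("mean", "initial", "none")) {
  normalization <- match.arg(normalization)
  if (!(rho > 0 && rho <= 1)) stop("rho must be in (0, 1]", call. = FALSE)
  endpoint <- if (inherits(y0, "char_sequence")) y0$endpoint else "y0"
  yv <- if (inherits(y0, "char_sequence")) y0$values else y0
  M <- if (inherits(X, "peak_matrix")) X$areas else as.matrix(X)
  if (!is.null(names(yv)) && !is.null(rownames(M))) {
    missing_rows <- setdiff(names(yv), rownames(M))
    if (length(missing_rows)) {
      stop(sprintf("samples in y0 absent from X: %s",
                   paste(missing_rows, collapse = ", ")), call. = FALSE)
    }
    M <- M[names(yv), , drop = FALSE]
  }
  if (length(yv) < 3) stop("characteristic sequence needs >= 3 samples",
                           call. = FALSE)
  stopifnot(nrow(M) == length(yv), all(is.finite(yv)), all(is.finite(M)))

  norm_seq <- function(x) {
    switch(normalization,
      mean = {
        m <- mean(x)
        if (m == 0) stop("sequence mean is zero; cannot mean-normalize",
                         call. = FALSE)
        x / m
      },
      initial = {
        if (x[1] == 0) stop("first element is zero; cannot initial-normalize",
                            call. = FALSE)
        x / x[1]
      },
      none = x
    )
  }
  yn <- norm_seq(yv)
  Xn <- apply(M, 2, norm_seq)
  if (normalization == "mean" && stats::sd(yn) == 0) {
    stop("characteristic sequence is constant under mean normalization",
         call. = FALSE)
  }

  delta <- abs(Xn - yn)                      # samples x peaks
  dmin <- min(delta); dmax <- max(delta)
  if (dmax == 0) {
    warning("all sequences identical to y0: all relational degrees are 1",
            call. = FALSE)
    r <- rep(1, ncol(M))
  } else {
    xi <- (dmin + rho * dmax) / (delta + rho * dmax)
    r <- colMeans(xi)
  }
  names(r) <- colnames(M)
  rk <- rank(-r, ties.method = "first")
  structure(list(endpoint = endpoint, degree = r, rank = rk, rho = rho,
                 normalization = normalization, samples = rownames(M)),
            class = "gra_result")
}

#' Combine gray relational results into a wide degree/rank table
#'
#' One row per peak; for each endpoint a degree column (`cor.<endpoint>`)
#' and a rank column (`rank.<endpoint>`).
#'
#' @param results list of `gra_result` objects over the same peak set.
#' @return data frame with a `peak` column followed by per-endpoint degree
#'   and rank columns.
#' @export
rank_table <- function(results) {
  stopifnot(length(results) >= 1)
  peak_sets <- lapply(results, function(r) names(r$degree))
  if (length(unique(peak_sets)) != 1) {
    stop("gra results cover different peak sets", call. = FALSE)
  }
  out <- data.frame(peak = peak_sets[[1]], stringsAsFactors = FALSE)
  for (r in results) {
    out[[paste0("cor.", r$endpoint)]] <- unname(r$degree)
    out[[paste0("rank.", r$endpoint)]] <- unname(r$rank)
  }
  out
}

#' @export
print.gra_result <- function(x, ...) {
  top <- names(sort(x$rank))[seq_len(min(3, length(x$rank)))]
  cat(sprintf("gra_result [%s]: %d peaks, rho = %g, %s normalization; top: %s\n",
              x$endpoint, length(x$degree), x$rho, x$normalization,
              paste(top, collapse = ", ")))
  invisible(x)
}
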