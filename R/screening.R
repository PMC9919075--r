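#' Consensus screen for active peaks from GRA and PLS evidence
#'
#' Combines, per peak and endpoint, three pieces of evidence: a high gray
#' relational degree (`degree > gra_cut` OR `rank <= gra_top_k` -- both the
#' degree-threshold and top-rank readings of "highly correlated" are
#' encoded, OR-combined), a VIP above `vip_cut`, and a positive regression
#' coefficient (models are fit with activity oriented positive, see
#' [fit_endpoint_models()]). The consensus score counts the endpoints where
#' all three hold; a peak is called active when the score reaches
#' `min_endpoints`.
#'
#' @param gra named list of `gra_result` objects (one per endpoint).
#' @param pls named list of `pls_model` objects over the same endpoints and
#'   peaks.
#' @param gra_cut relational-degree threshold, in (0, 1] (default 0.8).
#' @param gra_top_k rank threshold (default 6).
#' @param vip_cut VIP threshold (default 1).
#' @param min_endpoints endpoints required for an active call (default: all
#'   shared endpoints).
#' @return object of class `screening_report`: data frame with one row per
#'   peak (`peak`, `score`, `mean_gra`, `active`), with the per-endpoint
#'   evidence flags in `attr(, "evidence")`.
#' @export
screen_active <- function(gra, pls, gra_cut = 0.8, gra_top_k = 6,
                          vip_cut = 1.0, min_endpoints = NULL) {
  if (!(gra_cut > 0 && gra_cut <= 1)) {
    stop("gra_cut must be in (0, 1]", call. = FALSE)
  }
  endpoints <- intersect(names(gra), names(pls))
  if (length(endpoints) == 0) {
    stop("gra and pls share no endpoints", call. = FALSE)
  }
  peaks <- names(gra[[endpoints[1]]]$degree)
  for (e in endpoints) {
    if (!identical(names(gra[[e]]$degree), peaks) ||
        !identical(names(pls[[e]]$vip), peaks)) {
      stop("gra and pls results cover different peak sets", call. = FALSE)
    }
  }
  if (is.null(min_endpoints)) min_endpoints <- length(endpoints)

  np <- length(peaks)
  gra_high <- vip_high <- pos_coef <- matrix(
    FALSE, np, length(endpoints), dimnames = list(peaks, endpoints))
  degs <- matrix(NA_real_, np, length(endpoints),
                 dimnames = list(peaks, endpoints))
  for (e in endpoints) {
    g <- gra[[e]]
    degs[, e] <- g$degree
    gra_high[, e] <- g$degree > gra_cut | g$rank <= gra_top_k
    vip_high[, e] <- pls[[e]]$vip > vip_cut
    pos_coef[, e] <- pls[[e]]$b > 0
  }
  all3 <- gra_high & vip_high & pos_coef
  score <- rowSums(all3)
  report <- data.frame(
    peak = peaks,
    score = score,
    mean_gra = rowMeans(degs),
    active = score >= min_endpoints,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(report, "evidence") <- list(gra_high = gra_high, vip_high = vip_high,
                                   positive_coef = pos_coef,
                                   degrees = degs)
  attr(report, "thresholds") <- list(gra_cut = gra_cut, gra_top_k = gra_top_k,
                                     vip_cut = vip_cut,
                                     min_endpoints = min_endpoints)
  class(report) <- c("screening_report", "data.frame")
  report
}

#' Order peaks by consensus evidence
#'
#' Descending consensus score, ties broken by descending mean gray
#' relational degree, then by peak index (input order).
#'
#' @param report a `screening_report`.
#' @return character vector of peak names, strongest evidence first.
#' @export
rank_consensus <- function(report) {
  stopifnot(inherits(report, "screening_report"))
  if (nrow(report) == 0) return(character())
  ord <- order(-report$score, -report$mean_gra, seq_len(nrow(report)))
  report$peak[ord]
}

#' @export
print.screening_report <- function(x, ...) {
  th <- attr(x, "thresholds")
  act <- x$peak[x$active]
  cat(sprintf(
    "screening_report: %d peaks, %d called active (gra > %g or top %d, VIP > %g, positive coefficient in >= %d endpoints)\n",
    nrow(x), length(act), th$gra_cut, th$gra_top_k, th$vip_cut,
    th$min_endpoints))
  if (length(act)) cat("active:", paste(act, collapse = ", "), "\n")
  invisible(x)
}
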