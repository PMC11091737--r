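# Probe pre-filtering ahead of clock training.
#
# Arrays applied across many species show a technical artifact: probes whose
# oligo does not align to the target genome pile up at intermediate
# methylation, turning the usual bimodal beta distribution (peaks near 0 and
# 1) trimodal with a peak near 0.5. The filters here remove such probes by
# mean methylation, by detection p-value, or by an explicit per-species
# mappability annotation.

probe_selection <- function(kept, removed, params = list()) {
  stopifnot(is.character(kept), is.character(removed) || length(removed) == 0)
  if (length(intersect(kept, names(removed)))) {
    stop("internal error: kept and removed overlap", call. = FALSE)
  }
  structure(list(kept = kept, removed = removed, params = params),
            class = "probe_selection")
}

#' @method print probe_selection
#' @export
print.probe_selection <- function(x, ...) {
  cat("<probe_selection> kept ", length(x$kept), ", removed ",
      length(x$removed), "\n", sep = "")
  invisible(x)
}

#' Middle filter: drop probes with mean beta near 0.5
#'
#' Removes probe p iff `lower <= mean(beta[p, ]) <= upper`, the mean taken
#' over non-missing samples. Probes with all values missing are removed with
#' reason `"all_missing"`. The default window [0.3, 0.7] is a pragmatic
#' reading of "approximately 0.5": wide enough to catch the non-mappable
#' artifact peak, narrow enough to spare genuinely intermediate biology.
#'
#' @param betas probes x samples beta matrix.
#' @param lower,upper window bounds, `0 <= lower < upper <= 1`.
#' @return a `probe_selection` (fields `kept`, `removed`, `params`).
#' @export
middle_filter <- function(betas, lower = 0.3, upper = 0.7) {
  if (!(is.numeric(lower) && is.numeric(upper) &&
        lower >= 0 && lower <= upper && upper <= 1)) {
    stop("invalid middle window: need 0 <= lower <= upper <= 1",
         call. = FALSE)
  }
  if (nrow(betas) == 0) {
    return(probe_selection(character(0), character(0),
                           list(lower = lower, upper = upper)))
  }
  validate_betas(betas)
  means <- rowMeans(betas, na.rm = TRUE)
  all_missing <- !is.finite(means)
  in_window <- !all_missing & means >= lower & means <= upper
  removed <- c(
    stats::setNames(rep("middle", sum(in_window)),
                    rownames(betas)[in_window]),
    stats::setNames(rep("all_missing", sum(all_missing)),
                    rownames(betas)[all_missing]))
  probe_selection(kept = rownames(betas)[!in_window & !all_missing],
                  removed = removed,
                  params = list(lower = lower, upper = upper))
}

#' Detection p-value filter
#'
#' Removes a probe iff the fraction of samples where its detection p-value
#' exceeds `p_threshold` is greater than `max_fail_fraction`. The default
#' `max_fail_fraction = 0` is the strictest reading — a single failing
#' sample removes the probe; real cohorts typically relax it.
#'
#' @param pvals probes x samples matrix of detection p-values in [0, 1].
#' @param p_threshold per-sample failure threshold (default 0.05).
#' @param max_fail_fraction tolerated fraction of failing samples
#'   (default 0).
#' @param betas optional beta matrix cross-checked for identical dimnames.
#' @return a `probe_selection`.
#' @export
detection_p_filter <- function(pvals, p_threshold = 0.05,
                               max_fail_fraction = 0, betas = NULL) {
  stopifnot(is.matrix(pvals), is.numeric(pvals))
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1))) {
    stop("detection p-values must lie in [0,1]", call. = FALSE)
  }
  if (!(p_threshold >= 0 && p_threshold <= 1 &&
        max_fail_fraction >= 0 && max_fail_fraction <= 1)) {
    stop("thresholds must lie in [0,1]", call. = FALSE)
  }
  if (!is.null(betas) &&
      (!identical(dim(pvals), dim(betas)) ||
       !identical(dimnames(pvals), dimnames(betas)))) {
    stop("detection p-value matrix does not match the beta matrix shape",
         call. = FALSE)
  }
  fail_frac <- rowMeans(pvals > p_threshold, na.rm = TRUE)
  out <- fail_frac > max_fail_fraction
  probe_selection(
    kept = rownames(pvals)[!out],
    removed = stats::setNames(
      sprintf("detection_p: %.3g of samples failed p > %g",
              fail_frac[out], p_threshold),
      rownames(pvals)[out]),
    params = list(p_threshold = p_threshold,
                  max_fail_fraction = max_fail_fraction))
}

#' Mappability filter
#'
#' Keeps only probes whose oligonucleotide sequence maps to the target
#' species' genome, per an externally supplied annotation (one probe id per
#' line in the CLI). Input order is preserved.
#'
#' @param probes character vector of probe ids.
#' @param annotation character vector (or set) of mappable probe ids.
#' @return a `probe_selection`.
#' @export
mappability_filter <- function(probes, annotation) {
  stopifnot(is.character(probes))
  annotation <- as.character(annotation)
  keep <- probes %in% annotation
  if (!any(keep) && length(probes) > 0) {
    warning("mappability annotation shares no probes with the input; ",
            "every probe removed — is the annotation for the right platform?",
            call. = FALSE)
  }
  probe_selection(
    kept = probes[keep],
    removed = stats::setNames(rep("not_mappable", sum(!keep)), probes[!keep]),
    params = list(n_annotation = length(annotation)))
}

#' Histogram diagnostic for the trimodal artifact
#'
#' Summarizes the distribution of per-probe mean betas: histogram counts
#' over [0, 1] plus the fraction of probes whose mean falls in the middle
#' window. A clearly non-zero middle fraction indicates non-mappable-probe
#' artifact (or a need for mappability filtering).
#'
#' @param betas probes x samples beta matrix.
#' @param bins number of histogram bins (>= 3).
#' @param lower,upper middle window used for the fraction.
#' @return list with `breaks`, `counts`, `middle_fraction`, `n_probes`.
#' @export
bimodality_report <- function(betas, bins = 20, lower = 0.3, upper = 0.7) {
  stopifnot(bins >= 3)
  if (nrow(betas) == 0) {
    return(list(breaks = seq(0, 1, length.out = bins + 1),
                counts = rep(0L, bins), middle_fraction = NA_real_,
                n_probes = 0L))
  }
  validate_betas(betas)
  means <- rowMeans(betas, na.rm = TRUE)
  means <- means[is.finite(means)]
  h <- graphics::hist(means, breaks = seq(0, 1, length.out = bins + 1),
                      plot = FALSE)
  list(breaks = h$breaks, counts = h$counts,
       middle_fraction = mean(means >= lower & means <= upper),
       n_probes = length(means))
}

# Subset a beta matrix to a probe selection's kept set (order preserved).
apply_selection <- function(betas, selection) {
  stopifnot(inherits(selection, "probe_selection"))
  betas[selection$kept, , drop = FALSE]
}
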