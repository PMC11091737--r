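# Epigenome-wide association of methylation with a numeric outcome
# (typically age), and fixed-weight Stouffer meta-analysis across strata
# such as species or tissue.

#' Per-probe correlation EWAS
#'
#' Correlates every CpG probe with a numeric outcome across samples.
#' Inference runs through the Fisher transform: `z = atanh(r) * sqrt(n-3)`,
#' two-sided p from the standard normal, and Benjamini-Hochberg q-values
#' over the non-NA probes. Probes with fewer than `min_n` pairwise-complete
#' observations are reported as NA.
#'
#' @param betas probes x samples beta matrix.
#' @param outcome numeric vector, one value per sample (aligned to the
#'   columns of `betas`, or named by sample id).
#' @param min_n minimum pairwise-complete sample count per probe
#'   (default 10).
#' @param method `"pearson"` (default) or `"bicor"` (biweight
#'   midcorrelation, robust to outlying betas); both share the Fisher-z
#'   inference path.
#' @param outcome_name label stored in the result.
#' @param stratum label stored in the result (used by [meta_ewas()]).
#' @return `data.frame` of class `ewas_result`: probe, stratum, n, r, z,
#'   p, q.
#' @export
ewas_correlate <- function(betas, outcome, min_n = 10,
                           method = c("pearson", "bicor"),
                           outcome_name = "outcome", stratum = "all") {
  method <- match.arg(method)
  validate_betas(betas)
  if (!is.null(names(outcome))) {
    outcome <- outcome[colnames(betas)]
  }
  if (length(outcome) != ncol(betas)) {
    stop("outcome length does not match number of samples", call. = FALSE)
  }
  if (stats::sd(outcome, na.rm = TRUE) == 0 || all(is.na(outcome))) {
    stop("outcome is constant; correlation undefined", call. = FALSE)
  }

  n_used <- rowSums(!is.na(betas) & !is.na(rep(outcome, each = nrow(betas))))
  r <- if (method == "pearson") {
    drop(stats::cor(t(betas), outcome, use = "pairwise.complete.obs"))
  } else {
    apply(betas, 1, function(b) bicor_pair(b, outcome))
  }
  r[n_used < min_n] <- NA_real_

  z <- atanh(pmin(pmax(r, -1), 1)) * sqrt(pmax(n_used - 3, 0))
  p <- 2 * stats::pnorm(-abs(z))
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")

  out <- data.frame(probe = rownames(betas), stratum = stratum,
                    n = as.integer(n_used), r = unname(r), z = unname(z),
                    p = unname(p), q = unname(q), stringsAsFactors = FALSE)
  attr(out, "outcome_name") <- outcome_name
  class(out) <- c("ewas_result", class(out))
  out
}

# Biweight midcorrelation of two vectors (pairwise complete). Falls back to
# Pearson when the MAD of either side is zero.
bicor_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(NA_real_)
  w <- function(v) {
    med <- stats::median(v)
    mad <- stats::median(abs(v - med))
    if (mad == 0) return(NULL)
    u <- (v - med) / (9 * mad)
    wt <- (1 - u^2)^2 * (abs(u) < 1)
    (v - med) * wt
  }
  a <- w(x); b <- w(y)
  if (is.null(a) || is.null(b)) return(stats::cor(x, y))
  denom <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  if (denom == 0) return(NA_real_)
  sum(a * b) / denom
}

#' Stouffer meta-analysis of EWAS results across strata
#'
#' Combines per-probe z statistics over strata:
#' `z_meta = sum(w_s * z_s) / sqrt(sum(w_s^2))` with weights `sqrt(n_s)`
#' (default) or equal. Probes are aligned by id over the union; strata
#' where a probe is NA simply do not contribute to it. p and BH q are
#' recomputed from `z_meta`.
#'
#' @param results list of >= 2 [ewas_correlate()] results.
#' @param weights `"sqrt_n"` (default) or `"equal"`.
#' @return `data.frame` of class `ewas_result`: probe, n_strata, z, p, q.
#' @export
meta_ewas <- function(results, weights = c("sqrt_n", "equal")) {
  weights <- match.arg(weights)
  stopifnot(is.list(results))
  if (length(results) < 2) {
    stop("meta-analysis needs at least 2 strata", call. = FALSE)
  }
  probes <- sort(unique(unlist(lapply(results, `[[`, "probe"))))
  num <- stats::setNames(rep(0, length(probes)), probes)
  den <- num
  n_strata <- stats::setNames(rep(0L, length(probes)), probes)
  for (res in results) {
    idx <- match(res$probe, probes)
    ok <- !is.na(res$z) & is.finite(res$z)
    w <- if (weights == "sqrt_n") sqrt(res$n) else rep(1, nrow(res))
    num[idx[ok]] <- num[idx[ok]] + w[ok] * res$z[ok]
    den[idx[ok]] <- den[idx[ok]] + w[ok]^2
    n_strata[idx[ok]] <- n_strata[idx[ok]] + 1L
  }
  all_na <- n_strata == 0L
  if (any(all_na)) {
    message("dropping ", sum(all_na), " probe(s) with no usable stratum")
  }
  probes <- probes[!all_na]
  z <- num[!all_na] / sqrt(den[!all_na])
  p <- 2 * stats::pnorm(-abs(z))
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(probe = probes, n_strata = n_strata[!all_na],
                    z = unname(z), p = unname(p), q = unname(q),
                    stringsAsFactors = FALSE)
  class(out) <- c("ewas_result", class(out))
  out
}
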