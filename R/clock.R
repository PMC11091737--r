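#' Clock definition
#'
#' A fitted (or loaded) epigenetic clock: an intercept and a sparse set of
#' per-CpG coefficients on the transformed-age scale, plus the transform
#' that maps chronological age to that scale (and back).
#'
#' @param clock_name character scalar.
#' @param intercept numeric scalar, transformed-age units.
#' @param coefficients named numeric vector (probe id -> coefficient).
#'   Zero-valued entries are dropped on construction.
#' @param transform a [transform_spec()]; defaults to identity.
#' @param provenance free-form list of metadata (alpha, lambda, seed, n, p,
#'   training set description, ...).
#' @return object of class `clock_definition`.
#' @export
clock_definition <- function(clock_name, intercept, coefficients = numeric(0),
                             transform = transform_spec("identity"),
                             provenance = list()) {
  stopifnot(is.character(clock_name), length(clock_name) == 1L,
            is.numeric(intercept), length(intercept) == 1L,
            is.finite(intercept),
            is.numeric(coefficients),
            inherits(transform, "transform_spec"))
  if (length(coefficients) > 0) {
    if (is.null(names(coefficients)) || anyNA(names(coefficients)) ||
        any(!nzchar(names(coefficients)))) {
      stop("coefficients must be named by probe id", call. = FALSE)
    }
    if (anyDuplicated(names(coefficients))) {
      stop("duplicate probe ids in coefficients", call. = FALSE)
    }
    if (any(!is.finite(coefficients))) {
      stop("non-finite coefficient values", call. = FALSE)
    }
    coefficients <- coefficients[coefficients != 0]
  }
  structure(list(clock_name = clock_name,
                 intercept = as.numeric(intercept),
                 coefficients = coefficients,
                 transform = transform,
                 provenance = provenance),
            class = "clock_definition")
}

#' @method print clock_definition
#' @export
print.clock_definition <- function(x, ...) {
  cat("<clock_definition> ", x$clock_name, "\n",
      "  intercept:    ", format(x$intercept), "\n",
      "  coefficients: ", length(x$coefficients), " CpG probes\n",
      "  transform:    ", x$transform$name, "\n", sep = "")
  invisible(x)
}

#' Linear predictor of a clock for one sample
#'
#' Computes intercept + sum of coefficient * beta over the clock's probes.
#' Under the default `strict` policy every clock probe must be present and
#' non-missing; under `drop_warn` absent or missing probes are dropped from
#' the sum and their count reported via a warning and the `n_missing`
#' attribute.
#'
#' @param sample_betas named numeric vector, probe id -> beta value.
#' @param clock a [clock_definition()].
#' @param missing_policy `"strict"` or `"drop_warn"`.
#' @return numeric scalar (transformed-age scale) with attribute `n_missing`.
#' @export
linear_predictor <- function(sample_betas, clock,
                             missing_policy = c("strict", "drop_warn")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(clock, "clock_definition"))
  probes <- names(clock$coefficients)
  vals <- sample_betas[probes]
  absent <- is.na(vals)
  if (any(absent)) {
    if (missing_policy == "strict") {
      stop("missing beta values for ", sum(absent), " clock probe(s): ",
           paste(utils::head(probes[absent], 5), collapse = ", "),
           " (use missing_policy='drop_warn' to drop them)", call. = FALSE)
    }
    warning(sum(absent), " clock probe(s) missing; dropped from the linear ",
            "predictor", call. = FALSE)
  }
  lp <- clock$intercept +
    sum(clock$coefficients[!absent] * vals[!absent])
  attr(lp, "n_missing") <- sum(absent)
  lp
}

#' Predict DNAm age for all samples of a beta matrix
#'
#' Applies a clock to every sample: computes the linear predictor on the
#' transformed-age scale, then maps it back to years through the clock's
#' inverse age transformation. Species-parameterized transforms resolve
#' their life-history parameters per sample via the sample sheet and the
#' species table; the identity transform needs neither.
#'
#' @param betas numeric probes x samples matrix (see [validate_betas()]).
#' @param clock a [clock_definition()].
#' @param sheet sample sheet `data.frame` with `sample_id` and `species`
#'   columns; may be `NULL` for species-free transforms.
#' @param species_table species characteristics `data.frame`
#'   (see [read_species_table()]); may be `NULL` for species-free transforms.
#' @param missing_policy `"strict"` (default) or `"drop_warn"`.
#' @return `data.frame` with columns `sample_id`, `linear_predictor`,
#'   `dnam_age` (years), in the column order of `betas`.
#' @export
predict_age <- function(betas, clock, sheet = NULL, species_table = NULL,
                        missing_policy = c("strict", "drop_warn")) {
  missing_policy <- match.arg(missing_policy)
  validate_betas(betas)
  stopifnot(inherits(clock, "clock_definition"))
  samples <- colnames(betas)

  probes <- names(clock$coefficients)
  if (length(probes) > 0) {
    present <- probes %in% rownames(betas)
    sub <- matrix(NA_real_, nrow = length(probes), ncol = length(samples),
                  dimnames = list(probes, samples))
    sub[present, ] <- betas[probes[present], , drop = FALSE]
    n_missing <- colSums(is.na(sub))
    if (any(n_missing > 0)) {
      if (missing_policy == "strict") {
        bad <- samples[n_missing > 0][1]
        stop("sample '", bad, "' is missing ", n_missing[[bad]],
             " clock probe(s) (strict policy); ",
             "use missing_policy='drop_warn' to drop them", call. = FALSE)
      }
      warning("dropped missing clock probes: ", sum(n_missing),
              " probe-sample pairs across ", sum(n_missing > 0),
              " sample(s)", call. = FALSE)
    }
    contrib <- sub * clock$coefficients
    lp <- clock$intercept + colSums(contrib, na.rm = TRUE)
  } else {
    lp <- rep(clock$intercept, length(samples))
    names(lp) <- samples
  }

  needs_species <- clock$transform$name != "identity" &&
    !all(c("L", "g", "m", "k") %in% names(clock$transform$params))
  if (clock$transform$name == "identity") {
    dnam_age <- inverse_transform_age(lp, clock$transform)
  } else if (!needs_species ||
             length(resolvable_without_species(clock$transform))) {
    # Try a species-free inverse first; fall back to per-sample resolution.
    dnam_age <- tryCatch(
      inverse_transform_age(lp, clock$transform),
      error = function(e) NULL)
    if (is.null(dnam_age)) {
      dnam_age <- per_sample_inverse(lp, clock$transform, samples, sheet,
                                     species_table)
    }
  } else {
    dnam_age <- per_sample_inverse(lp, clock$transform, samples, sheet,
                                   species_table)
  }

  data.frame(sample_id = samples,
             linear_predictor = unname(lp),
             dnam_age = unname(dnam_age),
             stringsAsFactors = FALSE)
}

resolvable_without_species <- function(spec) {
  need <- switch(spec$name,
    identity = character(0),
    log_linear = c("m"),
    relative_age = c("L", "g"),
    loglog_relative_age = c("L", "g"),
    relative_adult_age = c("L", "g", "m"))
  if (all(need %in% names(spec$params))) TRUE else character(0)
}

per_sample_inverse <- function(lp, spec, samples, sheet, species_table) {
  if (is.null(sheet) || is.null(species_table)) {
    stop("transform '", spec$name, "' needs species parameters: supply a ",
         "sample sheet and species table (or put L/g/m in the transform ",
         "params)", call. = FALSE)
  }
  validate_sheet(sheet, require_age = FALSE)
  sp_of <- sheet$species[match(samples, sheet$sample_id)]
  if (anyNA(sp_of)) {
    stop("sample(s) absent from sample sheet: ",
         paste(utils::head(samples[is.na(sp_of)], 5), collapse = ", "),
         call. = FALSE)
  }
  vapply(seq_along(samples), function(i) {
    inverse_transform_age(lp[[i]], spec, species_row(species_table, sp_of[i]))
  }, numeric(1))
}
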