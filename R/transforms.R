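#' Age-transformation specification
#'
#' An epigenetic clock regresses a transformed age F(y) on methylation beta
#' values; the transform is part of the clock definition and must be inverted
#' to report DNAm age in years. A `transform_spec` names one of the registered
#' transforms and optionally overrides life-history parameters that would
#' otherwise be resolved from the species table.
#'
#' Registered transforms (a = chronological age in years):
#' \describe{
#'   \item{identity}{F(a) = a.}
#'   \item{log_linear}{F(a) = log((a+k)/(m+k)) for a < m, (a-m)/(m+k) for
#'     a >= m, with m the age of sexual maturity and offset k (default 1
#'     year). Continuous with continuous first derivative at a = m.}
#'   \item{relative_age}{F(a) = (a+g)/(L+g) with L the maximum lifespan and
#'     g the gestation time; domain a > -g.}
#'   \item{loglog_relative_age}{F(a) = -log(-log(R)) with R = (a+g)/(L+g);
#'     domain R in (0, 1), i.e. -g < a < L.}
#'   \item{relative_adult_age}{log_linear applied on the relative-age scale:
#'     R = (a+g)/(L+g) with anchor m' = (m+g)/(L+g) and offset k' = k/(L+g)
#'     (k default 1 year).}
#' }
#'
#' @param name transform name, one of the registered names above.
#' @param params named list overriding species parameters: `L` (maximum
#'   lifespan, years), `g` (gestation, years), `m` (sexual maturity, years),
#'   `k` (log-linear offset, years, default 1), and logical `clamp` (default
#'   `FALSE`): when `TRUE`, relative ages R >= 1 are clamped to 1 - 1e-6
#'   instead of rejected.
#' @return an object of class `transform_spec`.
#' @export
transform_spec <- function(name = "identity", params = list()) {
  if (!is.character(name) || length(name) != 1L || !(name %in% TRANSFORM_NAMES)) {
    stop("unknown transform name: ", paste(name, collapse = ","),
         " (registered: ", paste(TRANSFORM_NAMES, collapse = ", "), ")",
         call. = FALSE)
  }
  stopifnot(is.list(params))
  structure(list(name = name, params = params), class = "transform_spec")
}

TRANSFORM_NAMES <- c("identity", "log_linear", "relative_age",
                     "loglog_relative_age", "relative_adult_age")

#' @method print transform_spec
#' @export
print.transform_spec <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste0(" (", paste(names(x$params), unlist(x$params), sep = "=",
                       collapse = ", "), ")")
  } else ""
  cat("<transform_spec> ", x$name, ps, "\n", sep = "")
  invisible(x)
}

# Resolve the parameters a transform needs, params overriding species values.
# `species` is a one-row data.frame/list with max_lifespan, gestation,
# sexual_maturity (any subset), or NULL.
resolve_transform_params <- function(spec, species = NULL) {
  get_par <- function(short, column, default = NULL) {
    if (!is.null(spec$params[[short]])) return(as.numeric(spec$params[[short]]))
    if (!is.null(species) && !is.null(species[[column]]) &&
        !is.na(species[[column]])) {
      return(as.numeric(species[[column]]))
    }
    if (!is.null(default)) return(default)
    stop("transform '", spec$name, "' needs parameter '", short,
         "' but it is neither in the spec params nor resolvable from the ",
         "species characteristics", call. = FALSE)
  }
  need <- switch(spec$name,
    identity            = character(0),
    log_linear          = c("m", "k"),
    relative_age        = c("L", "g"),
    loglog_relative_age = c("L", "g"),
    relative_adult_age  = c("L", "g", "m", "k"))
  out <- list()
  for (s in need) {
    out[[s]] <- switch(s,
      L = get_par("L", "max_lifespan"),
      g = get_par("g", "gestation"),
      m = get_par("m", "sexual_maturity"),
      k = get_par("k", "k_offset", default = 1))
  }
  out$clamp <- isTRUE(spec$params$clamp)
  out
}

# Relative age R = (a+g)/(L+g), with optional clamp of R >= 1.
rel_age <- function(age, L, g, clamp, require_lt1 = TRUE) {
  r <- (age + g) / (L + g)
  if (any(r <= 0)) {
    stop("age outside transform domain: relative age must be > 0 (age > -g); ",
         "offending age(s): ",
         paste(utils::head(age[r <= 0], 5), collapse = ", "), call. = FALSE)
  }
  if (require_lt1 && any(r >= 1)) {
    if (clamp) {
      r <- pmin(r, 1 - 1e-6)
    } else {
      stop("age outside transform domain: relative age reached 1 ",
           "(age >= maximum lifespan); offending age(s): ",
           paste(utils::head(age[r >= 1], 5), collapse = ", "),
           "; set clamp=TRUE in the transform params to clamp", call. = FALSE)
    }
  }
  r
}

log_linear_fwd <- function(a, m, k) {
  if (any(a + k <= 0)) {
    stop("age outside transform domain: need age > -k (k=", k, ")",
         call. = FALSE)
  }
  ifelse(a < m, log((a + k) / (m + k)), (a - m) / (m + k))
}

log_linear_inv <- function(x, m, k) {
  ifelse(x < 0, (m + k) * exp(x) - k, x * (m + k) + m)
}

#' Transform a chronological age
#'
#' Applies the forward transform F named by `spec` to `age`. Strictly
#' increasing on its domain; see [transform_spec()] for formulas and domains.
#'
#' @param age numeric vector of ages in years.
#' @param spec a [transform_spec()].
#' @param species optional one-row species record (list or data.frame row
#'   with `max_lifespan`, `gestation`, `sexual_maturity`) used to resolve
#'   parameters not given in `spec$params`.
#' @return numeric vector of transformed ages.
#' @export
transform_age <- function(age, spec, species = NULL) {
  stopifnot(inherits(spec, "transform_spec"), is.numeric(age))
  p <- resolve_transform_params(spec, species)
  switch(spec$name,
    identity = age,
    log_linear = {
      check_m_positive(p$m)
      log_linear_fwd(age, p$m, p$k)
    },
    relative_age = {
      check_L_positive(p$L)
      rel_age(age, p$L, p$g, p$clamp, require_lt1 = FALSE)
    },
    loglog_relative_age = {
      check_L_positive(p$L)
      r <- rel_age(age, p$L, p$g, p$clamp, require_lt1 = TRUE)
      -log(-log(r))
    },
    relative_adult_age = {
      check_L_positive(p$L)
      r <- rel_age(age, p$L, p$g, p$clamp, require_lt1 = FALSE)
      m_rel <- (p$m + p$g) / (p$L + p$g)
      k_rel <- p$k / (p$L + p$g)
      log_linear_fwd(r, m_rel, k_rel)
    })
}

#' Invert a transformed age back to years
#'
#' Exact closed-form inverse of each registered transform, so that
#' `inverse_transform_age(transform_age(a, s, sp), s, sp) == a` up to
#' floating-point error.
#'
#' @param x numeric vector of transformed ages (values in the image of F).
#' @inheritParams transform_age
#' @return numeric vector of ages in years.
#' @export
inverse_transform_age <- function(x, spec, species = NULL) {
  stopifnot(inherits(spec, "transform_spec"), is.numeric(x))
  p <- resolve_transform_params(spec, species)
  switch(spec$name,
    identity = x,
    log_linear = log_linear_inv(x, p$m, p$k),
    # The relative-age map is affine, so its inverse is total: a noisy
    # linear predictor slightly below 0 inverts to a (slightly negative)
    # DNAm age rather than erroring, matching how relative-age clocks are
    # reported in practice. Set clamp=TRUE to floor the relative age at 0.
    relative_age = {
      r <- if (p$clamp) pmax(x, 1e-6) else x
      r * (p$L + p$g) - p$g
    },
    loglog_relative_age = {
      r <- exp(-exp(-x))
      r * (p$L + p$g) - p$g
    },
    relative_adult_age = {
      m_rel <- (p$m + p$g) / (p$L + p$g)
      k_rel <- p$k / (p$L + p$g)
      r <- log_linear_inv(x, m_rel, k_rel)
      r * (p$L + p$g) - p$g
    })
}

check_L_positive <- function(L) {
  if (!is.finite(L) || L <= 0) stop("max_lifespan must be > 0", call. = FALSE)
}
check_m_positive <- function(m) {
  if (!is.finite(m) || m <= 0) stop("sexual_maturity must be > 0", call. = FALSE)
}
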