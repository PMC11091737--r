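#' Options for penalized clock fitting
#'
#' @param alpha elastic-net mixing parameter in [0, 1]; 1 is the LASSO,
#'   0 is ridge. Default 0.5.
#' @param n_folds folds for the internal cross-validation that selects
#'   lambda; >= 3. Default 10.
#' @param lambda_rule `"min"` (lambda minimizing mean CV error) or
#'   `"one_se"` (largest lambda within one standard error of that minimum).
#' @param seed integer seed controlling fold assignment; the global RNG
#'   stream is never touched.
#' @param standardize standardize predictors internally before fitting
#'   (coefficients are always returned on the original beta scale).
#' @param fold_by_species assign internal CV folds by species rather than at
#'   random (prevents within-species leakage in multi-species training).
#' @return object of class `fit_options`.
#' @export
fit_options <- function(alpha = 0.5, n_folds = 10,
                        lambda_rule = c("min", "one_se"),
                        seed = 1, standardize = TRUE,
                        fold_by_species = FALSE) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
            is.numeric(n_folds), n_folds >= 3,
            is.numeric(seed), length(seed) == 1L)
  structure(list(alpha = alpha, n_folds = as.integer(n_folds),
                 lambda_rule = lambda_rule, seed = as.integer(seed),
                 standardize = isTRUE(standardize),
                 fold_by_species = isTRUE(fold_by_species)),
            class = "fit_options")
}

# Log-spaced lambda path: 100 values from lambda_max (smallest lambda that
# zeroes every coefficient) down four orders of magnitude.
lambda_path <- function(X, y, alpha, standardize, n_lambda = 100,
                        min_ratio = 1e-4) {
  n <- nrow(X)
  yc <- y - mean(y)
  if (standardize) {
    sds <- sqrt(colMeans(X^2) - colMeans(X)^2)  # glmnet's 1/n convention
    sds[sds == 0] <- 1
    ip <- abs(crossprod(X, yc) / sds)
  } else {
    ip <- abs(crossprod(X, yc))
  }
  lambda_max <- max(ip) / n / max(alpha, 1e-3)
  if (!is.finite(lambda_max) || lambda_max <= 0) lambda_max <- 1
  exp(seq(log(lambda_max), log(lambda_max * min_ratio), length.out = n_lambda))
}

# glmnet refuses a single predictor; pad with an all-zero dummy column
# (zero variance => its coefficient is always 0) and strip it afterwards.
pad_single_column <- function(X) {
  if (ncol(X) >= 2) return(X)
  cbind(X, ".zero_pad." = 0)
}

#' Select the penalty strength by internal cross-validation
#'
#' Runs k-fold cross-validation over a log-spaced lambda path (100 values
#' from the smallest all-zero lambda down four orders of magnitude) and
#' returns the optimum under the requested rule. Fold assignment is drawn
#' from `opts$seed`, so the result is reproducible.
#'
#' @param X numeric samples x probes matrix, no missing values.
#' @param y numeric response (transformed ages), non-constant.
#' @param opts a [fit_options()].
#' @param species optional character vector (length `nrow(X)`) used when
#'   `opts$fold_by_species` is `TRUE`.
#' @return list with `lambda_opt`, `lambda_rule`, and `cv_curve`
#'   (`data.frame` of lambda, mean CV MSE, and its standard error).
#' @export
select_lambda <- function(X, y, opts = fit_options(), species = NULL) {
  stopifnot(is.matrix(X), is.numeric(y), nrow(X) == length(y))
  if (anyNA(X)) stop("X contains missing values; impute upstream", call. = FALSE)
  if (!all(is.finite(y))) stop("non-finite values in y", call. = FALSE)
  if (stats::sd(y) == 0) {
    stop("response y is constant; cannot select lambda", call. = FALSE)
  }
  n <- nrow(X)
  if (n < opts$n_folds) {
    stop("need at least n_folds (", opts$n_folds, ") samples, got ", n,
         call. = FALSE)
  }
  path <- lambda_path(X, y, opts$alpha, opts$standardize)
  if (opts$fold_by_species) {
    if (is.null(species)) {
      stop("fold_by_species=TRUE needs the species vector", call. = FALSE)
    }
    foldid <- as.integer(factor(species))
  } else {
    foldid <- with_local_seed(opts$seed,
                              sample(rep_len(seq_len(opts$n_folds), n)))
  }
  cvfit <- glmnet::cv.glmnet(pad_single_column(X), y, alpha = opts$alpha,
                             lambda = path, foldid = foldid,
                             standardize = opts$standardize,
                             family = "gaussian")
  lambda_opt <- if (opts$lambda_rule == "min") cvfit$lambda.min else
    cvfit$lambda.1se
  list(lambda_opt = lambda_opt,
       lambda_rule = opts$lambda_rule,
       cv_curve = data.frame(lambda = cvfit$lambda, cvm = cvfit$cvm,
                             cvsd = cvfit$cvsd))
}

#' Fit an elastic-net clock at a fixed penalty
#'
#' Minimizes `(1/2n) sum (y_i - b0 - x_i'b)^2 +
#' lambda * (alpha*|b|_1 + (1-alpha)/2*|b|_2^2)`. The solver is warm-started
#' along a path from the all-zero lambda down to the target, which makes the
#' fit both fast and deterministic. Only non-zero coefficients are stored.
#'
#' @inheritParams select_lambda
#' @param lambda penalty strength, >= 0 (0 gives the least-squares limit).
#' @param transform the [transform_spec()] recorded in the clock (the ages
#'   in `y` are assumed already transformed).
#' @param name clock name recorded in the definition.
#' @return a [clock_definition()]; provenance records alpha, lambda, seed,
#'   n, and p.
#' @export
fit_clock <- function(X, y, lambda, opts = fit_options(),
                      transform = transform_spec("identity"),
                      name = "unnamed_clock") {
  stopifnot(is.matrix(X), is.numeric(y), nrow(X) == length(y),
            is.numeric(lambda), length(lambda) == 1L, lambda >= 0)
  if (anyNA(X) || any(!is.finite(X))) {
    stop("non-finite values in X", call. = FALSE)
  }
  if (!all(is.finite(y))) stop("non-finite values in y", call. = FALSE)
  if (is.null(colnames(X))) {
    stop("X must carry probe ids as column names", call. = FALSE)
  }
  Xp <- pad_single_column(X)
  path <- lambda_path(X, y, opts$alpha, opts$standardize, n_lambda = 50)
  lambda_max <- path[1]
  if (lambda >= lambda_max) {
    lam_seq <- c(lambda_max * 1.01, lambda)
  } else if (lambda > 0) {
    lam_seq <- exp(seq(log(lambda_max), log(lambda), length.out = 50))
    lam_seq[length(lam_seq)] <- lambda
  } else {
    lam_seq <- c(exp(seq(log(lambda_max), log(lambda_max * 1e-4),
                         length.out = 49)), 0)
  }
  fit <- glmnet::glmnet(Xp, y, alpha = opts$alpha, lambda = lam_seq,
                        standardize = opts$standardize, family = "gaussian",
                        thresh = 1e-12, maxit = 10^6)
  cf <- as.matrix(stats::coef(fit, s = lambda, exact = FALSE))
  intercept <- cf["(Intercept)", 1]
  beta <- cf[-1, 1]
  beta <- beta[names(beta) != ".zero_pad."]
  beta <- beta[beta != 0]
  clock_definition(
    clock_name = name,
    intercept = intercept,
    coefficients = beta,
    transform = transform,
    provenance = list(alpha = opts$alpha, lambda = lambda, seed = opts$seed,
                      n = nrow(X), p = ncol(X),
                      lambda_rule = opts$lambda_rule,
                      standardize = opts$standardize))
}

# Transform the sheet's ages to the clock scale, resolving per-sample
# species parameters. Returns a numeric vector in sheet row order.
transform_ages <- function(sheet, transform, species_table = NULL) {
  if (transform$name == "identity") return(as.numeric(sheet$age))
  vapply(seq_len(nrow(sheet)), function(i) {
    sp <- if (!is.null(species_table)) {
      species_row(species_table, sheet$species[i])
    } else NULL
    transform_age(sheet$age[i], transform, sp)
  }, numeric(1))
}

# Mean-impute missing betas per probe (rows); warn when any probe needed
# more than `warn_fraction` of its values imputed.
impute_probe_means <- function(betas, warn_fraction = 0.2) {
  miss <- is.na(betas)
  if (!any(miss)) return(betas)
  frac <- rowMeans(miss)
  if (any(frac > warn_fraction)) {
    warning(sum(frac > warn_fraction), " probe(s) had more than ",
            round(100 * warn_fraction), "% of samples imputed; consider ",
            "removing them upstream", call. = FALSE)
  }
  means <- rowMeans(betas, na.rm = TRUE)
  means[is.nan(means)] <- 0.5  # all-missing probe: neutral fill
  idx <- which(miss, arr.ind = TRUE)
  betas[idx] <- means[idx[, 1]]
  betas
}

#' Build an epigenetic clock from a training cohort
#'
#' End-to-end training: transform ages, select lambda by internal
#' cross-validation, fit the elastic net at that lambda, and report
#' in-sample accuracy on the years scale. Probe pre-filtering is *not*
#' applied implicitly; filter the beta matrix first if desired.
#'
#' @param betas probes x samples beta matrix.
#' @param sheet sample sheet with `sample_id`, `age` (years), `species`.
#' @param species_table species characteristics table (may be `NULL` for
#'   species-free transforms).
#' @param transform a [transform_spec()].
#' @param opts a [fit_options()].
#' @param name clock name.
#' @return list with `clock` (a [clock_definition()]) and `training_report`
#'   (in-sample r and MAE in years, lambda selection summary).
#' @export
build_clock <- function(betas, sheet, species_table = NULL,
                        transform = transform_spec("identity"),
                        opts = fit_options(), name = "trained_clock") {
  validate_betas(betas)
  validate_sheet(sheet, betas)
  sheet <- sheet[match(colnames(betas), sheet$sample_id), , drop = FALSE]
  y <- transform_ages(sheet, transform, species_table)
  betas_imp <- impute_probe_means(betas)
  X <- t(betas_imp)
  sel <- select_lambda(X, y, opts, species = sheet$species)
  clock <- fit_clock(X, y, sel$lambda_opt, opts, transform, name)
  preds <- predict_age(betas_imp, clock, sheet, species_table)
  r <- stats::cor(preds$dnam_age, sheet$age)
  mae <- mean(abs(preds$dnam_age - sheet$age))
  list(clock = clock,
       training_report = list(
         transform = transform$name,
         lambda_opt = sel$lambda_opt,
         lambda_rule = sel$lambda_rule,
         n_nonzero = length(clock$coefficients),
         pearson_r = r,
         mae_years = mae,
         cv_curve = sel$cv_curve))
}
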