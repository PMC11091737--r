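#' Accuracy metrics for age predictions
#'
#' @param pred_ages predicted ages, years.
#' @param true_ages true chronological ages, years.
#' @return list with `pearson_r`, `mae_years`, `median_ae_years`.
#' @export
cv_metrics <- function(pred_ages, true_ages) {
  if (length(pred_ages) != length(true_ages)) {
    stop("pred_ages and true_ages differ in length", call. = FALSE)
  }
  if (length(pred_ages) < 2) stop("need at least 2 samples", call. = FALSE)
  r <- if (stats::sd(true_ages) == 0) NA_real_ else
    stats::cor(pred_ages, true_ages)
  list(pearson_r = r,
       mae_years = mean(abs(pred_ages - true_ages)),
       median_ae_years = stats::median(abs(pred_ages - true_ages)))
}

# Shared machinery for LOO / LOSO. `folds` is a named list mapping fold id
# to the sample ids held out in that fold. A single lambda (computed once on
# the full data) is reused for every fold unless per_fold_lambda = TRUE.
run_cv_folds <- function(betas, sheet, species_table, transform, opts,
                         folds, per_fold_lambda = FALSE) {
  # canonical sample order (sorted ids) so that results do not depend on
  # the column order of the input matrix
  orig_ids <- colnames(betas)
  betas <- betas[, order(colnames(betas)), drop = FALSE]
  sheet <- sheet[match(colnames(betas), sheet$sample_id), , drop = FALSE]
  y_all <- transform_ages(sheet, transform, species_table)
  X_all <- t(impute_probe_means(betas))

  lambda_opt <- NA_real_
  if (!per_fold_lambda) {
    sel <- select_lambda(X_all, y_all, opts, species = sheet$species)
    lambda_opt <- sel$lambda_opt
  }

  fold_clocks <- vector("list", length(folds))
  names(fold_clocks) <- names(folds)
  pred <- data.frame(sample_id = sheet$sample_id,
                     fold_id = NA_character_,
                     linear_predictor = NA_real_,
                     dnam_age = NA_real_,
                     true_age = sheet$age,
                     stringsAsFactors = FALSE)

  for (f in names(folds)) {
    test_ids <- folds[[f]]
    train <- !(sheet$sample_id %in% test_ids)
    # leakage check is a hard assertion, not merely a test
    stopifnot(sum(!train) == length(test_ids),
              !any(sheet$sample_id[train] %in% test_ids))
    y_tr <- y_all[train]
    if (stats::sd(y_tr) == 0) {
      stop("training ages are constant in fold '", f, "'", call. = FALSE)
    }
    lam <- if (per_fold_lambda) {
      select_lambda(X_all[train, , drop = FALSE], y_tr, opts,
                    species = sheet$species[train])$lambda_opt
    } else lambda_opt
    clk <- fit_clock(X_all[train, , drop = FALSE], y_tr, lam, opts,
                     transform, name = paste0("fold_", f))
    fold_clocks[[f]] <- clk
    p <- predict_age(betas[, test_ids, drop = FALSE], clk, sheet,
                     species_table)
    idx <- match(p$sample_id, pred$sample_id)
    pred$fold_id[idx] <- f
    pred$linear_predictor[idx] <- p$linear_predictor
    pred$dnam_age[idx] <- p$dnam_age
  }
  stopifnot(!anyNA(pred$fold_id))  # exactly one prediction per sample

  metrics <- cv_metrics(pred$dnam_age, pred$true_age)
  metrics$transformed_scale <- cv_metrics(pred$linear_predictor, y_all)
  pred <- pred[match(orig_ids, pred$sample_id), , drop = FALSE]
  rownames(pred) <- NULL
  structure(list(predictions = pred,
                 fold_clocks = fold_clocks,
                 metrics = metrics,
                 lambda = lambda_opt,
                 options = opts,
                 transform = transform),
            class = "cv_result")
}

#' @method print cv_result
#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", length(x$fold_clocks), " folds, ",
      nrow(x$predictions), " samples\n",
      "  pearson r: ", format(x$metrics$pearson_r, digits = 4), "\n",
      "  MAE:       ", format(x$metrics$mae_years, digits = 4), " years\n",
      sep = "")
  invisible(x)
}

#' Leave-one-out cross-validation of a clock
#'
#' For every sample: refit the clock on all other samples and predict the
#' held-out one. For efficiency the penalty lambda is selected once on the
#' full data and reused for every fold (optimal lambdas across folds
#' converge closely); set `per_fold_lambda = TRUE` to re-select per fold.
#' Each fold's coefficient table is archived in `fold_clocks`.
#'
#' @inheritParams build_clock
#' @param per_fold_lambda re-run the internal CV within each fold instead of
#'   reusing the full-data lambda.
#' @return a `cv_result`: per-sample predictions (years and transformed
#'   scale), the list of per-fold clocks, and pooled metrics.
#' @export
loo_estimate <- function(betas, sheet, species_table = NULL,
                         transform = transform_spec("identity"),
                         opts = fit_options(), per_fold_lambda = FALSE) {
  validate_betas(betas)
  validate_sheet(sheet, betas)
  if (ncol(betas) < opts$n_folds + 1) {
    stop("LOO needs at least n_folds + 1 samples", call. = FALSE)
  }
  ids <- colnames(betas)
  folds <- stats::setNames(as.list(ids), ids)
  run_cv_folds(betas, sheet, species_table, transform, opts, folds,
               per_fold_lambda)
}

#' Leave-one-species-out cross-validation of a clock
#'
#' One fold per species: all samples of that species are excluded from
#' training and predicted by a clock fitted on the remaining species. The
#' single-lambda shortcut of [loo_estimate()] applies here too. Per-species
#' metrics are reported alongside the pooled metrics.
#'
#' @inheritParams loo_estimate
#' @return a `cv_result` with an extra `per_species` metrics table.
#' @export
loso_estimate <- function(betas, sheet, species_table = NULL,
                          transform = transform_spec("identity"),
                          opts = fit_options(), per_fold_lambda = FALSE) {
  validate_betas(betas)
  validate_sheet(sheet, betas)
  sheet_o <- sheet[match(colnames(betas), sheet$sample_id), , drop = FALSE]

  no_species <- is.na(sheet_o$species) | !nzchar(as.character(sheet_o$species))
  if (any(no_species)) {
    warning("excluding ", sum(no_species), " sample(s) with missing species ",
            "from LOSO", call. = FALSE)
    keep <- sheet_o$sample_id[!no_species]
    betas <- betas[, keep, drop = FALSE]
    sheet_o <- sheet_o[!no_species, , drop = FALSE]
  }
  species <- unique(sheet_o$species)
  if (length(species) < 2) {
    stop("LOSO requires at least 2 species, found ", length(species),
         call. = FALSE)
  }
  folds <- lapply(species, function(s) sheet_o$sample_id[sheet_o$species == s])
  names(folds) <- species
  res <- run_cv_folds(betas, sheet_o, species_table, transform, opts, folds,
                      per_fold_lambda)
  per_sp <- do.call(rbind, lapply(species, function(s) {
    p <- res$predictions[res$predictions$fold_id == s, , drop = FALSE]
    m <- if (nrow(p) >= 2) cv_metrics(p$dnam_age, p$true_age) else
      list(pearson_r = NA_real_, mae_years = mean(abs(p$dnam_age - p$true_age)),
           median_ae_years = stats::median(abs(p$dnam_age - p$true_age)))
    data.frame(species = s, n = nrow(p), pearson_r = m$pearson_r,
               mae_years = m$mae_years, stringsAsFactors = FALSE)
  }))
  res$per_species <- per_sp
  res
}
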