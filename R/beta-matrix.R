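#' Validate a beta-value matrix
#'
#' Beta matrices are plain numeric matrices with CpG probes in rows and
#' samples in columns, dimnames required. Values are methylation fractions
#' in [0, 1]; `NA` is allowed. This validator is called by every function
#' that consumes betas; it rejects out-of-range values and duplicate ids.
#'
#' @param betas numeric matrix, probes x samples, with rownames (probe ids)
#'   and colnames (sample ids).
#' @param what label used in error messages.
#' @return the matrix, invisibly, after validation.
#' @export
validate_betas <- function(betas, what = "betas") {
  if (!is.matrix(betas) || !is.numeric(betas)) {
    stop(what, " must be a numeric matrix (probes x samples)", call. = FALSE)
  }
  if (is.null(rownames(betas)) || is.null(colnames(betas))) {
    stop(what, " must have rownames (probe ids) and colnames (sample ids)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(betas))) {
    stop(what, ": duplicate probe ids: ",
         paste(utils::head(unique(rownames(betas)[duplicated(rownames(betas))]), 5),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(betas))) {
    stop(what, ": duplicate sample ids: ",
         paste(utils::head(unique(colnames(betas)[duplicated(colnames(betas))]), 5),
               collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(betas) & (betas < 0 | betas > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    show <- utils::head(seq_len(nrow(bad)), 10)
    msg <- paste(sprintf("probe %s, sample %s, value %g",
                         rownames(betas)[bad[show, 1]],
                         colnames(betas)[bad[show, 2]],
                         betas[bad[show, , drop = FALSE]]),
                 collapse = "; ")
    stop(what, ": ", nrow(bad), " value(s) outside [0,1]: ", msg,
         call. = FALSE)
  }
  invisible(betas)
}

# Check a sample sheet against a beta matrix: same sample set, ages present.
validate_sheet <- function(sheet, betas = NULL, require_age = TRUE) {
  stopifnot(is.data.frame(sheet))
  need <- c("sample_id", if (require_age) "age", "species")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("sample sheet has duplicate sample_id values", call. = FALSE)
  }
  if (require_age && anyNA(sheet$age)) {
    stop("sample sheet has missing ages for sample(s): ",
         paste(utils::head(sheet$sample_id[is.na(sheet$age)], 5),
               collapse = ", "), call. = FALSE)
  }
  if (!is.null(betas)) {
    if (!setequal(sheet$sample_id, colnames(betas))) {
      stop("sample sheet ids do not match beta matrix sample ids",
           call. = FALSE)
    }
  }
  invisible(sheet)
}

# Look up one species row (as a list) in a species characteristics table.
species_row <- function(species_table, species) {
  key <- normalize_species_key(species)
  idx <- match(key, normalize_species_key(species_table$species))
  if (is.na(idx)) {
    stop("species '", species, "' not found in species table", call. = FALSE)
  }
  as.list(species_table[idx, , drop = FALSE])
}

normalize_species_key <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}
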