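# Readers and writers for the toolkit's table dialects: clock coefficient
# CSVs (with '#' metadata header lines), beta matrices, sample sheets,
# species characteristics tables (AnAge-style), and the bundled-clock
# registry. All readers reject malformed input with located errors rather
# than silently coercing.

# Column-name canonicalization maps (case-insensitive).
CLOCK_VAR_ALIASES <- c("var", "cpg", "probe", "probe_id", "cgid")
CLOCK_COEF_ALIASES <- c("coef", "beta", "coefficient", "weight")

match_alias <- function(cols, aliases, what, path) {
  hit <- which(tolower(cols) %in% aliases)
  if (length(hit) == 0) {
    stop(path, ": no ", what, " column (accepted names: ",
         paste(aliases, collapse = ", "), ")", call. = FALSE)
  }
  hit[1]
}

#' Read a clock coefficient file
#'
#' Clock files are CSVs with a probe-id column (`var`, also accepted:
#' `CpG`, `probe`) and a coefficient column (`coef`, also: `beta`), with
#' exactly one row whose id is the literal token `(Intercept)`. Metadata
#' travels in comment header lines: `# clock_name: ...`, `# transform:
#' <name>`, `# transform_params: L=10,g=0.5`. A file with no declared
#' transform defaults to identity with a warning.
#'
#' @param path file path.
#' @return a [clock_definition()].
#' @export
read_clock <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines)
  meta <- parse_clock_meta(lines[meta_lines])
  body <- lines[setdiff(seq_along(lines), meta_lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) {
    stop(path, ": no data rows", call. = FALSE)
  }
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  vcol <- match_alias(names(df), CLOCK_VAR_ALIASES, "probe-id", path)
  ccol <- match_alias(names(df), CLOCK_COEF_ALIASES, "coefficient", path)
  vars <- as.character(df[[vcol]])
  coefs_raw <- df[[ccol]]
  coefs <- suppressWarnings(as.numeric(coefs_raw))
  bad <- which(is.na(coefs) | !is.finite(coefs))
  if (length(bad)) {
    stop(path, ": unparseable coefficient(s) at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ": ",
         paste(utils::head(coefs_raw[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  is_int <- vars == "(Intercept)"
  if (sum(is_int) == 0) {
    stop(path, ": no (Intercept) row", call. = FALSE)
  }
  if (sum(is_int) > 1) {
    stop(path, ": multiple (Intercept) rows at data lines ",
         paste(which(is_int), collapse = ", "), call. = FALSE)
  }
  probes <- vars[!is_int]
  if (anyDuplicated(probes)) {
    dup <- unique(probes[duplicated(probes)])
    stop(path, ": duplicate probe id(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  cf <- stats::setNames(coefs[!is_int], probes)
  n_zero <- sum(cf == 0)
  if (n_zero > 0) {
    message(path, ": dropping ", n_zero, " zero coefficient(s)")
  }
  transform <- if (is.null(meta$transform)) {
    warning(path, ": no transform declared; defaulting to identity",
            call. = FALSE)
    transform_spec("identity")
  } else {
    transform_spec(meta$transform,
                   if (is.null(meta$transform_params)) list() else
                     meta$transform_params)
  }
  clock_definition(
    clock_name = if (is.null(meta$clock_name))
      tools::file_path_sans_ext(basename(path)) else meta$clock_name,
    intercept = coefs[is_int],
    coefficients = cf,
    transform = transform,
    provenance = list(source = path))
}

parse_clock_meta <- function(lines) {
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      key <- m[2]; val <- trimws(m[3])
      if (key == "transform_params") {
        kv <- strsplit(strsplit(val, ",")[[1]], "=")
        params <- lapply(kv, function(x) as.numeric(trimws(x[2])))
        names(params) <- vapply(kv, function(x) trimws(x[1]), character(1))
        meta$transform_params <- params
      } else {
        meta[[key]] <- val
      }
    }
  }
  meta
}

#' Write a clock coefficient file
#'
#' Emits the strict dialect read by [read_clock()]: metadata comment
#' header, then `var,coef` rows — intercept first, probes in lexicographic
#' order, floats at 17 significant digits for a bit-faithful round trip.
#'
#' @param clock a [clock_definition()].
#' @param path output file path.
#' @export
write_clock <- function(clock, path) {
  stopifnot(inherits(clock, "clock_definition"))
  meta <- c(paste0("# clock_name: ", clock$clock_name),
            paste0("# transform: ", clock$transform$name))
  params <- clock$transform$params
  params <- params[vapply(params, is.numeric, logical(1))]
  if (length(params)) {
    meta <- c(meta, paste0("# transform_params: ",
                           paste(names(params),
                                 vapply(params, function(v)
                                   sprintf("%.17g", v), character(1)),
                                 sep = "=", collapse = ",")))
  }
  cf <- clock$coefficients[order(names(clock$coefficients))]
  rows <- c("var,coef",
            sprintf("(Intercept),%.17g", clock$intercept),
            if (length(cf)) sprintf("%s,%.17g", names(cf), cf))
  writeLines(c(meta, rows), path)
  invisible(NULL)
}

#' Read a beta-value matrix from CSV/TSV
#'
#' First column holds row ids; the delimiter is sniffed by `data.table`.
#' Values must be in [0, 1] or missing (empty, `NA`, `NaN`,
#' case-insensitive); out-of-range values are errors listing up to 10
#' offenders. Orientation is normalized internally to probes x samples.
#'
#' @param path file path.
#' @param orientation `"probes_in_rows"` (default) or `"samples_in_rows"`.
#' @return numeric probes x samples matrix.
#' @export
read_beta_matrix <- function(path, orientation = c("probes_in_rows",
                                                   "samples_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, na.strings = c("", "NA",
                          "NaN", "na", "nan"), data.table = FALSE)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids)) {
    stop(path, ": duplicate row ids: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad_cols <- names(dt)[-1][!vapply(dt[-1], is.numeric, logical(1))]
    stop(path, ": non-numeric column(s): ",
         paste(utils::head(bad_cols, 5), collapse = ", "), call. = FALSE)
  }
  rownames(m) <- ids
  if (orientation == "samples_in_rows") m <- t(m)
  validate_betas(m, what = path)
  m
}

#' Write a beta matrix (probes x samples CSV)
#'
#' @param betas probes x samples matrix.
#' @param path output path.
#' @export
write_beta_matrix <- function(betas, path) {
  validate_betas(betas)
  # 17 significant digits => the written text re-parses to the same double
  chr <- matrix(sprintf("%.17g", betas), nrow = nrow(betas),
                dimnames = dimnames(betas))
  chr[is.na(betas)] <- NA_character_
  df <- data.frame(probe_id = rownames(betas), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, quote = FALSE)
  invisible(NULL)
}

SHEET_ALIASES <- list(
  sample_id = c("sample_id", "sampleid", "basename", "id", "sample"),
  age = c("age", "age_years", "chronological_age"),
  species = c("species", "specieslatinname", "latin_name"),
  tissue = c("tissue", "tissue_type"))

SPECIES_ALIASES <- list(
  species = c("species", "specieslatinname", "latin_name"),
  max_lifespan = c("max_lifespan", "maxagecaped", "maximum_lifespan",
                   "maxlifespan", "maxage"),
  gestation = c("gestation", "gestation_years", "gestationyears",
                "gestation_time"),
  sexual_maturity = c("sexual_maturity", "averagedmaturity",
                      "averagedmaturity.yrs", "age_of_sexual_maturity",
                      "maturity"))

canonicalize_columns <- function(df, aliases, required, path) {
  out <- df
  for (canon in names(aliases)) {
    hit <- which(tolower(names(out)) %in% aliases[[canon]])
    if (length(hit) > 0) names(out)[hit[1]] <- canon
  }
  miss <- setdiff(required, names(out))
  if (length(miss)) {
    stop(path, ": missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a sample sheet
#'
#' CSV with header; column names are matched case-insensitively against a
#' canonicalization map (`SampleID`/`Basename` -> `sample_id`, `Age` ->
#' `age`, ...). Ages are years. Extra columns pass through untouched.
#'
#' @param path file path.
#' @param required canonical column names that must be present.
#' @return `data.frame` with canonical columns `sample_id`, `age`,
#'   `species` (and whatever else the file carries).
#' @export
read_sample_sheet <- function(path,
                              required = c("sample_id", "age", "species")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  df <- canonicalize_columns(df, SHEET_ALIASES, required, path)
  df$sample_id <- as.character(df$sample_id)
  if ("age" %in% names(df)) {
    age_num <- suppressWarnings(as.numeric(df$age))
    bad <- which(!is.na(df$age) & is.na(age_num))
    if (length(bad)) {
      stop(path, ": non-numeric age at data line(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    df$age <- age_num
  }
  df
}

#' Read a species characteristics table (AnAge-style)
#'
#' Life-history parameters per species: maximum lifespan `L`, gestation
#' time `g`, and age of sexual maturity `m`, all in years. Column names
#' are canonicalized (`maxAgeCaped`/`maximum_lifespan` -> `max_lifespan`,
#' ...). Rows are validated (`L > 0`, `m < L`, `g < L`); exact duplicate
#' rows are deduplicated with a warning, conflicting duplicates are an
#' error.
#'
#' @param path file path.
#' @return `data.frame` with columns `species`, `max_lifespan`,
#'   `gestation`, `sexual_maturity`.
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  df <- canonicalize_columns(df, SPECIES_ALIASES,
                             c("species", "max_lifespan"), path)
  for (col in intersect(c("max_lifespan", "gestation", "sexual_maturity"),
                        names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v))
    if (length(bad)) {
      stop(path, ": non-numeric ", col, " at data line(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    df[[col]] <- v
  }
  df$species <- as.character(df$species)
  key <- normalize_species_key(df$species)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    for (d in dups) {
      rows <- df[key == d, , drop = FALSE]
      if (nrow(unique(rows[setdiff(names(rows), "species")])) > 1) {
        stop(path, ": conflicting duplicate rows for species '",
             rows$species[1], "'", call. = FALSE)
      }
    }
    warning(path, ": deduplicated ", sum(duplicated(key)),
            " identical duplicate species row(s)", call. = FALSE)
    df <- df[!duplicated(key), , drop = FALSE]
  }
  validate_species_table(df, path)
  df
}

validate_species_table <- function(df, path = "species table") {
  bad_L <- !is.na(df$max_lifespan) & df$max_lifespan <= 0
  if (any(bad_L)) {
    stop(path, ": non-positive max_lifespan for species ",
         paste(df$species[bad_L], collapse = ", "), call. = FALSE)
  }
  if ("sexual_maturity" %in% names(df)) {
    bad <- !is.na(df$sexual_maturity) & !is.na(df$max_lifespan) &
      df$sexual_maturity >= df$max_lifespan
    if (any(bad)) {
      stop(path, ": sexual_maturity >= max_lifespan for species ",
           paste(df$species[bad], collapse = ", "), call. = FALSE)
    }
  }
  if ("gestation" %in% names(df)) {
    bad <- !is.na(df$gestation) & !is.na(df$max_lifespan) &
      df$gestation >= df$max_lifespan
    if (any(bad)) {
      stop(path, ": gestation >= max_lifespan for species ",
           paste(df$species[bad], collapse = ", "), call. = FALSE)
    }
  }
  invisible(df)
}

#' Registry of available clock files
#'
#' Lists the clock CSVs bundled with the package (synthetic fixture clocks
#' only — published consortium clocks are not redistributed here, but any
#' conforming CSV dropped into `user_dir` is picked up). Every file is
#' parsed on registry build, so a malformed clock fails loudly and names
#' the file.
#'
#' @param user_dir optional directory of additional clock CSVs.
#' @return `data.frame`: clock_name, transform, n_probes, path.
#' @export
get_clock_registry <- function(user_dir = NULL) {
  bundled <- system.file("extdata", "clocks", package = "ageclock")
  dirs <- c(bundled, user_dir)
  files <- unlist(lapply(dirs[nzchar(dirs)], list.files, pattern = "\\.csv$",
                         full.names = TRUE))
  if (length(files) == 0) {
    return(data.frame(clock_name = character(0), transform = character(0),
                      n_probes = integer(0), path = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(files, function(f) {
    clk <- tryCatch(suppressWarnings(suppressMessages(read_clock(f))),
                    error = function(e) {
      stop("clock registry: failed to parse '", f, "': ",
           conditionMessage(e), call. = FALSE)
    })
    data.frame(clock_name = clk$clock_name,
               transform = clk$transform$name,
               n_probes = length(clk$coefficients),
               path = f, stringsAsFactors = FALSE)
  })
  reg <- do.call(rbind, rows)
  if (anyDuplicated(reg$clock_name)) {
    stop("clock registry: duplicate clock_name ",
         paste(unique(reg$clock_name[duplicated(reg$clock_name)]),
               collapse = ", "), call. = FALSE)
  }
  reg
}
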