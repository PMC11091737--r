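# Seeded simulator of multi-species methylation cohorts with the
# statistical structure the rest of the package assumes: bimodal baseline
# beta values (peaks near 0 and 1), a tunable fraction of mid-methylation
# artifact probes emulating non-mappable CpGs (the trimodal peak near 0.5),
# and age-signal probes whose beta is linear in transformed age. Because the
# signal is linear on the transformed-age scale, clock recovery is exactly
# within model class — the right fixture for testing the estimator, not for
# mimicking biology.

#' Simulation configuration
#'
#' Defaults describe the package's standard acceptance cohort: 3 species
#' with maximum lifespans 10/25/60 years, 50 samples each, 2000 probes of
#' which 100 carry age signal, 10% mid-methylation artifact probes, and
#' Gaussian noise with sd 0.03 on the beta scale.
#'
#' @param n_samples samples per species (recycled over species).
#' @param species data.frame with `species`, `max_lifespan`, `gestation`,
#'   `sexual_maturity` (years).
#' @param n_probes total probes.
#' @param n_signal_probes probes carrying age signal.
#' @param slope_range absolute slope of beta on transformed age for signal
#'   probes, drawn uniformly; sign points away from the baseline boundary
#'   (hypomethylated probes gain methylation with age and vice versa).
#' @param artifact_fraction share of probes forced to mean ~0.5 with low
#'   variance and no age signal.
#' @param noise_sd Gaussian noise sd on the beta scale.
#' @param missing_rate fraction of beta values set missing at random.
#' @param transform a [transform_spec()] defining the transformed-age scale
#'   on which the signal is linear.
#' @param seed integer seed; the cohort is reproducible bit-for-bit.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 50,
                       species = default_sim_species(),
                       n_probes = 2000,
                       n_signal_probes = 100,
                       slope_range = c(0.15, 0.4),
                       artifact_fraction = 0.1,
                       noise_sd = 0.03,
                       missing_rate = 0,
                       transform = transform_spec("relative_age"),
                       seed = 42) {
  stopifnot(n_signal_probes <= n_probes,
            artifact_fraction >= 0, artifact_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1,
            noise_sd >= 0)
  if (any(species$max_lifespan <= 0)) {
    stop("degenerate species: max_lifespan must be > 0", call. = FALSE)
  }
  structure(list(n_samples = n_samples, species = species,
                 n_probes = n_probes, n_signal_probes = n_signal_probes,
                 slope_range = slope_range,
                 artifact_fraction = artifact_fraction,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 transform = transform, seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_sim_species <- function() {
  data.frame(
    species = c("species_A", "species_B", "species_C"),
    max_lifespan = c(10, 25, 60),
    gestation = c(0.06, 0.2, 0.6),
    sexual_maturity = c(1, 4, 12),
    stringsAsFactors = FALSE)
}

#' Simulate a multi-species methylation cohort
#'
#' Ages are uniform on (0, 0.9 L) per species. Non-artifact probes draw a
#' bimodal baseline (half near beta 0.08, half near 0.92); artifact probes
#' get mean ~0.5 and low variance. Signal probes add
#' `slope * F(age)` to the baseline, with the slope sign pointing away from
#' the nearer boundary. Gaussian noise is added and values are clipped to
#' [0, 1]; the clip fraction is reported and warned about above 5%.
#'
#' @param cfg a [sim_config()].
#' @return list with `betas` (probes x samples matrix), `sheet` (sample
#'   sheet data.frame), `species_table`, and `truth` (data.frame of signal
#'   probe ids and slopes, plus the artifact probe ids as an attribute);
#'   `clip_fraction` attribute on `betas`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  sp <- cfg$species
  n_sp <- nrow(sp)
  n_per <- rep_len(cfg$n_samples, n_sp)
  n <- sum(n_per)
  P <- cfg$n_probes

  with_local_seed(cfg$seed, {
    species_of <- rep(sp$species, n_per)
    ages <- unlist(lapply(seq_len(n_sp), function(i) {
      stats::runif(n_per[i], min = 1e-3, max = 0.9 * sp$max_lifespan[i])
    }))
    sample_ids <- sprintf("S%03d", seq_len(n))
    sheet <- data.frame(sample_id = sample_ids, age = ages,
                        species = species_of,
                        tissue = "blood", stringsAsFactors = FALSE)

    f_age <- vapply(seq_len(n), function(i) {
      transform_age(ages[i], cfg$transform,
                    species_row(sp, species_of[i]))
    }, numeric(1))

    probe_ids <- sprintf("cg%05d", seq_len(P))
    n_artifact <- round(cfg$artifact_fraction * P)
    artifact_idx <- if (n_artifact > 0) seq_len(n_artifact) else integer(0)
    non_artifact <- setdiff(seq_len(P), artifact_idx)
    signal_idx <- if (cfg$n_signal_probes > 0) {
      sort(sample(non_artifact, cfg$n_signal_probes))
    } else integer(0)

    # baselines: bimodal for regular probes, tight mid for artifact probes
    base <- numeric(P)
    lowhigh <- stats::runif(length(non_artifact)) < 0.5
    base[non_artifact[lowhigh]] <-
      stats::rbeta(sum(lowhigh), 4, 46)        # mean 0.08, near 0
    base[non_artifact[!lowhigh]] <-
      stats::rbeta(sum(!lowhigh), 46, 4)       # mean 0.92, near 1
    base[artifact_idx] <- pmin(pmax(
      stats::rnorm(n_artifact, 0.5, 0.03), 0.35), 0.65)

    slopes <- numeric(P)
    if (length(signal_idx)) {
      mag <- stats::runif(length(signal_idx), cfg$slope_range[1],
                          cfg$slope_range[2])
      slopes[signal_idx] <- ifelse(base[signal_idx] < 0.5, mag, -mag)
    }

    mu <- matrix(base, nrow = P, ncol = n) +
      outer(slopes, f_age)
    artifact_noise_sd <- min(cfg$noise_sd, 0.02)  # artifact peak is tight
    noise_sd_vec <- rep(cfg$noise_sd, P)
    noise_sd_vec[artifact_idx] <- artifact_noise_sd
    betas <- mu + matrix(stats::rnorm(P * n), nrow = P) * noise_sd_vec

    clipped <- betas < 0 | betas > 1
    betas[betas < 0] <- 0
    betas[betas > 1] <- 1
    clip_fraction <- mean(clipped)
    if (clip_fraction > 0.05) {
      warning("clip fraction ", round(clip_fraction, 3),
              " exceeds 5%; consider smaller slopes or noise", call. = FALSE)
    }

    if (cfg$missing_rate > 0) {
      betas[stats::runif(P * n) < cfg$missing_rate] <- NA_real_
    }
    dimnames(betas) <- list(probe_ids, sample_ids)
    attr(betas, "clip_fraction") <- clip_fraction

    truth <- data.frame(probe = probe_ids[signal_idx],
                        slope = slopes[signal_idx],
                        stringsAsFactors = FALSE)
    attr(truth, "artifact_probes") <- probe_ids[artifact_idx]

    list(betas = betas, sheet = sheet, species_table = sp, truth = truth)
  })
}

#' Corrupt one array by permuting its values across probes
#'
#' Destroys the sample's inter-array correlation while preserving its
#' marginal beta distribution — the canonical planted outlier for QC tests.
#'
#' @param betas probes x samples beta matrix.
#' @param sample_id the column to corrupt.
#' @param seed permutation seed.
#' @return the modified matrix (a copy).
#' @export
corrupt_sample <- function(betas, sample_id, seed = 1) {
  validate_betas(betas)
  if (!(sample_id %in% colnames(betas))) {
    stop("unknown sample: ", sample_id, call. = FALSE)
  }
  with_local_seed(seed, {
    perm <- sample(nrow(betas))
    betas[, sample_id] <- betas[perm, sample_id]
  })
  betas
}
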