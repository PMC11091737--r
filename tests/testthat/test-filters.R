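# Probe pre-filters: middle window, detection p-value, mappability, and
# the trimodality diagnostic.

test_that("middle_filter removes probes whose mean is in the window", {
  b <- tiny_betas(cbind(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9)),
                  probes = c("cg1", "cg2", "cg3"))
  sel <- middle_filter(b, 0.3, 0.7)
  expect_identical(sel$kept, c("cg1", "cg3"))
  expect_identical(names(sel$removed), "cg2")
  # degenerate window removes only probes whose mean is exactly 0.5
  sel2 <- middle_filter(b, 0.5, 0.5)
  expect_identical(names(sel2$removed), "cg2")
  expect_error(middle_filter(b, 0.7, 0.3), "invalid middle window")
  # all-missing probes are removed with their own reason
  bna <- b; bna["cg1", ] <- NA
  sel3 <- middle_filter(bna)
  expect_identical(unname(sel3$removed[["cg1"]]), "all_missing")
  # empty input
  sel4 <- middle_filter(b[0, , drop = FALSE])
  expect_length(sel4$kept, 0)
})

test_that("detection_p_filter applies the fail-fraction rule", {
  p <- matrix(0.001, 4, 10,
              dimnames = list(sprintf("cg%d", 1:4), sprintf("s%d", 1:10)))
  expect_length(detection_p_filter(p)$removed, 0)
  p["cg2", 3] <- 0.2
  sel <- detection_p_filter(p, 0.05, max_fail_fraction = 0)
  expect_identical(names(sel$removed), "cg2")
  sel2 <- detection_p_filter(p, 0.05, max_fail_fraction = 0.5)
  expect_length(sel2$removed, 0)  # 1/10 failing <= 0.5
  expect_error(detection_p_filter(p * 30), "\\[0,1\\]")
  b <- matrix(0.5, 3, 10)
  expect_error(detection_p_filter(p, betas = b), "shape")
})

test_that("mappability_filter is an order-preserving intersection", {
  expect_identical(mappability_filter(c("a", "b", "c"), c("c", "a"))$kept,
                   c("a", "c"))
  expect_identical(mappability_filter(c("a", "b"), c("a", "b", "z"))$kept,
                   c("a", "b"))
  expect_warning(sel <- mappability_filter(c("a", "b"), "q"),
                 "every probe removed")
  expect_length(sel$kept, 0)
})

test_that("filters are idempotent and partition the input", {
  co <- small_cohort(n = 20, p = 100, seed = 61)
  b <- co$betas
  sel <- middle_filter(b)
  expect_setequal(c(sel$kept, names(sel$removed)), rownames(b))
  expect_length(intersect(sel$kept, names(sel$removed)), 0)
  sel_again <- middle_filter(b[sel$kept, , drop = FALSE])
  expect_identical(sel_again$kept, sel$kept)
  expect_length(sel_again$removed, 0)
})

test_that("mappability and middle filters commute", {
  co <- small_cohort(n = 15, p = 80, seed = 67)
  b <- co$betas
  ann <- rownames(b)[seq(1, 80, by = 2)]
  k1 <- middle_filter(b[mappability_filter(rownames(b), ann)$kept, ])$kept
  m2 <- middle_filter(b)$kept
  k2 <- mappability_filter(m2, ann)$kept
  expect_setequal(k1, k2)
})

test_that("bimodality_report quantifies the artifact peak", {
  sim <- simulate_cohort(sim_config(n_samples = 15, n_probes = 600,
                                    n_signal_probes = 0,
                                    artifact_fraction = 0.1, seed = 9))
  rep_tri <- bimodality_report(sim$betas)
  expect_equal(rep_tri$middle_fraction, 0.1, tolerance = 0.2)
  sim2 <- simulate_cohort(sim_config(n_samples = 15, n_probes = 600,
                                     n_signal_probes = 0,
                                     artifact_fraction = 0, seed = 9))
  expect_lt(bimodality_report(sim2$betas)$middle_fraction, 0.01)
  b1 <- tiny_betas(matrix(0.5, 1, 3))
  expect_equal(bimodality_report(b1, bins = 5)$middle_fraction, 1)
  expect_error(bimodality_report(b1, bins = 2), "bins")
})
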