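# EWAS of age and Stouffer meta-analysis.

test_that("perfectly linear probes reach |r| = 1 with mirrored signs", {
  ages <- seq(1, 10, length.out = 12)
  b <- rbind(up = ages / 12, down = 1 - ages / 12,
             flat = rep(0.4, 12))
  colnames(b) <- sprintf("s%02d", 1:12)
  set.seed(2)
  b["flat", ] <- b["flat", ] + rnorm(12, 0, 0.01)
  res <- ewas_correlate(b, stats::setNames(ages, colnames(b)), min_n = 5)
  expect_equal(res$r[res$probe == "up"], 1)
  expect_equal(res$r[res$probe == "down"], -1)
  expect_equal(res$r[res$probe == "up"], -res$r[res$probe == "down"])
  expect_error(ewas_correlate(b, rep(3, 12)), "constant")
})

test_that("probes under min_n come back NA and are excluded from q", {
  set.seed(3)
  b <- tiny_betas(matrix(runif(60), 5, 12))
  b[1, 1:8] <- NA  # only 4 complete pairs
  res <- ewas_correlate(b, stats::setNames(runif(12), colnames(b)),
                        min_n = 10)
  expect_true(is.na(res$r[1]) && is.na(res$q[1]))
  expect_false(anyNA(res$q[-1]))
})

test_that("null p-values are uniform (seeded KS check)", {
  set.seed(12)
  n <- 50; P <- 5000
  b <- matrix(pmin(pmax(rnorm(n * P, 0.5, 0.08), 0), 1), P, n,
              dimnames = list(sprintf("cg%04d", 1:P), sprintf("s%02d", 1:n)))
  out <- stats::setNames(runif(n, 0, 10), colnames(b))
  res <- ewas_correlate(b, out)
  ks <- stats::ks.test(res$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("BH q-values match the textbook formula to 1e-12", {
  set.seed(13)
  p <- runif(500)^2
  b <- tiny_betas(matrix(runif(200 * 20), 200, 20))
  out <- stats::setNames(runif(20), colnames(b))
  res <- ewas_correlate(b, out)
  # independent oracle: step-up q_i = min_{j >= i} p_(j) * m / j
  m <- length(res$p)
  o <- order(res$p)
  q_oracle <- numeric(m)
  q_oracle[o] <- pmin(1, rev(cummin(rev(res$p[o] * m / seq_len(m)))))
  expect_lt(max(abs(res$q - q_oracle)), 1e-12)
  # monotone in p-rank
  expect_true(all(diff(res$q[o]) >= -1e-15))
})

test_that("Stouffer combination behaves on identical and opposed strata", {
  set.seed(14)
  b <- tiny_betas(matrix(runif(100 * 20), 100, 20))
  out <- stats::setNames(runif(20, 0, 5), colnames(b))
  e1 <- ewas_correlate(b, out, stratum = "s1")
  e2 <- e1; e2$stratum <- "s2"
  m_eq <- meta_ewas(list(e1, e2), weights = "equal")
  expect_equal(m_eq$z, sqrt(2) * e1$z[match(m_eq$probe, e1$probe)])
  e_neg <- e1; e_neg$z <- -e_neg$z
  m0 <- meta_ewas(list(e1, e_neg), weights = "equal")
  expect_equal(m0$z, rep(0, nrow(m0)))
  expect_error(meta_ewas(list(e1)), "at least 2")
})

test_that("meta-analysis concentrates a shared planted signal (frozen)", {
  hits <- 0
  for (rep in 1:20) {
    set.seed(1000 + rep)
    P <- 500; n <- 50; sig <- sprintf("cg%03d", 1:50)
    strata <- lapply(1:3, function(s) {
      out <- rnorm(n)
      b <- matrix(rnorm(P * n, 0.5, 0.05), P, n,
                  dimnames = list(sprintf("cg%03d", 1:P),
                                  sprintf("S%d_%02d", s, 1:n)))
      b[1:50, ] <- b[1:50, ] + 0.04 * rep(out, each = 50)
      b[b < 0] <- 0; b[b > 1] <- 1
      ewas_correlate(b, stats::setNames(out, colnames(b)))
    })
    m <- meta_ewas(strata)
    top <- m$probe[order(-abs(m$z))][1:50]
    if (all(sig %in% top)) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.95)
})

test_that("bicor tracks pearson on clean data and shares the z path", {
  set.seed(15)
  ages <- runif(30, 1, 20)
  b <- tiny_betas(rbind(0.2 + 0.02 * ages + rnorm(30, 0, 0.02),
                        runif(30)))
  colnames(b) <- sprintf("s%02d", 1:30)
  rp <- ewas_correlate(b, stats::setNames(ages, colnames(b)), min_n = 5)
  rb <- ewas_correlate(b, stats::setNames(ages, colnames(b)), min_n = 5,
                       method = "bicor")
  expect_equal(rb$r[1], rp$r[1], tolerance = 0.05)
  expect_true(all(!is.na(rb$p)))
})
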