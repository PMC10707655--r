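test_that("event matching: agreement, misses and the mixed 2x2 case", {
  h <- event_log(c(5, 20, 40), "human")
  m_same <- event_log(c(5, 20, 40), "machine")
  res <- match_events(m_same, h)
  expect_identical(res$tp, 3L)
  expect_identical(res$fp, 0L)
  expect_identical(res$fn, 0L)
  expect_true(all(res$pairs$delta_s == 0))

  res_empty <- match_events(event_log(numeric(0), "machine"), h)
  expect_identical(res_empty$fn, 3L)
  expect_identical(res_empty$tp, 0L)

  m <- event_log(c(10, 30), "machine")
  h2 <- event_log(c(12.5, 50), "human")
  res2 <- match_events(m, h2, tolerance_s = 5)
  expect_identical(res2$tp, 1L)
  expect_identical(res2$fp, 1L)
  expect_identical(res2$fn, 1L)
  expect_equal(res2$pairs$delta_s, -2.5)
  expect_setequal(res2$outcome_per_event$outcome, c("TP", "FP", "FN"))

  expect_error(match_events(event_log(1, "machine", "a"),
                            event_log(1, "human", "b")),
               class = "bw_validation_error")
})

test_that("matching is one-to-one and nearest-first", {
  # two machine events compete for one human event: the nearer one wins
  m <- event_log(c(9, 11), "machine")
  h <- event_log(10, "human")
  res <- match_events(m, h, tolerance_s = 5)
  expect_identical(res$tp, 1L)
  expect_identical(res$fp, 1L)
  expect_equal(res$pairs$delta_s, -1)
})

test_that("delta statistics use type-7 quartiles and flag the sign", {
  s1 <- delta_stats(c(-3, -3, -3))
  expect_equal(s1$median_s, -3)
  expect_equal(s1$iqr_s, 0)
  s2 <- delta_stats(c(-1, -2, -3, -4, -5))
  expect_equal(s2$median_s, -3)
  expect_equal(s2$iqr_s, 2)
  expect_equal(s2$lead_median_s, 3)
  s3 <- delta_stats(-2)
  expect_equal(s3$median_s, -2)
  expect_equal(s3$iqr_s, 0)
  expect_error(delta_stats(numeric(0)), class = "bw_validation_error")

  # sort-based oracle with explicit type-7 interpolation
  set.seed(50)
  for (i in 1:20) {
    x <- rnorm(sample(2:15, 1))
    st <- delta_stats(x)
    xs <- sort(x)
    q7 <- function(p) {
      hh <- (length(xs) - 1) * p
      lo <- floor(hh) + 1
      xs[lo] + (hh - floor(hh)) * (xs[min(lo + 1, length(xs))] - xs[lo])
    }
    expect_equal(st$median_s, q7(0.5), tolerance = 1e-12)
    expect_equal(st$iqr_s, q7(0.75) - q7(0.25), tolerance = 1e-12)
  }
})

test_that("kernel density estimate is normalised and shaped correctly", {
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

  k0 <- kde_density(rep(0, 5), bandwidth = 1)
  expect_equal(k0$x[which.max(k0$y)], 0, tolerance = 0.05)
  expect_equal(trapz(k0$x, k0$y), 1, tolerance = 1e-3)
  # symmetric about zero
  mid <- stats::approx(k0$x, k0$y, xout = c(-1.3, 1.3))$y
  expect_equal(mid[1], mid[2], tolerance = 1e-6)

  set.seed(51)
  k1 <- kde_density(rnorm(40, -3, 0.5))
  expect_equal(trapz(k1$x, k1$y), 1, tolerance = 1e-3)
  expect_lt(abs(k1$x[which.max(k1$y)] + 3), 0.5)

  # two points: closed-form mixture of two Gaussians
  k2 <- kde_density(c(-5, 5), bandwidth = 1)
  expect_equal(trapz(k2$x, k2$y), 1, tolerance = 1e-3)
  ref <- (stats::dnorm(k2$x, -5, 1) + stats::dnorm(k2$x, 5, 1)) / 2
  expect_equal(k2$y, ref, tolerance = 1e-6)
  peaks <- c(k2$y[which.min(abs(k2$x + 5))], k2$y[which.min(abs(k2$x - 5))])
  expect_equal(peaks[1], peaks[2], tolerance = 1e-3)

  expect_warning(kz <- kde_density(rep(2, 4)), "zero-variance")
  expect_true(kz$fallback)
  expect_error(kde_density(1), class = "bw_validation_error")
})

# Brute-force correspondence analysis oracle: explicit standardised
# residuals + SVD of an arbitrary two-way table.
ca_oracle <- function(tab) {
  P <- tab / sum(tab)
  r <- rowSums(P)
  c <- colSums(P)
  S <- (P - outer(r, c)) / sqrt(outer(r, c))
  sv <- svd(S)$d
  sv[sv > 1e-12]
}

test_that("MCA of two perfectly associated balanced binaries", {
  tab <- data.frame(a = rep(c("x", "y"), each = 10),
                    b = rep(c("x", "y"), each = 10))
  res <- mca(tab)
  # oracle: CA of the 2x2 contingency table (perfect association => sv 1);
  # indicator-matrix inertias for Q=2 are (1 +/- sv)/2 = {1, 0}
  sv <- ca_oracle(table(tab$a, tab$b))
  expect_equal(sv, 1, tolerance = 1e-10)
  expect_equal(res$principal_inertias[1], (1 + sv) / 2, tolerance = 1e-10)
  expect_lt(sum(res$principal_inertias[-1]), 1e-10)
  expect_equal(res$total_inertia, (res$J - res$Q) / res$Q, tolerance = 1e-10)
  expect_true(all(res$variable_sq_correlations >= 0 &
                    res$variable_sq_correlations <= 1 + 1e-12))
  expect_equal(unname(res$variable_sq_correlations[, 1]), c(1, 1),
               tolerance = 1e-10)
})

test_that("MCA total inertia equals (J - Q)/Q on random tables", {
  set.seed(52)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    tab <- data.frame(
      a = sample(letters[1:3], n, replace = TRUE),
      b = sample(letters[1:4], n, replace = TRUE),
      c = sample(letters[1:2], n, replace = TRUE)
    )
    res <- mca(tab)
    expect_equal(res$total_inertia, (res$J - res$Q) / res$Q,
                 tolerance = 1e-10)
    expect_true(all(res$principal_inertias >= -1e-12))
    expect_true(all(diff(res$principal_inertias) <= 1e-12))
  }
})

test_that("Q=2 MCA is equivalent to classical CA of the contingency table", {
  set.seed(53)
  for (i in 1:5) {
    n <- 90
    a <- sample(letters[1:3], n, replace = TRUE)
    # induce association so singular values are non-trivial
    b <- ifelse(runif(n) < 0.6, a, sample(letters[1:3], n, replace = TRUE))
    res <- mca(data.frame(a = a, b = b))
    sv <- ca_oracle(table(a, b))
    expected <- sort(c((1 + sv) / 2, (1 - sv) / 2), decreasing = TRUE)
    got <- sort(res$principal_inertias, decreasing = TRUE)[seq_along(expected)]
    expect_equal(got, expected, tolerance = 1e-8)
  }
})

test_that("MCA is invariant to row permutation and drops constant columns", {
  set.seed(54)
  tab <- data.frame(a = sample(c("x", "y"), 30, replace = TRUE),
                    b = sample(c("u", "v", "w"), 30, replace = TRUE))
  res1 <- mca(tab)
  perm <- sample(nrow(tab))
  res2 <- mca(tab[perm, ])
  expect_equal(res2$principal_inertias, res1$principal_inertias,
               tolerance = 1e-10)
  expect_equal(res2$individual_coordinates,
               abs_align(res1$individual_coordinates[perm, , drop = FALSE],
                         res2$individual_coordinates),
               tolerance = 1e-8)

  tab$const <- "k"
  expect_warning(res3 <- mca(tab), "constant")
  expect_equal(res3$Q, 2)
})

test_that("independent variables show no dominant outcome dimension", {
  set.seed(55)
  n <- 400
  tab <- data.frame(outcome = sample(c("TP", "FP", "FN"), n, replace = TRUE),
                    video = sample(paste0("v", 1:5), n, replace = TRUE),
                    timing = sample(c("early", "mid", "late"), n,
                                    replace = TRUE))
  res <- mca(tab)
  expect_equal(res$total_inertia, (res$J - res$Q) / res$Q, tolerance = 1e-10)
  # homogeneity-analysis identity: each principal inertia equals the mean
  # of the variable discrimination measures on that dimension
  expect_equal(unname(colMeans(res$variable_sq_correlations)),
               res$principal_inertias[1:2], tolerance = 1e-8)
  # under independence no variable is near-perfectly represented
  expect_lt(max(res$variable_sq_correlations), 0.8)
})

test_that("event-log CSV round trip", {
  dir <- withr::local_tempdir()
  log <- event_log(c(3.5, 60, 120.25), "machine", video_id = "v7")
  path <- file.path(dir, "events.csv")
  write_event_log(log, path)
  back <- read_event_logs(path)
  expect_length(back, 1)
  expect_equal(back[["v7/machine"]]$times, log$times)
  expect_error(read_event_logs(file.path(dir, "none.csv")),
               class = "bw_io_error")
})
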