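test_that("textbook Mann-Whitney cases come out exactly", {
  m <- mann_whitney_u(c(1, 2), c(3, 4), method = "exact")
  expect_equal(m$U, 0)
  expect_equal(m$p_two_sided, 1 / 3)

  # identical multisets: central U, p = 1
  m2 <- mann_whitney_u(c(5, 7, 9), c(5, 7, 9), method = "exact")
  expect_equal(m2$U, 3 * 3 / 2)
  expect_equal(m2$p_two_sided, 1)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact p equals the permutation-enumeration oracle", {
  set.seed(12)
  for (i in 1:200) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    # mix of continuous and tied data
    if (i %% 2 == 0) {
      x <- sample(1:6, n1, replace = TRUE)
      y <- sample(1:6, n2, replace = TRUE)
    } else {
      x <- rnorm(n1); y <- rnorm(n2)
    }
    got <- mann_whitney_u(x, y, method = "exact")$p_two_sided
    expect_equal(got, mwu_permutation_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("exact p matches wilcox.test on tie-free samples", {
  set.seed(30)
  for (i in 1:25) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1))
    ours <- mann_whitney_u(x, y, method = "exact")
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
    expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-9)
    expect_equal(ours$U1, unname(ref$statistic))
  }
})

test_that("swapping group labels reflects U and preserves p", {
  set.seed(44)
  for (method in c("exact", "normal_approx")) {
    x <- rnorm(8); y <- rnorm(6)
    a <- mann_whitney_u(x, y, method = method)
    b <- mann_whitney_u(y, x, method = method)
    expect_equal(b$U1, a$n1 * a$n2 - a$U1)
    expect_equal(a$U, b$U)
    expect_equal(a$p_two_sided, b$p_two_sided, tolerance = 1e-12)
    expect_gte(a$U, 0)
    expect_lte(a$U, a$n1 * a$n2)
  }
})

test_that("exact and normal approximation agree for moderate tie-free n", {
  set.seed(55)
  for (i in 1:20) {
    x <- rnorm(12); y <- rnorm(10, mean = runif(1, 0, 1.5))
    pe <- mann_whitney_u(x, y, method = "exact")$p_two_sided
    pn <- mann_whitney_u(x, y, method = "normal_approx")$p_two_sided
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("auto method honors size and ties", {
  x <- rnorm(5); y <- rnorm(5)
  expect_equal(mann_whitney_u(x, y)$method_used, "exact")
  expect_equal(mann_whitney_u(c(1, 1, 2), c(2, 3, 4))$method_used,
               "normal_approx")
  expect_equal(mann_whitney_u(rnorm(25), rnorm(25))$method_used,
               "normal_approx")
})

test_that("Spearman handles perfect, closed-form and tied cases", {
  s <- spearman_rho(1:5, c(10, 8, 6, 4, 2))
  expect_equal(s$rho, -1)
  expect_equal(s$band, "very strong")
  expect_equal(s$p_two_sided, 0)

  expect_equal(spearman_rho(1:3, c(3, 1, 2))$rho, -0.5)

  expect_error(spearman_rho(1:5, rep(3, 5)), "zero variance")
  expect_error(spearman_rho(1:2, 1:2), "n >= 3")
})

test_that("rank-Pearson rho equals the closed form on tie-free data", {
  set.seed(66)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    rho <- spearman_rho(x, y)$rho
    d <- rank(x) - rank(y)
    expect_equal(rho, 1 - 6 * sum(d^2) / (n * (n^2 - 1)), tolerance = 1e-12)
    expect_equal(rho, unname(stats::cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
  }
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(77)
  x <- rexp(15); y <- rnorm(15)
  base <- spearman_rho(x, y)$rho
  expect_equal(spearman_rho(log(x), y)$rho, base)
  expect_equal(spearman_rho(x, exp(y))$rho, base)
  expect_equal(spearman_rho(x^3, 1 / (1 + exp(-y)))$rho, base)
})

test_that("correlation strength bands follow the conventional cut points", {
  expect_equal(correlation_band(c(0.05, -0.2, 0.55, -0.78, 0.95)),
               c("negligible", "weak", "moderate", "strong", "very strong"))
  expect_equal(correlation_band(c(0.10, 0.40, 0.70, 0.90)),
               c("weak", "moderate", "strong", "very strong"))
})

make_cohort_table <- function(seed = 1, sep = FALSE) {
  set.seed(seed)
  n1 <- 8; n2 <- 6
  purrr::map_dfr(c("gastrocnemius", "soleus"), function(ro) {
    ttp_p <- if (sep) runif(n1, 100, 150) else rnorm(n1, 100, 30)
    ttp_c <- if (sep) runif(n2, 20, 60) else rnorm(n2, 60, 30)
    tibble::tibble(
      subject_id = c(sprintf("P%d", 1:n1), sprintf("C%d", 1:n2)),
      group = c(rep("PAOD", n1), rep("control", n2)),
      abi = c(runif(n1, 0.4, 0.9), runif(n2, 1.0, 1.3)),
      roi_label = ro,
      bl_ms = rnorm(n1 + n2, 23, 3),
      hpv_ms = rnorm(n1 + n2, 24, 3),
      ttp_s = c(ttp_p, ttp_c),
      overshoot_ms = rnorm(n1 + n2, 1, 0.8)
    )
  })
}

test_that("cohort summary has the expected bookkeeping shape", {
  tab <- make_cohort_table()
  rep <- summarize_cohort(tab)
  expect_equal(nrow(rep$comparisons), 2 * 4)   # ROIs x features
  expect_equal(nrow(rep$correlations), 2)      # one per ROI
  expect_true(all(rep$comparisons$p > 0 & rep$comparisons$p <= 1))
  expect_identical(tidy(rep), rep$comparisons)
  expect_identical(glance(rep), rep$correlations)

  expect_error(summarize_cohort(dplyr::filter(tab, group == "PAOD")),
               "both groups")
  expect_error(summarize_cohort(dplyr::select(tab, -abi)), "lacks")
})

test_that("complete TTP separation yields U = 0 at the minimal exact p", {
  tab <- make_cohort_table(sep = TRUE)
  rep <- summarize_cohort(tab, method = "exact")
  ttp_rows <- dplyr::filter(rep$comparisons, feature == "ttp_s")
  expect_true(all(ttp_rows$U == 0))
  expect_equal(ttp_rows$p, rep(2 / choose(14, 8), 2), tolerance = 1e-12)
})

test_that("comonotone-coupled cohorts always give negative TTP-ABI rho", {
  for (seed in 1:5) {
    tab <- draw_cohort_params(cohort_params(n_paod = 10, n_control = 6,
                                            seed = seed,
                                            severity_coupling = 1))
    ct <- tibble::tibble(
      subject_id = tab$subject_id, group = tab$group, abi = tab$abi,
      roi_label = "gastrocnemius", bl_ms = tab$bl_gastrocnemius,
      hpv_ms = tab$bl_gastrocnemius + tab$overshoot_gastrocnemius,
      ttp_s = tab$ttp_gastrocnemius,
      overshoot_ms = tab$overshoot_gastrocnemius
    )
    rep <- summarize_cohort(ct)
    expect_lt(rep$correlations$rho, 0)
  }
})

test_that("tidiers return one-row summaries", {
  m <- mann_whitney_u(rnorm(6), rnorm(7))
  expect_equal(nrow(tidy(m)), 1)
  expect_true(all(c("U", "p_value") %in% names(tidy(m))))
  s <- spearman_rho(rnorm(8), rnorm(8))
  expect_true(all(c("rho", "band") %in% names(tidy(s))))
})
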