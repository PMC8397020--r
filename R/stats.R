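#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The U statistic is
#' computed from joint average ranks (tie-aware). Under `method = "auto"`
#' the exact permutation null is used when `n1 * n2 <= 400` and the pooled
#' sample is tie-free (via a rank-sum counting recursion, the classical
#' no-tie shortcut); otherwise the normal approximation with tie-corrected
#' variance and continuity correction is used. `method = "exact"` with ties
#' enumerates all group assignments when feasible. Two-sided p-values
#' throughout, measured as the null probability of a U at least as far from
#' its mean `n1 n2 / 2` as observed.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param method `"auto"`, `"exact"` or `"normal_approx"`.
#' @return An object of class `mwu_test`: list with `n1`, `n2`, `U`
#'   (min(U1, U2), in `[0, n1 n2]`), `U1` (U of `x`), `p_two_sided`,
#'   `method_used`, and group summaries `mean1`, `sd1`, `mean2`, `sd2`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4), method = "exact")$p_two_sided  # 1/3
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact",
                                            "normal_approx")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y) || anyNA(x) || anyNA(y)) {
    stop("both samples must be non-empty and free of missing values",
         call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))                       # average ranks for ties
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  has_ties <- anyDuplicated(c(x, y)) > 0

  use_exact <- switch(method,
    exact = TRUE,
    normal_approx = FALSE,
    auto = n1 * n2 <= 400 && !has_ties
  )

  if (use_exact && !has_ties) {
    counts <- rank_sum_counts(n1, n2)      # P(U1 = u), u = 0..n1*n2
    dev <- abs(seq(0, n1 * n2) - mu)
    p <- sum(counts[dev >= abs(u1 - mu) - 1e-9]) / sum(counts)
    used <- "exact"
  } else if (use_exact) {
    nperm <- choose(n, n1)
    if (nperm > 2e5) {
      stop("exact method with ties infeasible for these sample sizes; ",
           "use method = 'normal_approx'", call. = FALSE)
    }
    idx <- utils::combn(n, n1)
    u_perm <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_perm - mu) >= abs(u1 - mu) - 1e-9)
    used <- "exact"
  } else {
    tie_tab <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u1 - mu - sign(u1 - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    used <- "normal_approx"
  }

  structure(
    list(n1 = n1, n2 = n2, U = min(u1, n1 * n2 - u1), U1 = u1,
         p_two_sided = p, method_used = used,
         mean1 = mean(x), sd1 = stats::sd(x),
         mean2 = mean(y), sd2 = stats::sd(y)),
    class = "mwu_test"
  )
}

# number of n1-subsets of ranks 1..(n1+n2) with each U1 value 0..n1*n2,
# by the standard recursion N(u; a, b) = N(u - b; a - 1, b) + N(u; a, b - 1)
rank_sum_counts <- function(n1, n2) {
  prev <- matrix(0, nrow = n1 * n2 + 1, ncol = n1 + 1)
  prev[1, ] <- 1                          # b = 0: only u = 0
  for (b in seq_len(n2)) {
    cur <- matrix(0, nrow = n1 * n2 + 1, ncol = n1 + 1)
    cur[1, 1] <- 1
    for (a in seq_len(n1)) {
      cur[, a + 1] <- prev[, a + 1]
      if (b <= n1 * n2) {
        shift <- c(rep(0, b), cur[seq_len(n1 * n2 + 1 - b), a])
        cur[, a + 1] <- cur[, a + 1] + shift
      }
    }
    prev <- cur
  }
  prev[, n1 + 1]
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U: U = %g (n1 = %d, n2 = %d), p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p_two_sided, x$method_used))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of the average-rank vectors, with a two-sided
#' p-value from the t approximation on `n - 2` degrees of freedom, and the
#' conventional strength band on `|rho|`: below 0.10 negligible,
#' 0.10-0.39 weak, 0.40-0.69 moderate, 0.70-0.89 strong, 0.90-1.00 very
#' strong (half-open intervals on the decimal boundaries).
#'
#' @param x,y Paired numeric samples, `n >= 3`.
#' @return An object of class `spearman_cor`: list with `n`, `rho`,
#'   `p_two_sided` and `band`.
#' @examples
#' spearman_rho(1:3, c(3, 1, 2))$rho  # -0.5
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need n >= 3 pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("undefined correlation: zero variance in a rank vector",
         call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  structure(list(n = n, rho = rho, p_two_sided = p,
                 band = correlation_band(rho)),
            class = "spearman_cor")
}

#' @rdname spearman_rho
#' @param rho A correlation coefficient in `[-1, 1]`.
#' @export
correlation_band <- function(rho) {
  a <- abs(rho)
  dplyr::case_when(
    a < 0.10 ~ "negligible",
    a < 0.40 ~ "weak",
    a < 0.70 ~ "moderate",
    a < 0.90 ~ "strong",
    TRUE ~ "very strong"
  )
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (n = %d, p = %.4g), %s\n",
              x$rho, x$n, x$p_two_sided, x$band))
  invisible(x)
}

#' Group comparison and ABI correlation report for a cohort
#'
#' For every ROI and curve feature, compares the PAOD and control
#' distributions (group mean, SD and a Mann-Whitney U test) and, per ROI,
#' correlates TTP with the ankle-brachial index across all subjects
#' (Spearman).
#'
#' @param table Cohort feature table: one row per subject x ROI with
#'   columns `subject_id`, `group` (`"PAOD"`/`"control"`), `abi`,
#'   `roi_label`, and the feature columns `bl_ms`, `hpv_ms`, `ttp_s`,
#'   `overshoot_ms`.
#' @param method Passed to [mann_whitney_u()].
#' @return An object of class `cohort_report`: list of tibbles
#'   `comparisons` (ROI x feature rows: group n/mean/sd, `U`, `p`) and
#'   `correlations` (one row per ROI: `n`, `rho`, `p`, `band` for TTP vs
#'   ABI).
#' @export
summarize_cohort <- function(table, method = "auto") {
  needed <- c("subject_id", "group", "abi", "roi_label",
              "bl_ms", "hpv_ms", "ttp_s", "overshoot_ms")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    stop("cohort table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(setdiff(c("PAOD", "control"), unique(table$group)))) {
    stop("both groups (PAOD, control) must be present", call. = FALSE)
  }
  feats <- c("bl_ms", "hpv_ms", "ttp_s", "overshoot_ms")
  rois <- unique(table$roi_label)

  comparisons <- purrr::map_dfr(rois, function(ro) {
    sub <- dplyr::filter(table, .data$roi_label == ro)
    purrr::map_dfr(feats, function(f) {
      xp <- sub[[f]][sub$group == "PAOD"]
      xc <- sub[[f]][sub$group == "control"]
      tst <- mann_whitney_u(xp, xc, method = method)
      tibble::tibble(
        roi_label = ro, feature = f,
        n_paod = tst$n1, mean_paod = tst$mean1, sd_paod = tst$sd1,
        n_control = tst$n2, mean_control = tst$mean2, sd_control = tst$sd2,
        U = tst$U, p = tst$p_two_sided, method = tst$method_used
      )
    })
  })

  correlations <- purrr::map_dfr(rois, function(ro) {
    sub <- dplyr::filter(table, .data$roi_label == ro)
    ct <- spearman_rho(sub$ttp_s, sub$abi)
    tibble::tibble(roi_label = ro, feature = "ttp_s_vs_abi", n = ct$n,
                   rho = ct$rho, p = ct$p_two_sided, band = ct$band)
  })

  structure(list(comparisons = comparisons, correlations = correlations),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n-- group comparisons --\n")
  print(x$comparisons)
  cat("-- TTP vs ABI correlations --\n")
  print(x$correlations)
  invisible(x)
}
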