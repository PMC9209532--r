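#' Dice coefficient between two binary regions
#'
#' `2 |A intersect B| / (|A| + |B|)`: 1 for identical non-empty masks, 0 for
#' disjoint ones. Used here to quantify how much the activation-related
#' regions of the two tapping tasks overlap — a *lower* between-task Dice
#' means better functional resolution.
#'
#' @param mask_a,mask_b logical arrays on the same grid; an
#'   `activation_region` is also accepted.
#' @param subject_id,arm_label optional identifiers carried on the result.
#' @return A `dice_result`: list with `dice`, `region_a_count`,
#'   `region_b_count`, `overlap_count`, `subject_id`, `arm_label`.
#' @export
dice <- function(mask_a, mask_b, subject_id = NA, arm_label = NA) {
  if (inherits(mask_a, "activation_region")) mask_a <- mask_a$mask
  if (inherits(mask_b, "activation_region")) mask_b <- mask_b$mask
  if (!identical(dim(mask_a), dim(mask_b))) stop("masks are on different grids")
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na + nb == 0L) stop("both masks are empty")
  ov <- sum(mask_a & mask_b)
  structure(list(dice = 2 * ov / (na + nb), region_a_count = na,
                 region_b_count = nb, overlap_count = ov,
                 subject_id = subject_id, arm_label = arm_label),
            class = "dice_result")
}

#' @export
print.dice_result <- function(x, ...) {
  cat(sprintf("<dice_result> %.4f  (|A|=%d, |B|=%d, overlap=%d)\n",
              x$dice, x$region_a_count, x$region_b_count, x$overlap_count))
  invisible(x)
}

# Exact null distribution of the signed-rank statistic W+ for the given
# midranks, by dynamic-programming convolution over the 2^n sign
# assignments (each rank enters W+ with prob 1/2). Ranks are doubled so
# tied midranks (k + 0.5) stay on an integer lattice.
signed_rank_exact_p <- function(w, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  dist <- numeric(total + 1L)       # index i -> P(2*W+ = i - 1)
  dist[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), dist[seq_len(total + 1L - r)])
    dist <- (dist + shifted) / 2
  }
  w2 <- round(2 * w)
  p_le <- sum(dist[seq_len(w2 + 1L)])
  p_ge <- sum(dist[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on paired differences. Zero differences are dropped
#' (classical Wilcoxon convention); absolute differences are midranked.
#' For `n <= 25` retained pairs the p-value comes from the exact null
#' distribution of the rank sum (computed by convolution, so ties are
#' handled exactly); above that a normal approximation with tie-corrected
#' variance and a 0.5 continuity correction is used.
#'
#' @param x,y paired measurements, or `y = NULL` with `x` the differences.
#' @param exact_limit largest n handled exactly (default 25).
#' @return A `wilcoxon_result`: `statistic` (W+, sum of positive ranks),
#'   `n_pairs`, `n_used`, `p_value`, `exact` flag.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 25L) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("x and y lengths differ")
    x - y
  }
  if (length(d) < 1L) stop("need at least one pair")
  n_pairs <- length(d)
  d <- d[d != 0]
  if (length(d) == 0L) stop("all paired differences are zero; test undefined")
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(w, r)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  structure(list(statistic = w, n_pairs = n_pairs, n_used = n,
                 p_value = p, exact = exact),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("<wilcoxon_result> W+ = %g, n = %d (%d non-zero), p = %.4g (%s)\n",
              x$statistic, x$n_pairs, x$n_used, x$p_value,
              if (x$exact) "exact" else "normal approx."))
  invisible(x)
}

#' Median and interquartile range
#'
#' Linear-interpolation quantiles (R's default type 7).
#'
#' @param values non-empty numeric vector.
#' @return Named vector `median`, `q1`, `q3`.
#' @export
summarize_iqr <- function(values) {
  if (length(values) == 0L) stop("empty input")
  q <- quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Paired comparison of two analysis arms across a cohort
#'
#' Takes per-subject metric values for two arms in long format and, for each
#' metric, reports each arm's median (IQR) and the two-sided Wilcoxon
#' signed-rank p-value of the paired differences. With a single subject the
#' test is skipped (p is `NA` with a notice); if every pair is tied the
#' error is caught and reported the same way.
#'
#' @param results data.frame with columns `subject`, `arm` (exactly two
#'   levels), `metric`, `value`; every subject must appear in both arms for
#'   each metric.
#' @param alpha significance level echoed in the report (default 0.05).
#' @return An `arm_comparison`: data.frame `table` (one row per metric) and
#'   the input `arms`.
#' @export
compare_arms <- function(results, alpha = 0.05) {
  need <- c("subject", "arm", "metric", "value")
  if (!all(need %in% names(results)))
    stop("`results` needs columns subject, arm, metric, value")
  arms <- sort(unique(results$arm))
  if (length(arms) != 2L) stop("exactly two arms are required")
  rows <- lapply(unique(results$metric), function(met) {
    sub <- results[results$metric == met, ]
    wide <- merge(sub[sub$arm == arms[1], c("subject", "value")],
                  sub[sub$arm == arms[2], c("subject", "value")],
                  by = "subject", suffixes = c("_1", "_2"))
    missing <- setdiff(unique(sub$subject), wide$subject)
    if (length(missing) > 0L)
      stop(sprintf("metric '%s': subjects without both arms: %s", met,
                   paste(missing, collapse = ", ")))
    s1 <- summarize_iqr(wide$value_1)
    s2 <- summarize_iqr(wide$value_2)
    if (nrow(wide) < 2L) {
      p <- NA_real_; note <- "single subject; test skipped"
    } else {
      wt <- tryCatch(wilcoxon_signed_rank(wide$value_1, wide$value_2),
                     error = function(e) NULL)
      if (is.null(wt)) { p <- NA_real_; note <- "all pairs tied; test skipped" }
      else { p <- wt$p_value; note <- "" }
    }
    data.frame(metric = met, n = nrow(wide),
               median_1 = s1["median"], q1_1 = s1["q1"], q3_1 = s1["q3"],
               median_2 = s2["median"], q1_2 = s2["q1"], q3_2 = s2["q3"],
               p_value = p, significant = !is.na(p) & p < alpha,
               note = note, row.names = NULL)
  })
  structure(list(table = do.call(rbind, rows), arms = arms, alpha = alpha),
            class = "arm_comparison")
}

#' @export
print.arm_comparison <- function(x, ...) {
  cat(sprintf("Paired arm comparison: %s vs %s (Wilcoxon signed-rank, two-sided)\n",
              x$arms[1], x$arms[2]))
  tb <- x$table
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-22s %s %.3f (%.3f-%.3f) | %s %.3f (%.3f-%.3f) | p = %s%s\n",
                tb$metric[i], x$arms[1], tb$median_1[i], tb$q1_1[i], tb$q3_1[i],
                x$arms[2], tb$median_2[i], tb$q1_2[i], tb$q3_2[i],
                ifelse(is.na(tb$p_value[i]), "NA",
                       formatC(tb$p_value[i], digits = 4, format = "g")),
                ifelse(nzchar(tb$note[i]), paste0(" [", tb$note[i], "]"), "")))
  }
  invisible(x)
}
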