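test_that("dice identities: self, disjoint, half overlap", {
  a <- array(FALSE, c(6, 6, 1)); a[2:3, 2:3, 1] <- TRUE
  expect_equal(dice(a, a)$dice, 1)
  b <- array(FALSE, c(6, 6, 1)); b[5:6, 5:6, 1] <- TRUE
  expect_equal(dice(a, b)$dice, 0)
  # |A| = |B| = 4, overlap 2 -> 0.5
  c1 <- array(FALSE, c(6, 6, 1)); c1[1, 1:4, 1] <- TRUE
  c2 <- array(FALSE, c(6, 6, 1)); c2[1, 3:6, 1] <- TRUE
  expect_equal(dice(c1, c2)$dice, 0.5)
  expect_error(dice(a, array(FALSE, c(5, 5, 1))), "grids")
  expect_error(dice(a & FALSE, a & FALSE), "empty")
})

test_that("dice is symmetric and monotone in overlap at fixed sizes", {
  set.seed(99)
  for (i in 1:25) {
    a <- random_mask(); b <- random_mask()
    if (sum(a) + sum(b) == 0) next
    expect_identical(dice(a, b)$dice, dice(b, a)$dice)
  }
  # shifting B toward A grows the overlap and the coefficient
  base <- array(FALSE, c(12, 12, 1)); base[4:8, 4:8, 1] <- TRUE
  d_prev <- -1
  for (shift in 4:0) {
    b <- array(FALSE, c(12, 12, 1)); b[(4:8) + shift, 4:8, 1] <- TRUE
    d_now <- dice(base, b)$dice
    expect_gte(d_now, d_prev)
    d_prev <- d_now
  }
})

# independent oracle: enumerate all 2^n sign assignments of the midranks
wilcoxon_enumeration_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  p_le <- mean(ws <= w + 1e-9)
  p_ge <- mean(ws >= w - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

test_that("wilcoxon exact p matches full sign enumeration (n <= 10)", {
  set.seed(7)
  for (n in 3:10) {
    for (rep in 1:3) {
      d <- round(rnorm(n), 2)
      d[d == 0] <- 0.5
      res <- wilcoxon_signed_rank(d)
      expect_true(res$exact)
      expect_equal(res$p_value, wilcoxon_enumeration_p(d), tolerance = 1e-12,
                   label = sprintf("n=%d rep=%d", n, rep))
    }
    # with deliberate ties in |d|
    d <- c(rep(1, ceiling(n / 2)), -seq_len(floor(n / 2)))
    expect_equal(wilcoxon_signed_rank(d)$p_value, wilcoxon_enumeration_p(d),
                 tolerance = 1e-12)
  }
})

test_that("wilcoxon agrees with stats::wilcox.test where conventions match", {
  set.seed(21)
  # exact, no ties
  x <- rnorm(12); y <- rnorm(12)
  ours <- wilcoxon_signed_rank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(unname(ours$statistic), unname(ref$statistic))
  # large n: normal approximation with continuity correction
  x <- rnorm(40); y <- rnorm(40, 0.3)
  ours <- wilcoxon_signed_rank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_false(ours$exact)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("wilcoxon contracts: all-positive n=6 and all-tied error", {
  res <- wilcoxon_signed_rank(rep(2, 6), rep(1, 6))
  expect_equal(res$p_value, 2 / 2^6)
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "zero")
})

test_that("summarize_iqr follows the type-7 convention", {
  s <- summarize_iqr(c(1, 2, 3, 4, 5))
  expect_equal(unname(s), c(3, 2, 4))
  s2 <- summarize_iqr(rep(4.2, 7))
  expect_equal(unname(s2), rep(4.2, 3))
  # sort-based independent oracle for type-7 quantiles
  q7 <- function(x, p) {
    x <- sort(x); h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  set.seed(31)
  v <- rnorm(23)
  s3 <- summarize_iqr(v)
  expect_equal(unname(s3), c(q7(v, .5), q7(v, .25), q7(v, .75)))
  expect_error(summarize_iqr(numeric(0)), "empty")
})

test_that("compare_arms reports paired medians, p-values and edge cases", {
  set.seed(4)
  n <- 8
  df <- rbind(
    data.frame(subject = 1:n, arm = "raw", metric = "dice",
               value = runif(n, 0.4, 0.8)),
    data.frame(subject = 1:n, arm = "stss", metric = "dice",
               value = runif(n, 0.1, 0.5)))
  cmp <- compare_arms(df)
  expect_equal(nrow(cmp$table), 1L)
  expect_equal(cmp$table$n, n)
  expect_true(cmp$table$p_value > 0 && cmp$table$p_value <= 1)
  # identical arms -> all ties -> skipped with notice
  df2 <- df; df2$value[df2$arm == "stss"] <- df2$value[df2$arm == "raw"]
  cmp2 <- compare_arms(df2)
  expect_true(is.na(cmp2$table$p_value))
  expect_match(cmp2$table$note, "tied")
  # single subject -> medians reported, test skipped
  df3 <- df[df$subject == 1, ]
  cmp3 <- compare_arms(df3)
  expect_true(is.na(cmp3$table$p_value))
  expect_match(cmp3$table$note, "single")
  # unpaired subject -> error
  df4 <- df[-1, ]
  expect_error(compare_arms(df4), "without both arms")
})
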