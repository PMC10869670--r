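test_that("composite rubric score spans 4 to 20 and validates sub-scores", {
  expect_equal(reader_score("r1", "s1", 75, 5, 5, 5, 5)$composite, 20L)
  expect_equal(reader_score("r1", "s1", 75, 1, 1, 1, 1)$composite, 4L)
  expect_equal(reader_score("r1", "s1", 50, 3, 4, 2, 5)$composite, 14L)
  expect_error(reader_score("r1", "s1", 50, 0, 4, 2, 5), "1..5")
  expect_error(reader_score("r1", "s1", 50, 3, 6, 2, 5), "1..5")
  df <- data.frame(arterial = c(5, 1), capillary = c(5, 1), venous = c(5, 1),
                   overall_quality = c(5, 1))
  expect_equal(composite_score(df), c(20L, 4L))
})

test_that("Kendall's W matches the rank-sum-variance oracle", {
  # perfect concordance
  r <- matrix(rep(1:5, 3), nrow = 3, byrow = TRUE)
  expect_equal(kendalls_w(r)$W, 1)
  # exactly reversed rankings of 4 subjects by 2 raters
  rev2 <- rbind(1:4, 4:1)
  kw <- kendalls_w(rev2)
  expect_equal(kw$W, kendalls_w_bruteforce(rev2))
  expect_equal(kw$W, 0)                      # rank sums all equal
  # random matrices, with and without ties
  set.seed(14)
  for (i in 1:10) {
    m <- sample(2:5, 1); n <- sample(4:10, 1)
    tied <- matrix(sample(1:5, m * n, TRUE), m, n)
    if (all(apply(tied, 1, function(x) length(unique(x)) == 1))) next
    expect_equal(kendalls_w(tied)$W, kendalls_w_bruteforce(tied))
    untied <- t(replicate(m, sample(1:n)))
    expect_equal(kendalls_w(untied)$W, kendalls_w_bruteforce(untied))
    # no ties: classical 12S/(m^2(n^3-n)) formula
    rk <- t(apply(untied, 1, rank))
    S <- sum((colSums(rk) - mean(colSums(rk)))^2)
    expect_equal(kendalls_w(untied)$W, 12 * S / (m^2 * (n^3 - n)))
  }
})

test_that("W is invariant under subject relabeling and monotone transforms", {
  set.seed(15)
  r <- matrix(sample(1:5, 3 * 8, TRUE), 3, 8)
  w0 <- kendalls_w(r)$W
  perm <- sample(8)
  expect_equal(kendalls_w(r[, perm])$W, w0)
  r2 <- r
  r2[2, ] <- 2 * r2[2, ] + 7                   # monotone transform, one rater
  expect_equal(kendalls_w(r2)$W, w0)
  # degenerate: every rater rates every subject identically
  expect_error(kendalls_w(matrix(3, 3, 4)), "undefined")
})

test_that("chi-square significance of W behaves sensibly", {
  r <- matrix(rep(1:6, 4), nrow = 4, byrow = TRUE)
  kw <- kendalls_w(r)
  expect_equal(kw$df, 5)
  expect_equal(kw$chisq, 4 * 5 * kw$W)
  expect_lt(kw$p, 0.01)                        # strong concordance
})

test_that("coefficient of variation is 100*sd/mean and scale-free", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(10, 20, 30)), 50)   # sd 10, mean 20
  x <- rlnorm(20)
  expect_equal(coefficient_of_variation(3.2 * x),
               coefficient_of_variation(x))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  expect_error(coefficient_of_variation(numeric(0)), "non-empty")
})

test_that("two-sample sample size reproduces the design calculation", {
  expect_equal(sample_size_two_means(16, 2, 13, 3, alpha = 0.05,
                                     power = 0.75), 12)
  # enormous effect hits the floor of n = 2
  expect_equal(sample_size_two_means(10, 1, 0, 1, 0.05, 0.75), 2)
  # more power demands more subjects
  expect_gt(sample_size_two_means(16, 2, 13, 3, 0.05, 0.90),
            sample_size_two_means(16, 2, 13, 3, 0.05, 0.75))
  expect_error(sample_size_two_means(10, 1, 10, 1), "zero effect")
  expect_error(sample_size_two_means(10, 0, 12, 1), "deviations")
})

test_that("noncentral-t sample size tracks the normal approximation", {
  za <- qnorm(0.975)
  for (case in list(c(10, 2, 10.8, 2, 0.8), c(5, 1.5, 5.5, 1.5, 0.9),
                    c(0, 3, 1, 3, 0.75))) {
    sp <- sqrt((case[2]^2 + case[4]^2) / 2)
    d <- abs(case[1] - case[3])
    n_norm <- ceiling(2 * (za + qnorm(case[5]))^2 * sp^2 / d^2)
    n_t <- sample_size_two_means(case[1], case[2], case[3], case[4],
                                 0.05, case[5])
    if (n_t >= 30) expect_lte(abs(n_t - n_norm), 2)
  }
})

test_that("score tables match a brute-force group-by", {
  set.seed(16)
  rows <- list()
  for (rd in c("R1", "R2", "R3")) for (st in sprintf("S%02d", 1:16))
    for (fr in c(50, 66, 75)) {
      rows[[length(rows) + 1L]] <-
        reader_score(rd, st, fr, sample(1:5, 1), sample(1:5, 1),
                     sample(1:5, 1), sample(1:5, 1))
    }
  scores <- do.call(rbind, rows)
  tab <- score_table_summary(scores)
  # 3 levels x (3 readers + Total)
  expect_equal(nrow(tab), 12)
  for (i in seq_len(nrow(tab))) {
    sub <- scores[scores$frr_level == tab$frr_level[i], ]
    if (tab$reader[i] != "Total")
      sub <- sub[sub$reader_id == tab$reader[i], ]
    x <- sub$composite
    expect_equal(tab$n[i], length(x))
    expect_equal(tab$mean[i], mean(x))
    expect_equal(tab$sd[i], sd(x))
    expect_equal(tab$ci_lower[i], mean(x) - qt(0.975, length(x) - 1) *
                   sd(x) / sqrt(length(x)))
  }
  # singleton and constant groups
  one <- score_table_summary(reader_score("R1", "S1", 50, 4, 4, 4, 4))
  expect_true(all(is.na(one$sd[one$n == 1])))
  const <- score_table_summary(do.call(rbind, rep(list(
    reader_score("R1", "S1", 50, 4, 4, 4, 4)), 3)))
  tot <- const[const$reader == "Total", ]
  expect_equal(tot$sd, 0)
  expect_equal(tot$ci_upper - tot$ci_lower, 0)
})

test_that("reader-score CSVs round-trip with composite derivation", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("reader_id,study_id,frr,arterial,capillary,venous,overall",
               "R1,S1,50,4,3,5,4", "R2,S1,50,2,2,3,3"), path)
  d <- read_reader_scores(path)
  expect_equal(d$composite, c(16L, 10L))
  writeLines(c("reader_id,study_id,frr,arterial", "R1,S1,50,4"), path)
  expect_error(read_reader_scores(path), "missing columns")
})
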