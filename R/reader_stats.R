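#' One rater's rubric scores for one study
#'
#' The subjective image-grading rubric scores four items from 1 to 5 —
#' arterial phase, capillary phase, venous phase, and overall image
#' quality — so the composite score ranges from 4 (uninterpretable, no
#' desired anatomy seen) to 20 (perfect reproduction at higher than needed
#' quality).
#'
#' @param reader_id,study_id Identifiers (coerced to character).
#' @param frr_level Frame-rate-reduction label of the graded study
#'   (e.g. 50, 66, 75).
#' @param arterial,capillary,venous,overall_quality Integer sub-scores in 1-5.
#' @return An object of class \code{reader_score} (a one-row data frame with
#'   a derived \code{composite} column).
#' @export
reader_score <- function(reader_id, study_id, frr_level, arterial, capillary,
                         venous, overall_quality) {
  subs <- c(arterial = arterial, capillary = capillary, venous = venous,
            overall_quality = overall_quality)
  for (nm in names(subs)) {
    v <- subs[[nm]]
    if (length(v) != 1L || is.na(v) || v != as.integer(v) || v < 1 || v > 5)
      stop("reader_score: sub-score '", nm, "' must be an integer in 1..5",
           call. = FALSE)
  }
  d <- data.frame(reader_id = as.character(reader_id),
                  study_id = as.character(study_id),
                  frr_level = as.character(frr_level),
                  arterial = as.integer(arterial),
                  capillary = as.integer(capillary),
                  venous = as.integer(venous),
                  overall_quality = as.integer(overall_quality))
  d$composite <- d$arterial + d$capillary + d$venous + d$overall_quality
  class(d) <- c("reader_score", "data.frame")
  d
}

#' Composite rubric score
#'
#' Sum of the four 1-5 sub-scores; always in [4, 20].
#'
#' @param score A \code{\link{reader_score}} or a data frame with columns
#'   \code{arterial}, \code{capillary}, \code{venous},
#'   \code{overall_quality}.
#' @return Integer composite score(s).
#' @export
composite_score <- function(score) {
  need <- c("arterial", "capillary", "venous", "overall_quality")
  stopifnot(is.data.frame(score), all(need %in% names(score)))
  sub <- as.matrix(score[need])
  if (any(is.na(sub)) || any(sub < 1) || any(sub > 5) ||
      any(sub != round(sub)))
    stop("composite_score: sub-scores must be integers in 1..5",
         call. = FALSE)
  as.integer(rowSums(sub))
}

#' Read reader scores from CSV
#'
#' Expected columns: \code{reader_id}, \code{study_id}, \code{frr}
#' (or \code{frr_level}), \code{arterial}, \code{capillary}, \code{venous},
#' \code{overall} (or \code{overall_quality}).
#'
#' @param path CSV file.
#' @return Data frame of validated scores with a \code{composite} column.
#' @export
read_reader_scores <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(d)[names(d) == "frr"] <- "frr_level"
  names(d)[names(d) == "overall"] <- "overall_quality"
  need <- c("reader_id", "study_id", "frr_level", "arterial", "capillary",
            "venous", "overall_quality")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_reader_scores: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d$composite <- composite_score(d)
  d$frr_level <- as.character(d$frr_level)
  d
}

#' Kendall's coefficient of concordance (tie-corrected)
#'
#' Agreement among \code{m} raters ranking \code{n} subjects.  Scores are
#' converted to mid-ranks within each rater (the rubric is heavily tied), and
#' \deqn{W = \frac{12 S}{m^2 (n^3 - n) - m T},}
#' where \code{S} is the sum of squared deviations of the column rank sums
#' from their mean and \code{T} the tie correction
#' \eqn{\sum (t^3 - t)} over tie groups of all raters.  Without ties this
#' reduces to the classical \code{12 S / (m^2 (n^3 - n))}.  Significance uses
#' the chi-square approximation \eqn{\chi^2 = m (n - 1) W} with
#' \code{n - 1} degrees of freedom.
#'
#' @param ratings Numeric matrix, raters in rows, subjects in columns.
#' @return List with \code{W} (in [0, 1]), \code{p}, \code{chisq}, \code{df}.
#' @export
kendalls_w <- function(ratings) {
  ratings <- as.matrix(ratings)
  m <- nrow(ratings); n <- ncol(ratings)
  if (m < 2L || n < 2L)
    stop("kendalls_w: need at least 2 raters and 2 subjects", call. = FALSE)
  if (any(!is.finite(ratings)))
    stop("kendalls_w: ratings must be finite", call. = FALSE)
  if (all(apply(ratings, 1, function(r) length(unique(r)) == 1L)))
    stop("kendalls_w: undefined (all raters rate every subject equally)",
         call. = FALSE)
  rk <- t(apply(ratings, 1, rank))            # mid-ranks within each rater
  colsum <- colSums(rk)
  S <- sum((colsum - mean(colsum))^2)
  Tcorr <- sum(apply(rk, 1, function(r) {
    tg <- table(r); sum(tg^3 - tg)
  }))
  denom <- m^2 * (n^3 - n) - m * Tcorr
  if (denom <= 0)
    stop("kendalls_w: undefined (all raters rate every subject equally)",
         call. = FALSE)
  W <- 12 * S / denom
  chisq <- m * (n - 1) * W
  list(W = W, p = stats::pchisq(chisq, df = n - 1, lower.tail = FALSE),
       chisq = chisq, df = n - 1)
}

#' Coefficient of variation
#'
#' \code{100 * sd / mean} with the sample standard deviation (n - 1
#' denominator); unitless, reported in percent.
#'
#' @param values Non-empty numeric series with nonzero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (!length(values) || any(!is.finite(values)))
    stop("coefficient_of_variation: need a non-empty finite series",
         call. = FALSE)
  m <- mean(values)
  if (m == 0)
    stop("coefficient_of_variation: undefined for zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Sample size for comparing two means (two-sided t-test)
#'
#' Smallest per-group \code{n} such that a two-sided two-sample t-test with
#' pooled standard deviation \code{sqrt((sd1^2 + sd2^2) / 2)} detects the
#' difference \code{|mean1 - mean2|} with the requested power, using the
#' noncentral-t distribution at \code{2n - 2} degrees of freedom.
#'
#' @param mean1,sd1 Hypothesized mean and SD of group 1.
#' @param mean2,sd2 Hypothesized mean and SD of group 2.
#' @param alpha Two-sided type-I error rate (default 0.05).
#' @param power Target power, in (0, 1) (default 0.75).
#' @return Integer sample size per group, >= 2.
#' @export
sample_size_two_means <- function(mean1, sd1, mean2, sd2, alpha = 0.05,
                                  power = 0.75) {
  if (sd1 <= 0 || sd2 <= 0)
    stop("sample_size_two_means: standard deviations must be > 0",
         call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("sample_size_two_means: alpha and power must lie in (0, 1)",
         call. = FALSE)
  delta <- abs(mean1 - mean2)
  if (delta == 0)
    stop("sample_size_two_means: zero effect size is infeasible",
         call. = FALSE)
  sp <- sqrt((sd1^2 + sd2^2) / 2)
  for (n in 2:1e6) {
    df <- 2 * n - 2
    ncp <- delta / (sp * sqrt(2 / n))
    tc <- stats::qt(1 - alpha / 2, df)
    pw <- stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tc, df, ncp = ncp)
    if (pw >= power) return(n)
  }
  stop("sample_size_two_means: no feasible n found", call. = FALSE)
}

#' Summary table of reader scores by reduction level and reader
#'
#' Groups composite scores by \code{(frr_level, reader_id)} and adds a
#' \code{"Total"} row per level: \code{n}, mean, sample SD, observed range,
#' and the t-based 95\% confidence interval
#' \code{mean +/- t(0.975, n-1) sd / sqrt(n)}.  SD and CI are blank
#' (\code{NA}) for singleton groups.
#'
#' @param scores Data frame with columns \code{frr_level} (or \code{frr}),
#'   \code{reader_id} and either \code{composite} or the four sub-score
#'   columns.
#' @return Data frame with columns \code{frr_level}, \code{reader},
#'   \code{n}, \code{mean}, \code{sd}, \code{min}, \code{max},
#'   \code{ci_lower}, \code{ci_upper}.
#' @export
score_table_summary <- function(scores) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 1L)
  names(scores)[names(scores) == "frr"] <- "frr_level"
  if (!"composite" %in% names(scores))
    scores$composite <- composite_score(scores)
  one <- function(x, level, reader) {
    n <- length(x)
    s <- if (n > 1) stats::sd(x) else NA_real_
    hw <- if (n > 1) stats::qt(0.975, n - 1) * s / sqrt(n) else NA_real_
    data.frame(frr_level = level, reader = reader, n = n, mean = mean(x),
               sd = s, min = min(x), max = max(x),
               ci_lower = mean(x) - hw, ci_upper = mean(x) + hw)
  }
  levels <- sort(unique(as.character(scores$frr_level)))
  out <- list()
  for (lv in levels) {
    sub <- scores[as.character(scores$frr_level) == lv, ]
    for (rd in sort(unique(as.character(sub$reader_id)))) {
      out[[length(out) + 1L]] <-
        one(sub$composite[as.character(sub$reader_id) == rd], lv, rd)
    }
    out[[length(out) + 1L]] <- one(sub$composite, lv, "Total")
  }
  do.call(rbind, out)
}
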