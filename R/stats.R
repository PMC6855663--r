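#' One-way fixed-effects analysis of variance
#'
#' Classical one-way ANOVA computed from the between/within sums of squares:
#' F = MS_between / MS_within with a p-value from the F distribution.
#' Implemented directly from the decomposition so the arithmetic is
#' auditable; base R's `aov()` serves as an independent cross-check in the
#' test-suite. When all observations are identical, F = 0 and p = 1; when
#' the within-group variance is zero but means differ, F is infinite and
#' p = 0 (flagged with a warning).
#'
#' @param groups list of >= 2 numeric vectors, one sample per group.
#' @return list with `F`, `dfBetween`, `dfWithin`, `p`.
#' @examples
#' oneWayAnova(list(c(1, 2), c(3, 4)))
#' @export
oneWayAnova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  n <- lengths(groups)
  if (any(n < 1)) stop("every group needs at least one observation", call. = FALSE)
  k <- length(groups)
  N <- sum(n)
  if (N - k < 1) stop("insufficient within-group degrees of freedom", call. = FALSE)
  all <- unlist(groups)
  grand <- mean(all)
  means <- vapply(groups, mean, numeric(1))
  ssB <- sum(n * (means - grand)^2)
  ssW <- sum(vapply(seq_len(k),
                    function(i) sum((groups[[i]] - means[i])^2), numeric(1)))
  dfB <- k - 1
  dfW <- N - k
  if (ssW == 0) {
    if (ssB == 0) return(list(F = 0, dfBetween = dfB, dfWithin = dfW, p = 1))
    warning("zero within-group variance with unequal means; F infinite", call. = FALSE)
    return(list(F = Inf, dfBetween = dfB, dfWithin = dfW, p = 0))
  }
  F <- (ssB / dfB) / (ssW / dfW)
  list(F = F, dfBetween = dfB, dfWithin = dfW,
       p = pf(F, dfB, dfW, lower.tail = FALSE))
}

#' Two-sample t-test
#'
#' Two-sided Student's t-test with pooled variance by default (the
#' convention behind "Student's t-test"); set `equalVar = FALSE` for the
#' Welch variant when group variances plainly differ. Degenerate zero-
#' variance input follows the continuity conventions: equal means give
#' t = 0, p = 1; unequal means give signed infinite t, p = 0 (flagged).
#'
#' @param a,b numeric samples, each with >= 2 observations.
#' @param equalVar pool the variances (default `TRUE`).
#' @return list with `t`, `df`, `p`.
#' @examples
#' twoSampleT(c(1, 2, 3), c(2, 3, 4))
#' @export
twoSampleT <- function(a, b, equalVar = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  delta <- mean(a) - mean(b)
  if (equalVar) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    df <- na + nb - 2
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (se == 0) {
    if (delta == 0) return(list(t = 0, df = df, p = 1))
    warning("zero variance with unequal means; t infinite", call. = FALSE)
    return(list(t = sign(delta) * Inf, df = df, p = 0))
  }
  t <- delta / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Holm (Bonferroni-Holm) step-down p-value adjustment
#'
#' Orders the m raw p-values ascending, multiplies the i-th smallest by
#' (m - i + 1), enforces monotonicity by a running maximum and caps at 1,
#' then returns the adjusted values in the original order. Controls the
#' family-wise error rate and is uniformly no more conservative than plain
#' Bonferroni.
#'
#' @param p raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @examples
#' holmAdjust(c(0.01, 0.02, 0.03))
#' @export
holmAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  adj[order(o)]
}

#' Per-day group comparisons with Holm correction
#'
#' For each requested measurement day, runs the omnibus one-way ANOVA over
#' per-animal RTVs of all arms, plus every pairwise two-sample t-test, and
#' applies the Holm correction. The correction family for the pairwise
#' tests is configurable: `"per-day"` (default) treats each day's set of
#' pairwise comparisons as one family, matching per-day reporting;
#' `"all-days"` pools every pairwise comparison across the analysed days
#' into a single family. The omnibus ANOVA p-values are adjusted as their
#' own family across days in both modes.
#'
#' @param cohort a [TumourCohort-class].
#' @param rtvs optional precomputed [relativeVolumes()] output.
#' @param days days to analyse; default: all post-baseline days on which
#'   every arm still has >= 2 measured animals.
#' @param family `"per-day"` or `"all-days"`.
#' @param equalVar passed to [twoSampleT()].
#' @param alpha significance level for the `significant` flag.
#' @return data.frame with columns `day`, `comparison`, `statistic`,
#'   `raw_p`, `adjusted_p`, `significant`.
#' @export
groupComparisons <- function(cohort, rtvs = relativeVolumes(cohort),
                             days = NULL, family = c("per-day", "all-days"),
                             equalVar = TRUE, alpha = 0.05) {
  stopifnot(is(cohort, "TumourCohort"))
  family <- match.arg(family)
  rtvs <- rtvs[!is.na(rtvs$rtv) & rtvs$day > 0, ]
  armNames <- arms(cohort)
  if (is.null(days)) {
    cnt <- table(rtvs$group, rtvs$day)
    ok <- apply(cnt >= 2, 2, all) & colSums(cnt > 0) == length(armNames)
    days <- as.numeric(colnames(cnt)[ok])
  }
  rows <- list()
  for (d in days) {
    samp <- lapply(armNames, function(g) rtvs$rtv[rtvs$group == g & rtvs$day == d])
    names(samp) <- armNames
    av <- oneWayAnova(samp)
    rows[[length(rows) + 1L]] <- data.frame(
      day = d, comparison = "anova", statistic = av$F, raw_p = av$p,
      stringsAsFactors = FALSE)
    prs <- utils::combn(armNames, 2)
    for (j in seq_len(ncol(prs))) {
      tt <- twoSampleT(samp[[prs[1, j]]], samp[[prs[2, j]]], equalVar = equalVar)
      rows[[length(rows) + 1L]] <- data.frame(
        day = d, comparison = paste(prs[1, j], "vs", prs[2, j]),
        statistic = tt$t, raw_p = tt$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- NA_real_
  isAnova <- out$comparison == "anova"
  out$adjusted_p[isAnova] <- holmAdjust(out$raw_p[isAnova])
  if (family == "per-day") {
    for (d in unique(out$day)) {
      idx <- !isAnova & out$day == d
      out$adjusted_p[idx] <- holmAdjust(out$raw_p[idx])
    }
  } else {
    out$adjusted_p[!isAnova] <- holmAdjust(out$raw_p[!isAnova])
  }
  out$significant <- out$adjusted_p < alpha
  rownames(out) <- NULL
  out
}
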