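#' One-way ANOVA from raw vectors or printed summaries
#'
#' Classical (equal-variance) one-way analysis of variance. Two input forms
#' are accepted: a list of per-subject numeric vectors, or a data.frame of
#' per-group summaries with columns \code{mean}, \code{sd} (sample, n-1
#' denominator), and \code{n}. The summary path reconstructs the
#' between-group sum of squares from means and the within-group sum of
#' squares from \eqn{(n_g - 1) s_g^2}, which is algebraically exact when the
#' summaries are exact; from a published table rounded to 2 decimals the F
#' statistic is reproduced only to a few percent.
#'
#' @param x List of numeric vectors (one per group), or a data.frame with
#'   columns \code{mean}, \code{sd}, \code{n}.
#' @return List with \code{F}, \code{p}, \code{df1}, \code{df2}.
#' @examples
#' anovaOneway(data.frame(mean = c(62.16, 61.85, 66.81),
#'                        sd = c(7.66, 6.56, 8.04), n = c(43, 26, 43)))
#' @export
anovaOneway <- function(x) {
  if (is.data.frame(x)) {
    need <- c("mean", "sd", "n")
    if (!all(need %in% colnames(x)))
      stop("summary input needs columns mean, sd, n")
    k <- nrow(x)
    if (k < 2L) stop("ANOVA needs >= 2 groups")
    if (any(x$n < 2L)) stop("each group needs n >= 2")
    N <- sum(x$n)
    gm <- sum(x$n * x$mean) / N
    ssb <- sum(x$n * (x$mean - gm)^2)
    ssw <- sum((x$n - 1) * x$sd^2)
    if (ssw == 0) stop("zero within-group variance in every group")
    Fst <- (ssb / (k - 1)) / (ssw / (N - k))
    return(list(F = Fst, p = stats::pf(Fst, k - 1, N - k, lower.tail = FALSE),
                df1 = k - 1, df2 = N - k))
  }
  stopifnot(is.list(x))
  if (length(x) < 2L) stop("ANOVA needs >= 2 groups")
  if (any(vapply(x, length, 0L) < 2L)) stop("each group needs n >= 2")
  g <- factor(rep(seq_along(x), vapply(x, length, 0L)))
  y <- unlist(x, use.names = FALSE)
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p = ft$p.value,
       df1 = unname(ft$parameter[1L]), df2 = unname(ft$parameter[2L]))
}

#' Pearson chi-square test of independence
#'
#' \eqn{\chi^2 = \sum (O - E)^2 / E} with expectations from the row and
#' column margins; no continuity correction (matching the group x sex
#' contingency analysis of demographic tables).
#'
#' @param counts Matrix of non-negative integer counts, >= 2 rows and
#'   >= 2 columns.
#' @return List with \code{statistic}, \code{p}, \code{df}.
#' @examples
#' chiSquareIndependence(rbind(CN = c(17, 26), bvFTD = c(17, 9),
#'                             PPA = c(24, 19)))
#' @export
chiSquareIndependence <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table needs >= 2 rows and >= 2 columns")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column margin")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Kruskal-Wallis test from an ordinal count table
#'
#' For an ordinal variable recorded as per-group category counts (e.g.
#' Clinical Dementia Rating: None < Very mild < Mild < Moderate < Severe),
#' assigns every subject in a category its mid-rank, computes
#' \deqn{H = \frac{12}{N(N+1)} \sum_g \frac{R_g^2}{n_g} - 3(N+1)}
#' and divides by the tie correction
#' \eqn{1 - \sum_c (t_c^3 - t_c)/(N^3 - N)}, where \eqn{t_c} is the number of
#' subjects in category c. No installed routine consumes count tables
#' directly, so the closed form is computed here; it agrees exactly with
#' \code{kruskal.test} run on the expanded per-subject data.
#'
#' @param counts Groups x categories matrix of non-negative integer counts;
#'   category columns must be in ascending ordinal order.
#' @return List with \code{H} (tie-corrected), \code{p} (asymptotic
#'   chi-square with groups - 1 df), \code{df}.
#' @examples
#' cdr <- rbind(CN    = c(43, 0, 0, 0, 0),
#'              bvFTD = c(0, 1, 9, 16, 0),
#'              PPA   = c(0, 24, 10, 9, 0))
#' kruskalWallisOrdinal(cdr)  # H = 92.91
#' @export
kruskalWallisOrdinal <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L) stop("need >= 2 groups")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0)) stop("empty group")
  t_c <- colSums(counts)
  if (sum(t_c > 0) < 2L)
    stop("all subjects in one category: H is undefined (tie correction is 0)")
  N <- sum(t_c)
  # mid-rank of category c: ranks (cum_{c-1}+1) .. cum_c average to
  # cum_{c-1} + (t_c + 1)/2
  midrank <- cumsum(t_c) - t_c + (t_c + 1) / 2
  Rg <- as.vector(counts %*% midrank)
  ng <- rowSums(counts)
  H <- 12 / (N * (N + 1)) * sum(Rg^2 / ng) - 3 * (N + 1)
  tie <- 1 - sum(t_c^3 - t_c) / (N^3 - N)
  H <- H / tie
  df <- nrow(counts) - 1L
  list(H = H, p = stats::pchisq(H, df, lower.tail = FALSE), df = df)
}

#' Bonferroni-corrected pairwise t tests
#'
#' All pairwise two-sample (pooled-variance) t tests between the groups; a
#' pair is flagged significant iff its unadjusted p is at most
#' \code{alpha / n_pairs}.
#'
#' @param groupValues Named list of per-subject numeric vectors.
#' @param alpha Family-wise level (default 0.05).
#' @return data.frame with columns group1, group2, t, p, p_threshold,
#'   significant.
#' @export
bonferroniPairwise <- function(groupValues, alpha = 0.05) {
  stopifnot(is.list(groupValues), length(groupValues) >= 2L)
  if (is.null(names(groupValues)))
    names(groupValues) <- paste0("group", seq_along(groupValues))
  if (any(vapply(groupValues, length, 0L) < 2L))
    stop("each group needs n >= 2")
  pairs <- utils::combn(names(groupValues), 2L)
  nPairs <- ncol(pairs)
  out <- lapply(seq_len(nPairs), function(k) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    ht <- stats::t.test(groupValues[[g1]], groupValues[[g2]],
                        var.equal = TRUE)
    data.frame(group1 = g1, group2 = g2, t = unname(ht$statistic),
               p = ht$p.value, p_threshold = alpha / nPairs,
               significant = ht$p.value <= alpha / nPairs)
  })
  do.call(rbind, out)
}

#' Demographic summary table for a cohort
#'
#' Per-group mean and sample (n-1) SD of the continuous covariates, with the
#' one-way ANOVA F and p per variable and the group x sex chi-square -- the
#' shape of a clinical Table 1.
#'
#' @param cohort A \linkS4class{CohortTable}.
#' @param variables Continuous covariates to summarize (default age and
#'   education).
#' @return data.frame with one row per (variable, group) plus test columns.
#' @export
cohortStats <- function(cohort, variables = c("age", "education")) {
  stopifnot(is(cohort, "CohortTable"))
  cd <- as.data.frame(colData(cohort))
  gs <- split(cd, cd$group)
  rows <- list()
  for (v in variables) {
    an <- anovaOneway(lapply(gs, `[[`, v))
    for (g in names(gs))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, group = g, n = nrow(gs[[g]]),
        mean = mean(gs[[g]][[v]]), sd = stats::sd(gs[[g]][[v]]),
        F = an$F, p = an$p)
  }
  out <- do.call(rbind, rows)
  sexTab <- table(cd$group, factor(cd$sex, levels = c(0, 1)))
  cs <- tryCatch(chiSquareIndependence(unclass(sexTab)),
                 error = function(e) list(statistic = NA_real_, p = NA_real_))
  attr(out, "sex_chisq") <- cs$statistic
  attr(out, "sex_chisq_p") <- cs$p
  out
}
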