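#' Assign specimens to age-quartile groups
#'
#' Groups are cut at the sample age quartiles with right-closed intervals
#' ("> a to <= b"), the boundary convention of cohort tables of the form
#' group 1 <= q1, group 2 in (q1, q2], group 3 in (q2, q3], group 4 > q3.
#' With distinct ages this yields counts as balanced as ties permit.
#'
#' @param ages Named numeric vector of ages in years (names = specimen ids),
#'   or a data frame with columns `specimen_id` and `age`.
#' @return Named integer vector mapping each specimen id to group 1..4.
#' @export
assign_age_quartiles <- function(ages) {
  if (is.data.frame(ages)) ages <- stats::setNames(ages$age, ages$specimen_id)
  if (is.null(names(ages)) || !all(nzchar(names(ages))))
    stop("ages must be named by specimen id")
  if (anyNA(ages))
    stop("missing age for specimen(s): ",
         paste(names(ages)[is.na(ages)], collapse = ", "))
  q <- stats::quantile(ages, c(0.25, 0.5, 0.75), names = FALSE)
  if (anyDuplicated(q))
    stop("degenerate quartiles: cut points coincide (ages too tied)")
  grp <- 1L + (ages > q[1]) + (ages > q[2]) + (ages > q[3])
  stats::setNames(as.integer(grp), names(ages))
}

#' Shapiro-Wilk normality gate
#'
#' Wraps the Shapiro-Wilk test (Royston's approximation, as implemented in
#' \code{stats::shapiro.test}) and reports whether the sample passes the
#' normality gate at alpha = 0.05 — the precondition for the parametric
#' ANOVA/t-test branch of the battery.
#'
#' @param values Numeric vector, 3 to 5000 non-missing values, not constant.
#' @return List with `statistic` (W), `p_value`, and `normal` (logical).
#' @export
shapiro_wilk_gate <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L || length(values) > 5000L)
    stop("Shapiro-Wilk requires between 3 and 5000 values")
  if (diff(range(values)) == 0)
    stop("degenerate input: all values identical")
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       normal = sw$p.value > 0.05)
}

#' Factorial ANOVA of complexity scores on age and sex
#'
#' Fits `score ~ age + sex + age:sex` with age continuous (each term then
#' has one degree of freedom) and sex as a two-level factor, and reports the
#' sequential (type I) ANOVA table. A factor-coded age variant
#' (`age_as_factor = TRUE`, quartile groups, 3 DF) is available for
#' sensitivity analysis.
#'
#' @param scores Per-specimen complexity scores.
#' @param ages Ages in years, same length; `NULL` fits the sex-only model
#'   `score ~ sex` (in which the sex F statistic equals the squared pooled
#'   two-sample t statistic).
#' @param sexes `"male"`/`"female"`, same length; both levels must occur.
#' @param age_as_factor Code age as quartile groups instead of a covariate.
#' @return An object of class `anova_table`: data frame with columns
#'   `term`, `df`, `sum_sq`, `f`, `p` (residual row included, F/p `NA`).
#' @export
complexity_anova <- function(scores, ages, sexes, age_as_factor = FALSE) {
  sex_only <- is.null(ages)
  if (sex_only) ages <- rep(0, length(scores))
  stopifnot(length(scores) == length(ages), length(scores) == length(sexes))
  keep <- !(is.na(scores) | is.na(ages) | is.na(sexes))
  if (sum(keep) < 5L) stop("need at least 5 complete cases")
  scores <- scores[keep]; ages <- ages[keep]; sexes <- sexes[keep]
  sexes <- factor(sexes, levels = c("female", "male"))
  if (nlevels(droplevels(sexes)) < 2L)
    stop("both sexes must be present in the cohort")
  age_term <- if (age_as_factor) {
    factor(assign_age_quartiles(stats::setNames(ages, seq_along(ages))))
  } else ages
  fit <- if (sex_only) stats::lm(scores ~ sexes)
  else stats::lm(scores ~ age_term * sexes)
  at <- stats::anova(fit)
  terms <- if (sex_only) c("sex", "residuals")
  else c("age", "sex", "age:sex", "residuals")
  out <- data.frame(term = terms,
                    df = as.integer(at$Df),
                    sum_sq = at$`Sum Sq`,
                    f = at$`F value`,
                    p = at$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  attr(out, "age_coding") <- if (sex_only) "none (sex-only model)"
  else if (age_as_factor) "quartile factor" else "continuous"
  attr(out, "ss_type") <- "sequential (type I)"
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, ...) {
  cat("ANOVA of complexity score (age ", attr(x, "age_coding"),
      ", ", attr(x, "ss_type"), " sums of squares)\n", sep = "")
  print.data.frame(data.frame(term = x$term, df = x$df,
                              F = signif(x$f, 5), p = signif(x$p, 4)),
                   row.names = FALSE)
  invisible(x)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down Holm correction of a vector of p values (computed through
#' \code{stats::p.adjust}): sorted ascending, p(i) is multiplied by
#' m - i + 1, a running maximum is enforced, values are capped at 1, and the
#' result is returned in the input order.
#'
#' @param pvalues Numeric vector of p values in [0, 1].
#' @return Adjusted p values, same order and length.
#' @export
holm_adjust <- function(pvalues) {
  if (!length(pvalues)) stop("empty p-value vector")
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "holm")
}

#' Pairwise age-group comparisons of complexity scores
#'
#' Welch (unequal-variance) two-sample t tests for every unordered pair of
#' groups, with Holm-Bonferroni adjustment across all pairs. A
#' pooled-variance variant is available via `var_equal`.
#'
#' @param scores Per-specimen complexity scores.
#' @param groups Group labels (e.g. age quartiles 1..4), same length;
#'   at least two groups, each with at least two members.
#' @param var_equal Use the pooled-variance t test instead of Welch.
#' @param alpha Significance level for the flags (default 0.05).
#' @return An object of class `pairwise_report`: data frame with columns
#'   `group1`, `group2`, `t`, `df`, `p_raw`, `p_holm`, `significant`.
#' @export
pairwise_group_tests <- function(scores, groups, var_equal = FALSE,
                                 alpha = 0.05) {
  stopifnot(length(scores) == length(groups))
  keep <- !(is.na(scores) | is.na(groups))
  scores <- scores[keep]; groups <- groups[keep]
  lv <- sort(unique(groups))
  if (length(lv) < 2L) stop("need at least two groups")
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop("every group needs at least 2 members (group ",
         names(sizes)[sizes < 2L][1L], " has ", min(sizes), ")")
  pairs <- utils::combn(lv, 2L)
  rows <- apply(pairs, 2L, function(pr) {
    tt <- stats::t.test(scores[groups == pr[1L]], scores[groups == pr[2L]],
                        var.equal = var_equal)
    c(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  })
  out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    t = rows["t", ], df = rows["df", ], p_raw = rows["p", ],
                    stringsAsFactors = FALSE)
  out$p_holm <- holm_adjust(out$p_raw)
  out$significant <- out$p_holm < alpha
  attr(out, "variant") <- if (var_equal) "pooled-variance t" else "Welch t"
  class(out) <- c("pairwise_report", "data.frame")
  out
}

#' @export
print.pairwise_report <- function(x, ...) {
  cat("Pairwise group comparisons (", attr(x, "variant"),
      ", Holm-adjusted)\n", sep = "")
  print.data.frame(data.frame(pair = paste(x$group1, "vs", x$group2),
                              p_raw = signif(x$p_raw, 4),
                              p_holm = signif(x$p_holm, 4),
                              sig = ifelse(x$significant, "*", "")),
                   row.names = FALSE)
  invisible(x)
}

#' Intra-rater intraclass correlation between two digitisation sessions
#'
#' Two-way model, absolute agreement, single measurement — ICC(A,1) — from
#' the standard mean-squares decomposition of the subjects x sessions table:
#' \deqn{ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E) / n)}
#' with subject mean square MS_R, session mean square MS_C, residual MS_E,
#' n subjects and k = 2 sessions. The consistency form ICC(C,1), which
#' ignores session-level offsets, is reported alongside; the model
#' descriptor is always carried so the convention is explicit.
#'
#' @param session1,session2 Named numeric vectors of per-specimen scores
#'   (names = specimen ids); the id sets must match and contain >= 5
#'   specimens.
#' @return An object of class `reliability_report`: `icc`,
#'   `icc_consistency`, `model`, `n_subjects`, `n_sessions`,
#'   `mean_squares`.
#' @export
intra_rater_icc <- function(session1, session2) {
  if (is.null(names(session1)) || is.null(names(session2)))
    stop("session scores must be named by specimen id")
  if (!setequal(names(session1), names(session2)))
    stop("specimen ids differ between sessions: ",
         paste(union(setdiff(names(session1), names(session2)),
                     setdiff(names(session2), names(session1))),
               collapse = ", "))
  ids <- names(session1)
  n <- length(ids)
  if (n < 5L) stop("need at least 5 specimens for a stable ICC")
  m <- cbind(session1[ids], session2[ids])
  k <- 2L
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- sum((m - outer(row_means, rep(1, k)) -
                   outer(rep(1, n), col_means) + grand)^2)
  msr <- ss_rows / (n - 1L)
  msc <- ss_cols / (k - 1L)
  mse <- ss_err / ((n - 1L) * (k - 1L))
  denom_a <- msr + (k - 1L) * mse + k * (msc - mse) / n
  denom_c <- msr + (k - 1L) * mse
  if (denom_a == 0) stop("degenerate data: no variance in either direction")
  structure(list(icc = (msr - mse) / denom_a,
                 icc_consistency = if (denom_c > 0) (msr - mse) / denom_c else NA_real_,
                 model = "two-way, absolute agreement, single measurement (ICC(A,1))",
                 n_subjects = n, n_sessions = k,
                 mean_squares = c(subjects = msr, sessions = msc, error = mse)),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("<reliability_report> ICC = ", format(x$icc, digits = 4), " [",
      x$model, "; ", x$n_subjects, " subjects x ", x$n_sessions,
      " sessions]\n", sep = "")
  invisible(x)
}
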