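#' Configuration of an analysis run
#'
#' Bundles every tunable of the pipeline so a run is reproducible from its
#' serialised config alone: semi-landmark density, sliding and GPA controls,
#' STFT parameters, and statistics flags. The config used is written
#' verbatim into every output directory.
#'
#' @param n_semilandmarks Semi-landmarks per suture (default 500).
#' @param slide_max_iter,slide_tol Sliding controls (see
#'   [slide_semilandmarks()]); `slide_max_iter = 0` skips sliding.
#' @param gpa_tol,gpa_max_iter GPA controls (see [gpa()]).
#' @param complexity A [complexity_params()] object.
#' @param var_equal Pooled-variance instead of Welch pairwise t tests.
#' @param age_as_factor Quartile-factor age coding in the ANOVA.
#' @param seed Seed recorded with the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_semilandmarks = 500L, slide_max_iter = 10L,
                       slide_tol = 1e-6, gpa_tol = 1e-10, gpa_max_iter = 100L,
                       complexity = complexity_params(), var_equal = FALSE,
                       age_as_factor = FALSE, seed = 1L) {
  if (!inherits(complexity, "complexity_params"))
    stop("complexity must be a complexity_params object")
  if (complexity$window_length > n_semilandmarks)
    stop("STFT window length exceeds the semi-landmark count")
  structure(list(n_semilandmarks = as.integer(n_semilandmarks),
                 slide_max_iter = as.integer(slide_max_iter),
                 slide_tol = slide_tol, gpa_tol = gpa_tol,
                 gpa_max_iter = as.integer(gpa_max_iter),
                 complexity = complexity, var_equal = isTRUE(var_equal),
                 age_as_factor = isTRUE(age_as_factor),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full suture analysis on a cohort
#'
#' Resample to equidistant semi-landmarks, slide, superimpose (GPA), build
#' the PCA morphospace, score PSD complexity, and (when requested and ages
#' are available) run the statistical battery: Shapiro-Wilk gate, factorial
#' ANOVA of score on age and sex, and Holm-corrected pairwise age-group t
#' tests. Only session-1 traces are analysed; use [reliability_analysis()]
#' for repeated sessions.
#'
#' @param cohort A [suture_cohort()].
#' @param config A [run_config()].
#' @param stats Run the statistical battery (requires ages for all
#'   specimens, and both sexes for the ANOVA).
#' @return An object of class `suture_analysis`: `aligned`
#'   (`aligned_sample`), `sliding` (`sliding_result`), `pca`
#'   (`pca_shapes`), `complexity` (`complexity_set`), `stats` (list with
#'   `normality`, `anova`, `pairwise`, `groups`; `NULL` when not run), and
#'   `config`.
#' @export
analyze_cohort <- function(cohort, config = run_config(), stats = TRUE) {
  if (!inherits(cohort, "suture_cohort")) stop("cohort must be a suture_cohort")
  ses1 <- cohort_session(cohort, 1L)
  curves <- lapply(ses1$traces, resample_equidistant,
                   n = config$n_semilandmarks)
  sliding <- if (config$slide_max_iter > 0L && length(curves) > 1L)
    slide_semilandmarks(curves, max_iter = config$slide_max_iter,
                        tol = config$slide_tol)
  else NULL
  if (!is.null(sliding)) curves <- sliding$curves
  aligned <- gpa(curves, tol = config$gpa_tol, max_iter = config$gpa_max_iter)
  pca <- if (length(curves) >= 2L) pca_shapes(aligned) else NULL
  cx <- score_sample(aligned, config$complexity)
  st <- NULL
  if (isTRUE(stats)) {
    meta <- cohort_metadata(ses1)
    if (anyNA(meta$age))
      stop("statistics requested but age missing for: ",
           paste(meta$specimen_id[is.na(meta$age)], collapse = ", "))
    scores <- as.data.frame(cx)
    j <- match(scores$specimen_id, meta$specimen_id)
    groups <- if (!is.null(ses1$group_labels))
      ses1$group_labels[scores$specimen_id]
    else assign_age_quartiles(stats::setNames(meta$age[j], meta$specimen_id[j]))
    st <- list(normality = shapiro_wilk_gate(scores$score),
               anova = if (length(unique(stats::na.omit(meta$sex[j]))) == 2L)
                 complexity_anova(scores$score, meta$age[j], meta$sex[j],
                                  age_as_factor = config$age_as_factor)
               else NULL,
               pairwise = pairwise_group_tests(scores$score, unname(groups),
                                               var_equal = config$var_equal),
               groups = groups)
  }
  structure(list(aligned = aligned, sliding = sliding, pca = pca,
                 complexity = cx, stats = st, config = config,
                 cohort = cohort),
            class = "suture_analysis")
}

#' @export
print.suture_analysis <- function(x, ...) {
  s <- vapply(x$complexity$results, `[[`, numeric(1), "score")
  cat("<suture_analysis> ", dim(x$aligned$aligned)[3L], " specimens, ",
      x$config$n_semilandmarks, " semi-landmarks\n", sep = "")
  if (!is.null(x$pca))
    cat("  PC1 ", sprintf("%.1f%%", 100 * x$pca$explained_fraction[1L]),
        ", PC2 ", sprintf("%.1f%%", 100 * x$pca$explained_fraction[min(2L,
          length(x$pca$explained_fraction))]), " of shape variance\n", sep = "")
  cat("  PSD complexity: mean ", format(mean(s), digits = 5), ", sd ",
      format(stats::sd(s), digits = 5), "\n", sep = "")
  if (!is.null(x$stats) && !is.null(x$stats$anova)) {
    a <- x$stats$anova
    cat("  ANOVA: age F = ", format(a$f[1L], digits = 5), " (p = ",
        format(a$p[1L], digits = 3), "); sex F = ",
        format(a$f[2L], digits = 5), " (p = ", format(a$p[2L], digits = 3),
        ")\n", sep = "")
  }
  invisible(x)
}

#' Intra-rater reliability across two digitisation sessions
#'
#' Runs the full pipeline (resample, slide, GPA, PSD score) independently on
#' each session's traces and computes the intraclass correlation of the
#' resulting per-specimen scores.
#'
#' @param cohort A [suture_cohort()] containing both sessions, or the
#'   session-1 cohort when `cohort2` is given.
#' @param cohort2 Optional second-session cohort.
#' @param config A [run_config()].
#' @return A `reliability_report` (see [intra_rater_icc()]) with the
#'   per-session score tables attached as attribute `"scores"`.
#' @export
reliability_analysis <- function(cohort, cohort2 = NULL,
                                 config = run_config()) {
  if (is.null(cohort2)) {
    c1 <- cohort_session(cohort, 1L)
    c2 <- cohort_session(cohort, 2L)
  } else {
    c1 <- cohort_session(cohort, 1L)
    c2 <- cohort_session(cohort2, unique(vapply(cohort2$traces, `[[`,
                                                integer(1), "session"))[1L])
  }
  score_one <- function(ch) {
    an <- analyze_cohort(suture_cohort(lapply(ch$traces, function(tr) {
      tr$session <- 1L; tr
    })), config, stats = FALSE)
    df <- as.data.frame(an$complexity)
    stats::setNames(df$score, df$specimen_id)
  }
  s1 <- score_one(c1)
  s2 <- score_one(c2)
  rep <- intra_rater_icc(s1, s2)
  attr(rep, "scores") <- data.frame(specimen_id = names(s1),
                                    session1 = unname(s1),
                                    session2 = unname(s2[names(s1)]))
  rep
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
}

#' Write all artifacts of an analysis to a directory
#'
#' Emits the aligned coordinates (long table), the morphospace table, the
#' complexity score table with its JSON parameter sidecar, the statistics
#' report as structured JSON, and the exact run config — everything needed
#' to reproduce the run bit for bit.
#'
#' @param analysis A `suture_analysis` from [analyze_cohort()].
#' @param dir Output directory (created if absent).
#' @param figures Also render PNG figures (morphospace scatter, PC extreme
#'   shapes, per-group score box plot).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir, figures = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arr <- analysis$aligned$aligned
  ids <- dimnames(arr)[[3L]]
  aligned_traces <- lapply(seq_along(ids), function(i)
    raw_trace(ids[i], arr[, , i]))
  write_trace_table(suture_cohort(aligned_traces),
                    file.path(dir, "aligned_coordinates.csv"))
  if (!is.null(analysis$pca))
    utils::write.csv(morphospace_table(analysis$pca, analysis$cohort),
                     file.path(dir, "morphospace.csv"), row.names = FALSE)
  write_complexity_scores(analysis$complexity,
                          file.path(dir, "complexity_scores.csv"))
  if (!is.null(analysis$stats)) {
    st <- analysis$stats
    .write_json(list(
      normality = st$normality,
      anova = if (!is.null(st$anova))
        list(age_coding = attr(st$anova, "age_coding"),
             ss_type = attr(st$anova, "ss_type"),
             table = as.data.frame(st$anova)),
      pairwise = if (!is.null(st$pairwise))
        list(variant = attr(st$pairwise, "variant"),
             table = as.data.frame(st$pairwise)),
      groups = as.list(st$groups)),
      file.path(dir, "stats_report.json"))
  }
  cfg <- unclass(analysis$config)
  cfg$complexity <- unclass(cfg$complexity)
  .write_json(cfg, file.path(dir, "run_config.json"))
  if (isTRUE(figures)) {
    grDevices::png(file.path(dir, "morphospace.png"), 800, 600)
    plot_morphospace(analysis); grDevices::dev.off()
    grDevices::png(file.path(dir, "pc_shapes.png"), 800, 600)
    plot_pc_shapes(analysis$pca); grDevices::dev.off()
    if (!is.null(analysis$stats)) {
      grDevices::png(file.path(dir, "group_scores.png"), 800, 600)
      plot_group_scores(analysis); grDevices::dev.off()
    }
  }
  invisible(dir)
}

#' Morphospace scatter (PC1 vs PC2) coloured by group
#' @param analysis A `suture_analysis` with a PCA component.
#' @export
plot_morphospace <- function(analysis) {
  tab <- morphospace_table(analysis$pca, analysis$cohort)
  grp <- if (all(is.na(tab$group))) rep(1L, nrow(tab)) else tab$group
  graphics::plot(tab$pc1, tab$pc2, col = grp, pch = ifelse(
    is.na(tab$sex), 1L, ifelse(tab$sex == "male", 17L, 19L)),
    xlab = sprintf("PC1 (%.1f%%)", 100 * analysis$pca$explained_fraction[1L]),
    ylab = sprintf("PC2 (%.1f%%)", 100 * analysis$pca$explained_fraction[2L]),
    main = "Suture morphospace")
  graphics::abline(h = 0, v = 0, col = "grey80")
}

#' Extreme shape reconstructions along PC1 and PC2
#' @param pca A `pca_shapes` object.
#' @param sd_units Score excursion in units of the component's standard
#'   deviation (default 2).
#' @export
plot_pc_shapes <- function(pca, sd_units = 2) {
  graphics::par(mfrow = c(2, 1), mar = c(2, 2, 2, 1))
  for (pc in 1:2) {
    s <- sd_units * sqrt(pca$eigenvalues[pc])
    lo <- shape_along_pc(pca, pc, -s)
    hi <- shape_along_pc(pca, pc, s)
    graphics::plot(pca$mean_shape, type = "l", col = "grey50", asp = 1,
                   main = sprintf("PC%d: -%g SD (blue) to +%g SD (red)",
                                  pc, sd_units, sd_units),
                   xlab = "", ylab = "")
    graphics::lines(lo, col = "blue")
    graphics::lines(hi, col = "red")
  }
  graphics::par(mfrow = c(1, 1))
}

#' Per-group complexity score box plot
#' @param analysis A `suture_analysis` with statistics.
#' @export
plot_group_scores <- function(analysis) {
  df <- as.data.frame(analysis$complexity)
  grp <- analysis$stats$groups[df$specimen_id]
  graphics::boxplot(df$score ~ grp, xlab = "age group",
                    ylab = "PSD complexity score",
                    main = "Complexity by age group")
}
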