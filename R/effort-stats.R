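# Inferential layer: within-subject z-scoring, repeated-measures ANOVA with
# effect-wise Greenhouse-Geisser correction and an optional between-subject
# covariate, and Bonferroni-corrected paired post hoc comparisons.

#' Z-score a measure within each subject
#'
#' Standardises a per-trial measure across all trials of each individual, so
#' different saccadic parameters can enter the same statistical model.  After
#' transformation each subject's values have mean 0 and SD 1.  Subjects with
#' zero variance get all-zero scores and a warning.
#'
#' @param data A tibble of per-trial values.
#' @param value Column to standardise (tidy-eval).
#' @param subject Subject-identifier column (tidy-eval).
#' @return `data` with an added `z` column.
#' @export
zscore_within_subject <- function(data, value, subject) {
  out <- dplyr::mutate(
    dplyr::group_by(data, {{ subject }}),
    z = {
      v <- {{ value }}
      s <- stats::sd(v)
      if (dplyr::n() < 2 || is.na(s) || s == 0) {
        rlang::warn("Zero variance within a subject: z-scores set to 0.")
        rep(0, dplyr::n())
      } else (v - mean(v)) / s
    })
  dplyr::ungroup(out)
}

#' Mean-center a between-subject covariate
#'
#' @param x One value per subject.
#' @return `x` minus its mean (sums to zero; idempotent).
#' @export
mean_center <- function(x) x - mean(x)

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Univariate repeated-measures ANOVA on a complete subject x within-cell
#' grid of cell means, with optional between-subject terms: a continuous
#' covariate (mean-centered internally; its interactions with the within
#' factors are part of the model) and/or a group factor.  Sphericity is
#' handled by the Greenhouse-Geisser correction with an effect-specific
#' epsilon estimated from each within-effect's contrast covariance; F is
#' unchanged while degrees of freedom and p are scaled by epsilon.  Effects
#' with a single numerator df (two-level factors) are exactly spherical and
#' have epsilon 1.  Effect sizes are partial eta squared,
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Cell means, one row per subject x within-factor cell.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of within-subject factor columns (1-3).
#' @param subject Name of the subject-identifier column.
#' @param covariate Optional name of a subject-level continuous covariate
#'   column.
#' @param between Optional name of a subject-level group factor column.
#' @return An object of class `effort_anova`; its `table` element (also via
#'   [tidy()]) has one row per effect with `effect`, `F`, `df1`, `df2`
#'   (GG-corrected), `epsilon`, `p` (uncorrected), `p_gg`, `eta_p2`.
#' @export
rm_anova <- function(data, dv, within, subject, covariate = NULL,
                     between = NULL) {
  abort_if(length(within) < 1, "Need at least one within-subject factor.",
           class = "ocuvigor_design_error")
  for (w in within) {
    abort_if(length(unique(data[[w]])) < 2,
             sprintf("Within factor `%s` has fewer than 2 levels.", w),
             class = "ocuvigor_design_error")
  }
  cells <- do.call(tidyr::expand_grid,
                   purrr::map(rlang::set_names(within),
                              ~ sort(unique(data[[.x]]))))
  n_cells <- nrow(cells)
  counts <- dplyr::count(data, .data[[subject]])
  bad <- counts[[subject]][counts$n != n_cells]
  abort_if(length(bad) > 0,
           paste("Incomplete within-subject grid for subject(s):",
                 paste(bad, collapse = ", ")),
           class = "ocuvigor_design_error")

  # wide response matrix, columns in `cells` order
  data$.cell <- do.call(paste, c(purrr::map(within, ~ data[[.x]]),
                                 sep = "|"))
  cell_lab <- do.call(paste, c(purrr::map(within, ~ cells[[.x]]),
                               sep = "|"))
  wide <- tidyr::pivot_wider(
    dplyr::select(data, dplyr::all_of(subject), ".cell",
                  dplyr::all_of(dv)),
    names_from = ".cell", values_from = dplyr::all_of(dv))
  abort_if(anyNA(wide), "Missing cell values after pivot.",
           class = "ocuvigor_design_error")
  Y <- as.matrix(wide[, cell_lab, drop = FALSE])

  subj_info <- dplyr::distinct(
    data, dplyr::across(dplyr::all_of(c(subject, covariate, between))))
  subj_info <- subj_info[match(wide[[subject]], subj_info[[subject]]), ]
  rhs <- c(if (!is.null(covariate)) ".cov", if (!is.null(between)) ".grp")
  df_between <- data.frame(row.names = seq_len(nrow(Y)))
  if (!is.null(covariate)) df_between$.cov <- mean_center(subj_info[[covariate]])
  if (!is.null(between)) df_between$.grp <- factor(subj_info[[between]])
  form <- stats::as.formula(
    paste("Y ~", if (length(rhs)) paste(rhs, collapse = " * ") else "1"))
  idata <- as.data.frame(purrr::map(cells, factor))
  idesign <- stats::as.formula(paste("~", paste(within, collapse = " * ")))
  mod <- stats::lm(form, data = df_between)
  an <- car::Anova(mod, idata = idata, idesign = idesign, type = 3)
  s <- suppressWarnings(summary(an, multivariate = FALSE))

  ut <- s$univariate.tests
  tab <- tibble::tibble(
    effect = rownames(ut),
    ss = unname(ut[, "Sum Sq"]), df1 = unname(ut[, "num Df"]),
    ss_err = unname(ut[, "Error SS"]), df2 = unname(ut[, "den Df"]),
    F = unname(ut[, "F value"]), p = unname(ut[, "Pr(>F)"]))
  tab <- tab[tab$effect != "(Intercept)", ]
  tab$epsilon <- 1
  tab$p_gg <- tab$p
  pa <- s$pval.adjustments
  if (!is.null(pa) && nrow(pa) > 0) {
    m <- match(rownames(pa), tab$effect)
    tab$epsilon[m] <- unname(pa[, "GG eps"])
    tab$p_gg[m] <- unname(pa[, "Pr(>F[GG])"])
  }
  tab$eta_p2 <- tab$ss / (tab$ss + tab$ss_err)
  tab <- dplyr::mutate(tab,
                       df1 = .data$df1 * .data$epsilon,
                       df2 = .data$df2 * .data$epsilon)
  tab <- dplyr::select(tab, "effect", "F", "df1", "df2", "epsilon", "p",
                       "p_gg", "eta_p2")
  tab$effect <- gsub("\\.cov", covariate %||% ".cov", tab$effect)
  tab$effect <- gsub("\\.grp", between %||% ".grp", tab$effect)
  structure(list(table = tab, model = mod, anova = an,
                 within = within, n_subjects = nrow(Y)),
            class = "effort_anova")
}

#' @export
print.effort_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (n = %d), GG-corrected:\n",
              x$n_subjects))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Tidy / glance methods for `effort_anova`
#'
#' @param x An `effort_anova` object.
#' @param ... Unused.
#' @return `tidy()`: the effects table; `glance()`: a one-row tibble with
#'   the subject count and the number of effects.
#' @method tidy effort_anova
#' @export
tidy.effort_anova <- function(x, ...) x$table

#' @rdname tidy.effort_anova
#' @method glance effort_anova
#' @export
glance.effort_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_effects = nrow(x$table))
}

#' Post hoc paired comparisons with Bonferroni correction
#'
#' Paired t tests between within-subject cells, Bonferroni-corrected over
#' the number of comparisons (`p * m`, capped at 1), with Cohen's dz
#' (mean of paired differences over their SD).  Two-tailed by default; the
#' one-tailed variant tests the alternative that the first-listed cell is
#' greater.  Pairs with zero-variance differences are reported with `t = 0`,
#' `p = 1`, `dz = 0` when the means are equal.
#'
#' @param data Cell values, one row per subject x cell.
#' @param dv Dependent-variable column name.
#' @param cell Cell-label column name.
#' @param subject Subject column name.
#' @param pairs Optional list of length-2 character vectors naming the cell
#'   pairs to compare; defaults to all pairs.
#' @param tails `"two"` or `"one"`.
#' @return Tibble per pair: `cell_a`, `cell_b`, `mean_diff`, `t`, `df`,
#'   `p`, `p_bonferroni`, `dz`, `tails`.
#' @export
posthoc_paired <- function(data, dv, cell, subject, pairs = NULL,
                           tails = c("two", "one")) {
  tails <- match.arg(tails)
  lv <- unique(as.character(data[[cell]]))
  if (is.null(pairs)) {
    pairs <- utils::combn(lv, 2, simplify = FALSE)
  }
  m <- length(pairs)
  out <- purrr::map(pairs, function(pr) {
    a <- data[data[[cell]] == pr[1], c(subject, dv)]
    b <- data[data[[cell]] == pr[2], c(subject, dv)]
    j <- dplyr::inner_join(a, b, by = subject, suffix = c("_a", "_b"))
    abort_if(nrow(j) < 2, "Need >= 2 subjects for a paired comparison.",
             class = "ocuvigor_cohort_error")
    d <- j[[paste0(dv, "_a")]] - j[[paste0(dv, "_b")]]
    sdd <- stats::sd(d)
    n <- length(d)
    if (is.na(sdd) || sdd == 0) {
      md <- mean(d)
      tt <- if (md == 0) 0 else sign(md) * Inf
      p <- if (md == 0) 1 else if (tails == "two") 0 else
        (if (md > 0) 0 else 1)
      dz <- if (md == 0) 0 else sign(md) * Inf
    } else {
      tt <- mean(d) / (sdd / sqrt(n))
      p <- if (tails == "two") 2 * stats::pt(abs(tt), n - 1,
                                             lower.tail = FALSE)
      else stats::pt(tt, n - 1, lower.tail = FALSE)
      dz <- mean(d) / sdd
    }
    tibble::tibble(cell_a = pr[1], cell_b = pr[2], mean_diff = mean(d),
                   t = tt, df = n - 1, p = p,
                   p_bonferroni = pmin(1, p * m), dz = dz, tails = tails)
  })
  purrr::list_rbind(out)
}
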