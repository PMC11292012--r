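#' Align eyes into paretic-like and contralateral-like roles
#'
#' Healthy controls have no paretic side, so group comparisons need a fixed
#' side convention: the paretic side of patients is compared against the
#' *left* side of controls and the contralateral side against the *right*
#' side. This function relabels each per-eye summary row accordingly: for
#' patients, the eye on `paretic_side` becomes `paretic_like`; for healthy
#' subjects the left eye does. Every summary row appears exactly once in the
#' output.
#'
#' @param summaries Per-eye summary table: one row per subject and side, with
#'   columns `subject_id`, `side`, and the metric columns (see
#'   [summarize_eye()]).
#' @param metadata Subject table with columns `subject_id`, `group`
#'   (`healthy`, `acute`, or `synkinesis`) and `paretic_side` (`left`,
#'   `right`, or `none` for healthy).
#' @return The summary table with an added `role` column (`paretic_like` /
#'   `contra_like`) and the subject's `group`.
#' @export
align_sides <- function(summaries, metadata) {
  need <- c("subject_id", "group", "paretic_side")
  if (!all(need %in% names(metadata))) {
    stop_input(
      "metadata needs columns: %s",
      paste(need, collapse = ", ")
    )
  }
  m <- match(summaries$subject_id, metadata$subject_id)
  if (any(is.na(m))) {
    stop_input("summaries contain subject_id values missing from metadata")
  }
  grp <- metadata$group[m]
  par <- metadata$paretic_side[m]
  patient <- grp != "healthy"
  if (any(patient & !(par %in% c("left", "right")))) {
    stop_input("every patient must have paretic_side 'left' or 'right'")
  }
  ref <- ifelse(patient, par, "left")
  out <- summaries
  out$group <- grp
  out$role <- ifelse(out$side == ref, "paretic_like", "contra_like")
  out
}

test_result <- function(comparison, parameter, statistic, p_value,
                        adjusted, n) {
  data.frame(
    comparison = comparison, parameter = parameter,
    statistic = statistic, p_value = p_value,
    adjusted = adjusted, n = n,
    stringsAsFactors = FALSE
  )
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided Wilcoxon signed-rank test for dependent samples (e.g. paretic
#' vs contralateral eye within subjects). Zero differences are dropped before
#' testing and ties are mid-ranked (when ties or zeros are present the
#' normal approximation is used, otherwise the exact distribution).
#'
#' @param x,y Paired numeric vectors of equal length; at least 5 non-zero
#'   differences are required.
#' @param comparison,parameter Labels carried into the result row.
#' @return A one-row result data frame: `comparison`, `parameter`,
#'   `statistic` (V), `p_value`, `adjusted` (always `FALSE` here), `n`
#'   (pairs actually tested).
#' @export
paired_wilcoxon <- function(x, y, comparison = "paired", parameter = "") {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  d <- x[keep] - y[keep]
  nz <- d != 0
  if (!any(nz)) stop_input("all paired differences are zero")
  if (sum(nz) < 5L) {
    stop_input("need at least 5 non-zero differences (got %d)", sum(nz))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(d[nz], alternative = "two.sided")
  )
  test_result(
    comparison, parameter,
    statistic = unname(ht$statistic), p_value = ht$p.value,
    adjusted = FALSE, n = sum(nz)
  )
}

#' One-way ANOVA with Bonferroni-corrected post-hoc comparisons
#'
#' Classic equal-variance one-way analysis of variance across three groups,
#' followed by the three pairwise Welch two-sample comparisons with the
#' Bonferroni correction (raw p multiplied by 3, capped at 1).
#'
#' @param groups Named list of three numeric vectors (at least 2 values
#'   each), e.g. `list(healthy = ..., acute = ..., synkinesis = ...)`.
#' @param parameter Label carried into the result rows.
#' @return A result data frame with four rows: the omnibus F test
#'   (`adjusted = FALSE`) and the three pairwise comparisons
#'   (`adjusted = TRUE`).
#' @export
anova_bonferroni <- function(groups, parameter = "") {
  if (!is.list(groups) || length(groups) != 3L || is.null(names(groups))) {
    stop_input("'groups' must be a named list of three numeric vectors")
  }
  groups <- lapply(groups, function(v) v[is.finite(v)])
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop_cohort(
      "every group needs at least 2 values (got: %s)",
      paste(sizes, collapse = ", ")
    )
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), sizes))
  om <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  out <- test_result(
    "omnibus", parameter,
    statistic = unname(om$statistic), p_value = om$p.value,
    adjusted = FALSE, n = length(values)
  )
  pairs <- utils::combn(names(groups), 2L, simplify = FALSE)
  for (pr in pairs) {
    tt <- stats::t.test(groups[[pr[1]]], groups[[pr[2]]])
    out <- rbind(out, test_result(
      paste(pr, collapse = " vs "), parameter,
      statistic = unname(tt$statistic),
      p_value = min(1, 3 * tt$p.value),
      adjusted = TRUE, n = length(groups[[pr[1]]]) + length(groups[[pr[2]]])
    ))
  }
  out
}

#' Spearman correlation between a blink parameter and a PROM score
#'
#' Spearman's rho with mid-ranked ties and a two-sided p-value from the
#' t approximation; deliberately *not* corrected for multiplicity, mirroring
#' the exploratory use of patient-reported outcome correlations.
#'
#' @param blink_values,prom_values Paired numeric vectors, n >= 4.
#' @param comparison,parameter Labels carried into the result row.
#' @return A one-row result data frame with `statistic` = rho.
#' @export
spearman_prom <- function(blink_values, prom_values,
                          comparison = "spearman", parameter = "") {
  if (length(blink_values) != length(prom_values)) {
    stop_input("inputs must be paired (equal length)")
  }
  keep <- is.finite(blink_values) & is.finite(prom_values)
  x <- blink_values[keep]
  y <- prom_values[keep]
  if (length(x) < 4L) stop_input("need at least 4 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_input("correlation undefined for a constant input sequence")
  }
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  test_result(
    comparison, parameter,
    statistic = unname(ht$estimate), p_value = ht$p.value,
    adjusted = FALSE, n = length(x)
  )
}

blink_parameters <- function() {
  c(
    "avg_ear", "min_ear", "max_ear", "n_blinks_20min", "freq_per_min",
    "mean_duration_ms", "n_complete_20min", "freq_complete_per_min"
  )
}

mean_sd_label <- function(v) {
  sprintf("%.2f ± %.2f", mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE))
}

#' Build the group comparison report tables
#'
#' Assembles per-subject summaries and metadata into the four standard
#' reports of a side-aligned blink study:
#'
#' * `side_comparison` — per group and blink parameter, mean +/- SD on the
#'   paretic-like and contralateral-like side with the paired Wilcoxon p
#'   (one table-3-shaped block per group);
#' * `group_paretic` / `group_contra` — per blink parameter, three-group
#'   means +/- SD on the paretic-like (resp. contralateral-like) side with
#'   the ANOVA omnibus p and the three Bonferroni-corrected pairwise p's;
#' * `prom_correlations` — per group, blink parameter and PROM score,
#'   Spearman rho and uncorrected p.
#'
#' Statistics that cannot be computed on a given cohort (too few non-zero
#' differences, constant inputs, ...) are reported as `NA` rather than
#' aborting the whole report.
#'
#' @param summaries Per-eye summary table (`subject_id`, `side`, metrics).
#' @param metadata Subject metadata (`subject_id`, `group`, `paretic_side`,
#'   plus any PROM score columns named in `prom_cols`).
#' @param parameters Blink parameters to report (defaults to the standard
#'   eight).
#' @param prom_cols PROM columns of `metadata` to correlate against; defaults
#'   to every column whose name starts with `face_` or `fdi_`.
#' @return A list of class `blink_comparison_tables` with the four data
#'   frames described above.
#' @export
build_comparison_tables <- function(summaries, metadata,
                                    parameters = blink_parameters(),
                                    prom_cols = NULL) {
  aligned <- align_sides(summaries, metadata)
  groups <- c("healthy", "acute", "synkinesis")
  present <- intersect(groups, unique(aligned$group))
  if (length(present) == 0L) stop_cohort("cohort contains no known group")
  if (is.null(prom_cols)) {
    prom_cols <- grep("^(face|fdi)_", names(metadata), value = TRUE)
  }

  wide <- function(role) {
    aligned[aligned$role == role, , drop = FALSE]
  }
  pl <- wide("paretic_like")
  cl <- wide("contra_like")
  pl <- pl[order(pl$subject_id), , drop = FALSE]
  cl <- cl[order(cl$subject_id), , drop = FALSE]
  stopifnot(identical(pl$subject_id, cl$subject_id))

  side_rows <- list()
  for (g in present) {
    sel <- pl$group == g
    for (p in parameters) {
      x <- pl[[p]][sel]
      y <- cl[[p]][sel]
      pv <- tryCatch(paired_wilcoxon(x, y)$p_value, error = function(e) NA_real_)
      side_rows[[length(side_rows) + 1L]] <- data.frame(
        group = g, parameter = p,
        paretic_like = mean_sd_label(x), contra_like = mean_sd_label(y),
        p_value = pv, n = sum(sel), stringsAsFactors = FALSE
      )
    }
  }
  side_comparison <- do.call(rbind, side_rows)

  three_group <- function(tab) {
    if (length(present) < 3L) {
      return(NULL)
    }
    n_by_group <- vapply(groups, function(g) sum(tab$group == g), integer(1L))
    if (any(n_by_group < 2L)) {
      stop_cohort(
        "three-group comparison needs >= 2 subjects per group (got: %s)",
        paste(sprintf("%s=%d", groups, n_by_group), collapse = ", ")
      )
    }
    rows <- list()
    for (p in parameters) {
      gl <- lapply(groups, function(g) tab[[p]][tab$group == g])
      names(gl) <- groups
      # a parameter can be missing for a whole group (e.g. no blinks, so no
      # mean duration); report NA p-values instead of aborting the report
      res <- tryCatch(anova_bonferroni(gl, parameter = p),
        blinkr_cohort_error = function(e) NULL
      )
      pick <- function(cmp) {
        if (is.null(res)) NA_real_ else res$p_value[res$comparison == cmp]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p,
        healthy = mean_sd_label(gl$healthy),
        acute = mean_sd_label(gl$acute),
        synkinesis = mean_sd_label(gl$synkinesis),
        p_omnibus = pick("omnibus"),
        p_healthy_vs_acute = pick("healthy vs acute"),
        p_healthy_vs_synkinesis = pick("healthy vs synkinesis"),
        p_acute_vs_synkinesis = pick("acute vs synkinesis"),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, rows)
  }
  group_paretic <- three_group(pl)
  group_contra <- three_group(cl)
  if (length(present) < 3L) {
    warning("fewer than three groups present: three-group tables skipped")
  }

  prom_rows <- list()
  for (g in present) {
    sel <- pl$group == g
    meta_g <- metadata[match(pl$subject_id[sel], metadata$subject_id), ,
      drop = FALSE
    ]
    for (p in parameters) {
      for (q in prom_cols) {
        res <- tryCatch(
          spearman_prom(pl[[p]][sel], meta_g[[q]]),
          error = function(e) NULL
        )
        prom_rows[[length(prom_rows) + 1L]] <- data.frame(
          group = g, parameter = p, prom = q,
          rho = if (is.null(res)) NA_real_ else res$statistic,
          p_value = if (is.null(res)) NA_real_ else res$p_value,
          n = sum(sel), stringsAsFactors = FALSE
        )
      }
    }
  }
  prom_correlations <- do.call(rbind, prom_rows)

  structure(
    list(
      side_comparison = side_comparison,
      group_paretic = group_paretic,
      group_contra = group_contra,
      prom_correlations = prom_correlations
    ),
    class = "blink_comparison_tables"
  )
}

#' @export
print.blink_comparison_tables <- function(x, ...) {
  cat("<blink_comparison_tables>\n")
  for (nm in names(x)) {
    if (is.null(x[[nm]])) {
      cat(sprintf("  $%s: (skipped)\n", nm))
    } else {
      cat(sprintf("  $%s: %d rows\n", nm, nrow(x[[nm]])))
    }
  }
  invisible(x)
}
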