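#' Group means and standard deviations per parameter
#'
#' @param table Data frame with `subject_id`, `group` and one numeric column
#'   per parameter.
#' @param parameters Character vector of parameter columns to summarise;
#'   defaults to every numeric column other than identifiers.
#' @return A data.frame with columns `parameter`, `group`, `n`, `mean`,
#'   `sd` (sample SD, `n - 1` denominator; `NA` with a warning for
#'   single-subject groups).
#' @export
summarize_groups <- function(table, parameters = NULL) {
  parameters <- default_parameters(table, parameters)
  out <- expand.grid(parameter = parameters, group = unique(table$group),
                     stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$mean <- NA_real_; out$sd <- NA_real_
  for (i in seq_len(nrow(out))) {
    v <- table[table$group == out$group[i], out$parameter[i]]
    v <- v[!is.na(v)]
    out$n[i] <- length(v)
    out$mean[i] <- mean(v)
    out$sd[i] <- if (length(v) >= 2L) stats::sd(v) else NA_real_
  }
  if (any(out$n < 2L)) {
    warning("group(s) with fewer than 2 subjects: SD not defined",
            call. = FALSE)
  }
  out
}

default_parameters <- function(table, parameters) {
  if (is.null(parameters)) {
    num <- vapply(table, is.numeric, logical(1))
    parameters <- setdiff(names(table)[num], c("subject_id", "dose", "tmax"))
  }
  missing <- setdiff(parameters, names(table))
  if (length(missing)) {
    stop("parameter column(s) not in table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  parameters
}

#' Classical one-way fixed-effects ANOVA
#'
#' Wraps `stats::oneway.test(var.equal = TRUE)`. The degenerate case of zero
#' within-group variance with equal group means is defined as `F = 0, p = 1`;
#' zero within-group variance with unequal means gives `F = Inf, p = 0`.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @return A list with `f`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  ns <- table(groups)
  if (nlevels(groups) < 2L || any(ns < 2L)) {
    stop("one-way ANOVA needs >= 2 groups with >= 2 subjects each",
         call. = FALSE)
  }
  df1 <- nlevels(groups) - 1L
  df2 <- length(values) - nlevels(groups)
  wss <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  if (wss == 0) {
    means <- tapply(values, groups, mean)
    if (max(means) - min(means) == 0) {
      return(list(f = 0, p = 1, df_between = df1, df_within = df2))
    }
    return(list(f = Inf, p = 0, df_between = df1, df_within = df2))
  }
  ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(f = unname(ft$statistic), p = ft$p.value,
       df_between = df1, df_within = df2)
}

#' Pairwise pooled-variance t tests with Bonferroni correction
#'
#' Two-sided Student t tests (pooled variance over the two groups compared;
#' Welch available as an option) for every group pair, with the Bonferroni
#' adjustment `p_adj = min(1, m * p)` where `m` is the number of pairs.
#' Degenerate pairs with zero variance are defined as `p = 1` for equal
#' means and `p = 0` otherwise.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @param var_equal Pooled-variance Student t (`TRUE`, default) or Welch.
#' @return A data.frame with `group1`, `group2`, `p_raw`, `p_adj`.
#' @export
pairwise_t_bonferroni <- function(values, groups, var_equal = TRUE) {
  groups <- factor(groups)
  lev <- levels(groups)
  if (length(lev) < 2L) stop("need >= 2 groups", call. = FALSE)
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  res <- lapply(seq_len(m), function(j) {
    a <- values[groups == pairs[1, j]]
    b <- values[groups == pairs[2, j]]
    p <- tryCatch(
      stats::t.test(a, b, var.equal = var_equal)$p.value,
      error = function(e) if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j], p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- pmin(1, m * out$p_raw)
  out
}

#' Spearman correlation between a parameter and ordered group membership
#'
#' Rank correlation (midranks for the heavily tied group codes) between
#' per-subject values and an ordinal group coding (e.g. 0 = control,
#' 1 = 70% hepatectomy, 2 = 90% hepatectomy), with the p-value from the
#' t approximation. A negative rho indicates that the parameter decreases
#' with the extent of resection.
#'
#' @param values Numeric vector (e.g. per-subject clearance).
#' @param group_codes Ordinal numeric codes, same length.
#' @return A list with `rho` and `p`.
#' @export
spearman_group_trend <- function(values, group_codes) {
  if (length(values) < 5L) stop("need at least 5 observations", call. = FALSE)
  if (length(unique(values)) == 1L) {
    not_evaluable("all values identical: rank correlation undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(values, as.numeric(group_codes), method = "spearman",
                    exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Full three-group comparison report
#'
#' For each parameter: group means ± SD, the overall one-way ANOVA, and the
#' Bonferroni-corrected pairwise Student t tests; plus the Spearman trend of
#' clearance against the ordered groups when a `cl` column is present.
#'
#' @param table Parameter table (one row per subject, `group` column).
#' @param parameters Parameter columns to test; default as in
#'   [summarize_groups()].
#' @param group_order Optional character vector giving the ordinal ordering
#'   of groups for the Spearman trend; defaults to order of appearance.
#' @return An object of class `group_comparison_report`: a list with
#'   `summary` (means ± SD), `tests` (per-parameter ANOVA + pairwise
#'   data.frame) and `spearman_cl` (or `NULL`).
#' @export
compare_groups <- function(table, parameters = NULL, group_order = NULL) {
  parameters <- default_parameters(table, parameters)
  if (is.null(group_order)) group_order <- unique(table$group)
  groups <- factor(table$group, levels = group_order)
  if (nlevels(droplevels(groups)) < 2L) {
    stop("comparison requires at least 2 groups", call. = FALSE)
  }
  tests <- lapply(parameters, function(p) {
    v <- table[[p]]
    an <- one_way_anova(v, groups)
    pw <- pairwise_t_bonferroni(v, groups)
    list(parameter = p, anova_f = an$f, anova_p = an$p, pairwise = pw)
  })
  names(tests) <- parameters
  spearman_cl <- NULL
  if ("cl" %in% names(table)) {
    codes <- as.integer(groups) - 1L
    spearman_cl <- spearman_group_trend(table$cl, codes)
  }
  structure(list(summary = summarize_groups(table, parameters),
                 tests = tests,
                 spearman_cl = spearman_cl,
                 group_order = group_order),
            class = "group_comparison_report")
}

#' @export
print.group_comparison_report <- function(x, digits = 3, ...) {
  cat("Group comparison report\n")
  cat("=======================\n\n")
  cat("Means +/- SD by group:\n")
  s <- x$summary
  s$mean <- round(s$mean, 1); s$sd <- round(s$sd, 1)
  print(s, row.names = FALSE)
  cat("\nOne-way ANOVA and Bonferroni-adjusted pairwise Student t tests:\n")
  for (t in x$tests) {
    cat(sprintf("  %-22s F = %.2f, p = %s;", t$parameter, t$anova_f,
                format.pval(t$anova_p, digits = digits, eps = 1e-3)))
    pw <- t$pairwise
    cat(" ", paste(sprintf("%s vs %s: %s", pw$group1, pw$group2,
                           format.pval(pw$p_adj, digits = digits, eps = 1e-3)),
                   collapse = "; "), "\n")
  }
  if (!is.null(x$spearman_cl)) {
    cat(sprintf("\nSpearman trend of CL across groups: rho = %.3f, p = %s\n",
                x$spearman_cl$rho,
                format.pval(x$spearman_cl$p, digits = digits, eps = 1e-3)))
  }
  invisible(x)
}

#' Flatten a comparison report to plain lists for JSON export
#'
#' @param report A `group_comparison_report`.
#' @return A nested list mirroring the report, suitable for
#'   `jsonlite::write_json()`.
#' @export
report_to_list <- function(report) {
  stopifnot(inherits(report, "group_comparison_report"))
  list(summary = report$summary,
       tests = lapply(report$tests, function(t) {
         list(parameter = t$parameter, anova_f = t$anova_f,
              anova_p = t$anova_p, pairwise = t$pairwise)
       }),
       spearman_cl = report$spearman_cl,
       group_order = report$group_order)
}
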