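## ---- experiment-level statistics --------------------------------------------

#' Attach design labels to per-column results
#'
#' @param column_results data.frame of [analyze_column()] rows (one per
#'   column).
#' @param manifest design manifest from [experiment_design()] with
#'   `column_id`, `genotype`, `treatment`, `block`.
#' @return merged data.frame, one row per column, factors coded for ANOVA.
#' @export
aggregate_columns <- function(column_results, manifest) {
  need <- c("column_id", "genotype", "treatment", "block")
  if (!all(need %in% names(manifest)))
    stop("manifest must provide columns: ", paste(need, collapse = ", "))
  d <- merge(column_results, manifest[, need], by = "column_id")
  if (nrow(d) != nrow(column_results))
    stop("some columns are missing design labels")
  d$genotype <- factor(d$genotype)
  d$treatment <- factor(d$treatment)
  d$block <- factor(d$block)
  d[order(d$column_id), ]
}

#' Shapiro-Wilk normality test
#'
#' @param values numeric vector, 3 <= n <= 5000, not constant.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  if (length(unique(values)) < 2) stop("constant input: W is undefined")
  t <- shapiro.test(values)
  list(W = unname(t$statistic), p = unname(t$p.value))
}

#' Randomized-block two-factor ANOVA
#'
#' Partitions the response sums of squares into block, genotype, treatment,
#' genotype x treatment and residual, as in a randomized block design with
#' blocks as a fixed stratum.
#'
#' @param data data.frame from [aggregate_columns()].
#' @param response name of the response column (e.g. `"n_colonize"`).
#' @return data.frame ANOVA table: `term`, `df`, `ss`, `ms`, `F`, `p`.
#' @export
rbd_anova <- function(data, response) {
  f <- stats::as.formula(paste(response, "~ block + genotype * treatment"))
  fit <- aov(f, data = data)
  tab <- summary(fit)[[1]]
  term <- trimws(rownames(tab))
  if (tab[term == "Residuals", "Df"] < 1) stop("zero residual degrees of freedom")
  data.frame(term = term, df = tab$Df, ss = tab$`Sum Sq`, ms = tab$`Mean Sq`,
             F = tab$`F value`, p = tab$`Pr(>F)`, row.names = NULL)
}

#' Least significant difference
#'
#' `LSD = t(1 - alpha/2, df) * sqrt(2 * MSE / n)`: the smallest difference
#' between two means (each over `n_per_mean` observations) declared
#' significant at level `alpha`.
#'
#' @param mse residual mean square from the ANOVA.
#' @param df_resid residual degrees of freedom.
#' @param n_per_mean observations per mean.
#' @param alpha significance level (default 0.05).
#' @return the LSD (positive real).
#' @export
lsd <- function(mse, df_resid, n_per_mean, alpha = 0.05) {
  stopifnot(mse > 0, df_resid >= 1, n_per_mean >= 1)
  qt(1 - alpha / 2, df_resid) * sqrt(2 * mse / n_per_mean)
}

#' Combined outcome percentages per treatment
#'
#' Percentages over all detected interactions (colonize / cross) and over
#' determinate interactions only (changed / unchanged), by treatment.
#'
#' @param events events data.frame from [classify_events()] with a
#'   `treatment` column attached.
#' @return data.frame: `treatment`, `n_events`, `n_determinate`,
#'   `pct_colonize`, `pct_cross`, `pct_changed`, `pct_unchanged`.
#' @export
combined_percentages <- function(events) {
  if (!nrow(events)) stop("no events: percentages are undefined")
  if (is.null(events$treatment)) events$treatment <- "all"
  out <- lapply(split(events, events$treatment), function(e) {
    n <- nrow(e)
    det <- e$trajectory %in% c("changed", "unchanged")
    nd <- sum(det)
    data.frame(
      treatment = e$treatment[1], n_events = n, n_determinate = nd,
      pct_colonize = 100 * sum(e$classification == "colonize") / n,
      pct_cross = 100 * sum(e$classification == "cross") / n,
      pct_changed = if (nd) 100 * sum(e$trajectory == "changed") / nd else NA,
      pct_unchanged = if (nd) 100 * sum(e$trajectory == "unchanged") / nd else NA)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Full statistical report for an experiment
#'
#' Per-cell means and SDs, Shapiro-Wilk normality checks, randomized-block
#' ANOVA tables, LSD at the chosen alpha, and combined percentages per
#' treatment. Following the original analysis protocol the ANOVA is run on
#' the count responses regardless of the normality outcome; a note is
#' emitted when normality is rejected.
#'
#' @param agg data.frame from [aggregate_columns()].
#' @param events events data.frame with `treatment` attached (optional).
#' @param responses response columns to analyse.
#' @param alpha significance level for the LSD.
#' @return list of class `stats_report`: `cell_means`, `shapiro`, `anova`
#'   (named list of tables), `lsd` (named vector), `percentages`.
#' @export
stats_report <- function(agg, events = NULL,
                         responses = c("n_interactions", "n_colonize",
                                       "n_cross", "n_changed"),
                         alpha = 0.05) {
  cell <- do.call(rbind, lapply(split(agg, list(agg$genotype, agg$treatment)),
                                function(d) {
    cbind(data.frame(genotype = d$genotype[1], treatment = d$treatment[1],
                     n = nrow(d)),
          as.data.frame(lapply(d[responses], mean)),
          stats::setNames(as.data.frame(lapply(d[responses], stats::sd)),
                          paste0("sd_", responses)))
  }))
  rownames(cell) <- NULL
  shap <- lapply(stats::setNames(responses, responses), function(r) {
    tryCatch(shapiro_wilk(agg[[r]]), error = function(e) list(W = NA, p = NA))
  })
  for (r in responses) {
    if (!is.na(shap[[r]]$p) && shap[[r]]$p < 0.05)
      message("note: normality rejected for ", r,
              " (Shapiro-Wilk p = ", signif(shap[[r]]$p, 3),
              "); ANOVA run regardless, as in the original protocol")
  }
  an <- lapply(stats::setNames(responses, responses),
               function(r) rbd_anova(agg, r))
  n_cell <- min(table(agg$genotype, agg$treatment))
  lsds <- vapply(responses, function(r) {
    tab <- an[[r]]
    mse <- tab$ms[tab$term == "Residuals"]
    dfr <- tab$df[tab$term == "Residuals"]
    if (mse <= 0) return(NA_real_)
    lsd(mse, dfr, n_cell, alpha)
  }, 0)
  pct <- if (!is.null(events) && nrow(events)) combined_percentages(events)
    else NULL
  structure(list(cell_means = cell, shapiro = shap, anova = an, lsd = lsds,
                 percentages = pct, alpha = alpha),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("Cell means:\n"); print(x$cell_means, digits = 3)
  cat("\nLSD (alpha =", x$alpha, "):\n"); print(round(x$lsd, 3))
  for (r in names(x$anova)) {
    cat("\nANOVA:", r, "\n"); print(x$anova[[r]], digits = 3)
  }
  if (!is.null(x$percentages)) {
    cat("\nCombined percentages by treatment:\n")
    print(x$percentages, digits = 3)
  }
  invisible(x)
}

#' Write a stats report to JSON plus CSV tables
#'
#' @param report a `stats_report`.
#' @param dir output directory (created if needed).
#' @export
write_stats_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(
    list(cell_means = report$cell_means,
         shapiro = report$shapiro,
         anova = report$anova,
         lsd = as.list(report$lsd),
         percentages = report$percentages,
         alpha = report$alpha),
    file.path(dir, "stats_report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  write.csv(report$cell_means, file.path(dir, "cell_means.csv"),
            row.names = FALSE)
  for (r in names(report$anova))
    write.csv(report$anova[[r]], file.path(dir, paste0("anova_", r, ".csv")),
              row.names = FALSE)
  if (!is.null(report$percentages))
    write.csv(report$percentages, file.path(dir, "percentages.csv"),
              row.names = FALSE)
  invisible(file.path(dir, "stats_report.json"))
}
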