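#!/usr/bin/env Rscript
## Step 3: experiment-level statistics.
##
## Normality checks (Shapiro-Wilk), randomized-block ANOVA of the per-column
## counts (block + genotype * treatment), least significant differences at
## p = .05, and the combined-genotype outcome percentages per treatment.

suppressPackageStartupMessages(library(rootpore))

out <- "results"
manifest <- read.csv(file.path(out, "manifest.csv"))
col_results <- read.csv(file.path(out, "column_results.csv"))
events <- read.csv(file.path(out, "events.csv"))

agg <- aggregate_columns(col_results, manifest)
events <- merge(events, manifest[, c("column_id", "treatment")],
                by = "column_id")

report <- stats_report(agg, events)
print(report)
write_stats_report(report, file.path(out, "stats"))

an <- report$anova$n_colonize
cat(sprintf("\ntreatment effect on colonizations per column: F = %.2f, p = %.4g\n",
            an$F[an$term == "treatment"], an$p[an$term == "treatment"]))
cat("wrote", file.path(out, "stats"), "\n")
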