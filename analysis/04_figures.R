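#!/usr/bin/env Rscript

# Step 4 -- figures: the inverted-U accuracy/d' profiles and the criterion
# relief over the noise ladder, from the per-participant SDT summaries of
# step 2.  PDFs land in results/figures/.

suppressPackageStartupMessages({
  library(srbias)
  library(ggplot2)
})

path <- "results/run01/sdt_summary.csv"
if (!file.exists(path)) {
  stop("run analysis/02_group_inference.R first (missing ", path, ")")
}
s <- read.csv(path)
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

# sigma = 0 cannot sit on a log axis; plot against ladder rank instead
levs <- sort(unique(s$sigma))
s$sigma_f <- factor(formatC(s$sigma, format = "fg"),
                    levels = formatC(levs, format = "fg"))

plot_measure <- function(col, ylab, file, hline = NULL) {
  agg <- aggregate(s[[col]], list(sigma_f = s$sigma_f),
                   function(x) c(m = mean(x), se = sd(x) / sqrt(length(x))))
  agg <- data.frame(sigma_f = agg$sigma_f, m = agg$x[, "m"],
                    se = agg$x[, "se"])
  p <- ggplot(agg, aes(sigma_f, m, group = 1)) +
    geom_line(colour = "grey40") +
    geom_pointrange(aes(ymin = m - se, ymax = m + se)) +
    labs(x = expression("external noise" ~ sigma ~ "(grey levels)"),
         y = ylab) +
    theme_minimal(base_size = 12)
  if (!is.null(hline)) {
    p <- p + geom_hline(yintercept = hline, linetype = 2,
                        colour = "grey60")
  }
  ggsave(file.path("results/figures", file), p, width = 5, height = 3.4)
}

plot_measure("accuracy", "category accuracy", "accuracy_by_sigma.pdf")
plot_measure("dprime", "d'", "dprime_by_sigma.pdf")
plot_measure("criterion", "criterion c", "criterion_by_sigma.pdf",
             hline = 0)

message("Wrote results/figures/{accuracy,dprime,criterion}_by_sigma.pdf")
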