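#!/usr/bin/env Rscript

## Stage 4 — method ranking and the sensitivity/PPV trade-off.
##
## Ranks the methods by their overall F score within each data source
## (ties at the two-decimal display precision are flagged) and draws the
## sensitivity-PPV trade-off chart. Expected finding: ever-reported is the
## sensitivity-maximal / PPV-minimal extreme, and the two weight-of-evidence
## rules (ERA, MSM) sit together at the top of the F-score ranking.

library(linkenhance)

evaluation <- readr::read_csv("results/evaluation_all_records.csv", show_col_types = FALSE)
ranking <- compare_methods(evaluation)
readr::write_csv(ranking, "results/method_ranking.csv")

cat("Methods ranked by Total F score within each source:\n")
print(as.data.frame(ranking), digits = 4, row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(ranking, aes(sensitivity, ppv, colour = method, shape = source)) +
    geom_point(size = 3) +
    labs(
      x = "Record-level sensitivity (%)", y = "Record-level PPV (%)",
      title = "Sensitivity / PPV trade-off of the reporting methods"
    ) +
    theme_minimal()
  ggsave("results/sensitivity_ppv_tradeoff.png", p, width = 7, height = 5, dpi = 150)
  cat("\nwrote results/sensitivity_ppv_tradeoff.png\n")
}
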