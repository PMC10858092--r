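#!/usr/bin/env Rscript
# Duration-binned model comparison on a synthetic runner cohort, plus the
# out-of-sample protocol: fit both models per athlete (the hyperbolic one
# on its 2-15 min validity window, the power law on everything), score
# every effort by relative velocity error, and summarise per duration bin.
#
# Writes: results/binned_comparison.csv, results/out_of_sample.csv

suppressPackageStartupMessages({
  library(endurofit)
  library(dplyr)
})
dir.create("results", showWarnings = FALSE)

spec <- population_spec(
  n_athletes = 200, noise_sigma = 0.02,
  distances = c(400, 800, 1500, 3000, 5000, 10000, 21097.5, 42195),
  seed = 42
)
pop <- generate_population(spec)

cmp <- binned_errors(pop$efforts, absolute = TRUE)
write.csv(cmp, "results/binned_comparison.csv", row.names = FALSE)
cat("Mean |relative velocity error| by duration bin (200 synthetic runners):\n")
print(cmp |>
        mutate(bin = sprintf("%g-%g min", bin_lo / 60, bin_hi / 60),
               pct = 100 * mean_error) |>
        select(bin, model, pct, n_athletes) |>
        tidyr::pivot_wider(names_from = model, values_from = pct) |>
        as.data.frame(), digits = 3)
cat("\nBoth models are within a fraction of a percentage point inside the\n2-15 min window; outside it the window-fitted hyperbolic model's error\ngrows by an order of magnitude while the power law stays at the noise floor.\n")

oos <- out_of_sample(pop$efforts, n_train = 6, seed = 42)
write.csv(oos$summary, "results/out_of_sample.csv", row.names = FALSE)
cat(sprintf(
  "\nOut-of-sample protocol (6 training races per athlete, %d athletes excluded):\n",
  nrow(oos$excluded)
))
print(as.data.frame(oos$summary), digits = 3)
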