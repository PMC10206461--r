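#!/usr/bin/env Rscript
# Step 3 — select the analysis days: the four contexts (early / late
# production stage, cold external temperature, vaccination disturbance),
# the over-time Saturday series, and one representative observation per
# hen and context for the across-context analysis.

suppressMessages(library(aviarytraits))

beh <- read_behaviours("results/behaviours.csv")
temp <- utils::read.csv("results/temperature.csv")
temp$date <- as.Date(temp$date)
gt <- yaml::read_yaml("results/ground_truth.yaml")

dates <- sort(unique(temp$date))
ctx <- select_context_days(dates, temp, as.Date(unlist(gt$vaccination_dates)))
yaml::write_yaml(lapply(ctx, as.character), "results/contexts.yaml")

cat("Context days:\n")
for (nm in names(ctx))
  cat(sprintf("  %-12s %s\n", nm, paste(format(ctx[[nm]]), collapse = ", ")))
if (length(attr(ctx, "excluded")))
  cat("Excluded (multi-context):",
      paste(format(attr(ctx, "excluded")), collapse = ", "), "\n")

acx <- across_context_observations(beh, ctx)
utils::write.csv(acx, "results/across_context_observations.csv",
                 row.names = FALSE)
cat(sprintf("Across-context table: %d rows (%d hens; %d hen-contexts omitted)\n",
            nrow(acx), length(unique(acx$hen_id)),
            length(attr(acx, "omitted"))))
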