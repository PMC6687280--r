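#!/usr/bin/env Rscript
# Stage 3 -- community summaries and biotic indices per sample.
#
# Total abundance, family richness, SPEAR (log-abundance-weighted share of
# pesticide-sensitive taxa, %) and BMWP (sum of family tolerance scores).

library(streamstress)

abundance <- read.csv("results/data/abundance.csv")
traits <- read.csv("results/data/traits.csv")

idx <- community_indices(abundance, traits)
write.csv(idx, "results/indices.csv", row.names = FALSE)

cat("samples:", nrow(idx), "\n")
for (v in c("abundance", "richness", "spear", "bmwp")) {
  cat(sprintf("%-9s mean %7.1f  range %6.1f .. %6.1f\n", v, mean(idx[[v]]),
              min(idx[[v]]), max(idx[[v]])))
}
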