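#!/usr/bin/env Rscript
# Tabulate the 10-10 positions used by the five montages (proportional
# arc construction) and serialize each montage as YAML.
#
# Findings: Cz-C3 and Cz-T7 arcs are exactly 36 and 72 degrees; the four
# HD-4x1 cathodes sit 87.6-92.4 degrees apart in azimuth about C3.

suppressMessages(library(fieldlab))
dir.create("results/montages", recursive = TRUE, showWarnings = FALSE)

labels <- supported_positions()
tab <- t(sapply(labels, standard_position))
colnames(tab) <- c("x", "y", "z")
pos <- data.frame(label = labels, round(tab, 6),
                  angle_from_Cz_deg = round(acos(pmin(1, tab[, "z"])) *
                                              180 / pi, 3))
write.csv(pos, "results/positions_1010.csv", row.names = FALSE)
message(nrow(pos), " positions written")

for (m in c("M1-SO", "DLPFC", "Cz-Oz", "HD-4x1", "HD-2x2")) {
  write_montage_yaml(get_montage(m),
                     file.path("results/montages", paste0(m, ".yaml")))
}

# ring geometry of the 4x1 montage
c3 <- standard_position("C3")
ring <- sapply(c("Cz", "F3", "T7", "P3"), function(l)
  acos(sum(c3 * standard_position(l))) * 180 / pi)
cat("HD-4x1 ring: cathodes at", round(ring, 2), "deg from C3\n")
cat("arc radius on a 92 mm head:", round(mean(ring) * pi / 180 * 92, 1),
    "mm\n")
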