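#!/usr/bin/env Rscript
# Quantify within-person stability of the motive weights across the two
# sessions: the mismatched-pairing permutation test on Euclidean distances
# in weight space (10,000 iterations) and per-motive intraclass
# correlations of the profile-centered weights.

library(infomotives)

sw <- read.csv("results/subject_weights.csv")
w1 <- sw[sw$timepoint == "T1", ]
w2 <- sw[sw$timepoint == "T2", ]

perm <- permutation_stability_test(w1, w2, n_iter = 10000L, seed = 21L)
print(perm)
write.csv(perm$per_subject, "results/stability_distances.csv",
          row.names = FALSE)
jsonlite::write_json(
  list(actual_mean_distance = perm$actual_mean_distance,
       proportion_actual_smaller = perm$proportion_actual_smaller,
       mean_difference = perm$mean_difference,
       difference_range = perm$difference_range,
       n = perm$n, n_iter = perm$n_iter, seed = perm$seed),
  "results/stability_permutation.json", auto_unbox = TRUE, digits = NA)

icc <- icc_per_motive(w1, w2)
write.csv(icc, "results/stability_icc.csv", row.names = FALSE)
cat("\nICC of each motive weight across sessions (profile-centered):\n")
print(icc, row.names = FALSE, digits = 3)
cat("wrote results/stability_permutation.json, results/stability_icc.csv\n")
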