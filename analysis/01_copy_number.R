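#!/usr/bin/env Rscript
# Locus dosage under the Helmstetter-Cooper model: average copy number along
# the ori-ter axis for a range of division times, the log2 ori:ter ratio
# (C/tau), and the per-cell fork-count view.

library(replimet)

dir.create("results", showWarnings = FALSE)

C <- 40; D <- 20
taus <- c(20, 30, 40, 50, 70, 90, 120)
p <- seq(0, 1, by = 0.02)

tab <- do.call(rbind, lapply(taus, function(tau) {
  rp <- replication_params(C, D, tau)
  data.frame(tau = tau, mu_per_hour = growth_rate(tau), p = p,
             copy_number = average_copy_number(rp, p),
             log2_ptr = log2_ptr(rp))
}))
write.table(tab, "results/copy_number_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Average copy number n(p) = 2^(((1-p)C + D)/tau), C =", C, "D =", D, "\n")
cat(sprintf("  fast growth  (tau = 20): n(ori) = %.2f, n(ter) = %.2f, log2 PTR = %.2f\n",
            average_copy_number(replication_params(C, D, 20), 0),
            average_copy_number(replication_params(C, D, 20), 1), C / 20))
cat(sprintf("  slow growth (tau = 120): n(ori) = %.2f, n(ter) = %.2f, log2 PTR = %.2f\n",
            average_copy_number(replication_params(C, D, 120), 0),
            average_copy_number(replication_params(C, D, 120), 1), C / 120))
cat(sprintf("  growth rates: %.3f / h at tau = 20 min, %.3f / h at tau = 120 min\n",
            growth_rate(20), growth_rate(120)))

# per-cell view: ori:ter ratio jumps with the number of nested forks
cat(sprintf("  per-cell ori:ter ratio: %d:1 with three forks, %d:1 with one fork\n",
            instantaneous_copy_number(c(0.9, 0.2), 0.01),
            instantaneous_copy_number(0.5, 0.01)))
cat("wrote results/copy_number_profiles.tsv\n")
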