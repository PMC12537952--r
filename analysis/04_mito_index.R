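#!/usr/bin/env Rscript
# Bioenergetics indices: plate-normalized specific activities, cohort
# mean-centering, MHI and MRC, mtDNA copy number and density, followed by
# the 2x2 genotype x microbiome factorial contrasts on MHI and mtDNAcn.
suppressPackageStartupMessages(library(mitomotor))

enz <- read_table("results/data/enzymes.csv", "enzymes")
qp <- read_table("results/data/qpcr.csv", "qpcr")
feat <- mito_features(enz, qp)
out <- feat
out$mrc_cohort <- attr(feat, "mrc_cohort")
write_table(out, "results/mito_features.csv")

cat(sprintf("Cohort of %d animals; cohort MRC = %.1f\n",
            nrow(feat), attr(feat, "mrc_cohort")))
cat(sprintf("MHI: mean = %.1f (all-average animal would be 100), range %.1f-%.1f\n",
            mean(feat$mhi), min(feat$mhi), max(feat$mhi)))

lab <- do.call(rbind, strsplit(sub("_.*", "", feat$sample_id), ".",
                               fixed = TRUE))
for (endpoint in c("mhi", "mtdnacn")) {
  ffit <- fit_two_factor(feat[[endpoint]], lab[, 1], lab[, 2])
  ct <- pairwise_contrasts(ffit, c("ASO.SPF-WT.SPF", "ASO.GF-WT.GF",
                                   "ASO.SPF-ASO.GF", "WT.SPF-WT.GF"))
  ct$endpoint <- endpoint
  cat(sprintf("%s interaction coefficient = %.3g\n", endpoint,
              ffit$coefficients["genotypeASO:conditionGF", "Estimate"]))
  write_table(ct, sprintf("results/factorial_%s.csv", endpoint))
}
cat("wrote results/mito_features.csv, results/factorial_{mhi,mtdnacn}.csv\n")
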