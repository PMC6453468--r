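#!/usr/bin/env Rscript
# Risk-variant screening and locus construction: +/-100 kb regions
# merged on overlap, then LD expansion at r2 >= 0.5. Writes the locus
# catalog under results/.

library(riskeqtl)

bundle <- read_study_bundle("scratch/cohort")
geno <- impute_missing_dosages(filter_variants(bundle$geno)$geno)

screen <- screen_risk_variants(bundle$risk, geno)
cat("risk-variant screening:\n")
print(screen[, c("rsid", "status", "reason")])
write_tsv_table(screen, "results/risk_variant_screen.tsv")

regions <- build_regions(screen)
loci <- build_loci(regions, geno)
tab <- locus_table(loci)
cat(nrow(regions), "regions ->", nrow(tab), "loci\n")
print(tab)
write_tsv_table(tab, "results/locus_catalog.tsv")
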