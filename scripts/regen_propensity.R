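#!/usr/bin/env Rscript
# Regenerates inst/extdata/propensity_synthetic.tsv, the package's
# default residue-propensity table, from a fixed-seed set of synthetic
# toy interfaces (log-ratio of interface vs surface residue
# frequencies, add-one smoothed).  Real analyses should derive their
# own table from training structures via derive_propensity_table().
library(xtalface)

set.seed(1)
ifaces <- lapply(1:30, function(i) {
  toy <- make_toy_complex(n_res = 20, spacing = 4.8,
                          offset = sample(0:10, 1), seed = 1000 + i,
                          jitter = 0.1)
  detect_interface(toy$query, toy$partner, n_points = 1000)
})
tab <- derive_propensity_table(Filter(Negate(is.null), ifaces))
out <- data.frame(aa = names(tab), propensity = round(unname(tab), 4))
write.table(out, "inst/extdata/propensity_synthetic.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", nrow(out), "entries\n")
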