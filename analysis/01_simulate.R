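#!/usr/bin/env Rscript
# Generate the synthetic study set: ~85 labelled inhibitors (planted ADDRRR
# pharmacophore + linear decoration signal) and a 200-compound screening
# library with 20 planted actives. Writes SDF/CSV/JSON fixtures under
# results/data/ so every later stage can be rerun from files.
library(qsarphore)

seed <- as.integer(Sys.getenv("QSARPHORE_SEED", "1"))
spec <- synthetic_spec(seed = seed)
ds <- generate_dataset(spec)
paths <- write_fixture_files(ds, "results/data")
cat("Wrote", length(paths), "fixture files:\n")
cat(paste(" -", paths), sep = "\n")
acts <- vapply(ds$molecules, function(m) isTRUE(m$is_active), logical(1))
cat(sprintf("Dataset: %d compounds (%d active / %d inactive), library %d\n",
            length(ds$molecules), sum(acts), sum(!acts), length(ds$library)))
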