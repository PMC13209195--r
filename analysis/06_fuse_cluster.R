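#!/usr/bin/env Rscript
# Fuse the three screening scores, keep the upper 10%, and triage the
# survivors into clusters with one representative each.
library(qsarphore)

seed <- as.integer(Sys.getenv("QSARPHORE_SEED", "1"))
cfg <- pipeline_config(out_dir = "results/pipeline_run", seed = seed,
                       synthetic = synthetic_spec(seed = seed))
res <- run_pipeline(cfg)
cat("Pipeline reports in", cfg$out_dir, "\n")
cat(sprintf("Fused %d records -> %d selected; %d clusters\n",
            nrow(res$fused), nrow(res$selected),
            nrow(res$clusters$representatives)))
print(res$clusters$representatives)
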