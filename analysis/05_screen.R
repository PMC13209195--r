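#!/usr/bin/env Rscript
# Shape+color screen of the synthetic library against the best hypothesis
# reference ligand, with fitness and predicted activity for model matches,
# and the actives-recovered enrichment summary.
library(qsarphore)

seed <- as.integer(Sys.getenv("QSARPHORE_SEED", "1"))
ds <- generate_dataset(synthetic_spec(seed = seed))
sp <- diversity_split(ds$molecules, split_spec(seed = seed))
actives <- Filter(function(m) m$pIC50 > ACTIVE_PIC50_THRESHOLD, sp$train)
hyp <- find_common_pharmacophores(actives, k = 6)[[1]]
occ <- build_occupancy_matrix(sp$train, hyp)
y <- vapply(sp$train, `[[`, numeric(1), "pIC50")
model <- fit_qsar_pls(occ$X, y, grid = occ$grid, hypothesis = hyp,
                      ids = occ$ids)

query <- molecule("query", conformers = list(hyp$reference_conformer))
tab <- screen_library(ds$library, query, model = model)
dir.create("results", showWarnings = FALSE)
write_screen_table(tab, "results/screen_scores.csv")

truth <- ds$truth$compounds
lib_act <- truth$id[truth$role == "lib_active"]
top20 <- head(tab$compound_id, floor(0.2 * nrow(tab)))
cat(sprintf("Library %d compounds; %d planted actives; %d/%d recovered in the top 20%%\n",
            nrow(tab), length(lib_act), sum(lib_act %in% top20),
            length(lib_act)))
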