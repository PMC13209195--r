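#!/usr/bin/env Rscript
# External validation on the held-out 30%: q2, r0^2 twins, k slopes, rm^2,
# F statistics, LOO stability, and the six-part acceptance rule set.
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

rep <- validation_report(model, sp$test, X_train = occ$X)
dir.create("results", showWarnings = FALSE)
tab <- validation_table(setNames(list(rep), paste0(hyp$label, ".1")),
                        csv_path = "results/validation.csv")
print(tab)
cat("Accepted:", rep$accepted,
    if (!rep$accepted) paste("| failed:", paste(rep$failed_criteria,
                                                collapse = "; ")) else "",
    "\n")
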