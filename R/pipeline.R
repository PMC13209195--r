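#' End-to-end pipeline orchestration
#'
#' A single configuration object carries every stage's parameters, with
#' defaults equal to the protocol's published values (7:3 split, 8 x 2 A
#' distance bins, 1.0 A grid spacing, t cutoff 2.0, 2.0 A match tolerance,
#' 2 matched features, 1000-hit cap, 10% fusion cutoff, energy windows 10
#' and 30 kcal/mol). One global seed fans out to per-stage seeds by fixed
#' offsets so stages are individually reproducible; rerunning with the
#' same config reproduces every report byte for byte.
#'
#' @param out_dir run directory for reports.
#' @param seed global seed.
#' @param synthetic a [synthetic_spec()] or NULL to read datasets from
#'   `paths`.
#' @param paths optional named list: train, test, library (SDF files),
#'   docking_csv.
#' @param hypothesis_k sites per hypothesis.
#' @param n_score_hypotheses survival-score at most this many top
#'   candidate hypotheses.
#' @param partition a [partition_params()].
#' @param qsar list: spacing, max_factors, t_cutoff, min_support.
#' @param screening list: tolerance_A, min_match, hit_cap,
#'   energy_window_query, energy_window_library.
#' @param fusion list: columns, method, fraction.
#' @param cluster list: k.
#' @param stages character vector of stages to run.
#' @return list of class `qp_pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "qsarphore_run", seed = 1L,
                            synthetic = synthetic_spec(seed = seed),
                            paths = list(),
                            hypothesis_k = 6L,
                            n_score_hypotheses = 10L,
                            partition = partition_params(),
                            qsar = list(spacing = 1.0, max_factors = 10L,
                                        t_cutoff = 2.0, min_support = 0.2),
                            screening = list(tolerance_A = 2.0,
                                             min_match = 2L,
                                             hit_cap = 1000L,
                                             energy_window_query = 30,
                                             energy_window_library = 10),
                            fusion = list(columns = c("combined", "fitness",
                                                      "predicted_pIC50"),
                                          method = "sum", fraction = 0.10),
                            cluster = list(k = 8L),
                            stages = c("simulate", "hypotheses", "qsar",
                                       "validate", "screen", "fuse",
                                       "cluster")) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 synthetic = synthetic, paths = paths,
                 hypothesis_k = as.integer(hypothesis_k),
                 n_score_hypotheses = as.integer(n_score_hypotheses),
                 partition = partition, qsar = qsar, screening = screening,
                 fusion = fusion, cluster = cluster, stages = stages),
            class = "qp_pipeline_config")
}

#' Serialize / restore a pipeline config as YAML
#' @param config a `qp_pipeline_config`.
#' @param path YAML file.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$synthetic <- if (!is.null(x$synthetic)) {
    s <- unclass(x$synthetic)
    s$template_sites <- as.list(s$template_sites)
    s
  }
  x$partition <- unclass(x$partition)
  yaml::write_yaml(x, path, precision = 12L)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(x$synthetic)) {
    s <- x$synthetic
    ts <- as.data.frame(s$template_sites, stringsAsFactors = FALSE)
    syn <- synthetic_spec(
      n_actives = s$n_actives, n_inactives = s$n_inactives,
      n_library = s$n_library,
      template_sites = feature_sites(ts$kind,
                                     as.matrix(ts[, c("x", "y", "z")]),
                                     as.matrix(ts[, c("dx", "dy", "dz")])),
      site_jitter_A = s$site_jitter_A,
      activity_noise_sd = s$activity_noise_sd,
      active_pIC50_range = unlist(s$active_pIC50_range),
      inactive_pIC50_range = unlist(s$inactive_pIC50_range),
      n_decorations = s$n_decorations, n_conformers = s$n_conformers,
      library_active_fraction = s$library_active_fraction, seed = s$seed)
  }
  pipeline_config(
    out_dir = x$out_dir %||% "qsarphore_run", seed = x$seed, synthetic = syn, paths = x$paths,
    hypothesis_k = x$hypothesis_k,
    n_score_hypotheses = x$n_score_hypotheses,
    partition = partition_params(x$partition$n_bins,
                                 x$partition$bin_width_A,
                                 x$partition$min_actives_matched),
    qsar = x$qsar, screening = x$screening,
    fusion = list(columns = unlist(x$fusion$columns),
                  method = x$fusion$method, fraction = x$fusion$fraction),
    cluster = x$cluster, stages = unlist(x$stages))
}

#' @noRd
config_digest <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  scientific <- config
  scientific$out_dir <- NULL   # parameters, not output location
  write_pipeline_config(scientific, tmp)
  unname(tools::md5sum(tmp))
}

#' @noRd
provenance_header <- function(config) {
  ver <- tryCatch(as.character(utils::packageVersion("qsarphore")),
                  error = function(e) "dev")
  sprintf("# qsarphore %s | config md5 %s | seed %d",
          ver, config_digest(config), config$seed)
}

#' @noRd
write_report <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the discovery pipeline end to end
#'
#' Stages: simulate (or load), common-pharmacophore hypotheses with
#' survival ranking, QSAR fit on the best hypothesis, validation report,
#' library screening, score fusion with top-fraction cutoff, K-means
#' clustering of survivors. Reports are written under `config$out_dir`
#' (hypotheses.csv, validation.csv, screen_scores.csv, fused_selected.csv,
#' clusters.csv, run.log), each carrying a provenance header naming the
#' package version and config hash.
#'
#' @param config a [pipeline_config()].
#' @return list with the principal in-memory results, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "qp_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  header <- provenance_header(config)
  logf <- file.path(config$out_dir, "run.log")
  cat(header, "\n", file = logf, sep = "")
  logmsg <- function(...) {
    cat(sprintf("[%s] %s\n", "stage", paste0(...)), file = logf,
        append = TRUE)
    qp_log(...)
  }
  on_stage <- function(s) s %in% config$stages
  res <- list(config = config)

  # ---- data ----
  if (on_stage("simulate") && !is.null(config$synthetic)) {
    ds <- generate_dataset(config$synthetic)
    sp <- diversity_split(ds$molecules,
                          split_spec(seed = stage_seed(config$seed, 1)))
    res$dataset <- ds
    res$train <- sp$train
    res$test <- sp$test
    res$library <- ds$library
    logmsg("simulate: ", length(ds$molecules), " labelled compounds -> ",
           length(sp$train), " train / ", length(sp$test), " test; library ",
           length(ds$library))
  } else {
    if (is.null(config$paths$train)) stop("no synthetic spec and no train path")
    res$train <- perceive_dataset_features(
      read_dataset(config$paths$train, "sdf"))
    res$test <- if (!is.null(config$paths$test)) {
      perceive_dataset_features(read_dataset(config$paths$test, "sdf"))
    }
    res$library <- if (!is.null(config$paths$library)) {
      perceive_dataset_features(
        read_dataset(config$paths$library, "sdf", require_activity = FALSE))
    }
    logmsg("load: ", length(res$train), " train compounds")
  }

  # ---- hypotheses ----
  if (on_stage("hypotheses")) {
    actives <- Filter(function(m) !is.na(m$pIC50) &&
                        m$pIC50 > ACTIVE_PIC50_THRESHOLD, res$train)
    inactives <- Filter(function(m) !is.na(m$pIC50) &&
                          m$pIC50 <= ACTIVE_PIC50_THRESHOLD, res$train)
    logmsg("hypotheses: ", length(actives), " actives / ",
           length(inactives), " inactives in training set")
    hyps <- find_common_pharmacophores(actives, k = config$hypothesis_k,
                                       params = config$partition)
    logmsg("hypotheses: ", length(hyps), " surviving candidate(s)")
    n_score <- min(config$n_score_hypotheses, length(hyps))
    hyps[seq_len(n_score)] <- lapply(hyps[seq_len(n_score)], function(h) {
      score_hypothesis_survival(h, actives, inactives,
                                tolerance_A = config$screening$tolerance_A,
                                min_match = config$screening$min_match)
    })
    scored <- hyps[seq_len(n_score)]
    rank <- order(-vapply(scored, function(h) h$survival$ranking, numeric(1)),
                  vapply(scored, `[[`, character(1), "label"))
    res$hypotheses <- scored[rank]
    res$best_hypothesis <- res$hypotheses[[1]]
    write_report(write_hypothesis_report(res$hypotheses),
                 file.path(config$out_dir, "hypotheses.csv"), header)
    logmsg("hypotheses: best = ", res$best_hypothesis$label,
           " (ref ", res$best_hypothesis$reference_ligand_id, ")")
  }

  # ---- qsar ----
  if (on_stage("qsar")) {
    hyp <- res$best_hypothesis
    occ <- build_occupancy_matrix(res$train, hyp,
                                  spacing = config$qsar$spacing,
                                  tolerance_A = config$screening$tolerance_A,
                                  min_match = config$screening$min_match)
    y <- vapply(res$train, `[[`, numeric(1), "pIC50")
    res$model <- fit_qsar_pls(occ$X, y,
                              max_factors = config$qsar$max_factors,
                              t_cutoff = config$qsar$t_cutoff,
                              min_support = config$qsar$min_support,
                              grid = occ$grid, hypothesis = hyp,
                              ids = occ$ids)
    res$occupancy <- occ
    write_qsar_model(res$model, file.path(config$out_dir, "qsar_model.json"))
    logmsg("qsar: ", res$model$n_factors, " factor(s), ",
           length(res$model$retained_bit_index), " retained bits")
  }

  # ---- validation ----
  if (on_stage("validate")) {
    rep <- validation_report(res$model, res$test, X_train = res$occupancy$X)
    res$validation <- rep
    tab <- validation_table(stats::setNames(
      list(rep), paste0(res$best_hypothesis$label, ".1")))
    write_report(tab, file.path(config$out_dir, "validation.csv"), header)
    logmsg("validate: q2 = ", sprintf("%.3f", rep$q2), ", accepted = ",
           rep$accepted)
  }

  # ---- screening ----
  if (on_stage("screen")) {
    query <- molecule("query",
                      conformers = list(res$best_hypothesis$reference_conformer))
    res$screen <- screen_library(res$library, query, model = res$model,
                                 hit_cap = config$screening$hit_cap,
                                 tolerance_A = config$screening$tolerance_A,
                                 min_match = config$screening$min_match)
    if (!is.null(config$paths$docking_csv)) {
      res$screen <- join_docking_scores(res$screen, config$paths$docking_csv)
    }
    write_report(res$screen, file.path(config$out_dir, "screen_scores.csv"),
                 header)
    logmsg("screen: ", length(res$library), " compounds -> ",
           nrow(res$screen), " scored records")
  }

  # ---- fusion ----
  if (on_stage("fuse")) {
    cols <- intersect(config$fusion$columns, names(res$screen))
    fused <- fuse_scores(res$screen, columns = cols,
                         method = config$fusion$method)
    sel <- select_top_fraction(fused, fraction = config$fusion$fraction)
    res$fused <- fused
    res$selected <- sel
    write_report(sel, file.path(config$out_dir, "fused_selected.csv"), header)
    logmsg("fuse: ", nrow(fused), " -> ", nrow(sel), " selected (",
           config$fusion$method, " fusion, upper ",
           100 * config$fusion$fraction, "%)")
  }

  # ---- clustering ----
  if (on_stage("cluster")) {
    sel_ids <- res$selected$compound_id
    lib_ids <- vapply(res$library, `[[`, character(1), "id")
    sel_mols <- res$library[match(sel_ids, lib_ids)]
    k <- min(config$cluster$k, length(sel_mols))
    cl <- cluster_hits(sel_mols, res$selected$fused, k = k,
                       seed = stage_seed(config$seed, 7))
    res$clusters <- cl
    write_report(cl$representatives,
                 file.path(config$out_dir, "clusters.csv"), header)
    logmsg("cluster: ", length(sel_mols), " hits in ", k,
           " clusters; representatives: ",
           paste(cl$representatives$compound_id, collapse = ", "))
  }

  invisible(res)
}
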