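# End-to-end orchestration: synthetic family (or user FASTA) -> similarity
# network -> embedding -> hierarchy -> paralog groups -> Potts model ->
# burden (-> three-pool analysis when pools are provided), with a checksum
# manifest so reruns are verifiably reproducible.

#' Pipeline configuration
#'
#' All stage parameters with their defaults, one global seed, and stage
#' toggles. Unknown keys are rejected.
#'
#' @param seed global seed reused (with fixed offsets) by every stochastic
#'   stage.
#' @param family a [family_sim_config()] for the synthetic input (ignored
#'   when `genes` is supplied to [run_pipeline()]).
#' @param min_weight,top_k similarity-network parameters.
#' @param walk,dims,knn_k embedding parameters (`walk` a [walk_config()]).
#' @param resolutions,n_perm_prune,alpha_prune hierarchy parameters.
#' @param promoter_k,sim_seed_threshold paralog-grouping parameters.
#' @param lambda_h,lambda_J,theta Potts regularization / reweighting.
#' @param run_threepop toggle the three-pool stage (needs `pools` input).
#' @param tau_hi,tau_lo candidate-calling thresholds.
#' @param n_perm permutations for the burden and clustering tests.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, family = family_sim_config(seed = seed),
                            min_weight = 0, top_k = 500,
                            walk = NULL, dims = 128, knn_k = 10,
                            resolutions = NULL, n_perm_prune = 199,
                            alpha_prune = 0.05,
                            promoter_k = 12, sim_seed_threshold = 0.5,
                            lambda_h = NULL, lambda_J = NULL, theta = 0.8,
                            run_threepop = FALSE, tau_hi = 0.8, tau_lo = 0.2,
                            n_perm = 999) {
  walk <- walk %||% walk_config(seed = seed)
  structure(
    list(
      seed = check_count(seed, "seed", min = 0L), family = family,
      min_weight = min_weight, top_k = top_k, walk = walk, dims = dims,
      knn_k = knn_k, resolutions = resolutions,
      n_perm_prune = n_perm_prune, alpha_prune = alpha_prune,
      promoter_k = promoter_k, sim_seed_threshold = sim_seed_threshold,
      lambda_h = lambda_h, lambda_J = lambda_J, theta = theta,
      run_threepop = run_threepop, tau_hi = tau_hi, tau_lo = tau_lo,
      n_perm = n_perm
    ),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes network construction, embedding, hierarchy, paralog grouping,
#' Potts fitting and burden testing (plus the three-pool stage when `pools`
#' is given) and writes every artifact, a log, and an md5 manifest into
#' `outdir`. A rerun with the same inputs and seed produces byte-identical
#' artifacts.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created; must be empty or absent).
#' @param genes optional gene tibble; default generates the configured
#'   synthetic family.
#' @param truth optional truth list accompanying `genes`.
#' @param pools optional three-pool variant table for the threepop stage.
#' @return invisibly, a list with the in-memory results and the manifest
#'   tibble.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir, genes = NULL,
                         truth = NULL, pools = NULL) {
  if (dir.exists(outdir) && length(list.files(outdir)) > 0) {
    abort(sprintf("Output directory %s exists and is not empty.", outdir))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "pipeline.log")
  log_line <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = logf, append = TRUE)
  }
  log_line("pepfam pipeline, seed = %d", config$seed)
  log_line("config: %s", jsonlite::toJSON(
    config[setdiff(names(config), c("family", "walk"))],
    auto_unbox = TRUE, null = "null"
  ))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      log_line("stage %s FAILED: %s", name, conditionMessage(e))
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
        conditionMessage(e)
      ))
    })
    log_line("stage %s done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    res
  }

  if (is.null(genes)) {
    fam <- stage("simulate", generate_family(config$family))
    genes <- fam$genes
    truth <- fam$truth
  }
  write_fasta(setNames(genes$precursor, genes$gene_id),
    file.path(outdir, "precursors.fa"),
    type = "AA"
  )
  write_fasta(setNames(genes$cds, genes$gene_id),
    file.path(outdir, "cds.fa"),
    type = "DNA"
  )
  write_fasta(setNames(genes$promoter, genes$gene_id),
    file.path(outdir, "promoters.fa"),
    type = "DNA"
  )

  graph <- stage("simnet", {
    g <- build_graph(genes, min_weight = config$min_weight)
    prune_top_k(g, config$top_k)
  })
  write_graph_tsv(graph, file.path(outdir, "network.tsv"))

  emb <- stage("embed", {
    walks <- random_walks(graph, config$walk)
    embed_walks(walks, dims = config$dims,
      context_window = config$walk$context_window
    )
  })
  readr::write_tsv(tidy(emb), file.path(outdir, "embedding.tsv"))
  coords <- stage("project", project_2d(emb))
  readr::write_tsv(coords, file.path(outdir, "coords_2d.tsv"))

  tree <- stage("hierarchy", {
    parts <- multires_communities(graph,
      resolutions = config$resolutions,
      seed = config$seed
    )
    tr <- reconcile_tree(parts)
    prune_sisters_rf(tr,
      setNames(genes$dodecapeptide, genes$gene_id),
      n_perm = config$n_perm_prune, alpha = config$alpha_prune,
      seed = config$seed
    )
  })
  write_newick(hierarchy_newick(tree, genes_as_leaves = TRUE),
    file.path(outdir, "hierarchy.nwk")
  )
  jsonlite::write_json(
    lapply(split(
      names(tree$layers[[length(tree$layers)]]),
      tree$layers[[length(tree$layers)]]
    ), sort),
    file.path(outdir, "leaf_members.json")
  )

  groups <- stage("paralogs", {
    knn <- knn_graph(emb, k = min(config$knn_k, length(graph$nodes) - 1L))
    pn <- build_promoter_network(genes, k = config$promoter_k)
    assign_paralog_groups(genes, knn, pn, config$sim_seed_threshold)
  })
  readr::write_tsv(groups, file.path(outdir, "paralog_groups.tsv"))

  model <- stage("potts", fit_potts(
    genes$dodecapeptide,
    lambda_h = config$lambda_h, lambda_J = config$lambda_J,
    theta = config$theta
  ))
  write_potts_json(model, file.path(outdir, "potts_model.json"))
  wt <- consensus_motif(genes$dodecapeptide)
  land <- mutational_landscape(model, wt)
  readr::write_tsv(tidy(land), file.path(outdir, "landscape.tsv"))

  burden <- stage("burden", {
    recs <- build_burden_table(genes, model, truth, seed = config$seed)
    readr::write_tsv(recs, file.path(outdir, "burden_records.tsv"))
    if (any(recs$is_paralog_pair) && !all(recs$is_paralog_pair)) {
      bt <- paralog_burden_test(recs,
        n_perm = config$n_perm,
        seed = config$seed
      )
      jsonlite::write_json(
        list(
          estimate = bt$estimate, p_value = bt$p_value,
          n_per_stratum = as.list(setNames(
            as.integer(bt$strata), names(bt$strata)
          ))
        ),
        file.path(outdir, "burden_test.json"),
        auto_unbox = TRUE, digits = NA
      )
      bt
    } else {
      NULL
    }
  })

  threepop <- NULL
  if (config$run_threepop && !is.null(pools)) {
    threepop <- stage("threepop", {
      mis <- mutational_index(pools,
        tau_lo = config$tau_lo,
        tau_hi = config$tau_hi
      )
      cand <- call_candidates(mis,
        tau_hi = config$tau_hi,
        tau_lo = config$tau_lo
      )
      pn <- build_promoter_network(genes, k = config$promoter_k)
      pt <- if (length(cand) >= 2L && all(cand %in% pn$nodes)) {
        promoter_cluster_test(cand, pn,
          n_perm = config$n_perm,
          seed = config$seed
        )
      } else {
        NULL
      }
      readr::write_tsv(mis, file.path(outdir, "mutational_index.tsv"))
      jsonlite::write_json(
        list(
          candidates = cand,
          cluster_p_value = if (is.null(pt)) NULL else pt$p_value
        ),
        file.path(outdir, "candidates.json"),
        auto_unbox = TRUE, digits = NA
      )
      list(mis = mis, candidates = cand, cluster_test = pt)
    })
  }

  # the log carries wall-clock timings, so it stays out of the checksums
  files <- sort(setdiff(list.files(outdir), c("manifest.json", "pipeline.log")))
  manifest <- tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    dataframe = "rows", digits = NA
  )
  log_line("pipeline complete: %d artifacts", nrow(manifest))
  invisible(list(
    genes = genes, truth = truth, graph = graph, embedding = emb,
    coords = coords, tree = tree, groups = groups, model = model,
    burden = burden, threepop = threepop, manifest = manifest,
    outdir = outdir
  ))
}
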