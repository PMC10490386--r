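#' Build a pipeline run configuration
#'
#' Either point `tree_path`/`matrix_path` at real inputs or supply a
#' [synthetic_scenario()]; exactly one of the two. The master `seed`
#' deterministically derives an independent seed for each random stage
#' (null model, Mantel tests, NMDS), so changing one stage's override seed
#' leaves the others' output untouched.
#'
#' @param tree_path,matrix_path Paths to a Newick tree and a
#'   presence-absence table (both or neither).
#' @param adjacency_path Optional path to a two-column site-adjacency
#'   table.
#' @param scenario Optional [synthetic_scenario()] (alternative to paths).
#' @param metric Turnover matrix used for regionalization (default
#'   `"pbeta_sim"`, the phylogenetic Simpson turnover).
#' @param n_permutations Tip permutations for the null model and Mantel
#'   permutations (default 999).
#' @param method Linkage method, or `"auto"` to select by cophenetic fit.
#' @param k Number of regions, or `"auto"` for silhouette selection.
#' @param k_max Upper end of the silhouette search range (default
#'   `min(15, n - 1)`).
#' @param nmds_dimensions,nmds_starts NMDS settings (defaults 2 and 100).
#' @param transpose If `TRUE` the occurrence file has taxa in rows and is
#'   transposed on read.
#' @param seed Master seed.
#' @param ses_seed,mantel_seed,nmds_seed Optional per-stage overrides of
#'   the derived seeds.
#' @param out_dir Optional output directory; when given, all artifacts are
#'   written there.
#' @return A `run_config` list.
#' @export
run_config <- function(tree_path = NULL, matrix_path = NULL,
                       adjacency_path = NULL, scenario = NULL,
                       metric = c("pbeta_sim", "beta_sim"),
                       n_permutations = 999L,
                       method = "auto", k = "auto", k_max = NULL,
                       nmds_dimensions = 2L, nmds_starts = 100L,
                       transpose = FALSE,
                       seed = 1L, ses_seed = NULL, mantel_seed = NULL,
                       nmds_seed = NULL, out_dir = NULL) {
  metric <- match.arg(metric)
  have_paths <- !is.null(tree_path) && !is.null(matrix_path)
  if (identical(have_paths, !is.null(scenario))) {
    stop("supply either tree_path + matrix_path or a scenario, not both or neither")
  }
  stopifnot(n_permutations >= 2L, nmds_dimensions >= 1L, nmds_starts >= 1L)
  derived <- derive_seeds(seed)
  structure(list(tree_path = tree_path, matrix_path = matrix_path,
                 adjacency_path = adjacency_path, scenario = scenario,
                 metric = metric, n_permutations = as.integer(n_permutations),
                 method = method, k = k, k_max = k_max,
                 nmds_dimensions = as.integer(nmds_dimensions),
                 nmds_starts = as.integer(nmds_starts),
                 transpose = isTRUE(transpose),
                 seed = as.integer(seed),
                 ses_seed = if (is.null(ses_seed)) derived[["ses"]] else as.integer(ses_seed),
                 mantel_seed = if (is.null(mantel_seed)) derived[["mantel"]] else as.integer(mantel_seed),
                 nmds_seed = if (is.null(nmds_seed)) derived[["nmds"]] else as.integer(nmds_seed),
                 out_dir = out_dir),
            class = "run_config")
}

# stage seeds derived deterministically from the master seed
#' @keywords internal
derive_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 4L),
                  c("synth", "ses", "mantel", "nmds"))
}

#' @keywords internal
stage_log <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.1fs", stage,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full regionalization pipeline
#'
#' Executes, in order: input loading (or synthesis) and harmonization; the
#' four pairwise turnover matrices (Simpson and Jaccard turnover, taxonomic
#' and phylogenetic); Mantel tests among them and against the SES matrix;
#' the tip-shuffle SES ensemble with per-site summaries; linkage-method
#' selection by cophenetic fit; silhouette selection of the number of
#' regions; region/realm assignment; and NMDS of the regionalization
#' metric. Every stage is logged with its timing; all randomness is seeded
#' from the configuration, so a rerun with the same config reproduces the
#' summary byte for byte.
#'
#' @param config A [run_config()].
#' @return A `pipeline_result` list: inputs, the four distance matrices,
#'   `ses`, `mantel`, `method_selection`, `k_selection`, `assignment`,
#'   `nmds`, and `summary` (the JSON-ready structured summary).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$scenario)) {
    flora <- stage_log("synth", simulate_flora(config$scenario))
    tree <- flora$tree
    mat <- flora$mat
    truth <- flora$truth
  } else {
    tree <- stage_log("read_tree", read_tree(config$tree_path))
    mat <- stage_log("read_matrix",
                     read_matrix(config$matrix_path,
                                 transpose = config$transpose))
    truth <- NULL
  }
  adjacency <- if (!is.null(config$adjacency_path)) {
    as.matrix(utils::read.table(config$adjacency_path, header = TRUE,
                                stringsAsFactors = FALSE))
  }
  h <- stage_log("harmonize", harmonize(tree, mat))
  tree <- h$tree
  mat <- h$mat

  D <- list(
    beta_sim = stage_log("beta_sim", pairwise_beta(mat, "beta_sim")),
    beta_jtu = stage_log("beta_jtu", pairwise_beta(mat, "beta_jtu")),
    pbeta_sim = stage_log("pbeta_sim", pairwise_beta(mat, "pbeta_sim", tree)),
    pbeta_jtu = stage_log("pbeta_jtu", pairwise_beta(mat, "pbeta_jtu", tree))
  )

  ses <- stage_log("ses", ses_pbeta(mat, tree, "pbeta_sim",
                                    n_permutations = config$n_permutations,
                                    seed = config$ses_seed))

  mantel_pairs <- list(
    beta_jtu_vs_beta_sim = list(D$beta_jtu, D$beta_sim, FALSE),
    pbeta_jtu_vs_pbeta_sim = list(D$pbeta_jtu, D$pbeta_sim, FALSE),
    pbeta_sim_vs_beta_sim = list(D$pbeta_sim, D$beta_sim, FALSE),
    ses_vs_pbeta_sim = list(ses$ses, D$pbeta_sim, TRUE),
    ses_vs_beta_sim = list(ses$ses, D$beta_sim, TRUE)
  )
  mantel <- stage_log("mantel", lapply(mantel_pairs, function(p) {
    mantel_test(p[[1]], p[[2]], n_permutations = config$n_permutations,
                seed = config$mantel_seed, na_rm = p[[3]])
  }))

  Dreg <- D[[config$metric]]
  sel <- stage_log("select_method", select_method(Dreg))
  method <- if (identical(config$method, "auto")) sel$best_method else config$method
  L <- sel$fits[[method]]
  ksel <- stage_log("select_k", select_k(L, Dreg, k_max = config$k_max))
  k <- if (identical(config$k, "auto")) ksel$k_best else as.integer(config$k)
  assignment <- stage_log("assign_regions",
                          assign_regions(L, Dreg, k, adjacency = adjacency))
  ord <- stage_log("nmds", nmds(Dreg, n_dimensions = config$nmds_dimensions,
                                n_starts = config$nmds_starts,
                                seed = config$nmds_seed))

  site_table <- data.frame(
    site = rownames(mat),
    mean_beta_sim = site_mean(D$beta_sim),
    mean_pbeta_sim = site_mean(D$pbeta_sim),
    mean_ses = ses$site_mean_ses,
    significant = !is.na(ses$site_mean_ses) & abs(ses$site_mean_ses) > 1.96,
    region = assignment$table$region[match(rownames(mat), assignment$table$site)],
    realm = assignment$table$realm[match(rownames(mat), assignment$table$site)],
    row.names = NULL, stringsAsFactors = FALSE)

  summary <- list(
    seed = config$seed,
    n_sites = nrow(mat),
    n_taxa = ncol(mat),
    metric = config$metric,
    n_permutations = config$n_permutations,
    scenario = if (!is.null(config$scenario)) unclass(config$scenario),
    harmonization = h$report,
    mantel = lapply(mantel, function(m) list(r = m$r, p = m$p)),
    ses = list(n_sites_positive = ses$n_sites_positive,
               n_sites_negative = ses$n_sites_negative,
               n_sites_significant = ses$n_sites_significant,
               n_degenerate_pairs = ses$n_degenerate_pairs),
    method_selection = list(best_method = sel$best_method,
                            table = sel$table),
    k_selection = list(k = k, k_best_silhouette = ksel$k_best,
                       curve = ksel$silhouette_curve),
    regions = list(k = assignment$k,
                   n_realms = length(unique(assignment$table$realm)),
                   mean_silhouette = assignment$mean_silhouette,
                   criteria = assignment$criteria_report),
    nmds = list(stress = ord$stress, dimensions = config$nmds_dimensions,
                n_starts = config$nmds_starts)
  )

  res <- list(tree = tree, mat = mat, truth = truth, distances = D,
              ses = ses, mantel = mantel, method_selection = sel,
              k_selection = ksel, assignment = assignment, nmds = ord,
              site_table = site_table, summary = summary, config = config)
  class(res) <- "pipeline_result"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_tree(tree, p("tree.nwk"))
    write_matrix(mat, p("matrix.tsv"))
    for (nm in names(D)) write_distance(D[[nm]], p(paste0(nm, ".tsv")))
    write_distance(ses$ses, p("ses.tsv"))
    write_regions(assignment, p("regions.tsv"))
    utils::write.table(site_table, p("sites.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(site = rownames(ord$coordinates),
                                  ord$coordinates),
                       p("nmds.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(truth)) {
      utils::write.table(truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    write_tree(dendrogram_tree(assignment_linkage(res)), p("dendrogram.nwk"))
    write_summary(summary, p("summary.json"))
  }
  res
}

#' @keywords internal
assignment_linkage <- function(res) {
  method <- res$summary$method_selection$best_method
  if (!identical(res$config$method, "auto")) method <- res$config$method
  res$method_selection$fits[[method]]
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Floristic regionalization pipeline\n")
  cat(sprintf("  %d sites x %d taxa; metric %s\n",
              x$summary$n_sites, x$summary$n_taxa, x$summary$metric))
  cat(sprintf("  best linkage: %s; k = %d regions in %d realms\n",
              x$summary$method_selection$best_method, x$summary$regions$k,
              x$summary$regions$n_realms))
  cat(sprintf("  NMDS stress = %.4f\n", x$summary$nmds$stress))
  invisible(x)
}
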