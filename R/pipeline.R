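#' Configure an end-to-end analysis run
#'
#' Validates all inputs up front: file paths, region bounds, replicate
#' counts and the seed, so a misconfigured run fails before any compute.
#'
#' @param fasta Path to the aligned sample FASTA.
#' @param pops Path to the sample-to-population TSV.
#' @param reference Path to the reference FASTA (or a sequence string).
#' @param out_dir Output directory (created if absent).
#' @param region_set Statistics window (default [stat_regions()]).
#' @param tree_table Optional haplogroup tree-table TSV (enables
#'   haplogroup calls, frequencies and admixture).
#' @param clades Optional Newick file of dating clades with
#'   substitution-count branch lengths.
#' @param parent1,parent2_raw Optional parental haplogroup sets for the
#'   admixture partition (parent-1 precedence applies).
#' @param reps Coalescent simulations for neutrality p-values.
#' @param B Bootstrap replicates for the mismatch SSD/raggedness test.
#' @param n_perm Permutations per population pair for Fst significance.
#' @param seed Integer seed used for every stochastic stage.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(fasta, pops, reference, out_dir,
                            region_set = stat_regions(),
                            tree_table = NULL, clades = NULL,
                            parent1 = NULL, parent2_raw = NULL,
                            reps = 1000, B = 1000, n_perm = 1000,
                            seed = 1L) {
  stopifnot_region_set(region_set)
  for (p in c(fasta, pops)) {
    if (!file.exists(p)) abort(paste0("Input file not found: ", p))
  }
  if (!is.null(tree_table) && !file.exists(tree_table)) {
    abort(paste0("Tree table not found: ", tree_table))
  }
  if (!is.null(clades) && !file.exists(clades)) {
    abort(paste0("Clade Newick file not found: ", clades))
  }
  if (reps < 0 || B < 0 || n_perm < 0) abort("Replicate counts must be >= 0.")
  structure(
    list(fasta = fasta, pops = pops, reference = reference,
         out_dir = out_dir, region_set = region_set,
         tree_table = tree_table, clades = clades,
         parent1 = parent1, parent2_raw = parent2_raw,
         reps = reps, B = B, n_perm = n_perm, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Reproduces the standard analysis order on any dataset: molecular
#' diversity and neutrality tests per population, pairwise Fst with gene
#' flow and MDS, mismatch-distribution expansion fits with bootstrap
#' p-values and verdicts, optional haplogroup frequencies and admixture
#' partition, optional rho-based clade dating, and a median-joining
#' network. Each stage writes a TSV into `out_dir`; a plain-text log
#' records the seed, package version and stage progress. A stage failure
#' aborts with the stage name; outputs of completed stages remain on
#' disk.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the result tables/objects.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("Expected a pipeline_config; see pipeline_config().")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_line <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ..., "\n",
        file = log_path, append = TRUE, sep = "")
  }
  cat("", file = log_path)
  log_line("mtpopgen ", as.character(utils::packageVersion("mtpopgen")),
           ", seed ", config$seed)
  stage <- function(name, expr) {
    log_line("stage ", name, " start")
    out <- tryCatch(expr, error = function(e) {
      log_line("stage ", name, " FAILED: ", conditionMessage(e))
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
    log_line("stage ", name, " done")
    out
  }
  results <- list()
  ds <- stage("ingest", {
    profiles <- read_profiles(config$fasta, config$region_set,
                              config$reference)
    mt_dataset(profiles, read_pop_table(config$pops), config$region_set)
  })

  results$diversity <- stage("diversity", {
    div <- diversity_summary(ds, reps = config$reps,
                             seed = config$seed)
    readr::write_tsv(div, file.path(config$out_dir, "diversity.tsv"))
    div
  })

  if (length(unique(ds$population)) >= 2) {
    results$fst <- stage("structure", {
      fm <- fst_matrix(ds, n_perm = config$n_perm, seed = config$seed + 1L)
      readr::write_tsv(tidy(fm), file.path(config$out_dir, "fst.tsv"))
      fm
    })
    if (length(unique(ds$population)) >= 3) {
      results$mds <- stage("mds", {
        mds <- classical_mds(results$fst)
        readr::write_tsv(tidy(mds), file.path(config$out_dir, "mds.tsv"))
        mds
      })
    }
  }

  results$mismatch <- stage("mismatch", {
    pops <- unique(ds$population)
    tab <- purrr::map(pops, function(p) {
      spec <- mismatch_spectrum(ds, p)
      fit <- fit_expansion(spec, n = sum(ds$population == p))
      if (config$B > 0 && length(spec$counts) > 1) {
        fit <- expansion_test(fit, B = config$B, seed = config$seed + 2L)
      }
      div_row <- results$diversity[results$diversity$population == p, ]
      tibble(
        population = p, tau = fit$tau, theta0 = fit$theta0,
        theta1 = fit$theta1, ssd = fit$ssd, p_ssd = fit$p_ssd,
        raggedness = fit$raggedness, p_rag = fit$p_rag,
        verdict = expansion_verdict(div_row$fu_Fs, div_row$p_Fs, fit$p_ssd)
      )
    }) |> bind_rows()
    readr::write_tsv(tab, file.path(config$out_dir, "mismatch.tsv"))
    tab
  })

  if (!is.null(config$tree_table)) {
    results$haplogroups <- stage("haplogroups", {
      tree <- read_tree_table(config$tree_table)
      calls <- assign_haplogroups(ds, tree)
      readr::write_tsv(calls,
                       file.path(config$out_dir, "haplogroup_calls.tsv"))
      freqs <- haplogroup_frequencies(calls)
      readr::write_tsv(freqs,
                       file.path(config$out_dir, "haplogroup_freqs.tsv"))
      list(calls = calls, freqs = freqs)
    })
    if (!is.null(config$parent1) && !is.null(config$parent2_raw)) {
      results$admixture <- stage("admixture", {
        adm <- admixture_partition(results$haplogroups$freqs,
                                   parent1 = config$parent1,
                                   parent2_raw = config$parent2_raw)
        readr::write_tsv(adm, file.path(config$out_dir, "admixture.tsv"))
        adm
      })
    }
  }

  if (!is.null(config$clades)) {
    results$dating <- stage("dating", {
      trees <- ape::read.tree(config$clades)
      if (inherits(trees, "phylo")) trees <- list(clade1 = trees)
      dates <- date_clades(trees)
      readr::write_tsv(dates, file.path(config$out_dir, "dating.tsv"))
      dates
    })
  }

  results$network <- stage("network", {
    net <- median_joining(ds)
    write_network(net, file.path(config$out_dir, "network"))
    net
  })

  log_line("pipeline complete")
  invisible(results)
}
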