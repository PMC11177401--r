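#' Pipeline run configuration
#'
#' Bundles the stage toggles and all analysis parameters of the end-to-end
#' pipeline.  Defaults reproduce the conventional analysis settings: 2%
#' heteroplasmy frequency filter (5% as the stricter check), VCF filters of
#' quality 30 (or 90), per-sample depth 10-500 and under 10% missingness,
#' 25 bp depth windows, 500/100 sliding-Pi windows, 1 kb repeat flanks, and
#' a 0.05 significance level for maternity assignment.
#'
#' @param seed Integer seed governing all randomness of the run.
#' @param out_dir Output directory for stage files and the run report.
#' @param sim A [sim_config()] for the simulation stage (its seed is
#'   overridden by `seed`).
#' @param stages Character vector of stages to run, in dependency order;
#'   any subset of `c("simulate", "call", "copynum", "select", "inherit")`.
#' @param min_freq,strict_freq Heteroplasmy frequency thresholds.
#' @param min_depth Minimum depth for heteroplasmy calling.
#' @param vcf_min_qual,vcf_min_depth,vcf_max_depth,vcf_max_missing VCF
#'   filter settings.
#' @param depth_window Window size (bases) for windowed depth.
#' @param pi_window,pi_step Sliding nucleotide-diversity windows.
#' @param repeat_flank Flank length for repeat copy-number estimation.
#' @param alpha_sig Significance level for maternity assignment.
#' @param inputs Named list of input paths for runs that skip the
#'   simulation stage: `counts_dir`, `genome`, `gff`, `pedigree`,
#'   `totals`, `vcf`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       out_dir = tempfile("mitohet_run_"),
                       sim = sim_config(seed = seed),
                       stages = c("simulate", "call", "copynum", "select",
                                  "inherit"),
                       min_freq = 0.02, strict_freq = 0.05, min_depth = 10L,
                       vcf_min_qual = 30, vcf_min_depth = 10,
                       vcf_max_depth = 500, vcf_max_missing = 0.10,
                       depth_window = 25L, pi_window = 500L, pi_step = 100L,
                       repeat_flank = 1000L, alpha_sig = 0.05,
                       inputs = list()) {
  known <- c("simulate", "call", "copynum", "select", "inherit")
  if (!all(stages %in% known))
    stopf("unknown stage(s): %s", paste(setdiff(stages, known), collapse = ", "))
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), out_dir = out_dir, sim = sim,
                 stages = stages, min_freq = min_freq,
                 strict_freq = strict_freq, min_depth = min_depth,
                 vcf_min_qual = vcf_min_qual, vcf_min_depth = vcf_min_depth,
                 vcf_max_depth = vcf_max_depth,
                 vcf_max_missing = vcf_max_missing,
                 depth_window = depth_window, pi_window = pi_window,
                 pi_step = pi_step, repeat_flank = repeat_flank,
                 alpha_sig = alpha_sig, inputs = inputs),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order — simulate a matriline,
#' call heteroplasmic sites, estimate copy ratios and their association
#' with heteroplasmy, tabulate selection signals, and infer maternity and
#' the pedigree mutation rate — writing stage outputs under
#' `config$out_dir` and returning a consolidated report.  A rerun with the
#' same configuration and seed reproduces every output byte for byte.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report` echoing the configuration and the
#'   key per-stage statistics; also written as `report.json` in the output
#'   directory.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("mitohet")),
                 seed = config$seed, stages = config$stages)
  st <- function(s) s %in% config$stages
  env <- new.env(parent = emptyenv())

  if (st("simulate")) {
    sim <- config$sim
    gen <- simulate_genome(sim)
    state <- simulate_matriline(sim, gen$genome, gen$annotation)
    rc <- simulate_readcounts(state, gen$genome, sim)
    write_mito_fasta(gen$genome, file.path(config$out_dir, "genome.fa"))
    write_feature_table(gen$annotation, file.path(config$out_dir, "genome.gff"),
                        seqid = gen$genome$id)
    write_pedigree(state$individuals, file.path(config$out_dir, "pedigree.tsv"))
    write_truth_tables(state, file.path(config$out_dir, "truth"))
    write_readcount_tables(rc$counts, file.path(config$out_dir, "counts"))
    utils::write.table(rc$totals, file.path(config$out_dir, "totals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_sim_vcf(state, gen$genome, file.path(config$out_dir, "sim.vcf"),
                  counts = rc$counts)
    write_sim_config(sim, file.path(config$out_dir, "sim_config.yaml"))
    env$genome <- gen$genome; env$annotation <- gen$annotation
    env$state <- state; env$counts <- rc$counts; env$totals <- rc$totals
    env$pedigree <- state$individuals
    report$simulate <- list(n_individuals = nrow(state$individuals),
                            L_mt = sim$L_mt,
                            n_true_variable_sites =
                              sum(colSums(state$freqs > 0) > 0))
  } else {
    load_pipeline_inputs(config, env)
  }

  if (st("call")) {
    need_env(env, c("counts"), "call")
    env$sites <- call_het_sites(env$counts, min_freq = config$min_freq,
                                min_depth = config$min_depth)
    L <- if (!is.null(env$genome)) env$genome$length else max(env$counts$pos)
    env$summaries <- summarize_individuals(env$sites, L,
                                           individuals = unique(env$counts$individual))
    utils::write.table(env$sites, file.path(config$out_dir, "sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(env$summaries, file.path(config$out_dir, "summaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$call <- list(n_rows_in = nrow(env$counts),
                        n_sites_called = nrow(env$sites),
                        mean_n_variable = mean(env$summaries$n_variable))
  }

  if (st("copynum")) {
    need_env(env, c("totals", "summaries"), "copynum")
    ratios <- copy_ratio_table(env$totals)
    env$ratios <- ratios
    utils::write.table(ratios, file.path(config$out_dir, "ratios.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    assoc <- ratio_vs_het_association(ratios, env$summaries)
    report$copynum <- list(ratio_range = range(ratios$ratio),
                           assoc_slope = assoc$slope,
                           assoc_r_squared = assoc$r_squared,
                           assoc_p = assoc$p, n = assoc$n)
    if (!is.null(env$state)) {
      ref_id <- env$state$individuals$id[1]
      set.seed(sub_seed(config$seed, ref_id, "depth"))
      prof <- simulate_depth_profile(
        env$state$individuals$repeat_copies[1],
        config$sim$mean_depth, config$sim$repeat_region, config$sim$L_mt)
      est <- repeat_copy_number(prof, config$sim$repeat_region,
                                flank = config$repeat_flank)
      report$copynum$repeat_copies_true <- env$state$individuals$repeat_copies[1]
      report$copynum$repeat_copies_est <- est$copies
    }
  }

  if (st("select")) {
    need_env(env, c("sites", "genome", "annotation"), "select")
    sel <- selection_report(env$sites, env$genome, env$annotation)
    utils::write.table(sel, file.path(config$out_dir, "selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tab <- tabulate_positions(env$sites, env$genome, env$annotation)
    report$select <- list(pooled = as.list(tab$pooled),
                          n_unique_sites = tab$n_unique_sites)
  }

  if (st("inherit")) {
    need_env(env, c("sites", "pedigree"), "inherit")
    ped <- env$pedigree
    parents <- if (!is.null(env$state)) env$state$focal_parents else
      find_focal_parents(ped)
    offs <- ped$id[!is.na(ped$mother) & ped$mother %in% parents]
    asg <- assign_mothers(env$sites, parents, offs,
                          alpha_sig = config$alpha_sig)
    utils::write.table(asg, file.path(config$out_dir, "assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    maj <- count_majority_variants(env$sites)
    L <- if (!is.null(env$genome)) env$genome$length else max(env$sites$position)
    rate <- pedigree_mutation_rate(max(maj$n, 0L), nrow(ped), L)
    writeLines(sprintf("%s=%s", names(rate), vapply(rate, format, "")),
               file.path(config$out_dir, "mutation_rate.txt"))
    strict_counts <- table(factor(asg$strict_mother, levels = parents))
    loose_counts <- table(factor(asg$loose_mother, levels = parents))
    correct <- if (!is.null(env$state))
      mean(asg$loose_mother == ped$mother[match(asg$offspring, ped$id)],
           na.rm = TRUE) else NA_real_
    report$inherit <- list(n_offspring = length(offs),
                           strict_assigned = as.list(strict_counts),
                           loose_assigned = as.list(loose_counts),
                           loose_accuracy_vs_truth = correct,
                           n_majority_variants = maj$n,
                           mutation_rate = rate$rate)
  }

  class(report) <- "run_report"
  jsonlite::write_json(unclass(report),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  report
}

need_env <- function(env, what, stage) {
  missing <- what[!vapply(what, function(w) !is.null(env[[w]]), TRUE)]
  if (length(missing))
    stopf("stage '%s' requires upstream output(s): %s",
          stage, paste(missing, collapse = ", "))
}

load_pipeline_inputs <- function(config, env) {
  ins <- config$inputs
  if (!is.null(ins$genome)) env$genome <- read_mito_fasta(ins$genome)
  if (!is.null(ins$gff))
    env$annotation <- read_feature_table(ins$gff,
                                         L_mt = env$genome$length %||% NULL)
  if (!is.null(ins$pedigree)) env$pedigree <- read_pedigree(ins$pedigree)
  if (!is.null(ins$totals)) env$totals <- read_totals_tsv(ins$totals)
  if (!is.null(ins$counts_dir)) {
    files <- list.files(ins$counts_dir, pattern = "\\.tsv$", full.names = TRUE)
    env$counts <- do.call(rbind, lapply(files, read_readcount_tsv))
  }
  invisible(env)
}

# Focal parents of an externally supplied pedigree: the mothers of the
# largest final-generation sibship plus their full sibs' other parent.
find_focal_parents <- function(ped) {
  last <- ped[ped$generation == max(ped$generation), ]
  moms <- names(sort(table(last$mother), decreasing = TRUE))
  unique(c(moms, last$father[!is.na(last$father)]))[1:2]
}

#' Validate pipeline input files
#'
#' Checks formats, coordinate bounds, pedigree consistency and sample-id
#' agreement across the supplied inputs, distinguishing errors from
#' warnings; nothing is thrown, everything is reported.
#'
#' @param config A [run_config()] whose `inputs` name the files.
#' @return A data frame with columns `level` (`"error"`/`"warning"`),
#'   `input`, `message`.
#' @export
validate_inputs <- function(config) {
  entries <- list()
  add <- function(level, input, msg)
    entries[[length(entries) + 1L]] <<- data.frame(
      level = level, input = input, message = msg, stringsAsFactors = FALSE)
  ins <- config$inputs
  env <- new.env(parent = emptyenv())
  for (nm in names(ins)) {
    if (!file.exists(ins[[nm]]) && !dir.exists(ins[[nm]])) {
      add("error", nm, sprintf("path does not exist: %s", ins[[nm]]))
    }
  }
  try(suppressWarnings(load_pipeline_inputs(config, env)), silent = TRUE)

  if (!is.null(env$pedigree)) {
    ped <- env$pedigree
    known <- ped$id
    orphan <- setdiff(stats::na.omit(ped$mother), known)
    if (length(orphan))
      add("error", "pedigree",
          sprintf("mother id(s) absent from pedigree: %s",
                  paste(orphan, collapse = ", ")))
    for (i in seq_len(nrow(ped))) {
      m <- ped$mother[i]
      if (!is.na(m) && m %in% known &&
          ped$generation[match(m, known)] >= ped$generation[i])
        add("error", "pedigree",
            sprintf("individual %s not in a later generation than its mother %s",
                    ped$id[i], m))
    }
  }
  if (!is.null(env$counts) && !is.null(env$genome)) {
    if (any(env$counts$pos > env$genome$length))
      add("error", "counts_dir", "count positions exceed genome length")
  }
  if (!is.null(env$counts) && !is.null(env$pedigree)) {
    extra <- setdiff(unique(env$counts$individual), env$pedigree$id)
    if (length(extra))
      add("warning", "counts_dir",
          sprintf("individuals not in pedigree: %s",
                  paste(extra, collapse = ", ")))
  }
  if (!is.null(env$annotation) && !is.null(env$genome)) {
    if (any(pmax(env$annotation$start, env$annotation$end) > env$genome$length))
      add("error", "gff", "feature coordinates exceed genome length")
  }
  if (length(entries) == 0L)
    return(data.frame(level = character(0), input = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, entries)
}
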