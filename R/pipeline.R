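#' Pipeline configuration
#'
#' Bundles the inputs of the full analysis: one codon alignment per gene
#' (aligned FASTA, shared reference taxon), a rooted species tree, optional
#' per-branch times (tab-separated `branch`/`time` in myr), the nested
#' branch-model ledger to fit, neutral-decay settings and an output
#' directory.
#'
#' @param alignments Named character vector of aligned-FASTA paths (names =
#'   gene labels).
#' @param tree Path to a rooted Newick tree (or a Newick string).
#' @param reference Reference taxon present in every alignment.
#' @param times Optional path to a tab-separated table with columns
#'   `branch` (child node id) and `time` (myr).
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for every stochastic stage.
#' @param decay List of overrides for [decay_sim_config].
#' @param estimate_branch_lengths Passed to the model fits.
#' @param starts Initial omega values for every fit.
#' @param fit_control Optimiser control list for every fit.
#' @param verbose Print stage progress to stderr.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alignments, tree, reference, times = NULL,
                            out_dir = "orfdecay-out", seed = 1L,
                            decay = list(), estimate_branch_lengths = TRUE,
                            starts = c(0.5, 2), fit_control = list(),
                            verbose = FALSE) {
  if (is.null(names(alignments))) {
    names(alignments) <- paste0("gene", seq_along(alignments))
  }
  structure(list(alignments = alignments, tree = tree,
                 reference = reference, times = times, out_dir = out_dir,
                 seed = as.integer(seed), decay = decay,
                 estimate_branch_lengths = estimate_branch_lengths,
                 starts = starts, fit_control = fit_control,
                 verbose = verbose),
            class = "pipeline_config")
}

#' Run the full pseudogene-evolution analysis
#'
#' Executes, per gene: lesion scan, Dollo event mapping, branch
#' classification, alignment sanitization, the nested branch-model ledger
#' (one-ratio; intact vs pseudogene two-ratio with free and pinned
#' classes; intact/psi1/psi2 three-ratio with free and pinned classes) with
#' its LRT table, and a free-ratio fit. Then, across genes: the pooled
#' neutral disruption rate (when branch times are given), a neutral-decay
#' simulation, and for each gene pair the 2x2 pseudogene-overlap Fisher
#' test and the per-branch omega Spearman correlation. All tables are
#' written tab-separated under `out_dir` together with a reproducibility
#' manifest; every number in the returned report comes from one of those
#' files.
#'
#' @param config A [pipeline_config].
#' @return A `pipeline_report` list (also written to disk): per-gene
#'   results, `lrt_table`, `rate`, `decay`, `cross` and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message("[orfdecay] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  set.seed(config$seed)

  say("reading tree")
  tree <- stage("read_tree", {
    for (p in config$alignments) {
      if (!grepl(";", p, fixed = TRUE) && !file.exists(p)) {
        stop("alignment file not found: ", p)
      }
    }
    read_species_tree(config$tree)
  })
  times <- NULL
  if (!is.null(config$times)) {
    times <- stage("read_times", {
      utils::read.delim(config$times)
    })
  }

  genes <- names(config$alignments)
  per_gene <- list()
  all_events <- list(); all_classes <- list(); lrt_rows <- list()
  for (g in genes) {
    say("gene ", g, ": scan and classify")
    aln <- stage(paste0(g, ":read_alignment"),
                 read_codon_alignment(config$alignments[[g]],
                                      config$reference))
    events <- stage(paste0(g, ":scan"), scan_alignment(aln))
    mapped <- stage(paste0(g, ":map_events"), map_events(tree, events))
    classes <- stage(paste0(g, ":classify"),
                     classify_branches(tree, mapped))
    san <- stage(paste0(g, ":sanitize"), sanitize_alignment(aln))
    utils::write.table(dplyr::mutate(mapped, carriers = vapply(
      .data$carriers, paste, character(1), collapse = ",")),
      out(paste0(g, "_events.tsv")), sep = "\t", row.names = FALSE,
      quote = FALSE)
    utils::write.table(classes, out(paste0(g, "_branch_classes.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(san$log, out(paste0(g, "_removal_log.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_codon_alignment(san$alignment, out(paste0(g, "_sanitized.fasta")))
    cls_vec <- rep(NA_character_, length(tree$tip.label) + tree$Nnode)
    cls_vec[classes$branch] <- classes$class
    write_species_tree(tree, out(paste0(g, "_classes.nwk")),
                       classes = cls_vec)

    say("gene ", g, ": model ledger")
    ledger <- stage(paste0(g, ":ledger"), fit_model_ledger(
      san$alignment, tree, classes,
      estimate_branch_lengths = config$estimate_branch_lengths,
      starts = config$starts, control = config$fit_control))
    if (!is.null(ledger$lrt)) {
      lrt_rows[[g]] <- dplyr::mutate(ledger$lrt, gene = g, .before = 1L)
    }
    say("gene ", g, ": free-ratio")
    fr <- stage(paste0(g, ":free_ratio"), free_ratio(
      san$alignment, tree,
      estimate_branch_lengths = config$estimate_branch_lengths,
      starts = config$starts, control = config$fit_control))
    utils::write.table(fr$omega_by_branch,
                       out(paste0(g, "_omega_by_branch.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    per_gene[[g]] <- list(alignment = san$alignment, events = mapped,
                          classes = classes, ledger = ledger,
                          free_ratio = fr, removal_log = san$log)
    all_events[[g]] <- dplyr::mutate(mapped, gene = g, .before = 1L)
    all_classes[[g]] <- dplyr::mutate(classes, gene = g, .before = 1L)
  }

  lrt_table <- dplyr::bind_rows(lrt_rows)
  if (nrow(lrt_table)) {
    utils::write.table(lrt_table, out("lrt_table.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }

  rate <- NULL
  if (!is.null(times)) {
    say("pooled neutral disruption rate")
    exposures <- dplyr::bind_rows(lapply(genes, function(g) {
      tibble::tibble(gene = g, branch = times$branch,
                     exposure = times$time)
    }))
    rate <- stage("rate", neutral_disruption_rate(
      dplyr::bind_rows(all_events), dplyr::bind_rows(all_classes),
      exposures, unit = "myr"))
    utils::write.table(tidy(rate), out("disruption_rate.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }

  say("neutral decay simulation")
  decay_args <- utils::modifyList(list(seed = config$seed), config$decay)
  decay <- stage("decay_sim",
                 simulate_decay(do.call(decay_sim_config, decay_args)))
  utils::write.table(tidy(decay), out("decay_sim.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  cross <- list()
  if (length(genes) >= 2L) {
    say("cross-gene loss correlation")
    combos <- utils::combn(genes, 2L, simplify = FALSE)
    cross_rows <- lapply(combos, function(pr) {
      tab <- categorize_branch_pairs(per_gene[[pr[1]]]$classes,
                                     per_gene[[pr[2]]]$classes)
      sp <- tryCatch(
        spearman_branch_omega(per_gene[[pr[1]]]$free_ratio$omega_by_branch,
                              per_gene[[pr[2]]]$free_ratio$omega_by_branch),
        error = function(e) NULL)
      tibble::tibble(
        gene_a = pr[1], gene_b = pr[2],
        both = tab$a, a_only = tab$b, b_only = tab$c, neither = tab$d,
        fisher_p = fisher_exact_2x2(tab),
        r_s = if (is.null(sp)) NA_real_ else sp$r_s,
        spearman_p = if (is.null(sp)) NA_real_ else sp$p_value,
        n_used = if (is.null(sp)) NA_integer_ else sp$n_used)
    })
    cross <- dplyr::bind_rows(cross_rows)
    utils::write.table(cross, out("cross_loss.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }

  manifest <- c(
    paste0("orfdecay_version\t", as.character(utils::packageVersion("orfdecay"))),
    paste0("r_version\t", R.version.string),
    paste0("seed\t", config$seed),
    paste0("genes\t", paste(genes, collapse = ",")),
    paste0("config_hash\t", rlang::hash(config)),
    paste0("date\t", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")))
  writeLines(manifest, out("manifest.tsv"))

  structure(list(per_gene = per_gene, lrt_table = lrt_table, rate = rate,
                 decay = decay, cross = cross, out_dir = config$out_dir),
            class = "pipeline_report")
}

#' Fit the nested branch-model ledger for one gene
#'
#' Fits the standard hierarchy used to test pseudogene evolution: a
#' one-ratio model; a two-ratio model separating intact from pseudogene
#' (psi) lineages, plus versions with the pseudogene or the intact omega
#' pinned to 1; and a three-ratio model distinguishing founding (psi2)
#' from inherited (psi1) pseudogene lineages, plus versions pinning psi1
#' or psi2 to 1. Nested pairs are compared by LRT. Models involving psi
#' classes are skipped when the classification contains no such branches.
#'
#' @param aln Sanitized [codon_alignment].
#' @param tree Rooted [ape::phylo].
#' @param classes Tibble from [classify_branches].
#' @param ... Passed to [fit_codon_model].
#' @return List with `fits` (named list: `one_ratio`, `two_ratio`,
#'   `two_ratio_psi1fixed`, `two_ratio_intact1`, `three_ratio`,
#'   `three_ratio_psi1fixed`, `three_ratio_psi2fixed`) and `lrt` (tibble).
#' @export
fit_model_ledger <- function(aln, tree, classes, ...) {
  cls2 <- dplyr::mutate(classes, class = ifelse(
    .data$class %in% c("psi1", "psi2"), "psi", "intact"))
  has_psi <- any(cls2$class == "psi")
  has_psi1 <- any(classes$class == "psi1")
  fits <- list(one_ratio = fit_codon_model(aln, tree, one_ratio_model(),
                                           ...))
  tests <- list()
  if (has_psi) {
    fits$two_ratio <- fit_codon_model(aln, tree, branch_model(cls2), ...)
    fits$two_ratio_psifixed <- fit_codon_model(
      aln, tree, branch_model(cls2, fixed = c(psi = 1)), ...)
    fits$two_ratio_intact1 <- fit_codon_model(
      aln, tree, branch_model(cls2, fixed = c(intact = 1)), ...)
    tests$`one_ratio vs two_ratio` <- lrt(fits$one_ratio, fits$two_ratio)
    tests$`psi_fixed_1 vs two_ratio` <- lrt(fits$two_ratio_psifixed,
                                            fits$two_ratio)
    tests$`intact_fixed_1 vs two_ratio` <- lrt(fits$two_ratio_intact1,
                                               fits$two_ratio)
  }
  if (has_psi1) {
    fits$three_ratio <- fit_codon_model(aln, tree, branch_model(classes),
                                        ...)
    fits$three_ratio_psi1fixed <- fit_codon_model(
      aln, tree, branch_model(classes, fixed = c(psi1 = 1)), ...)
    fits$three_ratio_psi2fixed <- fit_codon_model(
      aln, tree, branch_model(classes, fixed = c(psi2 = 1)), ...)
    tests$`two_ratio vs three_ratio` <- lrt(fits$two_ratio,
                                            fits$three_ratio)
    tests$`psi1_fixed_1 vs three_ratio` <- lrt(fits$three_ratio_psi1fixed,
                                               fits$three_ratio)
    tests$`psi2_fixed_1 vs three_ratio` <- lrt(fits$three_ratio_psi2fixed,
                                               fits$three_ratio)
  }
  lrt_tbl <- if (length(tests)) {
    dplyr::bind_rows(tests, .id = "comparison")
  } else NULL
  list(fits = fits, lrt = lrt_tbl)
}
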