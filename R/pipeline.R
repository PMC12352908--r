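#' Run the full synthetic-data analysis pipeline
#'
#' End-to-end reproducible run over the package's two arms:
#'
#' 1. editing arm — simulate a CRISPR-Select experiment (FASTQ),
#'    classify reads, and compute the normalized Mut:WT* statistics;
#' 2. cohort arm — simulate a cohort, call mutation status / LOH /
#'    harmonized TMB, fit the locus-restricted mutational-signature
#'    exposures, screen gene pairs for exclusivity and cooccurrence,
#'    and run the survival analyses.
#'
#' Every output is a plain-text table or JSON file and all randomness
#' derives from `seed`, so two runs with the same seed produce
#' byte-identical output trees. A machine-readable manifest of inputs
#' and parameters is written alongside.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param depth Reads per simulated editing sample.
#' @param n_samples Cohort size.
#' @param mut_cisplatin_fitness Planted per-day fitness of Mut-carrying
#'   cells under cisplatin in the editing simulation.
#' @param guide Guide strategy of the simulated design.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(outdir, seed = 1L, depth = 1500L,
                         n_samples = 200L, mut_cisplatin_fitness = 0.8,
                         guide = "exon") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  design <- example_design(guide)
  write_amplicon_design(design, file.path(outdir, "design.yaml"))

  # editing arm
  mix <- default_genotype_mix(design,
                              mut_cisplatin_fitness = mut_cisplatin_fitness)
  sim <- simulate_select_experiment(design, mix, depth = depth, seed = seed,
                                    fastq_dir = file.path(outdir, "fastq"))
  outcomes <- quantify_experiment(sim)
  write_outcome_table(outcomes, file.path(outdir, "outcomes.tsv"))
  sel <- select_analysis(outcomes)
  utils::write.table(sel$per_replicate,
                     file.path(outdir, "select_per_replicate.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sel_json <- list(summary = sel$summary,
                   test = if (!is.null(sel$test)) unclass(sel$test))
  write_json_file(sel_json, file.path(outdir, "select_summary.json"))

  # cohort arm
  cohort <- simulate_cohort(n_samples = n_samples, seed = seed + 1000L)
  write_cohort_tables(cohort, outdir)
  status <- cohort_status_table(cohort)
  utils::write.table(status, file.path(outdir, "cohort_status.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  spectrum <- build_spectrum96(cohort$locus_mutations,
                               cohort$locus_reference)
  S <- synthetic_signature_matrix()
  fit <- fit_signatures_nnls(spectrum, S)
  utils::write.table(data.frame(channel = names(spectrum),
                                count = as.integer(spectrum)),
                     file.path(outdir, "spectrum96.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_json_file(list(exposures = as.list(fit$exposures),
                       residual_norm = fit$residual_norm),
                  file.path(outdir, "signature_exposures.json"))

  mats <- build_alteration_matrix(cohort$mutations,
                                  genes = rownames(cohort$alteration_truth),
                                  samples = cohort$clinical$sample)
  cooccur <- list()
  for (s in names(mats)) {
    M <- mats[[s]]
    res <- tryCatch(discover_screen(M), error = function(e) NULL)
    fis <- fisher_cooccurrence_screen(M)
    if (!is.null(res)) {
      res$stratum <- s
      cooccur[[s]] <- res
    }
    utils::write.table(fis, file.path(outdir,
                                      paste0("fisher_pairs_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(cooccur))
    utils::write.table(do.call(rbind, cooccur),
                       file.path(outdir, "discover_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  surv <- cohort_survival_analysis(cohort, status)
  utils::write.table(surv$km, file.path(outdir, "km_curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_json_file(surv$json, file.path(outdir, "survival.json"))

  manifest <- list(
    tool = "crisprselect",
    version = as.character(utils::packageVersion("crisprselect")),
    seed = seed,
    parameters = list(depth = depth, n_samples = n_samples,
                      mut_cisplatin_fitness = mut_cisplatin_fitness,
                      guide = guide),
    outputs = sort(setdiff(list.files(outdir, recursive = TRUE),
                           "manifest.json")))
  write_json_file(manifest, file.path(outdir, "manifest.json"))
  invisible(list(select = sel, status = status, exposures = fit,
                 cooccur = cooccur, survival = surv))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the three cohort tables as TSV
#'
#' @param cohort A `cohort_bundle`.
#' @param dir Output directory.
#' @export
write_cohort_tables <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$mutations, file.path(dir, "mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$segments, file.path(dir, "segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(paste0(">", names(cohort$locus_reference)),
               cohort$locus_reference),
             file.path(dir, "locus_reference.fasta"))
  utils::write.table(cohort$locus_mutations,
                     file.path(dir, "locus_mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Per-sample status calls and harmonized TMB for a cohort
#'
#' Applies the helicase-domain status rule, the pathogenicity rule for
#' TP53, the minor-copy-0 LOH rule and platform TMB harmonization to a
#' cohort bundle (or equivalent tables).
#'
#' @param cohort A `cohort_bundle`.
#' @param helicase_intervals Protein-residue intervals for the focal
#'   gene status call.
#' @return data.frame keyed by sample with `ercc2_status`,
#'   `tp53_status`, `loh`, `tmb`, `z`.
#' @export
cohort_status_table <- function(cohort,
                                helicase_intervals = ercc2_helicase_domains()) {
  clin <- cohort$clinical
  mut <- cohort$mutations
  locus <- cohort$truth$locus
  gene_interval <- list(chrom = locus$chrom, start = locus$start,
                        end = locus$end)
  ercc2 <- vapply(clin$sample, function(s)
    classify_ercc2_status(mut[mut$sample == s & mut$gene == locus$gene, ],
                          helicase_intervals), character(1))
  tp53 <- vapply(clin$sample, function(s)
    classify_tp53_status(mut[mut$sample == s & mut$gene == "TP53", ]),
    character(1))
  loh <- vapply(clin$sample, function(s)
    call_loh(gene_interval,
             cohort$segments[cohort$segments$sample == s, ]),
    character(1))
  tmb <- compute_tmb(clin$nonsyn_count, clin$platform)
  rec <- harmonize_tmb(data.frame(sample = clin$sample,
                                  platform = clin$platform,
                                  tmb = tmb$tmb))
  data.frame(sample = clin$sample,
             ercc2_status = unname(ercc2), tp53_status = unname(tp53),
             loh = unname(loh), platform = clin$platform,
             tmb = rec$tmb, tmb_z = rec$z,
             stringsAsFactors = FALSE)
}

#' Survival analyses of a cohort by mutation status
#'
#' Kaplan-Meier curves and log-rank test by focal-gene status, plus the
#' Cox model with focal-gene status, TP53 status and their interaction.
#'
#' @param cohort A `cohort_bundle`.
#' @param status Result of [cohort_status_table()].
#' @return List with `km` (long data.frame of curves), and `json`
#'   (log-rank and Cox summaries).
#' @export
cohort_survival_analysis <- function(cohort, status) {
  clin <- cohort$clinical
  grp <- status$ercc2_status[match(clin$sample, status$sample)]
  lr <- logrank_test(clin$time, clin$event, grp)
  km <- do.call(rbind, lapply(unique(grp), function(g) {
    cv <- km_curve(clin$time[grp == g], clin$event[grp == g])
    cbind(group = g, as.data.frame(cv))
  }))
  X <- cbind(ERCC2 = as.integer(grp == "MUT"),
             TP53 = as.integer(status$tp53_status[match(clin$sample,
                                                        status$sample)] == "MUT"))
  X <- cbind(X, interaction = X[, 1] * X[, 2])
  cox <- tryCatch(cox_ph_fit(clin$time, clin$event, X),
                  error = function(e) NULL)
  json <- list(logrank = unclass(lr),
               cox = if (!is.null(cox))
                 list(coefficients = as.list(cox$coefficients),
                      hazard_ratios = as.list(cox$hazard_ratios),
                      se = as.list(cox$se), p = as.list(cox$p),
                      converged = cox$converged))
  list(km = km, json = json, logrank = lr, cox = cox)
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's functions; see the `exec/`
#' wrapper script. Subcommands: `simulate-select`, `simulate-cohort`,
#' `quantify`, `select-stats`, `cohort`, `cooccur`, `survive`, `all`.
#' Common flags: `--seed <int>`, `--out <dir>`; `quantify` and
#' `select-stats` take `--design <yaml>` plus `--fastq <file>` /
#' `--outcomes <tsv>`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (invisibly): 0 success, 1 missing file,
#'   2 usage error.
#' @export
cs_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: crisprselect <subcommand> [--seed N] [--out DIR] ...",
    "subcommands: simulate-select simulate-cohort quantify select-stats",
    "             cohort cooccur survive all", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  sub <- args[1]
  opts <- parse_cli_options(args[-1])
  seed <- as.integer(opts[["seed"]] %||% 1L)
  out <- opts[["out"]] %||% "crisprselect-out"
  need_file <- function(key) {
    path <- opts[[key]]
    if (is.null(path)) { message("missing --", key); return(NULL) }
    if (!file.exists(path)) { message("file not found: ", path); return(NULL) }
    path
  }
  status <- switch(sub,
    "simulate-select" = {
      design <- example_design()
      mix <- default_genotype_mix(design, mut_cisplatin_fitness = 0.8)
      sim <- simulate_select_experiment(design, mix,
                                        depth = as.integer(opts[["depth"]] %||% 1500L),
                                        seed = seed, fastq_dir = file.path(out, "fastq"))
      write_amplicon_design(design, file.path(out, "design.yaml"))
      utils::write.table(sim$samples, file.path(out, "samples.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      0L
    },
    "simulate-cohort" = {
      cohort <- simulate_cohort(n_samples = as.integer(opts[["n"]] %||% 200L),
                                seed = seed)
      write_cohort_tables(cohort, out)
      0L
    },
    "quantify" = {
      dpath <- need_file("design"); fpath <- need_file("fastq")
      if (is.null(dpath) || is.null(fpath)) return(invisible(1L))
      design <- read_amplicon_design(dpath)
      ot <- quantify_sample(fpath, design)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_outcome_table(ot, file.path(out, "outcomes.tsv"))
      0L
    },
    "select-stats" = {
      opath <- need_file("outcomes")
      if (is.null(opath)) return(invisible(1L))
      ot <- read_outcome_table(opath)
      sel <- select_analysis(ot)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      utils::write.table(sel$per_replicate,
                         file.path(out, "select_per_replicate.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      0L
    },
    "cohort" = , "cooccur" = , "survive" = , "all" = {
      run_pipeline(out, seed = seed,
                   depth = as.integer(opts[["depth"]] %||% 1500L),
                   n_samples = as.integer(opts[["n"]] %||% 200L))
      0L
    },
    { message("unknown subcommand: ", sub, "\n", usage); 2L })
  invisible(status)
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- substring(args[i], 3)
      if (i + 1L <= length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      } else { opts[[key]] <- TRUE; i <- i + 1L }
    } else i <- i + 1L
  }
  opts
}
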