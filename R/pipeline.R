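# Pipeline orchestration: simulate a dataset to disk, run the five
# analyses (overall SCUB, partitioned SCUB, indel-region SCUB,
# methylation signature, allelic-group/sub-genome SCUB) from a config,
# and emit report TSVs plus a JSON summary and run manifest. Every table
# carries the underlying counts next to each ratio and p-value so every
# number is recomputable from the TSV alone.

#' Build an analysis configuration
#'
#' @param recipient_fasta,hybrid_fasta CDS FASTA paths.
#' @param aligned_fasta Optional aligned FASTA of recipient/hybrid pairs
#'   (gap `-`); `NULL` disables the indel-region stage.
#' @param chromosome_map Optional TSV path (`record_id`, `chromosome`);
#'   `NULL` disables the partition stages.
#' @param introgressed Introgressed chromosome set.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed recorded in the manifest.
#' @param alpha Significance threshold used for summary flags.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(recipient_fasta, hybrid_fasta,
                            aligned_fasta = NULL, chromosome_map = NULL,
                            introgressed =
                              default_introgressed_chromosomes(),
                            out_dir = "scub_results", seed = 1L,
                            alpha = 0.05) {
  structure(
    list(
      recipient_fasta = recipient_fasta,
      hybrid_fasta = hybrid_fasta,
      aligned_fasta = aligned_fasta,
      chromosome_map = chromosome_map,
      introgressed = introgressed,
      out_dir = out_dir,
      seed = as.integer(seed),
      alpha = alpha
    ),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from JSON
#' @param path JSON file with the fields of [analysis_config()].
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, x[intersect(
    names(x),
    names(formals(analysis_config))
  )])
}

write_tsv <- function(df, path) {
  write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

chi_or_na <- function(tab) {
  res <- tryCatch(suppressWarnings(chi_square_cross_table(tab)),
    error = function(e) NULL
  )
  if (is.null(res)) {
    return(c(chisq = NA_real_, df = NA_real_, p_value = NA_real_))
  }
  c(chisq = res$statistic, df = res$df, p_value = res$p_value)
}

# 2x4 ending-count table (samples x A/T/C/G) from two codon_counts
ending_cross_table <- function(counts_r, counts_h) {
  er <- total_ending_frequencies(counts_r)
  eh <- total_ending_frequencies(counts_h)
  rbind(recipient = er$n, hybrid = eh$n)
}

ending_row <- function(sample, partition, ef) {
  data.frame(
    sample = sample, partition = partition,
    n_A = ef$n[["A"]], n_T = ef$n[["T"]],
    n_C = ef$n[["C"]], n_G = ef$n[["G"]],
    f_A = ef$f[["A"]], f_T = ef$f[["T"]],
    f_C = ef$f[["C"]], f_G = ef$f[["G"]],
    cg_to_at = cg_to_at_ratio(ef),
    stringsAsFactors = FALSE
  )
}

# per-amino-acid SCUB table for one pair of pools
per_aa_table <- function(counts_r, counts_h, partition = "all") {
  rows <- lapply(sc_amino_acids(), function(aa) {
    cr <- per_aa_ending_counts(counts_r, aa)
    ch <- per_aa_ending_counts(counts_h, aa)
    chi <- chi_or_na(rbind(recipient = cr, hybrid = ch))
    data.frame(
      partition = partition,
      amino_acid = AA_THREE[[aa]],
      n_AT_recipient = cr[["n_AT"]], n_CG_recipient = cr[["n_CG"]],
      ratio_recipient = per_aa_scub_frequency(counts_r, aa),
      n_AT_hybrid = ch[["n_AT"]], n_CG_hybrid = ch[["n_CG"]],
      ratio_hybrid = per_aa_scub_frequency(counts_h, aa),
      chisq = chi[["chisq"]], p_value = chi[["p_value"]],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Simulate a recipient/hybrid dataset to disk
#'
#' Generates an ancestral (recipient) CDS set, mutates it into the
#' derived (hybrid) set, assigns chromosomes, and writes the full bundle:
#' `recipient.fasta`, `hybrid.fasta`, `aligned.fasta` (gap-exact pairs),
#' `chromosome_map.tsv`, `truth.json` and `params.json`.
#'
#' @param out_dir Output directory.
#' @param n_records Number of CDS records.
#' @param lengths Passed to [generate_ancestral_cds()].
#' @param params A [mutation_params()] object (its seed is used for the
#'   mutation stage; `seed` governs generation and chromosome
#'   assignment).
#' @param seed Integer master seed.
#' @param unmapped_frac Fraction of unmapped records.
#' @param introgressed Introgressed chromosome set.
#' @return Invisibly, a list of the written paths.
#' @export
simulate_dataset <- function(out_dir, n_records = 500L, lengths = NULL,
                             params = mutation_params(seed = seed),
                             seed = 1L, unmapped_frac = 0.05,
                             introgressed =
                               default_introgressed_chromosomes()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ancestral <- generate_ancestral_cds(n_records,
    lengths = lengths,
    seed = seed, sample = "recipient"
  )
  sim <- mutate_genome(ancestral, params, sample = "hybrid")
  chrom <- assign_chromosomes(ancestral$id,
    introgressed = introgressed,
    unmapped_frac = unmapped_frac,
    seed = seed + 1L
  )
  paths <- list(
    recipient_fasta = file.path(out_dir, "recipient.fasta"),
    hybrid_fasta = file.path(out_dir, "hybrid.fasta"),
    aligned_fasta = file.path(out_dir, "aligned.fasta"),
    chromosome_map = file.path(out_dir, "chromosome_map.tsv"),
    truth = file.path(out_dir, "truth.json"),
    params = file.path(out_dir, "params.json")
  )
  write_cds_fasta(ancestral, paths$recipient_fasta)
  write_cds_fasta(sim$derived, paths$hybrid_fasta)
  # unique ids per aligned record: <id>|recipient, <id>|hybrid
  alns <- lapply(sim$alignments, function(a) {
    pairwise_alignment(
      paste0(a$id_a, "|recipient"), paste0(a$id_b, "|hybrid"),
      a$aligned_a, a$aligned_b
    )
  })
  write_aligned_fasta(alns, paths$aligned_fasta)
  write_tsv(chrom, paths$chromosome_map)
  jsonlite::write_json(sim$truth, paths$truth,
    auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    c(unclass(params), list(n_records = n_records, seed = seed)),
    paths$params,
    auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Run the full SCUB shift analysis
#'
#' Executes the five report stages from a config and writes TSVs plus
#' `summary.json` and `manifest.json` into the output directory. Stages
#' needing an input that is not configured (alignments, chromosome map)
#' are skipped; the remaining stages run unchanged.
#'
#' @param config An [analysis_config()] (or path to its JSON form).
#' @return Invisibly, a list with the pooled per-sample counts, the stage
#'   tables, and the output paths.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  recipient <- read_cds_fasta(config$recipient_fasta, "recipient")
  hybrid <- read_cds_fasta(config$hybrid_fasta, "hybrid")
  counts_r_by_rec <- cds_codon_counts(recipient)
  counts_h_by_rec <- cds_codon_counts(hybrid)
  counts_r <- pool_codon_counts(counts_r_by_rec)
  counts_h <- pool_codon_counts(counts_h_by_rec)
  tables <- list()

  # --- stage 1: overall SCUB ---
  tables$per_aa <- per_aa_table(counts_r, counts_h)
  ef_r <- total_ending_frequencies(counts_r)
  ef_h <- total_ending_frequencies(counts_h)
  overall_chi <- chi_or_na(ending_cross_table(counts_r, counts_h))
  per_ending <- do.call(rbind, lapply(c("A", "T", "C", "G"), function(b) {
    tab <- rbind(
      recipient = c(ef_r$n[[b]], ef_r$n_sc - ef_r$n[[b]]),
      hybrid = c(ef_h$n[[b]], ef_h$n_sc - ef_h$n[[b]])
    )
    chi <- chi_or_na(tab)
    data.frame(
      ending = b,
      n_recipient = ef_r$n[[b]], n_hybrid = ef_h$n[[b]],
      f_recipient = ef_r$f[[b]], f_hybrid = ef_h$f[[b]],
      chisq = chi[["chisq"]], p_value = chi[["p_value"]],
      stringsAsFactors = FALSE
    )
  }))
  tables$total_endings <- rbind(
    ending_row("recipient", "all", ef_r),
    ending_row("hybrid", "all", ef_h)
  )
  tables$per_ending_tests <- per_ending
  tables$overall_test <- data.frame(
    comparison = "recipient_vs_hybrid_endings_2x4",
    chisq = overall_chi[["chisq"]], df = overall_chi[["df"]],
    p_value = overall_chi[["p_value"]], stringsAsFactors = FALSE
  )

  # --- stages 2 and 5: partitions ---
  if (!is.null(config$chromosome_map)) {
    assignments <- load_chromosome_map(config$chromosome_map,
      introgressed = config$introgressed
    )
    tables$partition_endings <- partition_stage(
      counts_r_by_rec, counts_h_by_rec, assignments,
      schemes = list(
        introgression_stage = c("all", "mapped", "introgression"),
        allelic_group = "allelic_group",
        subgenome = "subgenome"
      )
    )
    cons <- partition_consistency(
      counts_r_by_rec, counts_h_by_rec, assignments
    )
    tables$partition_consistency <- cons
  }

  # --- stage 3: indel regions ---
  if (!is.null(config$aligned_fasta)) {
    alns <- read_aligned_fasta(config$aligned_fasta)
    tables$indel_regions <- indel_region_stage(alns)
  }

  # --- stage 4: methylation signature ---
  codons_r <- cds_codon_lists(recipient)
  codons_h <- cds_codon_lists(hybrid)
  pairs_r <- boundary_pair_counts(codons_r)
  pairs_h <- boundary_pair_counts(codons_h)
  tables$methylation <- methylation_ratio_table(
    counts_r, counts_h, pairs_r, pairs_h
  )
  tables$ag_pairs <- ag_pair_stage(counts_r, counts_h)

  # --- write bundle ---
  paths <- write_report_bundle(tables, config)
  invisible(list(
    counts_recipient = counts_r, counts_hybrid = counts_h,
    tables = tables, paths = paths
  ))
}

partition_stage <- function(counts_r_by_rec, counts_h_by_rec, assignments,
                            schemes) {
  rows <- list()
  add_scheme <- function(scheme_names) {
    for (scheme in scheme_names) {
      pr <- partition_counts(counts_r_by_rec, assignments, scheme)
      ph <- partition_counts(counts_h_by_rec, assignments, scheme)
      for (lab in names(pr)) {
        if (pr[[lab]]$n_sc == 0L || ph[[lab]]$n_sc == 0L) next
        chi <- chi_or_na(ending_cross_table(pr[[lab]], ph[[lab]]))
        er <- total_ending_frequencies(pr[[lab]])
        eh <- total_ending_frequencies(ph[[lab]])
        rows[[length(rows) + 1L]] <<- cbind(
          scheme = scheme,
          rbind(
            ending_row("recipient", lab, er),
            ending_row("hybrid", lab, eh)
          ),
          chisq_between_samples = chi[["chisq"]],
          p_between_samples = chi[["p_value"]]
        )
      }
    }
  }
  for (s in schemes) add_scheme(s)
  do.call(rbind, rows)
}

# cross-partition consistency (Fig 2-style): per-amino-acid ratios across
# the four partition pools, summarised per sample by CV (per amino acid)
# and Cronbach's alpha (partitions as items, amino acids as cases)
partition_consistency <- function(counts_r_by_rec, counts_h_by_rec,
                                  assignments) {
  pools_for <- function(counts_by_rec) {
    c(
      partition_counts(counts_by_rec, assignments, "all"),
      partition_counts(counts_by_rec, assignments, "mapped")["mapped"],
      partition_counts(counts_by_rec, assignments, "introgression")
    )
  }
  rows <- list()
  for (sample in c("recipient", "hybrid")) {
    pools <- pools_for(
      if (sample == "recipient") counts_r_by_rec else counts_h_by_rec
    )
    pools <- Filter(function(p) p$n_sc > 0L, pools)
    if (length(pools) < 2L) next
    ratio_mat <- vapply(
      sc_amino_acids(),
      function(aa)

        vapply(pools, per_aa_scub_frequency, numeric(1), aa = aa),
      numeric(length(pools))
    )
    # ratio_mat: partitions (items) x amino acids (cases)
    cv_by_aa <- apply(ratio_mat, 2L, function(v) {
      if (anyNA(v)) NA_real_ else coefficient_of_variation(v)
    })
    complete <- !apply(ratio_mat, 2L, anyNA)
    alpha <- if (sum(complete) >= 2L) {
      cronbach_alpha(ratio_mat[, complete, drop = FALSE])
    } else {
      NA_real_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample = sample,
      n_partitions = length(pools),
      cv_min = min(cv_by_aa, na.rm = TRUE),
      cv_max = max(cv_by_aa, na.rm = TRUE),
      cronbach_alpha = alpha,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

indel_region_stage <- function(alns) {
  pool <- list(
    a = list(whole = list(), flank5 = list(), flank3 = list(), remote = list()),
    b = list(whole = list(), flank5 = list(), flank3 = list(), remote = list())
  )
  for (aln in alns) {
    rg <- alignment_region_codons(aln)
    for (side in c("a", "b")) {
      for (region in c("whole", "flank5", "flank3", "remote")) {
        pool[[side]][[region]][[length(pool[[side]][[region]]) + 1L]] <-
          rg[[side]][[region]]
      }
    }
  }
  samples <- c(a = "recipient", b = "hybrid")
  rows <- list()
  scub <- list()
  for (side in c("a", "b")) {
    scub[[side]] <- suppressWarnings(regional_scub(pool[[side]]))
    for (region in names(scub[[side]])) {
      ef <- scub[[side]][[region]]
      if (!inherits(ef, "ending_frequencies")) next
      rows[[length(rows) + 1L]] <- ending_row(samples[[side]], region, ef)
    }
  }
  tab <- do.call(rbind, rows)
  # within-sample flank-vs-remote and 5'-vs-3' chi-square
  tests <- list()
  for (side in c("a", "b")) {
    s <- scub[[side]]
    pairs <- list(
      c("two_sides", "remote"), c("flank5", "remote"),
      c("flank3", "remote"), c("flank5", "flank3")
    )
    for (pr in pairs) {
      e1 <- s[[pr[1]]]
      e2 <- s[[pr[2]]]
      if (!inherits(e1, "ending_frequencies") ||
        !inherits(e2, "ending_frequencies")) {
        next
      }
      chi <- chi_or_na(rbind(e1$n, e2$n))
      tests[[length(tests) + 1L]] <- data.frame(
        sample = samples[[side]],
        comparison = paste(pr, collapse = "_vs_"),
        chisq = chi[["chisq"]], p_value = chi[["p_value"]],
        stringsAsFactors = FALSE
      )
    }
  }
  list(endings = tab, tests = do.call(rbind, tests))
}

ag_pair_stage <- function(counts_r, counts_h) {
  rows <- lapply(ag_pair_amino_acids(), function(aa) {
    cr <- per_aa_ag_pair_counts(counts_r, aa)
    ch <- per_aa_ag_pair_counts(counts_h, aa)
    chi <- chi_or_na(rbind(recipient = cr, hybrid = ch))
    data.frame(
      amino_acid = AA_THREE[[aa]],
      n_A_recipient = cr[["n_A"]], n_G_recipient = cr[["n_G"]],
      ratio_recipient = per_aa_ag_pair_ratio(counts_r, aa),
      n_A_hybrid = ch[["n_A"]], n_G_hybrid = ch[["n_G"]],
      ratio_hybrid = per_aa_ag_pair_ratio(counts_h, aa),
      cross_sample = cross_sample_ratio(
        per_aa_ag_pair_ratio(counts_h, aa),
        per_aa_ag_pair_ratio(counts_r, aa)
      ),
      chisq = chi[["chisq"]], p_value = chi[["p_value"]],
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  # NCA/NCG-pair amino acids (second base C) vs the other seven, on
  # cross-sample ratios; n = 4 vs 7 is tiny and reported as-is
  nc_group <- c("Ala", "Pro", "Ser", "Thr")
  xs <- tab$cross_sample[tab$amino_acid %in% nc_group]
  ys <- tab$cross_sample[!tab$amino_acid %in% nc_group]
  tt <- if (sum(!is.na(xs)) >= 2L && sum(!is.na(ys)) >= 2L) {
    two_sample_t_test(xs, ys)
  } else {
    list(t = NA_real_, df = NA_real_, p_value = NA_real_)
  }
  list(
    table = tab,
    t_test = data.frame(
      comparison = "NC-pair(Ala,Pro,Ser,Thr)_vs_others_cross_sample",
      n_x = sum(!is.na(xs)), n_y = sum(!is.na(ys)),
      t = tt$t, df = tt$df, p_value = tt$p_value,
      stringsAsFactors = FALSE
    )
  )
}

write_report_bundle <- function(tables, config) {
  out <- config$out_dir
  paths <- list()
  put <- function(df, name) {
    p <- file.path(out, paste0(name, ".tsv"))
    write_tsv(df, p)
    paths[[name]] <<- p
  }
  put(tables$per_aa, "scub_per_amino_acid")
  put(tables$total_endings, "scub_total_endings")
  put(tables$per_ending_tests, "scub_per_ending_tests")
  put(tables$overall_test, "scub_overall_test")
  if (!is.null(tables$partition_endings)) {
    put(tables$partition_endings, "partition_endings")
  }
  if (!is.null(tables$partition_consistency)) {
    put(tables$partition_consistency, "partition_consistency")
  }
  if (!is.null(tables$indel_regions)) {
    put(tables$indel_regions$endings, "indel_region_endings")
    put(tables$indel_regions$tests, "indel_region_tests")
  }
  put(tables$methylation, "methylation_ratios")
  put(tables$ag_pairs$table, "ag_pair_ratios")
  put(tables$ag_pairs$t_test, "ag_pair_t_test")

  # summary flags at the configured alpha
  summary <- list(
    alpha = config$alpha,
    n_tests = list(
      per_amino_acid = nrow(tables$per_aa),
      per_ending = nrow(tables$per_ending_tests),
      methylation = nrow(tables$methylation),
      ag_pairs = nrow(tables$ag_pairs$table)
    ),
    overall_p = tables$overall_test$p_value,
    methylation_significant = tables$methylation$ratio[
      !is.na(tables$methylation$p_value) &
        tables$methylation$p_value < config$alpha
    ]
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  paths$summary <- file.path(out, "summary.json")

  # manifest: versions, seed, config echo + hash
  cfg_path <- file.path(out, "config.json")
  jsonlite::write_json(unclass(config), cfg_path,
    auto_unbox = TRUE,
    digits = NA, null = "null"
  )
  manifest <- list(
    package = "scubshift",
    package_version = as.character(packageVersion("scubshift")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  paths$config <- cfg_path
  paths$manifest <- file.path(out, "manifest.json")
  paths
}
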