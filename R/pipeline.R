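#' @title End-to-end pipeline orchestration
#' @name pipeline
#' @description Run the analysis stages (synthetic data generation,
#'   Table-1-style descriptive statistics, simulation batches, rejection
#'   ABC, Mantel test, NMDS) from a single configuration, with derived
#'   per-stage seeds and a machine-readable provenance file in every output
#'   directory.
NULL

#' Default run configuration
#'
#' The `"full"` profile reproduces the study configuration (5,000,000
#' simulations, tolerance 0.001, full sample sizes); the `"desk"` profile is
#' a laptop-scale setting (20,000 simulations, tolerance 0.01, sample sizes
#' scaled by 0.1) used throughout the tests.
#'
#' @param profile `"desk"` or `"full"`.
#' @param out_dir output directory.
#' @param seed master seed; stage seeds are derived from it.
#' @return Named list of configuration values.
#' @export
default_config <- function(profile = c("desk", "full"), out_dir = "results",
                           seed = 1L) {
  profile <- match.arg(profile)
  desk <- profile == "desk"
  list(
    profile = profile,
    out_dir = out_dir,
    seed = as.integer(seed),
    scale = if (desk) 0.1 else 1,
    n_sims = if (desk) 20000L else 5000000L,
    tolerance = if (desk) 0.01 else 0.001,
    seq_length = 240L,
    window = c(16023L, 16262L),
    n_null_sims = if (desk) 1000L else 10000L,
    n_perm_fst = if (desk) 1000L else 10000L,
    n_perm_mantel = 9999L,
    fst_estimator = "phi_st",
    prior = default_prior(),
    truth = list(N_D = 100, P = 0.7, M_E = 0.002, M_L = 1e-4))
}

#' Load a run configuration from a JSON file
#'
#' Values present in the file override the profile defaults.
#'
#' @param path JSON file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config(profile = if (!is.null(user$profile)) user$profile
                                   else "desk",
                         out_dir = if (!is.null(user$out_dir)) user$out_dir
                                   else "results",
                         seed = if (!is.null(user$seed)) user$seed else 1L)
  utils::modifyList(base, user)
}

.write_provenance <- function(dir, config, stage, extra = list()) {
  cfg <- config
  cfg$prior <- NULL
  prov <- c(list(stage = stage,
                 package = "cattleabc",
                 version = as.character(utils::packageVersion("cattleabc")),
                 config = cfg),
            extra)
  jsonlite::write_json(prov, file.path(dir, paste0("provenance_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run pipeline stages
#'
#' Stages: `"synth"` (write a pseudo-observed dataset), `"stats"`
#' (Table-1-style per-group diversity report and pairwise F-ST matrices),
#' `"simulate"` + `"abc"` (simulation table, rejection, posterior summary),
#' `"mantel"`, `"mds"`. Each stage writes TSV/JSON outputs plus a
#' provenance file into `config$out_dir` and returns its results
#' invisibly-by-name in the result list.
#'
#' @param config [default_config()] list (or a path accepted by
#'   [read_config()]).
#' @param stages character vector of stages, in order.
#' @return Named list of stage results.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("synth", "stats", "simulate", "abc",
                                    "mantel", "mds")) {
  if (is.character(config)) config <- read_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  tpl <- study_template(scale = config$scale,
                        seq_length = config$seq_length)

  if ("synth" %in% stages) {
    res$synth <- generate_pseudo_observed(
      config$truth, tpl, seed = derive_seed(config$seed, 11L),
      dir = file.path(config$out_dir, "synth"))
    .write_provenance(file.path(config$out_dir, "synth"), config, "synth",
                      list(seed_used = derive_seed(config$seed, 11L)))
  }

  obs <- res$synth
  if (is.null(obs)) {
    fa <- file.path(config$out_dir, "synth", "sequences.fasta")
    tsv <- file.path(config$out_dir, "synth", "metadata.tsv")
    if (!file.exists(fa))
      stop("no synth output found; run the 'synth' stage first or point ",
           "config$out_dir at an existing run")
    recs <- read_fasta(fa, anchor_start = config$window[1])
    md <- read_metadata(tsv)
    obs <- list(aln = extract_window(recs, config$window[1], config$window[2]),
                metadata = md)
  }
  md <- obs$metadata
  aln <- obs$aln

  if ("stats" %in% stages) {
    res$stats <- diversity_report(aln, md,
                                  n_null_sims = config$n_null_sims,
                                  seed = derive_seed(config$seed, 21L))
    write.table(res$stats, file.path(config$out_dir, "table1_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    anc_md <- md[md$epoch == "ancient", ]
    anc_aln <- aligned_seqs(aln$seqs[names(aln$seqs) %in% anc_md$sample_id],
                            aln$window)
    anc <- split_groups(anc_aln, anc_md, "region_group")
    anc <- anc[vapply(anc, length, integer(1)) >= 2]
    res$fst <- fst_matrix(anc, estimator = config$fst_estimator,
                          n_perm = config$n_perm_fst,
                          seed = derive_seed(config$seed, 22L))
    write.table(res$fst$fst, file.path(config$out_dir, "fst_matrix.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    write.table(res$fst$p, file.path(config$out_dir, "fst_pvalues.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    .write_provenance(config$out_dir, config, "stats")
  }

  if ("simulate" %in% stages || "abc" %in% stages) {
    scheme <- scheme_from_metadata(md)
    res$table <- run_simulation_batch(
      config$n_sims, scheme, mutation_model(seq_length = config$seq_length),
      prior = config$prior, seed = derive_seed(config$seed, 31L))
    write.table(res$table, file.path(config$out_dir, "simulation_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    .write_provenance(config$out_dir, config, "simulate",
                      list(seed_used = derive_seed(config$seed, 31L)))
  }

  if ("abc" %in% stages) {
    groups <- split_groups(aln, md, "abc_group")
    observed <- abc_stat_vector(groups)
    res$posterior <- rejection(observed, res$table,
                               tolerance = config$tolerance)
    res$posterior_summary <- posterior_summary(
      res$posterior, config$prior,
      n_perm = config$n_perm_fst, seed = derive_seed(config$seed, 32L))
    write.table(res$posterior$accepted,
                file.path(config$out_dir, "accepted.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    s <- res$posterior_summary
    jsonlite::write_json(
      list(modes = s$modes, hpd50 = s$hpd50, hpd95 = s$hpd95,
           joint_mode_ND_P = s$joint_mode_ND_P,
           correlation_r = s$correlation$r["N_D", "P"],
           correlation_p = s$correlation$p["N_D", "P"],
           tolerance = config$tolerance, n_sims = config$n_sims,
           statistics = stat_vector_names()),
      file.path(config$out_dir, "posterior_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .write_provenance(config$out_dir, config, "abc")
  }

  if ("mantel" %in% stages || "mds" %in% stages) {
    anc_md <- md[md$epoch == "ancient", ]
    anc_aln <- aligned_seqs(aln$seqs[names(aln$seqs) %in% anc_md$sample_id],
                            aln$window)
    anc <- split_groups(anc_aln, anc_md, "region_group")
    anc <- anc[vapply(anc, length, integer(1)) >= 2]
    anc_md <- anc_md[anc_md$region_group %in% names(anc), ]
    fst <- fst_matrix(anc, estimator = config$fst_estimator, n_perm = 0L,
                      seed = derive_seed(config$seed, 41L))
    gen_d <- reynolds_distance(fst$fst)
    if ("mantel" %in% stages) {
      geo <- geo_distance_matrix(anc_md, "region_group")
      geo <- geo[rownames(gen_d), rownames(gen_d)]
      ut <- upper.tri(gen_d)
      if (sd(gen_d[ut]) == 0) {
        message("genetic distance matrix is constant; Mantel test skipped")
        res$mantel <- list(r = NA_real_, p = NA_real_, r2 = NA_real_,
                           n_perm = config$n_perm_mantel)
      } else {
        res$mantel <- mantel_test(gen_d, geo, n_perm = config$n_perm_mantel,
                                  seed = derive_seed(config$seed, 42L))
      }
      jsonlite::write_json(res$mantel,
                           file.path(config$out_dir, "mantel.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    if ("mds" %in% stages) {
      res$mds <- nmds_embed(gen_d, seed = derive_seed(config$seed, 43L))
      pts <- data.frame(group = rownames(res$mds$points),
                        x = res$mds$points[, 1], y = res$mds$points[, 2])
      write.table(pts, file.path(config$out_dir, "mds_coordinates.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    .write_provenance(config$out_dir, config, "spatial")
  }

  invisible(res)
}

#' Table-1-style diversity report
#'
#' One row per group: sample size, haplotype count, haplotype diversity
#' (+/- sd), mean pairwise differences (+/- sd), Tajima's D and Fu's Fs with
#' simulation p-values. Undefined neutrality statistics (monomorphic groups)
#' are reported as NA, mirroring the "-" convention of summary tables.
#'
#' @param aln [aligned_seqs()] of all samples.
#' @param md validated metadata.
#' @param by grouping column.
#' @param n_null_sims null coalescent replicates for the p-values.
#' @param seed RNG seed.
#' @param min_n groups smaller than this are skipped.
#' @return data.frame report.
#' @export
diversity_report <- function(aln, md, by = "region_group",
                             n_null_sims = 10000L, seed = 1L, min_n = 2L) {
  groups <- split_groups(aln, md, by)
  groups <- groups[vapply(groups, length, integer(1)) >= min_n]
  rows <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    hap <- call_haplotypes(g)
    hd <- haplotype_diversity(hap$haplotypes$n)
    mp <- mean_pairwise_differences(g)
    td <- tajimas_d(g, n_null_sims, seed = derive_seed(seed, 2L * i))
    fs <- fus_fs(g, n_null_sims, seed = derive_seed(seed, 2L * i + 1L))
    data.frame(group = names(groups)[i], n = length(g),
               n_haplotypes = nrow(hap$haplotypes),
               H = hd$H, H_sd = hd$sd, pi = mp$pi, pi_sd = mp$sd,
               tajima_D = td$D, tajima_p = td$p,
               fu_Fs = fs$Fs, fu_p = fs$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
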