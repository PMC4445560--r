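#' @title Synthetic pseudo-observed datasets
#' @name synthetic_data
#' @description Generate model-simulated datasets with the statistical
#'   structure of the study design — 13 ancient spatiotemporal groups
#'   (Iran/Syria and Western Anatolia in the NE deme; Southeastern Europe,
#'   Southeastern Central Europe, Italy, Southern France, Spain and
#'   Central/Western Europe in the EU deme) plus modern Near Eastern and
#'   European samples — so every pipeline stage is testable without any
#'   external sequence download. Sequences are purely model-generated; no
#'   attempt is made to mimic real haplogroup motifs.
NULL

#' Study design template
#'
#' The default reproduces the study's sampling design: 24 ancient Near
#' Eastern/Anatolian, 169 ancient European, 100 modern Near Eastern and 497
#' modern European samples (790 in total), with the thirteen ancient groups
#' at their period bounds (years BCE) and coarse per-region coordinate
#' boxes. Ancient sampling ages are later drawn uniformly within each
#' group's period bounds.
#'
#' @param scale multiplier on group sizes; scaled sizes are floored at 2.
#' @param seq_length alignment length (240 default, 399 for the
#'   ancient-only window).
#' @return data.frame of class `study_template` (one row per group):
#'   `region_group, deme, epoch, n, age_bce_lo, age_bce_hi, lat_lo, lat_hi,
#'   lon_lo, lon_hi`.
#' @export
study_template <- function(scale = 1, seq_length = 240L) {
  g <- function(label, deme, epoch, n, lo, hi, lat, lon)
    data.frame(region_group = label, deme = deme, epoch = epoch, n = n,
               age_bce_lo = lo, age_bce_hi = hi,
               lat_lo = lat[1], lat_hi = lat[2],
               lon_lo = lon[1], lon_hi = lon[2], stringsAsFactors = FALSE)
  tpl <- rbind(
    g("IR 7,000-5,000 BCE",    "NE", "ancient", 10, 7000, 5000, c(32, 36), c(44, 52)),
    g("IR/S 4,000-1,400 BCE",  "NE", "ancient",  6, 4000, 1400, c(32, 36), c(38, 48)),
    g("WA 6,400-5,700 BCE",    "NE", "ancient",  8, 6400, 5700, c(37, 40), c(26, 31)),
    g("SEE 6,200-5,500 BCE",   "EU", "ancient", 34, 6200, 5500, c(40, 45), c(20, 28)),
    g("SEE 5,500-5,000 BCE",   "EU", "ancient", 21, 5500, 5000, c(40, 45), c(20, 28)),
    g("SEE 5,000-4,000 BCE",   "EU", "ancient",  8, 5000, 4000, c(40, 45), c(20, 28)),
    g("SEE 2,700-2,200 BCE",   "EU", "ancient",  7, 2700, 2200, c(40, 45), c(20, 28)),
    g("SECE 5,100-4,000 BCE",  "EU", "ancient", 20, 5100, 4000, c(45, 49), c(15, 20)),
    g("IT 6,000-5,500 BCE",    "EU", "ancient",  5, 6000, 5500, c(40, 45), c( 8, 15)),
    g("SF 5,500-4,500 BCE",    "EU", "ancient",  8, 5500, 4500, c(43, 45), c( 1,  6)),
    g("SP 2,700-1,600 BCE",    "EU", "ancient", 12, 2700, 1600, c(36, 42), c(-6,  0)),
    g("CWE 5,400-4,400 BCE",   "EU", "ancient", 26, 5400, 4400, c(47, 52), c( 2, 12)),
    g("CWE 4,400-2,500 BCE",   "EU", "ancient", 28, 4400, 2500, c(47, 52), c( 2, 12)),
    g("Near East (modern)",    "NE", "modern", 100,    0,    0, c(31, 40), c(28, 48)),
    g("Europe (modern)",       "EU", "modern", 497,    0,    0, c(36, 55), c(-8, 25)))
  tpl$n <- pmax(2L, as.integer(round(tpl$n * scale)))
  attr(tpl, "seq_length") <- as.integer(seq_length)
  class(tpl) <- c("study_template", "data.frame")
  tpl
}

# per-sample metadata drawn from a template: ages uniform within period
# bounds, sites uniform within the region box
.template_metadata <- function(template, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(template)), function(i) {
    tp <- template[i, ]
    n <- tp$n
    if (tp$epoch == "ancient") {
      age <- round(runif(n, tp$age_bce_hi, tp$age_bce_lo))
    } else {
      age <- rep(0, n)
    }
    data.frame(
      site = sprintf("site_%02d_%d", i, seq_len(n)),
      lat = round(runif(n, tp$lat_lo, tp$lat_hi), 3),
      lon = round(runif(n, tp$lon_lo, tp$lon_hi), 3),
      region_group = tp$region_group,
      age_bce_lo = age, age_bce_hi = age,
      epoch = tp$epoch,
      deme = tp$deme,
      stringsAsFactors = FALSE)
  })
  md <- do.call(rbind, rows)
  md <- cbind(sample_id = sprintf("syn%04d", seq_len(nrow(md))), md)
  md
}

#' Sampling scheme implied by a metadata table
#'
#' Converts per-sample point ages (midpoint rule) to generations BP and
#' pairs them with the deme implied by the group mapping.
#'
#' @param md validated metadata (with `abc_group`).
#' @param generation_time years per generation.
#' @param rule age rule, see [sample_ages_bce()].
#' @return [sampling_scheme()] with `group = abc_group` and an `id` column.
#' @export
scheme_from_metadata <- function(md, generation_time = 6,
                                 rule = "midpoint") {
  t_gen <- bce_to_generations(sample_ages_bce(md, rule), generation_time)
  deme <- sub("(ancient|modern)_", "", md$abc_group)
  sc <- sampling_scheme(deme, t_gen, group = md$abc_group)
  sc$id <- md$sample_id
  sc
}

#' Generate a pseudo-observed dataset
#'
#' Simulates sequences under the two-deme model at known parameters with
#' the template's sampling design, and writes them in exactly the schema the
#' input readers expect: a FASTA file, a metadata TSV, and a sidecar JSON
#' with the truth parameters and seed (kept separate so the analysis never
#' sees the answer).
#'
#' @param params named `N_D, P, M_E, M_L`.
#' @param template [study_template()].
#' @param seed integer seed (same seed, byte-identical files).
#' @param dir output directory (created); `NULL` returns objects only.
#' @param model_constants overrides for [demographic_model()].
#' @param metadata optional pre-built metadata table; when given, the
#'   sampling design (ages, sites) is taken from it instead of being drawn,
#'   so repeated datasets share one observed design (as the reference
#'   simulation table must).
#' @return List `aln` ([aligned_seqs()]), `metadata`, `scheme`, `truth`,
#'   and file `paths` when `dir` is given.
#' @export
generate_pseudo_observed <- function(params, template = study_template(),
                                     seed = 1L, dir = NULL,
                                     model_constants = list(),
                                     metadata = NULL) {
  md <- if (is.null(metadata)) {
    .template_metadata(template, seed = derive_seed(seed, 1L))
  } else metadata
  md <- validate_metadata(md)
  scheme <- scheme_from_metadata(md)
  L <- attr(template, "seq_length")
  mut <- mutation_model(seq_length = L)
  groups <- simulate_dataset(as.list(params), scheme, mut,
                             seed = derive_seed(seed, 2L),
                             model_constants = model_constants)
  seqs <- unlist(unname(lapply(groups, function(g) g$seqs)))
  seqs <- seqs[md$sample_id]
  aln <- aligned_seqs(seqs, c(16023L, 16023L + L - 1L))
  out <- list(aln = aln, metadata = md, scheme = scheme,
              truth = list(params = as.list(params), seed = seed,
                           seq_length = L))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "sequences.fasta")
    tsv <- file.path(dir, "metadata.tsv")
    truth <- file.path(dir, "truth.json")
    recs <- mapply(seq_record, md$sample_id, seqs,
                   MoreArgs = list(anchor_start = 16023L), SIMPLIFY = FALSE)
    write_fasta(recs, fa)
    write.table(md[, c(.META_COLS)], tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(out$truth, truth, auto_unbox = TRUE, digits = NA)
    out$paths <- list(fasta = fa, metadata = tsv, truth = truth)
  }
  out
}

#' Deterministic toy fixtures
#'
#' Small hand-specified alignments used across the test suite and examples:
#' a monomorphic 8-sequence group (the Southern-France-like case), the
#' 4-sequence 2-site alignment `AA/AT/TT/TT`, and a two-deme alignment with
#' groups fixed for haplotypes one substitution apart.
#'
#' @return Named list of [aligned_seqs()]: `monomorphic`, `tajima_toy`,
#'   `fst_toy_a`, `fst_toy_b`.
#' @export
make_toy_fixtures <- function() {
  base <- paste(rep("ACGT", 60), collapse = "")  # 240 bp
  mono <- setNames(rep(base, 8), paste0("sf", 1:8))
  taj <- setNames(c("AA", "AT", "TT", "TT"), paste0("t", 1:4))
  alt <- base
  substr(alt, 1, 1) <- "T"
  list(
    monomorphic = aligned_seqs(mono, c(16023L, 16262L)),
    tajima_toy = aligned_seqs(taj, c(1L, 2L)),
    fst_toy_a = aligned_seqs(setNames(rep(base, 4), paste0("a", 1:4)),
                             c(16023L, 16262L)),
    fst_toy_b = aligned_seqs(setNames(rep(alt, 4), paste0("b", 1:4)),
                             c(16023L, 16262L)))
}
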