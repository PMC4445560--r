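#' @title Serial-coalescent simulator for the two-deme domestication model
#' @name coalescent_sim
#' @description Backwards-in-time haploid (mtDNA, female-line) coalescent
#'   with heterochronous samples in two demes: a Near Eastern/Anatolian deme
#'   (NE) that passes through a domestication bottleneck of size `N_D` at
#'   1,750 generations BP and then grows exponentially to its modern size,
#'   and a European deme (EU) founded at 1,400 generations BP by a
#'   proportion `P` of the NE population, growing exponentially to its
#'   modern size. Symmetric migration at rate `M_E` from the split until
#'   5,000 BCE and `M_L` afterwards. Exponential-size epochs are integrated
#'   by closed-form time rescaling.
NULL

#' Construct the demographic model
#'
#' Fixed constants default to the study values; `N_D`, `P`, `M_E`, `M_L`
#' are the four free parameters.
#'
#' @param N_D domestication bottleneck female effective size.
#' @param P proportion of the NE deme founding Europe at the split.
#' @param M_E,M_L symmetric per-lineage per-generation migration rates in
#'   the early (split to 5,000 BCE) and late (5,000 BCE to present) epochs.
#' @param N_anc ancestral wild aurochs female effective size.
#' @param N_NE_modern,N_E_modern modern female effective sizes of the NE and
#'   EU demes.
#' @param T_dom,T_split domestication and European-split times (generations
#'   BP).
#' @param T_mig_change migration-rate change time; the default keeps
#'   5,000 BCE / 6 years exact (7000/6 generations).
#' @param generation_time years per generation.
#' @param size_scale_NE,size_scale_E multipliers on the modern sizes for
#'   sensitivity analyses.
#' @return A `demographic_model` list.
#' @export
demographic_model <- function(N_D = 100, P = 0.5, M_E = 0, M_L = 0,
                              N_anc = 45000, N_NE_modern = 1007170,
                              N_E_modern = 7942392,
                              T_dom = 1750, T_split = 1400,
                              T_mig_change = 7000 / 6,
                              generation_time = 6,
                              size_scale_NE = 1, size_scale_E = 1) {
  m <- list(N_D = N_D, P = P, M_E = M_E, M_L = M_L, N_anc = N_anc,
            N_NE_modern = N_NE_modern * size_scale_NE,
            N_E_modern = N_E_modern * size_scale_E,
            T_dom = T_dom, T_split = T_split, T_mig_change = T_mig_change,
            generation_time = generation_time)
  with(m, {
    if (any(c(N_D, N_anc, N_NE_modern, N_E_modern) <= 0))
      stop("population sizes must be > 0")
    if (P < 0 || P > 1) stop("P must lie in [0, 1]")
    if (!(T_dom > T_split && T_split > T_mig_change && T_mig_change > 0))
      stop("need T_dom > T_split > T_mig_change > 0")
    if (M_E < 0 || M_L < 0) stop("migration rates must be >= 0")
  })
  structure(m, class = "demographic_model")
}

#' Construct the mutation model
#'
#' The control-region mutation rate is fixed at 45% per site per million
#' years; at 6 years/generation this is `0.45e-6 * 6 = 2.7e-6` per site per
#' generation.
#'
#' @param rate_per_site_per_myr substitution rate (proportion per Myr).
#' @param seq_length number of sites.
#' @param generation_time years per generation.
#' @return A `mutation_model` list with the derived per-generation rate.
#' @export
mutation_model <- function(rate_per_site_per_myr = 0.45, seq_length = 240L,
                           generation_time = 6) {
  if (rate_per_site_per_myr < 0) stop("rate must be >= 0")
  if (seq_length < 1) stop("seq_length must be >= 1")
  structure(list(
    rate_per_site_per_myr = rate_per_site_per_myr,
    seq_length = as.integer(seq_length),
    mu_site_gen = rate_per_site_per_myr * 1e-6 * generation_time),
    class = "mutation_model")
}

#' Construct a sampling scheme
#'
#' @param deme character vector in `c("NE", "EU")`, one entry per sample (or
#'   per block when `n` is given).
#' @param time sampling times in generations BP.
#' @param n optional block sizes; entries are expanded.
#' @param group optional group labels carried through to the output.
#' @return data.frame `deme, time, group`, one row per sample.
#' @export
sampling_scheme <- function(deme, time, n = NULL, group = NULL) {
  if (!is.null(n)) {
    deme <- rep(deme, n)
    time <- rep(time, n)
    if (!is.null(group)) group <- rep(group, n)
  }
  if (is.null(group)) group <- deme
  stopifnot(length(deme) == length(time), all(deme %in% c("NE", "EU")),
            all(time >= 0), length(deme) >= 1)
  data.frame(deme = deme, time = time, group = group,
             stringsAsFactors = FALSE)
}

#' Deme size at a time in the past
#'
#' @param model [demographic_model()].
#' @param deme `"NE"` or `"EU"`.
#' @param t generations BP.
#' @return Female effective size at `t` (vectorised over `t`).
#' @export
deme_size_at <- function(model, deme, t) {
  stopifnot(all(t >= 0))
  if (deme == "NE") {
    r <- log(model$N_NE_modern / model$N_D) / model$T_dom
    ifelse(t >= model$T_dom, model$N_anc, model$N_NE_modern * exp(-r * t))
  } else if (deme == "EU") {
    if (any(t >= model$T_split))
      stop("EU deme does not exist at t >= T_split")
    if (model$P <= 0) stop("P = 0: empty European founder population")
    rne <- log(model$N_NE_modern / model$N_D) / model$T_dom
    N_E0 <- model$P * model$N_NE_modern * exp(-rne * model$T_split)
    r <- log(model$N_E_modern / N_E0) / model$T_split
    model$N_E_modern * exp(-r * t)
  } else stop("deme must be 'NE' or 'EU'")
}

#' Migration rate at a time in the past
#'
#' `M_L` on `[0, T_mig_change)`, `M_E` on `[T_mig_change, T_split)`, 0 at or
#' beyond the split (a single deme remains). Symmetric between demes.
#'
#' @param model [demographic_model()].
#' @param t generations BP (vectorised).
#' @return Per-lineage per-generation migration rate.
#' @export
migration_rate_at <- function(model, t) {
  stopifnot(all(t >= 0))
  ifelse(t < model$T_mig_change, model$M_L,
         ifelse(t < model$T_split, model$M_E, 0))
}

.check_scheme <- function(model, scheme) {
  if (any(scheme$deme == "EU" & scheme$time >= model$T_split))
    stop("EU samples must be younger than the split time")
  if (any(scheme$deme == "EU") && model$P <= 0)
    stop("P = 0 with EU samples: empty founder population")
}

#' Simulate a genealogy under the two-deme serial coalescent
#'
#' @param model [demographic_model()].
#' @param scheme [sampling_scheme()].
#' @param seed integer RNG seed (the simulator uses its own RNG stream; the
#'   result is a deterministic function of the seed).
#' @return A `genealogy` list: `parent`, `time` (generations BP, node order:
#'   tips in scheme order then internal nodes by coalescence time),
#'   `total_branch_length`, `tmrca`, `n_tips`, `scheme`.
#' @export
simulate_genealogy <- function(model, scheme, seed = 1L) {
  .check_scheme(model, scheme)
  g <- .sim_serial_cpp(as.numeric(scheme$time),
                       as.integer(scheme$deme == "EU"),
                       model$N_anc, model$N_NE_modern, model$N_E_modern,
                       model$N_D, model$P, model$M_E, model$M_L,
                       model$T_dom, model$T_split, model$T_mig_change,
                       as.integer(seed))
  g$scheme <- scheme
  class(g) <- "genealogy"
  g
}

#' Drop mutations on a genealogy (finite sites)
#'
#' Mutations arise as a Poisson process along each branch at rate
#' `mu_site_gen * seq_length` per generation; each hit selects a uniform
#' site and substitutes a uniformly chosen different base. The root sequence
#' is uniform random.
#'
#' @param g [simulate_genealogy()] result.
#' @param mut [mutation_model()].
#' @param seed integer RNG seed.
#' @return [aligned_seqs()] with sequences in the scheme's sample order,
#'   names `s1..sn` (or the scheme's row names).
#' @export
add_mutations <- function(g, mut, seed = 1L) {
  m <- .mutate_tree_cpp(g$parent, g$time, g$n_tips,
                        mut$seq_length, mut$mu_site_gen, as.integer(seed))
  seqs <- apply(m, 1, function(row) paste(c("A", "C", "G", "T")[row + 1],
                                          collapse = ""))
  names(seqs) <- if (!is.null(g$scheme$id)) g$scheme$id
                 else paste0("s", seq_len(g$n_tips))
  aligned_seqs(seqs, c(1L, mut$seq_length))
}

#' Simulate a grouped sequence dataset
#'
#' Composition of [simulate_genealogy()] and [add_mutations()]; a
#' deterministic function of `seed`.
#'
#' @param params named list/vector with `N_D, P, M_E, M_L`.
#' @param scheme [sampling_scheme()].
#' @param mut [mutation_model()].
#' @param seed integer seed.
#' @param model_constants optional list of overrides passed to
#'   [demographic_model()] (e.g. `size_scale_NE`).
#' @return Named list of [aligned_seqs()], one per `scheme$group` level.
#' @export
simulate_dataset <- function(params, scheme, mut = mutation_model(),
                             seed = 1L, model_constants = list()) {
  model <- do.call(demographic_model,
                   c(list(N_D = params[["N_D"]], P = params[["P"]],
                          M_E = params[["M_E"]], M_L = params[["M_L"]]),
                     model_constants))
  g <- simulate_genealogy(model, scheme, seed = seed)
  aln <- add_mutations(g, mut, seed = derive_seed(seed, 999983L))
  lapply(split(seq_len(nrow(scheme)), scheme$group), function(i)
    aligned_seqs(aln$seqs[i], aln$window))
}

# internal fast path: encoded matrix + genealogy, no string conversion
.simulate_ints <- function(params, scheme, mut, seed, model_constants = list()) {
  model <- do.call(demographic_model,
                   c(list(N_D = params[["N_D"]], P = params[["P"]],
                          M_E = params[["M_E"]], M_L = params[["M_L"]]),
                     model_constants))
  .check_scheme(model, scheme)
  g <- .sim_serial_cpp(as.numeric(scheme$time),
                       as.integer(scheme$deme == "EU"),
                       model$N_anc, model$N_NE_modern, model$N_E_modern,
                       model$N_D, model$P, model$M_E, model$M_L,
                       model$T_dom, model$T_split, model$T_mig_change,
                       as.integer(seed))
  .mutate_tree_cpp(g$parent, g$time, g$n_tips, mut$seq_length,
                   mut$mu_site_gen, as.integer(derive_seed(seed, 999983L)))
}
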