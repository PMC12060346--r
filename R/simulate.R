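# Synthetic-data module: negative-binomial count simulation of (i) the
# four-group focal sea-bass experiment and (ii) the ten-species ovary/testis
# panel, with known planted truth, so every downstream stage is testable
# without sequencing data.

#' Configure the synthetic-data generator
#'
#' Defaults emulate the study conditions of the focal experiment: ~300
#' annotated miRNAs, replicate structure FCT:3, FHT:3, MCT:4, MHT:4 (six
#' ovaries, eight testes), per-library mean depths asymmetric between
#' tissues (ovary 6.7e5, testis 1.03e6 reads, i.e. the reported per-library
#' means scaled down tenfold to keep simulations fast at identical relative
#' structure), a shared NB dispersion of 0.2 (variance = mu + alpha mu^2),
#' and baseline expression drawn log-normally
#' (log2 relative abundance ~ Normal(5, 2)) then normalized to a miRNome
#' composition, so baselines are true CPM summing to 1e6 and the configured
#' library sizes are realized in the column sums. The ten-species panel
#' shares 60% of seeds across all species (core) and assigns the rest to
#' exactly one species (private).
#'
#' @param n_mirnas number of simulated miRNAs.
#' @param replicates named integer vector of replicates per focal group
#'   (names FCT, FHT, MCT, MHT; each >= 2).
#' @param mean_library_size named numeric vector `c(ovary=, testis=)` of mean
#'   sequencing depths.
#' @param nb_dispersion NB dispersion alpha in variance = mu + alpha mu^2.
#' @param baseline_log2_mean,baseline_log2_sd parameters of the log2-CPM
#'   baseline distribution.
#' @param n_species number of panel species (prefix of [FISH_SPECIES]).
#' @param core_seed_fraction fraction of miRNAs present in every species;
#'   the remainder are private to exactly one species.
#' @param panel_replicates replicates per species and tissue in the panel.
#' @param library_cv coefficient of variation of the log-normal library-size
#'   draw.
#' @param species_log2_sd sd of a per-species log2 baseline wiggle in the
#'   panel (biological divergence between species).
#' @param planted_sex_biased data.frame with columns `id`, `direction`
#'   ("female" or "male"), `effect` (|log2| magnitude > 0) and `species`
#'   (comma-separated species codes the bias is planted in), or NULL.
#' @param planted_heat_de data.frame with columns `id`, `contrast`
#'   ("MHTvsMCT" or "FHTvsFCT") and `effect` (signed log2 applied to the
#'   heated group), or NULL.
#' @param rng_seed integer seed; all draws are deterministic functions of it.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_mirnas = 300L,
                              replicates = c(FCT = 3L, FHT = 3L,
                                             MCT = 4L, MHT = 4L),
                              mean_library_size = c(ovary = 6.7e5,
                                                    testis = 1.03e6),
                              nb_dispersion = 0.2,
                              baseline_log2_mean = 5,
                              baseline_log2_sd = 2,
                              n_species = 10L,
                              core_seed_fraction = 0.6,
                              panel_replicates = 3L,
                              library_cv = 0.2,
                              species_log2_sd = 0.25,
                              planted_sex_biased = NULL,
                              planted_heat_de = NULL,
                              rng_seed = 1L) {
  stopifnot(n_mirnas >= 1, nb_dispersion >= 0,
            core_seed_fraction >= 0, core_seed_fraction <= 1,
            n_species >= 2, n_species <= length(FISH_SPECIES),
            panel_replicates >= 2, library_cv > 0)
  if (!setequal(names(replicates), FOCAL_GROUPS) || any(replicates < 2)) {
    stop("replicates must name all of FCT, FHT, MCT, MHT with counts >= 2")
  }
  if (!all(c("ovary", "testis") %in% names(mean_library_size))) {
    stop("mean_library_size must name ovary and testis")
  }
  if (!is.null(planted_sex_biased)) {
    stopifnot(all(c("id", "direction", "effect", "species") %in%
                    names(planted_sex_biased)))
    if (!all(planted_sex_biased$direction %in% c("female", "male"))) {
      stop("planted sex-bias direction must be 'female' or 'male'")
    }
    if (any(!is.finite(planted_sex_biased$effect)) ||
        any(planted_sex_biased$effect <= 0)) {
      stop("planted sex-bias effects must be finite and > 0")
    }
    sp <- unlist(strsplit(planted_sex_biased$species, ",", fixed = TRUE))
    unknown <- setdiff(trimws(sp), FISH_SPECIES[seq_len(n_species)])
    if (length(unknown)) {
      stop("unknown species code in planted sex bias: ",
           paste(unknown, collapse = ", "))
    }
  }
  if (!is.null(planted_heat_de)) {
    stopifnot(all(c("id", "contrast", "effect") %in% names(planted_heat_de)))
    if (!all(planted_heat_de$contrast %in% c("MHTvsMCT", "FHTvsFCT"))) {
      stop("planted heat contrast must be 'MHTvsMCT' or 'FHTvsFCT'")
    }
    if (any(!is.finite(planted_heat_de$effect))) {
      stop("planted heat effects must be finite")
    }
  }
  structure(
    list(n_mirnas = as.integer(n_mirnas),
         replicates = replicates[FOCAL_GROUPS],
         mean_library_size = mean_library_size,
         nb_dispersion = nb_dispersion,
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd,
         n_species = as.integer(n_species),
         core_seed_fraction = core_seed_fraction,
         panel_replicates = as.integer(panel_replicates),
         library_cv = library_cv,
         species_log2_sd = species_log2_sd,
         planted_sex_biased = planted_sex_biased,
         planted_heat_de = planted_heat_de,
         rng_seed = as.integer(rng_seed)),
    class = "simulation_config")
}

# One RNG stream per stage, seeded from rng_seed by fixed offsets, so adding
# a stage never perturbs earlier draws.
stream_seed <- function(config, offset) {
  set.seed(config$rng_seed + offset)
}

random_rna <- function(n, length = 22L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), length, replace = TRUE),
          collapse = "")
  }, character(1L))
}

# Shared miRNA catalogue: names, sequences (unique seeds), baseline CPM and
# the core/private species assignment. Drawn from a fixed stream so the
# focal experiment and the species panel agree on identities.
mirna_catalog <- function(config) {
  stream_seed(config, 11L)
  n <- config$n_mirnas
  ids <- sprintf("mir-sim-%d", seq_len(n))
  seqs <- random_rna(n)
  while (anyDuplicated(extract_seed(seqs))) {
    dup <- duplicated(extract_seed(seqs))
    seqs[dup] <- random_rna(sum(dup))
  }
  # relative expression draw, normalized to a miRNome composition so that
  # baselines are true CPM (sum 1e6) and configured library sizes realize
  base_rel <- 2^stats::rnorm(n, config$baseline_log2_mean,
                             config$baseline_log2_sd)
  base_cpm <- base_rel / sum(base_rel) * 1e6
  species <- FISH_SPECIES[seq_len(config$n_species)]
  n_core <- round(config$core_seed_fraction * n)
  core <- rep(FALSE, n)
  if (n_core > 0) core[seq_len(n_core)] <- TRUE
  private_of <- rep(NA_character_, n)
  if (n_core < n) {
    private_of[(n_core + 1L):n] <-
      species[((seq_len(n - n_core) - 1L) %% length(species)) + 1L]
  }
  list(ids = ids, seqs = seqs, seeds = extract_seed(seqs),
       base_cpm = base_cpm, core = core, private_of = private_of,
       species = species)
}

check_planted_ids <- function(planted, ids, what) {
  if (is.null(planted)) return(invisible(NULL))
  unknown <- setdiff(planted$id, ids)
  if (length(unknown)) {
    stop(sprintf("planted %s id(s) not among the simulated miRNAs: %s",
                 what, paste(unknown, collapse = ", ")))
  }
}

draw_library_sizes <- function(mean_size, cv, n) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean_size) - sdlog^2 / 2, sdlog = sdlog)
}

draw_counts <- function(mu, alpha) {
  k <- matrix(0L, nrow = nrow(mu), ncol = ncol(mu), dimnames = dimnames(mu))
  if (alpha <= 0) {
    k[] <- stats::rpois(length(mu), lambda = mu)
  } else {
    k[] <- stats::rnbinom(length(mu), size = 1 / alpha, mu = mu)
  }
  k
}

#' Simulate the four-group focal heat experiment
#'
#' Counts are drawn NB(mean = baseline CPM x library size / 1e6 x 2^planted
#' effects, dispersion alpha). Sex-bias effects planted for the focal species
#' are applied symmetrically (half up in the biased tissue, half down in the
#' other) so total abundance is roughly conserved; heat effects are applied
#' in full to the heated group of the stated contrast.
#'
#' @param config a [simulation_config()].
#' @return list with elements `counts` ([mir_counts]), `samples` (sample
#'   sheet data.frame), `annotation` (focal-species annotation data.frame)
#'   and `truth` (planted effects and baselines).
#' @export
simulate_focal_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cat_ <- mirna_catalog(config)
  check_planted_ids(config$planted_sex_biased, cat_$ids, "sex-bias")
  check_planted_ids(config$planted_heat_de, cat_$ids, "heat")

  reps <- config$replicates
  samples <- do.call(rbind, lapply(FOCAL_GROUPS, function(g) {
    data.frame(sample_id = sprintf("%s_%d", g, seq_len(reps[[g]])),
               species = "dla", tissue = GROUP_TISSUE[[g]], group = g,
               replicate = seq_len(reps[[g]]), stringsAsFactors = FALSE)
  }))
  rownames(samples) <- NULL

  stream_seed(config, 21L)
  lib <- numeric(nrow(samples))
  for (tis in c("ovary", "testis")) {
    idx <- samples$tissue == tis
    lib[idx] <- draw_library_sizes(config$mean_library_size[[tis]],
                                   config$library_cv, sum(idx))
  }

  eff <- matrix(0, nrow = config$n_mirnas, ncol = nrow(samples),
                dimnames = list(cat_$ids, samples$sample_id))
  psb <- config$planted_sex_biased
  if (!is.null(psb)) {
    for (i in seq_len(nrow(psb))) {
      in_focal <- "dla" %in% trimws(strsplit(psb$species[i], ",")[[1L]])
      if (!in_focal) next
      b <- psb$effect[i]
      ovary <- samples$tissue == "ovary"
      if (psb$direction[i] == "female") {
        eff[psb$id[i], ovary] <- eff[psb$id[i], ovary] + b / 2
        eff[psb$id[i], !ovary] <- eff[psb$id[i], !ovary] - b / 2
      } else {
        eff[psb$id[i], ovary] <- eff[psb$id[i], ovary] - b / 2
        eff[psb$id[i], !ovary] <- eff[psb$id[i], !ovary] + b / 2
      }
    }
  }
  phd <- config$planted_heat_de
  if (!is.null(phd)) {
    for (i in seq_len(nrow(phd))) {
      heated <- if (phd$contrast[i] == "MHTvsMCT") "MHT" else "FHT"
      idx <- samples$group == heated
      eff[phd$id[i], idx] <- eff[phd$id[i], idx] + phd$effect[i]
    }
  }

  mu <- outer(cat_$base_cpm / 1e6, lib) * 2^eff
  dimnames(mu) <- list(cat_$ids, samples$sample_id)
  stream_seed(config, 22L)
  counts <- draw_counts(mu, config$nb_dispersion)

  annotation <- data.frame(name = cat_$ids, species = "dla",
                           mature_seq = cat_$seqs, seed = cat_$seeds,
                           family = NA_character_, stringsAsFactors = FALSE)
  truth <- list(sex_biased = config$planted_sex_biased,
                heat_de = config$planted_heat_de,
                baseline = data.frame(id = cat_$ids,
                                      base_cpm = cat_$base_cpm,
                                      stringsAsFactors = FALSE),
                expected_mean = mu)
  list(counts = mir_counts(counts), samples = samples,
       annotation = annotation, truth = truth)
}

#' Simulate the ten-species ovary/testis panel
#'
#' Core miRNAs are present in every species, private miRNAs in exactly one.
#' Planted sex-bias effects carry the stated |log2| in exactly the stated
#' species subset (female bias: ovary up by effect/2, testis down by
#' effect/2, so the planted log2 testis/ovary ratio equals -effect; male
#' bias is the mirror image). A mild per-species log-normal baseline wiggle
#' emulates biological divergence.
#'
#' @param config a [simulation_config()].
#' @return list with elements `counts` (nested list species -> tissue ->
#'   [mir_counts]), `profiles` (named list of [species_profile], mean CPM
#'   over replicates, names `species_tissue`), `annotation` (one row per
#'   species x present miRNA) and `truth` (planted effects plus per-species
#'   expressed id/seed sets).
#' @export
simulate_species_panel <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cat_ <- mirna_catalog(config)
  check_planted_ids(config$planted_sex_biased, cat_$ids, "sex-bias")
  species <- cat_$species

  stream_seed(config, 31L)
  wiggle <- matrix(stats::rnorm(length(species) * config$n_mirnas,
                                0, config$species_log2_sd),
                   nrow = length(species),
                   dimnames = list(species, cat_$ids))

  psb <- config$planted_sex_biased
  planted_in <- function(id, sp) {
    if (is.null(psb)) return(0)
    hit <- psb$id == id &
      vapply(strsplit(psb$species, ","), function(x) sp %in% trimws(x),
             logical(1L))
    if (!any(hit)) return(0)
    i <- which(hit)[1L]
    if (psb$direction[i] == "female") -psb$effect[i] else psb$effect[i]
  }

  counts <- list()
  profiles <- list()
  annotation <- list()
  stream_seed(config, 32L)
  lib_draws <- list()
  for (sp in species) for (tis in c("ovary", "testis")) {
    lib_draws[[paste(sp, tis, sep = "_")]] <-
      draw_library_sizes(config$mean_library_size[[tis]], config$library_cv,
                         config$panel_replicates)
  }

  stream_seed(config, 33L)
  for (sp in species) {
    present <- cat_$core | (!is.na(cat_$private_of) & cat_$private_of == sp)
    ids <- cat_$ids[present]
    base <- cat_$base_cpm[present] * 2^wiggle[sp, present]
    base <- base / sum(base) * 1e6  # each species' miRNome is a composition
    counts[[sp]] <- list()
    for (tis in c("ovary", "testis")) {
      # signed log2(T/O) planted per id; tissue receives +/- half of it
      ratio <- vapply(ids, planted_in, numeric(1L), sp = sp)
      tis_eff <- if (tis == "testis") ratio / 2 else -ratio / 2
      lib <- lib_draws[[paste(sp, tis, sep = "_")]]
      mu <- outer(base * 2^tis_eff / 1e6, lib)
      dimnames(mu) <- list(ids, sprintf("%s_%s_%d", sp, tis,
                                        seq_len(config$panel_replicates)))
      k <- draw_counts(mu, config$nb_dispersion)
      counts[[sp]][[tis]] <- mir_counts(k)
      mean_cpm <- rowMeans(cpm(counts[[sp]][[tis]]))
      profiles[[paste(sp, tis, sep = "_")]] <-
        species_profile(sp, tis, mean_cpm)
    }
    annotation[[sp]] <- data.frame(name = ids, species = sp,
                                   mature_seq = cat_$seqs[present],
                                   seed = cat_$seeds[present],
                                   family = NA_character_,
                                   stringsAsFactors = FALSE)
  }
  annotation <- do.call(rbind, annotation)
  rownames(annotation) <- NULL

  expressed <- lapply(species, function(sp) {
    pr <- profiles[c(paste(sp, "ovary", sep = "_"),
                     paste(sp, "testis", sep = "_"))]
    ids <- unique(unlist(lapply(pr, function(p) {
      names(p$values)[p$values >= 1]
    })))
    list(ids = ids,
         seeds = unique(cat_$seeds[match(ids, cat_$ids)]))
  })
  names(expressed) <- species

  truth <- list(sex_biased = psb,
                heat_de = config$planted_heat_de,
                baseline = data.frame(id = cat_$ids,
                                      base_cpm = cat_$base_cpm,
                                      stringsAsFactors = FALSE),
                expressed = expressed)
  list(counts = counts, profiles = profiles, annotation = annotation,
       truth = truth)
}

#' Write a simulated experiment to a directory of TSVs
#'
#' Emits `counts.tsv`, `samples.tsv`, `annotation.tsv` and truth manifests
#' (`truth_sex_biased.tsv`, `truth_heat_de.tsv`, `truth_baseline.tsv`) in the
#' core TSV dialect.
#'
#' @param sim result of [simulate_focal_experiment()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_count_matrix(sim$counts, file.path(dir, "counts.tsv"))
  write_sample_sheet(sim$samples, file.path(dir, "samples.tsv"))
  write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  if (!is.null(sim$truth$sex_biased)) {
    write_tsv_strict(sim$truth$sex_biased,
                     file.path(dir, "truth_sex_biased.tsv"))
  }
  if (!is.null(sim$truth$heat_de)) {
    write_tsv_strict(sim$truth$heat_de, file.path(dir, "truth_heat_de.tsv"))
  }
  write_tsv_strict(sim$truth$baseline, file.path(dir, "truth_baseline.tsv"))
  invisible(dir)
}
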