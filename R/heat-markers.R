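# Heat-recorder calling: the four focal contrasts, intersection of DEM sets
# with the conserved sex-bias markers, and concordance labelling.

COMPARISONS <- list(`1` = c(B = "MHT", A = "MCT"),
                    `2` = c(B = "FHT", A = "FCT"),
                    `3` = c(B = "MCT", A = "FCT"),
                    `4` = c(B = "MHT", A = "FHT"))

#' Run the four sex/temperature contrasts of the focal design
#'
#' Comparisons: 1 = MHT vs MCT, 2 = FHT vs FCT, 3 = MCT vs FCT,
#' 4 = MHT vs FHT. Fold changes are signed first-named group over second.
#' Each DEM set holds the miRNAs significant under the configured cutoffs.
#'
#' @param x a [mir_counts] object of the full 14-sample (or analogous)
#'   experiment.
#' @param samples sample sheet data.frame with all four groups.
#' @param config a [pipeline_config()].
#' @return list with `de` (named list of full [nb_wald_de()] tables per
#'   comparison id) and `dem` (named list of data.frames `mirna`, `log2fc`
#'   restricted to significant miRNAs).
#' @export
run_comparisons <- function(x, samples, config = pipeline_config()) {
  missing_grp <- setdiff(FOCAL_GROUPS, samples$group)
  if (length(missing_grp)) {
    stop("sample sheet is missing group(s): ",
         paste(missing_grp, collapse = ", "))
  }
  ids_of <- function(g) samples$sample_id[!is.na(samples$group) &
                                            samples$group == g]
  de <- lapply(COMPARISONS, function(cmp) {
    nb_wald_de(x, group_a = ids_of(cmp[["A"]]), group_b = ids_of(cmp[["B"]]),
               config = config)
  })
  dem <- lapply(de, function(d) {
    d[d$significant, c("mirna", "log2fc"), drop = FALSE]
  })
  list(de = de, dem = dem)
}

normalize_dem_map <- function(dem) {
  lapply(dem, function(d) {
    if (is.data.frame(d)) {
      stopifnot("mirna" %in% names(d))
      if (!"log2fc" %in% names(d)) d$log2fc <- NA_real_
      d[c("mirna", "log2fc")]
    } else {
      data.frame(mirna = as.character(d), log2fc = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
}

#' Annotate conserved markers with the contrasts they are DE in
#'
#' For each called marker, records the subset of the four comparisons in
#' which it is a DEM, with the focal signed log2 fold changes. Markers with
#' a non-empty DEM set are the "informative" markers; the rest are kept with
#' `informative = FALSE` rather than silently discarded.
#'
#' @param markers result of [call_conserved_markers()] (rows with
#'   `call == "none"` are ignored).
#' @param dem named list (names among "1".."4") of DEM sets: either
#'   data.frames with columns `mirna` and `log2fc`, or bare character
#'   vectors of miRNA ids (fold-change signs then unknown).
#' @return data.frame of marker records: marker columns plus `dem` (list
#'   column of integer comparison ids), `lfc_1` .. `lfc_4` (signed focal
#'   log2 fold change where DE, else NA) and `informative`.
#' @export
annotate_markers_with_dem <- function(markers, dem) {
  stopifnot(is.data.frame(markers), "call" %in% names(markers))
  dem <- normalize_dem_map(dem)
  bad <- setdiff(names(dem), c("1", "2", "3", "4"))
  if (length(bad)) stop("unknown comparison id(s): ", paste(bad, collapse = ", "))
  rec <- markers[markers$call != "none", , drop = FALSE]
  rec$dem <- vector("list", nrow(rec))
  for (k in c("1", "2", "3", "4")) {
    rec[[paste0("lfc_", k)]] <- rep(NA_real_, nrow(rec))
  }
  for (i in seq_len(nrow(rec))) {
    hits <- integer(0)
    for (k in names(dem)) {
      j <- match(rec$id[i], dem[[k]]$mirna)
      if (!is.na(j)) {
        hits <- c(hits, as.integer(k))
        rec[[paste0("lfc_", k)]][i] <- dem[[k]]$log2fc[j]
      }
    }
    rec$dem[[i]] <- sort(hits)
  }
  rec$informative <- lengths(rec$dem) > 0L
  rownames(rec) <- NULL
  rec
}

#' Flag heat-recorder markers and label concordance
#'
#' A heat-recorder is an informative marker that is a DEM in a within-sex
#' heat contrast (comparison 1, heated vs control testis, or 2, heated vs
#' control ovary). The concordance label compares the heat response with the
#' marker's conserved signature: a positive heat log2 fold change
#' strengthens the marker's own signal in the heated gonad
#' (`marker_sex_concordant`, e.g. an ovary-biased marker rising in heated
#' testis); a negative one suppresses it (`marker_sex_discordant`, e.g. a
#' testis-biased marker falling in heated testis). When both heat contrasts
#' flag a marker, comparison 1 supplies the sign.
#'
#' @param records result of [annotate_markers_with_dem()].
#' @return `records` with added logical `heat_recorder` and character
#'   `concordance` (`NA` for non-recorders) columns.
#' @export
call_heat_recorders <- function(records) {
  stopifnot(is.data.frame(records), "dem" %in% names(records))
  records$heat_recorder <- vapply(records$dem, function(d) {
    any(d %in% c(1L, 2L))
  }, logical(1L))
  records$concordance <- rep(NA_character_, nrow(records))
  for (i in which(records$heat_recorder)) {
    k <- if (1L %in% records$dem[[i]]) "1" else "2"
    f <- records[[paste0("lfc_", k)]][i]
    if (is.na(f)) {
      stop(sprintf("marker '%s' is flagged in comparison %s but carries no fold-change sign",
                   records$id[i], k))
    }
    records$concordance[i] <- if (f > 0) "marker_sex_concordant"
                              else "marker_sex_discordant"
  }
  records
}

#' Run the full synthetic pipeline end to end
#'
#' Simulates the focal experiment and the species panel, runs the four
#' contrasts, builds the cross-species ratio table, calls conserved markers,
#' annotates them with DEM sets and flags heat-recorders. Stage summaries
#' (counts surviving each filter) are reported via [message()].
#'
#' @param sim_config a [simulation_config()].
#' @param config a [pipeline_config()].
#' @param level identity level for the cross-species work (`"mature"` or
#'   `"seed"`).
#' @return list with elements `focal`, `panel`, `comparisons`,
#'   `ratio_table`, `markers`, `records`.
#' @export
run_pipeline <- function(sim_config = simulation_config(),
                         config = pipeline_config(),
                         level = c("mature", "seed")) {
  level <- match.arg(level)
  focal <- simulate_focal_experiment(sim_config)
  panel <- simulate_species_panel(sim_config)
  message(sprintf("simulated %d miRNAs x %d focal samples; %d panel species",
                  nrow(focal$counts$counts), ncol(focal$counts$counts),
                  sim_config$n_species))
  kept <- filter_low_counts(focal$counts, config$min_reads,
                            config$min_samples_expressed)$kept
  message(sprintf("low-count filter: %d of %d miRNAs kept",
                  length(kept), nrow(focal$counts$counts)))
  comparisons <- run_comparisons(focal$counts, focal$samples, config)
  message(sprintf("DEM per comparison: %s",
                  paste(sprintf("%s=%d", names(comparisons$dem),
                                vapply(comparisons$dem, nrow, integer(1L))),
                        collapse = ", ")))
  ratio_table <- sex_ratio_table(panel$profiles, panel$annotation,
                                 level = level, config = config)
  markers <- call_conserved_markers(ratio_table, config)
  message(sprintf("conserved markers: %d female, %d male of %d ids",
                  sum(markers$call == "female"), sum(markers$call == "male"),
                  nrow(markers)))
  records <- annotate_markers_with_dem(markers, comparisons$dem)
  records <- call_heat_recorders(records)
  message(sprintf("informative markers: %d; heat-recorders: %d",
                  sum(records$informative), sum(records$heat_recorder)))
  list(focal = focal, panel = panel, comparisons = comparisons,
       ratio_table = ratio_table, markers = markers, records = records)
}

#' Write the marker/heat-recorder report to TSV
#'
#' @param records result of [call_heat_recorders()].
#' @param path output path.
#' @export
write_marker_report <- function(records, path) {
  out <- records
  out$dem <- vapply(out$dem, paste, character(1L), collapse = "+")
  out$dem[out$dem == ""] <- NA_character_
  write_tsv_strict(out, path)
}
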