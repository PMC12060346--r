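# Sex-bias classification: per-species log2(testis/ovary) ratios with the
# zero-replacing pseudocount, per-species bias calls, tallies, and the
# conserved-marker rule (biased in >= 5 species, focal species mandatory).

#' Log2 testis/ovary expression ratio with zero replacement
#'
#' The testis mean CPM divided by the ovary mean CPM, log2-transformed.
#' A zero operand (the miRNA not expressed in that tissue) is replaced by
#' the pseudocount (default 1 CPM) to avoid division by zero. When both
#' operands are absent (NA) the ratio is NA: the species contributes no
#' ratio for that id.
#'
#' @param testis_value,ovary_value non-negative mean CPM values (vectors
#'   recycle; NA means the id is absent from that tissue's data).
#' @param pseudocount value substituted for a zero operand (default 1).
#' @return numeric vector of log2 ratios (NA where both operands absent).
#' @export
log2_sex_ratio <- function(testis_value, ovary_value, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  n <- max(length(testis_value), length(ovary_value))
  t_ <- rep_len(as.numeric(testis_value), n)
  o_ <- rep_len(as.numeric(ovary_value), n)
  if (any(t_ < 0, na.rm = TRUE) || any(o_ < 0, na.rm = TRUE)) {
    stop("expression values must be >= 0")
  }
  both_absent <- is.na(t_) & is.na(o_)
  t_[is.na(t_) | t_ == 0] <- pseudocount
  o_[is.na(o_) | o_ == 0] <- pseudocount
  out <- log2(t_ / o_)
  out[both_absent] <- NA_real_
  out
}

#' Classify a species' sex bias from its log2 ratio
#'
#' Female (ovary-biased) if the ratio is at or below minus the threshold,
#' male (testis-biased) if at or above plus the threshold, otherwise none.
#' Boundaries are inclusive.
#'
#' @param ratio numeric vector of log2(testis/ovary) ratios.
#' @param log2_bias_threshold positive threshold (default 1).
#' @return character vector over `{"female", "male", "none"}` (NA in, NA out).
#' @export
classify_species_bias <- function(ratio, log2_bias_threshold = 1) {
  stopifnot(log2_bias_threshold > 0)
  out <- rep(NA_character_, length(ratio))
  ok <- !is.na(ratio)
  if (any(!is.finite(ratio[ok]))) stop("ratios must be finite")
  out[ok] <- ifelse(ratio[ok] <= -log2_bias_threshold, "female",
                    ifelse(ratio[ok] >= log2_bias_threshold, "male", "none"))
  out
}

#' Tally ovary- and testis-biased species
#'
#' `count_O` is the number of species classified female (ratio <= -threshold)
#' and `count_T` the number classified male (ratio >= +threshold).
#'
#' @param ratios numeric vector of per-species log2 ratios (NAs skipped).
#' @param log2_bias_threshold positive threshold (default 1).
#' @return named integer vector `c(count_O = , count_T = )`.
#' @export
tally_bias <- function(ratios, log2_bias_threshold = 1) {
  cls <- classify_species_bias(ratios[!is.na(ratios)], log2_bias_threshold)
  c(count_O = sum(cls == "female"), count_T = sum(cls == "male"))
}

#' Build a per-species log2(testis/ovary) ratio table from panel profiles
#'
#' For every species with both an ovary and a testis profile, computes one
#' ratio per id. An id contributes a ratio for a species only if it appears
#' in that species' annotation (absence from the annotation is not zero
#' expression); an annotated id missing from a tissue's profile counts as
#' zero in that tissue and takes the pseudocount. At `level = "seed"`, mature
#' values are summed by seed within each species and tissue before the ratio.
#'
#' @param profiles named list of [species_profile] objects (as from
#'   [simulate_species_panel()] or [read_profile_dir()]).
#' @param annotation annotation data.frame (`name`, `species`, `seed`); may
#'   be NULL, in which case every profiled id counts as annotated.
#' @param level `"mature"` (ids are mature names) or `"seed"`.
#' @param config a [pipeline_config()] supplying the pseudocount.
#' @return data.frame with column `id` and one numeric column per species
#'   (NA where the species contributes no ratio).
#' @export
sex_ratio_table <- function(profiles, annotation = NULL,
                            level = c("mature", "seed"),
                            config = pipeline_config()) {
  level <- match.arg(level)
  species <- unique(vapply(profiles, function(p) p$species, character(1L)))
  get_values <- function(sp, tis) {
    hit <- Filter(function(p) p$species == sp && p$tissue == tis, profiles)
    if (length(hit) == 0L) return(NULL)
    v <- hit[[1L]]$values
    if (level == "seed") {
      if (is.null(annotation)) stop("seed-level ratios require an annotation")
      ann <- annotation[annotation$species == sp, ]
      seed <- ann$seed[match(names(v), ann$name)]
      v <- v[!is.na(seed)]
      seed <- seed[!is.na(seed)]
      v <- tapply(v, seed, sum)
      v <- stats::setNames(as.numeric(v), names(v))
    }
    v
  }
  ratio_by_species <- list()
  for (sp in species) {
    ov <- get_values(sp, "ovary")
    te <- get_values(sp, "testis")
    if (is.null(ov) || is.null(te)) next
    if (!is.null(annotation)) {
      ann <- annotation[annotation$species == sp, ]
      ids <- if (level == "seed") unique(ann$seed) else unique(ann$name)
    } else {
      ids <- union(names(ov), names(te))
    }
    t_ <- te[ids]
    o_ <- ov[ids]
    t_[is.na(t_)] <- 0
    o_[is.na(o_)] <- 0
    r <- log2_sex_ratio(t_, o_, config$pseudocount)
    ratio_by_species[[sp]] <- stats::setNames(r, ids)
  }
  if (length(ratio_by_species) == 0L) stop("no species with both tissues profiled")
  all_ids <- sort(unique(unlist(lapply(ratio_by_species, names))))
  out <- data.frame(id = all_ids, stringsAsFactors = FALSE)
  for (sp in names(ratio_by_species)) {
    out[[sp]] <- unname(ratio_by_species[[sp]][all_ids])
  }
  out
}

#' Call conserved sex-biased markers
#'
#' Applies the conserved-marker rule to a per-species ratio table: a marker
#' is called female iff at least `min_biased_species` species classify
#' female (log2 ratio <= -threshold) and the focal species itself classifies
#' female; the male call is symmetric. Rows where the focal species has no
#' ratio are never markers. Output is sorted by call (female, then male,
#' then none), then descending `max(count_O, count_T)`, then id, so reports
#' are diffable.
#'
#' @param ratio_table data.frame with column `id` and one numeric column per
#'   species code (as from [sex_ratio_table()]).
#' @param config a [pipeline_config()] supplying `log2_bias_threshold`,
#'   `min_biased_species` and `focal_species`.
#' @return data.frame: `id`, per-species ratio columns, `count_O`,
#'   `count_T`, `call`.
#' @export
call_conserved_markers <- function(ratio_table, config = pipeline_config()) {
  stopifnot(is.data.frame(ratio_table), "id" %in% names(ratio_table))
  sp_cols <- intersect(names(ratio_table), FISH_SPECIES)
  if (length(sp_cols) == 0L) stop("ratio table has no recognised species columns")
  if (!config$focal_species %in% sp_cols) {
    stop(sprintf("focal species '%s' not present in the ratio table",
                 config$focal_species))
  }
  thr <- config$log2_bias_threshold
  rmat <- as.matrix(ratio_table[sp_cols])
  tallies <- t(apply(rmat, 1L, tally_bias, log2_bias_threshold = thr))
  focal_cls <- classify_species_bias(rmat[, config$focal_species], thr)
  call <- rep("none", nrow(ratio_table))
  call[tallies[, "count_O"] >= config$min_biased_species &
         !is.na(focal_cls) & focal_cls == "female"] <- "female"
  call[tallies[, "count_T"] >= config$min_biased_species &
         !is.na(focal_cls) & focal_cls == "male"] <- "male"
  out <- data.frame(id = ratio_table$id, ratio_table[sp_cols],
                    count_O = as.integer(tallies[, "count_O"]),
                    count_T = as.integer(tallies[, "count_T"]),
                    call = call, stringsAsFactors = FALSE,
                    check.names = FALSE)
  ord <- order(match(out$call, c("female", "male", "none")),
               -pmax(out$count_O, out$count_T), out$id, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a marker table to TSV
#'
#' Columns: id, call, one column per species (log2 ratio or "."), count_O,
#' count_T.
#'
#' @param markers result of [call_conserved_markers()].
#' @param path output path.
#' @export
write_markers <- function(markers, path) {
  sp_cols <- intersect(names(markers), FISH_SPECIES)
  write_tsv_strict(markers[c("id", "call", sp_cols, "count_O", "count_T")],
                   path)
}
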