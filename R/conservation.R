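# Cross-species conservation: expressed-seed sets, UpSet-style exclusive
# membership patterns, relative abundance and top-k most-abundant profiles.

#' Expressed ids of a species/tissue profile
#'
#' Ids whose mean CPM is at or above the expression threshold (inclusive;
#' >= 1 CPM counts as expressed at the default).
#'
#' @param profile a [species_profile].
#' @param cpm_expression_threshold inclusive threshold (> 0).
#' @return character vector of expressed ids (possibly empty).
#' @export
expressed_seed_set <- function(profile, cpm_expression_threshold = 1) {
  stopifnot(inherits(profile, "species_profile"),
            cpm_expression_threshold > 0)
  names(profile$values)[profile$values >= cpm_expression_threshold]
}

#' Exclusive membership patterns over species sets (UpSet semantics)
#'
#' Assigns every element of the union to exactly one exclusive membership
#' pattern (which species' sets it belongs to), and reports the core set of
#' elements present in all species. Pattern counts therefore partition the
#' union.
#'
#' @param sets named list (>= 2 entries) of character vectors, one per
#'   species.
#' @return list with `patterns` (data.frame with one 0/1 column per species,
#'   a `count` column and a `members` list column, sorted by descending
#'   count then pattern) and `core` (character vector present in every set).
#' @export
intersection_counts <- function(sets) {
  if (!is.list(sets) || length(sets) == 0L) stop("sets must be a non-empty named list")
  if (length(sets) < 2L) stop("need at least 2 species sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must be uniquely named by species")
  }
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  key <- apply(member, 1L, function(r) paste(as.integer(r), collapse = ""))
  split_members <- split(universe, key)
  pat_keys <- names(split_members)
  pat <- do.call(rbind, lapply(pat_keys, function(k) {
    as.integer(strsplit(k, "")[[1L]])
  }))
  colnames(pat) <- names(sets)
  patterns <- data.frame(pat, check.names = FALSE)
  patterns$count <- lengths(split_members)
  patterns$members <- unname(split_members)
  ord <- order(-patterns$count, pat_keys)
  patterns <- patterns[ord, , drop = FALSE]
  rownames(patterns) <- NULL
  core <- universe[rowSums(member) == length(sets)]
  list(patterns = patterns, core = core)
}

#' Relative abundance of a profile over its whole miRNome
#'
#' Each id's percentage of the summed expression of the tissue's miRNome.
#' Ranked descending; ties broken by lexicographic id order.
#'
#' @param profile a [species_profile] with at least one positive value.
#' @return data.frame with columns `id` and `percent` (summing to 100).
#' @export
relative_abundance <- function(profile) {
  stopifnot(inherits(profile, "species_profile"))
  v <- profile$values
  total <- sum(v)
  if (total <= 0) stop("empty miRNome: all profile values are zero")
  pct <- 100 * v / total
  ord <- order(-pct, names(v), method = "radix")
  data.frame(id = names(v)[ord], percent = unname(pct[ord]),
             stringsAsFactors = FALSE)
}

#' Top-k most abundant ids of a profile
#'
#' @param profile a [species_profile].
#' @param k number of ids to return (>= 1; capped at the profile size).
#' @return data.frame with the `k` largest rows of [relative_abundance()].
#' @export
top_k <- function(profile, k) {
  stopifnot(k >= 1)
  ra <- relative_abundance(profile)
  utils::head(ra, n = min(as.integer(k), nrow(ra)))
}

#' Ids in every species' top-k for one tissue
#'
#' Intersection of the per-species top-k most abundant id sets; all profiles
#' must be of the same tissue.
#'
#' @param profiles list of [species_profile] objects, one per species.
#' @param k top-k size per species.
#' @return character vector of ids shared by every species' top-k.
#' @export
shared_top_set <- function(profiles, k) {
  stopifnot(length(profiles) >= 1)
  tissues <- unique(vapply(profiles, function(p) p$tissue, character(1L)))
  if (length(tissues) != 1L) {
    stop("mismatched tissues across profiles: ",
         paste(tissues, collapse = ", "))
  }
  sets <- lapply(profiles, function(p) top_k(p, k)$id)
  sort(Reduce(intersect, sets))
}

#' Write UpSet membership patterns and the core set to TSV
#'
#' @param ic result of [intersection_counts()].
#' @param patterns_path,core_path output paths.
#' @export
write_intersection <- function(ic, patterns_path, core_path) {
  pat <- ic$patterns
  pat$members <- vapply(pat$members, paste, character(1L), collapse = ",")
  write_tsv_strict(pat, patterns_path)
  write_tsv_strict(data.frame(id = ic$core, stringsAsFactors = FALSE),
                   core_path)
  invisible(NULL)
}
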