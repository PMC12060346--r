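# Readers and writers for the tab-separated formats the pipeline touches.
# Dialect: tab-separated, UTF-8, mandatory header row, "." for missing.

read_tsv_strict <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a miRNA count matrix from TSV
#'
#' Expects a header row whose first column is `mirna`, followed by one
#' numeric column per sample. Cells must be non-negative integers; duplicate
#' miRNA ids are rejected.
#'
#' @param path path to a tab-separated file.
#' @return a [mir_counts] object.
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2L || names(df)[1L] != "mirna") {
    stop("count matrix TSV must start with a 'mirna' column followed by samples")
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicated miRNA id in %s: '%s'",
                 path, ids[duplicated(ids)][1L]))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1L)))[1L]
    stop(sprintf("non-numeric count column '%s'", names(df)[-1L][bad]))
  }
  if (anyNA(m) || any(m < 0) || any(m != round(m))) {
    idx <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid count at row '%s', column '%s' (must be a non-negative integer)",
                 ids[idx[1L]], colnames(m)[idx[2L]]))
  }
  rownames(m) <- ids
  mir_counts(m)
}

#' Write a miRNA count matrix to TSV
#'
#' @param x a [mir_counts] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  m <- as_count_matrix(x)
  df <- data.frame(mirna = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
}

#' Read a sample sheet
#'
#' Columns: `sample_id`, `species`, `tissue` (ovary/testis), `group`
#' (FCT/FHT/MCT/MHT or missing for panel samples) and `replicate`. Group and
#' tissue must agree (F* groups are ovary, M* groups testis).
#'
#' @param path path to a tab-separated file.
#' @return a validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_strict(path)
  required <- c("sample_id", "species", "tissue", "group", "replicate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("sample sheet missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df$species <- as.character(df$species)
  df$tissue <- as.character(df$tissue)
  df$group <- as.character(df$group)
  validate_sample_sheet(df)
  df
}

validate_sample_sheet <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    stop(sprintf("duplicated sample_id '%s'",
                 df$sample_id[duplicated(df$sample_id)][1L]))
  }
  bad <- !df$tissue %in% c("ovary", "testis")
  if (any(bad)) {
    stop(sprintf("unknown tissue '%s' for sample '%s'",
                 df$tissue[bad][1L], df$sample_id[bad][1L]))
  }
  bad <- !is.na(df$group) & !df$group %in% FOCAL_GROUPS
  if (any(bad)) {
    stop(sprintf("unknown group '%s' for sample '%s'",
                 df$group[bad][1L], df$sample_id[bad][1L]))
  }
  has_grp <- !is.na(df$group)
  mism <- has_grp & GROUP_TISSUE[df$group] != df$tissue
  if (any(mism, na.rm = TRUE)) {
    stop(sprintf("group/tissue mismatch for sample '%s' (group %s implies %s)",
                 df$sample_id[mism][1L], df$group[mism][1L],
                 GROUP_TISSUE[df$group[mism][1L]]))
  }
  if (anyNA(df$replicate) || any(df$replicate < 1) ||
      any(df$replicate != round(df$replicate))) {
    stop("replicate must be a positive integer")
  }
  invisible(df)
}

#' Write a sample sheet to TSV
#' @param df a sample-sheet data.frame.
#' @param path output path.
#' @export
write_sample_sheet <- function(df, path) {
  validate_sample_sheet(df)
  write_tsv_strict(df[c("sample_id", "species", "tissue", "group", "replicate")],
                   path)
}

#' Read a mature-miRNA annotation table
#'
#' Columns: `name`, `species`, `mature_seq` and optionally `family`. The
#' 7-mer seed (positions 2-8) is filled in via [extract_seed()].
#'
#' @param path path to a tab-separated file.
#' @return data.frame with columns `name`, `species`, `mature_seq`, `seed`
#'   and `family`.
#' @export
read_annotation <- function(path) {
  df <- read_tsv_strict(path)
  required <- c("name", "species", "mature_seq")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("annotation missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$name <- as.character(df$name)
  df$species <- as.character(df$species)
  df$mature_seq <- toupper(as.character(df$mature_seq))
  n <- nchar(df$mature_seq)
  if (any(n < 16L | n > 28L)) {
    bad <- which(n < 16L | n > 28L)[1L]
    stop(sprintf("mature sequence for '%s' has length %d (expected 16-28 nt)",
                 df$name[bad], n[bad]))
  }
  df$seed <- extract_seed(df$mature_seq)
  if (!"family" %in% names(df)) df$family <- NA_character_
  df[c("name", "species", "mature_seq", "seed", "family")]
}

#' Write a mature-miRNA annotation table
#' @param df annotation data.frame (as from [read_annotation()]).
#' @param path output path.
#' @export
write_annotation <- function(df, path) {
  write_tsv_strict(df[intersect(c("name", "species", "mature_seq", "seed",
                                  "family"), names(df))], path)
}

#' Read mature miRNA sequences from a FASTA file
#'
#' Headers are taken as miRNA names; a leading three-letter species prefix
#' (e.g. `dla-miR-143-3p`) is parsed into the species field when it matches a
#' known panel code.
#'
#' @param path path to an uncompressed FASTA file of mature RNA sequences.
#' @return annotation data.frame as from [read_annotation()].
#' @export
read_annotation_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA annotation requires the Biostrings package")
  }
  seqs <- Biostrings::readBStringSet(path)
  nm <- names(seqs)
  prefix <- substr(nm, 1L, 3L)
  species <- ifelse(prefix %in% FISH_SPECIES & substr(nm, 4L, 4L) == "-",
                    prefix, NA_character_)
  df <- data.frame(name = nm, species = species,
                   mature_seq = toupper(as.character(seqs)),
                   stringsAsFactors = FALSE)
  df$mature_seq <- gsub("T", "U", df$mature_seq, fixed = TRUE)
  df$seed <- extract_seed(df$mature_seq)
  df$family <- NA_character_
  df
}

#' Read/write a species-tissue mean-CPM profile
#'
#' Profile TSVs have columns `id` and `mean_cpm`; the species code and
#' tissue are taken from the file name `<species>_<tissue>.tsv` unless given.
#'
#' @param path path to a profile TSV.
#' @param species,tissue optional overrides for the values parsed from the
#'   file name.
#' @return a [species_profile].
#' @export
read_profile <- function(path, species = NULL, tissue = NULL) {
  df <- read_tsv_strict(path)
  if (!all(c("id", "mean_cpm") %in% names(df))) {
    stop("profile TSV must have columns 'id' and 'mean_cpm'")
  }
  base <- sub("\\.tsv$", "", basename(path))
  parts <- strsplit(base, "_", fixed = TRUE)[[1L]]
  if (is.null(species)) species <- parts[1L]
  if (is.null(tissue)) tissue <- parts[2L]
  v <- df$mean_cpm
  names(v) <- as.character(df$id)
  species_profile(species, tissue, v)
}

#' @rdname read_profile
#' @param profile a [species_profile] to write.
#' @export
write_profile <- function(profile, path) {
  write_tsv_strict(data.frame(id = names(profile$values),
                              mean_cpm = unname(profile$values),
                              stringsAsFactors = FALSE), path)
}

#' Read every `<species>_<tissue>.tsv` profile in a directory
#'
#' @param dir directory of profile TSVs.
#' @param tissue optional tissue filter (`"ovary"` or `"testis"`).
#' @return named list of [species_profile] objects (names `species_tissue`).
#' @export
read_profile_dir <- function(dir, tissue = NULL) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (!length(files)) stop("no profile TSVs found in ", dir)
  profiles <- lapply(files, read_profile)
  names(profiles) <- vapply(profiles, function(p) {
    paste(p$species, p$tissue, sep = "_")
  }, character(1L))
  if (!is.null(tissue)) {
    profiles <- Filter(function(p) p$tissue == tissue, profiles)
  }
  profiles
}

#' The bundled cross-species gonadal marker ratio table
#'
#' A reference dataset of 33 conserved sex-biased gonadal miRNA markers in
#' ten fish species, as published for the heat-treated European sea bass
#' study system: per-species log2(testis/ovary) ratios (focal species `dla`
#' first; remaining printed values are assigned to the other species columns
#' positionally, which affects no computed quantity since only the focal
#' column enters the marker rule), the published sex call, the published DEM
#' column (which of the four sea-bass contrasts each marker was
#' differentially expressed in: 1 = MHT vs MCT, 2 = FHT vs FCT,
#' 3 = MCT vs FCT, 4 = MHT vs FHT) and the published count O / count T
#' tallies. Note that for several rows the published tallies differ by one
#' from a direct count of the published ratios at |log2| >= 1; the table
#' preserves the published values so the discrepancy stays visible.
#'
#' @return data.frame with columns `mirna`, `sex`, one numeric column per
#'   species code (NA where no ratio was published), `dem` (list column of
#'   integer comparison ids, possibly empty) and `count_o`/`count_t`
#'   (published tallies).
#' @export
gonadal_marker_table <- function() {
  path <- system.file("extdata", "gonadal_marker_ratios.tsv",
                      package = "mirheat", mustWork = TRUE)
  df <- read_tsv_strict(path)
  dem <- strsplit(ifelse(is.na(df$dem), "", df$dem), "+", fixed = TRUE)
  df$dem <- lapply(dem, function(x) sort(as.integer(x)))
  for (sp in FISH_SPECIES) df[[sp]] <- as.numeric(df[[sp]])
  df
}
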