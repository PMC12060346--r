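#' mirheat: conserved sex-biased miRNA markers of thermal history in fish gonads
#'
#' Tools for (i) simulating and analysing a four-group (sex x temperature)
#' gonadal small-RNA experiment, (ii) cross-species seed-region conservation
#' over a ten-species ovary/testis panel, (iii) a deterministic
#' log2(testis/ovary) sex-bias marker rule, and (iv) the intersection of both
#' that nominates "heat-recorder" miRNAs.
#'
#' @docType package
#' @name mirheat-package
#' @keywords internal
"_PACKAGE"

#' Three-letter codes of the ten fish species in the gonadal panel
#'
#' `dla` European sea bass (the focal species), `ola` Japanese medaka,
#' `aca` bowfin, `gac` three-spined stickleback, `dre` zebrafish,
#' `loc` spotted gar, `phy` striped catfish, `pfl` European perch,
#' `ame` black bullhead, `upy` eastern mudminnow.
#'
#' @export
FISH_SPECIES <- c("dla", "ola", "aca", "gac", "dre", "loc", "phy", "pfl",
                  "ame", "upy")

#' Experimental groups of the focal sea-bass design
#'
#' Female/male x control/high rearing temperature. Female groups are ovary
#' samples, male groups testis samples.
#'
#' @export
FOCAL_GROUPS <- c("FCT", "FHT", "MCT", "MHT")

GROUP_TISSUE <- c(FCT = "ovary", FHT = "ovary", MCT = "testis", MHT = "testis")

#' Extract the seed region (nucleotides 2-8) of a mature miRNA sequence
#'
#' The seed is the 7-mer at 1-based positions 2-8 of the mature strand, the
#' primary determinant of target recognition and the identity key used for
#' cross-species comparison. DNA-style `T` on input is mapped to `U` with a
#' warning.
#'
#' @param mature_seq character vector of mature RNA sequences over
#'   `{A,C,G,U}` (case-insensitive), each of length >= 8.
#' @return character vector of 7-mer seeds.
#' @examples
#' extract_seed("UGAGGUAGUAGGUUGUAUAGUU")  # "GAGGUAG"
#' @export
extract_seed <- function(mature_seq) {
  if (length(mature_seq) == 0L) return(character(0))
  if (!is.character(mature_seq) || anyNA(mature_seq)) {
    stop("mature_seq must be a character vector without NA")
  }
  s <- toupper(mature_seq)
  if (any(grepl("T", s, fixed = TRUE))) {
    warning("DNA alphabet detected: mapping T to U")
    s <- gsub("T", "U", s, fixed = TRUE)
  }
  bad <- grepl("[^ACGU]", s)
  if (any(bad)) {
    stop(sprintf("invalid alphabet in sequence '%s' (allowed: A, C, G, U)",
                 mature_seq[which(bad)[1L]]))
  }
  short <- nchar(s) < 8L
  if (any(short)) {
    stop(sprintf("sequence too short for seed: '%s' (need >= 8 nt)",
                 mature_seq[which(short)[1L]]))
  }
  substr(s, 2L, 8L)
}

#' Construct a miRNA count matrix object
#'
#' A thin container for a non-negative integer miRNA-by-sample count matrix
#' with per-sample library sizes (column sums), in the spirit of an edgeR
#' `DGEList`.
#'
#' @param counts numeric matrix, miRNAs in rows (rownames required), samples
#'   in columns (colnames required); entries must be non-negative integers.
#' @return an object of class `mir_counts`: a list with elements `counts`
#'   (integer matrix), `mirna_ids`, `sample_ids` and `library_sizes`.
#' @export
mir_counts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have rownames (miRNA ids) and colnames (sample ids)")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicated miRNA ids")
  if (anyDuplicated(colnames(counts))) stop("duplicated sample ids")
  if (anyNA(counts)) stop("counts contain NA")
  if (any(counts < 0)) stop("counts contain negative entries")
  if (any(counts != round(counts))) stop("counts contain non-integer entries")
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts,
         mirna_ids = rownames(counts),
         sample_ids = colnames(counts),
         library_sizes = colSums(counts)),
    class = "mir_counts")
}

#' @export
print.mir_counts <- function(x, ...) {
  cat(sprintf("mir_counts: %d miRNAs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("library sizes:", paste(format(x$library_sizes, big.mark = ","),
                              collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mir_counts <- function(x) dim(x$counts)

as_count_matrix <- function(x) {
  if (inherits(x, "mir_counts")) x$counts
  else if (is.matrix(x)) x
  else stop("expected a mir_counts object or a matrix")
}

#' Construct a species/tissue mean-CPM expression profile
#'
#' @param species three-letter species code (see [FISH_SPECIES]).
#' @param tissue `"ovary"` or `"testis"`.
#' @param values named non-negative numeric vector of mean CPM per miRNA (or
#'   per seed) id.
#' @return an object of class `species_profile`.
#' @export
species_profile <- function(species, tissue, values) {
  tissue <- match.arg(tissue, c("ovary", "testis"))
  if (!is.character(species) || length(species) != 1L || nchar(species) != 3L) {
    stop("species must be a single 3-letter code")
  }
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    stop("values must be uniquely named by miRNA/seed id")
  }
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0)) {
    stop("profile values must be finite and >= 0")
  }
  structure(list(species = species, tissue = tissue, values = values),
            class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("species_profile: %s %s, %d ids, total %.1f CPM\n",
              x$species, x$tissue, length(x$values), sum(x$values)))
  invisible(x)
}

#' Pipeline thresholds and defaults
#'
#' Houses every tunable threshold of the pipeline with its default:
#' the CPM expression threshold (>= 1 CPM counts as expressed), the
#' pseudocount substituted for a zero tissue value before the
#' log2(testis/ovary) ratio (1 CPM), the |log2 ratio| >= 1 bias threshold,
#' the minimum number of biased species for a conserved marker (5 of 10,
#' focal species mandatory), the adjusted-p significance cutoff (0.05)
#' against a null log fold change of 0, and the low-count filter (>= 10
#' reads in >= 10 samples).
#'
#' @param cpm_expression_threshold minimum mean CPM for an id to count as
#'   expressed (inclusive).
#' @param pseudocount CPM value substituted for a zero operand in the sex
#'   ratio.
#' @param log2_bias_threshold |log2 testis/ovary| at or beyond which a
#'   species is called biased.
#' @param min_biased_species minimum species biased in the same direction for
#'   a conserved marker call.
#' @param focal_species species whose bias is mandatory for a marker call.
#' @param adj_p_cutoff BH-adjusted p-value cutoff for significance.
#' @param lfc_null null log2 fold change of the Wald test.
#' @param min_reads,min_samples_expressed low-count filter: keep a miRNA iff
#'   at least `min_samples_expressed` samples have >= `min_reads` counts.
#' @param top_k size of the most-abundant ranking.
#' @param expressed_on `"mean"` (default) or `"any-sample"`: whether the
#'   expression filter applies to the replicate-mean CPM or to any single
#'   sample.
#' @param rng_seed integer seed for any randomised step.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(cpm_expression_threshold = 1,
                            pseudocount = 1,
                            log2_bias_threshold = 1,
                            min_biased_species = 5L,
                            focal_species = "dla",
                            adj_p_cutoff = 0.05,
                            lfc_null = 0,
                            min_reads = 10L,
                            min_samples_expressed = 10L,
                            top_k = 10L,
                            expressed_on = c("mean", "any-sample"),
                            rng_seed = 1L) {
  expressed_on <- match.arg(expressed_on)
  stopifnot(cpm_expression_threshold > 0, pseudocount > 0,
            log2_bias_threshold > 0, min_biased_species >= 1,
            adj_p_cutoff > 0, lfc_null >= 0,
            min_reads >= 0, min_samples_expressed >= 0, top_k >= 1)
  if (min_biased_species > length(FISH_SPECIES)) {
    stop("min_biased_species exceeds the number of panel species")
  }
  structure(
    list(cpm_expression_threshold = cpm_expression_threshold,
         pseudocount = pseudocount,
         log2_bias_threshold = log2_bias_threshold,
         min_biased_species = as.integer(min_biased_species),
         focal_species = focal_species,
         adj_p_cutoff = adj_p_cutoff,
         lfc_null = lfc_null,
         min_reads = as.integer(min_reads),
         min_samples_expressed = as.integer(min_samples_expressed),
         top_k = as.integer(top_k),
         expressed_on = expressed_on,
         rng_seed = as.integer(rng_seed)),
    class = "pipeline_config")
}
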