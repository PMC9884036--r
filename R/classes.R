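#' Diploid microsatellite genotype matrix
#'
#' Container for allele-size calls. Allele pairs are stored in canonical
#' sorted order; a call is either both alleles present or wholly missing
#' (`NA`), never half-called. Raw fragment sizes are kept as integers
#' together with the per-locus repeat-motif length so that consumers needing
#' repeat units (the M-ratio) can convert lazily.
#'
#' @param calls integer array `n_samples x n_loci x 2` of allele sizes, `NA`
#'   for missing. Single-allele missingness is rejected.
#' @param samples character vector of unique sample ids.
#' @param loci character vector of locus names.
#' @param motif_length integer vector (bp per repeat unit) per locus.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, samples, loci,
                            motif_length = rep(2L, length(loci))) {
  stopifnot(length(dim(calls)) == 3, dim(calls)[3] == 2)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (dim(calls)[1] != length(samples) || dim(calls)[2] != length(loci))
    stop("calls dimensions do not match samples/loci")
  half <- xor(is.na(calls[, , 1]), is.na(calls[, , 2]))
  if (any(half)) stop("half-missing genotype calls are not allowed")
  # canonical order: smaller allele first
  swap <- !is.na(calls[, , 1]) & calls[, , 1] > calls[, , 2]
  if (any(swap)) {
    tmp <- calls[, , 1][swap]
    calls[, , 1][swap] <- calls[, , 2][swap]
    calls[, , 2][swap] <- tmp
  }
  dimnames(calls) <- list(samples, loci, c("a1", "a2"))
  structure(
    list(calls = calls, samples = samples, loci = loci,
         motif_length = stats::setNames(as.integer(motif_length), loci)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$calls[, , 1]))
  cat(sprintf("genotype_matrix: %d samples x %d loci (%.1f%% missing calls)\n",
              length(x$samples), length(x$loci), 100 * miss))
  invisible(x)
}

#' Number of samples / loci in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @export
n_samples <- function(gm) length(gm$samples)

#' @rdname n_samples
#' @export
n_loci <- function(gm) length(gm$loci)

#' Subset a genotype matrix by sample and/or locus
#'
#' @param gm a `genotype_matrix`.
#' @param samples,loci character or index vectors; `NULL` keeps all.
#' @return a `genotype_matrix`.
#' @export
gm_subset <- function(gm, samples = NULL, loci = NULL) {
  si <- if (is.null(samples)) seq_along(gm$samples) else samples
  li <- if (is.null(loci)) seq_along(gm$loci) else loci
  calls <- gm$calls[si, li, , drop = FALSE]
  genotype_matrix(calls, gm$samples[si], gm$loci[li], gm$motif_length[li])
}

#' Equal-length nucleotide alignment
#'
#' Sequences are stored as upper-case character strings over the IUPAC
#' alphabet (ACGT, ambiguity codes, gap `-`, missing `N`).
#'
#' @param sequences named character vector of equal-length sequences.
#' @return an object of class `dna_alignment` with fields `samples`,
#'   `sequences`, `length_bp`.
#' @export
dna_alignment <- function(sequences) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must carry unique names")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1) {
    bad <- names(sequences)[lens != lens[1]]
    stop("unequal sequence lengths for: ", paste(bad, collapse = ", "))
  }
  legal <- "^[ACGTRYSWKMBDHVN-]*$"
  ok <- grepl(legal, sequences)
  if (!all(ok))
    stop("illegal characters in: ", paste(names(sequences)[!ok], collapse = ", "))
  structure(list(samples = names(sequences),
                 sequences = unname(sequences),
                 length_bp = unname(lens[1])),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("dna_alignment: %d sequences x %d bp\n",
              length(x$samples), x$length_bp))
  invisible(x)
}

# alignment as a character matrix (rows = samples)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequences, ""))
  rownames(m) <- aln$samples
  m
}

#' Subset an alignment by sample
#' @param aln a `dna_alignment`.
#' @param samples character or index vector.
#' @export
aln_subset <- function(aln, samples) {
  idx <- if (is.character(samples)) match(samples, aln$samples) else samples
  dna_alignment(stats::setNames(aln$sequences[idx], aln$samples[idx]))
}

#' Population partition
#'
#' Deterministic, ordered mapping of samples to groups (islands, collection
#' sites, sexes, ...). Group order is first-occurrence order unless levels
#' are given.
#'
#' @param group_of named character vector: sample id -> group label.
#' @param levels optional explicit group ordering.
#' @return an object of class `pop_partition`: a named factor.
#' @export
pop_partition <- function(group_of, levels = NULL) {
  if (is.null(names(group_of))) stop("group_of must be named by sample id")
  if (anyDuplicated(names(group_of))) stop("duplicate sample ids in partition")
  lv <- if (is.null(levels)) unique(unname(group_of)) else levels
  f <- factor(unname(group_of), levels = lv)
  if (anyNA(f)) stop("samples assigned to groups outside the level set")
  if (any(table(f) == 0)) stop("empty groups in partition")
  names(f) <- names(group_of)
  class(f) <- c("pop_partition", "factor")
  f
}

# partition restricted + aligned to a sample vector
part_align <- function(part, samples) {
  if (!all(samples %in% names(part)))
    stop("partition does not cover all samples")
  f <- factor(as.character(part[samples]), levels = levels(part))
  f <- droplevels(f)
  names(f) <- samples
  f
}

#' Validate a per-sample metadata table
#'
#' @param df data frame with required columns `sample_id`, `deme` and
#'   optional `site_id`, `lat`, `lon`, `sex`, `year`, `source`.
#' @return the validated data frame (invisibly classed `sample_metadata`).
#' @export
sample_metadata <- function(df) {
  if (!all(c("sample_id", "deme") %in% names(df)))
    stop("metadata requires sample_id and deme columns")
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  if ("sex" %in% names(df)) {
    bad <- !is.na(df$sex) & !df$sex %in% c("F", "M", "U")
    if (any(bad)) stop("sex token outside {F,M,U}: ",
                       paste(unique(df$sex[bad]), collapse = ", "))
  }
  if ("lat" %in% names(df) &&
      any(!is.na(df$lat) & (df$lat < -90 | df$lat > 90)))
    stop("latitude outside [-90, 90]")
  if ("lon" %in% names(df) &&
      any(!is.na(df$lon) & (df$lon < -180 | df$lon > 180)))
    stop("longitude outside [-180, 180]")
  if ("year" %in% names(df)) df$year <- as.integer(df$year)
  class(df) <- c("sample_metadata", class(df))
  df
}

#' Partition derived from a metadata column
#'
#' @param meta a `sample_metadata` data frame.
#' @param by column name to group by (default `"deme"`).
#' @return a `pop_partition` in row order of first occurrence.
#' @export
partition_from_metadata <- function(meta, by = "deme") {
  pop_partition(stats::setNames(as.character(meta[[by]]), meta$sample_id))
}
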