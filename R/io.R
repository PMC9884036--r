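#' Read a Genepop genotype file
#'
#' Accepts the standard 2- and 3-digit diploid Genepop dialects. Alleles are
#' decoded to integers; `00`/`000` codes become missing calls. Populations
#' are returned, in file order, as a partition labelled `pop1`, `pop2`, ...
#' unless the last sample name of each POP block is used (`label_by_last`),
#' which is the conventional Genepop population naming.
#'
#' @param path path to a `.gen` file.
#' @param motif_length optional integer vector of repeat-motif lengths, one
#'   per locus (default 2 bp).
#' @param label_by_last name populations after their final sample id
#'   (Genepop convention); default FALSE.
#' @return list with `genotypes` (`genotype_matrix`) and `partition`
#'   (`pop_partition`).
#' @export
read_genepop <- function(path, motif_length = NULL, label_by_last = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a Genepop file: too few lines")
  body <- lines[-1]                       # drop title line
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no POP separator found")
  loci <- trimws(body[seq_len(first_pop - 1)])
  # loci may be comma-separated on one line
  if (length(loci) == 1 && grepl(",", loci))
    loci <- trimws(strsplit(loci, ",")[[1]])
  rest <- body[first_pop:length(body)]
  pop_idx <- cumsum(grepl("^\\s*pop\\s*$", rest, ignore.case = TRUE))
  rows <- rest[!grepl("^\\s*pop\\s*$", rest, ignore.case = TRUE)]
  pops <- pop_idx[!grepl("^\\s*pop\\s*$", rest, ignore.case = TRUE)]

  ids <- character(length(rows))
  calls <- array(NA_integer_, c(length(rows), length(loci), 2))
  width <- NULL
  for (i in seq_along(rows)) {
    parts <- strsplit(rows[i], ",")[[1]]
    if (length(parts) < 2)
      stop("line ", i, ": missing comma after sample id")
    ids[i] <- trimws(parts[1])
    geno <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(geno) != length(loci))
      stop("line ", i, " (", ids[i], "): expected ", length(loci),
           " locus entries, found ", length(geno))
    w <- nchar(geno) / 2
    if (any(w != floor(w)) || length(unique(w)) != 1)
      stop("line ", i, " (", ids[i], "): inconsistent allele digit widths")
    if (is.null(width)) width <- w[1]
    if (w[1] != width)
      stop("line ", i, " (", ids[i], "): mixed digit widths across file")
    A <- as.integer(substr(geno, 1, width))
    B <- as.integer(substr(geno, width + 1, 2 * width))
    A[A == 0L] <- NA_integer_
    B[B == 0L] <- NA_integer_
    miss <- is.na(A) | is.na(B)
    A[miss] <- NA_integer_; B[miss] <- NA_integer_
    calls[i, , 1] <- A
    calls[i, , 2] <- B
  }
  if (anyDuplicated(ids))
    ids <- make.unique(ids, sep = "_")
  if (is.null(motif_length)) motif_length <- rep(2L, length(loci))
  gm <- genotype_matrix(calls, ids, loci, motif_length)
  pop_labels <- paste0("pop", seq_len(max(pops)))
  if (label_by_last)
    pop_labels <- vapply(seq_len(max(pops)),
                         function(p) ids[max(which(pops == p))], "")
  part <- pop_partition(stats::setNames(pop_labels[pops], ids))
  list(genotypes = gm, partition = part)
}

#' Write a genotype matrix as a 3-digit Genepop file
#'
#' @param gm a `genotype_matrix`.
#' @param part a `pop_partition` over the samples of `gm`.
#' @param path output path.
#' @param title title line content.
#' @export
write_genepop <- function(gm, part, path, title = "archipop export") {
  part <- part_align(part, gm$samples)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(gm$loci, con)
  for (g in levels(part)) {
    writeLines("POP", con)
    for (s in which(part == g)) {
      a <- gm$calls[s, , 1]; b <- gm$calls[s, , 2]
      a[is.na(a)] <- 0L; b[is.na(b)] <- 0L
      writeLines(paste0(gm$samples[s], " ,  ",
                        paste0(sprintf("%03d", a), sprintf("%03d", b),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a FASTA alignment
#'
#' Wraps [ape::read.FASTA()] and validates that all records share one length
#' and use the IUPAC alphabet; sequences are upper-cased.
#'
#' @param path FASTA file path.
#' @return a `dna_alignment`.
#' @export
read_fasta_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(x) paste(toupper(x), collapse = ""), "")
  dna_alignment(seqs)
}

#' Write an alignment to FASTA
#' @param aln a `dna_alignment`.
#' @param path output path.
#' @export
write_fasta_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$samples))
    writeLines(c(paste0(">", aln$samples[i]), aln$sequences[i]), con)
  invisible(path)
}

#' Read a delimited per-sample metadata table
#'
#' Delimiter is sniffed from the header (tab beats comma). Validates the
#' sample-record invariants: unique ids, sex in {F,M,U}, coordinates within
#' range.
#'
#' @param path csv/tsv path with a header row.
#' @return a validated `sample_metadata` data frame.
#' @export
read_sample_metadata <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  sample_metadata(df)
}

#' Write sample metadata
#' @param meta a `sample_metadata` data frame.
#' @param path output path (csv).
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.csv(as.data.frame(meta), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Screen an alignment for ambiguity codes (heteroplasmy candidates)
#'
#' Sequences with one or more IUPAC ambiguity codes (anything other than
#' A, C, G, T, N or the gap) are flagged: in mitochondrial data these are
#' candidate heteroplasmic individuals. The input is left untouched.
#'
#' @param aln a `dna_alignment`.
#' @return list with `clean` (alignment without flagged samples; equals the
#'   input when nothing is flagged) and `flagged` (character vector of ids).
#' @export
screen_ambiguous_sequences <- function(aln) {
  amb <- grepl("[RYSWKMBDHV]", aln$sequences)
  flagged <- aln$samples[amb]
  clean <- if (any(amb)) aln_subset(aln, which(!amb)) else aln
  list(clean = clean, flagged = flagged)
}

#' Summarise a dataset for validation
#'
#' @param gm optional `genotype_matrix`.
#' @param aln optional `dna_alignment`.
#' @param meta optional `sample_metadata`.
#' @return a character vector of human-readable summary lines (also printed).
#' @export
validate_dataset <- function(gm = NULL, aln = NULL, meta = NULL) {
  out <- character()
  if (!is.null(meta)) {
    out <- c(out, sprintf("metadata: %d samples, %d demes, sexes %s",
                          nrow(meta), length(unique(meta$deme)),
                          paste(names(table(meta$sex)), table(meta$sex),
                                sep = "=", collapse = " ")))
  }
  if (!is.null(gm)) {
    k <- apply(gm$calls, 2, function(x) length(unique(stats::na.omit(c(x)))))
    out <- c(out, sprintf(
      "genotypes: %d samples x %d loci, alleles/locus %d-%d, %.1f%% complete",
      n_samples(gm), n_loci(gm), min(k), max(k),
      100 * mean(!is.na(gm$calls[, , 1]))))
  }
  if (!is.null(aln)) {
    scr <- screen_ambiguous_sequences(aln)
    out <- c(out, sprintf("mtDNA: %d sequences x %d bp, %d with ambiguity codes",
                          length(aln$samples), aln$length_bp,
                          length(scr$flagged)))
  }
  cat(out, sep = "\n")
  invisible(out)
}
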