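#' @include AllClasses.R
NULL

#' Read an aligned FASTA file
#'
#' Reads one locus worth of pre-aligned sequences.  Sequences are upper-cased
#' and validated against the alphabet `A,C,G,T,N,-`; input order is
#' preserved.
#'
#' @param path path to an aligned FASTA file.
#' @param locusName locus label stored in the result.
#' @param inheritance `"mitochondrial"`, `"x_linked"` or `"autosomal"`.
#' @return a [SeqAlignment-class].
#' @export
readFastaAlignment <- function(path, locusName = basename(path),
                               inheritance = "autosomal") {
  if (!file.exists(path)) stop(sprintf("input error: no such file '%s'", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("input error: empty FASTA '%s'", path))
  seqs <- as.character(set)
  ids <- sub("\\s.*$", "", names(set))
  SeqAlignment(seqs, ids = ids, locus = locusName, inheritance = inheritance)
}

#' Write an alignment to FASTA
#'
#' @param aln a [SeqAlignment-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFastaAlignment <- function(aln, path) {
  stopifnot(is(aln, "SeqAlignment"))
  seqs <- apply(aln@mat, 1L, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- rownames(aln@mat)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Expects a TSV with header columns `sample_id`, `population` and optionally
#' `region`.
#'
#' @param path TSV file.
#' @return data.frame with columns `sample_id`, `population`, `region`.
#' @export
readPopmap <- function(path) {
  if (!file.exists(path)) stop(sprintf("input error: no such file '%s'", path))
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "population") %in% names(df)))
    stop("input error: popmap needs columns 'sample_id' and 'population'")
  if (anyDuplicated(df$sample_id))
    stop("input error: duplicate sample_id rows in popmap")
  if (is.null(df$region)) df$region <- df$population
  df[, c("sample_id", "population", "region")]
}

#' Read population coordinates
#'
#' Expects a TSV with header columns `population`, `latitude_deg`,
#' `longitude_deg` (signed decimal degrees, east/north positive; e.g. a site
#' at 93.26 degrees W is stored as longitude -93.26).
#'
#' @param path TSV file.
#' @return data.frame with columns `population`, `latitude_deg`,
#'   `longitude_deg`.
#' @export
readCoords <- function(path) {
  if (!file.exists(path)) stop(sprintf("input error: no such file '%s'", path))
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("population", "latitude_deg", "longitude_deg")
  if (!all(need %in% names(df)))
    stop("input error: coords needs columns population, latitude_deg, longitude_deg")
  if (anyDuplicated(df$population))
    stop("input error: duplicate population rows in coords")
  if (any(abs(df$latitude_deg) > 90) || any(abs(df$longitude_deg) > 180))
    stop("input error: coordinates out of range")
  df[, need]
}

#' Match a population map against an alignment
#'
#' @param aln a [SeqAlignment-class].
#' @param popmap data.frame as returned by [readPopmap()].
#' @return character vector of population codes, one per sequence of `aln`.
#' @export
populationOf <- function(aln, popmap) {
  idx <- match(sampleIDs(aln), popmap$sample_id)
  if (anyNA(idx)) {
    miss <- sampleIDs(aln)[is.na(idx)]
    stop(sprintf("input error: samples without population assignment: %s",
                 paste(head(miss, 5L), collapse = ", ")))
  }
  popmap$population[idx]
}

#' Sites analysed under complete deletion
#'
#' Logical vector marking alignment columns that are free of gaps (`-`) and
#' missing data (`N`) in every sequence.  All diversity statistics, haplotype
#' identity and AMOVA distances are computed on these sites only, which makes
#' haplotype and segregating-site counts invariant to indel placement.
#'
#' @param aln a [SeqAlignment-class].
#' @return logical vector of length `seqLength(aln)`.
#' @export
analysedSites <- function(aln) {
  m <- aln@mat
  colSums(m == "-" | m == "N") == 0L
}

#' Collapse aligned sequences to haplotypes
#'
#' Two sequences belong to the same haplotype when they are identical at all
#' analysed sites (see [analysedSites()]).  Haplotypes are labelled
#' `Hap_1, Hap_2, ...` in order of first occurrence and the first occurrence
#' is kept as the representative sequence.
#'
#' @param aln a [SeqAlignment-class].
#' @param popmap optional data.frame (see [readPopmap()]); when omitted all
#'   sequences are pooled into a single population `"all"`.
#' @return a [HaplotypeTable-class].
#' @examples
#' aln <- SeqAlignment(c(a = "AAAA", b = "AAAT", c = "AAAA"))
#' collapseHaplotypes(aln)
#' @export
collapseHaplotypes <- function(aln, popmap = NULL) {
  stopifnot(is(aln, "SeqAlignment"))
  keep <- analysedSites(aln)
  m <- aln@mat
  key <- if (any(keep))
    apply(m[, keep, drop = FALSE], 1L, paste, collapse = "") else
    rep("", nrow(m))
  first <- !duplicated(key)
  hap_of <- match(key, key[first])
  ids <- paste0("Hap_", seq_len(sum(first)))
  pop <- if (is.null(popmap)) rep("all", nrow(m)) else populationOf(aln, popmap)
  pops <- unique(pop)
  counts <- matrix(0L, nrow = length(ids), ncol = length(pops),
                   dimnames = list(ids, pops))
  for (i in seq_along(hap_of))
    counts[hap_of[i], pop[i]] <- counts[hap_of[i], pop[i]] + 1L
  seqs <- apply(m[first, , drop = FALSE], 1L, paste, collapse = "")
  names(seqs) <- ids
  new("HaplotypeTable", sequences = seqs, counts = counts,
      locus = aln@locus, inheritance = aln@inheritance)
}

#' Classify alignment sites
#'
#' Any site carrying a gap or `N` in at least one sequence is a gap site and
#' excluded from the polymorphism classes.  Among the remaining sites, a
#' variable site has two or more distinct bases; it is a singleton site when
#' exactly one minor variant is carried by a single sequence and otherwise
#' not parsimony informative, and parsimony informative when at least two
#' variants are each present in two or more sequences.  Site labels combine
#' the class with the number of variants (`pi_2`, `singleton_3`, ...);
#' reported site indices are 1-based.
#'
#' @param aln a [SeqAlignment-class].
#' @return a list of class `SiteClasses` with counts `n_variable`,
#'   `n_gap_sites`, `n_singleton_2var`, `n_pi_2var`, `n_pi_3var`,
#'   `n_other_variable` and a per-site `labels` character vector.
#' @export
classifySites <- function(aln) {
  stopifnot(is(aln, "SeqAlignment"))
  m <- aln@mat
  L <- ncol(m)
  labels <- character(L)
  for (s in seq_len(L)) {
    col <- m[, s]
    if (any(col == "-" | col == "N")) { labels[s] <- "gap"; next }
    tab <- table(col)
    nv <- length(tab)
    if (nv == 1L) { labels[s] <- "invariant"; next }
    informative <- sum(tab >= 2L) >= 2L
    labels[s] <- paste0(if (informative) "pi_" else "singleton_", nv)
  }
  is_var <- !labels %in% c("gap", "invariant")
  out <- list(
    n_variable = sum(is_var),
    n_gap_sites = sum(labels == "gap"),
    n_singleton_2var = sum(labels == "singleton_2"),
    n_pi_2var = sum(labels == "pi_2"),
    n_pi_3var = sum(labels == "pi_3"),
    n_other_variable = sum(is_var) - sum(labels %in%
      c("singleton_2", "pi_2", "pi_3")),
    labels = labels)
  class(out) <- "SiteClasses"
  out
}

#' @export
print.SiteClasses <- function(x, ...) {
  cat(sprintf(
    paste0("Site classification: %d variable, %d gap/missing sites\n",
           "  singleton (2 variants): %d\n  parsimony informative (2 variants): %d\n",
           "  parsimony informative (3 variants): %d\n  other variable: %d\n"),
    x$n_variable, x$n_gap_sites, x$n_singleton_2var, x$n_pi_2var,
    x$n_pi_3var, x$n_other_variable))
  invisible(x)
}

#' Write a haplotype table as TSV
#'
#' Columns: `haplotype_id`, `sequence`, then one count column per population.
#'
#' @param haps a [HaplotypeTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeHaplotypeTable <- function(haps, path) {
  stopifnot(is(haps, "HaplotypeTable"))
  df <- data.frame(haplotype_id = names(haps@sequences),
                   sequence = unname(haps@sequences),
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(haps@counts, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
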