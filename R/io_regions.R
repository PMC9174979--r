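#' @useDynLib mitophylo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# All coordinates in this package are 1-based inclusive "np" (nucleotide
# position) values on the reference mitogenome, matching the notation used in
# mtDNA haplogroup work. Input sequences are assumed pre-aligned to reference
# length; a length mismatch is an error, never an implicit alignment.

#' Read a FASTA file of mitogenome sequences
#'
#' Reads plain FASTA, uppercases the sequences and validates them against the
#' alphabet `A, C, G, T, N, -`. `N` is treated as missing data downstream,
#' `-` only as indel evidence.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of uppercase sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file does not exist: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  ids <- names(x)
  ids <- sub("\\s.*$", "", ids)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(x))
  bad <- regexpr("[^ACGTN-]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf(
      "illegal character '%s' in sequence '%s' at position %d",
      substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]
    ))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' Lines are wrapped at 60 columns; reading then writing is byte-identical
#' modulo that wrapping policy.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::BStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Define a region scheme on reference coordinates
#'
#' A region scheme is an ordered set of non-overlapping 1-based inclusive
#' intervals on the reference; sequences are analysed on the concatenation of
#' these intervals (e.g. the coding region, excluding the control regions).
#'
#' @param starts,ends Integer vectors of 1-based inclusive interval bounds.
#' @param label Scheme label.
#' @return An object of class `region_scheme`.
#' @export
region_scheme <- function(starts, ends, label = "region") {
  starts <- as.integer(starts)
  ends <- as.integer(ends)
  stopifnot(length(starts) == length(ends), length(starts) > 0L)
  if (any(is.na(starts)) || any(is.na(ends))) stop("NA interval bounds")
  if (any(starts < 1L)) stop("interval starts must be >= 1")
  if (any(ends < starts)) stop("interval end before start")
  o <- order(starts)
  starts <- starts[o]
  ends <- ends[o]
  if (length(starts) > 1L && any(starts[-1L] <= ends[-length(ends)])) {
    stop("intervals overlap")
  }
  structure(
    list(starts = starts, ends = ends, label = as.character(label)),
    class = "region_scheme"
  )
}

#' @export
print.region_scheme <- function(x, ...) {
  cat(sprintf(
    "Region scheme '%s': %d interval(s), %d bp\n  %s\n",
    x$label, length(x$starts), region_length(x),
    paste(sprintf("%d-%d", x$starts, x$ends), collapse = ", ")
  ))
  invisible(x)
}

#' Total length of a region scheme
#'
#' @param scheme A [region_scheme()].
#' @return Total bp count, the sum of inclusive interval lengths.
#' @export
region_length <- function(scheme) {
  stopifnot(inherits(scheme, "region_scheme"))
  sum(scheme$ends - scheme$starts + 1L)
}

#' The mitogenome coding-region scheme
#'
#' The standard analysis region for this package: the 15,601-bp concatenation
#' nps 1-14,859 + 16,068-16,740 + 18,075-18,143, i.e. the mitogenome minus the
#' two control regions.
#'
#' @return A [region_scheme()].
#' @export
coding_region_scheme <- function() {
  region_scheme(
    starts = c(1L, 16068L, 18075L),
    ends = c(14859L, 16740L, 18143L),
    label = "coding_region"
  )
}

#' The ND2 + CYB two-gene scheme
#'
#' The 2,075-bp concatenation of ND2 (nps 3,980-4,996) and CYB
#' (nps 13,696-14,753), used for comparisons with partial mtDNA sequences.
#'
#' @return A [region_scheme()].
#' @export
nd2_cyb_scheme <- function() {
  region_scheme(
    starts = c(3980L, 13696L),
    ends = c(4996L, 14753L),
    label = "nd2_cyb"
  )
}

#' Extract and concatenate the region-scheme subsequence
#'
#' @param sequence A single sequence string, aligned to reference coordinates.
#' @param scheme A [region_scheme()].
#' @return The concatenated subsequence, of length `region_length(scheme)`.
#' @export
extract_region <- function(sequence, scheme) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  stopifnot(inherits(scheme, "region_scheme"))
  n <- nchar(sequence)
  if (n < max(scheme$ends)) {
    i <- which.max(scheme$ends)
    stop(sprintf(
      "sequence (length %d) shorter than scheme interval %d-%d",
      n, scheme$starts[i], scheme$ends[i]
    ))
  }
  paste(substring(sequence, scheme$starts, scheme$ends), collapse = "")
}

#' Positions (np) covered by a region scheme, in concatenation order
#'
#' @param scheme A [region_scheme()].
#' @return Integer vector of reference positions.
#' @export
region_positions <- function(scheme) {
  stopifnot(inherits(scheme, "region_scheme"))
  unlist(mapply(seq.int, scheme$starts, scheme$ends, SIMPLIFY = FALSE),
         use.names = FALSE)
}

#' Default population to macro-group mapping
#'
#' South/Center/North macro-groups over the default sampling populations, used
#' for the diversity-versus-latitude contrasts. Editable: pass your own named
#' vector to [read_metadata()].
#'
#' @return Named character vector population -> macro-group.
#' @export
default_macro_groups <- function() {
  c(
    Algeria = "South", Spain = "South", Italy_S = "South", Israel = "South",
    Italy_N = "Center", Switzerland = "Center",
    Poland = "North", Ukraine = "North", Denmark = "North"
  )
}

#' Read a sample-metadata table
#'
#' Expects tab-separated text with header columns `sample_id`, `subspecies`,
#' `population`, `latitude`, `longitude`. A `macro_group` column is filled from
#' the population mapping; unknown populations get `"unassigned"`. Records with
#' missing coordinates are retained and flagged in `coords_missing`.
#'
#' @param path Path to a TSV file.
#' @param macro_groups Named character vector population -> macro-group.
#' @return A data.frame of sample metadata.
#' @export
read_metadata <- function(path, macro_groups = default_macro_groups()) {
  if (!file.exists(path)) stop("metadata file does not exist: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(df, macro_groups)
}

#' Validate and complete a sample-metadata data.frame
#'
#' @param df Data frame with the columns described in [read_metadata()].
#' @param macro_groups Named character vector population -> macro-group.
#' @return The validated data.frame with `macro_group` and `coords_missing`.
#' @export
validate_metadata <- function(df, macro_groups = default_macro_groups()) {
  need <- c("sample_id", "subspecies", "population", "latitude", "longitude")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0L) {
    stop("duplicate sample_id(s): ", paste(dup, collapse = ", "))
  }
  df$latitude <- as.numeric(df$latitude)
  df$longitude <- as.numeric(df$longitude)
  bad_lat <- which(!is.na(df$latitude) & abs(df$latitude) > 90)
  if (length(bad_lat) > 0L) {
    stop("latitude out of [-90, 90] for sample(s): ",
         paste(df$sample_id[bad_lat], collapse = ", "))
  }
  bad_lon <- which(!is.na(df$longitude) & abs(df$longitude) > 180)
  if (length(bad_lon) > 0L) {
    stop("longitude out of [-180, 180] for sample(s): ",
         paste(df$sample_id[bad_lon], collapse = ", "))
  }
  df$coords_missing <- is.na(df$latitude) | is.na(df$longitude)
  mg <- unname(macro_groups[df$population])
  mg[is.na(mg)] <- "unassigned"
  df$macro_group <- mg
  df
}

#' Read a reference gene annotation
#'
#' BED-like TSV but with 1-based inclusive coordinates (columns `gene`,
#' `start_np`, `end_np`, `strand`, `category`), plus a header line. Categories
#' are `protein_coding`, `tRNA`, `rRNA`, `control_region`.
#'
#' @param path Path to the annotation TSV.
#' @param reference_id Accession label of the reference the coordinates live on.
#' @param length Reference length in bp.
#' @return An object of class `reference_annotation`.
#' @export
read_annotation <- function(path, reference_id = "reference", length = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "start_np", "end_np", "strand", "category")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  }
  df$start_np <- as.integer(df$start_np)
  df$end_np <- as.integer(df$end_np)
  if (is.null(length)) length <- max(df$end_np)
  if (any(df$start_np < 1L) || any(df$end_np < df$start_np) ||
      any(df$end_np > length)) {
    stop("annotation intervals must satisfy 1 <= start_np <= end_np <= length")
  }
  ok <- c("protein_coding", "tRNA", "rRNA", "control_region")
  if (!all(df$category %in% ok)) {
    stop("unknown annotation category: ",
         paste(setdiff(df$category, ok), collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  o <- order(df$start_np)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  structure(
    list(
      reference_id = reference_id,
      length = as.integer(length),
      genes = df,
      genetic_code = "vertebrate_mitochondrial"
    ),
    class = "reference_annotation"
  )
}

#' @export
print.reference_annotation <- function(x, ...) {
  tab <- table(x$genes$category)
  cat(sprintf(
    "Reference annotation '%s' (%d bp): %s\n",
    x$reference_id, x$length,
    paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", ")
  ))
  invisible(x)
}

#' Packaged barn-swallow-like mitogenome annotation
#'
#' Loads the annotation fixture shipped with the package: a synthetic 18,143-bp
#' avian mitogenome layout (GO-II-style duplicated control-region architecture)
#' with 13 protein-coding, 22 tRNA, 2 rRNA genes and 2 control regions. ND2 and
#' CYB sit at their published barn-swallow coordinates (nps 3,980-4,996 and
#' 13,696-14,753); the remaining coordinates are plausible synthetic fill, not
#' a downloaded GenBank record.
#'
#' @return A `reference_annotation`.
#' @export
swallow_annotation <- function() {
  path <- system.file("extdata", "mitogenome_annotation_synthetic.tsv",
                      package = "mitophylo")
  if (path == "") stop("packaged annotation fixture not found")
  read_annotation(path, reference_id = "synthetic_HrrRS_like", length = 18143L)
}
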