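#' Read an aligned multi-FASTA file
#'
#' Reads a pre-aligned FASTA file (wrapped or unwrapped lines) into an
#' alignment tibble with one row per sequence. Symbols are normalised to
#' uppercase and `U` to `T`; the allowed alphabet is the 15 IUPAC nucleotide
#' codes plus the gap character `-`. Alignments are expected from an upstream
#' editor: no alignment is performed here, and ragged input is an error.
#' Alignment columns are addressed 1-based throughout the package.
#'
#' @param path path to a FASTA file.
#' @param marker optional marker label ("ITS", "rpl32-trnL", "petL-psbE", ...)
#'   stored in the `marker` column.
#' @return a tibble with columns `name`, `marker`, `seq`; all `seq` values
#'   have equal nchar (the alignment length).
#' @seealso [write_alignment()], [read_ribotype_panel()]
#' @export
read_alignment <- function(path, marker = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  aligned_matrix(names(set), as.character(set), marker = marker)
}

#' Construct and validate an alignment tibble
#'
#' @param names sequence identifiers (unique, non-empty).
#' @param seqs equal-length strings over the IUPAC + gap alphabet.
#' @param marker optional marker label.
#' @return validated alignment tibble (`name`, `marker`, `seq`).
#' @export
aligned_matrix <- function(names, seqs, marker = NA_character_) {
  aln <- tibble::tibble(
    name = as.character(names),
    marker = as.character(marker),
    seq = .normalize_symbol(as.character(seqs))
  )
  validate_alignment(aln)
}

#' @rdname aligned_matrix
#' @param aln an alignment tibble.
#' @export
validate_alignment <- function(aln) {
  stopifnot(is.data.frame(aln), all(c("name", "seq") %in% names(aln)))
  if (nrow(aln) == 0L) stop("alignment has no sequences", call. = FALSE)
  if (anyDuplicated(aln$name)) {
    stop("duplicate sequence names: ",
         paste(unique(aln$name[duplicated(aln$name)]), collapse = ", "),
         call. = FALSE)
  }
  len <- unique(nchar(aln$seq))
  if (length(len) != 1L) {
    stop("ragged alignment: sequence lengths ", paste(sort(len), collapse = ", "),
         call. = FALSE)
  }
  if (len < 1L) stop("alignment length must be >= 1", call. = FALSE)
  for (i in seq_len(nrow(aln))) {
    sym <- strsplit(aln$seq[i], "", fixed = TRUE)[[1]]
    bad <- which(!(sym %in% .iupac_alphabet))
    if (length(bad)) {
      stop(sprintf("illegal symbol %s in record '%s' at column %d",
                   sQuote(sym[bad[1]]), aln$name[i], bad[1]), call. = FALSE)
    }
  }
  aln
}

#' Alignment length in columns
#' @param aln an alignment tibble.
#' @return integer number of columns.
#' @export
alignment_length <- function(aln) nchar(aln$seq[[1]])

#' Write an alignment tibble to FASTA
#'
#' Round-trips with [read_alignment()]: reading back reproduces the
#' (normalised) sequences byte-identically, in order.
#'
#' @param aln alignment tibble (`name`, `seq`).
#' @param path output path.
#' @param width line-wrap width; `Inf` writes each sequence on one line.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, width = 70L) {
  validate_alignment(aln)
  lines <- unlist(purrr::map2(aln$name, aln$seq, function(nm, sq) {
    body <- if (is.finite(width) && nchar(sq) > width) {
      starts <- seq(1L, nchar(sq), by = width)
      substring(sq, starts, pmin(starts + width - 1L, nchar(sq)))
    } else sq
    c(paste0(">", nm), body)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a parental ribotype panel
#'
#' A ribotype panel is an aligned FASTA whose headers follow
#' `species_name|ribotype_id`; several ribotypes per species are allowed and
#' represent within-species ITS variants. Pair scoring considers every
#' ribotype combination across species and keeps the best one per species
#' pair.
#'
#' @param path FASTA path.
#' @return alignment tibble with extra columns `species`, `ribotype`.
#' @export
read_ribotype_panel <- function(path) {
  aln <- read_alignment(path, marker = "ITS")
  as_ribotype_panel(aln)
}

#' @rdname read_ribotype_panel
#' @param aln alignment tibble whose names are `species|ribotype`.
#' @export
as_ribotype_panel <- function(aln) {
  parts <- stringr::str_split_fixed(aln$name, stringr::fixed("|"), 2L)
  if (any(parts[, 2] == "")) {
    stop("panel headers must be 'species_name|ribotype_id'", call. = FALSE)
  }
  dplyr::mutate(aln, species = parts[, 1], ribotype = parts[, 2],
                .after = "name")
}

#' Read plastid haplotype references
#'
#' Reference haplotypes come as aligned FASTA with headers
#' `marker|haplotype_label` (e.g. `rpl32-trnL|A`).
#'
#' @param path FASTA path.
#' @return alignment tibble with columns `marker`, `haplotype`, `seq`.
#' @export
read_haplotype_refs <- function(path) {
  aln <- read_alignment(path)
  parts <- stringr::str_split_fixed(aln$name, stringr::fixed("|"), 2L)
  if (any(parts[, 2] == "")) {
    stop("haplotype headers must be 'marker|haplotype_label'", call. = FALSE)
  }
  out <- dplyr::mutate(aln, marker = parts[, 1], haplotype = parts[, 2])
  if (anyDuplicated(out[c("marker", "haplotype")])) {
    stop("haplotype labels must be unique within a marker", call. = FALSE)
  }
  out[c("name", "marker", "haplotype", "seq")]
}

#' Read the sample-metadata table
#'
#' Tab-separated with header; required columns `sample_id`, `region`,
#' `locality`; optional `taxon_label`, `fertile` (logical), and accession
#' columns `accession_its`, `accession_rpl32`, `accession_petl`.
#'
#' @param path TSV path.
#' @return tibble of sample records, one row per sample.
#' @export
read_samples <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  req <- c("sample_id", "region", "locality")
  missing <- setdiff(req, names(tab))
  if (length(missing)) {
    stop("sample table missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  empty <- !nzchar(tab$region %||% "") | is.na(tab$region) |
    !nzchar(tab$locality %||% "") | is.na(tab$locality)
  if (any(empty)) {
    stop("empty region/locality for sample(s): ",
         paste(tab$sample_id[empty], collapse = ", "), call. = FALSE)
  }
  if ("fertile" %in% names(tab)) tab$fertile <- as.logical(tab$fertile)
  tab
}

#' Read a species-to-haplotype map
#'
#' TSV with columns `marker`, `haplotype`, `species`; one row per
#' (marker, haplotype, species) association. Shared haplotypes (one label
#' mapped to several species) are allowed and simply cannot orient a cross
#' between two species that share it.
#'
#' @param path TSV path.
#' @return tibble (`marker`, `haplotype`, `species`).
#' @export
read_species_map <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  req <- c("marker", "haplotype", "species")
  missing <- setdiff(req, names(tab))
  if (length(missing)) {
    stop("species map missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab[req]
}

# split a sequence string into a character vector of symbols
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
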