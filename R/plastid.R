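#' Default species-to-haplotype map for the study system
#'
#' Plastid haplotype clades of the two intergenic spacers and the
#' water-crowfoot species that carry them: rpl32-trnL clades A, C, D, I and
#' petL-psbE clades A, C, F. The map is many-to-many -- a clade shared by two
#' species cannot orient a cross between them -- and can be replaced by any
#' tibble with the same three columns (see [read_species_map()]).
#'
#' @return tibble (`marker`, `haplotype`, `species`).
#' @export
batrachium_species_map <- function() {
  tibble::tribble(
    ~marker,      ~haplotype, ~species,
    "rpl32-trnL", "A",        "aquatilis",
    "rpl32-trnL", "A",        "fluitans",
    "rpl32-trnL", "C",        "kauffmannii",
    "rpl32-trnL", "D",        "kauffmannii",
    "rpl32-trnL", "D",        "aquatilis",
    "rpl32-trnL", "I",        "circinatus",
    "petL-psbE",  "A",        "aquatilis",
    "petL-psbE",  "A",        "fluitans",
    "petL-psbE",  "C",        "kauffmannii",
    "petL-psbE",  "C",        "aquatilis",
    "petL-psbE",  "F",        "circinatus"
  )
}

#' Assign plastid haplotypes by nearest reference
#'
#' Each query is assigned the reference haplotype with the fewest
#' mismatching informative columns (gaps and N excluded on either side).
#' Ties break alphabetically by label and are flagged. A query farther than
#' `delta_max` from every reference stays unassigned (`NA` label): slightly
#' deviating within-clade variants (one or two private substitutions) are
#' tolerated and flagged `deviant`.
#'
#' @param queries alignment tibble of plastid sequences (`name`, `seq`),
#'   aligned to the references.
#' @param refs haplotype reference tibble ([read_haplotype_refs()]; columns
#'   `marker`, `haplotype`, `seq`) for a single marker.
#' @param delta_max maximum accepted distance (default from [ht_config()]).
#' @return tibble: `sample_id`, `marker`, `haplotype`, `distance`,
#'   `deviant` (distance > 0), `tie`.
#' @export
assign_haplotypes <- function(queries, refs, delta_max = 2L) {
  if (nrow(refs) == 0L) stop("empty haplotype reference set", call. = FALSE)
  marker <- unique(refs$marker)
  if (length(marker) != 1L) {
    stop("refs must contain a single marker; got: ",
         paste(marker, collapse = ", "), call. = FALSE)
  }
  if (alignment_length(queries) != alignment_length(refs)) {
    stop("plastid queries not aligned to references (length mismatch)",
         call. = FALSE)
  }
  ref_chars <- lapply(refs$seq, function(s) .chars(.normalize_symbol(s)))
  purrr::map2_dfr(queries$name, queries$seq, function(id, qseq) {
    qs <- .chars(.normalize_symbol(qseq))
    d <- vapply(ref_chars, function(rc) .hamming(qs, rc), integer(1))
    ord <- order(d, refs$haplotype)
    best <- ord[1]
    tie <- sum(d == d[best]) > 1L
    if (d[best] > delta_max) {
      tibble::tibble(sample_id = id, marker = marker,
                     haplotype = NA_character_, distance = d[best],
                     deviant = NA, tie = tie)
    } else {
      tibble::tibble(sample_id = id, marker = marker,
                     haplotype = refs$haplotype[best], distance = d[best],
                     deviant = d[best] > 0L, tie = tie)
    }
  })
}

#' Orient hybrid crosses from maternally inherited plastid haplotypes
#'
#' Plastids are maternally inherited in these plants, so a hybrid's plastid
#' haplotype identifies its seed parent. For every hybrid call, each
#' available marker votes for the ITS parent whose species maps to the
#' sample's haplotype; a haplotype mapping to both ITS parents (shared
#' clade) or to neither casts no vote. Agreeing votes orient the cross
#' (maternal = voted species, paternal = the other ITS parent); opposing
#' votes are a CONFLICT; no votes leave the cross UNORIENTED.
#'
#' @param calls parentage tibble from [infer_parentage()]; only rows with
#'   verdict F1_HYBRID or COMPLEX_HYBRID are oriented.
#' @param assignments haplotype assignment tibble from [assign_haplotypes()]
#'   (one or both markers, rows bound together).
#' @param species_map tibble (`marker`, `haplotype`, `species`); default
#'   [batrachium_species_map()].
#' @return tibble: `sample_id`, `maternal`, `paternal`, `basis`
#'   (comma-joined markers that voted), `confidence`
#'   (ORIENTED / UNORIENTED / CONFLICT).
#' @export
orient_crosses <- function(calls, assignments,
                           species_map = batrachium_species_map()) {
  hyb <- dplyr::filter(calls, .data$verdict %in% c("F1_HYBRID", "COMPLEX_HYBRID"))
  if (nrow(hyb) == 0L) {
    stop("no hybrid calls to orient (verdicts must be F1_HYBRID or COMPLEX_HYBRID)",
         call. = FALSE)
  }
  purrr::pmap_dfr(hyb[c("sample_id", "parent_a", "parent_b")],
                  function(sample_id, parent_a, parent_b) {
    parents <- c(parent_a, parent_b)
    asn <- dplyr::filter(assignments, .data$sample_id == !!sample_id,
                         !is.na(.data$haplotype))
    votes <- character(0); basis <- character(0)
    for (k in seq_len(nrow(asn))) {
      mapped <- species_map$species[
        species_map$marker == asn$marker[k] &
          species_map$haplotype == asn$haplotype[k]]
      hit <- intersect(mapped, parents)
      if (length(hit) == 1L) {           # shared or unmapped clades cast no vote
        votes <- c(votes, hit)
        basis <- c(basis, asn$marker[k])
      }
    }
    if (length(votes) == 0L) {
      tibble::tibble(sample_id = sample_id, maternal = NA_character_,
                     paternal = NA_character_, basis = "",
                     confidence = "UNORIENTED")
    } else if (length(unique(votes)) > 1L) {
      tibble::tibble(sample_id = sample_id, maternal = NA_character_,
                     paternal = NA_character_,
                     basis = paste(basis, collapse = ","),
                     confidence = "CONFLICT")
    } else {
      maternal <- votes[1]
      tibble::tibble(sample_id = sample_id, maternal = maternal,
                     paternal = setdiff(parents, maternal)[1],
                     basis = paste(basis, collapse = ","),
                     confidence = "ORIENTED")
    }
  })
}

#' Crossing-direction statistic
#'
#' Fraction of oriented crosses in which the focal species acted as pollen
#' donor (paternal parent). A fraction of 1 means strictly unidirectional
#' crossing: the focal species never contributed the seed. UNORIENTED and
#' CONFLICT crosses are excluded from the denominator and reported
#' separately.
#'
#' @param crosses oriented-cross tibble from [orient_crosses()].
#' @param focal_species species name tested as pollen donor.
#' @return one-row tibble: `focal_species`, `fraction_paternal`,
#'   `n_oriented`, `n_paternal`, `n_unoriented`, `n_conflict`.
#' @export
directionality <- function(crosses, focal_species = "circinatus") {
  oriented <- dplyr::filter(crosses, .data$confidence == "ORIENTED")
  if (nrow(oriented) == 0L) {
    stop("directionality undefined: no ORIENTED crosses", call. = FALSE)
  }
  n_pat <- sum(oriented$paternal == focal_species)
  tibble::tibble(
    focal_species = focal_species,
    fraction_paternal = n_pat / nrow(oriented),
    n_oriented = nrow(oriented),
    n_paternal = n_pat,
    n_unoriented = sum(crosses$confidence == "UNORIENTED"),
    n_conflict = sum(crosses$confidence == "CONFLICT")
  )
}
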