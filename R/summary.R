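#' Round half away from zero to integer
#'
#' Reported percentages use conventional half-up rounding (0.5 always rounds
#' up), not banker's rounding, so printed figures like 48/66 -> 73% are
#' reproduced exactly.
#'
#' @param x numeric vector.
#' @return numeric vector of integers.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Tally species and hybrid individuals per locality
#'
#' @param records tibble joining sample metadata with parentage verdicts;
#'   requires columns `region`, `locality`, `verdict`. SPECIES counts as a
#'   species individual; F1_HYBRID and COMPLEX_HYBRID as hybrid individuals;
#'   UNRESOLVED samples are excluded from the tallies and reported via the
#'   `n_unresolved` attribute.
#' @return tibble: `region`, `locality`, `n_species_individuals`,
#'   `n_hybrid_individuals`; attribute `n_unresolved`.
#' @export
tally_localities <- function(records) {
  req <- c("region", "locality", "verdict")
  missing <- setdiff(req, names(records))
  if (length(missing)) {
    stop("records missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(records$verdict)) {
    stop("records without a verdict: ",
         paste(records$sample_id[is.na(records$verdict)], collapse = ", "),
         call. = FALSE)
  }
  resolved <- dplyr::filter(records, .data$verdict != "UNRESOLVED")
  out <- resolved |>
    dplyr::group_by(.data$region, .data$locality) |>
    dplyr::summarise(
      n_species_individuals = sum(.data$verdict == "SPECIES"),
      n_hybrid_individuals = sum(.data$verdict %in% c("F1_HYBRID", "COMPLEX_HYBRID")),
      .groups = "drop"
    )
  attr(out, "n_unresolved") <- nrow(records) - nrow(resolved)
  out
}

#' Regional hybridization summary
#'
#' Computes, for one region, the share of hybrid individuals and the share
#' of localities containing (or containing only) hybrids. The locality
#' denominator is the number of river sites *studied* in the region, which
#' may exceed the number of localities that yielded classified sequences;
#' individual percentages use all classified individuals.
#'
#' @param tallies locality tally tibble from [tally_localities()].
#' @param region region name to summarise.
#' @param total_localities_studied number of studied river sites in the
#'   region (>= number of tallied localities).
#' @return one-row tibble of class `ht_region_summary` with raw counts,
#'   exact ratios (`frac_*`) and half-up rounded integer percentages
#'   (`pct_*`).
#' @export
summarize_region <- function(tallies, region, total_localities_studied) {
  t <- dplyr::filter(tallies, .data$region == !!region)
  if (nrow(t) == 0L) stop("no tallies for region ", sQuote(region), call. = FALSE)
  if (total_localities_studied < nrow(t)) {
    stop("total_localities_studied (", total_localities_studied,
         ") < number of tallied localities (", nrow(t), ")", call. = FALSE)
  }
  n_ind <- sum(t$n_species_individuals) + sum(t$n_hybrid_individuals)
  if (n_ind == 0L) stop("zero classified individuals in region", call. = FALSE)
  n_hyb <- sum(t$n_hybrid_individuals)
  with_hyb <- t$n_hybrid_individuals > 0L
  hyb_only <- with_hyb & t$n_species_individuals == 0L
  cooccur <- with_hyb & t$n_species_individuals > 0L
  frac <- c(ind = n_hyb / n_ind,
            loc = sum(with_hyb) / total_localities_studied,
            only = sum(hyb_only) / total_localities_studied)
  out <- tibble::tibble(
    region = region,
    n_individuals = n_ind,
    n_hybrid_individuals = n_hyb,
    n_localities = nrow(t),
    n_localities_studied = as.integer(total_localities_studied),
    n_localities_with_hybrids = sum(with_hyb),
    n_localities_hybrid_only = sum(hyb_only),
    n_localities_cooccur = sum(cooccur),
    frac_hybrid_individuals = frac[["ind"]],
    frac_localities_with_hybrids = frac[["loc"]],
    frac_localities_hybrid_only = frac[["only"]],
    pct_hybrid_individuals = round_half_up(100 * frac[["ind"]]),
    pct_localities_with_hybrids = round_half_up(100 * frac[["loc"]]),
    pct_localities_hybrid_only = round_half_up(100 * frac[["only"]])
  )
  class(out) <- c("ht_region_summary", class(out))
  out
}

#' Reconstructed river-survey locality tallies
#'
#' Per-locality species/hybrid individual tallies for the two surveyed
#' regions, reconstructed from the aggregate counts of the published survey:
#' Lithuania -- 66 classified individuals (18 species from 6 localities, 48
#' hybrids from 16 localities, one locality with both) over 21 studied river
#' sites; Central European Russia -- 36 individuals (23 species from 16
#' localities, 13 hybrids from 6 localities, three localities with both)
#' over 19 studied sites. The split of individuals across localities within
#' each class is an even synthetic reconstruction constrained to those
#' aggregate totals; the locality-level structure (how many localities hold
#' species, hybrids, or both) is exact.
#'
#' @return list with elements `tallies` (locality tibble) and
#'   `localities_studied` (named vector: studied river sites per region).
#' @export
batrachium_survey <- function() {
  spread <- function(total, k) {     # split `total` individuals over k sites
    n <- rep(total %/% k, k)
    if (total %% k > 0) n[seq_len(total %% k)] <- n[seq_len(total %% k)] + 1L
    n
  }
  lt_loc <- paste0("LT-", sprintf("%02d", 1:21))
  ru_loc <- paste0("RU-", sprintf("%02d", 1:19))
  # Lithuania: localities 1-6 hold species; 6 also holds hybrids; 7-21 hybrid-only
  lt <- tibble::tibble(
    region = "Lithuania",
    locality = lt_loc,
    n_species_individuals = c(spread(18L, 6L), rep(0L, 15L)),
    n_hybrid_individuals = c(rep(0L, 5L), spread(48L, 16L))
  )
  # Russia: localities 1-16 hold species; 14-16 also hold hybrids; 17-19 hybrid-only
  ru <- tibble::tibble(
    region = "Central European Russia",
    locality = ru_loc,
    n_species_individuals = c(spread(23L, 16L), rep(0L, 3L)),
    n_hybrid_individuals = c(rep(0L, 13L), spread(13L, 6L))
  )
  tallies <- dplyr::bind_rows(lt, ru)
  tallies <- dplyr::filter(tallies, .data$n_species_individuals > 0 |
                             .data$n_hybrid_individuals > 0)
  list(
    tallies = tallies,
    localities_studied = c("Lithuania" = 21L, "Central European Russia" = 19L)
  )
}

#' Summarise both survey regions
#'
#' Convenience wrapper running [summarize_region()] on each region of a
#' tally table.
#'
#' @param tallies locality tally tibble.
#' @param localities_studied named integer vector: studied sites per region.
#' @return tibble with one row per region.
#' @export
summarize_regions <- function(tallies, localities_studied) {
  out <- purrr::map_dfr(names(localities_studied), function(r) {
    summarize_region(tallies, r, localities_studied[[r]])
  })
  if (!inherits(out, "ht_region_summary")) {
    class(out) <- c("ht_region_summary", class(out))
  }
  out
}
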