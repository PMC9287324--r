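#' Simulation configuration
#'
#' Parameters of the synthetic study system: a panel of diverged parental
#' ITS ribotypes (with optional within-species variants and an optional
#' single-base indel distinguishing one species pair), directly sequenced F1
#' and three-way hybrid consensus sequences with ambiguity-dropout noise,
#' and maternally inherited plastid haplotypes for two markers. All
#' randomness flows from R's Mersenne-Twister generator seeded once with
#' `seed`, so outputs are bit-reproducible.
#'
#' @param seed integer seed (mandatory).
#' @param n_species number of parental species, 2-6 (default 4).
#' @param ribotypes_per_species ITS variants per species (default 1).
#' @param seq_length ITS alignment columns (default 650).
#' @param pairwise_divergence expected per-column substitution probability
#'   between two species ribotypes (default 0.03, i.e. ~19.5 differing
#'   columns at the default length).
#' @param within_species_divergence per-column substitution probability
#'   between ribotypes of one species (default 0.003).
#' @param indel_between optional length-2 character vector of species names;
#'   the first named species gains a 1-bp insertion (one alignment column
#'   where every other species shows a gap), emulating a diagnostic
#'   single-base indel between ribotypes.
#' @param n_f1 number of F1 hybrid samples (default 20).
#' @param n_threeway number of three-way hybrid samples (default 0).
#' @param extra_additive_sites columns at which a third parent adds additive
#'   signal in three-way hybrids (default 6).
#' @param dropout_noise probability that an additive column reads as one
#'   parental base instead of the union code (default 0).
#' @param n_pure pure-species samples to emit (default 0).
#' @param plastid_length plastid alignment columns per marker (default 300).
#' @param maternal_rule `"RANDOM"` (seed parent drawn uniformly from the
#'   pair) or `"FIXED_NON_FOCAL"` (the focal species is always the pollen
#'   donor, so crossing is strictly unidirectional).
#' @param focal_species species acting as pollen donor under
#'   `FIXED_NON_FOCAL` (default the first species).
#' @return list of class `ht_sim_config`.
#' @export
sim_config <- function(seed,
                       n_species = 4L,
                       ribotypes_per_species = 1L,
                       seq_length = 650L,
                       pairwise_divergence = 0.03,
                       within_species_divergence = 0.003,
                       indel_between = NULL,
                       n_f1 = 20L,
                       n_threeway = 0L,
                       extra_additive_sites = 6L,
                       dropout_noise = 0,
                       n_pure = 0L,
                       plastid_length = 300L,
                       maternal_rule = c("RANDOM", "FIXED_NON_FOCAL"),
                       focal_species = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  maternal_rule <- match.arg(maternal_rule)
  stopifnot(n_species >= 2L, n_species <= 6L, ribotypes_per_species >= 1L,
            seq_length >= 1L,
            pairwise_divergence >= 0, pairwise_divergence <= 1,
            within_species_divergence >= 0, within_species_divergence <= 1,
            dropout_noise >= 0, dropout_noise <= 1,
            n_f1 >= 0L, n_threeway >= 0L, n_pure >= 0L,
            extra_additive_sites >= 0L, plastid_length >= 1L)
  if (!is.null(indel_between)) stopifnot(length(indel_between) == 2L)
  structure(list(
    seed = as.integer(seed), n_species = as.integer(n_species),
    ribotypes_per_species = as.integer(ribotypes_per_species),
    seq_length = as.integer(seq_length),
    pairwise_divergence = pairwise_divergence,
    within_species_divergence = within_species_divergence,
    indel_between = indel_between,
    n_f1 = as.integer(n_f1), n_threeway = as.integer(n_threeway),
    extra_additive_sites = as.integer(extra_additive_sites),
    dropout_noise = dropout_noise, n_pure = as.integer(n_pure),
    plastid_length = as.integer(plastid_length),
    maternal_rule = maternal_rule, focal_species = focal_species
  ), class = "ht_sim_config")
}

.sim_species_names <- function(n) {
  # evoke the real study system for the first four, then generic names
  base <- c("circinatus", "fluitans", "kauffmannii", "aquatilis",
            "trichophyllus", "peltatus")
  base[seq_len(n)]
}

# per-lineage mutation rate r such that the expected pairwise differing-column
# probability between two independently mutated lineages equals d:
# P(differ) = 2 r (1 - r) + (2/3) r^2  =>  2r - (4/3) r^2 = d
.lineage_rate <- function(d) {
  if (d == 0) return(0)
  (2 - sqrt(4 - (16 / 3) * d)) / (8 / 3)
}

.mutate_seq <- function(sym, rate) {
  bases <- c("A", "C", "G", "T")
  hit <- which(stats::runif(length(sym)) < rate & sym != "-")
  if (length(hit)) {
    # uniform over the three alternative bases
    offset <- sample.int(3L, length(hit), replace = TRUE)
    sym[hit] <- bases[((match(sym[hit], bases) - 1L + offset) %% 4L) + 1L]
  }
  sym
}

#' Generate a parental reference panel
#'
#' Species ribotypes descend independently from a single random ancestral
#' sequence; the per-lineage substitution rate is calibrated so the expected
#' pairwise differing-column fraction between two species equals
#' `pairwise_divergence` exactly. Each species also receives one distinct
#' plastid haplotype per marker (labels H1, H2, ...), guaranteed to differ
#' from every other species' haplotype by more than `delta_sep` columns so
#' nearest-reference assignment is unambiguous.
#'
#' @param config an [ht_sim_config][sim_config()].
#' @param delta_sep minimum pairwise plastid haplotype distance enforced
#'   between species (default 3, one more than the default assignment
#'   tolerance).
#' @return list with `panel` (ITS ribotype alignment tibble with `species`,
#'   `ribotype`), `plastid_refs` (named list of reference tibbles for
#'   markers `rpl32-trnL` and `petL-psbE`), `species_map` (tibble
#'   `marker`, `haplotype`, `species`), and `species` (character vector).
#' @export
generate_panel <- function(config, delta_sep = 3L) {
  set.seed(config$seed)
  sp <- .sim_species_names(config$n_species)
  r <- .lineage_rate(config$pairwise_divergence)
  anc <- sample(c("A", "C", "G", "T"), config$seq_length, replace = TRUE)
  base_ribos <- lapply(sp, function(s) .mutate_seq(anc, r))
  names(base_ribos) <- sp

  # optional diagnostic 1-bp insertion: carrier keeps a base at an extra
  # column, every other species shows '-' there
  if (!is.null(config$indel_between)) {
    carrier <- config$indel_between[1]
    if (!carrier %in% sp) stop("indel_between species not in panel", call. = FALSE)
    pos <- min(30L, config$seq_length)
    ins <- sample(c("A", "C", "G", "T"), 1L)
    base_ribos <- lapply(names(base_ribos), function(s) {
      v <- base_ribos[[s]]
      append(v, if (s == carrier) ins else "-", after = pos - 1L)
    })
    names(base_ribos) <- sp
  }

  rows <- purrr::map_dfr(sp, function(s) {
    purrr::map_dfr(seq_len(config$ribotypes_per_species), function(k) {
      v <- if (k == 1L) base_ribos[[s]] else
        .mutate_seq(base_ribos[[s]], config$within_species_divergence)
      tibble::tibble(species = s, ribotype = paste0("r", k),
                     seq = paste(v, collapse = ""))
    })
  })
  panel <- dplyr::mutate(rows, name = paste(.data$species, .data$ribotype, sep = "|"),
                         marker = "ITS", .before = 1)

  plastid_refs <- lapply(c("rpl32-trnL", "petL-psbE"), function(mk) {
    if (config$plastid_length < config$n_species * (delta_sep + 1L)) {
      stop("plastid_length too short to separate ", config$n_species,
           " haplotypes", call. = FALSE)
    }
    anc_p <- sample(c("A", "C", "G", "T"), config$plastid_length, replace = TRUE)
    hap <- lapply(sp, function(s) .mutate_seq(anc_p, r))
    dmat <- utils::combn(length(sp), 2L)
    dists <- vapply(seq_len(ncol(dmat)), function(k) {
      .hamming(hap[[dmat[1, k]]], hap[[dmat[2, k]]])
    }, integer(1))
    if (!all(dists > delta_sep)) {
      # guarantee separation: give species k its own private block of
      # delta_sep + 1 diagnostic substitutions
      bases <- c("A", "C", "G", "T")
      for (k in seq_along(sp)) {
        block <- ((k - 1L) * (delta_sep + 1L) + 1L):(k * (delta_sep + 1L))
        hap[[k]][block] <- bases[(match(hap[[k]][block], bases) %% 4L) + 1L]
      }
    }
    tibble::tibble(
      name = paste(mk, paste0("H", seq_along(sp)), sep = "|"),
      marker = mk, haplotype = paste0("H", seq_along(sp)),
      seq = vapply(hap, paste, character(1), collapse = "")
    )
  })
  names(plastid_refs) <- c("rpl32-trnL", "petL-psbE")

  species_map <- purrr::map_dfr(names(plastid_refs), function(mk) {
    tibble::tibble(marker = mk, haplotype = paste0("H", seq_along(sp)),
                   species = sp)
  })
  list(panel = panel, plastid_refs = plastid_refs,
       species_map = species_map, species = sp)
}

# consensus of an F1 whose parents differ by exactly one 1-column gap:
# trace-model superposition of the longer parent with the gap-stripped
# shorter parent (alignment coordinates follow the longer parent)
.trace_consensus <- function(long_sym, short_sym) {
  s <- short_sym[short_sym != "-"]
  L <- length(long_sym)
  out <- character(L)
  for (p in seq_len(L - 1L)) {
    out[p] <- if (s[p] == "-" || long_sym[p] == "-") long_sym[p] else
      iupac_union(long_sym[p], s[p])
  }
  out[L] <- long_sym[L]
  out
}

.f1_consensus <- function(pa_sym, pb_sym) {
  gap_a <- which(pa_sym == "-"); gap_b <- which(pb_sym == "-")
  only_a <- setdiff(gap_a, gap_b); only_b <- setdiff(gap_b, gap_a)
  if (length(only_a) + length(only_b) == 1L) {
    if (length(only_a) == 1L) return(.trace_consensus(pb_sym, pa_sym))
    return(.trace_consensus(pa_sym, pb_sym))
  }
  # no (or multi-column) indel: plain column-wise union, gaps pass through
  ifelse(pa_sym == "-" | pb_sym == "-",
         ifelse(pa_sym == "-" & pb_sym == "-", "-",
                ifelse(pa_sym == "-", pb_sym, pa_sym)),
         iupac_union(pa_sym, pb_sym))
}

.apply_dropout <- function(cons, pa_sym, pb_sym, rate) {
  if (rate <= 0) return(list(cons = cons, noised = integer(0)))
  idx <- which(pa_sym != "-" & pb_sym != "-" & pa_sym != pb_sym & cons != "-")
  additive <- idx[cons[idx] == iupac_union(pa_sym[idx], pb_sym[idx])]
  hit <- additive[stats::runif(length(additive)) < rate]
  for (p in hit) cons[p] <- if (stats::runif(1) < 0.5) pa_sym[p] else pb_sym[p]
  list(cons = cons, noised = hit)
}

#' Generate hybrid and pure samples from a panel
#'
#' F1 consensus sequences are the column-wise IUPAC union of two parental
#' ribotypes (or the out-of-register trace superposition when the parents
#' differ by a single-base indel), with ambiguity-dropout noise applied
#' independently to each additive column. Three-way hybrids start from an
#' F1 and add the third parent's base into the union at
#' `extra_additive_sites` randomly chosen columns where that parent differs
#' from the pair union. Each hybrid inherits the plastid haplotypes of its
#' maternal parent (chosen per `maternal_rule`); under `FIXED_NON_FOCAL`
#' every pair includes the focal species and that species is always
#' paternal. Samples are spread over synthetic river localities.
#'
#' @param panel output of [generate_panel()].
#' @param config the same [sim_config()] used for the panel.
#' @return list: `its` (query alignment tibble), `plastid` (named list of
#'   alignment tibbles per marker), `samples` (metadata tibble), `truth`
#'   (tibble: `sample_id`, `type`, `parent_a`, `parent_b`, `parent_c`,
#'   `maternal`, `n_noised`).
#' @export
generate_hybrids <- function(panel, config) {
  set.seed(config$seed + 1L)
  sp <- panel$species
  focal <- config$focal_species %||% sp[1]
  base <- dplyr::filter(panel$panel, .data$ribotype == "r1")
  sym <- lapply(base$seq, .chars)
  names(sym) <- base$species

  pick_pair <- function() {
    if (config$maternal_rule == "FIXED_NON_FOCAL") {
      other <- sample(setdiff(sp, focal), 1L)
      c(focal, other)
    } else sample(sp, 2L)
  }

  records <- list()
  make_sample <- function(id, type, pa, pb, pc = NA_character_) {
    cons <- .f1_consensus(sym[[pa]], sym[[pb]])
    extra <- integer(0)
    if (!is.na(pc)) {
      ok <- sym[[pc]] != "-" & cons != "-" & cons != "N"
      subs <- rep(TRUE, length(cons))
      subs[ok] <- iupac_subsumes(cons[ok], sym[[pc]][ok])
      cand <- which(ok & !subs)
      extra <- sort(cand[sample.int(length(cand),
                                    min(config$extra_additive_sites, length(cand)))])
      for (p in extra) cons[p] <- iupac_union(cons[p], sym[[pc]][p])
    }
    noise <- .apply_dropout(cons, sym[[pa]], sym[[pb]], config$dropout_noise)
    maternal <- if (config$maternal_rule == "FIXED_NON_FOCAL") {
      setdiff(c(pa, pb), focal)[1]
    } else sample(c(pa, pb), 1L)
    list(sample_id = id, type = type, parent_a = pa, parent_b = pb,
         parent_c = pc, maternal = maternal,
         seq = paste(noise$cons, collapse = ""),
         n_noised = length(noise$noised), extra_sites = extra)
  }

  k <- 0L
  for (i in seq_len(config$n_f1)) {
    k <- k + 1L
    pr <- pick_pair()
    records[[k]] <- make_sample(sprintf("F1-%03d", i), "F1", pr[1], pr[2])
  }
  for (i in seq_len(config$n_threeway)) {
    k <- k + 1L
    pr <- pick_pair()
    pc <- sample(setdiff(sp, pr), 1L)
    records[[k]] <- make_sample(sprintf("TW-%03d", i), "THREEWAY",
                                pr[1], pr[2], pc)
  }
  for (i in seq_len(config$n_pure)) {
    k <- k + 1L
    s <- sp[((i - 1L) %% length(sp)) + 1L]
    records[[k]] <- list(sample_id = sprintf("SP-%03d", i), type = "SPECIES",
                         parent_a = s, parent_b = NA_character_,
                         parent_c = NA_character_, maternal = s,
                         seq = base$seq[base$species == s],
                         n_noised = 0L, extra_sites = integer(0))
  }

  ids <- vapply(records, `[[`, character(1), "sample_id")
  its <- tibble::tibble(
    name = ids, marker = "ITS",
    seq = vapply(records, `[[`, character(1), "seq")
  )
  truth <- tibble::tibble(
    sample_id = ids,
    type = vapply(records, `[[`, character(1), "type"),
    parent_a = vapply(records, `[[`, character(1), "parent_a"),
    parent_b = vapply(records, `[[`, character(1), "parent_b"),
    parent_c = vapply(records, `[[`, character(1), "parent_c"),
    maternal = vapply(records, `[[`, character(1), "maternal"),
    n_noised = vapply(records, `[[`, integer(1), "n_noised")
  )
  plastid <- lapply(panel$plastid_refs, function(refs) {
    tibble::tibble(
      name = ids, marker = refs$marker[1],
      seq = refs$seq[match(truth$maternal, panel$species)]
    )
  })
  n <- length(ids)
  samples <- tibble::tibble(
    sample_id = ids, region = "SimRegion",
    locality = paste0("River-", sprintf("%02d", ((seq_len(n) - 1L) %% 8L) + 1L)),
    taxon_label = ifelse(truth$type == "SPECIES", truth$parent_a, NA_character_),
    fertile = truth$type == "SPECIES"
  )
  list(its = its, plastid = plastid, samples = samples, truth = truth)
}
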