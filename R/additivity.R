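#' Analysis configuration
#'
#' Thresholds governing verdicts, all expressed in alignment columns unless
#' noted. Defaults reflect the tolerance of within-species ribotype variation
#' observed in direct ITS sequencing (named ribotypes of one species commonly
#' differ by 1-2 substitutions).
#'
#' @param tau_species maximum mismatching non-gap columns between a query and
#'   a single panel ribotype for a pure-species call (default 2).
#' @param tau_residual maximum unexplained polymorphic columns tolerated in an
#'   F1 call; more residuals escalate the verdict to complex hybrid
#'   (default 2).
#' @param tau_noise tolerated fraction of testable downstream columns that may
#'   fail the indel-superposition test while the shift is still called
#'   consistent (default 0.05).
#' @param delta_max maximum mismatch count for assigning a plastid haplotype
#'   to its nearest reference (default 2).
#' @param focal_pollen_donor species name used as the focal paternal species
#'   by [directionality()] (default "circinatus").
#' @return a list of class `ht_config`.
#' @export
ht_config <- function(tau_species = 2L, tau_residual = 2L, tau_noise = 0.05,
                      delta_max = 2L, focal_pollen_donor = "circinatus") {
  stopifnot(tau_species >= 0, tau_residual >= 0,
            tau_noise >= 0, tau_noise <= 1, delta_max >= 0)
  structure(list(tau_species = as.integer(tau_species),
                 tau_residual = as.integer(tau_residual),
                 tau_noise = tau_noise,
                 delta_max = as.integer(delta_max),
                 focal_pollen_donor = focal_pollen_donor),
            class = "ht_config")
}

# symbol vector -> integer mask; gap -> 0, N -> NA (uninformative)
.mask_vec <- function(s) {
  sym <- .chars(.normalize_symbol(s))
  m <- unname(.iupac_mask[sym])
  m[sym == "-"] <- 0L
  bad <- is.na(m) & sym != "N"
  if (any(bad)) {
    stop(sprintf("illegal symbol %s at column %d", sQuote(sym[which(bad)[1]]),
                 which(bad)[1]), call. = FALSE)
  }
  m[sym == "N"] <- NA_integer_
  m
}

.site_labels <- c("INVARIANT", "PARENT_A", "PARENT_B", "ADDITIVE",
                  "RESIDUAL", "GAPPED")

# vectorised label codes (indices into .site_labels) from mask vectors
.classify_masks <- function(mq, ma, mb) {
  gapped <- is.na(mq) | is.na(ma) | is.na(mb) | mq == 0L | ma == 0L | mb == 0L
  un <- bitwOr(pmax(ma, 0L), pmax(mb, 0L))
  lab <- rep(5L, length(mq))                       # RESIDUAL
  same <- !gapped & ma == mb
  lab[same & mq == ma] <- 1L                       # INVARIANT
  diffp <- !gapped & ma != mb
  lab[diffp & mq == ma] <- 2L                      # PARENT_A
  lab[diffp & mq == mb] <- 3L                      # PARENT_B
  lab[diffp & mq != ma & mq != mb & mq == un] <- 4L  # ADDITIVE
  lab[gapped] <- 6L                                # GAPPED
  lab
}

# mask-level pair scoring; qs/as_/bs (symbol vectors) are needed only when the
# parents differ by a single 1-column gap and the shift model is attempted
.score_masks <- function(mq, ma, mb, qs, as_, bs, config) {
  lab <- .classify_masks(mq, ma, mb)
  tab <- tabulate(lab, nbins = 6L)
  residual_pos <- which(lab == 5L)
  additive_pos <- which(lab == 4L)
  indel <- list(applicable = FALSE, indel_position = NA_integer_,
                shift_consistent = NA, n_shift_explained = NA_integer_)
  shift_pos <- integer(0)
  if (sum(ma == 0L, na.rm = TRUE) + sum(mb == 0L, na.rm = TRUE) == 1L) {
    res <- tryCatch(
      shifted_superposition(paste(qs, collapse = ""),
                            paste(as_, collapse = ""),
                            paste(bs, collapse = ""),
                            tau_noise = config$tau_noise),
      error = function(e) list(applicable = FALSE))
    if (res$applicable) {
      indel <- list(applicable = TRUE, indel_position = res$indel_position,
                    shift_consistent = res$shift_consistent,
                    n_shift_explained = res$n_shift_explained)
      if (isTRUE(res$shift_consistent)) {
        shift_pos <- intersect(residual_pos, res$shift_positions[[1]])
        residual_pos <- setdiff(residual_pos, shift_pos)
      }
    }
  }
  list(n_additive = tab[4], n_parent_a = tab[2], n_parent_b = tab[3],
       n_parent_only = tab[2] + tab[3], n_residual = length(residual_pos),
       n_shift = length(shift_pos), n_invariant = tab[1], n_gapped = tab[6],
       additive_positions = additive_pos, residual_positions = residual_pos,
       indel = indel)
}

#' Classify alignment columns of a query against a candidate parent pair
#'
#' Each column of a directly sequenced query is compared with the same column
#' of two candidate parental ribotypes. A column is ADDITIVE when the parents
#' differ and the query shows exactly the IUPAC union of their symbols -- the
#' signature of both parental ITS copies superposed in one chromatogram.
#' A query matching just one parent at a differing column is PARENT_A /
#' PARENT_B (ambiguity dropout, common in real traces, is therefore not an
#' error). Columns where any comparand is a gap, or where the query reads N,
#' carry no additive evidence and are GAPPED. Everything else unexplained is
#' RESIDUAL.
#'
#' When the query matches one parent whose code already contains the other
#' parent's bases (possible only if a parent itself carries an ambiguity
#' code), the PARENT label takes precedence over ADDITIVE.
#'
#' @param query,parent_a,parent_b aligned sequence strings of equal length.
#' @return a tibble with one row per column: `position` (1-based), `label`,
#'   `observed`, `parent_a`, `parent_b`.
#' @export
classify_sites <- function(query, parent_a, parent_b) {
  if (length(unique(nchar(c(query, parent_a, parent_b)))) != 1L) {
    stop("query and parents must have equal aligned length", call. = FALSE)
  }
  mq <- .mask_vec(query); ma <- .mask_vec(parent_a); mb <- .mask_vec(parent_b)
  lab <- .classify_masks(mq, ma, mb)
  tibble::tibble(
    position = seq_along(mq),
    label = factor(.site_labels[lab], levels = .site_labels),
    observed = .chars(.normalize_symbol(query)),
    parent_a = .chars(.normalize_symbol(parent_a)),
    parent_b = .chars(.normalize_symbol(parent_b))
  )
}

#' Test the single-base indel superposition ("shift") pattern
#'
#' When two parental ribotypes differ by a 1-bp indel, the two reads in a
#' hybrid chromatogram run out of register downstream of the indel: at read
#' position p the trace superposes the longer parent's base at p with the
#' shorter parent's base at p, i.e. (in alignment coordinates, which follow
#' the longer parent) `union(parent_long[p], parent_short[p + 1])`. This
#' function locates the single 1-column gap, rebuilds that offset
#' superposition, and counts the downstream columns the query explains.
#'
#' @param query aligned query string (no gap at the indel column).
#' @param parent_a,parent_b aligned parental strings; exactly one must carry
#'   exactly one 1-column gap relative to the other. Order does not matter.
#' @param tau_noise tolerated fraction of unexplained testable columns.
#' @return one-row tibble: `applicable`, `indel_position`, `shift_consistent`,
#'   `n_shift_explained`, `n_testable`, `shift_positions` (list column of
#'   explained downstream positions). When the pair does not present exactly
#'   one single-column gap, `applicable` is `FALSE` and the remaining fields
#'   are `NA` (callers fall back to plain [classify_sites()]).
#' @export
shifted_superposition <- function(query, parent_a, parent_b,
                                  tau_noise = 0.05) {
  qs <- .chars(.normalize_symbol(query))
  as_ <- .chars(.normalize_symbol(parent_a))
  bs <- .chars(.normalize_symbol(parent_b))
  stopifnot(length(qs) == length(as_), length(qs) == length(bs))
  gaps_a <- which(as_ == "-"); gaps_b <- which(bs == "-")
  na_result <- tibble::tibble(
    applicable = FALSE, indel_position = NA_integer_,
    shift_consistent = NA, n_shift_explained = NA_integer_,
    n_testable = NA_integer_, shift_positions = list(integer())
  )
  one_gap <- (length(gaps_a) == 1L && length(gaps_b) == 0L) ||
    (length(gaps_b) == 1L && length(gaps_a) == 0L)
  if (!one_gap) return(na_result)
  if (length(gaps_a) == 1L) { short <- as_; long <- bs; g <- gaps_a } else {
    short <- bs; long <- as_; g <- gaps_b
  }
  if (qs[g] == "-") {
    stop("query has a gap at the indel column; superposition undefined",
         call. = FALSE)
  }
  L <- length(qs)
  s <- short[short != "-"]            # ungapped short parent, length L - 1
  testable <- integer(0); explained <- integer(0)
  downstream <- if (g <= L - 1L) seq(g, L - 1L) else integer(0)
  for (p in downstream) {
    trio <- c(qs[p], long[p], s[p])
    if (any(trio %in% c("-", "N"))) next
    testable <- c(testable, p)
    if (iupac_subsumes(qs[p], iupac_union(long[p], s[p]))) {
      explained <- c(explained, p)
    }
  }
  consistent <- length(testable) > 0L &&
    length(explained) >= (1 - tau_noise) * length(testable)
  tibble::tibble(
    applicable = TRUE, indel_position = g,
    shift_consistent = consistent,
    n_shift_explained = length(explained), n_testable = length(testable),
    shift_positions = list(explained)
  )
}

#' Score a candidate parent pair for one query
#'
#' Runs [classify_sites()] and tallies labels into the counts used to rank
#' parent pairs. If the two parents differ by exactly one 1-column gap, the
#' single-base indel superposition is also tested; when the shift is
#' consistent, downstream RESIDUAL columns it explains are moved out of the
#' residual count into `n_shift` (they are consequences of the register
#' shift, not independent unexplained sites).
#'
#' Symmetric in the two parents up to swapping the PARENT_A / PARENT_B
#' counts.
#'
#' @inheritParams shifted_superposition
#' @param config an [ht_config()].
#' @return one-row tibble with counts `n_additive`, `n_parent_a`,
#'   `n_parent_b`, `n_parent_only`, `n_residual`, `n_shift`, `n_invariant`,
#'   `n_gapped` (summing to the alignment length), list columns
#'   `additive_positions`, `residual_positions`, and the indel fields of
#'   [shifted_superposition()].
#' @export
score_pair <- function(query, parent_a, parent_b, config = ht_config()) {
  if (length(unique(nchar(c(query, parent_a, parent_b)))) != 1L) {
    stop("query and parents must have equal aligned length", call. = FALSE)
  }
  qs <- .chars(.normalize_symbol(query))
  as_ <- .chars(.normalize_symbol(parent_a))
  bs <- .chars(.normalize_symbol(parent_b))
  sc <- .score_masks(.mask_vec(query), .mask_vec(parent_a), .mask_vec(parent_b),
                     qs, as_, bs, config)
  tibble::tibble(
    n_additive = sc$n_additive,
    n_parent_a = sc$n_parent_a,
    n_parent_b = sc$n_parent_b,
    n_parent_only = sc$n_parent_only,
    n_residual = sc$n_residual,
    n_shift = sc$n_shift,
    n_invariant = sc$n_invariant,
    n_gapped = sc$n_gapped,
    additive_positions = list(sc$additive_positions),
    residual_positions = list(sc$residual_positions),
    indel_applicable = sc$indel$applicable,
    indel_position = sc$indel$indel_position,
    shift_consistent = sc$indel$shift_consistent,
    n_shift_explained = sc$indel$n_shift_explained
  )
}

# mismatch count over columns where both symbols are informative (no gap, no N)
.hamming <- function(sa, sb) {
  ok <- !(sa %in% c("-", "N")) & !(sb %in% c("-", "N"))
  sum(sa[ok] != sb[ok])
}

# residual positions of a pair that a third ribotype explains:
# the query's bases are contained in the three-way parental union
.explained_by_third <- function(qs, as_, bs, cs, positions) {
  keep <- integer(0)
  for (p in positions) {
    trio <- c(qs[p], as_[p], bs[p], cs[p])
    if (any(trio %in% c("-", "N"))) next
    u3 <- iupac_union(iupac_union(as_[p], bs[p]), cs[p])
    if (iupac_subsumes(u3, qs[p])) keep <- c(keep, p)
  }
  keep
}

#' Infer the parentage of each query sequence
#'
#' The per-sample decision procedure:
#' \enumerate{
#'   \item \strong{Species check}: the query is compared with every panel
#'     ribotype by mismatch count over informative columns; if the nearest
#'     ribotype is within `tau_species`, the sample is that SPECIES.
#'   \item \strong{Pair search}: otherwise every ribotype pair whose species
#'     differ is scored with [score_pair()]; per species pair the
#'     best-scoring ribotype combination is kept (hybrids carry the ITS
#'     copies of their local parental populations, so the representative
#'     ribotypes are chosen freely). Pairs rank by fewest residuals, then
#'     most additive sites, then fewest one-parent-only sites, then
#'     alphabetically -- deterministic throughout.
#'   \item \strong{Verdict}: the best pair is an F1_HYBRID when its residual
#'     count is within `tau_residual`; otherwise a COMPLEX_HYBRID, and every
#'     panel ribotype from a third species is ranked by how many residual
#'     columns it explains as an additional contributor (query bases
#'     contained in the three-way union). A query with no additive evidence
#'     for any pair is UNRESOLVED.
#' }
#'
#' @param queries alignment tibble of query sequences (columns `name`,
#'   `seq`), aligned to the panel.
#' @param panel ribotype panel tibble ([read_ribotype_panel()];
#'   columns `species`, `ribotype`, `seq`).
#' @param config an [ht_config()].
#' @return a tibble of class `ht_parentage` with one row per query:
#'   `sample_id`, `verdict` (SPECIES / F1_HYBRID / COMPLEX_HYBRID /
#'   UNRESOLVED), `species_match`, `species_distance`, `parent_a`,
#'   `parent_b`, `ribotype_a`, `ribotype_b`, the [score_pair()] counts,
#'   `residual_positions` and `additive_positions` (list columns),
#'   `third_parent`, `third_parent_explained`, and
#'   `third_parent_candidates` (list column of per-candidate tibbles).
#' @export
infer_parentage <- function(queries, panel, config = ht_config()) {
  stopifnot(nrow(panel) >= 2L)
  if (length(unique(panel$species)) < 2L) {
    stop("panel must contain ribotypes of at least two species", call. = FALSE)
  }
  L <- alignment_length(panel)
  if (alignment_length(queries) != L) {
    stop("queries are not aligned to the panel (length mismatch)",
         call. = FALSE)
  }
  panel_chars <- lapply(panel$seq, function(s) .chars(.normalize_symbol(s)))
  panel_masks <- lapply(panel$seq, .mask_vec)
  # cross-species ribotype pairs, each ordered alphabetically by species
  idx <- utils::combn(nrow(panel), 2L)
  keep <- panel$species[idx[1, ]] != panel$species[idx[2, ]]
  idx <- idx[, keep, drop = FALSE]
  if (ncol(idx) > 0L) {
    swap <- panel$species[idx[1, ]] > panel$species[idx[2, ]]
    idx[, swap] <- idx[2:1, swap]
  }
  calls <- purrr::map2(queries$name, queries$seq, function(id, qseq) {
    .infer_one(id, qseq, panel, panel_chars, panel_masks, idx, config)
  })
  out <- dplyr::bind_rows(calls)
  class(out) <- c("ht_parentage", class(out))
  out
}

.empty_call <- function(id) {
  tibble::tibble(
    sample_id = id, verdict = NA_character_,
    species_match = NA_character_, species_distance = NA_integer_,
    parent_a = NA_character_, parent_b = NA_character_,
    ribotype_a = NA_character_, ribotype_b = NA_character_,
    n_additive = NA_integer_, n_parent_only = NA_integer_,
    n_residual = NA_integer_, n_shift = NA_integer_,
    n_invariant = NA_integer_, n_gapped = NA_integer_,
    indel_position = NA_integer_, shift_consistent = NA,
    additive_positions = list(integer()), residual_positions = list(integer()),
    third_parent = NA_character_, third_parent_explained = NA_integer_,
    third_parent_candidates = list(tibble::tibble())
  )
}

.infer_one <- function(id, qseq, panel, panel_chars, panel_masks, idx, config) {
  call <- .empty_call(id)
  qs <- .chars(.normalize_symbol(qseq))
  mq <- .mask_vec(qseq)

  # (i) nearest single ribotype
  dists <- vapply(panel_chars, function(pc) .hamming(qs, pc), integer(1))
  ord <- order(dists, panel$species, panel$ribotype)
  best <- ord[1]
  call$species_match <- panel$species[best]
  call$species_distance <- dists[best]
  if (dists[best] <= config$tau_species) {
    call$verdict <- "SPECIES"
    return(call)
  }

  # (ii) best ribotype combination per species pair
  if (ncol(idx) == 0L) {
    call$verdict <- "UNRESOLVED"
    return(call)
  }
  scores <- lapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    sc <- .score_masks(mq, panel_masks[[i]], panel_masks[[j]],
                       qs, panel_chars[[i]], panel_chars[[j]], config)
    sc$i <- i; sc$j <- j
    sc
  })
  n_res <- vapply(scores, `[[`, numeric(1), "n_residual")
  n_add <- vapply(scores, `[[`, numeric(1), "n_additive")
  n_po <- vapply(scores, `[[`, numeric(1), "n_parent_only")
  ord <- order(n_res, -n_add, n_po,
               panel$species[idx[1, ]], panel$species[idx[2, ]],
               panel$ribotype[idx[1, ]], panel$ribotype[idx[2, ]])
  top <- scores[[ord[1]]]
  if (max(n_add) < 1L) {
    call$verdict <- "UNRESOLVED"
    return(call)
  }
  call$parent_a <- panel$species[top$i]
  call$parent_b <- panel$species[top$j]
  call$ribotype_a <- panel$ribotype[top$i]
  call$ribotype_b <- panel$ribotype[top$j]
  for (f in c("n_additive", "n_parent_only", "n_residual", "n_shift",
              "n_invariant", "n_gapped")) call[[f]] <- top[[f]]
  call$indel_position <- top$indel$indel_position
  call$shift_consistent <- top$indel$shift_consistent
  call$additive_positions <- list(top$additive_positions)
  call$residual_positions <- list(top$residual_positions)

  if (top$n_residual <= config$tau_residual) {
    call$verdict <- "F1_HYBRID"
    return(call)
  }

  # (iii) complex hybrid: rank third-parent candidates by residuals explained
  call$verdict <- "COMPLEX_HYBRID"
  res_pos <- top$residual_positions
  third <- which(!(panel$species %in% c(call$parent_a, call$parent_b)))
  if (length(third) > 0L && length(res_pos) > 0L) {
    cand <- purrr::map_dfr(third, function(k) {
      expl <- .explained_by_third(qs, panel_chars[[top$i]], panel_chars[[top$j]],
                                  panel_chars[[k]], res_pos)
      tibble::tibble(species = panel$species[k], ribotype = panel$ribotype[k],
                     n_explained = length(expl))
    })
    cand <- dplyr::arrange(cand, dplyr::desc(.data$n_explained),
                           .data$species, .data$ribotype)
    # one row per candidate species: its best ribotype
    cand <- dplyr::distinct(cand, .data$species, .keep_all = TRUE)
    call$third_parent_candidates <- list(cand)
    if (nrow(cand) > 0L && cand$n_explained[1] > 0L) {
      call$third_parent <- cand$species[1]
      call$third_parent_explained <- cand$n_explained[1]
    }
  }
  call
}

#' Additive positions shared by every member of a sample group
#'
#' Hybrid populations are often described by the additive sites *constant*
#' across all sampled individuals, as opposed to sites additive in only some
#' samples (ambiguity dropout, local ribotype variation). This intersects
#' per-sample additive position sets against a fixed parent pair.
#'
#' @param queries alignment tibble (one row per group member) or character
#'   vector of aligned sequences.
#' @param parent_a,parent_b aligned parental sequences.
#' @return integer vector of 1-based positions additive in every query.
#' @export
constant_additive_positions <- function(queries, parent_a, parent_b) {
  seqs <- if (is.data.frame(queries)) queries$seq else as.character(queries)
  if (length(seqs) == 0L) stop("empty sample group", call. = FALSE)
  sets <- lapply(seqs, function(q) {
    sites <- classify_sites(q, parent_a, parent_b)
    sites$position[sites$label == "ADDITIVE"]
  })
  Reduce(intersect, sets)
}
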