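#' End-to-end survey analysis on in-memory tables
#'
#' Chains the three analysis stages: ITS parentage inference
#' ([infer_parentage()]), plastid haplotype assignment and cross orientation
#' ([assign_haplotypes()], [orient_crosses()]), and regional summaries
#' ([tally_localities()], [summarize_region()]). Samples lacking a plastid
#' sequence are still classified and reported UNORIENTED.
#'
#' @param its query ITS alignment tibble (`name`, `seq`).
#' @param plastid named list of plastid query alignment tibbles, one per
#'   marker (names are marker labels); may be empty.
#' @param samples sample metadata tibble ([read_samples()]); `name`s of
#'   `its` must appear in `sample_id`.
#' @param panel ITS ribotype panel tibble ([read_ribotype_panel()]).
#' @param plastid_refs named list of haplotype reference tibbles per marker.
#' @param species_map tibble (`marker`, `haplotype`, `species`).
#' @param config an [ht_config()].
#' @param localities_studied optional named vector of studied river sites
#'   per region; defaults to the number of distinct localities with
#'   classified samples in each region.
#' @return list of class `ht_survey`: `calls`, `haplotypes`, `crosses`,
#'   `directionality`, `tallies`, `regions`.
#' @export
analyze_survey <- function(its, plastid = list(), samples, panel,
                           plastid_refs = list(),
                           species_map = batrachium_species_map(),
                           config = ht_config(),
                           localities_studied = NULL) {
  missing_meta <- setdiff(its$name, samples$sample_id)
  if (length(missing_meta)) {
    stop("ITS sequences without sample metadata: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  calls <- infer_parentage(its, panel, config)

  haps <- purrr::map_dfr(names(plastid), function(mk) {
    refs <- plastid_refs[[mk]]
    if (is.null(refs)) stop("no references for plastid marker ", mk, call. = FALSE)
    assign_haplotypes(plastid[[mk]], refs, delta_max = config$delta_max)
  })
  if (nrow(haps) == 0L) {
    haps <- tibble::tibble(sample_id = character(), marker = character(),
                           haplotype = character(), distance = integer(),
                           deviant = logical(), tie = logical())
  }

  is_hybrid <- calls$verdict %in% c("F1_HYBRID", "COMPLEX_HYBRID")
  crosses <- if (any(is_hybrid)) {
    orient_crosses(calls, haps, species_map)
  } else tibble::tibble(sample_id = character(), maternal = character(),
                        paternal = character(), basis = character(),
                        confidence = character())
  direction <- if (any(crosses$confidence == "ORIENTED")) {
    directionality(crosses, config$focal_pollen_donor)
  } else NULL

  records <- dplyr::left_join(samples, calls[c("sample_id", "verdict")],
                              by = "sample_id")
  records <- dplyr::filter(records, !is.na(.data$verdict))
  tallies <- tally_localities(records)
  if (is.null(localities_studied)) {
    localities_studied <- table(unique(tallies[c("region", "locality")])$region)
    localities_studied <- stats::setNames(as.integer(localities_studied),
                                          names(localities_studied))
  }
  regions <- summarize_regions(tallies, localities_studied)
  structure(list(calls = calls, haplotypes = haps, crosses = crosses,
                 directionality = direction, tallies = tallies,
                 regions = regions),
            class = "ht_survey")
}

#' @export
print.ht_survey <- function(x, ...) {
  cat("hybridtrace survey analysis\n")
  cat("  samples classified:", nrow(x$calls), "\n")
  v <- table(x$calls$verdict)
  cat("  verdicts:", paste(names(v), v, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$directionality)) {
    cat(sprintf("  directionality: %.2f of %d oriented crosses have %s paternal\n",
                x$directionality$fraction_paternal,
                x$directionality$n_oriented, x$directionality$focal_species))
  }
  for (i in seq_len(nrow(x$regions))) {
    r <- x$regions[i, ]
    cat(sprintf("  %s: %d%% hybrid individuals, %d%% localities with hybrids, %d%% hybrid-only\n",
                r$region, r$pct_hybrid_individuals,
                r$pct_localities_with_hybrids, r$pct_localities_hybrid_only))
  }
  invisible(x)
}

# flatten list columns for TSV export
.format_calls_tsv <- function(calls) {
  dplyr::mutate(
    calls,
    residual_positions = vapply(.data$residual_positions, paste,
                                character(1), collapse = ","),
    additive_positions = vapply(.data$additive_positions, paste,
                                character(1), collapse = ","),
    third_parent_candidates = vapply(.data$third_parent_candidates, function(tb) {
      if (!nrow(tb)) "" else
        paste(sprintf("%s:%d", tb$species, tb$n_explained), collapse = ";")
    }, character(1))
  )
}

#' Run the full pipeline from files and write the result bundle
#'
#' File-based front end over [analyze_survey()]: reads the aligned FASTA
#' inputs, the metadata TSV and the reference panels, and writes
#' `parentage.tsv`, `crosses.tsv`, `haplotypes.tsv`, `region_summary.tsv`
#' and `run_log.txt` into `out_dir`. Re-running on identical inputs and
#' configuration reproduces the TSVs byte-identically (timestamps are
#' confined to the log). On any validation failure partial outputs are
#' removed before the error propagates.
#'
#' @param its_path aligned ITS FASTA of query samples.
#' @param plastid_paths named character vector of aligned plastid FASTA
#'   paths (names are marker labels), or NULL.
#' @param samples_path sample metadata TSV.
#' @param panel_path ribotype panel FASTA (`species|ribotype` headers).
#' @param refs_path haplotype reference FASTA (`marker|label` headers), or
#'   NULL when no plastid data is supplied.
#' @param species_map_path optional species map TSV; default map used when
#'   NULL.
#' @param out_dir output directory (created if needed).
#' @param config an [ht_config()].
#' @param localities_studied optional named vector per region.
#' @return the [analyze_survey()] result bundle, invisibly.
#' @export
run_pipeline <- function(its_path, plastid_paths = NULL, samples_path,
                         panel_path, refs_path = NULL,
                         species_map_path = NULL, out_dir,
                         config = ht_config(), localities_studied = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- file.path(out_dir, c("parentage.tsv", "crosses.tsv",
                                  "haplotypes.tsv", "region_summary.tsv",
                                  "run_log.txt"))
  on_fail <- function(e) { unlink(outputs); stop(e) }
  res <- tryCatch({
    its <- read_alignment(its_path, marker = "ITS")
    samples <- read_samples(samples_path)
    panel <- read_ribotype_panel(panel_path)
    plastid <- list(); plastid_refs <- list()
    if (!is.null(plastid_paths)) {
      refs_all <- read_haplotype_refs(refs_path)
      for (mk in names(plastid_paths)) {
        plastid[[mk]] <- read_alignment(plastid_paths[[mk]], marker = mk)
        plastid_refs[[mk]] <- dplyr::filter(refs_all, .data$marker == mk)
      }
    }
    species_map <- if (is.null(species_map_path)) batrachium_species_map() else
      read_species_map(species_map_path)
    analyze_survey(its, plastid, samples, panel, plastid_refs, species_map,
                   config, localities_studied)
  }, error = on_fail)

  readr::write_tsv(.format_calls_tsv(res$calls), outputs[1])
  readr::write_tsv(res$crosses, outputs[2])
  readr::write_tsv(res$haplotypes, outputs[3])
  readr::write_tsv(res$regions, outputs[4])
  writeLines(c(
    paste("hybridtrace", as.character(utils::packageVersion("hybridtrace"))),
    paste("run at:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste("tau_species:", config$tau_species),
    paste("tau_residual:", config$tau_residual),
    paste("tau_noise:", config$tau_noise),
    paste("delta_max:", config$delta_max),
    paste("focal_pollen_donor:", config$focal_pollen_donor)
  ), outputs[5])
  invisible(res)
}

#' Write the synthetic bundle of [generate_hybrids()] to a directory
#'
#' Emits `its.fasta`, one FASTA per plastid marker, `samples.tsv`,
#' `truth.tsv`, `panel.fasta`, `plastid_refs.fasta` and `species_map.tsv`,
#' all plain text; the same seed yields byte-identical files.
#'
#' @param panel output of [generate_panel()].
#' @param bundle output of [generate_hybrids()].
#' @param out_dir output directory.
#' @return named character vector of written paths, invisibly.
#' @export
write_sim_bundle <- function(panel, bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    its = file.path(out_dir, "its.fasta"),
    rpl32 = file.path(out_dir, "rpl32.fasta"),
    petl = file.path(out_dir, "petl.fasta"),
    samples = file.path(out_dir, "samples.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    panel = file.path(out_dir, "panel.fasta"),
    refs = file.path(out_dir, "plastid_refs.fasta"),
    species_map = file.path(out_dir, "species_map.tsv")
  )
  write_alignment(bundle$its, paths[["its"]])
  write_alignment(bundle$plastid[["rpl32-trnL"]], paths[["rpl32"]])
  write_alignment(bundle$plastid[["petL-psbE"]], paths[["petl"]])
  readr::write_tsv(bundle$samples, paths[["samples"]])
  readr::write_tsv(bundle$truth, paths[["truth"]])
  write_alignment(panel$panel, paths[["panel"]])
  refs <- dplyr::bind_rows(panel$plastid_refs)
  write_alignment(refs, paths[["refs"]])
  readr::write_tsv(panel$species_map, paths[["species_map"]])
  invisible(paths)
}
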