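make_refs <- function(marker = "rpl32-trnL") {
  set.seed(41)
  d <- random_seq(120)
  mut <- function(s, k) {
    chars <- strsplit(s, "")[[1]]
    for (p in sample(length(chars), k))
      chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
    paste(chars, collapse = "")
  }
  tibble::tibble(
    name = paste(marker, c("A", "C", "D", "I"), sep = "|"),
    marker = marker,
    haplotype = c("A", "C", "D", "I"),
    seq = c(d, mut(d, 8), mut(d, 16), mut(d, 24))
  )
}

test_that("haplotype assignment matches the Hamming oracle and flags deviants", {
  refs <- make_refs()
  # identical to reference D
  q <- aligned_matrix("s1", refs$seq[refs$haplotype == "D"])
  asn <- assign_haplotypes(q, refs)
  expect_identical(asn$haplotype, "D")
  expect_equal(asn$distance, 0)
  expect_false(asn$deviant)

  # one private substitution within clade D: assigned, flagged deviant
  chars <- strsplit(refs$seq[refs$haplotype == "D"], "")[[1]]
  chars[50] <- setdiff(c("A", "C", "G", "T"), chars[50])[1]
  q2 <- aligned_matrix("s2", paste(chars, collapse = ""))
  asn2 <- assign_haplotypes(q2, refs)
  expect_identical(asn2$haplotype, "D")
  expect_equal(asn2$distance, 1)
  expect_true(asn2$deviant)
  expect_equal(asn2$distance, oracle_hamming(q2$seq, refs$seq[refs$haplotype == "D"]))

  # random queries: reported distance equals the oracle on the chosen ref
  set.seed(43)
  for (i in 1:10) {
    qs <- random_seq(120, c("A", "C", "G", "T", "-", "N"))
    a <- assign_haplotypes(aligned_matrix("r", qs), refs, delta_max = 1000)
    expect_equal(a$distance,
                 min(vapply(refs$seq, function(r) oracle_hamming(qs, r),
                            numeric(1))))
  }
})

test_that("queries beyond delta_max stay unassigned; ties are flagged", {
  refs <- make_refs()
  far <- paste(rep("A", 120), collapse = "")
  asn <- assign_haplotypes(aligned_matrix("far", far), refs, delta_max = 2)
  expect_true(is.na(asn$haplotype))

  # two identical references: tie broken alphabetically and flagged
  refs2 <- refs
  refs2$seq[2] <- refs2$seq[1]
  asn2 <- assign_haplotypes(aligned_matrix("q", refs$seq[1]), refs2)
  expect_identical(asn2$haplotype, "A")
  expect_true(asn2$tie)

  expect_error(assign_haplotypes(aligned_matrix("q", "ACG"), refs), "length")
  expect_error(assign_haplotypes(aligned_matrix("q", far), refs[0, ]), "empty")
})

fake_call <- function(id, pa, pb, verdict = "F1_HYBRID") {
  tibble::tibble(sample_id = id, verdict = verdict, parent_a = pa, parent_b = pb)
}
fake_asn <- function(id, marker, hap) {
  tibble::tibble(sample_id = id, marker = marker, haplotype = hap,
                 distance = 0L, deviant = FALSE, tie = FALSE)
}

test_that("crosses orient by the maternal (plastid-donor) parent", {
  smap <- batrachium_species_map()
  # fluitans haplotype A on both markers: fluitans maternal, circinatus paternal
  cr <- orient_crosses(fake_call("h1", "circinatus", "fluitans"),
                       dplyr::bind_rows(fake_asn("h1", "rpl32-trnL", "A"),
                                        fake_asn("h1", "petL-psbE", "A")), smap)
  expect_identical(cr$maternal, "fluitans")
  expect_identical(cr$paternal, "circinatus")
  expect_identical(cr$confidence, "ORIENTED")
  expect_identical(cr$basis, "rpl32-trnL,petL-psbE")

  # hypothetical reverse cross: circinatus plastid means circinatus maternal
  cr2 <- orient_crosses(fake_call("h2", "circinatus", "kauffmannii"),
                        fake_asn("h2", "rpl32-trnL", "I"), smap)
  expect_identical(cr2$maternal, "circinatus")
  expect_identical(cr2$paternal, "kauffmannii")

  # markers disagreeing on the maternal parent: CONFLICT
  cr3 <- orient_crosses(fake_call("h3", "circinatus", "fluitans"),
                        dplyr::bind_rows(fake_asn("h3", "rpl32-trnL", "A"),
                                         fake_asn("h3", "petL-psbE", "F")), smap)
  expect_identical(cr3$confidence, "CONFLICT")

  # haplotype mapping to both ITS parents cannot orient (shared clade)
  cr4 <- orient_crosses(fake_call("h4", "aquatilis", "fluitans"),
                        fake_asn("h4", "rpl32-trnL", "A"), smap)
  expect_identical(cr4$confidence, "UNORIENTED")

  # no assignment at all: UNORIENTED, pipeline-degraded but defined
  cr5 <- orient_crosses(fake_call("h5", "circinatus", "fluitans"),
                        fake_asn("other", "rpl32-trnL", "A"), smap)
  expect_identical(cr5$confidence, "UNORIENTED")

  expect_error(orient_crosses(fake_call("s", "a", "b", verdict = "SPECIES"),
                              fake_asn("s", "rpl32-trnL", "A"), smap),
               "no hybrid calls")
})

test_that("orientation never outputs a maternal species outside the ITS pair", {
  cfg <- sim_config(seed = 47, n_species = 5, n_f1 = 40)
  pan <- generate_panel(cfg)
  b <- generate_hybrids(pan, cfg)
  calls <- infer_parentage(b$its, pan$panel)
  haps <- dplyr::bind_rows(lapply(names(b$plastid), function(mk)
    assign_haplotypes(b$plastid[[mk]], pan$plastid_refs[[mk]])))
  cr <- orient_crosses(calls, haps, pan$species_map)
  merged <- dplyr::left_join(cr, calls, by = "sample_id")
  ok <- is.na(merged$maternal) |
    merged$maternal == merged$parent_a | merged$maternal == merged$parent_b
  expect_true(all(ok))
  # synthetic plastids are copied from the true maternal parent: full recovery
  truthm <- dplyr::left_join(cr, b$truth, by = "sample_id")
  oriented <- truthm[truthm$confidence == "ORIENTED", ]
  expect_gt(nrow(oriented), 0)
  expect_true(all(oriented$maternal.x == oriented$maternal.y))
})

test_that("directionality is the paternal fraction over oriented crosses", {
  cr <- tibble::tibble(
    sample_id = paste0("s", 1:12),
    maternal = c(rep("fluitans", 5), rep("circinatus", 5), NA, NA),
    paternal = c(rep("circinatus", 5), rep("fluitans", 5), NA, NA),
    basis = "rpl32-trnL",
    confidence = c(rep("ORIENTED", 10), "UNORIENTED", "CONFLICT")
  )
  d <- directionality(cr, "circinatus")
  expect_equal(d$fraction_paternal, 0.5)
  expect_equal(d$n_oriented, 10)
  expect_equal(d$n_unoriented, 1)
  expect_equal(d$n_conflict, 1)

  all_pat <- dplyr::mutate(cr[1:5, ], paternal = "circinatus")
  expect_equal(directionality(all_pat, "circinatus")$fraction_paternal, 1)

  expect_error(directionality(cr[11:12, ], "circinatus"), "undefined")
})
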