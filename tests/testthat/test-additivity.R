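test_that("classify_sites matches the truth-table oracle on constructed cases", {
  # identity: all invariant
  s <- classify_sites("ACGT", "ACGT", "ACGT")
  expect_identical(as.character(s$label), rep("INVARIANT", 4))

  # a single additive column: parents G vs A, sample reads R
  s <- classify_sites("R", "G", "A")
  expect_identical(as.character(s$label), "ADDITIVE")

  # 10-column mixed case: 2 additive, 1 residual, 7 invariant
  pa <- "ACGTACGTAC"
  pb <- "CCGTTCGTAC"   # differs from pa at 1, 5
  q  <- "MCGTWCGTTC"   # additive at 1 (M = A+C) and 5 (W = A+T), residual at 9
  s <- classify_sites(q, pa, pb)
  expect_identical(as.character(s$label), oracle_classify(q, pa, pb))
  expect_equal(sum(s$label == "ADDITIVE"), 2)
  expect_equal(sum(s$label == "RESIDUAL"), 1)
  expect_equal(sum(s$label == "INVARIANT"), 7)

  expect_error(classify_sites("ACG", "ACGT", "ACGT"), "equal aligned length")
})

test_that("classify_sites equals the oracle over every symbol triple", {
  sym <- c(iupac_codes(), "-")
  g <- expand.grid(q = sym, a = sym, b = sym, stringsAsFactors = FALSE)
  got <- as.character(classify_sites(paste(g$q, collapse = ""),
                                     paste(g$a, collapse = ""),
                                     paste(g$b, collapse = ""))$label)
  expect_identical(got, unname(oracle_triple_table[paste(g$q, g$a, g$b)]))
})

test_that("classify_sites equals the oracle on random full-length triples", {
  set.seed(11)
  sym <- c(iupac_codes(), "-")
  for (i in 1:25) {
    q <- random_seq(650, sym); a <- random_seq(650, sym); b <- random_seq(650, sym)
    expect_identical(as.character(classify_sites(q, a, b)$label),
                     oracle_classify(q, a, b))
  }
})

test_that("score_pair counts a constructed F1 and respects the sum invariant", {
  set.seed(3)
  pa <- random_seq(650)
  # plant exactly 20 differing columns
  diff_pos <- sort(sample(650, 20))
  pb_chars <- strsplit(pa, "")[[1]]
  for (p in diff_pos) pb_chars[p] <- setdiff(c("A", "C", "G", "T"), pb_chars[p])[1]
  pb <- paste(pb_chars, collapse = "")
  q <- oracle_f1(pa, pb)

  sc <- score_pair(q, pa, pb)
  expect_equal(sc$n_additive, 20)
  expect_equal(sc$n_residual, 0)
  expect_equal(sc$additive_positions[[1]], diff_pos)
  expect_equal(sc$n_additive + sc$n_parent_only + sc$n_residual +
                 sc$n_shift + sc$n_invariant + sc$n_gapped, 650)

  # query identical to one parent
  sc2 <- score_pair(pa, pa, pb)
  expect_equal(sc2$n_additive, 0)
  expect_equal(sc2$n_parent_only, 20)
  expect_equal(sc2$n_residual, 0)

  # symmetry up to the A/B label swap
  sc_ab <- score_pair(q, pa, pb)
  sc_ba <- score_pair(q, pb, pa)
  expect_equal(sc_ab$n_parent_a, sc_ba$n_parent_b)
  expect_equal(sc_ab$n_parent_b, sc_ba$n_parent_a)
  for (f in c("n_additive", "n_residual", "n_parent_only", "n_invariant",
              "n_gapped"))
    expect_equal(sc_ab[[f]], sc_ba[[f]], info = f)
})

test_that("score_pair count invariant holds on random inputs with gaps", {
  set.seed(19)
  sym <- c(iupac_codes(), "-")
  for (i in 1:20) {
    L <- sample(50:200, 1)
    q <- random_seq(L, sym); a <- random_seq(L, sym); b <- random_seq(L, sym)
    sc <- score_pair(q, a, b)
    expect_equal(sc$n_additive + sc$n_parent_only + sc$n_residual +
                   sc$n_shift + sc$n_invariant + sc$n_gapped, L)
  }
})

test_that("shifted superposition detects the out-of-register trace pattern", {
  # parents identical apart from a 1-column gap: the self-superposition of a
  # query equal to the long parent is consistent wherever adjacent bases agree
  long <- "AAAAAA"; short <- "AAA-AA"
  r <- shifted_superposition(long, short, long)
  expect_true(r$applicable)
  expect_equal(r$indel_position, 4)
  expect_true(r$shift_consistent)
  expect_equal(r$n_shift_explained, r$n_testable)

  # constructed union-consistent query over random parents
  set.seed(23)
  L <- 60; g <- 20
  long_chars <- strsplit(random_seq(L), "")[[1]]
  short_chars <- long_chars
  # diverge a few columns, then open the gap
  for (p in sample(setdiff(1:L, g), 8))
    short_chars[p] <- setdiff(c("A", "C", "G", "T"), short_chars[p])[2]
  short_chars[g] <- "-"
  s_stripped <- short_chars[short_chars != "-"]
  q_chars <- long_chars
  for (p in g:(L - 1)) q_chars[p] <- oracle_union(long_chars[p], s_stripped[p])
  q <- paste(q_chars, collapse = "")
  short <- paste(short_chars, collapse = "")
  long <- paste(long_chars, collapse = "")

  r <- shifted_superposition(q, short, long)
  expect_true(r$applicable)
  expect_equal(r$indel_position, g)
  expect_true(r$shift_consistent)
  expect_equal(r$n_shift_explained, r$n_testable)
  expect_equal(r$n_testable, L - g)

  # corrupt 30% of the downstream columns with a base outside the union
  corrupt <- sample(g:(L - 1), ceiling(0.3 * (L - g)))
  for (p in corrupt) {
    u <- oracle_sets[[oracle_union(long_chars[p], s_stripped[p])]]
    q_chars[p] <- setdiff(c("A", "C", "G", "T"), u)[1]
  }
  r2 <- shifted_superposition(paste(q_chars, collapse = ""), short, long)
  expect_false(r2$shift_consistent)

  # no indel, or several, is a not-applicable signal, not an error
  expect_false(shifted_superposition("ACGT", "ACGT", "ACGT")$applicable)
  expect_false(shifted_superposition("ACGT", "A--T", "ACGT")$applicable)

  # query gap at the indel column violates the precondition
  expect_error(shifted_superposition("AAA-AA", "AAA-AA", "AAAAAA"),
               "gap at the indel column")
})

test_that("score_pair folds consistent shift columns out of the residuals", {
  set.seed(29)
  cfg <- sim_config(seed = 101, n_species = 2, n_f1 = 5,
                    indel_between = c("circinatus", "fluitans"))
  pan <- generate_panel(cfg)
  b <- generate_hybrids(pan, cfg)
  pa <- pan$panel$seq[pan$panel$species == "circinatus"]
  pb <- pan$panel$seq[pan$panel$species == "fluitans"]
  sc <- score_pair(b$its$seq[1], pa, pb)
  expect_true(sc$indel_applicable)
  expect_true(sc$shift_consistent)
  expect_equal(sc$indel_position, 30)
  expect_lte(sc$n_residual, 2)    # shift consequences no longer counted
})

test_that("infer_parentage recovers species, F1 pairs and ambiguity dropout", {
  cfg <- sim_config(seed = 5, n_species = 4, n_f1 = 30, n_pure = 4)
  pan <- generate_panel(cfg)
  b <- generate_hybrids(pan, cfg)
  calls <- infer_parentage(b$its, pan$panel)
  merged <- dplyr::left_join(calls, b$truth, by = "sample_id")

  pure <- merged[merged$type == "SPECIES", ]
  expect_true(all(pure$verdict == "SPECIES"))
  expect_true(all(pure$species_match == pure$parent_a.y))
  expect_true(all(pure$species_distance == 0))

  f1 <- merged[merged$type == "F1", ]
  expect_true(all(f1$verdict == "F1_HYBRID"))
  expect_true(all(purrr::map2_lgl(
    purrr::map2(f1$parent_a.x, f1$parent_b.x, c),
    purrr::map2(f1$parent_a.y, f1$parent_b.y, c),
    setequal)))
  expect_true(all(f1$n_residual == 0))
})

test_that("a panel member with few private mutations is never called hybrid", {
  cfg <- sim_config(seed = 13, n_species = 4, n_f1 = 0)
  pan <- generate_panel(cfg)
  set.seed(31)
  for (i in seq_len(nrow(pan$panel))) {
    chars <- strsplit(pan$panel$seq[i], "")[[1]]
    for (p in sample(length(chars), 2))
      chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
    q <- aligned_matrix(paste0("mut", i), paste(chars, collapse = ""))
    call <- infer_parentage(q, pan$panel)
    expect_identical(call$verdict, "SPECIES")
    expect_identical(call$species_match, pan$panel$species[i])
    expect_lte(call$species_distance, 2)
  }
})

test_that("three-way hybrids escalate to COMPLEX with the right third parent", {
  cfg <- sim_config(seed = 17, n_species = 4, n_f1 = 0, n_threeway = 10)
  pan <- generate_panel(cfg)
  b <- generate_hybrids(pan, cfg)
  calls <- infer_parentage(b$its, pan$panel)
  merged <- dplyr::left_join(calls, b$truth, by = "sample_id")
  expect_true(all(merged$verdict == "COMPLEX_HYBRID"))
  # the inferred pair plus top third candidate recovers the parental trio
  trio_ok <- mapply(function(a, b2, c3, ta, tb, tc)
    setequal(c(a, b2, c3), c(ta, tb, tc)),
    merged$parent_a.x, merged$parent_b.x, merged$third_parent,
    merged$parent_a.y, merged$parent_b.y, merged$parent_c)
  expect_true(all(trio_ok))
  expect_true(all(merged$third_parent_explained >= merged$n_residual))
})

test_that("a mosaic with no additive evidence is UNRESOLVED", {
  cfg <- sim_config(seed = 19, n_species = 2, n_f1 = 3, dropout_noise = 1)
  pan <- generate_panel(cfg)
  b <- generate_hybrids(pan, cfg)
  calls <- infer_parentage(b$its, pan$panel)
  expect_true(all(calls$n_additive %in% c(NA, 0)))
  expect_true(all(calls$verdict %in% c("SPECIES", "UNRESOLVED")))
})

test_that("constant additive positions intersect per-sample additive sets", {
  pa <- "ACGTACGTACGT"; pb <- "TCGAACGAACGA"   # differ at 1,4,8,12
  q1 <- oracle_f1(pa, pb)                       # additive at all four
  # drop the additive code at column 8 in a second sample
  q2c <- strsplit(q1, "")[[1]]; q2c[8] <- substr(pa, 8, 8)
  q2 <- paste(q2c, collapse = "")
  expect_equal(constant_additive_positions(q1, pa, pb), c(1, 4, 8, 12))
  expect_equal(constant_additive_positions(c(q1, q2), pa, pb), c(1, 4, 12))
  expect_error(constant_additive_positions(character(0), pa, pb), "empty")
})

test_that("an engineered group shares exactly its 12-column additive core", {
  set.seed(37)
  pa <- random_seq(650)
  pb_chars <- strsplit(pa, "")[[1]]
  core <- sort(sample(650, 12))
  private_pool <- sort(sample(setdiff(1:650, core), 20))
  for (p in c(core, private_pool))
    pb_chars[p] <- setdiff(c("A", "C", "G", "T"), pb_chars[p])[1]
  pb <- paste(pb_chars, collapse = "")
  full <- oracle_f1(pa, pb)
  group <- vapply(1:4, function(k) {
    chars <- strsplit(full, "")[[1]]
    drop <- sample(private_pool, 10)   # each sample keeps a different subset
    for (p in drop) chars[p] <- substr(pa, p, p)
    paste(chars, collapse = "")
  }, character(1))
  got <- constant_additive_positions(group, pa, pb)
  expect_true(all(core %in% got))
  expect_true(all(got %in% c(core, private_pool)))
  # with every private site dropped somewhere, only the core survives
  group2 <- vapply(seq_along(private_pool), function(k) {
    chars <- strsplit(full, "")[[1]]
    chars[private_pool[k]] <- substr(pa, private_pool[k], private_pool[k])
    paste(chars, collapse = "")
  }, character(1))
  expect_equal(constant_additive_positions(group2, pa, pb), core)
})
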