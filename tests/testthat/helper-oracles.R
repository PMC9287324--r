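# Independent brute-force oracles used across the suite. These work on
# explicit base sets (character vectors), never on the package's bitmask
# encoding, so they can disagree with the implementation if it is wrong.

oracle_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_code_for <- function(set) {
  for (code in names(oracle_sets)) {
    if (setequal(oracle_sets[[code]], set)) return(code)
  }
  stop("no IUPAC code for set ", paste(set, collapse = ""))
}

oracle_union <- function(a, b) {
  oracle_code_for(union(oracle_sets[[a]], oracle_sets[[b]]))
}

oracle_subsumes <- function(a, b) {
  all(oracle_sets[[b]] %in% oracle_sets[[a]])
}

# per-column site label from the stated classification rule
oracle_site_label <- function(q, a, b) {
  if (any(c(q, a, b) %in% c("-", "N"))) return("GAPPED")
  if (a == b) return(if (q == a) "INVARIANT" else "RESIDUAL")
  if (q == a) return("PARENT_A")
  if (q == b) return("PARENT_B")
  if (setequal(oracle_sets[[q]], union(oracle_sets[[a]], oracle_sets[[b]])))
    return("ADDITIVE")
  "RESIDUAL"
}

# label lookup for every (query, parent_a, parent_b) symbol triple,
# enumerated once; random-sequence checks then index into it
oracle_symbols <- c(names(oracle_sets), "-")
oracle_triple_table <- local({
  g <- expand.grid(q = oracle_symbols, a = oracle_symbols, b = oracle_symbols,
                   stringsAsFactors = FALSE)
  g$label <- mapply(oracle_site_label, g$q, g$a, g$b)
  lab <- g$label
  names(lab) <- paste(g$q, g$a, g$b)
  lab
})

oracle_classify <- function(query, parent_a, parent_b) {
  qs <- strsplit(query, "")[[1]]
  as_ <- strsplit(parent_a, "")[[1]]
  bs <- strsplit(parent_b, "")[[1]]
  unname(oracle_triple_table[paste(qs, as_, bs)])
}

oracle_hamming <- function(a, b) {
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  ok <- !(sa %in% c("-", "N")) & !(sb %in% c("-", "N"))
  sum(sa[ok] != sb[ok])
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# build an F1 consensus by the set definition (independent of the package)
oracle_f1 <- function(parent_a, parent_b) {
  as_ <- strsplit(parent_a, "")[[1]]; bs <- strsplit(parent_b, "")[[1]]
  paste(mapply(function(x, y) {
    if (x == "-" && y == "-") "-" else if (x == "-") y else if (y == "-") x
    else oracle_code_for(union(oracle_sets[[x]], oracle_sets[[y]]))
  }, as_, bs), collapse = "")
}
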