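# Shared fixture builders (all generated in code; nothing on disk).

# random CDS of `n_codons` sense codons framed by ATG ... TAA
random_cds <- function(n_codons = 200, seed = 1) {
  set.seed(seed)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  sense <- setdiff(sense, "ATG")
  paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                      collapse = ""), "TAA")
}

# random mutation descriptor with its expected classification
random_mutation_spec <- function(ref, seed) {
  set.seed(seed)
  n <- nchar(ref)
  gc <- Biostrings::GENETIC_CODE
  kind <- sample(c("substitution", "deletion", "insertion", "transposon"),
                 1, prob = c(0.5, 0.2, 0.2, 0.1))
  # keep mutations away from the ends so alignment context is unambiguous
  pos <- sample(seq(31, n - 31), 1)
  if (kind == "substitution") {
    ref_base <- substr(ref, pos, pos)
    base <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1)
    ci <- ceiling(pos / 3)
    codon_ref <- substr(ref, 3 * ci - 2, 3 * ci)
    codon_alt <- codon_ref
    substr(codon_alt, pos - (3 * ci - 3), pos - (3 * ci - 3)) <- base
    expected <- if (gc[[codon_alt]] == "*") "nonsense"
                else if (gc[[codon_alt]] != gc[[codon_ref]]) "missense"
                else "silent"
    list(spec = list(type = "substitution", pos = pos, base = base),
         expected = expected)
  } else if (kind == "deletion") {
    len <- sample(1:12, 1)
    list(spec = list(type = "deletion", pos = pos, len = len),
         expected = "indel")
  } else if (kind == "insertion") {
    len <- sample(1:12, 1)
    ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    list(spec = list(type = "insertion", pos = pos, seq = ins),
         expected = "indel")
  } else {
    list(spec = list(type = "transposon", pos = pos),
         expected = "transposon")
  }
}

# brute-force one-sided hypergeometric tail: P(overlap >= x)
oracle_overlap_tail <- function(x, N, K, n) {
  ks <- max(0, n + K - N):min(n, K)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= x])
}

# brute-force one-sided rank-sum p over all subset assignments
oracle_ranksum_p <- function(x, y) {
  combined <- c(x, y)
  r <- rank(combined)
  k <- length(x)
  W_obs <- sum(r[seq_len(k)])
  sets <- utils::combn(length(combined), k)
  count <- 0L
  for (i in seq_len(ncol(sets))) {
    if (sum(r[sets[, i]]) >= W_obs - 1e-9) count <- count + 1L
  }
  count / ncol(sets)
}
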