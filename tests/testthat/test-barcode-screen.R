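# Barcode counting, normalisation, NB Wald enrichment, hit calling and
# the overlap/set-level tests.

test_that("count_barcodes assigns a constructed fixture exactly", {
  db <- simulate_barcode_db(5, seed = 1)
  reads <- c(rep(paste0("TTT", as.character(db[[1]]), "GGG"), 100),
             rep(paste0("CCA", as.character(db[[2]]), "AAC"), 50),
             strrep("A", 40))   # matches nothing
  res <- count_barcodes(Biostrings::DNAStringSet(reads), db)
  expect_equal(unname(res$counts[1:2]), c(100L, 50L))
  expect_equal(sum(res$counts), 150L)
  expect_equal(res$unassigned, 1L)
  # conservation: assigned + unassigned = reads
  expect_equal(sum(res$counts) + res$unassigned, length(reads))
})

test_that("count_barcodes finds reverse-complemented barcodes", {
  db <- simulate_barcode_db(4, seed = 9)
  rc <- as.character(Biostrings::reverseComplement(db[[3]]))
  res <- count_barcodes(paste0("AC", rc, "TG"), db)
  expect_equal(unname(res$counts[3]), 1L)
})

test_that("count_barcodes rejects ambiguous databases", {
  db <- Biostrings::DNAStringSet(c(a = "ACGTACGTACGTACGTACGT",
                                   b = "ACGTACGTACGTACGTACGT"))
  expect_error(count_barcodes("ACGT", db), "duplicate")
})

test_that("filter_low_counts drops strains below 10 in every sample", {
  m <- rbind(s1 = c(9, 9, 9, 9), s2 = c(9, 10, 3, 1),
             s3 = c(0, 0, 0, 0), s4 = c(100, 2, 5, 8),
             s5 = c(11, 12, 13, 14))
  tab <- count_table(m, c("control", "control", "drug", "drug"))
  kept <- filter_low_counts(tab)
  expect_equal(rownames(kept$counts), c("s2", "s4", "s5"))
  # min_count 0 is the identity
  expect_equal(rownames(filter_low_counts(tab, 0)$counts), rownames(m))
})

test_that("estimate_size_factors reproduces the hand-computed case", {
  m <- matrix(c(10, 20, 30, 40, 20, 40, 60, 80), ncol = 2)
  expect_equal(estimate_size_factors(m), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # two identical samples give unit factors
  expect_equal(estimate_size_factors(cbind(m[, 1], m[, 1])), c(1, 1))
  # scaling one sample by c multiplies its factor by c (relative)
  sf1 <- estimate_size_factors(m)
  m2 <- m; m2[, 2] <- m2[, 2] * 3
  sf2 <- estimate_size_factors(m2)
  expect_equal(sf2[2] / sf2[1], 3 * sf1[2] / sf1[1], tolerance = 1e-10)
  expect_error(estimate_size_factors(matrix(c(0, 1, 1, 0), 2)),
               "nonzero")
})

test_that("wald_enrichment is null when drug columns replay the controls", {
  cfg <- screen_sim_config(n_strains = 400, depth = 2e5, seed = 5)
  tab <- simulate_screen_counts(cfg)
  # drug columns literally a permutation of the control columns: per-strain
  # condition means are identical, so log2fc ~ 0 and q ~ 1
  ctrl <- tab$sample_meta$condition == "control"
  perm <- tab$counts[, ctrl][, c(2, 3, 1)]
  tab$counts[, !ctrl] <- perm
  st <- wald_enrichment(filter_low_counts(tab))
  expect_lt(max(abs(st$log2fc)), 0.05)
  expect_gt(min(st$q), 0.9)
  expect_true(all(st$q >= st$p))
})

test_that("planted 32-fold resistor is recovered (log2fc within 0.3, q < 0.05)", {
  cfg <- screen_sim_config(
    n_strains = 2000, depth = 1e6,
    planted_resistors = data.frame(strain = 10, log2fc = 5), seed = 42)
  st <- wald_enrichment(filter_low_counts(simulate_screen_counts(cfg)))
  hit <- st[st$strain == "strain_0010", ]
  expect_lt(abs(hit$log2fc - 5), 0.3)
  expect_lt(hit$q, 0.05)
})

test_that("BH adjustment is monotone in p", {
  cfg <- screen_sim_config(n_strains = 500, depth = 1e5, seed = 8)
  st <- wald_enrichment(filter_low_counts(simulate_screen_counts(cfg)))
  o <- order(st$p)
  expect_true(all(diff(st$q[o]) >= -1e-12))
  expect_true(all(st$q >= st$p - 1e-12 & st$q <= 1))
})

test_that("call_hits applies both thresholds and ignores ordering", {
  st <- data.frame(strain = c("a", "b", "c", "d"),
                   log2fc = c(4.1, 3.9, -4.2, 4.5),
                   q = c(0.01, 0.001, 0.04, 0.2))
  h <- call_hits(st)
  expect_equal(h$resistant, "a")   # b misses the fold cutoff, d misses q
  expect_equal(h$sensitive, "c")
  h2 <- call_hits(st[c(3, 1, 4, 2), ])
  expect_equal(sort(h2$resistant), sort(h$resistant))
  expect_equal(sort(h2$sensitive), sort(h$sensitive))
  empty <- call_hits(st[0, ])
  expect_length(empty$resistant, 0)
  expect_length(empty$sensitive, 0)
})

test_that("fisher_overlap equals exhaustive hypergeometric enumeration", {
  # [[2,0],[0,2]] over a universe of 4: one-tailed p = 1/6
  u <- letters[1:4]
  r <- fisher_overlap(hits = c("a", "b"), annotated = c("a", "b"),
                      universe = u)
  expect_equal(r$p, 1 / 6, tolerance = 1e-12)
  expect_equal(unname(r$table[1, 1]), 2)
  # annotated = universe forces overlap = |hits|: p = 1
  expect_equal(fisher_overlap(c("a", "c"), u, u)$p, 1)
  # random toy sets vs brute-force enumeration, universe <= 30
  set.seed(14)
  for (i in 1:25) {
    N <- sample(5:30, 1)
    u <- paste0("s", seq_len(N))
    hits <- sample(u, sample(1:N, 1))
    ann <- sample(u, sample(1:N, 1))
    got <- fisher_overlap(hits, ann, u)
    want <- oracle_overlap_tail(length(intersect(hits, ann)),
                                N, length(ann), length(hits))
    expect_equal(got$p, want, tolerance = 1e-10)
  }
  expect_error(fisher_overlap("a", "a", character(0)), "universe")
})

test_that("classify_slow_growers uses a strict cutoff", {
  od <- c(a = 0.10, b = 0.12, c = 0.11, d = 0.02, e = 0.5, f = 0.109)
  expect_setequal(classify_slow_growers(od), c("a", "d", "f"))
  # all at the boundary: strict < means none are slow
  expect_length(classify_slow_growers(c(x = 0.11, y = 0.11)), 0)
})

test_that("set_enrichment flags shifted sets and skips degenerate ones", {
  set.seed(30)
  st <- data.frame(strain = paste0("s", 1:300),
                   log2fc = rnorm(300, 0, 1))
  st$log2fc[1:20] <- st$log2fc[1:20] + 4
  sets <- list(up = paste0("s", 1:20),
               null = paste0("s", 101:130),
               tiny = paste0("s", 1:2),
               everything = st$strain)
  res <- suppressWarnings(set_enrichment(st, sets))
  expect_equal(res$direction[res$set == "up"], "up")
  expect_equal(res$direction[res$set == "null"], "none")
  # undersized and all-strain sets are skipped
  expect_false(any(c("tiny", "everything") %in% res$set))
})

test_that("set_enrichment null p-values are uniform", {
  set.seed(77)
  pvals <- vapply(1:200, function(i) {
    st <- data.frame(strain = paste0("s", 1:120),
                     log2fc = rnorm(120))
    suppressWarnings(
      set_enrichment(st, list(x = paste0("s", sample(120, 15))))$p_up)
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
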