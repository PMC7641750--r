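# helpers to build sequences with an exact substitution spectrum
seq_with_subs <- function(n, n_ts, n_tv) {
  base <- rep("A", n)
  other <- base
  if (n_ts > 0) other[seq_len(n_ts)] <- "G"                     # A->G ts
  if (n_tv > 0) other[n_ts + seq_len(n_tv)] <- "C"              # A->C tv
  list(a = paste(base, collapse = ""), b = paste(other, collapse = ""))
}

test_that("K80 distance matches the closed form and handles edge cases", {
  # P = 0.1, Q = 0.05 over 100 sites
  p <- seq_with_subs(100, 10, 5)
  expect_equal(k80_distance(p$a, p$b),
               -0.5 * log(1 - 2 * 0.1 - 0.05) - 0.25 * log(1 - 2 * 0.05),
               tolerance = 1e-12)
  expect_equal(k80_distance(p$a, p$b), 0.1701811, tolerance = 1e-6)
  expect_identical(k80_distance(p$a, p$a), 0)
  expect_equal(k80_distance(p$a, p$b), k80_distance(p$b, p$a))
  # N positions are excluded from both numerator and denominator
  a_n <- sub("^A", "N", p$a)
  expect_equal(k80_distance(a_n, p$b),
               k80_distance(substring(p$a, 2), substring(p$b, 2)))
  # saturation: P = 0.5 makes 1 - 2P - Q non-positive
  s <- seq_with_subs(100, 50, 0)
  expect_error(k80_distance(s$a, s$b), "saturated")
  expect_error(k80_distance("N", "A"), "comparable")
})

test_that("K80 transition probabilities are a proper, unit-rate kernel", {
  for (t in c(0.01, 0.1, 1)) {
    P <- shmtarget:::k80_prob(t, kappa = 3)
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(P > 0))
    expect_equal(P, t(P), tolerance = 1e-12)  # symmetric under uniform bf
  }
  # normalized to one expected substitution per site per unit t
  t <- 1e-6
  P <- shmtarget:::k80_prob(t, kappa = 3)
  expect_equal((1 - P[1, 1]) / t, 1, tolerance = 1e-4)
  # transition/transversion rate ratio equals kappa at small t
  expect_equal(P["A", "G"] / P["A", "C"], 3, tolerance = 1e-4)
  # t = 0 is the identity
  expect_equal(shmtarget:::k80_prob(0, 2), diag(4), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("pooled kappa estimate is 2 * ts/tv, clamped", {
  p <- seq_with_subs(60, 10, 2)
  expect_equal(shmtarget:::estimate_kappa(c(p$a, p$b)), 10)
  q <- seq_with_subs(60, 0, 10)
  expect_equal(shmtarget:::estimate_kappa(c(q$a, q$b)), 0.2)  # lower clamp
  # no transversions: fall back to the default of 2
  r <- seq_with_subs(60, 5, 0)
  expect_equal(shmtarget:::estimate_kappa(c(r$a, r$b)), 2)
})

test_that("topology building skips degenerate families and roots on germline", {
  germ <- random_seq(60, seed = 5)
  # fewer than two distinct member sequences: no signal
  one <- data.frame(read_id = c("r1", "r2"),
                    sequence = rep(mutate_seq(germ, 2, seed = 1), 2),
                    stringsAsFactors = FALSE)
  expect_null(build_topology(one, germ))
  # three distinct members: rooted tree with germline tip, dedupe counts
  seqs <- c(mutate_seq(germ, 2, seed = 1), mutate_seq(germ, 3, seed = 2),
            mutate_seq(germ, 4, seed = 3))
  fam <- data.frame(read_id = sprintf("r%d", 1:4),
                    sequence = c(seqs, seqs[1]), stringsAsFactors = FALSE)
  lin <- build_topology(fam, germ)
  expect_s3_class(lin$tree, "phylo")
  expect_true("germline" %in% lin$tree$tip.label)
  expect_identical(sum(lin$tip_counts), 5L)  # 4 reads + germline
  expect_identical(unname(lin$tip_counts["u1"]), 2L)
  expect_true(ape::is.rooted(lin$tree))
})

test_that("branch-length optimization does not decrease the likelihood", {
  germ <- random_seq(120, seed = 9)
  fam <- data.frame(read_id = sprintf("r%d", 1:5),
                    sequence = vapply(1:5, function(i)
                      mutate_seq(germ, 3 + i, seed = i), character(1)),
                    stringsAsFactors = FALSE)
  lin <- build_topology(fam, germ)
  pd <- shmtarget:::as_phyDat(lin$sequences)
  tr0 <- lin$utree
  tr0$edge.length <- pmax(tr0$edge.length, 1e-8)
  ll0 <- suppressWarnings(phangorn::pml(
    tr0, pd, bf = rep(0.25, 4),
    Q = c(1, lin$kappa, 1, 1, lin$kappa, 1), k = 1))$logLik
  opt <- optimize_branch_lengths(lin)
  expect_gte(opt$loglik, ll0)
  expect_true(all(opt$tree$edge.length >= 0))
})

test_that("marginal ancestral posteriors match brute-force enumeration", {
  set.seed(21)
  germ <- random_seq(18)
  tips <- c(mutate_seq(germ, 1), mutate_seq(germ, 2), mutate_seq(germ, 2))
  fam <- data.frame(read_id = sprintf("r%d", 1:3), sequence = tips,
                    stringsAsFactors = FALSE)
  lin <- reconstruct_ancestors(optimize_branch_lengths(
    build_topology(fam, germ)))
  # enumerate on the fitted (unrooted) tree with the same kappa and lengths
  ftree <- lin$fit$tree
  tip_enc <- lapply(lin$sequences[ftree$tip.label], shmtarget:::encode_seq)
  bf <- enumerate_marginals(ftree, tip_enc, lin$kappa)
  for (lab in ftree$node.label) {
    got <- shmtarget:::encode_seq(lin$sequences[[lab]])
    want <- bf[[lab]]
    for (site in seq_len(nrow(want))) {
      top <- max(want[site, ])
      clear <- sum(want[site, ] >= top - 1e-6) == 1L
      if (clear)
        expect_identical(got[site], which.max(want[site, ]),
                         label = sprintf("node %s site %d", lab, site))
    }
  }
})

test_that("branch construction counts events, exposure and length correctly", {
  parent <- "AANACGTACGTACG"   # N at position 2 (0-based)
  child <- "AANACCTACGAACG"   # subs at x = 5 (G->C) and x = 10 (C->A)
  b <- new_branch(parent, child, L = 12)
  # eligible: full ACGT 5-mer context and x < 12; the N poisons x in 0..4,
  # and positions 12,13 are out of range or flankless
  expect_identical(b$n_eligible, 7L)        # x = 5..11
  expect_identical(b$n_mut, 2L)
  expect_equal(b$t, 2 / 7)
  expect_identical(b$events$x, c(5L, 10L))
  expect_identical(b$events$fivemer, c("ACGTA", "CGTAC"))
  expect_identical(b$events$from, c("G", "T"))
  expect_identical(b$events$to, c("C", "A"))
  # identical sequences: exposure but no events, t = 0
  b0 <- new_branch(parent, parent, L = 12)
  expect_identical(b0$n_mut, 0L)
  expect_identical(b0$t, 0)
})

test_that("event counts over eligible positions equal the Hamming distance", {
  set.seed(31)
  for (i in 1:20) {
    p <- random_seq(80)
    ch <- mutate_seq(p, sample(0:8, 1))
    b <- new_branch(p, ch, L = 80)
    pe <- shmtarget:::encode_seq(p); ce <- shmtarget:::encode_seq(ch)
    elig <- !is.na(shmtarget:::context_indices(pe))
    expect_identical(b$n_mut, sum((pe != ce)[elig]))
  }
})

manual_lineage <- function(germ, mrca, children, n_distinct = 6L) {
  n <- length(children)
  tips <- paste0("(", paste(sprintf("t%d:0.1", seq_len(n)), collapse = ","),
                 ")anc1:0.1")
  tree <- ape::read.tree(text = paste0("(", tips, ",germline:0.1)Root;"))
  structure(list(lineage_id = "manual", tree = tree,
                 sequences = c(setNames(children, sprintf("t%d", seq_len(n))),
                               germline = germ, anc1 = mrca,
                               Root = germ),
                 germline = "germline", mrca = "anc1",
                 n_distinct = n_distinct),
            class = "shm_lineage")
}

test_that("branch extraction keeps only filtered post-MRCA branches", {
  cfg <- shm_config(L = 60, min_family_size = 6, max_branch_mutations = 10)
  # flip bases at given 1-based interior positions so every substitution
  # falls on an eligible (full-context) position
  flip_at <- function(seq, pos) {
    v <- strsplit(seq, "")[[1]]
    v[pos] <- chartr("ACGT", "CATG", v[pos])
    paste(v, collapse = "")
  }
  germ <- random_seq(60, seed = 41)
  mrca <- mutate_seq(germ, 3, seed = 42)
  heavy <- flip_at(mrca, 11:20)  # 10 subs: at the cap, excluded
  light <- flip_at(mrca, 25:26)
  lin <- manual_lineage(germ, mrca, c(heavy, light, mrca))
  br <- extract_mutation_events(lin, cfg)
  # heavy branch dropped; light branch and the zero-mutation branch kept
  expect_length(br, 2L)
  expect_setequal(vapply(br, function(b) b$n_mut, integer(1)), c(2L, 0L))
  # no branch starts at the germline: pre-MRCA mutations never appear
  ev <- events_table(br)
  expect_false(any(grepl("germline|Root", ev$branch_id)))
  # small lineages are excluded entirely
  small <- manual_lineage(germ, mrca, c(light, mrca), n_distinct = 5L)
  expect_identical(extract_mutation_events(small, cfg), list())
  # a branch with exactly cap - 1 mutations is retained
  nine <- flip_at(mrca, 31:39)
  lin9 <- manual_lineage(germ, mrca, c(nine, mrca))
  expect_identical(max(vapply(extract_mutation_events(lin9, cfg),
                              function(b) b$n_mut, integer(1))), 9L)
})

test_that("full lineage reconstruction recovers sparse true ancestors", {
  set.seed(51)
  germ <- random_seq(150)
  mrca <- mutate_seq(germ, 2)
  # star-like family: independent descendants of one MRCA
  kids <- vapply(1:6, function(i) mutate_seq(mrca, 2), character(1))
  fam <- data.frame(read_id = sprintf("r%d", 1:6), sequence = kids,
                    stringsAsFactors = FALSE)
  lin <- build_lineage(fam, germ)
  expect_identical(lin$sequences[[lin$mrca]], mrca)
  # events table sums to the per-branch mutation counts
  br <- extract_mutation_events(lin, shm_config(L = 150))
  ev <- events_table(br)
  expect_identical(nrow(ev), sum(vapply(br, function(b) b$n_mut, integer(1))))
})

test_that("lineages serialize to Newick and FASTA", {
  germ <- random_seq(90, seed = 61)
  fam <- data.frame(read_id = sprintf("r%d", 1:3),
                    sequence = vapply(1:3, function(i)
                      mutate_seq(germ, 2 + i, seed = 70 + i), character(1)),
                    stringsAsFactors = FALSE)
  lin <- build_lineage(fam, germ)
  dir <- withr::local_tempdir()
  write_lineage(lin, dir)
  tr <- ape::read.tree(file.path(dir, "lineage.nwk"))
  expect_setequal(tr$tip.label, lin$tree$tip.label)
  fa <- shmtarget:::read_fasta(file.path(dir, "lineage.fasta"))
  expect_identical(fa[names(lin$sequences)], unlist(lin$sequences))
})
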