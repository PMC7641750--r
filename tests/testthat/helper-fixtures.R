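# Programmatic fixtures shared across test files.

NUC4 <- c("A", "C", "G", "T")

# a small annotated-read table with controllable junction lengths and flags
toy_reads <- function(n = 4, junction_lengths = rep(20L, n),
                      productive = rep(FALSE, n),
                      v_gene = rep("V1", n), j_gene = rep("J1", n),
                      seed = 1) {
  set.seed(seed)
  seqs <- vapply(junction_lengths, function(jl)
    paste(sample(NUC4, 30 + jl, replace = TRUE), collapse = ""),
    character(1))
  annotated_reads(read_id = sprintf("r%02d", seq_len(n)),
                  sequence = seqs,
                  v_gene = v_gene, j_gene = j_gene,
                  cdr3_start = rep(15L, n),
                  cdr3_end = 15L + junction_lengths,
                  productive = productive)
}

# reads with fully specified CDR3 strings (shared flanks)
reads_with_cdr3 <- function(cdr3s, v_gene = "V1", j_gene = "J1",
                            productive = FALSE) {
  len <- unique(nchar(cdr3s))
  stopifnot(length(len) == 1)
  left <- strrep("A", 12); right <- strrep("G", 12)
  annotated_reads(read_id = sprintf("r%02d", seq_along(cdr3s)),
                  sequence = paste0(left, cdr3s, right),
                  v_gene = v_gene, j_gene = j_gene,
                  cdr3_start = nchar(left),
                  cdr3_end = nchar(left) + len,
                  productive = productive)
}

# mutate a sequence at `n` random positions (guaranteed base change)
mutate_seq <- function(seq, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- strsplit(seq, "")[[1]]
  idx <- sample(seq_along(v), n)
  for (i in idx) v[i] <- sample(setdiff(NUC4, v[i]), 1)
  paste(v, collapse = "")
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(NUC4, n, replace = TRUE), collapse = "")
}

# a flat mutability model over L positions
flat_model <- function(L = 60, gamma = 1) {
  mutability_model(rep(gamma, 1024), rep(1, L))
}

# random branches under a random model, for identity/property checks
random_branches <- function(n_branches = 20, len = 60, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_branches), function(i) {
    p <- random_seq(len)
    new_branch(p, mutate_seq(p, sample(0:6, 1)), L = len,
               lineage_id = sprintf("lin%d", (i - 1) %/% 4 + 1),
               branch_id = sprintf("b%d", i))
  })
}

# Brute-force marginal ancestral posteriors by enumerating all internal
# state assignments under K80; returns, per internal node, an L x 4
# posterior matrix. Tree must be rooted; tip sequences encoded 1..4 (NA=N).
enumerate_marginals <- function(tree, tip_enc, kappa) {
  labels <- c(tree$tip.label, tree$node.label)
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  edges <- tree$edge
  elen <- tree$edge.length
  L <- length(tip_enc[[1]])
  P <- lapply(elen, function(t) shmtarget:::k80_prob(t, kappa))
  states <- as.matrix(expand.grid(rep(list(1:4), n_int)))
  post <- lapply(seq_len(n_int), function(i) matrix(0, L, 4))
  for (site in seq_len(L)) {
    obs <- vapply(seq_len(n_tip), function(i) tip_enc[[labels[i]]][site],
                  integer(1))
    for (a in seq_len(nrow(states))) {
      lik <- 0.25  # uniform root prior
      ok <- TRUE
      for (e in seq_along(elen)) {
        par <- edges[e, 1]; ch <- edges[e, 2]
        sp <- states[a, par - n_tip]
        if (ch <= n_tip) {
          if (is.na(obs[ch])) next  # N: sums over states, prob 1
          lik <- lik * P[[e]][sp, obs[ch]]
        } else {
          lik <- lik * P[[e]][sp, states[a, ch - n_tip]]
        }
        if (lik == 0) { ok <- FALSE; break }
      }
      if (!ok) next
      for (i in seq_len(n_int))
        post[[i]][site, states[a, i]] <- post[[i]][site, states[a, i]] + lik
    }
  }
  post <- lapply(post, function(m) m / rowSums(m))
  names(post) <- labels[(n_tip + 1):(n_tip + n_int)]
  post
}

# independent coding of the total joint log-likelihood (event form) used as
# a grid-maximization oracle for tiny instances
oracle_loglik <- function(branches, gamma_by_fivemer, beta, L) {
  ll <- 0
  for (b in branches) {
    # zero-length branches contribute exactly zero log-likelihood, and
    # contexts seen only there carry no exposure (gamma undefined)
    if (b$t == 0) next
    pe <- shmtarget:::encode_seq(b$parent_seq)
    ce <- shmtarget:::encode_seq(b$child_seq)
    ctx <- shmtarget:::context_indices(pe)
    fm <- all_fivemers()
    for (i in seq_along(pe)) {
      x <- i - 1
      if (is.na(ctx[i]) || is.na(ce[i]) || x >= L) next
      mu <- gamma_by_fivemer[[fm[ctx[i]]]] * beta[i]
      ll <- ll - mu * b$t
      if (pe[i] != ce[i]) ll <- ll + log(exp(mu * b$t) - 1)
    }
  }
  ll
}
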