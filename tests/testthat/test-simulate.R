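test_that("beta profiles hit their landmark values", {
  L <- 400; delta <- 50
  expect_identical(make_beta_profile("flat", L), rep(1, L))
  s <- make_beta_profile("sin", L, delta)
  k <- make_beta_profile("cos", L, delta)
  # at x = 0: sin gives exp(-1), cos gives exp(1)
  expect_equal(s[1], exp(-1), tolerance = 1e-12)
  expect_equal(k[1], exp(1), tolerance = 1e-12)
  # extremes of the modulation
  expect_true(all(s >= exp(-3) - 1e-12 & s <= exp(1) + 1e-12))
  expect_true(all(k >= exp(-3) - 1e-12 & k <= exp(1) + 1e-12))
  expect_equal(s[1 + round(delta * pi / 2)], exp(1), tolerance = 1e-3)
})

test_that("the gamma table and templates are seeded and well-formed", {
  g1 <- random_gamma_table(seed = 3)
  g2 <- random_gamma_table(seed = 3)
  expect_identical(g1, g2)
  expect_identical(names(g1), all_fivemers())
  expect_true(all(g1 > 0))
  cfg1 <- sim_config(seed = 9)
  cfg2 <- sim_config(seed = 9)
  expect_identical(cfg1$v_templates, cfg2$v_templates)
  expect_identical(nchar(cfg1$v_templates), rep(270L, 12L))
  # junction support contains no in-frame length
  expect_true(all(cfg1$junction_lengths %% 3L != 0L))
  expect_error(sim_config(junction_lengths = c(25, 27)))
})

test_that("root sequences assemble V + junction + J with 0-based coordinates", {
  cfg <- sim_config(seed = 2)
  set.seed(5)
  root <- generate_root_sequence(cfg, v_index = 3, junction_length = 25)
  expect_identical(nchar(root$sequence), 270L + 25L + 70L)
  expect_identical(substring(root$sequence, 1, 270), cfg$v_templates[[3]])
  expect_identical(root$cdr3_start, 270L)
  expect_identical(root$cdr3_end, 295L)
  expect_identical(substring(root$sequence, 296), cfg$j_template)
  germ <- shmtarget:::germline_for(cfg, 3, 25)
  expect_identical(substring(germ, 271, 295), strrep("N", 25))
})

test_that("branch simulation mutates n distinct eligible positions", {
  model <- mutability_model(random_gamma_table(seed = 1),
                            make_beta_profile("sin", 100, 25))
  set.seed(7)
  parent <- random_seq(100)
  for (n in c(0L, 1L, 5L, 9L)) {
    sim <- simulate_branch_mutations(parent, n, model)
    expect_identical(nrow(sim$events), n)
    expect_identical(anyDuplicated(sim$events$x), 0L)
    expect_identical(shmtarget:::hamming(parent, sim$child_seq), n)
    expect_true(all(sim$events$from != sim$events$to))
    expect_true(all(sim$events$label == "targeted"))
    # only positions with defined positive mu are hit
    mu <- shmtarget:::position_mutability(shmtarget:::encode_seq(parent),
                                          model)
    expect_true(all(!is.na(mu[sim$events$x + 1L])))
  }
  expect_error(simulate_branch_mutations(parent, 1000L, model), "eligible")
})

test_that("placement frequencies are proportional to mu", {
  # two positions with rates 9:1 -> first position hit with p = 0.9
  mu <- c(9, 1)
  set.seed(11)
  n_rep <- 10000
  hits <- replicate(n_rep,
    shmtarget:::place_mutations(mu, 1:2, 1L)$pos)
  phat <- mean(hits == 1L)
  # binomial 4-sigma band around 0.9
  expect_lt(abs(phat - 0.9), 4 * sqrt(0.9 * 0.1 / n_rep))
  # chi-squared goodness of fit over 5 positions
  mu5 <- c(1, 2, 3, 4, 10)
  hits5 <- replicate(n_rep, shmtarget:::place_mutations(mu5, 1:5, 1L)$pos)
  obs <- tabulate(hits5, nbins = 5)
  p <- chisq.test(obs, p = mu5 / sum(mu5))$p.value
  expect_gt(p, 1e-4)
})

test_that("lineage simulation propagates sequences and conserves counts", {
  model <- mutability_model(random_gamma_table(seed = 2),
                            make_beta_profile("flat", 200))
  set.seed(13)
  topo <- random_topology(6, branch_mutations = 1:9)
  root <- random_seq(200)
  lin <- simulate_lineage(topo, root, model, lineage_id = "linA")
  expect_identical(lin$sequences[[setdiff(
    topo$node.label, topo$node.label[-1])[1]]], root)
  # each branch's Hamming distance equals its prescribed count
  edges <- reorder(topo, "cladewise")$edge
  labels <- c(topo$tip.label, topo$node.label)
  counts <- topo$branch_counts[match(paste(edges[, 1], edges[, 2]),
                                     paste(topo$edge[, 1], topo$edge[, 2]))]
  for (r in seq_len(nrow(edges))) {
    d <- shmtarget:::hamming(lin$sequences[[labels[edges[r, 1]]]],
                             lin$sequences[[labels[edges[r, 2]]]])
    expect_identical(d, counts[r])
  }
  expect_identical(nrow(lin$truth), sum(topo$branch_counts))
  expect_length(lin$branches, nrow(topo$edge))
})

test_that("follow-up placement matches the exponential law", {
  set.seed(17)
  eps <- 0.05; xi <- 10
  # analytic mean follow-ups per targeting event on an unbounded lattice
  expect_equal(expected_followups(eps, xi), 2 * eps / (1 - exp(-1 / xi)),
               tolerance = 1e-12)
  # measure the first follow-up batch, which is free of collision and
  # truncation effects: its size is a sum of independent Bernoulli draws
  # with mean sum_x epsilon exp(-|x - x0| / xi) ~ 2 eps / (1 - exp(-1/xi))
  mu <- rep(1, 4000)
  first_batch <- integer(2000)
  total_ratio_n <- c(f = 0L, t = 0L)
  for (rep in seq_along(first_batch)) {
    placed <- shmtarget:::place_mutations(mu, seq_along(mu), 40L,
                                          epsilon = eps, xi = xi)
    expect_length(placed$pos, 40L)             # totals conserved exactly
    expect_identical(anyDuplicated(placed$pos), 0L)
    targets <- which(placed$label == "targeted")
    end <- if (length(targets) > 1L) targets[2] - 1L else length(placed$label)
    first_batch[rep] <- end - targets[1]
    total_ratio_n <- total_ratio_n +
      c(sum(placed$label == "followup"), sum(placed$label == "targeted"))
  }
  # exact lattice sum excludes the targeted position itself (d = 0);
  # expected_followups() is the closed-form approximation including it
  m_exact <- 2 * eps * exp(-1 / xi) / (1 - exp(-1 / xi))
  m <- expected_followups(eps, xi)
  expect_lt(abs(m - m_exact), 2 * eps + 1e-12)
  se <- sd(first_batch) / sqrt(length(first_batch))
  expect_lt(abs(mean(first_batch) - m_exact), 4 * se + 1e-9)
  # the overall ratio sits below m (final-batch truncation and collisions
  # with already-mutated neighbours both bias it down) but not by much
  ratio <- total_ratio_n[["f"]] / total_ratio_n[["t"]]
  expect_gt(ratio, 0.6 * m)
  expect_lt(ratio, 1.2 * m)
  # epsilon = 0: everything is targeted
  p0 <- shmtarget:::place_mutations(mu, seq_along(mu), 20L, epsilon = 0)
  expect_true(all(p0$label == "targeted"))
})

test_that("follow-ups cluster near their targeting event", {
  set.seed(19)
  mu <- rep(1, 2000)
  gaps <- integer(0)
  for (rep in 1:200) {
    placed <- shmtarget:::place_mutations(mu, seq_along(mu), 2L,
                                          epsilon = 0.3, xi = 5)
    if (placed$label[2] == "followup")
      gaps <- c(gaps, abs(placed$pos[2] - placed$pos[1]))
  }
  expect_gt(length(gaps), 20)
  # mean |gap| for p(x) ~ exp(-|x|/5) is about 5.5; targeted pairs would
  # average about 670 on this lattice
  expect_lt(mean(gaps), 15)
})

test_that("repertoire simulation reaches the event target with valid reads", {
  model <- mutability_model(random_gamma_table(seed = 4),
                            make_beta_profile("flat", 400))
  cfg <- sim_config(seed = 4)
  sim <- simulate_repertoire(model, cfg, n_events_target = 400, seed = 21)
  expect_gte(sim$n_events, 400)
  expect_identical(sum(vapply(sim$lineages,
                              function(l) nrow(l$truth), integer(1))),
                   as.integer(sim$n_events))
  expect_s3_class(sim$reads, "annotated_reads")
  expect_true(all(!sim$reads$productive))
  # junction lengths are frameshifted, so every read is out-of-frame
  kept <- filter_out_of_frame(sim$reads)
  expect_identical(nrow(kept), nrow(sim$reads))
  # family sizes respect the configured support
  sizes <- vapply(sim$lineages, function(l) l$n_leaves, integer(1))
  expect_true(all(sizes >= 6 & sizes <= 60))
  # identical seeds reproduce the repertoire
  sim2 <- simulate_repertoire(model, cfg, n_events_target = 400, seed = 21)
  expect_identical(sim$reads$sequence, sim2$reads$sequence)
})

test_that("true branches apply the same filters as the pipeline extraction", {
  model <- mutability_model(random_gamma_table(seed = 6),
                            make_beta_profile("flat", 400))
  cfg <- sim_config(seed = 6, branch_mutations = 9:12)
  sim <- simulate_repertoire(model, cfg, n_events_target = 200, seed = 23)
  config <- shm_config(max_branch_mutations = 10)
  br <- true_branches(sim$lineages, config)
  expect_true(all(vapply(br, function(b) b$n_mut, integer(1)) < 10L))
  # with a permissive cap, branches with 10+ mutations appear
  br2 <- true_branches(sim$lineages, shm_config(max_branch_mutations = 99))
  expect_gt(length(br2), length(br))
})
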