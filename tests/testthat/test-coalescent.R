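test_that("lineage-count transition probabilities match closed forms", {
  for (t in c(0.1, 1, 10)) expect_equal(lineage_transition_prob(1, 1, t), 1)
  # two lineages: g(2,1,t) = 1 - exp(-t/(p*Ne))
  expect_equal(lineage_transition_prob(2, 1, 100, ne = 100, p = 1),
               1 - exp(-1), tolerance = 1e-10)
  expect_equal(lineage_transition_prob(2, 1, 100, ne = 100, p = 2),
               1 - exp(-0.5), tolerance = 1e-10)
  expect_equal(lineage_transition_prob(2, 2, 100, ne = 100, p = 1),
               exp(-1), tolerance = 1e-10)
  expect_error(lineage_transition_prob(2, 3, 1), "j <= i")
  expect_error(lineage_transition_prob(2, 1, -1), "negative")
})

test_that("transition rows are normalized and stable for up to 50 lineages", {
  set.seed(41)
  for (i in c(2, 10, 30, 50)) {
    for (tau in c(1e-4, 0.01, 0.3, 2, 20)) {
      row <- vapply(1:i, function(j) lineage_transition_prob(i, j, tau),
                    numeric(1))
      expect_true(all(row >= 0))
      expect_equal(sum(row), 1, tolerance = 1e-7)
    }
  }
})

test_that("alternating-sum and uniformization evaluations agree", {
  for (i in c(5, 20, 40)) {
    for (tau in c(0.05, 0.5, 3)) {
      a <- genefamsim:::gij_row(i, tau)
      b <- genefamsim:::gij_row_uniformization(i, tau)
      expect_equal(a, b, tolerance = 1e-6)
    }
  }
})

test_that("transition probabilities satisfy the semigroup property", {
  # composing two short intervals equals one long interval
  i <- 12
  for (taus in list(c(0.2, 0.3), c(0.05, 1), c(1, 2))) {
    g1 <- genefamsim:::gij_row  # row over j for fixed i
    direct <- g1(i, sum(taus))
    comp <- numeric(i)
    mid <- g1(i, taus[1])
    for (m in 1:i) if (mid[m] > 0)
      comp[1:m] <- comp[1:m] + mid[m] * g1(m, taus[2])
    expect_equal(direct, comp, tolerance = 1e-8)
  }
})

test_that("the count dynamic program matches exhaustive path enumeration on a cherry", {
  fx <- fix_locus_cherry(ne = 2, ind = 2, tau = 8)
  st <- coal_settings(ploidy = 1, default_ne = 2, default_individuals = 2)
  skel <- make_skeleton(fx$pruned, fx$species_tree, node = 2L, top_time = 8,
                        settings = st)
  dp <- subtree_count_dp(skel, st)
  # independent enumeration: child branch tops from g(2, ., tau_leaf),
  # convolved, then the stem transition
  tau_leaf <- 5 / 2          # 5 generations, Ne 2, p 1
  tau_stem <- 3 / 2
  gtop <- vapply(1:2, function(j) lineage_transition_prob(2, j, 5, ne = 2),
                 numeric(1))
  bot <- numeric(4)
  for (a in 1:2) for (b in 1:2)
    bot[a + b] <- bot[a + b] + gtop[a] * gtop[b]
  top <- numeric(4)
  for (m in 1:4) if (bot[m] > 0) {
    gm <- vapply(1:m, function(j) lineage_transition_prob(m, j, 3, ne = 2),
                 numeric(1))
    top[1:m] <- top[1:m] + bot[m] * gm
  }
  expect_equal(dp$bot_dist, bot, tolerance = 1e-10)
  expect_equal(dp$top_dist, top, tolerance = 1e-10)
  expect_equal(sum(dp$top_dist), 1, tolerance = 1e-9)
})

test_that("realized counts follow the bound-conditioned distribution", {
  fx <- fix_locus_cherry(ne = 2, ind = 2, tau = 8)
  st <- coal_settings(1, 2, 2)
  skel <- subtree_count_dp(make_skeleton(fx$pruned, fx$species_tree, 2L, 8, st), st)
  set.seed(42)
  draws <- replicate(4000, sample_counts(skel, st, root_count = 1)$bot_count)
  # conditional bottom-count distribution given top = 1 by enumeration
  bot <- skel$bot_dist
  w <- vapply(seq_along(bot), function(m)
    if (bot[m] > 0) bot[m] * lineage_transition_prob(m, 1, 3, ne = 2) else 0,
    numeric(1))
  w <- w / sum(w)
  obs <- tabulate(draws, nbins = length(w))
  keep <- w > 1e-6
  chi <- suppressWarnings(chisq.test(obs[keep], p = w[keep] / sum(w[keep])))
  expect_gt(chi$p.value, 0.01)
  # counts never increase rootward
  sk2 <- sample_counts(skel, st, root_count = 1)
  expect_true(all(diff(sk2$seg_counts) <= 0))
  expect_true(all(vapply(sk2$children, function(ch)
    ch$top_count <= ch$bot_count, logical(1))))
})

test_that("single-input branches pass through untouched", {
  fx <- fix_locus_single_branch(H = 10, tau = 3, ne = 2, ind = 1)
  st <- coal_settings(1, 2, 1)
  skel <- subtree_count_dp(make_skeleton(fx$pruned, fx$species_tree, 2L, 3, st), st)
  expect_equal(skel$top_dist, 1)
  set.seed(43)
  sk <- sample_counts(skel, st, 1)
  expect_equal(sk$bot_count, 1L)
  r <- simulate_unbounded_branch(1, 100, ne = 5)
  expect_equal(r$survivors, 1)
  expect_length(r$times, 0)
})

test_that("conditional coalescence times match closed-form and rejection oracles", {
  # i = 2 -> 1: truncated exponential on (0, t)
  set.seed(44)
  ne <- 10; t <- 15
  x <- replicate(4000, sample_conditional_times(2, 1, t, ne = ne))
  r <- 1 / ne
  cdf <- function(q) (1 - exp(-r * q)) / (1 - exp(-r * t))
  expect_gt(suppressWarnings(ks.test(x, cdf)$p.value), 0.01)
  expect_true(all(x > 0 & x < t))
  # i = j: empty
  expect_length(sample_conditional_times(3, 3, 5, ne = 1), 0)
  # i = 3 -> 1: joint law vs rejection (unconditioned runs ending at 1 by t)
  set.seed(45)
  first_times <- replicate(3000, sample_conditional_times(3, 1, t, ne = ne)[1])
  rej <- c()
  while (length(rej) < 3000) {
    r3 <- simulate_unbounded_branch(3, t, ne = ne)
    if (r3$survivors == 1) rej <- c(rej, r3$times[1])
  }
  expect_gt(suppressWarnings(ks.test(first_times, rej)$p.value), 0.01)
})

test_that("unbounded coalescent means: pairwise p*Ne, TMRCA 2*p*Ne*(1-1/k)", {
  set.seed(46)
  n <- 4000; ne <- 50
  for (p in 1:2) {
    pw <- replicate(n, simulate_unbounded_branch(2, Inf, ne = ne, p = p)$times[1])
    expect_lt(abs(mean(pw) - p * ne), 3 * sd(pw) / sqrt(n))
  }
  for (k in c(5, 10)) {
    tm <- replicate(n, max(simulate_unbounded_branch(k, Inf, ne = ne)$times))
    expect_lt(abs(mean(tm) - 2 * ne * (1 - 1 / k)), 3 * sd(tm) / sqrt(n))
  }
})

test_that("with no locus events the pipeline is a plain multispecies coalescent", {
  set.seed(47)
  sp <- simulate_bdsa(1e-6, 0, 5, height = 1e6)
  sp <- decorate_branches(sp, ne = 1000, gen_time = 1, individuals = 1)
  loc <- simulate_locus_tree(sp)
  g <- simulate_gene_tree(loc, coal_settings(1, 1000, 1))
  gt <- g$tree
  expect_equal(n_leaves(gt), 5)
  expect_equal(length(gt$parent), 2 * 5 - 1)
  # genealogy validity
  for (i in seq_along(gt$parent)) {
    if (!is.na(gt$parent[i])) expect_gt(gt$time[gt$parent[i]], gt$time[i])
  }
  expect_true(is_ultrametric(gt))
  # between-species coalescence cannot predate the species divergence
  lv <- tree_leaves(gt)
  sp_lv <- tree_leaves(sp)
  for (a in 1:(length(lv) - 1)) for (b in (a + 1):length(lv)) {
    sa <- sub("_.*", "", gt$label[lv[a]]); sb <- sub("_.*", "", gt$label[lv[b]])
    ia <- sp_lv[sp$label[sp_lv] == sa]; ib <- sp_lv[sp$label[sp_lv] == sb]
    div <- mrca_time(sp, c(ia, ib))
    expect_gte(mrca_time(gt, lv[c(a, b)]), div - 1e-9)
  }
})

test_that("bounded subtrees coalesce fully below the bound", {
  fx <- fix_locus_cherry(ne = 2, ind = 2, tau = 8)
  st <- coal_settings(1, 2, 2)
  set.seed(48)
  for (rep in 1:20) {
    g <- simulate_gene_tree(fx, st)
    gt <- g$tree
    # the bounded subtree covers all sampled copies here: the whole
    # genealogy must be resolved by the bound at 8
    expect_lte(gt$time[tree_root(gt)], 8)
    expect_equal(length(gt$parent), 2 * n_leaves(gt) - 1)
  }
})

test_that("rejection oracle acceptance rate estimates g(n, 1, T)", {
  fx <- fix_locus_single_branch(H = 10, tau = 3, ne = 2, ind = 3)
  st <- coal_settings(1, 2, 3)
  set.seed(49)
  tries <- replicate(800, rejection_oracle_bounded(fx, 2L, st)$tries)
  p_acc <- 1 / mean(tries)    # geometric
  expected <- lineage_transition_prob(3, 1, 3, ne = 2)
  se <- sd(tries) / sqrt(length(tries)) / mean(tries)^2
  expect_lt(abs(p_acc - expected), 4 * se + 0.02)
})

test_that("exact bounded sampler agrees with the rejection oracle (single branch)", {
  fx <- fix_locus_single_branch(H = 10, tau = 3, ne = 2, ind = 4)
  st <- coal_settings(1, 2, 4)
  set.seed(50)
  n <- 1200
  a <- replicate(n, {
    g <- simulate_gene_tree(fx, st); g$tree$time[tree_root(g$tree)]
  })
  b <- replicate(n, {
    o <- rejection_oracle_bounded(fx, 2L, st)
    o$tree$time[tree_root(o$tree)]
  })
  expect_gt(suppressWarnings(ks.test(a, b)$p.value), 0.01)
  expect_true(all(a <= 3))
})
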