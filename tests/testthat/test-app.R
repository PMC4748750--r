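test_that("a null run yields one gene copy per species", {
  cfg <- sim_config(n_replicates = 1, n_families = 1,
                    speciation_rate = 1e-6, n_taxa = 5, height = 1e6,
                    ne = 1000, individuals = 1)
  res <- run_simulation(cfg, seed = 5, out_dir = NULL)
  fam <- res$replicates[[1]]$families[[1]]
  expect_equal(n_leaves(fam$gene$tree),
               n_leaves(res$replicates[[1]]$species_tree))
  expect_equal(res$manifest$duplications, 0)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(n_replicates = 2, n_families = 2,
                    speciation_rate = "F:1e-6", n_taxa = 4, height = 1e6,
                    ne = "U:500,2000", individuals = 1,
                    dup_rate = "U:0,5e-7", loss_rate = "F:1e-7",
                    hgt_rate = "F:1e-7", alpha_gene = 2)
  d1 <- tempfile(); d2 <- tempfile()
  run_simulation(cfg, seed = 99, out_dir = d1)
  run_simulation(cfg, seed = 99, out_dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 4)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("manifest bookkeeping matches replicate and family counts", {
  cfg <- sim_config(n_replicates = 3, n_families = 2,
                    speciation_rate = 1e-6, n_taxa = 4, height = 1e6,
                    ne = 500, individuals = 1)
  res <- run_simulation(cfg, seed = 8)
  expect_equal(nrow(res$manifest), 6)
  expect_equal(length(unique(res$manifest$replicate)), 3)
  expect_equal(length(res$replicates), 3)
})

test_that("closed-form expectation helpers evaluate the printed formulas", {
  expect_equal(expected_values("yule_leaves", lt = 0), 2)
  expect_equal(expected_values("yule_leaves", lt = 1), 2 * exp(1))
  expect_equal(expected_values("yule_leaves", lambda = 2, t = 0.5), 2 * exp(1))
  expect_equal(expected_values("hgt_count", h = 1e-6, l = 5e6), 5)
  expect_error(expected_values("nope"), "unknown expectation")
})

test_that("duplication overestimation is non-negative and handles one-sided cases", {
  fx <- fix_locus_dup(H = 1e6, tau_d = 1e4, ne = 500, ind = 1)
  st <- coal_settings(1, 500, 1)
  set.seed(71)
  for (rep in 1:20) {
    g <- simulate_gene_tree(fx, st)
    ov <- duplication_overestimation(g, fx)
    expect_equal(ov$n_usable, 1)
    expect_gte(ov$mean, 0)
  }
  # a family with no duplication yields no usable rows
  sp <- fix_species_single(1e6, 500)
  loc0 <- simulate_locus_tree(sp)
  g0 <- simulate_gene_tree(loc0, st)
  ov0 <- duplication_overestimation(g0, loc0)
  expect_equal(ov0$n_usable, 0)
  expect_true(is.na(ov0$mean))
})

test_that("gene trees are older than the species tree root under the MSC", {
  cfg <- sim_config(n_replicates = 1, n_families = 5,
                    speciation_rate = 1e-6, n_taxa = 4, height = 1e6,
                    ne = 1000, individuals = 1)
  res <- run_simulation(cfg, seed = 12)
  s <- summarize_replicate(res$replicates[[1]])
  expect_true(all(s$gene_height >= s$species_height - 1e-9))
})

test_that("tiny populations eliminate deep coalescence and hence discordance", {
  set.seed(72)
  sp <- simulate_bdsa(1e-6, 0, 5, height = 1e6)
  sp <- decorate_branches(sp, ne = 1, gen_time = 1, individuals = 1)
  st <- coal_settings(1, 1, 1)
  disc <- 0; n <- 200
  for (r in 1:n) {
    loc <- simulate_locus_tree(sp)
    g <- simulate_gene_tree(loc, st)
    gt <- g$tree
    gt$label[tree_leaves(gt)] <- sub("_0_0$", "", gt$label[tree_leaves(gt)])
    rf <- ape::dist.topo(ape::unroot(as_phylo(gt)),
                         ape::unroot(as_phylo(sp)))
    if (rf > 0) disc <- disc + 1
  }
  expect_lt(disc / n, 0.02)
})

test_that("mapping tables tie every gene node to a locus and species branch", {
  set.seed(73)
  sp <- simulate_bdsa(1e-6, 0, 4, height = 1e6)
  sp <- decorate_branches(sp, ne = 1000, gen_time = 1, individuals = 2)
  loc <- simulate_locus_tree(sp, dup_rate = 3e-7)
  g <- simulate_gene_tree(loc, coal_settings(1, 1000, 2))
  map <- g$mapping
  expect_equal(sort(map$gene_node), seq_along(g$tree$parent))
  expect_true(all(map$locus_branch %in% seq_along(loc$pruned$parent)))
  expect_true(all(map$species_branch %in% seq_along(sp$parent)))
  # event times lie within the mapped locus branch's interval (up to the
  # root stem, which is unbounded above)
  for (r in seq_len(nrow(map))) {
    lb <- map$locus_branch[r]
    lo <- loc$pruned$time[lb]
    hi <- if (is.na(loc$pruned$parent[lb])) Inf
    else loc$pruned$time[loc$pruned$parent[lb]]
    expect_gte(map$time[r], lo - 1e-9)
    expect_lte(map$time[r], hi + 1e-9)
  }
})
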