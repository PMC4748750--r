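make_decorated <- function(n = 5, height = 1e6, ne = 100, ind = 1, seed = 1) {
  set.seed(seed)
  sp <- simulate_bdsa(1e-6, 0, n, height = height)
  decorate_branches(sp, ne = ne, gen_time = 1, individuals = ind)
}

test_that("null locus process reproduces the species tree exactly", {
  sp <- make_decorated(6)
  set.seed(31)
  for (rep in 1:5) {
    loc <- simulate_locus_tree(sp)
    expect_equal(loc$events$duplications, 0)
    expect_equal(loc$events$losses, 0)
    pr <- loc$pruned
    expect_equal(n_leaves(pr), n_leaves(sp))
    # same node times (topology identical by construction of the embedding)
    expect_equal(sort(pr$time), sort(sp$time))
    # leaf labels are species label + copy 0
    lv <- tree_leaves(pr)
    expect_setequal(pr$label[lv], paste0(sp$label[tree_leaves(sp)], "_0"))
  }
})

test_that("duplication-only growth in one species matches exp(rate*T)", {
  sp1 <- fix_species_single(1e6, ne = 100)
  ld <- 1.2e-6
  set.seed(32)
  n <- 2000
  nl <- replicate(n, n_leaves(simulate_locus_tree(sp1, dup_rate = ld)$pruned))
  se <- sd(nl) / sqrt(n)
  expect_lt(abs(mean(nl) - exp(ld * 1e6)), 3 * se)
  # single species, no loss: copies = duplications + 1 (bookkeeping identity)
  set.seed(33)
  for (rep in 1:10) {
    loc <- simulate_locus_tree(sp1, dup_rate = ld)
    expect_equal(n_leaves(loc$pruned), loc$events$duplications + 1)
  }
})

test_that("heavy loss can extinguish families; keep-empty reports them", {
  sp1 <- fix_species_single(1e6, ne = 100)
  set.seed(34)
  res <- replicate(60, is.null(simulate_locus_tree(sp1, loss_rate = 3e-6)$pruned))
  expect_gt(mean(res), 0.8)   # P(loss before present) = 1 - exp(-3) ~ 0.95
  loc <- simulate_locus_tree(sp1, loss_rate = 1e-2)
  expect_null(loc$pruned)
  expect_equal(loc$events$extant_leaves, 0)
})

test_that("receptor choice: uniform, inverse-distance weights, empty sets", {
  # species tree with three tips at controlled distances
  sp <- read_tree("((A:1,B:1):3,C:4);")
  A <- which(sp$label == "A"); B <- which(sp$label == "B")
  C <- which(sp$label == "C")
  # locus tree mirroring the species tree, all lineages alive at tau = 0.5
  loc <- structure(list(
    parent = c(NA_integer_, 1L, 2L, 2L, 1L), time = c(4, 1, 0, 0, 0),
    label = c(NA, NA, "A_0", "B_0", "C_0"),
    annot = list(list(event = "speciation", edge_species = tree_root(sp)),
                 list(event = "speciation", edge_species = sp$parent[A]),
                 list(event = "leaf", edge_species = A),
                 list(event = "leaf", edge_species = B),
                 list(event = "leaf", edge_species = C))), class = "timetree")
  donor <- 3L   # lineage in species A
  # candidates for HGT at tau = 0.5: B (distance 2*(1-0.5)=1) and C (2*(4-0.5)=7)
  set.seed(35)
  picks <- replicate(4000, choose_receptor(loc, donor, 0.5, "hgt", sp,
                                           mode = "inverse_distance"))
  pB <- mean(picks == 4L)
  w <- c(1 / 1, 1 / 7); expe <- w[1] / sum(w)
  expect_lt(abs(pB - expe), 3 * sqrt(expe * (1 - expe) / 4000))
  picks_u <- replicate(2000, choose_receptor(loc, donor, 0.5, "hgt", sp,
                                             mode = "uniform"))
  pBu <- mean(picks_u == 4L)
  expect_lt(abs(pBu - 0.5), 3 * sqrt(0.25 / 2000))
  # conversion with a single copy in the species: no candidate
  expect_true(is.na(choose_receptor(loc, donor, 0.5, "conv", sp)))
  # single candidate chosen with probability one: at tau = 3.5 only the
  # ancestral AB lineage (edge above node 2) and C are alive
  expect_equal(choose_receptor(loc, 2L, 3.5, "hgt", sp), 5L)
})

test_that("a realized transfer performs the SPR and marks the received copy", {
  sp <- make_decorated(2, height = 1e6, ne = 100)
  set.seed(36)
  repeat {
    loc <- simulate_locus_tree(sp, hgt_rate = 1.5e-6)
    if (loc$events$transfers_realized == 1 && loc$events$losses == 0) break
  }
  full <- loc$full
  ev <- vapply(full$annot, function(a) a$event %||% "", character(1))
  expect_equal(sum(ev == "transfer"), 1)
  expect_equal(sum(ev == "replacement_loss"), 1)
  tn <- which(ev == "transfer")
  kids <- tree_children(full, tn)
  expect_equal(length(kids), 2)
  bounded <- vapply(kids, function(k) isTRUE(full$annot[[k]]$bounded), logical(1))
  expect_equal(sum(bounded), 1)
  expect_equal(full$annot[[kids[bounded]]]$bound_time, full$time[tn])
  # both species still carry exactly one extant copy (replacing transfer)
  pr <- loc$pruned
  expect_equal(n_leaves(pr), 2)
  # attempted >= realized
  expect_gte(loc$events$transfers_attempted, loc$events$transfers_realized)
})

test_that("transfer counts follow the pure-birth expectation h*l", {
  sp <- make_decorated(6, height = 1e6, ne = 100)
  h <- 2e-6
  l <- count_events(simulate_locus_tree(sp))$length_gen
  set.seed(37)
  n <- 2000
  cnt <- replicate(n, count_events(simulate_locus_tree(sp, hgt_rate = h))$transfers_attempted)
  se <- sd(cnt) / sqrt(n)
  expect_lt(abs(mean(cnt) - h * l), 3 * se)
  # Poisson: variance close to the mean
  expect_lt(abs(var(cnt) - h * l), 4 * h * l * sqrt(2 / n) + 3 * se)
})

test_that("conversions pick a paralog in the same species", {
  sp1 <- fix_species_single(1e6, ne = 100)
  set.seed(38)
  got <- FALSE
  for (rep in 1:200) {
    loc <- simulate_locus_tree(sp1, dup_rate = 1e-6, conv_rate = 5e-7)
    if (loc$events$conversions_realized >= 1) { got <- TRUE; break }
  }
  expect_true(got)
  ev <- vapply(loc$full$annot, function(a) a$event %||% "", character(1))
  expect_gte(sum(ev == "conversion"), 1)
  # with a single copy a conversion can never realize
  loc0 <- simulate_locus_tree(sp1, conv_rate = 5e-7)
  expect_equal(loc0$events$conversions_realized, 0)
})
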