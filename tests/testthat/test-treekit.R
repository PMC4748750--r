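test_that("Newick reading reconstructs times from branch lengths", {
  tr <- read_tree("(A:1.0,B:1.0):0.0;")
  expect_equal(n_leaves(tr), 2)
  expect_equal(tr$time[tree_root(tr)], 1.0)
  expect_equal(sort(tr$time[tree_leaves(tr)]), c(0, 0))

  tr2 <- read_tree("((A:1,B:1):4,C:5);")
  expect_equal(n_leaves(tr2), 3)
  expect_equal(tr2$time[tree_root(tr2)], 5)
  expect_true(is_ultrametric(tr2))
})

test_that("malformed Newick reports a character position, negative lengths rejected", {
  expect_error(read_tree("(A:1,B:1;"), "character")
  expect_error(read_tree("(A:-1,B:1);"), "negative branch length")
})

test_that("write/read round trip preserves topology, labels and lengths", {
  set.seed(101)
  for (rep in 1:5) {
    tr <- random_tree(12)
    tr2 <- read_tree(write_tree(tr))
    d1 <- sort(leaf_depths(tr)); d2 <- sort(leaf_depths(tr2))
    expect_equal(names(d1), names(d2))
    expect_equal(d1, d2, tolerance = 1e-9)
    # fixpoint after one write/read cycle
    expect_identical(write_tree(tr2), write_tree(read_tree(write_tree(tr2))))
    # cross-check with an independent parser
    ph <- ape::read.tree(text = write_tree(tr))
    expect_equal(sort(ph$tip.label), sort(names(d1)))
  }
})

test_that("NHX annotations survive a round trip", {
  tr <- read_tree("(A:1,B:1[&&NHX:event=duplication:ne=500]):2;")
  b <- which(tr$label == "B")
  expect_identical(tr$annot[[b]]$event, "duplication")
  expect_equal(tr$annot[[b]]$ne, 500)
  out <- write_tree(tr, include_annotations = TRUE)
  expect_match(out, "event=duplication")
  tr2 <- read_tree(out)
  expect_identical(tr2$annot[[which(tr2$label == "B")]]$event, "duplication")
})

test_that("Nexus input with a Translate table yields translated labels", {
  nex <- c("#NEXUS", "BEGIN TREES;", "  TRANSLATE", "    1 A,", "    2 B,",
           "    3 C;",
           "  TREE t1 = ((1:1,2:1):1,3:2);", "END;")
  tr <- read_tree(paste(nex, collapse = "\n"), format = "nexus")
  lv <- tree_leaves(tr)
  expect_setequal(tr$label[lv], c("A", "B", "C"))
  expect_equal(tr$time[tree_root(tr)], 2)
})

test_that("pruning keeps retained node times and sums merged branch lengths", {
  tr <- read_tree("((A:1,B:1):1,C:2);")
  # identity when keeping everything
  pr <- prune_to_sampled(tr, c("A", "B", "C"))
  expect_equal(sort(leaf_depths(pr)), sort(leaf_depths(tr)))
  # caterpillar: dropping a leaf merges path lengths exactly
  cat3 <- read_tree("((A:1,B:1):2,C:3);")
  pr2 <- prune_to_sampled(cat3, c("A", "C"))
  d <- leaf_depths(pr2)
  expect_equal(unname(d["A"]), 3)
  expect_equal(unname(d["C"]), 3)
  expect_equal(n_leaves(pr2), 2)
  expect_error(prune_to_sampled(tr, character(0)), "lost")
})

test_that("pruning preserves times and pairwise leaf distances on random trees", {
  # pairwise patristic distances between kept leaves are invariant under
  # unary suppression; computed by explicit path enumeration
  pair_dist <- function(tr, la, lb) {
    lv <- tree_leaves(tr)
    a <- lv[tr$label[lv] == la]; b <- lv[tr$label[lv] == lb]
    anc <- function(i) {
      out <- i
      while (!is.na(tr$parent[i])) { i <- tr$parent[i]; out <- c(out, i) }
      out
    }
    m <- intersect(anc(a), anc(b))
    mr <- m[which.min(tr$time[m])]
    (tr$time[mr] - tr$time[a]) + (tr$time[mr] - tr$time[b])
  }
  set.seed(102)
  for (rep in 1:5) {
    tr <- random_tree(20)
    lv <- tree_leaves(tr)
    keep <- sample(tr$label[lv], 7)
    pr <- prune_to_sampled(tr, keep)
    for (i in 1:3) {
      ab <- sample(keep, 2)
      expect_equal(pair_dist(pr, ab[1], ab[2]), pair_dist(tr, ab[1], ab[2]),
                   tolerance = 1e-9)
    }
    # retained node times unchanged
    for (k in seq_along(pr$parent)) {
      oid <- pr$annot[[k]]$orig_id
      expect_equal(pr$time[k], tr$time[oid])
    }
  }
})

test_that("contemporary distances: identity, cherry value, path-walk oracle", {
  tr <- read_tree("((A:5,B:5):5,C:10);")
  A <- which(tr$label == "A"); B <- which(tr$label == "B")
  C <- which(tr$label == "C")
  expect_equal(distance_at_time(tr, A, A, 2), 0)
  # cherry with MRCA at 5, tau = 2 -> 2 * (5 - 2) = 6
  expect_equal(distance_at_time(tr, A, B, 2), 6)
  # oracle: walk edge segments of the path between the two contemporary points
  path_walk <- function(tr, a, b, tau) {
    anc_seq <- function(i) {
      out <- i
      while (!is.na(tr$parent[i])) { i <- tr$parent[i]; out <- c(out, i) }
      out
    }
    aa <- anc_seq(a); bb <- anc_seq(b)
    m <- intersect(aa, bb)
    mr <- m[which.min(tr$time[m])]
    (tr$time[mr] - tau) + (tr$time[mr] - tau)
  }
  for (tau in c(0.5, 3, 4.9)) {
    expect_equal(distance_at_time(tr, A, C, tau), path_walk(tr, A, C, tau))
    expect_equal(distance_at_time(tr, B, C, tau), path_walk(tr, B, C, tau))
  }
  expect_error(distance_at_time(tr, A, B, 7), "does not span")
})

test_that("contemporary distances are symmetric and satisfy the triangle inequality", {
  set.seed(103)
  tr <- random_tree(10, height = 4)
  lv <- tree_leaves(tr)
  tau <- 0.1
  prs <- combn(lv[1:4], 2)
  for (cix in seq_len(ncol(prs))) {
    a <- prs[1, cix]; b <- prs[2, cix]
    expect_equal(distance_at_time(tr, a, b, tau),
                 distance_at_time(tr, b, a, tau))
  }
  trio <- lv[1:3]
  dab <- distance_at_time(tr, trio[1], trio[2], tau)
  dbc <- distance_at_time(tr, trio[2], trio[3], tau)
  dac <- distance_at_time(tr, trio[1], trio[3], tau)
  expect_lte(dac, dab + dbc + 1e-12)
})
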