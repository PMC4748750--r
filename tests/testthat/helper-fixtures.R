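# Shared fixtures: hand-built species/locus structures used by the
# coalescent and app tests.  All trees are constructed in code.

mkpath <- function(spn, top) cbind(species = spn, t_top = top)

# single decorated species "(A:H);"
fix_species_single <- function(H, ne, ind = 1, g = 1) {
  sp <- read_tree(sprintf("(A:%.10g);", H))
  for (i in seq_along(sp$parent)) sp$annot[[i]] <- list(ne = ne, g = g)
  sp$annot[[which(sp$label == "A")]]$individuals <- ind
  sp
}

# locus fixture: one species, one bounded leaf (bound at tau); the bounded
# subtree is a single branch entered by `ind` sampled copies
fix_locus_single_branch <- function(H = 10, tau = 3, ne = 2, ind = 4) {
  sp <- fix_species_single(H, ne, ind)
  A <- which(sp$label == "A"); R <- tree_root(sp)
  pruned <- structure(list(
    parent = c(NA_integer_, 1L), time = c(H, 0), label = c(NA, "A_0"),
    annot = list(
      list(event = "speciation", species = R, sp_path = mkpath(R, Inf)),
      list(event = "leaf", species = A, bounded = TRUE, bound_time = tau,
           bound_source = "duplication", sp_path = mkpath(A, H)))),
    class = "timetree")
  list(pruned = pruned, species_tree = sp)
}

# locus fixture: bounded cherry spanning two species (2 + 2 copies)
fix_locus_cherry <- function(ne = 2, ind = 2, tau = 8) {
  sp <- read_tree("((A:5,B:5):5);")
  for (i in seq_along(sp$parent)) sp$annot[[i]] <- list(ne = ne, g = 1,
                                                        individuals = ind)
  A <- which(sp$label == "A"); B <- which(sp$label == "B")
  AB <- sp$parent[A]; R <- tree_root(sp)
  pruned <- structure(list(
    parent = c(NA_integer_, 1L, 2L, 2L), time = c(10, 5, 0, 0),
    label = c(NA, NA, "A_0", "B_0"),
    annot = list(
      list(event = "speciation", species = R, sp_path = mkpath(R, Inf)),
      list(event = "speciation", species = AB, bounded = TRUE,
           bound_time = tau, bound_source = "duplication",
           sp_path = mkpath(AB, 10)),
      list(event = "leaf", species = A, sp_path = mkpath(A, 5)),
      list(event = "leaf", species = B, sp_path = mkpath(B, 5)))),
    class = "timetree")
  list(pruned = pruned, species_tree = sp)
}

# locus fixture: a bounded subtree (bound at 12) containing a nested
# duplication whose new copy is itself bounded at 6; single species
fix_locus_nested <- function(ne = 3, ind = 2) {
  sp <- fix_species_single(20, ne, ind)
  A <- which(sp$label == "A"); R <- tree_root(sp)
  pruned <- structure(list(
    parent = c(NA_integer_, 1L, 2L, 2L, 4L, 4L),
    time = c(20, 12, 0, 6, 0, 0),
    label = c(NA, NA, "A_0", NA, "A_1", "A_2"),
    annot = list(
      list(event = "speciation", species = R, sp_path = mkpath(R, Inf)),
      list(event = "duplication", species = A, sp_path = mkpath(A, 20)),
      list(event = "leaf", species = A, sp_path = mkpath(A, 12)),
      list(event = "duplication", species = A, bounded = TRUE,
           bound_time = 12, bound_source = "duplication",
           sp_path = mkpath(A, 12)),
      list(event = "leaf", species = A, sp_path = mkpath(A, 6)),
      list(event = "leaf", species = A, bounded = TRUE, bound_time = 6,
           bound_source = "duplication", sp_path = mkpath(A, 6)))),
    class = "timetree")
  list(pruned = pruned, species_tree = sp)
}

# locus fixture: one duplication at tau_d in a single long species branch
# (the classic duplication-overestimation scenario)
fix_locus_dup <- function(H = 1e6, tau_d = 1e4, ne = 1000, ind = 1) {
  sp <- fix_species_single(H, ne, ind)
  A <- which(sp$label == "A"); R <- tree_root(sp)
  pruned <- structure(list(
    parent = c(NA_integer_, 1L, 2L, 2L), time = c(H, tau_d, 0, 0),
    label = c(NA, NA, "A_0", "A_1"),
    annot = list(
      list(event = "speciation", species = R, sp_path = mkpath(R, Inf)),
      list(event = "duplication", species = A, sp_path = mkpath(A, H)),
      list(event = "leaf", species = A, sp_path = mkpath(A, tau_d)),
      list(event = "leaf", species = A, bounded = TRUE, bound_time = tau_d,
           bound_source = "duplication", sp_path = mkpath(A, tau_d)))),
    class = "timetree")
  list(pruned = pruned, species_tree = sp)
}

# time of the most recent common ancestor of a set of nodes
mrca_time <- function(tr, ids) {
  anc <- function(i) {
    out <- i
    while (!is.na(tr$parent[i])) { i <- tr$parent[i]; out <- c(out, i) }
    out
  }
  min(tr$time[Reduce(intersect, lapply(ids, anc))])
}

tmrca_of_pattern <- function(tr, pattern) {
  lv <- tree_leaves(tr)
  mrca_time(tr, lv[grepl(pattern, tr$label[lv])])
}

# leaf depths (root-to-leaf path lengths) by explicit edge walking
leaf_depths <- function(tr) {
  lv <- tree_leaves(tr)
  d <- vapply(lv, function(i) {
    s <- 0
    while (!is.na(tr$parent[i])) {
      s <- s + tr$time[tr$parent[i]] - tr$time[i]
      i <- tr$parent[i]
    }
    s
  }, numeric(1))
  names(d) <- tr$label[lv]
  d
}

# random ultrametric tree for property tests
random_tree <- function(n, height = 1) {
  ph <- ape::rcoal(n)
  ph$edge.length <- ph$edge.length / max(ape::branching.times(ph)) * height
  read_tree(ape::write.tree(ph))
}
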