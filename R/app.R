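# Orchestration ------------------------------------------------------------
#
# One replicate = one species tree plus n_families locus/gene tree pairs.
# Everything is reconstructible from (config, seed): each simulation unit
# draws from a deterministic RNG substream keyed by (seed, replicate,
# family, purpose).

#' Run a full simulation
#'
#' For each replicate: resolve the parameter layers, simulate (or reuse) a
#' species tree, then per gene family a locus tree, a gene tree and its
#' substitution-scaled version.  Outputs are written one directory per
#' replicate: `s_tree.trees`, `l_trees.trees`, `g_trees<f>.trees`
#' (substitution units), `g_trees<f>.gen.trees` (time/generation units,
#' when `keep_generations`), per-family mapping TSVs, and a `manifest.tsv`
#' with every sampled parameter and tree statistic.
#'
#' @param config A [sim_config()] list (or path to a config file).
#' @param seed Master integer seed.
#' @param out_dir Output directory (`NULL` to skip writing files).
#' @param keep_generations Also write gene trees in time units.
#' @param verbosity 0-3; >= 1 writes mappings, >= 2 prints progress.
#' @return Invisibly, a list of replicate results (species tree, per-family
#'   locus/gene trees, manifest data.frame).
#' @export
run_simulation <- function(config, seed = 1L, out_dir = NULL,
                           keep_generations = FALSE, verbosity = 1L) {
  if (is.character(config)) config <- read_config(config)
  nrep <- as.integer(config$n_replicates %||% 1)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reps <- vector("list", nrep)
  for (r in seq_len(nrep)) {
    reps[[r]] <- run_replicate(config, seed, r)
    if (!is.null(out_dir))
      write_replicate(reps[[r]], file.path(out_dir, r), keep_generations,
                      verbosity)
    if (verbosity >= 2) message("replicate ", r, " done")
  }
  manifest <- do.call(rbind, lapply(reps, `[[`, "manifest"))
  if (!is.null(out_dir))
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(replicates = reps, manifest = manifest, seed = seed))
}

run_replicate <- function(config, seed, r) {
  layers <- resolve_layers(config, seed, r)
  rv <- layers$replicate
  ploidy <- config$ploidy %||% 1
  settings <- coal_settings(ploidy = ploidy,
                            default_ne = rv$ne %||% 10000,
                            default_individuals = rv$individuals %||% 1)
  clock <- clock_settings(subst_rate = rv$subst_rate %||% 1e-8,
                          alpha_species = rv$alpha_species,
                          alpha_family = rv$alpha_family,
                          alpha_gene = rv$alpha_gene)
  sp <- with_substream(seed, r, 0L, 1L, expr = {
    tr <- if (!is.null(rv$n_taxa))
      simulate_bdsa(rv$speciation_rate, rv$extinction_rate %||% 0,
                    n_taxa = max(2, round(rv$n_taxa)), height = rv$height)
    else
      simulate_ssa(rv$speciation_rate, rv$extinction_rate %||% 0,
                   origin_time = rv$height)
    if (!is.null(rv$outgroup) && rv$outgroup > 0)
      tr <- add_outgroup(tr, rv$outgroup)
    decorate_branches(tr, ne = rv$ne %||% 10000, gen_time = rv$gen_time %||% 1,
                      individuals = rv$individuals %||% 1, env = rv)
  })
  m_sp <- with_substream(seed, r, 0L, 2L, expr =
    species_layer_multipliers(sp, clock$alpha_species))
  nf <- nrow(layers$families)
  fams <- vector("list", nf)
  man_rows <- list()
  for (f in seq_len(nf)) {
    rates <- layers$families[f, ]
    fam <- with_substream(seed, r, f, 3L, expr = {
      loc <- simulate_locus_tree(sp, dup_rate = rates$dup_rate,
                                 loss_rate = rates$loss_rate,
                                 hgt_rate = rates$hgt_rate,
                                 conv_rate = rates$conv_rate,
                                 receptor_mode = config$receptor_mode %||% "uniform")
      if (is.null(loc$pruned) &&
          identical(config$lost_policy %||% "keep-empty", "resample")) {
        tries <- 0L
        while (is.null(loc$pruned) && tries < 1000L) {
          loc <- simulate_locus_tree(sp, dup_rate = rates$dup_rate,
                                     loss_rate = rates$loss_rate,
                                     hgt_rate = rates$hgt_rate,
                                     conv_rate = rates$conv_rate,
                                     receptor_mode = config$receptor_mode %||% "uniform")
          tries <- tries + 1L
        }
      }
      gene <- simulate_gene_tree(loc, settings)
      m_fam <- if (is.null(clock$alpha_family)) 1
      else sample_mean_one_multiplier(clock$alpha_family)
      scaled <- if (!is.null(gene))
        apply_clock_model(gene, loc, clock, m_species = m_sp, m_family = m_fam)
      else NULL
      list(locus = loc, gene = gene, scaled = scaled, m_family = m_fam,
           rates = rates)
    })
    fams[[f]] <- fam
    ev <- count_events(fam$locus)
    man_rows[[f]] <- data.frame(
      replicate = r, family = f,
      n_species = n_leaves(sp), species_height = sp$time[tree_root(sp)],
      dup_rate = rates$dup_rate, loss_rate = rates$loss_rate,
      hgt_rate = rates$hgt_rate, conv_rate = rates$conv_rate,
      ne = rv$ne %||% 10000, individuals = rv$individuals %||% 1,
      duplications = ev$duplications, losses = ev$losses,
      transfers_attempted = ev$transfers_attempted,
      transfers_realized = ev$transfers_realized,
      conversions_attempted = ev$conversions_attempted,
      conversions_realized = ev$conversions_realized,
      extant_leaves = ev$extant_leaves,
      locus_length_gen = ev$length_gen,
      gene_leaves = if (!is.null(fam$gene)) n_leaves(fam$gene$tree) else 0L,
      gene_height = if (!is.null(fam$gene))
        fam$gene$tree$time[tree_root(fam$gene$tree)] else NA_real_)
  }
  list(species_tree = sp, families = fams, layers = layers,
       m_species = m_sp, manifest = do.call(rbind, man_rows))
}

write_replicate <- function(rep, dir, keep_generations, verbosity) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(write_tree(rep$species_tree), file.path(dir, "s_tree.trees"))
  lt <- vapply(rep$families, function(f)
    if (!is.null(f$locus$pruned)) write_tree(f$locus$pruned,
                                             include_annotations = TRUE)
    else "", character(1))
  writeLines(lt, file.path(dir, "l_trees.trees"))
  for (f in seq_along(rep$families)) {
    fam <- rep$families[[f]]
    if (is.null(fam$gene)) next
    writeLines(write_tree(fam$scaled$tree),
               file.path(dir, sprintf("g_trees%d.trees", f)))
    if (keep_generations)
      writeLines(write_tree(fam$gene$tree),
                 file.path(dir, sprintf("g_trees%d.gen.trees", f)))
    if (verbosity >= 1)
      write_mapping(fam$gene$mapping,
                    file.path(dir, sprintf("mapping%d.tsv", f)))
  }
}

#' Closed-form expectations used by the validation suite
#'
#' `yule_leaves`: expected extant leaf count of a pure-birth tree started
#' from two lineages, `2 * exp(lambda * t)`.  `hgt_count`: expected number
#' of transfer events on a locus tree of total length `l` under a
#' pure-birth transfer process of rate `h`, `h * l`.
#'
#' @param kind `"yule_leaves"` or `"hgt_count"`.
#' @param ... For `yule_leaves`: `lambda`, `t` (or their product `lt`).
#'   For `hgt_count`: `h`, `l`.
#' @return The expectation (scalar).
#' @export
expected_values <- function(kind, ...) {
  args <- list(...)
  switch(kind,
    yule_leaves = {
      lt <- args$lt %||% (args$lambda * args$t)
      2 * exp(lt)
    },
    hgt_count = args$h * args$l,
    stop("unknown expectation kind: ", kind))
}

#' Duplication-time overestimation
#'
#' For every duplication surviving in the pruned locus tree with sampled
#' descendants in both copies, the distance (in generations) between the
#' duplication node and the first gene-tree coalescence joining a lineage
#' descending from the new copy with one from the old copy.  Reconciliation
#' methods unaware of the locus tree date the duplication at that
#' coalescence, hence the overestimate.
#'
#' @param gene Result of [simulate_gene_tree()].
#' @param locus Result of [simulate_locus_tree()].
#' @return A list with `per_duplication` (data.frame: locus node, times,
#'   overestimate in generations and time units), `mean` (replicate mean in
#'   generations; `NA` when no usable duplication), `n_usable`,
#'   `n_one_sided` (duplications with sampled descendants on one side only).
#' @export
duplication_overestimation <- function(gene, locus) {
  pruned <- locus$pruned
  sp <- locus$species_tree
  out <- data.frame()
  n_one_sided <- 0L
  if (is.null(pruned) || is.null(gene))
    return(list(per_duplication = out, mean = NA_real_, n_usable = 0L,
                n_one_sided = 0L))
  gt <- gene$tree
  ch <- children_list(pruned)
  gch <- children_list(gt)
  # gene leaves descending from each pruned locus node
  locus_desc <- function(lnode) {
    stack <- lnode; leaves <- integer(0)
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      kids <- ch[[i]]
      if (length(kids)) stack <- c(stack, kids) else leaves <- c(leaves, i)
    }
    leaves
  }
  glv <- tree_leaves(gt)
  gene_edge <- vapply(glv, function(i) gt$annot[[i]]$locus_edge, numeric(1))
  dups <- which(vapply(seq_along(pruned$parent), function(i) {
    a <- pruned$annot[[i]]
    isTRUE(a$bounded) && identical(a$bound_source, "duplication")
  }, logical(1)))
  for (d in dups) {
    dn <- pruned$parent[d]
    tau <- pruned$annot[[d]]$bound_time
    new_leaves <- locus_desc(d)
    # the old copy survives only if the duplication node itself is retained
    other <- if (!is.na(dn) &&
                 identical(pruned$annot[[dn]]$event, "duplication"))
      setdiff(ch[[dn]], d) else integer(0)
    if (!length(other)) { n_one_sided <- n_one_sided + 1L; next }
    old_leaves <- unlist(lapply(other, locus_desc))
    gnew <- glv[gene_edge %in% new_leaves]
    gold <- glv[gene_edge %in% old_leaves]
    if (!length(gnew) || !length(gold)) { n_one_sided <- n_one_sided + 1L; next }
    tmrca <- gene_mrca_time(gt, gnew, gold)
    # convert the time-axis distance to generations through the species
    # branches it spans (the coalescence sits above the duplication)
    gen <- timespan_generations(pruned, sp, d, tau, tmrca)
    out <- rbind(out, data.frame(locus_node = d, dup_time = tau,
                                 first_cross_coalescence = tmrca,
                                 over_time = tmrca - tau,
                                 over_gen = gen))
  }
  list(per_duplication = out,
       mean = if (nrow(out)) mean(out$over_gen) else NA_real_,
       n_usable = nrow(out), n_one_sided = n_one_sided)
}

# earliest (youngest-time) coalescence joining set A with set B
gene_mrca_time <- function(gt, A, B) {
  n <- length(gt$parent)
  hasA <- rep(FALSE, n); hasB <- rep(FALSE, n)
  hasA[A] <- TRUE; hasB[B] <- TRUE
  ord <- order(gt$time)
  best <- Inf
  for (i in ord) {
    p <- gt$parent[i]
    if (is.na(p)) next
    hasA[p] <- hasA[p] || hasA[i]
    hasB[p] <- hasB[p] || hasB[i]
  }
  # first node (smallest time) subtending both sets
  cand <- which(hasA & hasB)
  min(gt$time[cand])
}

# generations elapsed between times t0 < t1 along the ancestry of pruned
# locus node d (walking up through species branches)
timespan_generations <- function(pruned, sp, d, t0, t1) {
  gen <- 0
  node <- d
  t <- t0
  while (t < t1 - 1e-12 * max(1, t1)) {
    segs <- branch_species_segments(pruned, node)
    for (r in seq_len(nrow(segs))) {
      if (segs$t_hi[r] <= t) next
      hi <- min(segs$t_hi[r], t1)
      if (hi > t) {
        g <- sp$annot[[segs$species[r]]]$g %||% 1
        gen <- gen + (hi - t) * g
        t <- hi
      }
      if (t >= t1) break
    }
    if (t >= t1 - 1e-12 * max(1, t1)) break
    nxt <- pruned$parent[node]
    if (is.na(nxt)) break
    node <- nxt
  }
  gen
}

#' Summary statistics of a replicate
#'
#' @param rep One element of `run_simulation()$replicates`.
#' @return A data.frame with per-family tree statistics and an ILS
#'   indicator (gene/locus topology discordance on shared leaves, computed
#'   with \pkg{ape}'s Robinson-Foulds distance where both trees have >= 4
#'   shared leaves and one gene copy per species).
#' @export
summarize_replicate <- function(rep) {
  sp <- rep$species_tree
  rows <- lapply(seq_along(rep$families), function(f) {
    fam <- rep$families[[f]]
    loc <- fam$locus
    discord <- NA
    if (!is.null(fam$gene) && !is.null(loc$pruned)) {
      gt <- fam$gene$tree
      lt <- loc$pruned
      if (n_leaves(lt) >= 4 && n_leaves(gt) == n_leaves(lt)) {
        gph <- as_phylo(strip_gene_individual(gt))
        lph <- as_phylo(lt)
        if (setequal(gph$tip.label, lph$tip.label))
          discord <- tryCatch(
            ape::dist.topo(ape::unroot(gph), ape::unroot(lph)) > 0,
            error = function(e) NA)
      }
    }
    data.frame(family = f,
               locus_leaves = if (!is.null(loc$pruned)) n_leaves(loc$pruned) else 0L,
               gene_height = if (!is.null(fam$gene))
                 fam$gene$tree$time[tree_root(fam$gene$tree)] else NA_real_,
               species_height = sp$time[tree_root(sp)],
               discordant = discord)
  })
  do.call(rbind, rows)
}

strip_gene_individual <- function(gt) {
  lv <- tree_leaves(gt)
  gt$label[lv] <- sub("_[0-9]+$", "", gt$label[lv])
  gt
}
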