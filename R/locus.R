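# Locus tree simulation --------------------------------------------------
#
# Per gene family, locus lineages evolve inside the species tree: a linear
# birth-death process (duplication, loss) plus two pure-birth processes
# (replacing HGT, gene conversion) run along each species branch in
# preorder.  Transfers and conversions are recorded as pending events on
# the first pass; a second pass, in chronological order from the oldest
# event, picks a receptor among contemporary locus lineages and performs
# the subtree-prune-regraft: the receptor lineage is terminated by a
# replacement-loss node and its continuation toward the present is
# regrafted onto the donor.  New duplicate / received copies are coalescent
# bounds for the gene tree stage.
#
# Rates are per generation; a per-branch generation time g converts branch
# durations in time units to generations.

#' Simulate the locus tree of one gene family inside a species tree
#'
#' @param species_tree A decorated species `timetree` (annotations `ne`,
#'   `g`, `individuals`; see [decorate_branches()]).  A bare tree is
#'   accepted (Ne 10000, g 1, 1 individual).
#' @param dup_rate,loss_rate,hgt_rate,conv_rate Per-generation rates.
#' @param receptor_mode `"uniform"` or `"inverse_distance"`: how HGT/GC
#'   receptors are chosen among contemporary candidates (inverse-distance
#'   weights are `1/d` with `d` the patristic distance between donor and
#'   candidate species at the event time).
#' @return A list with components:
#'   \item{full}{the complete annotated locus `timetree` (lost subtrees
#'     retained, event kinds in `annot$event`);}
#'   \item{pruned}{the locus tree pruned to extant sampled leaves, or
#'     `NULL` when the family was completely lost;}
#'   \item{events}{tally of duplications, losses, attempted and realized
#'     transfers/conversions;}
#'   \item{species_tree}{the input tree (for downstream mapping).}
#' @export
simulate_locus_tree <- function(species_tree, dup_rate = 0, loss_rate = 0,
                                hgt_rate = 0, conv_rate = 0,
                                receptor_mode = c("uniform", "inverse_distance")) {
  receptor_mode <- match.arg(receptor_mode)
  stopifnot(dup_rate >= 0, loss_rate >= 0, hgt_rate >= 0, conv_rate >= 0)
  sp <- species_tree
  sp_ch <- children_list(sp)
  rates <- c(dup = dup_rate, loss = loss_rate, hgt = hgt_rate, conv = conv_rate)
  total <- sum(rates)

  tb <- tree_builder()
  pend <- new.env(parent = emptyenv())
  pend$events <- list()   # each: list(kind, time, donor_child = node id)
  copy_counter <- new.env(parent = emptyenv())
  copy_counter$v <- integer(length(sp$parent))

  g_of <- function(sp_node) sp$annot[[sp_node]]$g %||% 1

  # simulate one locus lineage along the species edge above sp_node,
  # entering at time t_entry; returns the id of the next locus node created
  sim_lineage <- function(sp_node, t_entry, parent_locus) {
    t <- t_entry
    t_end <- sp$time[sp_node]
    gb <- g_of(sp_node)
    pending_here <- list()
    node <- NA_integer_
    repeat {
      w <- if (total > 0) stats::rexp(1, total * gb) else Inf
      if (t - w <= t_end) {
        # reach the species node
        if (length(sp_ch[[sp_node]]) == 0L) {
          copy <- copy_counter$v[sp_node]
          copy_counter$v[sp_node] <- copy + 1L
          node <- tb_add(tb, parent_locus, t_end,
                         label = paste0(sp$label[sp_node], "_", copy),
                         annot = list(event = "leaf", species = sp_node,
                                      edge_species = sp_node))
        } else {
          node <- tb_add(tb, parent_locus, t_end,
                         annot = list(event = "speciation", species = sp_node,
                                      edge_species = sp_node))
          for (kid in sp_ch[[sp_node]]) sim_lineage(kid, t_end, node)
        }
        break
      }
      t <- t - w
      kind <- sample(names(rates), 1, prob = rates)
      if (kind == "dup") {
        node <- tb_add(tb, parent_locus, t,
                       annot = list(event = "duplication", species = sp_node,
                                    edge_species = sp_node))
        sim_lineage(sp_node, t, node)                      # original copy
        newc <- sim_lineage(sp_node, t, node)              # new (bounded) copy
        tb$annot[[newc]]$bounded <- TRUE
        tb$annot[[newc]]$bound_time <- t
        tb$annot[[newc]]$bound_source <- "duplication"
        break
      } else if (kind == "loss") {
        node <- tb_add(tb, parent_locus, t,
                       annot = list(event = "loss", species = sp_node,
                                    edge_species = sp_node))
        break
      } else {
        # transfer / conversion: donor lineage continues; resolved later
        pending_here[[length(pending_here) + 1L]] <-
          list(kind = kind, time = t, sp_node = sp_node)
      }
    }
    if (length(pending_here)) {
      for (ev in pending_here) {
        ev$donor_child <- node
        pend$events[[length(pend$events) + 1L]] <- ev
      }
    }
    node
  }

  # seed the process at the species root
  sp_root <- tree_root(sp)
  if (length(sp_ch[[sp_root]]) == 0L) {
    # single-species tree: one locus lineage from the root time
    lr <- tb_add(tb, NULL, sp$time[sp_root] + 0,
                 annot = list(event = "origin", species = sp_root,
                              edge_species = sp_root))
    # the origin node is a placeholder at the branch top with one child
    sim_lineage(sp_root, sp$time[sp_root], lr)
  } else {
    lr <- tb_add(tb, NULL, sp$time[sp_root],
                 annot = list(event = "speciation", species = sp_root,
                              edge_species = sp_root))
    for (kid in sp_ch[[sp_root]]) sim_lineage(kid, sp$time[sp_root], lr)
  }

  tr <- tb_finalize(tb)
  ntally <- c(duplications = sum(vapply(tr$annot, function(a)
                identical(a$event, "duplication"), logical(1))),
              losses = sum(vapply(tr$annot, function(a)
                identical(a$event, "loss"), logical(1))))

  res <- resolve_pending(tr, pend$events, sp, receptor_mode)
  tr <- res$tree
  events <- c(as.list(ntally), res$tally)

  # prune to extant leaves
  lv <- tree_leaves(tr)
  extant <- lv[vapply(lv, function(i)
    identical(tr$annot[[i]]$event, "leaf"), logical(1))]
  pruned <- if (length(extant)) {
    p <- prune_to_sampled(tr, tr$label[extant])
    annotate_species_paths(p, tr, sp)
  } else NULL
  events$extant_leaves <- length(extant)
  list(full = tr, pruned = pruned, events = events, species_tree = sp)
}

# Receptor choice and SPR -------------------------------------------------

# edges alive at time tau: child nodes whose edge [time[i], time[parent]]
# strictly spans tau
edges_alive_at <- function(tr, tau) {
  cand <- which(!is.na(tr$parent))
  cand[tr$time[cand] < tau & tr$time[tr$parent[cand]] > tau]
}

#' Choose a receptor for a transfer/conversion event
#'
#' @param tr The (current) locus `timetree`.
#' @param donor_child Node id identifying the donor edge (edge above it).
#' @param tau Event time.
#' @param kind `"hgt"` (receptor in a different species) or `"conv"`
#'   (paralogous lineage in the same species).
#' @param species_tree The species tree (for inverse-distance weighting).
#' @param mode `"uniform"` or `"inverse_distance"`.
#' @return The receptor's child-node id, or `NA` when no candidate exists.
#' @export
choose_receptor <- function(tr, donor_child, tau, kind, species_tree,
                            mode = c("uniform", "inverse_distance")) {
  mode <- match.arg(mode)
  alive <- edges_alive_at(tr, tau)
  alive <- setdiff(alive, donor_child)
  esp <- vapply(alive, function(i) tr$annot[[i]]$edge_species, numeric(1))
  donor_sp <- tr$annot[[donor_child]]$edge_species
  cand <- if (kind == "hgt") alive[esp != donor_sp] else alive[esp == donor_sp]
  if (!length(cand)) return(NA_integer_)
  if (length(cand) == 1L) return(cand)
  if (mode == "uniform" || kind == "conv") return(sample(cand, 1))
  d <- vapply(cand, function(i)
    distance_at_time(species_tree, tr$annot[[i]]$edge_species, donor_sp, tau),
    numeric(1))
  w <- 1 / pmax(d, .Machine$double.eps)
  cand[sample.int(length(cand), 1, prob = w)]
}

resolve_pending <- function(tr, events, species_tree, mode) {
  tally <- list(transfers_attempted = 0L, transfers_realized = 0L,
                conversions_attempted = 0L, conversions_realized = 0L)
  if (!length(events)) return(list(tree = tr, tally = tally))
  # strict chronological order, oldest (largest time) first; ties broken by
  # creation index
  ord <- order(-vapply(events, `[[`, numeric(1), "time"), seq_along(events))
  mut <- as_builder(tr)
  for (k in ord) {
    ev <- events[[k]]
    att <- if (ev$kind == "hgt") "transfers_attempted" else "conversions_attempted"
    tally[[att]] <- tally[[att]] + 1L
    cur <- tb_finalize(mut)
    rec <- choose_receptor(cur, ev$donor_child, ev$time, ev$kind, species_tree, mode)
    if (is.na(rec)) next
    rl <- if (ev$kind == "hgt") "transfers_realized" else "conversions_realized"
    tally[[rl]] <- tally[[rl]] + 1L
    d_child <- ev$donor_child
    d_par <- mut$parent[d_child]
    r_par <- mut$parent[rec]
    ekind <- if (ev$kind == "hgt") "transfer" else "conversion"
    dsp <- mut$annot[[d_child]]$edge_species
    # incorporation node on the donor edge
    Tn <- tb_add(mut, d_par, ev$time,
                 annot = list(event = ekind, species = dsp, edge_species = dsp))
    mut$parent[d_child] <- Tn
    # replacement-loss stub terminating the receptor lineage
    rsp <- mut$annot[[rec]]$edge_species
    tb_add(mut, r_par, ev$time,
           annot = list(event = "replacement_loss", species = rsp,
                        edge_species = rsp, replaced_by = Tn))
    # regraft the receptor's continuation under the donor; it becomes a
    # coalescent-bounded received copy
    mut$parent[rec] <- Tn
    a <- mut$annot[[rec]]
    a$bounded <- TRUE
    a$bound_time <- ev$time
    a$bound_source <- ekind
    mut$annot[[rec]] <- a
  }
  list(tree = tb_finalize(mut), tally = tally)
}

as_builder <- function(tr) {
  tb <- tree_builder(length(tr$parent))
  tb$parent <- tr$parent
  tb$time <- tr$time
  tb$label <- tr$label
  tb$annot <- tr$annot
  tb$n <- length(tr$parent)
  tb
}

# Species-path annotation -------------------------------------------------
# After pruning, a locus edge may span several species branches (suppressed
# speciations).  For the coalescent and the clock stages each pruned edge
# gets annot$sp_path: a matrix with rows (species node id, t_top) listing,
# bottom-up, in which species branch the edge lies up to which time.

annotate_species_paths <- function(pruned, full, sp) {
  for (i in seq_along(pruned$parent)) {
    a <- pruned$annot[[i]]
    segs_sp <- a$edge_species
    segs_top <- NA_real_
    chain <- a$pruned_chain %||% integer(0)
    # chain is youngest-first list of suppressed raw nodes above orig node
    sp_seq <- a$edge_species
    t_seq <- numeric(0)
    cur_nodes <- c(a$orig_id, chain)
    for (j in seq_along(cur_nodes)) {
      nd <- cur_nodes[j]
      rawp <- full$parent[nd]
      top <- if (is.na(rawp)) Inf else full$time[rawp]
      sp_here <- full$annot[[nd]]$edge_species
      if (j == 1L) {
        sp_seq <- sp_here; t_seq <- top
      } else if (sp_here == sp_seq[length(sp_seq)]) {
        t_seq[length(t_seq)] <- top
      } else {
        sp_seq <- c(sp_seq, sp_here); t_seq <- c(t_seq, top)
      }
    }
    a$sp_path <- cbind(species = sp_seq, t_top = t_seq)
    pruned$annot[[i]] <- a
  }
  pruned
}

#' Tally the events recorded on a simulated locus tree
#'
#' @param locus A result of [simulate_locus_tree()].
#' @return A list with event counts, extant leaf count, per-species copy
#'   counts, and the pruned-tree total length in generations (`length_gen`)
#'   and time units (`length_time`).
#' @export
count_events <- function(locus) {
  ev <- locus$events
  out <- ev
  pr <- locus$pruned
  sp <- locus$species_tree
  if (!is.null(pr)) {
    lens_t <- branch_length(pr)
    out$length_time <- sum(lens_t, na.rm = TRUE)
    gl <- 0
    for (i in seq_along(pr$parent)) {
      if (is.na(pr$parent[i])) next
      path <- pr$annot[[i]]$sp_path
      t0 <- pr$time[i]
      t_end <- pr$time[pr$parent[i]]
      for (r in seq_len(nrow(path))) {
        t1 <- min(path[r, "t_top"], t_end)
        g <- sp$annot[[path[r, "species"]]]$g %||% 1
        gl <- gl + max(0, t1 - t0) * g
        t0 <- t1
        if (t0 >= t_end) break
      }
    }
    out$length_gen <- gl
    lv <- tree_leaves(pr)
    spid <- vapply(lv, function(i) pr$annot[[i]]$species, numeric(1))
    out$copies_per_species <- table(sp$label[spid])
  } else {
    out$length_time <- 0; out$length_gen <- 0
    out$copies_per_species <- table(character(0))
  }
  out
}
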