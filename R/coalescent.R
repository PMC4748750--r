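# Gene tree simulation ----------------------------------------------------
#
# Gene genealogies evolve inside the pruned locus tree.  Branches that are
# not part of a bounded subtree follow the plain multispecies coalescent:
# exponential waits at rate k(k-1)/(2*p*Ne) per generation.  Subtrees
# founded by a duplication / transfer / conversion are coalescent-bounded:
# the sampled lineages must have coalesced down to exactly one by the
# founding event's time.  Those are sampled exactly (no rejection) by
# (i) a bottom-up dynamic program over the distribution of lineage counts
# on every branch, (ii) a top-down inverse-CDF sampling of the realized
# counts with the root count fixed to one, and (iii) inverse-CDF sampling
# of the coalescence times conditioned on the counts.
#
# Scaled time: tau = t_generations / (p * Ne), so that k lineages coalesce
# at rate k(k-1)/2 per scaled unit.  Under this convention the expected
# pairwise coalescence time is Ne generations for haploids (p = 1) and
# 2*Ne for diploids (p = 2).

#' Coalescent settings
#'
#' @param ploidy 1 (haploid) or 2 (diploid); scales the coalescence rate
#'   `k(k-1)/(2*p*Ne)` per generation.
#' @param default_ne Effective population size used for branches without an
#'   `ne` annotation.
#' @param default_individuals Sampled individuals per species for leaves
#'   without an `individuals` annotation.
#' @return A list of class `coal_settings`.
#' @export
coal_settings <- function(ploidy = 1, default_ne = 10000,
                          default_individuals = 1) {
  stopifnot(ploidy %in% c(1, 2), default_ne >= 1, default_individuals >= 1)
  structure(list(ploidy = ploidy, default_ne = default_ne,
                 default_individuals = default_individuals),
            class = "coal_settings")
}

# Lineage-count transition probabilities ----------------------------------

#' Probability that i lineages leave j ancestors after time t
#'
#' The classical alternating-sum closed form of the pure-death lineage
#' count process, evaluated in log space.  When catastrophic cancellation
#' is detected (small scaled times with many lineages) the whole row is
#' recomputed by uniformization of the death chain, a stable all-positive
#' series.
#'
#' @param i Initial lineage count.
#' @param j Ancestor count, `1 <= j <= i`.
#' @param t Elapsed time in generations.
#' @param ne Effective population size.
#' @param p Ploidy.
#' @return The transition probability.
#' @export
lineage_transition_prob <- function(i, j, t, ne = 1, p = 1) {
  if (j > i || j < 1) stop("need 1 <= j <= i")
  if (t < 0) stop("negative time")
  gij_row(i, t / (p * ne))[j]
}

# row of transition probabilities g(i, j, tau) for j = 1..i
gij_row <- function(i, tau) {
  i <- as.integer(i)
  if (i == 1L) return(1)
  if (tau == 0) return(c(rep(0, i - 1L), 1))
  out <- numeric(i)
  unstable <- FALSE
  for (j in seq_len(i)) {
    k <- j:i
    logmag <- -k * (k - 1) * tau / 2 + log(2 * k - 1) -
      lgamma(j + 1) - lgamma(k - j + 1) +
      (lgamma(j + k - 1) - lgamma(j)) +
      (lgamma(i + 1) - lgamma(i - k + 1)) -
      (lgamma(i + k) - lgamma(i))
    sgn <- ifelse((k - j) %% 2 == 0, 1, -1)
    M <- max(logmag)
    s <- sum(sgn * exp(logmag - M))
    sabs <- sum(exp(logmag - M))
    val <- exp(M) * s
    if (!is.finite(val) || val < -1e-12 || val > 1 + 1e-9 ||
        (sabs > 0 && abs(s) / sabs < 1e-8)) {
      unstable <- TRUE
      break
    }
    out[j] <- max(val, 0)
  }
  if (unstable || abs(sum(out) - 1) > 1e-7) out <- gij_row_uniformization(i, tau)
  out
}

# uniformization: e^{Q tau} row of the pure-death chain, all-positive terms
gij_row_uniformization <- function(i, tau) {
  lam <- i * (i - 1) / 2
  ltau <- lam * tau
  v <- numeric(i); v[i] <- 1
  # B = I + Q/lam acting on row vectors: state k keeps 1 - r_k/lam, moves
  # r_k/lam to k-1
  rates <- (1:i) * (0:(i - 1)) / 2 / lam
  acc <- numeric(i)
  # Poisson weights in log space, truncation at 1 - 1e-14 mass
  m_max <- max(20, ceiling(ltau + 12 * sqrt(ltau + 1)))
  logw <- -ltau
  cum <- exp(logw)
  acc <- acc + exp(logw) * v
  for (m in seq_len(m_max)) {
    nv <- v * (1 - rates)
    nv[1:(i - 1)] <- nv[1:(i - 1)] + v[2:i] * rates[2:i]
    v <- nv
    logw <- logw + log(ltau) - log(m)
    w <- exp(logw)
    acc <- acc + w * v
    cum <- cum + w
    if (cum > 1 - 1e-14 && m > ltau) break
  }
  # remaining mass: chain has essentially converged; assign to current v
  acc <- acc + max(0, 1 - cum) * v
  pmax(acc, 0)
}

# memoized row access (per-session cache, size-capped)
.gij_cache <- new.env(parent = emptyenv())
gij_cached <- function(i, tau) {
  key <- paste0(i, "_", signif(tau, 12))
  hit <- .gij_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- gij_row(i, tau)
  n <- (.gij_cache[["..n"]] %||% 0L) + 1L
  if (n > 20000L) {
    rm(list = ls(.gij_cache), envir = .gij_cache)
    n <- 1L
  }
  .gij_cache[["..n"]] <- n
  .gij_cache[[key]] <- val
  val
}

# g(i, j, tau) evaluated on a vector of scaled times; alternating-sum form
# with coefficients computed once.  Cancellation noise near tau -> 0 is
# clipped at zero (the true value there is itself ~0 unless j = i).
gij_curve <- function(i, j, tau_vec) {
  if (i == j) return(exp(-i * (i - 1) / 2 * tau_vec))
  k <- j:i
  logc <- log(2 * k - 1) - lgamma(j + 1) - lgamma(k - j + 1) +
    (lgamma(j + k - 1) - lgamma(j)) +
    (lgamma(i + 1) - lgamma(i - k + 1)) - (lgamma(i + k) - lgamma(i))
  sgn <- ifelse((k - j) %% 2 == 0, 1, -1)
  rates <- k * (k - 1) / 2
  if (max(logc) > 700) {
    # coefficients overflow double precision: per-point stable evaluation
    return(vapply(tau_vec, function(x) gij(i, j, x), numeric(1)))
  }
  v <- as.vector(crossprod(sgn * exp(logc), exp(-rates %o% tau_vec)))
  pmin(pmax(v, 0), 1)
}
gij <- function(i, j, tau) {
  if (j > i) return(0)
  gij_cached(i, tau)[j]
}

# Count distributions ------------------------------------------------------
# A count distribution is a numeric vector over counts 1..length(d).

dist_point <- function(k) c(rep(0, k - 1), 1)

dist_convolve <- function(a, b) {
  la <- length(a); lb <- length(b)
  out <- numeric(la + lb)
  for (x in seq_len(la)) {
    if (a[x] == 0) next
    out[x + seq_len(lb)] <- out[x + seq_len(lb)] + a[x] * b
  }
  out
}

dist_transition <- function(d, tau) {
  if (tau == 0) return(d)
  n <- length(d)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (d[i] < 1e-15) next
    out[1:i] <- out[1:i] + d[i] * gij_cached(i, tau)
  }
  out
}

#' Lineage-count dynamic program over a bounded locus subtree
#'
#' Bottom-up pass computing, for every branch of the subtree, the
#' distribution of the number of gene lineages entering (bottom) and
#' leaving (top) the branch, given fixed lineage inputs at the leaves.
#' Branches are split into segments wherever the effective population size
#' changes (suppressed species boundaries).
#'
#' @param skel A subtree skeleton as built by [make_skeleton()].
#' @param settings A [coal_settings()] object.
#' @return The skeleton with `bot_dist`, `seg_dists` and `top_dist` filled
#'   in at every node (each a probability vector over counts; sums to 1).
#' @export
subtree_count_dp <- function(skel, settings) {
  p <- settings$ploidy
  rec <- function(node) {
    if (length(node$children)) {
      node$children <- lapply(node$children, rec)
      d <- node$children[[1]]$top_dist
      for (k in seq_along(node$children)[-1])
        d <- dist_convolve(d, node$children[[k]]$top_dist)
    } else {
      d <- dist_point(node$input)
    }
    node$bot_dist <- d / sum(d)
    segd <- list(node$bot_dist)
    if (nrow(node$segs)) {
      for (s in seq_len(nrow(node$segs))) {
        tau <- seg_tau(node$segs[s, ], p)
        segd[[s + 1L]] <- dist_transition(segd[[s]], tau)
      }
    }
    node$seg_dists <- segd
    node$top_dist <- segd[[length(segd)]]
    node
  }
  rec(skel)
}

seg_tau <- function(seg, p) {
  dur_gen <- (seg[["t_hi"]] - seg[["t_lo"]]) * seg[["g"]]
  dur_gen / (p * seg[["ne"]])
}

#' Sample realized lineage counts from the count dynamic program
#'
#' Pre-order (root-to-tips) inverse-CDF sampling: the count at the subtree
#' root (the coalescent bound) is fixed to `root_count`; each branch's
#' bottom count is drawn with probability proportional to
#' `P_bottom(i) * g(i, top, tau)`, and children's top counts are drawn
#' jointly proportional to the product of their top-count probabilities
#' conditioned on summing to the parent's bottom count.
#'
#' @param skel A skeleton processed by [subtree_count_dp()].
#' @param settings A [coal_settings()] object.
#' @param root_count Fixed lineage count at the subtree root (1 under a
#'   coalescent bound).
#' @return The skeleton with `top_count`, `seg_counts` and `bot_count`
#'   filled in at every node.
#' @export
sample_counts <- function(skel, settings, root_count = 1L) {
  p <- settings$ploidy
  sample_from <- function(prob) {
    s <- sum(prob)
    if (s <= 0) stop("inconsistent lineage-count support (all-zero posterior)")
    sample.int(length(prob), 1, prob = prob)
  }
  rec <- function(node, top_count) {
    node$top_count <- top_count
    cnt <- top_count
    segc <- integer(length(node$seg_dists))
    segc[length(segc)] <- cnt
    if (nrow(node$segs)) {
      for (s in rev(seq_len(nrow(node$segs)))) {
        tau <- seg_tau(node$segs[s, ], p)
        dbot <- node$seg_dists[[s]]
        w <- numeric(length(dbot))
        for (i in cnt:length(dbot))
          if (dbot[i] > 0) w[i] <- dbot[i] * gij(i, cnt, tau)
        cnt <- sample_from(w)
        segc[s] <- cnt
      }
    }
    node$seg_counts <- segc
    node$bot_count <- cnt
    if (length(node$children) == 2L) {
      da <- node$children[[1]]$top_dist
      db <- node$children[[2]]$top_dist
      ja <- seq_len(length(da))
      w <- vapply(ja, function(a) {
        b <- cnt - a
        if (b < 1 || b > length(db)) return(0)
        da[a] * db[b]
      }, numeric(1))
      a <- sample_from(w)
      node$children[[1]] <- rec(node$children[[1]], a)
      node$children[[2]] <- rec(node$children[[2]], cnt - a)
    } else if (length(node$children) == 1L) {
      node$children[[1]] <- rec(node$children[[1]], cnt)
    } else if (length(node$children) > 2L) {
      stop("polytomy inside a bounded subtree")
    } else {
      if (cnt != node$input)
        stop("sampled leaf count ", cnt, " != fixed input ", node$input)
    }
    node
  }
  rec(skel, as.integer(root_count))
}

# Conditional coalescence times -------------------------------------------

#' Coalescence times conditioned on lineage counts
#'
#' Draws the `i - j` ordered coalescence times in `(0, t)` for a branch
#' entered by `i` lineages and left by `j`, one wait at a time: the k-th
#' wait has density proportional to `r_k exp(-r_k u) g(k-1, j, T - u)` with
#' `r_k = k(k-1)/(2 p Ne)`, inverted numerically (grid + bisection to
#' relative tolerance 1e-10).
#'
#' @param i,j Entering / leaving lineage counts (`j <= i`).
#' @param t Branch length in generations.
#' @param ne Effective population size.
#' @param p Ploidy.
#' @return Increasing vector of `i - j` times in generations from the
#'   branch bottom.
#' @export
sample_conditional_times <- function(i, j, t, ne = 1, p = 1) {
  if (j > i) stop("j > i")
  if (i == j) return(numeric(0))
  tau_total <- t / (p * ne)
  u <- sample_cond_times_scaled(i, j, tau_total)
  u * p * ne
}

sample_cond_times_scaled <- function(i, j, tau_total) {
  out <- numeric(i - j)
  elapsed <- 0
  idx <- 1L
  for (k in i:(j + 1L)) {
    Trem <- tau_total - elapsed
    rk <- k * (k - 1) / 2
    u <- draw_next_wait(k, j, rk, Trem)
    elapsed <- elapsed + u
    out[idx] <- elapsed
    idx <- idx + 1L
  }
  out
}

# density h(u) = rk exp(-rk u) g(k-1, j, Trem - u) on (0, Trem)
draw_next_wait <- function(k, j, rk, Trem, ngrid = 256L) {
  if (k - 1L == j + 0L && j >= 1L) {
    # closed form available: h(u) = rk e^{-rk u} e^{-rj (Trem-u)}
    rj <- j * (j - 1) / 2
    dr <- rk - rj
    un <- stats::runif(1)
    # CDF F(u) = (1 - e^{-dr u}) / (1 - e^{-dr Trem}) for dr > 0
    if (dr > 1e-12) {
      em <- -expm1(-dr * Trem)
      return(-log1p(-un * em) / dr)
    }
    return(un * Trem)
  }
  h <- function(u) rk * exp(-rk * u) * gij_curve(k - 1L, j, Trem - u)
  grid <- seq(0, Trem, length.out = ngrid + 1L)
  hv <- h(grid)
  trap <- (hv[-1] + hv[-length(hv)]) / 2 * diff(grid)
  cdf <- c(0, cumsum(trap))
  tot <- cdf[length(cdf)]
  if (!is.finite(tot) || tot <= 0) {
    # escalate resolution once, then give up
    if (ngrid < 4096L) return(draw_next_wait(k, j, rk, Trem, ngrid * 8L))
    stop("degenerate conditional waiting-time density")
  }
  un <- stats::runif(1) * tot
  cell <- findInterval(un, cdf, all.inside = TRUE)
  lo <- grid[cell]; hi <- grid[cell + 1L]
  Flo <- cdf[cell]
  # bisection on the continuous CDF inside the cell (local trapezoid)
  f_cell <- function(u) Flo + (h(lo) + h(u)) / 2 * (u - lo)
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f_cell(mid) < un) lo <- mid else hi <- mid
    if ((hi - lo) <= 1e-10 * max(hi, 1e-300)) break
  }
  (lo + hi) / 2
}

#' Plain coalescent along one unbounded branch
#'
#' Exponential waits at rate `k(k-1)/(2 p Ne)` per generation until the
#' branch top (or a single lineage) is reached.
#'
#' @param k_in Number of entering lineages.
#' @param t Branch length in generations (`Inf` for the root stem).
#' @param ne Effective population size.
#' @param p Ploidy.
#' @return List with `survivors` (count) and `times` (coalescence times in
#'   generations from the branch bottom, increasing).
#' @export
simulate_unbounded_branch <- function(k_in, t, ne = 1, p = 1) {
  k <- as.integer(k_in)
  times <- numeric(0)
  el <- 0
  while (k > 1L) {
    rate <- k * (k - 1) / (2 * p * ne)
    w <- stats::rexp(1, rate)
    if (el + w > t) break
    el <- el + w
    times <- c(times, el)
    k <- k - 1L
  }
  list(survivors = k, times = times)
}

# Skeletons ----------------------------------------------------------------
# A skeleton mirrors (part of) the pruned locus tree with per-branch
# homogeneous segments (constant Ne, g).  Leaves carry fixed lineage
# inputs; nested bounded children appear as single-input leaves.

#' Build a coalescent skeleton for a locus (sub)tree
#'
#' @param pruned The pruned locus `timetree`.
#' @param sp The species `timetree` (source of per-branch Ne, g,
#'   individuals).
#' @param node Root node id of the subtree (default: locus root).
#' @param top_time Absolute time at which the subtree's root branch ends
#'   (the coalescent bound for a bounded subtree, `Inf` for a free root).
#' @param settings A [coal_settings()] object.
#' @param descend_bounded Treat bounded children as single-input leaves
#'   (`TRUE`, the DP view) instead of descending into them.
#' @return A nested-list skeleton usable with [subtree_count_dp()].
#' @export
make_skeleton <- function(pruned, sp, node = NULL, top_time = Inf, settings,
                          descend_bounded = TRUE) {
  ch <- children_list(pruned)
  rec <- function(i, t_hi_cap, as_bound_leaf) {
    a <- pruned$annot[[i]]
    kids <- ch[[i]]
    if (as_bound_leaf) {
      # nested bounded child: one lineage emitted at its bound time
      bt <- a$bound_time
      segs <- make_skeleton_segs(pruned, sp, i, t_hi_cap, settings)
      segs <- segs[segs[, "t_hi"] > bt, , drop = FALSE]
      if (nrow(segs)) segs[1, "t_lo"] <- bt
      return(list(locus_node = i, kind = "boundleaf", input = 1L,
                  enter_time = bt, children = list(), segs = segs))
    }
    if (!length(kids)) {
      ind <- a$individuals %||%
        (sp$annot[[a$species]]$individuals %||% settings$default_individuals)
      return(list(locus_node = i, kind = "leaf", input = as.integer(ind),
                  enter_time = pruned$time[i], children = list(),
                  segs = make_skeleton_segs(pruned, sp, i, t_hi_cap, settings)))
    }
    kid_nodes <- lapply(kids, function(k2) {
      kb <- isTRUE(pruned$annot[[k2]]$bounded) && descend_bounded
      rec(k2, pruned$time[i], kb)
    })
    list(locus_node = i, kind = "internal", input = NA_integer_,
         enter_time = pruned$time[i], children = kid_nodes,
         segs = make_skeleton_segs(pruned, sp, i, t_hi_cap, settings))
  }
  if (is.null(node)) node <- tree_root(pruned)
  rec(node, top_time, FALSE)
}

# Full gene-tree simulation -----------------------------------------------

#' Simulate a gene tree inside a pruned locus tree
#'
#' Bounded subtrees (new duplicate / received transfer / received
#' conversion copies) are sampled exactly, innermost first, each emitting a
#' single lineage at its bounding event's time; all remaining branches
#' follow the multispecies coalescent in post-order.  The result is a
#' binary genealogy over all sampled gene copies with node times on the
#' species-tree time axis, plus a mapping of every gene node to its locus
#' branch and species branch.
#'
#' @param locus Result of [simulate_locus_tree()] (needs `$pruned`).
#' @param settings A [coal_settings()] object.
#' @return `NULL` for a fully lost family, else a list with `tree` (the
#'   gene `timetree`, times in the species-tree time axis), and `mapping`
#'   (data.frame `gene_node`, `locus_branch`, `species_branch`, `time`).
#' @export
simulate_gene_tree <- function(locus, settings = coal_settings()) {
  pruned <- locus$pruned
  if (is.null(pruned)) return(NULL)
  sp <- locus$species_tree
  p <- settings$ploidy
  gb <- tree_builder()
  mapping <- new.env(parent = emptyenv())
  mapping$gene_node <- integer(0)
  mapping$locus_branch <- integer(0)
  mapping$species_branch <- numeric(0)
  mapping$time <- numeric(0)
  note <- function(gnode, lbranch, sbranch, time) {
    n <- length(mapping$gene_node) + 1L
    mapping$gene_node[n] <- gnode
    mapping$locus_branch[n] <- lbranch
    mapping$species_branch[n] <- sbranch
    mapping$time[n] <- time
  }
  seg_cache <- vector("list", length(pruned$parent))
  segs_of <- function(i) {
    s <- seg_cache[[i]]
    if (is.null(s)) {
      s <- make_skeleton_segs(pruned, sp, i, Inf, settings)
      seg_cache[[i]] <<- s
    }
    s
  }
  cap_segs <- function(segs, t_hi_cap) {
    keep <- segs[, "t_lo"] < t_hi_cap
    segs <- segs[keep, , drop = FALSE]
    if (nrow(segs)) segs[nrow(segs), "t_hi"] <-
      min(segs[nrow(segs), "t_hi"], t_hi_cap)
    segs
  }
  species_at <- function(lnode, time) {
    path <- pruned$annot[[lnode]]$sp_path
    r <- which(path[, "t_top"] >= time - 1e-12)[1]
    if (is.na(r)) r <- nrow(path)
    path[r, "species"]
  }

  make_tips <- function(lnode) {
    a <- pruned$annot[[lnode]]
    ind <- a$individuals %||%
      (sp$annot[[a$species]]$individuals %||% settings$default_individuals)
    vapply(seq_len(ind) - 1L, function(d)
      tb_add(gb, NA_integer_, pruned$time[lnode],
             label = paste0(pruned$label[lnode], "_", d),
             annot = list(locus_edge = lnode, species = a$species)),
      integer(1))
  }

  coalesce_pair <- function(lins, time, lnode) {
    pick <- sample.int(length(lins), 2)
    node <- tb_add(gb, NA_integer_, time,
                   annot = list(locus_edge = lnode,
                                species = species_at(lnode, time)))
    gb$parent[lins[pick]] <- node
    note(node, lnode, species_at(lnode, time), time)
    c(lins[-pick], node)
  }

  # unbounded coalescent along the (segmented) edge above lnode
  run_edge_free <- function(lins, lnode, t_hi_cap) {
    segs <- cap_segs(segs_of(lnode), t_hi_cap)
    for (s in seq_len(nrow(segs))) {
      t <- segs[s, "t_lo"]; t1 <- segs[s, "t_hi"]
      ne <- segs[s, "ne"]; g <- segs[s, "g"]
      while (length(lins) > 1L) {
        k <- length(lins)
        rate_time <- k * (k - 1) / (2 * p * ne) * g   # per time unit
        w <- stats::rexp(1, rate_time)
        if (t + w > t1) break
        t <- t + w
        lins <- coalesce_pair(lins, t, lnode)
      }
      if (length(lins) == 1L) break
    }
    lins
  }

  # exact bounded sampler: returns the single lineage emitted at bound_time
  run_bounded <- function(lnode, bound_time) {
    skel <- build_skel_with_tips(lnode, bound_time)
    skel <- subtree_count_dp(skel, settings)
    skel <- sample_counts(skel, settings, root_count = 1L)
    lin <- assemble_genealogy(skel)
    lin
  }

  build_skel_with_tips <- function(lnode, bound_time) {
    ch <- children_list(pruned)
    rec <- function(i, t_hi_cap, as_bound_leaf) {
      a <- pruned$annot[[i]]
      if (as_bound_leaf) {
        lin <- run_bounded(i, a$bound_time)
        segs <- cap_segs(segs_of(i), t_hi_cap)
        segs <- segs[segs[, "t_hi"] > a$bound_time, , drop = FALSE]
        if (nrow(segs)) segs[1, "t_lo"] <- a$bound_time
        return(list(locus_node = i, kind = "boundleaf", input = 1L,
                    enter_time = a$bound_time, lineages = lin,
                    children = list(), segs = segs))
      }
      kids <- ch[[i]]
      if (!length(kids)) {
        tips <- make_tips(i)
        return(list(locus_node = i, kind = "leaf",
                    input = length(tips), enter_time = pruned$time[i],
                    lineages = tips, children = list(),
                    segs = cap_segs(segs_of(i), t_hi_cap)))
      }
      kid_nodes <- lapply(kids, function(k2)
        rec(k2, pruned$time[i], isTRUE(pruned$annot[[k2]]$bounded)))
      list(locus_node = i, kind = "internal", input = NA_integer_,
           enter_time = pruned$time[i], lineages = NULL,
           children = kid_nodes,
           segs = cap_segs(segs_of(i), t_hi_cap))
    }
    rec(lnode, bound_time, FALSE)
  }

  # post-order walk over a counted skeleton realizing coalescence times
  assemble_genealogy <- function(node) {
    lins <- if (length(node$children)) {
      unlist(lapply(node$children, assemble_genealogy))
    } else node$lineages
    stopifnot(length(lins) == node$bot_count)
    cnt_from <- node$bot_count
    if (nrow(node$segs)) {
      for (s in seq_len(nrow(node$segs))) {
        cnt_to <- node$seg_counts[s + 1L]
        seg <- node$segs[s, ]
        if (cnt_from > cnt_to) {
          dur_gen <- (seg[["t_hi"]] - seg[["t_lo"]]) * seg[["g"]]
          tms <- sample_conditional_times(cnt_from, cnt_to, dur_gen,
                                          ne = seg[["ne"]], p = p)
          for (u in tms) {
            t_abs <- seg[["t_lo"]] + u / seg[["g"]]
            lins <- coalesce_pair(lins, t_abs, node$locus_node)
          }
        }
        cnt_from <- cnt_to
      }
    }
    stopifnot(length(lins) == node$top_count)
    lins
  }

  # main multispecies-coalescent recursion (unbounded parts)
  ch <- children_list(pruned)
  msc <- function(i, t_hi_cap) {
    a <- pruned$annot[[i]]
    if (isTRUE(a$bounded)) {
      lin <- run_bounded(i, a$bound_time)
      # single lineage rides the rest of the edge untouched
      return(lin)
    }
    kids <- ch[[i]]
    lins <- if (!length(kids)) make_tips(i)
    else unlist(lapply(kids, function(k2) msc(k2, pruned$time[i])))
    run_edge_free(lins, i, t_hi_cap)
  }
  root <- tree_root(pruned)
  res <- msc(root, Inf)
  if (length(res) != 1L) stop("root coalescence incomplete")
  tr <- tb_finalize(gb)
  # record tip mappings
  lv <- tree_leaves(tr)
  for (i in lv) note(i, tr$annot[[i]]$locus_edge, tr$annot[[i]]$species,
                     tr$time[i])
  map <- data.frame(gene_node = mapping$gene_node,
                    locus_branch = mapping$locus_branch,
                    species_branch = mapping$species_branch,
                    time = mapping$time)
  map <- map[order(map$gene_node), ]
  rownames(map) <- NULL
  list(tree = tr, mapping = map)
}

make_skeleton_segs <- function(pruned, sp, i, t_hi_cap, settings) {
  path <- pruned$annot[[i]]$sp_path
  t_lo <- pruned$time[i]
  out <- matrix(numeric(0), ncol = 5,
                dimnames = list(NULL, c("t_lo", "t_hi", "ne", "g", "species")))
  for (r in seq_len(nrow(path))) {
    t_hi <- min(path[r, "t_top"], t_hi_cap)
    if (t_hi > t_lo) {
      spn <- path[r, "species"]
      out <- rbind(out, c(t_lo, t_hi,
                          sp$annot[[spn]]$ne %||% settings$default_ne,
                          sp$annot[[spn]]$g %||% 1, spn))
      t_lo <- t_hi
    }
    if (t_lo >= t_hi_cap) break
  }
  out
}

#' Rejection sampler for a bounded locus subtree (test oracle)
#'
#' Runs the unconditioned multispecies coalescent over the subtree and
#' accepts the run only when a single lineage remains at the bounding
#' event's time.  Distributionally equivalent to the exact dynamic-program
#' sampler; used as an independent oracle.
#'
#' @param locus Result of [simulate_locus_tree()].
#' @param node Root node id of the bounded subtree in `locus$pruned`.
#' @param settings A [coal_settings()] object.
#' @param max_tries Attempt cap.
#' @return A list with `tree` (genealogy over the subtree's tips, root at
#'   the final coalescence) and `tries`.
#' @export
rejection_oracle_bounded <- function(locus, node, settings = coal_settings(),
                                     max_tries = 1e6) {
  pruned <- locus$pruned
  sp <- locus$species_tree
  p <- settings$ploidy
  bound_time <- pruned$annot[[node]]$bound_time
  if (is.null(bound_time)) stop("node ", node, " carries no coalescent bound")
  ch <- children_list(pruned)
  for (try in seq_len(max_tries)) {
    gb <- tree_builder()
    reject <- FALSE
    rec <- function(i, t_hi_cap) {
      # nested bounds inside the subtree are enforced too: the free run up
      # a nested bounded edge is capped at its bound time and must have
      # reached a single lineage there
      a <- pruned$annot[[i]]
      nested <- isTRUE(a$bounded) && i != node
      cap <- if (nested) a$bound_time else t_hi_cap
      kids <- ch[[i]]
      lins <- if (!length(kids)) {
        ind <- a$individuals %||%
          (sp$annot[[a$species]]$individuals %||% settings$default_individuals)
        vapply(seq_len(ind), function(d)
          tb_add(gb, NA_integer_, pruned$time[i],
                 label = paste0(pruned$label[i], "_", d - 1L)), integer(1))
      } else unlist(lapply(kids, function(k2) rec(k2, pruned$time[i])))
      if (reject) return(lins)
      segs <- make_skeleton_segs(pruned, sp, i, cap, settings)
      for (s in seq_len(nrow(segs))) {
        t <- segs[s, "t_lo"]
        while (length(lins) > 1L) {
          k <- length(lins)
          w <- stats::rexp(1, k * (k - 1) / (2 * p * segs[s, "ne"]) * segs[s, "g"])
          if (t + w > segs[s, "t_hi"]) break
          t <- t + w
          pick <- sample.int(k, 2)
          nn <- tb_add(gb, NA_integer_, t)
          gb$parent[lins[pick]] <- nn
          lins <- c(lins[-pick], nn)
        }
      }
      if (nested && length(lins) > 1L) reject <<- TRUE
      lins
    }
    lins <- rec(node, bound_time)
    if (!reject && length(lins) == 1L)
      return(list(tree = tb_finalize(gb), tries = try))
  }
  stop("rejection oracle failed to accept within ", max_tries, " tries")
}
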