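# Species tree simulation ------------------------------------------------
#
# Two samplers for ultrametric species trees under a constant-rate
# birth-death process:
#   * SSA  - forward simulation from an origin time, two initial lineages,
#            extinct subtrees removed afterwards;
#   * BDSA - conditioned on the number of extant tips (and optionally the
#            origin height), drawing speciation times i.i.d. from the
#            reconstructed-process density and assembling a uniform ranked
#            topology.  Matches the SSA conditioned on the tip count by
#            construction.
# Rates are per time unit; the origin starts with two lineages, so the
# expected extant count under a pure-birth process is 2*exp(lambda*t).

#' Simulate a species tree forward from an origin time (SSA)
#'
#' Two lineages start at `origin_time` and undergo a linear birth-death
#' process (per-lineage speciation rate `lambda`, extinction rate `mu`)
#' until the present.  Extinct subtrees are pruned; replicates in which
#' fewer than two species survive are resampled.
#'
#' @param lambda Speciation rate per lineage per time unit (> 0).
#' @param mu Extinction rate per lineage per time unit (>= 0).
#' @param origin_time Origin of the process, time units before present.
#' @param max_retries Resampling cap for fully (or singly) surviving
#'   replicates before giving up.
#' @return An ultrametric binary `timetree` with >= 2 extant leaves; leaf
#'   labels are integers assigned in preorder.
#' @export
simulate_ssa <- function(lambda, mu = 0, origin_time, max_retries = 1e5) {
  stopifnot(lambda > 0, mu >= 0, origin_time > 0)
  for (try in seq_len(max_retries)) {
    tr <- ssa_once(lambda, mu, origin_time)
    if (!is.null(tr)) return(tr)
  }
  stop("no replicate with >= 2 surviving species after ", max_retries,
       " attempts; consider lowering the extinction rate or the origin time")
}

ssa_once <- function(lambda, mu, origin_time) {
  tb <- tree_builder()
  root <- tb_add(tb, NULL, origin_time)
  total <- lambda + mu
  grow <- function(parent, t0) {
    # simulate one lineage from time t0 toward the present; returns TRUE if
    # any descendant survives to time 0
    t <- t0
    repeat {
      w <- stats::rexp(1, total)
      if (t - w <= 0) {
        tb_add(tb, parent, 0)
        return(TRUE)
      }
      t <- t - w
      if (stats::runif(1) < lambda / total) {
        node <- tb_add(tb, parent, t)
        s1 <- grow(node, t)
        s2 <- grow(node, t)
        return(s1 || s2)
      } else {
        nd <- tb_add(tb, parent, t)
        tb$annot[[nd]] <- list(extinct = TRUE)
        return(FALSE)
      }
    }
  }
  s1 <- grow(root, origin_time)
  s2 <- grow(root, origin_time)
  if (!s1 && !s2) return(NULL)
  tr <- tb_finalize(tb)
  lv <- tree_leaves(tr)
  extant <- lv[tr$time[lv] == 0]
  if (length(extant) < 2) return(NULL)
  tr$label[extant] <- as.character(seq_along(extant))
  pr <- prune_to_sampled(tr, tr$label[extant])
  relabel_preorder(pr)
}

relabel_preorder <- function(tr) {
  lv <- tree_leaves(tr)
  ord <- preorder_nodes(tr)
  leaf_ord <- ord[ord %in% lv]
  tr$label[leaf_ord] <- as.character(seq_along(leaf_ord))
  tr
}

preorder_nodes <- function(tr) {
  ch <- children_list(tr)
  out <- integer(0)
  stack <- tree_root(tr)
  while (length(stack)) {
    i <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, i)
    kids <- ch[[i]]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  out
}

postorder_nodes <- function(tr) rev(preorder_nodes(tr))

# Conditioned reconstructed process --------------------------------------
# For one lineage of age t: P(no extant descendant) p0, and the geometric
# tail parameter eta of the extant-count distribution.

bd_p0 <- function(lambda, mu, t) {
  if (mu == 0) return(rep(0, length(t)))
  r <- lambda - mu
  if (abs(r) < 1e-12 * lambda) return(lambda * t / (1 + lambda * t))
  mu * (1 - exp(-r * t)) / (lambda - mu * exp(-r * t))
}

bd_eta <- function(lambda, mu, t) {
  r <- lambda - mu
  if (abs(r) < 1e-12 * lambda) return(lambda * t / (1 + lambda * t))
  lambda * (1 - exp(-r * t)) / (lambda - mu * exp(-r * t))
}

# P(N = k | one lineage of age t), vector k, scalar t
bd_count_pmf <- function(k, lambda, mu, t) {
  p0 <- bd_p0(lambda, mu, t)
  eta <- bd_eta(lambda, mu, t)
  out <- (1 - p0) * (1 - eta) * eta^(pmax(k, 1) - 1)
  out[k == 0] <- p0
  out
}

# P(N_total = n | two lineages of age t), vectorized over t
bd_count_pmf2 <- function(n, lambda, mu, t) {
  p0 <- bd_p0(lambda, mu, t)
  eta <- bd_eta(lambda, mu, t)
  q <- (1 - p0) * (1 - eta)
  # two extinct-or-not convolution: k from 0..n survivors on side one
  tot <- 2 * p0 * q * eta^(n - 1)          # one side extinct
  ks <- seq_len(n - 1)
  if (length(ks)) {
    # sum_k q^2 eta^{k-1} eta^{n-k-1} = (n-1) q^2 eta^{n-2}
    tot <- tot + (n - 1) * q^2 * eta^(pmax(n - 2, 0))
  }
  tot
}

# Inverse CDF of a single reconstructed speciation time on (0, t), i.e. the
# density lambda * p1(s) / (lambda * Q(t)) with Q(s) = (1-e^{-rs})/(lambda -
# mu e^{-rs}); analytic inversion.
bd_spec_time_quantile <- function(u, lambda, mu, t) {
  r <- lambda - mu
  if (mu == 0) {
    # truncated exponential, density lambda e^{-lambda s} / (1 - e^{-lambda t})
    return(-log(1 - u * (1 - exp(-lambda * t))) / lambda)
  }
  if (abs(r) < 1e-12 * lambda) {
    # critical case: Q(s) = s / (1 + lambda s)
    Qt <- t / (1 + lambda * t)
    c0 <- u * Qt
    return(c0 / (1 - lambda * c0))
  }
  Q <- function(s) (1 - exp(-r * s)) / (lambda - mu * exp(-r * s))
  c0 <- u * Q(t)
  x <- (1 - c0 * lambda) / (1 - c0 * mu)
  -log(x) / r
}

#' Simulate a species tree conditioned on the number of extant tips (BDSA)
#'
#' The process starts with two lineages at the origin height and is
#' conditioned on `n_taxa` extant species in total.  The split of tips
#' between the two origin lineages is drawn from the conditional
#' birth-death count distribution; each side's reconstructed speciation
#' times are i.i.d. draws from the conditional reconstructed-process
#' density, assembled into a uniform ranked topology.  When `height` is
#' missing it is first drawn from its conditional density given `n_taxa`
#' (uniform prior on the origin).
#'
#' @param lambda,mu Birth and death rates per time unit.
#' @param n_taxa Number of extant species (>= 2).
#' @param height Origin height; `NULL` to draw it.
#' @return An ultrametric binary `timetree` with exactly `n_taxa` leaves.
#' @export
simulate_bdsa <- function(lambda, mu = 0, n_taxa, height = NULL) {
  stopifnot(lambda > 0, mu >= 0, n_taxa >= 2)
  n <- as.integer(n_taxa)
  if (is.null(height)) height <- draw_conditional_height(lambda, mu, n)
  # split of tips between the two origin lineages (k, n-k), k = 0..n
  k <- seq(0L, n)
  w <- bd_count_pmf(k, lambda, mu, height) * bd_count_pmf(n - k, lambda, mu, height)
  w[k == 0 & n == 0] <- 0
  if (sum(w) <= 0) stop("degenerate conditional tip-split distribution")
  k1 <- sample(k, 1, prob = w)
  k2 <- n - k1
  tb <- tree_builder()
  build_side <- function(parent, ktips) {
    # reconstructed subtree with ktips tips: ktips-1 iid speciation times,
    # assembled tips-first by joining two uniformly chosen lineages at each
    # speciation time; returns the id of the side's top lineage node
    if (ktips == 1L) return(tb_add(tb, parent, 0))
    times <- sort(bd_spec_time_quantile(stats::runif(ktips - 1L), lambda, mu, height))
    active <- vapply(seq_len(ktips), function(i) tb_add(tb, NA_integer_, 0),
                     integer(1))
    for (s in times) {
      pick <- sample.int(length(active), 2)
      node <- tb_add(tb, NA_integer_, s)
      tb$parent[active[pick]] <- node
      active <- c(active[-pick], node)
    }
    tb$parent[active] <- if (is.null(parent)) NA_integer_ else parent
    active
  }
  if (k1 == 0L || k2 == 0L) {
    # one origin lineage left no survivors: the tree is the other side's
    # reconstructed tree, rooted at its own mrca (below the origin)
    build_side(NULL, max(k1, k2))
  } else {
    root <- tb_add(tb, NULL, height)
    build_side(root, k1)
    build_side(root, k2)
  }
  relabel_preorder(tb_finalize(tb))
}

# Conditional density of the origin height given n extant tips, uniform
# prior on the origin: p(t | n) proportional to P(n | t) with two origin
# lineages.  Sampled by numeric inversion of the CDF.
.height_cdf_cache <- new.env(parent = emptyenv())

draw_conditional_height <- function(lambda, mu, n) {
  key <- paste(signif(lambda, 12), signif(mu, 12), n)
  cached <- .height_cdf_cache[[key]]
  if (is.null(cached)) {
    pn <- function(t) bd_count_pmf2(n, lambda, mu, t)
    # locate an upper bound where the density has decayed
    tmax <- 1 / lambda
    repeat {
      if (pn(tmax) < 1e-8 * pn(tmax / 2) || tmax > 1e6 / lambda) break
      tmax <- tmax * 2
    }
    grid <- seq(0, tmax, length.out = 2048L)
    dens <- pn(grid)
    dens[!is.finite(dens)] <- 0
    cdf <- cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid))
    cdf <- c(0, cdf) / cdf[length(cdf)]
    cached <- list(grid = grid, cdf = cdf)
    .height_cdf_cache[[key]] <- cached
  }
  u <- stats::runif(1)
  i <- findInterval(u, cached$cdf, all.inside = TRUE)
  t0 <- cached$grid[i]; t1 <- cached$grid[i + 1]
  c0 <- cached$cdf[i]; c1 <- cached$cdf[i + 1]
  t0 + (u - c0) / max(c1 - c0, 1e-300) * (t1 - t0)
}

#' Attach an outgroup species
#'
#' Creates a new root at `(1 + rel) * h`, where `h` is the ingroup root
#' height, with the ingroup and a single pendant outgroup leaf as children.
#' Ingroup topology and node times are untouched.
#'
#' @param tr An ultrametric species `timetree`.
#' @param rel Relative outgroup distance (> 0).
#' @return A `timetree` with one extra leaf labeled `"0"` (the outgroup).
#' @export
add_outgroup <- function(tr, rel) {
  stopifnot(rel > 0)
  h <- tr$time[tree_root(tr)]
  n <- length(tr$parent)
  newroot <- n + 1L
  outleaf <- n + 2L
  parent <- c(tr$parent, NA_integer_, newroot)
  parent[tree_root(tr)] <- newroot
  structure(list(parent = as.integer(parent),
                 time = c(tr$time, (1 + rel) * h, 0),
                 label = c(tr$label, NA_character_, "0"),
                 annot = c(tr$annot, list(list()), list(list(outgroup = TRUE)))),
            class = "timetree")
}

#' Decorate species-tree branches with population parameters
#'
#' Every branch (node) receives an effective population size, a generation
#' time, and (leaves only) a number of sampled individuals, each drawn from
#' its distribution spec (constant when the spec is fixed).  The root node
#' carries the parameters used for the root stem.
#'
#' @param tr A species `timetree`.
#' @param ne,gen_time,individuals Distribution specs (or numbers).
#' @param env Environment of replicate-level values for `$name` references.
#' @return The decorated `timetree` (annotations `ne`, `g`, `individuals`).
#' @export
decorate_branches <- function(tr, ne = 10000, gen_time = 1, individuals = 1,
                              env = list()) {
  ne_sp <- parse_spec(ne); g_sp <- parse_spec(gen_time)
  ind_sp <- parse_spec(individuals)
  lv <- tree_leaves(tr)
  for (i in seq_along(tr$parent)) {
    a <- tr$annot[[i]]
    a$ne <- max(1, sample_value(ne_sp, env, positive = TRUE))
    a$g <- sample_value(g_sp, env, positive = TRUE)
    if (i %in% lv)
      a$individuals <- max(1L, as.integer(round(sample_value(ind_sp, env))))
    tr$annot[[i]] <- a
  }
  tr
}
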