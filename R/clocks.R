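# Substitution rate variation ---------------------------------------------
#
# Gene trees are simulated in time units and converted to expected
# substitutions per site.  Three independent layers of mean-one Gamma rate
# multipliers relax the clock:
#   * species layer  - one multiplier per species-tree branch, shared by
#     every gene family of the replicate (genome-wide effect);
#   * family layer   - one multiplier per locus tree (scales the whole
#     gene tree; ultrametricity is preserved);
#   * gene layer     - one multiplier per gene-tree branch.
# Generation times act upstream, on the time -> generations conversion, so
# a species branch of T time units contributes T*g generations to every
# lineage passing through it.  A gene branch spanning several species
# branches is scaled segment by segment (duration-weighted), which is the
# only convention preserving the mean rate.

#' Draw a mean-one Gamma rate multiplier
#'
#' Gamma(shape = alpha, scale = 1/alpha): mean 1, variance 1/alpha.  Large
#' alpha recovers a strict clock.
#'
#' @param alpha Shape parameter (> 0).
#' @param n Number of draws.
#' @return Numeric vector of multipliers.
#' @export
sample_mean_one_multiplier <- function(alpha, n = 1) {
  stopifnot(alpha > 0)
  stats::rgamma(n, shape = alpha, rate = alpha)
}

#' Clock settings
#'
#' @param subst_rate Substitutions per site per generation (> 0).
#' @param alpha_species,alpha_family,alpha_gene Gamma shapes of the three
#'   multiplier layers; `NULL` disables a layer (multiplier 1).
#' @return A list of class `clock_settings`.
#' @export
clock_settings <- function(subst_rate = 1e-8, alpha_species = NULL,
                           alpha_family = NULL, alpha_gene = NULL) {
  stopifnot(subst_rate > 0)
  structure(list(subst_rate = subst_rate, alpha_species = alpha_species,
                 alpha_family = alpha_family, alpha_gene = alpha_gene),
            class = "clock_settings")
}

#' Draw the species-layer multipliers for one replicate
#'
#' One multiplier per species-tree node (branch above it; the root value
#' is used for the root stem).  Shared across families.
#'
#' @param sp Species `timetree`.
#' @param alpha Gamma shape (`NULL` for a strict species layer).
#' @return Numeric vector indexed by species node id.
#' @export
species_layer_multipliers <- function(sp, alpha = NULL) {
  n <- length(sp$parent)
  if (is.null(alpha)) return(rep(1, n))
  sample_mean_one_multiplier(alpha, n)
}

#' Convert a gene tree from time units to expected substitutions per site
#'
#' Every gene branch is partitioned into segments at the species-branch
#' boundaries it crosses (through the locus-tree embedding); each segment
#' contributes `duration_time * g * subst_rate * m_species * m_family *
#' m_gene` substitutions.  Segments older than the species root use the
#' root branch's parameters.
#'
#' @param gene Result of [simulate_gene_tree()] (`$tree`, `$mapping`).
#' @param locus Result of [simulate_locus_tree()].
#' @param clock A [clock_settings()] object.
#' @param m_species Species-layer multipliers (from
#'   [species_layer_multipliers()]); `NULL` for all-ones.
#' @param m_family Family-layer multiplier (scalar).
#' @param m_gene Gene-layer multipliers per gene node (branch above it);
#'   `NULL` to draw them from `clock$alpha_gene` (or all-ones).
#' @return A list with `tree` (branch lengths in substitutions/site) and
#'   `branch_info` (per-branch generations and substitution lengths).
#' @export
apply_clock_model <- function(gene, locus, clock = clock_settings(),
                              m_species = NULL, m_family = 1, m_gene = NULL) {
  gt <- gene$tree
  pruned <- locus$pruned
  sp <- locus$species_tree
  nG <- length(gt$parent)
  if (is.null(m_species)) m_species <- rep(1, length(sp$parent))
  if (is.null(m_gene)) {
    m_gene <- if (is.null(clock$alpha_gene)) rep(1, nG)
    else sample_mean_one_multiplier(clock$alpha_gene, nG)
  }
  lp <- pruned$parent
  sublen <- rep(NA_real_, nG)
  genlen <- rep(NA_real_, nG)
  for (i in seq_len(nG)) {
    pnode <- gt$parent[i]
    if (is.na(pnode)) next
    t0 <- gt$time[i]
    t1 <- gt$time[pnode]
    ledge <- gt$annot[[i]]$locus_edge
    acc_sub <- 0; acc_gen <- 0
    t <- t0
    while (t < t1 - 1e-12 * max(1, t1)) {
      segs <- branch_species_segments(pruned, ledge)
      advanced <- FALSE
      for (r in seq_len(nrow(segs))) {
        if (segs$t_hi[r] <= t + 1e-12 * max(1, t)) next
        hi <- min(segs$t_hi[r], t1)
        if (hi > t) {
          spn <- segs$species[r]
          g <- sp$annot[[spn]]$g %||% 1
          dur_gen <- (hi - t) * g
          acc_gen <- acc_gen + dur_gen
          acc_sub <- acc_sub + dur_gen * clock$subst_rate *
            m_species[spn] * m_family * m_gene[i]
          t <- hi
          advanced <- TRUE
        }
        if (t >= t1) break
      }
      if (t >= t1 - 1e-12 * max(1, t1)) break
      # move to the parent locus edge
      nxt <- lp[ledge]
      if (is.na(nxt)) {
        if (!advanced) stop("gene branch ", i, " extends beyond the mapped stem")
        break
      }
      ledge <- nxt
    }
    sublen[i] <- acc_sub
    genlen[i] <- acc_gen
  }
  # rebuild a tree whose branch lengths are the substitution lengths
  depth <- numeric(nG)
  for (i in preorder_nodes(gt)) {
    p <- gt$parent[i]
    depth[i] <- if (is.na(p)) 0 else depth[p] + sublen[i]
  }
  out <- gt
  out$time <- max(depth) - depth
  list(tree = out,
       branch_info = data.frame(gene_node = seq_len(nG),
                                generations = genlen,
                                substitutions = sublen,
                                m_gene = m_gene))
}

# species segments of the (possibly merged) locus edge above pruned node i,
# including the infinite stem row for the locus root
branch_species_segments <- function(pruned, i) {
  path <- pruned$annot[[i]]$sp_path
  t_lo <- pruned$time[i]
  out <- data.frame(t_lo = numeric(0), t_hi = numeric(0), species = numeric(0))
  for (r in seq_len(nrow(path))) {
    t_hi <- path[r, "t_top"]
    out <- rbind(out, data.frame(t_lo = t_lo, t_hi = t_hi,
                                 species = path[r, "species"]))
    t_lo <- t_hi
  }
  if (is.na(pruned$parent[i]) &&
      (nrow(out) == 0 || is.finite(out$t_hi[nrow(out)]))) {
    spn <- if (nrow(out)) out$species[nrow(out)] else pruned$annot[[i]]$species
    out <- rbind(out, data.frame(t_lo = t_lo, t_hi = Inf, species = spn))
  }
  out
}
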