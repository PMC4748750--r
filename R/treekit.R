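# Rooted time trees ------------------------------------------------------
#
# All simulated trees live on a single backwards time axis: time 0 at the
# extant tips, increasing toward the root (coalescent convention).  Branch
# lengths are time differences between a node and its parent.  Nodes carry
# stable integer ids assigned at creation; ids survive pruning so that
# mapping tables remain valid after tree surgery.

#' Construct a rooted time tree
#'
#' A `timetree` is a flat node-table representation of a rooted tree in
#' which every node has a time (measured backwards from the present, in
#' generations or time units), a label, and a free-form annotation list.
#'
#' @param parent Integer vector; `parent[i]` is the parent node id of node
#'   `i`, `NA` for the root.  Node ids are positions in the vectors.
#' @param time Numeric vector of node times (backwards from the present).
#' @param label Character vector of node labels (`NA` allowed for internal
#'   nodes; leaf labels must be unique).
#' @param annot Optional list of per-node named lists (annotations such as
#'   event type, effective population size, rate multipliers).
#' @return An object of class `timetree`.
#' @export
timetree <- function(parent, time, label = rep(NA_character_, length(parent)),
                     annot = NULL) {
  n <- length(parent)
  stopifnot(length(time) == n, length(label) == n)
  if (is.null(annot)) annot <- rep(list(list()), n)
  tr <- structure(list(parent = as.integer(parent), time = as.numeric(time),
                       label = as.character(label), annot = annot),
                  class = "timetree")
  validate_timetree(tr)
  tr
}

validate_timetree <- function(tr) {
  n <- length(tr$parent)
  roots <- which(is.na(tr$parent))
  if (length(roots) != 1L)
    stop("timetree must have exactly one root, found ", length(roots))
  for (i in seq_len(n)) {
    p <- tr$parent[i]
    if (!is.na(p) && tr$time[p] < tr$time[i] - 1e-9 * max(1, abs(tr$time[i])))
      stop("node ", i, " is older than its parent (time ", tr$time[i],
           " > ", tr$time[p], ")")
  }
  lv <- tree_leaves(tr)
  lab <- tr$label[lv]
  lab <- lab[!is.na(lab)]
  if (anyDuplicated(lab)) stop("duplicate leaf labels: ",
                               paste(unique(lab[duplicated(lab)]), collapse = ", "))
  invisible(tr)
}

#' @export
print.timetree <- function(x, ...) {
  nl <- length(tree_leaves(x))
  cat("timetree:", length(x$parent), "nodes,", nl, "leaves, root height",
      format(x$time[tree_root(x)], digits = 6), "\n")
  invisible(x)
}

#' Node accessors
#'
#' `tree_root` returns the root node id, `tree_leaves` the leaf ids,
#' `tree_children` the children of a node, `n_leaves` the leaf count.
#' @param tr A `timetree`.
#' @param node A node id.
#' @return Integer node ids (or a count for `n_leaves`).
#' @export
tree_root <- function(tr) which(is.na(tr$parent))

#' @rdname tree_root
#' @export
tree_leaves <- function(tr) {
  n <- length(tr$parent)
  has_child <- rep(FALSE, n)
  has_child[tr$parent[!is.na(tr$parent)]] <- TRUE
  which(!has_child)
}

#' @rdname tree_root
#' @export
tree_children <- function(tr, node) which(!is.na(tr$parent) & tr$parent == node)

#' @rdname tree_root
#' @export
n_leaves <- function(tr) length(tree_leaves(tr))

children_list <- function(tr) {
  n <- length(tr$parent)
  ch <- vector("list", n)
  for (i in seq_len(n)) ch[[i]] <- integer(0)
  for (i in seq_len(n)) {
    p <- tr$parent[i]
    if (!is.na(p)) ch[[p]] <- c(ch[[p]], i)
  }
  ch
}

#' Branch length of the edge above a node
#' @param tr A `timetree`.
#' @param node Node id(s).
#' @return Numeric vector of branch lengths (NA for the root).
#' @export
branch_length <- function(tr, node = seq_along(tr$parent)) {
  ifelse(is.na(tr$parent[node]), NA_real_,
         tr$time[tr$parent[node]] - tr$time[node])
}

#' Test whether a tree is ultrametric
#'
#' All extant leaves (minimum-time leaves) must be at the same time.
#' @param tr A `timetree`.
#' @param tol Absolute tolerance on leaf-time differences.
#' @return Logical.
#' @export
is_ultrametric <- function(tr, tol = 1e-8) {
  lt <- tr$time[tree_leaves(tr)]
  diff(range(lt)) <= tol * max(1, tr$time[tree_root(tr)])
}

# Mutable tree builder ----------------------------------------------------
# Simulators grow trees node by node; an environment avoids copy-on-write.

tree_builder <- function(n0 = 64L) {
  tb <- new.env(parent = emptyenv())
  tb$parent <- rep(NA_integer_, n0)
  tb$time <- rep(NA_real_, n0)
  tb$label <- rep(NA_character_, n0)
  tb$annot <- vector("list", n0)
  tb$n <- 0L
  tb
}

tb_add <- function(tb, parent, time, label = NA_character_, annot = list()) {
  n <- tb$n + 1L
  if (n > length(tb$parent)) {
    grow <- length(tb$parent)
    tb$parent <- c(tb$parent, rep(NA_integer_, grow))
    tb$time <- c(tb$time, rep(NA_real_, grow))
    tb$label <- c(tb$label, rep(NA_character_, grow))
    tb$annot <- c(tb$annot, vector("list", grow))
  }
  tb$parent[n] <- if (is.null(parent)) NA_integer_ else as.integer(parent)
  tb$time[n] <- time
  tb$label[n] <- label
  tb$annot[[n]] <- annot
  tb$n <- n
  n
}

tb_finalize <- function(tb) {
  idx <- seq_len(tb$n)
  ann <- tb$annot[idx]
  ann[vapply(ann, is.null, logical(1))] <- list(list())
  structure(list(parent = tb$parent[idx], time = tb$time[idx],
                 label = tb$label[idx], annot = ann),
            class = "timetree")
}

# Newick / Nexus I/O ------------------------------------------------------

#' Read a tree from Newick or Nexus text
#'
#' Newick parsing supports branch lengths, quoted or plain labels and
#' NHX-style annotation comments (`[&&NHX:key=value:...]`).  Nexus input
#' (TREES block with an optional Translate table) is handled through
#' \pkg{ape}.  Node times are reconstructed from branch lengths by placing
#' the deepest leaf at time 0.
#'
#' @param text A Newick string, or the path to / contents of a Nexus file.
#' @param format `"newick"` or `"nexus"`.
#' @return A `timetree` (for Nexus files with several trees, the first).
#' @export
read_tree <- function(text, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (format == "nexus") {
    ph <- if (file.exists(text)) ape::read.nexus(text) else {
      tf <- tempfile(fileext = ".nex"); on.exit(unlink(tf))
      writeLines(text, tf)
      ape::read.nexus(tf)
    }
    if (inherits(ph, "multiPhylo")) ph <- ph[[1]]
    return(from_phylo(ph))
  }
  parse_newick(text)
}

parse_newick <- function(s) {
  s <- trimws(s)
  n <- nchar(s)
  if (n == 0L) stop("empty Newick string")
  pos <- 1L
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  advance <- function() pos <<- pos + 1L
  fail <- function(msg) stop("Newick parse error at character ", pos, ": ", msg)

  tb <- tree_builder()

  read_label <- function() {
    if (peek() == "'") {
      advance()
      out <- ""
      while (peek() != "'") {
        if (pos > n) fail("unterminated quoted label")
        out <- paste0(out, peek()); advance()
      }
      advance()
      return(out)
    }
    out <- ""
    while (pos <= n && !(peek() %in% c(":", ",", "(", ")", ";", "["))) {
      out <- paste0(out, peek()); advance()
    }
    out
  }
  read_annot <- function() {
    ann <- list()
    if (peek() == "[") {
      close <- regexpr("]", substr(s, pos, n), fixed = TRUE)
      if (close < 0) fail("unterminated comment")
      body <- substr(s, pos + 1L, pos + close - 2L)
      pos <<- pos + close
      if (startsWith(body, "&&NHX")) {
        body <- sub("^&&NHX:?", "", body)
        if (nzchar(body)) {
          for (kv in strsplit(body, ":", fixed = TRUE)[[1]]) {
            eq <- regexpr("=", kv, fixed = TRUE)
            if (eq > 0) {
              key <- substr(kv, 1, eq - 1)
              val <- substr(kv, eq + 1, nchar(kv))
              num <- suppressWarnings(as.numeric(val))
              ann[[key]] <- if (!is.na(num)) num else val
            }
          }
        }
      }
    }
    ann
  }
  # returns list(id, parent set later) with edge length stored temporarily
  elen <- new.env(parent = emptyenv()); elen$v <- numeric(0)
  read_clade <- function(parent_id) {
    id <- tb_add(tb, parent_id, NA_real_)
    if (peek() == "(") {
      advance()
      repeat {
        read_clade(id)
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        fail("expected ',' or ')'")
      }
    }
    lab <- read_label()
    if (nzchar(lab)) tb$label[id] <- lab
    ann <- read_annot()
    len <- NA_real_
    if (peek() == ":") {
      advance()
      numstr <- ""
      while (pos <= n && (peek() %in% c("0","1","2","3","4","5","6","7","8","9",
                                        ".", "-", "+", "e", "E"))) {
        numstr <- paste0(numstr, peek()); advance()
      }
      len <- suppressWarnings(as.numeric(numstr))
      if (is.na(len)) fail("bad branch length")
      if (len < 0) stop("negative branch length (", len, ") at character ", pos)
      ann2 <- read_annot()
      ann <- utils::modifyList(ann, ann2)
    }
    tb$annot[[id]] <- ann
    elen$v[id] <- len
    id
  }
  root <- read_clade(NULL)
  if (peek() != ";") fail("expected ';'")
  tr <- tb_finalize(tb)
  # depths from root, then convert to backwards times
  nn <- length(tr$parent)
  depth <- numeric(nn)
  ord <- order(vapply(seq_len(nn), function(i) node_depth_count(tr, i), numeric(1)))
  for (i in ord) {
    p <- tr$parent[i]
    L <- elen$v[i]
    if (is.na(L) || length(L) == 0) L <- 0
    depth[i] <- if (is.na(p)) 0 else depth[p] + L
  }
  maxd <- max(depth)
  tr$time <- maxd - depth
  validate_timetree(tr)
  tr
}

node_depth_count <- function(tr, i) {
  d <- 0
  while (!is.na(tr$parent[i])) { i <- tr$parent[i]; d <- d + 1 }
  d
}

#' Serialize a tree to Newick
#'
#' Branch lengths are written with 12 significant digits; annotations are
#' emitted as NHX comments when requested.
#'
#' @param tr A `timetree`.
#' @param include_annotations Emit `[&&NHX:...]` comments.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string ending in `;`.
#' @export
write_tree <- function(tr, include_annotations = FALSE, digits = 12) {
  ch <- children_list(tr)
  fmt <- function(x) sprintf("%.*g", digits, x)
  ann_str <- function(a) {
    a <- a[!vapply(a, is.null, logical(1))]
    keep <- vapply(a, function(v) length(v) == 1L && is.null(dim(v)) &&
                     (is.character(v) || is.numeric(v) || is.logical(v)),
                   logical(1))
    a <- a[keep]
    if (!length(a)) return("")
    paste0("[&&NHX:", paste(names(a), vapply(a, function(v)
      if (is.numeric(v)) fmt(v) else as.character(v), character(1)),
      sep = "=", collapse = ":"), "]")
  }
  rec <- function(i) {
    kids <- ch[[i]]
    body <- if (length(kids))
      paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")")
    else ""
    lab <- if (!is.na(tr$label[i])) tr$label[i] else ""
    p <- tr$parent[i]
    lenpart <- if (!is.na(p)) paste0(":", fmt(tr$time[p] - tr$time[i])) else ""
    annpart <- if (include_annotations) ann_str(tr$annot[[i]]) else ""
    paste0(body, lab, annpart, lenpart)
  }
  paste0(rec(tree_root(tr)), ";")
}

from_phylo <- function(ph) {
  nt <- length(ph$tip.label)
  nn <- nt + ph$Nnode
  parent <- rep(NA_integer_, nn)
  parent[ph$edge[, 2]] <- ph$edge[, 1]
  elen <- rep(0, nn)
  if (!is.null(ph$edge.length)) elen[ph$edge[, 2]] <- ph$edge.length
  if (any(elen < 0)) stop("negative branch length in input tree")
  depth <- numeric(nn)
  root <- which(is.na(parent))
  ord <- ph$edge[, 2][order(ph$edge[, 1])]  # parents precede children? ensure via repeated passes
  # simple BFS from root
  depth[root] <- 0
  queue <- root
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    kids <- ph$edge[ph$edge[, 1] == i, 2]
    depth[kids] <- depth[i] + elen[kids]
    queue <- c(queue, kids)
  }
  lab <- rep(NA_character_, nn)
  lab[seq_len(nt)] <- ph$tip.label
  timetree(parent, max(depth) - depth, lab)
}

#' Convert a `timetree` to an \pkg{ape} `phylo` object
#' @param tr A `timetree`.
#' @return A `phylo` object (annotations are dropped).
#' @export
as_phylo <- function(tr) {
  ape::read.tree(text = write_tree(tr))
}

# Pruning -----------------------------------------------------------------

#' Restrict a tree to a set of sampled leaves
#'
#' Returns the subtree induced by `keep`: unsampled leaves and their private
#' ancestry are removed, unary nodes are suppressed with branch lengths
#' summed.  Node times of retained nodes are unchanged.  Each retained node
#' keeps its original id in `annot$orig_id`, and inherits any coalescent
#' bound from a suppressed ancestor chain (`bounded`, `bound_time`; the
#' youngest bound on the chain wins, since a single lineage above the
#' youngest bound trivially satisfies the older ones).
#'
#' @param tr A `timetree`.
#' @param keep Character vector of leaf labels to retain.
#' @return A pruned `timetree`.
#' @export
prune_to_sampled <- function(tr, keep) {
  lv <- tree_leaves(tr)
  keep_ids <- lv[tr$label[lv] %in% keep]
  if (!length(keep)) stop("empty keep set: gene family completely lost")
  if (length(keep_ids) != length(keep))
    stop("unknown leaf labels: ",
         paste(setdiff(keep, tr$label[lv]), collapse = ", "))
  n <- length(tr$parent)
  retain <- rep(FALSE, n)
  for (i in keep_ids) {
    j <- i
    while (!is.na(j) && !retain[j]) { retain[j] <- TRUE; j <- tr$parent[j] }
  }
  ch <- children_list(tr)
  nkept <- integer(n)  # number of retained children
  for (i in which(retain)) nkept[i] <- sum(retain[ch[[i]]])
  # a retained node survives if it is a kept leaf or has >= 2 retained kids,
  # or is the root of the retained part with >= 2 kids
  keep_node <- rep(FALSE, n)
  keep_node[keep_ids] <- TRUE
  keep_node[retain & nkept >= 2L] <- TRUE
  # walk from each surviving node up through suppressed unary chain
  surv <- which(keep_node)
  new_id <- integer(n); new_id[surv] <- seq_along(surv)
  parent2 <- rep(NA_integer_, length(surv))
  ann2 <- vector("list", length(surv))
  for (k in seq_along(surv)) {
    i <- surv[k]
    a <- tr$annot[[i]]
    a$orig_id <- i
    chain <- integer(0)
    j <- tr$parent[i]
    while (!is.na(j) && !keep_node[j]) { chain <- c(chain, j); j <- tr$parent[j] }
    # inherit bound from suppressed chain: youngest (smallest time) wins; a
    # bound already on i itself is younger than anything above it
    if (is.null(a$bounded) || !isTRUE(a$bounded)) {
      for (cnode in chain) {
        ca <- tr$annot[[cnode]]
        if (isTRUE(ca$bounded)) {
          a$bounded <- TRUE
          a$bound_time <- ca$bound_time
          a$bound_source <- ca$bound_source
          break  # chain is walked youngest-first
        }
      }
    }
    if (length(chain)) a$pruned_chain <- chain
    parent2[k] <- if (is.na(j)) NA_integer_ else new_id[j]
    ann2[[k]] <- a
  }
  structure(list(parent = parent2, time = tr$time[surv],
                 label = tr$label[surv], annot = ann2),
            class = "timetree")
}

# Contemporary distances --------------------------------------------------

#' Patristic distance between two contemporary points
#'
#' Distance between the points at time `tau` on the branches above nodes
#' `a` and `b`: twice the elapsed time down from their most recent common
#' ancestor, `2 * (t_MRCA - tau)`.
#'
#' @param tr A `timetree`.
#' @param a,b Node ids; the branch above each must contain time `tau`.
#' @param tau Time point (backwards from present).
#' @return Distance in the tree's time units.
#' @export
distance_at_time <- function(tr, a, b, tau) {
  alive <- function(i) {
    p <- tr$parent[i]
    top <- if (is.na(p)) Inf else tr$time[p]
    tr$time[i] <= tau && tau <= top
  }
  if (!alive(a)) stop("branch above node ", a, " does not span time ", tau)
  if (!alive(b)) stop("branch above node ", b, " does not span time ", tau)
  if (a == b) return(0)
  anc <- function(i) {
    out <- i
    while (!is.na(tr$parent[i])) { i <- tr$parent[i]; out <- c(out, i) }
    out
  }
  aa <- anc(a); bb <- anc(b)
  common <- intersect(aa, bb)
  if (!length(common)) stop("nodes share no ancestor")
  mrca <- common[which.min(tr$time[common])]
  2 * (tr$time[mrca] - tau)
}

# Mapping tables ----------------------------------------------------------

#' Write a gene/locus/species mapping table
#'
#' @param map A data.frame with columns `gene_node`, `locus_branch`,
#'   `species_branch`, `time`.
#' @param path Output TSV path.
#' @export
write_mapping <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
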