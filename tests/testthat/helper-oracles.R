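## Independent oracles used to check the package implementations. These take
## deliberately different routes (explicit path walks, ancestor-set
## intersections, exhaustive enumeration) from the code under test.

## Sum of edge lengths along the explicitly enumerated tip-to-node path.
oracle_path_sum <- function(tree, tip_label, node) {
  tip <- match(tip_label, tree$tip.label)
  path <- ape::nodepath(tree, from = tip, to = node)
  s <- 0
  for (i in seq_len(length(path) - 1)) {
    e <- which(tree$edge[, 1] == path[i + 1] & tree$edge[, 2] == path[i] |
                 tree$edge[, 1] == path[i] & tree$edge[, 2] == path[i + 1])
    s <- s + tree$edge.length[e]
  }
  s
}

## MRCA by brute-force intersection of ancestor sets (deepest common one).
oracle_mrca <- function(tree, tips) {
  parent <- integer(length(tree$tip.label) + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  anc_set <- function(lbl) {
    nd <- match(lbl, tree$tip.label)
    out <- integer(0)
    while (parent[nd] != 0L) { nd <- parent[nd]; out <- c(out, nd) }
    out
  }
  common <- Reduce(intersect, lapply(tips, anc_set))
  ## the lowest common ancestor is the common ancestor with the most ancestors
  depth <- vapply(common, function(nd) {
    d <- 0L
    while (parent[nd] != 0L) { nd <- parent[nd]; d <- d + 1L }
    d
  }, integer(1))
  common[which.max(depth)]
}

## Exhaustive HPD: scan every window of sorted samples holding >= ceil(mass*n)
## points; shortest wins, ties to the smallest low endpoint.
oracle_hpd <- function(samples, mass = 0.95) {
  s <- sort(samples)
  n <- length(s)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1)) {
    j <- i + m - 1
    if ((s[j] - s[i]) < (best[2] - best[1])) best <- c(s[i], s[j])
  }
  best
}

## Exhaustive maximum cospeciation count: enumerate, bottom-up over the
## parasite tree, every placement of each internal node on every host node.
## A placement of a node at g is valid when at least one child is placed
## within the subtree of g (at most all-but-one children may switch away);
## the node scores 1 when its children's placements occupy >= 2 distinct
## child subtrees of g.
oracle_max_cosp <- function(tg) {
  h <- tg$host; p <- tg$parasite
  nh <- length(h$tip.label); H <- nh + h$Nnode
  np <- length(p$tip.label); P <- np + p$Nnode
  hkids <- split(h$edge[, 2], factor(h$edge[, 1], levels = seq_len(H)))
  pkids <- split(p$edge[, 2], factor(p$edge[, 1], levels = seq_len(P)))
  ## childof[g, x]: which child subtree of g contains x (0 = none)
  indesc <- matrix(FALSE, H, H)
  fill <- function(nd) {
    indesc[nd, nd] <<- TRUE
    for (cn in hkids[[nd]]) {
      fill(cn)
      indesc[, nd] <<- indesc[, nd] | indesc[, cn]
    }
  }
  fill(nh + 1L)
  childof <- matrix(0L, H, H)
  for (g in seq_len(H)) {
    for (ci in seq_along(hkids[[g]])) {
      childof[g, indesc[, hkids[[g]][ci]]] <- ci
    }
  }
  assoc_idx <- match(tg$assoc, h$tip.label)
  ## tab[[pn]]: vector over host positions g of the best count in subtree(pn)
  ## given pn is placed at g (-Inf where placement impossible)
  tab <- vector("list", P)
  eval_node <- function(pn) {
    ch <- pkids[[pn]]
    if (!length(ch)) {
      v <- rep(-Inf, H)
      v[assoc_idx[pn]] <- 0
      tab[[pn]] <<- v
      return(invisible(NULL))
    }
    for (cn in ch) eval_node(cn)
    opts <- lapply(ch, function(cn) which(is.finite(tab[[cn]])))
    combos <- as.matrix(expand.grid(opts))
    base <- vapply(seq_len(nrow(combos)), function(r) {
      sum(vapply(seq_along(ch), function(i) tab[[ch[i]]][combos[r, i]], 0))
    }, 0)
    v <- rep(-Inf, H)
    for (g in seq_len(H)) {
      for (r in seq_len(nrow(combos))) {
        if (!any(indesc[combos[r, ], g])) next  # no child stays: invalid
        cls <- childof[g, combos[r, ]]
        bonus <- as.integer(length(unique(cls[cls > 0])) >= 2)
        v[g] <- max(v[g], base[r] + bonus)
      }
    }
    tab[[pn]] <<- v
    invisible(NULL)
  }
  eval_node(np + 1L)
  max(tab[[np + 1L]])
}

## Random tanglegram on small trees with uniformly random tip associations.
random_tanglegram <- function(n_host, n_par, seed) {
  set.seed(seed)
  h <- ape::rtree(n_host, rooted = TRUE)
  h$tip.label <- paste0("H", seq_len(n_host))
  p <- ape::rtree(n_par, rooted = TRUE)
  p$tip.label <- paste0("p", seq_len(n_par))
  assoc <- stats::setNames(sample(h$tip.label, n_par, replace = TRUE),
                           p$tip.label)
  tanglegram(h, p, assoc)
}

## All permutations of a vector (rows of the returned matrix).
combinat_perms <- function(x) {
  n <- length(x)
  if (n == 1) return(matrix(x, 1, 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- combinat_perms(x[-i])
    out <- rbind(out, cbind(x[i], rest, deparse.level = 0))
  }
  out
}

## Calibrated (S, T) medians of the packaged foamy-virus lineage table.
fv_calibration_points <- function() {
  tab <- fv_timescales()
  tab[tab$calibrated, c("node", "s_median", "t_median")]
}
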