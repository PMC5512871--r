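#' Build a host-parasite tanglegram
#'
#' @param host Rooted host `phylo`.
#' @param parasite Rooted parasite (virus) `phylo`.
#' @param assoc Associations: a named character vector (names = parasite tip
#'   labels, values = host tip labels) or a two-column data frame
#'   `(parasite_tip, host_tip)`. Every parasite tip must map to exactly one
#'   existing host tip; several parasite tips may share a host tip.
#' @return Object of class `tanglegram`.
#' @export
tanglegram <- function(host, parasite, assoc) {
  stopifnot(inherits(host, "phylo"), inherits(parasite, "phylo"))
  if (is.data.frame(assoc)) {
    v <- as.character(assoc[[2]])
    names(v) <- as.character(assoc[[1]])
    assoc <- v
  }
  miss <- setdiff(parasite$tip.label, names(assoc))
  if (length(miss)) stop("unmapped parasite tip(s): ", paste(miss, collapse = ", "))
  assoc <- assoc[parasite$tip.label]
  bad <- setdiff(assoc, host$tip.label)
  if (length(bad)) stop("association to unknown host tip(s): ", paste(bad, collapse = ", "))
  structure(list(host = host, parasite = parasite, assoc = assoc),
            class = "tanglegram")
}

#' Read a parasite-to-host association map from TSV
#'
#' @param path Two-column TSV `parasite_tip  host_tip`, optional header.
#' @return Named character vector (parasite tip -> host tip).
#' @export
read_associations <- function(path) {
  if (!file.exists(path)) stop("association file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, header = FALSE)
  if (identical(tolower(as.character(df[1, 1])), "parasite_tip")) df <- df[-1, , drop = FALSE]
  v <- as.character(df[[2]])
  names(v) <- as.character(df[[1]])
  v
}

## Precompute host/parasite structure reused across permutation replicates.
.prep_tanglegram <- function(tg) {
  prep_tree <- function(tr) {
    ntip <- length(tr$tip.label)
    n_all <- ntip + tr$Nnode
    kids <- .children(tr)
    ## postorder: children before parents
    post <- integer(0)
    stack <- ntip + 1L
    seen <- logical(n_all)
    order_rev <- integer(0)
    while (length(stack)) {
      nd <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      order_rev <- c(order_rev, nd)
      stack <- c(stack, kids[[nd]])
    }
    post <- rev(order_rev)
    list(ntip = ntip, n_all = n_all, root = ntip + 1L, kids = kids, post = post)
  }
  h <- prep_tree(tg$host)
  p <- prep_tree(tg$parasite)
  ## desc[x, h]: is x in the host subtree rooted at h
  desc <- matrix(FALSE, h$n_all, h$n_all)
  for (nd in h$post) {
    desc[nd, nd] <- TRUE
    for (cn in h$kids[[nd]]) desc[, nd] <- desc[, nd] | desc[, cn]
  }
  h$desc <- desc
  h$internal <- which(vapply(h$kids, length, 1L) > 0)
  list(h = h, p = p,
       host_tip_idx = stats::setNames(seq_len(h$ntip), tg$host$tip.label))
}

## Max over matchings (>= 2 matched pairs) of sum of gains[i, j]; columns used
## at most once. gains may contain -Inf (infeasible pair). Returns -Inf when
## no such matching exists, else list(score, match) with match[i] = column of
## child i (0 = unmatched).
.best_cosp_matching <- function(gains) {
  k <- nrow(gains); m <- ncol(gains)
  if (k == 2L) {
    ## binary fast path: both children must be matched, to distinct columns
    if (m < 2L) return(list(score = -Inf, match = NULL))
    s <- outer(gains[1L, ], gains[2L, ], `+`)
    diag(s) <- -Inf
    best <- max(s)
    if (!is.finite(best)) return(list(score = -Inf, match = NULL))
    ij <- which(s == best, arr.ind = TRUE)[1L, ]
    return(list(score = best, match = c(ij[[1L]], ij[[2L]])))
  }
  best_score <- -Inf
  best_match <- NULL
  cur <- integer(k)
  rec <- function(i, used, nmatched, acc) {
    if (i > k) {
      if (nmatched >= 2 && acc > best_score) {
        best_score <<- acc
        best_match <<- cur
      }
      return(invisible(NULL))
    }
    ## skip (child i switched out / duplicated; contributes baseline only)
    cur[i] <<- 0L
    rec(i + 1L, used, nmatched, acc)
    for (j in seq_len(m)) {
      if (!used[j] && is.finite(gains[i, j])) {
        cur[i] <<- j
        used[j] <- TRUE
        rec(i + 1L, used, nmatched + 1L, acc + gains[i, j])
        used[j] <- FALSE
      }
    }
    cur[i] <<- 0L
    invisible(NULL)
  }
  rec(1L, logical(m), 0L, 0)
  if (!is.finite(best_score)) return(list(score = -Inf, match = NULL))
  list(score = best_score, match = best_match)
}

## Core DP. assoc_idx: host tip index per parasite tip (parasite tip order).
## A[p, h] = best score of parasite subtree p given p is placed within the
## host subtree rooted at h. At its placement g, an internal node is either a
## cospeciation (>= 2 children matched into distinct child subtrees of g;
## any further children switch freely) or a duplication / duplication+switch
## (at least one child stays within subtree(g); the others may switch
## anywhere) — mirroring the one-jump-per-event structure of event-based
## reconciliation. Returns list(max, A, B, cosp, at) for traceback.
.cosp_dp <- function(prep, assoc_idx, keep_tables = FALSE) {
  h <- prep$h; p <- prep$p
  A <- matrix(-Inf, p$n_all, h$n_all)
  B <- numeric(p$n_all)
  cosp <- if (keep_tables) matrix(-Inf, p$n_all, h$n_all) else NULL
  at <- if (keep_tables) matrix(-Inf, p$n_all, h$n_all) else NULL
  for (pn in p$post) {
    ch <- p$kids[[pn]]
    if (!length(ch)) {
      A[pn, ] <- ifelse(h$desc[assoc_idx[pn], ], 0, -Inf)
      B[pn] <- 0
      next
    }
    dup <- sum(B[ch])
    gmat <- A[ch, , drop = FALSE] - B[ch]
    ## duplication (+ switches) with pn placed exactly at g: the staying
    ## child is the one losing least by being pinned inside subtree(g)
    noncosp_g <- dup + apply(gmat, 2, max)
    cosp_g <- rep(-Inf, h$n_all)
    for (g in h$internal) {
      gm <- h$kids[[g]]
      bm <- .best_cosp_matching(gmat[, gm, drop = FALSE])
      if (is.finite(bm$score)) cosp_g[g] <- 1 + dup + bm$score
    }
    at_g <- pmax(noncosp_g, cosp_g)
    ## M[hh] = best placement score within subtree(hh)
    M <- rep(-Inf, h$n_all)
    for (hh in h$post) {
      M[hh] <- at_g[hh]
      for (cn in h$kids[[hh]]) M[hh] <- max(M[hh], M[cn])
    }
    A[pn, ] <- M
    B[pn] <- A[pn, h$root]
    if (keep_tables) { cosp[pn, ] <- cosp_g; at[pn, ] <- at_g }
  }
  list(max = B[p$root], A = A, B = B, cosp = cosp, at = at)
}

## Traceback of one optimal reconciliation: parasite internal node -> host
## node + event label.
.cosp_traceback <- function(tg, prep, assoc_idx, dp) {
  h <- prep$h; p <- prep$p
  mapping <- integer(p$n_all)
  event <- character(p$n_all)
  assign_node <- function(pn, hroot) {
    ch <- p$kids[[pn]]
    if (!length(ch)) {
      mapping[pn] <<- assoc_idx[pn]
      return(invisible(NULL))
    }
    target <- dp$A[pn, hroot]
    ## prefer a cospeciation placement realising the optimum
    cands <- which(h$desc[, hroot] & is.finite(dp$cosp[pn, ]) &
                     dp$cosp[pn, ] > target - 1e-9)
    if (length(cands)) {
      g <- cands[1]
      gm <- h$kids[[g]]
      gains <- dp$A[ch, gm, drop = FALSE] - dp$B[ch]
      bm <- .best_cosp_matching(gains)
      mapping[pn] <<- g
      event[pn] <<- "cospeciation"
      for (i in seq_along(ch)) {
        if (bm$match[i] > 0) assign_node(ch[i], gm[bm$match[i]])
        else assign_node(ch[i], h$root)
      }
    } else {
      g <- which(h$desc[, hroot] & dp$at[pn, ] > target - 1e-9)[1]
      gains <- dp$A[ch, g] - dp$B[ch]
      stay <- which.max(gains)
      mapping[pn] <<- g
      for (i in seq_along(ch)) {
        if (i == stay) assign_node(ch[i], g)
        else assign_node(ch[i], h$root)
      }
      outside <- any(!h$desc[mapping[ch], g])
      event[pn] <<- if (outside) "host switch" else "duplication"
    }
    invisible(NULL)
  }
  assign_node(p$root, h$root)
  internal <- which(vapply(p$kids, length, 1L) > 0)
  data.frame(parasite_node = internal, host_node = mapping[internal],
             event = event[internal], stringsAsFactors = FALSE)
}

#' Maximum achievable co-speciation count in a tanglegram
#'
#' Computes the exact maximum number of co-speciation events over all untimed
#' event-based reconciliations of the parasite tree into the host tree, the
#' objective induced by the vertex cost scheme co-speciation = -1 with all
#' other events (duplication, host switch, loss, failure to diverge) free.
#' Each parasite internal node is placed on a host node and labelled
#' co-speciation (children mapped into distinct host-child subtrees),
#' duplication (children within the same host subtree) or host switch (a
#' child mapped outside); losses are free and switch targets unconstrained,
#' but — as in event-based reconciliation, where a switch carries one
#' daughter lineage away — at least one child of every node remains within
#' its host subtree.
#' The maximisation is a dynamic programme over (parasite node, host node);
#' at polytomies the co-speciation condition is resolved by an exact
#' maximum-weight assignment of parasite-child subtrees to host-child
#' subtrees. Both trees may contain polytomies (e.g. after
#' [collapse_low_support()]).
#'
#' @param tg A [tanglegram()].
#' @return Object of class `reconciliation`: list with `max_cospeciations`,
#'   `n_parasite_internal`, and `mapping` (data frame: parasite internal
#'   node, host node, event label) realising the maximum.
#' @examples
#' h <- parse_newick("((A:1,B:1):1,C:1);")
#' p <- parse_newick("((a:1,b:1):1,c:1);")
#' tg <- tanglegram(h, p, c(a = "A", b = "B", c = "C"))
#' max_cospeciations(tg)$max_cospeciations  # 2
#' @export
max_cospeciations <- function(tg) {
  stopifnot(inherits(tg, "tanglegram"))
  prep <- .prep_tanglegram(tg)
  assoc_idx <- prep$host_tip_idx[tg$assoc]
  dp <- .cosp_dp(prep, assoc_idx, keep_tables = TRUE)
  mapping <- .cosp_traceback(tg, prep, assoc_idx, dp)
  res <- structure(list(
    max_cospeciations = as.integer(round(dp$max)),
    n_parasite_internal = tg$parasite$Nnode,
    mapping = mapping
  ), class = "reconciliation")
  stopifnot(sum(mapping$event == "cospeciation") == res$max_cospeciations)
  res
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("Maximum co-speciations: %d / %d parasite internal nodes (%.1f%%)\n",
              x$max_cospeciations, x$n_parasite_internal,
              100 * x$max_cospeciations / max(1, x$n_parasite_internal)))
  invisible(x)
}

#' Random tip mapping permutation test for co-speciation
#'
#' Assesses whether the observed maximum co-speciation count could arise by
#' chance: the multiset of host assignments is uniformly permuted among the
#' parasite tips `N` times (preserving how often each host tip is used), the
#' maximum co-speciation count is recomputed for each permutation, and the
#' p-value is the fraction of permutations reaching at least the observed
#' count (`k / N`, displayed as `< 1/N` when no permutation does).
#'
#' @param tg A [tanglegram()].
#' @param N Number of permutations (>= 1); 500 is the conventional sample
#'   size for this test.
#' @param seed Integer seed; identical seeds give identical results.
#' @return Object of class `tip_mapping_test`: list with `observed`, `N`,
#'   `k`, `p_value`, `p_display`, `seed`, and the vector of permuted counts.
#' @export
random_tip_mapping_test <- function(tg, N = 500L, seed = 1L) {
  stopifnot(inherits(tg, "tanglegram"))
  N <- as.integer(N)
  if (N < 1) stop("N must be >= 1")
  prep <- .prep_tanglegram(tg)
  assoc_idx <- prep$host_tip_idx[tg$assoc]
  observed <- .cosp_dp(prep, assoc_idx)$max
  set.seed(as.integer(seed))
  perm_counts <- vapply(seq_len(N), function(r) {
    .cosp_dp(prep, sample(assoc_idx))$max
  }, numeric(1))
  k <- sum(perm_counts >= observed)
  structure(list(
    observed = as.integer(round(observed)), N = N, k = k,
    p_value = k / N,
    p_display = if (k == 0) sprintf("<%g", 1 / N) else sprintf("%g", k / N),
    seed = as.integer(seed), perm_counts = as.integer(round(perm_counts))
  ), class = "tip_mapping_test")
}

#' @export
print.tip_mapping_test <- function(x, ...) {
  cat(sprintf("Random tip mapping test: observed = %d, N = %d, P %s %s\n",
              x$observed, x$N, if (x$k == 0) "" else "=", x$p_display))
  invisible(x)
}
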