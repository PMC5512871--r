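## Seeded generators producing inputs with the statistical structure each
## analysis stage assumes, so the full toolchain can be exercised end to end
## without external data. All generators are deterministic given their seed.

#' Simulate a host-virus tanglegram by co-speciation with host switching
#'
#' Grows an ultrametric Yule host tree, then threads parasite lineages
#' through it: at each host split, a parasite lineage on that host
#' co-speciates (splits with the host) with probability `1 - switch_prob`,
#' or jumps to a uniformly chosen contemporary host lineage; after each
#' event every parasite lineage is lost with probability `loss_prob`.
#' Parasite tips are the surviving lineages at the host tips. Ground truth
#' is the number of recoverable co-speciation events: splits retained as
#' internal nodes of the pruned parasite tree whose surviving descendants
#' all stayed inside their natal host subtrees (events later erased by host
#' switching cannot be witnessed from tip data and are not counted, so the
#' ground truth always lower-bounds the reconciliation maximum).
#'
#' @param n_hosts Number of host tips (>= 3).
#' @param switch_prob Host-switch probability per host split, in `[0, 1)`.
#' @param loss_prob Loss probability per parasite lineage per event, in
#'   `[0, 1)`.
#' @param seed Integer seed.
#' @return List: `tanglegram` (a [tanglegram()]), `true_cospeciations`
#'   (integer), `host`, `parasite`, `assoc`.
#' @export
simulate_cophylogeny <- function(n_hosts, switch_prob = 0, loss_prob = 0,
                                 seed = 1L) {
  stopifnot(n_hosts >= 3, switch_prob >= 0, switch_prob < 1,
            loss_prob >= 0, loss_prob < 1)
  set.seed(as.integer(seed))
  for (try in 1:50) {
    host <- ape::rphylo(n_hosts, birth = 1, death = 0)
    host$tip.label <- paste0("H", seq_len(n_hosts))
    res <- .thread_parasites(host, switch_prob, loss_prob)
    if (!is.null(res) && length(res$assoc) >= 2) {
      tg <- tanglegram(host, res$parasite, res$assoc)
      return(list(tanglegram = tg, true_cospeciations = res$true_cosp,
                  host = host, parasite = res$parasite, assoc = res$assoc))
    }
  }
  stop("could not generate a tanglegram with >= 2 surviving parasite tips ",
       "after 50 attempts (parameters too extreme)")
}

## Thread parasite lineages through the host tree top-down. Each parasite
## lineage is a node in a growing event tree; cospeciation events are marked
## so the post-pruning ground truth can be counted.
.thread_parasites <- function(host, switch_prob, loss_prob) {
  ntip <- length(host$tip.label)
  kids <- .children(host)
  ## process host nodes in preorder by split time (root first); rphylo trees
  ## are ultrametric so node depth orders splits in time
  depth <- ape::node.depth.edgelength(host)
  internal <- ntip + seq_len(host$Nnode)
  internal <- internal[order(depth[internal])]
  ## parasite event-tree in parent-pointer form
  par_parent <- integer(0)
  par_host <- integer(0)     # current host lineage of each parasite lineage
  par_birth <- integer(0)    # host lineage at birth (natal subtree)
  par_alive <- logical(0)
  par_cosp <- logical(0)     # was this node born of a cospeciation split
  new_lineage <- function(parent, hostln, cosp) {
    par_parent <<- c(par_parent, parent)
    par_host <<- c(par_host, hostln)
    par_birth <<- c(par_birth, hostln)
    par_alive <<- c(par_alive, TRUE)
    par_cosp <<- c(par_cosp, cosp)
    length(par_parent)
  }
  ## host lineage = host node whose subtree-edge we currently sit on
  new_lineage(0L, ntip + 1L, FALSE)  # one parasite at the host root
  current_hosts <- ntip + 1L
  for (hnode in internal) {
    ch <- kids[[hnode]]
    current_hosts <- c(setdiff(current_hosts, hnode), ch)
    on_node <- which(par_alive & par_host == hnode)
    for (pl in on_node) {
      if (stats::runif(1) >= switch_prob) {
        ## cospeciation: split with the host
        par_alive[pl] <- FALSE
        for (hc in ch) new_lineage(pl, hc, TRUE)
      } else {
        ## jump to a uniformly chosen contemporary host lineage
        par_host[pl] <- current_hosts[sample.int(length(current_hosts), 1)]
      }
    }
    if (loss_prob > 0) {
      alive <- which(par_alive)
      kill <- alive[stats::runif(length(alive)) < loss_prob]
      par_alive[kill] <- FALSE
      par_parent  # no-op; lineages simply end
      par_host[kill] <- NA_integer_
    }
  }
  survivors <- which(par_alive & par_host <= ntip)
  if (length(survivors) < 2) return(NULL)
  ## prune: keep survivors and their ancestors; count retained cospeciations
  keep <- logical(length(par_parent))
  for (s in survivors) {
    nd <- s
    while (nd != 0L && !keep[nd]) { keep[nd] <- TRUE; nd <- par_parent[nd] }
  }
  n_child_kept <- integer(length(par_parent))
  for (nd in which(keep)) {
    pp <- par_parent[nd]
    if (pp != 0L) n_child_kept[pp] <- n_child_kept[pp] + 1L
  }
  ## ground truth counts the recoverable ("clean") cospeciation events: a
  ## retained split whose every surviving descendant tip stayed inside the
  ## natal host subtree of the child lineage it descends from. Clean events
  ## are jointly realisable by an event-based reconciliation, so they lower-
  ## bound the reconciliation maximum; events later erased by host switching
  ## are not counted (they are unwitnessable from tip data).
  n_host_all <- ntip + host$Nnode
  hdesc <- matrix(FALSE, n_host_all, n_host_all)
  hpost_rev <- rev(internal)
  for (t in seq_len(ntip)) hdesc[t, t] <- TRUE
  for (nd in c(hpost_rev)) {
    hdesc[nd, nd] <- TRUE
    for (cn in kids[[nd]]) hdesc[, nd] <- hdesc[, nd] | hdesc[, cn]
  }
  tip_hosts_under <- vector("list", length(par_parent))
  order_bottom_up <- order(seq_along(par_parent), decreasing = TRUE)
  for (nd in order_bottom_up) {
    if (!keep[nd]) next
    chn <- which(keep & par_parent == nd)
    if (!length(chn)) {
      tip_hosts_under[[nd]] <- par_host[nd]
    } else {
      tip_hosts_under[[nd]] <- unlist(tip_hosts_under[chn])
    }
  }
  split_nodes <- which(keep & n_child_kept >= 2L)
  true_cosp <- sum(vapply(split_nodes, function(nd) {
    chn <- which(keep & par_parent == nd)
    all(par_cosp[chn]) &&
      all(vapply(chn, function(ci) {
        all(hdesc[tip_hosts_under[[ci]], par_birth[ci]])
      }, logical(1)))
  }, logical(1)))
  ## emit the pruned parasite tree as Newick (suppress unary nodes)
  tips <- survivors
  tip_name <- stats::setNames(paste0("p", seq_along(tips)), tips)
  emit <- function(nd) {
    chn <- which(keep & par_parent == nd)
    if (!length(chn)) return(sprintf("%s:1", tip_name[[as.character(nd)]]))
    parts <- vapply(chn, emit, character(1))
    if (length(parts) == 1L) return(parts)  # unary: splice through
    sprintf("(%s):1", paste(parts, collapse = ","))
  }
  roots <- which(keep & par_parent == 0L)
  nwk <- emit(roots[1])
  nwk <- sub(":1$", ";", paste0(nwk, ""))
  if (!grepl(";$", nwk)) nwk <- paste0(nwk, ";")
  parasite <- parse_newick(nwk)
  assoc <- stats::setNames(host$tip.label[par_host[tips]], tip_name)
  assoc <- assoc[parasite$tip.label]
  list(parasite = parasite, assoc = assoc, true_cosp = true_cosp)
}

#' Simulate posterior tree samples under a known power-law clock
#'
#' Builds a caterpillar (ladder) tree whose focal-lineage node depths equal
#' `S_nodes`, then emits `n_trees` noisy copies with every branch length
#' multiplied by independent lognormal jitter with mean 1 and coefficient of
#' variation `rel_noise_sd` — a proxy for the spread of posterior tree
#' samples. Calibration timescales are set to the true power law
#' `T = 10^(alpha + beta * log10(S))` for the designated calibration nodes.
#'
#' @param alpha,beta True power-law parameters (`beta > 0`).
#' @param S_nodes Strictly increasing positive focal-lineage depths, one per
#'   internal node of the ladder (tip-ward to root-ward).
#' @param rel_noise_sd Relative branch-length noise (lognormal CV); 0 gives
#'   identical copies.
#' @param n_trees Number of posterior samples to emit.
#' @param seed Integer seed.
#' @param calib_idx Indices (into `S_nodes`) of the calibration nodes;
#'   default all.
#' @return List: `trees` (`multiPhylo`), `calibration` (data frame `node`,
#'   `t_median`, `t_low`, `t_high`, `source`), `specs` (named list of taxon
#'   sets, one per node), `focal_tip`, `truth` (`alpha`, `beta`, true `S`
#'   and `T` per node).
#' @export
simulate_tdrp_posterior <- function(alpha, beta, S_nodes, rel_noise_sd = 0,
                                    n_trees = 100L, seed = 1L,
                                    calib_idx = seq_along(S_nodes)) {
  stopifnot(beta > 0, all(S_nodes > 0), n_trees >= 1, rel_noise_sd >= 0)
  if (any(diff(S_nodes) <= 0)) stop("S_nodes must be strictly increasing")
  set.seed(as.integer(seed))
  k <- length(S_nodes)
  focal <- "FOCAL"
  og <- paste0("OG", seq_len(k))
  seg <- diff(c(0, S_nodes))  # focal-lineage segment lengths
  build_newick <- function(seglen) {
    nwk <- sprintf("%s:%.12g", focal, seglen[1])
    for (i in seq_len(k)) {
      stem <- if (i < k) sprintf(":%.12g", seglen[i + 1]) else ""
      nwk <- sprintf("(%s,%s:%.12g)node_%d%s", nwk, og[i], S_nodes[i], i, stem)
    }
    paste0(nwk, ";")
  }
  sdlog <- if (rel_noise_sd > 0) sqrt(log(1 + rel_noise_sd^2)) else 0
  meanlog <- -sdlog^2 / 2  # lognormal mean 1
  trees <- vector("list", n_trees)
  for (r in seq_len(n_trees)) {
    noise <- if (sdlog > 0) stats::rlnorm(k, meanlog, sdlog) else rep(1, k)
    trees[[r]] <- parse_newick(build_newick(seg * noise))
  }
  class(trees) <- "multiPhylo"
  T_true <- 10^(alpha + beta * log10(S_nodes))
  calibration <- data.frame(
    node = paste0("node_", calib_idx),
    t_median = T_true[calib_idx],
    t_low = T_true[calib_idx] * 0.9,
    t_high = T_true[calib_idx] * 1.1,
    source = "simulated",
    stringsAsFactors = FALSE
  )
  specs <- lapply(seq_len(k), function(i) c(focal, og[i]))
  names(specs) <- paste0("node_", seq_len(k))
  list(trees = trees, calibration = calibration, specs = specs,
       focal_tip = focal,
       truth = list(alpha = alpha, beta = beta, S = S_nodes, T = T_true))
}

## TN93 rate matrix (rows/cols A, C, G, T), scaled to one expected
## substitution per site per unit time
.tn93_rate_matrix <- function(pi, kappa1, kappa2) {
  piA <- pi[1]; piC <- pi[2]; piG <- pi[3]; piT <- pi[4]
  a1 <- kappa1; a2 <- kappa2; b <- 1
  Q <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  Q["A","G"] <- a1 * piG; Q["G","A"] <- a1 * piA
  Q["C","T"] <- a2 * piT; Q["T","C"] <- a2 * piC
  tv <- rbind(c(0,1,0,1), c(1,0,1,0), c(0,1,0,1), c(1,0,1,0))
  Q <- Q + b * tv * matrix(pi, 4, 4, byrow = TRUE)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

## exact P(t) = expm(Q t) via eigendecomposition
.tn93_pmatrix <- function(Q, t) {
  e <- eigen(Q)
  P <- Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate an aligned pair of sequences diverged under TN93
#'
#' Draws site ancestors from `freqs` and evolves two copies independently
#' for total divergence `d` (each branch `d/2`) using the exact TN93
#' transition probabilities, so the expectation of the TN93 distance
#' estimator on the pair is `d`.
#'
#' @param d Total divergence in substitutions/site (>= 0).
#' @param freqs Base frequencies `c(A, C, G, T)`, positive, summing to 1.
#' @param kappa1 A<->G transition/transversion rate ratio.
#' @param kappa2 C<->T transition/transversion rate ratio.
#' @param L Number of sites.
#' @param seed Integer seed.
#' @return Character vector of two equal-length sequences.
#' @export
simulate_tn93_pair <- function(d, freqs = rep(0.25, 4), kappa1 = 2, kappa2 = 2,
                               L = 1000L, seed = 1L) {
  stopifnot(d >= 0, L >= 1)
  if (length(freqs) != 4 || any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-8) {
    stop("freqs must be 4 positive values summing to 1")
  }
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  anc <- sample.int(4, L, replace = TRUE, prob = freqs)
  if (d == 0) {
    s <- paste(bases[anc], collapse = "")
    return(c(s, s))
  }
  Q <- .tn93_rate_matrix(freqs, kappa1, kappa2)
  P <- .tn93_pmatrix(Q, d / 2)
  evolve <- function(anc) {
    out <- integer(L)
    for (bcls in 1:4) {
      idx <- which(anc == bcls)
      if (length(idx)) {
        out[idx] <- sample.int(4, length(idx), replace = TRUE, prob = P[bcls, ])
      }
    }
    out
  }
  c(paste(bases[evolve(anc)], collapse = ""),
    paste(bases[evolve(anc)], collapse = ""))
}

.random_dna <- function(n, freqs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
        collapse = "")
}

#' Simulate a contig with a planted ERV (paired LTRs + TSD)
#'
#' Constructs `flank | TSD | LTR5 | internal | LTR3 | TSD | flank`, with the
#' two LTR copies diverged at `ltr_divergence` under TN93 and the identical
#' TSD motif copied to both element boundaries — the structure a genuine
#' germ-line retroviral integration leaves behind.
#'
#' @param ltr_len LTR length (nt).
#' @param internal_len Internal (gag-pol-env) length (nt).
#' @param tsd_len Target-site-duplication length, 4-6 nt.
#' @param ltr_divergence Total divergence between the LTR copies
#'   (substitutions/site).
#' @param flank_len Host flank length on each side (nt).
#' @param seed Integer seed.
#' @return List: `contig` (string), `id`, and `truth` with 0-based half-open
#'   coordinates (`ltr5`, `ltr3`, `tsd_left`, `tsd_right`, `element`), the
#'   `tsd` motif, the two LTR copies, and the planted `ltr_divergence`.
#' @export
simulate_erv_contig <- function(ltr_len = 400L, internal_len = 6000L,
                                tsd_len = 4L, ltr_divergence = 0,
                                flank_len = 2000L, seed = 1L) {
  stopifnot(ltr_len > 0, internal_len > 0, flank_len > 0,
            tsd_len >= 4, tsd_len <= 6, ltr_divergence >= 0)
  set.seed(as.integer(seed))
  tsd <- .random_dna(tsd_len)
  left <- .random_dna(flank_len)
  right <- .random_dna(flank_len)
  internal <- .random_dna(internal_len)
  pair <- simulate_tn93_pair(ltr_divergence, L = ltr_len,
                             seed = sample.int(.Machine$integer.max, 1))
  contig <- paste0(left, tsd, pair[1], internal, pair[2], tsd, right)
  ## 0-based half-open coordinates
  s_tsd_l <- flank_len
  s_ltr5 <- s_tsd_l + tsd_len
  s_int <- s_ltr5 + ltr_len
  s_ltr3 <- s_int + internal_len
  s_tsd_r <- s_ltr3 + ltr_len
  list(
    contig = contig,
    id = sprintf("synthetic_erv_seed%d", as.integer(seed)),
    truth = list(
      tsd = tsd,
      tsd_left = c(s_tsd_l, s_ltr5),
      ltr5 = c(s_ltr5, s_int),
      ltr3 = c(s_ltr3, s_tsd_r),
      tsd_right = c(s_tsd_r, s_tsd_r + tsd_len),
      element = c(s_ltr5, s_tsd_r),
      ltr_divergence = ltr_divergence,
      ltr_seqs = pair
    )
  )
}
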