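#' Parse Newick text into a rooted phylogeny
#'
#' Thin, validating wrapper around [ape::read.tree()]. Branch lengths are
#' substitutions/site; internal node labels are interpreted as clade support
#' when numeric (posterior probabilities in `[0,1]`, or bootstrap percentages
#' in `(1,100]`, which [node_support()] rescales to `[0,1]`).
#'
#' @param text Newick string. May contain several trees (one per `;`), in
#'   which case a `multiPhylo` list is returned.
#' @param file Path to a Newick file, used when `text` is missing.
#' @return A `phylo` object, or a `multiPhylo` list when the input holds more
#'   than one tree.
#' @examples
#' tr <- parse_newick("((A:0.1,B:0.2)0.95:0.3,C:0.6);")
#' node_support(tr)
#' @export
parse_newick <- function(text, file = NULL) {
  if (missing(text)) {
    stopifnot(is.character(file), length(file) == 1L)
    if (!file.exists(file)) stop("tree file not found: ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  stopifnot(is.character(text))
  text <- paste(text, collapse = "\n")
  .check_parens(text)
  trees <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(trees)) stop("Newick parse error: no tree could be read", call. = FALSE)
  if (inherits(trees, "multiPhylo")) {
    trees <- lapply(trees, .validate_phylogeny)
    class(trees) <- "multiPhylo"
    return(trees)
  }
  .validate_phylogeny(trees)
}

## Balanced-parenthesis pre-check so malformed input fails with the offending
## position rather than an opaque downstream error.
.check_parens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error: unbalanced ')' at character ", i, call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop("Newick parse error: ", depth, " unclosed '(' in input", call. = FALSE)
  }
  invisible(TRUE)
}

.validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylogeny")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!is.null(tree$edge.length)) {
    if (any(!is.finite(tree$edge.length))) {
      stop("non-finite branch length in tree", call. = FALSE)
    }
    if (any(tree$edge.length < 0)) {
      stop("negative branch length: ", min(tree$edge.length), call. = FALSE)
    }
  }
  ## reject numeric internal labels that cannot be support on any convention
  sup <- suppressWarnings(as.numeric(tree$node.label))
  if (any(!is.na(sup) & sup > 100)) {
    stop("internal node label > 100 cannot be interpreted as support", call. = FALSE)
  }
  if (any(!is.na(sup) & sup < 0)) {
    stop("negative internal node label cannot be interpreted as support", call. = FALSE)
  }
  tree
}

#' Write a phylogeny as Newick
#'
#' Branch lengths are written with 10 significant digits so that
#' `parse_newick(write_newick(tree))` round-trips topology, lengths and
#' labels.
#'
#' @param tree A `phylo` or `multiPhylo` object.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 10)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Numeric clade support of internal nodes
#'
#' Internal node labels are returned as support values in `[0,1]`:
#' labels already in `[0,1]` are used as-is (posterior probabilities),
#' labels in `(1,100]` are divided by 100 (bootstrap percentages), and
#' non-numeric or absent labels give `NA`.
#'
#' @param tree A `phylo` object.
#' @return Numeric vector of length `tree$Nnode` (ordered as ape internal
#'   node numbers `Ntip+1, ...`).
#' @export
node_support <- function(tree) {
  n <- tree$Nnode
  if (is.null(tree$node.label)) return(rep(NA_real_, n))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  resc <- !is.na(sup) & sup > 1 & sup <= 100
  sup[resc] <- sup[resc] / 100
  sup
}

## parent[i] = parent node of i (0 for the root); internal helper
.parents <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  parent <- integer(n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent
}

## children as a list indexed by node id
.children <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(n_all)))
}

#' Cumulative root-ward depths along a focal lineage
#'
#' Walks from a focal tip to the root, recording for each ancestor the total
#' branch length (substitutions/site) accumulated from the tip. This is the
#' per-lineage substitution count `S` used to calibrate time-dependent-rate
#' dating: node heights are measured from a chosen exogenous-virus tip down
#' the tree so that internal branches reflect exogenous viral evolution only.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param focal_tip Tip label to trace backward from.
#' @return A data frame of class `lineage_depths` with columns `node` (ape
#'   node id, tip-ward to root-ward) and `S` (cumulative substitutions/site);
#'   the first row is the focal tip's parent, the last row the root.
#' @examples
#' tr <- parse_newick("((A:0.1,B:0.2):0.3,C:0.6);")
#' lineage_depths(tr, "A")
#' @export
lineage_depths <- function(tree, focal_tip) {
  stopifnot(inherits(tree, "phylo"))
  tip <- match(focal_tip, tree$tip.label)
  if (is.na(tip)) stop("unknown tip label: ", focal_tip, call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  parent <- .parents(tree)
  elen <- numeric(length(parent))
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- length(tree$tip.label) + 1L
  nodes <- integer(0)
  S <- numeric(0)
  cur <- tip
  acc <- 0
  while (parent[cur] != 0L) {
    acc <- acc + elen[cur]
    cur <- parent[cur]
    nodes <- c(nodes, cur)
    S <- c(S, acc)
  }
  out <- data.frame(node = nodes, S = S)
  attr(out, "focal_tip") <- focal_tip
  class(out) <- c("lineage_depths", "data.frame")
  out
}

#' Collapse weakly supported nodes into polytomies
#'
#' Every internal non-root node whose support is below `threshold` is merged
#' with its most adjacent basal node: the weak edge is deleted and the node's
#' children reattach to its parent, keeping their own branch lengths (the
#' removed edge's length is discarded — the collapsed tree is meant for
#' topology-based co-speciation counting, where branch lengths play no role).
#' Nodes without support (including the root) are never collapsed.
#'
#' @param tree Rooted `phylo`.
#' @param threshold Support threshold in `[0,1]`; the conventional cut-off
#'   for Bayesian posterior probabilities is 0.80.
#' @return A `phylo` object, possibly with polytomies.
#' @examples
#' tr <- parse_newick("((A:1,B:1)0.5:1,C:1);")
#' write_newick(collapse_low_support(tr, 0.8))
#' @export
collapse_low_support <- function(tree, threshold = 0.8) {
  ## phylo objects always carry a single root node; basal polytomies (e.g.
  ## produced by an earlier collapse) are acceptable input
  stopifnot(inherits(tree, "phylo"), threshold >= 0, threshold <= 1)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  sup <- node_support(tree)
  sup[is.na(sup)] <- 1
  internal <- ntip + seq_len(tree$Nnode)
  drop <- internal[sup < threshold & internal != root]
  if (!length(drop)) return(tree)
  parent <- .parents(tree)
  elen <- numeric(length(parent))
  if (!is.null(tree$edge.length)) elen[tree$edge[, 2]] <- tree$edge.length
  lab <- function(node) {
    if (node <= ntip) tree$tip.label[node] else {
      if (is.null(tree$node.label)) "" else tree$node.label[node - ntip]
    }
  }
  kids <- .children(tree)
  ## splice chains of dropped nodes: replace each dropped child by its own
  ## (recursively spliced) children; then re-emit as Newick and re-parse so
  ## the ape node numbering stays canonical without manual bookkeeping
  splice <- function(node) {
    ch <- kids[[node]]
    out <- integer(0)
    for (cn in ch) {
      if (cn %in% drop) out <- c(out, splice(cn)) else out <- c(out, cn)
    }
    out
  }
  emit <- function(node) {
    ch <- splice(node)
    if (!length(kids[[node]])) {
      return(sprintf("%s:%.10g", lab(node), elen[node]))
    }
    parts <- vapply(ch, emit, character(1))
    if (node == root) {
      sprintf("(%s)%s;", paste(parts, collapse = ","), lab(node))
    } else {
      sprintf("(%s)%s:%.10g", paste(parts, collapse = ","), lab(node), elen[node])
    }
  }
  out <- parse_newick(emit(root))
  if (is.null(tree$edge.length)) out$edge.length <- NULL
  out
}

#' Most recent common ancestor of a taxon set
#'
#' Resolves a named taxon set to the ape node id of its MRCA. This makes
#' graphically identified calibration nodes reproducible: a node is defined
#' by the set of tips whose MRCA it is.
#'
#' @param tree Rooted `phylo`.
#' @param tips Character vector of >= 2 tip labels.
#' @return Integer ape node id.
#' @examples
#' tr <- parse_newick("((A,B),C);")
#' mrca_node(tr, c("A", "C"))  # the root
#' @export
mrca_node <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"), length(tips) >= 2)
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing)) {
    stop("tip label(s) not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  ape::getMRCA(tree, tips)
}

#' Read node-defining taxon sets from a TSV file
#'
#' Format: two tab-separated columns `node` and comma-separated tip labels,
#' e.g. `node_X<TAB>tipA,tipB`. A header line is optional.
#'
#' @param path TSV path.
#' @return Named list of character vectors (node name -> tip labels).
#' @export
read_node_specs <- function(path) {
  if (!file.exists(path)) stop("node spec file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^node\\t", lines[1])) lines <- lines[-1]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad)) stop("malformed node spec line ", bad[1], ": ", lines[bad[1]])
  out <- lapply(fields, function(f) trimws(strsplit(f[2], ",", fixed = TRUE)[[1]]))
  names(out) <- vapply(fields, `[[`, "", 1L)
  out
}

#' Write node-defining taxon sets to a TSV file
#' @param specs Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_node_specs <- function(specs, path) {
  lines <- c("node\ttips",
             vapply(names(specs), function(nm) {
               paste0(nm, "\t", paste(specs[[nm]], collapse = ","))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
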