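#' Find paired LTR candidates by self-comparison of a contig
#'
#' Long terminal repeats are the key feature defining ERV boundaries: a
#' freshly integrated provirus carries two identical direct repeats. This
#' function finds same-strand repeat pairs by exact k-mer seeding (k = 12),
#' clustering seed matches by diagonal, and refining each cluster with a
#' local pairwise alignment of the two candidate windows. All coordinates
#' are 0-based, half-open.
#'
#' @param contig Nucleotide string (or a list as returned by
#'   [simulate_erv_contig()]).
#' @param min_len Minimum repeat length (nt).
#' @param min_identity Minimum percent identity of the two copies.
#' @param max_gap Maximum separation between the end of the 5' copy and the
#'   start of the 3' copy (nt).
#' @param k Seed length.
#' @return Data frame (possibly 0 rows) with columns `start5`, `end5`,
#'   `start3`, `end3` (0-based half-open), `identity` (percent),
#'   `aln_length`; sorted by identity then span, both decreasing.
#' @export
find_ltr_pairs <- function(contig, min_len = 200L, min_identity = 80,
                           max_gap = 25000L, k = 12L) {
  if (is.list(contig)) contig <- contig$contig
  seq <- toupper(as.character(contig))
  L <- nchar(seq)
  empty <- data.frame(start5 = integer(0), end5 = integer(0),
                      start3 = integer(0), end3 = integer(0),
                      identity = numeric(0), aln_length = integer(0))
  if (L < 2 * min_len) return(empty)
  ## exact k-mer seeds (1-based positions)
  starts <- seq_len(L - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  pos_by_kmer <- split(starts[ok], kmers[ok])
  pos_by_kmer <- pos_by_kmer[lengths(pos_by_kmer) >= 2L &
                               lengths(pos_by_kmer) <= 20L]  # skip low-complexity
  if (!length(pos_by_kmer)) return(empty)
  mi <- integer(0); mj <- integer(0)
  for (p in pos_by_kmer) {
    cmb <- utils::combn(p, 2L)
    mi <- c(mi, cmb[1L, ]); mj <- c(mj, cmb[2L, ])
  }
  d <- mj - mi
  keep <- d >= max(50L, min_len %/% 2L) & d <= max_gap + L  # coarse; refined later
  mi <- mi[keep]; mj <- mj[keep]; d <- d[keep]
  if (!length(mi)) return(empty)
  ## cluster seed matches by diagonal (band +-20), then by position continuity
  ord <- order(d, mi)
  mi <- mi[ord]; mj <- mj[ord]; d <- d[ord]
  grp <- cumsum(c(1L, diff(d) > 20L))
  out <- list()
  for (g in unique(grp)) {
    sel <- grp == g
    gi <- mi[sel]; gj <- mj[sel]
    ## split on large positional gaps along the diagonal
    o2 <- order(gi)
    gi <- gi[o2]; gj <- gj[o2]
    sub <- cumsum(c(1L, diff(gi) > 500L))
    for (s in unique(sub)) {
      si <- gi[sub == s]; sj <- gj[sub == s]
      span <- max(si) + k - 1L - min(si) + 1L
      if (span < min_len / 2) next
      out[[length(out) + 1L]] <- c(min(si), max(si) + k - 1L, min(sj), max(sj) + k - 1L)
    }
  }
  if (!length(out)) return(empty)
  margin <- 60L
  rows <- list()
  for (cand in out) {
    a1 <- max(1L, cand[1] - margin)
    a2 <- min(cand[2] + margin, cand[3] - 1L)
    b1 <- max(cand[3] - margin, cand[2] + 1L)
    b2 <- min(L, cand[4] + margin)
    if (a2 - a1 + 1L < min_len || b2 - b1 + 1L < min_len) next
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(substr(seq, a1, a2)),
      Biostrings::DNAString(substr(seq, b1, b2)),
      type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3, baseOnly = FALSE),
      gapOpening = 5, gapExtension = 2)
    p1 <- aln@pattern@range
    p2 <- aln@subject@range
    s5 <- a1 + BiocGenerics::start(p1) - 1L
    e5 <- a1 + BiocGenerics::end(p1) - 1L
    s3 <- b1 + BiocGenerics::start(p2) - 1L
    e3 <- b1 + BiocGenerics::end(p2) - 1L
    ## refine boundaries: chance homology (e.g. a TSD-like motif inside the
    ## element) lets a local alignment creep a few nt past the true repeat
    ## ends, which would defeat downstream TSD detection. Trim the alignment
    ## to its maximal-scoring core under a strict column scoring (creep
    ## segments are net-negative there), then grow the ends back outward
    ## through matching genomic columns, jumping isolated mismatches only
    ## when backed by further exact matches.
    pa <- strsplit(as.character(aln@pattern), "", fixed = TRUE)[[1]]
    su <- strsplit(as.character(aln@subject), "", fixed = TRUE)[[1]]
    eq <- pa == su & pa != "-"
    colscore <- ifelse(eq, 1, ifelse(pa == "-" | su == "-", -7, -3))
    best <- 0; cur <- 0; i0 <- 1L; j0 <- 0L; istart <- 1L
    for (ii in seq_along(colscore)) {
      cur <- cur + colscore[ii]
      if (cur <= 0) { cur <- 0; istart <- ii + 1L }
      else if (cur > best) { best <- cur; i0 <- istart; j0 <- ii }
    }
    if (j0 < i0) next
    s5 <- s5 + sum(pa[seq_len(i0 - 1L)] != "-")
    s3 <- s3 + sum(su[seq_len(i0 - 1L)] != "-")
    if (j0 < length(eq)) {
      e5 <- e5 - sum(pa[(j0 + 1L):length(eq)] != "-")
      e3 <- e3 - sum(su[(j0 + 1L):length(eq)] != "-")
    }
    chr <- function(i) substr(seq, i, i)
    match_at <- function(i, j) chr(i) == chr(j) && chr(i) != "N"
    lookahead <- 4L
    repeat {  # leftward
      if (s5 <= 1L || s3 <= e5 + 1L) break
      if (match_at(s5 - 1L, s3 - 1L)) { s5 <- s5 - 1L; s3 <- s3 - 1L; next }
      ## isolated mismatch: step through only if the next columns all match
      back <- seq_len(lookahead)
      if (s5 - 1L - lookahead >= 1L && s3 - 1L - lookahead > e5 &&
            all(vapply(back, function(o) match_at(s5 - 1L - o, s3 - 1L - o),
                       logical(1)))) {
        s5 <- s5 - 1L; s3 <- s3 - 1L; next
      }
      break
    }
    repeat {  # rightward
      if (e3 >= L || e5 >= s3 - 1L) break
      if (match_at(e5 + 1L, e3 + 1L)) { e5 <- e5 + 1L; e3 <- e3 + 1L; next }
      fwd <- seq_len(lookahead)
      if (e3 + 1L + lookahead <= L && e5 + 1L + lookahead < s3 &&
            all(vapply(fwd, function(o) match_at(e5 + 1L + o, e3 + 1L + o),
                       logical(1)))) {
        e5 <- e5 + 1L; e3 <- e3 + 1L; next
      }
      break
    }
    core <- eq[i0:j0]
    alen <- j0 - i0 + 1L
    ident <- 100 * sum(core) / alen
    if (alen < min_len || ident < min_identity) next
    if (s3 <= e5) next                       # overlapping copies
    if (s3 - 1L - e5 > max_gap) next         # separation
    rows[[length(rows) + 1L]] <- data.frame(
      start5 = s5 - 1L, end5 = e5, start3 = s3 - 1L, end3 = e3,
      identity = ident, aln_length = alen)
  }
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  ## dedupe near-identical candidates (same repeat found from several clusters)
  res <- res[order(-res$identity, -(res$end3 - res$start5)), , drop = FALSE]
  kept <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!kept[i]) next
    for (j in seq_len(nrow(res))) {
      if (j <= i || !kept[j]) next
      ov5 <- min(res$end5[i], res$end5[j]) - max(res$start5[i], res$start5[j])
      ov3 <- min(res$end3[i], res$end3[j]) - max(res$start3[i], res$start3[j])
      if (ov5 > 0 && ov3 > 0) kept[j] <- FALSE
    }
  }
  res <- res[kept, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Find the target-site duplication flanking an LTR pair
#'
#' Upon integration the host target site is duplicated, leaving a short
#' identical motif immediately 5' of the 5' LTR and immediately 3' of the
#' 3' LTR. Searches for the longest exact match of length within
#' `len_range` between the two boundary windows, allowing a boundary slack
#' of +-`slack` nt (LTR edge inference is approximate).
#'
#' @param contig Nucleotide string (or [simulate_erv_contig()] output).
#' @param pair One row of [find_ltr_pairs()] output (or a list/vector with
#'   `start5` and `end3`, 0-based half-open).
#' @param len_range Motif length range searched, longest first.
#' @param slack Boundary slack in nt.
#' @return Object of class `tsd_call` (list with `motif`, `left`, `right`
#'   0-based half-open intervals), or `NULL` when no motif of at least the
#'   minimum length matches.
#' @export
find_tsd <- function(contig, pair, len_range = c(4L, 6L), slack = 2L) {
  if (is.list(contig) && !is.null(contig$contig)) contig <- contig$contig
  seq <- toupper(as.character(contig))
  L <- nchar(seq)
  b5 <- as.integer(pair[["start5"]])  # 0-based start of 5' LTR
  e3 <- as.integer(pair[["end3"]])    # 0-based end (exclusive) of 3' LTR
  lmin <- as.integer(len_range[1]); lmax <- as.integer(len_range[2])
  if (b5 < 6L || L - e3 < 6L) stop("insufficient flank around the element (need >= 6 nt)")
  shifts <- order(abs(seq(-slack, slack)))  # 0, -1, 1, -2, 2 preference
  shift_vals <- seq(-slack, slack)[shifts]
  for (len in seq(lmax, lmin)) {
    for (dl in shift_vals) {
      for (dr in shift_vals) {
        ls <- b5 + dl - len   # 0-based start of left motif
        rs <- e3 + dr         # 0-based start of right motif
        if (ls < 0L || rs + len > L) next
        left <- substr(seq, ls + 1L, ls + len)
        right <- substr(seq, rs + 1L, rs + len)
        if (left == right && !grepl("N", left, fixed = TRUE)) {
          return(structure(list(motif = left,
                                left = c(ls, ls + len),
                                right = c(rs, rs + len)),
                           class = "tsd_call"))
        }
      }
    }
  }
  NULL
}

#' @export
print.tsd_call <- function(x, ...) {
  cat(sprintf("TSD '%s': left [%d,%d), right [%d,%d) (0-based half-open)\n",
              x$motif, x$left[1], x$left[2], x$right[1], x$right[2]))
  invisible(x)
}

#' Annotate a contig: LTR pairs and their TSDs
#'
#' @inheritParams find_ltr_pairs
#' @param tsd_len_range Passed to [find_tsd()].
#' @return List with `ltr_pairs` (data frame) and `tsds` (list, one entry —
#'   possibly `NULL` — per pair).
#' @export
annotate_contig <- function(contig, min_len = 200L, min_identity = 80,
                            max_gap = 25000L, tsd_len_range = c(4L, 6L)) {
  if (is.list(contig) && !is.null(contig$contig)) contig <- contig$contig
  pairs <- find_ltr_pairs(contig, min_len = min_len,
                          min_identity = min_identity, max_gap = max_gap)
  tsds <- lapply(seq_len(nrow(pairs)), function(i) {
    tryCatch(find_tsd(contig, pairs[i, ], len_range = tsd_len_range),
             error = function(e) NULL)
  })
  list(ltr_pairs = pairs, tsds = tsds)
}

#' Write LTR/TSD annotations as BED-like TSV
#'
#' Columns: `contig start end name identity strand` (0-based half-open).
#'
#' @param annotation Output of [annotate_contig()].
#' @param contig_id Contig name for column 1.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(annotation, contig_id, path) {
  rows <- character(0)
  pr <- annotation$ltr_pairs
  for (i in seq_len(nrow(pr))) {
    rows <- c(rows,
              sprintf("%s\t%d\t%d\tLTR5_pair%d\t%.2f\t+", contig_id,
                      pr$start5[i], pr$end5[i], i, pr$identity[i]),
              sprintf("%s\t%d\t%d\tLTR3_pair%d\t%.2f\t+", contig_id,
                      pr$start3[i], pr$end3[i], i, pr$identity[i]))
    tsd <- annotation$tsds[[i]]
    if (!is.null(tsd)) {
      rows <- c(rows,
                sprintf("%s\t%d\t%d\tTSD_left_pair%d\t.\t+", contig_id,
                        tsd$left[1], tsd$left[2], i),
                sprintf("%s\t%d\t%d\tTSD_right_pair%d\t.\t+", contig_id,
                        tsd$right[1], tsd$right[2], i))
    }
  }
  writeLines(c("#contig\tstart\tend\tname\tidentity\tstrand", rows), path)
  invisible(path)
}

#' Write element annotations as GFF3
#'
#' @inheritParams write_annotation_bed
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, contig_id, path) {
  lines <- "##gff-version 3"
  pr <- annotation$ltr_pairs
  for (i in seq_len(nrow(pr))) {
    ## GFF3 is 1-based inclusive
    el_start <- pr$start5[i] + 1L
    el_end <- pr$end3[i]
    lines <- c(lines,
      sprintf("%s\tretroclock\tmobile_genetic_element\t%d\t%d\t%.2f\t+\t.\tID=erv%d",
              contig_id, el_start, el_end, pr$identity[i], i),
      sprintf("%s\tretroclock\tlong_terminal_repeat\t%d\t%d\t%.2f\t+\t.\tID=erv%d_ltr5;Parent=erv%d",
              contig_id, pr$start5[i] + 1L, pr$end5[i], pr$identity[i], i, i),
      sprintf("%s\tretroclock\tlong_terminal_repeat\t%d\t%d\t%.2f\t+\t.\tID=erv%d_ltr3;Parent=erv%d",
              contig_id, pr$start3[i] + 1L, pr$end3[i], pr$identity[i], i, i))
    tsd <- annotation$tsds[[i]]
    if (!is.null(tsd)) {
      lines <- c(lines,
        sprintf("%s\tretroclock\ttarget_site_duplication\t%d\t%d\t.\t+\t.\tID=erv%d_tsd_left;Parent=erv%d",
                contig_id, tsd$left[1] + 1L, tsd$left[2], i, i),
        sprintf("%s\tretroclock\ttarget_site_duplication\t%d\t%d\t.\t+\t.\tID=erv%d_tsd_right;Parent=erv%d",
                contig_id, tsd$right[1] + 1L, tsd$right[2], i, i))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
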