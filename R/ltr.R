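#' Tamura-Nei (TN93) pairwise distance between two aligned sequences
#'
#' Estimates the number of nucleotide substitutions per site between two
#' aligned sequences under the TN93 model, which distinguishes the two
#' transition classes (A<->G and C<->T) and allows unequal base frequencies.
#' Columns containing a gap or ambiguity in either sequence are excluded
#' (pairwise complete deletion); base frequencies are the empirical
#' frequencies averaged over both sequences on the usable columns.
#'
#' With `piR = piA + piG`, `piY = piC + piT`, transition proportions `P1`
#' (A<->G), `P2` (C<->T) and transversion proportion `Q`:
#' \deqn{d = \frac{2\pi_A\pi_G}{\pi_R} a_1 + \frac{2\pi_T\pi_C}{\pi_Y} a_2 +
#'       2\left(\pi_R\pi_Y - \frac{\pi_A\pi_G\pi_Y}{\pi_R} -
#'       \frac{\pi_T\pi_C\pi_R}{\pi_Y}\right) b}
#' where `a1 = -log(1 - piR*P1/(2 piA piG) - Q/(2 piR))`,
#' `a2 = -log(1 - piY*P2/(2 piT piC) - Q/(2 piY))` and
#' `b = -log(1 - Q/(2 piR piY))`.
#'
#' Degenerate compositions (a base class absent altogether, as in tiny toy
#' inputs) drop the corresponding vanished terms rather than failing; with
#' averaged frequencies an observed transition always implies positive
#' frequencies for both of its bases, so no information is discarded.
#'
#' @param seq1,seq2 Equal-length nucleotide strings (characters other than
#'   A/C/G/T, case-insensitive, are treated as missing), or a length-2
#'   `DNAStringSet`/character vector in `seq1`.
#' @return Object of class `tn93`: list with `d` (substitutions/site), `P1`,
#'   `P2`, `Q` (proportions over usable sites), `pi` (named frequency
#'   vector), and `L` (usable sites).
#' @examples
#' a <- paste(rep("ACGT", 10), collapse = "")
#' tn93_distance(a, a)$d  # 0
#' @export
tn93_distance <- function(seq1, seq2 = NULL) {
  if (is.null(seq2)) {
    if (length(seq1) != 2) stop("need exactly two sequences")
    seq2 <- seq1[[2]]; seq1 <- seq1[[1]]
  }
  s1 <- strsplit(toupper(as.character(seq1)), "", fixed = TRUE)[[1]]
  s2 <- strsplit(toupper(as.character(seq2)), "", fixed = TRUE)[[1]]
  if (length(s1) != length(s2)) stop("sequences must be aligned (equal length)")
  bases <- c("A", "C", "G", "T")
  use <- s1 %in% bases & s2 %in% bases
  L <- sum(use)
  if (L < 1) stop("no usable (gap-free, unambiguous) columns")
  s1 <- s1[use]; s2 <- s2[use]
  pi <- (c(table(factor(s1, bases))) + c(table(factor(s2, bases)))) / (2 * L)
  piA <- pi[["A"]]; piC <- pi[["C"]]; piG <- pi[["G"]]; piT <- pi[["T"]]
  diff <- s1 != s2
  is_ag <- diff & ((s1 == "A" & s2 == "G") | (s1 == "G" & s2 == "A"))
  is_ct <- diff & ((s1 == "C" & s2 == "T") | (s1 == "T" & s2 == "C"))
  P1 <- sum(is_ag) / L
  P2 <- sum(is_ct) / L
  Q <- sum(diff & !is_ag & !is_ct) / L
  ## degenerate compositions: with averaged frequencies an observed
  ## transition forces both of its base frequencies positive, so a vanished
  ## class always has zero observed count; its terms (coefficient and log)
  ## are elided below instead of producing 0 * log(0/0)
  piR <- piA + piG; piY <- piC + piT
  slog <- function(arg) {
    if (arg <= 0) stop("TN93 saturation: distance undefined (log of non-positive value)",
                       call. = FALSE)
    -log(arg)
  }
  a1 <- if (piA * piG > 0) slog(1 - piR * P1 / (2 * piA * piG) - Q / (2 * piR)) else 0
  a2 <- if (piT * piC > 0) slog(1 - piY * P2 / (2 * piT * piC) - Q / (2 * piY)) else 0
  b <- if (piR * piY > 0) {
    slog(1 - Q / (2 * piR * piY))
  } else {
    if (Q > 0) stop("TN93 saturation: distance undefined (single-class composition with transversions)",
                    call. = FALSE)
    0
  }
  c1 <- if (piR > 0) 2 * piA * piG / piR else 0
  c2 <- if (piY > 0) 2 * piT * piC / piY else 0
  cb <- 2 * (piR * piY -
               (if (piR > 0) piA * piG * piY / piR else 0) -
               (if (piY > 0) piT * piC * piR / piY else 0))
  d <- c1 * a1 + c2 * a2 + cb * b
  structure(list(d = d, P1 = P1, P2 = P2, Q = Q, pi = pi, L = L),
            class = "tn93")
}

#' @export
print.tn93 <- function(x, ...) {
  cat(sprintf("TN93 distance: d = %.6g subs/site (L = %d usable sites)\n", x$d, x$L))
  cat(sprintf("  P1 (A<->G) = %.4g  P2 (C<->T) = %.4g  Q (transversions) = %.4g\n",
              x$P1, x$P2, x$Q))
  cat("  base frequencies:", paste(sprintf("%s=%.3f", names(x$pi), x$pi), collapse = " "), "\n")
  invisible(x)
}

#' Date a retroviral integration from paired-LTR divergence
#'
#' At integration the two LTRs of a provirus are identical; they then diverge
#' independently at (approximately) the neutral rate of the host genome.
#' The age is therefore the per-lineage divergence `d/2` divided by the
#' neutral rate: `age_Myr = (d/2) / rate / 1e6`.
#'
#' @param d Pairwise distance between the paired LTRs (substitutions/site).
#' @param rate Neutral host rate(s), substitutions/site/year; a vector gives
#'   the age at each rate (e.g. the two bounds of a published rate range).
#' @return Object of class `ltr_age`: list with `d`, `per_lineage` (= d/2),
#'   `rate`, and `age_myr` (same length as `rate`).
#' @examples
#' ltr_age(0.044, c(0.924e-9, 1.53e-9))$age_myr
#' @export
ltr_age <- function(d, rate) {
  if (!is.finite(d) || d < 0) stop("d must be finite and >= 0")
  rate <- as.numeric(rate)
  if (any(!is.finite(rate)) || any(rate <= 0)) stop("rate must be > 0")
  structure(list(d = d, per_lineage = d / 2, rate = rate,
                 age_myr = (d / 2) / rate / 1e6),
            class = "ltr_age")
}

#' @export
print.ltr_age <- function(x, ...) {
  cat(sprintf("LTR integration age: d = %.4g, per-lineage divergence = %.4g\n",
              x$d, x$per_lineage))
  for (i in seq_along(x$rate)) {
    cat(sprintf("  rate %.3g subs/site/yr -> %.3g Myr\n", x$rate[i], x$age_myr[i]))
  }
  invisible(x)
}

#' Read an aligned LTR pair from FASTA
#'
#' @param path FASTA containing exactly two aligned (equal-length) sequences.
#' @return A `DNAStringSet` of length 2.
#' @export
read_aligned_pair <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 2) stop("expected exactly 2 sequences, got ", length(x))
  if (length(unique(Biostrings::width(x))) != 1) {
    stop("sequences are not aligned (unequal lengths)")
  }
  x
}
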