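# Sequence-derived protein features: length, amino-acid composition,
# Kyte-Doolittle hydrophobicity (GRAVY), aliphatic index, Eisenberg
# hydrophobic moment, and charge/pI by Henderson-Hasselbalch with the
# EMBOSS pKa set.

KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

EISENBERG <- c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
               Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
               L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
               S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08)

# EMBOSS pKa values
PKA_EMBOSS <- list(nterm = 8.6, cterm = 3.6,
                   pos = c(K = 10.8, R = 12.5, H = 6.5),
                   neg = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

AA_GROUPS <- list(
  aliphatic = c("A", "I", "L", "V"),
  aromatic = c("F", "W", "Y"),
  positive = c("K", "R", "H"),
  negative = c("D", "E"),
  polar_uncharged = c("S", "T", "N", "Q", "C"),
  tiny = c("A", "G", "S"))

aa_counts <- function(seq, warn = TRUE) {
  aa <- strsplit(toupper(seq), "")[[1]]
  std <- aa %in% names(KD_SCALE)
  if (warn && any(!std)) {
    warning(sum(!std), " non-standard residue(s) excluded from composition")
  }
  table(factor(aa[std], levels = names(KD_SCALE)))
}

charge_from_counts <- function(cnt, pH) {
  pos <- sum(vapply(names(PKA_EMBOSS$pos), function(a)
    cnt[[a]] / (1 + 10^(pH - PKA_EMBOSS$pos[[a]])), numeric(1))) +
    1 / (1 + 10^(pH - PKA_EMBOSS$nterm))
  neg <- sum(vapply(names(PKA_EMBOSS$neg), function(a)
    cnt[[a]] / (1 + 10^(PKA_EMBOSS$neg[[a]] - pH)), numeric(1))) +
    1 / (1 + 10^(PKA_EMBOSS$cterm - pH))
  pos - neg
}

pi_from_counts <- function(cnt) {
  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (charge_from_counts(cnt, mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-4) break
  }
  (lo + hi) / 2
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over ionisable side chains and termini with
#' the EMBOSS pKa set.
#'
#' @param seq amino-acid sequence (single string).
#' @param pH pH value (default 7.5).
#' @return net charge (elementary charges).
#' @export
protein_charge <- function(seq, pH = 7.5) {
  charge_from_counts(aa_counts(seq), pH)
}

#' Isoelectric point by bisection
#'
#' Finds the pH at which [protein_charge()] is zero (bisection on
#' [0, 14], tolerance 1e-4).
#'
#' @param seq amino-acid sequence.
#' @return pI estimate.
#' @export
protein_pi <- function(seq) {
  pi_from_counts(aa_counts(seq))
}

#' Sequence-derived protein feature vector
#'
#' Length, percentage of each standard amino acid and of residue groups
#' (aliphatic, aromatic, positive, negative, polar uncharged, tiny), GRAVY
#' hydrophobicity (Kyte-Doolittle mean), aliphatic index, maximal
#' Eisenberg hydrophobic moment (window 11, helix angle 100 degrees), net
#' charge at pH 7.5, and pI.  Non-standard residues are excluded from
#' composition with a warning.
#'
#' @param seq amino-acid sequence (single string).
#' @return named numeric vector.
#' @export
sequence_features <- function(seq) {
  cnt <- aa_counts(seq)
  n <- sum(cnt)
  if (n == 0) stop("no standard residues in sequence")
  pct <- 100 * as.numeric(cnt) / n
  names(pct) <- paste0("pct_", names(cnt))
  grp <- vapply(AA_GROUPS, function(g) 100 * sum(cnt[g]) / n, numeric(1))
  names(grp) <- paste0("pct_", names(grp))
  gravy <- sum(KD_SCALE[names(cnt)] * as.numeric(cnt)) / n
  # aliphatic index (mole-percent form)
  ai <- (100 * cnt[["A"]] + 2.9 * 100 * cnt[["V"]] +
         3.9 * 100 * (cnt[["I"]] + cnt[["L"]])) / n
  c(length = n, pct, grp, gravy = gravy, aliphatic_index = as.numeric(ai),
    hydrophobic_moment = hydrophobic_moment(seq),
    charge_ph7.5 = charge_from_counts(cnt, 7.5), pi = pi_from_counts(cnt))
}

#' Maximal hydrophobic moment
#'
#' Eisenberg hydrophobic moment `uH = |sum h_i exp(i n delta)| / w` over
#' sliding windows, maximised; `delta` defaults to the 100-degree
#' alpha-helix turn.
#'
#' @param seq amino-acid sequence.
#' @param window window length (default 11; shorter sequences use their
#'   full length).
#' @param angle turn angle in degrees.
#' @return maximal window hydrophobic moment.
#' @export
hydrophobic_moment <- function(seq, window = 11L, angle = 100) {
  aa <- strsplit(toupper(seq), "")[[1]]
  aa <- aa[aa %in% names(EISENBERG)]
  h <- EISENBERG[aa]
  w <- min(window, length(h))
  if (w < 1L) stop("no standard residues")
  th <- (seq_len(w) - 1) * angle * pi / 180
  best <- 0
  for (i in seq_len(length(h) - w + 1L)) {
    hw <- h[i:(i + w - 1L)]
    mu <- sqrt(sum(hw * sin(th))^2 + sum(hw * cos(th))^2) / w
    if (mu > best) best <- mu
  }
  best
}

#' Read protein sequences from a FASTA file
#'
#' Minimal single-pass FASTA reader returning a named character vector of
#' sequences (names = first token of the header).
#'
#' @param path FASTA file path.
#' @return named character vector.
#' @export
read_protein_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  ids <- sub("^>(\\S+).*", "\\1", lines[hdr])
  idx <- cumsum(hdr)
  seqs <- vapply(seq_along(ids), function(i)
    paste(lines[!hdr & idx == i], collapse = ""), character(1))
  stats::setNames(toupper(gsub("\\s", "", seqs)), ids)
}
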