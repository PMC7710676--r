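# Position-specific scoring-matrix scanning of wild-type vs mutant enhancer
# sequences.
#
# Motifs are read from MEME minimal format (letter-probability matrices) and
# converted to log2-odds against the stated background with pseudocount
# 1e-4.  A sequence is scored at every offset on both strands; the motif's
# best score on the wild-type minus its best score on the mutant sequence is
# the binding delta (positive = the mutation weakens the best site).

BASES <- c("A", "C", "G", "T")

#' Construct a PSSM
#'
#' @param motif_id motif name.
#' @param weights L x 4 numeric matrix of per-position per-base scores
#'   (log-odds scale), columns A, C, G, T.
#' @param background base frequencies (length 4, strictly positive, sum 1).
#' @return object of class `pssm`.
#' @export
pssm <- function(motif_id, weights, background = rep(0.25, 4)) {
  weights <- as.matrix(weights)
  stopifnot(ncol(weights) == 4, nrow(weights) >= 1,
            length(background) == 4, all(background > 0))
  background <- background / sum(background)
  colnames(weights) <- BASES
  structure(list(motif_id = motif_id, weights = weights,
                 background = background), class = "pssm")
}

#' Read motifs from a MEME minimal file
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections and the
#' optional `Background letter frequencies` line, converting probabilities to
#' log2-odds against the background with pseudocount `pseudo`.
#'
#' @param path path to the MEME minimal text file.
#' @param pseudo pseudocount added to letter probabilities (default 1e-4).
#' @return named list of [pssm()] objects.
#' @export
read_meme <- function(path, pseudo = 1e-4) {
  if (!file.exists(path)) enh_config_error(paste("no such motif file:", path))
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    tok <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    vals <- as.numeric(tok[seq(2, length(tok), by = 2)])
    names(vals) <- tok[seq(1, length(tok), by = 2)]
    bg <- unname(vals[BASES])
  }
  starts <- grep("^MOTIF", lines)
  if (!length(starts)) enh_data_error("no MOTIF blocks in MEME file")
  out <- list()
  for (s in starts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines[s:length(lines)])[1] + s - 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    probs <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    if (ncol(probs) != 4) enh_data_error("motif matrix must have 4 columns")
    probs <- (probs + pseudo) / (1 + 4 * pseudo)
    lo <- log2(sweep(probs, 2, bg, "/"))
    out[[id]] <- pssm(id, lo, bg)
  }
  out
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(seq)), "")[[1]]),
        collapse = "")
}

seq_to_idx <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], c(BASES, "N"))
}

scan_one_strand <- function(idx, W, background) {
  L <- nrow(W)
  n <- length(idx)
  # N (index 5) contributes the background-expected score at that position
  Wn <- cbind(W, drop(W %*% background))
  n_off <- n - L + 1
  scores <- vapply(seq_len(n_off), function(o) {
    sum(Wn[cbind(seq_len(L), idx[o:(o + L - 1)])])
  }, 0)
  scores
}

#' Best PSSM score over all offsets and both strands
#'
#' @param sequence character string over `{A,C,G,T,N}` at least as long as
#'   the motif.
#' @param pssm a [pssm()] object.
#' @return list `score`, `offset` (1-based window start on the given
#'   sequence), `strand` (`"+"`/`"-"`).  Ties resolve to the leftmost
#'   offset, forward strand first.
#' @export
pssm_best_score <- function(sequence, pssm) {
  idx <- seq_to_idx(sequence)
  if (any(is.na(idx)))
    enh_data_error("sequence contains characters outside {A,C,G,T,N}")
  L <- nrow(pssm$weights)
  if (length(idx) < L)
    enh_data_error("sequence shorter than motif")
  fwd <- scan_one_strand(idx, pssm$weights, pssm$background)
  idx_rc <- seq_to_idx(revcomp(sequence))
  rev_ <- scan_one_strand(idx_rc, pssm$weights, pssm$background)
  # map reverse-strand offsets back to the forward coordinate of the window
  n_off <- length(fwd)
  best_f <- which.max(fwd)
  best_r <- which.max(rev_)
  if (max(rev_) > max(fwd) + 1e-12) {
    list(score = rev_[best_r], offset = n_off - best_r + 1L, strand = "-")
  } else {
    list(score = fwd[best_f], offset = best_f, strand = "+")
  }
}

#' Change in predicted TF binding between wild-type and mutant sequence
#'
#' @param seq_wt,seq_mut equal-length windows centred on the variant.
#' @param pssm a [pssm()] object (or a list of them).
#' @return data.frame with `motif_id`, `best_score_wt`, `best_score_mut`,
#'   `delta` (= wt - mut; positive means the mutation weakens the best
#'   site), offsets and strands.
#' @export
binding_delta <- function(seq_wt, seq_mut, pssm) {
  motifs <- if (inherits(pssm, "pssm")) list(pssm) else pssm
  rows <- lapply(motifs, function(m) {
    wt <- pssm_best_score(seq_wt, m)
    mu <- pssm_best_score(seq_mut, m)
    data.frame(motif_id = m$motif_id,
               best_score_wt = wt$score, best_score_mut = mu$score,
               delta = wt$score - mu$score,
               best_offset_wt = wt$offset, best_offset_mut = mu$offset,
               strand_wt = wt$strand, strand_mut = mu$strand,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
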