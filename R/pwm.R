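#' Position weight matrix (PWM) objects
#'
#' A PWM stores, for each position of a fixed-width binding site, the
#' probability of observing each base (columns A, C, G, T). Sites are scored
#' by their log-likelihood ratio (LLR) against a background nucleotide
#' distribution; the highest-scoring word defines `llr_max`, the score of the
#' TF's optimal site.
#'
#' @param name motif name.
#' @param probs numeric matrix, width x 4, rows summing to 1 (columns in
#'   A, C, G, T order). When built from counts use [pwm_from_counts()].
#' @param background length-4 background base probability vector (A, C, G, T);
#'   defaults to uniform.
#' @param pseudocount pseudocount recorded for provenance (0 for probability
#'   input).
#' @return An object of class `"pwm"`.
#' @export
pwm <- function(name, probs, background = rep(0.25, 4), pseudocount = 0) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("PWM '", name, "': probs must have 4 columns (A,C,G,T)")
  if (any(probs <= 0)) stop("PWM '", name, "': all probabilities must be > 0 (use a pseudocount)")
  if (any(abs(rowSums(probs) - 1) > 1e-9))
    stop("PWM '", name, "': rows must sum to 1")
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0) || abs(sum(background) - 1) > 1e-9)
    stop("PWM '", name, "': background must be 4 positive probabilities summing to 1")
  dimnames(probs) <- list(NULL, c("A", "C", "G", "T"))
  structure(
    list(name = name, width = nrow(probs), probs = probs,
         background = background, pseudocount = pseudocount),
    class = "pwm")
}

#' @param counts width x 4 count matrix.
#' @rdname pwm
#' @export
pwm_from_counts <- function(name, counts, background = rep(0.25, 4), pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("PWM '", name, "': negative counts")
  if (any(rowSums(counts) == 0)) stop("PWM '", name, "': row of all zeros")
  p <- counts + pseudocount
  pwm(name, p / rowSums(p), background, pseudocount)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (width %d, llr_max %.3f)\n", x$name, x$width, llr_max(x)))
  print(round(x$probs, 3))
  invisible(x)
}

# per-position log(p/bg) matrix used by all scorers
llr_matrix <- function(pwm) {
  sweep(log(pwm$probs), 2, log(pwm$background), "-")
}

#' Maximal LLR score of a PWM
#'
#' The LLR of the optimal word `S_max`: the sum over positions of the best
#' per-position log-ratio.
#'
#' @param pwm a [pwm()] object.
#' @return numeric scalar (natural-log units).
#' @export
llr_max <- function(pwm) {
  sum(apply(llr_matrix(pwm), 1, max))
}

#' Consensus (optimal) word of a PWM
#' @param pwm a [pwm()] object.
#' @return character string of length `pwm$width`.
#' @export
consensus_word <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(llr_matrix(pwm), 1, which.max)], collapse = "")
}

BASES <- c("A", "C", "G", "T")

revcomp <- function(word) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(word, "")[[1]]), collapse = ""))
}

# PWM recognizing the reverse complement strand: rows reversed, A<->T, C<->G.
revcomp_pwm <- function(pwm) {
  p <- pwm$probs[pwm$width:1, c(4, 3, 2, 1), drop = FALSE]
  colnames(p) <- BASES
  bg <- pwm$background[c(4, 3, 2, 1)]
  out <- pwm
  out$probs <- p
  out$background <- bg
  out
}

#' LLR score of one word
#'
#' Scores a fixed word against a PWM: `sum_i log(P_i(word_i) / bg(word_i))`.
#' On the minus strand the reverse complement of the word is scored.
#'
#' @param pwm a [pwm()] object.
#' @param word DNA string over A, C, G, T with `nchar(word) == pwm$width`.
#' @param strand `"+"` or `"-"`.
#' @return numeric LLR (natural-log units).
#' @export
llr_score <- function(pwm, word, strand = "+") {
  if (nchar(word) != pwm$width)
    stop("word length ", nchar(word), " != PWM width ", pwm$width)
  if (strand == "-") word <- revcomp(word)
  idx <- match(strsplit(toupper(word), "")[[1]], BASES)
  if (anyNA(idx)) stop("word contains non-ACGT characters: ", word)
  m <- llr_matrix(pwm)
  sum(m[cbind(seq_len(pwm$width), idx)])
}

#' Annotate binding sites on a sequence
#'
#' Scans every window of a sequence, on both strands, with each PWM and
#' returns the windows whose LLR exceeds `threshold_frac * llr_max` (strict
#' inequality). At the same start and TF only the better-scoring strand is
#' kept (ties keep `+`). Windows containing ambiguous bases are skipped.
#' Sites of different TFs may overlap.
#'
#' @param seq DNA string.
#' @param pwms a single [pwm()] or list of PWMs.
#' @param threshold_frac site-calling threshold as a fraction of the optimal
#'   site's LLR; default 0.4.
#' @return data.frame of class `"binding_sites"` with columns `tf`, `start`
#'   (0-based), `length`, `strand`, `llr`, `llr_max`, sorted by start then tf.
#' @export
annotate_sites <- function(seq, pwms, threshold_frac = 0.4) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  stopifnot(threshold_frac > 0, threshold_frac <= 1)
  seq <- toupper(seq)
  if (nchar(seq) == 0) stop("empty sequence")
  base_idx <- match(strsplit(seq, "")[[1]], BASES)  # NA for ambiguous bases
  out <- list()
  for (p in pwms) {
    w <- p$width
    n_win <- nchar(seq) - w + 1L
    if (n_win < 1L) next
    lmax <- llr_max(p)
    thr <- threshold_frac * lmax
    fwd <- scan_windows(base_idx, llr_matrix(p), n_win, w)
    rev <- scan_windows(base_idx, llr_matrix(revcomp_pwm(p)), n_win, w)
    strand <- ifelse(rev > fwd, "-", "+")   # tie keeps +
    best <- pmax(fwd, rev)
    keep <- which(!is.na(best) & best > thr)
    if (length(keep))
      out[[length(out) + 1L]] <- data.frame(
        tf = p$name, start = keep - 1L, length = w,
        strand = strand[keep], llr = best[keep], llr_max = lmax,
        stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(tf = character(), start = integer(), length = integer(),
               strand = character(), llr = numeric(), llr_max = numeric(),
               stringsAsFactors = FALSE)
  res <- res[order(res$start, res$tf), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("binding_sites", "data.frame")
  res
}

# Vectorized scoring of all windows; windows touching an NA base score NA.
scan_windows <- function(base_idx, m, n_win, w) {
  score <- numeric(n_win)
  ok <- !is.na(base_idx)
  valid <- rep(TRUE, n_win)
  for (k in seq_len(w)) {
    b <- base_idx[k:(k + n_win - 1L)]
    valid <- valid & ok[k:(k + n_win - 1L)]
    score <- score + ifelse(is.na(b), 0, m[k, ifelse(is.na(b), 1L, b)])
  }
  score[!valid] <- NA_real_
  score
}

#' Randomly permute the positions of a PWM
#'
#' Shuffles the rows (positions) of the probability matrix uniformly at
#' random. Used to build negative-control motifs: column composition per
#' position, width, background and therefore `llr_max` are preserved, but the
#' positional arrangement -- and hence which words score well -- is destroyed.
#'
#' @param pwm a [pwm()] object.
#' @param rng_seed integer seed; the permutation is deterministic given it.
#' @return a new [pwm()] object.
#' @export
permute_pwm <- function(pwm, rng_seed) {
  if (pwm$width < 2L) return(pwm)
  perm <- with_seed(rng_seed, sample.int(pwm$width))
  out <- pwm
  out$probs <- pwm$probs[perm, , drop = FALSE]
  out
}
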