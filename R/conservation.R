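#' Cross-species conservation of annotated sites
#'
#' Given a gapped multiple alignment of orthologous CRM sequences (reference
#' first), annotates sites on the ungapped reference and tests, for each site
#' and each species, whether the aligned window still scores above the same
#' LLR threshold (on either strand). A window is non-conserved in a species
#' if the alignment places a gap (in any sequence) inside it.
#'
#' @param alignment named character vector of aligned sequences (equal
#'   lengths, `-` for gaps); the first entry is the reference.
#' @param pwms list of [pwm()] objects.
#' @param threshold_frac LLR threshold fraction (default 0.4, matching
#'   [annotate_sites()]).
#' @return list: `sites` (reference `binding_sites`), `conserved` (site x
#'   species logical matrix, reference column included and always TRUE).
#' @export
site_conservation <- function(alignment, pwms, threshold_frac = 0.4) {
  if (length(alignment) < 1) stop("alignment lacks a reference sequence")
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  aln <- toupper(alignment)
  if (length(unique(nchar(aln))) != 1) stop("aligned sequences differ in length")
  ref_chars <- strsplit(aln[[1]], "")[[1]]
  cols <- which(ref_chars != "-")           # alignment column of each ref base
  ref_seq <- paste(ref_chars[cols], collapse = "")
  sites <- annotate_sites(ref_seq, pwms, threshold_frac)
  pw <- setNames(pwms, vapply(pwms, `[[`, "", "name"))
  spp <- names(aln) %||% paste0("seq", seq_along(aln))
  cons <- matrix(FALSE, nrow(sites), length(aln), dimnames = list(NULL, spp))
  if (nrow(sites) == 0) return(list(sites = sites, conserved = cons))
  cons[, 1] <- TRUE
  chars <- lapply(aln, function(s) strsplit(s, "")[[1]])
  for (k in seq_len(nrow(sites))) {
    p <- pw[[sites$tf[k]]]
    thr <- threshold_frac * sites$llr_max[k]
    win_cols <- cols[(sites$start[k] + 1):(sites$start[k] + p$width)]
    span <- win_cols[p$width] - win_cols[1] + 1
    if (span != p$width) next               # reference gap inside the window
    for (s in seq_along(aln)[-1]) {
      word <- paste(chars[[s]][win_cols], collapse = "")
      if (grepl("[^ACGT]", word)) next      # gap or ambiguity in the species
      sc <- max(llr_score(p, word, "+"), llr_score(p, word, "-"))
      cons[k, s] <- sc > thr
    }
  }
  list(sites = sites, conserved = cons)
}

#' Strict conservation filter for binding sites
#'
#' Keeps a reference site only if its aligned window scores above the LLR
#' threshold in each of the first `n_species` sequences of the alignment
#' (site turnover is not tolerated). `n_species = 1` returns the unfiltered
#' reference annotation.
#'
#' @inheritParams site_conservation
#' @param n_species number of species (alignment rows, reference included)
#'   whose conservation is required.
#' @return filtered reference `binding_sites` data.frame.
#' @export
filter_strict <- function(alignment, pwms, n_species, threshold_frac = 0.4) {
  filter_turnover(alignment, pwms, n_species, min_species = n_species,
                  threshold_frac = threshold_frac)
}

#' Turnover-tolerant conservation filter
#'
#' Keeps a reference site if it is above threshold in at least `min_species`
#' of the first `n_species` sequences, so deeply conserved sites survive a
#' lineage-specific loss. The m-of-k rule is this package's significance
#' convention; `min_species = n_species` reduces to [filter_strict()].
#'
#' @inheritParams filter_strict
#' @param min_species minimum number of species (reference included) in which
#'   the site must be above threshold; default `ceiling(n_species/2) + 1`,
#'   capped at `n_species`.
#' @return filtered reference `binding_sites` data.frame.
#' @export
filter_turnover <- function(alignment, pwms, n_species,
                            min_species = min(ceiling(n_species / 2) + 1, n_species),
                            threshold_frac = 0.4) {
  if (n_species > length(alignment))
    stop("alignment has only ", length(alignment), " sequences, need ", n_species)
  stopifnot(min_species >= 1, min_species <= n_species)
  sc <- site_conservation(alignment, pwms, threshold_frac)
  keep <- rowSums(sc$conserved[, seq_len(n_species), drop = FALSE]) >= min_species
  out <- sc$sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(sc$sites)
  out
}

#' Read an aligned multi-FASTA file
#' @param file path to aligned FASTA (reference first).
#' @return named character vector of gapped sequences.
#' @export
read_alignment <- function(file) {
  x <- Biostrings::readBStringSet(file)
  aln <- toupper(as.character(x))
  names(aln) <- sub("\\s.*$", "", names(x))
  aln
}

#' Write an aligned multi-FASTA file
#' @param alignment named character vector of gapped sequences.
#' @param file output path.
#' @export
write_alignment <- function(alignment, file) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(alignment), file)
  invisible(file)
}
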