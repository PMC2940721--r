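#' Read PWMs from the block text format
#'
#' The file holds blocks of the form `>NAME WIDTH`, followed by WIDTH lines of
#' four whitespace-separated numbers (columns A, C, G, T), optionally
#' terminated by a line starting with `<`. Rows summing to ~1 are treated as
#' probabilities; otherwise the rows are counts and a pseudocount is added to
#' every cell before normalization.
#'
#' @param file path (or connection) to the PWM file.
#' @param background background base distribution applied to every motif.
#' @param pseudocount pseudocount per cell for count matrices; default 0.5.
#' @return list of [pwm()] objects in file order.
#' @export
read_pwms <- function(file, background = rep(0.25, 4), pseudocount = 0.5) {
  lines <- readLines(file)
  lines <- trimws(lines)
  pwms <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "<")) { i <- i + 1L; next }
    if (!startsWith(ln, ">"))
      stop("PWM parse error at line ", i, ": expected '>NAME WIDTH', got '", ln, "'")
    hdr <- strsplit(sub("^>", "", ln), "\\s+")[[1]]
    name <- hdr[1]
    width <- suppressWarnings(as.integer(hdr[2]))
    if (is.na(width) || width < 1L)
      stop("PWM parse error in motif '", name, "' at line ", i, ": bad width")
    if (i + width > length(lines))
      stop("PWM parse error in motif '", name, "': truncated block")
    rows <- matrix(NA_real_, width, 4)
    for (k in seq_len(width)) {
      vals <- suppressWarnings(as.numeric(strsplit(lines[i + k], "\\s+")[[1]]))
      if (length(vals) != 4L || anyNA(vals))
        stop("PWM parse error in motif '", name, "' at line ", i + k,
             ": expected 4 numeric values")
      rows[k, ] <- vals
    }
    is_probs <- all(abs(rowSums(rows) - 1) < 1e-4)
    pwms[[length(pwms) + 1L]] <-
      if (is_probs) pwm(name, rows / rowSums(rows), background, pseudocount = 0)
      else pwm_from_counts(name, rows, background, pseudocount)
    i <- i + width + 1L
  }
  pwms
}

#' Write PWMs in the block text format
#' @param pwms list of [pwm()] objects.
#' @param file output path.
#' @export
write_pwms <- function(pwms, file) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(file, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %d", p$name, p$width), con)
    writeLines(apply(p$probs, 1, function(r) paste(sprintf("%.8g", r), collapse = "\t")), con)
    writeLines("<", con)
  }
  invisible(file)
}

#' Read CRM sequences from FASTA
#'
#' Header names are truncated at the first whitespace.
#'
#' @param file FASTA path.
#' @return named character vector of uppercase DNA sequences.
#' @export
read_crm_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param file output path.
#' @export
write_crm_fasta <- function(seqs, file) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' Read a profile table (concentrations or expression)
#'
#' TSV with one row per entity: first column the entity name, remaining B
#' columns the per-bin values in `[0, 1]`.
#'
#' @param file TSV path.
#' @return numeric matrix, rownames = entity names, one column per bin.
#' @export
read_profile_table <- function(file) {
  d <- read.delim(file, header = TRUE, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- d[[1]]
  if (anyNA(m)) stop("non-numeric values in profile table ", file)
  m
}

#' Write a profile table
#' @param m numeric matrix with rownames.
#' @param file output path.
#' @param name header for the first (name) column.
#' @export
write_profile_table <- function(m, file, name = "name") {
  d <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(d) <- c(name, colnames(m) %||% paste0("bin", seq_len(ncol(m))))
  write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read the TF role table
#'
#' TSV with columns `name`, `role` (activator/repressor) and optionally
#' `binding_k`, `alpha`, `beta`, `coop_partners` (comma-separated TF names).
#'
#' @param file TSV path.
#' @return data.frame with at least `name` and `role`.
#' @export
read_tf_table <- function(file) {
  d <- read.delim(file, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("name", "role") %in% names(d)))
    stop("TF table must have 'name' and 'role' columns")
  if (!all(d$role %in% c("activator", "repressor")))
    stop("TF roles must be 'activator' or 'repressor'")
  d
}

#' Serialize / restore fitted model parameters
#'
#' Writes every [model_params()] field to a JSON text file; `read_model()`
#' restores an identical object.
#'
#' @param params a [model_params()] object.
#' @param file output path.
#' @export
write_model <- function(params, file) {
  x <- unclass(params)
  # named vectors become JSON objects so single-TF models keep their names
  for (f in c("binding_k", "alpha", "omega", "beta"))
    if (!is.null(x[[f]])) x[[f]] <- as.list(x[[f]])
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_model
#' @export
read_model <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  model_params(binding_k = unlist(x$binding_k), alpha = unlist(x$alpha),
               omega = if (length(x$omega)) unlist(x$omega) else NULL,
               beta = if (length(x$beta)) unlist(x$beta) else NULL,
               q_btm = x$q_btm, coop_range = x$coop_range, d_r = x$d_r,
               n_ma = if (is.character(x$n_ma) || is.null(x$n_ma)) Inf else x$n_ma,
               mode = x$mode)
}
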