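#' Alignment container
#'
#' A minimal container for a multiple-sequence alignment: a named character
#' vector of equal-length, gap-padded sequences plus a table of fragment
#' boundaries (0-based half-open column intervals) that tile the alignment.
#'
#' @param seqs Named character vector, all elements the same width.
#' @param name Fragment name recorded for a single-fragment alignment.
#' @return Object of class `alignment`.
#' @export
alignment <- function(seqs, name = "fragment") {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate taxon within one fragment: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("sequences have unequal lengths", call. = FALSE)
  structure(list(
    seqs = seqs,
    boundaries = data.frame(name = name, start = 0L, end = w,
                            stringsAsFactors = FALSE)
  ), class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("alignment:", length(x$seqs), "taxa x", alignment_length(x), "columns,",
      nrow(x$boundaries), "fragment(s)\n")
  invisible(x)
}

#' @rdname alignment
#' @param x An `alignment`.
#' @export
alignment_length <- function(x) {
  stopifnot(inherits(x, "alignment"))
  unname(nchar(x$seqs[1L]))
}

#' Read / write FASTA alignments
#'
#' I/O through Biostrings; sequences may be amino acid or nucleotide.
#'
#' @param path FASTA file path.
#' @param name Fragment name (defaults to the file name without extension).
#' @return [read_alignment()]: an `alignment`; [write_alignment()]: `path`,
#'   invisibly.
#' @export
read_alignment <- function(path, name = NULL) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  alignment(seqs, name = name)
}

#' @rdname read_alignment
#' @param aln An `alignment`.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "alignment"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln$seqs), path)
  invisible(path)
}

#' Concatenate fragment alignments into a supermatrix
#'
#' Taxa absent from a fragment (e.g. fragments that defied amplification)
#' are padded with `"-"` across that fragment's span. Fragment boundaries
#' are recorded as 0-based half-open intervals tiling the result.
#'
#' @param alignments Non-empty list of `alignment` objects, in order.
#' @param taxa Taxon universe; default: union over fragments, in order of
#'   first appearance.
#' @return An `alignment` whose length is the sum of the input lengths.
#' @export
concatenate_alignments <- function(alignments, taxa = NULL) {
  if (!length(alignments)) stop("empty fragment list", call. = FALSE)
  stopifnot(all(vapply(alignments, inherits, logical(1), "alignment")))
  if (is.null(taxa)) {
    taxa <- unique(unlist(lapply(alignments, function(a) names(a$seqs))))
  }
  pieces <- matrix("", length(taxa), length(alignments),
                   dimnames = list(taxa, NULL))
  bounds <- vector("list", length(alignments))
  at <- 0L
  for (j in seq_along(alignments)) {
    a <- alignments[[j]]
    w <- alignment_length(a)
    pad <- strrep("-", w)
    got <- a$seqs[match(taxa, names(a$seqs))]
    got[is.na(got)] <- pad
    pieces[, j] <- got
    bounds[[j]] <- data.frame(name = a$boundaries$name[1L],
                              start = at, end = at + w,
                              stringsAsFactors = FALSE)
    at <- at + w
  }
  seqs <- apply(pieces, 1L, paste, collapse = "")
  names(seqs) <- taxa
  out <- alignment(seqs)
  out$boundaries <- do.call(rbind, bounds)
  out
}

#' Filter alignment columns by gap and consensus fraction
#'
#' A reproducible proxy for manual alignment editing: keep columns whose
#' gap fraction is at most `max_gap_fraction` and whose modal residue
#' (among non-gap, non-ambiguous characters) reaches at least
#' `min_consensus_fraction` of the non-gap characters. `-` counts as gap;
#' `X` and `N` count as ambiguous and enter neither the consensus numerator
#' nor its denominator. Column order is preserved and fragment boundaries
#' are remapped.
#'
#' @param aln An `alignment`.
#' @param max_gap_fraction Maximum tolerated gap fraction, in `[0, 1]`.
#' @param min_consensus_fraction Minimum modal-residue fraction, in `[0, 1]`.
#' @return A filtered `alignment` (possibly of length 0).
#' @export
filter_columns <- function(aln, max_gap_fraction = 0.2,
                           min_consensus_fraction = 0) {
  stopifnot(inherits(aln, "alignment"),
            max_gap_fraction >= 0, max_gap_fraction <= 1,
            min_consensus_fraction >= 0, min_consensus_fraction <= 1)
  M <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  n <- nrow(M)
  gap_frac <- colMeans(M == "-")
  keep_gap <- gap_frac <= max_gap_fraction
  keep_cons <- vapply(seq_len(ncol(M)), function(j) {
    col <- M[, j]
    col <- col[!(col %in% c("-", "X", "N", "x", "n", "?"))]
    if (!length(col)) return(min_consensus_fraction <= 0)
    max(table(col)) / length(col) >= min_consensus_fraction
  }, logical(1))
  keep <- keep_gap & keep_cons
  seqs <- apply(M[, keep, drop = FALSE], 1L, paste, collapse = "")
  names(seqs) <- names(aln$seqs)
  b <- aln$boundaries
  new_b <- b
  cum <- 0L
  for (i in seq_len(nrow(b))) {
    w <- sum(keep[seq.int(b$start[i] + 1L, length.out = b$end[i] - b$start[i])])
    new_b$start[i] <- cum
    new_b$end[i] <- cum + w
    cum <- cum + w
  }
  out <- list(seqs = seqs, boundaries = new_b)
  class(out) <- "alignment"
  out
}

#' G/C content of nucleotide sequences
#'
#' Pooled `(G + C) / (A + C + G + T)` over one or more fragments; gaps
#' (`-`) and ambiguous bases (`N`) are excluded from both numerator and
#' denominator. Case-insensitive.
#'
#' @param seqs Character vector of nucleotide sequences (one taxon's
#'   fragments, pooled).
#' @return Fraction in `[0, 1]`, with attribute `bases` (number of counted
#'   bases).
#' @examples
#' gc_content("ATGC")   # 0.5
#' gc_content("AT-GN")  # 1/3
#' @export
gc_content <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  s <- toupper(paste(seqs, collapse = ""))
  counts <- table(strsplit(s, "", fixed = TRUE)[[1]])
  n_gc <- sum(counts[names(counts) %in% c("G", "C")])
  n_at <- sum(counts[names(counts) %in% c("A", "T")])
  total <- n_gc + n_at
  bad <- setdiff(names(counts), c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) {
    stop("unexpected characters in nucleotide sequence: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (total == 0L) stop("no countable bases (all gaps/N)", call. = FALSE)
  structure(n_gc / total, bases = as.integer(total))
}

#' Per-taxon G/C report over a set of fragment alignments
#'
#' @param alignments List of `alignment` objects (nucleotide); each taxon's
#'   bases are pooled across all fragments in which it occurs.
#' @return Data frame with columns `taxon`, `bases`, `gc` (fraction).
#' @export
gc_report <- function(alignments) {
  if (inherits(alignments, "alignment")) alignments <- list(alignments)
  taxa <- unique(unlist(lapply(alignments, function(a) names(a$seqs))))
  rows <- lapply(taxa, function(tx) {
    seqs <- unlist(lapply(alignments, function(a) unname(a$seqs[tx])))
    seqs <- seqs[!is.na(seqs)]
    g <- gc_content(seqs)
    data.frame(taxon = tx, bases = attr(g, "bases"), gc = as.numeric(g),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
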