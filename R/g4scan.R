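#' Scan sequences for putative G-quadruplex (PG4) motifs
#'
#' Finds, on both strands, all leftmost non-overlapping matches of the
#' quadruplex pattern `(GGG N1-7)x(min_tracts-1 or more) GGG` where `N` is any
#' of `A,C,G,T`.  Match semantics are those of a PCRE-style backtracking
#' engine: the repeated group is greedy (as many G-tracts as possible), each
#' loop token is greedy (longest first), and scanning resumes after the end of
#' the previous match.  Reverse-strand motifs are found by scanning the
#' reverse complement and mirroring coordinates back to the forward reference.
#'
#' Each matched span is then decomposed into stems (each exactly `GGG`) and
#' loops by the parse that maximizes the tract count first and takes each
#' loop longest-first: for a G-run longer than three, the 5'-most three Gs
#' form the stem and the surplus Gs fall into the adjacent loop, and a motif
#' of five or more well-separated tracts is recorded with its true tract
#' count rather than hiding extra `GGG` runs inside a loop token.  Recorded
#' loop lengths never exceed `max_loop`: a span that would need a longer
#' loop (for instance a 4-G run followed by a `max_loop`-nt spacer) is not a
#' match of the pattern in the first place -- the engine starts the match
#' after the surplus G instead.  Span finding and
#' tokenization are deliberately decoupled: spans always agree with a
#' standard regex engine, while tract counts stay faithful to the stem/loop
#' rule.
#'
#' @param seqs Named character vector of sequences (as from [read_fasta()]).
#' @param min_loop,max_loop Loop length bounds of the pattern token
#'   (defaults 1 and 7 nt).
#' @param min_tracts Minimum number of G-tracts (default 4).
#' @return A data.frame of motifs with columns `seq_id`, `start`, `end`
#'   (0-based half-open on the forward reference strand), `motif_strand`
#'   (strand carrying the G-rich run), `n_tracts`, `matched` (the G-rich
#'   sequence read 5' to 3' on the motif strand) and `loops` (comma-joined
#'   loop tokens, 5' to 3').
#' @export
scan_pg4 <- function(seqs, min_loop = 1L, max_loop = 7L, min_tracts = 4L) {
  stopifnot(min_loop >= 1L, max_loop >= min_loop, min_tracts >= 2L)
  if (is.null(names(seqs))) {
    if (length(seqs) == 1L) names(seqs) <- "seq"
    else stop("seqs must be a named character vector")
  }
  rcs <- reverse_complement(unname(seqs))
  acc <- list()
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    L <- nchar(seqs[[i]])
    for (strand in c("+", "-")) {
      scanned <- if (strand == "+") seqs[[i]] else rcs[[i]]
      h <- .cpp_scan_pg4(scanned, min_loop, max_loop, min_tracts)
      if (length(h$start) == 0L) next
      matched <- substring(scanned, h$start + 1L, h$end)
      if (strand == "+") {
        start <- h$start
        end <- h$end
      } else { # mirror coordinates back to the forward reference
        start <- L - h$end
        end <- L - h$start
      }
      acc[[length(acc) + 1L]] <- list(
        seq_id = rep(id, length(start)), start = start, end = end,
        motif_strand = rep(strand, length(start)),
        n_tracts = lengths(h$loops) + 1L, matched = matched,
        loops = vapply(h$loops, paste, character(1), collapse = ","))
    }
  }
  fld <- function(f) unlist(lapply(acc, `[[`, f), use.names = FALSE)
  out <- data.frame(
    seq_id = if (length(acc)) fld("seq_id") else character(0),
    start = if (length(acc)) as.integer(fld("start")) else integer(0),
    end = if (length(acc)) as.integer(fld("end")) else integer(0),
    motif_strand = if (length(acc)) fld("motif_strand") else character(0),
    n_tracts = if (length(acc)) as.integer(fld("n_tracts")) else integer(0),
    matched = if (length(acc)) fld("matched") else character(0),
    loops = if (length(acc)) fld("loops") else character(0),
    stringsAsFactors = FALSE)
  out <- out[order(out$seq_id, out$start, out$motif_strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Decompose a motif string into stems and loops
#'
#' Anchored parse of a full motif: the token assignment of the first
#' successful parse with the tract count maximized first, then each loop
#' token longest-first.  Equivalently, for G-runs longer than three, the
#' three 5'-most guanines form the stem and surplus guanines join the
#' adjacent loop.
#'
#' @param matched Motif string (must match the pattern end to end).
#' @param min_loop,max_loop Loop length bounds (defaults 1, 7).
#' @param min_tracts Minimum number of G-tracts (default 4).
#' @return List with `stems` (each `"GGG"`) and `loops` (character vector of
#'   length `n_tracts - 1`).
#' @export
decompose_pg4 <- function(matched, min_loop = 1L, max_loop = 7L,
                          min_tracts = 4L) {
  loops <- .cpp_parse_pg4(matched, min_loop, max_loop, min_tracts)
  if (is.null(loops)) stop("not a PG4 motif: ", matched)
  list(stems = rep("GGG", length(loops) + 1L), loops = loops)
}

#' Keep only motifs with exactly four G-tracts
#'
#' Motifs with more than four G-tracts are ambiguous as to which tracts form
#' the quadruplex stem and are excluded from loop-level analyses.
#'
#' @param motifs Motif data.frame from [scan_pg4()].
#' @return The subset with `n_tracts == 4`, order preserved.
#' @export
four_tract_subset <- function(motifs) {
  motifs[motifs$n_tracts == 4L, , drop = FALSE]
}

#' Remove duplicate motif records
#'
#' Motifs identical on (`seq_id`, `start`, `end`, `motif_strand`) are kept
#' once, so a motif assigned to several genes downstream is counted a single
#' time in loop and composition statistics.
#'
#' @param motifs Motif data.frame.
#' @return Deduplicated motif data.frame.
#' @export
deduplicate_motifs <- function(motifs) {
  key <- paste(motifs$seq_id, motifs$start, motifs$end, motifs$motif_strand)
  motifs[!duplicated(key), , drop = FALSE]
}

#' Loop tokens of each motif as a list of character vectors
#'
#' @param motifs Motif data.frame.
#' @return List of character vectors (one per motif).
#' @export
motif_loops <- function(motifs) {
  strsplit(motifs$loops, ",", fixed = TRUE)
}

#' Write motifs as BED6+ (extra columns: matched, loops)
#'
#' @param motifs Motif data.frame.
#' @param path Output path.
#' @export
write_motifs_bed <- function(motifs, path) {
  bed <- data.frame(chrom = motifs$seq_id, start = motifs$start,
                    end = motifs$end, name = "PG4",
                    score = motifs$n_tracts, strand = motifs$motif_strand,
                    matched = motifs$matched, loops = motifs$loops,
                    stringsAsFactors = FALSE)
  .write_tsv(bed, path)
}

#' Read motifs from the BED6+ written by [write_motifs_bed()]
#'
#' @param path Path to the BED6+ file.
#' @return Motif data.frame.
#' @export
read_motifs_bed <- function(path) {
  x <- .read_tsv(path)
  data.frame(seq_id = as.character(x$chrom), start = x$start, end = x$end,
             motif_strand = as.character(x$strand), n_tracts = x$score,
             matched = as.character(x$matched),
             loops = as.character(x$loops), stringsAsFactors = FALSE)
}
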