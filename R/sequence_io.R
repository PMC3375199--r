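#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased, `U` is mapped to `T`, and any character outside
#' the `{A,C,G,T,N}` alphabet is replaced by `N` with a warning.  This is the
#' canonical in-memory form used by every other function in the package: a
#' named character vector, one element per record, names taken from the first
#' whitespace-delimited token of each header.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return Named character vector of normalized sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate seq_id in FASTA file: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  bad <- gsub("[ACGTN]", "", seqs)
  n_bad <- sum(nchar(bad))
  if (n_bad > 0L) {
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1),
                   USE.NAMES = FALSE)
    warning(n_bad, " non-ACGTN character(s) replaced by N")
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Reverse complement of a DNA sequence
#'
#' Standard Watson-Crick complement over `{A,C,G,T,N}` (N maps to N),
#' reversed.  Vectorized over its input.
#'
#' @param bases Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse-complemented sequences.
#' @export
reverse_complement <- function(bases) {
  if (length(bases) == 0L) return(character(0))
  ok <- grepl("^[ACGTN]*$", bases)
  if (!all(ok))
    stop("sequence contains characters outside {A,C,G,T,N}")
  out <- character(length(bases))
  nz <- nchar(bases) > 0L
  if (any(nz)) {
    out[nz] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(bases[nz])))
  }
  names(out) <- names(bases)
  out
}

#' Read TSS annotations
#'
#' Supported dialects:
#' \describe{
#'   \item{bed6}{0-based half-open; TSS = start for `+`, end-1 for `-`;
#'     the BED name field is taken as `gene_id` (and `mrna_id`).}
#'   \item{gff3}{1-based closed, converted to 0-based; the identifier is
#'     taken from the `ID`, `Name`, `gene_id` or `transcript_id` attribute
#'     (first present).}
#'   \item{tsv}{header `gene_id mrna_id seq_id tss strand`, `tss` already a
#'     0-based position on the forward reference strand.}
#' }
#' All coordinates are returned 0-based on the forward reference strand;
#' `strand` is the coding strand of the mRNA.
#'
#' @param path Path to the annotation file.
#' @param dialect One of `"bed6"`, `"gff3"`, `"tsv"`.
#' @return A data.frame with columns `gene_id`, `mrna_id`, `seq_id`, `tss`,
#'   `strand`.
#' @export
read_annotation <- function(path, dialect = c("tsv", "bed6", "gff3")) {
  dialect <- match.arg(dialect)
  ann <- switch(dialect,
    bed6 = {
      x <- utils::read.table(path, sep = "\t", header = FALSE,
                             comment.char = "#", stringsAsFactors = FALSE)
      if (ncol(x) < 6L) stop("BED6 requires at least 6 columns")
      data.frame(gene_id = as.character(x[[4L]]),
                 mrna_id = as.character(x[[4L]]),
                 seq_id = as.character(x[[1L]]),
                 tss = ifelse(x[[6L]] == "+", x[[2L]], x[[3L]] - 1L),
                 strand = as.character(x[[6L]]),
                 stringsAsFactors = FALSE)
    },
    gff3 = {
      x <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                             comment.char = "#", stringsAsFactors = FALSE)
      if (ncol(x) < 9L) stop("GFF3 requires 9 columns")
      id <- .gff3_attr_id(x[[9L]])
      data.frame(gene_id = id, mrna_id = id,
                 seq_id = as.character(x[[1L]]),
                 tss = ifelse(x[[7L]] == "+", x[[4L]] - 1L, x[[5L]] - 1L),
                 strand = as.character(x[[7L]]),
                 stringsAsFactors = FALSE)
    },
    tsv = {
      x <- utils::read.table(path, sep = "\t", header = TRUE,
                             comment.char = "#", stringsAsFactors = FALSE)
      need <- c("gene_id", "mrna_id", "seq_id", "tss", "strand")
      if (!all(need %in% names(x)))
        stop("TSV annotation must have columns: ", paste(need, collapse = " "))
      x[need]
    })
  if (!all(ann$strand %in% c("+", "-")))
    stop("annotation records with missing or invalid strand")
  if (any(ann$tss < 0L)) stop("negative TSS coordinate")
  key <- paste(ann$mrna_id, ann$seq_id)
  if (anyDuplicated(key))
    stop("duplicate (mrna_id, seq_id) in annotation: ",
         key[duplicated(key)][1L])
  ann
}

.gff3_attr_id <- function(attrs) {
  pick <- function(a) {
    for (k in c("ID", "Name", "gene_id", "transcript_id")) {
      m <- regmatches(a, regexpr(paste0("(^|;)\\s*", k, "=[^;]+"), a))
      if (length(m) == 1L && nchar(m) > 0L)
        return(sub(paste0("^.*", k, "="), "", m))
    }
    stop("GFF3 record without ID/Name/gene_id/transcript_id attribute: ", a)
  }
  vapply(attrs, pick, character(1), USE.NAMES = FALSE)
}

#' Write TSS annotations in the package TSV dialect
#'
#' @param ann Annotation data.frame as returned by [read_annotation()].
#' @param path Output path.
#' @export
write_annotation <- function(ann, path) {
  .write_tsv(ann[c("gene_id", "mrna_id", "seq_id", "tss", "strand")], path)
}

#' Read a gene-list TSV (header: gene_id, set, direction)
#'
#' @param path Path to the TSV file.
#' @return Named list of character vectors, one per `set`/`direction`
#'   combination (names `"<set>.<direction>"`), each non-redundant.
#' @export
read_gene_lists <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_id", "set", "direction")
  if (!all(need %in% names(x)))
    stop("gene list TSV must have columns: ", paste(need, collapse = " "))
  split_key <- paste(x$set, x$direction, sep = ".")
  lapply(split(x$gene_id, split_key), unique)
}

#' Write gene lists in the package TSV dialect
#'
#' @param lists Named list of character vectors; names of the form
#'   `"<set>.<direction>"` (a bare name is written with direction
#'   `"universe"`).
#' @param path Output path.
#' @export
write_gene_lists <- function(lists, path) {
  rows <- lapply(names(lists), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) parts <- c(nm, "universe")
    data.frame(gene_id = unique(lists[[nm]]),
               set = parts[1L],
               direction = paste(parts[-1L], collapse = "."),
               stringsAsFactors = FALSE)
  })
  .write_tsv(do.call(rbind, rows), path)
}

# tab-separated writer with a commented provenance header
.write_tsv <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- tryCatch(as.character(utils::packageVersion("g4prom")),
                  error = function(e) "dev")
  hdr <- paste0("# g4prom ", ver)
  if (!is.null(params))
    hdr <- paste0(hdr, " | ", paste(names(params), unlist(params),
                                    sep = "=", collapse = " "))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# tab-separated reader skipping commented provenance headers
.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}
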