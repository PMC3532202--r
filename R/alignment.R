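# Alignment container: a taxon-by-site character matrix over IUPAC codes with
# a per-site inclusion mask ("full" keeps everything, "strict" drops columns
# flagged as alignment-ambiguous).

IUPAC_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L,
                N = 15L, "-" = 15L, "?" = 15L)

#' Construct an alignment with a site-inclusion mask
#'
#' @param x Character matrix (taxa in rows, sites in columns) of IUPAC
#'   nucleotide codes, gaps (`-`) and `N`/`?`; or a named character vector of
#'   equal-length sequences.
#' @param mask Logical vector, one entry per site; `TRUE` = included.
#'   Defaults to all sites included.
#' @return An object of class `kdr_alignment` with elements `seq` (matrix)
#'   and `mask`.
#' @export
alignment <- function(x, mask = NULL) {
  if (is.character(x) && is.null(dim(x))) {
    if (is.null(names(x))) stop("sequences must be named")
    n <- nchar(x)
    if (length(unique(n)) != 1)
      stop("sequences have unequal lengths; offending record: ",
           names(x)[which(n != n[1])[1]])
    x <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(x) <- names(n)
  }
  if (!is.matrix(x) || !is.character(x)) stop("x must be a character matrix")
  if (is.null(rownames(x))) stop("alignment rows must be named by taxon")
  if (anyDuplicated(rownames(x))) stop("duplicate taxon labels")
  x[] <- toupper(x)
  bad <- !(x %in% names(IUPAC_MASK))
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-nucleotide character '", x[bad][1], "' in record '",
         rownames(x)[i[1]], "' at site ", i[2])
  }
  if (is.null(mask)) mask <- rep(TRUE, ncol(x))
  if (length(mask) != ncol(x)) stop("mask length must equal site count")
  structure(list(seq = x, mask = as.logical(mask)), class = "kdr_alignment")
}

#' @export
print.kdr_alignment <- function(x, ...) {
  cat("Alignment:", nrow(x$seq), "taxa x", ncol(x$seq), "sites (",
      sum(x$mask), "included )\n")
  invisible(x)
}

n_taxa <- function(aln) nrow(aln$seq)
n_sites_included <- function(aln) sum(aln$mask)
aln_labels <- function(aln) rownames(aln$seq)

#' Read an aligned FASTA file
#'
#' All records must have equal length (pre-aligned input).  Malformed input
#' or ragged records produce an error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @param mask Optional site-inclusion mask (see [alignment()]).
#' @return A `kdr_alignment`.
#' @export
read_fasta_alignment <- function(path, mask = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0 || !startsWith(lines[1], ">"))
    stop("malformed FASTA: ", path, " does not start with a '>' header")
  hdr <- grepl("^>", lines)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(s) paste(s, collapse = ""), character(1))
  if (length(seqs) != length(ids)) {
    empty <- setdiff(seq_along(ids), as.integer(names(seqs)))
    stop("malformed FASTA: record '", ids[empty[1]], "' has no sequence")
  }
  names(seqs) <- ids
  n <- nchar(seqs)
  if (length(unique(n)) != 1)
    stop("unequal sequence lengths; offending record: '",
         ids[which(n != n[1])[1]], "' (", n[which(n != n[1])[1]],
         " vs ", n[1], " bases)")
  alignment(seqs, mask = mask)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# site-pattern compression of the included columns -> integer bitmask matrix
# (taxa x patterns) plus weights, for the likelihood engine
compress_patterns <- function(aln) {
  m <- aln$seq[, aln$mask, drop = FALSE]
  codes <- matrix(IUPAC_MASK[m], nrow = nrow(m))
  key <- apply(codes, 2, paste, collapse = ",")
  u <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[u])))
  list(pat = codes[, u, drop = FALSE], w = w, labels = rownames(aln$seq))
}

# empirical base frequencies with a pseudocount of 1 per state
empirical_freq <- function(aln) {
  m <- aln$seq[, aln$mask, drop = FALSE]
  cnt <- vapply(c("A", "C", "G", "T"), function(b) sum(m == b), numeric(1))
  # ambiguity codes contribute fractionally
  amb <- m[!(m %in% c("A", "C", "G", "T"))]
  if (length(amb)) {
    for (a in amb) {
      bits <- bitwAnd(IUPAC_MASK[[a]], c(1L, 2L, 4L, 8L)) > 0
      cnt[bits] <- cnt[bits] + 1 / sum(bits)
    }
  }
  cnt <- cnt + 1
  unname(cnt / sum(cnt))
}
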