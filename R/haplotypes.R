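# Haplotype classification for Vssc pyrethroid-resistance alleles: deduce
# the amino acids at codons 918 and 1014 from a sequenced fragment, assign
# the allele class (susceptible / kdr / kdr-his / super-kdr), extract the
# intron adjacent to codon 1014, group haplotypes by intron identity and
# name them in discovery order (kdr1, kdr-his1, super-kdr1, v1, ...).

#' Describe the layout of a sequenced Vssc fragment
#'
#' Offsets are 0-based columns of the aligned fragment; the intron is the
#' half-open interval `[intron_start, intron_end)`.  With
#' `canonical_geometry = TRUE` the layout is checked against the canonical
#' arrangement in which the intron begins three bases (one codon)
#' downstream of codon 1014, i.e. `intron_start == codon1014_offset + 6`.
#'
#' @param codon1014_offset 0-based column of the first base of codon 1014.
#' @param intron_start,intron_end 0-based half-open intron interval.
#' @param codon918_offset Optional 0-based column of the first base of
#'   codon 918 (when the fragment covers it).
#' @param canonical_geometry Assert the canonical intron placement.
#' @return An object of class `fragment_layout`.
#' @export
fragment_layout <- function(codon1014_offset, intron_start, intron_end,
                            codon918_offset = NULL,
                            canonical_geometry = FALSE) {
  if (codon1014_offset < 0 || intron_start < 0)
    stop("offsets must be non-negative")
  if (intron_start >= intron_end)
    stop("intron_start must be < intron_end")
  if (canonical_geometry && intron_start != codon1014_offset + 6)
    stop("canonical geometry requires intron_start == codon1014_offset + 6 ",
         "(intron three bases downstream of codon 1014)")
  structure(list(codon1014_offset = as.integer(codon1014_offset),
                 intron_start = as.integer(intron_start),
                 intron_end = as.integer(intron_end),
                 codon918_offset =
                   if (is.null(codon918_offset)) NULL
                   else as.integer(codon918_offset),
                 canonical_geometry = canonical_geometry),
            class = "fragment_layout")
}

# expand one IUPAC nucleotide to its base set
iupac_bases <- function(ch) {
  m <- IUPAC_MASK[[ch]]
  c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0]
}

#' Translate one codon, honouring IUPAC ambiguity
#'
#' Standard genetic code.  A codon containing a gap, or an ambiguity whose
#' resolutions translate to different amino acids, yields `'?'`.  An
#' ambiguity whose resolutions agree (e.g. `CAY` -> His) is translated.
#'
#' @param codon A 3-character nucleotide string.
#' @return A single amino-acid letter, `'*'` for stop, or `'?'`.
#' @export
translate_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1 || nchar(codon) != 3)
    stop("codon must be a single 3-character string")
  ch <- strsplit(toupper(codon), "")[[1]]
  bad <- !(ch %in% names(IUPAC_MASK))
  if (any(bad)) stop("non-nucleotide character '", ch[bad][1], "' in codon")
  if (any(ch %in% c("-", "?"))) return("?")
  combos <- expand.grid(iupac_bases(ch[1]), iupac_bases(ch[2]),
                        iupac_bases(ch[3]), stringsAsFactors = FALSE)
  aa <- unique(apply(combos, 1, function(b) seqinr::translate(b)))
  if (length(aa) == 1) aa else "?"
}

#' Classify a Vssc allele from the deduced 918/1014 amino acids
#'
#' Total function over amino-acid letters (including `'?'`):
#' M918+L1014 is susceptible, M918+F1014 is kdr, 1014H is kdr-his,
#' T918+F1014 is super-kdr; everything else (including unresolved `'?'`)
#' is `other`.
#'
#' @param aa918,aa1014 Single amino-acid letters or `'?'`.
#' @return One of `"susceptible"`, `"kdr"`, `"kdr-his"`, `"super-kdr"`,
#'   `"other"`.
#' @export
classify_allele <- function(aa918, aa1014) {
  if (aa1014 == "H" && aa918 == "M") return("kdr-his")
  if (aa918 == "M" && aa1014 == "L") return("susceptible")
  if (aa918 == "M" && aa1014 == "F") return("kdr")
  if (aa918 == "T" && aa1014 == "F") return("super-kdr")
  "other"
}

RESISTANT_CLASSES <- c("kdr", "kdr-his", "super-kdr")

#' Extract 918/1014 amino acids and the intron slice from a sequence
#'
#' Codons are read at the layout's offsets and translated; the intron is
#' the aligned half-open slice, retained verbatim (gap columns included),
#' since intron identity is compared on the aligned sequence.
#'
#' @param sequence Nucleotide string (aligned fragment).
#' @param layout A [fragment_layout()].
#' @return A list with `aa918`, `aa1014`, `intron`.
#' @export
extract_features <- function(sequence, layout) {
  if (!inherits(layout, "fragment_layout")) stop("layout must be a fragment_layout")
  n <- nchar(sequence)
  if (layout$codon1014_offset + 3 > n || layout$intron_end > n ||
      (!is.null(layout$codon918_offset) && layout$codon918_offset + 3 > n))
    stop("layout offsets exceed sequence length (", n, " bases)")
  o <- layout$codon1014_offset
  aa1014 <- translate_codon(substr(sequence, o + 1, o + 3))
  aa918 <- if (is.null(layout$codon918_offset)) "?" else {
    o9 <- layout$codon918_offset
    translate_codon(substr(sequence, o9 + 1, o9 + 3))
  }
  intron <- substr(sequence, layout$intron_start + 1, layout$intron_end)
  list(aa918 = aa918, aa1014 = aa1014, intron = intron)
}

# build classified records from named sequences
build_records <- function(seqs, layout) {
  out <- lapply(names(seqs), function(lab) {
    f <- extract_features(seqs[[lab]], layout)
    data.frame(label = lab, sequence = unname(seqs[[lab]]),
               aa918 = f$aa918, aa1014 = f$aa1014,
               class = classify_allele(f$aa918, f$aa1014),
               intron = f$intron, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' An empty haplotype catalog
#'
#' The catalog holds the named haplotypes discovered so far and the
#' per-class counters that drive discovery-order numbering.  It is an
#' explicit input/output so numbering is stable across input batches.
#'
#' @return An object of class `haplotype_catalog`.
#' @export
haplotype_catalog <- function() {
  structure(list(records = data.frame(name = character(0),
                                      class = character(0),
                                      aa918 = character(0),
                                      aa1014 = character(0),
                                      intron = character(0),
                                      sequence = character(0),
                                      stringsAsFactors = FALSE),
                 counters = c(susceptible = 0L, kdr = 0L, `kdr-his` = 0L,
                              `super-kdr` = 0L, other = 0L)),
            class = "haplotype_catalog")
}

class_prefix <- c(susceptible = "v", kdr = "kdr", `kdr-his` = "kdr-his",
                  `super-kdr` = "super-kdr", other = "other")

#' Assign discovery-order names to classified records
#'
#' A record whose (intron, aa918, aa1014) state matches an existing
#' haplotype reuses its name; otherwise it receives the class prefix plus
#' the next integer for that class (`v` for susceptible).  Idempotent:
#' replaying the same records leaves the catalog unchanged.
#'
#' @param records Data frame from classified sequences with columns
#'   `label`, `sequence`, `aa918`, `aa1014`, `class`, `intron`.
#' @param catalog A [haplotype_catalog()] (updated copy is returned).
#' @return A list with `catalog` (updated) and `names` (one per record).
#' @export
assign_names <- function(records, catalog = haplotype_catalog()) {
  nm <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    hit <- which(catalog$records$intron == r$intron &
                 catalog$records$aa918 == r$aa918 &
                 catalog$records$aa1014 == r$aa1014)
    if (length(hit)) {
      nm[i] <- catalog$records$name[hit[1]]
    } else {
      k <- catalog$counters[[r$class]] + 1L
      catalog$counters[[r$class]] <- k
      nm[i] <- paste0(class_prefix[[r$class]], k)
      catalog$records <- rbind(catalog$records,
                               data.frame(name = nm[i], class = r$class,
                                          aa918 = r$aa918, aa1014 = r$aa1014,
                                          intron = r$intron,
                                          sequence = r$sequence,
                                          stringsAsFactors = FALSE))
    }
  }
  list(catalog = catalog, names = nm)
}

#' Partition haplotypes by exact intron identity
#'
#' Haplotypes with identical aligned intron sequences fall in one group
#' (one "column" of the haplotype-sharing table).  Groups are ordered by
#' their first-discovered member; the result is a partition.
#'
#' @param x A `haplotype_catalog` or a data frame with `name`/`label` and
#'   `intron` columns.
#' @return A list of class `intron_groups`: `groups` (list of member name
#'   vectors), `group_of` (named integer vector).
#' @export
group_by_intron <- function(x) {
  rec <- if (inherits(x, "haplotype_catalog")) x$records else x
  nm <- if ("name" %in% names(rec)) rec$name else rec$label
  keep <- !duplicated(nm)
  nm <- nm[keep]
  intr <- rec$intron[keep]
  gid <- match(intr, unique(intr))
  groups <- split(nm, gid)
  names(groups) <- NULL
  structure(list(groups = groups,
                 group_of = setNames(gid, nm)),
            class = "intron_groups")
}

#' @export
print.intron_groups <- function(x, ...) {
  cat("Intron-identity groups:", length(x$groups), "\n")
  for (i in seq_along(x$groups))
    cat(sprintf("  [%d] %s\n", i, paste(x$groups[[i]], collapse = ", ")))
  invisible(x)
}

#' Classify a set of aligned sequences into a haplotype catalog
#'
#' End-to-end haplotype stage: extract features under the layout, classify,
#' and name against (an optionally pre-existing) catalog.
#'
#' @param x A `kdr_alignment`, named character vector of sequences, or a
#'   FASTA path.
#' @param layout A [fragment_layout()].
#' @param catalog Optional existing [haplotype_catalog()] to extend.
#' @return A list of class `haplotype_result`: `catalog`, `assignments`
#'   (data frame label -> name/class), `groups` ([group_by_intron()] of the
#'   catalog).
#' @export
classify_sequences <- function(x, layout, catalog = haplotype_catalog()) {
  seqs <- if (inherits(x, "kdr_alignment")) {
    setNames(apply(x$seq, 1, paste, collapse = ""), rownames(x$seq))
  } else if (is.character(x) && length(x) == 1 && file.exists(x)) {
    a <- read_fasta_alignment(x)
    setNames(apply(a$seq, 1, paste, collapse = ""), rownames(a$seq))
  } else if (is.character(x) && !is.null(names(x))) {
    toupper(x)
  } else stop("x must be an alignment, named sequences, or a FASTA path")
  rec <- build_records(seqs, layout)
  an <- assign_names(rec, catalog)
  structure(list(catalog = an$catalog,
                 assignments = data.frame(label = rec$label, name = an$names,
                                          class = rec$class,
                                          aa918 = rec$aa918,
                                          aa1014 = rec$aa1014,
                                          stringsAsFactors = FALSE),
                 groups = group_by_intron(an$catalog)),
            class = "haplotype_result")
}

#' @export
print.haplotype_result <- function(x, ...) {
  cat("Haplotype classification:", nrow(x$assignments), "sequences,",
      nrow(x$catalog$records), "distinct haplotypes\n")
  print(table(x$catalog$records$class))
  invisible(x)
}

#' Write a haplotype catalog as TSV
#'
#' Columns: name, class, aa918, aa1014, intron-group id.
#'
#' @param catalog A `haplotype_catalog`.
#' @param path Output path.
#' @export
write_catalog_tsv <- function(catalog, path) {
  g <- group_by_intron(catalog)
  df <- catalog$records[, c("name", "class", "aa918", "aa1014")]
  df$intron_group <- unname(g$group_of[catalog$records$name])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
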