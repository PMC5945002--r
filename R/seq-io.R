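# FASTA / aligned-FASTA / GFF3 / Newick readers and writers. Thin, validated
# wrappers over Biostrings, rtracklayer and ape so that every on-disk format
# the pipeline touches goes through one place.

.validate_alphabet <- function(seqs, alphabet) {
  allowed <- switch(alphabet,
    dna = c(DNA_BASES, "N"),
    protein = c(AA20, "X"),
    msa = c(AA20, "X", "-"),
    stop("unknown alphabet: ", alphabet))
  pat <- paste0("[^", paste(allowed, collapse = ""), "]")
  bad <- regexpr(pat, seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    sym <- substr(seqs[i], bad[i], bad[i])
    stop(sprintf("illegal character '%s' in record %d under %s alphabet",
                 sym, i, alphabet))
  }
  invisible(TRUE)
}

.check_ids <- function(ids) {
  if (any(!nzchar(ids)))
    stop("empty sequence id in record ", which(!nzchar(ids))[1L])
  if (anyDuplicated(ids))
    stop("duplicate sequence id in record ", anyDuplicated(ids), ": ",
         ids[anyDuplicated(ids)])
  invisible(TRUE)
}

#' Read a FASTA file with alphabet validation
#'
#' Records are returned in file order with sequences uppercased. DNA records
#' may contain `A/C/G/T/N`; protein records the 20 canonical residues plus
#' `X`. Duplicate or empty identifiers and out-of-alphabet characters are
#' format errors naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return A [Biostrings::DNAStringSet] or [Biostrings::AAStringSet].
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1", "acgt", ">c2", "GGCC"), tf)
#' readFasta(tf, "dna")
readFasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no FASTA records in ", path)
  seqs <- toupper(as.character(raw))
  ids <- names(raw)
  .check_ids(ids)
  if (any(nchar(seqs) < 1L))
    stop("empty sequence in record ", which(nchar(seqs) < 1L)[1L])
  .validate_alphabet(seqs, alphabet)
  out <- if (alphabet == "dna") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences as FASTA (60-column wrapped)
#'
#' @param x A named `XStringSet` or named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("all records must be named")
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a protein multiple alignment from aligned FASTA
#'
#' All rows must have identical width; gaps are `-`. De-gapping any row must
#' yield a valid protein sequence.
#'
#' @param path Path to an aligned FASTA file.
#' @return An [Biostrings::AAStringSet] of equal-width gapped rows.
#' @export
readMsa <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no alignment rows in ", path)
  seqs <- toupper(as.character(raw))
  .check_ids(names(raw))
  .validate_alphabet(seqs, "msa")
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment rows differ in width")
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- names(raw)
  out
}

#' @rdname readMsa
#' @param msa An equal-width gapped `AAStringSet` (or named character).
#' @param path Output path.
#' @export
writeMsa <- function(msa, path) {
  msa <- as.character(msa)
  if (length(unique(nchar(msa))) != 1L)
    stop("alignment rows differ in width")
  writeFasta(Biostrings::AAStringSet(msa), path)
}

# character matrix view of an alignment (rows = sequences)
msaMatrix <- function(msa) {
  ch <- as.character(msa)
  m <- do.call(rbind, strsplit(ch, "", fixed = TRUE))
  rownames(m) <- names(ch)
  m
}

#' Write predicted ORFs as GFF3
#'
#' ORFs are emitted as `CDS` features with 1-based inclusive coordinates
#' (the native convention of both `GRanges` and GFF3), strand, and
#' `has_start` / `has_stop` completeness flags in the attribute column.
#'
#' @param orfs A [GenomicRanges::GRanges] as returned by [findOrfs()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [readGff3()]
#' @export
writeGff3 <- function(orfs, path) {
  if (length(orfs) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  if (any(GenomicRanges::width(orfs) < 1L))
    stop("ORF with non-positive width")
  gr <- orfs
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$source <- "fhalminer"
  S4Vectors::mcols(gr)$phase <- 0L  # spans begin on a codon boundary
  keep <- intersect(c("type", "source", "phase", "orf_id", "frame",
                      "has_start", "has_stop", "protein"),
                    names(S4Vectors::mcols(gr)))
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, keep, drop = FALSE]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname writeGff3
#' @export
readGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  for (fl in c("has_start", "has_stop")) {
    if (!is.null(S4Vectors::mcols(gr)[[fl]]))
      S4Vectors::mcols(gr)[[fl]] <- as.logical(S4Vectors::mcols(gr)[[fl]])
  }
  gr
}

#' Write a phylogenetic tree as Newick
#'
#' Branch lengths are printed with six decimals and integer bootstrap
#' supports (if present as `node.label`) are kept as internal node labels.
#' Leaf labels containing whitespace are quoted.
#'
#' @param tree An [ape::phylo] object with unique, non-empty tip labels.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeNewickTree <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (any(!nzchar(tree$tip.label)) || anyDuplicated(tree$tip.label))
    stop("tree leaves must carry unique non-empty names")
  tr <- tree
  # ape mangles labels with Newick metacharacters; round-trip through
  # placeholder tokens and emit them quoted
  needs_quote <- grepl("[][();,:'[:space:]]", tr$tip.label)
  tokens <- sprintf("xQTIPx%dx", seq_len(sum(needs_quote)))
  orig <- tr$tip.label[needs_quote]
  tr$tip.label[needs_quote] <- tokens
  txt <- ape::write.tree(tr, digits = 6)
  for (i in seq_along(tokens))
    txt <- sub(tokens[i], sprintf("'%s'", orig[i]), txt, fixed = TRUE)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname writeNewickTree
#' @export
readNewickTree <- function(path) {
  ape::read.tree(path)
}
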