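# small in-code fixtures shared across tests

# a two-gene genome with one gene on each strand, built by hand so codon
# coordinates are known exactly:
#   ctg1: [spacer 6nt] gene_plus (9nt, +) [spacer 3nt] gene_minus (9nt, -) [spacer 3nt]
# gene_plus  coding: ATG GGA AAA        (Met Gly Lys)
# gene_minus coding: ATG CCA GAA        (Met Pro Glu) -> genomic revcomp TTCTGGCAT
tiny_genome <- function() {
  plus_cds <- "ATGGGAAAA"
  minus_cds <- "ATGCCAGAA"
  minus_genomic <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(minus_cds)))
  seqs <- paste0("ACACAC", plus_cds, "TTT", minus_genomic, "GGG")
  contigs <- Biostrings::DNAStringSet(seqs)
  names(contigs) <- "ctg1"
  genes <- data.frame(
    gene_id = c("gene_plus", "gene_minus"),
    contig = "ctg1",
    start = c(7L, 19L),
    end = c(15L, 27L),
    strand = c("+", "-"),
    stringsAsFactors = FALSE
  )
  structure(list(contigs = contigs, genes = genes, translation_table = "11"),
            class = "synthetic_genome")
}

# pileup over arbitrary site coordinates with given count matrices; built
# without construction-time validation so tests can feed malformed counts
# to the caller's own checks
make_pileup <- function(alt, total, contig = "ctg1", positions = NULL,
                        ref = "A", alt_base = "G") {
  alt <- as.matrix(alt)
  total <- as.matrix(total)
  n <- nrow(alt)
  coords <- data.frame(
    contig = rep_len(contig, n),
    position = positions %||% seq_len(n),
    ref_base = rep_len(ref, n),
    alt_base = rep_len(alt_base, n),
    stringsAsFactors = FALSE
  )
  structure(list(alt_counts = alt, total_counts = total,
                 site_coords = coords), class = "pileup")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
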