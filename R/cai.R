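## Codon Adaptation Index.
##
## Sharp-Li conventions: relative adaptiveness w of each codon is its count
## among the reference (highly expressed, typically ribosomal-protein) genes
## divided by the count of the most-used synonymous codon; unobserved codons
## are floored at 0.5 occurrences before division. CAI of a gene is the
## geometric mean of w over its codons, excluding Met, Trp and stop codons,
## whose families admit no choice.

GENETIC_CODE_DNA <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

EXCLUDED_AA <- c("M", "W", "*")

split_codons <- function(cds) {
  cds <- toupper(gsub("U", "T", cds))
  if (nchar(cds) %% 3 != 0) {
    abort("coding sequence length is not divisible by 3")
  }
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- GENETIC_CODE_DNA[codons]
  if (anyNA(aa)) {
    abort(paste0("invalid codon(s): ",
                 paste(unique(codons[is.na(aa)]), collapse = ", ")))
  }
  if (any(aa[-length(aa)] == "*")) {
    abort("internal stop codon in coding sequence")
  }
  codons
}

#' Build a codon usage table from reference genes
#'
#' Counts codons over a set of reference coding sequences (conventionally
#' the ribosomal-protein genes as proxies for high expression) and derives
#' the relative adaptiveness w of each degenerate codon. Codons unobserved
#' in the reference set are floored at 0.5 occurrences before division, so
#' w stays positive.
#'
#' @param reference_cds Character vector of nucleotide coding sequences
#'   (lengths divisible by 3), or a path to a FASTA file of them.
#' @return A list of class `codon_usage_table` with `counts` and `w`, both
#'   named by codon (the 59 degenerate codons for `w`).
#' @export
build_usage_table <- function(reference_cds) {
  if (length(reference_cds) == 1L && file.exists(reference_cds)) {
    reference_cds <- as.character(Biostrings::readDNAStringSet(reference_cds))
  }
  if (length(reference_cds) == 0L) abort("empty reference gene set")
  codons <- unlist(lapply(reference_cds, split_codons))
  counts <- table(factor(codons, levels = names(GENETIC_CODE_DNA)))
  counts <- stats::setNames(as.numeric(counts), names(counts))

  aa_of <- GENETIC_CODE_DNA
  degenerate <- names(aa_of)[!(aa_of %in% EXCLUDED_AA)]
  w <- stats::setNames(numeric(length(degenerate)), degenerate)
  for (a in unique(aa_of[degenerate])) {
    fam <- degenerate[aa_of[degenerate] == a]
    fam_counts <- pmax(counts[fam], 0.5)
    w[fam] <- fam_counts / max(fam_counts)
  }
  structure(list(counts = counts, w = w), class = "codon_usage_table")
}

#' Codon adaptation index of a gene
#'
#' Geometric mean of the relative adaptiveness values of the gene's codons,
#' excluding Met, Trp and stop codons. A value of 1 means the gene uses only
#' the preferred codon of every synonymous family.
#'
#' @param gene_cds Nucleotide coding sequence (length divisible by 3).
#' @param table A [build_usage_table()] result.
#' @return CAI in (0, 1\].
#' @export
cai <- function(gene_cds, table) {
  stopifnot(inherits(table, "codon_usage_table"))
  codons <- split_codons(gene_cds)
  keep <- codons[!(GENETIC_CODE_DNA[codons] %in% EXCLUDED_AA)]
  if (length(keep) == 0L) {
    abort("gene contains only Met/Trp/stop codons; CAI undefined")
  }
  geometric_mean(table$w[keep])
}
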