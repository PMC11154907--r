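#' Gene panels used throughout the analysis
#'
#' Two panels drive the pipeline: the 19 genes most frequently mutated in
#' HNSCC according to TCGA, over which tumour whole-exome variants are
#' analysed, and the 9-gene targeted panel used to sequence plasma cell-free
#' DNA (the plasma assay cannot see variants outside these 9 genes, so
#' ctDNA/tumour concordance denominators are restricted to them).
#'
#' Interval coordinates are nominal (approximate hg38 gene starts with a
#' fixed synthetic width); they exist so the simulator can place variants at
#' plausible unique positions without a reference genome, and carry no other
#' meaning.
#'
#' @return `hnscc_gene_panel()`: a tibble with columns `gene`, `chrom`,
#'   `start`, `end`. `plasma_panel_genes()`: a character vector of 9 gene
#'   symbols.
#' @export
hnscc_gene_panel <- function() {
  tibble::tribble(
    ~gene,     ~chrom,   ~start,
    "TP53",    "chr17",   7668000L,
    "FAT1",    "chr4",  186587000L,
    "CDKN2A",  "chr9",   21967000L,
    "PIK3CA",  "chr3",  179148000L,
    "NOTCH1",  "chr9",  136494000L,
    "KMT2D",   "chr12",  49018000L,
    "NSD1",    "chr5",  177133000L,
    "CASP8",   "chr2",  201233000L,
    "AJUBA",   "chr14",  22941000L,
    "NFE2L2",  "chr2",  177230000L,
    "TGFBR2",  "chr3",   30606000L,
    "HRAS",    "chr11",    532000L,
    "FBXW7",   "chr4",  152320000L,
    "PIK3R1",  "chr5",   68215000L,
    "PTEN",    "chr10",  87863000L,
    "RB1",     "chr13",  48303000L,
    "EPHA2",   "chr1",   16124000L,
    "ZNF750",  "chr17",  82826000L,
    "RASA1",   "chr5",   87267000L
  ) |>
    dplyr::mutate(end = .data$start + 99999L)
}

#' @rdname hnscc_gene_panel
#' @export
plasma_panel_genes <- function() {
  c("TP53", "NOTCH1", "PIK3CA", "KMT2D", "CDKN2A",
    "CASP8", "NSD1", "FAT1", "FBXW7")
}
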