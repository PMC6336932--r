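#' The packaged N. samayunkur annotation (GenBank MF991901)
#'
#' Loads the packaged transcription of the published feature table of
#' the marigold thrips (Neohydatothrips samayunkur) mitogenome: 39
#' features (13 PCGs, 22 tRNAs, 2 rRNAs, 2 control regions) on a
#' 15,295 bp circular molecule.  Only the annotation is packaged; the
#' nucleotide sequence itself is not required by any annotation-level
#' analysis and is not distributed.
#'
#' @return a \code{\link{mito_annotation}}.
#' @examples
#' ann <- read_nsamayunkur()
#' strand_counts(ann)  # 30 majority / 7 minority
#' @export
read_nsamayunkur <- function() {
  path <- system.file("extdata", "nsamayunkur_mf991901_features.tsv",
                      package = "mitocompr", mustWork = TRUE)
  parse_feature_table(path, genome_length = 15295,
                      genome_id = "N_samayunkur_MF991901")
}
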