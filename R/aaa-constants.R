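# Alphabet constants shared across modules (file sorts first so the
# constants exist when later files are sourced during development loads).

DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")
STOP_CODONS <- c("TAA", "TAG", "TGA")

SENSE_CODONS <- local({
  all_codons <- as.vector(outer(
    as.vector(outer(DNA_BASES, DNA_BASES, paste0)), DNA_BASES, paste0
  ))
  setdiff(all_codons, STOP_CODONS)
})
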