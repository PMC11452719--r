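## Shared constants (this file loads before every module file).

DNA_BASES <- c("A", "C", "G", "T")

BIOTYPE_PRIORITY <- c("miRNA", "rRNA", "snoRNA", "snRNA", "tRNA", "piRNA")
CATCHALL_BIOTYPES <- c("protein_coding", "lncRNA", "repeat_element", "pseudogene")

TRNA_ISOTYPES <- data.frame(
  aa = c("Ala", "Arg", "Asn", "Gly", "Glu", "Lys", "Met", "Ser", "Val", "Leu"),
  anticodon = c("AGC", "ACG", "GTT", "GCC", "CTC", "CTT", "CAT", "GCT", "CAC", "CAA"),
  stringsAsFactors = FALSE)
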