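## standard genetic code on the DNA alphabet (loaded before everything
## that builds codon tables at load time)
GENETIC_CODE_DNA <- {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), chartr("U", "T", names(gc)))
}
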