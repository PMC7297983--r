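# Reference hairpin cloning oligos (pSIREN-style cassettes) used as
# fixtures: two Zdhhc2 knockdown hairpins, a Bcl6 hairpin, and a scramble
# control. Stems are 21 or 22 nt.
reference_oligos <- c(
  `Bcl6-1` = "GATCCGCTGTCAAAGAGAAGGCTTTATTCAAGAGATAAAGCCTTCTCTTTGACAGCTTTTTTGATATCG",
  `Zdhhc2-2` = "GATCCGTGACAGATGCCAACTTATAATTCAAGAGATTATAAGTTGGCATCTGTCACTTTTTTGATATCG",
  `Zdhhc2-4` = "GATCCGCTACTCCTGCGGGACTAAATTTTCAAGAGAAATTTAGTCCCGCAGGAGTAGCTTTTTTGATATCG",
  `scramble-1` = "GATCCGTGCGTTGCTAGTACCAACCTATTCAAGAGATAGGTTGGTACTAGCAACGCACTTTTTTGATATCG"
)

reference_senses <- c(
  `Bcl6-1` = "GCTGTCAAAGAGAAGGCTTTA",
  `Zdhhc2-2` = "GTGACAGATGCCAACTTATAA",
  `Zdhhc2-4` = "GCTACTCCTGCGGGACTAAATT",
  `scramble-1` = "GTGCGTTGCTAGTACCAACCTA"
)

# Manifest over the four reference constructs.
reference_manifest <- function() {
  validate_manifest(data.frame(
    construct_id = names(reference_oligos),
    gene = c("Bcl6", "Zdhhc2", "Zdhhc2", "scramble"),
    sense = unname(reference_senses),
    oligo = unname(reference_oligos),
    stringsAsFactors = FALSE
  ))
}
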