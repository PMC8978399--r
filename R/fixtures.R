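#' Published terminal inverted repeats of the Jozin CACTA element family
#'
#' The 28-nt CACTA-anchored TIRs reported for complete Jozin elements in four
#' Chenopodium album agg. species, plus the single TIR/subTIR-complete CACTA
#' element found in the C. quinoa assembly (scaffold 3500).
#'
#' @format Named character vector of 28-nt DNA strings.
#' @export
jozin_tirs <- c(
  pamiricum        = "CACTAGTAGAAAAAACGTCATTTGTAAC",
  sosnowskyi       = "CACTAGTGGAAAAAAGTTCATTTGCAAC",
  iljinii          = "CACTAGTAGAAAAATGTACATTTGCGTC",
  vulvaria         = "CACTAGTACAAAAACGTACATTTACTTC",
  quinoa_scaffold3500 = "CACTAGTAGAAAAATAGAAATAGGCAAC"
)

#' Published subTIR unit motifs of the Jozin element family
#'
#' The 12-bp subterminal repeat units, repeated in direct orientation at the
#' 5' end and inverted orientation at the 3' end of each element. C. vulvaria
#' carries the same motif as C. iljinii.
#'
#' @format Named character vector of 12-bp DNA strings.
#' @export
jozin_subtir_motifs <- c(
  pamiricum  = "TATTTGTAACTA",
  sosnowskyi = "TATTTGTAACGG",
  iljinii    = "TATTTGCGTCAC",
  vulvaria   = "TATTTGCGTCAC"
)

#' Consensus monomer of the satellite DNA family captured by CACTA elements
#'
#' The 171-bp consensus monomer of the tandem-repeat (satDNA) family found as
#' a 5550-bp array (32.5 monomers) near the 3' end of a CACTA element in the
#' C. quinoa assembly (scaffold 3389). Two positions of the published
#' consensus were not recoverable from the printed record and are filled with
#' `A`; this does not affect the monomer length or periodicity that all
#' array arithmetic rests on.
#'
#' @format A 171-bp DNA string.
#' @export
chenopodium_sat_monomer <- paste0(
  "GCCATTTTGGTTGAAATTGCGTCCCAAAACCTCTTACTTGCTCTTTTCTTGTAATC", "AA",
  "TCAAGCATTAGTCACCTATAACTAAGTGATAATGACATGTTTTAACTAGTTATGAGCAATAGACATGAATTGTAGAAAATAGGCATCCTAGTAGCCAAAATGGCCTTACTTGA"
)

#' Structural summary of the described Jozin element families
#'
#' One row per element family with the published total length, TIR, subTIR
#' motif, per-end subTIR copy counts and conserved-domain-architecture type.
#' These rows parameterize [jozin_element_spec()], whose output reconstructs
#' each family at its published length.
#'
#' @format data.frame with columns `family`, `length`, `tir`, `motif`, `n5`,
#'   `n3`, `cda`.
#' @export
jozin_families <- data.frame(
  family = c("pamiricum", "sosnowskyi", "iljinii", "vulvaria",
             "quinoa_scaffold3500"),
  length = c(8380L, 8258L, 9210L, 10109L, 9486L),
  tir    = unname(jozin_tirs[c("pamiricum", "sosnowskyi", "iljinii",
                               "vulvaria", "quinoa_scaffold3500")]),
  motif  = c(unname(jozin_subtir_motifs[c("pamiricum", "sosnowskyi",
                                          "iljinii", "vulvaria")]),
             "TATTTGCGTCAC"),
  n5     = c(9L, 11L, 10L, 10L, 8L),
  n3     = c(10L, 8L, 13L, 11L, 8L),
  cda    = c("type2", "type1", "type4", "type4", "type1"),
  stringsAsFactors = FALSE
)
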