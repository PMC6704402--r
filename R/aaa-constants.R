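# shared constants; this file loads before all others

# the diel sampling design: hours after lights-on / after dark
TIMEPOINTS <- c("1ALO", "8ALO", "14ALO", "1AD", "5AD", "7AD")

LINEAGES <- c("Chlamydiae", "Glaucophyta", "Rhodophyta", "Viridiplantae",
              "other_bacteria", "other_eukaryote")

ARCHAEPLASTIDA <- c("Glaucophyta", "Rhodophyta", "Viridiplantae")

stop_codons <- c("TAA", "TAG", "TGA")

CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                paste0), c("T", "C", "A", "G"), paste0))
NONSTOP_CODONS <- setdiff(CODONS, stop_codons)
# codons that are stop-free on both strands in the aligned frame:
# neither the codon nor its reverse complement is a stop
DUAL_SAFE_CODONS <- setdiff(NONSTOP_CODONS, c("TTA", "CTA", "TCA"))
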