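>fwd qPCR primer, anneals to the extended 3' terminus (reverse complement of the new 3' end)
AAGCAGTGGGAGACCGAAGG
>rev qPCR primer, template-consistent 5'-end footprint
AAGCAGTGGGAGACCGAGTTATCCA
>rev_printed published reverse primer variant; disagrees with the template footprint at two adjacent positions
AAGCAGTGGGAGACGTAGTTATCCA
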